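## Binding-site stability and cation-pi geometry.
##
## Site stability: per frame, the reference Calpha set (by default the
## pore-lining M2 helix) is superposed onto its reference-frame pose by
## least-squares Kabsch fitting; the resulting rigid transform is applied
## to the site lipid's non-hydrogen headgroup atoms and their RMSD against
## the reference pose is reported, with no re-fitting on the lipid itself.
## Cation-pi geometry: minimum-image distance from the headgroup cation
## particle (choline N for PC/TAP, phosphorus for PG) to the centroid of
## the aromatic-ring heavy atoms.

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation (det = +1) and translation minimizing the RMSD
#' between paired point sets.
#'
#' @param mobile,reference n x 3 matrices of paired points (n >= 3,
#'   non-collinear).
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd` (the
#'   fit RMSD after superposition), and `apply(x)` transforming further
#'   points.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3)
    stop("mobile and reference must be paired n x 3 point sets")
  if (nrow(mobile) < 3) stop("need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (svd(A)$d[2] < 1e-8 * max(1, svd(A)$d[1]))
    stop("degenerate (collinear) point set; superposition is ill-defined")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cr - as.numeric(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(R = R, t = tvec, rmsd = rmsd,
       apply = function(x) sweep(as.matrix(x) %*% t(R), 2, tvec, "+"))
}

#' Definition of one of the five lipid-binding sites
#'
#' @param site site index 1-5 (maps to protein chains in symmetry order:
#'   the complementary chain bearing the aromatic residue).
#' @param chain chain id carrying the aromatic residue; default the
#'   site-th chain of `map`.
#' @param map a [symmetry_map()].
#' @param align a [selection_spec()] of reference Calpha atoms; default
#'   all-chain M2 helix Calphas (residues `m2_resids`).
#' @param lipid_id lipid molecule id assigned to the site (fixed at t = 0,
#'   never re-assigned; pass `NULL` with `nearest = TRUE` to pick the
#'   nearest headgroup in the reference frame, ties broken by lowest id).
#' @param aromatic_resid aromatic residue number (default 206).
#' @param ring_names ring heavy-atom names forming the aromatic centroid.
#' @param cation_names candidate cation particle names: choline nitrogen
#'   beads/atoms for PC/TAP, phosphorus for PG.
#' @param m2_resids residue numbers of the alignment helix.
#' @export
site_definition <- function(site, map, chain = NULL, align = NULL,
                            lipid_id = NULL,
                            aromatic_resid = 206,
                            ring_names = c("CG", "CD1", "NE1", "CE2",
                                           "CD2", "CE3", "CZ2", "CZ3",
                                           "CH2"),
                            cation_names = c("NC3", "PO4", "N", "P"),
                            m2_resids = 222:236) {
  if (is.null(chain)) chain <- map$chains[site]
  if (is.null(align))
    align <- selection_spec("M2_helix_CA", chain = map$chains,
                            resid = m2_resids, atom_names = "CA")
  structure(list(site = site, chain = chain, align = align,
                 lipid_id = lipid_id, aromatic_resid = aromatic_resid,
                 ring_names = ring_names, cation_names = cation_names),
            class = "site_definition")
}

site_lipid_rows <- function(top, site, reference = NULL) {
  p <- top$particles
  lid <- site$lipid_id
  if (is.null(lid)) {
    ## nearest-lipid mode: closest headgroup cation to the ring centroid in
    ## the reference frame, ties broken by lowest lipid id
    rows_ring <- which(p$chain == site$chain &
                       p$resid == site$aromatic_resid &
                       p$name %in% site$ring_names)
    if (!length(rows_ring)) stop("aromatic ring not found for site")
    xyz <- if (is.null(reference)) top$xyz else reference$xyz
    cen <- colMeans(xyz[rows_ring, , drop = FALSE])
    cat_rows <- which(!is.na(p$lipid_id) & p$name %in% site$cation_names)
    d <- sqrt(colSums((t(xyz[cat_rows, , drop = FALSE]) - cen)^2))
    ord <- order(d, p$lipid_id[cat_rows])
    lid <- p$lipid_id[cat_rows[ord[1]]]
  }
  which(!is.na(p$lipid_id) & p$lipid_id == lid)
}

#' Per-frame lipid headgroup RMSD after reference-helix superposition
#'
#' @param traj a trajectory.
#' @param top matching topology.
#' @param site a [site_definition()].
#' @param reference reference frame (default the first analyzed frame's
#'   pose).
#' @param window an [analysis_window()] or `NULL`.
#' @return numeric vector of per-frame RMSD (Angstrom) with attribute
#'   `times`.
#' @export
site_rmsd_series <- function(traj, top, site, reference = NULL,
                             window = NULL) {
  idx <- resolve_window(traj, window)
  if (!length(idx)) stop("analysis window resolves to zero frames")
  align_idx <- resolve_selection(top, site$align)
  if (length(align_idx) < 3) stop("alignment selection has < 3 particles")
  lip_rows <- site_lipid_rows(top, site, reference)
  p <- top$particles
  lip_rows <- lip_rows[!p$is_hydrogen[lip_rows]]
  if (!length(lip_rows)) stop("site lipid has no non-hydrogen atoms")
  if (is.null(reference)) reference <- get_frame(traj, idx[1])
  ref_align <- reference$xyz[align_idx, , drop = FALSE]
  ref_pose <- reference$xyz[lip_rows, , drop = FALSE]
  out <- vapply(idx, function(i) {
    f <- get_frame(traj, i)
    fit <- kabsch_superpose(f$xyz[align_idx, , drop = FALSE], ref_align)
    pose <- fit$apply(f$xyz[lip_rows, , drop = FALSE])
    sqrt(mean(rowSums((pose - ref_pose)^2)))
  }, 0)
  attr(out, "times") <- vapply(idx, function(i) get_frame(traj, i)$time, 0)
  out
}

#' Per-frame cation-to-aromatic-centroid distance
#'
#' Minimum-image distance from the site lipid's cation particle (choline N
#' for PC/TAP; phosphorus for PG, which lacks a choline group) to the
#' centroid of the aromatic-ring heavy atoms.
#'
#' @inheritParams site_rmsd_series
#' @return numeric per-frame distances (Angstrom) with attributes `times`,
#'   `frac_le_4.5` and `frac_le_6` (fractions of frames within the ideal
#'   cation-pi distance of 4.5 Angstrom, and within 6 Angstrom).
#' @export
cation_pi_series <- function(traj, top, site, reference = NULL,
                             window = NULL) {
  idx <- resolve_window(traj, window)
  if (!length(idx)) stop("analysis window resolves to zero frames")
  p <- top$particles
  ring_rows <- which(p$chain == site$chain &
                     p$resid == site$aromatic_resid &
                     p$name %in% site$ring_names & !p$is_hydrogen)
  if (length(ring_rows) < 5)
    stop("aromatic ring resolves to fewer than 5 particles")
  lip_rows <- site_lipid_rows(top, site, reference)
  cat_row <- lip_rows[p$name[lip_rows] %in% site$cation_names]
  if (length(cat_row) != 1)
    stop("expected exactly one cation particle for the site lipid, got ",
         length(cat_row))
  out <- vapply(idx, function(i) {
    f <- get_frame(traj, i)
    cen <- colMeans(f$xyz[ring_rows, , drop = FALSE])
    min_image_distance(f$xyz[cat_row, ], cen, f$box)
  }, 0)
  attr(out, "times") <- vapply(idx, function(i) get_frame(traj, i)$time, 0)
  attr(out, "frac_le_4.5") <- mean(out <= 4.5)
  attr(out, "frac_le_6") <- mean(out <= 6)
  out
}

#' Pool per-site series and summarize the distribution
#'
#' Samples from all sites and replicates are pooled with equal weight (a
#' distribution, not an average of scalars); the summary is a box-plot
#' convention: median, quartiles (median-unbiased, R type 8), whiskers at
#' the most extreme points within 1.5 IQR of the quartiles.
#'
#' @param series list (or single vector) of per-frame value series.
#' @param breaks histogram breaks (passed to [hist()]) for the returned
#'   probability density.
#' @return a `distribution_summary`: `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n`, per-series medians, and a histogram
#'   density (`$density`).
#' @export
pool_and_summarize <- function(series, breaks = "FD") {
  if (is.numeric(series)) series <- list(series)
  if (!length(series)) stop("need at least one series")
  pooled <- unlist(lapply(series, as.numeric), use.names = FALSE)
  q <- unname(quantile(pooled, c(0.25, 0.5, 0.75), type = 8))
  iqr <- q[3] - q[1]
  lo_cand <- pooled[pooled >= q[1] - 1.5 * iqr]
  hi_cand <- pooled[pooled <= q[3] + 1.5 * iqr]
  h <- hist(pooled, breaks = breaks, plot = FALSE)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(lo_cand), whisker_hi = max(hi_cand),
                 n = length(pooled),
                 per_series_median = vapply(series, median, 0),
                 density = data.frame(mid = h$mids, density = h$density)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "Distribution (n = %d): median %.3f [Q1 %.3f, Q3 %.3f], whiskers %.3f-%.3f\n",
    x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi))
  invisible(x)
}
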