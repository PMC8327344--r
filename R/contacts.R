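## Per-residue lipid contact frequency profiles.
##
## A residue is "in contact" in a frame if any of its particles (any bead in
## coarse-grained mode; any non-hydrogen atom in atomistic mode) lies within
## the threshold distance (minimum image) of any headgroup particle of any
## lipid of the requested class.  The profile is the fraction of analyzed
## frames in contact -- the frame-occupancy definition consistent with a
## ">33%" hot-residue rule.  Mean per-frame counts of distinct contacting
## lipids are reported as a secondary column.

#' Parameters for contact profiling
#'
#' @param mode `"cg"` (any residue bead, 5.5 Angstrom default threshold) or
#'   `"atomistic"` (non-hydrogen atoms, 3.2 Angstrom default).
#' @param threshold contact distance (Angstrom); the comparison is
#'   inclusive (`<=`).
#' @param lipid_class which lipid class to profile against.
#' @param headgroup a [selection_spec()] for the headgroup particles;
#'   default [headgroup_selection()] for the class and mode.
#' @param window an [analysis_window()]; default discards the first 25% of
#'   frames in cg mode and 50% in atomistic mode (equilibration conventions
#'   for long coarse-grained vs shorter atomistic runs).
#' @export
contact_params <- function(mode = c("cg", "atomistic"), threshold = NULL,
                           lipid_class = "lipid_PC", headgroup = NULL,
                           window = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "cg") 5.5 else 3.2
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(headgroup)) headgroup <- headgroup_selection(lipid_class, mode)
  if (is.null(window))
    window <- analysis_window(if (mode == "cg") 0.25 else 0.5)
  structure(list(mode = mode, threshold = threshold,
                 lipid_class = lipid_class, headgroup = headgroup,
                 window = window),
            class = "contact_params")
}

#' Compute a per-residue lipid contact profile
#'
#' @param traj a trajectory, or a list of replicate trajectories (each is
#'   windowed, then frames are pooled with equal weight).
#' @param top the matching `topology`.
#' @param params a [contact_params()].
#' @return a `contact_profile`: data.frame with one row per protein
#'   (chain, residue) and columns `chain`, `resid`, `resname`, `frequency`
#'   (in `[0, 1]`), `mean_contacts`; attributes record the lipid class,
#'   threshold, mode and `frames_analyzed`.
#' @export
compute_contact_profile <- function(traj, top, params = contact_params()) {
  stopifnot(inherits(params, "contact_params"))
  trajs <- if (inherits(traj, "trajectory")) list(traj) else traj
  head_idx <- resolve_selection(top, params$headgroup)
  if (!length(head_idx))
    stop("headgroup selection '", params$headgroup$name,
         "' resolves to no particles")
  p <- top$particles
  prot_idx <- which(p$mol_class == "protein" &
                    (params$mode == "cg" | !p$is_hydrogen))
  if (!length(prot_idx)) stop("topology contains no protein particles")

  ## residue bookkeeping, canonical (chain, resid) order
  key <- paste(p$chain[prot_idx], p$resid[prot_idx], sep = "\r")
  ord_keys <- unique(key[order(p$chain[prot_idx], p$resid[prot_idx])])
  res_of_particle <- match(key, ord_keys)
  n_res <- length(ord_keys)
  lip_of_head <- p$lipid_id[head_idx]

  hits <- numeric(n_res)
  counts <- numeric(n_res)
  frames_analyzed <- 0L
  thr <- params$threshold
  for (tr in trajs) {
    idx <- resolve_window(tr, params$window)
    for (i in idx) {
      f <- get_frame(tr, i)
      D <- min_image_dist_matrix(f$xyz[prot_idx, , drop = FALSE],
                                 f$xyz[head_idx, , drop = FALSE], f$box)
      contact_pp <- D <= thr
      in_contact <- rowSums(contact_pp) > 0
      res_contact <- tabulate(res_of_particle[in_contact], n_res) > 0
      hits <- hits + res_contact
      ## distinct lipids contacting each residue this frame
      touching <- which(contact_pp, arr.ind = TRUE)
      if (nrow(touching)) {
        rr <- res_of_particle[touching[, 1]]
        ll <- lip_of_head[touching[, 2]]
        counts <- counts + tabulate(
          unique_pairs_first(rr, ll), n_res)
      }
      frames_analyzed <- frames_analyzed + 1L
    }
  }
  if (frames_analyzed == 0L)
    stop("analysis window resolves to zero frames")

  first <- match(ord_keys, key)
  out <- data.frame(
    chain = p$chain[prot_idx][first],
    resid = p$resid[prot_idx][first],
    resname = p$resname[prot_idx][first],
    frequency = hits / frames_analyzed,
    mean_contacts = counts / frames_analyzed,
    stringsAsFactors = FALSE)
  structure(out, class = c("contact_profile", "data.frame"),
            lipid_class = params$lipid_class, threshold = thr,
            mode = params$mode, frames_analyzed = frames_analyzed)
}

## residue index of each distinct (residue, lipid) pair
unique_pairs_first <- function(res, lip) {
  res[!duplicated(paste(res, lip))]
}

#' Average a contact profile across the five symmetry-related subunits
#'
#' @param profile a `contact_profile`.
#' @param map a [symmetry_map()]; all five chains must be present in the
#'   profile.
#' @return data.frame with `resid` and `frequency` (arithmetic mean of the
#'   five per-chain frequencies), class `contact_profile_avg`.
#' @export
average_over_subunits <- function(profile, map) {
  stopifnot(inherits(map, "symmetry_map"))
  miss <- setdiff(map$chains, unique(profile$chain))
  if (length(miss))
    stop("profile lacks chain(s): ", paste(miss, collapse = ", "))
  sub <- profile[profile$chain %in% map$chains, ]
  resids <- sort(unique(sub$resid))
  freq <- vapply(resids, function(r) {
    v <- sub$frequency[sub$resid == r]
    if (length(v) != 5)
      stop("residue ", r, " is not present in all five chains")
    mean(v)
  }, 0)
  structure(data.frame(resid = resids, frequency = freq),
            class = c("contact_profile_avg", "data.frame"),
            lipid_class = attr(profile, "lipid_class"),
            threshold = attr(profile, "threshold"))
}

#' Classify hot (high-contact) residues
#'
#' Residues with subunit-averaged contact frequency strictly above the
#' cutoff, sorted by residue number.
#'
#' @param profile a `contact_profile_avg` (or any data.frame with `resid`
#'   and `frequency`).
#' @param cutoff frequency cutoff; default 0.33 (the ">33%" convention).
#' @return integer vector of residue numbers.
#' @export
classify_hot_residues <- function(profile, cutoff = 0.33) {
  sort(profile$resid[profile$frequency > cutoff])
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Contact profile:", nrow(x), "residues vs", attr(x, "lipid_class"),
      sprintf("(mode %s, threshold %.2f A, %d frames)\n",
              attr(x, "mode"), attr(x, "threshold"),
              attr(x, "frames_analyzed")))
  top <- x[order(-x$frequency), ][seq_len(min(5, nrow(x))), ]
  cat("  highest:", paste(sprintf("%s%d:%s=%.2f", top$resname, top$resid,
                                  top$chain, top$frequency),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Write a contact profile (plus subunit average and hot flags) to CSV
#' @param profile a `contact_profile`.
#' @param map a [symmetry_map()] used for the averaged column, or `NULL`.
#' @param path output CSV.
#' @param cutoff hot-residue cutoff.
#' @export
write_contacts_csv <- function(profile, map, path, cutoff = 0.33) {
  out <- as.data.frame(profile)
  out$lipid_class <- attr(profile, "lipid_class")
  if (!is.null(map)) {
    avg <- average_over_subunits(profile, map)
    out$averaged_frequency <- avg$frequency[match(out$resid, avg$resid)]
    hot <- classify_hot_residues(avg, cutoff)
    out$hot <- as.integer(out$resid %in% hot)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
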