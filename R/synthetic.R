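## Synthetic membrane generator.
##
## Emulates the statistical structure the trajectory analyses assume: lipids
## diffusing laterally in two leaflets around a static C5-symmetric protein
## placeholder, with five outer-leaflet binding wells whose depth depends on
## the headgroup charge class (cationic/zwitterionic attracted at the
## aromatic site, anionic at the inner basic patch).  Dynamics are 2D
## overdamped Langevin per leaflet (fixed z); distances to ring centroids
## remain fully 3D.  This is a ground-truth generator, not a physical
## membrane simulator: no electrostatics, no leaflet coupling, no protein
## flexibility.

#' Specification of a planar two-leaflet synthetic membrane
#'
#' Defaults mirror the reference conditions the analyses were built for:
#' a laterally square 300 x 300 Angstrom membrane with an 80/20
#' zwitterionic/anionic (PC/PG) lipid mix and no cationic lipid.
#'
#' @param box_xy lateral box edges (Angstrom).
#' @param n_lipids_per_leaflet lipid count per leaflet.
#' @param class_fractions named fractions for `lipid_PC`, `lipid_PG`,
#'   `lipid_TAP`; must sum to 1.
#' @param leaflet_z half-separation of the two headgroup planes (Angstrom).
#' @param box_z box height (Angstrom).
#' @param with_tails also emit two ghost tail particles per lipid (rigidly
#'   following the headgroup) so atomistic-style selections have non-head
#'   atoms to exclude.
#' @export
membrane_spec <- function(box_xy = c(300, 300), n_lipids_per_leaflet = 200,
                          class_fractions = c(lipid_PC = 0.8,
                                              lipid_PG = 0.2,
                                              lipid_TAP = 0),
                          leaflet_z = 17, box_z = 100, with_tails = FALSE) {
  fr <- class_fractions[LIPID_CLASSES]
  fr[is.na(fr)] <- 0
  names(fr) <- LIPID_CLASSES
  if (abs(sum(fr) - 1) > 1e-9) stop("class_fractions must sum to 1")
  if (n_lipids_per_leaflet < 0 ||
      n_lipids_per_leaflet != round(n_lipids_per_leaflet))
    stop("n_lipids_per_leaflet must be a non-negative integer")
  structure(list(box_xy = box_xy, n_lipids_per_leaflet = n_lipids_per_leaflet,
                 class_fractions = fr, leaflet_z = leaflet_z, box_z = box_z,
                 with_tails = isTRUE(with_tails)),
            class = "membrane_spec")
}

#' C5-symmetric protein placeholder
#'
#' Five chains (A-E) generated by exact 72-degree rotations of chain A about
#' the box axis.  Each chain carries marker residues mimicking the residues
#' the analyses interrogate: an M1 aromatic residue with a 6-particle planar
#' ring (the cation-pi site), an M3 polar residue near the site, an
#' inner-leaflet basic cluster, and Calpha traces for the M1-M4 helices (M2
#' is the superposition reference).
#'
#' @param radius protein footprint radius (Angstrom); lipids are excluded
#'   from a soft-walled disc slightly larger than this.
#' @param leaflet_z headgroup plane half-separation; must match the
#'   [membrane_spec()] used with it.
#' @param aromatic_resid,polar_resid,basic_resids residue numbers of the
#'   marker residues (author numbering).
#' @param m1_resids,m2_resids,m3_resids,m4_resids helix Calpha residue
#'   ranges.
#' @export
protein_placeholder <- function(radius = 30, leaflet_z = 17,
                                aromatic_resid = 206, polar_resid = 264,
                                basic_resids = c(286, 299, 301),
                                m1_resids = 200:210, m2_resids = 222:236,
                                m3_resids = 258:270, m4_resids = 312:320) {
  ring_names <- c("CG", "CD1", "NE1", "CE2", "CD2", "CE3")
  structure(list(radius = radius, leaflet_z = leaflet_z,
                 aromatic_resid = aromatic_resid, polar_resid = polar_resid,
                 basic_resids = basic_resids, m1_resids = m1_resids,
                 m2_resids = m2_resids, m3_resids = m3_resids,
                 m4_resids = m4_resids, ring_names = ring_names,
                 site_radius = radius + 4,       # well centers (x,y radius)
                 ring_radius = radius + 1.5,     # ring centroid radius
                 ring_z_offset = 3.5,            # ring centroid above leaflet
                 wall_radius = radius + 2,
                 wall_k = 1),
            class = "protein_placeholder")
}

## Chain-A particle table + coordinates, later rotated for chains B-E.
## Returns data.frame(name, resid, resname, x, y, z) relative to the axis.
placeholder_chain_atoms <- function(pp) {
  zl <- pp$leaflet_z
  helix <- function(resids, r, z_hi, z_lo, phi0, twist = 0.25) {
    n <- length(resids)
    th <- phi0 + (seq_len(n) - 1) * twist
    data.frame(name = "CA", resid = resids, resname = "ALA",
               x = r * cos(th), y = r * sin(th),
               z = seq(z_hi, z_lo, length.out = n))
  }
  m1 <- helix(pp$m1_resids, pp$radius - 1, zl + 7, zl - 13, 0, 0.08)
  m1$resname[m1$resid == pp$aromatic_resid] <- "TRP"
  m2 <- helix(pp$m2_resids, 8, zl + 3, -zl + 9, 0.5, 0.45)
  m3 <- helix(pp$m3_resids, pp$radius - 4, zl + 3, -zl + 7, 0.42, 0.12)
  m3$resname[m3$resid == pp$polar_resid] <- "GLN"
  m4 <- helix(pp$m4_resids, pp$radius + 2, -zl + 5, zl + 5, -0.35, 0.12)
  ## aromatic ring: hexagon of radius 1.4 A in the plane spanned by the
  ## tangential direction and z, centered outside M1 facing the membrane
  cen <- c(pp$ring_radius, 0, zl + pp$ring_z_offset)
  ang <- (0:5) * pi / 3
  tangent <- c(0, 1, 0)
  ring <- data.frame(name = pp$ring_names, resid = pp$aromatic_resid,
                     resname = "TRP",
                     x = cen[1] + 0 * ang,
                     y = cen[2] + 1.4 * cos(ang) * tangent[2],
                     z = cen[3] + 1.4 * sin(ang))
  ## polar side chain bead near the site mouth
  polar <- data.frame(name = "SC1", resid = pp$polar_resid, resname = "GLN",
                      x = (pp$radius + 0.5) * cos(0.14),
                      y = (pp$radius + 0.5) * sin(0.14),
                      z = zl + 1)
  ## inner-leaflet basic cluster (M3-M4 loop)
  nb <- length(pp$basic_resids)
  bth <- 0.55 + (seq_len(nb) - 1) * 0.14
  basic <- data.frame(name = "SC1", resid = pp$basic_resids, resname = "ARG",
                      x = pp$radius * cos(bth), y = pp$radius * sin(bth),
                      z = -zl + c(2, 1, 2)[seq_len(nb)])
  rbind(m1, m2, m3, m4, ring, polar, basic)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = FALSE)
}

#' Assemble a synthetic membrane system
#'
#' Places lipids on a jittered square lattice outside the protein footprint,
#' assigns leaflets and charge classes by stratified (largest-remainder)
#' sampling, and builds the protein placeholder by exact five-fold rotation.
#' Deterministic for a given `params$seed`.
#'
#' @param spec a [membrane_spec()].
#' @param protein a [protein_placeholder()], or `NULL` for a protein-free
#'   (ideal-gas) membrane.
#' @param params a [sim_params()]; `seed` and `site_lipid_class` are used
#'   at build time.
#' @return a `membrane_system`: `$topology`, `$frame0`, and generator
#'   metadata (`$site_centers_outer`, `$site_centers_inner`, `$leaflet`,
#'   `$lipid_class`, `$head_rows`, `$site_lipid_ids`, ...).
#' @export
build_membrane_system <- function(spec, protein = protein_placeholder(),
                                  params = sim_params()) {
  stopifnot(inherits(spec, "membrane_spec"))
  set.seed(params$seed)
  box <- c(spec$box_xy, spec$box_z)
  center <- c(box[1] / 2, box[2] / 2, box[3] / 2)

  ## --- protein particles -------------------------------------------------
  prot_df <- NULL
  site_outer <- site_inner <- NULL
  if (!is.null(protein)) {
    if (pi * protein$wall_radius^2 >= spec$box_xy[1] * spec$box_xy[2])
      stop("protein excluded area exceeds the box area")
    chainA <- placeholder_chain_atoms(protein)
    chains <- LETTERS[1:5]
    prot_df <- do.call(rbind, lapply(0:4, function(k) {
      xyz <- as.matrix(chainA[, c("x", "y", "z")]) %*% t(rot_z(2 * pi * k / 5))
      data.frame(name = chainA$name, resid = chainA$resid,
                 resname = chainA$resname, chain = chains[k + 1],
                 x = xyz[, 1] + center[1], y = xyz[, 2] + center[2],
                 z = xyz[, 3] + center[3])
    }))
    ang5 <- 2 * pi * (0:4) / 5
    site_outer <- cbind(center[1] + protein$site_radius * cos(ang5),
                        center[2] + protein$site_radius * sin(ang5))
    inner_ang <- ang5 + 0.69   # over the basic cluster
    site_inner <- cbind(center[1] + (protein$radius + 3) * cos(inner_ang),
                        center[2] + (protein$radius + 3) * sin(inner_ang))
  }

  ## --- lipid placement ---------------------------------------------------
  n <- spec$n_lipids_per_leaflet
  counts <- stratified_counts(n, spec$class_fractions)
  a <- max(6, sqrt(spec$box_xy[1] * spec$box_xy[2] / max(1, 2.2 * n)))
  gx <- seq(a / 2, spec$box_xy[1] - a / 2, by = a)
  gy <- seq(a / 2, spec$box_xy[2] - a / 2, by = a)
  lattice <- as.matrix(expand.grid(x = gx, y = gy))
  if (!is.null(protein)) {
    r2 <- (lattice[, 1] - center[1])^2 + (lattice[, 2] - center[2])^2
    lattice <- lattice[r2 > (protein$wall_radius + 2)^2, , drop = FALSE]
  }
  if (nrow(lattice) < n)
    stop("infeasible lipid packing: requested ", n, " per leaflet, ",
         "at most ", nrow(lattice), " lattice sites available")

  place_leaflet <- function(zplane, side) {
    if (n == 0) return(NULL)
    cls <- sample(rep(LIPID_CLASSES, counts))
    if (identical(init, "equilibrium") && !is.null(protein)) {
      centers <- if (side == "outer") site_outer else site_inner
      wall <- list(center = center[1:2], R0 = protein$wall_radius,
                   k = protein$wall_k)
      xy <- matrix(NA_real_, n, 2)
      for (cl in unique(cls)) {
        rows <- which(cls == cl)
        xy[rows, ] <- sample_boltzmann_xy(
          length(rows), params$well_depths[[side]][cl], centers,
          params$well_width, params$kT, wall, box)
      }
      return(data.frame(x = xy[, 1], y = xy[, 2], z = zplane, class = cls))
    }
    pick <- lattice[sample(nrow(lattice), n), , drop = FALSE]
    jit <- matrix(runif(2 * n, -0.2 * a, 0.2 * a), ncol = 2)
    data.frame(x = pick[, 1] + jit[, 1], y = pick[, 2] + jit[, 2],
               z = zplane, class = cls)
  }
  init <- params$init
  zo <- center[3] + spec$leaflet_z
  zi <- center[3] - spec$leaflet_z
  up <- place_leaflet(zo, "outer")
  dn <- place_leaflet(zi, "inner")

  ## optional tracked lipids seeded at the five outer wells
  site_ids <- integer(0)
  seeded <- NULL
  if (!is.null(params$site_lipid_class) && !is.null(protein)) {
    seeded <- data.frame(x = site_outer[, 1], y = site_outer[, 2], z = zo,
                         class = params$site_lipid_class)
  }
  lip <- rbind(up, seeded, dn)
  leaflet <- c(rep("U", NROW(up) + NROW(seeded)), rep("L", NROW(dn)))

  ## --- particle table ----------------------------------------------------
  resname_of <- c(lipid_PC = "POPC", lipid_PG = "POPG", lipid_TAP = "DOTAP")
  head_of <- c(lipid_PC = "NC3", lipid_PG = "PO4", lipid_TAP = "NC3")
  nlip <- NROW(lip)
  lip_dfs <- NULL
  if (nlip > 0) {
    per <- if (spec$with_tails) 3L else 1L
    tail_dir <- ifelse(leaflet == "U", -1, 1)
    mk <- function(j, nm, dz) {
      data.frame(name = nm, resid = 1000L + seq_len(nlip),
                 resname = resname_of[lip$class], chain = leaflet,
                 x = lip$x, y = lip$y, z = lip$z + dz)
    }
    lip_dfs <- mk(1, head_of[lip$class], 0)
    if (spec$with_tails)
      lip_dfs <- rbind(lip_dfs,
                       mk(2, "C1A", tail_dir * 4),
                       mk(3, "C2A", tail_dir * 8))
  }
  all_df <- rbind(prot_df, lip_dfs)
  particles <- data.frame(name = all_df$name, resid = all_df$resid,
                          resname = all_df$resname, chain = all_df$chain,
                          is_hydrogen = FALSE,
                          mol_class = classify_resnames(all_df$resname,
                                                        warn = FALSE),
                          stringsAsFactors = FALSE)
  xyz <- wrap_coords(as.matrix(all_df[, c("x", "y", "z")]), box)
  top <- new_topology(particles, xyz, box, title = "lipidsite synthetic membrane")

  nprot <- NROW(prot_df)
  head_rows <- if (nlip) nprot + seq_len(nlip) else integer(0)
  if (!is.null(seeded))
    site_ids <- top$particles$lipid_id[head_rows[NROW(up) + seq_len(5)]]

  structure(list(
    topology = top,
    frame0 = list(xyz = top$xyz, box = box, time = 0),
    box = box, center = center, spec = spec, protein = protein,
    site_centers_outer = site_outer, site_centers_inner = site_inner,
    leaflet = leaflet, lipid_class = if (nlip) lip$class else character(0),
    head_rows = head_rows, site_lipid_ids = site_ids,
    lattice = list(spacing = a, min_separation = 0.6 * a),
    seed = params$seed), class = "membrane_system")
}

## Draw n lateral positions from the single-lipid Boltzmann density
## exp(-U/kT) on a 1 A grid (cell choice by weight, uniform jitter within
## the cell).  Used for equilibrium initialization.
sample_boltzmann_xy <- function(n, depth, centers, width, kT, wall, box) {
  res <- 1
  gx <- seq(res / 2, box[1] - res / 2, by = res)
  gy <- seq(res / 2, box[2] - res / 2, by = res)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  g <- landscape_grad(pts, rep(depth, nrow(pts)), centers, width, wall, box)
  w <- exp(-g$U / kT)
  cells <- sample.int(nrow(pts), n, replace = TRUE, prob = w)
  pts[cells, , drop = FALSE] +
    matrix(runif(2 * n, -res / 2, res / 2), ncol = 2)
}

## largest-remainder apportionment of n among named fractions
stratified_counts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Langevin simulation parameters for the synthetic membrane
#'
#' @param kT thermal energy (sets the energy unit; well depths are in kT).
#' @param D lateral diffusion coefficient (Angstrom^2 per time unit).
#' @param dt integration time step (time units; saved-frame times are
#'   reported in ns = one time unit).
#' @param n_frames number of frames to save.
#' @param save_stride integration steps between saved frames.
#' @param well_depths list with named vectors `outer` and `inner`: well
#'   depth in kT per lipid class at the five aromatic (outer-leaflet) sites
#'   and the five basic-cluster (inner-leaflet) patches.
#' @param well_width Gaussian well width sigma (Angstrom).
#' @param seed master integer seed; replicate r uses `seed + r`.
#' @param site_lipid_class if non-NULL, five extra lipids of this class are
#'   seeded at the outer well centers at build time (tracked site lipids).
#' @param init initial lipid placement: `"uniform"` (jittered lattice; the
#'   run then relaxes toward equilibrium) or `"equilibrium"` (positions
#'   drawn from the single-lipid Boltzmann density, so the run starts
#'   stationary -- appropriate when comparing sampled occupancies against
#'   the quadrature oracle without a long burn-in).
#' @export
sim_params <- function(kT = 1, D = 1, dt = 0.5, n_frames = 400,
                       save_stride = 10,
                       well_depths = list(
                         outer = c(lipid_PC = 6, lipid_PG = 0, lipid_TAP = 8),
                         inner = c(lipid_PC = 0, lipid_PG = 6, lipid_TAP = 0)),
                       well_width = 3, seed = 1,
                       site_lipid_class = NULL,
                       init = c("uniform", "equilibrium")) {
  if (dt <= 0 || D <= 0 || n_frames <= 0 || well_width <= 0)
    stop("dt, D, n_frames and well_width must all be positive")
  for (side in c("outer", "inner")) {
    d <- well_depths[[side]][LIPID_CLASSES]
    d[is.na(d)] <- 0
    names(d) <- LIPID_CLASSES
    well_depths[[side]] <- d
  }
  structure(list(kT = kT, D = D, dt = dt, n_frames = n_frames,
                 save_stride = save_stride, well_depths = well_depths,
                 well_width = well_width, seed = seed,
                 site_lipid_class = site_lipid_class,
                 init = match.arg(init)),
            class = "sim_params")
}

## Potential energy and gradient of the planted landscape for one leaflet.
## pos: m x 2 lipid positions; depths: per-lipid well depth vector (kT);
## centers: k x 2 well centers.  Returns list(U, gx, gy) per lipid.
landscape_grad <- function(pos, depths, centers, width, wall, box) {
  m <- nrow(pos)
  U <- numeric(m); gx <- numeric(m); gy <- numeric(m)
  w2 <- width^2
  if (!is.null(centers) && any(depths > 0)) {
    for (s in seq_len(nrow(centers))) {
      dx <- pos[, 1] - centers[s, 1]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- pos[, 2] - centers[s, 2]
      dy <- dy - box[2] * round(dy / box[2])
      e <- exp(-(dx * dx + dy * dy) / (2 * w2))
      U <- U - depths * e
      gx <- gx + depths * e * dx / w2
      gy <- gy + depths * e * dy / w2
    }
  }
  if (!is.null(wall)) {
    dx <- pos[, 1] - wall$center[1]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- pos[, 2] - wall$center[2]
    dy <- dy - box[2] * round(dy / box[2])
    r <- sqrt(dx * dx + dy * dy)
    pen <- wall$R0 - r
    inside <- pen > 0 & r > 1e-9
    if (any(inside)) {
      U[inside] <- U[inside] + 0.5 * wall$k * pen[inside]^2
      f <- wall$k * pen[inside] / r[inside]   # outward push
      gx[inside] <- gx[inside] - f * dx[inside]
      gy[inside] <- gy[inside] - f * dy[inside]
    }
  }
  list(U = U, gx = gx, gy = gy)
}

system_wall <- function(system) {
  if (is.null(system$protein)) return(NULL)
  list(center = system$center[1:2], R0 = system$protein$wall_radius,
       k = system$protein$wall_k)
}

## per-lipid well depth vectors for each leaflet
leaflet_depths <- function(system, params, leaflet) {
  side <- if (leaflet == "U") "outer" else "inner"
  unname(params$well_depths[[side]][system$lipid_class])[
    system$leaflet == leaflet]
}

#' Run overdamped Langevin dynamics on a synthetic membrane system
#'
#' The protein is static; each lipid headgroup performs 2D overdamped
#' Langevin dynamics in its leaflet plane with periodic wrapping:
#' `dx = -(D/kT) grad(U) dt + sqrt(2 D dt) xi`, where U sums the Gaussian
#' binding wells of the lipid's leaflet (depth by charge class) and the soft
#' repulsive wall at the protein footprint.  Deterministic given
#' `params$seed`.
#'
#' @param system a `membrane_system` from [build_membrane_system()].
#' @param params a [sim_params()].
#' @param replicate integer replicate index; the effective seed is
#'   `params$seed + replicate` (recorded on the returned object).
#' @return an in-memory trajectory; saved frame `i` is at time
#'   `i * dt * save_stride`.  Attribute `seed_used` records the seed.
#' @export
simulate_membrane <- function(system, params = sim_params(), replicate = 0L) {
  stopifnot(inherits(system, "membrane_system"))
  seed_used <- params$seed + as.integer(replicate)
  set.seed(seed_used)
  box <- system$box
  wall <- system_wall(system)
  nlip <- length(system$head_rows)
  isU <- system$leaflet == "U"
  pos <- system$frame0$xyz[system$head_rows, 1:2, drop = FALSE]
  depthU <- if (any(isU)) leaflet_depths(system, params, "U") else numeric(0)
  depthD <- if (any(!isU)) leaflet_depths(system, params, "L") else numeric(0)
  mob <- params$D / params$kT * params$dt
  kick <- sqrt(2 * params$D * params$dt)
  max_drift <- params$well_width / 2
  ## overdamped stability of the wall spring: the restoring step must be
  ## smaller than the penetration or the integrator oscillates
  if (!is.null(wall) && mob * wall$k >= 1)
    stop("wall restoring step exceeds the penetration (D/kT * wall_k * dt ",
         ">= 1); use a smaller dt")

  frames <- vector("list", params$n_frames)
  template <- system$frame0$xyz
  step_once <- function(pos) {
    drift <- matrix(0, nlip, 2)
    if (any(isU)) {
      g <- landscape_grad(pos[isU, , drop = FALSE], depthU,
                          system$site_centers_outer, params$well_width,
                          NULL, box)
      drift[isU, ] <- -mob * cbind(g$gx, g$gy)
    }
    if (any(!isU)) {
      g <- landscape_grad(pos[!isU, , drop = FALSE], depthD,
                          system$site_centers_inner, params$well_width,
                          NULL, box)
      drift[!isU, ] <- -mob * cbind(g$gx, g$gy)
    }
    ## the well force sets the time-step limit; the wall force is a
    ## self-limiting restoring spring handled by the stability check above
    if (nlip && max(abs(drift)) > max_drift)
      stop("deterministic step displacement exceeds well_width/2; ",
           "use a smaller dt (or larger well_width)")
    if (!is.null(wall) && nlip) {
      g <- landscape_grad(pos, numeric(nlip), NULL, params$well_width,
                          wall, box)
      drift <- drift - mob * cbind(g$gx, g$gy)
    }
    pos <- pos + drift + matrix(rnorm(2 * nlip, sd = kick), nlip, 2)
    pos[, 1] <- pos[, 1] %% box[1]
    pos[, 2] <- pos[, 2] %% box[2]
    pos
  }
  tails <- system$spec$with_tails
  for (fi in seq_len(params$n_frames)) {
    for (s in seq_len(params$save_stride)) pos <- step_once(pos)
    xyz <- template
    xyz[system$head_rows, 1:2] <- pos
    if (tails && nlip) {
      xyz[system$head_rows + nlip, 1:2] <- pos
      xyz[system$head_rows + 2L * nlip, 1:2] <- pos
    }
    frames[[fi]] <- list(xyz = xyz, box = box,
                         time = fi * params$dt * params$save_stride)
  }
  traj <- trajectory_memory(frames)
  attr(traj, "seed_used") <- seed_used
  traj
}

#' Equilibrium site occupancy by direct Boltzmann quadrature
#'
#' The brute-force oracle for the sampled contact frequencies: integrates
#' the Boltzmann weight `exp(-U/kT)` of a single lipid of one class over its
#' leaflet plane on a fine grid, and reports the equilibrium probability
#' that the lipid is within the contact threshold of the given site's
#' marker-residue particles (3D minimum-image distance, matching the
#' contact criterion used downstream).
#'
#' @param system a `membrane_system`.
#' @param params a [sim_params()] (for well depths, width, kT).
#' @param lipid_class the lipid class to integrate.
#' @param leaflet `"U"` (outer) or `"L"` (lower, inner).
#' @param site site index 1-5.
#' @param threshold contact threshold (Angstrom), default coarse-grained 5.5.
#' @param grid_res quadrature grid resolution (Angstrom).
#' @param n_lipids if given, also report the probability that at least one
#'   of `n_lipids` independent lipids of the class is in contact.
#' @return list with `p_single`, and `p_any` when `n_lipids` is given.
#' @export
ground_truth_occupancy <- function(system, params, lipid_class = "lipid_PC",
                                   leaflet = "U", site = 1, threshold = 5.5,
                                   grid_res = 1, n_lipids = NULL) {
  box <- system$box
  zplane <- system$center[3] +
    ifelse(leaflet == "U", 1, -1) * system$spec$leaflet_z
  gx <- seq(grid_res / 2, box[1] - grid_res / 2, by = grid_res)
  gy <- seq(grid_res / 2, box[2] - grid_res / 2, by = grid_res)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  depth <- params$well_depths[[ifelse(leaflet == "U", "outer", "inner")]][
    lipid_class]
  centers <- if (leaflet == "U") system$site_centers_outer
             else system$site_centers_inner
  g <- landscape_grad(pts, rep(depth, nrow(pts)), centers,
                      params$well_width, system_wall(system), box)
  w <- exp(-g$U / params$kT)
  ## contact indicator against the site's marker residue particles
  contact <- site_contact_indicator(system, site, leaflet, pts, zplane,
                                    threshold)
  p <- sum(w * contact) / sum(w)
  out <- list(p_single = p)
  if (!is.null(n_lipids)) out$p_any <- 1 - (1 - p)^n_lipids
  out
}

## TRUE for quadrature points whose headgroup position (x, y, zplane) lies
## within `threshold` of any particle of the site's marker residue.
site_contact_indicator <- function(system, site, leaflet, pts, zplane,
                                   threshold) {
  if (is.null(system$protein)) stop("system has no protein placeholder")
  top <- system$topology
  chain <- LETTERS[1:5][site]
  resid <- if (leaflet == "U") system$protein$aromatic_resid
           else system$protein$basic_resids
  rows <- which(top$particles$chain == chain & top$particles$resid %in% resid)
  if (!length(rows)) stop("site residue not found for chain ", chain)
  ref <- top$xyz[rows, , drop = FALSE]
  hit <- rep(FALSE, nrow(pts))
  for (r in seq_len(nrow(ref))) {
    dx <- pts[, 1] - ref[r, 1]
    dx <- dx - system$box[1] * round(dx / system$box[1])
    dy <- pts[, 2] - ref[r, 2]
    dy <- dy - system$box[2] * round(dy / system$box[2])
    dz <- zplane - ref[r, 3]
    hit <- hit | (dx * dx + dy * dy + dz * dz <= threshold^2)
  }
  hit
}

#' Export generator ground truth as JSON
#'
#' Site centers, well depths, tracked site-lipid ids and quadrature
#' occupancies, for validating downstream analyses against the generator.
#'
#' @param system a `membrane_system`.
#' @param params the [sim_params()] used.
#' @param path output JSON path.
#' @param threshold contact threshold used for the quadrature occupancies.
#' @export
write_ground_truth <- function(system, params, path, threshold = 5.5) {
  n_outer <- sum(system$leaflet == "U" & system$lipid_class == "lipid_PC")
  gt <- list(
    seed = system$seed,
    box = system$box,
    leaflet_z = system$spec$leaflet_z,
    site_residues = c(system$protein$aromatic_resid),
    site_centers_outer = system$site_centers_outer,
    site_centers_inner = system$site_centers_inner,
    well_depths = params$well_depths,
    well_width = params$well_width,
    site_lipid_ids = system$site_lipid_ids,
    occupancy = lapply(setNames(LIPID_CLASSES, LIPID_CLASSES), function(cl) {
      nl <- sum(system$leaflet == "U" & system$lipid_class == cl)
      o <- ground_truth_occupancy(system, params, cl, "U", 1,
                                  threshold = threshold,
                                  n_lipids = max(nl, 1))
      list(p_single = o$p_single, p_any = o$p_any, n_lipids_outer = nl)
    }))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(gt)
}
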