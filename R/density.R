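## Time-averaged 3D occupancy density of a selection on a regular grid.
##
## Units: molecules/nm^3 (1 nm^3 = 1000 A^3).  Voxel assignment is the
## half-open convention floor((x - origin)/spacing) after wrapping into the
## primary cell, so the grid integral is exactly the mean number of
## selected particles per frame.

#' Compute an occupancy density grid
#'
#' Per frame, each selected particle increments its containing voxel
#' (minimum-image wrapped into the primary cell); final values are
#' `counts / (frames x voxel_volume_nm3)`.  The grid covers the full
#' periodic box, origin at the box corner.
#'
#' @param traj a trajectory (or list of replicate trajectories, pooled
#'   after windowing).
#' @param top matching `topology`.
#' @param selection a [selection_spec()] or integer particle indices.
#' @param spacing voxel edge (Angstrom); default 2.
#' @param window an [analysis_window()] or `NULL` for all frames.
#' @return a `density_grid`: `origin` (Angstrom), `spacing`, `dim`,
#'   `values` (3D array, molecules/nm^3) and `frames_averaged`.
#' @export
compute_density_grid <- function(traj, top, selection, spacing = 2,
                                 window = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  sel <- resolve_selection(top, selection)
  if (!length(sel)) stop("density selection resolves to no particles")
  trajs <- if (inherits(traj, "trajectory")) list(traj) else traj
  box <- get_frame(trajs[[1]], 1)$box
  dims <- pmax(1L, as.integer(ceiling(box / spacing - 1e-9)))
  counts <- array(0, dims)
  nfr <- 0L
  for (tr in trajs) {
    idx <- resolve_window(tr, window)
    for (i in idx) {
      f <- get_frame(tr, i)
      xyz <- wrap_coords(f$xyz[sel, , drop = FALSE], box)
      vox <- floor(xyz / spacing)
      ## particles exactly on the upper boundary wrap to voxel 0
      for (k in 1:3) vox[vox[, k] >= dims[k], k] <- 0
      lin <- 1 + vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3])
      tab <- tabulate(lin, prod(dims))
      counts <- counts + array(tab, dims)
      nfr <- nfr + 1L
    }
  }
  if (nfr == 0L) stop("analysis window resolves to zero frames")
  voxel_nm3 <- spacing^3 / 1000
  structure(list(origin = c(0, 0, 0), spacing = rep(spacing, 3),
                 dim = dims, values = counts / (nfr * voxel_nm3),
                 frames_averaged = nfr, box = box),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("Density grid:", paste(x$dim, collapse = " x "), "voxels, spacing",
      paste(signif(x$spacing, 4), collapse = "/"), "A,",
      x$frames_averaged, "frames\n")
  cat(sprintf("  max %.3f molecules/nm^3; integral %.3f molecules\n",
              max(x$values), grid_integral(x)))
  invisible(x)
}

#' Integral of a density grid (mean molecule count per frame)
#' @param grid a `density_grid`.
#' @export
grid_integral <- function(grid) {
  sum(grid$values) * prod(grid$spacing) / 1000
}

#' Threshold a density grid and report connected components
#'
#' Voxels with `value >= level` form the mask; connected components use
#' 6-connectivity (faces only, no periodic stitching) and are reported with
#' their value-weighted centroids in Angstrom.
#'
#' @param grid a `density_grid`.
#' @param level isosurface level, molecules/nm^3.
#' @return list with `mask` (logical array), `n_components`, and
#'   `components`: data.frame of voxel counts, total weight and centroid
#'   x/y/z per component.
#' @export
threshold_mask <- function(grid, level) {
  if (level < 0) stop("level must be >= 0")
  mask <- grid$values >= level & grid$values > 0
  dims <- grid$dim
  lab <- array(0L, dims)
  comp <- list()
  nc <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nc <- nc + 1L
    queue <- start
    lab[start] <- nc
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      a <- arrayInd(v, dims)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        nb <- a
        nb[d] <- nb[d] + s
        if (nb[d] < 1 || nb[d] > dims[d]) next
        li <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nc
          queue <- c(queue, li)
        }
      }
    }
    comp[[nc]] <- members
  }
  comps <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    m <- comp[[ci]]
    a <- arrayInd(m, dims)
    w <- grid$values[m]
    cen <- grid$origin + (colSums((a - 0.5) * w) / sum(w)) * grid$spacing
    data.frame(component = ci, n_voxels = length(m), weight = sum(w),
               x = cen[1], y = cen[2], z = cen[3])
  }))
  list(mask = mask, labels = lab, n_components = nc,
       components = if (is.null(comps))
         data.frame(component = integer(0), n_voxels = integer(0),
                    weight = numeric(0), x = numeric(0), y = numeric(0),
                    z = numeric(0)) else comps)
}

#' Five-fold symmetrize a density grid about the box axis
#'
#' Averages the grid over the four non-trivial 72-degree rotations about
#' the vertical axis through the box center (nearest-voxel resampling).
#' On C5-symmetric systems this is a variance-reduction device; the raw
#' grid is always available alongside.
#'
#' @param grid a `density_grid`.
#' @export
symmetrize_c5 <- function(grid) {
  dims <- grid$dim
  cen <- grid$box[1:2] / 2
  acc <- grid$values
  ## voxel-center coordinates
  a <- arrayInd(seq_len(prod(dims)), dims)
  xy <- sweep((a[, 1:2] - 0.5), 2, grid$spacing[1:2], "*")
  for (k in 1:4) {
    th <- 2 * pi * k / 5
    rot <- cbind(cos(th) * (xy[, 1] - cen[1]) - sin(th) * (xy[, 2] - cen[2]),
                 sin(th) * (xy[, 1] - cen[1]) + cos(th) * (xy[, 2] - cen[2]))
    src_i <- pmin(pmax(1L, as.integer(ceiling((rot[, 1] + cen[1]) /
                                              grid$spacing[1]))), dims[1])
    src_j <- pmin(pmax(1L, as.integer(ceiling((rot[, 2] + cen[2]) /
                                              grid$spacing[2]))), dims[2])
    lin <- src_i + dims[1] * (src_j - 1 + dims[2] * (a[, 3] - 1))
    acc <- acc + array(grid$values[lin], dims)
  }
  grid$values <- acc / 5
  grid
}

#' Write a density grid as an OpenDX scalar field
#' @param grid a `density_grid`.
#' @param path output `.dx` path.
#' @export
write_opendx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dim
  writeLines(c(
    "# OpenDX scalar field written by lipidsite",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.17g %.17g %.17g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.17g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.17g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.17g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## OpenDX stores with z fastest
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))
  n <- length(v)
  full <- seq_len(n %/% 3 * 3)
  lines <- character(0)
  if (length(full))
    lines <- sprintf("%.17g %.17g %.17g",
                     v[seq(1, length(full), 3)],
                     v[seq(2, length(full), 3)],
                     v[seq(3, length(full), 3)])
  rest <- v[setdiff(seq_len(n), full)]
  if (length(rest))
    lines <- c(lines, paste(sprintf("%.17g", rest), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written in the gridpositions dialect
#' @param path a `.dx` file.
#' @return a `density_grid` (with `frames_averaged = NA`).
#' @export
read_opendx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (!length(gp)) stop("malformed OpenDX file: no gridpositions object")
  d <- as.integer(tail(strsplit(gp[1], "\\s+")[[1]], 3))
  og <- grep("^origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(og[1]), "\\s+")[[1]][2:4])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dl[1:3], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4]), numeric(3)))
  if (any(abs(deltas[upper.tri(deltas) | lower.tri(deltas)]) > 1e-12))
    stop("malformed OpenDX file: non-diagonal deltas unsupported")
  spacing <- diag(deltas)
  arr_at <- grep("data follows", lines)
  if (!length(arr_at)) stop("malformed OpenDX file: no data array")
  items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1",
                          lines[arr_at[1]]))
  vals <- numeric(0)
  i <- arr_at[1] + 1
  while (length(vals) < items && i <= length(lines)) {
    if (grepl("^(attribute|object)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != items || anyNA(vals))
    stop("malformed OpenDX file: expected ", items, " values")
  values <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  structure(list(origin = origin, spacing = spacing, dim = d,
                 values = values, frames_averaged = NA_integer_,
                 box = d * spacing),
            class = "density_grid")
}
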