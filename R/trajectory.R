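## Trajectories: ordered frames of coordinates with a per-frame box.
##
## Analyses access frames one at a time through get_frame(), so no stage
## needs the whole trajectory resident as parsed coordinates.  Three
## backends: in-memory (the synthetic generator), the package's plain-text
## frame format (documented in the README), and binary DCD via bio3d.

#' Number of frames in a trajectory
#' @param traj a trajectory object.
#' @export
n_frames <- function(traj) UseMethod("n_frames")

#' Extract one frame from a trajectory
#' @param traj a trajectory object.
#' @param i frame index (1-based, in time order).
#' @return list with `xyz` (n x 3 matrix, Angstrom), `box` (3-vector,
#'   Angstrom) and `time` (ns).
#' @export
get_frame <- function(traj, i) UseMethod("get_frame")

#' @export
print.trajectory <- function(x, ...) {
  n <- n_frames(x)
  cat("Trajectory:", n, "frames,", x$natoms, "particles\n")
  if (n > 0) {
    f1 <- get_frame(x, 1); f2 <- get_frame(x, n)
    cat("  time range (ns):", f1$time, "-", f2$time, "\n")
  }
  invisible(x)
}

## ---- in-memory backend -------------------------------------------------

#' Build an in-memory trajectory from a list of frames
#' @param frames list of `list(xyz, box, time)` in time order.
#' @export
trajectory_memory <- function(frames) {
  natoms <- if (length(frames)) nrow(frames[[1]]$xyz) else 0L
  structure(list(frames = frames, natoms = natoms),
            class = c("traj_memory", "trajectory"))
}

#' @export
n_frames.traj_memory <- function(traj) length(traj$frames)

#' @export
get_frame.traj_memory <- function(traj, i) traj$frames[[i]]

## ---- plain-text backend ------------------------------------------------

#' Write a trajectory to the package's plain-text frame format
#'
#' One `frame time <ns> box <lx> <ly> <lz>` header per frame followed by one
#' `x y z` line per particle, 1e-4 Angstrom precision.  The format exists so
#' synthetic trajectories are diffable, versionable text.
#'
#' @param traj a trajectory object (or list of frames).
#' @param path output path (conventionally `.trj`).
#' @export
write_traj_text <- function(traj, path) {
  if (!inherits(traj, "trajectory")) traj <- trajectory_memory(traj)
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_frames(traj)
  writeLines(c("LIPIDSITE_TRJ 1",
               paste("natoms", traj$natoms),
               paste("nframes", n)), con)
  for (i in seq_len(n)) {
    f <- get_frame(traj, i)
    writeLines(sprintf("frame time %.6f box %.4f %.4f %.4f",
                       f$time, f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%.4f %.4f %.4f",
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
  }
  invisible(path)
}

read_traj_text <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "LIPIDSITE_TRJ"))
    stop("not a lipidsite plain-text trajectory: ", path)
  natoms <- as.integer(strsplit(lines[2], " ")[[1]][2])
  nfr <- as.integer(strsplit(lines[3], " ")[[1]][2])
  if (is.na(natoms) || is.na(nfr)) stop("malformed trajectory header")
  hdr_at <- 4L + (0:max(0, nfr - 1)) * (natoms + 1L)
  if (nfr > 0 && (length(lines) < hdr_at[nfr] + natoms))
    stop("truncated trajectory file: ", path)
  structure(list(lines = lines, natoms = natoms, nfr = nfr, hdr_at = hdr_at),
            class = c("traj_text", "trajectory"))
}

#' @export
n_frames.traj_text <- function(traj) traj$nfr

#' @export
get_frame.traj_text <- function(traj, i) {
  stopifnot(i >= 1, i <= traj$nfr)
  h <- strsplit(traj$lines[traj$hdr_at[i]], "\\s+")[[1]]
  if (h[1] != "frame") stop("malformed frame header at frame ", i)
  tm <- as.numeric(h[3]); box <- as.numeric(h[5:7])
  xyz <- matrix(scan(text = traj$lines[(traj$hdr_at[i] + 1):
                                       (traj$hdr_at[i] + traj$natoms)],
                     quiet = TRUE), ncol = 3, byrow = TRUE)
  list(xyz = xyz, box = box, time = tm)
}

## ---- DCD backend (bio3d) ----------------------------------------------

read_traj_dcd <- function(path) {
  hdr <- read_dcd_header(path)
  xyz <- suppressWarnings(
    bio3d::read.dcd(path, cell = FALSE, verbose = FALSE))
  cell <- if (hdr$has_cell)
    suppressWarnings(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE))
  else NULL
  natoms <- ncol(xyz) / 3
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    box <- if (!is.null(cell)) as.numeric(cell[i, 1:3]) else c(NA, NA, NA)
    list(xyz = m, box = box, time = (i - 1) * hdr$dt)
  })
  trajectory_memory(frames)
}

read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  len <- readBin(con, "integer", 1, size = 4)
  magic <- readChar(con, 4)
  if (is.na(len) || len != 84 || magic != "CORD")
    stop("not a CHARMM/NAMD DCD file: ", path)
  icntrl <- readBin(con, "integer", 20, size = 4)
  list(nframes = icntrl[1], has_cell = icntrl[11] == 1, dt = 1)
}

#' Write a trajectory as a CHARMM-format DCD file (with unit-cell records)
#' @param traj a trajectory object.
#' @param path output path.
#' @export
write_dcd <- function(traj, path) {
  if (!inherits(traj, "trajectory")) traj <- trajectory_memory(traj)
  n <- n_frames(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload) {
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- n; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- n
  icntrl[11] <- 1L  # crystal records present
  icntrl[20] <- 24L
  rec(c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4)))
  title <- sprintf("%-80s", "lipidsite synthetic trajectory")
  rec(c(writeBin(1L, raw(), size = 4), charToRaw(title)))
  rec(writeBin(as.integer(traj$natoms), raw(), size = 4))
  for (i in seq_len(n)) {
    f <- get_frame(traj, i)
    ## CHARMM XTLABC order: A, cos(gamma), B, cos(beta), cos(alpha), C
    cell <- c(f$box[1], 0, f$box[2], 0, 0, f$box[3])
    rec(writeBin(as.numeric(cell), raw(), size = 8))
    for (k in 1:3)
      rec(writeBin(as.numeric(f$xyz[, k]), raw(), size = 4))
  }
  invisible(path)
}

## ---- loading and windows ----------------------------------------------

#' Load a trajectory and check it against a topology
#'
#' Supports the package's plain-text format (`.trj`/`.txt`) and binary DCD
#' (`.dcd`).  XTC is not readable here; convert to DCD or text first.
#' Frames are yielded in time order; the box is read per frame.
#'
#' @param top the matching `topology` (particle counts must agree).
#' @param path trajectory file.
#' @return a trajectory object.
#' @export
load_trajectory <- function(top, path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
                 trj = , txt = read_traj_text(path),
                 dcd = read_traj_dcd(path),
                 xtc = stop("XTC is not supported by this reader; ",
                            "convert to DCD or the plain-text format"),
                 stop("unsupported trajectory format '.", ext, "'"))
  if (n_frames(traj) > 0 && traj$natoms != n_particles(top))
    stop("trajectory particle count (", traj$natoms,
         ") does not match topology (", n_particles(top), ")")
  traj
}

#' Analysis window: which part of a trajectory to analyze
#'
#' Either a leading fraction of frames to discard (equilibration), or an
#' explicit `[t_start, t_end]` time interval in ns.
#'
#' @param fraction_discarded leading fraction of frames dropped, in `[0, 1)`.
#' @param t_start,t_end optional explicit time bounds (ns, inclusive);
#'   when given they override `fraction_discarded`.
#' @export
analysis_window <- function(fraction_discarded = 0, t_start = NULL,
                            t_end = NULL) {
  if (fraction_discarded < 0 || fraction_discarded >= 1)
    stop("fraction_discarded must be in [0, 1)")
  structure(list(fraction_discarded = fraction_discarded,
                 t_start = t_start, t_end = t_end),
            class = "analysis_window")
}

#' Resolve an analysis window to frame indices
#' @param traj a trajectory.
#' @param window an [analysis_window()] (or `NULL` for all frames).
#' @return integer frame indices.
#' @export
resolve_window <- function(traj, window = NULL) {
  n <- n_frames(traj)
  if (n == 0) return(integer(0))
  if (is.null(window)) return(seq_len(n))
  stopifnot(inherits(window, "analysis_window"))
  if (!is.null(window$t_start) || !is.null(window$t_end)) {
    times <- vapply(seq_len(n), function(i) get_frame(traj, i)$time, 0)
    lo <- if (is.null(window$t_start)) -Inf else window$t_start
    hi <- if (is.null(window$t_end)) Inf else window$t_end
    return(which(times >= lo & times <= hi))
  }
  drop <- floor(window$fraction_discarded * n)
  seq_len(n)[seq_len(n) > drop]
}
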