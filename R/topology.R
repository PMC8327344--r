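## Topology: the particle table shared by every analysis stage.
##
## A topology is a data.frame of particles (one row per bead or atom) plus
## the reference coordinates and box it was read with.  Residue numbering is
## author numbering (1-based, e.g. 206 for the M1 aromatic residue) and is
## never re-indexed.  Internal length unit is Angstrom everywhere; GRO files
## (nm) are converted on read/write.

#' Default residue-name to molecule-class lookup
#'
#' Maps residue names to the charge classes the analyses distinguish:
#' zwitterionic PC-like, anionic PG-like and cationic TAP-like lipids, and
#' protein residues.  Anything not in the lookup is classified `"other"`
#' with a warning at load time.
#'
#' @return named character vector mapping residue name to one of
#'   `"protein"`, `"lipid_PC"`, `"lipid_PG"`, `"lipid_TAP"`.
#' @export
default_class_lookup <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  c(setNames(rep("protein", length(aa)), aa),
    POPC = "lipid_PC", DPPC = "lipid_PC", POPE = "lipid_PC",
    POPG = "lipid_PG", DPPG = "lipid_PG",
    DOTAP = "lipid_TAP", DOTA = "lipid_TAP", DPTAP = "lipid_TAP")
}

MOLECULE_CLASSES <- c("protein", "lipid_PC", "lipid_PG", "lipid_TAP", "other")
LIPID_CLASSES <- c("lipid_PC", "lipid_PG", "lipid_TAP")

new_topology <- function(particles, xyz, box, title = "lipidsite topology") {
  stopifnot(is.data.frame(particles),
            nrow(particles) == nrow(xyz), ncol(xyz) == 3)
  need <- c("name", "resid", "resname", "chain", "is_hydrogen", "mol_class")
  miss <- setdiff(need, names(particles))
  if (length(miss)) stop("particle table lacks columns: ",
                         paste(miss, collapse = ", "))
  particles$mol_class <- factor(as.character(particles$mol_class),
                                levels = MOLECULE_CLASSES)
  if (anyNA(particles$mol_class)) stop("invalid molecule class")
  particles$lipid_id <- make_lipid_ids(particles)
  rownames(particles) <- NULL
  structure(list(particles = particles,
                 xyz = unname(as.matrix(xyz)),
                 box = as.numeric(box),
                 title = title),
            class = "topology")
}

## Lipid molecules are identified by (chain, resid); protein particles get NA.
make_lipid_ids <- function(p) {
  is_lip <- p$mol_class %in% LIPID_CLASSES
  id <- rep(NA_integer_, nrow(p))
  if (any(is_lip)) {
    key <- paste(p$chain[is_lip], p$resid[is_lip], sep = "/")
    id[is_lip] <- as.integer(factor(key, levels = unique(key)))
  }
  id
}

#' Number of particles in a topology
#' @param top a `topology` object.
#' @export
n_particles <- function(top) nrow(top$particles)

#' @export
print.topology <- function(x, ...) {
  p <- x$particles
  cat("Topology:", nrow(p), "particles,",
      length(unique(paste(p$chain, p$resid))), "residues,",
      length(unique(p$chain)), "chains\n")
  cat("  box (A):", paste(signif(x$box, 6), collapse = " x "), "\n")
  cls <- table(p$mol_class)
  cls <- cls[cls > 0]
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

classify_resnames <- function(resname, class_lookup = default_class_lookup(),
                              warn = TRUE) {
  cls <- unname(class_lookup[resname])
  unknown <- is.na(cls)
  if (any(unknown)) {
    if (warn)
      warning("unknown residue name(s) classified as 'other': ",
              paste(unique(resname[unknown]), collapse = ", "),
              call. = FALSE)
    cls[unknown] <- "other"
  }
  cls
}

#' Load a topology from a PDB or GRO coordinate file
#'
#' Residue names are mapped to molecule classes through `class_lookup`;
#' unknown names are classified `"other"` with a warning (never an error).
#' GRO files carry no chain identifiers, so all particles read from GRO get
#' chain `""` unless reassigned with [assign_chains()].
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @param class_lookup named vector mapping residue names to molecule
#'   classes, see [default_class_lookup()].
#' @param box optional box override (3-vector, Angstrom) for PDB files
#'   without a CRYST1 record.
#' @return a `topology` object: particle table (`$particles`), reference
#'   coordinates in Angstrom (`$xyz`), and box (`$box`).
#' @export
load_topology <- function(path, class_lookup = default_class_lookup(),
                          box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  top <- switch(ext,
                gro = read_gro(path, class_lookup),
                pdb = read_pdb_topology(path, class_lookup),
                stop("unsupported coordinate format '.", ext,
                     "': expected .pdb or .gro"))
  if (!is.null(box)) top$box <- as.numeric(box)
  check_box(top$box)
  top
}

read_gro <- function(path, class_lookup = default_class_lookup()) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < natoms + 3)
    stop("malformed GRO file: bad atom count")
  at <- lines[3:(natoms + 2)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("malformed GRO file: unparseable atom records")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop("malformed GRO file: bad box line")
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    stop("triclinic GRO box is not supported (orthorhombic only)")
  particles <- data.frame(
    name = name, resid = resid, resname = resname,
    chain = rep("", natoms),
    is_hydrogen = grepl("^[0-9]*H", name),
    mol_class = classify_resnames(resname, class_lookup),
    stringsAsFactors = FALSE)
  ## GRO is in nm; internal unit is Angstrom
  new_topology(particles, cbind(x, y, z) * 10, boxv[1:3] * 10,
               title = lines[1])
}

#' Write a topology (with its reference coordinates) to a GRO file
#'
#' Coordinates are converted from the internal Angstrom to the GRO nm
#' convention.  Chain identifiers are not representable in GRO and are
#' dropped; use [write_pdb()] when chains matter.
#'
#' @param top a `topology` object.
#' @param path output path.
#' @param xyz optional coordinate matrix overriding `top$xyz`.
#' @export
write_gro <- function(top, path, xyz = NULL) {
  if (is.null(xyz)) xyz <- top$xyz
  p <- top$particles
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(top$title, sprintf("%5d", n)), con)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   p$resid %% 100000, substr(p$resname, 1, 5),
                   substr(p$name, 1, 5), seq_len(n) %% 100000,
                   xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     top$box[1] / 10, top$box[2] / 10, top$box[3] / 10), con)
  invisible(path)
}

read_pdb_topology <- function(path, class_lookup = default_class_lookup()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  elesy <- a$elesy
  is_h <- (!is.na(elesy) & toupper(trimws(elesy)) == "H") |
    grepl("^[0-9]*H", trimws(a$elety))
  chain <- ifelse(is.na(a$chain), "", a$chain)
  particles <- data.frame(
    name = trimws(a$elety), resid = a$resno, resname = trimws(a$resid),
    chain = chain, is_hydrogen = is_h,
    mol_class = classify_resnames(trimws(a$resid), class_lookup),
    stringsAsFactors = FALSE)
  box <- c(NA_real_, NA_real_, NA_real_)
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                       substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(cr[1], 34, 40),
                                         substr(cr[1], 41, 47),
                                         substr(cr[1], 48, 54))))
    if (!anyNA(ang) && any(abs(ang - 90) > 1e-6))
      stop("triclinic PDB cell is not supported (orthorhombic only)")
    box <- v
  }
  if (anyNA(box))
    stop("PDB file has no usable CRYST1 box; pass box= to load_topology()")
  new_topology(particles, cbind(a$x, a$y, a$z), box,
               title = basename(path))
}

#' Write a topology to a minimal PDB file (with CRYST1 box and chains)
#' @inheritParams write_gro
#' @export
write_pdb <- function(top, path, xyz = NULL) {
  if (is.null(xyz)) xyz <- top$xyz
  p <- top$particles
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     top$box[1], top$box[2], top$box[3], 90, 90, 90), con)
  nm <- ifelse(nchar(p$name) < 4, paste0(" ", p$name), p$name)
  lines <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   seq_len(n) %% 100000, substr(nm, 1, 4),
                   substr(p$resname, 1, 4), substr(p$chain, 1, 1),
                   p$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Assign chain identifiers by residue-number ranges
#'
#' Utility for GRO-derived topologies (GRO has no chain field): each entry
#' of `ranges` is a `c(from, to)` residue interval assigned the
#' corresponding chain name.
#'
#' @param top a `topology`.
#' @param ranges named list of `c(from, to)` residue-number intervals.
#' @export
assign_chains <- function(top, ranges) {
  for (ch in names(ranges)) {
    r <- ranges[[ch]]
    sel <- top$particles$resid >= r[1] & top$particles$resid <= r[2]
    top$particles$chain[sel] <- ch
  }
  top
}

#' Build the five-fold symmetry map over protein chains
#'
#' @param top a `topology`.
#' @param chains character vector of the five protein chain ids in rotation
#'   order; by default the sorted distinct protein chains.
#' @return a `symmetry_map`: the ordered chain list.  Residue
#'   correspondence across chains is by identical residue number.
#' @export
symmetry_map <- function(top, chains = NULL) {
  if (is.null(chains)) {
    chains <- sort(unique(top$particles$chain[
      top$particles$mol_class == "protein"]))
  }
  if (length(chains) != 5)
    stop("a symmetry map needs exactly five chains, got ",
         length(chains), " (", paste(chains, collapse = ","), ")")
  structure(list(chains = as.character(chains)), class = "symmetry_map")
}

#' Rotate a chain id k steps around the five-fold axis
#' @param map a `symmetry_map`.
#' @param chain chain id present in the map.
#' @param k integer number of 72-degree steps.
#' @export
next_chain <- function(map, chain, k = 1L) {
  i <- match(chain, map$chains)
  if (anyNA(i)) stop("chain not in symmetry map: ", chain)
  map$chains[((i - 1 + k) %% 5) + 1]
}

#' Declarative particle selection
#'
#' A `selection_spec` filters the particle table on chain, residue numbers,
#' atom/bead names, residue names, molecule class and hydrogen exclusion.
#' Resolution is deterministic: matching particle indices in ascending
#' order, independent of input file ordering conventions.
#'
#' @param name label for the selection.
#' @param chain,resid,atom_names,resname,mol_class optional filters; each a
#'   vector of allowed values (`resid` may be any integer vector, e.g. a
#'   range `260:268`).
#' @param exclude_hydrogen drop hydrogens (atomistic mode).
#' @return a `selection_spec` object.
#' @export
selection_spec <- function(name, chain = NULL, resid = NULL,
                           atom_names = NULL, resname = NULL,
                           mol_class = NULL, exclude_hydrogen = FALSE) {
  structure(list(name = name, chain = chain, resid = resid,
                 atom_names = atom_names, resname = resname,
                 mol_class = mol_class,
                 exclude_hydrogen = isTRUE(exclude_hydrogen)),
            class = "selection_spec")
}

#' Resolve a selection against a topology
#' @param top a `topology`.
#' @param spec a `selection_spec` (or a plain integer index vector, passed
#'   through sorted).
#' @return sorted integer particle indices (1-based).
#' @export
resolve_selection <- function(top, spec) {
  if (is.numeric(spec)) return(sort(unique(as.integer(spec))))
  stopifnot(inherits(spec, "selection_spec"))
  p <- top$particles
  keep <- rep(TRUE, nrow(p))
  if (!is.null(spec$chain)) keep <- keep & p$chain %in% spec$chain
  if (!is.null(spec$resid)) keep <- keep & p$resid %in% spec$resid
  if (!is.null(spec$atom_names)) keep <- keep & p$name %in% spec$atom_names
  if (!is.null(spec$resname)) keep <- keep & p$resname %in% spec$resname
  if (!is.null(spec$mol_class))
    keep <- keep & as.character(p$mol_class) %in% spec$mol_class
  if (spec$exclude_hydrogen) keep <- keep & !p$is_hydrogen
  which(keep)
}

#' Built-in headgroup selections per lipid class
#'
#' Headgroup membership is configuration, not code: the default names cover
#' the single-bead coarse-grained convention used by the synthetic generator
#' (`NC3` choline bead for PC/TAP, `PO4` phosphate bead for PG) plus common
#' atomistic headgroup atom names.  Override by passing an explicit
#' [selection_spec()] to the analysis functions.
#'
#' @param lipid_class one of `"lipid_PC"`, `"lipid_PG"`, `"lipid_TAP"`.
#' @param mode `"cg"` (single terminal charged bead) or `"atomistic"`.
#' @export
headgroup_selection <- function(lipid_class = LIPID_CLASSES,
                                mode = c("cg", "atomistic")) {
  lipid_class <- match.arg(lipid_class)
  mode <- match.arg(mode)
  names_cg <- list(lipid_PC = "NC3", lipid_TAP = "NC3", lipid_PG = "PO4")
  names_aa <- list(
    lipid_PC = c("N", "C11", "C12", "C13", "C14", "C15", "P",
                 "O11", "O12", "O13", "O14"),
    lipid_TAP = c("N", "C11", "C12", "C13", "C14", "C15"),
    lipid_PG = c("P", "O11", "O12", "O13", "O14", "C11", "C12", "C13",
                 "OC2", "OC3"))
  nm <- if (mode == "cg") names_cg[[lipid_class]] else names_aa[[lipid_class]]
  selection_spec(paste0(lipid_class, "_headgroup_", mode),
                 atom_names = nm, mol_class = lipid_class,
                 exclude_hydrogen = (mode == "atomistic"))
}
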