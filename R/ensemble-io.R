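#' @keywords internal
"_PACKAGE"

# ---- containers -----------------------------------------------------------

#' Construct a structure object
#'
#' A minimal protein-structure container: an atom table (chain, author
#' residue number, residue name, atom name) plus an A x 3 coordinate matrix
#' in Angstrom. Residue numbering always follows the author (PDB) numbering;
#' matrices derived downstream use positional indices with an explicit label
#' map so the two never get conflated.
#'
#' @param atoms data.frame with columns `chain`, `resid` (integer author
#'   numbering), `resname` (3-letter code), `elety` (atom name).
#' @param xyz numeric A x 3 matrix of coordinates (Angstrom).
#' @return object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be an A x 3 matrix matching the atom table")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resid, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) record: ",
         key[which(duplicated(key))[1L]])
  }
  structure(list(atoms = atoms, xyz = unname(xyz)), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure an `md_structure`.
#' @return integer count of distinct (chain, resid) pairs.
#' @export
n_residues <- function(structure) {
  length(unique(paste(structure$atoms$chain, structure$atoms$resid)))
}

#' Construct an ensemble object
#'
#' An ordered set of coordinate frames over a fixed atom set, with a replica
#' label and a time stamp (ns) per frame. This is the universal input of the
#' analysis stages; a metatrajectory is simply an ensemble whose frames come
#' from several replicas concatenated in order.
#'
#' @param reference an `md_structure` defining the atom set.
#' @param coords numeric array A x 3 x F of frame coordinates (Angstrom).
#' @param replica character vector of length F (replica label per frame).
#' @param time numeric vector of length F, time stamps in ns, non-decreasing
#'   within each replica.
#' @return object of class `md_ensemble`.
#' @export
md_ensemble <- function(reference, coords, replica = NULL, time = NULL) {
  stopifnot(inherits(reference, "md_structure"))
  if (length(dim(coords)) != 3L) stop("coords must be an A x 3 x F array")
  A <- nrow(reference$xyz)
  if (dim(coords)[1L] != A || dim(coords)[2L] != 3L)
    stop(sprintf("coords atom count mismatch: expected %d, found %d",
                 A, dim(coords)[1L]))
  nf <- dim(coords)[3L]
  if (nf < 1L) stop("ensemble needs at least one frame")
  if (is.null(replica)) replica <- rep("r1", nf)
  if (is.null(time)) time <- seq_len(nf) - 1
  stopifnot(length(replica) == nf, length(time) == nf)
  for (r in unique(replica)) {
    tt <- time[replica == r]
    if (is.unsorted(tt)) stop("time stamps decrease within replica ", r)
  }
  structure(list(reference = reference, coords = unname(coords),
                 replica = as.character(replica), time = as.numeric(time)),
            class = "md_ensemble")
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat(sprintf("md_ensemble: %d frames x %d atoms, replicas: %s\n",
              n_frames(x), dim(x$coords)[1L],
              paste(unique(x$replica), collapse = ",")))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `md_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3L]

# Flatten to a bio3d-style F x 3A xyz matrix (x1,y1,z1,x2,...)
ensemble_xyz <- function(ensemble) {
  d <- dim(ensemble$coords)
  m <- aperm(ensemble$coords, c(2L, 1L, 3L))  # 3 x A x F
  dim(m) <- c(3L * d[1L], d[3L])
  t(m)
}

xyz_to_coords <- function(xyz) {
  xyz <- rbind(xyz)
  nf <- nrow(xyz)
  A <- ncol(xyz) / 3L
  m <- t(xyz)                       # 3A x F
  dim(m) <- c(3L, A, nf)
  aperm(m, c(2L, 1L, 3L))           # A x 3 x F
}

# ---- PDB structure I/O ----------------------------------------------------

#' Read a protein structure from a PDB file
#'
#' Multi-model files return the first model only. Author residue numbering
#' is preserved.
#'
#' @param path PDB file.
#' @return an `md_structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("zero atoms in ", path)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resid = at$resno, resname = at$resid,
                      elety = at$elety, stringsAsFactors = FALSE)
  xyz <- matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE)
  md_structure(atoms, xyz)
}

#' Write a structure (optionally with per-atom B-factors) to PDB
#'
#' The B-factor column is the standard vehicle for projecting a per-residue
#' scalar (RMSF, DF coordination, D-NEMD response) onto a 3-D structure.
#'
#' @param structure an `md_structure`.
#' @param path output file.
#' @param bfactor optional numeric vector, length A (per atom) or one value
#'   per residue (expanded over each residue's atoms).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, bfactor = NULL) {
  a <- structure$atoms
  b <- rep(0, nrow(a))
  if (!is.null(bfactor)) {
    if (length(bfactor) == nrow(a)) {
      b <- bfactor
    } else {
      rid <- residue_index(structure)
      if (length(bfactor) != max(rid))
        stop("bfactor length matches neither atoms nor residues")
      b <- bfactor[rid]
    }
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   resno = a$resid, resid = a$resname,
                   chain = a$chain, elety = a$elety, b = b)
  invisible(path)
}

# positional residue index (1..N) per atom, in atom order
residue_index <- function(structure) {
  key <- paste(structure$atoms$chain, structure$atoms$resid)
  match(key, unique(key))
}

#' Residue labels of a structure (chain + author residue id)
#' @param structure an `md_structure`.
#' @return data.frame with `chain` and `resid`, one row per residue.
#' @export
residue_labels <- function(structure) {
  key <- paste(structure$atoms$chain, structure$atoms$resid)
  first <- !duplicated(key)
  data.frame(chain = structure$atoms$chain[first],
             resid = structure$atoms$resid[first],
             stringsAsFactors = FALSE)
}

# ---- trajectory I/O -------------------------------------------------------

#' Load a multi-replica ensemble (metatrajectory) from trajectory files
#'
#' Frames are concatenated in the given file order with one replica label
#' per file, which is how pooled metatrajectories are assembled from
#' independent production replicas.
#'
#' @param topology an `md_structure` defining the atom set.
#' @param paths character vector of trajectory files (DCD or multi-model
#'   PDB).
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @param replica labels, one per file; default `r1`, `r2`, ...
#' @param stride keep every `stride`-th frame (>= 1).
#' @param dt time between stored frames in ns; frame k of a replica is
#'   stamped (k - 1) * dt after striding.
#' @return an `md_ensemble`.
#' @export
read_ensemble <- function(topology, paths, format = "auto",
                          replica = NULL, stride = 1L, dt = 1) {
  stopifnot(inherits(topology, "md_structure"), stride >= 1L)
  if (is.null(replica)) replica <- paste0("r", seq_along(paths))
  stopifnot(length(replica) == length(paths))
  A <- nrow(topology$xyz)
  xs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    fmt <- format
    if (fmt == "auto")
      fmt <- if (grepl("\\.dcd$", p, ignore.case = TRUE)) "dcd" else "pdb"
    xyz <- switch(fmt,
      dcd = bio3d::read.dcd(p, verbose = FALSE),
      pdb = bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz,
      stop("unsupported trajectory format: ", fmt))
    xyz <- rbind(xyz)
    if (ncol(xyz) != 3L * A)
      stop(sprintf("atom count mismatch in %s: expected %d, found %d",
                   p, A, ncol(xyz) / 3L))
    keep <- seq(1L, nrow(xyz), by = stride)
    xs[[i]] <- xyz[keep, , drop = FALSE]
  }
  nf <- vapply(xs, nrow, 1L)
  coords <- xyz_to_coords(do.call(rbind, xs))
  md_ensemble(topology, coords,
              replica = rep(replica, nf),
              time = unlist(lapply(nf, function(n) (seq_len(n) - 1) * dt)))
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ensemble an `md_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  a <- ensemble$reference$atoms
  xyz <- ensemble_xyz(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(xyz))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety),
      a$resname, a$chain, a$resid, m[, 1L], m[, 2L], m[, 3L], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write an ensemble to a DCD trajectory file
#'
#' Single-precision CHARMM-convention DCD (no unit cell), readable by
#' standard trajectory tools.
#'
#' @param ensemble an `md_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(ensemble, path) {
  co <- ensemble$coords
  A <- dim(co)[1L]; nf <- dim(co)[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  # header record: "CORD" + 20 control ints (slot 10 is a float; slot 20
  # marks the CHARMM dialect)
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wint(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(1, con, size = 4L, endian = "little")  # timestep placeholder
  wint(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84L)
  title <- formatC("Created by allodyn::write_dcd", width = -80L)
  wint(84L); wint(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wint(84L)
  wint(4L); wint(A); wint(4L)
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      wint(4L * A)
      writeBin(as.numeric(co[, ax, f]), con, size = 4L, endian = "little")
      wint(4L * A)
    }
  }
  invisible(path)
}

# ---- selections -----------------------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Select atoms of a structure
#'
#' Deterministic: indices are always returned in input atom order, so the
#' same rule on the same structure yields the same selection.
#'
#' @param structure an `md_structure`.
#' @param rule one of `"calpha"`, `"backbone"`, `"sidechain"`, `"all"`,
#'   `"resid"`.
#' @param resid residue filter applied on top of `rule` (also the payload of
#'   `rule = "resid"`): integer vector of author residue ids, or a range
#'   string such as `"10-12,30-40"`.
#' @param chain optional chain filter.
#' @param invert select the complement of the atom set the rule matched.
#' @param label label stored on the selection (defaults to the rule).
#' @return object of class `md_selection`: ordered atom indices + label.
#' @export
select_atoms <- function(structure, rule = "all", resid = NULL,
                         chain = NULL, invert = FALSE, label = NULL) {
  a <- structure$atoms
  keep <- switch(rule,
    all = rep(TRUE, nrow(a)),
    calpha = a$elety == "CA",
    backbone = a$elety %in% BACKBONE_ATOMS,
    sidechain = !(a$elety %in% BACKBONE_ATOMS),
    resid = rep(TRUE, nrow(a)),
    stop("unknown selection rule: ", rule))
  if (!is.null(resid)) keep <- keep & a$resid %in% parse_resid(resid)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (invert) keep <- !keep
  inds <- which(keep)
  if (length(inds) == 0L)
    stop("empty selection for rule '", rule, "'",
         if (!is.null(resid)) paste0(" with resid ",
                                     paste(resid, collapse = ",")))
  structure(list(inds = inds,
                 label = label %||% rule),
            class = "md_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a residue-range string
#'
#' @param x integer vector (returned as-is) or string like `"10-12,30,40-45"`.
#' @return integer vector of residue ids.
#' @export
parse_resid <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(gsub("\\s", "", x), ",")[[1L]]
  out <- lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1L]])
      seq(ab[1L], ab[2L])
    } else as.integer(p)
  })
  unlist(out)
}

#' @export
print.md_selection <- function(x, ...) {
  cat(sprintf("md_selection '%s': %d atoms\n", x$label, length(x$inds)))
  invisible(x)
}

#' Heuristic secondary-structure assignment from Calpha geometry
#'
#' A dihedral-free heuristic for when no assignment is supplied: residue i
#' is called helix when the Ca(i)-Ca(i+4) distance falls in the canonical
#' alpha-helical window, strand when Ca(i)-Ca(i+2) is extended. Users with a
#' reference assignment should pass residue ranges instead.
#'
#' @param structure an `md_structure` (needs a CA atom per residue).
#' @return character vector per residue: `"H"`, `"E"` or `"C"`.
#' @export
assign_sse <- function(structure) {
  ca <- select_atoms(structure, "calpha")
  xyz <- structure$xyz[ca$inds, , drop = FALSE]
  n <- nrow(xyz)
  d_k <- function(k) {
    if (n <= k) return(numeric(0))
    sqrt(rowSums((xyz[seq_len(n - k) + k, , drop = FALSE] -
                  xyz[seq_len(n - k), , drop = FALSE])^2))
  }
  d2 <- d_k(2L); d4 <- d_k(4L)
  sse <- rep("C", n)
  for (i in seq_len(n)) {
    h <- i <= length(d4) && d4[i] >= 4.9 && d4[i] <= 6.7
    e <- i <= length(d2) && d2[i] >= 6.3
    sse[i] <- if (h) "H" else if (e) "E" else "C"
  }
  sse
}

# ---- superposition --------------------------------------------------------

#' Least-squares superposition of an ensemble onto a reference
#'
#' Each frame is rigid-body transformed (rotation + translation) to minimise
#' the RMSD of the fit selection to the reference; all atoms move with the
#' fitted transform. Returns a new ensemble; the input is unmodified.
#'
#' @param ensemble an `md_ensemble`.
#' @param fit an `md_selection` with at least 3 atoms.
#' @param reference `NULL` (use the first frame) or an `md_structure`.
#' @return a superposed `md_ensemble`.
#' @export
superpose <- function(ensemble, fit, reference = NULL) {
  stopifnot(inherits(fit, "md_selection"))
  if (length(fit$inds) < 3L)
    stop("rotation under-determined: fit selection has fewer than 3 atoms")
  xyz <- ensemble_xyz(ensemble)
  ref <- if (is.null(reference)) xyz[1L, ] else as.vector(t(reference$xyz))
  if (length(ref) != ncol(xyz)) stop("reference atom count mismatch")
  k <- bio3d::atom2xyz(fit$inds)
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                           fixed.inds = k, mobile.inds = k)
  md_ensemble(ensemble$reference, xyz_to_coords(fitted),
              replica = ensemble$replica, time = ensemble$time)
}
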