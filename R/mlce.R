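# Matrix of Local Coupling Energies (MLCE).
#
# A symmetric residue-pair non-bonded interaction-energy matrix M is
# eigendecomposed, M = sum_a lambda_a v_a v_a'; the most negative
# eigenvalues carry the dominant stabilising couplings. A low-rank
# reconstruction over those components, Hadamard-masked by a Calpha contact
# matrix, yields the local coupling map. The strongest contiguous couplings
# mark the energetic folding core; the weakest mark soft spots (candidate
# interface / unfolding-prone regions).

#' Construct / validate an energy matrix
#'
#' @param values N x N numeric matrix (kcal/mol). Symmetrised on input;
#'   asymmetry beyond `tol` draws a warning.
#' @param labels residue label data.frame (`chain`, `resid`); defaults to
#'   chain A, 1..N.
#' @param tol symmetry tolerance (kcal/mol).
#' @return object of class `energy_matrix` (a matrix with a `labels`
#'   attribute).
#' @export
energy_matrix <- function(values, labels = NULL, tol = 1e-6) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("energy matrix must be square")
  if (!all(is.finite(values))) stop("non-finite energy entries")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    warning(sprintf("energy matrix asymmetric by %.3g kcal/mol; symmetrising",
                    asym))
  values <- (values + t(values)) / 2
  if (is.null(labels))
    labels <- data.frame(chain = "A", resid = seq_len(nrow(values)),
                         stringsAsFactors = FALSE)
  stopifnot(nrow(labels) == nrow(values))
  structure(values, labels = labels, class = c("energy_matrix", "matrix"))
}

#' Read a residue-labelled symmetric energy matrix from TSV
#'
#' Expects the layout written by [write_energy_matrix()]: a `residue`
#' column of chain+resid tags and one labelled column per residue.
#'
#' @param path TSV file.
#' @return an `energy_matrix`.
#' @export
read_energy_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tags <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  chain <- sub("^([A-Za-z]+).*", "\\1", tags)
  resid <- as.integer(sub("^[A-Za-z]+", "", tags))
  energy_matrix(m, data.frame(chain = chain, resid = resid,
                              stringsAsFactors = FALSE))
}

#' Write an energy matrix as residue-labelled TSV
#' @param em an `energy_matrix`; @param path output file.
#' @export
write_energy_matrix <- function(em, path) {
  write_matrix_tsv(unclass(em), attr(em, "labels"), path)
}

#' Calpha contact matrix of a structure
#'
#' C_ij = 1 when residues i and j (i != j) have their Calpha atoms within
#' `cutoff` Angstrom (closed interval: a pair at exactly the cutoff is a
#' contact; only pairs strictly farther are 0). Diagonal is 0.
#'
#' @param structure an `md_structure`.
#' @param selection an `md_selection` with one Calpha per residue; default
#'   selects all CA atoms.
#' @param cutoff Angstrom (default 6).
#' @return object of class `contact_matrix` (binary matrix, `cutoff` and
#'   `labels` attributes).
#' @export
build_contact_matrix <- function(structure, selection = NULL, cutoff = 6) {
  if (is.null(selection)) selection <- select_atoms(structure, "calpha")
  rid <- residue_index(structure)
  covered <- unique(rid[selection$inds])
  missing <- setdiff(seq_len(max(rid)), covered)
  if (length(missing) > 0L) {
    lab <- residue_labels(structure)
    stop("no Calpha site for residue(s): ",
         paste(paste0(lab$chain[missing], lab$resid[missing]),
               collapse = ", "))
  }
  xyz <- structure$xyz[selection$inds, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  C <- (d <= cutoff) * 1L
  diag(C) <- 0L
  labels <- residue_labels(structure)[rid[selection$inds], , drop = FALSE]
  rownames(labels) <- NULL
  base::structure(C, cutoff = cutoff, labels = labels,
                  class = c("contact_matrix", "matrix"))
}

#' Spectral (low-rank) reconstruction of an energy matrix
#'
#' Eigendecomposes M and rebuilds it from the k components with the most
#' negative eigenvalues (the information-bearing stabilising modes). With
#' `k = "auto"` components are added in ascending-eigenvalue order while
#' the cumulative |lambda| of included negative eigenvalues stays below
#' `energy_fraction` of the total |lambda| over all negative eigenvalues
#' (minimum 1 component) - a deterministic, spectrum-adaptive rule that
#' reduces to the single most negative mode for near-rank-1 spectra.
#'
#' @param em an `energy_matrix`.
#' @param k integer 1..N, or `"auto"`.
#' @param energy_fraction threshold for the auto rule (default 0.85).
#' @return list: `eigenvalues` (ascending), `k`, `reconstructed`
#'   (symmetric N x N), `vectors` (the k eigenvectors used).
#' @export
spectral_reconstruct <- function(em, k = "auto", energy_fraction = 0.85) {
  M <- unclass(em)
  n <- nrow(M)
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values)                      # ascending: most negative first
  lam <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  if (identical(k, "auto")) {
    neg <- lam[lam < 0]
    if (length(neg) == 0L) {
      k <- 1L
    } else {
      total <- sum(abs(neg))
      cum <- cumsum(abs(neg))
      k <- max(1L, sum(cum < energy_fraction * total))
    }
  }
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= n)
  Vk <- V[, seq_len(k), drop = FALSE]
  recon <- Vk %*% (lam[seq_len(k)] * t(Vk))
  recon <- (recon + t(recon)) / 2
  list(eigenvalues = lam, k = k, reconstructed = recon, vectors = Vk)
}

#' Local coupling map: Hadamard mask of a reconstruction by contacts
#'
#' @param reconstructed N x N matrix (from [spectral_reconstruct()]'s
#'   `reconstructed`).
#' @param contacts a `contact_matrix` of matching dimension.
#' @return N x N coupling map, zero wherever contacts are zero.
#' @export
mlce_map <- function(reconstructed, contacts) {
  if (!all(dim(reconstructed) == dim(contacts)))
    stop(sprintf("dimension mismatch: reconstruction %dx%d vs contacts %dx%d",
                 nrow(reconstructed), ncol(reconstructed),
                 nrow(contacts), ncol(contacts)))
  reconstructed * unclass(contacts)
}

#' Extract strongly coupled cores or weakly coupled soft spots
#'
#' Per-residue score = the most negative coupling to any contacting partner
#' (the residue's strongest stabilising interaction). Mode `"core"` keeps
#' the `fraction` of residues with the most negative scores; mode `"soft"`
#' keeps the `fraction` whose strongest coupling is weakest (closest to
#' zero). Ties at the boundary are all included. Kept residues are reported
#' as maximal sequence-contiguous runs of at least `min_run` residues,
#' sorted by mean score (most extreme first).
#'
#' @param map N x N coupling map (from [mlce_map()]).
#' @param contacts the `contact_matrix` used to build it.
#' @param mode `"soft"` or `"core"`.
#' @param fraction tail fraction of residues to keep (0 < fraction < 1).
#' @param min_run minimal run length (default 3).
#' @return data.frame of segments (`start`, `end`, positional indices;
#'   `score`, mean per-residue score), with the per-residue scores and the
#'   kept residue set in attributes `scores` and `residues`. Empty (with a
#'   warning) when nothing survives.
#' @export
extract_segments <- function(map, contacts, mode = c("soft", "core"),
                             fraction = 0.10, min_run = 3L) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(map)
  C <- unclass(contacts)
  score <- vapply(seq_len(n), function(i) {
    j <- which(C[i, ] == 1L)
    if (length(j) == 0L) return(NA_real_)
    min(map[i, j])
  }, 0)
  ok <- which(!is.na(score))
  if (length(ok) == 0L) {
    warning("no residue has any contact; empty result")
    return(empty_segments(score))
  }
  s <- score[ok]
  if (max(s) - min(s) <= 1e-12 * max(1, abs(max(s)))) {
    warning("all per-residue scores tied; no ", mode, " segments reported")
    return(empty_segments(score))
  }
  ntake <- max(1L, ceiling(fraction * length(ok)))
  srt <- sort(s, decreasing = (mode == "soft"))
  thr <- srt[ntake]
  keep <- if (mode == "soft") ok[s >= thr] else ok[s <= thr]
  runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
  segs <- do.call(rbind, lapply(runs, function(r) {
    if (length(r) < min_run) return(NULL)
    data.frame(start = min(r), end = max(r), length = length(r),
               score = mean(score[r]))
  }))
  if (is.null(segs)) {
    warning("no contiguous run of length >= ", min_run,
            " survives; empty result")
    return(empty_segments(score))
  }
  segs <- segs[order(segs$score, decreasing = (mode == "soft")), ,
               drop = FALSE]
  rownames(segs) <- NULL
  attr(segs, "scores") <- score
  attr(segs, "residues") <- sort(unlist(lapply(seq_len(nrow(segs)),
      function(i) seq(segs$start[i], segs$end[i]))))
  segs
}

empty_segments <- function(score) {
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), score = numeric(0))
  attr(out, "scores") <- score
  attr(out, "residues") <- integer(0)
  out
}

#' Full MLCE pipeline on an energy matrix + structure
#'
#' Convenience wrapper: spectral reconstruction, contact masking, and
#' extraction of both the folding core and the soft spots.
#'
#' @param em an `energy_matrix`.
#' @param structure `md_structure` for the contact matrix (or pass
#'   `contacts` directly).
#' @param contacts optional pre-built `contact_matrix`.
#' @param cutoff contact cutoff (A, default 6).
#' @param k eigencomponent count or `"auto"`.
#' @param fraction tail fraction for segment extraction.
#' @param min_run minimal segment length.
#' @return object of class `mlce_result`: `eigenvalues`, `k`,
#'   `reconstructed`, `map`, `contacts`, `core`, `soft`, `labels`.
#' @export
mlce <- function(em, structure = NULL, contacts = NULL, cutoff = 6,
                 k = "auto", fraction = 0.10, min_run = 3L) {
  if (is.null(contacts)) {
    if (is.null(structure)) stop("supply a structure or a contact matrix")
    contacts <- build_contact_matrix(structure, cutoff = cutoff)
  }
  sr <- spectral_reconstruct(em, k = k)
  map <- mlce_map(sr$reconstructed, contacts)
  core <- extract_segments(map, contacts, "core", fraction, min_run)
  soft <- extract_segments(map, contacts, "soft", fraction, min_run)
  base::structure(list(eigenvalues = sr$eigenvalues, k = sr$k,
                 reconstructed = sr$reconstructed, map = map,
                 contacts = contacts, core = core, soft = soft,
                 labels = attr(em, "labels")),
            class = "mlce_result")
}

#' @export
print.mlce_result <- function(x, ...) {
  cat(sprintf("mlce_result: %d residues, k = %d of %d eigencomponents\n",
              nrow(x$map), x$k, length(x$eigenvalues)))
  cat(sprintf("  core segments: %d; soft segments: %d\n",
              nrow(x$core), nrow(x$soft)))
  invisible(x)
}

#' Write MLCE segments as a BED-like TSV
#'
#' Tab-separated `chain`, `start_resid`, `end_resid`, `length`, `score`
#' using author residue numbering via the result's label map.
#'
#' @param segments segment data.frame from [extract_segments()].
#' @param labels residue label data.frame.
#' @param path output file.
#' @export
write_segments_tsv <- function(segments, labels, path) {
  out <- data.frame(
    chain = if (nrow(segments)) labels$chain[segments$start] else character(0),
    start_resid = if (nrow(segments)) labels$resid[segments$start] else integer(0),
    end_resid = if (nrow(segments)) labels$resid[segments$end] else integer(0),
    length = segments$length,
    score = if (nrow(segments)) sprintf("%.6f", segments$score) else character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
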