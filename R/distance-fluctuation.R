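# Distance-fluctuation (DF) analysis.
#
# DF_ij is the variance over frames of the inter-site (Calpha-Calpha)
# distance d_ij: low DF = the pair moves quasi-rigidly (high allosteric
# coordination), high DF = uncoordinated motion. Because d_ij is an internal
# coordinate, DF is invariant to any per-frame rigid-body motion; no
# superposition is required (or harmful).

#' Compute the residue-pair distance-fluctuation matrix
#'
#' Exact two-pass variance of every pairwise inter-site distance over all
#' frames of the ensemble (metatrajectory): first pass accumulates the mean
#' distance, second the squared deviations. Denominator is the frame count
#' (population variance over the pooled frames).
#'
#' @param ensemble an `md_ensemble` (>= 2 frames).
#' @param selection an `md_selection` mapping one site per residue
#'   (typically `select_atoms(structure, "calpha")`).
#' @param statistic `"variance"` (default, A^2) or `"sd"` (its square root,
#'   A).
#' @return object of class `df_matrix`: symmetric N x N `values` with zero
#'   diagonal, residue `labels`, `nframes`, and the `statistic` convention
#'   recorded.
#' @export
compute_df <- function(ensemble, selection, statistic = c("variance", "sd")) {
  statistic <- match.arg(statistic)
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("distance variance undefined for fewer than 2 frames")
  co <- ensemble$coords[selection$inds, , , drop = FALSE]
  n <- dim(co)[1L]
  mean_d <- matrix(0, n, n)
  for (f in seq_len(nf))
    mean_d <- mean_d + as.matrix(stats::dist(co[, , f]))
  mean_d <- mean_d / nf
  ss <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    dev <- as.matrix(stats::dist(co[, , f])) - mean_d
    ss <- ss + dev * dev
  }
  v <- ss / nf
  diag(v) <- 0
  dimnames(v) <- NULL
  if (statistic == "sd") v <- sqrt(v)
  labels <- residue_labels(ensemble$reference)[
    residue_index(ensemble$reference)[selection$inds], , drop = FALSE]
  rownames(labels) <- NULL
  structure(list(values = v, labels = labels, nframes = nf,
                 statistic = statistic),
            class = "df_matrix")
}

#' @export
print.df_matrix <- function(x, ...) {
  cat(sprintf("df_matrix: %d residues, %d frames, statistic = %s\n",
              nrow(x$values), x$nframes, x$statistic))
  invisible(x)
}

#' Block-average a DF matrix
#'
#' Coarse-grains the N x N matrix into ceiling(N / block_size)^2 blocks,
#' each holding the arithmetic mean of the residue pairs it covers (a
#' 40-residue block thus averages 1600 pairs). Trailing partial blocks are
#' averaged over their actual entry count, not padded.
#'
#' @param df a `df_matrix`.
#' @param block_size residues per block (default 40).
#' @return object of class `block_df_matrix`: B x B `values`, `block_size`,
#'   residue-range `block_labels`; the quantized view is `NULL` until
#'   [quantize_df()] fills it.
#' @export
block_average <- function(df, block_size = 40L) {
  stopifnot(block_size >= 1L)
  v <- df$values
  n <- nrow(v)
  grp <- ceiling(seq_len(n) / block_size)
  B <- max(grp)
  cnt <- tabulate(grp, B)
  s <- rowsum(v, grp, reorder = TRUE)          # B x n
  s <- t(rowsum(t(s), grp, reorder = TRUE))    # B x B
  vals <- unname(s / outer(cnt, cnt))
  lab <- vapply(seq_len(B), function(b) {
    r <- range(which(grp == b))
    sprintf("%d-%d", r[1L], r[2L])
  }, "")
  structure(list(values = vals, block_size = as.integer(block_size),
                 block_labels = lab, quantized = NULL, levels = NULL,
                 statistic = df$statistic),
            class = "block_df_matrix")
}

#' Quantize a block-averaged DF matrix into discrete shades
#'
#' Bins the block values into `levels` equal-width intervals spanning the
#' observed [min, max]; the maximum maps to the top level. Mirrors the
#' few-shade rendering used for coarse DF maps. A degenerate (constant)
#' matrix maps entirely to level 0.
#'
#' @param block a `block_df_matrix`.
#' @param levels number of shades (>= 2, default 5).
#' @return the input with `quantized` (integer levels in 0..levels-1) and
#'   `levels` filled.
#' @export
quantize_df <- function(block, levels = 5L) {
  stopifnot(levels >= 2L)
  v <- block$values
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0) {
    q <- matrix(0L, nrow(v), ncol(v))
  } else {
    width <- (hi - lo) / levels
    q <- pmin(as.integer(floor((v - lo) / width)), levels - 1L)
    q <- matrix(as.integer(q), nrow(v), ncol(v))
  }
  block$quantized <- q
  block$levels <- as.integer(levels)
  block
}

#' Difference between two DF matrices (state A minus state B)
#'
#' Positive entries mark pairs whose coordination is weaker (larger DF) in
#' state `a` than in state `b`; the result is antisymmetric under swapping
#' the arguments.
#'
#' @param a,b `df_matrix` objects over identical residue labels.
#' @return signed N x N matrix (same units as the inputs).
#' @export
df_difference <- function(a, b) {
  la <- paste(a$labels$chain, a$labels$resid)
  lb <- paste(b$labels$chain, b$labels$resid)
  if (length(la) != length(lb))
    stop(sprintf("residue label counts differ: %d vs %d",
                 length(la), length(lb)))
  if (any(la != lb)) {
    bad <- which(la != lb)[1L]
    stop(sprintf("residue labels disagree at position %d: '%s' vs '%s'",
                 bad, la[bad], lb[bad]))
  }
  if (a$statistic != b$statistic) stop("DF statistic conventions differ")
  a$values - b$values
}

#' Per-residue DF coordination profile
#'
#' Row means of the DF matrix excluding the diagonal: the average
#' coordination of each residue with every other residue (or with a named
#' partner subset, for queries like "coordination with the client").
#'
#' @param df a `df_matrix`.
#' @param partners optional integer positional indices of the partner
#'   subset to average over; `NULL` averages over all other residues.
#' @return numeric vector of length N.
#' @export
df_profile <- function(df, partners = NULL) {
  v <- df$values
  n <- nrow(v)
  if (is.null(partners)) {
    return((rowSums(v)) / (n - 1L))
  }
  partners <- as.integer(partners)
  if (length(partners) == 0L) stop("partner subset is empty")
  stopifnot(all(partners >= 1L), all(partners <= n))
  vapply(seq_len(n), function(i) {
    p <- setdiff(partners, i)
    if (length(p) == 0L) return(0)
    mean(v[i, p])
  }, 0)
}

#' Write a labelled DF (or any residue x residue) matrix as TSV
#'
#' @param values matrix; @param labels residue label data.frame
#'   (chain/resid); @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(values, labels, path) {
  tag <- paste0(labels$chain, labels$resid)
  df <- data.frame(residue = tag, values, check.names = FALSE)
  colnames(df) <- c("residue", tag)
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
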