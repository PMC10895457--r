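# Ensemble descriptors and conformational-family clustering.

#' Per-frame RMSD time series against a reference structure
#'
#' Each frame is least-squares superposed on the fit selection to the
#' reference, then the RMSD is measured over the measure selection (which
#' may differ, e.g. fit on ordered secondary structure, measure a
#' disordered region).
#'
#' @param ensemble an `md_ensemble`.
#' @param fit `md_selection` used for superposition (>= 3 atoms).
#' @param measure `md_selection` the RMSD is computed over; defaults to
#'   `fit`.
#' @param reference `md_structure`; defaults to the ensemble's reference.
#' @return object of class `rmsd_series`: numeric per-frame `values` (A)
#'   plus replica/time bookkeeping.
#' @export
rmsd_series <- function(ensemble, fit, measure = fit, reference = NULL) {
  if (is.null(reference)) reference <- ensemble$reference
  if (nrow(reference$xyz) != dim(ensemble$coords)[1L])
    stop("reference atom count does not match the ensemble")
  fitted <- superpose(ensemble, fit, reference = reference)
  ref <- reference$xyz[measure$inds, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(fitted)), function(f) {
    x <- fitted$coords[measure$inds, , f]
    sqrt(mean(rowSums((x - ref)^2)))
  }, 0)
  base::structure(list(values = vals, replica = ensemble$replica,
                       time = ensemble$time, fit = fit$label,
                       measure = measure$label),
                  class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series: %d frames, fit '%s', measure '%s', mean %.3f A\n",
              length(x$values), x$fit, x$measure, mean(x$values)))
  invisible(x)
}

#' Per-residue RMSF against the ensemble-average structure
#'
#' Frames are superposed (on the given selection) onto their running
#' average structure - one alignment pass to the first frame to build the
#' average, then a second pass onto that average - and RMSF_r is the root
#' mean squared displacement of each site from its average position.
#'
#' @param ensemble an `md_ensemble` (>= 2 frames).
#' @param selection one site per residue (typically Calpha).
#' @return numeric vector of per-residue RMSF (A).
#' @export
rmsf_profile <- function(ensemble, selection) {
  if (n_frames(ensemble) < 2L) stop("RMSF undefined for fewer than 2 frames")
  # initial alignment to the ensemble reference, not the first frame, so
  # the result does not depend on frame order
  e1 <- superpose(ensemble, selection, reference = ensemble$reference)
  avg <- apply(e1$coords, c(1L, 2L), mean)
  ref <- e1$reference
  ref$xyz <- avg
  e2 <- superpose(e1, selection, reference = ref)
  avg2 <- apply(e2$coords[selection$inds, , , drop = FALSE],
                c(1L, 2L), mean)
  dev2 <- sweep(e2$coords[selection$inds, , , drop = FALSE],
                c(1L, 2L), avg2)
  sqrt(apply(dev2^2, 1L, function(m) mean(colSums(matrix(m, nrow = 3L)))))
}

#' Cluster an ensemble into conformational families
#'
#' The protocol for isolating families of a disordered region: frames are
#' first aligned on the ordered (secondary-structure) selection, then
#' pairwise RMSD over the disordered selection - without refitting - feeds
#' average-linkage hierarchical agglomeration. The cluster count is chosen
#' to maximise the mean silhouette width over the candidate range (ties
#' broken toward fewer clusters); each cluster is represented by its medoid
#' frame.
#'
#' @param ensemble an `md_ensemble`.
#' @param align_sel ordered-region selection used for superposition.
#' @param cluster_sel disordered-region selection the RMSD is computed on.
#' @param k_candidates integer candidate cluster counts (default 2:10,
#'   clipped to F - 1).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return object of class `cluster_model`: `k`, `assignment` (per frame),
#'   `medoids` (frame indices), `silhouette` (named per candidate K),
#'   `rmsd` (frame x frame matrix).
#' @export
cluster_conformations <- function(ensemble, align_sel, cluster_sel,
                                  k_candidates = 2:10,
                                  linkage = c("average", "single",
                                              "complete")) {
  linkage <- match.arg(linkage)
  nf <- n_frames(ensemble)
  aligned <- superpose(ensemble, align_sel)
  m <- length(cluster_sel$inds)
  flat <- t(apply(aligned$coords[cluster_sel$inds, , , drop = FALSE], 3L,
                  identity))
  dim(flat) <- c(nf, 3L * m)
  d <- stats::dist(flat) / sqrt(m)
  dm <- as.matrix(d)
  if (max(d) < 1e-12) {
    warning("all frames identical over the cluster selection; K = 1")
    return(base::structure(list(k = 1L, assignment = rep(1L, nf),
                                medoids = 1L,
                                silhouette = stats::setNames(numeric(0),
                                                             character(0)),
                                rmsd = dm, linkage = linkage),
                           class = "cluster_model"))
  }
  k_candidates <- k_candidates[k_candidates >= 2L & k_candidates <= nf - 1L]
  if (length(k_candidates) == 0L) stop("no admissible candidate K")
  hc <- stats::hclust(d, method = linkage)
  sil <- vapply(k_candidates, function(k) {
    cl <- stats::cutree(hc, k = k)
    if (length(unique(cl)) < 2L) return(NA_real_)
    mean(cluster::silhouette(cl, dmatrix = dm)[, 3L])
  }, 0)
  names(sil) <- k_candidates
  best <- k_candidates[which.max(sil)]   # which.max takes the first maximum
  assignment <- stats::cutree(hc, k = best)
  medoids <- vapply(seq_len(best), function(cid) {
    members <- which(assignment == cid)
    members[which.min(rowSums(dm[members, members, drop = FALSE]))]
  }, 1L)
  base::structure(list(k = as.integer(best), assignment = assignment,
                       medoids = medoids, silhouette = sil, rmsd = dm,
                       linkage = linkage),
                  class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: K = %d (%s linkage), sizes: %s\n", x$k,
              x$linkage, paste(tabulate(x$assignment, x$k), collapse = ",")))
  if (length(x$silhouette))
    cat("  mean silhouette by K: ",
        paste(sprintf("%s:%.3f", names(x$silhouette), x$silhouette),
              collapse = "  "), "\n", sep = "")
  invisible(x)
}
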