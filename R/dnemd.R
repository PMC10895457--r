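# Dynamical non-equilibrium MD (D-NEMD) response analysis.
#
# Many short perturbed runs are branched off an equilibrium trajectory; the
# Kubo-Onsager subtraction computes the system's response as the average,
# over all branch pairs, of the per-residue Calpha deviation between the
# perturbed run and its unperturbed continuation at equivalent relative
# times. Averaging over pairs cancels the intrinsic fluctuations shared by
# both members, isolating the perturbation's effect.

#' Select branch-point frames from an equilibrium ensemble
#'
#' Per replica, keeps the frames whose time stamp sits on the grid
#' `discard + k * interval` (k = 1, 2, ...). The schedule is data-driven
#' over the frames actually present: the count is however many grid stamps
#' each replica's sampling covers, never a hard-coded number.
#'
#' @param ensemble an `md_ensemble` with replica labels and time stamps.
#' @param discard equilibration span to drop at the start of each replica
#'   (ns, default 100).
#' @param interval branch spacing (ns, default 20; > 0).
#' @param tol time-matching tolerance (ns).
#' @return data.frame with `replica`, `frame` (index into the ensemble) and
#'   `time` (ns), ordered by replica then time.
#' @export
extract_branch_points <- function(ensemble, discard = 100, interval = 20,
                                  tol = 1e-6) {
  stopifnot(interval > 0)
  out <- NULL
  for (r in unique(ensemble$replica)) {
    idx <- which(ensemble$replica == r)
    tt <- ensemble$time[idx]
    if (max(tt) <= discard)
      stop(sprintf("replica %s (%.6g ns) is not longer than the %.6g ns discard",
                   r, max(tt), discard))
    kmax <- floor((max(tt) - discard) / interval + tol)
    if (kmax < 1L) next
    grid <- discard + seq_len(kmax) * interval
    hit <- vapply(grid, function(g) {
      j <- which.min(abs(tt - g))
      if (abs(tt[j] - g) <= tol) idx[j] else NA_integer_
    }, 1L)
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0L)
      out <- rbind(out, data.frame(replica = r, frame = hit,
                                   time = ensemble$time[hit],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out) || nrow(out) == 0L)
    stop("no frame survives the branch-point schedule (discard ",
         discard, " ns, interval ", interval, " ns)")
  rownames(out) <- NULL
  out
}

#' Kubo-Onsager response profile from a paired run set
#'
#' For every residue r and relative time t: the mean over pairs of the
#' Euclidean deviation |x_perturbed(r, t) - x_unperturbed(r, t)|, with the
#' across-pair standard error. By default each perturbed frame is first
#' least-squares superposed onto its paired unperturbed frame over all
#' sites, removing rigid-body drift.
#'
#' @param pairs a `paired_run_set` (see [make_paired_dnemd_set()]) or any
#'   list with the same shape.
#' @param superpose_first superpose each perturbed frame onto its paired
#'   unperturbed frame before subtracting (default `TRUE`).
#' @param metric `"mean_norm"` (default: mean over pairs of per-residue
#'   deviation norms, the established D-NEMD practice) or `"norm_mean"`
#'   (norm of the mean displacement vector, for sensitivity checks).
#' @return object of class `response_profile`: `deviation` and `se`
#'   (N x T, Angstrom), `times`, `npairs`, `labels`, and the options used.
#' @export
compute_response <- function(pairs, superpose_first = TRUE,
                             metric = c("mean_norm", "norm_mean")) {
  metric <- match.arg(metric)
  pl <- pairs$pairs
  if (length(pl) < 1L) stop("need at least one run pair")
  nt <- length(pairs$times)
  n <- dim(pl[[1L]]$unperturbed)[1L]
  for (p in pl) {
    if (!identical(dim(p$unperturbed), dim(p$perturbed)) ||
        dim(p$unperturbed)[3L] != nt)
      stop("pair members do not cover the common relative time grid")
  }
  np <- length(pl)
  if (metric == "mean_norm") {
    dpair <- array(0, dim = c(n, nt, np))
    for (pi in seq_len(np)) {
      p <- pl[[pi]]
      for (ti in seq_len(nt)) {
        xu <- p$unperturbed[, , ti]
        xp <- p$perturbed[, , ti]
        if (superpose_first) xp <- kabsch_fit(xp, xu)
        dpair[, ti, pi] <- sqrt(rowSums((xp - xu)^2))
      }
    }
    # sorted accumulation: the profile is bit-identical under pair reorder
    dev <- apply(dpair, c(1L, 2L), function(d) sum(sort(d))) / np
    se <- if (np > 1L) {
      ssq <- apply(dpair, c(1L, 2L), function(d) sum(sort(d * d)))
      sqrt(pmax(0, (ssq - np * dev^2) / (np - 1L))) / sqrt(np)
    } else matrix(NA_real_, n, nt)
  } else {
    sum_v <- array(0, dim = c(n, 3L, nt))
    for (p in pl) {
      for (ti in seq_len(nt)) {
        xu <- p$unperturbed[, , ti]
        xp <- p$perturbed[, , ti]
        if (superpose_first) xp <- kabsch_fit(xp, xu)
        sum_v[, , ti] <- sum_v[, , ti] + (xp - xu)
      }
    }
    dev <- apply(sum_v / np, c(1L, 3L), function(v) sqrt(sum(v^2)))
    se <- matrix(NA_real_, n, nt)
  }
  structure(list(deviation = dev, se = se, times = pairs$times,
                 npairs = np, labels = pairs$labels,
                 superpose_first = superpose_first, metric = metric),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf(
    "response_profile: %d residues x %d times, %d pairs (metric %s)\n",
    nrow(x$deviation), length(x$times), x$npairs, x$metric))
  invisible(x)
}

# direct Kabsch superposition of one coordinate set onto another (N x 3);
# an exactly-identical pair short-circuits so a null perturbation stays an
# exact zero rather than picking up rotation round-off
kabsch_fit <- function(mobile, fixed) {
  if (identical(mobile, fixed)) return(fixed)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(A %*% R, 2L, cf, `+`)
}

#' Per-residue response at one time point
#'
#' Extracts the response column nearest the requested time (warning if not
#' an exact grid point) and, when a structure is supplied, returns it with
#' the response written into the B-factor column for 3-D rendering.
#'
#' @param profile a `response_profile`.
#' @param time requested relative time (ns), within the grid range.
#' @param structure optional `md_structure` with one residue per profile
#'   row.
#' @return list with `time` (the grid time used), `values` (length-N), and
#'   `structure` (B-factor-annotated copy, or `NULL`).
#' @export
response_snapshot <- function(profile, time, structure = NULL) {
  tt <- profile$times
  if (time < min(tt) - 1e-9 || time > max(tt) + 1e-9)
    stop(sprintf("time %.6g ns outside the response grid [%.6g, %.6g]",
                 time, min(tt), max(tt)))
  j <- which.min(abs(tt - time))
  if (abs(tt[j] - time) > 1e-9)
    warning(sprintf("time %.6g ns not on the grid; using nearest %.6g ns",
                    time, tt[j]))
  values <- profile$deviation[, j]
  out_struct <- NULL
  if (!is.null(structure)) {
    if (n_residues(structure) != length(values))
      stop("structure residue count does not match the profile")
    out_struct <- structure
    attr(out_struct, "bfactor") <- values[residue_index(structure)]
  }
  list(time = tt[j], values = values, structure = out_struct)
}

#' Write a response profile as TSV (residues x times)
#'
#' @param profile a `response_profile`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_response_tsv <- function(profile, path) {
  df <- data.frame(residue = paste0(profile$labels$chain,
                                    profile$labels$resid),
                   profile$deviation, check.names = FALSE)
  colnames(df) <- c("residue", sprintf("t%.6g", profile$times))
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
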