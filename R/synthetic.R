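# Synthetic ensembles with analytically known statistics.
#
# One pseudo-atom per residue (Calpha-like). Frames are i.i.d. draws from a
# Gaussian network: displacement covariance = sigma^2 * pseudo-inverse of the
# stiffness-weighted graph Laplacian (the elastic-network convention). This
# is a statistical emulator, not a physics simulator: every property the
# analyses consume (distance variances, planted responses, planted energetic
# couplings) is known in closed form.

#' Define a harmonic (elastic-network) ensemble model
#'
#' @param ref N x 3 reference coordinates (Angstrom), one site per residue.
#' @param springs data.frame with columns `i`, `j`, `k`: site pairs and
#'   their stiffness (kcal/mol/A^2, >= 0). The graph is symmetrised.
#' @param sigma site noise scale in Angstrom (> 0); the displacement
#'   covariance is `sigma^2 * pinv(Laplacian)` per axis.
#' @param restraint optional weak global restraint added to the Laplacian
#'   diagonal; needed only when the spring graph is disconnected.
#' @param seed default seed used by samplers when none is given.
#' @return object of class `harmonic_model`.
#' @export
harmonic_model <- function(ref, springs, sigma = 0.5, restraint = 0,
                           seed = 1L) {
  ref <- as.matrix(ref)
  stopifnot(ncol(ref) == 3L, sigma > 0, all(springs$k >= 0),
            restraint >= 0)
  n <- nrow(ref)
  stopifnot(all(springs$i >= 1L), all(springs$j <= n),
            all(springs$i != springs$j))
  structure(list(ref = unname(ref), springs = springs, sigma = sigma,
                 restraint = restraint, seed = seed, n = n),
            class = "harmonic_model")
}

# stiffness-weighted Laplacian (+ restraint on the diagonal)
model_laplacian <- function(model) {
  n <- model$n
  L <- matrix(0, n, n)
  s <- model$springs
  for (r in seq_len(nrow(s))) {
    i <- s$i[r]; j <- s$j[r]; k <- s$k[r]
    L[i, j] <- L[i, j] - k
    L[j, i] <- L[j, i] - k
    L[i, i] <- L[i, i] + k
    L[j, j] <- L[j, j] + k
  }
  L + diag(model$restraint, n)
}

# eigen-factor of the displacement distribution; errors on disconnection
model_factor <- function(model) {
  L <- model_laplacian(model)
  e <- eigen(L, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  zero <- e$values < tol
  if (model$restraint == 0 && sum(zero) > 1L)
    stop("coupling graph is disconnected: displacement covariance is ",
         "ill-defined (enable a global restraint)")
  keep <- !zero
  list(V = e$vectors[, keep, drop = FALSE],
       lambda = e$values[keep])
}

#' Per-axis displacement covariance implied by a harmonic model
#'
#' @param model a `harmonic_model`.
#' @return N x N covariance matrix (A^2) of site displacements along one
#'   Cartesian axis (axes are i.i.d.).
#' @export
model_covariance <- function(model) {
  f <- model_factor(model)
  model$sigma^2 * f$V %*% (t(f$V) / f$lambda)
}

#' Per-axis displacement variance of each site
#' @param model a `harmonic_model`.
#' @return numeric vector of length N (A^2, per axis).
#' @export
expected_site_variance <- function(model) diag(model_covariance(model))

# draw N x 3 x F displacements; Z optionally supplied for shared-noise runs
draw_displacements <- function(model, frames, Z = NULL) {
  f <- model_factor(model)
  m <- length(f$lambda)
  if (is.null(Z)) Z <- array(stats::rnorm(m * 3L * frames),
                             dim = c(m, 3L, frames))
  Tm <- model$sigma * f$V %*% diag(1 / sqrt(f$lambda), m)
  D <- Tm %*% matrix(Z, nrow = m)            # n x (3 * frames)
  array(D, dim = c(model$n, 3L, frames))
}

#' Sample an equilibrium ensemble from a harmonic model
#'
#' Frames are independent draws (time stamps are bookkeeping, not dynamics);
#' replicas differ only by their RNG substream. Bit-identical under the same
#' seed.
#'
#' @param model a `harmonic_model`.
#' @param frames frames per replica (>= 1).
#' @param replicas number of replicas (>= 1).
#' @param seed RNG seed; defaults to the model's.
#' @param dt sampling interval in ns; frame k of a replica is stamped
#'   (k - 1) * dt.
#' @return an `md_ensemble` over Calpha-like sites.
#' @export
sample_harmonic_ensemble <- function(model, frames, replicas = 1L,
                                     seed = model$seed, dt = 20) {
  stopifnot(frames >= 1L, replicas >= 1L)
  set.seed(seed)
  nf <- frames * replicas
  disp <- draw_displacements(model, nf)
  coords <- array(rep(t(model$ref), nf), dim = c(3L, model$n, nf))
  coords <- aperm(coords, c(2L, 1L, 3L)) + disp
  md_ensemble(synthetic_structure(model$ref), coords,
              replica = rep(paste0("r", seq_len(replicas)), each = frames),
              time = rep((seq_len(frames) - 1) * dt, replicas))
}

#' Build a one-site-per-residue structure from coordinates
#'
#' @param coords N x 3 matrix.
#' @param chain chain id (recycled over residues).
#' @return an `md_structure` of CA pseudo-atoms, residues numbered 1..N.
#' @export
synthetic_structure <- function(coords, chain = "A") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  md_structure(data.frame(chain = rep(chain, length.out = n),
                          resid = seq_len(n), resname = "ALA",
                          elety = "CA", stringsAsFactors = FALSE),
               coords)
}

#' Ideal alpha-helical Calpha trace
#' @param n number of residues.
#' @return n x 3 coordinate matrix (2.3 A radius, 1.5 A rise, 100 deg turn).
#' @export
helix_coords <- function(n) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n) - 1))
}

#' Compact random Calpha trace (globule)
#'
#' A 3.8-A-bond random walk softly confined to a sphere, giving a compact
#' chain with a realistic contact density for contact-matrix tests.
#'
#' @param n residues; @param seed RNG seed; @param radius confinement radius
#'   (defaults to ~3 * n^(1/3)).
#' @return n x 3 coordinate matrix.
#' @export
globule_coords <- function(n, seed = 1L, radius = NULL) {
  if (is.null(radius)) radius <- 3 * n^(1 / 3)
  set.seed(seed)
  x <- matrix(0, n, 3L)
  for (i in 2:n) {
    repeat {
      u <- stats::rnorm(3L)
      cand <- x[i - 1L, ] + 3.8 * u / sqrt(sum(u^2))
      if (sqrt(sum(cand^2)) <= radius || stats::runif(1L) < 0.05) break
    }
    x[i, ] <- cand
  }
  x
}

# ---- spring-graph builders ------------------------------------------------

#' Chain springs between sequence neighbours
#' @param n sites; @param k stiffness; @param sep neighbour separations to
#'   connect (default 1:2 keeps the chain stiff but flexible).
#' @return springs data.frame.
#' @export
springs_chain <- function(n, k = 5, sep = 1:2) {
  do.call(rbind, lapply(sep, function(s) {
    if (n <= s) return(NULL)
    data.frame(i = seq_len(n - s), j = seq_len(n - s) + s, k = k)
  }))
}

#' Distance-cutoff springs from reference coordinates
#' @param coords N x 3 reference; @param cutoff A; @param k stiffness.
#' @return springs data.frame (i < j pairs within cutoff).
#' @export
springs_contact <- function(coords, cutoff = 8, k = 2) {
  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L], k = k)
}

#' All-pairs springs
#' @param n sites; @param k stiffness.
#' @export
springs_full <- function(n, k = 1) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L], k = k)
}

# ---- paired D-NEMD sets ---------------------------------------------------

#' Generate a paired unperturbed/perturbed run set with known response
#'
#' Emulates the D-NEMD branching protocol: at each branch time an
#' unperturbed continuation and a perturbed run start from the same state.
#' The "same initial velocities" contract of real branched MD is emulated by
#' common random numbers: with `noise_sharing = 1` (default) both members of
#' a pair use identical noise draws, so the perturbed-minus-unperturbed
#' difference is exactly the planted displacement. `noise_sharing = 0` gives
#' fully independent members (the null calibration case); intermediate
#' values mix the two.
#'
#' @param model a `harmonic_model` for the equilibrium dynamics.
#' @param targets integer residue (site) indices receiving the displacement.
#' @param displacement function(t) -> length-3 Angstrom vector applied to
#'   every target site at relative time t (t > onset).
#' @param branch_times numeric vector of branch times (ns); must be
#'   non-empty.
#' @param run_length length of each branched run (ns).
#' @param dt sampling interval of the relative time grid (ns).
#' @param onset relative time at which the perturbation switches on.
#' @param seed RNG seed.
#' @param noise_sharing in [0, 1]; see above.
#' @return object of class `paired_run_set`: `pairs` (each with `unperturbed`
#'   and `perturbed` N x 3 x T arrays and `branch_time`), `times` (relative
#'   grid), `truth` (N x T planted response, A), `labels`, `model`.
#' @export
make_paired_dnemd_set <- function(model, targets, displacement,
                                  branch_times, run_length, dt = 1,
                                  onset = 0, seed = model$seed,
                                  noise_sharing = 1) {
  if (length(branch_times) == 0L) stop("branch_times must be non-empty")
  stopifnot(run_length >= dt, noise_sharing >= 0, noise_sharing <= 1)
  times <- seq(dt, run_length, by = dt)
  nt <- length(times)
  n <- model$n
  set.seed(seed)
  f <- model_factor(model)
  m <- length(f$lambda)
  truth <- matrix(0, n, nt)
  for (ti in seq_len(nt)) {
    if (times[ti] > onset) {
      v <- displacement(times[ti] - onset)
      truth[targets, ti] <- sqrt(sum(v^2))
    }
  }
  pairs <- vector("list", length(branch_times))
  for (p in seq_along(branch_times)) {
    Zu <- array(stats::rnorm(m * 3L * nt), dim = c(m, 3L, nt))
    Zi <- array(stats::rnorm(m * 3L * nt), dim = c(m, 3L, nt))
    Zp <- noise_sharing * Zu + sqrt(1 - noise_sharing^2) * Zi
    du <- draw_displacements(model, nt, Z = Zu)
    dp <- draw_displacements(model, nt, Z = Zp)
    base <- aperm(array(rep(t(model$ref), nt), dim = c(3L, n, nt)),
                  c(2L, 1L, 3L))
    unp <- base + du
    per <- base + dp
    for (ti in seq_len(nt)) {
      if (times[ti] > onset) {
        v <- displacement(times[ti] - onset)
        per[targets, , ti] <- per[targets, , ti] +
          matrix(v, length(targets), 3L, byrow = TRUE)
      }
    }
    pairs[[p]] <- list(unperturbed = unp, perturbed = per,
                       branch_time = branch_times[p])
  }
  structure(list(pairs = pairs, times = times, truth = truth,
                 labels = data.frame(chain = "A", resid = seq_len(n)),
                 targets = targets, model = model,
                 noise_sharing = noise_sharing),
            class = "paired_run_set")
}

#' @export
print.paired_run_set <- function(x, ...) {
  cat(sprintf("paired_run_set: %d pairs, %d sites, %d time points\n",
              length(x$pairs), dim(x$pairs[[1L]]$unperturbed)[1L],
              length(x$times)))
  invisible(x)
}

# ---- planted energy matrices ----------------------------------------------

#' Generate a residue-pair interaction-energy matrix with planted signal
#'
#' Builds a symmetric N x N energy matrix (kcal/mol) with (i) a strongly
#' coupled core block (mean entry -core_strength), (ii) a weakly coupled
#' soft patch whose rows are damped toward zero, and (iii) small symmetric
#' Gaussian background couplings elsewhere. With `background = 0` the matrix
#' is exact: core entries equal -core_strength, everything else 0.
#'
#' @param n residues.
#' @param core integer residue indices of the strongly coupled core.
#' @param core_strength positive, kcal/mol; core entries centre on its
#'   negative.
#' @param soft integer residue indices of the weak patch (disjoint from
#'   `core`).
#' @param background SD of the background couplings (kcal/mol, >= 0).
#' @param soft_scale damping factor applied to every coupling involving a
#'   soft residue.
#' @param seed RNG seed.
#' @return an `energy_matrix` (see [read_energy_matrix()]) with the planted
#'   sets stored in `attr(, "planted")`.
#' @export
make_energy_matrix <- function(n, core, core_strength = 10,
                               soft = integer(0), background = 0.3,
                               soft_scale = 0.05, seed = 1L) {
  if (core_strength <= 0) stop("core_strength must be positive")
  if (length(intersect(core, soft)) > 0L)
    stop("core and soft patch must be disjoint")
  set.seed(seed)
  M <- matrix(0, n, n)
  if (background > 0) {
    up <- upper.tri(M)
    M[up] <- stats::rnorm(sum(up), sd = background)
    M <- M + t(M)
  }
  off <- outer(core, core, function(i, j) i != j)
  M[core, core][off] <- M[core, core][off] - core_strength
  if (length(soft) > 0L) {
    fac <- rep(1, n)
    fac[soft] <- soft_scale
    damp <- outer(fac, fac, pmin)
    M <- M * damp
  }
  diag(M) <- 0
  labels <- data.frame(chain = "A", resid = seq_len(n),
                       stringsAsFactors = FALSE)
  em <- energy_matrix(M, labels)
  attr(em, "planted") <- list(core = sort(core), soft = sort(soft),
                              core_strength = core_strength,
                              background = background, seed = seed)
  em
}
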