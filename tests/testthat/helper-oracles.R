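# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Horn (1987) quaternion superposition: rotate+translate `mobile` onto
# `fixed` (both N x 3), least squares.
oracle_superpose <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  S <- crossprod(A, B)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
  sweep(A %*% t(R), 2, cf, `+`)
}

oracle_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# naive per-frame double-loop distance-variance matrix (population)
oracle_df <- function(coords) {
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- numeric(nf)
    for (f in seq_len(nf))
      d[f] <- sqrt(sum((coords[i, , f] - coords[j, , f])^2))
    out[i, j] <- mean((d - mean(d))^2)
  }
  out
}

# naive block averaging incl. partial trailing blocks
oracle_block_average <- function(v, bs) {
  n <- nrow(v); B <- ceiling(n / bs)
  out <- matrix(0, B, B)
  for (a in seq_len(B)) for (b in seq_len(B)) {
    ri <- ((a - 1) * bs + 1):min(a * bs, n)
    ci <- ((b - 1) * bs + 1):min(b * bs, n)
    out[a, b] <- mean(v[ri, ci])
  }
  out
}

# independent low-rank spectral reconstruction via SVD (signs recovered
# from u.v agreement), picking the k most negative eigenvalues
oracle_spectral <- function(M, k) {
  s <- svd(M)
  lam <- s$d * sign(colSums(s$u * s$v))
  idx <- order(lam)[seq_len(k)]
  out <- matrix(0, nrow(M), ncol(M))
  for (i in idx) out <- out + lam[i] * s$v[, i] %*% t(s$v[, i])
  out
}

# small random ensemble around a reference (iid Gaussian site noise)
random_ensemble <- function(n, frames, sigma = 0.5, seed = 1) {
  set.seed(seed)
  ref <- helix_coords(n)
  co <- array(0, dim = c(n, 3, frames))
  for (f in seq_len(frames))
    co[, , f] <- ref + matrix(rnorm(3 * n, sd = sigma), n, 3)
  md_ensemble(synthetic_structure(ref), co)
}

# apply a random rigid-body motion to every frame
rigid_shuffle <- function(ensemble, seed = 1) {
  set.seed(seed)
  co <- ensemble$coords
  for (f in seq_len(dim(co)[3])) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(
      w*w+x*x-y*y-z*z, 2*(x*y-w*z), 2*(x*z+w*y),
      2*(x*y+w*z), w*w-x*x+y*y-z*z, 2*(y*z-w*x),
      2*(x*z-w*y), 2*(y*z+w*x), w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
    co[, , f] <- sweep(co[, , f] %*% t(R), 2, rnorm(3, sd = 5), `+`)
  }
  md_ensemble(ensemble$reference, co, replica = ensemble$replica,
              time = ensemble$time)
}

# hand-written 3-atom PDB fixture
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       3.200   3.100   3.500  1.00  0.00",
    "END"), path)
  path
}
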