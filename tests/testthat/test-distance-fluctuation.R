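ca_sel <- function(e) select_atoms(e$reference, "calpha")

test_that("a rigid ensemble has an all-zero DF matrix", {
  ref <- helix_coords(5)
  co <- array(rep(ref, 4), dim = c(5, 3, 4))
  e <- md_ensemble(synthetic_structure(ref), co)
  df <- compute_df(e, ca_sel(e))
  expect_true(all(df$values == 0))
})

test_that("DF equals the analytic variance for a two-level separation", {
  # two sites at distance 1 A in half the frames, 3 A in the other half
  co <- array(0, dim = c(2, 3, 10))
  co[2, 1, ] <- rep(c(1, 3), each = 5)
  e <- md_ensemble(synthetic_structure(co[, , 1]), co)
  df <- compute_df(e, ca_sel(e))
  expect_equal(df$values[1, 2], 1.0)
  expect_equal(compute_df(e, ca_sel(e), statistic = "sd")$values[1, 2], 1.0)
  expect_error(compute_df(md_ensemble(e$reference, co[, , 1, drop = FALSE]),
                          ca_sel(e)), "fewer than 2")
})

test_that("DF matches a naive double-loop oracle on a harmonic ensemble", {
  m <- harmonic_model(helix_coords(8), springs_chain(8, 2), sigma = 0.5,
                      seed = 31)
  e <- sample_harmonic_ensemble(m, frames = 300)
  df <- compute_df(e, ca_sel(e))
  expect_lt(max(abs(df$values - oracle_df(e$coords))), 1e-10)
  expect_identical(df$values, t(df$values))
  expect_true(all(diag(df$values) == 0))
})

test_that("DF is invariant to per-frame rigid-body motion", {
  m <- harmonic_model(helix_coords(8), springs_chain(8, 2), seed = 13)
  e <- sample_harmonic_ensemble(m, frames = 120)
  df0 <- compute_df(e, ca_sel(e))
  df1 <- compute_df(rigid_shuffle(e, seed = 3), ca_sel(e))
  expect_lt(max(abs(df1$values - df0$values)), 1e-9)
  df2 <- compute_df(superpose(e, ca_sel(e)), ca_sel(e))
  expect_lt(max(abs(df2$values - df0$values)), 1e-9)
})

test_that("relabelling residues permutes DF rows and columns identically", {
  m <- harmonic_model(helix_coords(6), springs_chain(6, 2), seed = 17)
  e <- sample_harmonic_ensemble(m, frames = 80)
  perm <- c(3, 1, 6, 2, 5, 4)
  ep <- md_ensemble(synthetic_structure(m$ref[perm, ]),
                    e$coords[perm, , , drop = FALSE])
  df <- compute_df(e, ca_sel(e))
  dfp <- compute_df(ep, ca_sel(ep))
  expect_equal(dfp$values, df$values[perm, perm])
})

test_that("DF decreases monotonically with mutual stiffness", {
  ref <- rbind(c(0, 0, 0), c(15, 0, 0))
  dfk <- vapply(c(0.1, 1, 10), function(k) {
    m <- harmonic_model(ref, data.frame(i = 1, j = 2, k = k),
                        sigma = 0.5, seed = 23)
    e <- sample_harmonic_ensemble(m, frames = 20000)
    compute_df(e, ca_sel(e))$values[1, 2]
  }, 0)
  expect_true(all(diff(dfk) < 0))
})

test_that("metatrajectory DF equals the pooled per-replica variance", {
  m <- harmonic_model(helix_coords(5), springs_chain(5, 2), seed = 29)
  e <- sample_harmonic_ensemble(m, frames = 60, replicas = 3)
  df_meta <- compute_df(e, ca_sel(e))$values
  # pooled population variance from per-replica sufficient statistics
  reps <- unique(e$replica)
  n <- 5
  sum1 <- sum2 <- matrix(0, n, n); total <- 0
  for (r in reps) {
    idx <- which(e$replica == r)
    for (f in idx) {
      d <- as.matrix(stats::dist(e$coords[, , f]))
      sum1 <- sum1 + d; sum2 <- sum2 + d * d
    }
    total <- total + length(idx)
  }
  pooled <- sum2 / total - (sum1 / total)^2
  diag(pooled) <- 0
  expect_lt(max(abs(df_meta - pooled)), 1e-9)
})

test_that("block averaging matches a brute-force loop, edge blocks included", {
  m <- harmonic_model(helix_coords(9), springs_chain(9, 2), seed = 37)
  e <- sample_harmonic_ensemble(m, frames = 50)
  df <- compute_df(e, ca_sel(e))
  # constant matrix: every block value is the constant
  dfc <- df; dfc$values <- matrix(2.5, 9, 9)
  expect_true(all(block_average(dfc, 4)$values == 2.5))
  # exact 2x2 case and partial-edge case against the oracle
  for (bs in c(3, 4, 9, 20)) {
    b <- block_average(df, bs)
    expect_equal(b$values, oracle_block_average(df$values, bs))
  }
  expect_equal(dim(block_average(df, 20)$values), c(1L, 1L))
})

test_that("the 100-residue, block-40 layout reproduces the loop oracle", {
  set.seed(41)
  v <- matrix(rnorm(100 * 100)^2, 100, 100)
  v <- (v + t(v)) / 2; diag(v) <- 0
  df <- list(values = v,
             labels = data.frame(chain = "A", resid = 1:100),
             nframes = 2L, statistic = "variance")
  class(df) <- "df_matrix"
  b <- block_average(df, 40)
  expect_equal(dim(b$values), c(3L, 3L))
  expect_equal(b$values, oracle_block_average(v, 40))
  expect_equal(b$block_labels, c("1-40", "41-80", "81-100"))
})

test_that("quantization fills equal-width levels with max at the top", {
  b <- list(values = matrix(c(0, 1, 2, 3, 4, 3, 2, 1, 0), 3, 3),
            block_size = 1L, block_labels = c("1", "2", "3"),
            quantized = NULL, levels = NULL, statistic = "variance")
  class(b) <- "block_df_matrix"
  q <- quantize_df(b, 5)
  expect_identical(q$quantized, matrix(as.integer(b$values), 3, 3))
  # constant matrix degenerates to level 0
  bc <- b; bc$values <- matrix(1, 3, 3)
  expect_true(all(quantize_df(bc, 5)$quantized == 0L))
  # binning bounds hold on random matrices
  set.seed(43)
  for (rep in 1:5) {
    bv <- b; bv$values <- matrix(runif(9, 0, 10), 3, 3)
    q <- quantize_df(bv, 5)
    width <- (max(bv$values) - min(bv$values)) / 5
    lo <- min(bv$values)
    expect_true(all(bv$values >= lo + q$quantized * width - 1e-12))
    expect_true(all(bv$values <= lo + (q$quantized + 1) * width + 1e-12))
  }
})

test_that("DF differences are antisymmetric and flag label mismatches", {
  m <- harmonic_model(helix_coords(6), springs_chain(6, 2), seed = 47)
  e1 <- sample_harmonic_ensemble(m, frames = 40, seed = 1)
  e2 <- sample_harmonic_ensemble(m, frames = 40, seed = 2)
  a <- compute_df(e1, ca_sel(e1)); b <- compute_df(e2, ca_sel(e2))
  expect_true(all(df_difference(a, a) == 0))
  expect_equal(df_difference(a, b), -df_difference(b, a))
  b2 <- b; b2$labels$resid[3] <- 99L
  expect_error(df_difference(a, b2), "position 3")
})

test_that("a planted decoupled block dominates the DF difference", {
  # state B lacks the springs coordinating two small distal sites
  n <- 40; s1 <- 1:8; s2 <- 33:40
  ref <- helix_coords(n)
  intra <- rbind(springs_chain(n, 5), springs_contact(ref, 7, 3))
  inter <- expand.grid(i = s1, j = s2); inter$k <- 2
  mA <- harmonic_model(ref, rbind(intra, inter), seed = 53)
  mB <- harmonic_model(ref, intra, seed = 54)
  eA <- sample_harmonic_ensemble(mA, frames = 400)
  eB <- sample_harmonic_ensemble(mB, frames = 400)
  d <- df_difference(compute_df(eB, ca_sel(eB)), compute_df(eA, ca_sel(eA)))
  ut <- upper.tri(d)
  thr <- stats::quantile(d[ut], 0.9)
  top <- d > thr & ut
  inter_block <- outer(seq_len(n) %in% s1, seq_len(n) %in% s2) & ut
  frac_top_in_block <- sum(top & inter_block) / sum(top)
  frac_block <- sum(inter_block) / sum(ut)
  expect_gte(frac_top_in_block / frac_block, 5)
})

test_that("per-residue profiles equal masked row means", {
  v <- matrix(2, 3, 3); diag(v) <- 0
  df <- list(values = v, labels = data.frame(chain = "A", resid = 1:3),
             nframes = 2L, statistic = "variance")
  class(df) <- "df_matrix"
  expect_equal(df_profile(df), c(2, 2, 2))
  z <- df; z$values <- matrix(0, 3, 3)
  expect_equal(df_profile(z), c(0, 0, 0))
  set.seed(59)
  v <- matrix(runif(64), 8, 8); v <- (v + t(v)) / 2; diag(v) <- 0
  dfr <- list(values = v, labels = data.frame(chain = "A", resid = 1:8),
              nframes = 2L, statistic = "variance")
  class(dfr) <- "df_matrix"
  subset <- c(2, 5, 7)
  got <- df_profile(dfr, partners = subset)
  for (i in 1:8) {
    p <- setdiff(subset, i)
    expect_equal(got[i], mean(v[i, p]))
  }
  expect_error(df_profile(dfr, partners = integer(0)), "empty")
})
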