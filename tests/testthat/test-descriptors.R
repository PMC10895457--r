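test_that("RMSD of reference copies is zero and rigid shifts are removed", {
  ref <- helix_coords(10)
  s <- synthetic_structure(ref)
  co <- array(rep(ref, 5), dim = c(10, 3, 5))
  e <- md_ensemble(s, co)
  ca <- select_atoms(s, "calpha")
  expect_true(all(rmsd_series(e, ca)$values < 1e-9))
  shifted <- co
  shifted[, 1, ] <- shifted[, 1, ] + 2   # 2 A x-translation, every frame
  es <- md_ensemble(s, shifted)
  expect_true(all(rmsd_series(es, ca, ca, reference = s)$values < 1e-9))
})

test_that("RMSD matches a per-frame quaternion-fit oracle", {
  e <- rigid_shuffle(random_ensemble(15, 10, sigma = 0.8, seed = 127),
                     seed = 128)
  s <- e$reference
  ca <- select_atoms(s, "calpha")
  rs <- rmsd_series(e, ca, ca, reference = s)
  for (f in seq_len(10)) {
    fitted <- oracle_superpose(e$coords[, , f], s$xyz)
    expect_lt(abs(rs$values[f] - oracle_rmsd(fitted, s$xyz)), 1e-8)
  }
})

test_that("all-atom RMSD is invariant to per-frame rigid motion", {
  e <- random_ensemble(12, 8, sigma = 0.6, seed = 131)
  ca <- select_atoms(e$reference, "calpha")
  r0 <- rmsd_series(e, ca, ca, reference = e$reference)$values
  r1 <- rmsd_series(rigid_shuffle(e, seed = 132), ca, ca,
                    reference = e$reference)$values
  expect_lt(max(abs(r1 - r0)), 1e-9)
})

test_that("RMSF is zero for a static ensemble and order-invariant", {
  ref <- helix_coords(8)
  s <- synthetic_structure(ref)
  co <- array(rep(ref, 4), dim = c(8, 3, 4))
  ca <- select_atoms(s, "calpha")
  expect_true(all(rmsf_profile(md_ensemble(s, co), ca) < 1e-9))
  e <- random_ensemble(8, 30, sigma = 0.4, seed = 137)
  r1 <- rmsf_profile(e, select_atoms(e$reference, "calpha"))
  perm <- sample(30)
  ep <- md_ensemble(e$reference, e$coords[, , perm])
  r2 <- rmsf_profile(ep, select_atoms(ep$reference, "calpha"))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("RMSF approaches sigma * sqrt(3) for isotropic site noise", {
  e <- random_ensemble(50, 10000, sigma = 0.5, seed = 139)
  ca <- select_atoms(e$reference, "calpha")
  r <- rmsf_profile(e, ca)
  expect_lt(max(abs(r - 0.5 * sqrt(3)) / (0.5 * sqrt(3))), 0.05)
})

test_that("two well-separated planted families give K = 2 at full purity", {
  n <- 20
  ref <- helix_coords(n)
  s <- synthetic_structure(ref)
  set.seed(149)
  co <- array(0, dim = c(n, 3, 200))
  truth <- rep(1:2, each = 100)
  for (f in 1:200) {
    x <- ref + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    if (truth[f] == 2) x[11:20, 1] <- x[11:20, 1] + 8  # displaced tail
    co[, , f] <- x
  }
  e <- md_ensemble(s, co)
  al <- select_atoms(s, "resid", resid = 1:10, label = "ordered")
  cl <- select_atoms(s, "resid", resid = 11:20, label = "disordered")
  model <- cluster_conformations(e, al, cl, k_candidates = 2:6)
  expect_equal(model$k, 2L)
  purity <- max(table(model$assignment, truth)[, 1]) +
            max(table(model$assignment, truth)[, 2])
  expect_equal(purity / 200, 1.0)
  expect_true(all(model$silhouette >= -1 & model$silhouette <= 1))
})

test_that("three planted families are recovered in at least 18 of 20 seeds", {
  n <- 15
  ref <- helix_coords(n)
  s <- synthetic_structure(ref)
  al <- select_atoms(s, "resid", resid = 1:8, label = "ordered")
  cl <- select_atoms(s, "resid", resid = 9:15, label = "disordered")
  offsets <- list(c(0, 0, 0), c(7, 0, 0), c(0, 7, 0))
  hits <- 0
  for (sd in 1:20) {
    set.seed(sd)
    co <- array(0, dim = c(n, 3, 90))
    fam <- rep(1:3, each = 30)
    for (f in 1:90) {
      x <- ref + matrix(rnorm(3 * n, sd = 0.35), n, 3)
      x[9:15, ] <- sweep(x[9:15, ], 2, unlist(offsets[fam[f]]), `+`)
      co[, , f] <- x
    }
    e <- md_ensemble(s, co)
    model <- cluster_conformations(e, al, cl, k_candidates = 2:6)
    if (model$k == 3L) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("duplicating every frame changes neither K nor the medoid shape", {
  n <- 12
  ref <- helix_coords(n)
  s <- synthetic_structure(ref)
  set.seed(151)
  co <- array(0, dim = c(n, 3, 60))
  fam <- rep(1:2, each = 30)
  for (f in 1:60) {
    x <- ref + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    if (fam[f] == 2) x[7:12, 1] <- x[7:12, 1] + 8
    co[, , f] <- x
  }
  al <- select_atoms(s, "resid", resid = 1:6)
  cl <- select_atoms(s, "resid", resid = 7:12)
  m1 <- cluster_conformations(md_ensemble(s, co), al, cl, 2:5)
  m2 <- cluster_conformations(
    md_ensemble(s, co[, , rep(1:60, each = 2)]), al, cl, 2:5)
  expect_equal(m2$k, m1$k)
  # duplicated medoids are copies of the originals
  med1 <- lapply(m1$medoids, function(f) co[, , f])
  med2 <- lapply(m2$medoids, function(f) co[, , ceiling(f / 2)])
  expect_equal(length(med1), length(med2))
})

test_that("identical frames collapse to a single cluster with a warning", {
  ref <- helix_coords(8)
  s <- synthetic_structure(ref)
  co <- array(rep(ref, 10), dim = c(8, 3, 10))
  al <- select_atoms(s, "resid", resid = 1:4)
  cl <- select_atoms(s, "resid", resid = 5:8)
  expect_warning(m <- cluster_conformations(md_ensemble(s, co), al, cl),
                 "identical")
  expect_equal(m$k, 1L)
})

test_that("medoids minimise summed within-cluster RMSD (brute force)", {
  n <- 10
  ref <- helix_coords(n)
  s <- synthetic_structure(ref)
  set.seed(157)
  co <- array(0, dim = c(n, 3, 40))
  fam <- rep(1:2, each = 20)
  for (f in 1:40) {
    x <- ref + matrix(rnorm(3 * n, sd = 0.4), n, 3)
    if (fam[f] == 2) x[6:10, 1] <- x[6:10, 1] + 7
    co[, , f] <- x
  }
  al <- select_atoms(s, "resid", resid = 1:5)
  cl <- select_atoms(s, "resid", resid = 6:10)
  m <- cluster_conformations(md_ensemble(s, co), al, cl, 2:4)
  for (cid in seq_len(m$k)) {
    members <- which(m$assignment == cid)
    sums <- rowSums(m$rmsd[members, members, drop = FALSE])
    expect_equal(m$medoids[cid], members[which.min(sums)])
  }
})
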