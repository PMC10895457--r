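test_that("PDB structures read back with author numbering and coordinates", {
  p <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$xyz[1, ], c(1, 2, 3))
  expect_equal(s$atoms$elety, c("N", "CA", "C"))
  expect_equal(unique(s$atoms$resid), 1L)
})

test_that("multi-model PDB structures return the first model only", {
  m <- harmonic_model(helix_coords(5), springs_chain(5, 3), seed = 2)
  e <- sample_harmonic_ensemble(m, frames = 3)
  p <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(e, p)
  s <- read_structure(p)
  expect_equal(s$xyz, e$coords[, , 1], tolerance = 2e-3)
  expect_gt(max(abs(s$xyz - e$coords[, , 2])), 1e-2)
})

test_that("structure and trajectory round trips hold format precision", {
  m <- harmonic_model(helix_coords(6), springs_chain(6, 3), seed = 4)
  e <- sample_harmonic_ensemble(m, frames = 7)
  s <- synthetic_structure(m$ref)
  ps <- tempfile(fileext = ".pdb")
  write_structure(s, ps)
  expect_lt(max(abs(read_structure(ps)$xyz - s$xyz)), 1e-3)

  pd <- tempfile(fileext = ".dcd")
  write_dcd(e, pd)
  e_dcd <- read_ensemble(s, pd)
  expect_lt(max(abs(e_dcd$coords - e$coords)), 1e-5)

  pp <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(e, pp)
  e_pdb <- read_ensemble(s, pp)
  expect_lt(max(abs(e_pdb$coords - e$coords)), 1e-3)
})

test_that("B-factor annotation survives a PDB round trip", {
  s <- synthetic_structure(helix_coords(8))
  b <- seq(0.05, 0.4, by = 0.05)
  p <- tempfile(fileext = ".pdb")
  write_structure(s, p, bfactor = b)
  pdb <- bio3d::read.pdb(p, verbose = FALSE)
  expect_equal(pdb$atom$b, b, tolerance = 1e-2)
})

test_that("ensemble loading concatenates replicas with labels and stride", {
  m <- harmonic_model(helix_coords(4), springs_chain(4, 3), seed = 6)
  s <- synthetic_structure(m$ref)
  paths <- character(4)
  for (r in 1:4) {
    e <- sample_harmonic_ensemble(m, frames = 5, seed = r)
    paths[r] <- tempfile(fileext = ".pdb")
    write_ensemble_pdb(e, paths[r])
  }
  meta <- read_ensemble(s, paths)
  expect_equal(n_frames(meta), 20L)
  expect_equal(unique(meta$replica), paste0("r", 1:4))
  expect_equal(as.vector(table(meta$replica)), rep(5L, 4))

  e10 <- sample_harmonic_ensemble(m, frames = 10, seed = 9)
  p10 <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(e10, p10)
  expect_equal(n_frames(read_ensemble(s, p10, stride = 2L)), 5L)
  expect_error(read_ensemble(synthetic_structure(helix_coords(5)), p10),
               "mismatch")
})

test_that("selections are deterministic, ordered and partition the atoms", {
  p <- tempfile(fileext = ".pdb")
  n <- 20
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(chain = "A", resid = i, resname = "ALA",
               elety = c("N", "CA", "C", "O", "CB"))))
  s <- md_structure(atoms, matrix(rnorm(5 * n * 3), ncol = 3))
  ca <- select_atoms(s, "calpha")
  expect_equal(length(ca$inds), n)
  expect_false(is.unsorted(ca$inds))
  rr <- select_atoms(s, "resid", resid = "10-12")
  expect_equal(sort(unique(s$atoms$resid[rr$inds])), 10:12)
  bb <- select_atoms(s, "backbone")
  sc <- select_atoms(s, "sidechain")
  expect_equal(length(bb$inds) + length(sc$inds), nrow(s$atoms))
  expect_identical(select_atoms(s, "calpha")$inds, ca$inds)
  expect_error(select_atoms(s, "resid", resid = 999), "empty selection")
})

test_that("duplicate atom records are rejected with the offending key", {
  atoms <- data.frame(chain = "A", resid = c(1, 1), resname = "ALA",
                      elety = c("CA", "CA"))
  expect_error(md_structure(atoms, matrix(0, 2, 3)), "A 1 CA")
})

test_that("superposition removes rigid-body motion and is idempotent", {
  e <- random_ensemble(10, 6, sigma = 0, seed = 3)   # frames == reference
  er <- rigid_shuffle(e, seed = 5)
  ca <- select_atoms(er$reference, "calpha")
  fit <- superpose(er, ca)
  ref <- fit$coords[, , 1]
  for (f in seq_len(n_frames(fit)))
    expect_lt(oracle_rmsd(fit$coords[, , f], ref), 1e-6)
  # input unmodified
  expect_gt(max(abs(er$coords[, , 2] - fit$coords[, , 2])), 1e-3)
  # idempotence
  fit2 <- superpose(fit, ca)
  expect_lt(max(abs(fit2$coords - fit$coords)), 1e-9)
})

test_that("superposition is optimal against a quaternion oracle", {
  set.seed(11)
  for (case in 1:10) {
    fixed <- matrix(rnorm(50 * 3, sd = 4), 50, 3)
    mobile <- fixed + matrix(rnorm(50 * 3, sd = 0.7), 50, 3)
    mobile <- rigid_shuffle(
      md_ensemble(synthetic_structure(mobile),
                  array(mobile, dim = c(50, 3, 1))), seed = case)$coords[, , 1]
    ens <- md_ensemble(synthetic_structure(mobile),
                       array(mobile, dim = c(50, 3, 1)))
    ours <- superpose(ens, select_atoms(ens$reference, "all"),
                      reference = synthetic_structure(fixed))$coords[, , 1]
    theirs <- oracle_superpose(mobile, fixed)
    expect_lt(max(abs(ours - theirs)), 1e-8)
    # the direct single-frame fit used inside the D-NEMD subtraction
    expect_lt(max(abs(allodyn:::kabsch_fit(mobile, fixed) - theirs)), 1e-8)
  }
})

test_that("superposition never increases the fit-selection RMSD", {
  e <- random_ensemble(12, 8, sigma = 1.2, seed = 7)
  er <- rigid_shuffle(e, seed = 8)
  ca <- select_atoms(er$reference, "calpha")
  ref0 <- er$coords[, , 1]
  fit <- superpose(er, ca)
  for (f in seq_len(n_frames(er))) {
    pre <- oracle_rmsd(er$coords[, , f], ref0)
    post <- oracle_rmsd(fit$coords[, , f], fit$coords[, , 1])
    expect_lte(post, pre + 1e-9)
  }
  expect_error(superpose(er, structure(list(inds = 1:2, label = "x"),
                                       class = "md_selection")),
               "under-determined")
})

test_that("secondary-structure heuristic flags an ideal helix as helical", {
  s <- synthetic_structure(helix_coords(20))
  sse <- assign_sse(s)
  expect_gte(mean(sse[1:16] == "H"), 0.9)
})
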