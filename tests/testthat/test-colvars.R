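test_that("radius of gyration: degenerate and closed-form cases", {
  coincident <- mol_structure(matrix(1.5, 4, 3), rep(2, 4))
  expect_equal(radius_of_gyration(coincident), 0)

  dumbbell <- mol_structure(rbind(c(0, 0, 0), c(0.2, 0, 0)), c(1, 1))
  expect_equal(radius_of_gyration(dumbbell), 0.1)
})

test_that("radius of gyration matches the brute-force definition", {
  s <- .with_seed_test(31, {
    mol_structure(matrix(rnorm(30), 10, 3), runif(10, 1, 20))
  })
  expect_equal(radius_of_gyration(s), rg_oracle(s$coords, s$masses),
               tolerance = 1e-12)
})

test_that("Rg is invariant under rigid motion and scales linearly with coordinates", {
  s <- .with_seed_test(32, {
    mol_structure(matrix(rnorm(45), 15, 3), runif(15, 1, 16))
  })
  R <- .with_seed_test(33, felbind:::.random_rotation())
  moved <- mol_structure(s$coords %*% t(R) + 3.3, s$masses)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(s),
               tolerance = 1e-12)
  for (scale in c(0.5, 2, 3.7)) {
    scaled <- mol_structure(s$coords * scale, s$masses)
    expect_equal(radius_of_gyration(scaled),
                 scale * radius_of_gyration(s), tolerance = 1e-12)
  }
})

test_that("kabsch_rmsd is zero up to rigid motion and rejects mismatches", {
  ts <- toy_structures(n_atoms = 40, n_frames = 2, noise = 0, seed = 41)
  expect_equal(kabsch_rmsd(ts$reference, ts$reference), 0)
  for (f in ts$frames) {
    expect_lt(kabsch_rmsd(f, ts$reference), 1e-10)
  }
  small <- mol_structure(matrix(rnorm(9), 3, 3), rep(1, 3))
  expect_error(kabsch_rmsd(small, ts$reference), "atom-count",
               class = "felbind_input_error")
})

test_that("kabsch_rmsd matches exhaustive minimisation over rotations", {
  base <- .with_seed_test(42, matrix(runif(60, 0, 2), 20, 3))
  pert <- .with_seed_test(43, base + matrix(rnorm(60, sd = 0.05), 20, 3))
  s_ref <- mol_structure(base, rep(1, 20))
  s_mob <- mol_structure(pert, rep(1, 20))
  ours <- kabsch_rmsd(s_mob, s_ref, fit_weights = "uniform")
  expect_equal(ours, rmsd_oracle(pert, base), tolerance = 1e-6)
})

test_that("kabsch_rmsd agrees with bio3d superposition", {
  ts <- toy_structures(n_atoms = 30, n_frames = 1, noise = 0.08, seed = 44)
  mob <- ts$frames[[1]]
  ours <- kabsch_rmsd(mob, ts$reference, fit_weights = "uniform")
  fixed <- as.vector(t(ts$reference$coords))
  fitted <- suppressWarnings( # bio3d notes it fits on all positions
    bio3d::fit.xyz(fixed = fixed, mobile = as.vector(t(mob$coords))))
  # deviation of the bio3d-superposed coordinates (bio3d::rmsd rounds)
  theirs <- sqrt(mean(colSums(matrix((fitted - fixed)^2, nrow = 3))))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("rmsd properties: symmetry and superposition optimality", {
  for (seed in 1:5) {
    ts <- toy_structures(n_atoms = 25, n_frames = 1, noise = 0.1,
                         seed = 50 + seed)
    a <- ts$reference
    b <- ts$frames[[1]]
    expect_equal(kabsch_rmsd(a, b, fit_weights = "uniform"),
                 kabsch_rmsd(b, a, fit_weights = "uniform"),
                 tolerance = 1e-10)
    raw <- sqrt(mean(rowSums((a$coords - b$coords)^2)))
    expect_lte(kabsch_rmsd(b, a, fit_weights = "uniform"), raw + 1e-12)
  }
})

test_that("proper rotations only: a mirrored structure is not matched exactly", {
  s <- .with_seed_test(61, mol_structure(matrix(rnorm(36), 12, 3), rep(1, 12)))
  mirrored <- mol_structure(s$coords %*% diag(c(-1, 1, 1)), s$masses)
  # a reflection would give 0; the determinant correction must forbid that
  expect_gt(kabsch_rmsd(mirrored, s), 1e-3)
})

test_that("cv_timeseries computes one sample per frame against a fixed reference", {
  ts <- toy_structures(n_atoms = 20, n_frames = 3, noise = 0, seed = 71)
  ref <- ts$reference

  cv1 <- cv_timeseries(list(ref), ref)
  expect_s3_class(cv1, "cv_samples")
  expect_equal(cv1$rg, radius_of_gyration(ref))
  expect_equal(cv1$rmsd, 0)

  cv3 <- cv_timeseries(list(ref, ref, ref), ref)
  expect_equal(nrow(cv3), 3L)
  expect_equal(cv3$time, c(0, 10, 20))
  expect_true(all(cv3$rmsd == cv3$rmsd[1]) && all(cv3$rg == cv3$rg[1]))

  # breathing trajectory: uniform scaling s per frame makes Rg linear in s
  scales <- c(0.8, 1, 1.25)
  frames <- lapply(scales, function(s) mol_structure(ref$coords * s,
                                                     ref$masses))
  cvb <- cv_timeseries(frames, ref)
  expect_equal(cvb$rg, scales * radius_of_gyration(ref), tolerance = 1e-12)

  bad <- c(frames, list(mol_structure(matrix(0.5, 2, 3), c(1, 1))))
  expect_error(cv_timeseries(bad, ref), "frame 4",
               class = "felbind_input_error")
})
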