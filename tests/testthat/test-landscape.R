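toy_cv <- function(rg, rmsd) {
  cv_samples(time = seq(0, by = 10, length.out = length(rg)), rg, rmsd)
}

test_that("single-occupancy landscape: one zero bin, the rest flagged", {
  cv <- toy_cv(rep(1.1, 20), rep(0.2, 20))
  fel <- build_fel(cv, n_bins = c(5, 5))
  expect_equal(sum(!is.na(fel$g)), 1L)
  expect_equal(fel$g[!is.na(fel$g)], 0)
  expect_equal(sum(fel$counts), 20L)
})

test_that("equal occupancy gives a flat landscape at zero", {
  pts <- expand.grid(rg = c(1.0, 1.2), rmsd = c(0.1, 0.3))
  cv <- toy_cv(rep(pts$rg, each = 25), rep(pts$rmsd, each = 25))
  fel <- build_fel(cv, n_bins = c(4, 4))
  occupied <- fel$g[!is.na(fel$g)]
  expect_equal(length(occupied), 4L)
  expect_true(all(occupied == 0))
})

test_that("landscape normalisation: minimum occupied bin is zero, all g non-negative", {
  cv <- two_basin_cv(5000, seed = 81)
  fel <- build_fel(cv, n_bins = c(30, 30))
  expect_equal(min(fel$g, na.rm = TRUE), 0)
  expect_true(all(fel$g[!is.na(fel$g)] >= 0))
  expect_true(all(is.na(fel$g[fel$counts == 0])))
  # rebuilding from identical input is bit-identical
  fel2 <- build_fel(two_basin_cv(5000, seed = 81), n_bins = c(30, 30))
  expect_identical(fel$g, fel2$g)
  expect_error(build_fel(cv, n_bins = c(1, 10)),
               class = "felbind_config_error")
})

test_that("two-basin mixture recovers the analytic population gap", {
  cv <- two_basin_cv(1e5, p = c(0.8, 0.2), seed = 82)
  fel <- build_fel(cv, n_bins = c(40, 40))
  gap <- fel_basin_gap(fel, split = 1.175, axis = "rg")
  expect_equal(gap$gap_population, kT(298) * log(4), tolerance = 0.03)
  expect_equal(attr(cv, "gap_true"), kT(298) * log(4), tolerance = 1e-12)
  # the modal-bin estimator agrees with the population one at histogram
  # noise level (kT/sqrt(peak count))
  peak <- max(fel$counts)
  expect_equal(gap$gap_min, gap$gap_population,
               tolerance = 4 * kT(298) / sqrt(peak) / gap$gap_population)
})

test_that("equal populations give equal basin depths within sampling error", {
  cv <- two_basin_cv(4e4, p = c(0.5, 0.5), seed = 83)
  fel <- build_fel(cv, n_bins = c(40, 40))
  gap <- fel_basin_gap(fel, split = 1.175, axis = "rg")
  expect_lt(abs(gap$gap_population), 0.02)
})

test_that("separable distributions make the 2-D landscape additive in 1-D parts", {
  n <- 1e5
  cv <- .with_seed_test(84, {
    cv_samples(time = seq(0, by = 10, length.out = n),
               rg = rnorm(n, 1.15, 0.03), rmsd = abs(rnorm(n, 0.4, 0.05)))
  })
  fel <- build_fel(cv, n_bins = c(20, 20))
  # 1-D free energies from the marginal counts on the same grid
  cx <- rowSums(fel$counts)
  cy <- colSums(fel$counts)
  gx <- -fel$kT * log(cx / max(cx))
  gy <- -fel$kT * log(cy / max(cy))
  pred <- outer(gx, gy, `+`)
  well <- which(fel$counts >= 100)
  resid <- fel$g[well] - pred[well]
  resid <- resid - mean(resid) # additivity holds up to a constant
  expect_lt(sqrt(mean(resid^2)), 0.05 * diff(range(fel$g[well])))
})

test_that("lookup honours bin membership, policies and warnings", {
  cv <- toy_cv(c(rep(1.0, 30), rep(1.2, 10)), c(rep(0.1, 30), rep(0.3, 10)))
  fel <- build_fel(cv, n_bins = c(6, 6))
  expect_equal(fel_lookup(fel, 1.0, 0.1), 0)
  expect_equal(fel_lookup(fel, 1.2, 0.3), -fel$kT * log(10 / 30))
  # outside the grid: nearest occupied bin with a warning
  expect_warning(
    out <- fel_lookup(fel, 5, 5, policy = "nearest_occupied"),
    class = "felbind_lookup_warning")
  expect_equal(out, -fel$kT * log(10 / 30))
  expect_error(fel_lookup(fel, 5, 5, policy = "error"),
               class = "felbind_landscape_error")
  expect_error(fel_lookup(fel, 1.05, 0.15, policy = "error"),
               class = "felbind_landscape_error")
})

test_that("interior empty bin resolves to the hand-enumerated nearest neighbour", {
  # hand-built 3x3 grid with an empty centre bin
  counts <- matrix(c(8, 5, 4,
                     4, 0, 2,
                     4, 2, 2), 3, 3, byrow = TRUE)
  kt <- kT(298)
  g <- -kt * log(counts / 8)
  g[counts == 0] <- NA_real_
  fel <- structure(list(rg_edges = seq(0.95, 1.25, by = 0.1),
                        rmsd_edges = seq(0.05, 0.35, by = 0.1),
                        g = g, counts = counts, kT = kt,
                        n_samples = sum(counts)),
                   class = "fel_grid")
  expect_true(is.na(fel$g[2, 2]))
  # query dead centre of bin (2, 2): its four edge-neighbours tie at index
  # distance 1; the deterministic column-major scan selects bin (2, 1),
  # count 4 -> g = -kT ln(4/8)
  expect_warning(val <- fel_lookup(fel, 1.10, 0.2), "empty bin")
  expect_equal(val, -kt * log(4 / 8))
})

test_that("correction term averages per-conformation lookups with exact arithmetic", {
  cv <- toy_cv(c(rep(1.0, 40), rep(1.2, 10)), c(rep(0.1, 40), rep(0.3, 10)))
  fel <- build_fel(cv, n_bins = c(6, 6))
  g_minor <- -fel$kT * log(10 / 40)

  at_min <- toy_cv(rep(1.0, 5), rep(0.1, 5))
  corr0 <- correction_term(fel, at_min)
  expect_equal(corr0$mean, 0)
  expect_equal(corr0$sem, 0)

  mixed <- toy_cv(c(1.0, 1.0, 1.0, 1.0, 1.2), c(0.1, 0.1, 0.1, 0.1, 0.3))
  corr <- correction_term(fel, mixed)
  expect_equal(corr$per_conformation, c(0, 0, 0, 0, g_minor))
  expect_equal(corr$mean, g_minor / 5)
  expect_equal(corr$sem, sd(c(0, 0, 0, 0, g_minor)) / sqrt(5))
})

test_that("conformations in the minor basin recover the population gap", {
  cv <- two_basin_cv(1e5, p = c(0.8, 0.2), seed = 85)
  fel <- build_fel(cv, n_bins = c(40, 40))
  confs <- toy_cv(rep(1.25, 5), rep(0.35, 5))
  corr <- correction_term(fel, confs)
  expect_equal(corr$mean, kT(298) * log(4), tolerance = 0.12)
})

test_that("apply_correction adds the mean and combines uncertainties", {
  expect_equal(apply_correction(-17.05, 1.04)$dg_corrected, -16.01)
  expect_equal(apply_correction(-12.52, 1.66)$dg_corrected, -10.86)
  expect_equal(apply_correction(-7.3, 0)$dg_corrected, -7.3)

  corr <- structure(list(mean = 1.0, sem = 0.07,
                         per_conformation = rep(1, 5)),
                    class = "correction_result")
  res <- apply_correction(-10, corr, dg_stderr = 0.33)
  expect_equal(res$stderr, sqrt(0.33^2 + 0.07^2))
  res_lin <- apply_correction(-10, corr, dg_stderr = 0.33,
                              error_combine = "linear")
  expect_equal(res_lin$stderr, 0.4)
})

test_that("tail extraction picks evenly strided conformations from the last window", {
  cv <- toy_cv(seq(1, 1.5, length.out = 51), rep(0.2, 51)) # t = 0..500 ps
  tail5 <- tail_conformations(cv, n = 5, window = 100)
  expect_equal(nrow(tail5), 5L)
  expect_true(all(tail5$time >= 400))
  expect_equal(tail5$time, c(400, 430, 450, 470, 500))
})
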