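test_that("fermi function: symmetry point, complement identity, closed form", {
  expect_equal(fermi(0, 1), 0.5)
  kt <- kT(298)
  expect_equal(fermi(kt * log(3), kt), 0.25)
  x <- kt * c(-700, -3.2, 0, 1e-8, 4.7, 700)
  expect_equal(fermi(x, kt) + fermi(-x, kt), rep(1, length(x)))
  expect_true(all(is.finite(fermi(x, kt))))
  expect_true(all(fermi(x, kt) >= 0 & fermi(x, kt) <= 1))
  # the deep tail stays strictly positive so its logarithm is usable
  expect_gt(fermi(700 * kt, kt), 0)
  expect_error(fermi(1, 0), class = "felbind_domain_error")
})

test_that("bar_pair: identical Hamiltonians give zero, symmetry gives near zero", {
  w0 <- window_samples(0, 0.5, rep(0, 50), rep(0, 50))
  est <- bar_pair(w0)
  expect_equal(est$dg, 0)
  expect_equal(est$C, 0)

  # forward and reverse drawn from the same distribution -> dg ~ 0
  sym <- .with_seed_test(21, {
    window_samples(0, 1, rnorm(5000, 1, 2), rnorm(5000, 1, 2))
  })
  expect_lt(abs(bar_pair(sym)$dg), 0.15)
})

test_that("bar_pair recovers the designed free energy of Crooks-consistent windows", {
  w <- gaussian_work_windows(dg_true = 2.0, sigma = 1.0, n = 1e4, seed = 101)[[1]]
  est <- bar_pair(w)
  expect_equal(est$dg, 2.0, tolerance = 0.05 / 2.0)
  # cross-check against one-sided exponential averaging at large n
  ea <- exp_averaging(w)
  expect_equal(unname(ea["forward"]), 2.0, tolerance = 0.05)
  expect_equal(unname(ea["reverse"]), 2.0, tolerance = 0.05)
})

test_that("bar_pair rejects empty directions and bad tolerances", {
  w <- window_samples(0, 1, numeric(0), rnorm(5))
  expect_error(bar_pair(w), class = "felbind_input_error")
  w2 <- gaussian_work_windows(1, 1, 100, seed = 1)[[1]]
  expect_error(bar_pair(w2, tol = -1), class = "felbind_domain_error")
})

test_that("antisymmetry: swapping forward and reverse roles negates dg", {
  for (seed in 1:6) {
    dg <- c(-2.5, -0.5, 0, 0.7, 1.9, 3.1)[seed]
    w <- gaussian_work_windows(dg, sigma = 1.3, n = 3000, seed = 300 + seed)[[1]]
    swapped <- window_samples(w$lambda_k, w$lambda_j,
                              w$du_reverse, w$du_forward, w$temperature)
    expect_equal(bar_pair(w)$dg + bar_pair(swapped)$dg, 0, tolerance = 1e-7)
  }
})

test_that("exponential averaging brackets BAR in expectation", {
  # the one-sided estimators are biased in opposite directions (Jensen);
  # averaged over replicates the forward estimate sits above BAR and the
  # reverse below. (Sample-wise bracketing does not hold in general.)
  means <- rowMeans(vapply(1:80, function(s) {
    w <- gaussian_work_windows(1.0, sigma = 1.5, n = 400,
                               seed = 8000 + s)[[1]]
    c(exp_averaging(w), bar = bar_pair(w)$dg)
  }, numeric(3)))
  expect_gt(means[["forward"]], means[["bar"]])
  expect_gt(means[["bar"]], means[["reverse"]])
  expect_equal(means[["bar"]], 1.0, tolerance = 0.03)
})

test_that("parameter recovery over the design grid: bias below 0.05 kcal/mol", {
  grid <- expand.grid(dg = c(-3, -1, 0, 1, 3), sigma = c(0.5, 2))
  bias <- mapply(function(dg, sigma) {
    w <- gaussian_work_windows(dg, sigma = sigma, n = 1e4,
                               seed = 7000 + round(100 * dg + 10 * sigma))[[1]]
    bar_pair(w)$dg - dg
  }, grid$dg, grid$sigma)
  expect_lt(max(abs(bias)), 0.05)
})

test_that("bar_chain sums pairwise estimates and checks contiguity", {
  ws <- gaussian_work_windows(c(1, 1), sigma = 1, n = 5000, seed = 17)
  res <- bar_chain(ws)
  expect_s3_class(res, "free_energy_result")
  expect_equal(nrow(res$per_window), 2L)
  expect_equal(res$dg, sum(res$per_window$dg))
  expect_equal(res$dg, 2.0, tolerance = 0.08)

  # chain of identical zero-dG windows telescopes to zero
  zero <- lapply(1:4, function(i) {
    window_samples((i - 1) / 4, i / 4, rep(0, 10), rep(0, 10))
  })
  expect_equal(bar_chain(zero)$dg, 0)

  # a window empty in both directions is a pair of identical states
  empty <- window_samples(0, 1, numeric(0), numeric(0))
  expect_equal(bar_chain(list(empty))$dg, 0)

  broken <- list(window_samples(0, 0.5, rnorm(10), rnorm(10)),
                 window_samples(0.6, 1, rnorm(10), rnorm(10)))
  expect_error(bar_chain(broken), "contiguous",
               class = "felbind_schedule_error")
})

test_that("bootstrap stderr: zero for degenerate input, reproducible, calibrated", {
  w0 <- window_samples(0, 1, rep(0, 40), rep(0, 40))
  expect_equal(bar_stderr(w0, n_boot = 50, seed = 3), 0)

  w <- gaussian_work_windows(1.5, sigma = 1, n = 3000, seed = 23)[[1]]
  se1 <- bar_stderr(w, n_boot = 200, seed = 5)
  se2 <- bar_stderr(w, n_boot = 200, seed = 5)
  expect_identical(se1, se2)
  expect_gt(se1, 0)

  # oracle: stderr from repeated independent regeneration
  regen <- vapply(1:50, function(s) {
    bar_pair(gaussian_work_windows(1.5, sigma = 1, n = 3000,
                                   seed = 9000 + s)[[1]])$dg
  }, numeric(1))
  expect_equal(se1, sd(regen), tolerance = 0.3)
  expect_error(bar_stderr(w, n_boot = 1), class = "felbind_input_error")
})
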