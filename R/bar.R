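#' Hamiltonian-difference samples for one lambda-window pair
#'
#' Container for the energy-difference samples needed by the Bennett
#' acceptance ratio estimator between two adjacent alchemical states j and
#' k. The forward samples are `H_k - H_j` evaluated on configurations drawn
#' from ensemble j; the reverse samples are `H_j - H_k` evaluated in
#' ensemble k. All energies are kcal/mol.
#'
#' @param lambda_j,lambda_k coupling-parameter values of the two states,
#'   each in `[0, 1]`.
#' @param du_forward numeric vector, `H_k - H_j` sampled in ensemble j
#'   (kcal/mol).
#' @param du_reverse numeric vector, `H_j - H_k` sampled in ensemble k
#'   (kcal/mol).
#' @param temperature simulation temperature in Kelvin.
#' @return an object of class `window_samples`.
#' @seealso [bar_pair()], [bar_chain()], [gaussian_work_windows()]
#' @export
window_samples <- function(lambda_j, lambda_k, du_forward, du_reverse,
                           temperature = 298) {
  if (!.is_number(lambda_j) || !.is_number(lambda_k) ||
      lambda_j < 0 || lambda_j > 1 || lambda_k < 0 || lambda_k > 1) {
    .fail("lambda values must be single numbers in [0, 1]",
          "felbind_domain_error")
  }
  if (!is.numeric(du_forward) || !is.numeric(du_reverse) ||
      anyNA(du_forward) || anyNA(du_reverse) ||
      any(!is.finite(du_forward)) || any(!is.finite(du_reverse))) {
    .fail("energy-difference samples must be finite numeric vectors",
          "felbind_input_error")
  }
  kT(temperature) # validates temperature
  structure(
    list(lambda_j = lambda_j, lambda_k = lambda_k,
         du_forward = as.numeric(du_forward),
         du_reverse = as.numeric(du_reverse),
         temperature = temperature),
    class = "window_samples")
}

#' @export
print.window_samples <- function(x, ...) {
  cat(sprintf(
    "<window_samples> lambda %.4g -> %.4g | %d fwd, %d rev samples | %g K\n",
    x$lambda_j, x$lambda_k, length(x$du_forward), length(x$du_reverse),
    x$temperature))
  invisible(x)
}

#' Fermi function
#'
#' `f(x) = 1 / (1 + exp(x / kT))`, the weighting function at the core of
#' the Bennett acceptance ratio estimator. Evaluated through the logistic
#' CDF so it neither overflows nor underflows to an invalid value for
#' `|x/kT|` up to several hundred.
#'
#' @param x energy (kcal/mol); vectorised.
#' @param kT thermal energy (kcal/mol), positive.
#' @return values in `(0, 1)`; `fermi(x, kT) + fermi(-x, kT) == 1`.
#' @examples
#' fermi(0, 1)                 # 0.5
#' fermi(0.592 * log(3), 0.592) # 0.25
#' @export
fermi <- function(x, kT) {
  if (!.is_number(kT) || kT <= 0) {
    .fail("`kT` must be a single positive energy (kcal/mol)",
          "felbind_domain_error")
  }
  stats::plogis(-x / kT)
}

#' Bennett acceptance ratio estimate for one window pair
#'
#' Solves for the shift constant C at which the sum of Fermi weights of the
#' reverse samples (shifted by +C) equals that of the forward samples
#' (shifted by -C), the self-consistency condition of the minimum-variance
#' two-state estimator. The free energy difference then follows as
#' `dg = C + kT * ln(N_j / N_k)`; with equal sample counts, `dg = C`.
#'
#' @param w a [window_samples()] object with both directions non-empty.
#' @param tol convergence tolerance on the per-sample imbalance of the two
#'   Fermi-weight averages (kcal/mol scale, dimensionless weights).
#' @param max_iter maximum root-refinement iterations.
#' @return list with elements `dg` (kcal/mol), `C` (kcal/mol, the Bennett
#'   shift constant) and `iterations`.
#' @examples
#' w <- gaussian_work_windows(dg_true = 2, sigma = 1, n = 2000, seed = 1)[[1]]
#' bar_pair(w)$dg
#' @export
bar_pair <- function(w, tol = 1e-8, max_iter = 200L) {
  if (!inherits(w, "window_samples")) {
    .fail("`w` must be a window_samples object", "felbind_input_error")
  }
  if (!.is_number(tol) || tol <= 0) {
    .fail("`tol` must be a single positive number", "felbind_domain_error")
  }
  nf <- length(w$du_forward)
  nr <- length(w$du_reverse)
  if (nf == 0L || nr == 0L) {
    .fail("BAR requires non-empty samples in both directions",
          "felbind_input_error")
  }
  kt <- kT(w$temperature)
  ## Imbalance of Fermi-weight sums; strictly increasing in C, so the root
  ## is unique and bracketable.
  h <- function(C) {
    sum(fermi(w$du_forward - C, kt)) - sum(fermi(w$du_reverse + C, kt))
  }
  C0 <- (mean(w$du_forward) - mean(w$du_reverse)) / 2
  half <- max(1, 2 * stats::sd(c(w$du_forward, -w$du_reverse)), na.rm = TRUE)
  lo <- C0 - half
  hi <- C0 + half
  it_bracket <- 0L
  while (h(lo) > 0 && it_bracket < 60L) {
    lo <- lo - 2 * half
    it_bracket <- it_bracket + 1L
  }
  while (h(hi) < 0 && it_bracket < 120L) {
    hi <- hi + 2 * half
    it_bracket <- it_bracket + 1L
  }
  root <- tryCatch(
    stats::uniroot(h, c(lo, hi), tol = .Machine$double.eps^0.75,
                   maxiter = as.integer(max_iter)),
    error = function(e) NULL)
  scale <- sqrt(as.numeric(nf) * as.numeric(nr))
  if (is.null(root) || abs(h(root$root)) > tol * scale) {
    last_C <- if (is.null(root)) C0 else root$root
    .fail(sprintf(
      "BAR self-consistency not reached after %d iterations (last C = %.6g)",
      max_iter, last_C),
      "felbind_convergence_error", last_C = last_C)
  }
  C <- root$root
  list(dg = C + kt * log(nf / nr), C = C,
       iterations = root$iter + it_bracket)
}

#' Chain BAR estimates across an ordered lambda schedule
#'
#' Sums pairwise BAR estimates over an ordered list of window pairs; the
#' total free energy difference between the end states is the telescoping
#' sum of the per-window differences. Adjacent windows must share their
#' lambda endpoints. A window that is empty in both directions is treated
#' as a pair of identical states and contributes zero.
#'
#' @param windows list of [window_samples()] ordered along the schedule.
#' @param tol,max_iter passed to [bar_pair()].
#' @return object of class `free_energy_result`: list with `dg` (kcal/mol),
#'   `stderr` (`NA` until filled by [bar_stderr()]) and `per_window`
#'   data frame (`lambda_j`, `lambda_k`, `dg`, `C`, `iterations`).
#' @export
bar_chain <- function(windows, tol = 1e-8, max_iter = 200L) {
  if (inherits(windows, "window_samples")) windows <- list(windows)
  if (!is.list(windows) || length(windows) == 0L ||
      !all(vapply(windows, inherits, logical(1), "window_samples"))) {
    .fail("`windows` must be a non-empty list of window_samples",
          "felbind_input_error")
  }
  if (length(windows) > 1L) {
    lj <- vapply(windows, `[[`, numeric(1), "lambda_j")
    lk <- vapply(windows, `[[`, numeric(1), "lambda_k")
    gap <- abs(lk[-length(lk)] - lj[-1])
    if (any(gap > 1e-8)) {
      .fail(sprintf(
        "lambda chain is not contiguous at pair %d (lambda_k = %.4g, next lambda_j = %.4g)",
        which(gap > 1e-8)[1], lk[which(gap > 1e-8)[1]],
        lj[which(gap > 1e-8)[1] + 1]),
        "felbind_schedule_error")
    }
  }
  rows <- lapply(windows, function(w) {
    if (length(w$du_forward) == 0L && length(w$du_reverse) == 0L) {
      return(data.frame(lambda_j = w$lambda_j, lambda_k = w$lambda_k,
                        dg = 0, C = 0, iterations = 0L))
    }
    est <- bar_pair(w, tol = tol, max_iter = max_iter)
    data.frame(lambda_j = w$lambda_j, lambda_k = w$lambda_k,
               dg = est$dg, C = est$C, iterations = est$iterations)
  })
  per_window <- do.call(rbind, rows)
  structure(list(dg = sum(per_window$dg), stderr = NA_real_,
                 per_window = per_window),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result> dg = %.4f kcal/mol", x$dg))
  if (is.finite(x$stderr)) cat(sprintf(" +/- %.4f", x$stderr))
  cat(sprintf(" over %d window pair(s)\n", nrow(x$per_window)))
  invisible(x)
}

#' Bootstrap standard error of a chained BAR estimate
#'
#' Resamples frames with replacement independently within each window and
#' direction, re-runs the chained estimate, and reports the standard
#' deviation over bootstrap replicates. Deterministic for a fixed seed.
#'
#' @param windows list of [window_samples()] (or a single window).
#' @param n_boot number of bootstrap replicates, at least 2.
#' @param seed integer seed; global RNG state is left untouched.
#' @return non-negative standard error in kcal/mol.
#' @export
bar_stderr <- function(windows, n_boot = 200L, seed = 1L) {
  if (inherits(windows, "window_samples")) windows <- list(windows)
  if (!.is_number(n_boot) || n_boot < 2) {
    .fail("`n_boot` must be at least 2", "felbind_input_error")
  }
  .with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      res <- lapply(windows, function(w) {
        wf <- w$du_forward
        wr <- w$du_reverse
        if (length(wf)) wf <- wf[sample.int(length(wf), replace = TRUE)]
        if (length(wr)) wr <- wr[sample.int(length(wr), replace = TRUE)]
        window_samples(w$lambda_j, w$lambda_k, wf, wr, w$temperature)
      })
      bar_chain(res)$dg
    }, numeric(1))
    stats::sd(boots)
  })
}

#' One-sided exponential-averaging (Zwanzig) estimates
#'
#' Forward and reverse free energy perturbation estimates on the same
#' samples, computed via log-sum-exp shifting. The BAR estimate always lies
#' between the two; used as an independent bracket in validation.
#'
#' @param w a [window_samples()] object.
#' @return named numeric vector `c(forward =, reverse =)` in kcal/mol.
#' @export
exp_averaging <- function(w) {
  if (!inherits(w, "window_samples")) {
    .fail("`w` must be a window_samples object", "felbind_input_error")
  }
  if (length(w$du_forward) == 0L || length(w$du_reverse) == 0L) {
    .fail("both directions must be non-empty", "felbind_input_error")
  }
  kt <- kT(w$temperature)
  lse <- function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }
  c(forward = -kt * lse(-w$du_forward / kt),
    reverse = kt * lse(-w$du_reverse / kt))
}
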