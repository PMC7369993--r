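#' Crooks-consistent Gaussian work distributions with known free energy
#'
#' Ground-truth generator for BAR validation. For each window with target
#' free energy difference `dg_true` and fluctuation width `sigma`, forward
#' samples are drawn from `N(dg_true + sigma^2 / (2 kT), sigma)` and
#' reverse samples from `N(-dg_true + sigma^2 / (2 kT), sigma)`. This pair
#' satisfies the Crooks fluctuation theorem
#' `P_F(W) / P_R(-W) = exp((W - dg_true) / kT)` exactly, so the exact free
#' energy difference of the constructed pair is `dg_true` by analytic
#' identity — a closed-form oracle for any two-state estimator.
#'
#' @param dg_true numeric vector: target free energy per window
#'   (kcal/mol); one window is generated per element.
#' @param sigma work-fluctuation standard deviation(s), positive; recycled.
#' @param n samples per direction per window; recycled.
#' @param temperature temperature in Kelvin.
#' @param lambdas optional vector of `length(dg_true) + 1` lambda values;
#'   defaults to a uniform schedule over `[0, 1]`.
#' @param seed integer seed; global RNG state is untouched.
#' @return list of [window_samples()], one per window.
#' @examples
#' w <- gaussian_work_windows(dg_true = c(1, 1), sigma = 1, n = 500, seed = 7)
#' bar_chain(w)$dg # close to 2
#' @export
gaussian_work_windows <- function(dg_true, sigma = 1, n = 1000L,
                                  temperature = 298, lambdas = NULL,
                                  seed = 1L) {
  m <- length(dg_true)
  if (m == 0L || !is.numeric(dg_true) || anyNA(dg_true)) {
    .fail("`dg_true` must be a non-empty numeric vector",
          "felbind_validation_error")
  }
  sigma <- rep_len(sigma, m)
  n <- rep_len(as.integer(n), m)
  if (any(sigma <= 0) || any(n < 1L)) {
    .fail("`sigma` must be positive and `n` at least 1",
          "felbind_validation_error")
  }
  if (is.null(lambdas)) {
    lambdas <- seq(0, 1, length.out = m + 1L)
  } else if (length(lambdas) != m + 1L) {
    .fail("`lambdas` must have one more value than `dg_true`",
          "felbind_validation_error")
  }
  kt <- kT(temperature)
  .with_seed(seed, {
    lapply(seq_len(m), function(i) {
      shift <- sigma[i]^2 / (2 * kt)
      window_samples(
        lambda_j = lambdas[i], lambda_k = lambdas[i + 1L],
        du_forward = stats::rnorm(n[i], dg_true[i] + shift, sigma[i]),
        du_reverse = stats::rnorm(n[i], -dg_true[i] + shift, sigma[i]),
        temperature = temperature)
    })
  })
}

#' Two-basin collective-variable mixture with known populations
#'
#' Emulates apo-state (Rg, RMSD) statistics as a mixture of two 2-D
#' Gaussian basins with stated populations. The exact inter-basin free
#' energy gap is `-kT ln(p2 / p1)`, giving a closed-form oracle for the
#' landscape construction. Defaults place well-separated basins at values
#' realistic for a small folded protein domain.
#'
#' @param n number of samples.
#' @param p length-2 populations summing to 1.
#' @param centers 2 x 2 matrix, one `(rg, rmsd)` row per basin (nm).
#' @param sds 2 x 2 matrix of per-basin standard deviations (nm), or a
#'   single number used throughout.
#' @param temperature temperature in Kelvin (recorded for convenience).
#' @param dt frame spacing in ps for the generated time column.
#' @param seed integer seed.
#' @return a [cv_samples()] table with attribute `gap_true` (kcal/mol,
#'   the analytic basin free-energy gap) and `assignment` (basin index per
#'   sample). Warns when basins are closer than 3 standard deviations on
#'   either axis (gap no longer identifiable from histogram populations).
#' @export
two_basin_cv <- function(n, p = c(0.8, 0.2),
                         centers = rbind(c(1.10, 0.15), c(1.25, 0.35)),
                         sds = 0.015, temperature = 298, dt = 10,
                         seed = 1L) {
  if (!.is_number(n) || n < 1) {
    .fail("`n` must be a positive count", "felbind_validation_error")
  }
  if (length(p) != 2L || any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
    .fail("`p` must be two positive populations summing to 1",
          "felbind_validation_error")
  }
  centers <- as.matrix(centers)
  if (!all(dim(centers) == c(2L, 2L))) {
    .fail("`centers` must be a 2 x 2 matrix of (rg, rmsd) rows",
          "felbind_validation_error")
  }
  if (length(sds) == 1L) sds <- matrix(sds, 2, 2)
  sds <- as.matrix(sds)
  if (any(sds <= 0)) {
    .fail("`sds` must be positive", "felbind_validation_error")
  }
  sep <- abs(centers[1, ] - centers[2, ]) / (sds[1, ] + sds[2, ])
  if (all(sep < 3)) {
    .warn(paste0("basins closer than 3 standard deviations on every axis; ",
                 "the free-energy gap is not identifiable from histogram ",
                 "populations"),
          "felbind_overlap_warning")
  }
  kt <- kT(temperature)
  .with_seed(seed, {
    basin <- sample.int(2L, n, replace = TRUE, prob = p)
    rg <- stats::rnorm(n, centers[basin, 1], sds[basin, 1])
    rmsd <- stats::rnorm(n, centers[basin, 2], sds[basin, 2])
    out <- cv_samples(time = (seq_len(n) - 1) * dt,
                      rg = pmax(rg, 0), rmsd = pmax(rmsd, 0))
    attr(out, "gap_true") <- -kt * log(p[2] / p[1])
    attr(out, "assignment") <- basin
    out
  })
}

## Random proper rotation matrix (QR of a Gaussian matrix, det +1).
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Toy structures under known rigid motions and controlled noise
#'
#' Builds a random reference structure and frames that are the reference
#' under random rigid rotation + translation, plus a per-atom displacement
#' of fixed magnitude `noise` in a uniformly random direction. Since the
#' rigid part is removed exactly by superposition and the displacements
#' have fixed length, the expected post-superposition RMSD of each frame
#' is `noise` (exact in the large-N limit).
#'
#' @param n_atoms atoms per structure.
#' @param n_frames number of generated frames.
#' @param noise per-atom displacement magnitude (nm); may be a vector with
#'   one value per frame. Zero gives exact rigid copies.
#' @param box edge of the cubic region (nm) in which reference atoms are
#'   placed uniformly.
#' @param seed integer seed.
#' @return list with `reference` ([mol_structure()]), `frames` (list of
#'   [mol_structure()]) and `known_rmsd` (numeric, nm: the designed
#'   displacement magnitude per frame).
#' @export
toy_structures <- function(n_atoms = 50L, n_frames = 5L, noise = 0,
                           box = 2, seed = 1L) {
  if (!.is_number(n_atoms) || n_atoms < 1 ||
      !.is_number(n_frames) || n_frames < 1) {
    .fail("`n_atoms` and `n_frames` must be positive counts",
          "felbind_validation_error")
  }
  noise <- rep_len(noise, n_frames)
  if (any(noise < 0)) {
    .fail("`noise` must be non-negative", "felbind_validation_error")
  }
  .with_seed(seed, {
    ref <- mol_structure(
      matrix(stats::runif(3 * n_atoms, 0, box), ncol = 3),
      masses = stats::runif(n_atoms, 1, 16))
    frames <- lapply(seq_len(n_frames), function(f) {
      R <- .random_rotation()
      t_vec <- stats::runif(3, -box, box)
      moved <- ref$coords %*% t(R) + matrix(t_vec, n_atoms, 3, byrow = TRUE)
      if (noise[f] > 0) {
        dir <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        moved <- moved + noise[f] * dir
      }
      mol_structure(moved, ref$masses)
    })
    list(reference = ref, frames = frames, known_rmsd = noise)
  })
}

#' Synthetic full thermodynamic cycle with designed binding free energy
#'
#' Generates Gaussian-work windows for both decoupling legs with designed
#' per-leg totals and combines them with the analytical restraint term so
#' the designed standard binding free energy is known exactly:
#' `dg_design = -dg_prot + dg_solv + boresch_dg(rest)`.
#'
#' @param dg_prot_total designed complex-leg decoupling total (kcal/mol).
#' @param dg_solv_total designed solution-leg decoupling total (kcal/mol).
#' @param rest a [boresch_restraint()]; its analytic value closes the
#'   cycle.
#' @param n_windows_prot,n_windows_solv windows per leg.
#' @param sigma work-fluctuation width (kcal/mol).
#' @param n samples per direction per window.
#' @param temperature temperature in Kelvin.
#' @param seed integer seed.
#' @return list with `prot_windows`, `solv_windows`, `restraint`,
#'   `dg_design` (kcal/mol) and the per-leg designed totals.
#' @export
synthetic_cycle <- function(dg_prot_total, dg_solv_total, rest,
                            n_windows_prot = 6L, n_windows_solv = 4L,
                            sigma = 1, n = 1000L, temperature = 298,
                            seed = 1L) {
  if (!inherits(rest, "boresch_restraint")) {
    .fail("`rest` must be a boresch_restraint", "felbind_input_error")
  }
  split_total <- function(total, k) rep(total / k, k)
  prot <- gaussian_work_windows(split_total(dg_prot_total, n_windows_prot),
                                sigma = sigma, n = n,
                                temperature = temperature, seed = seed)
  solv <- gaussian_work_windows(split_total(dg_solv_total, n_windows_solv),
                                sigma = sigma, n = n,
                                temperature = temperature,
                                seed = seed + 104729L)
  dg_restr <- boresch_dg(rest)
  list(prot_windows = prot, solv_windows = solv, restraint = rest,
       dg_prot_total = dg_prot_total, dg_solv_total = dg_solv_total,
       dg_design = -dg_prot_total + dg_solv_total + dg_restr)
}
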