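#' Molecular structure: coordinates plus masses
#'
#' Minimal coordinate container for collective-variable computation: an
#' `N x 3` coordinate matrix in nm and a vector of N positive atomic
#' masses (amu).
#'
#' @param coords numeric `N x 3` matrix of coordinates (nm).
#' @param masses numeric vector of N positive masses (amu).
#' @return object of class `mol_structure`.
#' @seealso [read_coordinates()], [radius_of_gyration()], [kabsch_rmsd()]
#' @export
mol_structure <- function(coords, masses) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) < 1L ||
      any(!is.finite(coords))) {
    .fail("`coords` must be a finite numeric N x 3 matrix with N >= 1",
          "felbind_input_error")
  }
  masses <- as.numeric(masses)
  if (length(masses) != nrow(coords) || anyNA(masses) ||
      any(!is.finite(masses)) || any(masses <= 0)) {
    .fail("`masses` must be one positive finite mass per atom",
          "felbind_input_error")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, masses = masses,
                 atom_count = nrow(coords)),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure> %d atoms, total mass %.2f amu\n",
              x$atom_count, sum(x$masses)))
  invisible(x)
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )`, the mass-weighted
#' RMS distance of the atoms from their centre of mass. Invariant under
#' rigid translation and rotation.
#'
#' @param s a [mol_structure()].
#' @return radius of gyration in nm (non-negative).
#' @export
radius_of_gyration <- function(s) {
  if (!inherits(s, "mol_structure")) {
    .fail("`s` must be a mol_structure", "felbind_input_error")
  }
  w <- s$masses / sum(s$masses)
  com <- colSums(s$coords * w)
  d2 <- rowSums(sweep(s$coords, 2, com)^2)
  sqrt(sum(w * d2))
}

#' Minimum RMSD after optimal rigid superposition (Kabsch)
#'
#' Superimposes `mobile` onto `reference` by the rotation that minimises
#' the (fit-)weighted sum of squared deviations, obtained from the SVD of
#' the weighted covariance matrix with the determinant-sign correction so
#' that only proper rotations (no reflections) are returned, then reports
#' the root-mean-square deviation of the superposed coordinates.
#'
#' By default the fit is mass-weighted and the reported deviation is
#' unweighted, the dominant convention of trajectory-analysis tools; both
#' choices can be changed independently.
#'
#' @param mobile,reference [mol_structure()] objects with equal atom
#'   counts and consistent atom ordering.
#' @param fit_weights `"mass"` or `"uniform"`: weights for centring and
#'   for the rotational fit.
#' @param dev_weights `"uniform"` or `"mass"`: weights for the reported
#'   deviation.
#' @return minimum RMSD in nm.
#' @export
kabsch_rmsd <- function(mobile, reference,
                        fit_weights = c("mass", "uniform"),
                        dev_weights = c("uniform", "mass")) {
  if (!inherits(mobile, "mol_structure") ||
      !inherits(reference, "mol_structure")) {
    .fail("`mobile` and `reference` must be mol_structure objects",
          "felbind_input_error")
  }
  if (mobile$atom_count != reference$atom_count) {
    .fail(sprintf("atom-count mismatch: mobile has %d, reference has %d",
                  mobile$atom_count, reference$atom_count),
          "felbind_input_error")
  }
  fit_weights <- match.arg(fit_weights)
  dev_weights <- match.arg(dev_weights)
  n <- mobile$atom_count
  wf <- if (fit_weights == "mass") mobile$masses else rep(1, n)
  wf <- wf / sum(wf)
  P <- sweep(mobile$coords, 2, colSums(mobile$coords * wf))
  Q <- sweep(reference$coords, 2, colSums(reference$coords * wf))
  H <- t(P * wf) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- P %*% t(R)
  wd <- if (dev_weights == "mass") mobile$masses else rep(1, n)
  wd <- wd / sum(wd)
  sqrt(sum(wd * rowSums((Pr - Q)^2)))
}

#' Collective-variable time series over trajectory frames
#'
#' Computes one `(time, Rg, RMSD)` row per frame: the mass-weighted radius
#' of gyration of each frame and its Kabsch RMSD against a fixed reference
#' structure (by convention the first production frame).
#'
#' @param frames list of [mol_structure()] frames.
#' @param reference fixed reference [mol_structure()].
#' @param times optional numeric vector of frame times (ps, non-decreasing).
#'   Defaults to `0, dt, 2*dt, ...`.
#' @param dt frame spacing in ps used when `times` is absent (default 10).
#' @param ... passed to [kabsch_rmsd()].
#' @return object of classes `cv_samples`/`data.frame` with columns
#'   `time` (ps), `rg` (nm), `rmsd` (nm).
#' @export
cv_timeseries <- function(frames, reference, times = NULL, dt = 10, ...) {
  if (inherits(frames, "mol_structure")) frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L) {
    .fail("`frames` must be a non-empty list of mol_structure objects",
          "felbind_input_error")
  }
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "mol_structure") ||
        f$atom_count != reference$atom_count) {
      .fail(sprintf("frame %d is not atom-compatible with the reference", i),
            "felbind_input_error")
    }
  }
  if (is.null(times)) {
    times <- (seq_along(frames) - 1) * dt
  } else if (length(times) != length(frames) || is.unsorted(times)) {
    .fail("`times` must be non-decreasing with one value per frame",
          "felbind_input_error")
  }
  cv_samples(
    time = times,
    rg = vapply(frames, radius_of_gyration, numeric(1)),
    rmsd = vapply(frames, kabsch_rmsd, numeric(1),
                  reference = reference, ...))
}

#' Construct a collective-variable sample table
#'
#' @param time times in ps, non-decreasing.
#' @param rg radii of gyration in nm, non-negative.
#' @param rmsd RMSD values in nm, non-negative.
#' @return object of classes `cv_samples`/`data.frame`.
#' @export
cv_samples <- function(time, rg, rmsd) {
  if (length(time) != length(rg) || length(rg) != length(rmsd)) {
    .fail("`time`, `rg`, `rmsd` must have equal lengths",
          "felbind_input_error")
  }
  if (anyNA(c(time, rg, rmsd)) || any(!is.finite(c(time, rg, rmsd)))) {
    .fail("collective-variable samples must be finite",
          "felbind_input_error")
  }
  if (any(rg < 0) || any(rmsd < 0)) {
    .fail("`rg` and `rmsd` must be non-negative", "felbind_domain_error")
  }
  if (is.unsorted(time)) {
    .fail("`time` must be non-decreasing within a series",
          "felbind_domain_error")
  }
  structure(data.frame(time = time, rg = rg, rmsd = rmsd),
            class = c("cv_samples", "data.frame"))
}
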