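#' Build a two-dimensional free energy landscape over (Rg, RMSD)
#'
#' Histograms the collective-variable samples on a regular 2-D grid and
#' converts bin populations into relative Gibbs free energies,
#' `G(bin) = -kT ln( n(bin) / n_max )`, so the most populated bin sits at
#' exactly zero and every occupied bin carries a non-negative value. Empty
#' bins carry no free energy (flagged `NA`), never zero. No kernel
#' smoothing is applied: populations enter the landscape raw.
#'
#' The grid spans the sample range on each axis padded by one bin width on
#' both sides.
#'
#' @param samples a [cv_samples()] table (columns `rg`, `rmsd`) with at
#'   least one row.
#' @param n_bins integer vector of length 2: bins along (Rg, RMSD); each
#'   at least 2. Default `c(100, 100)`.
#' @param temperature temperature in Kelvin fixing `kT`.
#' @return object of class `fel_grid`: list with `rg_edges`, `rmsd_edges`
#'   (bin-edge vectors, nm), `g` (free-energy matrix, kcal/mol, `NA` for
#'   empty bins), `counts`, `kT` (kcal/mol) and `n_samples`.
#' @seealso [fel_lookup()], [correction_term()], [two_basin_cv()]
#' @export
build_fel <- function(samples, n_bins = c(100L, 100L), temperature = 298) {
  if (!is.data.frame(samples) || !all(c("rg", "rmsd") %in% names(samples)) ||
      nrow(samples) < 1L) {
    .fail("`samples` must be a cv_samples table with at least one row",
          "felbind_input_error")
  }
  n_bins <- as.integer(round(n_bins))
  if (length(n_bins) == 1L) n_bins <- rep(n_bins, 2L)
  if (length(n_bins) != 2L || any(!is.finite(n_bins)) || any(n_bins < 2L)) {
    .fail("`n_bins` must give at least 2 bins along each axis",
          "felbind_config_error")
  }
  kt <- kT(temperature)
  edges_for <- function(x, nb) {
    r <- range(x)
    span <- diff(r)
    if (span == 0) span <- max(abs(r[1]), 0.1) * 0.1
    w <- span / max(nb - 2L, 1L)    # interior width; one pad bin each side
    seq(r[1] - w, r[1] - w + nb * w, length.out = nb + 1L)
  }
  rg_edges <- edges_for(samples$rg, n_bins[1])
  rmsd_edges <- edges_for(samples$rmsd, n_bins[2])
  ix <- findInterval(samples$rg, rg_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(samples$rmsd, rmsd_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, n_bins[1], n_bins[2])
  tab <- table(factor(ix, levels = seq_len(n_bins[1])),
               factor(iy, levels = seq_len(n_bins[2])))
  counts[] <- as.integer(tab)
  g <- -kt * log(counts / max(counts))
  g[counts == 0L] <- NA_real_
  structure(list(rg_edges = rg_edges, rmsd_edges = rmsd_edges,
                 g = g, counts = counts, kT = kt,
                 n_samples = nrow(samples)),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(!is.na(x$g))
  cat(sprintf(
    paste0("<fel_grid> %d x %d bins over Rg [%.3g, %.3g] nm x RMSD ",
           "[%.3g, %.3g] nm\n  %d samples, %d occupied bins, ",
           "max G = %.3g kcal/mol (kT = %.4g)\n"),
    nrow(x$g), ncol(x$g), min(x$rg_edges), max(x$rg_edges),
    min(x$rmsd_edges), max(x$rmsd_edges), x$n_samples, occ,
    max(x$g, na.rm = TRUE), x$kT))
  invisible(x)
}

## Bin index of a point along one axis, or NA when outside the grid.
.bin_index <- function(x, edges) {
  if (x < edges[1] || x > edges[length(edges)]) return(NA_integer_)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Look up the free energy at a collective-variable point
#'
#' Returns the free energy of the grid bin containing `(rg, rmsd)`. Points
#' falling in an empty bin or outside the grid are handled per `policy`:
#' `"nearest_occupied"` (default) substitutes the nearest occupied bin by
#' Euclidean distance in bin-index space (ties broken deterministically by
#' a column-major scan of the grid) and emits a warning; `"error"` fails.
#'
#' @param fel a [build_fel()] grid.
#' @param rg,rmsd query point (nm); vectorised over equal lengths.
#' @param policy `"nearest_occupied"` or `"error"`.
#' @return free energy value(s) in kcal/mol.
#' @export
fel_lookup <- function(fel, rg, rmsd,
                       policy = c("nearest_occupied", "error")) {
  if (!inherits(fel, "fel_grid")) {
    .fail("`fel` must be a fel_grid", "felbind_input_error")
  }
  policy <- match.arg(policy)
  if (length(rg) != length(rmsd)) {
    .fail("`rg` and `rmsd` must have equal lengths", "felbind_input_error")
  }
  occ <- which(!is.na(fel$g), arr.ind = TRUE)
  vapply(seq_along(rg), function(i) {
    ii <- .bin_index(rg[i], fel$rg_edges)
    jj <- .bin_index(rmsd[i], fel$rmsd_edges)
    outside <- is.na(ii) || is.na(jj)
    if (!outside && !is.na(fel$g[ii, jj])) return(fel$g[ii, jj])
    if (policy == "error") {
      .fail(sprintf(
        "point (rg = %.4g, rmsd = %.4g) falls %s the landscape",
        rg[i], rmsd[i], if (outside) "outside" else "in an empty bin of"),
        "felbind_landscape_error")
    }
    ## clamp to grid, then nearest occupied bin in index space
    ci <- .bin_index(min(max(rg[i], fel$rg_edges[1]),
                         fel$rg_edges[length(fel$rg_edges)]), fel$rg_edges)
    cj <- .bin_index(min(max(rmsd[i], fel$rmsd_edges[1]),
                         fel$rmsd_edges[length(fel$rmsd_edges)]),
                     fel$rmsd_edges)
    d2 <- (occ[, 1] - ci)^2 + (occ[, 2] - cj)^2
    k <- which.min(d2)
    .warn(sprintf(
      "point (rg = %.4g, rmsd = %.4g) is %s; using nearest occupied bin",
      rg[i], rmsd[i], if (outside) "outside the landscape"
      else "in an empty bin"),
      "felbind_lookup_warning")
    fel$g[occ[k, 1], occ[k, 2]]
  }, numeric(1))
}

#' Free-energy-landscape correction term
#'
#' The flexibility correction for a complex: each end-state conformation
#' from the decoupling simulation is mapped onto the apo-state landscape by
#' its (Rg, RMSD) and the corresponding free energies are averaged. The
#' mean is the correction term added to the raw alchemical estimate; its
#' standard error of the mean (`sd / sqrt(n)`) quantifies conformational
#' spread.
#'
#' @param fel a [build_fel()] grid of the apo state.
#' @param confs [cv_samples()] of the extracted end-state conformations
#'   (non-empty; conventionally the five frames of the last 100 ps, see
#'   [tail_conformations()]).
#' @param policy lookup policy, see [fel_lookup()].
#' @return object of class `correction_result`: list with `mean`, `sem`
#'   (kcal/mol; `sem` is `NA` for a single conformation) and
#'   `per_conformation`.
#' @export
correction_term <- function(fel, confs,
                            policy = c("nearest_occupied", "error")) {
  if (!is.data.frame(confs) || nrow(confs) < 1L ||
      !all(c("rg", "rmsd") %in% names(confs))) {
    .fail("`confs` must be a non-empty cv_samples table",
          "felbind_input_error")
  }
  per <- fel_lookup(fel, confs$rg, confs$rmsd, policy = match.arg(policy))
  n <- length(per)
  structure(list(mean = mean(per),
                 sem = if (n > 1L) stats::sd(per) / sqrt(n) else NA_real_,
                 per_conformation = per),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "<correction_result> mean = %.4f kcal/mol (sem %.4f, n = %d)\n",
    x$mean, x$sem, length(x$per_conformation)))
  invisible(x)
}

#' Apply the landscape correction to a calculated binding free energy
#'
#' `dg_corrected = dg_calculated + mean(correction)`. When standard errors
#' are available for both terms they are combined, by default in
#' quadrature (`sqrt(se_dg^2 + sem^2)`); `"linear"` adds them.
#'
#' @param dg_calculated raw alchemical binding free energy (kcal/mol).
#' @param corr a [correction_term()] result, or a bare number treated as a
#'   correction with zero uncertainty.
#' @param dg_stderr optional standard error of `dg_calculated`.
#' @param error_combine `"quadrature"` (default) or `"linear"`.
#' @return list with `dg_corrected` (kcal/mol) and `stderr` (kcal/mol or
#'   `NA` when no uncertainties were supplied).
#' @examples
#' apply_correction(-17.05, 1.04)$dg_corrected # -16.01
#' @export
apply_correction <- function(dg_calculated, corr, dg_stderr = NULL,
                             error_combine = c("quadrature", "linear")) {
  if (!.is_number(dg_calculated)) {
    .fail("`dg_calculated` must be a single number (kcal/mol)",
          "felbind_input_error")
  }
  error_combine <- match.arg(error_combine)
  if (is.numeric(corr) && length(corr) == 1L) {
    corr <- structure(list(mean = corr, sem = NA_real_,
                           per_conformation = corr),
                      class = "correction_result")
  }
  if (!inherits(corr, "correction_result")) {
    .fail("`corr` must be a correction_result or a single number",
          "felbind_input_error")
  }
  se <- NA_real_
  ses <- c(if (!is.null(dg_stderr)) dg_stderr,
           if (is.finite(corr$sem)) corr$sem)
  if (length(ses)) {
    se <- if (error_combine == "quadrature") sqrt(sum(ses^2)) else sum(ses)
  }
  list(dg_corrected = dg_calculated + corr$mean, stderr = se)
}

#' Inter-basin free energy gap from a landscape
#'
#' Reads the free energy difference between two basins off a built
#' landscape, with the basins separated by a straight cut along one axis.
#' Two estimators are returned:
#' \describe{
#'   \item{`gap_population`}{`-kT ln(P_minor / P_major)` from the summed
#'     bin populations of each basin. Boltzmann-integrating the landscape
#'     this way is statistically tight (binomial noise of order
#'     `kT/sqrt(n_basin)`) and equals the depth difference of the basin
#'     minima exactly when the basins have matching shape.}
#'   \item{`gap_min`}{difference of the minimum bin free energies (the two
#'     modal bins). Conceptually direct but carries Poisson noise of order
#'     `kT/sqrt(n_peak_bin)`, which is substantial for raw histograms.}
#' }
#'
#' @param fel a [build_fel()] grid.
#' @param split cut position (nm) separating the basins.
#' @param axis `"rg"` or `"rmsd"`: axis along which to cut.
#' @return list with `gap_population`, `gap_min` (kcal/mol, positive when
#'   the second basin — above the cut — is the minor one) and the basin
#'   populations.
#' @export
fel_basin_gap <- function(fel, split, axis = c("rg", "rmsd")) {
  if (!inherits(fel, "fel_grid")) {
    .fail("`fel` must be a fel_grid", "felbind_input_error")
  }
  axis <- match.arg(axis)
  edges <- if (axis == "rg") fel$rg_edges else fel$rmsd_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  below <- centers < split
  if (!any(below) || all(below)) {
    .fail("`split` must cut the grid into two non-empty parts",
          "felbind_input_error")
  }
  pick <- function(keep) {
    if (axis == "rg") list(counts = fel$counts[keep, , drop = FALSE],
                           g = fel$g[keep, , drop = FALSE])
    else list(counts = fel$counts[, keep, drop = FALSE],
              g = fel$g[, keep, drop = FALSE])
  }
  a <- pick(below)
  b <- pick(!below)
  n_a <- sum(a$counts)
  n_b <- sum(b$counts)
  if (n_a == 0L || n_b == 0L) {
    .fail("one side of the cut holds no samples", "felbind_input_error")
  }
  list(gap_population = -fel$kT * log(n_b / n_a),
       gap_min = min(b$g, na.rm = TRUE) - min(a$g, na.rm = TRUE),
       n_below = n_a, n_above = n_b)
}

#' Evenly strided end-state conformations from the tail of a series
#'
#' Selects `n` conformations, evenly strided, from the final `window` ps
#' of a collective-variable time series — the extraction protocol for the
#' conformations entering [correction_term()] (five frames from the last
#' 100 ps by default).
#'
#' @param cv a [cv_samples()] table.
#' @param n number of conformations to extract.
#' @param window length of the tail in ps.
#' @return a [cv_samples()] subset with `n` rows (fewer only when the tail
#'   itself holds fewer samples).
#' @export
tail_conformations <- function(cv, n = 5L, window = 100) {
  if (!is.data.frame(cv) || nrow(cv) < 1L) {
    .fail("`cv` must be a non-empty cv_samples table", "felbind_input_error")
  }
  if (!.is_number(n) || n < 1) {
    .fail("`n` must be a positive count", "felbind_input_error")
  }
  t_end <- max(cv$time)
  tail_idx <- which(cv$time >= t_end - window)
  pick <- unique(round(seq(1, length(tail_idx), length.out = min(n, length(tail_idx)))))
  out <- cv[tail_idx[pick], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cv_samples", "data.frame")
  out
}
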