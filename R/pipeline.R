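#' Run a full ABFE analysis for one complex
#'
#' Wires the per-complex workflow: chained BAR estimates for the complex
#' and solution decoupling legs, bootstrap standard errors, the analytical
#' Boresch restraint term, and assembly of the thermodynamic cycle.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{`prot_windows`}{list of [window_samples()] for the complex
#'       leg (required).}
#'     \item{`solv_windows`}{list of [window_samples()] for the solution
#'       leg (required).}
#'     \item{`restraint`}{a [boresch_restraint()] (required).}
#'     \item{`n_boot`}{bootstrap replicates for leg standard errors
#'       (default 100).}
#'     \item{`seed`}{integer seed (default 1).}
#'   }
#' @return object of class `abfe_report`: per-leg free energies with
#'   standard errors, the restraint term and the assembled binding free
#'   energy (both per-leg and propagated uncertainties are reported).
#' @export
run_abfe <- function(config) {
  config <- .load_config(config)
  for (leg in c("prot_windows", "solv_windows")) {
    if (is.null(config[[leg]])) {
      .fail(sprintf("missing leg data: `%s` is required in the config", leg),
            "felbind_config_error")
    }
  }
  if (is.null(config$restraint)) {
    .fail("missing `restraint` definition in the config",
          "felbind_config_error")
  }
  n_boot <- config$n_boot %||% 100L
  seed <- config$seed %||% 1L
  prot <- bar_chain(config$prot_windows)
  solv <- bar_chain(config$solv_windows)
  prot$stderr <- bar_stderr(config$prot_windows, n_boot = n_boot,
                            seed = seed)
  solv$stderr <- bar_stderr(config$solv_windows, n_boot = n_boot,
                            seed = seed + 1L)
  dg_restr <- boresch_dg(config$restraint)
  legs <- cycle_legs(prot$dg, solv$dg, dg_restr,
                     se_prot = prot$stderr, se_solv = solv$stderr,
                     se_restr = 0)
  total <- assemble_binding_dg(legs)
  structure(list(prot = prot, solv = solv, dg_restr_on_solv = dg_restr,
                 dg_binding = total$dg, stderr = total$stderr,
                 seed = seed),
            class = "abfe_report")
}

#' @export
print.abfe_report <- function(x, ...) {
  cat("<abfe_report>\n")
  cat(sprintf("  complex leg (decouple):  %8.3f +/- %.3f kcal/mol\n",
              x$prot$dg, x$prot$stderr))
  cat(sprintf("  solution leg (decouple): %8.3f +/- %.3f kcal/mol\n",
              x$solv$dg, x$solv$stderr))
  cat(sprintf("  restraint on (analytic): %8.3f kcal/mol\n",
              x$dg_restr_on_solv))
  cat(sprintf("  dG_binding:              %8.3f +/- %.3f kcal/mol\n",
              x$dg_binding, x$stderr))
  invisible(x)
}

#' Run the landscape correction workflow for one complex
#'
#' Builds (or accepts) the apo-state free energy landscape, maps the
#' end-state conformations onto it, and applies the averaged correction to
#' the calculated binding free energy.
#'
#' @param config named list (or YAML path) with entries:
#'   \describe{
#'     \item{`fel`}{a [build_fel()] grid, or `apo_cv` (a [cv_samples()]
#'       table) from which to build one.}
#'     \item{`confs`}{[cv_samples()] of extracted end-state conformations
#'       (required).}
#'     \item{`dg_calculated`}{raw binding free energy (required).}
#'     \item{`dg_stderr`}{optional standard error of `dg_calculated`.}
#'     \item{`n_bins`, `temperature`, `policy`, `error_combine`}{options
#'       forwarded to [build_fel()], [correction_term()] and
#'       [apply_correction()].}
#'   }
#' @return object of class `correction_report` with the landscape used,
#'   the correction term and the corrected value.
#' @export
run_correction <- function(config) {
  config <- .load_config(config)
  if (is.null(config$dg_calculated)) {
    .fail("missing `dg_calculated` in the config", "felbind_config_error")
  }
  if (is.null(config$confs)) {
    .fail("missing `confs` (end-state conformations) in the config",
          "felbind_config_error")
  }
  fel <- config$fel
  if (is.null(fel)) {
    if (is.null(config$apo_cv)) {
      .fail("config needs either a prebuilt `fel` or `apo_cv` samples",
            "felbind_config_error")
    }
    fel <- build_fel(config$apo_cv,
                     n_bins = config$n_bins %||% c(100L, 100L),
                     temperature = config$temperature %||% 298)
  }
  corr <- correction_term(fel, config$confs,
                          policy = config$policy %||% "nearest_occupied")
  res <- apply_correction(config$dg_calculated, corr,
                          dg_stderr = config$dg_stderr,
                          error_combine = config$error_combine %||%
                            "quadrature")
  structure(list(fel = fel, correction = corr,
                 dg_calculated = config$dg_calculated,
                 dg_corrected = res$dg_corrected, stderr = res$stderr),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report>\n")
  cat(sprintf("  dG_calculated: %8.3f kcal/mol\n", x$dg_calculated))
  cat(sprintf("  dG_correction: %8.3f +/- %.3f kcal/mol (n = %d)\n",
              x$correction$mean, x$correction$sem,
              length(x$correction$per_conformation)))
  cat(sprintf("  dG_corrected:  %8.3f", x$dg_corrected))
  if (is.finite(x$stderr)) cat(sprintf(" +/- %.3f", x$stderr))
  cat(" kcal/mol\n")
  invisible(x)
}

#' Evaluate a benchmark dataset against experiment
#'
#' Converts experimental affinities to free energies where the dataset
#' does not already carry them, optionally applies stored corrections, and
#' computes the benchmark metrics.
#'
#' @param config named list (or YAML path) with entries:
#'   \describe{
#'     \item{`dataset`}{a `complex_dataset` data frame or a CSV path for
#'       [read_dataset()] (required).}
#'     \item{`corrected`}{logical: evaluate `dg_calculated +
#'       dg_correction` instead of `dg_calculated` (default `FALSE`).}
#'     \item{`temperature`}{Kelvin, for affinity conversion (default 298).}
#'   }
#' @return an [evaluate_predictions()] report.
#' @export
run_evaluate <- function(config) {
  config <- .load_config(config)
  ds <- config$dataset
  if (is.null(ds)) {
    .fail("missing `dataset` in the config", "felbind_config_error")
  }
  if (is.character(ds)) ds <- read_dataset(ds)
  temperature <- config$temperature %||% 298
  ref <- ds$dg_experimental
  if (is.null(ref)) ref <- rep(NA_real_, nrow(ds))
  need <- !is.finite(ref)
  if (any(need)) {
    ref[need] <- dg_from_affinity(ds$affinity_value[need],
                                  ds$affinity_unit[need],
                                  temperature = temperature)
  }
  pred <- ds$dg_calculated
  if (isTRUE(config$corrected)) {
    if (is.null(ds$dg_correction) || anyNA(ds$dg_correction)) {
      .fail("`corrected = TRUE` requires a complete dg_correction column",
            "felbind_config_error")
    }
    pred <- pred + ds$dg_correction
  }
  evaluate_predictions(pred, ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Accept either an in-memory list or a YAML file path.
.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      .fail("reading YAML configs requires the 'yaml' package",
            "felbind_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    .fail("`config` must be a named list or a YAML file path",
          "felbind_config_error")
  }
  config
}

#' MDMX inhibitor benchmark table
#'
#' The five-complex MDMX benchmark (crystal structures 3LBJ, 2N14, 2N06,
#' 2N0U and the docked ligand WK23): calculated absolute binding free
#' energies with standard errors, IC50 affinities and experimental binding
#' free energies.
#'
#' @return a `complex_dataset` data frame with 5 rows.
#' @seealso [mdm2_benchmark()], [read_dataset()]
#' @export
mdmx_benchmark <- function() {
  read_dataset(system.file("extdata", "mdmx_benchmark.csv",
                           package = "felbind", mustWork = TRUE))
}

#' MDM2 inhibitor benchmark table
#'
#' The fourteen-complex MDM2 benchmark spanning pyrazolopyrrolidinone to
#' morpholinone chemotypes: calculated binding free energies, landscape
#' correction terms, corrected values, affinities (IC50 or Ki) and
#' experimental free energies.
#'
#' @return a `complex_dataset` data frame with 14 rows.
#' @export
mdm2_benchmark <- function() {
  read_dataset(system.file("extdata", "mdm2_benchmark.csv",
                           package = "felbind", mustWork = TRUE))
}
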