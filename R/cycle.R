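#' Lambda schedule for one decoupling leg
#'
#' Ordered coupling-parameter values for the coulomb, van der Waals and
#' (complex leg only) bonded-restraint transformations. Each window is one
#' lambda state simulated independently; the window count of a schedule is
#' the total number of lambda values across its components.
#'
#' @param coulomb,vdw,bonded numeric vectors of lambda values in `[0, 1]`;
#'   `bonded` may be `NULL` for the solution leg.
#' @return object of class `lambda_schedule`.
#' @seealso [default_schedules()], [validate_schedule()]
#' @export
lambda_schedule <- function(coulomb, vdw, bonded = NULL) {
  for (v in list(coulomb, vdw)) {
    if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v))) {
      .fail("schedule components must be non-empty finite numeric vectors",
            "felbind_input_error")
    }
  }
  if (!is.null(bonded) && (!is.numeric(bonded) || any(!is.finite(bonded)))) {
    .fail("`bonded` must be numeric when present", "felbind_input_error")
  }
  structure(list(coulomb = as.numeric(coulomb), vdw = as.numeric(vdw),
                 bonded = if (is.null(bonded)) NULL else as.numeric(bonded)),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> %d windows (coulomb %d, vdw %d%s)\n",
              n_windows(x), length(x$coulomb), length(x$vdw),
              if (is.null(x$bonded)) ""
              else sprintf(", bonded %d", length(x$bonded))))
  invisible(x)
}

#' Total number of lambda windows in a schedule
#'
#' @param s a [lambda_schedule()].
#' @return integer window count.
#' @export
n_windows <- function(s) {
  if (!inherits(s, "lambda_schedule")) {
    .fail("`s` must be a lambda_schedule", "felbind_input_error")
  }
  length(s$coulomb) + length(s$vdw) + length(s$bonded)
}

#' Default decoupling schedules
#'
#' The lambda schedules of the ABFE protocol: electrostatics switched off
#' first over five uniformly spaced windows (step 0.25), then van der
#' Waals interactions over fifteen non-uniform windows; the complex leg
#' additionally switches the ligand restraints on over ten bonded windows.
#' Totals: 20 windows for the solution leg, 30 for the complex leg.
#'
#' @return list with elements `solution` and `complex`, each a
#'   [lambda_schedule()].
#' @examples
#' n_windows(default_schedules()$complex) # 30
#' @export
default_schedules <- function() {
  coulomb <- c(0, 0.25, 0.5, 0.75, 1)
  vdw <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.65, 0.7, 0.75,
           0.8, 0.85, 0.9, 0.95, 1)
  bonded <- c(0.01, 0.025, 0.05, 0.075, 0.1, 0.2, 0.35, 0.5, 0.75, 1)
  list(solution = lambda_schedule(coulomb, vdw),
       complex = lambda_schedule(coulomb, vdw, bonded))
}

#' Validate a lambda schedule
#'
#' Report-based check: flags out-of-range, duplicated or non-increasing
#' lambda values per component and reports window counts. Never throws.
#'
#' @param s a [lambda_schedule()].
#' @return list with `valid` (logical), `issues` (character vector),
#'   `n_windows` and `per_component` counts.
#' @export
validate_schedule <- function(s) {
  if (!inherits(s, "lambda_schedule")) {
    .fail("`s` must be a lambda_schedule", "felbind_input_error")
  }
  issues <- character(0)
  comps <- list(coulomb = s$coulomb, vdw = s$vdw, bonded = s$bonded)
  comps <- comps[!vapply(comps, is.null, logical(1))]
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (any(v < 0 | v > 1)) {
      issues <- c(issues, sprintf(
        "%s: lambda out of [0, 1]: %s", nm,
        paste(v[v < 0 | v > 1], collapse = ", ")))
    }
    if (anyDuplicated(v)) {
      issues <- c(issues, sprintf(
        "%s: duplicated lambda: %s", nm,
        paste(unique(v[duplicated(v)]), collapse = ", ")))
    }
    if (is.unsorted(v, strictly = TRUE) && !anyDuplicated(v)) {
      issues <- c(issues, sprintf("%s: lambda values not increasing", nm))
    }
  }
  list(valid = length(issues) == 0L, issues = issues,
       n_windows = n_windows(s),
       per_component = vapply(comps, length, integer(1)))
}

#' Free energy legs of the binding thermodynamic cycle
#'
#' @param dg_prot_decouple free energy of turning off electrostatics, van
#'   der Waals and restraints for the ligand in complex (kcal/mol).
#' @param dg_solv_decouple free energy of turning off electrostatics and
#'   van der Waals for the ligand in solution (kcal/mol).
#' @param dg_restr_on_solv analytical free energy of restraining the
#'   non-interacting ligand at standard concentration (kcal/mol), from
#'   [boresch_dg()].
#' @param se_prot,se_solv,se_restr optional standard errors per leg.
#' @return object of class `cycle_legs`.
#' @export
cycle_legs <- function(dg_prot_decouple, dg_solv_decouple, dg_restr_on_solv,
                       se_prot = NA_real_, se_solv = NA_real_,
                       se_restr = NA_real_) {
  for (v in c(dg_prot_decouple, dg_solv_decouple, dg_restr_on_solv)) {
    if (!.is_number(v)) {
      .fail("all cycle legs must be finite numbers (kcal/mol)",
            "felbind_input_error")
    }
  }
  structure(list(dg_prot_decouple = dg_prot_decouple,
                 dg_solv_decouple = dg_solv_decouple,
                 dg_restr_on_solv = dg_restr_on_solv,
                 se_prot = se_prot, se_solv = se_solv, se_restr = se_restr),
            class = "cycle_legs")
}

#' Assemble the standard binding free energy from the cycle legs
#'
#' Closes the non-physical thermodynamic cycle:
#' `dG_binding = -dG_prot_decouple + dG_solv_decouple + dG_restr_on_solv`,
#' with both decoupling legs expressed as the free energy of turning
#' interactions off. Leg uncertainties, where present, combine in
#' quadrature.
#'
#' @param legs a [cycle_legs()] object.
#' @return list with `dg` (kcal/mol) and `stderr` (kcal/mol or `NA`).
#' @examples
#' assemble_binding_dg(cycle_legs(10, -2, 1))$dg # -11
#' @export
assemble_binding_dg <- function(legs) {
  if (!inherits(legs, "cycle_legs")) {
    .fail("`legs` must be a cycle_legs object", "felbind_input_error")
  }
  ses <- c(legs$se_prot, legs$se_solv, legs$se_restr)
  ses <- ses[is.finite(ses)]
  list(dg = -legs$dg_prot_decouple + legs$dg_solv_decouple +
         legs$dg_restr_on_solv,
       stderr = if (length(ses)) sqrt(sum(ses^2)) else NA_real_)
}
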