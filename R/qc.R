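# Model quality control: futile energy cycles, dead-end metabolites, and
# functional validation tests.

#' Closed-system energy cycle test
#'
#' With every exchange closed, no energy drain should be able to carry
#' flux: a positive optimum means internal pathway cycles can generate
#' energy from nothing. Failures are reported with the loop participants
#' from [detect_loops()] as witnesses.
#'
#' @param model a `metabolic_model` or wrapper.
#' @param energy_drains reaction ids of energy drains (e.g. ATP
#'   maintenance hydrolysis).
#' @param tol flux tolerance.
#' @return a `qc_report` data.frame: `test`, `outcome` (`pass`/`fail`),
#'   `value`, `witnesses`.
#' @export
energy_cycle_test <- function(model, energy_drains, tol = 1e-6) {
  model <- as_metabolic_model(model)
  if (!length(energy_drains)) {
    warning("no energy drains listed; vacuous pass")
    return(.qc_report(data.frame(test = "energy_cycle", outcome = "pass",
                                 value = 0, witnesses = "",
                                 stringsAsFactors = FALSE)))
  }
  unknown <- setdiff(energy_drains, model$reactions$id)
  if (length(unknown)) stop("unknown energy drain(s): ",
                            paste(unknown, collapse = ", "))
  ex <- model$reactions$id[model$reactions$kind == "exchange"]
  closed <- set_bounds(model, ex, lb = 0, ub = 0)
  rows <- lapply(energy_drains, function(d) {
    sol <- fba(closed, setNames(1, d), "max")
    val <- if (sol$status == "optimal") sol$objective_value else Inf
    ok <- sol$status == "optimal" && val <= tol
    wit <- if (ok) "" else paste(detect_loops(model, tol), collapse = ",")
    data.frame(test = paste0("energy_cycle:", d),
               outcome = if (ok) "pass" else "fail",
               value = val, witnesses = wit, stringsAsFactors = FALSE)
  })
  .qc_report(do.call(rbind, rows))
}

.qc_report <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("qc_report", "data.frame"))
}

#' Find dead-end metabolites
#'
#' A dead end is a metabolite that is only ever produced or only ever
#' consumed across all reactions, taking reversibility into account: a
#' species touched by a reversible reaction can be both made and consumed
#' through it and is not a dead end on that account.
#'
#' @param model a `metabolic_model` or wrapper.
#' @return character vector of dead-end metabolite ids (empty for a
#'   gap-free model).
#' @export
dead_end_metabolites <- function(model) {
  model <- as_metabolic_model(model)
  producible <- consumable <- setNames(logical(nrow(model$metabolites)),
                                       model$metabolites$id)
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    st <- model$stoichiometry[[rid]]
    fwd <- model$reactions$upper_bound[i] > 0
    rev <- model$reactions$lower_bound[i] < 0
    prod <- names(st)[(st > 0 & fwd) | (st < 0 & rev)]
    cons <- names(st)[(st < 0 & fwd) | (st > 0 & rev)]
    producible[prod] <- TRUE
    consumable[cons] <- TRUE
  }
  names(producible)[producible != consumable]
}

#' Define a functional validation test
#'
#' @param name test label.
#' @param medium named list exchange reaction id -> `c(lb, ub)` bound
#'   overrides defining the growth medium.
#' @param target either a named numeric objective over existing reactions,
#'   or a single metabolite id for which a temporary demand drain is
#'   synthesized.
#' @param expectation `"feasible_positive"` (the optimum must exceed tol)
#'   or `"zero"` (it must not).
#' @return a `function_test` object.
#' @export
function_test <- function(name, medium = list(), target,
                          expectation = c("feasible_positive", "zero")) {
  expectation <- match.arg(expectation)
  structure(list(name = name, medium = medium, target = target,
                 expectation = expectation), class = "function_test")
}

#' Run a suite of functional validation tests
#'
#' For each test the medium bounds are applied, a temporary demand drain is
#' added when the target is a metabolite id, and the target is maximized by
#' FBA. The shipped default suites (see [load_function_suite()] and
#' `inst/extdata/qc/`) encode universal tests (precursor, amino acid,
#' nucleotide, glycogen-analogue and biomass production) and cell-specific
#' tests (hepatic gluconeogenesis from lactate/alanine and urea synthesis,
#' adipocyte triacylglycerol storage from glucose and fatty acids, myocyte
#' ATP production from glucose).
#'
#' @param model a `metabolic_model` or wrapper.
#' @param suite non-empty list of [function_test()] objects.
#' @param tol positivity tolerance.
#' @return a `qc_report` data.frame with per-test `outcome`
#'   (`pass`/`fail`/`error`), `value` and witness notes.
#' @export
run_function_tests <- function(model, suite, tol = 1e-6) {
  stopifnot(length(suite) >= 1)
  model <- as_metabolic_model(model)
  rows <- lapply(suite, function(ft) {
    stopifnot(inherits(ft, "function_test"))
    m <- model
    out <- tryCatch({
      for (rid in names(ft$medium)) {
        bo <- ft$medium[[rid]]
        m <- set_bounds(m, rid, lb = bo[1], ub = bo[2])
      }
      if (is.character(ft$target) && length(ft$target) == 1L) {
        if (!ft$target %in% m$metabolites$id) {
          stop("unknown target metabolite: ", ft$target)
        }
        m <- add_reaction(m, ".DM_target", setNames(-1, ft$target),
                          lb = 0, ub = 1000, kind = "biomass")
        objective <- c(".DM_target" = 1)
      } else {
        objective <- ft$target
      }
      sol <- fba(m, objective, "max")
      val <- if (sol$status == "optimal") sol$objective_value else NA_real_
      ok <- switch(ft$expectation,
                   feasible_positive = !is.na(val) && val > tol,
                   zero = !is.na(val) && abs(val) <= tol)
      data.frame(test = ft$name, outcome = if (ok) "pass" else "fail",
                 value = val,
                 witnesses = if (ok) "" else paste0("status=", sol$status),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(test = ft$name, outcome = "error", value = NA_real_,
                 witnesses = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out
  })
  .qc_report(do.call(rbind, rows))
}

#' Load a functional test suite from a JSON file
#'
#' Suite files are JSON arrays of objects with fields `name`, `medium`
#' (object of reaction id -> [lb, ub]), `target` (metabolite id or object
#' of reaction id -> coefficient) and `expectation`. The suites shipped
#' under `inst/extdata/qc/` target the toy fixtures.
#'
#' @param path JSON file path.
#' @return list of [function_test()] objects.
#' @export
load_function_suite <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    medium <- lapply(x$medium, function(b) unlist(b))
    target <- if (is.list(x$target)) unlist(x$target) else x$target
    function_test(x$name, medium, target, x$expectation)
  })
}
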