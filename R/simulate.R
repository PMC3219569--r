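# Constraint-based analysis: FBA, FVA, flux-span metrics, loop detection,
# lexicographic multi-objective optimization and carbon-fate accounting.

.FLUX_TOL <- 1e-6

# model -> LP pieces; fixes are extra rows list(coef=named vec, sense, rhs)
.model_lp <- function(model, fixes = list()) {
  S <- as.matrix(stoich_matrix(model))
  n <- ncol(S)
  A <- S
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  for (fx in fixes) {
    row <- numeric(n)
    idx <- match(names(fx$coef), colnames(S))
    if (anyNA(idx)) {
      stop("unknown reaction in constraint: ",
           paste(names(fx$coef)[is.na(idx)], collapse = ", "))
    }
    row[idx] <- unname(fx$coef)
    A <- rbind(A, row)
    sense <- c(sense, fx$sense)
    rhs <- c(rhs, fx$rhs)
  }
  list(A = A, sense = sense, rhs = rhs,
       lb = model$reactions$lower_bound, ub = model$reactions$upper_bound,
       rxn = colnames(S))
}

.obj_vector <- function(objective, rxn) {
  obj <- numeric(length(rxn))
  if (length(objective)) {
    idx <- match(names(objective), rxn)
    if (anyNA(idx)) {
      stop("objective references unknown reaction(s): ",
           paste(names(objective)[is.na(idx)], collapse = ", "))
    }
    obj[idx] <- unname(objective)
  }
  obj
}

#' Flux balance analysis
#'
#' Solves `max (or min) c'v` subject to the steady-state mass balance
#' `S v = 0` and the flux bounds `lb <= v <= ub`.
#'
#' @param model a `metabolic_model` (or a wrapper such as a
#'   `multi_tissue_model`).
#' @param objective named numeric objective coefficients over reaction ids;
#'   defaults to the model objective.
#' @param direction `"max"` or `"min"`.
#' @param fixes list of extra linear constraints, each
#'   `list(coef = <named numeric>, sense = "="/"<="/">=", rhs = <numeric>)`.
#' @return a `flux_solution`: `status` (`optimal`/`infeasible`/`unbounded`),
#'   `fluxes` (named vector v), `objective_value`. For an optimal solution
#'   `max |S v| <= 1e-6` and every flux respects its bounds to the same
#'   tolerance.
#' @export
fba <- function(model, objective = NULL, direction = c("max", "min"),
                fixes = list()) {
  direction <- match.arg(direction)
  model <- as_metabolic_model(model)
  if (is.null(objective)) objective <- model$objective
  lp <- .model_lp(model, fixes)
  obj <- .obj_vector(objective, lp$rxn)
  res <- lp_solve(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub, direction)
  sol <- structure(
    list(status = res$status,
         fluxes = setNames(if (res$status == "optimal") res$x
                           else rep(NA_real_, length(lp$rxn)), lp$rxn),
         objective_value = res$objval),
    class = "flux_solution")
  if (sol$status == "optimal") {
    resid <- max(abs(as.matrix(stoich_matrix(model)) %*% sol$fluxes))
    if (resid > .FLUX_TOL) {
      stop("solver error: steady-state residual ", format(resid), " exceeds 1e-6")
    }
  }
  sol
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution status=%s objective=%s>\n", x$status,
              format(x$objective_value)))
  if (x$status == "optimal") {
    nz <- x$fluxes[abs(x$fluxes) > .FLUX_TOL]
    cat(sprintf("  %d reactions carrying flux (|v| > 1e-6)\n", length(nz)))
  }
  invisible(x)
}

# normalize user 'fixes' that are (objective, value, fraction) triples into
# constraint rows; direction "max" keeps >= fraction*value
.objective_fixes <- function(fixes) {
  lapply(fixes, function(fx) {
    if (!is.null(fx$coef)) return(fx)        # already a constraint row
    frac <- if (is.null(fx$fraction)) 1 else fx$fraction
    dir <- if (is.null(fx$direction)) "max" else fx$direction
    list(coef = fx$objective,
         sense = if (dir == "max") ">=" else "<=",
         rhs = frac * fx$value)
  })
}

#' Flux variability analysis
#'
#' Iteratively and independently minimizes and maximizes every requested
#' reaction flux over the constrained solution space; the flux span of a
#' reaction is the difference between its maximum and minimum flux.
#'
#' @param model a `metabolic_model` or wrapper.
#' @param reactions reaction ids to analyze (default: all).
#' @param fixes list of fixes; either constraint rows (see [fba()]) or
#'   objective fixes `list(objective=, value=, fraction=, direction=)`,
#'   applied as `c'v >= fraction * value` for maximization objectives.
#' @return an `fva_result` data.frame: `reaction_id`, `min_flux`,
#'   `max_flux`, `span`.
#' @export
fva <- function(model, reactions = NULL, fixes = list()) {
  model <- as_metabolic_model(model)
  fixes <- .objective_fixes(fixes)
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  lp <- .model_lp(model, fixes)
  feas <- lp_solve(numeric(length(lp$rxn)), lp$A, lp$sense, lp$rhs,
                   lp$lb, lp$ub, "max")
  if (feas$status != "optimal") {
    # name the binding fix by dropping them one at a time
    for (k in seq_along(fixes)) {
      lp2 <- .model_lp(model, fixes[-k])
      f2 <- lp_solve(numeric(length(lp2$rxn)), lp2$A, lp2$sense, lp2$rhs,
                     lp2$lb, lp2$ub, "max")
      if (f2$status == "optimal") {
        stop("infeasible under fixes; binding fix #", k, " (",
             paste(names(fixes[[k]]$coef), collapse = "+"), " ",
             fixes[[k]]$sense, " ", format(fixes[[k]]$rhs), ")")
      }
    }
    stop("model infeasible under the supplied fixes")
  }
  res <- data.frame(reaction_id = reactions, min_flux = NA_real_,
                    max_flux = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    obj <- .obj_vector(setNames(1, reactions[i]), lp$rxn)
    lo <- lp_solve(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub, "min")
    hi <- lp_solve(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("solver error during FVA on ", reactions[i])
    }
    res$min_flux[i] <- lo$objval
    res$max_flux[i] <- hi$objval
  }
  res$span <- res$max_flux - res$min_flux
  structure(res, class = c("fva_result", "data.frame"))
}

#' Detect reactions in thermodynamically infeasible internal loops
#'
#' Closes all exchange reactions (bounds to zero) and runs FVA; with
#' nothing entering or leaving, any reaction still able to carry flux can
#' only do so as part of an internal loop violating loop-law
#' thermodynamics.
#'
#' @param model a `metabolic_model` or wrapper.
#' @param tol flux threshold (default `1e-6`).
#' @return character vector of loop-participant reaction ids.
#' @export
detect_loops <- function(model, tol = .FLUX_TOL) {
  model <- as_metabolic_model(model)
  ex <- model$reactions$id[model$reactions$kind == "exchange"]
  closed <- set_bounds(model, ex, lb = 0, ub = 0)
  # forced-throughput bounds (maintenance demands etc.) are relaxed so the
  # all-zero flux vector is feasible; only cyclic capability remains
  closed$reactions$lower_bound <- pmin(closed$reactions$lower_bound, 0)
  closed$reactions$upper_bound <- pmax(closed$reactions$upper_bound, 0)
  candidates <- setdiff(closed$reactions$id, ex)
  vr <- fva(closed, candidates)
  vr$reaction_id[abs(vr$min_flux) >= tol | abs(vr$max_flux) >= tol]
}

#' Classify reactions by flux variability
#'
#' Partitions the analyzed reactions into `zero` (fixed at zero),
#' `fixed_nonzero` (equal nonzero minimum and maximum) and `variable`
#' (span at least `tol`), excluding loop participants from all three, and
#' computes the mean non-zero flux span normalized by the carbon input
#' (units mmol/h/body per mmol C).
#'
#' @param fva_result an [fva()] result.
#' @param loop_set reaction ids to exclude (from [detect_loops()]).
#' @param carbon_input_mmolC total carbon uptake of the scenario in mmol
#'   C/h; must be positive.
#' @param tol span/zero threshold (default `1e-6`).
#' @return a `flux_classification` list: `classes` (data.frame reaction_id,
#'   class in zero/fixed_nonzero/variable/loop), `counts`,
#'   `mean_nonzero_span` (0 with `empty_variable_set = TRUE` when no
#'   reaction has span >= tol).
#' @export
classify <- function(fva_result, loop_set = character(0), carbon_input_mmolC,
                     tol = .FLUX_TOL) {
  stopifnot(carbon_input_mmolC > 0)
  miss <- setdiff(loop_set, fva_result$reaction_id)
  if (length(miss)) {
    stop("loop_set reaction(s) missing from FVA result: ",
         paste(miss, collapse = ", "))
  }
  cls <- ifelse(fva_result$reaction_id %in% loop_set, "loop",
         ifelse(fva_result$span >= tol, "variable",
         ifelse(abs(fva_result$min_flux) < tol & abs(fva_result$max_flux) < tol,
                "zero", "fixed_nonzero")))
  classes <- data.frame(reaction_id = fva_result$reaction_id, class = cls,
                        span = fva_result$span, stringsAsFactors = FALSE)
  counts <- c(zero = sum(cls == "zero"),
              fixed_nonzero = sum(cls == "fixed_nonzero"),
              variable = sum(cls == "variable"),
              loop = sum(cls == "loop"))
  vs <- fva_result$span[cls == "variable"]
  empty <- length(vs) == 0
  structure(list(classes = classes, counts = counts,
                 mean_nonzero_span = if (empty) 0
                                     else mean(vs / carbon_input_mmolC),
                 carbon_input_mmolC = carbon_input_mmolC,
                 empty_variable_set = empty),
            class = "flux_classification")
}

#' @export
print.flux_classification <- function(x, ...) {
  cat("<flux_classification>\n  counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      sprintf("\n  mean non-zero flux span: %.4g per mmol C%s\n",
              x$mean_nonzero_span,
              if (x$empty_variable_set) " (no variable reactions)" else ""))
  invisible(x)
}

#' Define a simulation scenario
#'
#' A scenario bundles the constraint overrides and the (possibly
#' lexicographic) objective sequence of one integrated metabolic state.
#'
#' @param name scenario label.
#' @param bound_overrides named list reaction id -> `c(lb, ub)`.
#' @param objectives ordered list of stages, each
#'   `list(objective = <named numeric>, direction = "max"/"min",
#'   fix_fraction = <(0,1]>)`; after each stage its achieved optimum is
#'   fixed at `fix_fraction * optimum` before the next stage.
#' @param deactivate_tissues tissue tags whose reactions are silenced
#'   (bounds 0); requires applying to a `multi_tissue_model`.
#' @param carbon_sources exchange reaction ids supplying carbon.
#' @param carbon_sinks named list of reaction-id groups for carbon-fate
#'   accounting.
#' @return a `scenario` object.
#' @export
scenario <- function(name, bound_overrides = list(), objectives = list(),
                     deactivate_tissues = character(0),
                     carbon_sources = character(0), carbon_sinks = list()) {
  for (st in objectives) {
    fr <- if (is.null(st$fix_fraction)) 1 else st$fix_fraction
    if (fr <= 0 || fr > 1) stop("fix_fraction must lie in (0, 1]")
  }
  structure(list(name = name, bound_overrides = bound_overrides,
                 objectives = objectives,
                 deactivate_tissues = deactivate_tissues,
                 carbon_sources = carbon_sources, carbon_sinks = carbon_sinks),
            class = "scenario")
}

#' Apply a scenario's constraints to a model
#'
#' @param model a `metabolic_model` or `multi_tissue_model` (required when
#'   the scenario deactivates tissues).
#' @param sc a [scenario()].
#' @param strict error on overrides naming absent reactions (default);
#'   `FALSE` skips them, useful when comparing model variants that lack
#'   optional machinery such as the buffer exchanges.
#' @return a `metabolic_model` with overridden bounds.
#' @export
apply_scenario <- function(model, sc, strict = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  m0 <- as_metabolic_model(model)
  if (identical(attr(m0, "scenario_applied"), sc$name)) return(m0)  # idempotent
  if (length(sc$deactivate_tissues)) {
    if (!inherits(model, "multi_tissue_model")) {
      stop("scenario deactivates tissues; a multi_tissue_model is required")
    }
    off <- model$provenance$reaction_id[
      model$provenance$tissue %in% sc$deactivate_tissues]
    model$model <- set_bounds(model$model, off, lb = 0, ub = 0)
  }
  m <- as_metabolic_model(model)
  for (rid in names(sc$bound_overrides)) {
    if (!strict && !rid %in% m$reactions$id) next
    bo <- sc$bound_overrides[[rid]]
    m <- set_bounds(m, rid, lb = bo[1], ub = bo[2])
  }
  attr(m, "scenario_applied") <- sc$name
  m
}

#' Lexicographic (Pareto-style) multi-objective FBA
#'
#' Optimizes the scenario's objectives in order; after each stage the
#' achieved optimum is fixed as a constraint at
#' `fix_fraction * optimum` (an equality band of width
#' `1e-6 * max(1, |optimum|)` when `fix_fraction = 1`, a one-sided bound
#' otherwise) before the next stage is optimized.
#'
#' @param model a `metabolic_model` or `multi_tissue_model`; scenario
#'   bounds are applied first.
#' @param sc a [scenario()] with at least one objective stage.
#' @return the final stage's `flux_solution`, with `stages` (data.frame of
#'   per-stage optima) and `fixes` attached.
#' @export
lexicographic_fba <- function(model, sc) {
  stopifnot(inherits(sc, "scenario"), length(sc$objectives) >= 1)
  m <- apply_scenario(model, sc)
  fixes <- list()
  stages <- data.frame(stage = integer(0), optimum = numeric(0),
                       fixed_at = numeric(0))
  sol <- NULL
  for (k in seq_along(sc$objectives)) {
    st <- sc$objectives[[k]]
    dir <- if (is.null(st$direction)) "max" else st$direction
    frac <- if (is.null(st$fix_fraction)) 1 else st$fix_fraction
    sol <- fba(m, st$objective, dir, fixes = fixes)
    if (sol$status != "optimal") {
      stop("lexicographic stage ", k, " (", sc$name, ") is ", sol$status,
           "; a previous fix is too tight")
    }
    opt <- sol$objective_value
    if (frac == 1) {
      band <- .FLUX_TOL * max(1, abs(opt))
      fixes <- c(fixes,
                 list(list(coef = st$objective, sense = ">=", rhs = opt - band),
                      list(coef = st$objective, sense = "<=", rhs = opt + band)))
      fixed_at <- opt
    } else {
      sense <- if (dir == "max") ">=" else "<="
      fixes <- c(fixes, list(list(coef = st$objective, sense = sense,
                                  rhs = frac * opt)))
      fixed_at <- frac * opt
    }
    stages <- rbind(stages, data.frame(stage = k, optimum = opt,
                                       fixed_at = fixed_at))
  }
  sol$stages <- stages
  sol$fixes <- fixes
  sol
}

# carbon atoms of a metabolite id in a model
.carbon_count <- function(model, met_id) {
  i <- match(met_id, model$metabolites$id)
  f <- model$metabolites$formula[i]
  if (is.na(f)) stop("metabolite ", met_id, " has no formula; carbon ",
                     "accounting impossible")
  fm <- parse_formula(f)
  if ("C" %in% names(fm)) unname(fm[["C"]]) else 0
}

#' Carbon-fate accounting of a flux solution
#'
#' Normalizes the named sinks' carbon consumption by the total carbon
#' input: input carbon is the summed uptake flux times carbon count over
#' the source exchanges; each named sink group's fraction is its net
#' carbon consumption divided by the input; the remainder is reported as
#' the implicit `maintenance` fraction. All fractions sum to one.
#'
#' @param model the model the solution was computed on (after scenario
#'   application).
#' @param solution an optimal `flux_solution`.
#' @param source_exchanges exchange reaction ids importing carbon
#'   (negative flux = uptake).
#' @param sinks named list of reaction-id groups (exchanges secreting, or
#'   drain reactions consuming, the sink species).
#' @return named numeric vector of fractions, including `maintenance`.
#' @export
carbon_split <- function(model, solution, source_exchanges, sinks) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal") stop("solution is not optimal")
  model <- as_metabolic_model(model)
  # net carbon consumed by reaction r per unit flux: -sum(coef * nC)
  net_consumed <- function(rid) {
    st <- model$stoichiometry[[rid]]
    ncs <- vapply(names(st), function(mm) .carbon_count(model, mm), 0)
    -solution$fluxes[[rid]] * sum(st * ncs)
  }
  input <- -sum(vapply(source_exchanges, net_consumed, 0))
  if (input <= .FLUX_TOL) {
    stop("undefined-split error: total carbon input is ", format(input))
  }
  out <- vapply(sinks, function(grp) sum(vapply(grp, net_consumed, 0)) / input, 0)
  c(out, maintenance = 1 - sum(out))
}

#' Run a full scenario report
#'
#' Convenience wrapper: applies the scenario, runs [lexicographic_fba()],
#' FVA under the stage fixes, [detect_loops()], [classify()] and
#' [carbon_split()].
#'
#' @param mt a `multi_tissue_model`.
#' @param sc a [scenario()].
#' @param tissue_of optional per-tissue breakdown helper: when `TRUE`
#'   (default) classification counts are also reported per tissue.
#' @return list with `solution`, `fva`, `loops`, `classification`,
#'   `per_tissue` (list of per-tissue `flux_classification`), `split`.
#' @export
simulate_scenario <- function(mt, sc, tissue_of = TRUE) {
  stopifnot(inherits(mt, "multi_tissue_model"))
  m <- apply_scenario(mt, sc)
  sol <- lexicographic_fba(m, sc)
  vr <- fva(m, fixes = sol$fixes)
  loops <- detect_loops(m)
  input_C <- 0
  for (se in sc$carbon_sources) {
    st <- m$stoichiometry[[se]]
    nC <- .carbon_count(m, names(st)[1])
    input_C <- input_C + max(0, -sol$fluxes[[se]] * -st[[1]]) * nC
  }
  cl <- classify(vr, loops, carbon_input_mmolC = input_C)
  per_tissue <- NULL
  if (isTRUE(tissue_of)) {
    per_tissue <- lapply(setNames(mt$tissues, mt$tissues), function(tt) {
      ids <- mt$provenance$reaction_id[mt$provenance$tissue == tt]
      classify(vr[vr$reaction_id %in% ids, , drop = FALSE],
               intersect(loops, ids), carbon_input_mmolC = input_C)
    })
  }
  split <- if (length(sc$carbon_sinks)) {
    carbon_split(m, sol, sc$carbon_sources, sc$carbon_sinks)
  } else NULL
  list(solution = sol, fva = vr, loops = loops, classification = cl,
       per_tissue = per_tissue, split = split)
}
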