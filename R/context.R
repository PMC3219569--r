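# Expression-driven context-specific model extraction (GIMME) and
# FVA-based differential reaction-activity comparison.

#' Consensus gene presence states for one tissue and group
#'
#' A gene is deemed present iff its call is `P` in every sample of the
#' tissue/group; both `A` (absent) and `M` (marginal) calls break the
#' consensus (the strict reading of a unanimity rule).
#'
#' @param calls an `expression_calls` data.frame with columns `tissue`,
#'   `group`, `sample`, `gene`, `call` (values `P`/`A`/`M`), e.g. from
#'   [toy_expression()] or [read_expression_calls()].
#' @param tissue,group the stratum to summarize.
#' @return named character vector gene -> `"present"`/`"absent"`.
#' @export
consensus_states <- function(calls, tissue, group) {
  sub <- calls[calls$tissue == tissue & calls$group == group, , drop = FALSE]
  if (!nrow(sub)) stop("no samples for tissue '", tissue, "', group '", group, "'")
  tab <- tapply(sub$call == "P", sub$gene, all)
  setNames(ifelse(tab, "present", "absent"), names(tab))
}

#' Read an expression call table from TSV
#'
#' Expected columns: tissue, group, sample, gene, call (P/A/M).
#'
#' @param path TSV file path.
#' @return an `expression_calls` data.frame.
#' @export
read_expression_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tissue", "group", "sample", "gene", "call")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$call %in% c("P", "A", "M"))) {
    stop("format error: calls must be P, A or M")
  }
  class(df) <- c("expression_calls", class(df))
  df
}

#' Map gene states to reaction presence states
#'
#' Evaluates each reaction's GPR rule against the gene states of the
#' reaction's tissue of origin (resolved through the provenance map when a
#' `multi_tissue_model` is given). Reactions with an empty GPR are present
#' (spontaneous transport/diffusion, blood-compartment machinery).
#'
#' @param model a `metabolic_model` or `multi_tissue_model`.
#' @param gene_states either a single named vector (applied to all
#'   reactions) or a named list tissue tag -> named state vector.
#' @return named character vector reaction id -> `"present"`/`"absent"`.
#' @export
reaction_states <- function(model, gene_states) {
  is_mt <- inherits(model, "multi_tissue_model")
  m <- as_metabolic_model(model)
  per_tissue <- is.list(gene_states) && !is.null(names(gene_states))
  out <- setNames(character(nrow(m$reactions)), m$reactions$id)
  for (i in seq_len(nrow(m$reactions))) {
    rid <- m$reactions$id[i]
    states <- if (!per_tissue) gene_states else {
      tt <- if (is_mt) provenance_lookup(model, rid)$tissue_tag else NA
      if (!is.na(tt) && tt %in% names(gene_states)) gene_states[[tt]]
      else character(0)
    }
    out[rid] <- evaluate_gpr(m$reactions$gpr[i], states)
  }
  out
}

#' Extract a context-specific model with the GIMME linear program
#'
#' Solves: minimize the total absolute flux through reactions whose genes
#' are absent, subject to steady state, the flux bounds, and the required
#' metabolic functionality (RMF) achieving at least
#' `fraction * parent optimum`. Absent reactions carrying no flux in the
#' minimizing solution are removed; absent reactions that must carry flux
#' to sustain the RMF are retained (`retained_despite_absent`). Penalties
#' are binary (1 per unit absent-reaction flux): with binary
#' presence/absence calls upstream, the original expression-distance
#' weighting degenerates to this.
#'
#' @param mt a `multi_tissue_model` (or plain `metabolic_model`).
#' @param rstates reaction states from [reaction_states()].
#' @param rmf named numeric objective map: the required metabolic
#'   functionality.
#' @param fraction required fraction of the parent optimum, in (0, 1];
#'   default 0.9.
#' @param scenario_fixes optional extra fixes (constraint rows) active
#'   during extraction and stored for later FVA comparison.
#' @return a `context_model`: `model` (reduced), `removed`,
#'   `retained_despite_absent`, `rmf` (objective, fraction, parent optimum,
#'   threshold), `penalty`, `parent_reactions`, and the parent provenance
#'   restricted to the kept reactions.
#' @export
gimme_extract <- function(mt, rstates, rmf, fraction = 0.9,
                          scenario_fixes = list()) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  m <- as_metabolic_model(mt)
  parent <- fba(m, rmf, "max", fixes = scenario_fixes)
  if (parent$status != "optimal" || parent$objective_value <= .FLUX_TOL) {
    stop("RMF infeasible or zero in the parent model (status ",
         parent$status, ")")
  }
  opt <- parent$objective_value
  absent <- names(rstates)[rstates == "absent"]
  absent <- intersect(absent, m$reactions$id)

  lp <- .model_lp(m, c(scenario_fixes,
                       list(list(coef = rmf, sense = ">=", rhs = fraction * opt))))
  n <- length(lp$rxn)
  k <- length(absent)
  if (k > 0) {
    # v_i = p_i - n_i for absent i; minimize sum(p_i + n_i)
    ext <- matrix(0, nrow(lp$A) + k, 2 * k)
    A2 <- rbind(lp$A, matrix(0, k, n))
    for (j in seq_len(k)) {
      i <- match(absent[j], lp$rxn)
      A2[nrow(lp$A) + j, i] <- 1
      ext[nrow(lp$A) + j, j] <- -1
      ext[nrow(lp$A) + j, k + j] <- 1
    }
    A2 <- cbind(A2, ext)
    obj <- c(numeric(n), rep(1, 2 * k))
    res <- lp_solve(obj, A2, c(lp$sense, rep("=", k)), c(lp$rhs, numeric(k)),
                    c(lp$lb, numeric(2 * k)), c(lp$ub, rep(1e9, 2 * k)), "min")
    if (res$status != "optimal") stop("GIMME LP failed: ", res$status)
    v <- setNames(res$x[seq_len(n)], lp$rxn)
    penalty <- res$objval
  } else {
    v <- parent$fluxes
    penalty <- 0
  }
  removed <- absent[abs(v[absent]) <= .FLUX_TOL]
  retained <- setdiff(absent, removed)

  reduced <- if (length(removed)) remove_reactions(m, removed,
                                                   prune_metabolites = FALSE)
             else m
  ctx <- structure(
    list(model = reduced, removed = removed,
         retained_despite_absent = retained,
         rmf = list(objective = rmf, fraction = fraction,
                    parent_optimum = opt, threshold = fraction * opt),
         scenario_fixes = scenario_fixes,
         penalty = penalty,
         parent_reactions = m$reactions$id,
         provenance = if (inherits(mt, "multi_tissue_model")) {
           mt$provenance[mt$provenance$reaction_id %in% reduced$reactions$id, ,
                         drop = FALSE]
         } else NULL),
    class = "context_model")
  # guarantee: the context still achieves the RMF threshold
  chk <- fba(reduced, rmf, "max", fixes = scenario_fixes)
  if (chk$status != "optimal" ||
      chk$objective_value < fraction * opt - .FLUX_TOL) {
    stop("internal error: context model fails its RMF guarantee")
  }
  ctx
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf(paste0("<context_model %d/%d reactions kept, %d removed, ",
                     "%d retained despite absent, penalty=%.4g>\n"),
              nrow(x$model$reactions), length(x$parent_reactions),
              length(x$removed), length(x$retained_despite_absent), x$penalty))
  invisible(x)
}

#' Differential reaction activity between two context-specific models
#'
#' Runs FVA on each context under its RMF constraint and scenario fixes; a
#' reaction is active iff its flux range reaches `tol` in absolute value.
#' Reactions inactive in both contexts are removed from the comparison;
#' the rest are partitioned into exclusively-active and shared sets, with
#' a per-tissue breakdown when provenance is available. Activity, not mere
#' network membership, is compared: a reaction present in a context but
#' FVA-blocked there is not counted as active.
#'
#' @param ctxA,ctxB `context_model`s derived from the same parent.
#' @param tol activity threshold (default `1e-6`, matching the flux
#'   classification tolerance).
#' @return a `differential_activity` list: `only_in_A`, `only_in_B`,
#'   `active_in_both`, `inactive_in_both`, `per_tissue` (data.frame of
#'   counts), `compared` (all reaction ids considered).
#' @export
differential_activity <- function(ctxA, ctxB, tol = .FLUX_TOL) {
  stopifnot(inherits(ctxA, "context_model"), inherits(ctxB, "context_model"))
  if (!identical(sort(ctxA$parent_reactions), sort(ctxB$parent_reactions))) {
    stop("context models derive from different parents")
  }
  active_set <- function(ctx) {
    fx <- c(ctx$scenario_fixes,
            list(list(coef = ctx$rmf$objective, sense = ">=",
                      rhs = ctx$rmf$threshold)))
    vr <- fva(ctx$model, fixes = fx)
    vr$reaction_id[vr$max_flux >= tol | vr$min_flux <= -tol]
  }
  aA <- active_set(ctxA); aB <- active_set(ctxB)
  compared <- union(ctxA$model$reactions$id, ctxB$model$reactions$id)
  res <- list(only_in_A = setdiff(aA, aB),
              only_in_B = setdiff(aB, aA),
              active_in_both = intersect(aA, aB),
              inactive_in_both = setdiff(compared, union(aA, aB)),
              compared = compared)
  prov <- ctxA$provenance
  if (!is.null(prov)) {
    provB <- ctxB$provenance
    tiss <- function(ids) {
      p <- rbind(prov, provB)
      p <- p[!duplicated(p$reaction_id), , drop = FALSE]
      table(factor(p$tissue[match(ids, p$reaction_id)],
                   levels = sort(unique(p$tissue))))
    }
    res$per_tissue <- data.frame(
      tissue = sort(unique(c(prov$tissue, provB$tissue))),
      only_in_A = as.integer(tiss(res$only_in_A)),
      only_in_B = as.integer(tiss(res$only_in_B)),
      active_in_both = as.integer(tiss(res$active_in_both)),
      stringsAsFactors = FALSE)
  }
  structure(res, class = "differential_activity")
}

#' @export
print.differential_activity <- function(x, ...) {
  cat(sprintf(paste0("<differential_activity only_A=%d only_B=%d both=%d ",
                     "inactive=%d of %d compared>\n"),
              length(x$only_in_A), length(x$only_in_B),
              length(x$active_in_both), length(x$inactive_in_both),
              length(x$compared)))
  invisible(x)
}

#' Sensitivity of consensus calls to sample removal
#'
#' For each replicate, drops `ceiling(drop_fraction * n)` samples uniformly
#' at random from every tissue/group stratum, recomputes the consensus
#' states and records which genes flip relative to the full-data consensus.
#' Because a unanimity cannot be broken by removing samples, flips can only
#' go absent -> present.
#'
#' @param calls an `expression_calls` data.frame.
#' @param drop_fraction fraction of samples to drop, in (0, 0.5].
#' @param n_reps number of random replicates.
#' @param seed integer RNG seed; identical seeds give identical reports.
#' @return list with `flip_rates` (data.frame tissue, group, gene,
#'   flip_rate) and `overall_stability` (1 - mean flip rate).
#' @export
call_stability <- function(calls, drop_fraction, n_reps = 100L, seed = 1L) {
  if (drop_fraction <= 0 || drop_fraction > 0.5) {
    stop("drop_fraction must lie in (0, 0.5]")
  }
  strata <- unique(calls[, c("tissue", "group")])
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    tt <- strata$tissue[i]; gg <- strata$group[i]
    sub <- calls[calls$tissue == tt & calls$group == gg, , drop = FALSE]
    samples <- unique(sub$sample)
    n <- length(samples)
    ndrop <- ceiling(drop_fraction * n)
    if (n - ndrop < 1L) stop("group exhausted: tissue ", tt, " group ", gg)
    full <- consensus_states(calls, tt, gg)
    flips <- setNames(numeric(length(full)), names(full))
    for (r in seq_len(n_reps)) {
      keep <- setdiff(samples, sample(samples, ndrop))
      red <- consensus_states(sub[sub$sample %in% keep, , drop = FALSE], tt, gg)
      flips <- flips + (red[names(full)] != full)
    }
    rows[[i]] <- data.frame(tissue = tt, group = gg, gene = names(full),
                            flip_rate = unname(flips) / n_reps,
                            stringsAsFactors = FALSE)
  }
  fr <- do.call(rbind, rows)
  rownames(fr) <- NULL
  list(flip_rates = fr, overall_stability = 1 - mean(fr$flip_rate))
}
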