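#' @importFrom Matrix sparseMatrix
#' @importFrom stats setNames
NULL

.REACTION_KINDS <- c("internal", "transporter", "exchange", "biomass", "buffer")

#' Construct a constraint-based metabolic model
#'
#' The central container of the package. Metabolite identifiers follow the
#' bracket convention `"<base_id>[<compartment>]"` (for example `glc[c]`,
#' `lac[h_c]`, `h[bl]`), which stays deterministic and collision-free when
#' tissue models are merged into a multi-tissue model.
#'
#' @param metabolites data.frame with columns `id`, `base_id`, `compartment`,
#'   `name`, `formula` (Hill-notation elemental composition, `NA` for
#'   pseudo-species), `charge` (integer).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gpr` (boolean gene rule as text, `""` for none),
#'   `subsystem`, `kind` (one of internal, transporter, exchange, biomass,
#'   buffer).
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids (negative =
#'   substrate).
#' @param objective named numeric vector of objective coefficients over
#'   reaction ids (may be empty).
#' @param genes character vector of registered gene ids; defaults to the
#'   genes referenced by the GPR rules.
#' @param compartments data.frame with columns `id` and `extracellular`;
#'   defaults to the compartments referenced by the metabolites, with
#'   `"e"` and `"bl"` (and tissue-tagged `*_e`) marked extracellular.
#' @param id optional model identifier.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = numeric(0), genes = NULL,
                            compartments = NULL, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$kind)) reactions$kind <- "internal"
  if (is.null(metabolites$name)) metabolites$name <- metabolites$base_id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  reactions$gpr[is.na(reactions$gpr)] <- ""

  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  if (is.null(compartments)) {
    comps <- sort(unique(metabolites$compartment))
    compartments <- data.frame(
      id = comps,
      extracellular = grepl("(^|_)e$|^bl$", comps),
      stringsAsFactors = FALSE
    )
  }
  model <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         objective = objective,
         genes = genes,
         compartments = compartments),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks identifier uniqueness, registered compartments, bound ordering,
#' non-empty stoichiometries without zero coefficients, the single-metabolite
#' form of exchange reactions, and that the objective references existing
#' reactions. Called by every constructor; exported for use after manual
#' surgery on a model.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors with a `consistency error` message
#'   otherwise.
#' @export
validate_model <- function(model) {
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    stop("consistency error: duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxn$id)) {
    stop("consistency error: duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  if (!all(met$compartment %in% model$compartments$id)) {
    stop("consistency error: unregistered compartment(s): ",
         paste(setdiff(met$compartment, model$compartments$id), collapse = ", "))
  }
  if (!all(rxn$kind %in% .REACTION_KINDS)) {
    stop("consistency error: unknown reaction kind(s): ",
         paste(setdiff(rxn$kind, .REACTION_KINDS), collapse = ", "))
  }
  bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad)) stop("consistency error: lower_bound > upper_bound for ",
                        paste(bad, collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxn$id)) {
    stop("consistency error: stoichiometry entries do not match reaction ids")
  }
  for (rid in rxn$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0) stop("consistency error: empty stoichiometry in ", rid)
    if (any(st == 0)) stop("consistency error: zero coefficient in ", rid)
    miss <- setdiff(names(st), met$id)
    if (length(miss)) {
      stop("consistency error: reaction ", rid,
           " references unknown metabolite(s): ", paste(miss, collapse = ", "))
    }
  }
  exch <- rxn$id[rxn$kind == "exchange"]
  for (rid in exch) {
    if (length(model$stoichiometry[[rid]]) != 1L) {
      stop("consistency error: exchange reaction ", rid,
           " must involve exactly one metabolite")
    }
  }
  if (length(model$objective) &&
      !all(names(model$objective) %in% rxn$id)) {
    stop("consistency error: objective references unknown reaction(s): ",
         paste(setdiff(names(model$objective), rxn$id), collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'>  %d metabolites x %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  kinds <- table(x$reactions$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  if (length(x$objective)) {
    cat("  objective:", paste(sprintf("%+g %s", x$objective, names(x$objective)),
                              collapse = " "), "\n")
  }
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Builds the sparse m x n stoichiometric matrix S: one row per metabolite,
#' one column per reaction, entries the signed coefficients. The nonzero
#' pattern equals the union of the reaction stoichiometries.
#'
#' @param model a `metabolic_model`.
#' @return a sparse `Matrix` with metabolite ids as rownames and reaction
#'   ids as colnames.
#' @export
stoich_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rids)) {
    st <- model$stoichiometry[[rids[j]]]
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Number of reactions / metabolites
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' Set flux bounds on reactions
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids.
#' @param lb,ub numeric scalars or vectors recycled over `reaction_ids`;
#'   `NA` leaves the existing bound untouched.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_ids, lb = NA, ub = NA) {
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  }
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  keep <- !is.na(lb); model$reactions$lower_bound[idx[keep]] <- lb[keep]
  keep <- !is.na(ub); model$reactions$upper_bound[idx[keep]] <- ub[keep]
  validate_model(model)
  model
}

#' Remove reactions (and any orphaned metabolites) from a model
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to drop.
#' @param prune_metabolites drop metabolites no longer used by any reaction.
#' @return the reduced model.
#' @export
remove_reactions <- function(model, reaction_ids, prune_metabolites = TRUE) {
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  keep <- !(model$reactions$id %in% reaction_ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model$objective <- model$objective[names(model$objective) %in% model$reactions$id]
  if (prune_metabolites) {
    used <- unique(unlist(lapply(model$stoichiometry, names)))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  }
  rownames(model$reactions) <- NULL; rownames(model$metabolites) <- NULL
  validate_model(model)
  model
}

#' Add a reaction to a model
#'
#' Metabolites referenced by `stoichiometry` that are not yet registered can
#' be supplied through `new_metabolites`.
#'
#' @param model a `metabolic_model`.
#' @param id new reaction id.
#' @param stoichiometry named numeric vector over metabolite ids.
#' @param lb,ub flux bounds (default reversible within the conventional
#'   +-1000 envelope).
#' @param gpr gene rule string, `""` for none.
#' @param subsystem,kind annotation fields.
#' @param new_metabolites optional data.frame in `metabolites` layout.
#' @return the extended model.
#' @export
add_reaction <- function(model, id, stoichiometry, lb = -1000, ub = 1000,
                         gpr = "", subsystem = "", kind = "internal",
                         new_metabolites = NULL) {
  if (id %in% model$reactions$id) stop("reaction id already present: ", id)
  if (!is.null(new_metabolites)) {
    new_metabolites <- as.data.frame(new_metabolites, stringsAsFactors = FALSE)
    if (is.null(new_metabolites$name)) new_metabolites$name <- new_metabolites$base_id
    if (is.null(new_metabolites$formula)) new_metabolites$formula <- NA_character_
    if (is.null(new_metabolites$charge)) new_metabolites$charge <- NA_integer_
    new_metabolites <- new_metabolites[!(new_metabolites$id %in% model$metabolites$id), ,
                                       drop = FALSE]
    model$metabolites <- rbind(model$metabolites,
                               new_metabolites[, names(model$metabolites)])
    newc <- setdiff(model$metabolites$compartment, model$compartments$id)
    if (length(newc)) {
      model$compartments <- rbind(model$compartments, data.frame(
        id = newc, extracellular = grepl("(^|_)e$|^bl$", newc),
        stringsAsFactors = FALSE))
    }
  }
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
    subsystem = subsystem, kind = kind, stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  newg <- setdiff(gpr_genes(gpr), model$genes)
  if (length(newg)) model$genes <- sort(c(model$genes, newg))
  validate_model(model)
  model
}

# parse an equation string like "2 lac[bl] + 6 atp[h_c] -> glc[bl]" into a
# named coefficient vector; "<->"/"<=>" both accepted for reversible arrows.
parse_equation <- function(eq) {
  arrow <- regmatches(eq, regexpr("<->|<=>|->", eq))
  if (length(arrow) == 0) stop("format error: no reaction arrow in: ", eq)
  sides <- strsplit(eq, "<->|<=>|->")[[1]]
  if (length(sides) > 2) stop("format error: multiple arrows in: ", eq)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "" || side == "nothing") return(numeric(0))
    terms <- trimws(strsplit(side, "\\+")[[1]])
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.]+(?:[eE][+-]?[0-9]+)?[ ]+)?(.+)$", tm))[[1]]
      coef <- if (is.na(m[2]) || m[2] == "") 1 else as.numeric(m[2])
      metid <- trimws(m[3])
      if (metid == "") stop("format error: bad term '", tm, "' in: ", eq)
      out[metid] <- (if (metid %in% names(out)) out[metid] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], 1) else numeric(0)
  st <- lhs
  for (nm in names(rhs)) st[nm] <- (if (nm %in% names(st)) st[nm] else 0) + rhs[nm]
  st <- st[st != 0]
  if (!length(st)) stop("format error: net-empty stoichiometry in: ", eq)
  st
}

# render a coefficient vector back to a canonical equation string
format_equation <- function(st, reversible) {
  fmt_side <- function(v) {
    if (!length(v)) return("")
    v <- v[order(names(v))]
    paste(vapply(seq_along(v), function(i) {
      cf <- v[i]
      if (cf == 1) names(v)[i] else paste(format(cf, digits = 15), names(v)[i])
    }, ""), collapse = " + ")
  }
  lhs <- fmt_side(-st[st < 0])
  rhs <- fmt_side(st[st > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

# split "<base>[<comp>]" into its parts
split_met_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)\\[([^][]+)\\]$", id))[[1]]
  if (length(m) != 3) stop("format error: metabolite id not in 'base[comp]' form: ", id)
  c(base = m[2], comp = m[3])
}
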