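# Multi-tissue integration: tissue tagging, merging through a blood
# compartment, bicarbonate buffering, and whole-body biomass rescaling.

#' Tag a tissue model for multi-tissue merging
#'
#' Renames every compartment, metabolite and reaction so that ids carry the
#' tissue tag: metabolite `glc[c]` tagged `"h"` becomes `glc[h_c]`, reaction
#' `GNG` becomes `GNG[h]`. Extracellular compartments (those flagged
#' `extracellular` in the compartment registry) become `<tag>_e` and are the
#' species later identified with the blood compartment.
#'
#' @param model an untagged `metabolic_model`.
#' @param tissue_tag short tissue label, conventionally `"a"` (adipocyte),
#'   `"h"` (hepatocyte), `"m"` (myocyte).
#' @param biomass_reaction_id id (pre-tagging) of the biomass maintenance
#'   reaction; must have kind `"biomass"`.
#' @param mass_params optional list with entries `wet_mass_g`,
#'   `cell_fraction`, `water_fraction`, `growth_rate_per_h`, used by
#'   [rescale_biomass()].
#' @return a `tissue_model`: the tagged model plus tag, biomass pointer,
#'   mass parameters and a provenance map back to the original reaction ids.
#' @export
tag_model <- function(model, tissue_tag, biomass_reaction_id = NULL,
                      mass_params = NULL) {
  stopifnot(is.character(tissue_tag), length(tissue_tag) == 1L, nzchar(tissue_tag))
  if (any(grepl(paste0("^", tissue_tag, "_"), model$compartments$id))) {
    stop("tag collision: model already carries tissue tag '", tissue_tag, "'")
  }
  comp_map <- setNames(paste0(tissue_tag, "_", model$compartments$id),
                       model$compartments$id)
  met_map <- setNames(
    sprintf("%s[%s]", model$metabolites$base_id,
            comp_map[model$metabolites$compartment]),
    model$metabolites$id)
  rxn_map <- setNames(sprintf("%s[%s]", model$reactions$id, tissue_tag),
                      model$reactions$id)

  met <- model$metabolites
  met$id <- unname(met_map[met$id])
  met$compartment <- unname(comp_map[met$compartment])
  comps <- model$compartments
  comps$id <- unname(comp_map[comps$id])
  rxn <- model$reactions
  orig_ids <- rxn$id
  rxn$id <- unname(rxn_map[rxn$id])
  stoich <- lapply(model$stoichiometry, function(st) {
    setNames(unname(st), unname(met_map[names(st)]))
  })
  names(stoich) <- unname(rxn_map[names(model$stoichiometry)])
  objective <- model$objective
  if (length(objective)) names(objective) <- unname(rxn_map[names(objective)])

  tagged <- metabolic_model(met, rxn, stoich, objective, genes = model$genes,
                            compartments = comps,
                            id = paste0(model$id, "_", tissue_tag))
  if (!is.null(biomass_reaction_id)) {
    bm <- unname(rxn_map[biomass_reaction_id])
    if (is.na(bm) || !bm %in% tagged$reactions$id) {
      stop("consistency error: biomass reaction '", biomass_reaction_id,
           "' not found")
    }
    if (tagged$reactions$kind[tagged$reactions$id == bm] != "biomass") {
      stop("consistency error: biomass reaction '", biomass_reaction_id,
           "' does not have kind 'biomass'")
    }
  } else bm <- NULL
  if (!is.null(mass_params)) {
    fr <- unlist(mass_params[c("cell_fraction", "water_fraction")])
    if (any(fr < 0 | fr > 1)) {
      stop("mass_params fractions must lie in [0, 1]")
    }
  }
  structure(list(model = tagged, tissue_tag = tissue_tag,
                 biomass_reaction_id = bm, mass_params = mass_params,
                 provenance = data.frame(reaction_id = tagged$reactions$id,
                                         original_id = orig_ids,
                                         stringsAsFactors = FALSE),
                 scaled = FALSE),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model tag='%s'%s>\n", x$tissue_tag,
              if (x$scaled) " (biomass rescaled to mmol/h/body)" else ""))
  print(x$model)
  invisible(x)
}

#' Rescale a tissue's biomass function to whole-body units
#'
#' Converts from the canonical per-gram-dry-weight units to mmol/h/body:
#' dry cell mass `D = wet_mass_g * cell_fraction * (1 - water_fraction)`,
#' every stoichiometric coefficient of the biomass maintenance reaction is
#' multiplied by `D`, so a biomass flux of 1/h drains the maintenance of the
#' whole tissue, and the biomass lower bound is set to the in-vitro growth
#' rate so that simulations always pay the tissue's turnover.
#'
#' @param tissue a `tissue_model` with `mass_params` set.
#' @return the rescaled `tissue_model` (rescaling twice is an error).
#' @export
rescale_biomass <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  if (isTRUE(tissue$scaled)) stop("tissue biomass already rescaled")
  mp <- tissue$mass_params
  if (is.null(mp) || anyNA(unlist(mp[c("wet_mass_g", "cell_fraction",
                                       "water_fraction")]))) {
    stop("mass_params (wet_mass_g, cell_fraction, water_fraction) must be set")
  }
  if (is.null(tissue$biomass_reaction_id)) {
    stop("tissue has no biomass reaction designated")
  }
  D <- mp$wet_mass_g * mp$cell_fraction * (1 - mp$water_fraction)
  if (D <= 0) stop("degenerate-scale error: dry cell mass is ", D, " g")
  bm <- tissue$biomass_reaction_id
  tissue$model$stoichiometry[[bm]] <- tissue$model$stoichiometry[[bm]] * D
  gr <- mp$growth_rate_per_h
  if (!is.null(gr) && !is.na(gr)) {
    tissue$model <- set_bounds(tissue$model, bm, lb = gr)
  }
  tissue$dry_mass_g <- D
  tissue$scaled <- TRUE
  tissue
}

#' Merge tissue models through a new blood compartment
#'
#' Every tissue's extracellular species is identified with the blood species
#' of the same base id; all tissue-level exchange reactions are deleted, so
#' intercellular transport happens only through each tissue's existing
#' transporters; one blood exchange reaction `EX_<base>[bl]` is created per
#' whitelisted base id, allowing the blood compartment to take up (negative
#' flux) or secrete (positive flux) that metabolite to the extra-system.
#' Merge order is deterministic: tissues sorted by tag, reactions by id
#' within each tissue.
#'
#' @param tissues list of `tissue_model`s with distinct tags (at least 2).
#' @param blood_exchange_whitelist character vector of metabolite base ids
#'   that may cross between blood and the extra-system.
#' @return a `multi_tissue_model`: `$model` (the merged `metabolic_model`),
#'   `$provenance` (reaction id -> tissue tag + original id),
#'   `$blood_exchange_ids`, `$buffer_reaction_ids` (empty until
#'   [add_buffer()]), `$tissues`.
#' @export
merge_models <- function(tissues, blood_exchange_whitelist = character(0)) {
  if (length(tissues) < 2L) stop("need at least two tissue models to merge")
  tags <- vapply(tissues, function(t) t$tissue_tag, "")
  if (anyDuplicated(tags)) stop("duplicate tissue tags: ",
                                paste(tags[duplicated(tags)], collapse = ", "))
  tissues <- tissues[order(tags)]
  tags <- sort(tags)

  all_met <- list(); all_rxn <- list(); all_st <- list(); prov <- list()
  genes <- character(0)
  for (ti in tissues) {
    mod <- ti$model
    extr <- mod$compartments$id[mod$compartments$extracellular]
    is_ext <- mod$metabolites$compartment %in% extr
    met_map <- setNames(mod$metabolites$id, mod$metabolites$id)
    met_map[is_ext] <- sprintf("%s[bl]", mod$metabolites$base_id[is_ext])

    met <- mod$metabolites
    met$id <- unname(met_map[met$id])
    met$compartment[is_ext] <- "bl"
    rxn <- mod$reactions
    keep <- rxn$kind != "exchange"
    ord <- order(rxn$id[keep])
    rxn <- rxn[keep, , drop = FALSE][ord, , drop = FALSE]
    st <- lapply(mod$stoichiometry[rxn$id], function(s) {
      setNames(unname(s), unname(met_map[names(s)]))
    })
    all_met[[ti$tissue_tag]] <- met
    all_rxn[[ti$tissue_tag]] <- rxn
    all_st <- c(all_st, st)
    op <- ti$provenance
    prov[[ti$tissue_tag]] <- data.frame(
      reaction_id = rxn$id, tissue = ti$tissue_tag,
      original_id = op$original_id[match(rxn$id, op$reaction_id)],
      stringsAsFactors = FALSE)
    genes <- union(genes, mod$genes)
  }
  met <- do.call(rbind, all_met)
  # blood species contributed by several tissues must agree chemically
  dup <- met[duplicated(met$id) | duplicated(met$id, fromLast = TRUE), , drop = FALSE]
  for (mid in unique(dup$id)) {
    sub <- dup[dup$id == mid, , drop = FALSE]
    if (length(unique(ifelse(is.na(sub$formula), "", sub$formula))) > 1 ||
        length(unique(ifelse(is.na(sub$charge), -9999L, sub$charge))) > 1) {
      stop("consistency error: tissues disagree on formula/charge of ", mid)
    }
  }
  met <- met[!duplicated(met$id), , drop = FALSE]
  rxn <- do.call(rbind, all_rxn)
  rownames(met) <- rownames(rxn) <- NULL

  ex_ids <- character(0)
  for (base in blood_exchange_whitelist) {
    bid <- sprintf("%s[bl]", base)
    rid <- sprintf("EX_%s[bl]", base)
    if (!bid %in% met$id) {
      stop("consistency error: whitelist metabolite '", base,
           "' has no blood species in any tissue; exchange would dangle")
    }
    rxn <- rbind(rxn, data.frame(id = rid, lower_bound = -1000,
                                 upper_bound = 1000, gpr = "", subsystem = "Exchange",
                                 kind = "exchange", stringsAsFactors = FALSE))
    all_st[[rid]] <- setNames(-1, bid)
    ex_ids <- c(ex_ids, rid)
  }
  prov <- do.call(rbind, c(prov, list(data.frame(
    reaction_id = ex_ids, tissue = "bl",
    original_id = rep("created", length(ex_ids)), stringsAsFactors = FALSE))))
  rownames(prov) <- NULL

  # prune species that no reaction references any more (e.g. an
  # extracellular species whose only role was its deleted tissue exchange)
  used <- unique(unlist(lapply(all_st[rxn$id], names)))
  met <- met[met$id %in% used, , drop = FALSE]

  comps <- do.call(rbind, lapply(tissues, function(t) t$model$compartments))
  comps <- comps[comps$id %in% met$compartment, , drop = FALSE]
  comps <- rbind(comps, data.frame(id = "bl", extracellular = TRUE,
                                   stringsAsFactors = FALSE))
  comps <- comps[!duplicated(comps$id), , drop = FALSE]
  comps$extracellular <- comps$id == "bl"
  rownames(comps) <- NULL

  merged <- metabolic_model(met, rxn, all_st[rxn$id], objective = numeric(0),
                            genes = sort(genes), compartments = comps,
                            id = paste0("multi_", paste(tags, collapse = "")))
  mt <- structure(list(model = merged, provenance = prov,
                       blood_exchange_ids = ex_ids,
                       buffer_reaction_ids = character(0),
                       tissues = tags,
                       mass_params = setNames(
                         lapply(tissues, function(t) t$mass_params), tags)),
                  class = "multi_tissue_model")
  validate_multi_tissue(mt)
  mt
}

#' Validate multi-tissue invariants
#'
#' Exchange reactions must touch only blood metabolites; every blood
#' metabolite must take part in at least one transporter, exchange or
#' buffer reaction; provenance must cover every reaction exactly once.
#'
#' @param mt a `multi_tissue_model`.
#' @return the object, invisibly.
#' @export
validate_multi_tissue <- function(mt) {
  mod <- mt$model
  blood <- mod$metabolites$id[mod$metabolites$compartment == "bl"]
  for (rid in mod$reactions$id[mod$reactions$kind == "exchange"]) {
    if (!all(names(mod$stoichiometry[[rid]]) %in% blood)) {
      stop("consistency error: exchange ", rid, " touches a non-blood metabolite")
    }
  }
  touch <- unique(unlist(lapply(
    mod$reactions$id[mod$reactions$kind %in% c("transporter", "exchange", "buffer")],
    function(r) names(mod$stoichiometry[[r]]))))
  orphan <- setdiff(blood, touch)
  if (length(orphan)) {
    stop("consistency error: blood metabolite(s) not connected to any ",
         "transporter or exchange: ", paste(orphan, collapse = ", "))
  }
  if (!setequal(mt$provenance$reaction_id, mod$reactions$id) ||
      anyDuplicated(mt$provenance$reaction_id)) {
    stop("consistency error: provenance is not total over reactions")
  }
  invisible(mt)
}

#' @export
print.multi_tissue_model <- function(x, ...) {
  cat(sprintf("<multi_tissue_model tissues=[%s] blood_exchanges=%d buffer=%d>\n",
              paste(x$tissues, collapse = ","), length(x$blood_exchange_ids),
              length(x$buffer_reaction_ids)))
  print(x$model)
  invisible(x)
}

#' Add the blood bicarbonate buffer
#'
#' Adds the reversible carbonic-acid hydration couple
#' `co2[bl] + h2o[bl] <-> h[bl] + hco3[bl]` to the blood compartment (the
#' renal proton-balancing function), together with blood exchanges for co2
#' and hco3 if absent. Without it the merged model generally admits no
#' steady state, because proton-coupled transporters and charged-metabolite
#' exchanges leave the blood proton unbalanced. Idempotent.
#'
#' @param mt a `multi_tissue_model`.
#' @return the model with `$buffer_reaction_ids` populated.
#' @export
add_buffer <- function(mt) {
  rid <- "BUFFER_hco3[bl]"
  if (rid %in% mt$model$reactions$id) return(mt)
  specs <- data.frame(
    base = c("co2", "h2o", "h", "hco3"),
    formula = c("CO2", "H2O", "H", "CHO3"),
    charge = c(0L, 0L, 1L, -1L), stringsAsFactors = FALSE)
  specs$id <- sprintf("%s[bl]", specs$base)
  newm <- specs[!specs$id %in% mt$model$metabolites$id, , drop = FALSE]
  nm <- if (nrow(newm)) data.frame(
    id = newm$id, base_id = newm$base, compartment = "bl", name = newm$base,
    formula = newm$formula, charge = newm$charge, stringsAsFactors = FALSE) else NULL
  mt$model <- add_reaction(
    mt$model, rid,
    setNames(c(-1, -1, 1, 1), sprintf("%s[bl]", c("co2", "h2o", "h", "hco3"))),
    lb = -1000, ub = 1000, subsystem = "Blood buffer", kind = "buffer",
    new_metabolites = nm)
  mt$provenance <- rbind(mt$provenance, data.frame(
    reaction_id = rid, tissue = "bl", original_id = "created",
    stringsAsFactors = FALSE))
  for (base in c("co2", "hco3")) {
    ex <- sprintf("EX_%s[bl]", base)
    if (!ex %in% mt$model$reactions$id) {
      mt$model <- add_reaction(mt$model, ex, setNames(-1, sprintf("%s[bl]", base)),
                               lb = -1000, ub = 1000, subsystem = "Exchange",
                               kind = "exchange")
      mt$blood_exchange_ids <- c(mt$blood_exchange_ids, ex)
      mt$provenance <- rbind(mt$provenance, data.frame(
        reaction_id = ex, tissue = "bl", original_id = "created",
        stringsAsFactors = FALSE))
    }
  }
  mt$buffer_reaction_ids <- rid
  validate_multi_tissue(mt)
  mt
}

#' Look up the tissue of origin of a reaction
#'
#' @param mt a `multi_tissue_model`.
#' @param reaction_id reaction id in the merged model.
#' @return list with `tissue_tag` and `original_id` (`"bl"`/`"created"` for
#'   blood-compartment reactions built during integration).
#' @export
provenance_lookup <- function(mt, reaction_id) {
  i <- match(reaction_id, mt$provenance$reaction_id)
  if (is.na(i)) stop("lookup error: unknown reaction id: ", reaction_id)
  list(tissue_tag = mt$provenance$tissue[i],
       original_id = mt$provenance$original_id[i])
}

#' Restrict a multi-tissue model to a single tissue
#'
#' Reproduces the "individual" simulation setup: all reactions belonging to
#' the other tissues are deactivated (bounds set to zero) while the blood
#' compartment and its exchanges stay in place, and the extra-system
#' exchanges are opened so the lone tissue can reach a mass-balanced steady
#' state without its partner tissues acting as sources or sinks.
#'
#' @param mt a `multi_tissue_model`.
#' @param tissue_tag tissue to keep active.
#' @param open_exchanges open every blood exchange to `[-1000, 1000]`.
#' @return a `multi_tissue_model` with the other tissues silenced.
#' @export
individual_tissue <- function(mt, tissue_tag, open_exchanges = TRUE) {
  if (!tissue_tag %in% mt$tissues) stop("unknown tissue tag: ", tissue_tag)
  off <- mt$provenance$reaction_id[!(mt$provenance$tissue %in% c(tissue_tag, "bl"))]
  mt$model <- set_bounds(mt$model, off, lb = 0, ub = 0)
  if (open_exchanges) {
    mt$model <- set_bounds(mt$model, mt$blood_exchange_ids, lb = -1000, ub = 1000)
  }
  mt
}

#' Coerce a model to a tissue_model, tagging only if needed
#'
#' Convenience for file-based workflows: a model whose compartments already
#' carry the tissue tag (e.g. written out by [save_model()] after
#' [tag_model()]) is wrapped as-is with provenance reconstructed from the
#' `<id>[<tag>]` reaction naming; an untagged model is passed through
#' [tag_model()].
#'
#' @inheritParams tag_model
#' @return a `tissue_model`.
#' @export
as_tissue_model <- function(model, tissue_tag, biomass_reaction_id = NULL,
                            mass_params = NULL) {
  if (inherits(model, "tissue_model")) return(model)
  if (!any(grepl(paste0("^", tissue_tag, "_"), model$compartments$id))) {
    return(tag_model(model, tissue_tag, biomass_reaction_id, mass_params))
  }
  suffix <- paste0("[", tissue_tag, "]")
  orig <- ifelse(endsWith(model$reactions$id, suffix),
                 substr(model$reactions$id, 1,
                        nchar(model$reactions$id) - nchar(suffix)),
                 model$reactions$id)
  structure(list(model = model, tissue_tag = tissue_tag,
                 biomass_reaction_id = biomass_reaction_id,
                 mass_params = mass_params,
                 provenance = data.frame(reaction_id = model$reactions$id,
                                         original_id = orig,
                                         stringsAsFactors = FALSE),
                 scaled = FALSE),
            class = "tissue_model")
}

# accept either a bare metabolic_model or a wrapper that carries one
as_metabolic_model <- function(x) {
  if (inherits(x, "metabolic_model")) return(x)
  if (!is.null(x$model) && inherits(x$model, "metabolic_model")) return(x$model)
  stop("not a metabolic model: ", class(x)[1])
}
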