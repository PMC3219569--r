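# Plain tab-delimited model format.
#
# A model is stored as two TSV files: `<path>` with one row per reaction
# (reaction_id, equation, lower_bound, upper_bound, objective_coefficient,
# gpr, subsystem, kind) and a metabolite sidecar `<path>` with ".tsv"
# replaced by ".mets.tsv" (id, name, formula, charge). Metabolite ids use
# the bracket convention "base[compartment]". Equations look like
# "2 lac[bl] + 6 atp[h_c] -> glc[bl]"; the reversible arrow is "<->".
# Exchange sign convention: negative exchange flux imports the metabolite
# into the blood/system from the extra-system, positive secretes it.

.sidecar_path <- function(path) {
  if (grepl("\\.tsv$", path)) sub("\\.tsv$", ".mets.tsv", path)
  else paste0(path, ".mets.tsv")
}

load_model_table <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("format error: metabolite sidecar not found: ", side)
  rx <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  mt <- utils::read.delim(side, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("reaction_id", "equation", "lower_bound", "upper_bound",
            "objective_coefficient", "gpr", "subsystem", "kind")
  miss <- setdiff(need, names(rx))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "), " in ", path)
  miss <- setdiff(c("id", "formula", "charge"), names(mt))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "), " in ", side)

  stoich <- list()
  for (i in seq_len(nrow(rx))) {
    stoich[[rx$reaction_id[i]]] <- parse_equation(rx$equation[i])
  }
  parts <- t(vapply(mt$id, split_met_id, c(base = "", comp = "")))
  metabolites <- data.frame(
    id = mt$id, base_id = unname(parts[, "base"]),
    compartment = unname(parts[, "comp"]),
    name = if ("name" %in% names(mt)) mt$name else unname(parts[, "base"]),
    formula = ifelse(nzchar(mt$formula), mt$formula, NA_character_),
    charge = suppressWarnings(as.integer(mt$charge)),
    stringsAsFactors = FALSE)

  lbs <- suppressWarnings(as.numeric(rx$lower_bound))
  ubs <- suppressWarnings(as.numeric(rx$upper_bound))
  # bounds absent in the file default to the conventional +-1000 envelope;
  # reversibility is encoded purely as lower_bound < 0
  lbs[is.na(lbs) | !nzchar(rx$lower_bound)] <- -1000
  ubs[is.na(ubs) | !nzchar(rx$upper_bound)] <- 1000
  reactions <- data.frame(
    id = rx$reaction_id, lower_bound = lbs, upper_bound = ubs,
    gpr = rx$gpr, subsystem = rx$subsystem, kind = rx$kind,
    stringsAsFactors = FALSE)
  oc <- suppressWarnings(as.numeric(rx$objective_coefficient))
  oc[is.na(oc)] <- 0
  objective <- setNames(oc[oc != 0], rx$reaction_id[oc != 0])

  metabolites <- metabolites[order(metabolites$id), , drop = FALSE]
  rownames(metabolites) <- NULL
  mid <- sub("\\.tsv$", "", basename(path))
  metabolic_model(metabolites, reactions, stoich, objective, id = mid)
}

save_model_table <- function(model, path) {
  rx <- model$reactions
  eqs <- vapply(rx$id, function(rid) {
    format_equation(model$stoichiometry[[rid]], rx$lower_bound[rx$id == rid] < 0)
  }, "")
  oc <- rep(0, nrow(rx))
  if (length(model$objective)) {
    oc[match(names(model$objective), rx$id)] <- unname(model$objective)
  }
  out <- data.frame(
    reaction_id = rx$id, equation = unname(eqs),
    lower_bound = format(rx$lower_bound, digits = 15, trim = TRUE, scientific = FALSE),
    upper_bound = format(rx$upper_bound, digits = 15, trim = TRUE, scientific = FALSE),
    objective_coefficient = format(oc, digits = 15, trim = TRUE, scientific = FALSE),
    gpr = rx$gpr, subsystem = rx$subsystem, kind = rx$kind,
    stringsAsFactors = FALSE)
  mt <- model$metabolites[order(model$metabolites$id), , drop = FALSE]
  side <- data.frame(
    id = mt$id, name = mt$name,
    formula = ifelse(is.na(mt$formula), "", mt$formula),
    charge = ifelse(is.na(mt$charge), "", as.character(mt$charge)),
    stringsAsFactors = FALSE)
  tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(side, .sidecar_path(path), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e)))
  invisible(NULL)
}

#' Load a metabolic model from file
#'
#' @param path file path. For `format = "table"`, the metabolite sidecar
#'   `<path with .mets.tsv>` must sit next to it.
#' @param format `"sbml"` or `"table"`; guessed from the file extension when
#'   omitted (`.xml`/`.sbml` vs `.tsv`).
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "sbml", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "table"
  }
  if (format == "sbml") load_model_sbml(path) else load_model_table(path)
}

#' Save a metabolic model to file
#'
#' `load_model(save_model(x))` is the identity on all semantic fields
#' (stoichiometry, bounds, GPR rules, objective, formulas, charges), and the
#' table format is byte-stable under save-load-save.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"sbml"` (written as Level 3 with flux bounds) or
#'   `"table"`; guessed from the extension when omitted.
#' @return `NULL`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "sbml", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "table"
  }
  if (format == "sbml") save_model_sbml(model, path) else save_model_table(model, path)
}
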