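# Elemental and charge balance checking.

#' Parse a Hill-notation chemical formula
#'
#' @param formula e.g. `"C6H12O6"`, `"C10H12N5O13P3"`. `NA`/empty gives an
#'   empty map.
#' @return named numeric vector element -> count.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    return(setNames(numeric(0), character(0)))
  }
  pat <- "([A-Z][a-z]?)([0-9]*\\.?[0-9]*)"
  matches <- gregexpr(pat, formula)[[1]]
  if (matches[1] == -1 ||
      sum(attr(matches, "match.length")) != nchar(formula)) {
    stop("format error: unparseable formula: ", formula)
  }
  parts <- regmatches(formula, gregexpr(pat, formula))[[1]]
  out <- numeric(0)
  for (p in parts) {
    el <- sub("[0-9.]*$", "", p)
    ct <- sub("^[A-Za-z]+", "", p)
    ct <- if (nzchar(ct)) as.numeric(ct) else 1
    out[el] <- (if (el %in% names(out)) out[el] else 0) + ct
  }
  if (any(out < 0)) stop("format error: negative element count in ", formula)
  out
}

#' Per-reaction element and charge balance report
#'
#' For each checked reaction reports the net element counts and net charge;
#' a reaction is balanced iff every net is zero. Exchange, biomass and
#' buffer-flagged reactions are skipped by default: exchanges are openly
#' unbalanced by construction and biomass drains are pseudo-chemical.
#' A checked reaction touching a metabolite without a formula is reported
#' as `uncheckable`, never silently as balanced.
#'
#' @param model a `metabolic_model`.
#' @param skip_kinds reaction kinds exempt from checking.
#' @param tol numeric tolerance on net counts.
#' @return data.frame with columns `reaction_id`, `status`
#'   (`balanced`/`unbalanced`/`uncheckable`), `net_charge`, and `net`
#'   (a compact `el:+n` listing of nonzero element nets).
#' @export
balance_report <- function(model, skip_kinds = c("exchange", "biomass", "buffer"),
                           tol = 1e-9) {
  met <- model$metabolites
  formulas <- setNames(met$formula, met$id)
  charges <- setNames(met$charge, met$id)
  check_ids <- model$reactions$id[!(model$reactions$kind %in% skip_kinds)]
  rows <- lapply(check_ids, function(rid) {
    st <- model$stoichiometry[[rid]]
    fs <- formulas[names(st)]
    if (any(is.na(fs)) || any(is.na(charges[names(st)]))) {
      return(data.frame(reaction_id = rid, status = "uncheckable",
                        net_charge = NA_real_, net = NA_character_,
                        stringsAsFactors = FALSE))
    }
    net <- numeric(0)
    for (i in seq_along(st)) {
      fm <- parse_formula(fs[i])
      for (el in names(fm)) {
        net[el] <- (if (el %in% names(net)) net[el] else 0) + st[i] * fm[el]
      }
    }
    net_charge <- sum(st * charges[names(st)])
    nz <- net[abs(net) > tol]
    balanced <- length(nz) == 0 && abs(net_charge) <= tol
    data.frame(
      reaction_id = rid,
      status = if (balanced) "balanced" else "unbalanced",
      net_charge = net_charge,
      net = if (length(nz)) paste(sprintf("%s:%+g", names(nz), nz), collapse = " ")
            else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(reaction_id = character(0), status = character(0),
                      net_charge = numeric(0), net = character(0))
  }
  out
}
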