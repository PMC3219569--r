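# Gene-protein-reaction (GPR) boolean rules.
#
# Rules are stored as text ("g1 and (g2 or g3)") and parsed on demand into a
# nested-list expression tree: a leaf is a gene id string; an internal node
# is list(op = "and"/"or", args = list(...)). AND encodes complex subunits,
# OR encodes isozymes.

#' Parse a GPR rule string into an expression tree
#'
#' Accepts `and`/`or` (case-insensitive, also `&`/`|`) with parentheses.
#' `or` binds less tightly than `and`.
#'
#' @param rule rule text; `""` or `NA` yield `NULL` (the empty rule).
#' @return a nested list tree, a gene-id string, or `NULL`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- .gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens; st$pos <- 1L
  tree <- .gpr_parse_or(st)
  if (st$pos <= length(st$tokens)) {
    stop("structural error: trailing tokens in GPR rule: ", rule)
  }
  tree
}

.gpr_tokenize <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}

.gpr_peek <- function(st) {
  if (st$pos > length(st$tokens)) NA_character_ else st$tokens[st$pos]
}

.gpr_parse_or <- function(st) {
  args <- list(.gpr_parse_and(st))
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gpr_parse_and <- function(st) {
  args <- list(.gpr_parse_atom(st))
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gpr_parse_atom <- function(st) {
  tk <- .gpr_peek(st)
  if (is.na(tk)) stop("structural error: unexpected end of GPR rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_parse_or(st)
    if (!identical(.gpr_peek(st), ")")) {
      stop("structural error: unbalanced parenthesis in GPR rule")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("structural error: misplaced token '", tk, "' in GPR rule")
  }
  st$pos <- st$pos + 1L
  tk
}

#' Genes referenced by a GPR rule
#'
#' @param rule rule text or parsed tree.
#' @return character vector of gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.character(rule) && length(rule) == 1L) parse_gpr(rule) else rule
  collect <- function(nd) {
    if (is.null(nd)) return(character(0))
    if (is.character(nd)) return(nd)
    unlist(lapply(nd$args, collect))
  }
  unique(collect(tree))
}

#' Evaluate a GPR rule against gene presence states
#'
#' AND nodes are present iff all children are present; OR nodes iff any
#' child is. The empty rule evaluates to present (spontaneous reactions,
#' diffusion). Genes missing from `gene_states` are treated as present:
#' absence of evidence is not evidence of absence, the conservative
#' direction of the consensus presence rule.
#'
#' @param rule rule text or parsed tree.
#' @param gene_states named character/logical vector: `"present"`/`"absent"`
#'   (or `TRUE`/`FALSE`) per gene id.
#' @return `"present"` or `"absent"`.
#' @export
evaluate_gpr <- function(rule, gene_states = character(0)) {
  tree <- if (is.character(rule) && length(rule) == 1L) parse_gpr(rule) else rule
  if (is.logical(gene_states)) {
    gene_states <- setNames(ifelse(gene_states, "present", "absent"),
                            names(gene_states))
  }
  ev <- function(nd) {
    if (is.character(nd)) {
      if (!nd %in% names(gene_states)) return(TRUE)
      return(identical(unname(gene_states[nd]), "present"))
    }
    if (!is.list(nd) || is.null(nd$op) || is.null(nd$args) || !length(nd$args)) {
      stop("structural error: malformed GPR tree node")
    }
    vals <- vapply(nd$args, ev, logical(1))
    if (nd$op == "and") all(vals) else if (nd$op == "or") any(vals) else
      stop("structural error: unknown GPR operator '", nd$op, "'")
  }
  if (is.null(tree)) return("present")
  if (ev(tree)) "present" else "absent"
}

#' Deparse a GPR tree back to rule text
#' @param tree parsed GPR tree (or rule text, returned normalized).
#' @return canonical rule string.
#' @export
deparse_gpr <- function(tree) {
  if (is.character(tree) && length(tree) == 1L && grepl("[ ()]", tree)) {
    tree <- parse_gpr(tree)
  }
  go <- function(nd, parent_op = NULL) {
    if (is.null(nd)) return("")
    if (is.character(nd)) return(nd)
    inner <- paste(vapply(nd$args, go, "", parent_op = nd$op),
                   collapse = paste0(" ", nd$op, " "))
    if (!is.null(parent_op) && parent_op == "and" && nd$op == "or") {
      inner <- paste0("(", inner, ")")
    }
    inner
  }
  go(tree)
}
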