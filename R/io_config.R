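# JSON scenario configuration files.
#
# A scenario file is a JSON object with fields name, bound_overrides
# (object: reaction id -> [lb, ub]), objectives (array of {objective:
# {reaction: coefficient, ...}, direction, fix_fraction}),
# deactivate_tissues, carbon_sources, carbon_sinks (object: name ->
# [reaction ids]). The same schema carries the mass-parameter configs
# keyed by tissue tag.

#' Load a scenario from a JSON file
#'
#' @param path JSON file path (see `inst/extdata/scenarios/` for the
#'   shipped toy scenarios).
#' @return a [scenario()] object.
#' @export
load_scenario <- function(path) {
  x <- jsonlite::read_json(path)
  scenario(
    name = x$name,
    bound_overrides = lapply(x$bound_overrides, function(b) unlist(b)),
    objectives = lapply(x$objectives, function(st) {
      list(objective = unlist(st$objective),
           direction = if (is.null(st$direction)) "max" else st$direction,
           fix_fraction = if (is.null(st$fix_fraction)) 1 else st$fix_fraction)
    }),
    deactivate_tissues = as.character(unlist(x$deactivate_tissues)),
    carbon_sources = as.character(unlist(x$carbon_sources)),
    carbon_sinks = lapply(x$carbon_sinks, function(g) as.character(unlist(g))))
}

#' Save a scenario to a JSON file
#'
#' @param sc a [scenario()].
#' @param path output path.
#' @return `NULL`, invisibly.
#' @export
save_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  x <- list(
    name = sc$name,
    bound_overrides = lapply(sc$bound_overrides, function(b) unname(as.numeric(b))),
    objectives = lapply(sc$objectives, function(st) {
      list(objective = as.list(st$objective),
           direction = if (is.null(st$direction)) "max" else st$direction,
           fix_fraction = if (is.null(st$fix_fraction)) 1 else st$fix_fraction)
    }),
    deactivate_tissues = sc$deactivate_tissues,
    carbon_sources = sc$carbon_sources,
    carbon_sinks = lapply(sc$carbon_sinks, identity))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
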