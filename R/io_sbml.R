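# SBML read/write.
#
# On write we emit Level 3 Version 1 with the fbc (version 2) flux-bounds,
# gene-product and objective constructs. On read we accept both that dialect
# and the older Level 2 convention used by 2000s-era COBRA exports, where
# bounds live in kineticLaw parameters named LOWER_BOUND/UPPER_BOUND and
# gene associations and formulas live in notes (GENE_ASSOCIATION:,
# FORMULA:, CHARGE:). SBML SIds cannot contain brackets, so species ids are
# sanitized ("glc[h_c]" -> "M_glc_h_c") and the authoritative bracket id is
# carried in the name attribute; foreign files fall back to
# "M_<base>_<compartment>" de-sanitization against the compartment
# attribute.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.sanitize_sid <- function(x) {
  y <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", y), y, paste0("x", y))
}

.num_attr <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

save_model_sbml <- function(model, path) {
  met <- model$metabolites; rxn <- model$reactions
  sp_sid <- setNames(paste0("M_", .sanitize_sid(met$id)), met$id)
  rx_sid <- setNames(paste0("R_", .sanitize_sid(rxn$id)), rxn$id)
  gn_sid <- setNames(paste0("G_", .sanitize_sid(model$genes)), model$genes)
  if (anyDuplicated(sp_sid) || anyDuplicated(rx_sid) || anyDuplicated(gn_sid)) {
    stop("I/O error: identifier sanitization produced a collision; ",
         "rename the colliding ids before writing SBML")
  }

  bvals <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  bid <- setNames(paste0("mtfba_bnd_", seq_along(bvals)), .num_attr(bvals))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", .sanitize_sid(model$id)),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" name=\"%s\" constant=\"true\"/>",
            .sanitize_sid(model$compartments$id),
            .xml_escape(model$compartments$id)),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    fbcattr <- ""
    if (!is.na(met$charge[i])) {
      fbcattr <- paste0(fbcattr, sprintf(" fbc:charge=\"%d\"", met$charge[i]))
    }
    if (!is.na(met$formula[i])) {
      fbcattr <- paste0(fbcattr, sprintf(" fbc:chemicalFormula=\"%s\"",
                                         .xml_escape(met$formula[i])))
    }
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\"",
             " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
             " constant=\"false\"%s/>"),
      sp_sid[met$id[i]], .xml_escape(met$id[i]),
      .sanitize_sid(met$compartment[i]), fbcattr))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (v in names(bid)) {
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>", bid[[v]], v))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")

  gpr_xml <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (is.character(tree)) {
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                     pad, gn_sid[tree]))
    }
    tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(tree$args, gpr_xml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }

  for (i in seq_len(nrow(rxn))) {
    rid <- rxn$id[i]
    st <- model$stoichiometry[[rid]]
    rev <- rxn$lower_bound[i] < 0
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\"",
             " fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
      rx_sid[rid], .xml_escape(rid), tolower(as.character(rev)),
      bid[[.num_attr(rxn$lower_bound[i])]], bid[[.num_attr(rxn$upper_bound[i])]]))
    lines <- c(lines,
      "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
      sprintf("          <p>SUBSYSTEM: %s</p>", .xml_escape(rxn$subsystem[i])),
      sprintf("          <p>KIND: %s</p>", rxn$kind[i]),
      "        </body></notes>")
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lines <- c(lines, "        <listOfReactants>",
        sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                sp_sid[names(subs)], .num_attr(-unname(subs))),
        "        </listOfReactants>")
    }
    if (length(prods)) {
      lines <- c(lines, "        <listOfProducts>",
        sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                sp_sid[names(prods)], .num_attr(unname(prods))),
        "        </listOfProducts>")
    }
    if (nzchar(rxn$gpr[i])) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpr_xml(parse_gpr(rxn$gpr[i]), 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  lines <- c(lines, "    <fbc:listOfObjectives fbc:activeObjective=\"obj1\">",
             "      <fbc:objective fbc:id=\"obj1\" fbc:type=\"maximize\">")
  if (length(model$objective)) {
    lines <- c(lines, "        <fbc:listOfFluxObjectives>",
      sprintf("          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"%s\"/>",
              rx_sid[names(model$objective)], .num_attr(unname(model$objective))),
      "        </fbc:listOfFluxObjectives>")
  }
  lines <- c(lines, "      </fbc:objective>", "    </fbc:listOfObjectives>")
  if (length(model$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
      sprintf("      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\" fbc:name=\"%s\"/>",
              gn_sid[model$genes], .xml_escape(model$genes), .xml_escape(model$genes)),
      "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("I/O error writing ", path, ": ",
                                    conditionMessage(e)))
  invisible(NULL)
}

load_model_sbml <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: cannot parse SBML in ",
                                           path, ": ", conditionMessage(e)))
  level <- xml2::xml_attr(doc, "level")
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) stop("format error: no <model> element in ", path)

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  comp_map <- setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")) |
             !nzchar(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"), xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))

  note_field <- function(node, key) {
    ps <- xml2::xml_find_all(node, "./notes//p")
    txts <- if (length(ps)) xml2::xml_text(ps) else {
      nt <- xml2::xml_text(xml2::xml_find_first(node, "./notes"))
      if (is.na(nt)) character(0) else strsplit(nt, "\n")[[1]]
    }
    for (txt in txts) {
      m <- regmatches(txt, regexec(paste0("^\\s*", key, ":\\s*(.*)$"), txt))[[1]]
      if (length(m) == 2) return(trimws(m[2]))
    }
    NA_character_
  }

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("format error: no species defined in ", path)
  sp_sid <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_comp_sid <- xml2::xml_attr(sp_nodes, "compartment")
  sp_comp <- unname(ifelse(sp_comp_sid %in% names(comp_map),
                           comp_map[sp_comp_sid], sp_comp_sid))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"

  # bracket id: prefer a name of the form base[comp]; otherwise de-sanitize
  met_id <- character(length(sp_nodes))
  base_id <- character(length(sp_nodes))
  for (i in seq_along(sp_nodes)) {
    if (!is.na(sp_name[i]) && grepl("^.*\\[[^][]+\\]$", sp_name[i])) {
      met_id[i] <- sp_name[i]
      base_id[i] <- split_met_id(sp_name[i])[["base"]]
    } else {
      base <- sub("^M_", "", sp_sid[i])
      suffix <- paste0("_", sp_comp_sid[i])
      if (endsWith(base, suffix)) base <- substr(base, 1, nchar(base) - nchar(suffix))
      base_id[i] <- base
      met_id[i] <- sprintf("%s[%s]", base, sp_comp[i])
    }
  }
  charge <- suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge")))
  formula <- xml2::xml_attr(sp_nodes, "chemicalFormula")
  for (i in seq_along(sp_nodes)) {       # legacy notes fallback
    if (is.na(formula[i])) {
      f <- note_field(sp_nodes[[i]], "FORMULA")
      if (!is.na(f) && nzchar(f)) formula[i] <- f
    }
    if (is.na(charge[i])) {
      ch <- note_field(sp_nodes[[i]], "CHARGE")
      if (!is.na(ch)) charge[i] <- suppressWarnings(as.integer(ch))
    }
  }
  sid2met <- setNames(met_id, sp_sid)

  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           xml2::xml_attr(gp_nodes, "id"), xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  par_nodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  par_val <- setNames(suppressWarnings(as.numeric(xml2::xml_attr(par_nodes, "value"))),
                      xml2::xml_attr(par_nodes, "id"))

  assoc_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      return(if (gid %in% names(gp_label)) gp_label[[gid]] else gid)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_text, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  if (!n) stop("format error: no reactions defined in ", path)
  ids <- xml2::xml_attr(rx_nodes, "id")
  names_attr <- xml2::xml_attr(rx_nodes, "name")
  rxn_id <- ifelse(!is.na(names_attr) & nzchar(names_attr), names_attr,
                   sub("^R_", "", ids))
  stoich <- list()
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  subsystem <- character(n); kind <- character(n)
  obj_from_kinetic <- numeric(0)

  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    st <- numeric(0)
    for (sr in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% names(sid2met)) {
        stop("format error: reaction ", rxn_id[i],
             " references undeclared species ", sid)
      }
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      mid <- sid2met[[sid]]
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) - coef
    }
    for (sr in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      sid <- xml2::xml_attr(sr, "species")
      if (!sid %in% names(sid2met)) {
        stop("format error: reaction ", rxn_id[i],
             " references undeclared species ", sid)
      }
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      mid <- sid2met[[sid]]
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + coef
    }
    # drop boundary-condition species (legacy encoding of system boundaries)
    bmet <- met_id[boundary]
    st <- st[!(names(st) %in% bmet)]
    if (!length(st)) {
      stop("format error: reaction ", rxn_id[i],
           " has no non-boundary metabolites")
    }
    stoich[[rxn_id[i]]] <- st

    rev <- !identical(xml2::xml_attr(node, "reversible"), "false")
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    lb_i <- if (!is.na(lbref) && lbref %in% names(par_val)) par_val[[lbref]] else NA
    ub_i <- if (!is.na(ubref) && ubref %in% names(par_val)) par_val[[ubref]] else NA
    if (is.na(lb_i) || is.na(ub_i)) {   # Level 2: kineticLaw parameters
      kl <- xml2::xml_find_all(node, "./kineticLaw//parameter")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id"); knm <- xml2::xml_attr(kl, "name")
        key <- ifelse(is.na(kid), knm, kid)
        kv <- setNames(suppressWarnings(as.numeric(xml2::xml_attr(kl, "value"))), key)
        if (is.na(lb_i) && "LOWER_BOUND" %in% names(kv)) lb_i <- kv[["LOWER_BOUND"]]
        if (is.na(ub_i) && "UPPER_BOUND" %in% names(kv)) ub_i <- kv[["UPPER_BOUND"]]
        if ("OBJECTIVE_COEFFICIENT" %in% names(kv) &&
            !is.na(kv[["OBJECTIVE_COEFFICIENT"]]) &&
            kv[["OBJECTIVE_COEFFICIENT"]] != 0) {
          obj_from_kinetic[rxn_id[i]] <- kv[["OBJECTIVE_COEFFICIENT"]]
        }
      }
    }
    if (is.na(lb_i)) lb_i <- if (rev) -1000 else 0
    if (is.na(ub_i)) ub_i <- 1000
    lb[i] <- lb_i; ub[i] <- ub_i

    ga <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      gpr[i] <- if (length(kids)) sub("^\\((.*)\\)$", "\\1", assoc_to_text(kids[[1]]))
                else ""
    } else {
      gtxt <- note_field(node, "GENE_ASSOCIATION")
      gpr[i] <- if (!is.na(gtxt)) gtxt else ""
    }
    ss <- note_field(node, "SUBSYSTEM")
    subsystem[i] <- if (!is.na(ss)) ss else ""
    kd <- note_field(node, "KIND")
    if (!is.na(kd) && kd %in% .REACTION_KINDS) {
      kind[i] <- kd
    } else {
      comps <- unique(vapply(names(st), function(m) split_met_id(m)[["comp"]], ""))
      kind[i] <- if (length(st) == 1L) "exchange"
                 else if (length(comps) > 1L) "transporter" else "internal"
    }
  }

  # objective: fbc active objective, else legacy kineticLaw coefficients
  objective <- obj_from_kinetic
  act <- xml2::xml_attr(xml2::xml_find_first(doc, ".//*[local-name()='listOfObjectives']"),
                        "activeObjective")
  objs <- xml2::xml_find_all(doc, ".//*[local-name()='listOfObjectives']/*[local-name()='objective']")
  for (ob in objs) {
    if (!is.na(act) && !identical(xml2::xml_attr(ob, "id"), act)) next
    fo <- xml2::xml_find_all(ob, ".//*[local-name()='fluxObjective']")
    if (length(fo)) {
      rsid <- xml2::xml_attr(fo, "reaction")
      coef <- as.numeric(xml2::xml_attr(fo, "coefficient"))
      rmap <- setNames(rxn_id, ids)
      objective <- setNames(coef, unname(rmap[rsid]))
    }
    break
  }

  keep <- !boundary
  parts <- t(vapply(met_id[keep], split_met_id, c(base = "", comp = "")))
  metabolites <- data.frame(
    id = met_id[keep], base_id = base_id[keep],
    compartment = unname(parts[, "comp"]),
    name = ifelse(is.na(sp_name[keep]), base_id[keep], sp_name[keep]),
    formula = formula[keep], charge = charge[keep], stringsAsFactors = FALSE)
  metabolites <- metabolites[order(metabolites$id), , drop = FALSE]
  rownames(metabolites) <- NULL
  reactions <- data.frame(
    id = rxn_id, lower_bound = lb, upper_bound = ub, gpr = gpr,
    subsystem = subsystem, kind = kind, stringsAsFactors = FALSE)
  used <- unique(unlist(lapply(stoich, names)))
  metabolites <- metabolites[metabolites$id %in% used, , drop = FALSE]
  mid <- xml2::xml_attr(mnode, "id")
  metabolic_model(metabolites, reactions, stoich,
                  objective[!is.na(names(objective))],
                  id = if (is.na(mid)) basename(path) else mid)
}
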