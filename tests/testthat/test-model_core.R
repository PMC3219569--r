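# Domain types, GPR evaluation, balance checking, and the file formats.

test_that("model invariants are enforced", {
  m <- tiny_diamond()
  expect_s3_class(m, "metabolic_model")
  # duplicate reaction id
  expect_error(add_reaction(m, "r1", c("A[c]" = -1, "B[c]" = 1)),
               "already present")
  # dangling metabolite
  expect_error(add_reaction(m, "bad", c("Z[c]" = -1, "B[c]" = 1)),
               "unknown metabolite")
  # bounds ordering
  expect_error(set_bounds(m, "r1", lb = 5, ub = 1), "lower_bound > upper_bound")
  # exchange with two metabolites
  bad <- m
  bad$stoichiometry[["EX_A"]] <- c("A[c]" = -1, "B[c]" = 1)
  expect_error(validate_model(bad), "exactly one metabolite")
})

test_that("the stoichiometric matrix mirrors the reaction stoichiometries", {
  m <- tiny_diamond()
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(n_metabolites(m), n_reactions(m)))
  for (r in m$reactions$id) {
    col <- S[, r]
    nz <- col[col != 0]
    st <- m$stoichiometry[[r]]
    expect_setequal(names(nz), names(st))
    expect_equal(unname(nz[names(st)]), unname(st))
  }
})

test_that("equation parsing handles coefficients, arrows, and errors", {
  st <- mtfba:::parse_equation("2 lac[bl] + 6 atp[h_c] -> glc[bl] + 6 adp[h_c]")
  expect_equal(st[["lac[bl]"]], -2)
  expect_equal(st[["atp[h_c]"]], -6)
  expect_equal(st[["glc[bl]"]], 1)
  expect_error(mtfba:::parse_equation("a[c] b[c]"), "no reaction arrow")
  expect_error(mtfba:::parse_equation("a[c] -> a[c]"), "net-empty")
  # round trip through the text form
  eq <- mtfba:::format_equation(st, reversible = FALSE)
  expect_equal(sort(mtfba:::parse_equation(eq)), sort(st))
})

test_that("GPR evaluation follows AND/OR semantics", {
  states <- c(g1 = "present", g2 = "absent", g3 = "absent")
  expect_identical(evaluate_gpr("g1 and g2", states), "absent")
  expect_identical(evaluate_gpr("g1 or g2", states), "present")
  expect_identical(evaluate_gpr("(g1 and g2) or g3",
                                c(g1 = "absent", g2 = "absent", g3 = "absent")),
                   "absent")
  expect_identical(evaluate_gpr("", states), "present")       # empty rule
  expect_identical(evaluate_gpr("gX", states), "present")     # unknown gene
  expect_error(evaluate_gpr("g1 and (g2", states), "structural error")
  expect_error(evaluate_gpr("and g1", states), "structural error")
})

test_that("GPR evaluation is monotone in gene presence", {
  set.seed(42)
  rules <- c("g1 and (g2 or g3)", "(g1 or g2) and (g3 or g4)",
             "g1 or (g2 and g3 and g4)", "g1 and g2 and g3")
  genes <- paste0("g", 1:4)
  for (rule in rules) {
    for (rep in 1:20) {
      st <- setNames(sample(c("present", "absent"), 4, replace = TRUE), genes)
      base <- evaluate_gpr(rule, st)
      idx <- which(st == "absent")
      if (!length(idx)) next
      flip <- idx[sample.int(length(idx), 1)]
      st2 <- st; st2[flip] <- "present"
      after <- evaluate_gpr(rule, st2)
      expect_false(base == "present" && after == "absent")
    }
  }
})

test_that("balance_report does the atom and charge bookkeeping", {
  mets <- data.frame(
    id = c("glc[c]", "lac[c]", "h[c]", "h2o[bl]", "h2o[c]"),
    base_id = c("glc", "lac", "h", "h2o", "h2o"),
    compartment = c("c", "c", "c", "bl", "c"),
    name = "", formula = c("C6H12O6", "C3H5O3", "H", "H2O", "H2O"),
    charge = c(0L, -1L, 1L, 0L, 0L), stringsAsFactors = FALSE)
  rxn <- data.frame(
    id = c("h2ot", "glyc_ok", "glyc_noH"),
    lower_bound = 0, upper_bound = 10, gpr = "", subsystem = "",
    kind = c("transporter", "internal", "internal"), stringsAsFactors = FALSE)
  st <- list(h2ot = c("h2o[bl]" = -1, "h2o[c]" = 1),
             glyc_ok = c("glc[c]" = -1, "lac[c]" = 2, "h[c]" = 2),
             glyc_noH = c("glc[c]" = -1, "lac[c]" = 2))
  m <- metabolic_model(mets, rxn, st, id = "bal")
  rep <- balance_report(m)
  expect_identical(rep$status[rep$reaction_id == "h2ot"], "balanced")
  expect_identical(rep$status[rep$reaction_id == "glyc_ok"], "balanced")
  bad <- rep[rep$reaction_id == "glyc_noH", ]
  expect_identical(bad$status, "unbalanced")
  expect_equal(bad$net_charge, -2)         # 2 lac- appear from neutral glc
  expect_match(bad$net, "H:-2")            # two H short on the right
})

test_that("missing formulas are uncheckable, never silently balanced", {
  mets <- simple_mets(c("A[c]", "B[c]"))
  mets$formula[2] <- NA
  m <- metabolic_model(
    mets, data.frame(id = "r", lower_bound = 0, upper_bound = 1, gpr = "",
                     subsystem = "", kind = "internal", stringsAsFactors = FALSE),
    list(r = c("A[c]" = -1, "B[c]" = 1)))
  expect_identical(balance_report(m)$status, "uncheckable")
})

test_that("seeded coefficient mutations are each caught by balance_report", {
  set.seed(11)
  base <- toy_tissue("liver")$model
  checkable <- balance_report(base)
  stopifnot(all(checkable$status == "balanced"))
  pool <- checkable$reaction_id
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    victims <- sample(pool, k)
    mut <- base
    for (v in victims) {
      st <- mut$stoichiometry[[v]]
      i <- sample(seq_along(st), 1)
      st[i] <- st[i] + sample(c(-1, 1), 1)
      mut$stoichiometry[[v]] <- st[st != 0]
    }
    repm <- balance_report(mut)
    flagged <- repm$reaction_id[repm$status != "balanced"]
    expect_setequal(flagged, victims)
  }
})

test_that("a 3-reaction table file loads with the expected shape", {
  td <- withr::local_tempdir()
  p <- file.path(td, "mini.tsv")
  writeLines(c(
    "reaction_id\tequation\tlower_bound\tupper_bound\tobjective_coefficient\tgpr\tsubsystem\tkind",
    "EX_A\tA[e] <->\t-10\t1000\t0\t\t\texchange",
    "At\tA[e] <-> A[c]\t\t\t0\tg1\t\ttransporter",
    "AtoB\tA[c] -> B[c]\t0\t1000\t1\tg2 and g3\tcore\tinternal"), p)
  writeLines(c("id\tname\tformula\tcharge",
               "A[e]\tA\tC3H6O3\t0", "A[c]\tA\tC3H6O3\t0",
               "B[c]\tB\tC3H6O3\t0"), file.path(td, "mini.mets.tsv"))
  m <- load_model(p)
  expect_equal(n_reactions(m), 3)
  expect_equal(length(unique(m$metabolites$base_id)), 2)  # A and B
  # absent bounds defaulted to the +-1000 envelope, reversible lb < 0
  expect_equal(m$reactions$lower_bound[m$reactions$id == "At"], -1000)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "At"], 1000)
  expect_equal(m$objective, c(AtoB = 1))
  expect_error(load_model(file.path(td, "nope.tsv")), "not found")
})

test_that("table format round-trips byte-stably and SBML semantically", {
  mt <- toy_multitissue()
  mod <- mt$model
  mod$objective <- c("EX_glc[bl]" = 1)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "m1.tsv")
  save_model(mod, p1)
  m1 <- load_model(p1)
  expect_models_equal(mod, m1)
  p2 <- file.path(td, "m2.tsv")
  save_model(m1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(file.path(td, "m1.mets.tsv")),
                   readLines(file.path(td, "m2.mets.tsv")))

  px <- file.path(td, "m.xml")
  save_model(mod, px)
  mx <- load_model(px)
  expect_models_equal(mod, mx)
  expect_identical(mx$objective, mod$objective)
  # reversibility encoded on the reaction element
  doc <- xml2::read_xml(px); xml2::xml_ns_strip(doc)
  rx <- xml2::xml_find_all(doc, ".//reaction")
  rev_attr <- setNames(xml2::xml_attr(rx, "reversible") == "true",
                       xml2::xml_attr(rx, "name"))
  expect_true(rev_attr[["LDH[h]"]])
  expect_false(rev_attr[["GNG[h]"]])
})

test_that("legacy Level 2 SBML with kineticLaw bounds and notes loads", {
  td <- withr::local_tempdir()
  pl2 <- file.path(td, "legacy.xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="legacy"><listOfCompartments><compartment id="c"/><compartment id="b"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_glc_c" compartment="c"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>FORMULA: C6H12O6</p><p>CHARGE: 0</p></body></notes></species>',
    '<species id="M_lac_c" compartment="c"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>FORMULA: C3H5O3</p><p>CHARGE: -1</p></body></notes></species>',
    '<species id="M_glc_b" compartment="b" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_GLYC" reversible="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: g1 and g2</p><p>SUBSYSTEM: Glycolysis</p></body></notes>',
    '<listOfReactants><speciesReference species="M_glc_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_lac_c" stoichiometry="2"/></listOfProducts>',
    '<kineticLaw><listOfParameters><parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="99"/><parameter id="OBJECTIVE_COEFFICIENT" value="1"/></listOfParameters></kineticLaw></reaction>',
    '<reaction id="R_EX_glc" reversible="true"><listOfReactants><speciesReference species="M_glc_c"/></listOfReactants><listOfProducts><speciesReference species="M_glc_b"/></listOfProducts></reaction>',
    '</listOfReactions></model></sbml>'), pl2)
  m <- load_model(pl2)
  expect_equal(n_reactions(m), 2)
  g <- m$reactions[m$reactions$id == "GLYC", ]
  expect_equal(c(g$lower_bound, g$upper_bound), c(0, 99))
  expect_identical(g$gpr, "g1 and g2")
  expect_identical(g$subsystem, "Glycolysis")
  expect_equal(m$objective, c(GLYC = 1))
  # boundary species dropped: the exchange keeps one metabolite
  expect_identical(m$reactions$kind[m$reactions$id == "EX_glc"], "exchange")
  expect_equal(m$metabolites$charge[m$metabolites$id == "lac[c]"], -1L)
  # reversible without explicit bounds -> -1000..1000
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_glc"], -1000)
})

test_that("formula parsing covers multi-letter elements and bad input", {
  f <- parse_formula("C10H12N5O13P3")
  expect_equal(f[["C"]], 10); expect_equal(f[["P"]], 3)
  expect_equal(parse_formula("CHO3"), c(C = 1, H = 1, O = 3))
  expect_equal(length(parse_formula(NA)), 0)
  expect_error(parse_formula("12AB"), "unparseable")
})
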