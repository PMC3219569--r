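# Small hand-built models used across the test files.

simple_mets <- function(ids, formula = "C3H6O3", charge = 0L) {
  parts <- t(vapply(ids, mtfba:::split_met_id, c(base = "", comp = "")))
  data.frame(id = ids, base_id = unname(parts[, "base"]),
             compartment = unname(parts[, "comp"]),
             name = unname(parts[, "base"]),
             formula = formula, charge = charge, stringsAsFactors = FALSE)
}

# A(3C) enters at a fixed rate and reaches B by two parallel routes
tiny_diamond <- function(uptake = 10) {
  metabolic_model(
    simple_mets(c("A[c]", "B[c]")),
    data.frame(id = c("EX_A", "r1", "r2", "EX_B"),
               lower_bound = c(-uptake, 0, 0, 0),
               upper_bound = c(-uptake, 1000, 1000, 1000),
               gpr = c("", "g1", "g2", ""), subsystem = "",
               kind = c("exchange", "internal", "internal", "exchange"),
               stringsAsFactors = FALSE),
    list(EX_A = c("A[c]" = -1), r1 = c("A[c]" = -1, "B[c]" = 1),
         r2 = c("A[c]" = -1, "B[c]" = 1), EX_B = c("B[c]" = -1)),
    id = "diamond")
}

# fully determined linear chain
tiny_chain <- function(uptake = 5, uptake_fixed = TRUE) {
  metabolic_model(
    simple_mets(c("A[c]", "B[c]")),
    data.frame(id = c("EX_A", "r1", "EX_B"),
               lower_bound = c(-uptake, 0, 0),
               upper_bound = c(if (uptake_fixed) -uptake else 0, 1000, 1000),
               gpr = c("", "gmid", ""), subsystem = "",
               kind = c("exchange", "internal", "exchange"),
               stringsAsFactors = FALSE),
    list(EX_A = c("A[c]" = -1), r1 = c("A[c]" = -1, "B[c]" = 1),
         EX_B = c("B[c]" = -1)),
    id = "chain")
}

# append a reversible 3-cycle x1 -> x2 -> x3 -> x1 to any model
add_three_cycle <- function(model) {
  xm <- simple_mets(c("x1[c]", "x2[c]", "x3[c]"))
  model <- add_reaction(model, "cyc1", c("x1[c]" = -1, "x2[c]" = 1),
                        lb = -1000, ub = 1000, new_metabolites = xm)
  model <- add_reaction(model, "cyc2", c("x2[c]" = -1, "x3[c]" = 1),
                        lb = -1000, ub = 1000)
  add_reaction(model, "cyc3", c("x3[c]" = -1, "x1[c]" = 1),
               lb = -1000, ub = 1000)
}

# closed system that mints energy: a -> b charges "atp", b -> a is free
energy_cycle_model <- function() {
  mets <- simple_mets(c("a[c]", "b[c]", "cof_hi[c]", "cof_lo[c]"))
  metabolic_model(
    mets,
    data.frame(id = c("charge", "relax", "drain"),
               lower_bound = 0, upper_bound = 1000,
               gpr = "", subsystem = "",
               kind = "internal", stringsAsFactors = FALSE),
    list(charge = c("a[c]" = -1, "cof_lo[c]" = -1, "b[c]" = 1, "cof_hi[c]" = 1),
         relax = c("b[c]" = -1, "a[c]" = 1),
         drain = c("cof_hi[c]" = -1, "cof_lo[c]" = 1)),
    id = "futile")
}

expect_models_equal <- function(a, b) {
  expect_setequal(a$reactions$id, b$reactions$id)
  ia <- order(a$reactions$id); ib <- order(b$reactions$id)
  expect_equal(a$reactions$lower_bound[ia], b$reactions$lower_bound[ib])
  expect_equal(a$reactions$upper_bound[ia], b$reactions$upper_bound[ib])
  norm_gpr <- function(g) vapply(g, function(x) deparse_gpr(x), "")
  expect_equal(norm_gpr(a$reactions$gpr[ia]), norm_gpr(b$reactions$gpr[ib]),
               ignore_attr = TRUE)
  for (r in a$reactions$id) {
    sa <- a$stoichiometry[[r]]; sb <- b$stoichiometry[[r]]
    expect_setequal(names(sa), names(sb))
    expect_equal(unname(sa[sort(names(sa))]), unname(sb[sort(names(sb))]),
                 tolerance = 1e-12)
  }
  ja <- order(a$metabolites$id); jb <- order(b$metabolites$id)
  expect_equal(a$metabolites$formula[ja], b$metabolites$formula[jb])
  expect_equal(a$metabolites$charge[ja], b$metabolites$charge[jb])
}
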