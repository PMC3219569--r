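# FBA, FVA, classification, loops, lexicographic optimization, carbon fate.

test_that("FBA: nothing enters, nothing moves", {
  m <- tiny_diamond(uptake = 10)
  closed <- set_bounds(m, c("EX_A", "EX_B"), lb = 0, ub = 0)
  sol <- fba(closed, c(r1 = 1), "max")
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA solutions satisfy steady state and bounds", {
  mt <- toy_multitissue()
  m <- apply_scenario(mt, toy_scenario_spec("cori"))
  sol <- fba(m, c("EX_glc[bl]" = 1), "max")
  expect_identical(sol$status, "optimal")
  S <- stoich_matrix(m)
  expect_lt(max(abs(as.matrix(S) %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-6))
  expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-6))
})

test_that("toy Cori system: hand LP gives 5/3 glucose", {
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("cori")
  m <- apply_scenario(mt, sc)
  sol <- fba(m, c("EX_glc[bl]" = 1), "max")
  # 2x + y = 6, 15y - 6x >= 30  =>  x <= 5/3
  expect_equal(sol$objective_value, 5 / 3, tolerance = 1e-7)
})

test_that("FVA: diamond ranges, determined chain, fixed objective", {
  dm <- tiny_diamond(uptake = 10)
  vr <- fva(dm)
  expect_equal(vr$min_flux[vr$reaction_id == "r1"], 0, tolerance = 1e-7)
  expect_equal(vr$max_flux[vr$reaction_id == "r1"], 10, tolerance = 1e-7)
  expect_equal(vr$span[vr$reaction_id == "r1"], 10, tolerance = 1e-7)

  ch <- tiny_chain(uptake = 5)
  vc <- fva(ch)
  expect_equal(vc$min_flux[vc$reaction_id != "EX_A"], c(5, 5), tolerance = 1e-7)
  expect_equal(vc$span, rep(0, 3), tolerance = 1e-7)

  # the objective reaction itself, fixed at its optimum
  opt <- fba(dm, c(EX_B = 1), "max")$objective_value
  vf <- fva(dm, "EX_B",
            fixes = list(list(objective = c(EX_B = 1), value = opt,
                              fraction = 1)))
  expect_equal(vf$min_flux, opt, tolerance = 1e-6)
  expect_equal(vf$max_flux, opt, tolerance = 1e-6)
})

test_that("FVA equals brute-force vertex enumeration on small toys", {
  models <- list(tiny_diamond(10), tiny_chain(5),
                 add_three_cycle(tiny_chain(5, uptake_fixed = FALSE)))
  for (m in models) {
    expect_lte(n_reactions(m), 12)
    got <- fva(m)
    ref <- oracle_fva(m)
    expect_equal(got$min_flux, ref$min_flux, tolerance = 1e-6)
    expect_equal(got$max_flux, ref$max_flux, tolerance = 1e-6)
  }
})

test_that("FVA sandwiches any feasible solution", {
  mt <- toy_multitissue()
  m <- apply_scenario(mt, toy_scenario_spec("alanine"))
  sol <- fba(m, c("EX_glc[bl]" = 1), "max")
  vr <- fva(m)
  i <- match(vr$reaction_id, names(sol$fluxes))
  expect_true(all(sol$fluxes[i] >= vr$min_flux - 1e-6))
  expect_true(all(sol$fluxes[i] <= vr$max_flux + 1e-6))
})

test_that("infeasible fixes name the binding fix", {
  dm <- tiny_diamond(uptake = 10)
  expect_error(
    fva(dm, "r1", fixes = list(list(objective = c(EX_B = 1), value = 50,
                                    fraction = 1))),
    "binding fix")
})

test_that("loop detection flags exactly the injected cycle", {
  base <- tiny_chain(5, uptake_fixed = FALSE)
  expect_length(detect_loops(base), 0)
  looped <- add_three_cycle(base)
  expect_setequal(detect_loops(looped), c("cyc1", "cyc2", "cyc3"))
})

test_that("classification partitions reactions and normalizes spans", {
  # diamond: A is a 3-carbon species, uptake 10 -> 30 mmol C input
  dm <- tiny_diamond(uptake = 10)
  vr <- fva(dm)
  cl <- classify(vr, character(0), carbon_input_mmolC = 30)
  expect_equal(sum(cl$counts), nrow(vr))
  expect_equal(unname(cl$counts["variable"]), 2)       # r1, r2
  expect_equal(unname(cl$counts["fixed_nonzero"]), 2)  # EX_A, EX_B
  expect_equal(cl$mean_nonzero_span, 10 / 30, tolerance = 1e-7)

  # fully determined chain: no variable reactions, explicit empty flag
  ch <- tiny_chain(5)
  cc <- classify(fva(ch), character(0), carbon_input_mmolC = 15)
  expect_true(cc$empty_variable_set)
  expect_equal(cc$mean_nonzero_span, 0)
  expect_equal(unname(cc$counts["zero"]), 0)
  expect_equal(unname(cc$counts["fixed_nonzero"]), 3)

  # loop exclusion covers every reaction exactly once
  lp <- add_three_cycle(tiny_chain(5))
  vl <- fva(lp)
  cl2 <- classify(vl, c("cyc1", "cyc2", "cyc3"), carbon_input_mmolC = 15)
  expect_equal(sum(cl2$counts), nrow(vl))
  expect_equal(unname(cl2$counts["loop"]), 3)
  expect_error(classify(vl, "ghost", 15), "missing from FVA result")
})

test_that("zero and fixed_nonzero are disjoint classes", {
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("cori")
  m <- apply_scenario(mt, sc)
  sol <- lexicographic_fba(m, sc)
  vr <- fva(m, fixes = sol$fixes)
  cl <- classify(vr, detect_loops(m), carbon_input_mmolC = 18)
  z <- cl$classes$reaction_id[cl$classes$class == "zero"]
  f <- cl$classes$reaction_id[cl$classes$class == "fixed_nonzero"]
  expect_length(intersect(z, f), 0)
  zi <- match(z, vr$reaction_id)
  expect_true(all(abs(vr$min_flux[zi]) < 1e-6 & abs(vr$max_flux[zi]) < 1e-6))
  fi <- match(f, vr$reaction_id)
  expect_true(all(abs(vr$min_flux[fi]) >= 1e-6 | abs(vr$max_flux[fi]) >= 1e-6))
})

test_that("lexicographic FBA: reduction, order dependence, stage records", {
  dm <- tiny_diamond(uptake = 10)
  # single objective at fraction 1 is plain FBA
  sc1 <- scenario("one", objectives = list(
    list(objective = c(EX_B = 1), direction = "max", fix_fraction = 1)))
  expect_equal(lexicographic_fba(dm, sc1)$objective_value,
               fba(dm, c(EX_B = 1), "max")$objective_value, tolerance = 1e-9)

  # two objectives competing for one substrate: order decides
  comp <- metabolic_model(
    simple_mets(c("A[c]", "P[c]", "Q[c]")),
    data.frame(id = c("EX_A", "o1", "o2", "EX_P", "EX_Q"),
               lower_bound = c(-10, 0, 0, 0, 0),
               upper_bound = c(0, 1000, 1000, 1000, 1000),
               gpr = "", subsystem = "",
               kind = c("exchange", "internal", "internal",
                        "exchange", "exchange"),
               stringsAsFactors = FALSE),
    list(EX_A = c("A[c]" = -1), o1 = c("A[c]" = -1, "P[c]" = 1),
         o2 = c("A[c]" = -1, "Q[c]" = 1),
         EX_P = c("P[c]" = -1), EX_Q = c("Q[c]" = -1)), id = "competing")
  fwd <- lexicographic_fba(comp, scenario("fwd", objectives = list(
    list(objective = c(o1 = 1), direction = "max", fix_fraction = 1),
    list(objective = c(o2 = 1), direction = "max", fix_fraction = 1))))
  # the second stage can only move within the +-1e-5 equality band of the
  # first stage's fix
  expect_equal(fwd$stages$optimum, c(10, 0), tolerance = 1e-4)
  rev <- lexicographic_fba(comp, scenario("rev", objectives = list(
    list(objective = c(o2 = 1), direction = "max", fix_fraction = 1),
    list(objective = c(o1 = 1), direction = "max", fix_fraction = 1))))
  expect_equal(rev$stages$optimum, c(10, 0), tolerance = 1e-4)
  expect_equal(fwd$fluxes[["o1"]], 10, tolerance = 1e-6)
  expect_equal(rev$fluxes[["o2"]], 10, tolerance = 1e-6)
})

test_that("absorptive-style staging orders storage objectives", {
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("absorptive")
  sol <- lexicographic_fba(mt, sc)
  expect_identical(sol$status, "optimal")
  # adipose triacylglycerol first: fatty-acid limited at uptake/3
  expect_equal(sol$stages$optimum[1], 1, tolerance = 1e-6)
  # the fixed stage keeps its flux in the final solution
  expect_equal(sol$fluxes[["TAGSTOR[a]"]], 1, tolerance = 1e-5)
  expect_equal(nrow(sol$stages), 3)
})

test_that("carbon split: total conversion, toy Cori, fraction closure", {
  # single reaction A(6C) -> B(6C), all input exported as B
  conv <- metabolic_model(
    simple_mets(c("A[c]", "B[c]"), formula = "C6H12O6"),
    data.frame(id = c("EX_A", "r", "EX_B"),
               lower_bound = c(-4, 0, 0), upper_bound = c(-4, 1000, 1000),
               gpr = "", subsystem = "",
               kind = c("exchange", "internal", "exchange"),
               stringsAsFactors = FALSE),
    list(EX_A = c("A[c]" = -1), r = c("A[c]" = -1, "B[c]" = 1),
         EX_B = c("B[c]" = -1)), id = "conv")
  sol <- fba(conv, c(EX_B = 1), "max")
  sp <- carbon_split(conv, sol, "EX_A", list(B = "EX_B"))
  expect_equal(unname(sp["B"]), 1, tolerance = 1e-9)
  expect_equal(unname(sp["maintenance"]), 0, tolerance = 1e-9)

  mt <- toy_multitissue()
  sc <- toy_scenario_spec("cori")
  m <- apply_scenario(mt, sc)
  solc <- fba(m, c("EX_glc[bl]" = 1), "max")
  spc <- carbon_split(m, solc, sc$carbon_sources, sc$carbon_sinks)
  expect_equal(unname(spc["glucose"]), 10 / 18, tolerance = 1e-6)
  expect_equal(unname(spc["maintenance"]), 8 / 18, tolerance = 1e-6)
  expect_equal(sum(spc), 1, tolerance = 1e-9)

  # no carbon in -> undefined split
  conv0 <- set_bounds(conv, "EX_A", lb = 0, ub = 0)
  s0 <- fba(conv0, c(EX_B = 1), "max")
  expect_error(carbon_split(conv0, s0, "EX_A", list(B = "EX_B")),
               "undefined-split")
})

test_that("adding tissues shrinks the solution space of shared reactions", {
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("cori")
  m_int <- apply_scenario(mt, sc)
  mt_sc <- mt; mt_sc$model <- m_int
  ind <- individual_tissue(mt_sc, "h", open_exchanges = TRUE)
  hm <- mt$provenance$reaction_id[mt$provenance$tissue == "h"]
  f_int <- fva(m_int, hm)
  f_ind <- fva(ind, hm)
  expect_true(all(f_int$span <= f_ind$span + 1e-6))
  expect_lt(mean(f_int$span), mean(f_ind$span))
})

test_that("scaling all bounds by k scales the FBA optimum by k", {
  mt <- toy_multitissue()
  m <- apply_scenario(mt, toy_scenario_spec("cori"))
  base <- fba(m, c("EX_glc[bl]" = 1), "max")$objective_value
  for (k in c(0.5, 4)) {
    m2 <- m
    m2$reactions$lower_bound <- k * m2$reactions$lower_bound
    m2$reactions$upper_bound <- k * m2$reactions$upper_bound
    expect_equal(fba(m2, c("EX_glc[bl]" = 1), "max")$objective_value,
                 k * base, tolerance = 1e-6)
  }
})

test_that("scenario files round-trip through JSON", {
  sc <- toy_scenario_spec("alanine")
  td <- withr::local_tempdir()
  p <- file.path(td, "alanine.json")
  save_scenario(sc, p)
  sc2 <- load_scenario(p)
  expect_identical(sc2$name, sc$name)
  expect_equal(sc2$bound_overrides, sc$bound_overrides)
  expect_equal(sc2$carbon_sinks, sc$carbon_sinks)
  mt <- toy_multitissue()
  expect_equal(lexicographic_fba(mt, sc2)$objective_value,
               lexicographic_fba(mt, sc)$objective_value, tolerance = 1e-9)
})
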