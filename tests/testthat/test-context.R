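# Consensus calls, reaction states, GIMME extraction, differential
# activity, and call-stability analysis.

make_calls <- function(gene_calls, tissue = "h", group = "grpA") {
  # gene_calls: named list gene -> vector of per-sample calls
  do.call(rbind, lapply(names(gene_calls), function(g) {
    v <- gene_calls[[g]]
    data.frame(tissue = tissue, group = group,
               sample = paste0("s", seq_along(v)), gene = g, call = v,
               stringsAsFactors = FALSE)
  }))
}

test_that("consensus requires unanimity; M breaks it", {
  calls <- make_calls(list(g1 = c("P", "P", "P"),
                           g2 = c("P", "P", "A"),
                           g3 = c("P", "M", "P")))
  st <- consensus_states(calls, "h", "grpA")
  expect_identical(unname(st["g1"]), "present")
  expect_identical(unname(st["g2"]), "absent")
  expect_identical(unname(st["g3"]), "absent")
  expect_error(consensus_states(calls, "h", "nope"), "no samples")
})

test_that("reaction states resolve rules per tissue of origin", {
  dm <- tiny_diamond()
  st <- reaction_states(dm, c(g1 = "present", g2 = "absent"))
  expect_identical(unname(st["r1"]), "present")
  expect_identical(unname(st["r2"]), "absent")
  expect_identical(unname(st["EX_A"]), "present")   # empty GPR

  # conflicting per-tissue states: the hepatic rule must see hepatic states
  mt <- toy_multitissue()
  gs <- list(h = c(g_h_slc2a1 = "absent"), m = c(g_h_slc2a1 = "present"))
  rs <- reaction_states(mt, gs)
  expect_identical(unname(rs["GLCt2[h]"]), "absent")
  expect_identical(unname(rs["GLCt1[h]"]), "present")
  # OR rule with one present isozyme stays present
  rs2 <- reaction_states(mt, list(h = c(g_h_ldha = "absent",
                                        g_h_ldhb = "present")))
  expect_identical(unname(rs2["LDH[h]"]), "present")
})

test_that("GIMME: identity when everything is present", {
  dm <- tiny_diamond(uptake = 10)
  rs <- setNames(rep("present", 4), dm$reactions$id)
  ctx <- gimme_extract(dm, rs, c(EX_B = 1), fraction = 0.9)
  expect_length(ctx$removed, 0)
  expect_length(ctx$retained_despite_absent, 0)
  expect_equal(ctx$penalty, 0)
  expect_equal(n_reactions(ctx$model), 4)
})

test_that("GIMME removes a redundant absent path and keeps the RMF", {
  dm <- tiny_diamond(uptake = 10)
  dm <- set_bounds(dm, "EX_A", lb = -10, ub = 0)
  rs <- setNames(rep("present", 4), dm$reactions$id)
  rs["r2"] <- "absent"
  ctx <- gimme_extract(dm, rs, c(EX_B = 1), fraction = 0.9)
  expect_identical(ctx$removed, "r2")
  expect_length(ctx$retained_despite_absent, 0)
  got <- fba(ctx$model, c(EX_B = 1), "max")
  expect_gte(got$objective_value, 9 - 1e-6)
})

test_that("GIMME retains an essential absent reaction, penalty = 0.9 x max", {
  ch <- tiny_chain(uptake = 10, uptake_fixed = FALSE)
  rs <- setNames(rep("present", 3), ch$reactions$id)
  rs["r1"] <- "absent"
  ctx <- gimme_extract(ch, rs, c(EX_B = 1), fraction = 0.9)
  expect_identical(ctx$retained_despite_absent, "r1")
  expect_length(ctx$removed, 0)
  expect_equal(ctx$penalty, 0.9 * 10, tolerance = 1e-6)
})

test_that("GIMME guards its preconditions", {
  dm <- tiny_diamond(10)
  rs <- setNames(rep("present", 4), dm$reactions$id)
  expect_error(gimme_extract(dm, rs, c(EX_B = 1), fraction = 0),
               "fraction")
  expect_error(gimme_extract(dm, rs, c(EX_B = 1), fraction = 1.2),
               "fraction")
  closed <- set_bounds(dm, "EX_A", lb = 0, ub = 0)
  expect_error(gimme_extract(closed, rs, c(EX_B = 1)), "RMF infeasible")
})

test_that("GIMME penalty is monotone in the absent set", {
  set.seed(5)
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("starvation")
  m <- apply_scenario(mt, sc)
  rmf <- c("EX_glc[bl]" = 1)
  cand <- setdiff(m$reactions$id, names(rmf))
  small <- sample(cand, 4)
  large <- union(small, sample(setdiff(cand, small), 4))
  pen <- vapply(list(large, small), function(ab) {
    rs <- setNames(ifelse(m$reactions$id %in% ab, "absent", "present"),
                   m$reactions$id)
    gimme_extract(m, rs, rmf, fraction = 0.9)$penalty
  }, 0)
  # shrinking the absent set (enlarging the present set) cannot raise it
  expect_lte(pen[2], pen[1] + 1e-6)
})

test_that("every context model achieves its RMF fraction", {
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("starvation")
  m <- apply_scenario(mt, sc)
  mts <- mt; mts$model <- m
  rmf <- c("EX_glc[bl]" = 1)
  for (scen in c("identical", "drop_redundant", "drop_essential")) {
    calls <- toy_expression(mt, scen)
    gs <- lapply(setNames(mt$tissues, mt$tissues), function(tt) {
      consensus_states(calls, tt, "grpB")
    })
    ctx <- gimme_extract(mts, reaction_states(mts, gs), rmf, 0.9)
    got <- fba(ctx$model, rmf, "max")
    expect_gte(got$objective_value, 0.9 * ctx$rmf$parent_optimum - 1e-6)
    expect_length(intersect(ctx$removed, ctx$retained_despite_absent), 0)
    expect_setequal(c(ctx$model$reactions$id, ctx$removed),
                    ctx$parent_reactions)
  }
})

test_that("differential activity: identity, redundant drop, blocked reactions", {
  mt <- toy_multitissue()
  sc <- toy_scenario_spec("starvation")
  m <- apply_scenario(mt, sc)
  mts <- mt; mts$model <- m
  rmf <- c("EX_glc[bl]" = 1)
  ctx_of <- function(scen, group) {
    calls <- toy_expression(mt, scen)
    gs <- lapply(setNames(mt$tissues, mt$tissues), function(tt) {
      consensus_states(calls, tt, group)
    })
    gimme_extract(mts, reaction_states(mts, gs), rmf, 0.9)
  }
  # identical contexts -> empty exclusive sets
  a <- ctx_of("identical", "grpA"); b <- ctx_of("identical", "grpB")
  da <- differential_activity(a, b)
  expect_length(da$only_in_A, 0)
  expect_length(da$only_in_B, 0)
  # partition covers the compared reactions
  expect_length(da$compared,
                length(da$only_in_A) + length(da$only_in_B) +
                  length(da$active_in_both) + length(da$inactive_in_both))

  # dropping the redundant exporter flips exactly that reaction
  b2 <- ctx_of("drop_redundant", "grpB")
  da2 <- differential_activity(a, b2)
  expect_identical(da2$only_in_A, "GLCt2[h]")
  expect_length(da2$only_in_B, 0)
  pt <- da2$per_tissue
  expect_equal(pt$only_in_A[pt$tissue == "h"], 1)
  expect_equal(sum(pt$only_in_A), 1)

  # essential drop: GIMME adds the reaction back, so no activity difference
  b3 <- ctx_of("drop_essential", "grpB")
  da3 <- differential_activity(a, b3)
  expect_length(da3$only_in_A, 0)
  expect_length(da3$only_in_B, 0)

  # a reaction present in B but FVA-blocked there is not "active in B":
  # fat tissue is idle in starvation (no substrate reaches it), so its
  # internal lipogenesis is membership-present yet activity-blocked
  expect_true("TAGS[a]" %in% b2$model$reactions$id)
  expect_false("TAGS[a]" %in% c(da2$only_in_B, da2$active_in_both))
})

test_that("mismatched parents are rejected", {
  dm <- tiny_diamond(10)
  dm <- set_bounds(dm, "EX_A", lb = -10, ub = 0)
  rs <- setNames(rep("present", 4), dm$reactions$id)
  ctxA <- gimme_extract(dm, rs, c(EX_B = 1), 0.9)
  ch <- tiny_chain(5, uptake_fixed = FALSE)
  ctxB <- gimme_extract(ch, setNames(rep("present", 3), ch$reactions$id),
                        c(EX_B = 1), 0.9)
  expect_error(differential_activity(ctxA, ctxB), "different parents")
})

test_that("call stability: unanimity is unbreakable, single-A flips at 1/2", {
  # unanimous P: no subsetting can flip it
  calls <- make_calls(list(g1 = rep("P", 4)))
  st <- call_stability(calls, 0.5, n_reps = 50, seed = 9)
  expect_equal(st$flip_rates$flip_rate, 0)
  expect_equal(st$overall_stability, 1)

  # one A among 4 samples, drop 2: flip probability 2/4 = 0.5
  calls2 <- make_calls(list(g2 = c("A", "P", "P", "P")))
  st2 <- call_stability(calls2, 0.5, n_reps = 4000, seed = 11)
  expect_equal(st2$flip_rates$flip_rate, 0.5, tolerance = 0.05)

  # same seed -> identical report
  st3 <- call_stability(calls2, 0.5, n_reps = 4000, seed = 11)
  expect_identical(st2, st3)

  expect_error(call_stability(calls2, 0.9, 10, 1), "drop_fraction")
})

test_that("dropping samples only moves genes absent -> present", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    genes <- paste0("g", 1:5)
    gene_calls <- lapply(setNames(genes, genes), function(g) {
      sample(c("P", "A", "M"), n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    })
    calls <- make_calls(gene_calls)
    full <- consensus_states(calls, "h", "grpA")
    keep <- sample(unique(calls$sample), sample(1:(n - 1), 1))
    red <- consensus_states(calls[calls$sample %in% keep, , drop = FALSE],
                            "h", "grpA")
    moved_wrong <- full[names(red)] == "present" & red == "absent"
    expect_false(any(moved_wrong))
  }
})
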