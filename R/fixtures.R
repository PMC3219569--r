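# Deterministic toy fixtures: three small, elementally and charge balanced,
# proton-explicit tissue models (gluconeogenic liver, glycolytic muscle,
# lipogenic fat) whose merged behaviour has closed-form optima.
#
# Stoichiometric yields are integers chosen for hand-checkability, not
# biochemical precision: 15 ATP per lactate oxidized, 6 ATP per glucose
# synthesized from lactate, 3 ATP per urea, 12.5 ATP per pyruvate oxidized.
# Every internal and transport reaction passes balance_report(); protons are
# explicit and cross membranes only via symports/antiports (lactate,
# alanine, fatty acid, pyruvate move with H+; ammonium exchanges against
# H+), so the merged model needs the blood bicarbonate buffer to simulate.

.toy_formulas <- function() {
  data.frame(
    base = c("glc", "lac", "pyr", "ala", "urea", "o2", "co2", "h2o", "h",
             "hco3", "atp", "adp", "pi", "nad", "nadh", "nh4", "glyc",
             "fa", "tag"),
    formula = c("C6H12O6", "C3H5O3", "C3H3O3", "C3H7NO2", "CH4N2O", "O2",
                "CO2", "H2O", "H", "CHO3", "C10H12N5O13P3", "C10H12N5O10P2",
                "HPO4", "C21H26N7O14P2", "C21H27N7O14P2", "H4N", "C3H8O3",
                "C16H31O2", "C51H98O6"),
    charge = c(0L, -1L, -1L, 0L, 0L, 0L, 0L, 0L, 1L, -1L, -4L, -3L, -2L,
               -1L, -2L, 1L, 0L, -1L, 0L),
    stringsAsFactors = FALSE)
}

#' Parameters of the toy three-tissue world
#'
#' The defaults are the stated conditions of all frozen fixture optima:
#' blood lactate or alanine supply of 6 mmol/h for the nutrient-limited
#' cycles, hepatic ATP maintenance demand of 30 mmol/h, and integer
#' stoichiometric yields (15 ATP gained per lactate fully oxidized, 6 ATP
#' spent per glucose synthesized).
#'
#' @param uptake named numeric, blood supply rates in mmol/h for the
#'   scenario substrates.
#' @param maintenance named numeric, ATP maintenance lower bounds in mmol/h
#'   per tissue tag.
#' @param proton_coupling logical; when `FALSE` the metabolite transporters
#'   drop their H+ coupling, which breaks proton balancing on purpose (the
#'   resulting merged model is infeasible with or without the buffer).
#' @param redundant_glc_transporter logical; give the liver a second,
#'   isozyme-encoded glucose exporter (used by the expression scenarios).
#' @param seed integer seed recorded for expression-call generation.
#' @return a `toy_scenario` parameter object.
#' @export
toy_scenario <- function(uptake = c(lac = 6, ala = 6, glc = 10, fa = 3, nh4 = 5),
                         maintenance = c(a = 1, h = 30, m = 2),
                         proton_coupling = TRUE,
                         redundant_glc_transporter = TRUE,
                         seed = 1L) {
  stopifnot(all(uptake >= 0), all(maintenance >= 0))
  structure(list(uptake = uptake, maintenance = maintenance,
                 yield_atp_per_lac = 15L, atp_per_glc = 6L,
                 proton_coupling = isTRUE(proton_coupling),
                 redundant_glc_transporter = isTRUE(redundant_glc_transporter),
                 seed = as.integer(seed)),
            class = "toy_scenario")
}

# helper: assemble a tissue model from equation strings
.build_toy <- function(id, rxdf, mets_used) {
  ftab <- .toy_formulas()
  mets <- do.call(rbind, lapply(names(mets_used), function(comp) {
    bases <- mets_used[[comp]]
    i <- match(bases, ftab$base)
    data.frame(id = sprintf("%s[%s]", bases, comp), base_id = bases,
               compartment = comp, name = bases,
               formula = ftab$formula[i], charge = ftab$charge[i],
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(rxdf$equation, parse_equation)
  names(stoich) <- rxdf$id
  reactions <- data.frame(id = rxdf$id, lower_bound = rxdf$lb,
                          upper_bound = rxdf$ub, gpr = rxdf$gpr,
                          subsystem = rxdf$subsystem, kind = rxdf$kind,
                          stringsAsFactors = FALSE)
  metabolic_model(mets, reactions, stoich, id = id)
}

.rx <- function(id, equation, lb, ub, gpr = "", subsystem = "", kind = "internal") {
  data.frame(id = id, equation = equation, lb = lb, ub = ub, gpr = gpr,
             subsystem = subsystem, kind = kind, stringsAsFactors = FALSE)
}

#' Generate a toy tissue model
#'
#' Builds one of three small balanced tissue models (compartments `c` and
#' extracellular `e`), already tagged for merging:
#' * `liver` ("h"): gluconeogenesis from lactate (2 lac + 6 atp -> glc),
#'   lactate oxidation (lac + 3 o2 -> 3 co2 + 15 atp), lactate
#'   dehydrogenase, alanine deamination to pyruvate, urea synthesis, ATP
#'   maintenance, biomass stub, and glucose export.
#' * `muscle` ("m"): glycolysis to pyruvate with NADH bookkeeping, lactate
#'   and alanine export paths, ATP maintenance, biomass stub.
#' * `fat` ("a"): glycerol synthesis from glucose, triacylglycerol
#'   esterification from imported fatty acids, pyruvate oxidation, a
#'   triacylglycerol storage drain, ATP maintenance, biomass stub.
#'
#' @param kind `"liver"`, `"muscle"` or `"fat"`.
#' @param params a [toy_scenario()] object.
#' @return a `tissue_model` (tags `"h"`, `"m"`, `"a"` respectively).
#' @export
toy_tissue <- function(kind = c("liver", "muscle", "fat"),
                       params = toy_scenario()) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "toy_scenario"))
  pc <- params$proton_coupling
  sym <- function(met, from = "e", to = "c", h = pc) {
    # proton-coupled symport equation text
    if (h) sprintf("%s[%s] + h[%s] <-> %s[%s] + h[%s]", met, from, from, met, to, to)
    else sprintf("%s[%s] <-> %s[%s]", met, from, met, to)
  }
  builders <- list(
    liver = function() {
      rx <- rbind(
        .rx("GNG", "2 lac[c] + 6 atp[c] + 6 h2o[c] -> glc[c] + 6 adp[c] + 6 pi[c] + 4 h[c]",
            0, 1000, "g_h_pck1 and g_h_fbp1", "Gluconeogenesis"),
        .rx("LACOX", "lac[c] + 3 o2[c] + 15 adp[c] + 15 pi[c] + 16 h[c] -> 3 co2[c] + 15 atp[c] + 18 h2o[c]",
            0, 1000, "g_h_oxphos", "Energy metabolism"),
        .rx("LDH", "pyr[c] + nadh[c] + h[c] <-> lac[c] + nad[c]",
            -1000, 1000, "g_h_ldha or g_h_ldhb", "Energy metabolism"),
        .rx("ALADH", "ala[c] + nad[c] + h2o[c] -> pyr[c] + nh4[c] + nadh[c] + h[c]",
            0, 1000, "g_h_gpt", "Amino acid metabolism"),
        .rx("UREA", "2 nh4[c] + co2[c] + 3 atp[c] + 2 h2o[c] -> urea[c] + 3 adp[c] + 3 pi[c] + 5 h[c]",
            0, 1000, "g_h_cps1 and g_h_otc and g_h_arg1", "Urea cycle"),
        .rx("ATPM", "atp[c] + h2o[c] -> adp[c] + pi[c] + h[c]",
            0, 1000, "", "Maintenance"),
        .rx("BIOMASS", "10 atp[c] + 10 h2o[c] -> 10 adp[c] + 10 pi[c] + 10 h[c]",
            0, 1000, "", "Maintenance", "biomass"),
        .rx("GLCt1", "glc[c] -> glc[e]", 0, 1000, "g_h_slc2a2", "Transport",
            "transporter"),
        .rx("LACt", sym("lac"), -1000, 1000, "g_h_mct1", "Transport", "transporter"),
        # alanine is neutral: proton coupling would move net charge, so it
        # crosses as a plain uniport
        .rx("ALAt", "ala[e] <-> ala[c]", -1000, 1000, "g_h_slc38a2", "Transport",
            "transporter"),
        .rx("UREAt", "urea[c] <-> urea[e]", -1000, 1000, "", "Transport", "transporter"),
        .rx("O2t", "o2[e] <-> o2[c]", -1000, 1000, "", "Transport", "transporter"),
        .rx("CO2t", "co2[c] <-> co2[e]", -1000, 1000, "", "Transport", "transporter"),
        .rx("H2Ot", "h2o[c] <-> h2o[e]", -1000, 1000, "", "Transport", "transporter"))
      if (params$redundant_glc_transporter) {
        rx <- rbind(rx, .rx("GLCt2", "glc[c] -> glc[e]", 0, 1000, "g_h_slc2a1",
                            "Transport", "transporter"))
      }
      ex <- c("glc", "lac", "ala", "urea", "o2", "co2", "h2o", "h")
      rx <- rbind(rx, do.call(rbind, lapply(ex, function(b) {
        .rx(paste0("EX_", b), sprintf("%s[e] <->", b), -1000, 1000, "",
            "Exchange", "exchange")
      })))
      mets <- list(
        c = c("glc", "lac", "pyr", "ala", "urea", "o2", "co2", "h2o", "h",
              "atp", "adp", "pi", "nad", "nadh", "nh4"),
        e = ex)
      list(model = .build_toy("toy_liver", rx, mets), tag = "h")
    },
    muscle = function() {
      rx <- rbind(
        .rx("GLYCP", "glc[c] + 2 nad[c] + 2 adp[c] + 2 pi[c] -> 2 pyr[c] + 2 nadh[c] + 2 atp[c] + 2 h2o[c] + 2 h[c]",
            0, 1000, "g_m_pfkm and g_m_pkm", "Glycolysis"),
        .rx("LDHm", "pyr[c] + nadh[c] + h[c] -> lac[c] + nad[c]",
            0, 1000, "g_m_ldha", "Glycolysis"),
        .rx("ALATA", "pyr[c] + nh4[c] + nadh[c] + h[c] -> ala[c] + nad[c] + h2o[c]",
            0, 1000, "g_m_gpt2", "Amino acid metabolism"),
        .rx("ATPM", "atp[c] + h2o[c] -> adp[c] + pi[c] + h[c]",
            0, 1000, "", "Maintenance"),
        .rx("BIOMASS", "10 atp[c] + 10 h2o[c] -> 10 adp[c] + 10 pi[c] + 10 h[c]",
            0, 1000, "", "Maintenance", "biomass"),
        .rx("GLCt", "glc[e] -> glc[c]", 0, 1000, "g_m_slc2a4", "Transport",
            "transporter"),
        .rx("LACt", if (pc) "lac[c] + h[c] -> lac[e] + h[e]" else "lac[c] -> lac[e]",
            0, 1000, "g_m_mct4", "Transport", "transporter"),
        .rx("ALAt", "ala[c] -> ala[e]", 0, 1000, "g_m_slc38a2", "Transport",
            "transporter"),
        .rx("NH4t", if (pc) "nh4[e] + h[c] -> nh4[c] + h[e]" else "nh4[e] -> nh4[c]",
            0, 1000, "", "Transport", "transporter"),
        .rx("H2Ot", "h2o[c] <-> h2o[e]", -1000, 1000, "", "Transport", "transporter"))
      ex <- c("glc", "lac", "ala", "nh4", "h2o", "h")
      rx <- rbind(rx, do.call(rbind, lapply(ex, function(b) {
        .rx(paste0("EX_", b), sprintf("%s[e] <->", b), -1000, 1000, "",
            "Exchange", "exchange")
      })))
      mets <- list(
        c = c("glc", "lac", "pyr", "ala", "h2o", "h", "atp", "adp", "pi",
              "nad", "nadh", "nh4"),
        e = ex)
      list(model = .build_toy("toy_muscle", rx, mets), tag = "m")
    },
    fat = function() {
      rx <- rbind(
        .rx("GLYCS", "glc[c] + atp[c] + h2o[c] -> glyc[c] + pyr[c] + adp[c] + pi[c] + 2 h[c]",
            0, 1000, "g_a_gpd1", "Lipogenesis"),
        .rx("TAGS", "glyc[c] + 3 fa[c] + 3 atp[c] -> tag[c] + 3 adp[c] + 3 pi[c]",
            0, 1000, "g_a_dgat1", "Lipogenesis"),
        .rx("PYROX", "2 pyr[c] + 5 o2[c] + 25 adp[c] + 25 pi[c] + 27 h[c] -> 6 co2[c] + 25 atp[c] + 29 h2o[c]",
            0, 1000, "g_a_pdh and g_a_oxphos", "Energy metabolism"),
        .rx("ATPM", "atp[c] + h2o[c] -> adp[c] + pi[c] + h[c]",
            0, 1000, "", "Maintenance"),
        .rx("BIOMASS", "10 atp[c] + 10 h2o[c] -> 10 adp[c] + 10 pi[c] + 10 h[c]",
            0, 1000, "", "Maintenance", "biomass"),
        .rx("TAGSTOR", "tag[c] ->", 0, 1000, "", "Storage", "biomass"),
        .rx("GLCt", "glc[e] -> glc[c]", 0, 1000, "g_a_slc2a4", "Transport",
            "transporter"),
        .rx("GLYCt", "glyc[c] <-> glyc[e]", -1000, 1000, "g_a_aqp7", "Transport",
            "transporter"),
        .rx("FAt", sym("fa"), -1000, 1000, "g_a_cd36", "Transport", "transporter"),
        .rx("PYRt", if (pc) "pyr[c] + h[c] -> pyr[e] + h[e]" else "pyr[c] -> pyr[e]",
            0, 1000, "g_a_mct1", "Transport", "transporter"),
        .rx("O2t", "o2[e] <-> o2[c]", -1000, 1000, "", "Transport", "transporter"),
        .rx("CO2t", "co2[c] <-> co2[e]", -1000, 1000, "", "Transport", "transporter"),
        .rx("H2Ot", "h2o[c] <-> h2o[e]", -1000, 1000, "", "Transport", "transporter"))
      ex <- c("glc", "glyc", "fa", "pyr", "o2", "co2", "h2o", "h")
      rx <- rbind(rx, do.call(rbind, lapply(ex, function(b) {
        .rx(paste0("EX_", b), sprintf("%s[e] <->", b), -1000, 1000, "",
            "Exchange", "exchange")
      })))
      mets <- list(
        c = c("glc", "glyc", "pyr", "fa", "tag", "o2", "co2", "h2o", "h",
              "atp", "adp", "pi"),
        e = ex)
      list(model = .build_toy("toy_fat", rx, mets), tag = "a")
    })
  built <- builders[[kind]]()
  masses <- list(
    h = list(wet_mass_g = 1800, cell_fraction = 0.8, water_fraction = 0.7,
             growth_rate_per_h = 0),
    m = list(wet_mass_g = 28000, cell_fraction = 1.0, water_fraction = 0.75,
             growth_rate_per_h = 0),
    a = list(wet_mass_g = 15000, cell_fraction = 1.0, water_fraction = 0.15,
             growth_rate_per_h = 0))
  tag_model(built$model, built$tag, biomass_reaction_id = "BIOMASS",
            mass_params = masses[[built$tag]])
}

#' Generate the merged toy multi-tissue model
#'
#' Merges the liver, muscle and fat toys through the blood compartment and
#' adds the bicarbonate buffer (unless `buffer = FALSE`). The whitelist
#' covers glc, lac, ala, urea, o2, co2, h2o, fa, pyr and nh4 -- but never
#' the proton, which is exactly why the buffer is needed.
#'
#' @param params a [toy_scenario()].
#' @param buffer add the bicarbonate buffer (default `TRUE`).
#' @return a `multi_tissue_model`.
#' @export
toy_multitissue <- function(params = toy_scenario(), buffer = TRUE) {
  tissues <- list(toy_tissue("liver", params), toy_tissue("muscle", params),
                  toy_tissue("fat", params))
  wl <- c("glc", "lac", "ala", "urea", "o2", "co2", "h2o", "fa", "pyr",
          "nh4", "glyc")
  mt <- merge_models(tissues, wl)
  if (buffer) mt <- add_buffer(mt)
  mt
}

#' Closed-form optima of the toy scenarios
#'
#' The fixture manifest: hand-derived optima of the toy multi-tissue
#' scenarios at the parameters in `params`, against which solver results
#' are asserted. For the default parameters (lactate/alanine input 6,
#' hepatic maintenance 30, yields 15 and 6):
#' * Cori: max hepatic glucose output `5/3` mmol/h
#'   (from `2g + y = 6`, `15y - 6g >= 30`), carbon split glucose
#'   `10/18 = 0.5556`, maintenance `0.4444`.
#' * Alanine: max glucose `17/12` (urea synthesis costs 9 ATP for 6 N),
#'   carbon split glucose `17/36`, urea `1/6`, maintenance `13/36`.
#'
#' @param params a [toy_scenario()].
#' @return nested list of expected values per scenario.
#' @export
toy_manifest <- function(params = toy_scenario()) {
  L <- unname(params$uptake["lac"]); A <- unname(params$uptake["ala"])
  M <- unname(params$maintenance["h"])
  yl <- params$yield_atp_per_lac; cg <- params$atp_per_glc
  # Cori: max g s.t. 2g + y = L, yl*y - cg*g >= M
  g_cori <- (yl * L - M) / (2 * yl + cg)
  cori_in_C <- 3 * L
  # Alanine: urea costs 3 ATP per 2 N -> 1.5*A total; same lactate algebra
  g_ala <- (yl * A - M - 1.5 * A) / (2 * yl + cg)
  ala_in_C <- 3 * A
  list(
    cori = list(glucose_out = g_cori,
                split = c(glucose = 6 * g_cori / cori_in_C,
                          maintenance = 1 - 6 * g_cori / cori_in_C)),
    alanine = list(glucose_out = g_ala, urea_out = A / 2,
                   split = c(glucose = 6 * g_ala / ala_in_C,
                             urea = (A / 2) / ala_in_C,
                             maintenance = 1 - 6 * g_ala / ala_in_C -
                               (A / 2) / ala_in_C)),
    absorptive = list(tag_stored = unname(params$uptake["fa"]) / 3))
}

#' Scenario definitions for the toy multi-tissue model
#'
#' Returns a `scenario` object (see [scenario()]) reproducing one of the
#' integrated metabolic states on the toy model: the Cori cycle (blood
#' lactate in, hepatic glucose out), the alanine cycle (blood alanine in,
#' glucose + urea out), the absorptive state (glucose/fatty acid/ammonium
#' in; lexicographic storage objectives), or prolonged starvation (storage
#' objectives turned into inputs, hepatic glucose production maximized).
#'
#' @param name one of `"cori"`, `"alanine"`, `"absorptive"`, `"starvation"`.
#' @param params a [toy_scenario()].
#' @return a `scenario` object.
#' @export
toy_scenario_spec <- function(name = c("cori", "alanine", "absorptive",
                                       "starvation"),
                              params = toy_scenario()) {
  name <- match.arg(name)
  L <- unname(params$uptake["lac"]); A <- unname(params$uptake["ala"])
  G <- unname(params$uptake["glc"]); FA <- unname(params$uptake["fa"])
  N <- unname(params$uptake["nh4"]); M <- params$maintenance
  closed_uptake <- function(ex) {
    # secretion allowed, uptake forbidden
    stats::setNames(lapply(ex, function(e) c(0, 1000)), ex)
  }
  base_ex <- c("EX_glc[bl]", "EX_lac[bl]", "EX_ala[bl]", "EX_urea[bl]",
               "EX_fa[bl]", "EX_pyr[bl]", "EX_nh4[bl]", "EX_glyc[bl]")
  open <- list("EX_o2[bl]" = c(-1000, 1000), "EX_h2o[bl]" = c(-1000, 1000),
               "EX_co2[bl]" = c(-1000, 1000), "EX_hco3[bl]" = c(-1000, 1000))
  switch(name,
    cori = scenario(
      name = "cori",
      bound_overrides = c(closed_uptake(setdiff(base_ex, "EX_lac[bl]")), open,
                          list("EX_lac[bl]" = c(-L, -L),
                               "ATPM[h]" = c(M[["h"]], 1000))),
      deactivate_tissues = "a",
      objectives = list(list(objective = c("EX_glc[bl]" = 1),
                             direction = "max", fix_fraction = 1)),
      carbon_sources = "EX_lac[bl]",
      carbon_sinks = list(glucose = "EX_glc[bl]")),
    alanine = scenario(
      name = "alanine",
      bound_overrides = c(closed_uptake(setdiff(base_ex, "EX_ala[bl]")), open,
                          list("EX_ala[bl]" = c(-A, -A),
                               "ATPM[h]" = c(M[["h"]], 1000))),
      deactivate_tissues = "a",
      objectives = list(list(objective = c("EX_glc[bl]" = 1),
                             direction = "max", fix_fraction = 1)),
      carbon_sources = "EX_ala[bl]",
      carbon_sinks = list(glucose = "EX_glc[bl]", urea = "EX_urea[bl]")),
    absorptive = scenario(
      name = "absorptive",
      bound_overrides = c(
        closed_uptake(c("EX_lac[bl]", "EX_ala[bl]", "EX_urea[bl]", "EX_pyr[bl]",
                        "EX_glyc[bl]")),
        open,
        list("EX_glc[bl]" = c(-G, 0), "EX_fa[bl]" = c(-FA, 0),
             "EX_nh4[bl]" = c(-N, 0),
             "ATPM[a]" = c(M[["a"]], 1000), "ATPM[m]" = c(M[["m"]], 1000))),
      objectives = list(
        list(objective = c("TAGSTOR[a]" = 1), direction = "max", fix_fraction = 1),
        list(objective = c("ALAt[m]" = 1), direction = "max", fix_fraction = 0.5),
        list(objective = c("ATPM[m]" = 1), direction = "max", fix_fraction = 1)),
      carbon_sources = c("EX_glc[bl]", "EX_fa[bl]"),
      carbon_sinks = list(triacylglycerol = "TAGSTOR[a]")),
    starvation = scenario(
      name = "starvation",
      bound_overrides = c(
        closed_uptake(c("EX_glc[bl]", "EX_lac[bl]", "EX_urea[bl]", "EX_nh4[bl]",
                        "EX_fa[bl]", "EX_pyr[bl]", "EX_glyc[bl]")),
        open,
        # the absorptive storage objective is inverted: muscle protein
        # breakdown (alanine release) feeds hepatic glucose production
        list("EX_ala[bl]" = c(-A, 0),
             "ATPM[h]" = c(M[["h"]], 1000), "ATPM[m]" = c(M[["m"]], 1000))),
      objectives = list(list(objective = c("EX_glc[bl]" = 1),
                             direction = "max", fix_fraction = 1)),
      carbon_sources = "EX_ala[bl]",
      carbon_sinks = list(glucose = "EX_glc[bl]", urea = "EX_urea[bl]")))
}

#' Generate synthetic expression call sets for the toy model
#'
#' Emits per-tissue, two-group, `n_samples`-sample present/absent call
#' tables over the toy gene registry:
#' * `identical`: every gene present in every sample of both groups.
#' * `drop_redundant`: group B lacks `g_h_slc2a1`, the isozyme of the
#'   redundant second hepatic glucose exporter; its reaction is removable
#'   without touching the required metabolic functionality.
#' * `drop_essential`: group B lacks `g_h_pck1`, on the only path to
#'   hepatic glucose production; GIMME must add the reaction back in.
#'
#' @param mt the toy `multi_tissue_model` (provides the gene universe).
#' @param scenario one of `"identical"`, `"drop_redundant"`,
#'   `"drop_essential"`.
#' @param seed integer; recorded for determinism (the generator is fully
#'   deterministic given its arguments).
#' @param n_samples samples per tissue and group.
#' @return an `expression_calls` data.frame (tissue, group, sample, gene,
#'   call).
#' @export
toy_expression <- function(mt, scenario = c("identical", "drop_redundant",
                                            "drop_essential"),
                           seed = 1L, n_samples = 4L) {
  scenario <- match.arg(scenario)
  genes <- mt$model$genes
  tissue_of_gene <- function(g) {
    m <- regmatches(g, regexec("^g_([ahm])_", g))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  tis <- vapply(genes, tissue_of_gene, "")
  rows <- list()
  for (tt in intersect(c("a", "h", "m"), unique(tis))) {
    gs <- genes[tis == tt]
    for (grp in c("grpA", "grpB")) {
      for (s in seq_len(n_samples)) {
        call <- rep("P", length(gs))
        if (grp == "grpB") {
          drop_gene <- switch(scenario, identical = NA_character_,
                              drop_redundant = "g_h_slc2a1",
                              drop_essential = "g_h_pck1")
          if (!is.na(drop_gene)) call[gs == drop_gene] <- "A"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          tissue = tt, group = grp, sample = sprintf("%s_%s_s%d", tt, grp, s),
          gene = gs, call = call, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("expression_calls", class(out))
  out
}
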