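# Built-in scenario designs. Each emulates the qualitative signal structure
# of one class of tri-label biosynthesis experiment:
#   cellcycle       - one asynchronously dividing cell line with full phase
#                     structure (mitotic suppression of nascent RNA, late-
#                     mitotic suppression of nascent protein).
#   pbmc_timecourse - six barcoded stimulation time points (0/0.25/0.5/1/2/5 h)
#                     over seven immune populations, with RNA-early /
#                     protein-late activation kinetics and late CD69.
#   marrow_hierarchy- twelve bone-marrow populations including a B-cell
#                     developmental continuum with a latent pseudotime
#                     coordinate and a nascent-RNA burst after IgM onset.

#' Panels, designs and configs for the built-in scenarios
#'
#' `scenario_panel()` returns the channel panel, `make_scenario()` the fully
#' parameterized [experiment_design()], `scenario_config()` a matching
#' [load_config()]-style pipeline configuration (gates, clustering channels,
#' annotation rules, comparisons), and `scenario_annotation()` the ordered
#' first-match annotation rules.
#'
#' @param name One of `"cellcycle"`, `"pbmc_timecourse"`,
#'   `"marrow_hierarchy"`.
#' @param seed Simulation seed.
#' @param n_events Events per condition; defaults: 10,000 (cellcycle), 4,000
#'   per time point (pbmc_timecourse), 100,000 (marrow_hierarchy).
#' @param ... Scenario-specific overrides: `m_g2_bru_ratio` /
#'   `mlate_puro_ratio` (cellcycle, default 0.3), `inhibitor`
#'   (`list(model, dose)`).
#' @return See above.
#' @export
make_scenario <- function(name = c("cellcycle", "pbmc_timecourse",
                                   "marrow_hierarchy"),
                          seed = 0L, n_events = NULL, ...) {
  name <- match.arg(name)
  switch(name,
         cellcycle = scenario_cellcycle(seed, n_events %||% 10000L, ...),
         pbmc_timecourse = scenario_pbmc(seed, n_events %||% 4000L, ...),
         marrow_hierarchy = scenario_marrow(seed, n_events %||% 100000L, ...))
}

#' @rdname make_scenario
#' @export
scenario_names <- function() {
  c("cellcycle", "pbmc_timecourse", "marrow_hierarchy")
}

bead_channel_defs <- function() {
  panel(channel_def("bead_Ce140", "Ce140", "bead"),
        channel_def("bead_Eu151", "Eu151", "bead"),
        channel_def("bead_Eu153", "Eu153", "bead"),
        channel_def("bead_Ho165", "Ho165", "bead"),
        channel_def("bead_Lu175", "Lu175", "bead"))
}

barcode_channel_defs <- function() {
  panel(channel_def("bc_Pd102", "Pd102", "barcode"),
        channel_def("bc_Pd104", "Pd104", "barcode"),
        channel_def("bc_Pd105", "Pd105", "barcode"),
        channel_def("bc_Pd106", "Pd106", "barcode"),
        channel_def("bc_Pd108", "Pd108", "barcode"),
        channel_def("bc_Pd110", "Pd110", "barcode"))
}

core_channel_defs <- function() {
  panel(channel_def("IdU", "I127", "biosynthesis"),
        channel_def("BRU", "Tm169", "biosynthesis"),
        channel_def("Puromycin", "Gd158", "biosynthesis"),
        channel_def("cisplatin", "Pt195", "viability"),
        channel_def("cCaspase3", "Yb174", "viability"),
        channel_def("DNA_Ir191", "Ir191", "dna_content"))
}

#' @rdname make_scenario
#' @export
scenario_panel <- function(name = c("cellcycle", "pbmc_timecourse",
                                    "marrow_hierarchy")) {
  name <- match.arg(name)
  core <- core_channel_defs()
  beads <- bead_channel_defs()
  switch(name,
    cellcycle = rbind(core,
      panel(channel_def("CyclinB1", "Tb159", "phenotype"),
            channel_def("pHH3", "Gd156", "phenotype"),
            channel_def("p4EBP1", "Er167", "signaling"),
            channel_def("pS6", "Yb172", "signaling")),
      beads),
    pbmc_timecourse = rbind(core,
      panel(channel_def("CD45", "Y89", "phenotype"),
            channel_def("CD3", "Nd145", "phenotype"),
            channel_def("CD4", "Gd157", "phenotype"),
            channel_def("CD8", "Nd146", "phenotype"),
            channel_def("CD19", "Nd142", "phenotype"),
            channel_def("CD56", "Yb176", "phenotype"),
            channel_def("CD14", "Nd148", "phenotype"),
            channel_def("CD33", "Nd150", "phenotype"),
            channel_def("CD11c", "Sm147", "phenotype"),
            channel_def("CD123", "Eu152", "phenotype"),
            channel_def("HLADR", "Sm149", "phenotype"),
            channel_def("CD69", "Dy162", "phenotype"),
            channel_def("p4EBP1", "Er167", "signaling"),
            channel_def("pS6", "Yb172", "signaling"),
            channel_def("TNFa", "Dy164", "signaling"),
            channel_def("IFNg", "Gd160", "signaling")),
      beads, barcode_channel_defs()),
    marrow_hierarchy = rbind(core,
      panel(channel_def("CD45", "Y89", "phenotype"),
            channel_def("CD34", "Nd143", "phenotype"),
            channel_def("CD38", "Er168", "phenotype"),
            channel_def("CD90", "Dy161", "phenotype"),
            channel_def("CD19", "Nd142", "phenotype"),
            channel_def("CD10", "Gd155", "phenotype"),
            channel_def("CD20", "Dy163", "phenotype"),
            channel_def("IgM", "Yb171", "phenotype"),
            channel_def("CD3", "Nd145", "phenotype"),
            channel_def("CD56", "Yb176", "phenotype"),
            channel_def("CD14", "Nd148", "phenotype"),
            channel_def("CD33", "Nd150", "phenotype"),
            channel_def("CD123", "Eu152", "phenotype"),
            channel_def("CD235", "Pr141", "phenotype"),
            channel_def("CD138", "Nd144", "phenotype"),
            channel_def("pS6", "Yb172", "signaling")),
      beads))
}

#' Cell-cycle population specification
#'
#' The default asynchronously dividing line: 2% mitotic frequency, IdU high
#' only in S, CyclinB1 negative/mid/high across G0G1/S/G2 (dropping again in
#' late mitosis), p-HH3 high only in mitosis, BRU in mitosis at
#' `m_g2_bru_ratio` of the G2 median, puromycin reduced only in late mitosis
#' at `mlate_puro_ratio` of its early-mitotic level, p-4EBP1 maximal in early
#' mitosis.
#'
#' @param m_g2_bru_ratio Mitotic/G2 ratio of the BRU median (< 1).
#' @param mlate_puro_ratio Late-/early-mitotic ratio of the puromycin median.
#' @param s_fraction S-phase fraction (default 0.30).
#' @param m_fraction Total mitotic fraction (default 0.02).
#' @return A [population_spec()].
#' @export
cellcycle_spec <- function(m_g2_bru_ratio = 0.3, mlate_puro_ratio = 0.3,
                           s_fraction = 0.30, m_fraction = 0.02) {
  g2 <- 0.13
  g0 <- 1 - s_fraction - g2 - m_fraction
  bru_g2 <- 150
  puro_early <- 200
  population_spec(
    "HeLa", 1,
    channel_medians = c(BRU = 100, Puromycin = 150, CyclinB1 = 2, pHH3 = 2,
                        p4EBP1 = 10, pS6 = 30, DNA_Ir191 = 300),
    phase_profile = list(
      fractions = c(G0G1 = g0, S = s_fraction, G2 = g2,
                    M_early = 0.6 * m_fraction, M_late = 0.4 * m_fraction),
      medians = list(
        G0G1 = list(IdU = 1),
        S = list(IdU = 200, CyclinB1 = 50, BRU = 120, Puromycin = 180),
        G2 = list(IdU = 1, CyclinB1 = 200, BRU = bru_g2, Puromycin = 200),
        M_early = list(IdU = 1, CyclinB1 = 200, pHH3 = 150,
                       BRU = m_g2_bru_ratio * bru_g2,
                       Puromycin = puro_early, p4EBP1 = 60),
        M_late = list(IdU = 1, CyclinB1 = 30, pHH3 = 150,
                      BRU = m_g2_bru_ratio * bru_g2,
                      Puromycin = mlate_puro_ratio * puro_early,
                      p4EBP1 = 30))))
}

scenario_cellcycle <- function(seed, n_events, m_g2_bru_ratio = 0.3,
                               mlate_puro_ratio = 0.3, inhibitor = NULL) {
  experiment_design(
    panel = scenario_panel("cellcycle"),
    populations = list(cellcycle_spec(m_g2_bru_ratio, mlate_puro_ratio)),
    n_events = n_events,
    dead_fraction = 0.03, apoptotic_fraction = 0.02, bead_fraction = 0.01,
    inhibitor = inhibitor, seed = seed)
}

# PMA/ionomycin kinetics: multiplicative factors on the baseline medians per
# stimulation time. Nascent RNA rises within the first hour and returns to
# baseline by 5 h; nascent protein rises late (2-5 h); CD69 surfaces only
# from 2 h; S6/4EBP1 phosphorylation is immediate; cytokines accumulate late.
pbmc_kinetics <- function() {
  times <- c("0", "0.25", "0.5", "1", "2", "5")
  f <- function(...) stats::setNames(c(...), times)
  list(times = times,
       BRU       = f(1, 1.6, 2.5, 2.5, 1.3, 1.0),
       Puromycin = f(1, 1.0, 1.0, 1.0, 1.8, 2.2),
       CD69      = f(1, 1.0, 1.0, 1.0, 3.0, 6.0),
       pS6       = f(1, 3.0, 3.0, 2.0, 1.5, 1.2),
       p4EBP1    = f(1, 2.0, 2.0, 1.5, 1.2, 1.0),
       TNFa      = f(1, 1.0, 1.0, 1.2, 2.0, 4.0),
       IFNg      = f(1, 1.0, 1.0, 1.0, 1.5, 3.0))
}

pbmc_populations <- function() {
  base <- c(CD45 = 200, CD69 = 2, IdU = 1, DNA_Ir191 = 300, pS6 = 20)
  pop <- function(name, frequency, ...) {
    population_spec(name, frequency,
                    channel_medians = c(base, c(...)),
                    idu_positive_fraction = 0.01)
  }
  list(
    pop("CD4T", 0.25, CD3 = 200, CD4 = 200, BRU = 60, Puromycin = 90,
        p4EBP1 = 8),
    pop("CD8T", 0.15, CD3 = 200, CD8 = 200, BRU = 55, Puromycin = 90,
        p4EBP1 = 8),
    pop("Bcell", 0.12, CD19 = 200, HLADR = 200, BRU = 150, Puromycin = 100,
        p4EBP1 = 8),
    pop("NK", 0.10, CD56 = 200, BRU = 50, Puromycin = 100, p4EBP1 = 10),
    pop("Monocyte", 0.25, CD14 = 200, CD33 = 200, CD11c = 150, HLADR = 150,
        BRU = 70, Puromycin = 250, p4EBP1 = 40),
    pop("DC", 0.05, CD11c = 200, HLADR = 200, CD123 = 60, BRU = 70,
        Puromycin = 220, p4EBP1 = 35),
    pop("Basophil", 0.08, CD123 = 200, BRU = 40, Puromycin = 80, p4EBP1 = 8))
}

scenario_pbmc <- function(seed, n_events, inhibitor = NULL) {
  kin <- pbmc_kinetics()
  pops0 <- pbmc_populations()
  samples <- lapply(kin$times, function(tm) {
    pops <- lapply(pops0, function(p) {
      for (ch in setdiff(names(kin), "times")) {
        if (ch %in% names(p$channel_medians))
          p$channel_medians[[ch]] <- p$channel_medians[[ch]] * kin[[ch]][[tm]]
      }
      p
    })
    list(name = tm, populations = pops)
  })
  experiment_design(
    panel = scenario_panel("pbmc_timecourse"),
    samples = samples, n_events = n_events,
    dead_fraction = 0.04, apoptotic_fraction = 0.03, bead_fraction = 0.01,
    barcode_scheme = barcode_scheme(barcode_channel_defs()$name, k = 3L,
                                    doublet_rate = 0.02),
    spillover = list(list(src = "CD4", dst = "Puromycin", fraction = 0.01)),
    inhibitor = inhibitor,
    noise = list(sensitivity = c(1, 0.9)),
    seed = seed)
}

#' B-cell developmental continuum specification
#'
#' A single population whose phenotype is a smooth function of a latent
#' pseudotime coordinate `tau ~ Uniform(0, 1)`: CD34 decays, CD10 peaks in
#' the pro-/pre-B window, CD19 then CD20 rise, surface IgM rises with
#' half-rise at `tau = 0.6`, and nascent RNA (BRU) shows a burst centred at
#' `tau = 0.75` -- after IgM onset. Early coordinates (`tau < 0.35`) are
#' proliferative (25% S phase).
#'
#' @param frequency Population frequency within the marrow design.
#' @param bru_burst_center Centre of the nascent-RNA burst on the latent axis.
#' @param igm_half_rise IgM sigmoid midpoint on the latent axis.
#' @return A [population_spec()] with a `latent` block.
#' @export
b_continuum_spec <- function(frequency = 0.185, bru_burst_center = 0.75,
                             igm_half_rise = 0.6) {
  population_spec(
    "Bcell", frequency,
    channel_medians = c(CD45 = 200, Puromycin = 100, DNA_Ir191 = 300,
                        pS6 = 20),
    latent = list(
      channels = list(
        CD34 = function(tau) 150 * (1 - tau)^2 + 1,
        CD19 = function(tau) 1 + 199 * stats::plogis((tau - 0.25) / 0.08),
        CD10 = function(tau) 5 + 120 * exp(-(tau - 0.35)^2 / (2 * 0.15^2)),
        CD20 = function(tau) 1 + 149 * stats::plogis((tau - 0.7) / 0.08),
        IgM  = function(tau) 1 + 199 * stats::plogis((tau - igm_half_rise) / 0.06),
        BRU  = function(tau) 20 + 250 * exp(-(tau - bru_burst_center)^2 /
                                              (2 * 0.07^2))),
      idu_fraction = function(tau) ifelse(tau < 0.35, 0.25, 0.02)))
}

marrow_populations <- function() {
  pop <- function(name, frequency, idu, ...) {
    population_spec(name, frequency, channel_medians = c(DNA_Ir191 = 300, ...),
                    idu_positive_fraction = idu)
  }
  list(
    pop("HSC", 0.010, 0.02, CD45 = 100, CD34 = 200, CD38 = 2, CD90 = 150,
        BRU = 60, Puromycin = 80, pS6 = 15),
    pop("MPP", 0.015, 0.04, CD45 = 100, CD34 = 200, CD38 = 2, CD90 = 2,
        BRU = 90, Puromycin = 110, pS6 = 15),
    pop("CMP", 0.020, 0.12, CD45 = 100, CD34 = 200, CD38 = 150, CD33 = 60,
        BRU = 110, Puromycin = 160, pS6 = 20),
    pop("GMP", 0.030, 0.18, CD45 = 150, CD34 = 200, CD38 = 150, CD33 = 150,
        BRU = 120, Puromycin = 180, pS6 = 20),
    pop("MEP", 0.020, 0.20, CD45 = 80, CD34 = 200, CD38 = 150, CD235 = 60,
        BRU = 150, Puromycin = 200, pS6 = 20),
    pop("Erythroid", 0.150, 0.35, CD45 = 30, CD235 = 250, BRU = 250,
        Puromycin = 300, pS6 = 30),
    pop("Monocyte", 0.200, 0.02, CD45 = 200, CD14 = 200, CD33 = 150,
        BRU = 80, Puromycin = 250, pS6 = 25),
    pop("DC", 0.030, 0.02, CD45 = 200, CD123 = 200, CD33 = 60, BRU = 90,
        Puromycin = 220, pS6 = 25),
    pop("NK", 0.080, 0.01, CD45 = 200, CD56 = 200, BRU = 50, Puromycin = 100,
        pS6 = 15),
    pop("Tcell", 0.250, 0.01, CD45 = 200, CD3 = 200, BRU = 40, Puromycin = 90,
        pS6 = 15),
    pop("Plasma", 0.010, 0.01, CD45 = 100, CD138 = 250, CD38 = 250,
        CD19 = 30, BRU = 2, Puromycin = 500, pS6 = 40),
    b_continuum_spec(0.185))
}

scenario_marrow <- function(seed, n_events, inhibitor = NULL) {
  experiment_design(
    panel = scenario_panel("marrow_hierarchy"),
    populations = marrow_populations(),
    n_events = n_events,
    dead_fraction = 0.03, apoptotic_fraction = 0.02, bead_fraction = 0.01,
    inhibitor = inhibitor, seed = seed)
}

#' @rdname make_scenario
#' @export
scenario_annotation <- function(name = c("cellcycle", "pbmc_timecourse",
                                         "marrow_hierarchy")) {
  name <- match.arg(name)
  r <- ann_rule
  switch(name,
    cellcycle = list(r("HeLa", "DNA_Ir191 > 1")),
    pbmc_timecourse = list(
      r("Monocyte", "CD14 > 3"),
      r("Bcell", "CD19 > 3"),
      r("DC", "CD11c > 3"),
      r("CD4T", "CD3 > 3", "CD4 > 3"),
      r("CD8T", "CD3 > 3", "CD8 > 3"),
      r("NK", "CD56 > 3"),
      r("Basophil", "CD123 > 3")),
    marrow_hierarchy = list(
      r("Plasma", "CD138 > 3"),
      r("Erythroid", "CD235 > 3", "CD34 < 2"),
      r("Monocyte", "CD14 > 3"),
      r("NK", "CD56 > 3"),
      r("Tcell", "CD3 > 3"),
      r("DC", "CD123 > 3", "CD34 < 2"),
      r("Bcell", "CD19 > 2.5"),
      r("Bcell", "CD10 > 2.5"),
      r("GMP", "CD34 > 2.5", "CD33 > 3"),
      r("MEP", "CD34 > 2.5", "CD235 > 2"),
      r("HSC", "CD34 > 2.5", "CD90 > 3", "CD38 < 2"),
      r("MPP", "CD34 > 2.5", "CD38 < 2"),
      r("CMP", "CD34 > 2.5", "CD38 > 2.5")))
}

#' @rdname make_scenario
#' @export
scenario_config <- function(name = c("cellcycle", "pbmc_timecourse",
                                     "marrow_hierarchy"), seed = 0L,
                            n_events = NULL) {
  name <- match.arg(name)
  p <- scenario_panel(name)
  pheno <- p$name[p$kind == "phenotype"]
  cfg <- default_config()
  cfg$panel <- p
  cfg$scenario <- name
  cfg$n_events <- n_events
  cfg$seed <- seed
  cfg$gates <- list(
    gate_rule("cisplatin", "gt", NA, scale = "transformed", action = "drop"),
    gate_rule("cCaspase3", "gt", NA, scale = "transformed", action = "drop"))
  cfg$clustering$channels <- switch(name,
    cellcycle = c("CyclinB1", "pHH3"),
    pbmc_timecourse = setdiff(pheno, "CD69"),
    marrow_hierarchy = pheno)
  cfg$clustering$n_nodes <- switch(name, marrow_hierarchy = 175L, 150L)
  cfg$annotation <- scenario_annotation(name)
  cfg$fr$channels <- c("BRU", "Puromycin")
  if (name == "pbmc_timecourse") {
    cfg$barcode <- utils::modifyList(cfg$barcode, list(
      channels = barcode_channel_defs()$name, k = 3L))
    cfg$comparisons <- list(condition_label = "sample", control = "0")
  }
  if (name == "marrow_hierarchy") {
    cfg$fr$reference <- "HSC"
    cfg$trajectory$lineage <- "Bcell"
    cfg$trajectory$channels <- c("CD34", "CD19", "CD10", "CD20", "IgM")
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
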