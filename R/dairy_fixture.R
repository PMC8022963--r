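# Dairy-cattle case study built programmatically: a herd of 184 animals in
# five age cohorts (calf, heifer, cow-L1..L3) receiving semen from a breeding
# company (250 bulls / 2,000 cows), five standardized index traits, 25
# breeding cycles (5 burn-in + 20 measured).
#
# The farm split 44/40/36/34/30 (sum 184) is this package's documented
# assumption, as are company-cow phenotyping at cow-L3 level and index-on-
# phenotype selection on the cow side. Bulls are selected top-25 (top-50 in
# Low_SelectionIntensity) by single-step GBLUP with only bulls genotyped and
# the two most recent company cow cohorts as training data.

DAIRY_SCENARIOS <- c("baseline", "pedigree_BVE", "ssBLUP_BVE",
                     "Low_SelectionIntensity", "Change_IndexWeights")

dairyTraits <- function(n_qtl, index_weights) {
  defs <- data.frame(
    id = c("RZM", "RZE", "RZR", "RZS", "RZKm"),
    mean = 100, gsd = 12,
    h2 = c(0.30, 0.25, 0.02, 0.15, 0.05),
    repeatability = c(0.50, 0.25, 0.06, 0.22, 0.09),
    n_qtl = as.integer(n_qtl), stringsAsFactors = FALSE)
  corr <- matrix(c(
     1.00, 0.00, -0.25, -0.05, -0.05,
     0.00, 1.00,  0.10,  0.20,  0.00,
    -0.25, 0.10,  1.00,  0.20,  0.25,
    -0.05, 0.20,  0.20,  1.00,  0.10,
    -0.05, 0.00,  0.25,  0.10,  1.00), 5, 5, byrow = TRUE)
  newTraitSet(defs, genetic_correlation = corr, residual_correlation = corr,
              indices = list(main = setNames(index_weights, defs$id)))
}

#' Build one scenario of the dairy-cattle case study
#'
#' Scenarios: `"baseline"` (farm selection on phenotype index),
#' `"pedigree_BVE"` (farm selection by pedigree BLUP), `"ssBLUP_BVE"`
#' (calves genotyped, farm selection by single-step GBLUP),
#' `"Low_SelectionIntensity"` (top-50 instead of top-25 sires) and
#' `"Change_IndexWeights"` (index weights 30/20/15/10/5 instead of
#' 45/15/10/7/3). All else is shared.
#'
#' @param name scenario name.
#' @param scale cohort scaling factor in (0, 1]; sizes and selection counts
#'   are multiplied and rounded half-up with a floor of one.
#' @param n_markers,n_qtl marker panel size and QTL per trait.
#' @param cycles number of breeding cycles (default 25 = 5 burn-in + 20).
#' @return a [BreedingProgram-class] (already scaled).
#' @export
dairyScenario <- function(name = "baseline", scale = 1, n_markers = 11600,
                          n_qtl = 1000, cycles = 25L) {
  name <- match.arg(name, DAIRY_SCENARIOS)
  if (!isProportion(scale) || scale == 0) stop("invalid scale")
  weights <- if (name == "Change_IndexWeights") {
    c(30, 20, 15, 10, 5)
  } else c(45, 15, 10, 7, 3)
  nTop <- if (name == "Low_SelectionIntensity") 50L else 25L
  farmCrit <- switch(name, pedigree_BVE = "pedigree_blup",
                     ssBLUP_BVE = "ssgblup", "phenotype")
  calfGeno <- if (name == "ssBLUP_BVE") 1 else 0

  cowL3Class <- list(RZM = 3, RZE = 1, RZR = 4, RZS = 3, RZKm = 3)
  nodes <- list(
    cohortNode("bullsC", 250, sex = "male", founder = TRUE,
               genotyped_share = 1, housing_class = "bull",
               subpopulation = "base"),
    cohortNode("cowsC", 2000, sex = "female", founder = TRUE,
               phenotyping_class = cowL3Class, housing_class = "cow",
               subpopulation = "base"),
    cohortNode("topBulls", nTop, sex = "male", housing_class = "sire"),
    cohortNode("calf", 44, sex = "female", founder = TRUE,
               genotyped_share = calfGeno, housing_class = "farm",
               subpopulation = "base"),
    cohortNode("heifer", 40, sex = "female", founder = TRUE,
               phenotyping_class = list(RZR = 1), housing_class = "farm",
               subpopulation = "base"),
    cohortNode("cowL1", 36, sex = "female", founder = TRUE,
               phenotyping_class = list(RZM = 1, RZE = 1, RZR = 1,
                                        RZS = 1, RZKm = 1),
               housing_class = "farm", subpopulation = "base"),
    cohortNode("cowL2", 34, sex = "female", founder = TRUE,
               phenotyping_class = list(RZM = 1, RZR = 1, RZS = 1, RZKm = 1),
               housing_class = "farm", subpopulation = "base"),
    cohortNode("cowL3", 30, sex = "female", founder = TRUE,
               phenotyping_class = list(RZM = 1, RZR = 1, RZS = 1, RZKm = 1),
               housing_class = "farm", subpopulation = "base"),
    cohortNode("damsPool", 140, sex = "female", housing_class = "farm"),
    cohortNode("calfPlus", 44, sex = "female", genotyped_share = calfGeno,
               housing_class = "farm")
  )

  farmSel <- function(from, to, n) {
    sel <- list(criterion = farmCrit, n_selected = n, index = "main")
    if (farmCrit != "phenotype") {
      sel$training <- c("heifer@0", "cowL1@0", "cowL2@0", "cowL3@0")
    }
    breedingEdge(from, to, "repeat", generation_time = 1,
                 repeat_count = cycles, link_action = "selection",
                 selection = sel)
  }
  edges <- list(
    breedingEdge("bullsC", "topBulls", "selection",
                 selection = list(criterion = "ssgblup", n_selected = nTop,
                                  index = "main",
                                  training = c("cowsC@0", "cowsC@-1"))),
    breedingEdge("heifer", "damsPool", "combine"),
    breedingEdge("cowL1", "damsPool", "combine"),
    breedingEdge("cowL2", "damsPool", "combine"),
    breedingEdge("cowL3", "damsPool", "combine"),
    breedingEdge("topBulls", "calfPlus", "reproduction",
                 reproduction = list(second_parent = "damsPool")),
    breedingEdge("topBulls", "bullsC", "repeat", generation_time = 1,
                 repeat_count = cycles, link_action = "reproduction",
                 reproduction = list(second_parent = "cowsC")),
    breedingEdge("topBulls", "cowsC", "repeat", generation_time = 1,
                 repeat_count = cycles, link_action = "reproduction",
                 reproduction = list(second_parent = "cowsC")),
    breedingEdge("calfPlus", "calf", "repeat", generation_time = 1,
                 repeat_count = cycles, link_action = "aging"),
    farmSel("calf", "heifer", 40),
    farmSel("heifer", "cowL1", 36),
    farmSel("cowL1", "cowL2", 34),
    farmSel("cowL2", "cowL3", 30)
  )

  program <- breedingProgram(
    nodes = nodes, edges = edges,
    traits = dairyTraits(n_qtl, weights),
    culling = list(list(housing_class = "farm", age = 6),
                   list(housing_class = "bull", age = 1),
                   list(housing_class = "sire", age = 2),
                   list(housing_class = "cow", age = 2)),
    subpopulations = list(list(label = "base",
                               freq_rule = list(type = "uniform",
                                                lo = 0.1, hi = 0.9))),
    economy = list(interest_rate = 0.05,
                   costs = list(genotyping = 50, phenotyping = 10,
                                housing = list(farm = 100, bull = 120, cow = 120,
                                               sire = 150),
                                fixed = 1000)),
    general = list(species = "cattle", scale = 1, litter_size = 1,
                   map = list(n_chromosomes = 29, total_length = 24,
                              n_markers = as.integer(n_markers))))
  applyScale(program, scale)
}

#' Run the dairy case study across scenarios and replicates
#'
#' Builds, expands and simulates each scenario `replicates` times with
#' deterministically derived seeds, standardizes trait trajectories of the
#' newly generated calves to 100 at the standardization cycle and summarizes
#' the final cycle in the layout of a scenario-comparison table (trait means
#' with standard errors in brackets, plus mean inbreeding).
#'
#' @param scenarios character vector of scenario names.
#' @param replicates replicates per scenario.
#' @param seed master seed; per-run seeds are derived from it.
#' @param scale,n_markers,n_qtl,cycles forwarded to [dairyScenario()].
#' @param standardize_at cycle whose calf mean is pinned to 100.
#' @param options extra [runProgram()] options.
#' @return list: `comparison` (trajectory data.frame, see
#'   [compareScenarios()]), `table` (final-cycle summary), `accuracy`
#'   (company-bull BVE accuracy per trait, averaged over post-burn-in cycles
#'   and replicates), `results` (per-scenario replicate lists).
#' @export
runStudy <- function(scenarios = DAIRY_SCENARIOS, replicates = 2L, seed = 1L,
                     scale = 0.5, n_markers = 5800, n_qtl = 500,
                     cycles = 25L, standardize_at = 5L, options = list()) {
  stopifnot(replicates >= 1L)
  seeds <- matrix(deriveSeeds(seed, length(scenarios) * replicates),
                  nrow = length(scenarios))
  results <- list()
  acc <- list()
  calfSeq <- sprintf("calfPlus_%d", seq_len(cycles))
  postBurn <- sprintf("bullsC_%d", seq(standardize_at + 1L, cycles))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    prog <- dairyScenario(sc, scale = scale, n_markers = n_markers,
                          n_qtl = n_qtl, cycles = cycles)
    ex <- resolveRepeats(prog)
    sch <- scheduleGeneration(ex)
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      reps[[r]] <- runProgram(ex, master_seed = seeds[si, r], schedule = sch,
                              options = options)
    }
    results[[sc]] <- reps
    accMat <- vapply(reps, function(res) {
      rowMeans(vapply(postBurn, function(cid) {
        a <- res@snapshots[[cid]]$accuracy
        if (is.null(a)) rep(NA_real_, 5L) else a
      }, numeric(5L)), na.rm = TRUE)
    }, numeric(5L))
    acc[[sc]] <- rowMeans(accMat, na.rm = TRUE)
  }
  comparison <- compareScenarios(results, calfSeq,
                                 standardize_at = standardize_at)
  tab <- studyTable(comparison, cycles)
  list(comparison = comparison, table = tab, accuracy = acc,
       results = results)
}

# Final-cycle summary in the comparison-table layout: standardized trait
# means (SE) plus inbreeding (SE) per scenario.
studyTable <- function(comparison, final_cycle) {
  last <- comparison[comparison$cycle == final_cycle, ]
  out <- list()
  for (sc in unique(last$scenario)) {
    row <- last[last$scenario == sc, ]
    out[[sc]] <- data.frame(scenario = sc, trait = row$trait,
                            mean = row$mean, se = row$se,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cycle rate of inbreeding from a comparison trajectory
#'
#' Slope of the mean inbreeding of new calves regressed on cycle index over
#' `from`..the last cycle.
#'
#' @param comparison output of [compareScenarios()] / `runStudy()$comparison`.
#' @param scenario scenario name.
#' @param from first cycle included (default 5, the standardization cycle).
#' @return slope in inbreeding units per cycle.
#' @export
inbreedingRate <- function(comparison, scenario, from = 5L) {
  d <- comparison[comparison$scenario == scenario &
                  comparison$trait == "inbreeding" &
                  comparison$cycle >= from, ]
  unname(coef(lm(mean ~ cycle, data = d))[2L])
}

#' Genetic progress of a trait between two cycles
#'
#' Difference of the (standardized) calf-cohort mean between `to` and `from`.
#'
#' @inheritParams inbreedingRate
#' @param trait trait id.
#' @param to,from cycle indices.
#' @return progress in (standardized) trait units.
#' @export
geneticProgress <- function(comparison, scenario, trait, from = 5L, to = NULL) {
  d <- comparison[comparison$scenario == scenario & comparison$trait == trait, ]
  if (is.null(to)) to <- max(d$cycle)
  d$mean[d$cycle == to] - d$mean[d$cycle == from]
}
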