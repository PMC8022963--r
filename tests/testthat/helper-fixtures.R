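# Shared builders for small in-code fixtures.

oneTrait <- function(h2 = 0.3, r = 0.5, gsd = 12, mean = 100, n_qtl = 50L) {
  newTraitSet(data.frame(id = "T1", mean = mean, gsd = gsd, h2 = h2,
                         repeatability = r, n_qtl = n_qtl))
}

twoTraits <- function(rho = 0, n_qtl = 50L) {
  newTraitSet(data.frame(id = c("T1", "T2"), mean = 100, gsd = 12,
                         h2 = c(0.3, 0.25), repeatability = c(0.5, 0.25),
                         n_qtl = n_qtl),
              genetic_correlation = matrix(c(1, rho, rho, 1), 2),
              residual_correlation = diag(2))
}

# The five dairy index traits of the German total-merit evaluation system
# with the parameter values used throughout the case study.
dairyTraitsForTest <- function(n_qtl = 500L) {
  defs <- data.frame(
    id = c("RZM", "RZE", "RZR", "RZS", "RZKm"),
    mean = 100, gsd = 12,
    h2 = c(0.30, 0.25, 0.02, 0.15, 0.05),
    repeatability = c(0.50, 0.25, 0.06, 0.22, 0.09),
    n_qtl = n_qtl)
  corr <- matrix(c(
     1.00, 0.00, -0.25, -0.05, -0.05,
     0.00, 1.00,  0.10,  0.20,  0.00,
    -0.25, 0.10,  1.00,  0.20,  0.25,
    -0.05, 0.20,  0.20,  1.00,  0.10,
    -0.05, 0.00,  0.25,  0.10,  1.00), 5, 5, byrow = TRUE)
  newTraitSet(defs, genetic_correlation = corr, residual_correlation = corr,
              indices = list(main = c(RZM = 45, RZE = 15, RZR = 10,
                                      RZS = 7, RZKm = 3)))
}

tinyMapSpec <- function(n_chromosomes = 2L, total_length = 2, n_markers = 100L) {
  list(n_chromosomes = n_chromosomes, total_length = total_length,
       n_markers = n_markers)
}

# Two founder cohorts feeding one offspring cohort.
matingProgram <- function(n_sires = 5L, n_dams = 10L, n_kids = 20L,
                          traits = oneTrait(), map = tinyMapSpec(),
                          kid_sex = "mixed") {
  breedingProgram(
    nodes = list(cohortNode("sires", n_sires, sex = "male", founder = TRUE),
                 cohortNode("dams", n_dams, sex = "female", founder = TRUE),
                 cohortNode("kids", n_kids, sex = kid_sex)),
    edges = list(breedingEdge("sires", "kids", "reproduction",
                              generation_time = 1,
                              reproduction = list(second_parent = "dams"))),
    traits = traits, general = list(map = map))
}

# A repeated random-mating population of constant size closed by one repeat
# edge: herd -> herd' each cycle, no selection.
driftProgram <- function(n = 25L, cycles = 8L, traits = oneTrait(),
                         map = tinyMapSpec(5L, 5, 500L)) {
  breedingProgram(
    nodes = list(cohortNode("herd", n, sex = "mixed", founder = TRUE)),
    edges = list(breedingEdge("herd", "herd", "repeat", generation_time = 1,
                              repeat_count = cycles,
                              link_action = "reproduction",
                              reproduction = list(second_parent = "herd"))),
    traits = traits,
    culling = list(list(age = 2)),
    general = list(map = map))
}

# Index selection on own phenotype, repeated over cycles.
selectionProgram <- function(n = 60L, n_sel_m = 5L, cycles = 5L,
                             traits = oneTrait(h2 = 0.5, r = 0.5),
                             map = tinyMapSpec(3L, 3, 300L)) {
  breedingProgram(
    nodes = list(cohortNode("herd", n, sex = "mixed", founder = TRUE,
                            phenotyping_class = list(T1 = 1)),
                 cohortNode("chosen", n_sel_m, sex = "mixed")),
    edges = list(
      breedingEdge("herd", "chosen", "selection",
                   selection = list(criterion = "phenotype",
                                    n_selected = n_sel_m)),
      breedingEdge("chosen", "herd", "repeat", generation_time = 1,
                   repeat_count = cycles, link_action = "reproduction",
                   reproduction = list(second_parent = "chosen"))),
    traits = traits,
    culling = list(list(age = 2)),
    general = list(map = map))
}

# Random but structurally valid program, for round-trip property tests.
randomProgram <- function(seed) {
  set.seed(seed)
  nf <- sample(1:3, 1)
  ng <- sample(1:3, 1)
  nodes <- list()
  for (i in seq_len(nf)) {
    nodes[[i]] <- cohortNode(paste0("F", i), sample(2:50, 1),
                             sex = sample(c("male", "female", "mixed"), 1),
                             founder = TRUE,
                             genotyped_share = round(runif(1), 3),
                             time_point = sample(0:2, 1))
  }
  edges <- list()
  traits <- data.frame(id = paste0("T", seq_len(sample(1:3, 1))))
  traits$mean <- round(runif(nrow(traits), 50, 150), 2)
  traits$gsd <- round(runif(nrow(traits), 1, 20), 2)
  traits$h2 <- round(runif(nrow(traits), 0.05, 0.9), 2)
  traits$repeatability <- pmin(1, traits$h2 + round(runif(nrow(traits), 0, 0.1), 2))
  traits$n_qtl <- sample(10:100, nrow(traits), replace = TRUE)
  for (g in seq_len(ng)) {
    src <- paste0(if (g == 1L) "F" else "G", sample(seq_len(if (g == 1L) nf else 1), 1))
    id <- paste0("G", g)
    act <- sample(c("aging", "selection", "reproduction"), 1)
    srcN <- nodes[[match(src, vapply(nodes, function(n) n$id, ""))]]$n_individuals
    nodes[[length(nodes) + 1L]] <- cohortNode(
      id, max(1L, srcN - 1L), sex = "mixed",
      phenotyping_class = setNames(list(sample(0:2, 1)), traits$id[1]))
    edges[[length(edges) + 1L]] <- switch(act,
      aging = breedingEdge(src, id, "aging", generation_time = runif(1, 0, 2)),
      selection = breedingEdge(src, id, "selection",
                               selection = list(criterion = "random",
                                                n_selected = max(1L, srcN - 1L))),
      reproduction = breedingEdge(src, id, "reproduction",
                                  generation_time = 1,
                                  reproduction = list(second_parent = src)))
  }
  breedingProgram(nodes, edges, newTraitSet(traits),
                  general = list(map = tinyMapSpec()))
}

# Minimal fake SimulationResult for evaluation-module tests that do not need
# a simulated population (e.g. confidence-band coverage on a known mean).
fakeResult <- function(cohort_means, traits = oneTrait(), n_per_cohort = 10L,
                       sd = 1, inb = 0) {
  prog <- breedingProgram(
    nodes = list(cohortNode("a", n_per_cohort, founder = TRUE)),
    edges = list(), traits = traits, general = list(map = tinyMapSpec()))
  ex <- new("ExpandedProgram", nodes = prog@nodes, edges = list(),
            provenance = data.frame(node = "a", origin = "a",
                                    repeat_index = 0L), program = prog)
  snaps <- list()
  for (ci in seq_along(cohort_means)) {
    df <- data.frame(id = seq_len(n_per_cohort), sex = 1L, sire = 0L,
                     dam = 0L, birth = 0, genotyped = FALSE, inb = inb)
    for (t in traits@traits$id) {
      df[[paste0("tv_", t)]] <- rnorm(n_per_cohort, cohort_means[ci], sd)
      df[[paste0("phen_", t)]] <- NA_real_
      df[[paste0("ebv_", t)]] <- NA_real_
    }
    snaps[[names(cohort_means)[ci]]] <- list(
      time = ci, individuals = df, meanInbreeding = inb,
      meanKinship = NA_real_, qtlFreq = NULL, accuracy = NULL)
  }
  new("SimulationResult", snapshots = snaps,
      schedule = data.frame(node = names(cohort_means),
                            time = seq_along(cohort_means)),
      ledger = data.frame(time = numeric(0), category = character(0),
                          amount = numeric(0)),
      masterSeed = 1L, map = createMap(1, 1, 2),
      effects = withr::with_preserve_seed(
        assignQtlEffects(traits, createMap(1, 1, max(traits@traits$n_qtl) + 1),
                         0.5)),
      expanded = ex, genotypes = list())
}
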