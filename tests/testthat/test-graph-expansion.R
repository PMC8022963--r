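# Chain of b nodes closed by one repeat edge of count r.
chainWithRepeat <- function(b, r, traits = oneTrait()) {
  nodes <- lapply(seq_len(b), function(i) {
    cohortNode(paste0("N", i), 4, founder = i == 1L)
  })
  edges <- list()
  if (b > 1L) {
    for (i in seq_len(b - 1L)) {
      edges[[i]] <- breedingEdge(paste0("N", i), paste0("N", i + 1L), "aging")
    }
  }
  edges[[length(edges) + 1L]] <- breedingEdge(paste0("N", b), "N1", "repeat",
                                              generation_time = 1,
                                              repeat_count = r)
  breedingProgram(nodes, edges, traits, general = list(map = tinyMapSpec()))
}

test_that("expansion of a repeat-free program is the identity", {
  prog <- matingProgram()
  ex <- resolveRepeats(prog)
  expect_equal(nodeIds(ex), nodeIds(prog))
  expect_equal(length(ex@edges), length(prog@edges))
  expect_equal(ex@provenance$repeat_index, rep(0L, 3L))
})

test_that("a 3-node cycle with repeat count 2 unrolls to the golden graph", {
  ex <- resolveRepeats(chainWithRepeat(3, 2))
  expect_setequal(nodeIds(ex),
                  c("N1_1", "N2_1", "N3_1", "N1_2", "N2_2", "N3_2"))
  acts <- vapply(ex@edges, function(e) e$action, "")
  expect_false(any(acts == "repeat"))
  # the repeat instantiates as an aging link from copy 1's origin to copy 2's
  # target; there is no link out of the final copy
  lab <- vapply(ex@edges, function(e) paste(e$from, e$to), "")
  expect_true("N3_1 N1_2" %in% lab)
  expect_false(any(grepl("^N3_2 ", lab)))
  # provenance maps every copy back to its original node
  expect_setequal(unique(ex@provenance$origin), c("N1", "N2", "N3"))
})

test_that("expanded body size follows the r*b count law", {
  for (r in c(1L, 2L, 5L)) {
    for (b in c(1L, 3L, 7L)) {
      ex <- resolveRepeats(chainWithRepeat(b, r), check = FALSE)
      expect_length(ex@nodes, r * b)
    }
  }
})

test_that("nested repeats resolve innermost-first", {
  tr <- oneTrait()
  prog <- breedingProgram(
    nodes = list(cohortNode("S", 4, founder = TRUE), cohortNode("A", 4),
                 cohortNode("B", 4), cohortNode("E", 4)),
    edges = list(breedingEdge("S", "A", "aging"),
                 breedingEdge("A", "B", "aging"),
                 breedingEdge("B", "E", "aging"),
                 breedingEdge("B", "A", "repeat", repeat_count = 3,
                              generation_time = 1),
                 breedingEdge("E", "S", "repeat", repeat_count = 2,
                              generation_time = 1)),
    traits = tr, general = list(map = tinyMapSpec()))
  ex <- resolveRepeats(prog, check = FALSE)
  # inner body {A,B} -> 6 copies, then the outer region {S, A_1..B_3, E} x 2
  expect_length(ex@nodes, 16L)
  acts <- vapply(ex@edges, function(e) e$action, "")
  expect_false(any(acts == "repeat"))
})

test_that("founders-only programs schedule at time 0 in id order", {
  tr <- oneTrait()
  prog <- breedingProgram(
    nodes = list(cohortNode("b", 3, founder = TRUE),
                 cohortNode("a", 3, founder = TRUE)),
    edges = list(), traits = tr, general = list(map = tinyMapSpec()))
  sch <- scheduleGeneration(resolveRepeats(prog, check = FALSE))
  expect_equal(sch$node, c("a", "b"))
  expect_equal(sch$time, c(0, 0))
})

test_that("generation times follow the longest path and training adds dependencies", {
  tr <- oneTrait()
  prog <- breedingProgram(
    nodes = list(cohortNode("A", 10, founder = TRUE,
                            phenotyping_class = list(T1 = 1)),
                 cohortNode("B", 10, phenotyping_class = list(T1 = 1)),
                 cohortNode("C", 5)),
    edges = list(breedingEdge("A", "B", "aging", generation_time = 1),
                 breedingEdge("A", "C", "selection", generation_time = 2,
                              selection = list(criterion = "pedigree_blup",
                                               n_selected = 5,
                                               training = "B"))),
    traits = tr, general = list(map = tinyMapSpec()))
  sch <- scheduleGeneration(resolveRepeats(prog))
  expect_equal(sch$node, c("A", "B", "C"))
  expect_equal(sch$time, c(0, 1, 2))
})

test_that("schedules are valid topological orders (independent oracle)", {
  # oracle: every dependency (edge, second parent, training ref) must point
  # backwards in the schedule, and times must equal the longest path
  checkTopo <- function(ex, sch) {
    posOf <- setNames(seq_len(nrow(sch)), sch$node)
    for (e in ex@edges) {
      expect_lt(posOf[[e$from]], posOf[[e$to]])
      if (!is.null(e$reproduction$second_parent)) {
        expect_lt(posOf[[e$reproduction$second_parent]], posOf[[e$to]])
      }
      for (tc in e$selection$training) expect_lt(posOf[[tc]], posOf[[e$to]])
    }
    # independent longest-path recomputation by relaxation to fixpoint
    t2 <- setNames(vapply(ex@nodes, function(n) n$time_point, 0), nodeIds(ex))
    repeat {
      changed <- FALSE
      for (e in ex@edges) {
        cand <- t2[[e$from]] + e$generation_time
        if (cand > t2[[e$to]] + 1e-12) { t2[[e$to]] <- cand; changed <- TRUE }
      }
      if (!changed) break
    }
    expect_equal(unname(t2[sch$node]), sch$time, tolerance = 1e-10)
  }
  for (b in c(2L, 4L)) {
    for (r in c(2L, 3L)) {
      ex <- resolveRepeats(chainWithRepeat(b, r), check = FALSE)
      checkTopo(ex, scheduleGeneration(ex))
    }
  }
  exD <- resolveRepeats(dairyScenario("baseline", scale = 0.1,
                                      n_markers = 290, n_qtl = 20,
                                      cycles = 2L))
  checkTopo(exD, scheduleGeneration(exD))
})

test_that("dairy expansion yields serial copies scheduled in cycle order", {
  cycles <- 4L
  prog <- dairyScenario("baseline", scale = 0.1, n_markers = 290,
                        n_qtl = 20, cycles = cycles)
  ex <- resolveRepeats(prog)
  expect_length(ex@nodes, 10L * cycles)
  sch <- scheduleGeneration(ex)
  posOf <- setNames(seq_len(nrow(sch)), sch$node)
  prov <- ex@provenance
  for (orig in unique(prov$origin)) {
    copies <- prov[prov$origin == orig, ]
    copies <- copies[order(copies$repeat_index), ]
    expect_true(all(diff(posOf[copies$node]) > 0),
                info = sprintf("copies of %s out of order", orig))
  }
})

test_that("mismatched repeat counts in one cycle region are rejected", {
  tr <- oneTrait()
  prog <- breedingProgram(
    nodes = list(cohortNode("A", 4, founder = TRUE), cohortNode("B", 4)),
    edges = list(breedingEdge("A", "B", "aging"),
                 breedingEdge("B", "A", "repeat", repeat_count = 2),
                 breedingEdge("B", "A", "repeat", repeat_count = 3)),
    traits = tr, general = list(map = tinyMapSpec()))
  expect_true("REPEAT_COUNT_MISMATCH" %in% validateProgram(prog)@errors$code)
  expect_error(resolveRepeats(prog), "validation|disagree")
})
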