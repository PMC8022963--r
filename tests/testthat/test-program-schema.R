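test_that("a minimal program parses to the expected structure", {
  prog <- matingProgram()
  json <- serializeProgram(prog)
  p2 <- parseProgram(json)
  expect_s4_class(p2, "BreedingProgram")
  expect_length(programNodes(p2), 3L)
  expect_length(programEdges(p2), 1L)
  expect_equal(nodeIds(p2), c("sires", "dams", "kids"))
  expect_equal(programEdges(p2)[[1L]]$action, "reproduction")
})

test_that("the dairy baseline serializes and re-parses with its index weights", {
  prog <- dairyScenario("baseline", scale = 0.5, n_markers = 580,
                        n_qtl = 50, cycles = 3L)
  p2 <- parseProgram(serializeProgram(prog))
  expect_true(programEquals(prog, p2))
  w <- traitSet(p2)@indices$main
  expect_equal(unname(w[c("RZM", "RZE", "RZR", "RZS", "RZKm")]),
               c(45, 15, 10, 7, 3))
  expect_equal(sum(w), 80)
  farm <- c("calf", "heifer", "cowL1", "cowL2", "cowL3")
  expect_true(all(farm %in% nodeIds(p2)))
  expect_equal(nrow(traitSet(p2)@traits), 5L)
})

test_that("parse/serialize round-trip is the identity on random programs", {
  for (seed in 1:20) {
    prog <- randomProgram(seed)
    json <- serializeProgram(prog)
    expect_true(programEquals(prog, parseProgram(json)),
                info = sprintf("seed %d", seed))
  }
})

test_that("serialization is canonical and drops empty optional blocks", {
  prog <- matingProgram()
  # build the structurally equal program with nodes defined in another order,
  # then reorder; serialization must be byte-identical
  progB <- breedingProgram(prog@nodes, prog@edges, prog@traits,
                           general = prog@general)
  expect_identical(serializeProgram(prog), serializeProgram(progB))
  expect_false(grepl("\"culling\"", serializeProgram(prog)))
  expect_false(grepl("\"economy\"", serializeProgram(prog)))
})

test_that("unknown keys warn and required fields are enforced", {
  base <- jsonlite::fromJSON(serializeProgram(matingProgram()),
                             simplifyVector = FALSE)
  withExtra <- base
  withExtra$vis_layout <- list(x = 1)
  withExtra$nodes[[1L]]$color <- "red"
  txt <- jsonlite::toJSON(withExtra, auto_unbox = TRUE)
  # one warning for the program-level key, one for the node-level key
  expect_warning(expect_warning(parseProgram(txt), "unknown key"),
                 "unknown key")

  noId <- base
  noId$nodes[[1L]]$id <- NULL
  expect_error(parseProgram(jsonlite::toJSON(noId, auto_unbox = TRUE)), "'id'")
  noN <- base
  noN$nodes[[2L]]$n_individuals <- NULL
  expect_error(parseProgram(jsonlite::toJSON(noN, auto_unbox = TRUE)),
               "'n_individuals'")
  expect_error(parseProgram("{not json"), "lexical|parse|invalid")
})

test_that("validation flags loops, dangling ends, oversized selections and founder inputs", {
  tr <- oneTrait()
  loop <- breedingProgram(
    nodes = list(cohortNode("A", 10, founder = TRUE), cohortNode("B", 10)),
    edges = list(breedingEdge("A", "B", "aging"),
                 breedingEdge("B", "A", "aging")),
    traits = tr)
  repLoop <- validateProgram(loop)
  expect_true("LOOP" %in% repLoop@errors$code)
  # founder A also gains an incoming non-repeat edge through the loop
  expect_true("FOUNDER_INCOMING" %in% repLoop@errors$code)

  oversel <- breedingProgram(
    nodes = list(cohortNode("A", 40, founder = TRUE), cohortNode("B", 50)),
    edges = list(breedingEdge("A", "B", "selection",
                              selection = list(criterion = "random",
                                               n_selected = 50))),
    traits = tr)
  expect_true("SELECTION_EXCEEDS_SOURCE" %in%
                validateProgram(oversel)@errors$code)

  dangling <- breedingProgram(
    nodes = list(cohortNode("A", 10, founder = TRUE)),
    edges = list(breedingEdge("A", "ghost", "aging")), traits = tr)
  expect_true("DANGLING" %in% validateProgram(dangling)@errors$code)

  badTrait <- breedingProgram(
    nodes = list(cohortNode("A", 10, founder = TRUE,
                            phenotyping_class = list(NOPE = 1))),
    edges = list(), traits = tr)
  expect_true("UNDEFINED_TRAIT" %in% validateProgram(badTrait)@errors$code)

  badIndex <- breedingProgram(
    nodes = list(cohortNode("A", 10, founder = TRUE)), edges = list(),
    traits = newTraitSet(tr@traits, indices = list(ix = c(NOPE = 1))))
  expect_true("UNDEFINED_TRAIT" %in% validateProgram(badIndex)@errors$code)
})

test_that("repeat edges whose cycle cannot close are rejected", {
  tr <- oneTrait()
  # A and B are disconnected, so B can never be reached from A
  broken <- breedingProgram(
    nodes = list(cohortNode("A", 10, founder = TRUE),
                 cohortNode("B", 10, founder = TRUE)),
    edges = list(breedingEdge("B", "A", "repeat", repeat_count = 3)),
    traits = tr)
  expect_true("REPEAT_UNREACHABLE" %in% validateProgram(broken)@errors$code)
})

test_that("validation is deterministic, side-effect-free, and clean programs expand", {
  prog <- dairyScenario("baseline", scale = 0.25, n_markers = 290,
                        n_qtl = 20, cycles = 2L)
  r1 <- validateProgram(prog)
  r2 <- validateProgram(prog)
  expect_identical(r1@errors, r2@errors)
  expect_identical(r1@warnings, r2@warnings)
  expect_true(isValid(r1))
  expect_equal(nrow(r1@warnings), 0L)
  # any program with empty errors can be expanded and scheduled
  for (seed in 1:8) {
    p <- randomProgram(seed)
    if (isValid(validateProgram(p))) {
      expect_no_error(scheduleGeneration(resolveRepeats(p, check = FALSE)))
    }
  }
})
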