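# One shared small run with everything retained, reused across blocks.
evalFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prog <- dairyScenario("baseline", scale = 0.1, n_markers = 290,
                            n_qtl = 20, cycles = 3L)
      cache <<- runProgram(resolveRepeats(prog), master_seed = 9,
                           options = list(retain_genotypes = TRUE))
    }
    cache
  }
})

test_that("observed phenotypes are record means, absent where unrecorded", {
  res <- evalFixture()
  calves <- observedPhenotypes(res, "calfPlus_1")
  expect_true(all(is.na(calves)))          # calves carry no records
  cows <- observedPhenotypes(res, "cowsC_1")
  expect_false(anyNA(cows))
  expect_error(observedPhenotypes(res, "nope"), "unknown cohort")
})

test_that("phenotypes equal true values when h2 = r = 1", {
  ts <- newTraitSet(data.frame(id = "T1", mean = 0, gsd = 1, h2 = 1,
                               repeatability = 1, n_qtl = 20L))
  prog <- breedingProgram(
    nodes = list(cohortNode("a", 10, founder = TRUE,
                            phenotyping_class = list(T1 = 1))),
    edges = list(), traits = ts, general = list(map = tinyMapSpec()))
  res <- runProgram(resolveRepeats(prog), master_seed = 10)
  expect_equal(observedPhenotypes(res, "a")[, 1], trueValues(res, "a")[, 1],
               tolerance = 1e-10)
})

test_that("true values match an independent recomputation from genotypes", {
  res <- evalFixture()
  g <- res@genotypes[["calfPlus_2"]]
  haps <- lapply(seq_along(g$ids), function(i) {
    list(h1 = g$A1[i, ], h2 = g$A2[i, ], o1 = g$O1[i, ], o2 = g$O2[i, ])
  })
  recomputed <- trueGenomicValues(haps, res@effects)
  stored <- trueValues(res, "calfPlus_2")
  expect_equal(unname(stored), unname(recomputed), tolerance = 1e-9)
  # founder cohorts start near the target mean of 100
  f <- trueValues(res, "cowsC_1")
  expect_lt(abs(mean(f[, "RZM"]) - 100), 3 * 12 / sqrt(nrow(f)))
})

test_that("accuracy is the EBV/true-value correlation with clear errors", {
  res <- evalFixture()
  # cycle-2 bulls are related to the phenotyped cows (cycle-1 founder bulls
  # are not, so their EBVs are uniformly zero)
  acc <- bveAccuracy(res, "bullsC_2", "RZM")
  expect_true(acc >= -1 && acc <= 1)
  expect_error(bveAccuracy(res, "calfPlus_1", "RZM"), "no EBVs")
  # degenerate checks on a synthetic result
  fake <- fakeResult(c(a = 100), n_per_cohort = 200L)
  sn <- fake@snapshots$a
  sn$individuals$ebv_T1 <- sn$individuals$tv_T1
  fake@snapshots$a <- sn
  expect_equal(bveAccuracy(fake, "a", "T1"), 1)
  set.seed(30)
  sn$individuals$ebv_T1 <- rnorm(200)
  fake@snapshots$a <- sn
  expect_lt(abs(bveAccuracy(fake, "a", "T1")), 2 / sqrt(200))
})

test_that("IBD kinship and inbreeding follow pedigree expectations", {
  res <- evalFixture()
  f <- kinshipInbreeding(res, "cowsC_1")
  expect_equal(f$mean_inbreeding, 0)
  expect_equal(unname(f$mean_kinship), 0, tolerance = 1e-12)

  # full sibs: kinship 0.25
  tr <- oneTrait(n_qtl = 20L)
  fs <- breedingProgram(
    nodes = list(cohortNode("s", 1, sex = "male", founder = TRUE),
                 cohortNode("d", 1, sex = "female", founder = TRUE),
                 cohortNode("kids", 12, sex = "mixed")),
    edges = list(breedingEdge("s", "kids", "reproduction", generation_time = 1,
                              reproduction = list(second_parent = "d"))),
    traits = tr, general = list(map = tinyMapSpec(20L, 20, 2000L)))
  resFS <- runProgram(resolveRepeats(fs), master_seed = 11,
                      options = list(kinship_sample = 12L,
                                     kinship_markers = 2000L))
  expect_lt(abs(kinshipInbreeding(resFS, "kids")$mean_kinship - 0.25), 0.03)

  # sire x daughter mating: offspring inbreeding 0.25
  sd_ <- breedingProgram(
    nodes = list(cohortNode("s", 1, sex = "male", founder = TRUE),
                 cohortNode("d", 1, sex = "female", founder = TRUE),
                 cohortNode("daughters", 8, sex = "female"),
                 cohortNode("inbred", 12, sex = "mixed")),
    edges = list(breedingEdge("s", "daughters", "reproduction",
                              generation_time = 1,
                              reproduction = list(second_parent = "d")),
                 breedingEdge("s", "inbred", "reproduction",
                              generation_time = 2,
                              reproduction = list(second_parent = "daughters"))),
    traits = tr, general = list(map = tinyMapSpec(20L, 20, 2000L)))
  resSD <- runProgram(resolveRepeats(sd_), master_seed = 12)
  expect_lt(abs(kinshipInbreeding(resSD, "inbred")$mean_inbreeding - 0.25),
            0.03)
})

test_that("QTL reports carry the largest effects and exact frequencies", {
  res <- evalFixture()
  rep_ <- qtlReport(res, "calfPlus_2", top_k = 5L)
  expect_equal(nrow(rep_), 25L)  # 5 traits x 5 QTL
  expect_true(all(rep_$frequency >= 0 & rep_$frequency <= 1))
  # frequencies match a brute-force genotype count
  g <- res@genotypes[["calfPlus_2"]]
  qi <- res@effects@markerIndex
  mk <- res@map@markers$id[qi]
  freq <- colMeans((g$A1[, qi, drop = FALSE] + g$A2[, qi, drop = FALSE]) / 2)
  expect_equal(rep_$frequency, freq[match(rep_$marker, mk)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # top_k are sorted by |effect| within trait
  one <- rep_[rep_$trait == "RZM", ]
  expect_true(all(diff(abs(one$effect)) <= 1e-12))
})

test_that("under selection, favourable top-QTL alleles gain frequency", {
  shifts <- c()
  for (repl in 1:10) {
    prog <- selectionProgram(n = 50L, n_sel_m = 6L, cycles = 4L,
                             traits = oneTrait(h2 = 0.8, r = 0.8, n_qtl = 30L))
    res <- runProgram(resolveRepeats(prog), master_seed = 400 + repl)
    eff <- res@effects@effects[, 1]
    top <- order(-abs(eff))[1:10]
    f1 <- res@snapshots[["herd_1"]]$qtlFreq[top]
    f4 <- res@snapshots[["herd_4"]]$qtlFreq[top]
    shifts <- c(shifts, mean(sign(eff[top]) * (f4 - f1)))
  }
  expect_gte(sum(shifts > 0), 8L)
  expect_gt(mean(shifts), 0)
})

test_that("scenario comparison standardizes to 100 and flags identity", {
  set.seed(31)
  mk <- function() fakeResult(c(c1 = 50, c2 = 50, c3 = 50), sd = 0.01)
  cmp <- compareScenarios(list(s1 = list(mk(), mk())), c("c1", "c2", "c3"),
                          standardize_at = 1L)
  tv <- cmp[cmp$trait == "T1", ]
  expect_equal(tv$mean, rep(100, 3), tolerance = 0.05)
  # two identical scenarios: overlapping bands, difference ~ 0
  r1 <- list(fakeResult(c(c1 = 10, c2 = 20), sd = 0.1),
             fakeResult(c(c1 = 10, c2 = 20), sd = 0.1))
  r2 <- list(fakeResult(c(c1 = 10, c2 = 20), sd = 0.1),
             fakeResult(c(c1 = 10, c2 = 20), sd = 0.1))
  cmp2 <- compareScenarios(list(a = r1, b = r2), c("c1", "c2"))
  wide <- cmp2[cmp2$trait == "T1" & cmp2$cycle == 2, ]
  expect_lt(abs(diff(wide$mean)), 1)
  expect_error(compareScenarios(list(a = r1), c("c1", "nope")),
               "not simulated")
})

test_that("standardization preserves the sign of scenario differences", {
  # scenarios with different gains; re-expressing trait units by any common
  # affine map a*x + b must not flip the post-standardization comparison
  set.seed(32)
  mkScen <- function(gain, a, b) {
    lapply(1:3, function(i) {
      fakeResult(c(c1 = a * 10 + b, c2 = a * (10 + gain) + b), sd = a * 0.5)
    })
  }
  base <- compareScenarios(list(hi = mkScen(25, 1, 0), lo = mkScen(18, 1, 0)),
                           c("c1", "c2"), standardize_at = 1L)
  resc <- compareScenarios(list(hi = mkScen(25, 7, -300),
                                lo = mkScen(18, 7, -300)),
                           c("c1", "c2"), standardize_at = 1L)
  pick <- function(cmp) {
    d <- cmp[cmp$trait == "T1" & cmp$cycle == 2, c("scenario", "mean")]
    d$mean[d$scenario == "hi"] - d$mean[d$scenario == "lo"]
  }
  expect_equal(sign(pick(base)), 1)
  expect_equal(sign(pick(resc)), 1)
})

test_that("95% confidence bands achieve nominal coverage on a null model", {
  set.seed(33)
  covered <- 0L
  for (run in 1:200) {
    reps <- lapply(1:8, function(i) fakeResult(c(c1 = 42), n_per_cohort = 5L,
                                               sd = 1))
    cmp <- compareScenarios(list(s = reps), "c1")
    row <- cmp[cmp$trait == "T1", ]
    covered <- covered + (row$lower <= 42 && 42 <= row$upper)
  }
  # binomial 99.9% envelope around 0.95 * 200
  expect_gt(covered, 200 * 0.95 - 3.3 * sqrt(200 * 0.95 * 0.05))
  expect_lte(covered, 200)
})

test_that("cost discounting follows the closed form", {
  led <- data.frame(time = c(0, 2, 5), category = "x",
                    amount = c(10, 100, 50))
  expect_equal(discountedCost(led, 0), 160)
  single <- data.frame(time = 2, category = "x", amount = 100)
  expect_equal(discountedCost(single, 0.05), 100 / 1.05^2, tolerance = 1e-10)
  expect_equal(discountedCost(single, 0.05), 90.70295, tolerance = 1e-5)
  # brute-force per-entry oracle
  i <- 0.07
  expect_equal(discountedCost(led, i),
               sum(vapply(seq_len(nrow(led)), function(k) {
                 led$amount[k] / (1 + i)^led$time[k]
               }, 1)))
  expect_equal(discountedCost(led, 0.07, horizon = 2),
               10 + 100 / 1.07^2)
  expect_error(discountedCost(led, -0.1), "interest")
})
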