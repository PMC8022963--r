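# A 5-animal pedigree: 2 unrelated founders, their two offspring, and one
# grand-offspring.
toyPed <- function() {
  data.frame(id = c("f1", "f2", "o1", "o2", "g1"),
             sire = c(NA, NA, "f1", "f1", "o1"),
             dam = c(NA, NA, "f2", "f2", "o2"), stringsAsFactors = FALSE)
}

test_that("the tabular A matrix matches hand-derived relationships", {
  A <- makeA(toyPed())
  expect_equal(unname(diag(A)), c(1, 1, 1, 1, 1.25))
  expect_equal(A["o1", "o2"], 0.5)    # full sibs
  expect_equal(A["f1", "o1"], 0.5)    # parent-offspring
  expect_equal(A["f1", "f2"], 0)
  expect_equal(A["g1", "o1"], 0.75)   # parent that is also an uncle via o2
})

test_that("the sparse A-inverse inverts A on non-inbred pedigrees", {
  ped <- toyPed()[1:4, ]  # non-inbred part
  A <- makeA(ped)
  Ainv <- as.matrix(makeAinv(ped))
  expect_equal(unname(A %*% Ainv[rownames(A), colnames(A)]), diag(4),
               tolerance = 1e-10)
})

test_that("single records with no relatives shrink by h2 towards the mean", {
  set.seed(20)
  n <- 10L
  ped <- data.frame(id = as.character(1:n), sire = NA, dam = NA)
  h2 <- 0.25
  y <- rnorm(n, 50, 4)
  rec <- data.frame(id = as.character(1:n), trait = "T1", n = 1, y = y)
  tr <- data.frame(id = "T1", h2 = h2, repeatability = h2, gsd = sqrt(h2) * 4)
  ebv <- estimateBreedingValues(ped, rec, tr, method = "pedigree_blup")
  # for unrelated single-record animals the MME reduce to EBV = h2 (y - mu)
  mu <- mean(y)  # GLS mean with equal weights
  expect_equal(unname(ebv[, 1]), h2 * (y - mu), tolerance = 1e-8)
})

test_that("pedigree BLUP equals a generalized-least-squares oracle", {
  ped <- toyPed()
  h2 <- 0.25
  gsd <- 2
  sigmaP2 <- gsd^2 / h2
  set.seed(21)
  y <- rnorm(5, 10, sqrt(sigmaP2))
  nrec <- c(1, 2, 1, 3, 1)
  rec <- data.frame(id = ped$id, trait = "T1", n = nrec, y = y)
  tr <- data.frame(id = "T1", h2 = h2, repeatability = h2, gsd = gsd)
  ebv <- estimateBreedingValues(ped, rec, tr, method = "pedigree_blup")

  # oracle: u-hat = sigmaA2 A Z' V^-1 (y - X mu-hat) from the explicit
  # variance matrix; inbreeding-aware A from the tabular method
  A <- makeA(ped)
  sigmaA2 <- gsd^2
  R <- diag(((1 - h2) / nrec) * sigmaP2)
  V <- A * sigmaA2 + R
  X <- matrix(1, 5, 1)
  Vi <- solve(V)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  uhat <- sigmaA2 * A %*% Vi %*% (y - as.numeric(mu))
  expect_lt(max(abs(ebv[ped$id, 1] - uhat[, 1])), 1e-8)
})

test_that("single-step collapses to pure GBLUP when everyone is genotyped", {
  set.seed(22)
  mp <- createMap(2, 2, 200)
  founders <- drawFounders(mp, 30L, list(frequencies = 0.5), rng_seed = 23)
  dos <- do.call(rbind, lapply(founders, function(h) h$h1 + h$h2))
  rownames(dos) <- as.character(1:30)
  ped <- data.frame(id = as.character(1:30), sire = NA, dam = NA)
  h2 <- 0.4
  y <- rnorm(30, 0, 1)
  rec <- data.frame(id = ped$id, trait = "T1", n = 1, y = y)
  tr <- data.frame(id = "T1", h2 = h2, repeatability = h2, gsd = sqrt(h2))
  # fixed frequencies: with observed frequencies the centring makes G
  # exactly singular, which only the blending could absorb
  ebvSS <- estimateBreedingValues(ped, rec, tr, method = "ssgblup",
                                  genotypes = dos, blend_w = 0,
                                  g_freqs = rep(0.5, ncol(dos)))

  # oracle: dense GBLUP MME with the same G (A never enters)
  G <- makeG(dos, freqs = rep(0.5, ncol(dos)))
  sigmaA2 <- h2
  sigmaE2 <- (1 - h2)
  Ginv <- solve(G + diag(1e-12, 30))
  lhs <- rbind(cbind(30 / sigmaE2, t(rep(1, 30)) / sigmaE2),
               cbind(rep(1, 30) / sigmaE2,
                     diag(30) / sigmaE2 + Ginv / sigmaA2))
  rhs <- c(sum(y) / sigmaE2, y / sigmaE2)
  sol <- solve(lhs, rhs)
  expect_lt(max(abs(ebvSS[, 1] - sol[-1])), 1e-6)
})

test_that("G (VanRaden 1) centres and scales by allele frequencies", {
  dos <- rbind(a = c(0, 1, 2, 1), b = c(2, 1, 0, 1))
  p <- colMeans(dos) / 2
  G <- makeG(dos)
  Z <- sweep(dos, 2, 2 * p)
  expect_equal(G, Z %*% t(Z) / (2 * sum(p * (1 - p))))
  expect_error(makeG(rbind(c(0, 0), c(0, 0))), "monomorphic")
})

test_that("phenotype-mean EBVs are own record means with NA for unrecorded", {
  ped <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  rec <- data.frame(id = "a", trait = "T1", n = 2, y = 7)
  tr <- data.frame(id = "T1", h2 = 0.3, repeatability = 0.3, gsd = 1)
  ebv <- estimateBreedingValues(ped, rec, tr, method = "phenotype_mean")
  expect_equal(ebv["a", 1], 7)
  expect_true(is.na(ebv["b", 1]))
})

test_that("missing training records raise a BVE error", {
  ped <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  rec <- data.frame(id = character(), trait = character(), n = numeric(),
                    y = numeric())
  tr <- data.frame(id = "T1", h2 = 0.3, repeatability = 0.3, gsd = 1)
  expect_error(estimateBreedingValues(ped, rec, tr, method = "pedigree_blup"),
               "BVE error")
})

test_that("pedigree A equals twice the empirical IBD kinship on toy crosses", {
  mp <- createMap(20, 20, 2000)
  set.seed(24)
  sires <- drawFounders(mp, 2L, list(frequencies = 0.5), rng_seed = 25)
  dams <- drawFounders(mp, 4L, list(frequencies = 0.5), rng_seed = 26,
                       origin_start = 5L)
  off <- generateOffspring(sires, dams, 12L, mp)
  ped <- data.frame(
    id = c(paste0("s", 1:2), paste0("d", 1:4), paste0("o", 1:12)),
    sire = c(rep(NA, 6), paste0("s", off$sire)),
    dam = c(rep(NA, 6), paste0("d", off$dam)))
  A <- makeA(ped)
  ibdKin <- function(a, b) {
    (mean(a$o1 == b$o1) + mean(a$o1 == b$o2) +
     mean(a$o2 == b$o1) + mean(a$o2 == b$o2)) / 4
  }
  err <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    err <- c(err, abs(A[paste0("o", i), paste0("o", j)] / 2 -
                        ibdKin(off$haplotypes[[i]], off$haplotypes[[j]])))
  }
  expect_lt(max(err), 0.05)
  expect_lt(mean(err), 0.03)
})

test_that("progeny-tested EBV accuracy rises with training-set size", {
  mp <- createMap(5, 5, 500)
  ts <- oneTrait(h2 = 0.3, r = 0.3, n_qtl = 200L)
  wins <- 0L
  for (repl in 1:10) {
    eff <- assignQtlEffects(ts, mp, 0.5, rng_seed = 30 + repl)
    set.seed(60 + repl)
    nS <- 12L
    sires <- drawFounders(mp, nS, list(frequencies = 0.5), rng_seed = 90 + repl)
    sTv <- trueGenomicValues(sires, eff)[, 1]
    accAt <- function(progPerSire) {
      dams <- drawFounders(mp, progPerSire, list(frequencies = 0.5),
                           rng_seed = 500 + repl * progPerSire)
      recs <- list(); peds <- list()
      for (s in seq_len(nS)) {
        off <- generateOffspring(sires[s], dams, progPerSire, mp, effects = eff)
        ph <- phenotypeCohort(
          matrix(off$true_values[, 1], ncol = 1, dimnames = list(NULL, "T1")),
          ts, c(T1 = 1))
        oid <- sprintf("s%d_o%d", s, seq_len(progPerSire))
        peds[[s]] <- data.frame(id = oid, sire = sprintf("s%d", s), dam = NA)
        recs[[s]] <- data.frame(id = oid, trait = "T1", n = 1,
                                y = ph$records$T1[, 1])
      }
      ped <- rbind(data.frame(id = sprintf("s%d", 1:nS), sire = NA, dam = NA),
                   do.call(rbind, peds))
      ebv <- estimateBreedingValues(ped, do.call(rbind, recs), ts,
                                    method = "pedigree_blup")
      cor(ebv[sprintf("s%d", 1:nS), 1], sTv)
    }
    a <- vapply(c(3L, 12L, 45L), accAt, 1)
    wins <- wins + (a[3] > a[1])
  }
  expect_gte(wins, 8L)
})
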