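# Stochastic engine primitives: meiosis, offspring generation, phenotype
# records and age-based culling.
#
# Recombination follows a Haldane model: per chromosome the crossover count is
# Poisson with mean equal to the chromosome length in Morgan, breakpoints are
# uniform and there is no interference. Gametes copy alleles AND founder-origin
# labels segment-wise, so identity by descent can be read off the labels later.

# Batch meiosis: one gamete per row of the parental haplotype matrices.
# A1/A2 alleles, O1/O2 origin labels (n x markers). Returns H (alleles) and
# O (origins).
batchMeiosis <- function(A1, A2, O1, O2, map) {
  n <- nrow(A1)
  M <- ncol(A1)
  H <- matrix(0L, n, M)
  Og <- matrix(0L, n, M)
  ci <- chromIndex(map)
  for (c in seq_along(ci)) {
    mi <- ci[[c]]
    pos <- map@markers$pos[mi]
    L <- map@chromosomes$length[c]
    phase <- matrix(sample(0:1, n, replace = TRUE), n, length(mi))
    k <- rpois(n, L)
    tot <- sum(k)
    if (tot) {
      gi <- rep(seq_len(n), k)
      bp <- runif(tot, 0, L)
      for (j in seq_len(tot)) {
        sel <- pos >= bp[j]
        if (any(sel)) phase[gi[j], sel] <- phase[gi[j], sel] + 1L
      }
    }
    use2 <- phase %% 2L == 1L
    hc <- A1[, mi, drop = FALSE]
    oc <- O1[, mi, drop = FALSE]
    if (any(use2)) {
      a2 <- A2[, mi, drop = FALSE]
      o2 <- O2[, mi, drop = FALSE]
      hc[use2] <- a2[use2]
      oc[use2] <- o2[use2]
    }
    H[, mi] <- hc
    Og[, mi] <- oc
  }
  list(H = H, O = Og)
}

#' Simulate one meiosis
#'
#' Crossover counts are Poisson(length in Morgan) per chromosome with uniform
#' breakpoints and no interference (Haldane); the start phase is random. The
#' gamete copies alleles and founder-origin labels segment-wise.
#'
#' @param parent haplotype pair `list(h1, h2, o1, o2)` (see [drawFounders()]).
#' @param map a [GeneticMap-class].
#' @return list with `h` (gamete alleles) and `o` (origin labels).
#' @export
meiosis <- function(parent, map) {
  g <- batchMeiosis(matrix(parent$h1, 1), matrix(parent$h2, 1),
                    matrix(parent$o1, 1), matrix(parent$o2, 1), map)
  list(h = as.integer(g$H[1, ]), o = as.integer(g$O[1, ]))
}

# Draw dams in random order without replacement until exhausted, then with
# replacement; litters of `litter` consecutive offspring share a dam.
drawDams <- function(dams, n, litter = 1L) {
  needed <- ceiling(n / litter)
  perm <- resample(dams)
  sel <- if (needed <= length(perm)) {
    perm[seq_len(needed)]
  } else {
    c(perm, resample(dams, needed - length(perm), replace = TRUE))
  }
  rep(sel, each = litter)[seq_len(n)]
}

#' Generate offspring from two parent sets
#'
#' Each offspring receives one gamete per parent via [meiosis()]. Dams are
#' drawn in random order without replacement until exhausted, then with
#' replacement; sires are drawn uniformly with replacement (semen is treated
#' as unlimited). Sex is fixed by `sex` or Bernoulli(0.5) for `"mixed"`.
#'
#' @param sires,dams lists of haplotype pairs.
#' @param n number of offspring.
#' @param map a [GeneticMap-class].
#' @param effects optional [QTLEffects-class]; adds true genomic values.
#' @param sex `"male"`, `"female"` or `"mixed"`.
#' @param litter_size offspring per selected dam before moving on.
#' @return list: `haplotypes` (offspring pairs), `sire`, `dam` (parent
#'   indices), `sex` (1 male / 2 female), `true_values` (or NULL).
#' @export
generateOffspring <- function(sires, dams, n, map, effects = NULL,
                              sex = "mixed", litter_size = 1L) {
  if (!length(sires) || !length(dams)) {
    stop("reproduction error: empty parent set")
  }
  si <- resample(seq_along(sires), n, replace = TRUE)
  di <- drawDams(seq_along(dams), n, litter_size)
  sA1 <- do.call(rbind, lapply(sires[si], `[[`, "h1"))
  sA2 <- do.call(rbind, lapply(sires[si], `[[`, "h2"))
  sO1 <- do.call(rbind, lapply(sires[si], `[[`, "o1"))
  sO2 <- do.call(rbind, lapply(sires[si], `[[`, "o2"))
  dA1 <- do.call(rbind, lapply(dams[di], `[[`, "h1"))
  dA2 <- do.call(rbind, lapply(dams[di], `[[`, "h2"))
  dO1 <- do.call(rbind, lapply(dams[di], `[[`, "o1"))
  dO2 <- do.call(rbind, lapply(dams[di], `[[`, "o2"))
  pat <- batchMeiosis(sA1, sA2, sO1, sO2, map)
  mat <- batchMeiosis(dA1, dA2, dO1, dO2, map)
  sx <- switch(sex, male = rep(1L, n), female = rep(2L, n),
               mixed = 1L + rbinom(n, 1L, 0.5))
  haps <- lapply(seq_len(n), function(i) {
    list(h1 = pat$H[i, ], h2 = mat$H[i, ], o1 = pat$O[i, ], o2 = mat$O[i, ])
  })
  tv <- if (!is.null(effects)) {
    qi <- effects@markerIndex
    valuesFromDosage(pat$H[, qi, drop = FALSE] + mat$H[, qi, drop = FALSE],
                     effects)
  }
  list(haplotypes = haps, sire = si, dam = di, sex = sx, true_values = tv)
}

# Correlated normal draws: n x length(sub) matrix with correlation R[sub,sub]
# and per-trait standard deviations sds (aligned with sub).
correlatedNormal <- function(n, R, sub, sds) {
  k <- length(sub)
  z <- matrix(rnorm(n * k), n, k)
  if (k > 1L) {
    Rs <- R[sub, sub]
    ch <- tryCatch(chol(Rs), error = function(e) chol(Rs + diag(1e-8, k)))
    z <- z %*% ch
  }
  sweep(z, 2, sds, "*")
}

#' Simulate phenotype records for a cohort
#'
#' Each record is the true genomic value plus a permanent-environment
#' deviation (drawn once per individual, variance (r - h2) * sigmaP2) and a
#' transient residual (variance (1 - r) * sigmaP2); both follow the residual
#' correlation across the traits recorded together. The selection-usable
#' phenotype is the mean of the accumulated records.
#'
#' @param true_values matrix (individuals x traits, trait-named columns).
#' @param trait_set a [TraitSet-class].
#' @param counts named vector: number of new records per trait.
#' @param pe optional pre-drawn permanent-environment matrix (same shape as
#'   `true_values`); drawn fresh when NULL.
#' @return list: `records` (per trait a matrix individuals x count),
#'   `means` (record means per trait), `pe`.
#' @export
phenotypeCohort <- function(true_values, trait_set, counts, pe = NULL) {
  tr <- trait_set@traits
  unknown <- setdiff(names(counts), tr$id)
  if (length(unknown)) {
    stop(sprintf("unknown trait(s) in phenotyping class: %s",
                 paste(unknown, collapse = ", ")))
  }
  n <- nrow(true_values)
  k <- nrow(tr)
  sigmaP2 <- tr$gsd^2 / tr$h2
  if (is.null(pe)) {
    peSd <- sqrt(pmax(tr$repeatability - tr$h2, 0) * sigmaP2)
    pe <- correlatedNormal(n, trait_set@residualCorrelation, seq_len(k), peSd)
    colnames(pe) <- tr$id
  }
  resSd <- sqrt((1 - tr$repeatability) * sigmaP2)
  cnt <- setNames(rep(0L, k), tr$id)
  cnt[names(counts)] <- unlist(counts)
  records <- setNames(lapply(tr$id, function(t) {
    matrix(NA_real_, n, cnt[[t]])
  }), tr$id)
  maxc <- max(cnt, 0L)
  for (round_ in seq_len(maxc)) {
    sub <- which(cnt >= round_)
    eps <- correlatedNormal(n, trait_set@residualCorrelation, sub, resSd[sub])
    for (j in seq_along(sub)) {
      t <- tr$id[sub[j]]
      records[[t]][, round_] <- true_values[, t] + pe[, t] + eps[, j]
    }
  }
  means <- vapply(tr$id, function(t) {
    if (cnt[[t]] > 0L) rowMeans(records[[t]]) else rep(NA_real_, n)
  }, numeric(n))
  if (n == 1L) means <- matrix(means, 1, dimnames = list(NULL, tr$id))
  list(records = records, means = means, pe = pe)
}

#' Apply culling rules to individuals
#'
#' Individuals whose age (current time minus birth) reaches a rule's
#' threshold for their housing class are marked dead; rules with a survival
#' probability additionally kill each individual independently. Dead
#' individuals are never selected or mated but remain available to pedigree
#' and breeding-value estimation.
#'
#' @param individuals data.frame with columns `birth`, `housing_class`,
#'   `alive`.
#' @param rules list of `list(housing_class =, age =, survival =)`; a NULL
#'   `housing_class` matches every class, `survival` (per period) is applied
#'   once per call.
#' @param time current program time.
#' @return updated logical `alive` vector.
#' @export
applyCulling <- function(individuals, rules, time) {
  alive <- individuals$alive
  for (rule in rules) {
    sel <- alive
    if (!is.null(rule$housing_class)) {
      sel <- sel & individuals$housing_class == rule$housing_class
    }
    if (!is.null(rule$age)) {
      kill <- sel & (time - individuals$birth >= rule$age)
      alive[kill] <- FALSE
    }
    if (!is.null(rule$survival)) {
      cand <- which(sel & alive)
      if (length(cand)) {
        dead <- cand[runif(length(cand)) >= rule$survival]
        alive[dead] <- FALSE
      }
    }
  }
  alive
}

#' Select the top individuals by score
#'
#' Ranks by score, descending, taking the top `n_selected`; ties are broken
#' by id (ascending) for reproducibility.
#'
#' @param scores numeric vector named by individual id.
#' @param n_selected number to keep.
#' @return the selected ids, in rank order.
#' @export
selectIndividuals <- function(scores, n_selected) {
  if (n_selected > length(scores)) {
    stop(sprintf("selection error: %d requested from %d candidates",
                 n_selected, length(scores)))
  }
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(n_selected)]
}
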