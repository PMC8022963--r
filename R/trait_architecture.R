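# Correlated multi-trait QTL architectures and selection indices.
#
# All traits share one QTL position set (pleiotropy), with per-QTL effect
# vectors drawn from a zero-mean multivariate normal whose correlation is the
# requested genetic correlation matrix. Effects are rescaled per trait and an
# intercept added so that, under the founder allele frequencies, the expected
# founder genetic mean and variance hit the targets: for independent loci,
# var(g) = sum over QTL of 2 p (1 - p) a^2 and E(g) = intercept + sum 2 p a.

#' Sample QTL positions and additive effects for a trait set
#'
#' @param trait_set a [TraitSet-class].
#' @param map a [GeneticMap-class].
#' @param founder_frequencies per-marker allele frequencies of the founder
#'   population (length = number of markers), used for scaling.
#' @param rng_seed integer seed.
#' @return a [QTLEffects-class].
#' @export
assignQtlEffects <- function(trait_set, map, founder_frequencies,
                             rng_seed = 1L) {
  tr <- trait_set@traits
  m <- nMarkers(map)
  if (length(founder_frequencies) == 1L) {
    founder_frequencies <- rep(founder_frequencies, m)
  }
  stopifnot(length(founder_frequencies) == m)
  if (any(tr$n_qtl > m)) stop("n_qtl exceeds the number of markers")
  Rg <- trait_set@geneticCorrelation
  ev <- eigen(Rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("architecture error: genetic correlation matrix is not positive semi-definite")
  }
  set.seed(as.integer(rng_seed))
  nq <- max(tr$n_qtl)
  idx <- sort(sample.int(m, nq))
  k <- nrow(tr)
  raw <- MASS::mvrnorm(nq, mu = rep(0, k),
                       Sigma = Rg + diag(1e-10, k))
  raw <- matrix(raw, nrow = nq, ncol = k)
  # traits with fewer QTL use the first n_qtl sampled positions
  for (t in seq_len(k)) if (tr$n_qtl[t] < nq) raw[seq(tr$n_qtl[t] + 1L, nq), t] <- 0
  p <- founder_frequencies[idx]
  w <- 2 * p * (1 - p)
  intercepts <- numeric(k)
  for (t in seq_len(k)) {
    v <- sum(w * raw[, t]^2)
    if (v <= 0) stop("degenerate architecture: zero expected genetic variance")
    raw[, t] <- raw[, t] * tr$gsd[t] / sqrt(v)
    intercepts[t] <- tr$mean[t] - sum(2 * p * raw[, t])
  }
  colnames(raw) <- tr$id
  new("QTLEffects", markerIndex = as.integer(idx), effects = raw,
      intercepts = setNames(intercepts, tr$id), traitIds = tr$id)
}

# Dosage matrix (individuals x QTL) -> true genomic values (individuals x traits).
valuesFromDosage <- function(dos, effects) {
  v <- dos %*% effects@effects
  sweep(v, 2, effects@intercepts, "+")
}

#' True genomic values of individuals
#'
#' Purely additive: value = intercept + sum over QTL of effect times allele
#' dosage (0, 1 or 2).
#'
#' @param haplotypes list of haplotype pairs as returned by [drawFounders()].
#' @param effects a [QTLEffects-class] defined on the same map.
#' @return matrix (individuals x traits) of genomic values.
#' @export
trueGenomicValues <- function(haplotypes, effects) {
  qi <- effects@markerIndex
  nm <- length(haplotypes[[1]]$h1)
  if (max(qi) > nm) stop("map mismatch: QTL index beyond the haplotype length")
  dos <- do.call(rbind, lapply(haplotypes, function(h) h$h1[qi] + h$h2[qi]))
  valuesFromDosage(dos, effects)
}

#' Selection-index value: weighted sum of trait values
#'
#' @param trait_values named numeric vector, or a matrix with trait columns.
#' @param index named numeric weight vector.
#' @param missing_zero if `TRUE`, traits without an available value contribute
#'   zero (the convention for phenotype-based indices where records accrue
#'   with age); if `FALSE`, a missing value for a nonzero weight is an error.
#' @return scalar, or one value per matrix row.
#' @export
indexValue <- function(trait_values, index, missing_zero = FALSE) {
  wnames <- names(index)
  if (is.matrix(trait_values) || is.data.frame(trait_values)) {
    tv <- as.matrix(trait_values)
    out <- numeric(nrow(tv))
    for (tn in wnames) {
      if (index[[tn]] == 0) next
      if (!tn %in% colnames(tv)) {
        if (missing_zero) next
        stop(sprintf("index error: no value for trait '%s'", tn))
      }
      col <- unname(tv[, tn])
      if (missing_zero) col[is.na(col)] <- 0
      if (any(is.na(col))) {
        stop(sprintf("index error: missing value for trait '%s'", tn))
      }
      out <- out + index[[tn]] * col
    }
    return(out)
  }
  out <- 0
  for (tn in wnames) {
    if (index[[tn]] == 0) next
    v <- if (tn %in% names(trait_values)) trait_values[[tn]] else NULL
    if (is.null(v) || is.na(v)) {
      if (missing_zero) next
      stop(sprintf("index error: no value for trait '%s'", tn))
    }
    out <- out + index[[tn]] * v
  }
  out
}
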