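# Breeding-value estimation: phenotype means, pedigree BLUP and single-step
# GBLUP on the animal model.
#
# Repeated records are collapsed to individual means y_i with effective
# residual variance ((1 - r)/n_i + (r - h2)) * sigmaP2, where r is the
# repeatability: the transient part averages out over n_i records while the
# permanent-environment part does not. Variance components are the true
# simulation parameters (no REML), isolating selection-design effects from
# estimation noise. Mixed-model equations are solved sparse; the pedigree
# relationship inverse uses Henderson's rules (no inbreeding adjustment in
# the solver; the exact tabular A is available for cross-checks).

#' Pedigree relationship matrix (tabular method)
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (NA = unknown);
#'   reordered internally so parents precede offspring.
#' @return dense numeric relationship matrix with `id` dimnames.
#' @export
makeA <- function(ped) {
  ped <- orderPedigree(ped)
  n <- nrow(ped)
  id <- as.character(ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rowv <- numeric(i - 1L)
      if (!is.na(s)) rowv <- rowv + 0.5 * A[s, j]
      if (!is.na(d)) rowv <- rowv + 0.5 * A[d, j]
      A[i, j] <- rowv
      A[j, i] <- rowv
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the pedigree relationship matrix (Henderson's rules)
#'
#' Ignores inbreeding in the Mendelian-sampling variances (exact for
#' non-inbred pedigrees, the standard approximation in large evaluations).
#'
#' @inheritParams makeA
#' @return sparse symmetric matrix with `id` dimnames.
#' @export
makeAinv <- function(ped) {
  ped <- orderPedigree(ped)
  n <- nrow(ped)
  id <- as.character(ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(a, b, v) {
    k <<- k + 1L
    ii[k] <<- a; jj[k] <<- b; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    nk <- sum(!is.na(c(s, d)))
    alpha <- switch(nk + 1L, 1, 4 / 3, 2)
    add(i, i, alpha)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -alpha / 2); add(p, i, -alpha / 2)
        for (q in c(s, d)) if (!is.na(q)) add(p, q, alpha / 4)
      }
    }
  }
  Matrix::sparseMatrix(i = ii[seq_len(k)], j = jj[seq_len(k)],
                       x = xx[seq_len(k)], dims = c(n, n),
                       dimnames = list(id, id))
}

# Submatrix A[g, g] via sparse Cholesky solves with A-inverse (avoids
# forming the full tabular A).
makeA22 <- function(Ainv, gidx) {
  n <- nrow(Ainv)
  E <- Matrix::sparseMatrix(i = gidx, j = seq_along(gidx), x = 1,
                            dims = c(n, length(gidx)))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ainv), LDL = FALSE)
  X <- Matrix::solve(ch, E, system = "A")
  out <- as.matrix(X[gidx, , drop = FALSE])
  dimnames(out) <- list(rownames(Ainv)[gidx], rownames(Ainv)[gidx])
  (out + t(out)) / 2
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 sum p (1 - p)) with Z the allele-dosage matrix centred at
#' twice the observed allele frequencies of the genotyped set (or supplied
#' frequencies).
#'
#' @param dosage matrix (individuals x markers) of allele dosages 0/1/2 with
#'   individual ids as rownames.
#' @param freqs optional per-marker allele frequencies; default observed.
#' @return dense relationship matrix.
#' @export
makeG <- function(dosage, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(dosage) / 2
  Z <- sweep(dosage, 2, 2 * freqs)
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all markers monomorphic; G is undefined")
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(dosage), rownames(dosage))
  G
}

# Reorder a pedigree so that parents precede offspring.
orderPedigree <- function(ped) {
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[!ped$sire %in% ped$id] <- NA
  ped$dam[!ped$dam %in% ped$id] <- NA
  placed <- character(0)
  rest <- ped
  while (nrow(rest)) {
    ok <- (is.na(rest$sire) | rest$sire %in% placed) &
      (is.na(rest$dam) | rest$dam %in% placed)
    if (!any(ok)) stop("pedigree contains a cycle")
    placed <- c(placed, rest$id[ok])
    rest <- rest[!ok, , drop = FALSE]
  }
  ped[match(placed, ped$id), , drop = FALSE]
}

# Build the single-step H-inverse: A-inverse plus the genomic correction on
# the genotyped block, with G blended towards A22 for invertibility. With
# observed allele frequencies G is exactly singular (column centring puts the
# ones vector in its null space), which the blending absorbs; fixed `g_freqs`
# avoid it altogether.
makeHinv <- function(Ainv, genotypes, blend_w = 0.05, g_freqs = NULL) {
  gid <- rownames(genotypes)
  gidx <- match(gid, rownames(Ainv))
  if (anyNA(gidx)) stop("genotyped individuals missing from the pedigree")
  G <- makeG(genotypes, freqs = g_freqs)
  A22 <- makeA22(Ainv, gidx)
  Gb <- (1 - blend_w) * G + blend_w * A22
  Ginv <- tryCatch(solve(Gb), error = function(e) {
    stop("solver error: blended G is singular; increase the blend weight")
  })
  A22inv <- tryCatch(solve(A22), error = function(e) {
    stop("solver error: A22 is singular")
  })
  corr <- Ginv - A22inv
  g <- length(gidx)
  Ainv + Matrix::sparseMatrix(i = rep(gidx, times = g),
                              j = rep(gidx, each = g),
                              x = as.numeric(corr), dims = dim(Ainv))
}

#' Estimate breeding values
#'
#' Single-trait animal-model evaluation per trait, with repeated records
#' entered as individual means and an adjusted residual variance (see the
#' module header). Methods: `"phenotype_mean"` (EBV = own record mean, NA
#' without records), `"pedigree_blup"` (MME with the pedigree relationship
#' inverse) and `"ssgblup"` (MME with the single-step H-inverse combining
#' pedigree and genomic information for partially genotyped populations).
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` covering everyone
#'   to be evaluated (parents may be unknown / NA).
#' @param records data.frame with columns `id`, `trait`, `n` (record count)
#'   and `y` (mean of the records).
#' @param traits a [TraitSet-class] or data.frame with columns `id`, `h2`,
#'   `repeatability`, `gsd`.
#' @param method one of `"phenotype_mean"`, `"pedigree_blup"`, `"ssgblup"`.
#' @param genotypes dosage matrix (rownames = ids) for `"ssgblup"`.
#' @param blend_w G-matrix blending weight towards A22 (default 0.05).
#' @param g_freqs optional fixed allele frequencies for G; default observed.
#' @return matrix (pedigree ids x traits) of EBVs.
#' @export
estimateBreedingValues <- function(ped, records, traits,
                                   method = c("pedigree_blup", "ssgblup",
                                              "phenotype_mean"),
                                   genotypes = NULL, blend_w = 0.05,
                                   g_freqs = NULL) {
  method <- match.arg(method)
  if (is(traits, "TraitSet")) traits <- traits@traits
  ped <- orderPedigree(ped)
  ids <- as.character(ped$id)
  ebv <- matrix(NA_real_, length(ids), nrow(traits),
                dimnames = list(ids, traits$id))
  records$id <- as.character(records$id)

  if (method == "phenotype_mean") {
    for (t in traits$id) {
      rt <- records[records$trait == t, ]
      ebv[, t] <- rt$y[match(ids, rt$id)]
    }
    return(ebv)
  }

  Kinv <- if (method == "ssgblup") {
    if (is.null(genotypes) || !nrow(genotypes)) {
      stop("ssgblup needs a genotype dosage matrix")
    }
    makeHinv(makeAinv(ped), genotypes, blend_w, g_freqs = g_freqs)
  } else {
    makeAinv(ped)
  }

  for (ti in seq_len(nrow(traits))) {
    t <- traits$id[ti]
    h2 <- traits$h2[ti]
    r <- traits$repeatability[ti]
    sigmaP2 <- traits$gsd[ti]^2 / h2
    sigmaA2 <- traits$gsd[ti]^2
    rt <- records[records$trait == t & records$n > 0, ]
    if (!nrow(rt)) {
      stop(sprintf("BVE error: no phenotyped training individuals for trait '%s'", t))
    }
    ridx <- match(rt$id, ids)
    if (anyNA(ridx)) stop("records reference individuals outside the pedigree")
    rvar <- ((1 - r) / rt$n + (r - h2)) * sigmaP2
    rvar <- pmax(rvar, 1e-8 * sigmaP2)
    Rinv <- 1 / rvar
    nrec <- nrow(rt)
    nind <- length(ids)
    Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = ridx, x = 1,
                              dims = c(nrec, nind))
    X <- matrix(1, nrec, 1)
    XRX <- sum(Rinv)
    XRZ <- Matrix::crossprod(X * Rinv, Z)
    ZRZ <- Matrix::crossprod(Z * Rinv, Z)
    lhs <- rbind(cbind(Matrix::Matrix(XRX), XRZ),
                 cbind(Matrix::t(XRZ), ZRZ + Kinv / sigmaA2))
    rhs <- c(sum(Rinv * rt$y), as.numeric(Matrix::crossprod(Z, Rinv * rt$y)))
    sol <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(lhs), LDL = FALSE,
                             perm = TRUE)
      as.numeric(Matrix::solve(ch, rhs, system = "A"))
    }, error = function(e) {
      stop("solver error: mixed-model equations are singular; ",
           "consider increasing the blend weight")
    })
    ebv[, t] <- sol[-1L]
  }
  ebv
}
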