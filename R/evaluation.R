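# Output analysis: phenotypes, true values, BVE accuracy, IBD kinship and
# inbreeding, major QTL, replicate-averaged scenario comparison and the
# discounted cost ledger.

getSnapshot <- function(result, cohort_id) {
  sn <- result@snapshots[[cohort_id]]
  if (is.null(sn)) stop(sprintf("unknown cohort '%s'", cohort_id))
  sn
}

snapMatrix <- function(sn, prefix, traitIds) {
  out <- vapply(traitIds, function(t) sn$individuals[[paste0(prefix, t)]],
                numeric(nrow(sn$individuals)))
  if (nrow(sn$individuals) == 1L) {
    out <- matrix(out, 1, dimnames = list(NULL, traitIds))
  }
  rownames(out) <- as.character(sn$individuals$id)
  out
}

resultTraitIds <- function(result) result@expanded@program@traits@traits$id

#' Observed phenotypes of a cohort
#'
#' Per-individual record means; individuals without records report `NA`,
#' never zero.
#'
#' @param result a [SimulationResult-class].
#' @param cohort_id expanded node id.
#' @return matrix (individuals x traits).
#' @export
observedPhenotypes <- function(result, cohort_id) {
  sn <- getSnapshot(result, cohort_id)
  snapMatrix(sn, "phen_", resultTraitIds(result))
}

#' True genomic values of a cohort
#'
#' @inheritParams observedPhenotypes
#' @return matrix (individuals x traits); always defined.
#' @export
trueValues <- function(result, cohort_id) {
  sn <- getSnapshot(result, cohort_id)
  if (!nrow(sn$individuals)) stop(sprintf("cohort '%s' is empty", cohort_id))
  snapMatrix(sn, "tv_", resultTraitIds(result))
}

#' Accuracy of breeding-value estimation within a cohort
#'
#' Pearson correlation between EBVs and true genomic values.
#'
#' @inheritParams observedPhenotypes
#' @param trait trait id.
#' @return correlation in \[-1, 1\].
#' @export
bveAccuracy <- function(result, cohort_id, trait) {
  sn <- getSnapshot(result, cohort_id)
  e <- sn$individuals[[paste0("ebv_", trait)]]
  t_ <- sn$individuals[[paste0("tv_", trait)]]
  if (is.null(e) || all(is.na(e))) {
    stop(sprintf("accuracy error: cohort '%s' has no EBVs for trait '%s'",
                 cohort_id, trait))
  }
  ok <- !is.na(e)
  cor(e[ok], t_[ok])
}

#' IBD kinship and inbreeding of a cohort
#'
#' Empirical identity by descent from founder-origin labels: the kinship of a
#' pair is the probability that one allele sampled from each is a copy of the
#' same founder allele; an individual's inbreeding is the IBD probability of
#' its two alleles. Both are estimated over the run's markers (the pairwise
#' kinship over a documented sample of individuals and marker positions).
#'
#' @inheritParams observedPhenotypes
#' @return list with `mean_kinship`, `mean_inbreeding` and the per-individual
#'   `inbreeding` vector.
#' @export
kinshipInbreeding <- function(result, cohort_id) {
  sn <- getSnapshot(result, cohort_id)
  if (all(is.na(sn$individuals$inb))) {
    stop(sprintf("origin labels were not retained for cohort '%s'", cohort_id))
  }
  list(mean_kinship = sn$meanKinship,
       mean_inbreeding = sn$meanInbreeding,
       inbreeding = sn$individuals$inb)
}

#' Major-QTL report for a cohort
#'
#' The `top_k` QTL by absolute effect per trait, with their allele
#' frequencies in the named cohort.
#'
#' @inheritParams observedPhenotypes
#' @param top_k number of QTL per trait.
#' @return data.frame: trait, marker id, chromosome, effect, frequency.
#' @export
qtlReport <- function(result, cohort_id, top_k = 10L) {
  sn <- getSnapshot(result, cohort_id)
  if (is.null(sn$qtlFreq)) {
    stop(sprintf("QTL frequencies were not recorded for cohort '%s'", cohort_id))
  }
  eff <- result@effects
  mk <- result@map@markers[eff@markerIndex, ]
  out <- list()
  for (t in eff@traitIds) {
    a <- eff@effects[, t]
    ord <- order(-abs(a))[seq_len(min(top_k, length(a)))]
    out[[t]] <- data.frame(trait = t, marker = mk$id[ord],
                           chrom = mk$chrom[ord], effect = a[ord],
                           frequency = sn$qtlFreq[ord],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-trait summary of a cohort
#'
#' @inheritParams observedPhenotypes
#' @return data.frame with phenotype and true-value means/SDs, BVE accuracy,
#'   and the cohort's mean kinship and inbreeding.
#' @export
cohortSummary <- function(result, cohort_id) {
  sn <- getSnapshot(result, cohort_id)
  tid <- resultTraitIds(result)
  ph <- snapMatrix(sn, "phen_", tid)
  tv <- snapMatrix(sn, "tv_", tid)
  ebv <- snapMatrix(sn, "ebv_", tid)
  acc <- vapply(tid, function(t) {
    e <- ebv[, t]; ok <- !is.na(e)
    if (sum(ok) > 2L && sd(e[ok]) > 0) cor(e[ok], tv[ok, t]) else NA_real_
  }, 1)
  data.frame(trait = tid,
             phen_mean = colMeans(ph, na.rm = TRUE),
             phen_sd = apply(ph, 2, sd, na.rm = TRUE),
             tv_mean = colMeans(tv), tv_sd = apply(tv, 2, sd),
             accuracy = acc,
             mean_kinship = sn$meanKinship,
             mean_inbreeding = sn$meanInbreeding,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare scenarios over a cohort sequence, averaged across replicates
#'
#' For each scenario and trait, the trajectory of cohort-mean true genomic
#' values is shifted by one common offset so that the replicate mean at the
#' standardization cycle equals 100 (the field's usual presentation scale);
#' mean inbreeding trajectories are reported unshifted under the pseudo-trait
#' `"inbreeding"`. 95% confidence bands are mean +/- 1.96 SE over replicates.
#'
#' @param results named list: scenario -> list of [SimulationResult-class]
#'   replicates, all simulating the same cohort sequence.
#' @param cohort_sequence character vector of expanded node ids in cycle
#'   order (e.g. the calf cohorts of cycles 1..25).
#' @param standardize_at index into `cohort_sequence` at which trait means
#'   are pinned to 100; `NULL` skips standardization.
#' @return data.frame: scenario, cycle, cohort, trait, mean, se, lower,
#'   upper, n_replicates.
#' @export
compareScenarios <- function(results, cohort_sequence, standardize_at = NULL) {
  stopifnot(length(results) >= 1L)
  traitIds <- resultTraitIds(results[[1L]][[1L]])
  out <- list()
  for (sc in names(results)) {
    reps <- results[[sc]]
    for (r in reps) {
      missing <- setdiff(cohort_sequence, names(r@snapshots))
      if (length(missing)) {
        stop(sprintf("scenario '%s': cohort sequence not simulated (%s)",
                     sc, paste(missing, collapse = ", ")))
      }
    }
    R <- length(reps)
    # trajectories: replicate x cycle, per trait (+ inbreeding)
    for (t in c(traitIds, "inbreeding")) {
      tra <- vapply(reps, function(r) {
        vapply(cohort_sequence, function(cid) {
          sn <- r@snapshots[[cid]]
          if (t == "inbreeding") sn$meanInbreeding
          else mean(sn$individuals[[paste0("tv_", t)]])
        }, 1)
      }, numeric(length(cohort_sequence)))
      tra <- matrix(tra, nrow = length(cohort_sequence))
      if (t != "inbreeding" && !is.null(standardize_at)) {
        shift <- 100 - mean(tra[standardize_at, ])
        tra <- tra + shift
      }
      mu <- rowMeans(tra)
      se <- if (R > 1L) apply(tra, 1, sd) / sqrt(R) else rep(NA_real_, nrow(tra))
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, cycle = seq_along(cohort_sequence),
        cohort = cohort_sequence, trait = t, mean = mu, se = se,
        lower = mu - 1.96 * se, upper = mu + 1.96 * se,
        n_replicates = R, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Discounted total of a cost ledger
#'
#' Sum of amount / (1 + i)^time over all entries at or before the horizon.
#'
#' @param ledger data.frame with columns `time`, `amount` (e.g.
#'   [costLedger()] of a result).
#' @param interest_rate per-period rate, >= 0.
#' @param horizon last time point included (default all).
#' @return discounted total in money units.
#' @export
discountedCost <- function(ledger, interest_rate = 0, horizon = Inf) {
  if (interest_rate < 0) stop("interest rate must be >= 0")
  keep <- ledger$time <= horizon
  sum(ledger$amount[keep] / (1 + interest_rate)^ledger$time[keep])
}
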