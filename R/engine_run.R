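# Schedule execution: population state, per-node dispatch, breeding-value
# estimation glue, snapshots and the cost ledger.
#
# The population lives in an environment with preallocated, doubling vectors
# and matrices. Haplotypes sit in a chunked store (one chunk per generated
# batch, so adding a cohort never rewrites existing chunks); a chunk is
# released once none of its individuals is alive or the parent of a living
# animal, which bounds memory by the number of concurrently "needed" genomes
# rather than the total number ever simulated.

newPopulation <- function(map, traitSet, effects) {
  pop <- new.env(parent = emptyenv())
  pop$map <- map
  pop$traits <- traitSet
  pop$effects <- effects
  k <- nrow(traitSet@traits)
  pop$k <- k
  pop$traitIds <- traitSet@traits$id
  pop$n <- 0L
  cap <- 256L
  pop$cap <- cap
  pop$sex <- integer(cap)
  pop$sire <- integer(cap)
  pop$dam <- integer(cap)
  pop$birth <- numeric(cap)
  pop$alive <- logical(cap)
  pop$genotyped <- logical(cap)
  pop$housing <- character(cap)
  pop$tv <- matrix(NA_real_, cap, k)
  pop$pe <- matrix(NA_real_, cap, k)
  pop$recSum <- matrix(0, cap, k)
  pop$recN <- matrix(0L, cap, k)
  pop$ebv <- matrix(NA_real_, cap, k)
  # chunked haplotype store: chunkOf[id] = 0 means dropped
  pop$chunks <- list()
  pop$chunkLive <- integer(0)
  pop$chunkOf <- integer(cap)
  pop$rowIn <- integer(cap)
  pop$nextOrigin <- 1L
  pop$cohorts <- list()
  pop$cohortTime <- numeric(0)
  pop
}

ensureCap <- function(pop, add) {
  need <- pop$n + add
  if (need <= pop$cap) return(invisible())
  newCap <- max(need, 2L * pop$cap)
  grow <- function(x) { length(x) <- newCap; x }
  for (f in c("sex", "sire", "dam", "chunkOf", "rowIn")) {
    v <- grow(pop[[f]]); v[is.na(v)] <- 0L; pop[[f]] <- v
  }
  b <- grow(pop$birth); b[is.na(b)] <- 0; pop$birth <- b
  for (f in c("alive", "genotyped")) {
    v <- grow(pop[[f]]); v[is.na(v)] <- FALSE; pop[[f]] <- v
  }
  h <- grow(pop$housing); h[is.na(h)] <- ""; pop$housing <- h
  growM <- function(m, fill) {
    out <- matrix(fill, newCap, ncol(m)); out[seq_len(nrow(m)), ] <- m; out
  }
  pop$tv <- growM(pop$tv, NA_real_)
  pop$pe <- growM(pop$pe, NA_real_)
  pop$recSum <- growM(pop$recSum, 0)
  pop$recN <- growM(pop$recN, 0L)
  pop$ebv <- growM(pop$ebv, NA_real_)
  pop$cap <- newCap
  invisible()
}

# Register individuals; mats holds A1/A2/O1/O2 (n x markers). Returns ids.
addIndividuals <- function(pop, mats, sex, sire, dam, birth, housing) {
  n <- nrow(mats$A1)
  ensureCap(pop, n)
  ids <- pop$n + seq_len(n)
  pop$n <- pop$n + n
  pop$sex[ids] <- sex
  pop$sire[ids] <- sire
  pop$dam[ids] <- dam
  pop$birth[ids] <- birth
  pop$alive[ids] <- TRUE
  pop$genotyped[ids] <- FALSE
  pop$housing[ids] <- housing
  cid <- length(pop$chunks) + 1L
  pop$chunks[[cid]] <- mats[c("A1", "A2", "O1", "O2")]
  pop$chunkLive[cid] <- n
  pop$chunkOf[ids] <- cid
  pop$rowIn[ids] <- seq_len(n)
  qi <- pop$effects@markerIndex
  dos <- mats$A1[, qi, drop = FALSE] + mats$A2[, qi, drop = FALSE]
  tv <- valuesFromDosage(dos, pop$effects)
  pop$tv[ids, ] <- tv
  tr <- pop$traits@traits
  peSd <- sqrt(pmax(tr$repeatability - tr$h2, 0) * tr$gsd^2 / tr$h2)
  pop$pe[ids, ] <- correlatedNormal(n, pop$traits@residualCorrelation,
                                    seq_len(pop$k), peSd)
  ids
}

gcHaplotypes <- function(pop) {
  if (!pop$n) return(invisible())
  ids <- seq_len(pop$n)
  alive <- ids[pop$alive[ids]]
  needed <- logical(pop$n)
  needed[alive] <- TRUE
  par <- unique(c(pop$sire[alive], pop$dam[alive]))
  par <- par[par > 0L]
  needed[par] <- TRUE
  drop <- ids[!needed & pop$chunkOf[ids] > 0L]
  if (length(drop)) {
    tab <- table(pop$chunkOf[drop])
    ci <- as.integer(names(tab))
    pop$chunkLive[ci] <- pop$chunkLive[ci] - as.integer(tab)
    pop$chunkOf[drop] <- 0L
    dead <- ci[pop$chunkLive[ci] <= 0L]
    for (cu in dead) pop$chunks[cu] <- list(NULL)
  }
  invisible()
}

hapRetained <- function(pop, ids) pop$chunkOf[ids] > 0L

# Gather haplotype/origin matrices for individuals, in the given order.
gatherHap <- function(pop, ids) {
  ch <- pop$chunkOf[ids]
  if (any(ch == 0L)) {
    stop("haplotypes no longer retained for requested individuals")
  }
  ri <- pop$rowIn[ids]
  m <- ncol(pop$chunks[[ch[1L]]]$A1)
  out <- list()
  for (f in c("A1", "A2", "O1", "O2")) {
    mat <- matrix(0L, length(ids), m)
    for (cu in unique(ch)) {
      w <- which(ch == cu)
      mat[w, ] <- pop$chunks[[cu]][[f]][ri[w], , drop = FALSE]
    }
    out[[f]] <- mat
  }
  out
}

phenMeans <- function(pop, ids) {
  s <- pop$recSum[ids, , drop = FALSE]
  n <- pop$recN[ids, , drop = FALSE]
  out <- s / n
  out[n == 0L] <- NA_real_
  colnames(out) <- pop$traitIds
  rownames(out) <- as.character(ids)
  out
}

indexWeights <- function(traitSet, index_id) {
  if (!is.null(index_id)) {
    w <- traitSet@indices[[index_id]]
    if (is.null(w)) stop(sprintf("selection index '%s' is not defined", index_id))
    return(w)
  }
  setNames(rep(1, nrow(traitSet@traits)), traitSet@traits$id)
}

# Pedigree / single-step evaluation for a selection edge. Writes EBVs into
# the population and returns per-trait accuracy over the candidates.
runBveSelection <- function(pop, cand, training, method, opts) {
  ids <- unique(c(cand, training))
  for (d in seq_len(opts$bve_depth)) {
    par <- unique(c(pop$sire[ids], pop$dam[ids]))
    ids <- unique(c(ids, par[par > 0L]))
  }
  ids <- sort(ids)
  inSet <- function(p) ifelse(p %in% ids, as.character(p), NA_character_)
  ped <- data.frame(id = as.character(ids),
                    sire = inSet(pop$sire[ids]),
                    dam = inSet(pop$dam[ids]), stringsAsFactors = FALSE)
  recs <- list()
  for (ti in seq_len(pop$k)) {
    nn <- pop$recN[ids, ti]
    has <- nn > 0L
    if (any(has)) {
      recs[[length(recs) + 1L]] <- data.frame(
        id = as.character(ids[has]), trait = pop$traitIds[ti],
        n = nn[has], y = pop$recSum[ids[has], ti] / nn[has],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  genotypes <- NULL
  if (method == "ssgblup") {
    g <- ids[pop$genotyped[ids] & hapRetained(pop, ids)]
    if (length(g)) {
      h <- gatherHap(pop, g)
      genotypes <- h$A1 + h$A2
      rownames(genotypes) <- as.character(g)
    }
  }
  ebv <- estimateBreedingValues(ped, records, pop$traits, method = method,
                                genotypes = genotypes, blend_w = opts$blend_w)
  got <- as.integer(rownames(ebv))
  pop$ebv[got, ] <- ebv
  acc <- vapply(seq_len(pop$k), function(ti) {
    e <- pop$ebv[cand, ti]; t_ <- pop$tv[cand, ti]
    if (length(cand) > 2L && sd(e) > 0 && sd(t_) > 0) cor(e, t_) else NA_real_
  }, 1)
  setNames(acc, pop$traitIds)
}

# Mean pairwise IBD kinship over a sample of individuals and markers.
sampleKinship <- function(pop, ids, n_sample, n_markers) {
  ids <- ids[hapRetained(pop, ids)]
  if (length(ids) < 2L || n_sample < 2L) return(NA_real_)
  if (length(ids) > n_sample) ids <- sort(resample(ids, n_sample))
  h <- gatherHap(pop, ids)
  mk <- ncol(h$O1)
  cols <- if (mk > n_markers) sort(sample.int(mk, n_markers)) else seq_len(mk)
  O1 <- h$O1[, cols, drop = FALSE]
  O2 <- h$O2[, cols, drop = FALSE]
  s <- length(ids)
  tot <- 0
  for (i in seq_len(s - 1L)) {
    for (j in seq(i + 1L, s)) {
      tot <- tot + (mean(O1[i, ] == O1[j, ]) + mean(O1[i, ] == O2[j, ]) +
                    mean(O2[i, ] == O1[j, ]) + mean(O2[i, ] == O2[j, ])) / 4
    }
  }
  tot / (s * (s - 1L) / 2L)
}

defaultRunOptions <- function(options = list()) {
  modifyList(list(retain_genotypes = character(0), kinship_sample = 30L,
                  kinship_markers = 1000L, bve_depth = 2L, blend_w = 0.05,
                  verbose = FALSE), options)
}

#' Run an expanded breeding program
#'
#' Executes the schedule entry by entry, dispatching founder draws, offspring
#' generation, selection (with breeding-value estimation where requested),
#' phenotyping, genotyping, age-based culling and cost accounting, and
#' snapshots every cohort. Fully reproducible from `master_seed`: each node
#' draws from its own deterministically derived child seed.
#'
#' @param expanded an [ExpandedProgram-class] (see [resolveRepeats()]).
#' @param master_seed integer seed.
#' @param schedule optional precomputed [scheduleGeneration()] result.
#' @param map optional [GeneticMap-class]; defaults to the program's
#'   `general$map` spec, else a cattle-like 29-chromosome map.
#' @param effects optional [QTLEffects-class]; drawn from the trait set and
#'   founder allele frequencies when NULL.
#' @param options list: `retain_genotypes` (node ids, or TRUE for all),
#'   `kinship_sample` and `kinship_markers` (sampling for cohort kinship),
#'   `bve_depth` (ancestor generations kept in the evaluation pedigree),
#'   `blend_w` (G blending), `verbose`.
#' @return a [SimulationResult-class].
#' @export
runProgram <- function(expanded, master_seed = 1L, schedule = NULL,
                       map = NULL, effects = NULL, options = list()) {
  stopifnot(is(expanded, "ExpandedProgram"))
  opts <- defaultRunOptions(options)
  prog <- expanded@program
  if (is.null(schedule)) schedule <- scheduleGeneration(expanded)
  ids_ <- nodeIds(expanded)
  byId <- setNames(expanded@nodes, ids_)
  nN <- nrow(schedule)
  seeds <- deriveSeeds(master_seed, nN + 1L)

  set.seed(seeds[1L])
  if (is.null(map)) {
    ms <- prog@general$map
    map <- if (is.null(ms)) {
      createMap(29, 24, 11600)
    } else if (is(ms, "GeneticMap")) ms else {
      createMap(ms$n_chromosomes, ms$total_length, ms$n_markers)
    }
  }
  subpops <- prog@subpopulations
  if (!length(subpops)) subpops <- list(list(label = "default"))
  labels <- vapply(subpops, function(s) lget(s, "label", "default"), "")
  freqs <- lapply(subpops, resolveFrequencies, n_markers = nMarkers(map))
  names(freqs) <- labels
  if (is.null(effects)) {
    effects <- assignQtlEffects(prog@traits, map, freqs[[1L]],
                                rng_seed = seeds[1L])
  }
  pop <- newPopulation(map, prog@traits, effects)
  snaps <- new.env(parent = emptyenv())
  genoKeep <- list()
  ledger <- list()
  costs <- lget(prog@economy, "costs", list())
  addCost <- function(time, category, amount) {
    if (!is.null(amount) && is.finite(amount) && amount != 0) {
      ledger[[length(ledger) + 1L]] <<- data.frame(time = time,
                                                   category = category,
                                                   amount = amount)
    }
  }
  litterDefault <- lget(prog@general, "litter_size", 1L)
  curTime <- -Inf

  for (j in seq_len(nN)) {
    nodeId <- schedule$node[j]
    tnow <- schedule$time[j]
    node <- byId[[nodeId]]
    set.seed(seeds[j + 1L])

    if (tnow > curTime) {
      # once per time step: survival-probability culling and fixed costs
      if (is.finite(curTime)) {
        survRules <- Filter(function(r) !is.null(r$survival), prog@culling)
        if (length(survRules) && pop$n) {
          idsAll <- seq_len(pop$n)
          df <- data.frame(birth = pop$birth[idsAll],
                           housing_class = pop$housing[idsAll],
                           alive = pop$alive[idsAll])
          pop$alive[idsAll] <- applyCulling(df, survRules, tnow)
        }
      }
      addCost(tnow, "fixed", lget(costs, "fixed", NULL))
      curTime <- tnow
    }

    inc <- Filter(function(e) e$to == nodeId, expanded@edges)
    members <- integer(0)
    accuracy <- NULL

    if (!length(inc)) {
      sp <- lget(node, "subpopulation", labels[1L])
      if (!sp %in% labels) sp <- labels[1L]
      mats <- drawFounderMatrices(node$n_individuals, freqs[[sp]],
                                  origin_start = pop$nextOrigin)
      pop$nextOrigin <- mats$next_origin
      n <- node$n_individuals
      sex <- switch(node$sex, male = rep(1L, n), female = rep(2L, n),
                    mixed = 1L + rbinom(n, 1L, 0.5))
      members <- addIndividuals(pop, mats, sex, 0L, 0L, tnow,
                                node$housing_class)
    } else {
      reproEdges <- list()
      for (e in inc) {
        act <- e$action
        if (act == "reproduction") {
          reproEdges[[length(reproEdges) + 1L]] <- e
        } else if (act %in% c("aging", "combine")) {
          src <- pop$cohorts[[e$from]]
          members <- c(members, src[pop$alive[src]])
        } else if (act == "split") {
          src <- pop$cohorts[[e$from]]
          src <- src[pop$alive[src]]
          used <- lget(pop$splitUsed, e$from, integer(0))
          avail <- setdiff(src, used)
          take <- min(node$n_individuals, length(avail))
          got <- sort(resample(avail, take))
          if (is.null(pop$splitUsed)) pop$splitUsed <- list()
          pop$splitUsed[[e$from]] <- c(used, got)
          members <- c(members, got)
        } else if (act == "selection") {
          src <- pop$cohorts[[e$from]]
          cand <- src[pop$alive[src]]
          if (!length(cand)) {
            stop(sprintf("selection error on edge %s: no living candidates",
                         edgeLabel(e)))
          }
          sel <- e$selection
          nSel <- if (!is.null(sel$n_selected)) sel$n_selected else {
            max(1L, as.integer(floor(sel$proportion * length(cand) + 0.5)))
          }
          if (nSel > length(cand)) {
            stop(sprintf("selection error on edge %s: %d requested from %d alive",
                         edgeLabel(e), nSel, length(cand)))
          }
          crit <- sel$criterion
          w <- indexWeights(prog@traits, sel$index)
          scores <- if (crit == "random") {
            setNames(runif(length(cand)), cand)
          } else if (crit %in% c("phenotype", "index")) {
            setNames(indexValue(phenMeans(pop, cand), w, missing_zero = TRUE),
                     cand)
          } else {
            training <- integer(0)
            for (tc in sel$training) {
              training <- c(training, pop$cohorts[[tc]])
            }
            accuracy <- runBveSelection(pop, cand, unique(training), crit, opts)
            if (!is.null(snaps[[e$from]])) {
              sn <- snaps[[e$from]]
              rows <- match(cand, sn$individuals$id)
              for (t in pop$traitIds) {
                sn$individuals[[paste0("ebv_", t)]][rows] <-
                  pop$ebv[cand, match(t, pop$traitIds)]
              }
              sn$accuracy <- accuracy
              snaps[[e$from]] <- sn
            }
            setNames(indexValue(pop$ebv[cand, , drop = FALSE] |>
                                  `colnames<-`(pop$traitIds), w), cand)
          }
          members <- c(members, as.integer(selectIndividuals(scores, nSel)))
        }
      }
      if (length(reproEdges)) {
        nTot <- node$n_individuals
        nEach <- rep(nTot %/% length(reproEdges), length(reproEdges))
        nEach[seq_len(nTot %% length(reproEdges))] <-
          nEach[seq_len(nTot %% length(reproEdges))] + 1L
        for (ei in seq_along(reproEdges)) {
          e <- reproEdges[[ei]]
          if (nEach[ei] == 0L) next
          sset <- pop$cohorts[[e$from]]
          sset <- sset[pop$alive[sset]]
          dnode <- e$reproduction$second_parent
          dset <- if (is.null(dnode)) integer(0) else pop$cohorts[[dnode]]
          dset <- dset[pop$alive[dset]]
          if (!length(sset) || !length(dset)) {
            stop(sprintf("reproduction error on edge %s: empty parent set",
                         edgeLabel(e)))
          }
          sires <- sset[pop$sex[sset] == 1L]
          dams <- dset[pop$sex[dset] == 2L]
          if (!length(sires)) sires <- sset
          if (!length(dams)) dams <- dset
          litter <- lget(e$reproduction, "litter_size", litterDefault)
          n <- nEach[ei]
          si <- resample(sires, n, replace = TRUE)
          di <- drawDams(dams, n, litter)
          sh <- gatherHap(pop, si)
          dh <- gatherHap(pop, di)
          pg <- batchMeiosis(sh$A1, sh$A2, sh$O1, sh$O2, map)
          mg <- batchMeiosis(dh$A1, dh$A2, dh$O1, dh$O2, map)
          sexed <- isTRUE(e$reproduction$use_sexed_semen)
          sex <- if (node$sex == "male") rep(1L, n)
            else if (node$sex == "female") rep(2L, n)
            else if (sexed) rep(2L, n)
            else 1L + rbinom(n, 1L, 0.5)
          kids <- addIndividuals(pop,
                                 list(A1 = pg$H, A2 = mg$H, O1 = pg$O, O2 = mg$O),
                                 sex, si, di, tnow, node$housing_class)
          members <- c(members, kids)
        }
      }
      members <- unique(members)
    }

    pop$cohorts[[nodeId]] <- members
    pop$cohortTime[nodeId] <- tnow
    # individuals take on the housing class of the cohort they enter, so
    # culling rules can address life stages (e.g. retired sires) directly
    if (length(members)) pop$housing[members] <- node$housing_class

    # phenotyping: new records for this node's class
    pc <- node$phenotyping_class
    if (length(pc) && length(members)) {
      tvm <- pop$tv[members, , drop = FALSE]
      colnames(tvm) <- pop$traitIds
      ph <- phenotypeCohort(tvm, prog@traits, pc,
                            pe = pop$pe[members, , drop = FALSE] |>
                              `colnames<-`(pop$traitIds))
      for (t in names(pc)) {
        cnt <- pc[[t]]
        if (cnt > 0L) {
          ti <- match(t, pop$traitIds)
          pop$recSum[members, ti] <- pop$recSum[members, ti] +
            rowSums(ph$records[[t]])
          pop$recN[members, ti] <- pop$recN[members, ti] + as.integer(cnt)
        }
      }
      phCost <- lget(costs, "phenotyping", NULL)
      if (!is.null(phCost)) {
        nRec <- sum(unlist(pc)) * length(members)
        addCost(tnow, "phenotyping", phCost * nRec)
      }
    }

    # genotyping
    gs <- lget(node, "genotyped_share", 0)
    if (gs > 0 && length(members)) {
      newly <- members[!pop$genotyped[members]]
      nG <- as.integer(round(gs * length(members)))
      nG <- min(nG, length(newly))
      if (nG > 0L) {
        gsel <- if (nG == length(newly)) newly else sort(resample(newly, nG))
        pop$genotyped[gsel] <- TRUE
        addCost(tnow, "genotyping", lget(costs, "genotyping", 0) * nG)
      }
    }

    hc <- lget(costs, "housing", list())
    if (length(members) && !is.null(hc[[node$housing_class]])) {
      addCost(tnow, "housing", hc[[node$housing_class]] * length(members))
    }

    # age-threshold culling (idempotent, applied after every node)
    ageRules <- Filter(function(r) !is.null(r$age), prog@culling)
    if (length(ageRules) && pop$n) {
      idsAll <- seq_len(pop$n)
      df <- data.frame(birth = pop$birth[idsAll],
                       housing_class = pop$housing[idsAll],
                       alive = pop$alive[idsAll])
      pop$alive[idsAll] <- applyCulling(df, ageRules, tnow)
    }

    # snapshot
    inb <- rep(NA_real_, length(members))
    ok <- hapRetained(pop, members)
    mh <- if (any(ok)) gatherHap(pop, members[ok])
    if (any(ok)) inb[ok] <- rowMeans(mh$O1 == mh$O2)
    snap <- list(
      time = tnow,
      individuals = {
        df <- data.frame(id = members, sex = pop$sex[members],
                         sire = pop$sire[members], dam = pop$dam[members],
                         birth = pop$birth[members],
                         genotyped = pop$genotyped[members], inb = inb)
        pm <- phenMeans(pop, members)
        for (ti in seq_len(pop$k)) {
          t <- pop$traitIds[ti]
          df[[paste0("tv_", t)]] <- pop$tv[members, ti]
          df[[paste0("phen_", t)]] <- pm[, ti]
          df[[paste0("ebv_", t)]] <- pop$ebv[members, ti]
        }
        df
      },
      meanInbreeding = if (length(inb)) mean(inb, na.rm = TRUE) else NA_real_,
      meanKinship = sampleKinship(pop, members, opts$kinship_sample,
                                  opts$kinship_markers),
      qtlFreq = if (length(members) && any(ok)) {
        qi <- effects@markerIndex
        colMeans((mh$A1[, qi, drop = FALSE] +
                  mh$A2[, qi, drop = FALSE]) / 2)
      } else NULL,
      accuracy = accuracy
    )
    snaps[[nodeId]] <- snap

    keepG <- isTRUE(opts$retain_genotypes) ||
      (is.character(opts$retain_genotypes) && nodeId %in% opts$retain_genotypes)
    if (keepG && length(members) && all(hapRetained(pop, members))) {
      genoKeep[[nodeId]] <- c(list(ids = members), gatherHap(pop, members))
    }
    if (!isTRUE(opts$retain_genotypes)) gcHaplotypes(pop)
    if (opts$verbose) {
      message(sprintf("[%s] t=%.2f n=%d", nodeId, tnow, length(members)))
    }
  }

  ledgerDf <- if (length(ledger)) do.call(rbind, ledger) else {
    data.frame(time = numeric(0), category = character(0), amount = numeric(0))
  }
  new("SimulationResult",
      snapshots = mget(schedule$node, envir = snaps), schedule = schedule,
      ledger = ledgerDf,
      masterSeed = as.integer(master_seed), map = map, effects = effects,
      expanded = expanded, genotypes = genoKeep)
}

#' Validate, expand, schedule and run a breeding program in one call
#'
#' @param program a [BreedingProgram-class].
#' @inheritParams runProgram
#' @return a [SimulationResult-class].
#' @export
simulateProgram <- function(program, master_seed = 1L, options = list()) {
  rep_ <- validateProgram(program)
  if (!isValid(rep_)) {
    stop("program has validation errors; see validateProgram()")
  }
  ex <- resolveRepeats(program, check = FALSE)
  runProgram(ex, master_seed = master_seed, options = options)
}

#' Scale cohort sizes and selection counts of a program
#'
#' Multiplies every `n_individuals` and `n_selected` by `scale`, rounding
#' half-up with a floor of one individual, and resets `general$scale` to 1.
#'
#' @param program a [BreedingProgram-class].
#' @param scale factor in (0, 1]; defaults to the program's `general$scale`.
#' @return the scaled [BreedingProgram-class].
#' @export
applyScale <- function(program, scale = NULL) {
  if (is.null(scale)) scale <- lget(program@general, "scale", 1)
  if (scale == 1) return(program)
  program@nodes <- lapply(program@nodes, function(nd) {
    nd$n_individuals <- scaleCount(nd$n_individuals, scale)
    nd
  })
  program@edges <- lapply(program@edges, function(e) {
    if (!is.null(e$selection$n_selected)) {
      e$selection$n_selected <- scaleCount(e$selection$n_selected, scale)
    }
    e
  })
  program@general$scale <- 1
  program
}
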