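# Genetic maps and founder populations.
#
# Founder haplotypes are independent Bernoulli draws per marker from the
# subpopulation's allele frequencies (no linkage disequilibrium at creation;
# LD builds up over burn-in cycles). Every founder haplotype receives a fresh
# origin label that is inherited segment-wise through meiosis, which is the
# basis for identity-by-descent kinship and inbreeding tracking.

#' Create a genetic map with uniformly spaced markers
#'
#' @param n_chromosomes number of chromosomes.
#' @param total_length total map length in Morgan (split equally unless
#'   `chromosome_lengths` is given).
#' @param n_markers total marker count, distributed as evenly as possible.
#' @param chromosome_lengths optional per-chromosome lengths in Morgan.
#' @return a [GeneticMap-class]; positions run from 0 to the chromosome length.
#' @examples
#' createMap(1, 1, 11)  # markers at 0.0, 0.1, ..., 1.0
#' @export
createMap <- function(n_chromosomes, total_length, n_markers,
                      chromosome_lengths = NULL) {
  stopifnot(isCount(n_chromosomes), n_markers >= n_chromosomes)
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- rep(total_length / n_chromosomes, n_chromosomes)
  }
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chroms <- data.frame(name = as.character(seq_len(n_chromosomes)),
                       length = chromosome_lengths, stringsAsFactors = FALSE)
  mk <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
    m <- per[ci]
    pos <- if (m == 1L) 0 else seq(0, chromosome_lengths[ci], length.out = m)
    data.frame(chrom = chroms$name[ci],
               id = sprintf("c%s_m%d", chroms$name[ci], seq_len(m)),
               pos = pos, bp = NA_integer_, stringsAsFactors = FALSE)
  }))
  rownames(mk) <- NULL
  new("GeneticMap", chromosomes = chroms, markers = mk)
}

#' Read / write a genetic map table
#'
#' Plain text with columns chromosome, marker id, position in Morgan and an
#' optional physical position in bp; whitespace- or comma-separated.
#'
#' @param path file path.
#' @return [GeneticMap-class] for `readMap`; `writeMap` returns the path
#'   invisibly.
#' @export
readMap <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tb <- read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE)
  if (ncol(tb) < 3L) stop("map file needs >= 3 columns: chrom, id, pos_morgan")
  names(tb)[1:3] <- c("chrom", "id", "pos")
  tb$chrom <- as.character(tb$chrom)
  tb$bp <- if (ncol(tb) >= 4L) as.integer(tb[[4L]]) else NA_integer_
  tb <- tb[order(match(tb$chrom, unique(tb$chrom)), tb$pos), ]
  chroms <- data.frame(name = unique(tb$chrom),
                       length = vapply(unique(tb$chrom), function(cn) {
                         max(tb$pos[tb$chrom == cn], .Machine$double.eps)
                       }, 1), stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  new("GeneticMap", chromosomes = chroms,
      markers = tb[c("chrom", "id", "pos", "bp")])
}

#' @param map a [GeneticMap-class].
#' @rdname readMap
#' @export
writeMap <- function(map, path) {
  mk <- map@markers
  write.table(mk[c("chrom", "id", "pos", "bp")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

nMarkers <- function(map) nrow(map@markers)

# Per-chromosome marker index ranges, as a list of integer vectors.
chromIndex <- function(map) {
  split(seq_len(nrow(map@markers)),
        match(map@markers$chrom, map@chromosomes$name))
}

# Resolve a subpopulation spec into a per-marker allele-frequency vector.
# Specs carry either `frequencies` (one per marker) or `freq_rule`
# (list(type = "uniform", lo, hi)), drawn with the current RNG stream.
resolveFrequencies <- function(subpop, n_markers) {
  if (!is.null(subpop$frequencies)) {
    f <- unlist(subpop$frequencies)
    if (length(f) == 1L) f <- rep(f, n_markers)
    if (length(f) != n_markers) {
      stop(sprintf("subpopulation '%s': %d frequencies for %d markers",
                   lget(subpop, "label", "?"), length(f), n_markers))
    }
    if (any(f < 0 | f > 1)) stop("allele frequencies must be in [0, 1]")
    return(f)
  }
  rule <- subpop$freq_rule
  if (is.null(rule)) return(rep(0.5, n_markers))
  if (!identical(rule$type, "uniform")) {
    stop(sprintf("unknown frequency rule type '%s'", rule$type))
  }
  runif(n_markers, rule$lo, rule$hi)
}

# Matrix-level founder draw used by the engine: returns integer matrices
# A1/A2 (alleles, n x m) and O1/O2 (founder-origin labels), with labels
# starting at `origin_start`.
drawFounderMatrices <- function(n, freqs, origin_start = 1L) {
  m <- length(freqs)
  A1 <- matrix(as.integer(runif(n * m) < rep(freqs, each = n)), n, m)
  A2 <- matrix(as.integer(runif(n * m) < rep(freqs, each = n)), n, m)
  labs <- origin_start + seq_len(2L * n) - 1L
  O1 <- matrix(rep(labs[seq(1L, 2L * n, by = 2L)], m), n, m)
  O2 <- matrix(rep(labs[seq(2L, 2L * n, by = 2L)], m), n, m)
  list(A1 = A1, A2 = A2, O1 = O1, O2 = O2, next_origin = origin_start + 2L * n)
}

#' Draw founder individuals from per-marker allele frequencies
#'
#' Each haplotype allele at marker m is an independent Bernoulli draw with the
#' subpopulation's frequency at m; each founder haplotype gets a unique origin
#' label, so founder inbreeding is exactly zero.
#'
#' @param map a [GeneticMap-class].
#' @param node a [cohortNode()] with `founder = TRUE`, or an integer count.
#' @param subpop subpopulation spec: `list(label =, frequencies =)` or
#'   `list(label =, freq_rule = list(type = "uniform", lo =, hi =))`.
#' @param rng_seed integer seed; the draw is reproducible given the seed.
#' @param origin_start first founder-origin label to assign; pass a larger
#'   value when combining founders from several calls so labels stay unique.
#' @return list of haplotype pairs, each `list(h1, h2, o1, o2)` with one entry
#'   per marker (`h*` alleles in \{0,1\}, `o*` founder-origin labels).
#' @export
drawFounders <- function(map, node, subpop = list(), rng_seed = 1L,
                         origin_start = 1L) {
  n <- if (is.list(node)) {
    if (!isTRUE(node$founder)) stop("drawFounders needs a founder node")
    node$n_individuals
  } else as.integer(node)
  set.seed(as.integer(rng_seed))
  freqs <- resolveFrequencies(subpop, nMarkers(map))
  mats <- drawFounderMatrices(n, freqs, origin_start = as.integer(origin_start))
  lapply(seq_len(n), function(i) {
    list(h1 = mats$A1[i, ], h2 = mats$A2[i, ],
         o1 = mats$O1[i, ], o2 = mats$O2[i, ])
  })
}

#' Import phased founder genotypes from a VCF file
#'
#' Requires phased GT fields; positions are taken from POS and converted to
#' Morgan at 1e8 bp per Morgan when no map is supplied.
#'
#' @param path VCF file.
#' @param map optional [GeneticMap-class] matching the VCF markers.
#' @return list with elements `haplotypes` (as in [drawFounders()]) and `map`.
#' @export
importVcfFounders <- function(path, map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("importVcfFounders requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt))) stop("VCF genotypes must be phased ('|')")
  fx <- v@fix
  if (is.null(map)) {
    pos_bp <- as.integer(fx[, "POS"])
    chrom <- as.character(fx[, "CHROM"])
    chroms <- data.frame(name = unique(chrom),
                         length = vapply(unique(chrom), function(cn) {
                           max(pos_bp[chrom == cn]) / 1e8
                         }, 1), stringsAsFactors = FALSE)
    mk <- data.frame(chrom = chrom, id = as.character(fx[, "ID"]),
                     pos = pos_bp / 1e8, bp = pos_bp, stringsAsFactors = FALSE)
    map <- new("GeneticMap", chromosomes = chroms, markers = mk)
  }
  n <- ncol(gt)
  h1 <- apply(gt, 2, function(g) as.integer(substr(g, 1, 1)))
  h2 <- apply(gt, 2, function(g) as.integer(substr(g, 3, 3)))
  haps <- lapply(seq_len(n), function(i) {
    list(h1 = h1[, i], h2 = h2[, i],
         o1 = rep(2L * i - 1L, nrow(gt)), o2 = rep(2L * i, nrow(gt)))
  })
  list(haplotypes = haps, map = map)
}

#' Import founder genotypes from PLINK classic ped/map files
#'
#' Alleles coded 1/2 (as written by [exportPedmap()]); genetic positions are
#' read from the map's cM column.
#'
#' @param ped_path,map_path the .ped and .map files.
#' @return list with elements `haplotypes`, `map` and `pedigree` (the first
#'   six .ped columns).
#' @export
importPedmapFounders <- function(ped_path, map_path) {
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  names(mp) <- c("chrom", "id", "cm", "bp")[seq_len(ncol(mp))]
  mp$chrom <- as.character(mp$chrom)
  chroms <- data.frame(name = unique(mp$chrom),
                       length = vapply(unique(mp$chrom), function(cn) {
                         max(mp$cm[mp$chrom == cn]) / 100
                       }, 1), stringsAsFactors = FALSE)
  map <- new("GeneticMap", chromosomes = chroms,
             markers = data.frame(chrom = mp$chrom, id = mp$id,
                                  pos = mp$cm / 100,
                                  bp = if ("bp" %in% names(mp)) mp$bp else NA_integer_,
                                  stringsAsFactors = FALSE))
  pd <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(mp)
  if (ncol(pd) != 6L + 2L * m) {
    stop(sprintf("ped file has %d columns; expected %d for %d markers",
                 ncol(pd), 6L + 2L * m, m))
  }
  geno <- as.matrix(pd[, -(1:6), drop = FALSE])
  haps <- lapply(seq_len(nrow(pd)), function(i) {
    a <- as.integer(geno[i, seq(1L, 2L * m, by = 2L)]) - 1L
    b <- as.integer(geno[i, seq(2L, 2L * m, by = 2L)]) - 1L
    list(h1 = a, h2 = b, o1 = rep(2L * i - 1L, m), o2 = rep(2L * i, m))
  })
  list(haplotypes = haps, map = map, pedigree = pd[, 1:6])
}
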