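# Standard-format exports: VCF 4.2 and PLINK classic ped/map.
#
# Genotypes must have been retained for the exported cohorts (runProgram
# option `retain_genotypes`). Markers without physical positions get a
# synthetic bp = round(Morgan * 1e8), flagged in the VCF header.

cohortGenotypes <- function(result, cohort_ids) {
  got <- list()
  for (cid in cohort_ids) {
    g <- result@genotypes[[cid]]
    if (is.null(g)) {
      stop(sprintf("genotypes were not retained for cohort '%s'", cid))
    }
    got[[cid]] <- g
  }
  got
}

markerPositionsBp <- function(map) {
  bp <- map@markers$bp
  synth <- is.na(bp)
  bp[synth] <- as.integer(round(map@markers$pos[synth] * 1e8))
  list(bp = bp, synthetic = any(synth))
}

#' Export cohort genotypes as a VCF 4.2 file
#'
#' One sample column per individual (named `ind_<id>`), phased GT, REF=A and
#' ALT=B placeholder alleles, positions from the map.
#'
#' @param result a [SimulationResult-class] run with `retain_genotypes`.
#' @param cohort_ids expanded node ids to export.
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportVcf <- function(result, cohort_ids, path) {
  gs <- cohortGenotypes(result, cohort_ids)
  map <- result@map
  pos <- markerPositionsBp(map)
  ids <- unlist(lapply(gs, function(g) g$ids), use.names = FALSE)
  dup <- !duplicated(ids)
  A1 <- do.call(rbind, lapply(gs, function(g) g$A1))[dup, , drop = FALSE]
  A2 <- do.call(rbind, lapply(gs, function(g) g$A2))[dup, , drop = FALSE]
  ids <- ids[dup]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=BreedSim",
           if (pos$synthetic) "##INFO=<ID=SYNTHPOS,Number=0,Type=Flag,Description=\"Physical positions synthesized as round(Morgan*1e8)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind_", ids)), collapse = "\t"))
  m <- nrow(map@markers)
  gtcols <- matrix(paste0(t(A1), "|", t(A2)), nrow = m)
  lines <- vapply(seq_len(m), function(i) {
    paste(c(map@markers$chrom[i], pos$bp[i], map@markers$id[i], "A", "B",
            ".", "PASS", if (pos$synthetic) "SYNTHPOS" else ".", "GT",
            gtcols[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Export cohort genotypes as PLINK classic ped/map files
#'
#' `.map` columns: chromosome, marker id, genetic position in cM, bp.
#' `.ped` columns: FID IID PAT MAT SEX PHENO followed by two allele columns
#' per marker, alleles coded 1 (reference) / 2 (alternative); unknown parents
#' are 0, sexes 1 = male / 2 = female.
#'
#' @inheritParams exportVcf
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return character vector of the two paths, invisibly.
#' @export
exportPedmap <- function(result, cohort_ids, prefix) {
  gs <- cohortGenotypes(result, cohort_ids)
  map <- result@map
  pos <- markerPositionsBp(map)
  mapPath <- paste0(prefix, ".map")
  pedPath <- paste0(prefix, ".ped")
  write.table(data.frame(map@markers$chrom, map@markers$id,
                         map@markers$pos * 100, pos$bp),
              mapPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  lines <- character(0)
  for (cid in names(gs)) {
    g <- gs[[cid]]
    sn <- result@snapshots[[cid]]$individuals
    rows <- match(g$ids, sn$id)
    geno <- matrix("", length(g$ids), 2L * ncol(g$A1))
    geno[, seq(1L, ncol(geno), by = 2L)] <- as.character(g$A1 + 1L)
    geno[, seq(2L, ncol(geno), by = 2L)] <- as.character(g$A2 + 1L)
    known <- function(p) ifelse(p > 0L, as.character(p), "0")
    lines <- c(lines, vapply(seq_along(g$ids), function(i) {
      paste(c(cid, g$ids[i], known(sn$sire[rows[i]]), known(sn$dam[rows[i]]),
              sn$sex[rows[i]], -9, geno[i, ]), collapse = " ")
    }, ""))
  }
  writeLines(lines, pedPath)
  invisible(c(pedPath, mapPath))
}
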