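#' @import methods
#' @importFrom stats rnorm rbinom rpois runif cor var sd coef lm setNames
#'   quantile qnorm aggregate complete.cases
#' @importFrom utils modifyList head tail read.table write.table
NULL

#' Genetic map of markers on chromosomes
#'
#' Positions are in Morgan and strictly increasing within a chromosome.
#' Physical positions (bp) are optional; where absent they are `NA` and
#' exporters substitute a documented synthetic position.
#'
#' @slot chromosomes data.frame with columns `name` and `length` (Morgan).
#' @slot markers data.frame with columns `chrom`, `id`, `pos` (Morgan) and
#'   `bp` (integer or NA).
#' @export
setClass("GeneticMap",
  representation(chromosomes = "data.frame", markers = "data.frame"),
  validity = function(object) {
    msg <- character()
    ch <- object@chromosomes
    mk <- object@markers
    if (!all(c("name", "length") %in% names(ch))) {
      msg <- c(msg, "chromosomes needs columns name, length")
    } else if (any(ch$length <= 0)) {
      msg <- c(msg, "chromosome lengths must be > 0")
    }
    if (!all(c("chrom", "id", "pos") %in% names(mk))) {
      msg <- c(msg, "markers needs columns chrom, id, pos")
    } else {
      for (cn in unique(mk$chrom)) {
        p <- mk$pos[mk$chrom == cn]
        if (any(diff(p) <= 0)) {
          msg <- c(msg, sprintf("marker positions not strictly increasing on chromosome %s", cn))
          break
        }
      }
      if (anyDuplicated(mk$id)) msg <- c(msg, "marker ids must be unique")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Multi-trait architecture parameters and selection indices
#'
#' @slot traits data.frame with columns `id`, `mean`, `gsd`, `h2`,
#'   `repeatability`, `n_qtl`.
#' @slot geneticCorrelation,residualCorrelation correlation matrices over the
#'   traits (symmetric, unit diagonal, positive semi-definite).
#' @slot indices named list of named numeric weight vectors.
#' @export
setClass("TraitSet",
  representation(traits = "data.frame", geneticCorrelation = "matrix",
                 residualCorrelation = "matrix", indices = "list"),
  validity = function(object) {
    msg <- character()
    tr <- object@traits
    need <- c("id", "mean", "gsd", "h2", "repeatability", "n_qtl")
    if (!all(need %in% names(tr))) {
      return(paste("traits needs columns", paste(need, collapse = ", ")))
    }
    if (anyDuplicated(tr$id)) msg <- c(msg, "trait ids must be unique")
    if (any(tr$h2 <= 0 | tr$h2 > 1)) msg <- c(msg, "h2 must be in (0, 1]")
    if (any(tr$repeatability < tr$h2 - 1e-12 | tr$repeatability > 1)) {
      msg <- c(msg, "repeatability must be in [h2, 1]")
    }
    if (any(tr$n_qtl < 1)) msg <- c(msg, "n_qtl must be positive")
    k <- nrow(tr)
    for (nm in c("geneticCorrelation", "residualCorrelation")) {
      m <- slot(object, nm)
      if (!all(dim(m) == c(k, k))) {
        msg <- c(msg, sprintf("%s must be %d x %d", nm, k, k))
      } else {
        bad <- checkCorrelation(m, nm)
        if (!is.null(bad)) msg <- c(msg, bad)
      }
    }
    for (nm in names(object@indices)) {
      w <- object@indices[[nm]]
      if (any(!is.finite(w))) msg <- c(msg, sprintf("index '%s' has non-finite weights", nm))
    }
    if (length(msg)) msg else TRUE
  }
)

#' A breeding program: cohort nodes, action edges and parameter blocks
#'
#' Nodes and edges are stored as named lists mirroring the JSON dialect
#' (see [parseProgram()]); traits are a [TraitSet-class]. Structural checks
#' beyond basic shape live in [validateProgram()].
#'
#' @slot nodes,edges lists of named lists.
#' @slot traits a [TraitSet-class].
#' @slot culling list of culling rules.
#' @slot subpopulations list of founder subpopulation specifications.
#' @slot economy list of cost settings.
#' @slot general list: species, map spec, cohort scale, default litter size.
#' @export
setClass("BreedingProgram",
  representation(nodes = "list", edges = "list", traits = "TraitSet",
                 culling = "list", subpopulations = "list",
                 economy = "list", general = "list"),
  validity = function(object) {
    ids <- vapply(object@nodes, function(n) n$id, "")
    if (anyDuplicated(ids)) return("node ids must be unique")
    TRUE
  }
)

#' Findings from structural validation of a breeding program
#'
#' @slot errors,warnings data.frames with columns `code`, `where`, `message`.
#' @export
setClass("ValidationReport",
  representation(errors = "data.frame", warnings = "data.frame"))

#' A repeat-free breeding program plus provenance of unrolled copies
#'
#' @slot nodes,edges lists as in [BreedingProgram-class], with no repeat edges.
#' @slot provenance data.frame with columns `node`, `origin`, `repeat_index`
#'   (0 for nodes outside any repeated region).
#' @slot program the original [BreedingProgram-class] (parameter blocks).
#' @export
setClass("ExpandedProgram",
  representation(nodes = "list", edges = "list", provenance = "data.frame",
                 program = "BreedingProgram"),
  validity = function(object) {
    acts <- vapply(object@edges, function(e) e$action, "")
    if (any(acts == "repeat")) return("expanded program must not contain repeat edges")
    TRUE
  }
)

#' QTL positions and additive effects realizing a trait architecture
#'
#' @slot markerIndex integer vector of QTL marker indices into the map.
#' @slot effects matrix (QTL x traits) of additive effects per alternative allele.
#' @slot intercepts numeric per-trait offsets so founder means hit their targets.
#' @slot traitIds character vector of trait ids (column order of `effects`).
#' @export
setClass("QTLEffects",
  representation(markerIndex = "integer", effects = "matrix",
                 intercepts = "numeric", traitIds = "character"),
  validity = function(object) {
    if (nrow(object@effects) != length(object@markerIndex)) {
      return("effects must have one row per QTL")
    }
    if (ncol(object@effects) != length(object@traitIds) ||
        length(object@intercepts) != length(object@traitIds)) {
      return("effects/intercepts must match traitIds")
    }
    TRUE
  }
)

#' Result of simulating an expanded breeding program
#'
#' One snapshot per scheduled cohort: an individuals data.frame (pedigree,
#' sex, true values, record means, EBVs, genotype flag, IBD inbreeding),
#' the simulated time, mean pairwise IBD kinship, QTL allele frequencies and,
#' where a breeding-value estimation ran on the cohort, its realized accuracy.
#'
#' @slot snapshots named list (by expanded node id).
#' @slot schedule data.frame with columns `node`, `time`.
#' @slot ledger data.frame of cost entries (`time`, `category`, `amount`).
#' @slot masterSeed integer seed the run was started from.
#' @slot map the [GeneticMap-class] used.
#' @slot effects the [QTLEffects-class] used.
#' @slot expanded the [ExpandedProgram-class] that was run.
#' @slot genotypes named list of retained per-cohort haplotype/origin matrices.
#' @export
setClass("SimulationResult",
  representation(snapshots = "list", schedule = "data.frame",
                 ledger = "data.frame", masterSeed = "integer",
                 map = "GeneticMap", effects = "QTLEffects",
                 expanded = "ExpandedProgram", genotypes = "list"))

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d chromosomes, %d markers, %.3f Morgan total\n",
              nrow(object@chromosomes), nrow(object@markers),
              sum(object@chromosomes$length)))
})

setMethod("show", "TraitSet", function(object) {
  cat(sprintf("TraitSet: %d traits (%s); %d selection index/indices\n",
              nrow(object@traits), paste(object@traits$id, collapse = ", "),
              length(object@indices)))
})

setMethod("show", "BreedingProgram", function(object) {
  acts <- vapply(object@edges, function(e) e$action, "")
  cat(sprintf("BreedingProgram: %d nodes, %d edges (%d repeat), %d traits\n",
              length(object@nodes), length(object@edges),
              sum(acts == "repeat"), nrow(object@traits@traits)))
})

setMethod("show", "ExpandedProgram", function(object) {
  cat(sprintf("ExpandedProgram: %d nodes, %d edges (repeat-free)\n",
              length(object@nodes), length(object@edges)))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d error(s), %d warning(s)\n",
              nrow(object@errors), nrow(object@warnings)))
  if (nrow(object@errors)) {
    for (i in seq_len(nrow(object@errors))) {
      cat(sprintf("  ERROR %s [%s]: %s\n", object@errors$code[i],
                  object@errors$where[i], object@errors$message[i]))
    }
  }
  if (nrow(object@warnings)) {
    for (i in seq_len(nrow(object@warnings))) {
      cat(sprintf("  WARNING %s [%s]: %s\n", object@warnings$code[i],
                  object@warnings$where[i], object@warnings$message[i]))
    }
  }
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d cohort snapshots, seed %d\n",
              length(object@snapshots), object@masterSeed))
})

#' Accessors for program and result components
#'
#' @param x a [BreedingProgram-class], [ExpandedProgram-class] or
#'   [SimulationResult-class].
#' @return `programNodes`/`programEdges` return lists of named lists;
#'   `traitSet` the [TraitSet-class]; `isValid` a logical;
#'   `resultSchedule`/`costLedger` data.frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
programNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
programEdges <- function(x) x@edges

#' @rdname accessors
#' @export
traitSet <- function(x) {
  if (is(x, "ExpandedProgram")) x@program@traits else x@traits
}

#' @rdname accessors
#' @export
nodeIds <- function(x) vapply(x@nodes, function(n) n$id, "")

#' @param report a [ValidationReport-class].
#' @rdname accessors
#' @export
isValid <- function(report) nrow(report@errors) == 0L

#' @rdname accessors
#' @export
resultSchedule <- function(x) x@schedule

#' @rdname accessors
#' @export
costLedger <- function(x) x@ledger
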