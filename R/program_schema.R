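# JSON dialect for breeding programs: constructors, parser, canonical
# serializer and structural validation.
#
# Top-level keys: format_version, general, nodes, edges, traits, culling,
# subpopulations, economy. Unknown keys anywhere warn and are dropped, so
# files from other front-ends degrade gracefully instead of failing.

FORMAT_VERSION <- "1.0"

NODE_KEYS <- c("id", "n_individuals", "sex", "founder", "phenotyping_class",
               "genotyped_share", "housing_class", "time_point", "subpopulation")
EDGE_KEYS <- c("from", "to", "action", "generation_time", "selection",
               "reproduction", "repeat_count", "link_action")
SELECTION_KEYS <- c("criterion", "n_selected", "proportion", "index", "training")
REPRODUCTION_KEYS <- c("second_parent", "litter_size", "use_sexed_semen")
ACTIONS <- c("reproduction", "selection", "aging", "combine", "split", "repeat")
CRITERIA <- c("random", "phenotype", "index", "pedigree_blup", "ssgblup")

#' Construct a cohort node
#'
#' @param id unique node identifier.
#' @param n_individuals cohort size (positive integer).
#' @param sex one of `"male"`, `"female"`, `"mixed"`.
#' @param founder logical; founder cohorts are drawn from allele frequencies
#'   instead of being generated by an incoming edge.
#' @param phenotyping_class named numeric vector/list: number of new phenotype
#'   records per trait gained at this node.
#' @param genotyped_share proportion of the cohort that is genotyped.
#' @param housing_class cost-category key for the economy module.
#' @param time_point non-negative program time (used for founder nodes).
#' @param subpopulation optional founder origin label.
#' @return a named list in the canonical node shape.
#' @export
cohortNode <- function(id, n_individuals, sex = "mixed", founder = FALSE,
                       phenotyping_class = list(), genotyped_share = 0,
                       housing_class = "default", time_point = 0,
                       subpopulation = NULL) {
  stopifnot(is.character(id), length(id) == 1L, isCount(n_individuals),
            sex %in% c("male", "female", "mixed"),
            isProportion(genotyped_share), time_point >= 0)
  pc <- as.list(phenotyping_class)
  if (length(pc) && (is.null(names(pc)) || any(names(pc) == ""))) {
    stop("phenotyping_class must be a named trait -> count mapping")
  }
  if (any(unlist(pc) < 0)) stop("phenotyping_class counts must be non-negative")
  list(id = id, n_individuals = as.integer(n_individuals), sex = sex,
       founder = isTRUE(founder), phenotyping_class = pc,
       genotyped_share = genotyped_share, housing_class = housing_class,
       time_point = time_point, subpopulation = subpopulation)
}

#' Construct a breeding-action edge
#'
#' Repeat edges close a breeding cycle: they carry `repeat_count` and an
#' optional `link_action` (default `"aging"`) with the usual selection or
#' reproduction settings, describing the concrete edge instantiated between
#' consecutive copies of the cycle during expansion.
#'
#' @param from,to node ids.
#' @param action one of reproduction, selection, aging, combine, split, repeat.
#' @param generation_time non-negative time the action takes.
#' @param selection list: `criterion` (random, phenotype, index, pedigree_blup,
#'   ssgblup), `n_selected` or `proportion`, optional `index` (index id) and
#'   `training` (node ids, optionally `"node@-k"` to address the copy k cycles
#'   earlier).
#' @param reproduction list: `second_parent` (node id), optional `litter_size`,
#'   `use_sexed_semen`.
#' @param repeat_count positive integer (repeat edges only).
#' @param link_action action instantiated between cycle copies (repeat edges).
#' @return a named list in the canonical edge shape.
#' @export
breedingEdge <- function(from, to, action, generation_time = 0,
                         selection = NULL, reproduction = NULL,
                         repeat_count = NULL, link_action = NULL) {
  stopifnot(is.character(from), is.character(to), action %in% ACTIONS,
            generation_time >= 0)
  if (action == "repeat") {
    if (!isCount(repeat_count)) stop("repeat edges need a positive repeat_count")
    repeat_count <- as.integer(repeat_count)
    if (is.null(link_action)) link_action <- "aging"
    stopifnot(link_action %in% setdiff(ACTIONS, "repeat"))
  } else if (!is.null(repeat_count)) {
    stop("repeat_count is only allowed on repeat edges")
  }
  eff <- if (action == "repeat") link_action else action
  if (eff == "selection" && is.null(selection)) {
    stop("selection edges need selection settings")
  }
  if (eff != "selection" && !is.null(selection)) {
    stop("selection settings are only allowed on selection edges")
  }
  if (eff == "reproduction" && is.null(reproduction)) {
    stop("reproduction edges need reproduction settings")
  }
  if (!is.null(selection)) {
    stopifnot(selection$criterion %in% CRITERIA)
    if (is.null(selection$n_selected) && is.null(selection$proportion)) {
      stop("selection needs n_selected or proportion")
    }
  }
  list(from = from, to = to, action = action,
       generation_time = generation_time, selection = selection,
       reproduction = reproduction, repeat_count = repeat_count,
       link_action = if (action == "repeat") link_action else NULL)
}

#' Construct a trait set
#'
#' @param traits data.frame with columns `id`, `mean`, `gsd`, `h2`,
#'   `repeatability`, `n_qtl`.
#' @param genetic_correlation,residual_correlation correlation matrices
#'   (default identity).
#' @param indices named list of named weight vectors.
#' @return a [TraitSet-class].
#' @export
newTraitSet <- function(traits, genetic_correlation = NULL,
                        residual_correlation = NULL, indices = list()) {
  k <- nrow(traits)
  if (is.null(genetic_correlation)) genetic_correlation <- diag(k)
  if (is.null(residual_correlation)) residual_correlation <- diag(k)
  dimnames(genetic_correlation) <- list(traits$id, traits$id)
  dimnames(residual_correlation) <- list(traits$id, traits$id)
  indices <- lapply(indices, function(w) {
    v <- unlist(w)
    storage.mode(v) <- "double"
    v
  })
  new("TraitSet", traits = as.data.frame(traits),
      geneticCorrelation = genetic_correlation,
      residualCorrelation = residual_correlation, indices = indices)
}

#' Construct a breeding program
#'
#' @param nodes list of [cohortNode()] lists.
#' @param edges list of [breedingEdge()] lists.
#' @param traits a [TraitSet-class].
#' @param culling list of rules: `list(housing_class =, age =, survival =)`.
#' @param subpopulations list of `list(label =, frequencies = | freq_rule =)`.
#' @param economy list: `interest_rate`, `costs` (named: genotyping,
#'   phenotyping, housing (named by class), fixed).
#' @param general list: `species`, `scale`, `litter_size`, `map`.
#' @return a [BreedingProgram-class].
#' @export
breedingProgram <- function(nodes, edges, traits, culling = list(),
                            subpopulations = list(), economy = list(),
                            general = list()) {
  general <- modifyList(list(species = "generic", scale = 1, litter_size = 1),
                        general)
  new("BreedingProgram", nodes = nodes, edges = edges, traits = traits,
      culling = culling, subpopulations = subpopulations,
      economy = economy, general = general)
}

dropUnknownKeys <- function(x, keep, where) {
  extra <- setdiff(names(x), keep)
  if (length(extra)) {
    warning(sprintf("ignoring unknown key(s) %s in %s",
                    paste(sQuote(extra), collapse = ", "), where),
            call. = FALSE)
    x <- x[intersect(names(x), keep)]
  }
  x
}

#' Parse a JSON breeding-program description
#'
#' Unknown keys are ignored with a warning; missing optional blocks receive
#' documented defaults. Malformed JSON raises a parse error with position
#' information; a node without `id` or `n_individuals` raises a schema error
#' naming the field.
#'
#' @param json_text UTF-8 JSON string, or the path of a JSON file.
#' @return a [BreedingProgram-class].
#' @seealso [serializeProgram()], [validateProgram()]
#' @export
parseProgram <- function(json_text) {
  if (length(json_text) == 1L && !grepl("[{]", json_text) &&
      file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  raw <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  raw <- dropUnknownKeys(raw, c("format_version", "general", "nodes", "edges",
                                "traits", "culling", "subpopulations",
                                "economy"), "program")
  nodes <- lapply(seq_along(raw$nodes), function(i) {
    nd <- dropUnknownKeys(raw$nodes[[i]], NODE_KEYS, sprintf("node %d", i))
    for (f in c("id", "n_individuals")) {
      if (is.null(nd[[f]])) {
        stop(sprintf("schema error: node %d is missing required field '%s'", i, f))
      }
    }
    cohortNode(id = nd$id, n_individuals = nd$n_individuals,
               sex = lget(nd, "sex", "mixed"),
               founder = lget(nd, "founder", FALSE),
               phenotyping_class = lget(nd, "phenotyping_class", list()),
               genotyped_share = lget(nd, "genotyped_share", 0),
               housing_class = lget(nd, "housing_class", "default"),
               time_point = lget(nd, "time_point", 0),
               subpopulation = nd$subpopulation)
  })
  edges <- lapply(seq_along(raw$edges), function(i) {
    ed <- dropUnknownKeys(raw$edges[[i]], EDGE_KEYS, sprintf("edge %d", i))
    for (f in c("from", "to", "action")) {
      if (is.null(ed[[f]])) {
        stop(sprintf("schema error: edge %d is missing required field '%s'", i, f))
      }
    }
    sel <- ed$selection
    if (!is.null(sel)) {
      sel <- dropUnknownKeys(sel, SELECTION_KEYS, sprintf("edge %d selection", i))
      if (!is.null(sel$training)) sel$training <- unlist(sel$training)
    }
    rep_ <- ed$reproduction
    if (!is.null(rep_)) {
      rep_ <- dropUnknownKeys(rep_, REPRODUCTION_KEYS,
                              sprintf("edge %d reproduction", i))
    }
    breedingEdge(from = ed$from, to = ed$to, action = ed$action,
                 generation_time = lget(ed, "generation_time", 0),
                 selection = sel, reproduction = rep_,
                 repeat_count = ed$repeat_count, link_action = ed$link_action)
  })
  tr <- raw$traits
  if (is.null(tr) || is.null(tr$defs) || !length(tr$defs)) {
    stop("schema error: program is missing required block 'traits.defs'")
  }
  defs <- do.call(rbind, lapply(tr$defs, function(d) {
    data.frame(id = d$id, mean = lget(d, "mean", 0), gsd = d$gsd,
               h2 = d$h2, repeatability = lget(d, "repeatability", d$h2),
               n_qtl = as.integer(lget(d, "n_qtl", 100)),
               stringsAsFactors = FALSE)
  }))
  asMatrix <- function(m) {
    if (is.null(m)) return(NULL)
    do.call(rbind, lapply(m, unlist))
  }
  traits <- newTraitSet(defs, asMatrix(tr$genetic_correlation),
                        asMatrix(tr$residual_correlation),
                        lget(tr, "indices", list()))
  breedingProgram(nodes = nodes, edges = edges, traits = traits,
                  culling = lget(raw, "culling", list()),
                  subpopulations = lget(raw, "subpopulations", list()),
                  economy = lget(raw, "economy", list()),
                  general = lget(raw, "general", list()))
}

# Recursively sort object keys and drop NULL / empty-optional entries so that
# structurally equal programs serialize byte-identically.
canonicalize <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, TRUE)]
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

#' Serialize a breeding program to canonical JSON
#'
#' Keys are sorted, optional empty blocks dropped and numbers written at full
#' precision, so `parseProgram(serializeProgram(p))` is the identity and two
#' structurally equal programs serialize byte-identically.
#'
#' @param program a [BreedingProgram-class].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
serializeProgram <- function(program, path = NULL) {
  stopifnot(is(program, "BreedingProgram"))
  ts <- program@traits
  obj <- list(
    format_version = FORMAT_VERSION,
    general = program@general,
    nodes = program@nodes,
    edges = program@edges,
    traits = list(
      defs = lapply(seq_len(nrow(ts@traits)), function(i) as.list(ts@traits[i, ])),
      # rows/columns in trait-definition order as plain arrays, so canonical
      # key sorting cannot scramble them
      genetic_correlation = lapply(seq_len(nrow(ts@geneticCorrelation)),
                                   function(i) unname(ts@geneticCorrelation[i, ])),
      residual_correlation = lapply(seq_len(nrow(ts@residualCorrelation)),
                                    function(i) unname(ts@residualCorrelation[i, ])),
      indices = lapply(ts@indices, as.list)
    ),
    culling = program@culling,
    subpopulations = program@subpopulations,
    economy = program@economy
  )
  for (opt in c("culling", "subpopulations", "economy")) {
    if (!length(obj[[opt]])) obj[[opt]] <- NULL
  }
  if (!length(obj$traits$indices)) obj$traits$indices <- NULL
  txt <- as.character(jsonlite::toJSON(canonicalize(obj), auto_unbox = TRUE,
                                       digits = NA, null = "null", pretty = TRUE))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Test two programs for structural equality
#'
#' @param a,b [BreedingProgram-class] objects.
#' @return logical.
#' @export
programEquals <- function(a, b) {
  identical(serializeProgram(a), serializeProgram(b))
}

edgeLabel <- function(e) sprintf("%s->%s", e$from, e$to)

# Effective action of an edge once repeat links are instantiated.
effectiveAction <- function(e) if (e$action == "repeat") e$link_action else e$action

#' Validate a breeding program
#'
#' Performs structural checks and returns all findings in a report; it never
#' raises. Detected errors include cycles in the non-repeat subgraph, dangling
#' edge endpoints, selection counts exceeding the source cohort, founder nodes
#' with incoming non-repeat edges, repeat edges whose cycle can never close,
#' conflicting repeat counts within one cycle region, and references to
#' undefined traits or training cohorts. A program with an empty error table
#' can be expanded and scheduled.
#'
#' @param program a [BreedingProgram-class].
#' @return a [ValidationReport-class].
#' @export
validateProgram <- function(program) {
  errs <- list()
  warns <- list()
  addErr <- function(code, where, message) {
    errs[[length(errs) + 1L]] <<- data.frame(code = code, where = where,
                                             message = message)
  }
  addWarn <- function(code, where, message) {
    warns[[length(warns) + 1L]] <<- data.frame(code = code, where = where,
                                               message = message)
  }
  ids <- nodeIds(program)
  nById <- setNames(vapply(program@nodes, function(n) n$n_individuals, 1L), ids)
  traitIds <- program@traits@traits$id

  for (nd in program@nodes) {
    bad <- setdiff(names(nd$phenotyping_class), traitIds)
    if (length(bad)) {
      addErr("UNDEFINED_TRAIT", nd$id,
             sprintf("phenotyping_class references undefined trait(s): %s",
                     paste(bad, collapse = ", ")))
    }
    if (!is.null(nd$subpopulation) && !isTRUE(nd$founder)) {
      addWarn("SUBPOP_NON_FOUNDER", nd$id,
              "subpopulation label on a non-founder node is ignored")
    }
  }
  for (nm in names(program@traits@indices)) {
    bad <- setdiff(names(program@traits@indices[[nm]]), traitIds)
    if (length(bad)) {
      addErr("UNDEFINED_TRAIT", nm,
             sprintf("index '%s' references undefined trait(s): %s", nm,
                     paste(bad, collapse = ", ")))
    }
  }

  for (e in program@edges) {
    for (endp in c(e$from, e$to)) {
      if (!endp %in% ids) {
        addErr("DANGLING", edgeLabel(e),
               sprintf("edge endpoint '%s' is not a node", endp))
      }
    }
    sel <- e$selection
    if (!is.null(sel)) {
      if (!is.null(sel$n_selected) && e$from %in% ids &&
          sel$n_selected > nById[[e$from]]) {
        addErr("SELECTION_EXCEEDS_SOURCE", edgeLabel(e),
               sprintf("selecting %d from node '%s' of size %d",
                       sel$n_selected, e$from, nById[[e$from]]))
      }
      for (tc in sel$training) {
        if (!sub("@-?[0-9]+$", "", tc) %in% ids) {
          addErr("TRAINING_UNKNOWN_NODE", edgeLabel(e),
                 sprintf("training cohort '%s' is not a node", tc))
        }
      }
      if (!is.null(sel$index) && !sel$index %in% names(program@traits@indices)) {
        addErr("UNDEFINED_INDEX", edgeLabel(e),
               sprintf("selection index '%s' is not defined", sel$index))
      }
    }
    if (effectiveAction(e) == "reproduction") {
      sp <- e$reproduction$second_parent
      if (!is.null(sp) && !sp %in% ids) {
        addErr("DANGLING", edgeLabel(e),
               sprintf("second parent node '%s' is not a node", sp))
      }
    }
  }

  nonRepeat <- Filter(function(e) e$action != "repeat", program@edges)
  for (e in nonRepeat) {
    tgt <- program@nodes[[match(e$to, ids)]]
    if (!is.na(match(e$to, ids)) && isTRUE(tgt$founder)) {
      addErr("FOUNDER_INCOMING", edgeLabel(e),
             sprintf("founder node '%s' has an incoming non-repeat edge", e$to))
    }
  }

  cyc <- findCycle(ids, nonRepeat)
  if (!is.null(cyc)) {
    addErr("LOOP", paste(cyc, collapse = "->"),
           "cycle in the non-repeat subgraph; close breeding cycles with repeat edges")
  }

  repEdges <- Filter(function(e) e$action == "repeat", program@edges)
  if (length(repEdges) && is.null(cyc) &&
      !any(vapply(errs, function(d) d$code == "DANGLING", TRUE))) {
    bodies <- lapply(repEdges, function(e) repeatBody(program, e))
    for (i in seq_along(repEdges)) {
      if (!repEdges[[i]]$from %in% bodies[[i]]) {
        addErr("REPEAT_UNREACHABLE", edgeLabel(repEdges[[i]]),
               "repeat origin is not reachable from the repeat target; the cycle can never close")
      }
    }
    grp <- mergeRegions(ids, program@edges, repEdges, bodies)
    regions <- lapply(grp, function(g) unique(unlist(bodies[g])))
    gCounts <- vapply(grp, function(g) repEdges[[g[1L]]]$repeat_count, 1L)
    for (cf in repeatConflicts(regions, gCounts)) {
      addErr("REPEAT_COUNT_MISMATCH",
             paste(vapply(repEdges[unlist(grp[cf])], edgeLabel, ""),
                   collapse = ", "),
             sprintf("repeat edges of one cycle region disagree on counts: %s",
                     paste(gCounts[cf], collapse = ", ")))
    }
  }

  emptyRep <- data.frame(code = character(), where = character(),
                         message = character())
  new("ValidationReport",
      errors = if (length(errs)) do.call(rbind, errs) else emptyRep,
      warnings = if (length(warns)) do.call(rbind, warns) else emptyRep)
}
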