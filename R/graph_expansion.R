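# Repeat-edge resolution and generation scheduling.
#
# A repeat edge declares that the breeding cycle it closes is carried out
# `repeat_count` times. Expansion unrolls the cycle region into serial copies
# suffixed "_1", "_2", ...; each repeat edge is instantiated as a concrete
# action edge (aging by default) from its origin in copy k to its target in
# copy k+1. Several repeat edges may close the same cycle (e.g. aging of
# calves, selection of replacements and reproduction of the nucleus all
# crossing into the next cycle); their bodies are merged into one region and
# unrolled together.

# Depth-first cycle detection; returns one cycle as a node-id vector or NULL.
findCycle <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (e in edges) {
    if (e$from %in% ids && e$to %in% ids) adj[[e$from]] <- c(adj[[e$from]], e$to)
  }
  state <- setNames(rep(0L, length(ids)), ids)  # 0 new, 1 on stack, 2 done
  cycle <- NULL
  visit <- function(v, path) {
    if (!is.null(cycle)) return()
    state[v] <<- 1L
    for (w in adj[[v]]) {
      if (state[w] == 1L) {
        i <- match(w, path)
        cycle <<- c(path[i:length(path)], w)
        return()
      }
      if (state[w] == 0L) visit(w, c(path, w))
      if (!is.null(cycle)) return()
    }
    state[v] <<- 2L
  }
  for (v in ids) if (state[v] == 0L) visit(v, v)
  cycle
}

# Forward reachability over an adjacency list.
reachableFrom <- function(start, adj) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# Adjacency treating repeat edges as ordinary from->to links, plus implicit
# second-parent links for reproduction. `skip` drops one edge; `count`
# restricts the repeat edges considered to those with that repeat count
# (repeat edges of a different count belong to another -- possibly nested --
# cycle level and must not leak into this body).
fullAdjacency <- function(ids, edges, skip = NULL, count = NULL) {
  adj <- setNames(vector("list", length(ids)), ids)
  add <- function(a, b) if (a %in% ids && b %in% ids) adj[[a]] <<- c(adj[[a]], b)
  for (e in edges) {
    if (!is.null(skip) && identical(e, skip)) next
    if (!is.null(count) && e$action == "repeat" && e$repeat_count != count) next
    add(e$from, e$to)
    if (effectiveAction(e) == "reproduction" &&
        !is.null(e$reproduction$second_parent)) {
      add(e$reproduction$second_parent, e$to)
    }
  }
  adj
}

# Body of a repeat edge: nodes on a path target => N => origin, with all other
# repeat edges (and second-parent links) treated as ordinary edges.
repeatBody <- function(program, e) {
  ids <- nodeIds(program)
  adj <- fullAdjacency(ids, program@edges, skip = e, count = e$repeat_count)
  fromTarget <- reachableFrom(e$to, adj)
  radj <- setNames(vector("list", length(ids)), ids)
  for (a in ids) for (b in adj[[a]]) radj[[b]] <- c(radj[[b]], a)
  toOrigin <- reachableFrom(e$from, radj)
  intersect(fromTarget, toOrigin)
}

# Group repeat edges with EQUAL counts whose bodies overlap or are joined by
# any edge; unequal-count overlaps are left separate (nested regions are
# expanded innermost-first, equal-region overlaps are a validation error).
mergeRegions <- function(ids, edges, repEdges, bodies) {
  n <- length(repEdges)
  if (!n) return(list())
  counts <- vapply(repEdges, function(e) e$repeat_count, 1L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) parent[find(i)] <<- find(j)
  touches <- function(bi, bj) {
    if (length(intersect(bi, bj))) return(TRUE)
    for (e in edges) {
      if ((e$from %in% bi && e$to %in% bj) || (e$from %in% bj && e$to %in% bi)) {
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (counts[i] == counts[j] && touches(bodies[[i]], bodies[[j]])) {
        union2(i, j)
      }
    }
  }
  split(seq_len(n), vapply(seq_len(n), find, 1L))
}

# Conflicting repeat groups: overlapping regions with different counts where
# neither region strictly contains the other.
repeatConflicts <- function(regions, counts) {
  out <- list()
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i >= j || counts[[i]] == counts[[j]]) next
      if (!length(intersect(regions[[i]], regions[[j]]))) next
      iInJ <- all(regions[[i]] %in% regions[[j]]) &&
        length(regions[[i]]) < length(regions[[j]])
      jInI <- all(regions[[j]] %in% regions[[i]]) &&
        length(regions[[j]]) < length(regions[[i]])
      if (!iInJ && !jInI) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

# Rewrite a node reference inside an unrolled region for copy k.
# "X" -> "X_k" if X is in the region; "X@-l" -> copy max(1, k-l).
rewriteRef <- function(ref, region, k) {
  m <- regmatches(ref, regexec("^(.*)@(-?[0-9]+)$", ref))[[1]]
  if (length(m)) {
    base <- m[2]
    lag <- -as.integer(m[3])
    if (base %in% region) return(sprintf("%s_%d", base, max(1L, k - lag)))
    return(base)
  }
  if (ref %in% region) sprintf("%s_%d", ref, k) else ref
}

rewriteEdgeRefs <- function(e, region, k) {
  if (!is.null(e$selection)) {
    if (!is.null(e$selection$training)) {
      e$selection$training <- vapply(e$selection$training, rewriteRef, "",
                                     region = region, k = k, USE.NAMES = FALSE)
    }
  }
  if (!is.null(e$reproduction) && !is.null(e$reproduction$second_parent)) {
    e$reproduction$second_parent <- rewriteRef(e$reproduction$second_parent,
                                               region, k)
  }
  e
}

#' Unroll repeat edges into an explicit repeat-free program
#'
#' Iteratively detects cycle regions closed by repeat edges, duplicates each
#' region once per repeat count (copies suffixed `"_1"`, `"_2"`, ...), wires
#' copy k's repeat origins to copy k+1's repeat targets with the repeat edge's
#' link action, and repeats until no repeat edges remain. Nested repeats are
#' resolved innermost-first; regions whose repeat counts disagree or whose
#' cycle can never close raise an expansion error. A repeat-free program is
#' returned unchanged (up to provenance bookkeeping).
#'
#' @param program a [BreedingProgram-class]; must validate without errors.
#' @param check set `FALSE` to skip re-running [validateProgram()].
#' @return an [ExpandedProgram-class].
#' @export
resolveRepeats <- function(program, check = TRUE) {
  if (check) {
    rep_ <- validateProgram(program)
    if (!isValid(rep_)) {
      stop("program has validation errors; fix them before expansion:\n",
           paste(sprintf("  %s [%s]: %s", rep_@errors$code, rep_@errors$where,
                         rep_@errors$message), collapse = "\n"))
    }
  }
  nodes <- program@nodes
  edges <- program@edges
  prov <- setNames(lapply(nodes, function(n) list(origin = n$id, k = 0L)),
                   nodeIds(program))

  repeat {
    isRep <- vapply(edges, function(e) e$action == "repeat", TRUE)
    if (!any(isRep)) break
    cur <- breedingProgram(nodes, edges, program@traits,
                           general = program@general)
    repEdges <- edges[isRep]
    bodies <- lapply(repEdges, function(e) repeatBody(cur, e))
    for (i in seq_along(repEdges)) {
      if (!repEdges[[i]]$from %in% bodies[[i]]) {
        stop(sprintf("expansion error: repeat edge %s can never close its cycle",
                     edgeLabel(repEdges[[i]])))
      }
    }
    ids <- nodeIds(cur)
    groups <- mergeRegions(ids, edges, repEdges, bodies)
    regions <- lapply(groups, function(g) unique(unlist(bodies[g])))
    gCounts <- vapply(groups, function(g) repEdges[[g[1L]]]$repeat_count, 1L)
    if (length(repeatConflicts(regions, gCounts))) {
      stop(sprintf("expansion error: repeat counts disagree within one cycle region (%s)",
                   paste(sort(unique(gCounts)), collapse = ", ")))
    }
    # Innermost-first: defer a group whose region strictly contains another's.
    ready <- NULL
    for (gi in seq_along(groups)) {
      contains <- any(vapply(seq_along(groups), function(gj) {
        gj != gi && all(regions[[gj]] %in% regions[[gi]]) &&
          length(regions[[gj]]) < length(regions[[gi]])
      }, TRUE))
      if (!contains) { ready <- gi; break }
    }
    if (is.null(ready)) {
      stop("expansion error: mutually nested repeat regions cannot be resolved")
    }
    g <- groups[[ready]]
    region <- regions[[ready]]
    r <- gCounts[[ready]]
    inGroup <- function(e) {
      e$action == "repeat" && any(vapply(repEdges[g], identical, TRUE, x = e))
    }

    newNodes <- list()
    for (nd in nodes) {
      if (!nd$id %in% region) {
        newNodes[[length(newNodes) + 1L]] <- nd
        next
      }
      for (k in seq_len(r)) {
        cp <- nd
        cp$id <- sprintf("%s_%d", nd$id, k)
        if (k > 1L) cp$founder <- FALSE
        old <- prov[[nd$id]]
        prov[[cp$id]] <- list(origin = old$origin, k = k)
        newNodes[[length(newNodes) + 1L]] <- cp
      }
      prov[[nd$id]] <- NULL
    }

    newEdges <- list()
    push <- function(e) newEdges[[length(newEdges) + 1L]] <<- e
    for (e in edges) {
      fin <- e$from %in% region
      tin <- e$to %in% region
      if (inGroup(e)) {
        for (k in seq_len(r - 1L)) {
          le <- e
          le$action <- e$link_action
          le$link_action <- NULL
          le$repeat_count <- NULL
          le$from <- sprintf("%s_%d", e$from, k)
          le$to <- sprintf("%s_%d", e$to, k + 1L)
          push(rewriteEdgeRefs(le, region, k))
        }
      } else if (fin && tin) {
        for (k in seq_len(r)) {
          ce <- e
          ce$from <- sprintf("%s_%d", e$from, k)
          ce$to <- sprintf("%s_%d", e$to, k)
          push(rewriteEdgeRefs(ce, region, k))
        }
      } else if (!fin && tin) {
        ce <- e
        ce$to <- sprintf("%s_1", e$to)
        push(rewriteEdgeRefs(ce, region, 1L))
      } else if (fin && !tin) {
        ce <- e
        ce$from <- sprintf("%s_%d", e$from, r)
        push(rewriteEdgeRefs(ce, region, r))
      } else {
        push(e)
      }
    }
    nodes <- newNodes
    edges <- newEdges
  }

  provDf <- do.call(rbind, lapply(names(prov), function(id) {
    data.frame(node = id, origin = prov[[id]]$origin,
               repeat_index = prov[[id]]$k, stringsAsFactors = FALSE)
  }))
  new("ExpandedProgram", nodes = nodes, edges = edges,
      provenance = provDf, program = program)
}

#' Derive the total generation order of an expanded program
#'
#' The simulated time of a node is the maximum over its incoming edges of the
#' source time plus the edge's generation time (founder nodes use their own
#' `time_point`). Cohorts referenced as breeding-value training sets count as
#' dependencies of the selection target. The order is a topological order
#' refined by simulated time, with ties broken lexicographically by node id.
#'
#' @param expanded an [ExpandedProgram-class].
#' @return data.frame with columns `node` and `time`, in generation order.
#' @export
scheduleGeneration <- function(expanded) {
  ids <- nodeIds(expanded)
  byId <- setNames(expanded@nodes, ids)
  # dependency list: (from, to, gen_time); training deps carry time 0
  deps <- list()
  for (e in expanded@edges) {
    deps[[length(deps) + 1L]] <- list(from = e$from, to = e$to,
                                      dt = e$generation_time)
    if (!is.null(e$selection$training)) {
      for (tc in e$selection$training) {
        deps[[length(deps) + 1L]] <- list(from = tc, to = e$to, dt = 0)
      }
    }
    if (effectiveAction(e) == "reproduction" &&
        !is.null(e$reproduction$second_parent)) {
      deps[[length(deps) + 1L]] <- list(from = e$reproduction$second_parent,
                                        to = e$to, dt = e$generation_time)
    }
  }
  deps <- Filter(function(d) d$from %in% ids && d$to %in% ids, deps)
  indeg <- setNames(rep(0L, length(ids)), ids)
  for (d in deps) indeg[d$to] <- indeg[d$to] + 1L
  time <- setNames(vapply(expanded@nodes, function(n) n$time_point, 0), ids)
  pend <- indeg
  order_ <- character(0)
  avail <- ids[pend == 0L]
  while (length(avail)) {
    v <- avail[order(time[avail], avail)][1L]
    order_ <- c(order_, v)
    avail <- setdiff(avail, v)
    for (d in deps) {
      if (d$from == v) {
        time[d$to] <- max(time[d$to], time[v] + d$dt)
        pend[d$to] <- pend[d$to] - 1L
        if (pend[d$to] == 0L) avail <- c(avail, d$to)
      }
    }
  }
  if (length(order_) < length(ids)) {
    stuck <- setdiff(ids, order_)
    stop(sprintf("scheduling error: dependency cycle among nodes: %s",
                 paste(stuck, collapse = ", ")))
  }
  data.frame(node = order_, time = unname(time[order_]),
             stringsAsFactors = FALSE)
}
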