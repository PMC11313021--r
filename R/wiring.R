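#' The dummy neighbor sentinel used in wiring entries
#'
#' Degree-one vertices are wired against a dummy contig on their missing
#' side; this constant is the id used for that placeholder.
#' @export
wiring_dummy <- function() DUMMY

#' Wire a single vertex
#'
#' Selects the pair of edges incident on a contig vertex through which a
#' path may run. Degree one: the sole edge is paired with a dummy contig
#' (shared support 0). Degree two: the unique incident pair is wired
#' unconditionally — a chain vertex has one predecessor and one successor
#' and there is nothing to choose; its shared support may be 0. Degree
#' three or more (a branching vertex): pairs are ranked by the shared link
#' set `|L_i` intersect `L_j|` (reads supporting a through-path), then by
#' the combined edge support `|L_i| + |L_j|` (which prefers the two
#' strongest direct junctions over weak long-range edges), then
#' lexicographically; the top pair is wired only if it strictly beats the
#' runner-up on the first two criteria — a branch whose best pair is
#' ambiguous carries no usable routing evidence and is left unwired, so
#' walks reaching it terminate there.
#'
#' @param vertex contig id of the vertex being wired.
#' @param incident named list: neighbor id -> link set (character vector of
#'   read ids) of the connecting edge.
#' @return a list with elements `vertex`, `left`, `right`, `shared_support`,
#'   or NULL if the vertex is left unwired. `left` is [wiring_dummy()] for
#'   degree-one vertices.
#' @export
wire_vertex <- function(vertex, incident) {
  stopifnot(length(incident) >= 1, !is.null(names(incident)))
  nbs <- sort(names(incident))
  if (length(nbs) == 1) {
    return(list(vertex = vertex, left = DUMMY, right = nbs[1],
                shared_support = 0L))
  }
  best <- NULL
  second <- NULL # runner-up score, for the ambiguity terminator
  for (i in seq_len(length(nbs) - 1)) {
    for (j in seq(i + 1, length(nbs))) {
      a <- nbs[i]; b <- nbs[j]
      shared <- length(intersect(incident[[a]], incident[[b]]))
      total <- length(incident[[a]]) + length(incident[[b]])
      # nbs is sorted, so (a, b) is already the canonical pair order and
      # iteration is lexicographic: strict improvement only.
      if (is.null(best) || shared > best$shared ||
          (shared == best$shared && total > best$total)) {
        second <- best
        best <- list(a = a, b = b, shared = shared, total = total)
      } else if (is.null(second) || shared > second$shared ||
                 (shared == second$shared && total > second$total)) {
        second <- list(a = a, b = b, shared = shared, total = total)
      }
    }
  }
  if (length(nbs) >= 3 && !is.null(second) &&
      second$shared == best$shared && second$total == best$total)
    return(NULL)
  list(vertex = vertex, left = best$a, right = best$b,
       shared_support = as.integer(best$shared))
}

vertex_pair_scores <- function(incident) {
  nbs <- sort(names(incident))
  rows <- list()
  for (i in seq_len(length(nbs) - 1)) {
    for (j in seq(i + 1, length(nbs))) {
      rows[[length(rows) + 1L]] <- data.frame(
        a = nbs[i], b = nbs[j],
        shared = length(intersect(incident[[nbs[i]]], incident[[nbs[j]]])),
        total = length(incident[[nbs[i]]]) + length(incident[[nbs[j]]]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[order(-df$shared, -df$total, df$a, df$b), , drop = FALSE]
}

# Estimate on which side of vertex sequence `c_seq` a neighbor lies, and the
# gap between them, by placing both on a linking read (frame normalized to
# the vertex's forward strand). Majority side over up to 3 linking reads.
edge_side_gap <- function(c_seq, n_seq, rids, reads, params) {
  sides <- integer(0); gaps <- numeric(0)
  len_c <- nchar(c_seq); len_n <- nchar(n_seq)
  for (rid in head(sort(rids), 3)) {
    r <- reads[[rid]]
    if (is.null(r) || is.na(r)) next
    cc <- chain_anchors(r, c_seq, params$anchor_k, params$min_anchors,
                        params$band)
    cn <- chain_anchors(r, n_seq, params$anchor_k, params$min_anchors,
                        params$band)
    if (is.null(cc) || is.null(cn)) next
    len_r <- nchar(r)
    if (cc$strand == "-") {
      au <- len_r - (cc$read_start + len_c)
      av <- len_r - (cn$read_start + len_n)
    } else {
      au <- cc$read_start
      av <- cn$read_start
    }
    if (av == au) next
    if (av > au) {
      sides <- c(sides, 1L); gaps <- c(gaps, av - (au + len_c))
    } else {
      sides <- c(sides, -1L); gaps <- c(gaps, au - (av + len_n))
    }
  }
  if (length(sides) == 0 || sum(sides) == 0) return(NULL)
  s <- sign(sum(sides))
  list(side = s, gap = stats::median(gaps[sides == s]))
}

# Break a top-score tie at a branching vertex with read-anchor geometry:
# admissible pairs place their two neighbors on opposite sides of the
# vertex; among those, the pair with the smallest estimated gaps wins.
arbitrate_tie <- function(v, incident, scores, graph, sources, reads,
                          params) {
  top <- scores[scores$shared == scores$shared[1] &
                  scores$total == scores$total[1], , drop = FALSE]
  nbs <- unique(c(top$a, top$b))
  geo <- lapply(setNames(nbs, nbs), function(n)
    edge_side_gap(source_sequence(sources[[v]]),
                  source_sequence(sources[[n]]),
                  graph$edges[[edge_key(v, n)]], reads, params))
  best <- NULL
  for (i in seq_len(nrow(top))) {
    ga <- geo[[top$a[i]]]; gb <- geo[[top$b[i]]]
    if (is.null(ga) || is.null(gb)) next
    if (ga$side * gb$side != -1) next
    cost <- abs(ga$gap) + abs(gb$gap) # large overlaps are as suspect as
                                      # large gaps
    if (is.null(best) || cost < best$cost)
      best <- list(a = top$a[i], b = top$b[i], cost = cost,
                   shared = top$shared[i])
  }
  if (is.null(best)) return(NULL)
  list(vertex = v, left = best$a, right = best$b,
       shared_support = as.integer(best$shared))
}

#' Wire every vertex of a contig graph
#'
#' Applies [wire_vertex()] independently to every non-isolated vertex;
#' isolated vertices get no entry. The result does not depend on vertex
#' processing order. When `sources` and `reads` are supplied, a branching
#' vertex whose top pair ties on the link-set criteria — which
#' [wire_vertex()] alone would leave unwired — is arbitrated geometrically:
#' each tied neighbor is placed on a linking read together with the vertex,
#' admissible pairs must flank the vertex on opposite sides, and the pair
#' with the smallest estimated gaps is wired. Vertices with no admissible
#' pair stay unwired.
#'
#' @param graph a [contig_graph()].
#' @param sources optional named list/vector of vertex sequences (contigs
#'   or scaffold records) enabling geometric tie arbitration.
#' @param reads optional named character vector of linking-read sequences.
#' @param params a [stitch_params()] (anchor parameters for arbitration).
#' @return named list: vertex id -> wiring entry (vertices left unwired are
#'   absent).
#' @export
wire_graph <- function(graph, sources = NULL, reads = NULL,
                       params = stitch_params()) {
  out <- list()
  for (v in names(graph$vertices)) {
    if (graph_degree(graph, v) == 0) next
    incident <- incident_link_sets(graph, v)
    ent <- wire_vertex(v, incident)
    if (is.null(ent) && length(incident) >= 3 && !is.null(sources) &&
        !is.null(reads)) {
      ent <- arbitrate_tie(v, incident, vertex_pair_scores(incident), graph,
                           sources, reads, params)
    }
    if (!is.null(ent)) out[[v]] <- ent
  }
  out
}

new_path <- function(steps, start_reason, end_reason) {
  # normalize whole-path reversal: lexicographically smaller terminal first
  if (length(steps) > 1 && steps[length(steps)] < steps[1]) {
    steps <- rev(steps)
    tmp <- start_reason; start_reason <- end_reason; end_reason <- tmp
  }
  list(steps = steps, orientations = rep("?", length(steps)),
       start_reason = start_reason, end_reason = end_reason)
}

#' Owned steps of a path
#'
#' A terminal step appended because the walk hit a vertex wired to a
#' different predecessor, an already-visited vertex, or an unwired branch
#' vertex belongs to another path (or to its own singleton); such "borrowed"
#' terminals are excluded here so that every contig is owned by exactly one
#' path. All other steps are owned.
#'
#' @param path a path from [enumerate_paths()].
#' @return character vector of owned contig ids, in path order.
#' @export
path_owned_steps <- function(path) {
  borrowed <- c("foreign_predecessor", "visited", "no_wire")
  steps <- path$steps
  if (length(steps) >= 2 && path$end_reason %in% borrowed)
    steps <- steps[-length(steps)]
  if (length(steps) >= 2 && path$start_reason %in% borrowed)
    steps <- steps[-1]
  steps
}

#' Enumerate maximal edge-disjoint acyclic paths from a wired graph
#'
#' Paths are grown from a work queue of degree-one vertices (processed in
#' sorted id order unless `queue_order` overrides it). At each vertex the
#' walk follows the vertex's wiring entry only if that entry pairs the
#' arrival edge with a departure edge. Termination: (a) reaching a vertex
#' whose wiring chose a different predecessor appends that vertex and stops;
#' (b) reaching an already-visited vertex appends it and stops (unless it is
#' a step of the current path itself — the pure-cycle closure — in which
#' case nothing is appended, keeping paths acyclic); (c) reaching a
#' degree-one vertex appends it and stops; reaching an unwired branch vertex
#' appends it and stops. After the queue drains, each still-unvisited wired
#' vertex (a pure-cycle component) seeds a new path from its smallest id.
#' Isolated vertices, and unwired vertices never reached by a walk, are
#' emitted as singleton paths so that no contig is dropped.
#'
#' The output is invariant to `queue_order` (up to whole-path reversal,
#' which is normalized away), no two paths share an edge, and no path
#' revisits a vertex.
#'
#' @param graph a [contig_graph()].
#' @param wiring wiring map from [wire_graph()] on the same graph.
#' @param queue_order optional character vector permuting the degree-one
#'   work queue (must be a permutation of it).
#' @return list of paths; each path has `steps`, `orientations` (all `"?"`;
#'   orientations are assigned during stitching), `start_reason` and
#'   `end_reason`.
#' @export
enumerate_paths <- function(graph, wiring, queue_order = NULL) {
  for (v in names(wiring)) {
    ent <- wiring[[v]]
    nbs <- graph$adjacency[[v]]
    ok <- (ent$left == DUMMY || ent$left %in% nbs) && ent$right %in% nbs
    if (!ok) stop("wiring entry at ", v, " names a non-neighbor")
  }
  visited <- new.env(parent = emptyenv())
  is_visited <- function(v) isTRUE(visited[[v]])
  paths <- list()

  walk <- function(start, first_next, start_reason) {
    steps <- start
    assign(start, TRUE, envir = visited)
    prev <- start
    cur <- first_next
    end_reason <- NULL
    repeat {
      if (is_visited(cur)) {
        if (cur %in% steps) {
          # pure-cycle closure onto this walk's own start: appending would
          # re-create the cycle, so stop one edge short
          end_reason <- "cycle_seed"
        } else {
          steps <- c(steps, cur)
          end_reason <- "visited"
        }
        break
      }
      if (graph_degree(graph, cur) == 1) {
        steps <- c(steps, cur)
        assign(cur, TRUE, envir = visited)
        end_reason <- "degree_one"
        break
      }
      ent <- wiring[[cur]]
      if (is.null(ent)) {
        steps <- c(steps, cur)
        end_reason <- "no_wire"
        break
      }
      nxt <- if (identical(ent$left, prev)) ent$right
             else if (identical(ent$right, prev)) ent$left
             else NA_character_
      if (is.na(nxt)) {
        steps <- c(steps, cur)
        end_reason <- "foreign_predecessor"
        break
      }
      steps <- c(steps, cur)
      assign(cur, TRUE, envir = visited)
      prev <- cur
      cur <- nxt
    }
    new_path(steps, start_reason, end_reason)
  }

  queue <- sort(names(graph$vertices)[
    vapply(names(graph$vertices), function(v) graph_degree(graph, v) == 1,
           logical(1))])
  if (!is.null(queue_order)) {
    if (!setequal(queue_order, queue))
      stop("queue_order must be a permutation of the degree-one vertices")
    queue <- queue_order
  }
  for (v in queue) {
    if (is_visited(v)) next
    paths[[length(paths) + 1L]] <-
      walk(v, graph$adjacency[[v]][1], "degree_one")
  }

  # pure-cycle components: no degree-one vertex feeds the queue, so seed
  # them from their smallest-id wired vertex (canonical regardless of
  # queue_order, preserving determinism of the output set)
  repeat {
    left <- sort(setdiff(names(wiring),
                         ls(envir = visited)))
    left <- left[!vapply(left, is_visited, logical(1))]
    if (length(left) == 0) break
    s <- left[1]
    ent <- wiring[[s]]
    first <- min(ent$left, ent$right)
    paths[[length(paths) + 1L]] <- walk(s, first, "cycle_seed")
  }

  # isolated vertices and unwired vertices never reached by any walk
  for (v in sort(names(graph$vertices))) {
    if (is_visited(v)) next
    if (graph_degree(graph, v) == 0) {
      paths[[length(paths) + 1L]] <- new_path(v, "no_wire", "no_wire")
      assign(v, TRUE, envir = visited)
    } else if (is.null(wiring[[v]])) {
      paths[[length(paths) + 1L]] <- new_path(v, "no_wire", "no_wire")
      assign(v, TRUE, envir = visited)
    }
  }
  paths
}

#' Edges traversed by a path
#'
#' @param path a path from [enumerate_paths()].
#' @return character vector of edge keys (consecutive step pairs).
#' @keywords internal
path_edges <- function(path) {
  s <- path$steps
  if (length(s) < 2) return(character(0))
  edge_key(s[-length(s)], s[-1])
}

#' Normalize a path set for comparison
#'
#' Unordered set of step vectors, each normalized for whole-path reversal;
#' used to compare enumeration runs under permuted processing orders.
#'
#' @param paths list of paths.
#' @return sorted character vector, one collapsed string per path.
#' @export
normalize_path_set <- function(paths) {
  sort(vapply(paths, function(p) {
    s <- p$steps
    r <- rev(s)
    if (paste(r, collapse = ",") < paste(s, collapse = ",")) s <- r
    paste(s, collapse = ",")
  }, character(1)))
}
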