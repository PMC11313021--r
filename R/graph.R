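EDGE_SEP <- "\x1f"

edge_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = EDGE_SEP), paste(b, a, sep = EDGE_SEP))
}

edge_key_split <- function(key) strsplit(key, EDGE_SEP, fixed = TRUE)[[1]]

#' Construct a contig graph
#'
#' @param vertices named numeric vector: contig id -> length in bp.
#' @param edges named list: edge key -> character vector of linking read ids
#'   (the edge's link set). Use [build_contig_graph()] to build from a
#'   mapping table.
#' @return object of class `contig_graph`.
#' @export
contig_graph <- function(vertices, edges = list()) {
  stopifnot(!is.null(names(vertices)), !anyDuplicated(names(vertices)))
  structure(list(vertices = vertices, edges = edges,
                 adjacency = build_adjacency(names(vertices), edges)),
            class = "contig_graph")
}

build_adjacency <- function(vertex_ids, edges) {
  adj <- setNames(vector("list", length(vertex_ids)), vertex_ids)
  for (key in names(edges)) {
    ends <- edge_key_split(key)
    adj[[ends[1]]] <- c(adj[[ends[1]]], ends[2])
    adj[[ends[2]]] <- c(adj[[ends[2]]], ends[1])
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("<contig_graph: %d vertices, %d edges, total support %d>\n",
              length(x$vertices), length(x$edges),
              sum(lengths(x$edges))))
  invisible(x)
}

#' Build the contig graph from a mapping table
#'
#' Mapping tuples are grouped by read id; every unordered pair of distinct
#' contigs mapped by one read contributes that read id to the pair's link
#' set (once per edge, regardless of how many end/rank tuples produced the
#' pair). Reads whose tuples all hit the same contig create no edge. All
#' contigs in `contig_lengths` become vertices, so unmapped contigs are kept
#' as isolated vertices.
#'
#' @param mapping mapping table (see [mapping_table()]).
#' @param contig_lengths named numeric vector of contig lengths.
#' @return a [contig_graph()].
#' @export
build_contig_graph <- function(mapping, contig_lengths) {
  unknown <- setdiff(unique(mapping$contig_id), names(contig_lengths))
  if (length(unknown))
    stop("mapping references unknown contig id: ",
         paste(unknown, collapse = ", "))
  keys <- character(0)
  rids <- character(0)
  if (nrow(mapping)) {
    by_read <- split(mapping$contig_id, mapping$read_id)
    for (rid in names(by_read)) {
      contigs <- sort(unique(by_read[[rid]]))
      if (length(contigs) < 2) next
      pairs <- utils::combn(contigs, 2)
      pk <- edge_key(pairs[1, ], pairs[2, ])
      keys <- c(keys, pk)
      rids <- c(rids, rep(rid, length(pk)))
    }
  }
  edge_list <- lapply(split(rids, keys), function(x) sort(unique(x)))
  edge_list <- edge_list[sort(names(edge_list))]
  contig_graph(contig_lengths, edge_list)
}

#' Filter graph edges by support
#'
#' Removes edges whose support (link-set size) is below `min_support`;
#' vertices are always retained.
#'
#' @param graph a [contig_graph()].
#' @param min_support minimum number of linking reads (>= 1).
#' @return a [contig_graph()].
#' @export
filter_edges <- function(graph, min_support = 1) {
  stopifnot(min_support >= 1)
  keep <- lengths(graph$edges) >= min_support
  contig_graph(graph$vertices, graph$edges[keep])
}

#' Transitive reduction of a contig graph
#'
#' Long reads spanning an entire short contig link the contigs on either
#' side of it directly, adding a "skip" edge that parallels the two-step
#' chain through the middle contig. Such edges inflate vertex degrees and
#' mislead the wiring heuristic. This routine removes them the way string
#' graphs are reduced: edges are visited weakest support first (ties broken
#' by edge key) and an edge is dropped when its endpoints are still
#' connected through a common neighbor by two surviving edges. True chain
#' edges survive because their parallel long-range edges are weaker and are
#' removed before them.
#'
#' @param graph a [contig_graph()].
#' @return a [contig_graph()] with reducible edges removed.
#' @export
reduce_transitive <- function(graph) {
  keys <- names(graph$edges)
  if (length(keys) < 3) return(graph)
  ord <- order(lengths(graph$edges), keys)
  alive <- setNames(rep(TRUE, length(keys)), keys)
  adj <- graph$adjacency
  for (key in keys[ord]) {
    ends <- edge_key_split(key)
    common <- intersect(adj[[ends[1]]], adj[[ends[2]]])
    common <- setdiff(common, ends)
    if (length(common) == 0) next
    reducible <- any(vapply(common, function(b) {
      alive[[edge_key(ends[1], b)]] && alive[[edge_key(b, ends[2])]]
    }, logical(1)))
    if (reducible) {
      alive[[key]] <- FALSE
      adj[[ends[1]]] <- setdiff(adj[[ends[1]]], ends[2])
      adj[[ends[2]]] <- setdiff(adj[[ends[2]]], ends[1])
    }
  }
  contig_graph(graph$vertices, graph$edges[names(alive)[alive]])
}

#' Edge support values
#'
#' @param graph a [contig_graph()].
#' @return named integer vector: edge key -> number of linking reads.
#' @export
edge_support <- function(graph) {
  setNames(as.integer(lengths(graph$edges)), names(graph$edges))
}

graph_degree <- function(graph, v) length(graph$adjacency[[v]])

incident_link_sets <- function(graph, v) {
  nbs <- graph$adjacency[[v]]
  setNames(lapply(nbs, function(u) graph$edges[[edge_key(v, u)]]), nbs)
}
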