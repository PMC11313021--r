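# Shared test fixtures: graph builders, random corpora, and an independent
# brute-force wiring oracle. Everything is generated in code under fixed
# seeds; no data files.

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Build a contig_graph from a list of edges, each list(a, b, reads).
graph_from_edges <- function(edges, extra_vertices = character(0),
                             lengths = NULL) {
  ids <- sort(unique(c(unlist(lapply(edges, function(e) c(e[[1]], e[[2]]))),
                       extra_vertices)))
  if (is.null(lengths)) lengths <- setNames(rep(5000, length(ids)), ids)
  el <- list()
  for (e in edges) {
    key <- contigwire:::edge_key(e[[1]], e[[2]])
    el[[key]] <- sort(unique(c(el[[key]], e[[3]])))
  }
  contig_graph(lengths, el[sort(names(el))])
}

# Random graphs mixing planted chains, branches and cycles with random link
# sets; the corpus used by the path-property tests.
random_link_graph <- function(seed, max_vertices = 60) {
  withr::with_seed(seed, {
    nv <- sample(4:max_vertices, 1)
    ids <- sprintf("v%03d", seq_len(nv))
    edges <- list()
    rpool <- sprintf("r%04d", 1:500)
    add_edge <- function(a, b) {
      list(a, b, sample(rpool, sample(1:6, 1)))
    }
    # a backbone chain
    for (i in seq_len(nv - 1)) {
      if (runif(1) < 0.85) edges[[length(edges) + 1]] <-
          add_edge(ids[i], ids[i + 1])
    }
    # random branches
    n_extra <- rpois(1, nv / 5)
    for (k in seq_len(n_extra)) {
      ab <- sample(ids, 2)
      edges[[length(edges) + 1]] <- add_edge(ab[1], ab[2])
    }
    # occasionally close a cycle
    if (runif(1) < 0.4 && nv >= 6) {
      i <- sample(seq_len(nv - 3), 1)
      edges[[length(edges) + 1]] <- add_edge(ids[i], ids[i + 3])
    }
    graph_from_edges(edges, extra_vertices = ids)
  })
}

# Independent oracle for wire_vertex: exhaustive scoring with explicit
# sorting, written against the documented rule set rather than sharing code
# with the implementation.
brute_force_wire <- function(vertex, incident) {
  nbs <- names(incident)
  if (length(nbs) == 1)
    return(list(vertex = vertex, left = contigwire::wiring_dummy(),
                right = sort(nbs), shared_support = 0L))
  pairs <- t(utils::combn(sort(nbs), 2))
  score <- data.frame(a = pairs[, 1], b = pairs[, 2],
                      shared = NA_integer_, total = NA_integer_)
  for (i in seq_len(nrow(score))) {
    la <- incident[[score$a[i]]]
    lb <- incident[[score$b[i]]]
    score$shared[i] <- sum(la %in% lb)
    score$total[i] <- length(la) + length(lb)
  }
  score <- score[order(-score$shared, -score$total, score$a, score$b), ]
  if (length(nbs) >= 3 && nrow(score) >= 2 &&
      score$shared[1] == score$shared[2] &&
      score$total[1] == score$total[2]) return(NULL)
  list(vertex = vertex, left = score$a[1], right = score$b[1],
       shared_support = as.integer(score$shared[1]))
}

# Random wire_vertex inputs for oracle comparisons.
random_incident <- function(seed, max_neighbors = 8) {
  withr::with_seed(seed, {
    k <- sample(1:max_neighbors, 1)
    nbs <- sprintf("n%02d", sample(1:50, k))
    rpool <- sprintf("r%03d", 1:40)
    setNames(lapply(seq_len(k), function(i) sample(rpool, sample(1:8, 1))),
             nbs)
  })
}

# All edges used by a path set (for edge-disjointness checks), as a vector
# with one entry per traversed edge.
all_path_edges <- function(paths) {
  unlist(lapply(paths, contigwire:::path_edges))
}

# Cached study-conditions fixture run, shared by the acceptance tests.
fixture_cache <- new.env(parent = emptyenv())
get_fixture_run <- function() {
  if (is.null(fixture_cache$run)) {
    ds <- simulate_scaffolding_dataset(seed = 1)
    res <- run_pipeline(ds$contigs, ds$reads)
    fixture_cache$run <- list(ds = ds, res = res,
                              truth = rbind(ds$truth_contigs,
                                            ds$truth_reads))
  }
  fixture_cache$run
}
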