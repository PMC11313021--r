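test_that("wire_vertex picks the pair with the largest shared link set", {
  # brute force over the 3 pairs: |{r2}| = 1 beats the two empty ones
  ent <- wire_vertex("c", list(a = c("r1", "r2"), b = c("r2", "r3"),
                               d = "r4"))
  expect_identical(ent$left, "a")
  expect_identical(ent$right, "b")
  expect_identical(ent$shared_support, 1L)
})

test_that("degree-one vertices wire against the dummy contig", {
  ent <- wire_vertex("c", list(a = "r1"))
  expect_identical(ent$left, wiring_dummy())
  expect_identical(ent$right, "a")
  expect_identical(ent$shared_support, 0L)
})

test_that("degree-two vertices wire their unique pair even without shared reads", {
  # a chain vertex has exactly one predecessor and one successor; there is
  # nothing to choose, so the pair is wired with shared support 0
  ent <- wire_vertex("c", list(a = "r1", b = "r2"))
  expect_identical(c(ent$left, ent$right), c("a", "b"))
  expect_identical(ent$shared_support, 0L)
})

test_that("an ambiguous branching vertex stays unwired", {
  # four pairwise-disjoint equal-sized link sets: every pair ties
  expect_null(wire_vertex("c", list(a = "r1", b = "r2", d = "r3", e = "r4")))
  # clear combined-support winner among shared-0 pairs wires
  ent <- wire_vertex("c", list(a = c("r1", "r2", "r3"),
                               b = c("r4", "r5", "r6"), d = "r7"))
  expect_identical(c(ent$left, ent$right), c("a", "b"))
})

test_that("wire_vertex agrees with the exhaustive brute-force oracle", {
  for (seed in 1:300) {
    inc <- random_incident(seed)
    got <- wire_vertex("c", inc)
    want <- brute_force_wire("c", inc)
    if (is.null(want)) {
      expect_null(got, label = paste("seed", seed))
    } else {
      expect_identical(got[c("left", "right", "shared_support")],
                       want[c("left", "right", "shared_support")],
                       label = paste("seed", seed))
    }
  }
})

test_that("wire_graph wires chains and leaves ambiguous stars unwired", {
  expect_identical(wire_graph(contig_graph(c(a = 1))), list())
  chain <- graph_from_edges(list(list("a", "b", "r1"), list("b", "c", "r1")))
  W <- wire_graph(chain)
  expect_identical(c(W$b$left, W$b$right), c("a", "c"))
  expect_identical(W$b$shared_support, 1L)
  expect_identical(W$a$left, wiring_dummy())
  expect_identical(W$c$left, wiring_dummy())
  star <- graph_from_edges(list(list("s", "a", "r1"), list("s", "b", "r2"),
                                list("s", "d", "r3"), list("s", "e", "r4")))
  Ws <- wire_graph(star)
  expect_null(Ws$s)
  expect_identical(length(Ws), 4L) # the four leaves are dummy-wired
})

test_that("a fully wired chain enumerates as a single path", {
  chain <- graph_from_edges(list(list("a", "b", "r1"), list("b", "c", "r1")))
  paths <- enumerate_paths(chain, wire_graph(chain))
  expect_length(paths, 1)
  expect_identical(paths[[1]]$steps, c("a", "b", "c"))
  expect_identical(paths[[1]]$start_reason, "degree_one")
  expect_identical(paths[[1]]$end_reason, "degree_one")
})

test_that("walks truncate at vertices wired to a different predecessor", {
  # at b the (c, g) pair shares r2 and out-ranks pairs involving a, so a
  # path arriving from a appends b and stops; a second path runs through b
  g <- graph_from_edges(list(list("a", "b", "r1"),
                             list("b", "c", c("r2", "r3")),
                             list("b", "g", c("r2", "r4"))))
  W <- wire_graph(g)
  expect_setequal(c(W$b$left, W$b$right), c("c", "g"))
  paths <- enumerate_paths(g, W)
  norm <- normalize_path_set(paths)
  expect_true("a,b" %in% norm)
  expect_true("c,b,g" %in% norm)
  # b is interior exactly once; the edge sets of the two paths are disjoint
  edges <- all_path_edges(paths)
  expect_identical(anyDuplicated(edges), 0L)
})

test_that("a consistently wired triangle yields one acyclic path, one edge unused", {
  tri <- graph_from_edges(list(list("a", "b", "r1"), list("b", "c", "r1"),
                               list("a", "c", "r1")))
  W <- wire_graph(tri)
  paths <- enumerate_paths(tri, W)
  expect_length(paths, 1)
  expect_identical(sort(paths[[1]]$steps), c("a", "b", "c"))
  expect_length(contigwire:::path_edges(paths[[1]]), 2)
  expect_identical(anyDuplicated(paths[[1]]$steps), 0L)
})

test_that("unwired and isolated vertices emit singleton paths", {
  g <- graph_from_edges(list(list("s", "a", "r1"), list("s", "b", "r2"),
                             list("s", "d", "r3"), list("s", "e", "r4")),
                        extra_vertices = "lonely")
  paths <- enumerate_paths(g, wire_graph(g))
  singles <- vapply(paths, function(p) length(p$steps) == 1, logical(1))
  expect_setequal(unlist(lapply(paths[singles], `[[`, "steps")),
                  c("s", "lonely"))
  # every vertex appears among owned steps exactly once
  owned <- unlist(lapply(paths, path_owned_steps))
  expect_setequal(owned, names(g$vertices))
  expect_identical(anyDuplicated(owned), 0L)
})

test_that("borrowed terminals are excluded from owned steps", {
  p <- list(steps = c("a", "b", "x"), orientations = rep("?", 3),
            start_reason = "degree_one", end_reason = "visited")
  expect_identical(path_owned_steps(p), c("a", "b"))
  rev_p <- list(steps = c("x", "b", "a"), orientations = rep("?", 3),
                start_reason = "foreign_predecessor",
                end_reason = "degree_one")
  expect_identical(path_owned_steps(rev_p), c("b", "a"))
  single <- list(steps = "a", orientations = "?",
                 start_reason = "no_wire", end_reason = "no_wire")
  expect_identical(path_owned_steps(single), "a")
})

test_that("wiring entries naming non-neighbors are rejected", {
  chain <- graph_from_edges(list(list("a", "b", "r1")))
  W <- list(a = list(vertex = "a", left = wiring_dummy(), right = "zzz",
                     shared_support = 0L))
  expect_error(enumerate_paths(chain, W), "non-neighbor")
})

test_that("paths are edge-disjoint and acyclic over a random corpus", {
  for (seed in 1:40) {
    g <- random_link_graph(seed)
    paths <- enumerate_paths(g, wire_graph(g))
    edges <- all_path_edges(paths)
    expect_identical(anyDuplicated(edges), 0L, label = paste("seed", seed))
    for (p in paths) {
      interior <- p$steps
      expect_identical(anyDuplicated(interior), 0L,
                       label = paste("seed", seed))
    }
    # ownership covers every vertex exactly once
    owned <- unlist(lapply(paths, path_owned_steps))
    expect_setequal(owned, names(g$vertices))
    expect_identical(anyDuplicated(owned), 0L)
  }
})

test_that("enumeration output is invariant to queue processing order", {
  for (seed in 1:15) {
    g <- random_link_graph(seed)
    W <- wire_graph(g)
    ref <- normalize_path_set(enumerate_paths(g, W))
    queue <- sort(names(g$vertices)[vapply(names(g$vertices), function(v)
      length(g$adjacency[[v]]) == 1, logical(1))])
    withr::with_seed(seed + 1000, {
      for (k in 1:5) {
        perm <- sample(queue)
        expect_identical(normalize_path_set(enumerate_paths(g, W, perm)),
                         ref, label = paste("seed", seed, "perm", k))
      }
    })
  }
})

test_that("geometric arbitration resolves ties using linking reads", {
  # genome layout L - C - R; vertex C ties between pairs because all link
  # sets are disjoint singletons; placements on the linking reads identify
  # L and R as flanking C on opposite sides
  genome <- rand_dna(30000, seed = 91)
  sources <- list(L = substr(genome, 1, 9000),
                  C = substr(genome, 9501, 18000),
                  R = substr(genome, 18501, 28000),
                  X = rand_dna(8000, seed = 92))
  reads <- c(rl = substr(genome, 5000, 14999),  # spans L-C junction
             rr = substr(genome, 14000, 23999), # spans C-R junction
             rx = paste0(substr(genome, 12000, 15999),
                         substr(sources$X, 1, 4000))) # chimeric C-X link
  g <- graph_from_edges(list(list("C", "L", "rl"), list("C", "R", "rr"),
                             list("C", "X", "rx")))
  expect_null(wire_vertex("C", contigwire:::incident_link_sets(g, "C")))
  W <- wire_graph(g, sources = sources, reads = reads)
  expect_identical(sort(c(W$C$left, W$C$right)), c("L", "R"))
})
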