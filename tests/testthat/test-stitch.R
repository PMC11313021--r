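mk_path <- function(steps, start = "degree_one", end = "degree_one") {
  list(steps = steps, orientations = rep("?", length(steps)),
       start_reason = start, end_reason = end)
}

test_that("batch partitioning is greedy first-fit by descending size", {
  paths <- c(lapply(1:10, function(i) mk_path(sprintf("c%d_%d", i, 1:3))))
  b <- partition_batches(paths, 8192)
  expect_length(b, 1)
  # sizes 5, 4, 3 with capacity 6: no two fit together
  p5 <- mk_path(sprintf("a%d", 1:5))
  p4 <- mk_path(sprintf("b%d", 1:4))
  p3 <- mk_path(sprintf("d%d", 1:3))
  b2 <- partition_batches(list(p3, p5, p4), 6)
  expect_length(b2, 3)
  expect_identical(lengths(lapply(b2, `[[`, "paths")), rep(1L, 3))
  # sizes 4, 3, 3 with capacity 6: the two 3s share the second batch
  b3 <- partition_batches(list(mk_path(sprintf("a%d", 1:4)),
                               mk_path(sprintf("b%d", 1:3)),
                               mk_path(sprintf("d%d", 1:3))), 6)
  expect_length(b3, 2)
  # an oversize path still gets its own batch
  b4 <- partition_batches(list(mk_path(sprintf("x%d", 1:10))), 4)
  expect_length(b4, 1)
  expect_length(b4[[1]]$paths[[1]]$steps, 10)
  expect_length(partition_batches(list(), 10), 0)
})

test_that("batching conserves the multiset of paths", {
  withr::with_seed(55, {
    paths <- lapply(1:30, function(i)
      mk_path(sprintf("p%02d_%d", i, seq_len(sample(1:12, 1)))))
  })
  b <- partition_batches(paths, 10)
  flat <- unlist(lapply(b, function(x)
    lapply(x$paths, function(p) paste(p$steps, collapse = ","))))
  expect_setequal(flat, vapply(paths, function(p)
    paste(p$steps, collapse = ","), character(1)))
  expect_length(flat, length(paths))
})

test_that("batch read sets are unions over the batch's contigs", {
  m <- mapping_table(c("r1", "r2", "r3"), rep("5p", 3), c("A", "A", "B"),
                     rep(0.9, 3), rep(1L, 3))
  b <- list(paths = list(mk_path("A")), batch_id = 1L)
  expect_identical(collect_batch_reads(b, m), c("r1", "r2"))
  b2 <- list(paths = list(mk_path(c("A", "B"))), batch_id = 2L)
  expect_identical(collect_batch_reads(b2, m), c("r1", "r2", "r3"))
  # a read bridging contigs placed in two different batches appears in both
  m3 <- mapping_table(c("rb", "rb"), c("5p", "3p"), c("A", "B"),
                      c(0.9, 0.9), c(1L, 1L))
  expect_true("rb" %in% collect_batch_reads(b, m3))
  expect_true("rb" %in% collect_batch_reads(list(paths = list(mk_path("B")),
                                                 batch_id = 3L), m3))
})

test_that("anchor chains recover embedded placements and strands", {
  read <- rand_dna(9000, seed = 61)
  contig <- substr(read, 501, 4500)
  ch <- chain_anchors(read, contig)
  expect_identical(ch$strand, "+")
  expect_identical(ch$read_start, 500)
  expect_gte(ch$n_anchors, 5)
  ch2 <- chain_anchors(read, revcomp(contig))
  expect_identical(ch2$strand, "-")
  expect_identical(ch2$read_start, 500)
  expect_null(chain_anchors(rand_dna(5000, seed = 62),
                            rand_dna(3000, seed = 63)))
})

test_that("a single-contig path passes the contig through unchanged", {
  ctg <- c(A = rand_dna(4000, seed = 64))
  sc <- stitch_path(mk_path("A"), as.list(ctg), id = "s1")
  expect_length(sc, 1)
  expect_identical(sc[[1]]$sequence, ctg[["A"]])
  expect_identical(sc[[1]]$components$component_id, "A")
  expect_identical(sc[[1]]$components$orientation, "+")
})

test_that("two adjacent contigs stitch into the exact genome substring", {
  genome <- rand_dna(30000, seed = 65)
  contigs <- list(A = substr(genome, 1001, 9000),
                  B = substr(genome, 9011, 17000)) # 10 bp true gap
  read <- substr(genome, 5001, 15000)              # spans the junction
  sc <- stitch_path(mk_path(c("A", "B")), contigs,
                    linking_reads = setNames(list("r1"),
                                             contigwire:::edge_key("A", "B")),
                    reads = c(r1 = read), id = "s")
  expect_length(sc, 1)
  expect_identical(sc[[1]]$sequence, substr(genome, 1001, 17000))
  expect_identical(sc[[1]]$components$component_id, c("A", "r1", "B"))
  # gap-filling read component carries its source coordinates
  expect_equal(sc[[1]]$components$end[2] - sc[[1]]$components$start[2], 10)
})

test_that("reverse-oriented paths stitch through frame flipping", {
  genome <- rand_dna(30000, seed = 66)
  contigs <- list(A = revcomp(substr(genome, 1001, 9000)), # stored reversed
                  B = substr(genome, 9011, 17000))
  read <- substr(genome, 5001, 15000)
  sc <- stitch_path(mk_path(c("A", "B")), contigs,
                    setNames(list("r1"), contigwire:::edge_key("A", "B")),
                    c(r1 = read), id = "s")
  expect_length(sc, 1)
  got <- sc[[1]]$sequence
  want <- substr(genome, 1001, 17000)
  expect_true(got == want || got == revcomp(want))
})

test_that("junctions without consistent linking reads split or N-join", {
  contigs <- list(A = rand_dna(3000, seed = 67),
                  B = rand_dna(3000, seed = 68))
  # default: split into two scaffolds
  sc <- stitch_path(mk_path(c("A", "B")), contigs, id = "s")
  expect_length(sc, 2)
  expect_identical(sc[[1]]$sequence, contigs$A)
  expect_identical(sc[[2]]$sequence, contigs$B)
  expect_match(sc[[1]]$id, "_s01$")
  # "gap" fallback: single scaffold with the default N run
  scg <- stitch_path(mk_path(c("A", "B")), contigs,
                     params = stitch_params(junction_fallback = "gap"),
                     id = "s")
  expect_length(scg, 1)
  expect_identical(scg[[1]]$sequence,
                   paste0(contigs$A, strrep("N", 100), contigs$B))
  expect_identical(scg[[1]]$components$gap_before, c(0L, 100L))
})

test_that("stitching a missing source is an error", {
  expect_error(stitch_path(mk_path(c("A", "Z")),
                           list(A = rand_dna(1000, seed = 1))),
               "no source sequence")
})

test_that("assemble_batches concatenates per-batch results deterministically", {
  genome <- rand_dna(24000, seed = 69)
  contigs <- c(A = substr(genome, 1, 8000), B = substr(genome, 8021, 16000),
               C = rand_dna(5000, seed = 70))
  reads <- c(r1 = substr(genome, 4001, 14000))
  mapping <- mapping_table(c("r1", "r1"), c("5p", "3p"), c("A", "B"),
                           c(0.9, 0.9), c(1L, 1L))
  batches <- partition_batches(list(mk_path(c("A", "B")), mk_path("C")), 2)
  out <- assemble_batches(batches, as.list(contigs), reads, mapping)
  expect_length(out, 2)
  ids <- vapply(out, function(s) s$id, character(1))
  expect_identical(ids, sort(ids)) # batch-then-path order
  expect_identical(assemble_batches(list(), as.list(contigs), reads,
                                    mapping), list())
  # every contig of every path appears in exactly one component list
  comp <- unlist(lapply(out, function(s) s$components$component_id))
  comp <- comp[comp %in% names(contigs)]
  expect_setequal(comp, names(contigs))
  expect_identical(anyDuplicated(comp), 0L)
})

test_that("scaffold slices of scaffold records flatten to leaf components", {
  genome <- rand_dna(20000, seed = 71)
  inner <- scaffold_record(
    "part1", paste0(substr(genome, 1, 5000), strrep("N", 50),
                    substr(genome, 5051, 9000)),
    data.frame(component_id = c("c1", "c2"), orientation = c("+", "+"),
               start = c(0L, 5050L), end = c(5000L, 9000L),
               source_start = c(0L, 0L), source_end = c(5000L, 3950L),
               gap_before = c(0L, 50L)))
  sc <- stitch_path(mk_path("part1"), list(part1 = inner), id = "outer")
  expect_identical(sc[[1]]$components$component_id, c("c1", "c2"))
  expect_identical(sc[[1]]$sequence, inner$sequence)
})
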