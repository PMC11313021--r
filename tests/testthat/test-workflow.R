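# Workflow tests run on reduced problem sizes (50-80 kb genomes, low-ish
# coverage) to keep the suite fast; the full study conditions are exercised
# by the acceptance tests.

small_dataset <- function(seed = 101, genome_length = 60000, ...) {
  simulate_scaffolding_dataset(genome_length = genome_length,
                               repeats = list(), seed = seed, ...)
}

test_that("contig expansion grows N50 and conserves contigs", {
  ds <- small_dataset()
  p1 <- phase_contig_expansion(ds$contigs, ds$reads, cw_config())
  expect_gt(p1$report$nx_after, p1$report$nx_before)
  comp <- unlist(lapply(p1$scaffolds, function(s) s$components$component_id))
  comp <- comp[comp %in% names(ds$contigs)]
  expect_setequal(comp, names(ds$contigs))
  expect_identical(anyDuplicated(comp), 0L)
  expect_true(all(p1$used_read_ids %in% names(ds$reads)))
  expect_error(phase_contig_expansion(character(0), ds$reads), "contigs")
})

test_that("reads unrelated to the contigs pass contigs through unchanged", {
  ds <- small_dataset(seed = 102)
  other <- simulate_long_reads(simulate_genome(30000, seed = 555)$sequence,
                               coverage = 2, seed = 556)
  expect_warning(p1 <- phase_contig_expansion(ds$contigs, other$reads,
                                              cw_config()),
                 "no reads mapped")
  expect_identical(length(p1$scaffolds), length(ds$contigs))
  expect_identical(sort(unname(scaffold_sequences(p1$scaffolds))),
                   sort(unname(ds$contigs)))
  expect_length(p1$used_read_ids, 0)
})

test_that("two unlinked contig clusters give at least two scaffolds", {
  g1 <- simulate_genome(40000, seed = 103)
  g2 <- simulate_genome(40000, seed = 104)
  c1 <- shred_to_contigs(g1$sequence, seed = 105)
  c2 <- shred_to_contigs(g2$sequence, seed = 106)
  contigs <- c(setNames(c1$contigs, paste0("g1_", names(c1$contigs))),
               setNames(c2$contigs, paste0("g2_", names(c2$contigs))))
  r1 <- simulate_long_reads(g1$sequence, coverage = 8, seed = 107)
  r2 <- simulate_long_reads(g2$sequence, coverage = 8, seed = 108)
  reads <- c(setNames(r1$reads, paste0("g1_", names(r1$reads))),
             setNames(r2$reads, paste0("g2_", names(r2$reads))))
  p1 <- phase_contig_expansion(contigs, reads, cw_config())
  expect_gte(length(p1$scaffolds), 2)
  # no scaffold mixes contigs from the two genomes
  for (s in p1$scaffolds) {
    src <- substr(s$components$component_id, 1, 2)
    expect_identical(length(unique(src[src %in% c("g1", "g2")])), 1L)
  }
})

test_that("islands form only from reads that map nowhere", {
  ds <- small_dataset(seed = 109)
  p1 <- phase_contig_expansion(ds$contigs, ds$reads, cw_config())
  unused <- ds$reads[!(names(ds$reads) %in% p1$used_read_ids)]
  p2 <- phase_longread_islands(unused, p1$scaffolds, cw_config())
  expect_true(length(p2$scaffolds) == 0 ||
                all(lengths(lapply(p2$scaffolds, function(s)
                  s$components$component_id)) >= 1))
  # no unused reads at all -> no islands
  p2b <- phase_longread_islands(ds$reads[0], p1$scaffolds, cw_config())
  expect_length(p2b$scaffolds, 0)
  expect_length(p2b$used_read_ids, 0)
})

test_that("a contig-free region is recovered by island scaffolds", {
  ds <- simulate_scaffolding_dataset(genome_length = 80000, repeats = list(),
                                     drop_region = c(30000, 50000),
                                     seed = 110)
  res <- run_pipeline(ds$contigs, ds$reads)
  expect_gt(length(res$gen2), 0)
  pl <- place_components(res$gen2, rbind(ds$truth_contigs, ds$truth_reads))
  hits <- vapply(split(pl, pl$scaffold_id), function(d)
    min(d$genome_start) < 50000 && max(d$genome_end) > 30000, logical(1))
  expect_gt(sum(hits), 0)
})

test_that("bridging without reads passes partials through", {
  ds <- small_dataset(seed = 111)
  p1 <- phase_contig_expansion(ds$contigs, ds$reads, cw_config())
  p3 <- phase_link_bridges(p1$scaffolds, ds$reads[0], cw_config())
  expect_identical(length(p3$scaffolds), length(p1$scaffolds))
  expect_length(p3$used_read_ids, 0)
  expect_error(phase_link_bridges(list(), ds$reads), "partial")
})

test_that("bridging only merges: final scaffold count never grows", {
  ds <- small_dataset(seed = 112)
  p1 <- phase_contig_expansion(ds$contigs, ds$reads, cw_config())
  p3 <- phase_link_bridges(p1$scaffolds, ds$reads, cw_config())
  expect_lte(length(p3$scaffolds), length(p1$scaffolds))
})

test_that("the pipeline is deterministic and writes its artifacts", {
  ds <- small_dataset(seed = 113, coverage = 8)
  wd <- withr::local_tempdir()
  res1 <- run_pipeline(ds$contigs, ds$reads, workdir = wd)
  res2 <- run_pipeline(ds$contigs, ds$reads)
  expect_identical(scaffold_sequences(res1$final),
                   scaffold_sequences(res2$final))
  for (f in c("mapping.tsv", "graph.gfa", "paths.txt", "scaffolds.fa",
              "scaffolds.agp", "report.json"))
    expect_true(file.exists(file.path(wd, f)), label = f)
  back <- read_sequences(file.path(wd, "scaffolds.fa"))
  expect_identical(unname(as.character(back)),
                   unname(scaffold_sequences(res1$final)))
  # AGP + component sources reconstruct the scaffold FASTA
  rec <- reconstruct_from_agp(file.path(wd, "scaffolds.agp"),
                              c(ds$contigs, ds$reads))
  orig <- scaffold_sequences(res1$final)
  expect_identical(unname(rec[names(orig)]), unname(orig))
})

test_that("pipeline inputs can be file paths", {
  ds <- small_dataset(seed = 114, coverage = 5)
  fa <- withr::local_tempfile(fileext = ".fa")
  fr <- withr::local_tempfile(fileext = ".fa")
  write_sequences(ds$contigs, fa)
  write_sequences(ds$reads, fr)
  res <- run_pipeline(fa, fr)
  res2 <- run_pipeline(ds$contigs, ds$reads)
  expect_identical(scaffold_sequences(res$final),
                   scaffold_sequences(res2$final))
})

test_that("phase switches disable islands and bridges", {
  ds <- small_dataset(seed = 115, coverage = 5)
  res <- run_pipeline(ds$contigs, ds$reads,
                      cw_config(islands = FALSE, bridges = FALSE))
  expect_length(res$gen2, 0)
  expect_identical(res$reports$phase, "expansion")
  expect_identical(length(res$final) - sum(grepl("^singleton_",
    vapply(res$final, function(s) s$id, character(1)))),
    length(res$gen1))
})

test_that("per-phase used-read sets are pairwise disjoint", {
  ds <- simulate_scaffolding_dataset(genome_length = 80000, repeats = list(),
                                     drop_region = c(30000, 50000),
                                     seed = 116)
  res <- run_pipeline(ds$contigs, ds$reads)
  u <- res$used_read_ids
  expect_length(intersect(u$expansion, u$islands), 0)
  expect_length(intersect(u$expansion, u$bridges), 0)
  expect_length(intersect(u$islands, u$bridges), 0)
  expect_true(all(unlist(u) %in% names(ds$reads)))
})

test_that("YAML configuration round-trips through read_config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mapper:", "  k: 13", "  tau: 0.25", "graph:",
               "  min_support: 2", "  reduce: false", "scaffold:",
               "  gap_default: 50", "phases:", "  islands: false",
               "seed: 7"), f)
  cfg <- read_config(f)
  expect_identical(cfg$mapper$k, 13L)
  expect_identical(cfg$mapper$tau, 0.25)
  expect_identical(cfg$min_support, 2L)
  expect_false(cfg$reduce)
  expect_identical(cfg$scaffold$gap_default, 50L)
  expect_false(cfg$islands)
  expect_true(cfg$bridges)
  expect_identical(cfg$seed, 7L)
})
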