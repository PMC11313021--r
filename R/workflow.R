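#' Pipeline configuration
#'
#' Bundles the mapper, graph and stitcher settings together with phase
#' switches. Defaults are the package's reference study conditions.
#'
#' @param mapper a [mapper_params()].
#' @param min_support minimum edge support retained in the contig graph.
#' @param reduce apply [reduce_transitive()] to the contig graph before
#'   wiring (recommended whenever reads are long relative to contigs).
#' @param scaffold a [stitch_params()].
#' @param islands run the long-read island phase.
#' @param bridges run the bridge-linking phase.
#' @param bridge_reads `"all"` (default): the bridge phase queries every
#'   input read not consumed into an island — junction-spanning reads whose
#'   ends straddled a contig boundary in phase 1 map cleanly to the longer
#'   partial-scaffold flanks and give missed junctions a second chance;
#'   `"unused"`: only reads left over from earlier phases are queried.
#' @param bridge_rounds maximum number of bridge iterations. While partial
#'   scaffolds are shorter than the reads, reads span across whole partials
#'   and direct junction edges are sparse; each round lengthens the
#'   partials, and once they exceed the read length junction evidence
#'   becomes dense, so iterating the identical bridge machinery converges.
#'   The loop stops early as soon as a round merges nothing.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic given the mapper salt; the seed is applied to the RNG at
#'   entry for any downstream consumer).
#' @return a `cw_config` list.
#' @export
cw_config <- function(mapper = mapper_params(), min_support = 1,
                      reduce = TRUE, scaffold = stitch_params(),
                      islands = TRUE, bridges = TRUE,
                      bridge_reads = c("all", "unused"), bridge_rounds = 4,
                      seed = 42) {
  bridge_reads <- match.arg(bridge_reads)
  stopifnot(inherits(mapper, "mapper_params"),
            inherits(scaffold, "stitch_params"), min_support >= 1,
            bridge_rounds >= 1)
  structure(list(mapper = mapper, min_support = as.integer(min_support),
                 reduce = isTRUE(reduce), scaffold = scaffold,
                 islands = isTRUE(islands), bridges = isTRUE(bridges),
                 bridge_reads = bridge_reads,
                 bridge_rounds = as.integer(bridge_rounds),
                 seed = as.integer(seed)),
            class = "cw_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror [cw_config()]: `mapper.{k,w,trials,end_len,tau,
#' top_n,salt}`, `graph.min_support`, `scaffold.{batch_size,anchor_k,
#' min_anchors,gap_default,band}`, `phases.{islands,bridges}`, `seed`.
#' Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `cw_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(lst, defaults) {
    args <- as.list(defaults)
    for (nm in intersect(names(lst), names(args))) args[[nm]] <- lst[[nm]]
    args
  }
  mp <- do.call(mapper_params,
                take(y$mapper, formals(mapper_params)))
  sp <- do.call(stitch_params,
                take(y$scaffold, formals(stitch_params)))
  cw_config(mapper = mp,
            min_support = if (!is.null(y$graph$min_support))
              y$graph$min_support else 1,
            reduce = if (!is.null(y$graph$reduce)) y$graph$reduce else TRUE,
            scaffold = sp,
            islands = if (!is.null(y$phases$islands)) y$phases$islands
                      else TRUE,
            bridges = if (!is.null(y$phases$bridges)) y$phases$bridges
                      else TRUE,
            seed = if (!is.null(y$seed)) y$seed else 42)
}

phase_report <- function(phase, n_subjects, n_reads_in, n_reads_used,
                         n_scaffolds_out, nx_before, nx_after) {
  data.frame(phase = phase, n_subjects = n_subjects,
             n_reads_in = n_reads_in, n_reads_used = n_reads_used,
             n_scaffolds_out = n_scaffolds_out,
             nx_before = nx_before, nx_after = nx_after,
             stringsAsFactors = FALSE)
}

run_wiring_stage <- function(subjects, reads, mapping, config, id_prefix) {
  graph <- build_contig_graph(mapping,
                              setNames(nchar(vapply(subjects,
                                                    source_sequence,
                                                    character(1))),
                                       names(subjects)))
  if (config$min_support > 1) graph <- filter_edges(graph, config$min_support)
  if (config$reduce) graph <- reduce_transitive(graph)
  wiring <- wire_graph(graph, sources = subjects, reads = reads,
                       params = config$scaffold)
  paths <- enumerate_paths(graph, wiring)
  batches <- partition_batches(paths, config$scaffold$batch_size)
  scaffolds <- assemble_batches(batches, subjects, reads, mapping,
                                config$scaffold, id_prefix = id_prefix)
  list(graph = graph, wiring = wiring, paths = paths, batches = batches,
       scaffolds = scaffolds)
}

#' Phase 1: contig expansion
#'
#' Maps long-read ends to contigs, builds the contig graph, wires it,
#' enumerates paths and stitches them into the first generation of partial
#' scaffolds. Reads are considered used when they appear in the link set of
#' any graph edge or map to any contig placed in a scaffold — with every
#' contig placed (conservation), that is every mapped read. Isolated
#' contigs pass through unchanged as singleton scaffolds.
#'
#' @param contigs named character vector of contigs.
#' @param reads named character vector of long reads.
#' @param config a [cw_config()].
#' @return list with `scaffolds`, `used_read_ids`, `mapping`, `graph`,
#'   `paths`, `report`.
#' @export
phase_contig_expansion <- function(contigs, reads, config = cw_config()) {
  if (length(contigs) == 0) stop("contig expansion requires contigs")
  mapping <- map_reads(contigs, reads, config$mapper)
  if (nrow(mapping) == 0)
    warning("no reads mapped to contigs; ",
            "contigs pass through as singleton scaffolds")
  stage <- run_wiring_stage(as.list(contigs), reads, mapping, config,
                            id_prefix = "scaffold")
  used <- unique(mapping$read_id)
  list(scaffolds = stage$scaffolds, used_read_ids = used, mapping = mapping,
       graph = stage$graph, paths = stage$paths,
       report = phase_report("expansion", length(contigs), length(reads),
                             length(used), length(stage$scaffolds),
                             nx_metric(nchar(contigs), sum(nchar(contigs))),
                             nx_metric(nchar(scaffold_sequences(
                               stage$scaffolds)),
                               sum(nchar(contigs)))))
}

#' Phase 2: long-read island construction
#'
#' Reads unused by contig expansion are remapped against the first
#' generation of partial scaffolds; those that map are set aside (they stay
#' available as bridge candidates for phase 3). Reads that remain unmapped
#' fall in gap regions between scaffolds and are assembled into island
#' scaffolds by reusing the whole graph/wiring/stitching machinery with the
#' unmapped reads themselves playing the contig role.
#'
#' @param unused_reads named character vector of reads not used in phase 1.
#' @param gen1 list of phase-1 [scaffold_record()]s.
#' @param config a [cw_config()].
#' @return list with `scaffolds` (gen2 islands), `used_read_ids`,
#'   `remapped_read_ids` (reads that mapped to gen1 and were set aside),
#'   `report`.
#' @export
phase_longread_islands <- function(unused_reads, gen1,
                                   config = cw_config()) {
  nx_in <- if (length(unused_reads)) nx_metric(nchar(unused_reads),
                                               sum(nchar(unused_reads)))
           else 0
  if (length(unused_reads) == 0 ||
      length(gen1) == 0) {
    return(list(scaffolds = list(), used_read_ids = character(0),
                remapped_read_ids = character(0),
                report = phase_report("islands", length(gen1),
                                      length(unused_reads), 0, 0, nx_in, 0)))
  }
  m1 <- map_reads(scaffold_sequences(gen1), unused_reads, config$mapper)
  remapped <- unique(m1$read_id)
  island_reads <- unused_reads[!(names(unused_reads) %in% remapped)]
  if (length(island_reads) == 0) {
    return(list(scaffolds = list(), used_read_ids = character(0),
                remapped_read_ids = remapped,
                report = phase_report("islands", length(gen1),
                                      length(unused_reads), 0, 0, nx_in, 0)))
  }
  m2 <- map_reads(island_reads, island_reads, config$mapper,
                  exclude_self = TRUE)
  stage <- run_wiring_stage(as.list(island_reads), island_reads, m2, config,
                            id_prefix = "island")
  used <- names(island_reads)
  list(scaffolds = stage$scaffolds, used_read_ids = used,
       remapped_read_ids = remapped,
       report = phase_report("islands", length(gen1), length(unused_reads),
                             length(used), length(stage$scaffolds), nx_in,
                             nx_metric(nchar(scaffold_sequences(
                               stage$scaffolds)),
                               max(1, sum(nchar(island_reads))))))
}

is_contained_in <- function(small, big, params) {
  ch <- chain_anchors(big, small, params$anchor_k, params$min_anchors,
                      params$band)
  if (is.null(ch)) return(FALSE)
  margin <- 200
  ch$read_start >= -margin &&
    ch$read_start + nchar(small) <= nchar(big) + margin &&
    ch$n_anchors >= 0.3 * max(1, nchar(small) - params$anchor_k)
}

# Partials whose sequence lies wholly inside another linked partial:
# they duplicate sequence already present and their graph edges create
# spurious branches, so they are excluded from bridging (candidate pairs
# come from the read mapping).
detect_contained_partials <- function(sources, mapping, params) {
  lens <- vapply(sources, function(s) nchar(source_sequence(s)), numeric(1))
  contained <- character(0)
  for (key in names(link_sets_from_mapping(mapping))) {
    ends <- edge_key_split(key)
    p <- if (lens[ends[1]] < lens[ends[2]] ||
             (lens[ends[1]] == lens[ends[2]] && ends[1] > ends[2]))
      ends[1] else ends[2]
    q <- setdiff(ends, p)
    if (p %in% contained) next
    if (is_contained_in(source_sequence(sources[[p]]),
                        source_sequence(sources[[q]]), params))
      contained <- c(contained, p)
  }
  contained
}

#' Phase 3: link partial scaffolds with bridges
#'
#' Reruns the expansion machinery with the union of first- and
#' second-generation partial scaffolds in the contig role and the remaining
#' reads as queries. Partials whose sequence is wholly contained in a
#' linked partial are set aside (they would only duplicate sequence and
#' distort the wiring) and pass through unchanged, as do partials that do
#' not join anything.
#'
#' @param partials list of [scaffold_record()]s (gen1 and gen2).
#' @param remaining_reads named character vector of reads not used by
#'   earlier phases.
#' @param config a [cw_config()].
#' @param id_prefix prefix for newly stitched scaffold ids.
#' @return list with `scaffolds` (final), `used_read_ids`, `report`.
#' @export
phase_link_bridges <- function(partials, remaining_reads,
                               config = cw_config(), id_prefix = "final") {
  if (length(partials) == 0) stop("bridge linking requires partial scaffolds")
  nx_in <- nx_metric(nchar(scaffold_sequences(partials)),
                     sum(nchar(scaffold_sequences(partials))))
  if (length(remaining_reads) == 0) {
    return(list(scaffolds = partials, used_read_ids = character(0),
                report = phase_report("bridges", length(partials), 0, 0,
                                      length(partials), nx_in, nx_in)))
  }
  sources <- setNames(partials,
                      vapply(partials, function(s) s$id, character(1)))
  mapping <- map_reads(scaffold_sequences(partials), remaining_reads,
                       config$mapper)
  contained <- detect_contained_partials(sources, mapping, config$scaffold)
  keep <- setdiff(names(sources), contained)
  mapping_kept <- mapping[!(mapping$contig_id %in% contained), , drop = FALSE]
  stage <- run_wiring_stage(sources[keep], remaining_reads, mapping_kept,
                            config, id_prefix = id_prefix)
  scaffolds <- c(stage$scaffolds, sources[contained])
  used <- unique(mapping_kept$read_id)
  list(scaffolds = scaffolds, used_read_ids = used,
       report = phase_report("bridges", length(partials),
                             length(remaining_reads), length(used),
                             length(scaffolds), nx_in,
                             nx_metric(nchar(scaffold_sequences(scaffolds)),
                               sum(nchar(scaffold_sequences(partials))))))
}

#' Run the full three-phase scaffolding pipeline
#'
#' Contig expansion, long-read island construction (optional) and bridge
#' linking (optional), with read bookkeeping between phases: the used-read
#' sets of the three phases are pairwise disjoint. Given a fixed
#' configuration the pipeline is deterministic, so reruns are byte-identical.
#'
#' @param contigs named character vector of contigs, or a FASTA path.
#' @param reads named character vector of long reads, or a FASTA/FASTQ path.
#' @param config a [cw_config()].
#' @param workdir optional directory; when given, intermediate artifacts
#'   (mapping TSV, GFA, paths file) and final outputs (scaffolds.fa,
#'   scaffolds.agp, report.json) are written there.
#' @return list with `gen1`, `gen2`, `final` (lists of scaffold records),
#'   `reports` (one data.frame row per executed phase), `used_read_ids`
#'   (per-phase list).
#' @export
run_pipeline <- function(contigs, reads, config = cw_config(),
                         workdir = NULL) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- read_sequences(contigs)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_sequences(reads)
  withr::local_seed(config$seed)
  if (!is.null(workdir)) dir.create(workdir, showWarnings = FALSE,
                                    recursive = TRUE)

  p1 <- phase_contig_expansion(contigs, reads, config)
  reports <- p1$report
  unused <- reads[!(names(reads) %in% p1$used_read_ids)]

  if (config$islands) {
    p2 <- phase_longread_islands(unused, p1$scaffolds, config)
    reports <- rbind(reports, p2$report)
    remaining <- unused[!(names(unused) %in% p2$used_read_ids)]
  } else {
    p2 <- list(scaffolds = list(), used_read_ids = character(0))
    remaining <- unused
  }

  partials <- c(p1$scaffolds, p2$scaffolds)
  if (config$bridges) {
    queries <- if (config$bridge_reads == "all")
      reads[!(names(reads) %in% p2$used_read_ids)] else remaining
    p3 <- list(scaffolds = partials, used_read_ids = character(0))
    for (round in seq_len(config$bridge_rounds)) {
      step <- phase_link_bridges(p3$scaffolds, queries, config,
                                 id_prefix = sprintf("final_r%d", round))
      merged <- length(step$scaffolds) < length(p3$scaffolds)
      p3 <- list(scaffolds = step$scaffolds,
                 used_read_ids = union(p3$used_read_ids,
                                       step$used_read_ids))
      reports <- rbind(reports, step$report)
      if (!merged) break
    }
    p3$used_read_ids <- setdiff(p3$used_read_ids,
                                c(p1$used_read_ids, p2$used_read_ids))
  } else {
    p3 <- list(scaffolds = partials, used_read_ids = character(0))
  }

  # conservation: a contig whose component citation was consumed by overlap
  # deduplication during merging (its bases are still present through other
  # components) re-enters as a pass-through singleton scaffold
  cited <- unlist(lapply(p3$scaffolds,
                         function(s) s$components$component_id))
  for (ctg in setdiff(names(contigs), cited)) {
    L <- nchar(contigs[[ctg]])
    p3$scaffolds[[length(p3$scaffolds) + 1L]] <- scaffold_record(
      paste0("singleton_", ctg), contigs[[ctg]],
      data.frame(component_id = ctg, orientation = "+", start = 0L,
                 end = L, source_start = 0L, source_end = L,
                 gap_before = 0L, stringsAsFactors = FALSE))
  }

  if (!is.null(workdir)) {
    write_mapping(p1$mapping, file.path(workdir, "mapping.tsv"))
    write_gfa(p1$graph, file.path(workdir, "graph.gfa"))
    write_paths(p1$paths, file.path(workdir, "paths.txt"))
    write_sequences(scaffold_sequences(p3$scaffolds),
                    file.path(workdir, "scaffolds.fa"))
    write_agp(p3$scaffolds, file.path(workdir, "scaffolds.agp"))
    jsonlite::write_json(reports, file.path(workdir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(gen1 = p1$scaffolds, gen2 = p2$scaffolds, final = p3$scaffolds,
       reports = reports,
       used_read_ids = list(expansion = p1$used_read_ids,
                            islands = p2$used_read_ids,
                            bridges = p3$used_read_ids))
}
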