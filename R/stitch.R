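#' Stitcher parameters
#'
#' @param batch_size maximum contigs per assembly batch (a single oversize
#'   path still forms its own batch).
#' @param anchor_k anchor k-mer length (<= 26).
#' @param min_anchors minimum co-linear shared anchors for a read/contig
#'   placement to be trusted.
#' @param gap_default length of the N run inserted by the `"gap"` junction
#'   fallback.
#' @param band diagonal band width in bp within which anchor seeds are
#'   considered co-linear.
#' @param junction_fallback what to do with a junction for which no linking
#'   read places both contigs consistently: `"split"` (default) ends the
#'   scaffold there — inconsistent placements across all linking reads
#'   signal a spurious adjacency, and an N-join would turn it into a
#'   misjoin; `"gap"` joins across a run of `gap_default` Ns.
#' @return a `stitch_params` list.
#' @export
stitch_params <- function(batch_size = 8192, anchor_k = 21, min_anchors = 5,
                          gap_default = 100, band = 50,
                          junction_fallback = c("split", "gap")) {
  junction_fallback <- match.arg(junction_fallback)
  stopifnot(batch_size >= 1, anchor_k >= 5, anchor_k <= 26, min_anchors >= 1,
            gap_default >= 0, band >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 anchor_k = as.integer(anchor_k),
                 min_anchors = as.integer(min_anchors),
                 gap_default = as.integer(gap_default),
                 band = as.integer(band),
                 junction_fallback = junction_fallback),
            class = "stitch_params")
}

#' Partition paths into fixed-size batches
#'
#' Greedy first-fit over paths in descending length (number of steps):
#' each path goes into the first batch whose remaining capacity holds it, or
#' opens a new batch. A single path longer than `s` gets its own batch.
#' Paths are never split or duplicated.
#'
#' @param paths list of paths (see [enumerate_paths()]).
#' @param s batch capacity in contigs.
#' @return list of batches, each a list with `batch_id`, `paths`.
#' @export
partition_batches <- function(paths, s) {
  stopifnot(s >= 1)
  if (length(paths) == 0) return(list())
  sizes <- vapply(paths, function(p) length(p$steps), integer(1))
  ord <- order(-sizes) # stable: ties keep input order
  batches <- list()
  loads <- integer(0)
  for (i in ord) {
    fit <- which(loads + sizes[i] <= s)
    if (length(fit) == 0) {
      batches[[length(batches) + 1L]] <- list(paths = list(paths[[i]]))
      loads <- c(loads, sizes[i])
    } else {
      j <- fit[1]
      batches[[j]]$paths <- c(batches[[j]]$paths, list(paths[[i]]))
      loads[j] <- loads[j] + sizes[i]
    }
  }
  for (j in seq_along(batches)) batches[[j]]$batch_id <- j
  batches
}

#' Read ids mapped to any contig of a batch
#'
#' @param batch a batch from [partition_batches()].
#' @param mapping mapping table.
#' @return character vector of read ids.
#' @export
collect_batch_reads <- function(batch, mapping) {
  contigs <- unique(unlist(lapply(batch$paths, function(p) p$steps)))
  sort(unique(mapping$read_id[mapping$contig_id %in% contigs]))
}

uniq_kmer_positions <- function(codes) {
  keep <- !is.na(codes)
  vals <- codes[keep]
  pos <- which(keep) - 1L
  dup <- duplicated(vals) | duplicated(vals, fromLast = TRUE)
  list(val = vals[!dup], pos = pos[!dup])
}

best_diagonal_chain <- function(rp, cp, band) {
  d <- sort(rp - cp)
  hi <- findInterval(d + band, d)
  counts <- hi - seq_along(d) + 1L
  i <- which.max(counts)
  list(n = counts[i], offset = stats::median(d[i:hi[i]]))
}

#' Chain shared anchors between a read and a contig
#'
#' Anchor seeds are `anchor_k`-mers occurring exactly once in both
#' sequences; the densest strand-consistent diagonal band of seeds is kept
#' as the chain. The reported `read_start` is the chain's median diagonal:
#' the read coordinate at which the oriented contig (forward for strand
#' `+`, reverse-complemented for `-`) begins; it may be negative when the
#' contig extends left of the read.
#'
#' @param read,contig base strings.
#' @param anchor_k anchor k-mer length.
#' @param min_anchors minimum chain size.
#' @param band diagonal band width in bp.
#' @return list with `strand`, `read_start`, `n_anchors`, or NULL when no
#'   strand reaches `min_anchors`.
#' @export
chain_anchors <- function(read, contig, anchor_k = 21, min_anchors = 5,
                          band = 50) {
  r <- uniq_kmer_positions(cpp_kmer_codes(read, anchor_k))
  if (length(r$val) == 0) return(NULL)
  best <- NULL
  for (strand in c("+", "-")) {
    cseq <- if (strand == "+") contig else revcomp(contig)
    co <- uniq_kmer_positions(cpp_kmer_codes(cseq, anchor_k))
    m <- match(r$val, co$val)
    sel <- !is.na(m)
    if (sum(sel) == 0) next
    chain <- best_diagonal_chain(r$pos[sel], co$pos[m[sel]], band)
    if (is.null(best) || chain$n > best$n_anchors)
      best <- list(strand = strand, read_start = chain$offset,
                   n_anchors = chain$n)
  }
  if (is.null(best) || best$n_anchors < min_anchors) return(NULL)
  best
}

# Fraction of distinct k-mers shared between two sequences (relative to
# the smaller set). Used to verify that an implied overlap between two
# sequences being joined really is the same sequence.
kmer_agreement <- function(a, b, k) {
  ka <- unique(cpp_kmer_codes(a, k))
  kb <- unique(cpp_kmer_codes(b, k))
  ka <- ka[!is.na(ka)]; kb <- kb[!is.na(kb)]
  if (length(ka) == 0 || length(kb) == 0) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

source_sequence <- function(src) {
  if (inherits(src, "scaffold_record")) src$sequence else src
}

# Component rows (local coordinates) for the slice [from, to) of a source
# displayed in orientation `orient`. Leaves yield one row; scaffold records
# are flattened so components always reference leaf sequences.
oriented_slice_components <- function(id, src, orient, from, to) {
  if (!inherits(src, "scaffold_record")) {
    L <- nchar(src)
    if (orient == "+") {
      ss <- from; se <- to
    } else {
      ss <- L - to; se <- L - from
    }
    return(data.frame(component_id = id, orientation = orient,
                      start = 0L, end = to - from,
                      source_start = ss, source_end = se,
                      gap_before = 0L, stringsAsFactors = FALSE))
  }
  comp <- src$components
  L <- nchar(src$sequence)
  if (orient == "-") {
    comp <- comp[rev(seq_len(nrow(comp))), , drop = FALSE]
    new_start <- L - comp$end
    new_end <- L - comp$start
    comp$start <- new_start
    comp$end <- new_end
    comp$orientation <- ifelse(comp$orientation == "+", "-", "+")
  }
  keep <- comp$end > from & comp$start < to
  comp <- comp[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    a <- comp$start[i]; b <- comp$end[i]
    lt <- max(0L, from - a); rt <- max(0L, b - to)
    o <- comp$orientation[i]
    ss <- comp$source_start[i]; se <- comp$source_end[i]
    if (o == "+") { ss <- ss + lt; se <- se - rt }
    else { ss <- ss + rt; se <- se - lt }
    data.frame(component_id = comp$component_id[i], orientation = o,
               start = max(a, from) - from, end = min(b, to) - from,
               source_start = ss, source_end = se, gap_before = 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(empty_components())))
}

empty_components <- function() {
  data.frame(component_id = character(), orientation = character(),
             start = integer(), end = integer(), source_start = integer(),
             source_end = integer(), gap_before = integer(),
             stringsAsFactors = FALSE)
}

oriented_slice_seq <- function(src, orient, from, to) {
  s <- source_sequence(src)
  if (orient == "-") s <- revcomp(s)
  substr(s, from + 1L, to)
}

# Shared-edge link sets of a mapping table: edge key -> read ids, with each
# read contributing at most once per unordered contig pair.
link_sets_from_mapping <- function(mapping) {
  keys <- character(0); rids <- character(0)
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
  lapply(split(rids, keys), function(x) sort(unique(x)))
}

#' Stitch one path into scaffold sequences
#'
#' Walks consecutive pairs of owned contigs along a path. For each junction
#' the linking read with the best combined anchor chains to both contigs is
#' chosen; placing both contigs on that read fixes the second contig's
#' orientation and either merges an overlap (contig bases preferred over
#' read bases) or inserts the read's intervening bases as a gap-filling
#' component. A junction for which no linking read places both contigs
#' consistently is handled by `params$junction_fallback`: `"split"` ends
#' the scaffold and starts a new one at the second contig, `"gap"` joins
#' across a run of `gap_default` Ns. Orientations propagate along the path;
#' the first contig of each output scaffold is fixed to `+`. Terminal steps
#' borrowed from other paths (see [path_owned_steps()]) are not stitched.
#'
#' @param path a path from [enumerate_paths()].
#' @param sources named list (or character vector) of contig sequences or
#'   [scaffold_record()]s for the path's steps.
#' @param linking_reads named list: edge key -> candidate linking read ids
#'   (see [link_sets_from_mapping()]).
#' @param reads named character vector of read sequences.
#' @param params a [stitch_params()].
#' @param id scaffold id (suffixed `_s01`, `_s02`, ... if the path splits).
#' @return list of [scaffold_record()]s (length 1 unless split).
#' @export
stitch_path <- function(path, sources, linking_reads = list(),
                        reads = character(), params = stitch_params(),
                        id = "scaffold_1") {
  owned <- path_owned_steps(path)
  missing_src <- setdiff(owned, names(sources))
  if (length(missing_src))
    stop("no source sequence for contig(s): ",
         paste(missing_src, collapse = ", "))
  finished <- list()
  pieces <- character(0)
  comps <- list(empty_components())
  offset <- 0L
  add_unit <- function(seq, comp_rows) {
    pieces <<- c(pieces, seq)
    if (nrow(comp_rows)) {
      comp_rows$start <- comp_rows$start + offset
      comp_rows$end <- comp_rows$end + offset
      comps[[length(comps) + 1L]] <<- comp_rows
    }
    offset <<- offset + nchar(seq)
  }
  finish <- function() {
    comp <- do.call(rbind, comps)
    comp$gap_before <- c(if (nrow(comp)) comp$start[1] else integer(0),
                         comp$start[-1] - comp$end[-nrow(comp)])
    finished[[length(finished) + 1L]] <<-
      scaffold_record("tmp", paste(pieces, collapse = ""), comp)
    pieces <<- character(0)
    comps <<- list(empty_components())
    offset <<- 0L
  }

  u <- owned[1]
  o_prev <- "+"
  fresh <- TRUE # segment holds only u; its orientation is still free
  len_u <- nchar(source_sequence(sources[[u]]))
  add_unit(oriented_slice_seq(sources[[u]], "+", 0L, len_u),
           oriented_slice_components(u, sources[[u]], "+", 0L, len_u))

  for (v in owned[-1][seq_len(max(0, length(owned) - 1))]) {
    len_v <- nchar(source_sequence(sources[[v]]))
    cand <- linking_reads[[edge_key(u, v)]]
    best <- NULL
    for (rid in cand) {
      r <- reads[[rid]]
      if (is.null(r) || is.na(r)) next
      cu <- chain_anchors(r, source_sequence(sources[[u]]), params$anchor_k,
                          params$min_anchors, params$band)
      cv <- chain_anchors(r, source_sequence(sources[[v]]), params$anchor_k,
                          params$min_anchors, params$band)
      if (is.null(cu) || is.null(cv)) next
      len_r <- nchar(r)
      # a fresh segment's seed contig may still be flipped wholesale, so
      # both of its orientations are admissible frames
      for (o_u in if (fresh) c("+", "-") else o_prev) {
        flip <- !identical(cu$strand, o_u)
        if (flip) {
          au <- len_r - (cu$read_start + len_u)
          av <- len_r - (cv$read_start + len_v)
          ov <- if (cv$strand == "+") "-" else "+"
        } else {
          au <- cu$read_start
          av <- cv$read_start
          ov <- cv$strand
        }
        if (av <= au) next                 # v must lie to the right of u
        if (av + len_v <= au + len_u) next # and extend beyond it
        over_len <- (au + len_u) - av
        if (over_len > 5 * params$band) {
          # an implied overlap must really be shared sequence; a
          # repeat-mediated pile-up agrees only across the repeat copy
          tail_u <- substr(oriented_slice_seq(sources[[u]], o_u, 0L, len_u),
                           len_u - over_len + 1L, len_u)
          head_v <- substr(oriented_slice_seq(sources[[v]], ov, 0L, len_v),
                           1L, over_len)
          if (kmer_agreement(tail_u, head_v, params$anchor_k) < 0.5) next
        }
        score <- cu$n_anchors + cv$n_anchors
        if (is.null(best) || score > best$score)
          best <- list(rid = rid, flip = flip, au = au, av = av, ov = ov,
                       o_u = o_u, len_r = len_r, score = score)
      }
    }
    if (!is.null(best)) {
      if (fresh && best$o_u != o_prev) {
        # re-seed the segment with u reverse-complemented
        pieces <- character(0)
        comps <- list(empty_components())
        offset <- 0L
        add_unit(oriented_slice_seq(sources[[u]], best$o_u, 0L, len_u),
                 oriented_slice_components(u, sources[[u]], best$o_u, 0L,
                                           len_u))
      }
      over <- (best$au + len_u) - best$av
      if (over < 0) {
        gs <- best$au + len_u
        ge <- best$av
        frame_read <- if (best$flip) revcomp(reads[[best$rid]])
                      else reads[[best$rid]]
        filler <- substr(frame_read, gs + 1L, ge)
        f_orient <- if (best$flip) "-" else "+"
        ss <- if (best$flip) best$len_r - ge else gs
        se <- if (best$flip) best$len_r - gs else ge
        add_unit(filler,
                 data.frame(component_id = best$rid, orientation = f_orient,
                            start = 0L, end = ge - gs, source_start = ss,
                            source_end = se, gap_before = 0L,
                            stringsAsFactors = FALSE))
        add_unit(oriented_slice_seq(sources[[v]], best$ov, 0L, len_v),
                 oriented_slice_components(v, sources[[v]], best$ov, 0L,
                                           len_v))
      } else {
        add_unit(oriented_slice_seq(sources[[v]], best$ov, over, len_v),
                 oriented_slice_components(v, sources[[v]], best$ov, over,
                                           len_v))
      }
      o_prev <- best$ov
      fresh <- FALSE
    } else if (params$junction_fallback == "split") {
      finish()
      add_unit(oriented_slice_seq(sources[[v]], "+", 0L, len_v),
               oriented_slice_components(v, sources[[v]], "+", 0L, len_v))
      o_prev <- "+"
      fresh <- TRUE
    } else {
      add_unit(strrep("N", params$gap_default), empty_components())
      add_unit(oriented_slice_seq(sources[[v]], "+", 0L, len_v),
               oriented_slice_components(v, sources[[v]], "+", 0L, len_v))
      o_prev <- "+"
      fresh <- FALSE
    }
    u <- v
    len_u <- len_v
  }
  finish()
  for (i in seq_along(finished)) {
    finished[[i]]$id <- if (length(finished) == 1) id
                        else sprintf("%s_s%02d", id, i)
  }
  finished
}

#' Assemble path batches into scaffolds
#'
#' The builtin backend runs [stitch_path()] on every path of every batch;
#' scaffold ids encode batch and path indices and the output order is
#' deterministic. The external backend writes each batch's contigs and
#' mapped reads to a FASTA pair in `workdir` and invokes a user command
#' template (with `{in_contigs}`, `{in_reads}`, `{out}` placeholders); its
#' per-batch output FASTA is collected as single-component scaffolds. A
#' failing external command makes the batch fall back to the builtin
#' stitcher with a warning.
#'
#' @param batches batches from [partition_batches()].
#' @param sources named list/vector of contig sequences or
#'   [scaffold_record()]s.
#' @param reads named character vector of read sequences.
#' @param mapping mapping table (provides per-edge linking reads and batch
#'   read sets).
#' @param params a [stitch_params()].
#' @param backend `"builtin"` (default) or `"external"`.
#' @param backend_cmd command template for the external backend.
#' @param workdir scratch directory for the external backend.
#' @param id_prefix prefix for scaffold ids.
#' @return list of [scaffold_record()]s.
#' @export
assemble_batches <- function(batches, sources, reads, mapping,
                             params = stitch_params(),
                             backend = c("builtin", "external"),
                             backend_cmd = NULL, workdir = tempdir(),
                             id_prefix = "scaffold") {
  backend <- match.arg(backend)
  link_sets <- link_sets_from_mapping(mapping)
  out <- list()
  for (b in batches) {
    if (backend == "external") {
      ext <- try_external_batch(b, sources, reads, mapping, backend_cmd,
                                workdir, id_prefix)
      if (!is.null(ext)) {
        out <- c(out, ext)
        next
      }
    }
    for (pi in seq_along(b$paths)) {
      sid <- sprintf("%s_b%03d_p%03d", id_prefix, b$batch_id, pi)
      out <- c(out,
               stitch_path(b$paths[[pi]], sources, link_sets, reads, params,
                           sid))
    }
  }
  out
}

try_external_batch <- function(batch, sources, reads, mapping, backend_cmd,
                               workdir, id_prefix) {
  if (is.null(backend_cmd)) {
    warning("external backend requested without backend_cmd; using builtin")
    return(NULL)
  }
  contigs <- unique(unlist(lapply(batch$paths, function(p) p$steps)))
  rid <- collect_batch_reads(batch, mapping)
  in_contigs <- file.path(workdir, sprintf("batch%03d_contigs.fa",
                                           batch$batch_id))
  in_reads <- file.path(workdir, sprintf("batch%03d_reads.fa",
                                         batch$batch_id))
  out_fa <- file.path(workdir, sprintf("batch%03d_out.fa", batch$batch_id))
  write_sequences(vapply(sources[contigs], source_sequence, character(1)),
                  in_contigs)
  write_sequences(reads[rid], in_reads)
  cmd <- gsub("{in_contigs}", in_contigs,
              gsub("{in_reads}", in_reads,
                   gsub("{out}", out_fa, backend_cmd, fixed = TRUE),
                   fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(out_fa)) {
    warning("external backend failed for batch ", batch$batch_id,
            "; falling back to builtin stitcher")
    return(NULL)
  }
  seqs <- read_sequences(out_fa)
  lapply(seq_along(seqs), function(i) {
    sid <- sprintf("%s_b%03d_x%03d", id_prefix, batch$batch_id, i)
    L <- nchar(seqs[[i]])
    scaffold_record(sid, seqs[[i]],
                    data.frame(component_id = names(seqs)[i],
                               orientation = "+", start = 0L, end = L,
                               source_start = 0L, source_end = L,
                               gap_before = 0L, stringsAsFactors = FALSE))
  })
}
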