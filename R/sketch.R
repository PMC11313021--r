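#' Mapper parameters
#'
#' Parameters of the alignment-free minimizer/minhash end-mapper. Defaults:
#' `k = 15`, `w = 10` (minimizer scheme dense enough for 2 kb read ends),
#' `trials = 30` minhash trials, `end_len = 2000` bp sampled from each read
#' end, `tau = 0.2` minimum sketch similarity to report, `top_n = 1` subject
#' per read end, `salt = 42` seeding the trial hash functions. With
#' `top_n = 1` each read maps to at most two contigs (one per end), which
#' keeps partial cross-matches between exact repeat copies out of the
#' contig graph: near a repeat, the true local subject always out-scores
#' the other copy's flank. Values above 1 report secondary hits.
#'
#' @param k minimizer k-mer length (1..26).
#' @param w minimizer window, in k-mers.
#' @param trials number of minhash trials (sketch length).
#' @param end_len bases taken from either end of a long read.
#' @param tau minimum similarity in \[0, 1\] for a mapping to be reported.
#' @param top_n maximum subjects reported per read end.
#' @param salt integer seed for the trial hash functions.
#' @return a `mapper_params` list.
#' @export
mapper_params <- function(k = 15, w = 10, trials = 30, end_len = 2000,
                          tau = 0.2, top_n = 1, salt = 42) {
  stopifnot(k >= 1, k <= 26, w >= 1, trials >= 1, end_len >= k + w - 1,
            tau >= 0, tau <= 1, top_n >= 1)
  structure(list(k = as.integer(k), w = as.integer(w),
                 trials = as.integer(trials), end_len = as.integer(end_len),
                 tau = tau, top_n = as.integer(top_n),
                 salt = as.integer(salt)),
            class = "mapper_params")
}

#' Extract minimizers from a sequence
#'
#' Standard (w, k)-minimizer scheme: for every window of `w` consecutive
#' k-mers, the minimum k-mer under the chosen ordering is emitted; the result
#' is the deduplicated set. In canonical mode each k-mer is replaced by the
#' smaller of itself and its reverse complement under the same ordering, so
#' the minimizer set of a sequence equals that of its reverse complement.
#' K-mers containing N are skipped.
#'
#' @param sequence a base string.
#' @param k,w minimizer parameters.
#' @param ordering `"hash"` (default; fixed 64-bit mixer) or
#'   `"lexicographic"`.
#' @param canonical use canonical k-mers (default TRUE).
#' @return character vector: the set of minimizer k-mers (order unspecified).
#' @export
#' @examples
#' extract_minimizers("ACGTACG", k = 3, w = 2, ordering = "lexicographic",
#'                    canonical = FALSE)
extract_minimizers <- function(sequence, k, w,
                               ordering = c("hash", "lexicographic"),
                               canonical = TRUE) {
  ordering <- match.arg(ordering)
  if (nchar(sequence) < k + w - 1) {
    message("sequence shorter than k + w - 1 (", nchar(sequence),
            " bp): no minimizers")
    return(character(0))
  }
  cpp_minimizers(sequence, as.integer(k), as.integer(w),
                 if (ordering == "hash") 0L else 1L, canonical)
}

#' Minhash sketch of a minimizer set
#'
#' For trial t in 0..trials-1 the sketch slot is the minimum of a fixed
#' 64-bit hash H(m, salt xor t) over all k-mers m in the set. Deterministic
#' given (set, trials, salt), independent of set order.
#'
#' @param kmers character vector of k-mers (a set; duplicates allowed but
#'   ignored).
#' @param trials sketch length.
#' @param salt integer seed.
#' @return numeric vector of `trials` hash values, or NULL ("unsketchable")
#'   for an empty set; callers must treat NULL as unmapped.
#' @export
jem_sketch <- function(kmers, trials = 30, salt = 42) {
  if (length(kmers) == 0) return(NULL)
  cpp_sketch(as.character(kmers), as.integer(trials), as.numeric(salt))
}

#' Similarity of two sketches
#'
#' Fraction of sketch slots in which the two sketches agree; an unbiased
#' estimate of the Jaccard index of the underlying minimizer sets.
#'
#' @param a,b sketches of equal length (see [jem_sketch()]).
#' @return numeric in \[0, 1\].
#' @export
sketch_similarity <- function(a, b) {
  if (is.null(a) || is.null(b)) stop("cannot compare an unsketchable result")
  if (length(a) != length(b)) stop("sketch length mismatch")
  mean(a == b)
}

#' Extract the two ends of a long read
#'
#' Reads at least `2 * end_len` long yield their first and last `end_len`
#' bases as ends 5p and 3p; reads between `end_len` and `2 * end_len` yield
#' two overlapping ends; reads shorter than `end_len` yield a single
#' "whole" entry.
#'
#' @param sequence read bases.
#' @param end_len end length in bp.
#' @return data.frame with columns `end` and `sequence`.
#' @export
extract_read_ends <- function(sequence, end_len) {
  len <- nchar(sequence)
  if (len < end_len) {
    return(data.frame(end = "whole", sequence = sequence,
                      stringsAsFactors = FALSE))
  }
  data.frame(end = c("5p", "3p"),
             sequence = c(substr(sequence, 1L, end_len),
                          substr(sequence, len - end_len + 1L, len)),
             stringsAsFactors = FALSE)
}

#' Map long-read ends to subject sequences
#'
#' Subjects are sketched in windows of `end_len` bases (stride half a
#' window), so that a read end is compared against similarly-sized
#' minimizer sets wherever it lands on the subject — the subject-side
#' analogue of sketching only the ends of the query, and what keeps the
#' similarity of a contained end high regardless of subject length. A
#' subject's similarity to a read end is the maximum over its windows. Per
#' end, subjects with similarity >= `tau` are reported in descending
#' similarity (ties broken by subject id), capped at `top_n` and ranked
#' from 1. A read is "mapped" iff it has at least one tuple.
#'
#' @param subjects named character vector of subject sequences (contigs, or
#'   partial scaffolds / reads in later phases).
#' @param reads named character vector of long reads.
#' @param params a [mapper_params()].
#' @param exclude_self drop subject hits whose id equals the query read id
#'   (used when reads are mapped against themselves).
#' @return a mapping table (see [mapping_table()]).
#' @export
map_reads <- function(subjects, reads, params = mapper_params(),
                      exclude_self = FALSE) {
  stopifnot(inherits(params, "mapper_params"))
  if (length(subjects) == 0) stop("subjects must be non-empty")
  if (length(reads) == 0) return(mapping_table())

  win_sketches <- list()
  win_subject <- character(0)
  short <- 0L
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    L <- nchar(s)
    if (L < params$k + params$w - 1) {
      short <- short + 1L
      next
    }
    starts <- if (L <= params$end_len) 0L
              else unique(c(seq(0L, L - params$end_len,
                                by = max(1L, params$end_len %/% 2L)),
                            L - params$end_len))
    any_win <- FALSE
    for (st in starts) {
      win <- substr(s, st + 1L, min(L, st + params$end_len))
      mins <- if (nchar(win) < params$k + params$w - 1) character(0)
              else cpp_minimizers(win, params$k, params$w, 0L, TRUE)
      sk <- jem_sketch(mins, params$trials, params$salt)
      if (is.null(sk)) next
      any_win <- TRUE
      win_sketches[[length(win_sketches) + 1L]] <- sk
      win_subject <- c(win_subject, names(subjects)[i])
    }
    if (!any_win) short <- short + 1L
  }
  if (short > 0)
    message(short, " subject(s) too short to sketch; never matched")
  subj_mat <- if (length(win_sketches))
    do.call(cbind, win_sketches) else NULL # trials x n_windows

  rows <- vector("list", length(reads) * 2L)
  n_rows <- 0L
  for (i in seq_along(reads)) {
    rid <- names(reads)[i]
    ends <- extract_read_ends(reads[[i]], params$end_len)
    for (j in seq_len(nrow(ends))) {
      if (is.null(subj_mat)) next
      mins <- if (nchar(ends$sequence[j]) < params$k + params$w - 1)
        character(0)
      else cpp_minimizers(ends$sequence[j], params$k, params$w, 0L, TRUE)
      sk <- jem_sketch(mins, params$trials, params$salt)
      if (is.null(sk)) next
      win_sims <- colMeans(subj_mat == sk)
      sims <- vapply(split(win_sims, win_subject), max, numeric(1))
      cand <- which(sims >= params$tau)
      if (exclude_self) cand <- cand[names(sims)[cand] != rid]
      if (length(cand) == 0) next
      ord <- cand[order(-sims[cand], names(sims)[cand])]
      ord <- head(ord, params$top_n)
      n_rows <- n_rows + 1L
      rows[[n_rows]] <- data.frame(
        read_id = rid, end = ends$end[j], contig_id = names(sims)[ord],
        similarity = unname(sims[ord]), rank = seq_along(ord),
        stringsAsFactors = FALSE)
    }
  }
  if (n_rows == 0) return(mapping_table())
  out <- do.call(rbind, rows[seq_len(n_rows)])
  mapping_table(out$read_id, out$end, out$contig_id, out$similarity, out$rank)
}
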