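random_bases <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_substitutions <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a genome, optionally with planted repeats
#'
#' Bases are i.i.d. at the requested GC content. Each repeat specification
#' plants `copies` copies of one random unit at non-overlapping loci,
#' mutated down to the stated identity (1.0 = exact copies). Deterministic
#' given the seed; the caller's RNG state is untouched.
#'
#' @param length genome length in bp (>= 10000).
#' @param repeats list of repeat specs, each a list/vector with
#'   `unit_length`, `copies` (>= 2) and `identity` in (0, 1].
#' @param gc GC content in (0, 1).
#' @param seed integer seed.
#' @return list with `sequence` (named character vector of length 1, id
#'   `"genome"`) and `repeat_intervals` (data.frame unit, copy, start, end;
#'   0-based half-open).
#' @export
simulate_genome <- function(length, repeats = list(), gc = 0.5, seed = 1) {
  stopifnot(length >= 10000)
  withr::with_seed(seed, {
    genome <- random_bases(length, gc)
    intervals <- data.frame(unit = integer(), copy = integer(),
                            start = integer(), end = integer())
    occupied <- matrix(numeric(0), ncol = 2) # planted [start, end) intervals
    for (u in seq_along(repeats)) {
      spec <- as.list(repeats[[u]])
      ul <- as.integer(spec$unit_length)
      copies <- as.integer(spec$copies)
      identity <- as.numeric(spec$identity)
      stopifnot(copies >= 2, identity > 0, identity <= 1)
      if (copies * ul >= length)
        stop("repeat copies do not fit in the genome")
      unit <- random_bases(ul, gc)
      placed <- 0L
      tries <- 0L
      while (placed < copies) {
        tries <- tries + 1L
        if (tries > 1000L) stop("could not place repeat copies")
        s <- sample.int(length - ul + 1L, 1) - 1L
        overlaps <- nrow(occupied) > 0 &&
          any(s < occupied[, 2] & s + ul > occupied[, 1])
        if (overlaps) next
        n_sub <- rbinom(1, ul, 1 - identity)
        copy_seq <- mutate_substitutions(unit, n_sub)
        substr(genome, s + 1L, s + ul) <- copy_seq
        occupied <- rbind(occupied, c(s, s + ul))
        placed <- placed + 1L
        intervals <- rbind(intervals,
                           data.frame(unit = u, copy = placed, start = s,
                                      end = s + ul))
      }
    }
    list(sequence = c(genome = genome), repeat_intervals = intervals)
  })
}

#' Shred a genome into contigs with gaps
#'
#' Emulates the fragment structure of a short-read assembly: non-overlapping
#' intervals are sampled left to right with lognormal lengths (mean
#' `mean_len`, coefficient of variation `len_cv`) separated by
#' exponentially-sized gaps whose mean is chosen so that total contig bases
#' approximate `covered_frac` of the genome. Each contig is emitted on a
#' random strand. Truth placements are recorded.
#'
#' @param genome named character vector of length 1 (see
#'   [simulate_genome()]), or a bare string.
#' @param mean_len mean contig length in bp.
#' @param len_cv coefficient of variation of contig length.
#' @param covered_frac target fraction of the genome covered by contigs.
#' @param min_len minimum contig length in bp.
#' @param seed integer seed.
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame seq_id, genome_start, genome_end, strand; 0-based
#'   half-open).
#' @export
shred_to_contigs <- function(genome, mean_len = 5000, len_cv = 0.5,
                             covered_frac = 0.85, min_len = 500, seed = 1) {
  stopifnot(covered_frac > 0, covered_frac <= 1)
  gseq <- genome[[1]]
  L <- nchar(gseq)
  sdlog <- sqrt(log(1 + len_cv^2))
  meanlog <- log(mean_len) - sdlog^2 / 2
  gap_mean <- mean_len * (1 / covered_frac - 1)
  withr::with_seed(seed, {
    pos <- if (gap_mean > 0) round(runif(1, 0, gap_mean)) else 0
    ids <- character(0); seqs <- character(0)
    starts <- integer(0); ends <- integer(0); strands <- character(0)
    i <- 0L
    while (pos < L - min_len) {
      len <- max(min_len, round(rlnorm(1, meanlog, sdlog)))
      len <- min(len, L - pos)
      i <- i + 1L
      s <- pos; e <- pos + len
      frag <- substr(gseq, s + 1L, e)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") frag <- revcomp(frag)
      ids <- c(ids, sprintf("contig_%05d", i))
      seqs <- c(seqs, frag)
      starts <- c(starts, s); ends <- c(ends, e)
      strands <- c(strands, strand)
      gap <- if (gap_mean > 0) round(stats::rexp(1, 1 / gap_mean)) else 0
      pos <- e + gap
    }
    list(contigs = setNames(seqs, ids),
         truth = data.frame(seq_id = ids, genome_start = starts,
                            genome_end = ends, strand = strands,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate HiFi-like long reads
#'
#' Start positions are uniform, lengths are normal(`median_len`, `len_sd`)
#' truncated to \[1000, genome length\], strands random, and reads are drawn
#' until their total length reaches `coverage` times the genome length.
#' Errors are uniform substitutions at `error_rate`; truth placements are
#' recorded pre-error.
#'
#' @param genome named character vector of length 1, or a bare string.
#' @param coverage target sequencing depth (> 0).
#' @param median_len median (= mean of the truncated normal's centre) read
#'   length in bp.
#' @param len_sd read length standard deviation in bp.
#' @param error_rate substitution rate in \[0, 0.1).
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame seq_id, genome_start, genome_end, strand).
#' @export
simulate_long_reads <- function(genome, coverage = 10, median_len = 10000,
                                len_sd = 3400, error_rate = 0.002, seed = 1) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.1)
  gseq <- genome[[1]]
  L <- nchar(gseq)
  withr::with_seed(seed, {
    target <- coverage * L
    total <- 0
    ids <- character(0); seqs <- character(0)
    starts <- integer(0); ends <- integer(0); strands <- character(0)
    i <- 0L
    while (total < target) {
      len <- round(rnorm(1, median_len, len_sd))
      len <- max(1000L, min(as.integer(len), L))
      s <- sample.int(L - len + 1L, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      frag <- substr(gseq, s + 1L, s + len)
      if (strand == "-") frag <- revcomp(frag)
      if (error_rate > 0) {
        n_err <- rbinom(1, len, error_rate)
        frag <- mutate_substitutions(frag, n_err)
      }
      i <- i + 1L
      ids <- c(ids, sprintf("read_%06d", i))
      seqs <- c(seqs, frag)
      starts <- c(starts, s); ends <- c(ends, s + len)
      strands <- c(strands, strand)
      total <- total + len
    }
    list(reads = setNames(seqs, ids),
         truth = data.frame(seq_id = ids, genome_start = starts,
                            genome_end = ends, strand = strands,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a complete scaffolding dataset
#'
#' Bundles [simulate_genome()], [shred_to_contigs()] and
#' [simulate_long_reads()] into the package's reference study conditions: a
#' 200 kb genome with one exact 3 kb repeat in two copies, contigs of mean
#' 5 kb covering 85% of the genome, and long reads at 10x coverage with
#' 10 kb median length (s.d. 3.4 kb) and 0.2% substitution error. Sub-seeds
#' for the three generators are derived from `seed`.
#'
#' @param genome_length genome length in bp.
#' @param repeats repeat specs for [simulate_genome()].
#' @param contig_mean_len,contig_len_cv,covered_frac contig shredding
#'   parameters.
#' @param coverage,read_median_len,read_len_sd,error_rate long-read
#'   parameters.
#' @param drop_region optional `c(start, end)` (0-based half-open): contigs
#'   overlapping this genome interval are removed, creating a contig-free
#'   region covered only by long reads.
#' @param seed integer seed.
#' @return list with `genome`, `genome_length`, `repeat_intervals`,
#'   `contigs`, `truth_contigs`, `reads`, `truth_reads`.
#' @export
simulate_scaffolding_dataset <- function(
    genome_length = 200000,
    repeats = list(list(unit_length = 3000, copies = 2, identity = 1.0)),
    contig_mean_len = 5000, contig_len_cv = 0.5, covered_frac = 0.85,
    coverage = 10, read_median_len = 10000, read_len_sd = 3400,
    error_rate = 0.002, drop_region = NULL, seed = 1) {
  gen <- simulate_genome(genome_length, repeats = repeats, seed = seed)
  ctg <- shred_to_contigs(gen$sequence, mean_len = contig_mean_len,
                          len_cv = contig_len_cv,
                          covered_frac = covered_frac, seed = seed + 1L)
  rds <- simulate_long_reads(gen$sequence, coverage = coverage,
                             median_len = read_median_len,
                             len_sd = read_len_sd, error_rate = error_rate,
                             seed = seed + 2L)
  if (!is.null(drop_region)) {
    hit <- ctg$truth$genome_start < drop_region[2] &
      ctg$truth$genome_end > drop_region[1]
    ctg$contigs <- ctg$contigs[!hit]
    ctg$truth <- ctg$truth[!hit, , drop = FALSE]
  }
  list(genome = gen$sequence, genome_length = genome_length,
       repeat_intervals = gen$repeat_intervals,
       contigs = ctg$contigs, truth_contigs = ctg$truth,
       reads = rds$reads, truth_reads = rds$truth)
}
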