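#' Nx / NGx length metric
#'
#' Smallest length `L` such that pieces of length >= `L` together reach at
#' least `x` percent of `denominator`. With `denominator = sum(lengths)`
#' this is the Nx statistic; with the genome length it is NGx. Returns 0
#' when the pieces cannot reach the threshold.
#'
#' @param lengths piece lengths in bp.
#' @param denominator reference total in bp (> 0).
#' @param x percentage threshold in (0, 100).
#' @return length in bp.
#' @export
#' @examples
#' nx_metric(c(30, 20, 10), 60, 50) # 30
nx_metric <- function(lengths, denominator, x = 50) {
  stopifnot(denominator > 0, x > 0, x < 100)
  if (length(lengths) == 0) return(0)
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  need <- x / 100 * denominator
  idx <- which(cs >= need)
  if (length(idx) == 0) return(0)
  unname(s[idx[1]])
}

#' Place scaffold components on the truth genome
#'
#' Maps every component of every scaffold to its genome interval using the
#' simulation truth, composing the component's orientation in the scaffold
#' with the source sequence's truth strand (the composed orientation is `+`
#' iff the two agree).
#'
#' @param scaffolds list of [scaffold_record()] objects.
#' @param truth data.frame with seq_id, genome_start, genome_end, strand
#'   (union of contig and read truth as needed).
#' @return data.frame with one row per component: scaffold_id, component_id,
#'   scaffold_start, scaffold_end, genome_start, genome_end, orientation.
#' @export
place_components <- function(scaffolds, truth) {
  ti <- match(unlist(lapply(scaffolds, function(s) s$components$component_id)),
              truth$seq_id)
  if (anyNA(ti)) {
    miss <- unique(unlist(lapply(scaffolds, function(s)
      setdiff(s$components$component_id, truth$seq_id))))
    stop("no truth placement for component(s): ",
         paste(head(miss, 5), collapse = ", "))
  }
  rows <- lapply(scaffolds, function(sc) {
    comp <- sc$components
    if (nrow(comp) == 0) return(NULL)
    t <- truth[match(comp$component_id, truth$seq_id), , drop = FALSE]
    src_len <- t$genome_end - t$genome_start
    gs <- ifelse(t$strand == "+",
                 t$genome_start + comp$source_start,
                 t$genome_start + (src_len - comp$source_end))
    ge <- ifelse(t$strand == "+",
                 t$genome_start + comp$source_end,
                 t$genome_start + (src_len - comp$source_start))
    data.frame(scaffold_id = sc$id, component_id = comp$component_id,
               scaffold_start = comp$start, scaffold_end = comp$end,
               genome_start = gs, genome_end = ge,
               orientation = ifelse(comp$orientation == t$strand, "+", "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

interval_union_bases <- function(starts, ends) {
  if (length(starts) == 0) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Evaluate scaffolds against simulation truth
#'
#' A misjoin is an adjacent component pair within a scaffold whose composed
#' orientations differ, whose genome order contradicts the scaffold order,
#' or whose genome gap deviates from the scaffold gap by more than `slack`.
#' Reported metrics: N50 and NG50 of the scaffold lengths, `ngm50` (NG50
#' after splitting scaffolds at misjoined adjacencies; the truth-based
#' analogue of alignment-corrected NG50), genome fraction (% of genome
#' covered by at least one placed component), duplication ratio (placed
#' component bases over distinct genome bases covered), misjoin count,
#' adjacency accuracy and scaffold count.
#'
#' @param scaffolds list of [scaffold_record()] objects.
#' @param truth truth placements (see [place_components()]).
#' @param genome_length genome length in bp.
#' @param slack tolerated absolute difference between scaffold gap and
#'   genome gap in bp.
#' @return list of metrics (class `assembly_metrics`).
#' @export
evaluate_against_truth <- function(scaffolds, truth, genome_length,
                                   slack = 2000) {
  placed <- place_components(scaffolds, truth)
  lens <- nchar(scaffold_sequences(scaffolds))
  misjoins <- 0L
  pairs <- 0L
  split_lengths <- numeric(0)
  for (sc in scaffolds) {
    p <- placed[placed$scaffold_id == sc$id, , drop = FALSE]
    p <- p[order(p$scaffold_start), , drop = FALSE]
    n <- nrow(p)
    bad <- logical(if (n > 1) n - 1 else 0)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        pairs <- pairs + 1L
        a <- p[i, ]; b <- p[i + 1, ]
        if (a$orientation != b$orientation) { bad[i] <- TRUE; next }
        genome_gap <- if (a$orientation == "+") b$genome_start - a$genome_end
                      else a$genome_start - b$genome_end
        scaffold_gap <- b$scaffold_start - a$scaffold_end
        order_ok <- if (a$orientation == "+")
          b$genome_start >= a$genome_start else b$genome_start <= a$genome_start
        if (!order_ok || abs(genome_gap - scaffold_gap) > slack)
          bad[i] <- TRUE
      }
      misjoins <- misjoins + sum(bad)
    }
    # split scaffold length at misjoined adjacencies for ngm50
    if (n == 0) next
    brk <- which(bad)
    seg_start <- c(1, brk + 1)
    seg_end <- c(brk, n)
    seg_len <- vapply(seq_along(seg_start), function(k) {
      p$scaffold_end[seg_end[k]] - p$scaffold_start[seg_start[k]]
    }, numeric(1))
    split_lengths <- c(split_lengths, seg_len)
  }
  covered <- interval_union_bases(placed$genome_start, placed$genome_end)
  placed_bases <- sum(placed$genome_end - placed$genome_start)
  structure(list(
    n50 = nx_metric(lens, sum(lens), 50),
    ng50 = nx_metric(lens, genome_length, 50),
    ngm50 = nx_metric(split_lengths, genome_length, 50),
    genome_fraction = 100 * covered / genome_length,
    duplication_ratio = if (covered > 0) placed_bases / covered else 0,
    misjoins = as.integer(misjoins),
    adjacency_accuracy = if (pairs > 0) 1 - misjoins / pairs else 1,
    n_scaffolds = length(scaffolds)
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "assembly metrics: n_scaffolds=%d  N50=%d  NG50=%d  NGM50=%d\n",
    "  genome_fraction=%.2f%%  duplication=%.3f  misjoins=%d  ",
    "adjacency_accuracy=%.4f\n"),
    x$n_scaffolds, x$n50, x$ng50, x$ngm50, x$genome_fraction,
    x$duplication_ratio, x$misjoins, x$adjacency_accuracy))
  invisible(x)
}
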