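#' Read sequences from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed; detected by magic bytes, not extension)
#' FASTA or FASTQ file into a named character vector of uppercase sequences.
#' FASTQ qualities are discarded. IUPAC ambiguity codes other than N are
#' replaced by N with a warning. Record order is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (default; sniffed from the first record character),
#'   `"fasta"` or `"fastq"`.
#' @return named character vector; names are record ids (first whitespace
#'   token of the header), with the remainder of each header retained in the
#'   `"descriptions"` attribute.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    if (length(first) == 0L) {
      format <- "fasta" # empty file: treat as empty FASTA
    } else if (startsWith(first, ">")) {
      format <- "fasta"
    } else if (startsWith(first, "@")) {
      format <- "fastq"
    } else {
      stop("format error in ", path, " at line 1: expected '>' or '@', got ",
           substr(first, 1, 20))
    }
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " record(s) contained non-ACGTN ambiguity codes; ",
            "replaced by N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param line_width bases per sequence line.
#' @return invisibly, `path`.
#' @export
write_sequences <- function(seqs, path, line_width = 80) {
  stopifnot(line_width >= 1)
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

MAPPING_ENDS <- c("5p", "3p", "whole")

#' Construct a mapping table
#'
#' @param read_id,end,contig_id,similarity,rank column vectors; `end` must be
#'   one of `"5p"`, `"3p"`, `"whole"`.
#' @return data.frame with columns read_id, end, contig_id, similarity, rank.
#' @export
mapping_table <- function(read_id = character(), end = character(),
                          contig_id = character(), similarity = numeric(),
                          rank = integer()) {
  df <- data.frame(read_id = as.character(read_id), end = as.character(end),
                   contig_id = as.character(contig_id),
                   similarity = as.numeric(similarity),
                   rank = as.integer(rank), stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$end %in% MAPPING_ENDS))
    stop("unknown end token: ", paste(setdiff(df$end, MAPPING_ENDS), collapse = ", "))
  df
}

#' Write a mapping table to TSV
#'
#' Five tab-separated columns (read_id, end, contig_id, similarity, rank)
#' with a header line; similarity is printed with six decimals.
#'
#' @param mapping mapping table (see [mapping_table()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mapping <- function(mapping, path) {
  out <- mapping
  out$similarity <- sprintf("%.6f", out$similarity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mapping TSV written by [write_mapping()]
#'
#' @param path input path.
#' @return mapping table.
#' @export
read_mapping <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character",
                                  "numeric", "integer"))
  if (nrow(df) && !all(df$end %in% MAPPING_ENDS))
    stop("format error in ", path, ": unknown end token ",
         paste(unique(setdiff(df$end, MAPPING_ENDS)), collapse = ", "))
  mapping_table(df$read_id, df$end, df$contig_id, df$similarity, df$rank)
}

#' Construct a scaffold record
#'
#' A scaffold is a sequence plus an ordered component list describing which
#' slice of which source sequence (contig or gap-filling read) occupies which
#' interval of the scaffold. Coordinates are 0-based half-open; `start`/`end`
#' index the scaffold, `source_start`/`source_end` index the source on its
#' forward strand. Runs of N between components are implied by
#' `start[i] - end[i-1]` and mirrored in `gap_before`.
#'
#' @param id scaffold id.
#' @param sequence scaffold bases.
#' @param components data.frame with columns component_id, orientation
#'   (`"+"`/`"-"`), start, end, source_start, source_end, gap_before.
#' @return object of class `scaffold_record`.
#' @export
scaffold_record <- function(id, sequence, components) {
  stopifnot(is.character(id), nchar(sequence) > 0)
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  needed <- c("component_id", "orientation", "start", "end",
              "source_start", "source_end", "gap_before")
  stopifnot(all(needed %in% names(components)))
  components <- components[, needed]
  if (nrow(components)) {
    if (is.unsorted(components$start, strictly = TRUE) &&
        nrow(components) > 1)
      stop("components must be ascending within the scaffold")
    gaps <- c(components$start[1],
              components$start[-1] - components$end[-nrow(components)])
    if (any(gaps < 0)) stop("components overlap within scaffold ", id)
    if (!identical(as.integer(gaps), as.integer(components$gap_before)))
      stop("gap_before inconsistent with component coordinates")
    if (components$end[nrow(components)] != nchar(sequence))
      stop("components do not tile the scaffold sequence")
  }
  structure(list(id = id, sequence = unname(sequence),
                 components = components),
            class = "scaffold_record")
}

#' @export
print.scaffold_record <- function(x, ...) {
  cat(sprintf("<scaffold %s: %d bp, %d component(s)>\n",
              x$id, nchar(x$sequence), nrow(x$components)))
  invisible(x)
}

#' Extract sequences from a list of scaffold records
#'
#' @param scaffolds list of [scaffold_record()] objects.
#' @return named character vector of scaffold sequences.
#' @export
scaffold_sequences <- function(scaffolds) {
  setNames(vapply(scaffolds, function(s) s$sequence, character(1)),
           vapply(scaffolds, function(s) s$id, character(1)))
}

#' Write scaffolds to AGP v2.1
#'
#' Component lines are type W referencing the component id (contig or
#' gap-filling read) with 1-based inclusive coordinates and orientation; runs
#' of N between components become gap lines of type N with gap_type
#' "scaffold", linkage "yes" and linkage evidence "map".
#'
#' @param scaffolds list of [scaffold_record()] objects.
#' @param path output path.
#' @param sources optional named character vector of component source
#'   sequences; when given, component ids are validated against it.
#' @return invisibly, `path`.
#' @export
write_agp <- function(scaffolds, path, sources = NULL) {
  lines <- c("##agp-version\t2.1")
  for (sc in scaffolds) {
    comp <- sc$components
    if (!is.null(sources)) {
      unknown <- setdiff(comp$component_id, names(sources))
      if (length(unknown))
        stop("AGP component references unknown source id: ",
             paste(unknown, collapse = ", "))
    }
    part <- 0L
    for (i in seq_len(nrow(comp))) {
      if (comp$gap_before[i] > 0) {
        part <- part + 1L
        lines <- c(lines, paste(sc$id,
                                comp$end[i - 1] + 1L, comp$start[i], part,
                                "N", comp$gap_before[i], "scaffold", "yes",
                                "map", sep = "\t"))
      }
      part <- part + 1L
      lines <- c(lines, paste(sc$id, comp$start[i] + 1L, comp$end[i], part,
                              "W", comp$component_id[i],
                              comp$source_start[i] + 1L, comp$source_end[i],
                              comp$orientation[i], sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an AGP file written by [write_agp()]
#'
#' @param path AGP path.
#' @return data.frame of AGP lines with columns object, object_beg,
#'   object_end, part_number, component_type, and the W/N payload columns.
#' @export
read_agp <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) stop("malformed AGP line in ", path)
  m <- do.call(rbind, parts)
  data.frame(object = m[, 1], object_beg = as.integer(m[, 2]),
             object_end = as.integer(m[, 3]), part_number = as.integer(m[, 4]),
             component_type = m[, 5], f6 = m[, 6], f7 = m[, 7], f8 = m[, 8],
             f9 = m[, 9], stringsAsFactors = FALSE)
}

#' Rebuild scaffold sequences from an AGP file and component sequences
#'
#' The round-trip oracle for [write_agp()]: reconstructs every scaffold from
#' its AGP lines plus the source sequences (contigs and gap-filling reads).
#'
#' @param path AGP path.
#' @param sources named character vector of component source sequences.
#' @return named character vector of scaffold sequences.
#' @export
reconstruct_from_agp <- function(path, sources) {
  agp <- read_agp(path)
  out <- character(0)
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$object_beg), , drop = FALSE]
    pieces <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (rows$component_type[i] == "N") {
        pieces[i] <- strrep("N", as.integer(rows$f6[i]))
      } else {
        src <- sources[[rows$f6[i]]]
        if (is.null(src)) stop("unknown AGP component: ", rows$f6[i])
        piece <- substr(src, as.integer(rows$f7[i]), as.integer(rows$f8[i]))
        if (rows$f9[i] == "-") piece <- revcomp(piece)
        pieces[i] <- piece
      }
    }
    out[obj] <- paste(pieces, collapse = "")
  }
  out
}

#' Write enumerated paths to a text file
#'
#' One path per line as tab-separated `contig_id:orientation` tokens
#' (orientation `?` before stitching).
#'
#' @param paths list of paths (see [enumerate_paths()]).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_paths <- function(paths, path) {
  lines <- vapply(paths, function(p) {
    paste(paste0(p$steps, ":", p$orientations), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a paths file written by [write_paths()]
#'
#' @param path file path.
#' @return list of paths with steps and orientations (terminal reasons are
#'   not serialized and read back as NA).
#' @export
read_paths <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    toks <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ids <- sub(":[^:]*$", "", toks)
    ori <- sub("^.*:", "", toks)
    if (!all(ori %in% c("+", "-", "?")))
      stop("malformed path token in ", path)
    list(steps = ids, orientations = ori,
         start_reason = NA_character_, end_reason = NA_character_)
  })
}

#' Export a contig graph to GFA1
#'
#' S lines carry contig lengths (sequence omitted), L lines use a 0M overlap
#' and carry the edge support value in a `SV:i:` tag.
#'
#' @param graph a [contig_graph()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gfa <- function(graph, path) {
  s_lines <- sprintf("S\t%s\t*\tLN:i:%d", names(graph$vertices),
                     as.integer(graph$vertices))
  l_lines <- vapply(names(graph$edges), function(key) {
    ends <- edge_key_split(key)
    sprintf("L\t%s\t+\t%s\t+\t0M\tSV:i:%d", ends[1], ends[2],
            length(graph$edges[[key]]))
  }, character(1))
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}
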