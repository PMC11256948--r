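#' Read query sequences from FASTA
#'
#' Names are truncated at the first whitespace and sequences uppercased;
#' record order is preserved.  Characters outside A/C/G/T are kept
#' verbatim (they score as mismatches against everything but an identical
#' character).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_queries <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records")
  if (any(Biostrings::width(set) == 0L)) stop("empty FASTA record")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

# Map a canonical walk to GAF path steps: maximal runs of consecutive
# canonical vertices from one original segment collapse to the segment
# name, or to "name:start-end" (0-based half-open offsets) when the run
# covers the segment only partially.
walk_steps <- function(gc, walk) {
  seg <- gc$origin$segment[walk]
  off <- gc$origin$offset[walk]
  len <- gc$origin$seg_len[walk]
  k <- length(walk)
  # a run must be consecutive within one segment; a repeated vertex (the
  # rho == psi junction) breaks the run even though the segment repeats
  new_run <- c(TRUE, seg[-1L] != seg[-k] | off[-1L] != off[-k] + 1L)
  starts <- which(new_run)
  ends <- c(starts[-1L] - 1L, k)
  vapply(seq_along(starts), function(r) {
    i1 <- starts[r]; i2 <- ends[r]
    if (off[i1] == 0L && off[i2] == len[i1] - 1L) seg[i1]
    else sprintf("%s:%d-%d", seg[i1], off[i1], off[i2] + 1L)
  }, character(1L))
}

gaf_cigar <- function(cols) {
  op <- ifelse(!is.na(cols$x) & !is.na(cols$y), "M",
               ifelse(is.na(cols$x), "I", "D"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Serialize alignments to GAF
#'
#' One line per record, with the 12 mandatory GAF columns (0-based,
#' half-open coordinates; strand always `+`; mapping quality 255) plus the
#' tags `AS:i:` (score rounded to the nearest integer), `ZS:f:` (exact,
#' possibly fractional, score), `cg:Z:` (M/I/D cigar) and, for records
#' carrying a recombination, `rc:Z:p1,p2,rho-segment,psi-segment,breakpoint,
#' displacement`.  GAF has no notion of a virtual arc, so the walk is
#' emitted contiguously and the junction is only distinguishable through
#' the `rc` tag.
#'
#' @param records a `graph_alignment` or list of them.
#' @param gc the `canonical_graph` the records refer to.
#' @param file optional output path.
#' @return character vector of GAF lines (invisibly when `file` is given).
#' @export
write_gaf <- function(records, gc, file = NULL) {
  if (inherits(records, "graph_alignment")) records <- list(records)
  lines <- vapply(records, function(a) {
    qn <- a$query_name; ql <- a$query_len
    steps <- walk_steps(gc, a$walk)
    plen <- length(a$walk)  # canonical vertices each spell one character
    both <- !is.na(a$columns$x) & !is.na(a$columns$y)
    matches <- sum(gc$labels[a$walk[a$columns$x[both]]] ==
                     split_chars(a$query)[a$columns$y[both]])
    tags <- c(sprintf("AS:i:%d", as.integer(round(a$score))),
              sprintf("ZS:f:%s", format(a$score, digits = 15L)),
              sprintf("cg:Z:%s", gaf_cigar(a$columns)))
    if (!is.null(a$recombination)) {
      ev <- a$recombination
      tags <- c(tags, sprintf(
        "rc:Z:%s,%s,%s,%s,%d,%s", ev$p1, ev$p2,
        gc$origin$segment[ev$rho], gc$origin$segment[ev$psi],
        ev$breakpoint, format(ev$displacement)))
    }
    paste(c(qn, ql, 0L, ql, "+",
            paste0(">", steps, collapse = ""),
            plen, 0L, plen, matches, nrow(a$columns), 255L, tags),
          collapse = "\t")
  }, character(1L))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Parse a GAF line back against its graph
#'
#' Resolves the walk steps (full segments or `segment:start-end` partial
#' runs) to canonical vertex ids and returns the mandatory fields and
#' tags.  Used for round-trip validation and downstream evaluation.
#'
#' @param line a single GAF line.
#' @param gc the `canonical_graph` the line was written against.
#' @return list with `query_name`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `walk` (canonical ids), `path_len`,
#'   `path_start`, `path_end`, `matches`, `block_len`, `mapq`, `tags`
#'   (named character vector).
#' @export
parse_gaf <- function(line, gc) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 12L) stop("malformed GAF line")
  steps <- strsplit(f[6L], ">", fixed = TRUE)[[1L]]
  steps <- steps[nzchar(steps)]
  seg_index <- split(seq_along(gc$origin$segment), gc$origin$segment)
  walk <- unlist(lapply(steps, function(st) {
    m <- regmatches(st, regexec("^(.*):([0-9]+)-([0-9]+)$", st))[[1L]]
    if (length(m) == 4L && m[2L] %in% names(seg_index)) {
      ids <- seg_index[[m[2L]]]
      ids <- ids[order(gc$origin$offset[ids])]
      ids[(as.integer(m[3L]) + 1L):as.integer(m[4L])]
    } else {
      if (!(st %in% names(seg_index))) stop("unknown segment in walk: ", st)
      ids <- seg_index[[st]]
      ids[order(gc$origin$offset[ids])]
    }
  }), use.names = FALSE)
  tags <- f[-(1:12)]
  tag_names <- sub(":.*$", "", tags)
  tag_vals <- sub("^[^:]*:[^:]*:", "", tags)
  list(query_name = f[1L], query_len = as.integer(f[2L]),
       query_start = as.integer(f[3L]), query_end = as.integer(f[4L]),
       strand = f[5L], walk = walk, path_len = as.integer(f[7L]),
       path_start = as.integer(f[8L]), path_end = as.integer(f[9L]),
       matches = as.integer(f[10L]), block_len = as.integer(f[11L]),
       mapq = as.integer(f[12L]),
       tags = stats::setNames(tag_vals, tag_names))
}
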