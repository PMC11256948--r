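#' Jaccard similarity of two node sets
#'
#' `|intersection| / |union|` of the true mosaic node set and the aligned
#' node set.  Node sets are compared on canonical vertex ids, so partial
#' coverage of a long original segment counts proportionally.
#'
#' @param true_nodes,aligned_nodes vectors of vertex ids (or names).
#' @return a fraction in `[0, 1]`.
#' @export
jaccard_nodes <- function(true_nodes, aligned_nodes) {
  a <- unique(true_nodes); b <- unique(aligned_nodes)
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard similarity of two empty sets is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Canonical vertex ids originating from a set of segments
#'
#' Expands original GFA segment names to the canonical single-character
#' vertices they were split into, for node-set comparisons between a truth
#' walk (recorded on the original graph) and an alignment walk (on the
#' canonical graph).
#'
#' @param gc a `canonical_graph`.
#' @param segments character vector of original segment names.
#' @return integer vector of canonical vertex ids.
#' @export
segment_nodes <- function(gc, segments) {
  which(gc$origin$segment %in% segments)
}

#' Edit distance between a query and the sequence spelled by a walk
#'
#' Plain Levenshtein distance (unit costs) between the query and
#' `spell_path(g, walk)`.
#'
#' @param query query string.
#' @param g a variation graph.
#' @param walk integer vertex ids.
#' @return nonnegative integer.
#' @export
edit_distance_to_path <- function(query, g, walk) {
  as.integer(utils::adist(query, spell_path(g, walk)))
}

#' Minimum number of path switches explaining a walk
#'
#' The smallest `k` such that the walk splits into `k + 1` consecutive
#' blocks, each a *contiguous* subpath of a single distinguished path.
#' Computed by dynamic programming over (walk position x path) with unit
#' switch cost; a walk that follows one path throughout costs 0.
#'
#' @param walk integer vertex ids.
#' @param g a variation graph.
#' @return nonnegative integer.
#' @export
min_switches <- function(walk, g) {
  K <- length(walk)
  if (K == 0L) stop("empty walk")
  P <- length(g$paths)
  pos <- vapply(g$paths, function(p) match(walk, p), integer(K))
  pos <- matrix(pos, nrow = K)
  on <- !is.na(pos)
  orphan <- which(rowSums(on) == 0L)
  if (length(orphan) > 0L)
    stop("walk vertex at position ", orphan[1L], " lies on no path")
  f <- ifelse(on[1L, ], 0, Inf)
  if (K > 1L) for (i in 2:K) {
    contig <- on[i, ] & on[i - 1L, ] & (pos[i, ] == pos[i - 1L, ] + 1L)
    stay <- ifelse(contig, f, Inf)
    f <- ifelse(on[i, ], pmin(stay, min(f) + 1), Inf)
  }
  as.integer(min(f))
}

#' Breakpoint localisation error
#'
#' Absolute distance in bp between the reported and the true breakpoint.
#' A missing report when the truth contains a recombination is a miss, not
#' a distance: `NA` is returned.
#'
#' @param reported reported breakpoint (query coordinate) or `NULL`/`NA`.
#' @param true_breakpoint simulated breakpoint.
#' @return nonnegative numeric, or `NA` for a miss.
#' @export
breakpoint_error <- function(reported, true_breakpoint) {
  if (is.null(reported) || is.na(reported)) return(NA_real_)
  abs(as.numeric(reported) - as.numeric(true_breakpoint))
}

#' Variant-free window around a simulated breakpoint
#'
#' All breakpoints inside the returned interval `[lo, hi]` produce the
#' same mosaic sequence and are therefore indistinguishable from the true
#' one: `hi` is the longest common prefix of the query with the first
#' parent's sequence, and `lo` marks the longest common suffix with the
#' second parent's.  A correctly recovered breakpoint must fall inside
#' this window.
#'
#' @param query the simulated recombinant sequence.
#' @param spell_p1,spell_p2 full spelled sequences of the two parents.
#' @return integer vector `c(lo, hi)`.
#' @export
breakpoint_window <- function(query, spell_p1, spell_p2) {
  q <- split_chars(query)
  a <- split_chars(spell_p1)
  b <- split_chars(spell_p2)
  n <- length(q)
  k <- min(n, length(a))
  pref <- if (k == 0L) 0L else {
    neq <- which(q[seq_len(k)] != a[seq_len(k)])
    if (length(neq) == 0L) k else neq[1L] - 1L
  }
  k <- min(n, length(b))
  suf <- if (k == 0L) 0L else {
    neq <- which(rev(q)[seq_len(k)] != rev(b)[seq_len(k)])
    if (length(neq) == 0L) k else neq[1L] - 1L
  }
  c(lo = n - suf, hi = pref)
}

#' Per-query accuracy metrics table
#'
#' One row per alignment record: Jaccard node similarity against the truth
#' walk, edit distance between the query and the spelled alignment walk,
#' the minimum number of path switches explaining the walk, the breakpoint
#' error, and whether a recombination was reported.
#'
#' @param records list of `graph_alignment` objects.
#' @param truths list of truth records (as produced by
#'   [simulate_recombinant()], `$truth`), parallel to `records`.
#' @param g the original variation graph the truths refer to.
#' @param gc its canonical form used for alignment.
#' @return a data frame.
#' @export
alignment_metrics <- function(records, truths, g, gc) {
  stopifnot(length(records) == length(truths))
  rows <- lapply(seq_along(records), function(i) {
    a <- records[[i]]; tr <- truths[[i]]
    true_segs <- g$seg_names[setdiff(tr$walk, c(g$source, g$sink))]
    rec <- a$recombination
    data.frame(
      query = a$query_name,
      score = a$score,
      jaccard = jaccard_nodes(segment_nodes(gc, true_segs), a$walk),
      edit_distance = edit_distance_to_path(a$query, gc, a$walk),
      n_switches = min_switches(a$walk, gc),
      recombination = !is.null(rec),
      breakpoint = if (is.null(rec)) NA_integer_ else rec$breakpoint,
      breakpoint_error = if (isTRUE(tr$recombinant))
        breakpoint_error(if (is.null(rec)) NA else rec$breakpoint,
                         tr$breakpoint) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
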