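#' Scoring scheme for graph alignment
#'
#' Penalties are stored as nonnegative magnitudes and subtracted in the
#' recurrences, so `mismatch = 4` means each mismatching column contributes
#' -4.  The defaults are the configuration used throughout for bacterial
#' gene graphs: match 2, mismatch 4, gap 4 (linear), recombination opening
#' 4, recombination extension 0.1 per displacement unit, and a breakpoint
#' window covering the middle 95% of the query.
#'
#' @param match nonnegative match score per column.
#' @param mismatch nonnegative mismatch penalty magnitude.
#' @param gap nonnegative per-column gap penalty magnitude (linear model).
#' @param rec_open nonnegative recombination opening penalty (d_o).
#' @param rec_ext nonnegative recombination extension penalty per
#'   displacement unit (d_e); may be fractional.
#' @param window fraction in (0, 1] of the query length within which a
#'   recombination breakpoint may be placed (centred window); 1 allows any
#'   breakpoint.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = 4, gap = 4,
                           rec_open = 4, rec_ext = 0.1, window = 0.95) {
  stopifnot(match >= 0, mismatch >= 0, gap >= 0,
            rec_open >= 0, rec_ext >= 0, window > 0, window <= 1)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 rec_open = rec_open, rec_ext = rec_ext, window = window),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "scoring scheme: match %g, mismatch %g, gap %g (linear), rec-open %g, rec-ext %g, window %g\n",
    x$match, x$mismatch, x$gap, x$rec_open, x$rec_ext, x$window))
  invisible(x)
}

# Global Needleman-Wunsch matrix of a query against a reference character
# chain, linear gaps.  Rows r = 0..m reference characters consumed, columns
# i = 0..n query characters consumed.  Each row is filled with vectorised
# pmax; the serial within-row dependency M[r,i] = max(cand[i], M[r,i-1]-g)
# collapses to a cummax because the gap model is linear:
#   M[r,i] = cummax(c(M[r,0], cand + g*i))[i+1] - g*i.
nw_row_matrix <- function(ref, qry, sc) {
  m <- length(ref); n <- length(qry)
  gp <- sc$gap
  mat <- matrix(0, nrow = m + 1L, ncol = n + 1L)
  mat[1L, ] <- -gp * (0:n)
  if (m == 0L) return(mat)
  iseq <- seq_len(n)
  for (r in seq_len(m)) {
    prev <- mat[r, ]
    first <- prev[1L] - gp
    if (n == 0L) { mat[r + 1L, 1L] <- first; next }
    sub <- ifelse(ref[r] == qry, sc$match, -sc$mismatch)
    cand <- pmax(prev[-1L] - gp, prev[-(n + 1L)] + sub)
    mat[r + 1L, ] <- cummax(c(first, cand + gp * iseq)) - gp * (0:n)
  }
  mat
}

# Traceback through an nw_row_matrix from cell (r_end, i_end) to (0, 0).
# Deterministic preference: match/mismatch, then vertical gap (reference
# consumed, gap in query), then horizontal gap.  Returns columns as two
# integer vectors x (reference char index or NA) and y (query index or NA).
nw_traceback <- function(mat, ref, qry, sc, r_end, i_end) {
  x <- integer(0L); y <- integer(0L)
  r <- r_end; i <- i_end
  while (r > 0L || i > 0L) {
    here <- mat[r + 1L, i + 1L]
    if (r > 0L && i > 0L &&
        here == mat[r, i] + (if (ref[r] == qry[i]) sc$match else -sc$mismatch)) {
      x <- c(r, x); y <- c(i, y); r <- r - 1L; i <- i - 1L
    } else if (r > 0L && here == mat[r, i + 1L] - sc$gap) {
      x <- c(r, x); y <- c(NA_integer_, y); r <- r - 1L
    } else {
      x <- c(NA_integer_, x); y <- c(i, y); i <- i - 1L
    }
  }
  list(x = x, y = y)
}

split_chars <- function(s) {
  if (nchar(s) == 0L) character(0L) else strsplit(s, "", fixed = TRUE)[[1L]]
}

# Forward matrices for all paths: per path a list(ids, chars, mat) where
# mat[r+1, i+1] = M[v, i, p] for v the r-th labelled vertex of p (r = 0 is
# the source row, r = m_p also stands for the sink since its label is
# empty).
forward_all <- function(gc, qchars, sc) {
  lapply(names(gc$paths), function(nm) {
    ids <- path_labelled(gc, nm)
    chars <- gc$labels[ids]
    list(name = nm, ids = ids, chars = chars,
         mat = nw_row_matrix(chars, qchars, sc))
  })
}

# Backward matrices: per path a matrix S with S[c, j+1] = R[v, j, p] =
# optimal score of aligning the query suffix s[(j+1)..n] against the path
# portion spelled by characters c..m_p (row m_p+1 is the empty portion,
# i.e. the sink).  Computed by running the forward recurrence on the
# reversed instance and flipping indices.
backward_all <- function(gc, qchars, sc) {
  n <- length(qchars)
  lapply(names(gc$paths), function(nm) {
    ids <- path_labelled(gc, nm)
    chars <- gc$labels[ids]
    m <- length(chars)
    rev_mat <- nw_row_matrix(rev(chars), rev(qchars), sc)
    list(name = nm, ids = ids, chars = chars, rev_mat = rev_mat,
         smat = rev_mat[(m + 1L):1L, (n + 1L):1L, drop = FALSE])
  })
}

#' Forward dynamic-programming matrices
#'
#' Fills, for every path `p` of the canonical graph, the matrix of optimal
#' global-alignment scores `M[v, i, p]` between the initial portion of `p`
#' ending at vertex `v` and the `i`-long query prefix, with the four-case
#' linear-gap recurrence (vertical gap, horizontal gap, mismatch, match).
#' Off-path entries are conceptually `-Inf` and are not materialised: each
#' path is stored as one dense (|p|+1) x (n+1) table.
#'
#' @param gc a `canonical_graph`.
#' @param query a query string.
#' @param sc a [scoring_scheme()].
#' @return an object of class `dp_state` with components `forward` (per-path
#'   tables) and `best` (per-(vertex, position) best and second-best scores
#'   over paths, the second best constrained to a different path).
#' @export
forward_matrices <- function(gc, query, sc = scoring_scheme()) {
  qchars <- split_chars(query)
  fw <- forward_all(gc, qchars, sc)
  structure(list(query = query, n = length(qchars), sc = sc,
                 forward = fw,
                 best = best_summaries(gc, fw, side = "M")),
            class = "dp_state")
}

#' Backward dynamic-programming matrices
#'
#' The mirrored suffix matrices `R[v, i, p]`: the optimal score of aligning
#' the query suffix starting after position `i` against the final portion
#' of path `p` starting at vertex `v`.  Equivalent to the forward pass on
#' the arc-reversed graph with the reversed query, index-mapped back.
#'
#' @inheritParams forward_matrices
#' @return an object of class `dp_state` with components `backward` and
#'   `best` (per-(vertex, position) best/second-best over paths).
#' @export
backward_matrices <- function(gc, query, sc = scoring_scheme()) {
  qchars <- split_chars(query)
  bw <- backward_all(gc, qchars, sc)
  structure(list(query = query, n = length(qchars), sc = sc,
                 backward = bw,
                 best = best_summaries(gc, bw, side = "R")),
            class = "dp_state")
}

#' Combined forward/backward state
#'
#' Computes both passes plus the per-(vertex, position) best and
#' second-best path summaries needed to place a recombination while
#' honouring the two-different-paths requirement.
#'
#' @inheritParams forward_matrices
#' @return a `dp_state` with `forward`, `backward`, `bestM`, `bestR`.
#' @export
dp_state <- function(gc, query, sc = scoring_scheme()) {
  qchars <- split_chars(query)
  fw <- forward_all(gc, qchars, sc)
  bw <- backward_all(gc, qchars, sc)
  structure(list(query = query, n = length(qchars), sc = sc,
                 forward = fw, backward = bw,
                 bestM = best_summaries(gc, fw, side = "M"),
                 bestR = best_summaries(gc, bw, side = "R")),
            class = "dp_state")
}

# Vertex-level best/second-best over paths.  For side "M", score[v, i+1] =
# M[v, i, p]; for side "R", score[v, i+1] = R[v, i, p].  The second best is
# constrained to come from a different path than the best.
best_summaries <- function(gc, tables, side = c("M", "R")) {
  side <- match.arg(side)
  nv <- length(gc$labels)
  n1 <- ncol(if (side == "M") tables[[1L]]$mat else tables[[1L]]$smat)
  best <- matrix(-Inf, nv, n1); best_p <- matrix(NA_integer_, nv, n1)
  best2 <- matrix(-Inf, nv, n1); best2_p <- matrix(NA_integer_, nv, n1)
  for (pi in seq_along(tables)) {
    tb <- tables[[pi]]
    m <- length(tb$ids)
    if (side == "M") {
      verts <- c(gc$paths[[pi]][1L], tb$ids, gc$paths[[pi]][length(gc$paths[[pi]])])
      rows <- tb$mat[c(1L, seq_len(m) + 1L, m + 1L), , drop = FALSE]
    } else {
      verts <- c(gc$paths[[pi]][1L], tb$ids, gc$paths[[pi]][length(gc$paths[[pi]])])
      rows <- tb$smat[c(1L, seq_len(m), m + 1L), , drop = FALSE]
    }
    for (k in seq_along(verts)) {
      v <- verts[k]; s <- rows[k, ]
      gt <- s > best[v, ]
      # displaced best becomes candidate second best (different path by
      # construction); otherwise challenge the second best directly
      new2 <- ifelse(gt, best[v, ], ifelse(s > best2[v, ], s, best2[v, ]))
      new2_p <- ifelse(gt, best_p[v, ], ifelse(s > best2[v, ], pi, best2_p[v, ]))
      best2[v, ] <- new2; best2_p[v, ] <- new2_p
      best_p[v, ] <- ifelse(gt, pi, best_p[v, ])
      best[v, ] <- ifelse(gt, s, best[v, ])
    }
  }
  list(best = best, best_path = best_p, best2 = best2, best2_path = best2_p)
}

#' Optimal alignment without recombination
#'
#' Aligns the query globally against every distinguished path and returns
#' the best one: the path `p*` maximizing `M[sink, n, p]`, its score, and a
#' full traceback as ordered column pairs.  Ties between paths are broken
#' by the smallest path index; traceback ties prefer match/mismatch over a
#' vertical gap over a horizontal gap, so output is deterministic.
#'
#' @inheritParams forward_matrices
#' @param name query name carried into the record.
#' @return a `graph_alignment` record: `walk` (labelled canonical vertex
#'   ids), `columns` (data frame of x = walk position, y = query position,
#'   `NA` marking gaps), `score`, `path_name`, and `recombination = NULL`.
#' @export
align_no_recombination <- function(gc, query, sc = scoring_scheme(),
                                   name = "query") {
  qchars <- split_chars(query)
  if (length(qchars) == 0L) stop("empty query")
  fw <- forward_all(gc, qchars, sc)
  finals <- vapply(fw, function(tb) tb$mat[nrow(tb$mat), ncol(tb$mat)],
                   numeric(1L))
  bi <- which.max(finals)  # first maximum = smallest path index
  tb <- fw[[bi]]
  cols <- nw_traceback(tb$mat, tb$chars, qchars, sc,
                       r_end = length(tb$chars), i_end = length(qchars))
  new_alignment(name = name, query = query, walk = tb$ids,
                columns = data.frame(x = cols$x, y = cols$y),
                score = finals[bi], path_name = tb$name,
                recombination = NULL)
}

new_alignment <- function(name, query, walk, columns, score, path_name,
                          recombination) {
  structure(list(query_name = name, query = query,
                 query_len = nchar(query), walk = walk, columns = columns,
                 score = score, path_name = path_name,
                 recombination = recombination),
            class = "graph_alignment")
}

#' @export
print.graph_alignment <- function(x, ...) {
  cat(sprintf("graph alignment of '%s' (%d bp): score %g, path %s\n",
              x$query_name, x$query_len, x$score,
              paste(x$path_name, collapse = " -> ")))
  if (!is.null(x$recombination)) {
    ev <- x$recombination
    cat(sprintf(
      "  recombination %s -> %s at breakpoint %d (displacement %g)\n",
      ev$p1, ev$p2, ev$breakpoint, ev$displacement))
  }
  invisible(x)
}

#' Re-score an alignment record from its columns
#'
#' Independent check of every traceback: validates the column pairs
#' (strictly increasing non-gap positions on both sides, no gap-only
#' columns, each walk and query position used exactly once) and sums
#' per-column substitution scores plus linear gap penalties over the
#' maximal gap runs.  For a record carrying a recombination event the
#' affine recombination penalty `rec_open + rec_ext * displacement` is
#' subtracted as well (disable with `include_recombination_penalty =
#' FALSE` to obtain the bare alignment value).
#'
#' @param a a `graph_alignment`.
#' @param gc the `canonical_graph` it was computed on.
#' @param query the query string.
#' @param sc the [scoring_scheme()].
#' @param include_recombination_penalty subtract the recombination penalty
#'   when an event is present (default `TRUE`).
#' @return the numeric score.
#' @export
rescore_alignment <- function(a, gc, query, sc = scoring_scheme(),
                              include_recombination_penalty = TRUE) {
  x <- a$columns$x; y <- a$columns$y
  if (any(is.na(x) & is.na(y))) stop("gap-only column")
  xs <- x[!is.na(x)]; ys <- y[!is.na(y)]
  if (!identical(as.integer(xs), seq_along(a$walk)))
    stop("walk positions must each appear exactly once, in order")
  if (!identical(as.integer(ys), seq_len(nchar(query))))
    stop("query positions must each appear exactly once, in order")
  labs <- gc$labels[a$walk]
  qchars <- split_chars(query)
  both <- !is.na(x) & !is.na(y)
  subs <- ifelse(labs[x[both]] == qchars[y[both]], sc$match, -sc$mismatch)
  score <- sum(subs) - sc$gap * sum(!both)
  if (include_recombination_penalty && !is.null(a$recombination))
    score <- score - sc$rec_open - sc$rec_ext * a$recombination$displacement
  score
}
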