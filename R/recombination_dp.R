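#' Tabulate recombination displacements over all path pairs
#'
#' For every ordered pair of distinct paths the table records the
#' positions of their shared vertices on both paths (acyclicity guarantees
#' the shared vertices occur in the same relative order on the two paths)
#' together with, for every position, the index of the nearest shared
#' vertex strictly before and strictly after it.  Any displacement query
#' `(p1, p2, rho, psi)` is then answered in O(1): the branching vertex is
#' the deepest shared vertex preceding both recombination vertices and the
#' consolidating vertex the shallowest shared vertex following both.
#' Construction scans each path pair once.
#'
#' @param gc a `canonical_graph` (any validated variation graph works).
#' @return an object of class `displacement_table`.
#' @export
build_displacement_table <- function(gc) {
  nms <- names(gc$paths)
  pairs <- list()
  for (i1 in seq_along(nms)) for (i2 in seq_along(nms)) {
    if (i1 == i2) next
    v1 <- gc$paths[[i1]]; v2 <- gc$paths[[i2]]
    posP <- which(v1 %in% v2)
    shared <- v1[posP]
    posQ <- match(shared, v2)
    if (is.unsorted(posQ, strictly = TRUE))
      stop("shared vertices out of order; graph is not acyclic?")
    L1 <- length(v1); L2 <- length(v2)
    pairs[[paste(nms[i1], nms[i2], sep = "\r")]] <- list(
      p1 = nms[i1], p2 = nms[i2], verts1 = v1, verts2 = v2,
      shared = shared, posP = posP, posQ = posQ,
      kA1 = findInterval(seq_len(L1) - 1L, posP),
      kB1 = findInterval(seq_len(L1), posP) + 1L,
      kA2 = findInterval(seq_len(L2) - 1L, posQ),
      kB2 = findInterval(seq_len(L2), posQ) + 1L)
  }
  structure(list(path_names = nms, pairs = pairs),
            class = "displacement_table")
}

pair_entry <- function(tab, p1, p2) {
  e <- tab$pairs[[paste(p1, p2, sep = "\r")]]
  if (is.null(e)) stop("unknown path pair: ", p1, ", ", p2)
  e
}

#' Displacement of a recombination
#'
#' Locates the branching vertex `alpha` (deepest vertex shared by both
#' paths that strictly precedes `rho` on `p1` and `psi` on `p2`) and the
#' consolidating vertex `beta` (shallowest shared vertex strictly
#' following both), and evaluates the displacement
#' `||a1| - |a2| + 1| + ||b1| - |b2| - 1|`, where `a1` is the subpath of
#' `p1` from `alpha` to `rho`, `b1` from `rho` to `beta`, and `a2`, `b2`
#' the analogues on `p2`, all vertex counts inclusive of both endpoints.
#' The recombination vertices must be labelled vertices (not the source or
#' sink, for which no branching/consolidating vertex exists).
#'
#' @param tab a [build_displacement_table()] result.
#' @param p1,p2 names of two distinct paths.
#' @param rho vertex id on `p1` where the prefix alignment ends.
#' @param psi vertex id on `p2` where the suffix alignment starts.
#' @return a list with `alpha`, `beta` (vertex ids), the four subpath
#'   vertex counts `a1_len`, `a2_len`, `b1_len`, `b2_len`, and
#'   `displacement`.
#' @export
displacement <- function(tab, p1, p2, rho, psi) {
  if (p1 == p2) stop("recombination requires two different paths")
  e <- pair_entry(tab, p1, p2)
  r <- match(rho, e$verts1)
  t <- match(psi, e$verts2)
  if (is.na(r)) stop("rho is not a vertex of path ", p1)
  if (is.na(t)) stop("psi is not a vertex of path ", p2)
  kA <- min(e$kA1[r], e$kA2[t])
  kB <- max(e$kB1[r], e$kB2[t])
  if (kA < 1L || kB > length(e$shared))
    stop("no branching/consolidating vertex: rho and psi must be labelled vertices")
  a1 <- r - e$posP[kA] + 1L
  a2 <- t - e$posQ[kA] + 1L
  b1 <- e$posP[kB] - r + 1L
  b2 <- e$posQ[kB] - t + 1L
  list(alpha = e$shared[kA], beta = e$shared[kB],
       a1_len = a1, a2_len = a2, b1_len = b1, b2_len = b2,
       displacement = abs(a1 - a2 + 1L) + abs(b1 - b2 - 1L))
}

# Displacement matrix for one ordered path pair over all labelled vertex
# pairs: D[c1, c2] is the displacement of switching after the c1-th
# labelled vertex of p1 onto the c2-th labelled vertex of p2.  Labelled
# vertex c sits at path position c + 1 (position 1 is the source).
pair_displacement_matrix <- function(e) {
  m1 <- length(e$verts1) - 2L
  m2 <- length(e$verts2) - 2L
  rv <- seq_len(m1) + 1L
  tw <- seq_len(m2) + 1L
  KA <- pmin(matrix(e$kA1[rv], m1, m2), matrix(e$kA2[tw], m1, m2, byrow = TRUE))
  KB <- pmax(matrix(e$kB1[rv], m1, m2), matrix(e$kB2[tw], m1, m2, byrow = TRUE))
  RV <- matrix(rv, m1, m2)
  TW <- matrix(tw, m1, m2, byrow = TRUE)
  abs((RV - e$posP[KA]) - (TW - e$posQ[KA]) + 1L) +
    abs((e$posP[KB] - RV) - (e$posQ[KB] - TW) - 1L)
}

# Breakpoint window: query indices j (prefix length) allowed to host a
# recombination.  A window fraction f maps to the centred interval
# [ceil(n(1-f)/2), floor(n(1+f)/2)], clamped to [1, n] since an alignment
# with a recombination requires a nonempty prefix.
breakpoint_window_indices <- function(n, window) {
  lo <- max(1L, as.integer(ceiling(n * (1 - window) / 2)))
  hi <- min(n, as.integer(floor(n * (1 + window) / 2)))
  if (lo > hi) integer(0L) else lo:hi
}

#' Optimal alignment with at most one recombination
#'
#' Combines the forward and backward per-path matrices: the result is the
#' better of (a) the optimal no-recombination alignment and (b) the best
#' juxtaposition, over all ordered pairs of distinct paths `(p, q)`, all
#' vertex pairs `(v, w)` and all breakpoints `j` inside the window, of the
#' prefix alignment `M[v, j, p]`, the suffix alignment `R[w, j+1, q]`, and
#' the affine recombination penalty `rec_open + rec_ext * d(v, w)` with
#' `d` the tabulated displacement for that path pair.  Iterating over all
#' distinct path pairs (rather than only the per-cell argmax paths)
#' guarantees the reported score is the exact optimum even though the
#' displacement term depends on which pair is chosen.
#'
#' Ties are resolved deterministically: no recombination on a tie with
#' case (a); otherwise smallest breakpoint, then smallest `(v, w)` in
#' topological order, then lexicographically smallest `(p, q)`.
#'
#' @inheritParams align_no_recombination
#' @param tab optional precomputed [build_displacement_table()]; computed
#'   on the fly when `NULL`.
#' @return a `graph_alignment`; when case (b) wins it carries a
#'   `recombination` event (paths, recombination vertices `rho`/`psi`,
#'   branching/consolidating vertices, subpath lengths, displacement,
#'   breakpoint, and whether the junction needed a virtual arc) and its
#'   walk is the mosaic of the two path portions, with exactly one virtual
#'   arc when `(rho, psi)` is not an arc of the graph.
#' @export
align_with_recombination <- function(gc, query, sc = scoring_scheme(),
                                     name = "query", tab = NULL) {
  qchars <- split_chars(query)
  if (length(qchars) == 0L) stop("empty query")
  n <- length(qchars)
  base <- align_no_recombination(gc, query, sc, name = name)
  nms <- names(gc$paths)
  jwin <- breakpoint_window_indices(n, sc$window)
  if (length(nms) < 2L || length(jwin) == 0L || !is.finite(sc$rec_open))
    return(base)
  if (is.null(tab)) tab <- build_displacement_table(gc)
  fw <- forward_all(gc, qchars, sc)
  bw <- backward_all(gc, qchars, sc)

  best <- NULL  # list(score, j, v, w, i1, i2)
  better <- function(a, b) {
    if (a$score != b$score) return(a$score > b$score)
    if (a$j != b$j) return(a$j < b$j)
    if (a$v != b$v) return(a$v < b$v)
    if (a$w != b$w) return(a$w < b$w)
    if (nms[a$i1] != nms[b$i1]) return(nms[a$i1] < nms[b$i1])
    nms[a$i2] < nms[b$i2]
  }
  ord <- order(nms)
  for (i1 in ord) for (i2 in ord) {
    if (i1 == i2) next
    e <- pair_entry(tab, nms[i1], nms[i2])
    D <- pair_displacement_matrix(e)
    m1 <- nrow(D); m2 <- ncol(D)
    if (m1 == 0L || m2 == 0L) next
    pen <- -sc$rec_ext * D - sc$rec_open
    ids1 <- fw[[i1]]$ids; ids2 <- bw[[i2]]$ids
    Amat <- fw[[i1]]$mat; Smat <- bw[[i2]]$smat
    for (j in jwin) {
      a <- Amat[seq_len(m1) + 1L, j + 1L]
      b <- Smat[seq_len(m2), j + 1L]
      S <- pen + a + rep(b, each = m1)
      mx <- max(S)
      if (!is.null(best) && mx < best$score) next
      hits <- which(S == mx)
      vi <- (hits - 1L) %% m1 + 1L
      wi <- (hits - 1L) %/% m1 + 1L
      k <- order(ids1[vi], ids2[wi])[1L]
      cand <- list(score = mx, j = j, v = ids1[vi[k]], w = ids2[wi[k]],
                   i1 = i1, i2 = i2, c1 = vi[k], c2 = wi[k])
      if (is.null(best) || better(cand, best)) best <- cand
    }
  }
  if (is.null(best) || best$score <= base$score) return(base)

  # build the mosaic record
  i1 <- best$i1; i2 <- best$i2; j <- best$j
  tb1 <- fw[[i1]]; tb2 <- bw[[i2]]
  c1 <- best$c1; c2 <- best$c2
  m2 <- length(tb2$chars)
  pre <- nw_traceback(tb1$mat, tb1$chars, qchars, sc, r_end = c1, i_end = j)
  # suffix traceback runs in the reversed instance, then indices are
  # mirrored back and the columns reversed
  suf_rev <- nw_traceback(tb2$rev_mat, rev(tb2$chars), rev(qchars), sc,
                          r_end = m2 - c2 + 1L, i_end = n - j)
  suf_x <- rev(ifelse(is.na(suf_rev$x), NA_integer_, m2 - suf_rev$x + 1L))
  suf_y <- rev(ifelse(is.na(suf_rev$y), NA_integer_, n - suf_rev$y + 1L))
  walk <- c(tb1$ids[seq_len(c1)], tb2$ids[c2:m2])
  cols <- data.frame(
    x = c(pre$x, ifelse(is.na(suf_x), NA_integer_, suf_x - c2 + 1L + c1)),
    y = c(pre$y, suf_y))
  ev <- displacement(tab, nms[i1], nms[i2], rho = best$v, psi = best$w)
  arc_exists <- paste(best$v, best$w) %in% arc_keys(gc)
  event <- list(p1 = nms[i1], p2 = nms[i2], rho = best$v, psi = best$w,
                alpha = ev$alpha, beta = ev$beta,
                a1_len = ev$a1_len, a2_len = ev$a2_len,
                b1_len = ev$b1_len, b2_len = ev$b2_len,
                displacement = ev$displacement, breakpoint = j,
                virtual_arc = !(arc_exists || best$v == best$w))
  new_alignment(name = name, query = query, walk = walk, columns = cols,
                score = best$score,
                path_name = c(nms[i1], nms[i2]), recombination = event)
}

#' Best distinct path pair for a candidate recombination cell
#'
#' Given the per-(vertex, position) best and second-best path summaries of
#' a [dp_state()], returns the pair of *different* paths `(p, q)` among the
#' best/second-best choices on each side maximizing
#' `M[v, j, p] + R[w, j+1, q]`, as required by the definition of a
#' recombination.  Returns `-Inf` when no distinct finite pair exists.
#'
#' @param state a [dp_state()].
#' @param v,w vertex ids (prefix end, suffix start).
#' @param j breakpoint (prefix length).
#' @return list with `prefix_path`, `suffix_path` (names or `NA`), `score`.
#' @export
enforce_distinct_paths <- function(state, v, w, j) {
  if (is.null(state$bestM)) stop("state must carry both passes; use dp_state()")
  bm <- state$bestM; br <- state$bestR
  sM <- bm$best[v, j + 1L]; pM <- bm$best_path[v, j + 1L]
  s2M <- bm$best2[v, j + 1L]; p2M <- bm$best2_path[v, j + 1L]
  sR <- br$best[w, j + 1L]; qR <- br$best_path[w, j + 1L]
  s2R <- br$best2[w, j + 1L]; q2R <- br$best2_path[w, j + 1L]
  nms <- vapply(state$forward, `[[`, character(1L), "name")
  res <- function(pi, qi, s) {
    if (!is.finite(s) || is.na(pi) || is.na(qi))
      list(prefix_path = NA_character_, suffix_path = NA_character_,
           score = -Inf)
    else list(prefix_path = nms[pi], suffix_path = nms[qi], score = s)
  }
  if (!is.na(pM) && !is.na(qR) && pM != qR) return(res(pM, qR, sM + sR))
  cand1 <- if (!is.na(q2R)) sM + s2R else -Inf
  cand2 <- if (!is.na(p2M)) s2M + sR else -Inf
  if (cand1 >= cand2) res(pM, q2R, cand1) else res(p2M, qR, cand2)
}
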