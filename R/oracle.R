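#' Textbook global alignment score (reference implementation)
#'
#' Plain cell-by-cell Needleman-Wunsch with linear gap penalties, sharing
#' no code with the row-vectorised matrices used by the aligner.  Used as
#' an independent check, not for performance.
#'
#' @param a,b strings to align globally.
#' @param sc a [scoring_scheme()]; only match/mismatch/gap are used.
#' @return the optimal global alignment score.
#' @export
nw_global <- function(a, b, sc = scoring_scheme()) {
  A <- split_chars(a); B <- split_chars(b)
  oracle_nw_matrix(A, B, sc)[length(A) + 1L, length(B) + 1L]
}

# Full forward matrix, explicit loops over every cell.
oracle_nw_matrix <- function(A, B, sc) {
  la <- length(A); lb <- length(B)
  M <- matrix(0, la + 1L, lb + 1L)
  M[, 1L] <- -sc$gap * (0:la)
  M[1L, ] <- -sc$gap * (0:lb)
  if (la > 0L && lb > 0L) {
    for (r in 1:la) for (i in 1:lb) {
      d <- if (A[r] == B[i]) sc$match else -sc$mismatch
      M[r + 1L, i + 1L] <- max(M[r, i] + d,
                               M[r, i + 1L] - sc$gap,
                               M[r + 1L, i] - sc$gap)
    }
  }
  M
}

# Suffix matrix filled by its own backward recurrence: T[c, i+1] is the
# optimal score of aligning the query suffix starting after position i
# against reference characters c..m (row m+1 = empty reference portion).
oracle_suffix_matrix <- function(A, B, sc) {
  la <- length(A); lb <- length(B)
  T <- matrix(0, la + 1L, lb + 1L)
  T[la + 1L, ] <- -sc$gap * (lb:0)
  T[, lb + 1L] <- -sc$gap * (la:0)
  if (la > 0L && lb > 0L) {
    for (c in la:1) for (i in (lb - 1L):0) {
      d <- if (A[c] == B[i + 1L]) sc$match else -sc$mismatch
      T[c, i + 1L] <- max(T[c + 1L, i + 2L] + d,
                          T[c + 1L, i + 1L] - sc$gap,
                          T[c, i + 2L] - sc$gap)
    }
  }
  T
}

#' Branching/consolidating vertices and displacement by naive scan
#'
#' Oracle twin of [displacement()]: finds the branching vertex by
#' intersecting the sets of vertices strictly preceding `rho` on `p1` and
#' strictly preceding `psi` on `p2` and taking the deepest, symmetrically
#' the consolidating vertex, then applies the displacement formula
#' directly.  No tabulation.
#'
#' @param g a variation graph (canonical or not).
#' @param p1,p2 names of two distinct paths.
#' @param rho,psi vertex ids on `p1` and `p2`.
#' @return list with `alpha`, `beta`, `displacement`.
#' @export
naive_alpha_beta_displacement <- function(g, p1, p2, rho, psi) {
  if (p1 == p2) stop("recombination requires two different paths")
  v1 <- g$paths[[p1]]; v2 <- g$paths[[p2]]
  if (is.null(v1) || is.null(v2)) stop("unknown path name")
  r <- match(rho, v1); t <- match(psi, v2)
  if (is.na(r)) stop("rho is not a vertex of path ", p1)
  if (is.na(t)) stop("psi is not a vertex of path ", p2)
  pre <- v1[seq_len(r - 1L)]
  pre <- pre[pre %in% v2[seq_len(t - 1L)]]
  post <- v1[seq_len(length(v1) - r) + r]
  post <- post[post %in% v2[seq_len(length(v2) - t) + t]]
  if (length(pre) == 0L || length(post) == 0L)
    stop("no branching/consolidating vertex: rho and psi must be labelled vertices")
  alpha <- pre[length(pre)]
  beta <- post[1L]
  a1 <- r - match(alpha, v1) + 1L
  a2 <- t - match(alpha, v2) + 1L
  b1 <- match(beta, v1) - r + 1L
  b2 <- match(beta, v2) - t + 1L
  list(alpha = alpha, beta = beta,
       displacement = abs(a1 - a2 + 1L) + abs(b1 - b2 - 1L))
}

#' Brute-force recombination-aware optimum
#'
#' Exhaustive reference for the aligner: takes the maximum of (i) every
#' path's global alignment score against the query and (ii), for every
#' ordered pair of distinct paths, every prefix-end vertex on the first,
#' every suffix-start vertex on the second and every breakpoint in the
#' window, the sum of the two half scores minus the affine recombination
#' penalty with the naively scanned displacement.  Guarded to small
#' instances; intended purely as a test oracle.
#'
#' @param gc a `canonical_graph`.
#' @param query query string.
#' @param sc a [scoring_scheme()].
#' @return list with `score`, `no_recombination_score`, `has_recombination`,
#'   and `tie_set`, a data frame of all optimal `(p1, p2, j, rho, psi)`
#'   combinations when a recombination wins (empty otherwise).
#' @export
brute_force_recombination <- function(gc, query, sc = scoring_scheme()) {
  nms <- names(gc$paths)
  n <- nchar(query)
  if (length(nms) > 8L || n > 100L || length(gc$labels) > 200L)
    stop("instance too large for the brute-force oracle")
  B <- split_chars(query)
  mats <- lapply(nms, function(nm) {
    ids <- path_labelled(gc, nm)
    A <- gc$labels[ids]
    list(ids = ids, A = A,
         fwd = oracle_nw_matrix(A, B, sc),
         suf = oracle_suffix_matrix(A, B, sc))
  })
  names(mats) <- nms
  norec <- max(vapply(mats, function(m)
    m$fwd[nrow(m$fwd), ncol(m$fwd)], numeric(1L)))
  jwin <- breakpoint_window_indices(n, sc$window)
  best <- -Inf
  ties <- list()
  if (length(nms) >= 2L && length(jwin) > 0L && is.finite(sc$rec_open)) {
    for (p1 in nms) for (p2 in nms) {
      if (p1 == p2) next
      m1 <- mats[[p1]]; m2 <- mats[[p2]]
      k1 <- length(m1$A); k2 <- length(m2$A)
      if (k1 == 0L || k2 == 0L) next
      D <- matrix(0, k1, k2)
      for (c1 in seq_len(k1)) for (c2 in seq_len(k2)) {
        D[c1, c2] <- naive_alpha_beta_displacement(
          gc, p1, p2, m1$ids[c1], m2$ids[c2])$displacement
      }
      for (c1 in seq_len(k1)) for (j in jwin) {
        sc2b <- m1$fwd[c1 + 1L, j + 1L] + m2$suf[seq_len(k2), j + 1L] -
          sc$rec_open - sc$rec_ext * D[c1, ]
        mx <- max(sc2b)
        if (mx > best) { best <- mx; ties <- list() }
        if (mx == best) {
          for (c2 in which(sc2b == best)) {
            ties[[length(ties) + 1L]] <- data.frame(
              p1 = p1, p2 = p2, j = j,
              rho = m1$ids[c1], psi = m2$ids[c2],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  has_rec <- best > norec
  list(score = max(norec, best),
       no_recombination_score = norec,
       has_recombination = has_rec,
       tie_set = if (has_rec) do.call(rbind, ties) else
         data.frame(p1 = character(0L), p2 = character(0L),
                    j = integer(0L), rho = integer(0L), psi = integer(0L)))
}

#' Independent Needleman-Wunsch score via Biostrings
#'
#' A second, external route to the global linear-gap score, delegated to
#' `Biostrings::pairwiseAlignment` with a custom substitution matrix and
#' `gapOpening = 0` (linear gaps).  Used to cross-check [nw_global()] and
#' as the per-path reference in the equivalence tests.
#'
#' @inheritParams nw_global
#' @return the optimal global alignment score.
#' @export
nw_reference_score <- function(a, b, sc = scoring_scheme()) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(-sc$gap * (nchar(a) + nchar(b)))
  alph <- unique(c(split_chars(a), split_chars(b)))
  sm <- matrix(-sc$mismatch, length(alph), length(alph),
               dimnames = list(alph, alph))
  diag(sm) <- sc$match
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = sm, gapOpening = 0,
    gapExtension = sc$gap, type = "global"))
}
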