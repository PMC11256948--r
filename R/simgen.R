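#' Generate a synthetic variation graph with SNP/indel bubbles
#'
#' Emulates a bacterial gene pangenome graph: a random backbone sequence
#' with variant sites planted at spaced positions; each site is either a
#' SNP (two parallel single-base vertices) or a short indel (an insert
#' segment that paths may skip).  Each path is assigned one allele per
#' site (both alleles of every site are guaranteed to be used by at least
#' one path) and the graph is the union of the resulting walks, so every
#' arc is covered by the path set.  The spelled haplotype strings are
#' attached as `attr(g, "haplotypes")`.
#'
#' @param n_paths number of distinguished paths (>= 2).
#' @param n_variant_sites number of variant sites to plant.
#' @param base_length backbone length in bp.
#' @param indel_fraction probability that a site is an indel rather than a
#'   SNP.
#' @param seed optional integer seed; the generator is bit-reproducible
#'   given identical parameters and seed.
#' @return a validated `variation_graph` with multi-character backbone
#'   vertices (canonicalize before aligning).
#' @export
make_graph <- function(n_paths = 5L, n_variant_sites = 10L,
                       base_length = 150L, indel_fraction = 0.25,
                       seed = NULL) {
  if (n_paths < 2L) stop("n_paths must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  candidates <- seq(4L, base_length - 4L, by = 3L)
  if (n_variant_sites > 0L && length(candidates) < n_variant_sites)
    stop("base_length too short for the requested number of variant sites")
  bases <- c("A", "C", "G", "T")
  bb <- sample(bases, base_length, replace = TRUE)
  sites <- if (n_variant_sites > 0L)
    sort(sample(candidates, n_variant_sites)) else integer(0L)
  is_indel <- stats::runif(length(sites)) < indel_fraction

  labels <- character(0L); seg_names <- character(0L)
  add_vertex <- function(lab, nm) {
    labels <<- c(labels, lab); seg_names <<- c(seg_names, nm)
    length(labels)
  }
  src <- add_vertex("", "__source__")
  # per site: the vertex ids of its two allele branches (each a vertex
  # sequence; an absent indel allele is the empty sequence)
  site_alleles <- vector("list", length(sites))
  spine <- list(list(src))  # elements: list of alternative vertex chains
  cursor <- 1L
  for (k in seq_along(sites)) {
    p <- sites[k]
    chunk_end <- if (is_indel[k]) p else p - 1L
    if (cursor <= chunk_end) {
      cid <- add_vertex(paste(bb[cursor:chunk_end], collapse = ""),
                        sprintf("c%02d", k))
      spine[[length(spine) + 1L]] <- list(cid)
    }
    if (is_indel[k]) {
      ins <- paste(sample(bases, sample(1:4, 1L), replace = TRUE),
                   collapse = "")
      iid <- add_vertex(ins, sprintf("i%02d", k))
      site_alleles[[k]] <- list(iid, integer(0L))
    } else {
      alt <- sample(setdiff(bases, bb[p]), 1L)
      aid <- add_vertex(bb[p], sprintf("s%02da", k))
      bid <- add_vertex(alt, sprintf("s%02db", k))
      site_alleles[[k]] <- list(aid, bid)
    }
    spine[[length(spine) + 1L]] <- site_alleles[[k]]
    cursor <- p + 1L
  }
  if (cursor <= base_length) {
    cid <- add_vertex(paste(bb[cursor:base_length], collapse = ""),
                      sprintf("c%02d", length(sites) + 1L))
    spine[[length(spine) + 1L]] <- list(cid)
  }
  snk <- add_vertex("", "__sink__")
  spine[[length(spine) + 1L]] <- list(snk)

  # allele matrix: 1 or 2 per (path, site); force both alleles in use
  alleles <- matrix(sample(1:2, n_paths * length(sites), replace = TRUE),
                    nrow = n_paths)
  if (length(sites) > 0L) for (k in seq_along(sites)) {
    if (length(unique(alleles[, k])) == 1L)
      alleles[(k - 1L) %% n_paths + 1L, k] <- 3L - alleles[1L, k]
  }
  path_names <- sprintf("path%02d", seq_len(n_paths))
  site_of_element <- match(seq_along(spine),
                           which(vapply(spine, length, integer(1L)) == 2L))
  walks <- lapply(seq_len(n_paths), function(h) {
    unlist(lapply(seq_along(spine), function(el) {
      alt <- spine[[el]]
      if (length(alt) == 1L) alt[[1L]]
      else alt[[alleles[h, site_of_element[el]]]]
    }), use.names = FALSE)
  })
  names(walks) <- path_names
  arcs <- unique(do.call(rbind, lapply(walks, function(w)
    cbind(w[-length(w)], w[-1L]))))
  g <- variation_graph(labels, arcs, walks, source = src, sink = snk,
                       seg_names = seg_names)
  attr(g, "haplotypes") <- vapply(path_names, function(nm)
    spell_path(g, g$paths[[nm]]), character(1L))
  g
}

#' Minimal edge-cover path subset
#'
#' Iteratively drops paths that cover no arc uniquely: scanning paths in
#' name order, a path is removed from the working set `K` when every arc
#' it contains is also covered by another path still in `K`.  The
#' resulting subset covers exactly the arcs covered by the full path set.
#'
#' @param g a variation graph.
#' @return character vector of retained path names.
#' @export
select_edge_cover_paths <- function(g) {
  keys <- lapply(g$paths, function(p) paste(p[-length(p)], p[-1L]))
  K <- sort(names(g$paths))
  for (nm in sort(names(g$paths))) {
    others <- unique(unlist(keys[setdiff(K, nm)], use.names = FALSE))
    if (all(keys[[nm]] %in% others)) K <- setdiff(K, nm)
  }
  K
}

#' Simulate a recombinant query from two paths
#'
#' Emits `prefix of spell(p1) + suffix of spell(p2)` with the cut anchored
#' at a shared vertex, so the mosaic corresponds to a walk of the graph:
#' the truth records the mosaic vertex set (all of `p1` up to the anchor,
#' all of `p2` after it) and the breakpoint in query coordinates.  The
#' anchor is drawn uniformly among shared vertices whose prefix length
#' falls inside `window` (fractions of the `p1` sequence length).  With
#' `p2 == p1` the function produces a non-recombinant control equal to the
#' full `p1` sequence.  With `require_identifiable = TRUE`, anchors are
#' re-drawn until the prefix identifies `p1` uniquely among all paths and
#' the suffix identifies `p2` uniquely (so exact recovery of the simulated
#' pair is well-posed); an error is raised if no such anchor exists.
#'
#' @param g a variation graph (original or canonical).
#' @param p1,p2 parent path names.
#' @param window numeric `(lo, hi)` fractions bounding the breakpoint.
#' @param seed optional integer seed.
#' @param require_identifiable restrict to anchors with unambiguous
#'   parents (default `FALSE`).
#' @return list with `name`, `seq`, and `truth` (fields `recombinant`,
#'   `p1`, `p2`, `breakpoint`, `walk`, `anchor`, `anchored`).
#' @export
simulate_recombinant <- function(g, p1, p2, window = c(0.1, 0.9),
                                 seed = NULL, require_identifiable = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  spells <- vapply(names(g$paths), function(nm)
    spell_path(g, g$paths[[nm]]), character(1L))
  if (p1 == p2) {
    return(list(name = sprintf("control_%s", p1), seq = spells[[p1]],
                truth = list(recombinant = FALSE, p1 = p1, p2 = p1,
                             breakpoint = NA_integer_,
                             walk = g$paths[[p1]], anchor = NA_integer_,
                             anchored = TRUE)))
  }
  v1 <- g$paths[[p1]]; v2 <- g$paths[[p2]]
  if (is.null(v1) || is.null(v2)) stop("unknown path name")
  nA <- nchar(spells[[p1]])
  cum1 <- cumsum(nchar(g$labels[v1]))
  cand <- which(v1 %in% v2)
  cand <- cand[cand < length(v1)]                     # not the sink
  js <- cum1[cand]
  keep <- js >= max(1, ceiling(window[1] * nA)) & js <= floor(window[2] * nA)
  # the spelled suffix of p2 after the anchor must be nonempty
  t2 <- match(v1[cand], v2)
  sfx_len <- nchar(spells[[p2]]) - cumsum(nchar(g$labels[v2]))[t2]
  cand <- cand[keep & sfx_len > 0L]
  if (length(cand) == 0L)
    stop("no shared-vertex anchor inside the breakpoint window")
  ord <- sample(length(cand))
  for (ci in ord) {
    r <- cand[ci]
    anchor <- v1[r]
    t <- match(anchor, v2)
    j <- cum1[r]
    prefix <- substr(spells[[p1]], 1L, j)
    suffix <- substr(spells[[p2]], j2_start <- nchar(spells[[p2]]) -
                       sfx_at(g, v2, t) + 1L, nchar(spells[[p2]]))
    qry <- paste0(prefix, suffix)
    if (require_identifiable) {
      # the reported breakpoint may fall anywhere in the variant-free
      # window around the cut, so the parents must be unambiguous over
      # the whole window: no other path may match the query prefix up to
      # the window start, nor the query suffix back to the window end
      n <- nchar(qry)
      pm <- vapply(spells, function(s) prefix_match_len(qry, s), integer(1L))
      sm <- vapply(spells, function(s) suffix_match_len(qry, s), integer(1L))
      lo <- n - sm[[p2]]
      hi <- pm[[p1]]
      if (any(pm[setdiff(names(spells), p1)] >= lo) ||
          any(sm[setdiff(names(spells), p2)] >= n - hi)) next
    }
    return(list(
      name = sprintf("rec_%s_%s_%d", p1, p2, j), seq = qry,
      truth = list(recombinant = TRUE, p1 = p1, p2 = p2,
                   breakpoint = j,
                   walk = c(v1[seq_len(r)], v2[seq_len(length(v2) - t) + t]),
                   anchor = anchor, anchored = TRUE)))
  }
  stop("no identifiable anchor for pair ", p1, "/", p2)
}

prefix_match_len <- function(a, b) {
  ca <- split_chars(a); cb <- split_chars(b)
  k <- min(length(ca), length(cb))
  if (k == 0L) return(0L)
  neq <- which(ca[seq_len(k)] != cb[seq_len(k)])
  if (length(neq) == 0L) k else neq[1L] - 1L
}

suffix_match_len <- function(a, b) {
  prefix_match_len(paste(rev(split_chars(a)), collapse = ""),
                   paste(rev(split_chars(b)), collapse = ""))
}

# spelled length of path portion strictly after position t
sfx_at <- function(g, verts, t) {
  if (t >= length(verts)) return(0L)
  sum(nchar(g$labels[verts[(t + 1L):length(verts)]]))
}

#' Substitution mutations at a fixed per-base rate
#'
#' Each position is independently substituted, with probability `rate`, by
#' a base different from the original (substitution-only model; no indels
#' are introduced).
#'
#' @param seq a nucleotide string.
#' @param rate per-position substitution probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return list with `seq` (mutated string) and `positions` (1-based
#'   mutated positions).
#' @export
mutate_query <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  chars <- split_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), positions = hit)
}

#' Write a simulated fixture to disk
#'
#' Emits the graph as GFA, the queries as FASTA and the per-query truth as
#' JSON (segment names rather than internal ids, so the files are
#' self-contained), for command-line end-to-end runs.
#'
#' @param dir output directory (created if missing).
#' @param g a variation graph.
#' @param queries list of simulated queries as returned by
#'   [simulate_recombinant()] (optionally mutated).
#' @return invisibly, the three file paths.
#' @export
write_fixture <- function(dir, g, queries) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gfa <- file.path(dir, "graph.gfa")
  fa <- file.path(dir, "queries.fasta")
  js <- file.path(dir, "truth.json")
  write_gfa(g, gfa)
  writeLines(unlist(lapply(queries, function(q)
    c(paste0(">", q$name), q$seq))), fa)
  truth <- lapply(queries, function(q) {
    tr <- q$truth
    list(name = q$name, recombinant = tr$recombinant, p1 = tr$p1,
         p2 = tr$p2, breakpoint = tr$breakpoint,
         walk_segments = g$seg_names[setdiff(tr$walk, c(g$source, g$sink))])
  })
  jsonlite::write_json(truth, js, auto_unbox = TRUE, null = "null")
  invisible(c(gfa = gfa, fasta = fa, truth = js))
}
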