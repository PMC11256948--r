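# Fixtures are built in code; no data files.

# two disjoint 3-vertex branches sharing only the virtual source/sink:
# p1 spells "AAA", p2 spells "CCC"
tiny_two_path_graph <- function() {
  load_gfa(c(
    "S\ta1\tA", "S\ta2\tA", "S\ta3\tA",
    "S\tc1\tC", "S\tc2\tC", "S\tc3\tC",
    "L\ta1\t+\ta2\t+\t0M", "L\ta2\t+\ta3\t+\t0M",
    "L\tc1\t+\tc2\t+\t0M", "L\tc2\t+\tc3\t+\t0M",
    "P\tp1\ta1+,a2+,a3+\t*", "P\tp2\tc1+,c2+,c3+\t*"))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a random bubble graph plus its canonical form
random_fixture <- function(seed, n_paths = sample(3:5, 1),
                           n_sites = sample(3:5, 1),
                           base_length = sample(26:34, 1),
                           indel_fraction = 0.3) {
  g <- make_graph(n_paths = n_paths, n_variant_sites = n_sites,
                  base_length = base_length,
                  indel_fraction = indel_fraction, seed = seed)
  list(g = g, gc = canonicalize(g))
}

# a random query loosely related to the graph: a recombinant of two random
# paths, optionally mutated
random_query <- function(g, seed, rate = sample(c(0, 0.03, 0.08), 1)) {
  set.seed(seed)
  nms <- names(g$paths)
  pr <- sample(nms, 2)
  q <- simulate_recombinant(g, pr[1], pr[2])
  if (rate > 0) q$seq <- mutate_query(q$seq, rate)$seq
  q$seq
}

path_labelled_ids <- function(g, nm) {
  setdiff(g$paths[[nm]], c(g$source, g$sink))
}

# read M[v, j, p] / R[v, j, p] out of a dp_state for a single vertex
m_of <- function(st, pi, v, j, gc) {
  tb <- st$forward[[pi]]
  p <- gc$paths[[pi]]
  if (v == p[1]) return(tb$mat[1, j + 1])
  if (v == p[length(p)]) return(tb$mat[nrow(tb$mat), j + 1])
  pos <- match(v, tb$ids)
  if (is.na(pos)) -Inf else tb$mat[pos + 1, j + 1]
}

r_of <- function(st, qi, w, j, gc) {
  tb <- st$backward[[qi]]
  p <- gc$paths[[qi]]
  if (w == p[1]) return(tb$smat[1, j + 1])
  if (w == p[length(p)]) return(tb$smat[nrow(tb$smat), j + 1])
  pos <- match(w, tb$ids)
  if (is.na(pos)) -Inf else tb$smat[pos, j + 1]
}

# independent Levenshtein distance (unit-cost DP), oracle for adist-based
# edit_distance_to_path
lev_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- c(i, rep(0L, length(B)))
    for (j in seq_along(B)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(B) + 1]
}

# exhaustive partition search for the minimum number of path switches:
# enumerates all block decompositions (pruned when a block is valid on no
# path, since blocks cannot become valid by extension)
exhaustive_min_switches <- function(walk, g) {
  K <- length(walk)
  block_ok <- function(i, j) any(vapply(g$paths, function(p) {
    pos <- match(walk[i:j], p)
    !anyNA(pos) && (j == i || all(diff(pos) == 1L))
  }, logical(1)))
  best <- Inf
  recurse <- function(start, used) {
    if (used >= best) return(invisible())
    for (end in start:K) {
      if (!block_ok(start, end)) break
      if (end == K) best <<- min(best, used)
      else recurse(end + 1L, used + 1L)
    }
  }
  recurse(1L, 0L)
  best
}

# a walk stitched from segments of randomly chosen paths (graph-valid
# junctions are not required to be arcs; min_switches only needs each
# block on some path, so we cut at shared vertices)
random_mosaic_walk <- function(g, n_blocks, seed) {
  set.seed(seed)
  nms <- names(g$paths)
  p <- g$paths[[sample(nms, 1)]]
  walk <- p[seq_len(sample(2:4, 1) + 1)]
  for (b in seq_len(n_blocks - 1)) {
    nxt <- g$paths[[sample(nms, 1)]]
    at <- match(walk[length(walk)], nxt)
    if (is.na(at) || at >= length(nxt)) next
    take <- sample(seq_len(length(nxt) - at), 1)
    walk <- c(walk, nxt[at + seq_len(take)])
  }
  walk
}
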