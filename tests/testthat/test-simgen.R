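test_that("a graph without variant sites is a chain of identical paths", {
  g <- make_graph(n_paths = 3, n_variant_sites = 0, base_length = 40,
                  seed = 1)
  spells <- vapply(names(g$paths), function(nm)
    spell_path(g, g$paths[[nm]]), character(1))
  expect_length(unique(spells), 1L)
  expect_identical(nchar(spells[[1]]), 40L)
  # a chain: every vertex has at most one successor
  expect_lte(max(table(g$arcs[, 1])), 1L)
})

test_that("a single SNP site makes exactly one two-branch bubble", {
  g <- make_graph(n_paths = 2, n_variant_sites = 1, base_length = 30,
                  indel_fraction = 0, seed = 2)
  branch <- which(table(factor(g$arcs[, 1],
                               levels = seq_along(g$labels))) == 2)
  expect_length(branch, 1L)
  alleles <- g$arcs[g$arcs[, 1] == branch, 2]
  expect_identical(nchar(g$labels[alleles]), c(1L, 1L))
  expect_false(g$labels[alleles[1]] == g$labels[alleles[2]])
})

test_that("paths spell the generator's haplotype strings", {
  for (s in 1:20) {
    g <- make_graph(n_paths = sample(2:6, 1),
                    n_variant_sites = sample(0:8, 1),
                    base_length = sample(40:80, 1), seed = 3000 + s)
    hap <- attr(g, "haplotypes")
    for (nm in names(g$paths)) {
      expect_identical(spell_path(g, g$paths[[nm]]), hap[[nm]])
    }
    expect_silent(validate_variation_graph(g))
  }
})

test_that("generation is bit-reproducible given the seed", {
  g1 <- make_graph(seed = 77)
  g2 <- make_graph(seed = 77)
  expect_identical(g1, g2)
  q1 <- simulate_recombinant(g1, "path01", "path03", seed = 5)
  q2 <- simulate_recombinant(g2, "path01", "path03", seed = 5)
  expect_identical(q1, q2)
})

test_that("edge-cover selection keeps arc coverage exactly", {
  # all paths identical -> a single representative survives
  g0 <- make_graph(n_paths = 3, n_variant_sites = 0, base_length = 30,
                   seed = 4)
  expect_length(select_edge_cover_paths(g0), 1L)
  # two paths with disjoint alleles at every site both survive
  g1 <- make_graph(n_paths = 2, n_variant_sites = 4, base_length = 40,
                   indel_fraction = 0, seed = 5)
  expect_identical(select_edge_cover_paths(g1), c("path01", "path02"))
  # random graphs: arcs(K) == arcs(P)
  arcs_of <- function(g, nms) unique(unlist(lapply(nms, function(nm) {
    p <- g$paths[[nm]]
    paste(p[-length(p)], p[-1])
  })))
  for (s in 1:15) {
    g <- make_graph(n_paths = sample(3:6, 1), n_variant_sites = sample(2:6, 1),
                    base_length = 50, seed = 4000 + s)
    K <- select_edge_cover_paths(g)
    expect_setequal(arcs_of(g, K), arcs_of(g, names(g$paths)))
  }
})

test_that("recombinants are anchored mosaics with a windowed breakpoint", {
  for (s in 1:15) {
    g <- make_graph(seed = 4500 + s)
    nms <- names(g$paths)
    set.seed(s)
    pr <- sample(nms, 2)
    q <- simulate_recombinant(g, pr[1], pr[2], seed = 4600 + s)
    tr <- q$truth
    expect_true(tr$recombinant)
    n1 <- nchar(spell_path(g, g$paths[[pr[1]]]))
    expect_gte(tr$breakpoint, floor(0.1 * n1))
    expect_lte(tr$breakpoint, ceiling(0.9 * n1))
    # prefix comes from p1, suffix from p2
    expect_identical(substr(q$seq, 1, tr$breakpoint),
                     substr(spell_path(g, g$paths[[pr[1]]]), 1, tr$breakpoint))
    s2 <- spell_path(g, g$paths[[pr[2]]])
    sfx <- nchar(q$seq) - tr$breakpoint
    expect_identical(substr(q$seq, tr$breakpoint + 1, nchar(q$seq)),
                     substr(s2, nchar(s2) - sfx + 1, nchar(s2)))
    # the truth walk spells the query
    expect_identical(spell_path(g, tr$walk), q$seq)
  }
})

test_that("the control mode reproduces the parent sequence", {
  g <- make_graph(seed = 11)
  q <- simulate_recombinant(g, "path02", "path02")
  expect_false(q$truth$recombinant)
  expect_identical(q$seq, spell_path(g, g$paths$path02))
})

test_that("mutation rates 0 and 1 behave deterministically", {
  s <- rand_seq(50)
  expect_identical(mutate_query(s, 0, seed = 1)$seq, s)
  m <- mutate_query(s, 1, seed = 1)
  expect_identical(length(m$positions), 50L)
  expect_true(all(strsplit(m$seq, "")[[1]] != strsplit(s, "")[[1]]))
})

test_that("mutation counts follow the binomial expectation", {
  set.seed(42)
  n <- 2000L; rate <- 0.05; reps <- 60L
  counts <- vapply(seq_len(reps), function(i)
    length(mutate_query(rand_seq(n), rate)$positions), numeric(1))
  se <- sqrt(n * rate * (1 - rate) / reps)
  expect_lt(abs(mean(counts) - n * rate), 3 * se)
})
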