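sc_rec <- scoring_scheme(window = 1)

test_that("displacement matches the hand-worked bubble examples", {
  g <- tiny_two_path_graph()
  tab <- build_displacement_table(g)
  # rho at branch position 2 of p1, psi at position 3 of p2: alpha = source,
  # beta = sink, |a1| = 3, |a2| = 4, |b1| = 3, |b2| = 2 -> displacement 0
  d <- displacement(tab, p1 = "p1", p2 = "p2",
                    rho = g$paths$p1[3], psi = g$paths$p2[4])
  expect_identical(d$alpha, g$source)
  expect_identical(d$beta, g$sink)
  expect_identical(c(d$a1_len, d$a2_len, d$b1_len, d$b2_len), c(3L, 4L, 3L, 2L))
  expect_identical(d$displacement, 0L)
  # mirror positions in a symmetric bubble force displacement 1 + 1 = 2
  d2 <- displacement(tab, "p1", "p2", g$paths$p1[3], g$paths$p2[3])
  expect_identical(d2$displacement, 2L)
  # paths sharing only source and sink: alpha/beta pinned to them
  for (r in 2:4) for (t in 2:4) {
    dd <- displacement(tab, "p1", "p2", g$paths$p1[r], g$paths$p2[t])
    expect_identical(dd$alpha, g$source)
    expect_identical(dd$beta, g$sink)
  }
})

test_that("displacement of twin paths switching at the same vertex is 2", {
  g <- load_gfa(c("S\t1\tA", "S\t2\tC", "S\t3\tG",
                  "L\t1\t+\t2\t+\t0M", "L\t2\t+\t3\t+\t0M",
                  "P\tp\t1+,2+,3+\t*", "P\tq\t1+,2+,3+\t*"))
  tab <- build_displacement_table(g)
  for (k in 2:4) {
    d <- displacement(tab, "p", "q", g$paths$p[k], g$paths$q[k])
    expect_identical(d$displacement, 2L)
  }
})

test_that("recombination vertices must be labelled vertices", {
  g <- tiny_two_path_graph()
  tab <- build_displacement_table(g)
  expect_error(displacement(tab, "p1", "p2", g$source, g$paths$p2[2]),
               "branching/consolidating")
  expect_error(displacement(tab, "p1", "p2", g$paths$p1[2], g$sink),
               "branching/consolidating")
  expect_error(displacement(tab, "p1", "p1", 2L, 3L), "different paths")
  expect_error(displacement(tab, "p1", "p2", g$paths$p2[2], g$paths$p2[2]),
               "not a vertex")
})

test_that("tabulated displacement equals the naive scan oracle", {
  for (s in 1:10) {
    fx <- random_fixture(seed = 1500 + s, n_paths = 3,
                         n_sites = sample(2:3, 1),
                         base_length = sample(18:24, 1))
    gc <- fx$gc
    tab <- build_displacement_table(gc)
    nms <- names(gc$paths)
    for (p1 in nms) for (p2 in setdiff(nms, p1)) {
      lab1 <- path_labelled_ids(gc, p1)
      lab2 <- path_labelled_ids(gc, p2)
      rho <- sample(lab1, min(6, length(lab1)))
      psi <- sample(lab2, min(6, length(lab2)))
      for (r in rho) for (t in psi) {
        a <- displacement(tab, p1, p2, r, t)
        b <- naive_alpha_beta_displacement(gc, p1, p2, r, t)
        expect_identical(a$alpha, b$alpha)
        expect_identical(a$beta, b$beta)
        expect_identical(a$displacement, b$displacement)
      }
    }
  }
})

test_that("a mosaic beats both pure paths when the query mixes them", {
  g <- tiny_two_path_graph()
  gc <- canonicalize(g)
  sc <- scoring_scheme(window = 1)
  a <- align_with_recombination(gc, "AAC", sc)
  expect_equal(a$score, 2)  # 3 matches (6) minus rec-open (4)
  ev <- a$recombination
  expect_identical(ev$p1, "p1")
  expect_identical(ev$p2, "p2")
  expect_identical(ev$breakpoint, 2L)
  expect_identical(ev$displacement, 0L)
  expect_true(ev$virtual_arc)
  expect_equal(rescore_alignment(a, gc, "AAC", sc), a$score)
  # the walk contains exactly one junction that is not an arc of the graph
  steps <- paste(a$walk[-length(a$walk)], a$walk[-1])
  expect_identical(sum(!(steps %in% paste(gc$arcs[, 1], gc$arcs[, 2]))), 1L)
})

test_that("a query spelling an existing path reports no recombination", {
  g <- tiny_two_path_graph()
  gc <- canonicalize(g)
  a <- align_with_recombination(gc, "AAA", sc_rec)
  expect_null(a$recombination)
  expect_equal(a$score, 6)
})

test_that("recombination optimum equals the brute-force oracle", {
  for (s in 1:15) {
    fx <- random_fixture(seed = 1700 + s)
    q <- random_query(fx$g, 1800 + s)
    sc <- scoring_scheme(window = if (s %% 2) 0.95 else 1)
    a <- align_with_recombination(fx$gc, q, sc)
    bf <- brute_force_recombination(fx$gc, q, sc)
    expect_identical(a$score, bf$score)
    expect_identical(!is.null(a$recombination), bf$has_recombination)
    if (!is.null(a$recombination)) {
      ev <- a$recombination
      expect_true(any(bf$tie_set$p1 == ev$p1 & bf$tie_set$p2 == ev$p2 &
                        bf$tie_set$j == ev$breakpoint))
      expect_identical(rescore_alignment(a, fx$gc, q, sc), a$score)
    }
  }
})

test_that("an infinite opening penalty reduces to the linear aligner", {
  for (s in 1:8) {
    fx <- random_fixture(seed = 1900 + s)
    q <- random_query(fx$g, 1950 + s)
    sc <- scoring_scheme(rec_open = Inf, window = 1)
    a <- align_with_recombination(fx$gc, q, sc)
    b <- align_no_recombination(fx$gc, q, sc)
    expect_null(a$recombination)
    expect_identical(a$score, b$score)
    expect_identical(a$walk, b$walk)
  }
})

test_that("raising the opening penalty never adds recombinations", {
  set.seed(99)
  fixtures <- lapply(1:6, function(s) {
    fx <- random_fixture(seed = 2100 + s)
    list(gc = fx$gc, q = random_query(fx$g, 2150 + s, rate = 0.05))
  })
  counts <- vapply(c(4, 28, 48), function(dopen) {
    sc <- scoring_scheme(rec_open = dopen)
    sum(vapply(fixtures, function(f)
      !is.null(align_with_recombination(f$gc, f$q, sc)$recombination),
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("enforce_distinct_paths matches exhaustive pair enumeration", {
  for (s in 1:6) {
    fx <- random_fixture(seed = 2300 + s)
    q <- random_query(fx$g, 2350 + s)
    st <- dp_state(fx$gc, q, sc_rec)
    n <- nchar(q)
    nms <- names(fx$gc$paths)
    set.seed(2400 + s)
    for (rep in 1:12) {
      v <- sample(length(fx$gc$labels), 1)
      w <- sample(length(fx$gc$labels), 1)
      j <- sample(0:n, 1)
      got <- enforce_distinct_paths(st, v, w, j)
      # exhaustive: all ordered distinct path pairs through full matrices
      best <- -Inf; bp <- NA; bq <- NA
      for (pi in seq_along(nms)) for (qi in seq_along(nms)) {
        if (pi == qi) next
        mv <- m_of(st, pi, v, j, fx$gc)
        rw <- r_of(st, qi, w, j, fx$gc)
        if (mv + rw > best) { best <- mv + rw; bp <- pi; bq <- qi }
      }
      expect_identical(got$score, best)
      if (is.finite(best)) {
        # the returned pair attains the same optimum (ties may differ)
        mv <- m_of(st, match(got$prefix_path, nms), v, j, fx$gc)
        rw <- r_of(st, match(got$suffix_path, nms), w, j, fx$gc)
        expect_identical(mv + rw, best)
        expect_false(got$prefix_path == got$suffix_path)
      }
    }
  }
})

test_that("best and second-best recombination summaries use distinct paths", {
  fx <- random_fixture(seed = 2500)
  st <- dp_state(fx$gc, random_query(fx$g, 2550), sc_rec)
  ok <- is.finite(st$bestR$best2)
  expect_true(all(st$bestR$best_path[ok] != st$bestR$best2_path[ok]))
})
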