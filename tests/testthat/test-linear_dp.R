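sc_default <- scoring_scheme()

test_that("forward matrix reproduces hand-checked scores", {
  g <- load_gfa(c("S\t1\tACGT", "P\tx\t1+\t*"))
  gc <- canonicalize(g)
  st <- forward_matrices(gc, "ACGT", sc_default)
  tb <- st$forward[[1]]
  expect_equal(tb$mat[nrow(tb$mat), ncol(tb$mat)], 8)  # four matches

  g1 <- load_gfa(c("S\t1\tA", "P\tx\t1+\t*"))
  gc1 <- canonicalize(g1)
  a <- align_no_recombination(gc1, "C", sc_default)
  expect_equal(a$score, -4)  # substitution beats two gaps at -8
})

test_that("boundary conditions hold: source row and column-zero depths", {
  fx <- random_fixture(seed = 31)
  st <- forward_matrices(fx$gc, random_query(fx$g, 32), sc_default)
  for (tb in st$forward) {
    n <- ncol(tb$mat) - 1
    expect_equal(tb$mat[1, ], -sc_default$gap * (0:n))        # M[v0, i, p]
    expect_equal(tb$mat[, 1], -sc_default$gap * (0:length(tb$chars)))
  }
  # second-best summaries always come from a different path than the best
  finite2 <- is.finite(st$best$best2)
  expect_true(all(st$best$best_path[finite2] != st$best$best2_path[finite2]))
})

test_that("per-path scores equal an independent global aligner", {
  for (s in 1:20) {
    fx <- random_fixture(seed = 700 + s)
    q <- random_query(fx$g, 800 + s)
    st <- forward_matrices(fx$gc, q, sc_default)
    for (tb in st$forward) {
      expect_identical(tb$mat[nrow(tb$mat), ncol(tb$mat)],
                       nw_reference_score(spell_path(fx$gc, tb$ids), q,
                                          sc_default))
    }
  }
})

test_that("backward matrices mirror the forward pass", {
  for (s in 1:10) {
    fx <- random_fixture(seed = 900 + s)
    q <- random_query(fx$g, 950 + s)
    n <- nchar(q)
    fwd <- forward_matrices(fx$gc, q, sc_default)
    bwd <- backward_matrices(fx$gc, q, sc_default)
    for (k in seq_along(fwd$forward)) {
      mf <- fwd$forward[[k]]$mat
      sm <- bwd$backward[[k]]$smat
      # whole-alignment symmetry: R[source, 0, p] == M[sink, n, p]
      expect_identical(sm[1, 1], mf[nrow(mf), ncol(mf)])
      # R equals the forward recurrence on the reversed instance
      rev_ref <- paste(rev(strsplit(spell_path(fx$gc, fwd$forward[[k]]$ids),
                                    "")[[1]]), collapse = "")
      rev_q <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
      st_rev <- nw_reference_score(rev_ref, rev_q, sc_default)
      expect_identical(sm[1, 1], st_rev)
    }
  }
})

test_that("palindromic instance: backward matrix is the mirrored forward", {
  g <- load_gfa(c("S\t1\tAA", "P\tx\t1+\t*"))
  gc <- canonicalize(g)
  fwd <- forward_matrices(gc, "AA", sc_default)$forward[[1]]$mat
  bwd <- backward_matrices(gc, "AA", sc_default)$backward[[1]]$smat
  expect_equal(bwd, fwd[rev(seq_len(nrow(fwd))), rev(seq_len(ncol(fwd)))],
               ignore_attr = TRUE)
})

test_that("align_no_recombination picks the best path and rescoring agrees", {
  g <- tiny_two_path_graph()
  gc <- canonicalize(g)
  a <- align_no_recombination(gc, "AAA", sc_default)
  expect_equal(a$score, 6)
  expect_identical(a$path_name, "p1")
  a2 <- align_no_recombination(gc, "AAC", sc_default)
  expect_equal(a2$score, 0)  # 2 matches - 1 mismatch on p1
  expect_identical(a2$path_name, "p1")
  expect_equal(rescore_alignment(a2, gc, "AAC", sc_default), a2$score)
})

test_that("returned score is the max over paths and tracebacks re-score", {
  for (s in 1:25) {
    fx <- random_fixture(seed = 1100 + s)
    q <- random_query(fx$g, 1200 + s)
    a <- align_no_recombination(fx$gc, q, sc_default)
    ref <- max(vapply(names(fx$gc$paths), function(nm)
      nw_reference_score(spell_path(fx$gc, fx$gc$paths[[nm]]), q,
                         sc_default), numeric(1)))
    expect_identical(a$score, ref)
    expect_identical(rescore_alignment(a, fx$gc, q, sc_default), a$score)
  }
})

test_that("appending a mismatching base never gains more than a match", {
  for (s in 1:8) {
    fx <- random_fixture(seed = 1300 + s)
    q <- random_query(fx$g, 1350 + s)
    s0 <- align_no_recombination(fx$gc, q, sc_default)$score
    for (b in c("A", "C", "G", "T")) {
      s1 <- align_no_recombination(fx$gc, paste0(q, b), sc_default)$score
      expect_lte(s1, s0 + sc_default$match)
    }
  }
})

test_that("rescore_alignment validates column structure", {
  g <- tiny_two_path_graph()
  gc <- canonicalize(g)
  a <- align_no_recombination(gc, "AAA", sc_default)
  bad <- a
  bad$columns <- bad$columns[c(2, 1, 3), ]
  expect_error(rescore_alignment(bad, gc, "AAA", sc_default), "in order")
  bad2 <- a
  bad2$columns <- rbind(bad2$columns, data.frame(x = NA, y = NA))
  expect_error(rescore_alignment(bad2, gc, "AAA", sc_default), "gap-only")
  # a 3-long gap with |g| = 4 contributes -12
  g3 <- load_gfa(c("S\t1\tACGTTT", "P\tx\t1+\t*"))
  gc3 <- canonicalize(g3)
  a3 <- align_no_recombination(gc3, "ACG", sc_default)
  expect_equal(a3$score, 3 * 2 - 12)
  expect_equal(rescore_alignment(a3, gc3, "ACG", sc_default), a3$score)
})
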