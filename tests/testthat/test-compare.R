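test_that("superposition partitions contacts into matched and *_only sets", {
  a <- contact_map(data.frame(i = c(1, 2), j = c(9, 11)), seq_length = 20)
  b <- contact_map(data.frame(i = c(1, 3), j = c(9, 14)), seq_length = 20)
  cls <- superpose_maps(a, b, min_sep = 0)
  expect_equal(pair_keys(cls[cls$class == "matched", ]), "1 9")
  expect_equal(pair_keys(cls[cls$class == "predicted_only", ]), "2 11")
  expect_equal(pair_keys(cls[cls$class == "model_only", ]), "3 14")

  ident <- superpose_maps(a, a, min_sep = 0)
  expect_true(all(ident$class == "matched"))

  disjoint <- superpose_maps(a, contact_map(data.frame(i = 5, j = 15),
                                            seq_length = 20), min_sep = 0)
  expect_equal(sum(disjoint$class == "matched"), 0)

  expect_error(superpose_maps(a, contact_map(data.frame(i = 1, j = 9),
                                             seq_length = 30), min_sep = 0),
               "mismatch.*20.*30")
})

test_that("superposition refuses disagreeing sequences", {
  a <- contact_map(data.frame(i = 1, j = 9), sequence = "MAAAAAAAAW")
  b <- contact_map(data.frame(i = 1, j = 9), sequence = "MWWWWWWWWA")
  expect_error(superpose_maps(a, b, min_sep = 0), "sequences.*disagree")
})

test_that("swapping the inputs exchanges the *_only sets", {
  set.seed(9)
  for (rep in 1:10) {
    p <- random_contact_map(40, 25)
    m <- random_contact_map(40, 25)
    ab <- superpose_maps(p, m, min_sep = 0)
    ba <- superpose_maps(m, p, min_sep = 0)
    expect_identical(pair_keys(ab[ab$class == "matched", ]),
                     pair_keys(ba[ba$class == "matched", ]))
    expect_identical(pair_keys(ab[ab$class == "model_only", ]),
                     pair_keys(ba[ba$class == "predicted_only", ]))
  }
})

test_that("satisfaction is the realized fraction of selected predictions", {
  L <- 60
  p <- contact_map(data.frame(i = 1:10, j = 1:10 + 30, score = (10:1) / 10),
                   seq_length = L)
  realized <- tibble::as_tibble(p)[1:7, ]
  m <- contact_map(realized, seq_length = L)
  expect_equal(satisfaction_score(p, m, min_sep = 23, top_n = 10), 0.7)
  expect_equal(satisfaction_score(p, p, min_sep = 23, top_n = 10), 1.0)
  empty_model <- contact_map(data.frame(i = 1, j = 3), seq_length = L)
  expect_equal(as.numeric(satisfaction_score(p, empty_model,
                                             min_sep = 23, top_n = 10)), 0)

  none <- contact_map(data.frame(i = 1, j = 5), seq_length = L)
  s <- satisfaction_score(none, m, min_sep = 23, top_n = 5)
  expect_equal(as.numeric(s), 0)
  expect_true(isTRUE(attr(s, "undefined")))
})

test_that("satisfaction equals the set-intersection oracle on random instances", {
  set.seed(33)
  for (rep in 1:30) {
    L <- sample(30:100, 1)
    p <- random_contact_map(L, sample(10:60, 1))
    m <- random_contact_map(L, sample(10:60, 1))
    min_sep <- sample(c(0, 5, 12, 23), 1)
    top_n <- sample(3:20, 1)
    # oracle: filter, sort, slice, intersect -- independently of superpose
    pk <- pair_keys(p)[abs(p$i - p$j) >= min_sep]
    ps <- p$score[abs(p$i - p$j) >= min_sep]
    ord <- order(-ps, p$i[abs(p$i - p$j) >= min_sep],
                 p$j[abs(p$i - p$j) >= min_sep])
    sel <- pk[ord[seq_len(min(top_n, length(pk)))]]
    mk <- pair_keys(m)[abs(m$i - m$j) >= min_sep]
    expected <- if (length(sel)) length(intersect(sel, mk)) / length(sel) else 0
    got <- satisfaction_score(p, m, min_sep = min_sep, top_n = top_n)
    expect_equal(as.numeric(got), expected)
  }
})

test_that("raising min_sep can only drop or retain realized predictions", {
  # the realized fraction over a fixed denominator (all uniformly scored
  # predictions) is non-increasing in min_sep; the ratio over the shrinking
  # survivor count is deliberately not asserted -- it is not monotone
  set.seed(14)
  for (rep in 1:10) {
    L <- 80
    n <- 50
    p <- random_contact_map(L, n, scores = rep(0.5, n))
    m <- random_contact_map(L, n)
    realized <- vapply(c(0, 4, 8, 16, 24), function(ms) {
      cls <- superpose_maps(p, m, min_sep = ms, top_n = n)
      sum(cls$class == "matched") / n
    }, numeric(1))
    expect_true(all(diff(realized) <= 1e-12))
  }
})

test_that("classification tidies, summarizes and exports", {
  a <- contact_map(data.frame(i = c(1, 2), j = c(9, 11)), seq_length = 20)
  b <- contact_map(data.frame(i = c(1, 3), j = c(9, 14)), seq_length = 20)
  cls <- superpose_maps(a, b, min_sep = 0)
  td <- tidy(cls)
  expect_named(td, c("i", "j", "class"))
  g <- glance(cls)
  expect_equal(g$n_matched, 1L)
  expect_equal(g$satisfaction, 0.5)
  txt <- write_match(cls)
  expect_match(txt, "^i\tj\tclass\n")
  expect_match(txt, "3\t14\tmodel_only")
})
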