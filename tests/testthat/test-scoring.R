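test_that("weighted_score evaluates the log-ratio directly", {
  expect_identical(weighted_score(0.5, 0.5, 0.3, 0.3), 0)
  expect_equal(weighted_score(0.9, 0.1, 0, 0), log(0.1 / 0.9),
               tolerance = 1e-12)
  expect_equal(weighted_score(0.5, 0.5, 1, 0), log(0.5), tolerance = 1e-12)
  # flooring keeps the score finite at the boundary
  expect_true(is.finite(weighted_score(1, 0.5, 0, 0)))
  expect_true(is.finite(weighted_score(0.5, 1, 1, 1)))
})

test_that("naive_score depends on the weights alone", {
  expect_identical(naive_score(0.4, 0.4), 0)
  expect_equal(naive_score(1, 0), -log(2), tolerance = 1e-12)
  expect_equal(naive_score(0, 1), log(2), tolerance = 1e-12)
})

test_that("classification is strict-below-threshold", {
  expect_identical(classify(-2.2), "damaging")
  expect_identical(classify(0), "tolerated")       # boundary -> tolerated
  expect_identical(classify(-0.5, threshold = -1.5), "tolerated")
  expect_identical(classify(c(-1, 1, 0)), c("damaging", "tolerated",
                                            "tolerated"))
})

test_that("score antisymmetry and monotonicity hold on random inputs", {
  set.seed(17)
  n <- 500
  Pw <- runif(n, 1e-9, 1)
  Pm <- runif(n, 1e-9, 1)
  Wd <- runif(n)
  Wn <- runif(n)
  s <- weighted_score(Pw, Pm, Wd, Wn)
  expect_equal(s, -weighted_score(Pm, Pw, Wn, Wd), tolerance = 1e-12)
  # with equal weights, score reduces to the conservation term exactly
  s0 <- weighted_score(Pw, Pm, Wd, Wd)
  expect_equal(s0, log(pmax(1 - Pw, 1e-9)) - log(pmax(1 - Pm, 1e-9)),
               tolerance = 1e-12)
  # with Pw = Pm the score is exactly the naive score
  expect_equal(weighted_score(Pw, Pw, Wd, Wn), naive_score(Wd, Wn),
               tolerance = 1e-12)
  # monotone: raising Pw or Wd can only lower the score
  eps <- 0.05
  ok_w <- Pw + eps <= 1
  expect_true(all(weighted_score(Pw[ok_w] + eps, Pm[ok_w], Wd[ok_w],
                                 Wn[ok_w]) <= s[ok_w] + 1e-12))
  ok_d <- Wd + eps <= 1
  expect_true(all(weighted_score(Pw[ok_d], Pm[ok_d], Wd[ok_d] + eps,
                                 Wn[ok_d]) <= s[ok_d] + 1e-12))
  ok_m <- Pm + eps <= 1
  expect_true(all(weighted_score(Pw[ok_m], Pm[ok_m] + eps, Wd[ok_m],
                                 Wn[ok_m]) >= s[ok_m] - 1e-12))
})

test_that("score_variants runs the full per-site pipeline", {
  set <- tiny_set()
  # A5C sits on dom1 state 2 (emission 0.9 on C... state 2 is peaked on C)
  ds <- variants_df(list("protA", "C5A", "disease", "metabolic"),
                    list("protA", "A2C", "neutral", ""))
  idx <- variant_model_index(set, ds)
  scheme <- weight_scheme("disease_specific", concept = "metabolic")
  cnt <- count_mappings(ds, scheme, idx)
  out <- score_variants(ds, set, cnt, scheme, background = uniform_dist())

  # first variant: domain state is far more informative than the uniform
  # backbone, so dom1 is chosen; wild-type C is its dominant residue
  expect_identical(out$model_id[[1]], "dom1")
  expect_identical(out$state[[1]], 2L)
  expect_equal(out$Pw[[1]], 0.9, tolerance = 1e-6)
  expect_identical(out$warning[[1]], "")
  w <- weights_from_counts(cnt[cnt$model_id == "dom1", ])
  expect_equal(out$score[[1]],
               eq1_direct(out$Pw[[1]], out$Pm[[1]], w$Wd, w$Wn),
               tolerance = 1e-9)

  # second variant: only the (uniform) ab initio model covers residue 2,
  # and with uniform emissions Pw == Pm
  expect_identical(out$model_id[[2]], "protA")
  expect_equal(out$Pw[[2]], out$Pm[[2]], tolerance = 1e-12)
  # protA's ab initio model collects both records: d=1, n=1
  expect_equal(out$Wn[[2]], 0.5, tolerance = 1e-12)
  expect_equal(out$Wd[[2]], 0.5, tolerance = 1e-12)
})

test_that("zero-weight models reduce to the pure conservation ratio", {
  set <- tiny_set()
  train <- variants_df(list("protA", "C5A", "disease", "metabolic"))
  test <- variants_df(list("protB", "C3A", "neutral", ""))
  scheme <- weight_scheme("inherited")
  cnt <- count_mappings(train, scheme, variant_model_index(set, train))
  out <- score_variants(test, set, cnt, scheme,
                        background = uniform_dist())
  # protB's ab initio model has no mapped training data... but residue 3
  # of protB is dom1 state 2, which was trained; use residue 1 instead
  test2 <- variants_df(list("protB", "A1C", "neutral", ""))
  out2 <- score_variants(test2, set, cnt, scheme,
                         background = uniform_dist())
  expect_identical(out2$model_id[[1]], "protB")
  expect_identical(c(out2$Wd[[1]], out2$Wn[[1]]), c(0, 0))
  expect_equal(out2$score[[1]],
               log(pmax(1 - out2$Pw[[1]], 1e-9)) -
                 log(pmax(1 - out2$Pm[[1]], 1e-9)),
               tolerance = 1e-12)
})

test_that("leave-one-out changes only the scored variant's own side", {
  set <- tiny_set()
  ds <- variants_df(list("protA", "C5A", "disease", "metabolic"),
                    list("protA", "C5D", "disease", "metabolic"),
                    list("protA", "A5G", "neutral", ""))
  scheme <- weight_scheme("disease_specific", concept = "metabolic")
  idx <- variant_model_index(set, ds)
  cnt <- count_mappings(ds, scheme, idx)
  with_loo <- score_variants(ds, set, cnt, scheme, loo = TRUE,
                             background = uniform_dist(),
                             model_index = idx)
  no_loo <- score_variants(ds, set, cnt, scheme, loo = FALSE,
                           background = uniform_dist(), model_index = idx)
  # dom1 full counts: d=2, n=1. LOO for a disease record: d=1, n=1
  expect_equal(no_loo$Wd[[1]], 2 / 3, tolerance = 1e-12)
  expect_equal(with_loo$Wd[[1]], 1 / 2, tolerance = 1e-12)
  # LOO for the neutral record: d=2, n=0
  expect_equal(with_loo$Wn[[3]], 0, tolerance = 1e-12)
})

test_that("wild-type/profile disagreement is a warning, not an error", {
  set <- tiny_set()
  # dom1 state 2 is dominated by C; claiming wild-type D there is suspect
  ds <- variants_df(list("protA", "D5A", "disease", "metabolic"))
  scheme <- weight_scheme("disease_specific", concept = "metabolic")
  cnt <- count_mappings(ds, scheme, variant_model_index(set, ds))
  out <- score_variants(ds, set, cnt, scheme, background = uniform_dist())
  expect_match(out$warning[[1]], "not the dominant residue")
})
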