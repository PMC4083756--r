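test_that("normalized statistics reproduce published benchmark rows", {
  # musculoskeletal, disease-specific weighting
  st <- normalized_stats(confusion_matrix(tp = 4120, fp = 3123,
                                          tn = 77675, fn = 1983))
  expect_identical(round_half_up(st, 2),
                   c(accuracy = 0.82, precision = 0.95, specificity = 0.96,
                     sensitivity = 0.68, npv = 0.75, mcc = 0.66))
  # chance-level classifier
  st2 <- normalized_stats(confusion_matrix(50, 50, 50, 50))
  expect_equal(unname(st2), c(0.5, 0.5, 0.5, 0.5, 0.5, 0),
               tolerance = 1e-12)
  # perfect classifier
  st3 <- normalized_stats(confusion_matrix(10, 0, 10, 0))
  expect_equal(unname(st3), rep(1, 6), tolerance = 1e-12)
  expect_error(normalized_stats(confusion_matrix(0, 5, 5, 0)), "non-empty")
})

test_that("raw and normalized statistics differ exactly as class imbalance", {
  cm <- confusion_matrix(tp = 4120, fp = 3123, tn = 77675, fn = 1983)
  raw <- raw_stats(cm)
  expect_equal(raw[["precision"]], 4120 / 7243, tolerance = 1e-12)
  expect_lt(raw[["precision"]], 0.6)   # vs 0.95 normalized
  # symmetric matrices: raw == normalized
  sym <- confusion_matrix(30, 12, 30, 12)
  expect_equal(raw_stats(sym), normalized_stats(sym), tolerance = 1e-12)
  expect_equal(unname(raw_stats(confusion_matrix(1, 0, 1, 0))), rep(1, 6),
               tolerance = 1e-12)
})

test_that("normalized statistics are invariant under class rescaling", {
  set.seed(23)
  for (i in 1:100) {
    cm <- confusion_matrix(tp = sample(1:500, 1), fp = sample(1:500, 1),
                           tn = sample(1:500, 1), fn = sample(1:500, 1))
    a <- runif(1, 0.01, 50)
    b <- runif(1, 0.01, 50)
    scaled <- confusion_matrix(cm[["tp"]] * a, cm[["fp"]] * b,
                               cm[["tn"]] * b, cm[["fn"]] * a)
    expect_equal(normalized_stats(scaled), normalized_stats(cm),
                 tolerance = 1e-9)
  }
  # normalized accuracy is always the sensitivity/specificity midpoint
  cm <- confusion_matrix(40, 7, 93, 13)
  st <- normalized_stats(cm)
  expect_equal(st[["accuracy"]],
               (st[["sensitivity"]] + st[["specificity"]]) / 2,
               tolerance = 1e-12)
})

test_that("ROC handles separation, ties and the worked example", {
  expect_equal(roc_auc(c(-3, -2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1, tolerance = 1e-12)
  expect_equal(roc_auc(rep(0, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                    FALSE))$auc, 0.5, tolerance = 1e-12)
  # positives {-3, -1}, negatives {-2, 0}: of the four ordered pairs only
  # (-1, -2) is discordant and there are no ties, so AUC = 3/4
  expect_equal(roc_auc(c(-3, -1, -2, 0),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75,
               tolerance = 1e-12)
  expect_equal(auc_brute(c(-3, -1, -2, 0), c(TRUE, TRUE, FALSE, FALSE)),
               0.75, tolerance = 1e-12)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both classes")
  # the curve starts at (0,0) and ends at (1,1)
  r <- roc_auc(rnorm(20), rep(c(TRUE, FALSE), 10))
  expect_identical(c(r$points$fpr[1], r$points$tpr[1]), c(0, 0))
  n <- nrow(r$points)
  expect_identical(c(r$points$fpr[n], r$points$tpr[n]), c(1, 1))
})

test_that("trapezoidal AUC equals pairwise concordance and pROC", {
  set.seed(67)
  for (i in 1:60) {
    n <- sample(5:80, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- round(rnorm(n), sample(c(0, 1, 6), 1))  # induce ties
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
  scores <- round(rnorm(300), 1)
  labels <- runif(300) < 0.4
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, direction = ">",
    levels = c(FALSE, TRUE), quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("protein-level cross-validation partitions and is seeded", {
  sim <- simulate_dataset(fixture_config(seed = 3, n_proteins = 24,
                                         n_variants = c(40, 40, 40)))
  scheme <- weight_scheme("disease_specific", concept = "metabolic")
  cv1 <- kfold_cv(sim$variants, sim$profiles, scheme, k = 4, seed = 9)
  cv2 <- kfold_cv(sim$variants, sim$profiles, scheme, k = 4, seed = 9)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$scores$score, cv2$scores$score)
  # every variant is scored exactly once across folds
  key <- paste(cv1$scores$protein_id, cv1$scores$substitution)
  expect_identical(sort(key),
                   sort(paste(sim$variants$protein_id,
                              sim$variants$substitution)))
  # folds are by protein: no protein straddles folds
  by_prot <- tapply(cv1$scores$fold, cv1$scores$protein_id,
                    function(f) length(unique(f)))
  expect_true(all(by_prot == 1))
  expect_error(kfold_cv(sim$variants, sim$profiles, scheme, k = 500,
                        seed = 1), "exceeds")
  expect_error(kfold_cv(sim$variants, sim$profiles, scheme, k = 1,
                        seed = 1), "at least 2")
})

test_that("benchmark reports one row per method with sane degenerate rows", {
  sim <- simulate_dataset(fixture_config(seed = 5, n_proteins = 24,
                                         n_variants = c(40, 40, 40)))
  all_damaging <- rep(-1, nrow(sim$variants))
  bm <- benchmark(sim$variants, sim$profiles, "metabolic",
                  methods = c("disease_specific", "naive"),
                  extra_scores = list(always_damaging = all_damaging))
  expect_identical(nrow(bm), 3L)
  expect_setequal(bm$algorithm,
                  c("disease_specific", "naive", "always_damaging"))
  deg <- bm[bm$algorithm == "always_damaging", ]
  expect_identical(c(deg$sensitivity, deg$specificity, deg$mcc),
                   c(1, 0, 0))
  expect_identical(deg$tn + deg$fp,
                   sum(!(grepl("metabolic", sim$variants$concepts) &
                           sim$variants$label == "disease")))
  expect_error(benchmark(sim$variants, sim$profiles, "eye"),
               "no positives")
})

test_that("packaged reference statistics all recompute from their counts", {
  chk <- check_reference_benchmarks()
  expect_identical(nrow(chk), 96L)   # 16 rows x 6 statistics
  expect_true(all(chk$agree))
})
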