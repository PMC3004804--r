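test_that("ROC AUC matches brute-force pair counting, with midrank ties", {
  sc <- stats::setNames(c(3, 2, 1, 0), c("a", "b", "c", "d"))
  lab <- make_labels(c(a = TRUE, b = FALSE, c = TRUE, d = FALSE))
  r <- roc_auc(sc, lab)
  expect_equal(r$auc, 0.75)  # 3 of 4 active/inactive pairs concordant
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))

  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    scores <- stats::setNames(sample(round(stats::rnorm(n), 1)), paste0("m", 1:n))
    labels <- stats::setNames(stats::runif(n) < 0.4, names(scores))
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, make_labels(labels))$auc,
                 brute_force_auc(scores, labels))
  }
})

test_that("AUC is a ranking statistic: transform-invariant, sign-flipping", {
  set.seed(23)
  scores <- stats::setNames(stats::rnorm(80), paste0("m", 1:80))
  labels <- stats::setNames(stats::runif(80) < 0.3, names(scores))
  lab <- make_labels(labels)
  a0 <- roc_auc(scores, lab)$auc
  expect_equal(roc_auc(exp(2 * scores) + 5, lab)$auc, a0)    # increasing map
  expect_equal(roc_auc(-scores, lab)$auc, 1 - a0)            # reversal
  expect_error(roc_auc(scores, make_labels(stats::setNames(rep(TRUE, 80),
                                                           names(scores)))),
               "negative")
})

test_that("truth tables and trivial baselines obey the exact identities", {
  n <- 400
  ids <- paste0("m", 1:n)
  labels <- stats::setNames(seq_len(n) <= 0.37 * n, ids)
  lab <- make_labels(labels)
  all_tox <- stats::setNames(rep(TRUE, n), ids)
  all_clean <- stats::setNames(rep(FALSE, n), ids)
  expect_equal(truth_table(all_tox, lab)$accuracy, mean(labels))
  expect_equal(truth_table(all_clean, lab)$accuracy, 1 - mean(labels))
  tt <- truth_table(all_tox, lab)
  expect_equal(tt$sensitivity, 1)
  expect_true(is.na(truth_table(all_clean, lab)$sensitivity) ||
                truth_table(all_clean, lab)$sensitivity == 0)
})

test_that("cross-validation is deterministic, fold-balanced, and honest on noise", {
  uni <- generate_universe(seed = 41, n_series = 16L, series_size = 15L)
  assay <- generate_assay(uni, "A", seed = 42)
  lab <- label_top_fraction(assay, 0.2)
  cv1 <- kfold_cv(uni$compounds, lab, k = 5, seed = 7)
  cv2 <- kfold_cv(uni$compounds, lab, k = 5, seed = 7)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_identical(cv1$mean_auc, cv2$mean_auc)
  expect_gt(cv1$mean_auc, 0.8)   # planted signal is learnable

  shuffled <- make_labels(stats::setNames(
    with_seed_shuffle(lab$labels, 99), names(lab$labels)))
  cvs <- kfold_cv(uni$compounds, shuffled, k = 5, seed = 7)
  expect_lt(abs(cvs$mean_auc - 0.5), 0.08)
})

test_that("k = n cross-validation reduces to leave-one-out", {
  cs <- toy_compounds(list(c("f"), c("f", "g"), c("g"), c("h"), c("h", "g"),
                           c("f", "h")),
                      ids = paste0("m", 1:6))
  lab <- make_labels(stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                                     cs$id))
  cv <- suppressWarnings(kfold_cv(cs, lab, k = 6, seed = 1))
  expect_equal(cv$k, 6)
  # every fold holds out exactly one molecule: single-class test sets, so
  # fold AUCs are undefined but truth tables cover one compound each
  sizes <- vapply(cv$fold, function(f) f$truth$n, numeric(1))
  expect_equal(sort(sizes), rep(1, 6))
})

test_that("cutoff scan finds the planted optimum and skips degenerate cutoffs", {
  # noiseless screen: actives separate perfectly at any sane cutoff
  uni <- generate_universe(seed = 51, n_series = 10L, series_size = 12L,
                           p_toxic_series = 0.4, lipo_tox_shift = 0)
  assay <- generate_assay(uni, "A", noise_sd = 0, baseline = 0, seed = 52)
  truth <- uni$truth
  confirmed <- truth$id[truth$potency > 0.5]
  scan <- cutoff_scan(assay, uni$compounds, confirmed,
                      grid = seq(10, 90, by = 20))
  expect_s3_class(scan, "cutoff_scan")
  expect_true(scan$optimum %in% seq(10, 90, by = 20))
  expect_gt(scan$optimum_auc, 0.95)
  # single-point grid returns that cutoff
  one <- cutoff_scan(assay, uni$compounds, confirmed, grid = 40)
  expect_equal(one$optimum, 40)
  # a cutoff above every value is skipped with a reason
  skip_scan <- cutoff_scan(assay, uni$compounds, confirmed,
                           grid = c(40, 99.5))
  expect_true(skip_scan$scan$skipped[2])
  expect_match(skip_scan$scan$reason[2], "actives")
})

test_that("within-class and cross-set similarity diagnostics behave", {
  cs <- toy_compounds(list(c("1", "2"), c("1", "2"), c("9"), c("3", "4"),
                           c("3", "5")),
                      ids = c("t1", "t2", "t3", "n1", "n2"))
  lab <- make_labels(c(t1 = TRUE, t2 = TRUE, t3 = TRUE, n1 = FALSE, n2 = FALSE))
  w <- max_within_class_similarity(cs, lab)
  expect_equal(w$max_similarity[w$id == "t1"], 1)   # identical twin
  expect_equal(w$max_similarity[w$id == "t2"], 1)
  expect_equal(w$max_similarity[w$id == "t3"], 0)   # disjoint from class
  expect_equal(w$max_similarity[w$id == "n1"], 1 / 3)  # {3,4} vs {3,5}
  means <- attr(w, "class_means")
  expect_true(all(is.finite(means)))

  q <- toy_compounds(list(c("1", "2"), c("zz")), ids = c("q1", "q2"))
  xs <- cross_set_similarity(q, cs, lab)
  expect_equal(xs$max_vs_toxic[xs$id == "q1"], 1)
  expect_equal(xs$max_vs_toxic[xs$id == "q2"], 0)
  expect_equal(xs$max_vs_non_toxic[xs$id == "q2"], 0)
  expect_equal(xs$max_vs_non_toxic[xs$id == "q1"],
               tanimoto(c("1", "2"), c("3", "4")))

  # singleton class: undefined within-class similarity
  lab1 <- make_labels(c(t1 = TRUE, t2 = FALSE, t3 = FALSE, n1 = FALSE,
                        n2 = FALSE))
  w1 <- max_within_class_similarity(cs, lab1)
  expect_true(is.na(w1$max_similarity[w1$id == "t1"]))
})

test_that("score-agreement binning concentrates mass correctly", {
  set.seed(61)
  ids <- paste0("m", 1:300)
  s <- stats::setNames(stats::rnorm(300), ids)
  lab <- make_labels(stats::setNames(s > 0.5, ids))
  # identical scores: every occupied cell is on the diagonal
  tab <- score_agreement_table(s, s, lab, n_bins = 8)
  expect_true(all(tab$bin_a == tab$bin_b))
  expect_equal(sum(tab$n), 300)
  # independent scores: occupied cells scatter off the diagonal
  s2 <- stats::setNames(stats::rnorm(300), ids)
  tab2 <- score_agreement_table(s, s2, lab, n_bins = 8)
  expect_gt(sum(tab2$bin_a != tab2$bin_b), nrow(tab2) / 4)
  expect_warning(score_agreement_table(s, stats::setNames(rep(1, 300), ids),
                                       lab), "constant")
})
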