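test_that("Laplacian correction shrinks toward the baseline rate", {
  # unsampled feature: estimate is exactly the baseline
  for (p in seq(0.05, 0.95, by = 0.1))
    expect_equal(laplace_probability(0, 0, p), p)
  # worked example: p=0.5 (K=2), A_D=3, T_D=4 -> (3+1)/(4+2)
  expect_equal(laplace_probability(3, 4, 0.5), 4 / 6)
  # the corrected value undershoots the raw frequency 3/4 (shrinkage)
  expect_lt(laplace_probability(3, 4, 0.5), 3 / 4)
  expect_error(laplace_probability(0, 0, 1), "degenerate")
  expect_error(laplace_probability(3, 2, 0.5), "a_d")
})

test_that("fitting reproduces hand-computed weights and is deterministic", {
  # feature f only in the two actives: w = ln(((2+1)/(2+2))/0.5) = ln 1.5
  cs <- toy_compounds(list(c("f"), c("f"), c("g"), c("h")),
                      ids = c("a1", "a2", "i1", "i2"))
  lab <- make_labels(c(a1 = TRUE, a2 = TRUE, i1 = FALSE, i2 = FALSE))
  m <- fit_bayes(cs, lab)
  expect_equal(unname(m$w["f"]), log(1.5))
  expect_equal(m$p_active * m$K, 1)

  # feature in every molecule of both classes: weight exactly 0
  cs2 <- toy_compounds(list(c("u", "x"), c("u", "y"), c("u", "z"), c("u", "w")),
                       ids = names(lab$labels))
  m2 <- fit_bayes(cs2, lab)
  expect_equal(unname(m2$w["u"]), 0)

  expect_identical(fit_bayes(cs, lab)$w, m$w)
  expect_error(fit_bayes(cs, make_labels(c(a1 = TRUE, a2 = TRUE, i1 = TRUE,
                                           i2 = TRUE))), "degenerate")
})

test_that("scores are sums of log relative likelihoods with neutral fallback", {
  cs <- toy_compounds(list(c("f"), c("f"), c("g"), c("h")),
                      ids = c("a1", "a2", "i1", "i2"))
  lab <- make_labels(c(a1 = TRUE, a2 = TRUE, i1 = FALSE, i2 = FALSE))
  m <- fit_bayes(cs, lab)
  sc <- score_bayes(m, toy_compounds(list(c("f"), character(0), c("nope")),
                                     ids = c("hit", "empty", "unseen")))
  expect_equal(sc$score[sc$id == "hit"], log(1.5))
  expect_true(sc$predicted[sc$id == "hit"])
  expect_equal(sc$score[sc$id == "empty"], 0)
  expect_false(sc$predicted[sc$id == "empty"])
  expect_equal(sc$score[sc$id == "unseen"], 0)
  # identical feature sets score identically
  twin <- score_bayes(m, toy_compounds(list(c("f", "g"), c("g", "f")),
                                       ids = c("t1", "t2")))
  expect_equal(twin$score[1], twin$score[2])
})

test_that("score equals the brute-force corrected probability product", {
  set.seed(21)
  vocab <- as.character(1:6)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    feats <- lapply(seq_len(n), function(i)
      sample(vocab, sample(0:6, 1)))
    labels <- logical(n)
    labels[sample(n, sample(1:(n - 1), 1))] <- TRUE
    if (!any(labels) || all(labels)) next
    ids <- paste0("m", seq_len(n))
    cs <- toy_compounds(feats, ids = ids)
    m <- fit_bayes(cs, make_labels(stats::setNames(labels, ids)))
    probe_feats <- sample(vocab, sample(1:6, 1))
    got <- score_bayes(m, toy_compounds(list(probe_feats), ids = "probe"))$score
    want <- brute_force_score(probe_feats, feats, labels)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("weights are monotone in the active count and invariant to relabelling", {
  # at fixed T_D, more actives containing the feature -> larger weight
  p <- 0.3
  w <- log(laplace_probability(0:5, 5, p) / p)
  expect_true(all(diff(w) > 0))

  # permuting feature ids leaves scores unchanged
  cs <- toy_compounds(list(c("f", "g"), c("f"), c("g"), c("h")),
                      ids = paste0("m", 1:4))
  lab <- make_labels(stats::setNames(c(TRUE, TRUE, FALSE, FALSE),
                                     paste0("m", 1:4)))
  perm <- c(f = "zz", g = "qq", h = "aa")
  cs_perm <- toy_compounds(lapply(cs$features, function(x) unname(perm[x])),
                           ids = cs$id)
  s1 <- score_bayes(fit_bayes(cs, lab), cs)$score
  s2 <- score_bayes(fit_bayes(cs_perm, lab), cs_perm)$score
  expect_equal(s1, s2)
})

test_that("descriptor bins learn from training data and clamp outside it", {
  set.seed(5)
  n <- 200
  ids <- sprintf("m%03d", 1:n)
  x <- c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 4))
  lab <- make_labels(stats::setNames(rep(c(FALSE, TRUE), each = n / 2), ids))
  cs <- compound_set(ids, features = rep(list(character(0)), n),
                     descriptors = data.frame(alogp = x))
  m <- fit_bayes(cs, lab)
  expect_true("alogp" %in% m$descriptor_names)
  # extreme probes map to the extreme bins: far-high resembles actives
  probe <- compound_set(c("lo", "hi"),
                        features = list(character(0), character(0)),
                        descriptors = data.frame(alogp = c(-50, 50)))
  sc <- score_bayes(m, probe)
  expect_lt(sc$score[sc$id == "lo"], 0)
  expect_gt(sc$score[sc$id == "hi"], 0)
})

test_that("class imbalance changes scores but not the ranking quality much", {
  uni <- generate_universe(seed = 31, n_series = 20L, series_size = 20L)
  assay <- generate_assay(uni, "A", seed = 32)
  lab <- label_top_fraction(assay, 0.2)
  ids <- uni$compounds$id
  test_ids <- ids[seq(1, length(ids), by = 4)]
  train_ids <- setdiff(ids, test_ids)
  cs_train <- cs_subset(uni$compounds, train_ids)
  m1 <- fit_bayes(cs_train, lab)
  # duplicate every inactive training molecule (changes p_active)
  inact <- train_ids[!lab$labels[train_ids]]
  dup <- cs_subset(uni$compounds, inact)
  dup$id <- paste0(dup$id, "_dup")
  names(dup$features) <- dup$id
  cs_dup <- cs_union(cs_train, dup)
  lab_dup <- make_labels(c(lab$labels,
                           stats::setNames(lab$labels[inact], dup$id)))
  m2 <- fit_bayes(cs_dup, lab_dup)
  expect_true(abs(m2$p_active - m1$p_active) > 0.05)
  cs_test <- cs_subset(uni$compounds, test_ids)
  auc1 <- roc_auc(score_bayes(m1, cs_test), lab)$auc
  auc2 <- roc_auc(score_bayes(m2, cs_test), lab)$auc
  expect_lte(abs(auc1 - auc2), 0.02)
})

test_that("threshold selection maximizes Youden's J with tie to the left", {
  sc <- stats::setNames(c(-1, 1), c("n", "p"))
  lab <- make_labels(c(n = FALSE, p = TRUE))
  expect_equal(choose_threshold(sc, lab, method = "best_split"), 0)
  expect_equal(choose_threshold(method = "zero"), 0)
  # perfectly separated: midpoint of the gap
  sc2 <- stats::setNames(c(1, 2, 10, 11), c("a", "b", "c", "d"))
  lab2 <- make_labels(c(a = FALSE, b = FALSE, c = TRUE, d = TRUE))
  expect_equal(choose_threshold(sc2, lab2, method = "best_split"), 6)
  expect_warning(
    th <- choose_threshold(stats::setNames(c(2, 2), c("a", "b")),
                           make_labels(c(a = TRUE, b = FALSE)),
                           method = "best_split"),
    "equal")
  expect_equal(th, 2)
})
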