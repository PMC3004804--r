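#' ROC analysis of a scored, labelled set
#'
#' The ROC score (AUC) is computed with the rank statistic using midranks
#' for tied scores — the Mann-Whitney estimate of the probability that a
#' randomly chosen toxic compound outranks a randomly chosen non-toxic one
#' (ties counting one half). This equals the trapezoidal area under the
#' ROC curve traced over all score thresholds.
#'
#' @param scores numeric scores named by compound id, or a data.frame from
#'   [score_bayes()].
#' @param labelled a `labelled_set` covering the scored ids.
#' @return object of class `roc_result`: list with `auc`, `curve` (a
#'   data.frame of (fpr, tpr) from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labelled) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$id)
  lab <- labelled$labels[match(names(scores), names(labelled$labels))]
  if (anyNA(lab)) stop("roc_auc: labels missing for some scored compounds")
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L) stop("roc_auc: no positive (toxic) compounds in the set")
  if (n_neg == 0L) stop("roc_auc: no negative (non-toxic) compounds in the set")
  r <- rank(scores)  # midranks for ties
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]; l_ord <- lab[ord]
  grp_end <- c(which(diff(s_ord) != 0), length(s_ord))  # threshold per distinct score
  tp <- cumsum(l_ord)[grp_end]
  fp <- cumsum(!l_ord)[grp_end]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC=%.4f (%d toxic vs %d non-toxic)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Truth table of predictions against experimental labels
#'
#' @param scored data.frame from [score_bayes()] (uses the `predicted`
#'   column), or a named logical vector of predictions.
#' @param labelled a `labelled_set`.
#' @return a `truth_table` (see [truth_table_counts()]) with sensitivity,
#'   specificity and accuracy; undefined metrics (zero denominator) are NA.
#' @export
truth_table <- function(scored, labelled) {
  if (is.data.frame(scored))
    pred <- stats::setNames(scored$predicted, scored$id)
  else pred <- scored
  lab <- labelled$labels[match(names(pred), names(labelled$labels))]
  if (anyNA(lab)) stop("truth_table: labels missing for some predictions")
  truth_table_counts(tp = sum(pred & lab), fp = sum(pred & !lab),
                     tn = sum(!pred & !lab), fn = sum(!pred & lab))
}

#' k-fold cross-validation of the Bayes learner
#'
#' The data are split into k random, roughly equal-sized folds
#' (unstratified: plain random sets). For each fold a model is fitted on
#' the other k-1 folds and evaluated on the held-out fold; per-fold AUC and
#' truth table are returned with mean and sample-SD AUC. A fold whose test
#' set lacks one class gets an undefined AUC and is excluded from the mean
#' with a warning.
#'
#' @param cs a [compound_set()].
#' @param labelled a `labelled_set` covering `cs`.
#' @param k number of folds, default 5.
#' @param seed integer seed making the fold assignment reproducible.
#' @param ... passed to [fit_bayes()] (e.g. `n_bins`, `use_descriptors`).
#' @return object of class `cv_result`: `k`, `seed`, `fold` (list of
#'   per-fold `roc` and `truth`), `fold_auc`, `mean_auc`, `sd_auc`.
#' @export
kfold_cv <- function(cs, labelled, k = 5L, seed = 0L, ...) {
  stopifnot(inherits(cs, "compound_set"), k >= 2L)
  n <- nrow(cs)
  if (n < k) stop("kfold_cv: fewer molecules than folds")
  lab <- labelled$labels[match(cs$id, names(labelled$labels))]
  if (min(sum(lab), sum(!lab)) < k)
    warning("kfold_cv: a class has fewer members than folds; ",
            "some test folds may lack it")
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  folds <- vector("list", k)
  fold_auc <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    test <- fold_of == i
    model <- fit_bayes(cs_subset(cs, cs$id[!test]),
                       labelled, ...)
    scored <- score_bayes(model, cs_subset(cs, cs$id[test]))
    roc <- tryCatch(roc_auc(scored, labelled), error = function(e) NULL)
    tt <- truth_table(scored, labelled)
    folds[[i]] <- list(roc = roc, truth = tt)
    if (!is.null(roc)) fold_auc[i] <- roc$auc
  }
  if (anyNA(fold_auc))
    warning("kfold_cv: ", sum(is.na(fold_auc)),
            " fold(s) had a single-class test set; excluded from the mean AUC")
  ok <- !is.na(fold_auc)
  structure(list(k = k, seed = as.integer(seed), fold = folds,
                 fold_auc = fold_auc,
                 mean_auc = mean(fold_auc[ok]),
                 sd_auc = stats::sd(fold_auc[ok])),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold (seed %d): ROC %.3f +/- %.3f\n",
              x$k, x$seed, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Activity-cutoff optimisation scan
#'
#' Model building is cheap enough that the best activity cutoff for a
#' single-concentration screen can be found empirically: for each candidate
#' percent-inhibition cutoff, label the primary screen by `value > cutoff`,
#' fit a model, score the screen, and compute the ROC score taking the
#' confirmed actives (from the follow-up potency assay) as positives and
#' all other primary compounds as negatives. The optimum is the cutoff with
#' the highest ROC; ties break toward the lowest cutoff.
#'
#' @param primary an [assay_dataset()] with percent-inhibition readout.
#' @param cs the [compound_set()] for the primary screen.
#' @param confirmed_actives character vector of compound ids confirmed
#'   toxic in the follow-up assay (must be a subset of the primary ids).
#' @param grid ordered candidate cutoffs (%), default `seq(-20, 100, 1)`.
#' @param eval_mode `"full"` (default): one model trained on the whole
#'   screen at each cutoff, scoring every compound; `"cv"`: 5-fold
#'   cross-validated scoring (each compound scored by the model not trained
#'   on it), mean AUC reported.
#' @param seed fold seed for `eval_mode = "cv"`.
#' @param ... passed to [fit_bayes()].
#' @return object of class `cutoff_scan`: data.frame `scan` with columns
#'   `cutoff`, `auc`, `n_active`, `skipped`, `reason`; plus `optimum` and
#'   `optimum_auc`.
#' @export
cutoff_scan <- function(primary, cs, confirmed_actives,
                        grid = seq(-20, 100, by = 1),
                        eval_mode = c("full", "cv"), seed = 0L, ...) {
  eval_mode <- match.arg(eval_mode)
  stopifnot(inherits(primary, "assay_dataset"), length(grid) >= 1L)
  if (is.unsorted(grid, strictly = TRUE)) stop("cutoff_scan: grid must be strictly increasing")
  if (!all(confirmed_actives %in% names(primary$values)))
    stop("cutoff_scan: confirmed_actives must be a subset of primary compounds")
  eval_lab <- new_labelled_set(
    stats::setNames(names(primary$values) %in% confirmed_actives,
                    names(primary$values)),
    rule = list(kind = "confirmed_actives"))
  cs <- cs_subset(cs, names(primary$values))
  auc <- rep(NA_real_, length(grid))
  n_act <- integer(length(grid))
  reason <- character(length(grid))
  for (g in seq_along(grid)) {
    lab <- label_fixed(primary, grid[g])
    n_act[g] <- n_toxic(lab)
    if (n_act[g] < 2L || length(lab$labels) - n_act[g] < 2L) {
      reason[g] <- sprintf("cutoff %g leaves %d actives / %d inactives",
                           grid[g], n_act[g], length(lab$labels) - n_act[g])
      next
    }
    if (eval_mode == "full") {
      model <- fit_bayes(cs, lab, ...)
      scored <- score_bayes(model, cs)
      auc[g] <- roc_auc(scored, eval_lab)$auc
    } else {
      cv <- suppressWarnings(kfold_cv_scores(cs, lab, k = 5L, seed = seed, ...))
      auc[g] <- roc_auc(cv, eval_lab)$auc
    }
  }
  scan <- data.frame(cutoff = grid, auc = auc, n_active = n_act,
                     skipped = is.na(auc), reason = reason,
                     stringsAsFactors = FALSE)
  if (all(is.na(auc))) stop("cutoff_scan: every grid point was skipped")
  opt <- grid[which.max(auc)]   # first maximum = lowest cutoff on ties
  structure(list(scan = scan, optimum = opt,
                 optimum_auc = max(auc, na.rm = TRUE)),
            class = "cutoff_scan")
}

# Out-of-fold scores: every compound scored by the model whose training
# folds exclude it. Used by cutoff_scan(eval_mode = "cv").
kfold_cv_scores <- function(cs, labelled, k = 5L, seed = 0L, ...) {
  n <- nrow(cs)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  out <- data.frame(id = cs$id, score = NA_real_, predicted = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    test <- fold_of == i
    model <- fit_bayes(cs_subset(cs, cs$id[!test]), labelled, ...)
    sc <- score_bayes(model, cs_subset(cs, cs$id[test]))
    out$score[test] <- sc$score
    out$predicted[test] <- sc$predicted
  }
  out
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("<cutoff_scan> %d cutoffs (%d skipped); optimum %g%% (ROC %.3f)\n",
              nrow(x$scan), sum(x$scan$skipped), x$optimum, x$optimum_auc))
  invisible(x)
}

#' Per-compound maximum within-class Tanimoto similarity
#'
#' For every compound, the highest Tanimoto similarity to any *other*
#' compound of the same class (toxic or non-toxic). A tight toxic class
#' (high mean) indicates structure-activity series; compounds in a
#' singleton class get NA ("undefined").
#'
#' @param cs a [compound_set()].
#' @param labelled a `labelled_set` covering `cs`.
#' @return data.frame `id`, `toxic`, `max_similarity`, plus attribute
#'   `class_means` (named numeric: toxic / non_toxic mean of defined values).
#' @export
max_within_class_similarity <- function(cs, labelled) {
  lab <- labelled$labels[match(cs$id, names(labelled$labels))]
  if (anyNA(lab)) stop("max_within_class_similarity: labels missing")
  out <- data.frame(id = cs$id, toxic = lab, max_similarity = NA_real_,
                    stringsAsFactors = FALSE)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(lab == cls)
    if (length(idx) < 2L) next
    feats <- cs$features[idx]
    sims <- pairwise_max_tanimoto(feats)
    out$max_similarity[idx] <- sims
  }
  means <- c(toxic = mean(out$max_similarity[out$toxic], na.rm = TRUE),
             non_toxic = mean(out$max_similarity[!out$toxic], na.rm = TRUE))
  attr(out, "class_means") <- means
  out
}

# max Tanimoto of each feature set to any other in the list
pairwise_max_tanimoto <- function(feats) {
  n <- length(feats)
  best <- numeric(n)
  sizes <- lengths(feats)
  for (i in seq_len(n - 1L)) {
    fi <- feats[[i]]
    for (j in (i + 1L):n) {
      ni <- length(intersect(fi, feats[[j]]))
      den <- sizes[i] + sizes[j] - ni
      s <- if (den == 0L) 0 else ni / den
      if (s > best[i]) best[i] <- s
      if (s > best[j]) best[j] <- s
    }
  }
  best
}

#' Maximum similarity of query compounds to each reference class
#'
#' For each query compound, the highest Tanimoto similarity to the toxic
#' reference compounds and to the non-toxic reference compounds — the
#' chemical-space overlap diagnostic used to explain failed cross-assay
#' predictions.
#'
#' @param query a [compound_set()] of query molecules.
#' @param reference a [compound_set()] of reference molecules.
#' @param reference_labels a `labelled_set` covering the reference set.
#' @return data.frame `id`, `max_vs_toxic`, `max_vs_non_toxic` (empty query
#'   gives an empty data.frame). An empty reference class is an error.
#' @export
cross_set_similarity <- function(query, reference, reference_labels) {
  lab <- reference_labels$labels[match(reference$id,
                                       names(reference_labels$labels))]
  if (anyNA(lab)) stop("cross_set_similarity: reference labels missing")
  if (!any(lab) || !any(!lab))
    stop("cross_set_similarity: both reference classes must be non-empty")
  max_to <- function(f, refs) {
    if (length(refs) == 0L) return(NA_real_)
    max(vapply(refs, function(r) {
      ni <- length(intersect(f, r))
      den <- length(f) + length(r) - ni
      if (den == 0L) 0 else ni / den
    }, numeric(1)))
  }
  tox_refs <- reference$features[lab]
  non_refs <- reference$features[!lab]
  data.frame(
    id = query$id,
    max_vs_toxic = vapply(query$features, max_to, numeric(1), refs = tox_refs),
    max_vs_non_toxic = vapply(query$features, max_to, numeric(1), refs = non_refs),
    stringsAsFactors = FALSE)
}

#' Two-dimensional score-agreement binning
#'
#' Bins two models' scores of the same compounds into an `n_bins` x
#' `n_bins` grid of equal-width bins over each score's range, and reports
#' per-cell totals and toxic fraction — the data behind the binned
#' pie-chart view of whether two models rank the same compounds as toxic.
#'
#' @param scores_a,scores_b numeric scores named by compound id (or
#'   [score_bayes()] data.frames); must share the same id domain.
#' @param labelled a `labelled_set` covering the compounds.
#' @param n_bins bins per axis, default 16.
#' @return data.frame `bin_a`, `bin_b`, `n`, `n_toxic`, `toxic_fraction`
#'   (cells with n = 0 omitted), with attributes `breaks_a`, `breaks_b`.
#' @export
score_agreement_table <- function(scores_a, scores_b, labelled, n_bins = 16L) {
  if (is.data.frame(scores_a)) scores_a <- stats::setNames(scores_a$score, scores_a$id)
  if (is.data.frame(scores_b)) scores_b <- stats::setNames(scores_b$score, scores_b$id)
  ids <- names(scores_a)
  if (!setequal(ids, names(scores_b)))
    stop("score_agreement_table: score sets must cover the same compounds")
  scores_b <- scores_b[ids]
  lab <- labelled$labels[match(ids, names(labelled$labels))]
  if (anyNA(lab)) stop("score_agreement_table: labels missing")
  axis_bins <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning("score_agreement_table: constant scores on one axis; single bin")
      return(list(bin = rep(1L, length(x)), breaks = rng))
    }
    br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    list(bin = pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
         breaks = br)
  }
  ba <- axis_bins(scores_a); bb <- axis_bins(scores_b)
  key <- interaction(ba$bin, bb$bin, drop = TRUE)
  agg <- data.frame(
    bin_a = as.integer(tapply(ba$bin, key, `[`, 1L)),
    bin_b = as.integer(tapply(bb$bin, key, `[`, 1L)),
    n = as.integer(tapply(lab, key, length)),
    n_toxic = as.integer(tapply(lab, key, sum)))
  agg$toxic_fraction <- agg$n_toxic / agg$n
  agg <- agg[order(agg$bin_a, agg$bin_b), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "breaks_a") <- ba$breaks
  attr(agg, "breaks_b") <- bb$breaks
  agg
}
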