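#' Laplacian-corrected feature probability
#'
#' For a feature D seen in `t_d` training molecules of which `a_d` are
#' active, the naive estimate A_D/(A_D+I_D) is unreliable for rarely
#' sampled features. The Laplacian-modified estimate adds K = 1/P(active)
#' virtual samples at the baseline hit rate:
#'
#'   P_corr(active|D) = (A_D + P(active) * K) / ((A_D + I_D) + K)
#'                    = (A_D + 1) / (T_D + 1/P(active))
#'
#' so that as T_D approaches 0 the estimate converges to P(active), i.e. an
#' unsampled feature is assumed unrelated to activity.
#'
#' @param a_d number of active molecules containing the feature (vectorized).
#' @param t_d total number of molecules containing the feature.
#' @param p_active baseline activity rate, strictly in (0,1).
#' @return corrected probabilities, strictly in (0,1).
#' @export
laplace_probability <- function(a_d, t_d, p_active) {
  if (any(p_active <= 0) || any(p_active >= 1))
    stop("laplace_probability: p_active must be strictly inside (0,1) ",
         "(degenerate training set)")
  if (any(a_d < 0) || any(t_d < a_d))
    stop("laplace_probability: require 0 <= a_d <= t_d")
  (a_d + 1) / (t_d + 1 / p_active)
}

new_bayes_model <- function(n_active, n_inactive, feature_ids, a_d, t_d,
                            bin_edges, descriptor_names, n_bins, threshold) {
  p_active <- n_active / (n_active + n_inactive)
  w <- log(laplace_probability(a_d, t_d, p_active) / p_active)
  names(w) <- feature_ids
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 p_active = p_active, K = 1 / p_active,
                 feature_ids = feature_ids,
                 a_d = as.integer(a_d), t_d = as.integer(t_d), w = w,
                 bin_edges = bin_edges,
                 descriptor_names = descriptor_names,
                 n_bins = as.integer(n_bins),
                 threshold = as.numeric(threshold)),
            class = "bayes_model")
}

#' @export
print.bayes_model <- function(x, ...) {
  cat(sprintf(paste0("<bayes_model> %d active / %d inactive (P(active)=%.3f), ",
                     "%d features, %d binned descriptor(s), threshold=%g\n"),
              x$n_active, x$n_inactive, x$p_active, length(x$feature_ids),
              length(x$descriptor_names), x$threshold))
  invisible(x)
}

# Tokens for one compound set under a model's (or a training) binning:
# fingerprint feature ids verbatim, plus one categorical token per binned
# descriptor value. Values outside the training range fall in the extreme
# bins; NA descriptors contribute no token.
descriptor_tokens <- function(cs, bin_edges) {
  toks <- rep(list(character(0)), nrow(cs))
  for (nm in names(bin_edges)) {
    if (!nm %in% names(cs)) next
    inner <- bin_edges[[nm]]
    x <- cs[[nm]]
    ok <- !is.na(x)
    if (!any(ok)) next
    b <- findInterval(x[ok], inner) + 1L
    tk <- sprintf("d:%s:%d", nm, b)
    j <- which(ok)
    for (i in seq_along(j)) toks[[j[i]]] <- c(toks[[j[i]]], tk[i])
  }
  toks
}

compound_tokens <- function(cs, bin_edges) {
  dt <- descriptor_tokens(cs, bin_edges)
  mapply(function(f, d) c(f, d), cs$features, dt, SIMPLIFY = FALSE)
}

#' Fit a Laplacian-modified naive Bayes model
#'
#' Continuous descriptors are discretized into learned quantile bins
#' (default 10 per descriptor) and each molecule's bin memberships join its
#' fingerprint features as categorical tokens. For every token D the model
#' counts the actives containing it (A_D) and the total molecules
#' containing it (T_D), and stores the log relative likelihood
#' `w_D = ln(P_corr(active|D) / P(active))`. No feature pre-selection is
#' performed: tokens uncorrelated with activity shrink to weight ~ 0.
#'
#' @param cs a [compound_set()] (training molecules).
#' @param labelled a `labelled_set` covering the training molecules.
#' @param n_bins quantile bins per continuous descriptor, default 10.
#' @param use_descriptors include binned descriptor tokens (default TRUE
#'   when the compound set has descriptor columns).
#' @param threshold classification threshold on the score, default 0 (a
#'   score above 0 means above-baseline toxicity likelihood).
#' @return a `bayes_model`.
#' @export
fit_bayes <- function(cs, labelled, n_bins = 10L,
                      use_descriptors = TRUE, threshold = 0) {
  stopifnot(inherits(cs, "compound_set"), inherits(labelled, "labelled_set"))
  lab <- labelled$labels[match(cs$id, names(labelled$labels))]
  if (anyNA(lab))
    stop("fit_bayes: labels missing for ",
         sum(is.na(lab)), " training molecule(s)")
  if (nrow(cs) < 2L) stop("fit_bayes: need at least 2 molecules")
  n_active <- sum(lab); n_inactive <- sum(!lab)
  if (n_active == 0L || n_inactive == 0L)
    stop("fit_bayes: degenerate training set (single class)")

  bin_edges <- list()
  if (isTRUE(use_descriptors)) {
    for (nm in descriptor_names(cs)) {
      x <- cs[[nm]]
      x <- x[!is.na(x)]
      if (length(x) < 2L) next
      qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                            names = FALSE, type = 7)
      inner <- unique(qs[-c(1L, length(qs))])
      bin_edges[[nm]] <- inner   # interior edges; k edges -> k+1 bins
    }
  }
  toks <- compound_tokens(cs, bin_edges)
  all_tok <- unlist(toks, use.names = FALSE)
  if (length(all_tok) == 0L)
    stop("fit_bayes: no features or descriptors present in training set")
  tok_lab <- rep(lab, lengths(toks))
  t_tab <- table(all_tok)
  a_tab <- table(factor(all_tok[tok_lab], levels = names(t_tab)))
  new_bayes_model(n_active = n_active, n_inactive = n_inactive,
                  feature_ids = names(t_tab),
                  a_d = as.integer(a_tab), t_d = as.integer(t_tab),
                  bin_edges = bin_edges,
                  descriptor_names = names(bin_edges),
                  n_bins = n_bins, threshold = threshold)
}

#' Score molecules with a fitted model
#'
#' The Bayesian score of a molecule is the sum over its present tokens of
#' the stored log relative likelihoods (the log of the product of
#' Laplacian-corrected per-feature probabilities relative to baseline).
#' Tokens unseen in training contribute 0; a molecule with no known tokens
#' scores exactly 0 (neutral). Descriptor values outside the training range
#' map to the nearest extreme bin.
#'
#' @param model a `bayes_model`.
#' @param cs a [compound_set()] to score.
#' @return data.frame with columns `id`, `score`, and `predicted`
#'   (`score > model$threshold`).
#' @export
score_bayes <- function(model, cs) {
  stopifnot(inherits(model, "bayes_model"), inherits(cs, "compound_set"))
  toks <- compound_tokens(cs, model$bin_edges)
  n <- nrow(cs)
  scores <- numeric(n)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat)) {
    grp <- rep.int(seq_len(n), lengths(toks))
    v <- model$w[flat]
    v[is.na(v)] <- 0
    sums <- rowsum(v, grp)
    scores[as.integer(rownames(sums))] <- sums[, 1L]
  }
  data.frame(id = cs$id, score = scores,
             predicted = scores > model$threshold,
             stringsAsFactors = FALSE)
}

#' Choose a classification threshold
#'
#' `"zero"` returns 0, the natural neutral point of the log-relative score.
#' `"best_split"` maximizes Youden's J (sensitivity + specificity - 1) over
#' candidate thresholds placed midway between adjacent distinct scores;
#' ties are broken toward the lower threshold.
#'
#' @param scores numeric scores named by compound id (or a data.frame from
#'   [score_bayes()]).
#' @param labelled a `labelled_set` (required for `"best_split"`).
#' @param method `"zero"` or `"best_split"`.
#' @return a single numeric threshold.
#' @export
choose_threshold <- function(scores = NULL, labelled = NULL,
                             method = c("zero", "best_split")) {
  method <- match.arg(method)
  if (method == "zero") return(0)
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$id)
  if (is.null(scores) || is.null(labelled))
    stop("choose_threshold: best_split needs scores and labels")
  lab <- labelled$labels[names(scores)]
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("choose_threshold: all scores equal; J = 0")
    return(u)
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(th) {
    pred <- scores > th
    sens <- sum(pred & lab) / sum(lab)
    spec <- sum(!pred & !lab) / sum(!lab)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]   # which.max takes the first (lowest) maximiser
}
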