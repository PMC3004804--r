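#' Directed cross-prediction ROC matrix over an assay panel
#'
#' For each ordered pair of assays (i, j), fits a model on assay i's
#' labelled compounds and computes the ROC score of that model predicting
#' assay j's experimental labels. The matrix is generally asymmetric and
#' the diagonal is undefined. Assays with fewer than `min_actives` toxic
#' compounds, or on which a model cannot be fitted (single class), are
#' excluded and reported. Panels should be built within one readout type
#' (percent inhibition and IC50 networks are built separately: follow-up
#' IC50 sets are hit-enriched and less diverse than primary screens).
#'
#' @param panel named list; each element `list(dataset = assay_dataset,
#'   labels = labelled_set)`.
#' @param cs the [compound_set()] store resolving every measured id.
#' @param min_actives minimum toxic count per assay (default 10).
#' @param exclude_overlap drop compounds present in the training assay
#'   from the test assay before evaluating (default FALSE: shared
#'   compounds are kept).
#' @param ... passed to [fit_bayes()].
#' @return list with `roc` (numeric matrix, NA diagonal), `nodes`
#'   (data.frame `assay_id`, `n_compounds`, `n_toxic`), and `excluded`
#'   (data.frame `assay_id`, `reason`).
#' @export
cross_roc_matrix <- function(panel, cs, min_actives = 10L,
                             exclude_overlap = FALSE, ...) {
  stopifnot(is.list(panel), length(panel) >= 2L, !is.null(names(panel)))
  excluded <- data.frame(assay_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- character(0); models <- list()
  for (nm in names(panel)) {
    ent <- panel[[nm]]
    if (!filter_min_actives(ent$labels, min_actives)) {
      excluded <- rbind(excluded, data.frame(
        assay_id = nm,
        reason = sprintf("only %d toxic compounds (need %d)",
                         n_toxic(ent$labels), min_actives)))
      next
    }
    ids <- names(ent$dataset$values)
    m <- tryCatch(fit_bayes(cs_subset(cs, ids), ent$labels, ...),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) {
      excluded <- rbind(excluded,
                        data.frame(assay_id = nm, reason = m))
      next
    }
    models[[nm]] <- m
    keep <- c(keep, nm)
  }
  if (length(keep) < 2L)
    stop("cross_roc_matrix: fewer than 2 modellable assays")
  roc <- matrix(NA_real_, length(keep), length(keep),
                dimnames = list(train = keep, test = keep))
  for (i in keep) for (j in keep) {
    if (i == j) next
    test_ids <- names(panel[[j]]$dataset$values)
    if (exclude_overlap)
      test_ids <- setdiff(test_ids, names(panel[[i]]$dataset$values))
    if (length(test_ids) < 2L) next
    scored <- score_bayes(models[[i]], cs_subset(cs, test_ids))
    roc[i, j] <- tryCatch(roc_auc(scored, panel[[j]]$labels)$auc,
                          error = function(e) NA_real_)
  }
  nodes <- data.frame(
    assay_id = keep,
    n_compounds = vapply(keep, function(nm)
      length(panel[[nm]]$dataset$values), integer(1)),
    n_toxic = vapply(keep, function(nm)
      n_toxic(panel[[nm]]$labels), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(roc = roc, nodes = nodes, excluded = excluded)
}

#' Build a bidirectional prediction network
#'
#' Two assays are connected iff each one's model predicts the other's
#' outcome with a ROC score at or above the threshold (both directions).
#' Connected components of the resulting undirected graph identify groups
#' of assays whose data can be merged into one training set.
#'
#' @param matrix result of [cross_roc_matrix()] (or a bare named square
#'   numeric matrix).
#' @param threshold ROC threshold, default 0.60.
#' @param strict use `>` instead of the default `>=` comparison.
#' @return object of class `prediction_network`: `nodes`, `roc`,
#'   `threshold`, `edges` (data.frame `a`, `b`, `roc_ab`, `roc_ba`),
#'   `graph` (igraph), `components` (named membership vector).
#' @export
build_network <- function(matrix, threshold = 0.60, strict = FALSE) {
  if (is.list(matrix) && !is.null(matrix$roc)) {
    roc <- matrix$roc; nodes <- matrix$nodes
  } else {
    roc <- matrix
    nodes <- data.frame(assay_id = rownames(roc),
                        n_compounds = NA_integer_, n_toxic = NA_integer_,
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(roc) == ncol(roc), identical(rownames(roc), colnames(roc)))
  ids <- rownames(roc)
  cmp <- if (strict) `>` else `>=`
  ea <- character(0); eb <- character(0)
  rab <- numeric(0); rba <- numeric(0)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ok <- !is.na(roc[i, j]) && !is.na(roc[j, i]) &&
      cmp(roc[i, j], threshold) && cmp(roc[j, i], threshold)
    if (ok) {
      ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
      rab <- c(rab, roc[i, j]); rba <- c(rba, roc[j, i])
    }
  }
  edges <- data.frame(a = ea, b = eb, roc_ab = rab, roc_ba = rba,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = ids,
                          n_compounds = nodes$n_compounds,
                          n_toxic = nodes$n_toxic))
  igraph::E(g)$roc_ab <- edges$roc_ab
  igraph::E(g)$roc_ba <- edges$roc_ba
  comp <- igraph::components(g)$membership
  structure(list(nodes = nodes, roc = roc, threshold = threshold,
                 strict = strict, edges = edges, graph = g,
                 components = comp),
            class = "prediction_network")
}

#' @export
print.prediction_network <- function(x, ...) {
  cat(sprintf("<prediction_network> %d assays, %d edges (ROC %s %.2f), %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), if (x$strict) ">" else ">=",
              x$threshold, length(unique(x$components))))
  invisible(x)
}

#' Members of each connected component
#' @param network a `prediction_network`.
#' @return list of character vectors of assay ids, largest first.
#' @export
network_components <- function(network) {
  sp <- split(names(network$components), network$components)
  sp[order(-lengths(sp))]
}

#' Merge a network component into one training set
#'
#' Takes the union of the compounds of the member assays. A compound
#' measured in several assays is deduplicated to one record; under the
#' default `any_toxic` policy it is labelled toxic if toxic in any member
#' assay (cytotoxic-in-any-format is the alert semantics of a triage
#' tool), under `majority` by the majority of its labels, and under
#' `keep_duplicates` one suffixed record is kept per measurement.
#'
#' @param network a `prediction_network`.
#' @param panel the panel the network was built from.
#' @param cs the compound store.
#' @param component character vector of assay ids, or NULL for the largest
#'   component.
#' @param policy `"any_toxic"` (default), `"majority"`, `"keep_duplicates"`.
#' @return list with `compounds` (a [compound_set()]) and `labels` (a
#'   `labelled_set`).
#' @export
merge_component <- function(network, panel, cs, component = NULL,
                            policy = c("any_toxic", "majority",
                                       "keep_duplicates")) {
  policy <- match.arg(policy)
  if (is.null(component)) component <- network_components(network)[[1L]]
  stopifnot(length(component) >= 1L, all(component %in% names(panel)))
  lab_list <- lapply(panel[component], function(e) e$labels$labels)
  if (policy == "keep_duplicates") {
    ids <- unlist(lapply(seq_along(lab_list), function(i)
      names(lab_list[[i]])), use.names = FALSE)
    new_ids <- unlist(lapply(seq_along(lab_list), function(i)
      paste0(names(lab_list[[i]]), "@", component[i])), use.names = FALSE)
    base <- cs_subset(cs, ids)
    base$id <- new_ids
    names(base$features) <- new_ids
    labels <- stats::setNames(unlist(lab_list, use.names = FALSE), new_ids)
    return(list(compounds = base,
                labels = new_labelled_set(labels,
                  rule = list(kind = "merged", policy = policy,
                              assays = component))))
  }
  all_ids <- unique(unlist(lapply(lab_list, names), use.names = FALSE))
  if (length(all_ids) == 0L) stop("merge_component: empty union")
  votes_tox <- integer(length(all_ids)); votes_tot <- integer(length(all_ids))
  names(votes_tox) <- names(votes_tot) <- all_ids
  for (ll in lab_list) {
    idx <- names(ll)
    votes_tot[idx] <- votes_tot[idx] + 1L
    votes_tox[idx] <- votes_tox[idx] + as.integer(ll)
  }
  labels <- if (policy == "any_toxic") votes_tox > 0L
            else votes_tox * 2L > votes_tot
  names(labels) <- all_ids
  list(compounds = cs_subset(cs, all_ids),
       labels = new_labelled_set(labels,
         rule = list(kind = "merged", policy = policy, assays = component)))
}

#' Train and evaluate the general model from two networked panels
#'
#' Builds the cross-prediction network for the percent-inhibition panel
#' and for the IC50 panel separately, merges each network's chosen
#' component (default: largest) into a training set, and derives three
#' models: the percent-inhibition model, the IC50 model, and the combined
#' model trained on the union of both training sets. Each is evaluated by
#' k-fold cross-validation. A held-out test set of `holdout_fraction` of
#' each training set is set aside first; the two sub-models are re-trained
#' on the remainder, and their scores on the held-out compounds are
#' binned into the score-agreement table (do the two models rank the same
#' compounds as toxic?).
#'
#' @param panel_pi,panel_ic50 named panels (`list(dataset, labels)` each).
#' @param cs the compound store covering both panels.
#' @param threshold network ROC threshold (default 0.60).
#' @param holdout_fraction held-out fraction per training set (default 0.10).
#' @param k cross-validation folds (default 5).
#' @param seed integer seed (folds and holdout draw).
#' @param policy label-merge policy, see [merge_component()].
#' @param ... passed to [fit_bayes()].
#' @return object of class `merged_model_result`: `cv_pi`, `cv_ic50`,
#'   `cv_combined` ([kfold_cv()] results), `model_combined`,
#'   `network_pi`, `network_ic50`, `agreement` (score-agreement table on
#'   the holdout), `holdout_ids`.
#' @export
merged_model_pipeline <- function(panel_pi, panel_ic50, cs,
                                  threshold = 0.60, holdout_fraction = 0.10,
                                  k = 5L, seed = 0L,
                                  policy = "any_toxic", ...) {
  net_pi <- build_network(cross_roc_matrix(panel_pi, cs, ...),
                          threshold = threshold)
  net_ic <- build_network(cross_roc_matrix(panel_ic50, cs, ...),
                          threshold = threshold)
  tr_pi <- merge_component(net_pi, panel_pi, cs, policy = policy)
  tr_ic <- merge_component(net_ic, panel_ic50, cs, policy = policy)

  cv_pi <- kfold_cv(tr_pi$compounds, tr_pi$labels, k = k, seed = seed, ...)
  cv_ic <- kfold_cv(tr_ic$compounds, tr_ic$labels, k = k, seed = seed, ...)

  # combined training set: union of compounds, any_toxic across the two sets
  comb_ids <- unique(c(tr_pi$compounds$id, tr_ic$compounds$id))
  lab_comb <- stats::setNames(rep(FALSE, length(comb_ids)), comb_ids)
  for (tr in list(tr_pi, tr_ic)) {
    ll <- tr$labels$labels
    lab_comb[names(ll)] <- lab_comb[names(ll)] | ll
  }
  labels_comb <- new_labelled_set(lab_comb,
    rule = list(kind = "merged", policy = "any_toxic",
                assays = c(tr_pi$labels$rule$assays, tr_ic$labels$rule$assays)))
  cs_comb <- cs_subset(cs, comb_ids)
  cv_comb <- kfold_cv(cs_comb, labels_comb, k = k, seed = seed, ...)
  model_comb <- fit_bayes(cs_comb, labels_comb, ...)

  holdout <- with_seed(seed + 1L, unique(c(
    sample(tr_pi$compounds$id,
           max(1L, round(holdout_fraction * nrow(tr_pi$compounds)))),
    sample(tr_ic$compounds$id,
           max(1L, round(holdout_fraction * nrow(tr_ic$compounds)))))))
  fit_wo <- function(tr) {
    ids <- setdiff(tr$compounds$id, holdout)
    fit_bayes(cs_subset(cs, ids), tr$labels, ...)
  }
  m_pi <- fit_wo(tr_pi); m_ic <- fit_wo(tr_ic)
  hold_cs <- cs_subset(cs, holdout)
  agreement <- score_agreement_table(score_bayes(m_pi, hold_cs),
                                     score_bayes(m_ic, hold_cs),
                                     labels_comb)
  structure(list(cv_pi = cv_pi, cv_ic50 = cv_ic, cv_combined = cv_comb,
                 model_combined = model_comb,
                 network_pi = net_pi, network_ic50 = net_ic,
                 agreement = agreement, holdout_ids = holdout),
            class = "merged_model_result")
}

#' @export
print.merged_model_result <- function(x, ...) {
  cat(sprintf(paste0("<merged_model_result> CV ROC: percent-inhibition %.3f +/- %.3f | ",
                     "IC50 %.3f +/- %.3f | combined %.3f +/- %.3f\n"),
              x$cv_pi$mean_auc, x$cv_pi$sd_auc,
              x$cv_ic50$mean_auc, x$cv_ic50$sd_auc,
              x$cv_combined$mean_auc, x$cv_combined$sd_auc))
  invisible(x)
}

#' Export a prediction network
#'
#' Writes: (a) `<prefix>.tsv`, the three-column table of all defined
#' directed pairs with header `training_set`, `test_set`, `roc`; (b)
#' `<prefix>.sif`, one `a pp b` line per undirected edge (isolated nodes
#' as bare names); (c) `<prefix>.graphml` with node attributes
#' (n_compounds, n_toxic) and both directed ROC scores as edge
#' attributes, for external viewers; (d) `<prefix>.json`, a summary with
#' nodes, edges, threshold and components.
#'
#' @param network a `prediction_network`.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
export_network <- function(network, prefix) {
  roc <- network$roc
  idx <- which(!is.na(roc), arr.ind = TRUE)
  tsv <- data.frame(training_set = rownames(roc)[idx[, 1]],
                    test_set = colnames(roc)[idx[, 2]],
                    roc = roc[idx], stringsAsFactors = FALSE)
  tsv <- tsv[order(tsv$training_set, tsv$test_set), , drop = FALSE]
  f_tsv <- paste0(prefix, ".tsv")
  utils::write.table(tsv, f_tsv, sep = "\t", row.names = FALSE, quote = FALSE)

  f_sif <- paste0(prefix, ".sif")
  in_edge <- unique(c(network$edges$a, network$edges$b))
  sif <- c(sprintf("%s\tpp\t%s", network$edges$a, network$edges$b),
           setdiff(network$nodes$assay_id, in_edge))
  writeLines(sif, f_sif)

  f_gml <- paste0(prefix, ".graphml")
  igraph::write_graph(network$graph, f_gml, format = "graphml")

  f_json <- paste0(prefix, ".json")
  comp <- network_components(network)
  jsonlite::write_json(list(
    threshold = network$threshold, strict = network$strict,
    nodes = network$nodes, edges = network$edges,
    components = comp), f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = f_tsv, sif = f_sif, graphml = f_gml, json = f_json))
}
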