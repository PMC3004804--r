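#' Labelling rules
#'
#' Continuous assay readouts are converted to binary toxic/non-toxic labels
#' under one of three rules used throughout the package. For both readout
#' types higher values mean more cytotoxic, and every rule uses a strict
#' `value > cutoff` comparison.
#'
#' @name labelling
NULL

new_labelled_set <- function(labels, rule) {
  stopifnot(is.logical(labels), !is.null(names(labels)))
  structure(list(labels = labels, rule = rule), class = "labelled_set")
}

#' @export
print.labelled_set <- function(x, ...) {
  cat(sprintf("<labelled_set> %d compounds, %d toxic (%.1f%%), rule=%s\n",
              length(x$labels), sum(x$labels),
              100 * mean(x$labels), x$rule$kind))
  invisible(x)
}

#' Number of toxic compounds in a labelled set
#' @param labelled a `labelled_set`.
#' @return integer count of TRUE labels.
#' @export
n_toxic <- function(labelled) sum(labelled$labels)

#' Label by a fixed activity cutoff
#'
#' A compound is toxic iff its readout value is strictly greater than the
#' cutoff (e.g. pIC50 > 5.5 for the usual potency rule, or pIC50 > 4.64
#' for sparser panels).
#'
#' @param ds an [assay_dataset()].
#' @param cutoff finite numeric cutoff, on the readout's scale.
#' @return a `labelled_set`.
#' @export
label_fixed <- function(ds, cutoff) {
  stopifnot(inherits(ds, "assay_dataset"), is.finite(cutoff))
  new_labelled_set(ds$values > cutoff,
                   rule = list(kind = "fixed_cutoff", cutoff = cutoff))
}

#' Label the top fraction of an assay as toxic
#'
#' Exactly `ceiling(fraction * n)` compounds are labelled toxic, taking the
#' highest readout values first. Ties at the boundary are broken by
#' ascending compound id, so the labelling is deterministic.
#'
#' @param ds an [assay_dataset()].
#' @param fraction fraction in (0,1); default 0.20, the common fixed hit
#'   rate for cross-assay comparison.
#' @return a `labelled_set`.
#' @export
label_top_fraction <- function(ds, fraction = 0.20) {
  stopifnot(inherits(ds, "assay_dataset"),
            is.finite(fraction), fraction > 0, fraction < 1)
  n <- length(ds$values)
  if (n == 0L) stop("label_top_fraction: empty dataset")
  k <- as.integer(ceiling(fraction * n))
  ord <- order(-ds$values, names(ds$values))
  lab <- stats::setNames(logical(n), names(ds$values))
  lab[ord[seq_len(k)]] <- TRUE
  new_labelled_set(lab, rule = list(kind = "top_fraction", fraction = fraction))
}

#' Label by mean plus k standard deviations
#'
#' The cutoff is the mean readout plus `k` standard deviations (sample SD
#' by default, population SD via `sd_type`); compounds strictly above it
#' are toxic. With k = 3 on single-concentration percent-inhibition data
#' this is the conservative hit-calling rule that keeps confirmation-assay
#' false positives low.
#'
#' @param ds an [assay_dataset()].
#' @param k non-negative multiplier, default 3.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a `labelled_set`; the derived cutoff is in `$rule$cutoff`.
#' @export
label_mean_ksd <- function(ds, k = 3, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(ds, "assay_dataset"), is.finite(k))
  v <- ds$values
  if (length(v) < 2L) stop("label_mean_ksd: need at least 2 measurements")
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  if (s == 0) {
    warning("label_mean_ksd: zero variance; cutoff equals the mean")
  }
  cutoff <- mean(v) + k * s
  new_labelled_set(v > cutoff,
                   rule = list(kind = "mean_plus_ksd", k = k,
                               sd_type = sd_type, cutoff = cutoff))
}

#' Re-apply a stored labelling rule to a dataset
#'
#' The provenance invariant of a labelled set: applying its stored rule to
#' the dataset it came from reproduces the labels exactly.
#' @param ds an [assay_dataset()].
#' @param rule the `$rule` element of a `labelled_set`.
#' @return a `labelled_set`.
#' @export
apply_label_rule <- function(ds, rule) {
  switch(rule$kind,
    fixed_cutoff = label_fixed(ds, rule$cutoff),
    top_fraction = label_top_fraction(ds, rule$fraction),
    mean_plus_ksd = label_mean_ksd(ds, rule$k, rule$sd_type),
    stop("apply_label_rule: unknown rule kind '", rule$kind, "'"))
}

#' Does a labelled assay have enough actives to model?
#'
#' Assays with fewer than `min_actives` toxic compounds are excluded from
#' cross-prediction networks (too few positives to train or evaluate on).
#' @param labelled a `labelled_set`.
#' @param min_actives minimum toxic count, default 10.
#' @return TRUE iff the toxic count is at least `min_actives`.
#' @export
filter_min_actives <- function(labelled, min_actives = 10L) {
  n_toxic(labelled) >= min_actives
}

#' Write labels with provenance
#'
#' Writes a two-column TSV (`compound_id`, `label` as 0/1) and a JSON
#' provenance block `<path>.json` recording the rule.
#' @param labelled a `labelled_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labelled, path) {
  df <- data.frame(compound_id = names(labelled$labels),
                   label = as.integer(labelled$labels))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(labelled$rule, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
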