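#' Construct a compound set
#'
#' A compound set is the in-memory store for molecules: identity, optional
#' SMILES, a sparse binary feature set per molecule (circular-fingerprint
#' feature identifiers, carried as character strings because hashed feature
#' ids can exceed R's integer range), and optional continuous descriptors
#' (AlogP-like logP, molecular weight in Da, H-bond donor/acceptor counts,
#' rotatable-bond count, fractional polar surface area in \[0,1\]).
#'
#' @param id character vector of unique, non-empty compound identifiers.
#' @param features list of character vectors, one per compound (may be
#'   empty vectors). Coerced to character; duplicates within a molecule are
#'   collapsed (presence/absence semantics).
#' @param smiles optional character vector of SMILES strings (NA allowed).
#' @param descriptors optional data.frame (or named list) of numeric
#'   descriptor columns, one row per compound. Non-finite entries are kept
#'   as NA: a molecule missing a descriptor simply contributes no token for
#'   it when a model is fitted.
#' @return An object of class `compound_set`: a data.frame with columns
#'   `id`, `smiles`, list-column `features`, plus one numeric column per
#'   descriptor.
#' @export
compound_set <- function(id, features, smiles = NULL, descriptors = NULL) {
  id <- as.character(id)
  if (length(id) == 0L) stop("compound_set: at least one compound required")
  if (anyNA(id) || any(!nzchar(id))) stop("compound_set: ids must be non-empty")
  if (anyDuplicated(id)) stop("compound_set: duplicate compound ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(features) != length(id))
    stop("compound_set: features must have one element per id")
  features <- lapply(features, function(f) {
    f <- unique(as.character(f))
    f[!is.na(f) & nzchar(f)]
  })
  names(features) <- id
  if (is.null(smiles)) smiles <- rep(NA_character_, length(id))
  cs <- data.frame(id = id, smiles = as.character(smiles),
                   stringsAsFactors = FALSE)
  cs$features <- features
  if (!is.null(descriptors)) {
    descriptors <- as.data.frame(descriptors)
    if (nrow(descriptors) != length(id))
      stop("compound_set: descriptors must have one row per compound")
    for (nm in names(descriptors)) {
      v <- as.numeric(descriptors[[nm]])
      v[!is.finite(v)] <- NA_real_
      cs[[nm]] <- v
    }
  }
  class(cs) <- c("compound_set", "data.frame")
  cs
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d molecules, %d descriptor(s): %s\n",
              nrow(x), length(descriptor_names(x)),
              paste(descriptor_names(x), collapse = ", ")))
  invisible(x)
}

#' Descriptor column names of a compound set
#' @param cs a `compound_set`.
#' @return character vector of descriptor column names (possibly empty).
#' @export
descriptor_names <- function(cs) {
  setdiff(names(cs), c("id", "smiles", "features"))
}

#' Subset a compound set by id
#' @param cs a `compound_set`.
#' @param ids character vector of ids to keep (order preserved).
#' @return a `compound_set` restricted to `ids`.
#' @export
cs_subset <- function(cs, ids) {
  idx <- match(ids, cs$id)
  if (anyNA(idx)) stop("cs_subset: unknown ids: ",
                       paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  out <- cs[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("compound_set", "data.frame")
  out
}

#' Combine compound sets, deduplicating by id
#'
#' Later occurrences of an id already seen are dropped (first record wins);
#' feature sets and descriptors are taken from the kept record.
#' @param ... `compound_set` objects.
#' @return a `compound_set`.
#' @export
cs_union <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  all_desc <- unique(unlist(lapply(sets, descriptor_names)))
  rows <- list(); seen <- character(0)
  for (s in sets) {
    keep <- !(s$id %in% seen)
    if (!any(keep)) next
    s <- s[keep, , drop = FALSE]
    for (d in setdiff(all_desc, names(s))) s[[d]] <- NA_real_
    rows[[length(rows) + 1L]] <- s[, c("id", "smiles", "features", all_desc), drop = FALSE]
    seen <- c(seen, s$id)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("compound_set", "data.frame")
  out
}

#' Construct an assay dataset
#'
#' One assay's measurements: a readout type (single-concentration percent
#' inhibition, in %, or pIC50 in -log10 molar; for both, higher means more
#' cytotoxic) plus a named numeric vector of values per compound id.
#' Percent-inhibition values outside \[-20, 100\] are kept but flagged.
#'
#' @param assay_id non-empty string.
#' @param values named numeric vector (names are compound ids); must be
#'   finite.
#' @param readout `"percent_inhibition"` or `"pIC50"`.
#' @param metadata optional named list (cell_line, species, tissue,
#'   incubation_hours, endpoint_method, ...).
#' @return An object of class `assay_dataset`.
#' @export
assay_dataset <- function(assay_id, values,
                          readout = c("percent_inhibition", "pIC50"),
                          metadata = list()) {
  readout <- match.arg(readout)
  assay_id <- as.character(assay_id)
  if (length(assay_id) != 1L || !nzchar(assay_id))
    stop("assay_dataset: assay_id must be a non-empty string")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("assay_dataset: values must be named by compound id")
  if (anyDuplicated(names(values)))
    stop("assay_dataset: duplicate compound ids in measurements")
  values <- stats::setNames(as.numeric(values), names(values))
  if (any(!is.finite(values)))
    stop("assay_dataset: all measurement values must be finite")
  flagged <- character(0)
  if (readout == "percent_inhibition")
    flagged <- names(values)[values < -20 | values > 100]
  structure(list(assay_id = assay_id, readout = readout, values = values,
                 metadata = metadata, flagged = flagged),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("<assay_dataset> %s: %d compounds, readout=%s%s\n",
              x$assay_id, length(x$values), x$readout,
              if (length(x$flagged)) sprintf(" (%d value(s) outside [-20,100] flagged)",
                                             length(x$flagged)) else ""))
  invisible(x)
}

#' Read an assay activity table
#'
#' Reads a delimited text file with a header naming at least `compound_id`
#' and `value` columns (an optional `smiles` column is carried through).
#' Rows whose value is missing, empty, or non-finite violate the basic
#' business rules for an endpoint and are dropped; the drop count is
#' reported in the result.
#'
#' @param path path to a CSV (`.csv`) or TSV (anything else) file.
#' @param readout readout type recorded on the dataset.
#' @param assay_id assay identifier; default the file base name.
#' @param on_duplicate what to do when a compound id occurs more than once
#'   with conflicting values: `"error"` (default), `"first"`, or `"mean"`.
#' @param metadata optional metadata list. If a sidecar file `<path>.json`
#'   exists it is read and merged (explicit `metadata` entries win).
#' @return list with elements `dataset` (an [assay_dataset()]), `compounds`
#'   (a [compound_set()] with empty feature sets, carrying any SMILES), and
#'   `dropped` (number of rows removed).
#' @export
read_assay_table <- function(path, readout = c("percent_inhibition", "pIC50"),
                             assay_id = NULL,
                             on_duplicate = c("error", "first", "mean"),
                             metadata = list()) {
  readout <- match.arg(readout)
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("read_assay_table: no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE,
                          colClasses = NA, na.strings = c("NA", ""))
  for (col in c("compound_id", "value"))
    if (!col %in% names(df))
      stop("read_assay_table: missing mandatory column '", col, "'")
  n0 <- nrow(df)
  val <- suppressWarnings(as.numeric(df$value))
  keep <- !is.na(df$compound_id) & nzchar(as.character(df$compound_id)) &
    is.finite(val)
  df <- df[keep, , drop = FALSE]
  val <- val[keep]
  dropped <- n0 - nrow(df)
  ids <- as.character(df$compound_id)
  if (anyDuplicated(ids)) {
    agg <- switch(on_duplicate,
      error = {
        conflict <- tapply(val, ids, function(v) length(unique(v)) > 1L)
        if (any(conflict))
          stop("read_assay_table: duplicate compound ids with conflicting values: ",
               paste(utils::head(names(conflict)[conflict], 5), collapse = ", "))
        tapply(val, ids, `[`, 1L)
      },
      first = tapply(val, ids, `[`, 1L),
      mean = tapply(val, ids, mean))
    ord <- match(unique(ids), names(agg))
    val <- as.numeric(agg[ord]); names(val) <- names(agg)[ord]
    smi <- if ("smiles" %in% names(df))
      as.character(df$smiles)[match(names(val), ids)] else NULL
    ids <- names(val)
  } else {
    names(val) <- ids
    smi <- if ("smiles" %in% names(df)) as.character(df$smiles) else NULL
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sm <- jsonlite::read_json(side, simplifyVector = TRUE)
    metadata <- utils::modifyList(as.list(sm), metadata)
  }
  if (is.null(assay_id))
    assay_id <- sub("\\.[^.]*$", "", basename(path))
  ds <- assay_dataset(assay_id, val, readout = readout, metadata = metadata)
  cs <- compound_set(ids, features = rep(list(character(0)), length(ids)),
                     smiles = smi)
  list(dataset = ds, compounds = cs, dropped = dropped)
}

#' Write an assay dataset back to a delimited table
#'
#' Inverse of [read_assay_table()]: preserves the (id, value) multiset
#' exactly.
#' @param ds an [assay_dataset()].
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @param compounds optional [compound_set()] supplying a `smiles` column.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(ds, path, compounds = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(compound_id = names(ds$values), value = unname(ds$values),
                   stringsAsFactors = FALSE)
  if (!is.null(compounds)) {
    df$smiles <- compounds$smiles[match(df$compound_id, compounds$id)]
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted Bayes model to JSON
#'
#' The JSON carries a schema-version field, the class counts and baseline
#' rate, per-feature active/total counts, descriptor bin edges and the
#' classification threshold. [read_model()] of the written file scores any
#' molecule identically to the original model (weights are recomputed from
#' the stored exact integer counts).
#'
#' @param model a `bayes_model` from [fit_bayes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bayes_model"))
  obj <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    n_active = model$n_active, n_inactive = model$n_inactive,
    threshold = model$threshold, n_bins = model$n_bins,
    feature_ids = model$feature_ids,
    a_d = model$a_d, t_d = model$t_d,
    bin_edges = model$bin_edges,
    descriptor_names = model$descriptor_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  invisible(path)
}

#' Read a serialized Bayes model
#' @param path JSON path written by [write_model()].
#' @return a `bayes_model`.
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("read_model: cannot parse '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(obj$schema_version))
    stop("read_model: '", path, "' has no schema_version field")
  if (!identical(as.character(obj$schema_version), .MODEL_SCHEMA_VERSION))
    stop("read_model: schema version mismatch: file has '",
         obj$schema_version, "', this build reads '", .MODEL_SCHEMA_VERSION, "'")
  for (fld in c("n_active", "n_inactive", "feature_ids", "a_d", "t_d"))
    if (is.null(obj[[fld]])) stop("read_model: corrupt model file, missing '", fld, "'")
  bin_edges <- obj$bin_edges
  if (length(bin_edges) == 0) bin_edges <- list()
  new_bayes_model(n_active = as.integer(obj$n_active),
                  n_inactive = as.integer(obj$n_inactive),
                  feature_ids = as.character(obj$feature_ids),
                  a_d = as.integer(obj$a_d), t_d = as.integer(obj$t_d),
                  bin_edges = bin_edges,
                  descriptor_names = as.character(obj$descriptor_names %||% character(0)),
                  n_bins = as.integer(obj$n_bins %||% 10L),
                  threshold = as.numeric(obj$threshold %||% 0))
}

#' Truth-table counts
#'
#' A 2x2 confusion matrix of predicted against experimental class, with
#' derived sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/n. A zero denominator yields NA ("undefined") for that metric.
#' The counts may also be given as the percentage cells of a published
#' truth table; the derived fractions are unchanged by the common scale.
#'
#' @param tp,fp,tn,fn non-negative counts (or percentages of total).
#' @return object of class `truth_table`: list with the four cells, `n`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
truth_table_counts <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cells < 0)) stop("truth_table_counts: negative cell")
  n <- sum(cells)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 sensitivity = safe_div(tp, tp + fn),
                 specificity = safe_div(tn, tn + fp),
                 accuracy = safe_div(tp + tn, n)),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> TP=%g FP=%g TN=%g FN=%g | sens=%.3f spec=%.3f acc=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
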