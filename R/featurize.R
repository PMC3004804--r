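#' Tanimoto similarity between two sparse feature sets
#'
#' `|a intersect b| / |a union b|`. Both sets empty returns 0 with
#' attribute `both_empty = TRUE` (no evidence of similarity, flagged).
#' Note that a similarity of 1 does not imply the molecules are identical,
#' only that their feature sets coincide.
#'
#' @param a,b character vectors of feature ids (sets).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L)
    return(structure(0, both_empty = TRUE))
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' Featurize molecules from SMILES
#'
#' Computes, for each parsable SMILES, a functional-class circular
#' fingerprint (Morgan algorithm with pharmacophoric feature atom
#' invariants; default radius 3, i.e. diameter 6) as an unfolded sparse set
#' of hashed feature ids, together with the default physicochemical
#' descriptor block: an atomic-contribution logP estimate (`alogp`),
#' molecular weight (`mw`, Da), hydrogen-bond donor and acceptor counts
#' (`hbd`, `hba`), rotatable-bond count (`rotb`) and fractional polar
#' surface area (`fpsa`, TPSA divided by the total Labute surface area,
#' clamped to \[0,1\]; the fragment-based TPSA can slightly exceed the
#' area estimate for very small polar molecules).
#'
#' The chemistry is delegated to the RDKit toolkit through the `python`
#' interpreter on the PATH; feature ids are deterministic for a fixed
#' configuration and toolkit version. Unparsable SMILES do not abort the
#' batch: they are collected into the `errors` element of the result.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound ids, default `mol1..molN`.
#' @param radius neighbourhood radius (default 3; diameter 6).
#' @param invariants `"functional"` (pharmacophoric feature classes,
#'   default) or `"connectivity"` (plain ECFP-style).
#' @param fold_size optional power of two >= 1024 to fold hashed ids into;
#'   default NULL (unfolded).
#' @param python path to the Python interpreter with RDKit available.
#' @return list with `compounds` (a [compound_set()] of the successfully
#'   parsed molecules) and `errors` (data.frame `id`, `smiles`, `message`).
#' @export
featurize_smiles <- function(smiles, ids = NULL, radius = 3L,
                             invariants = c("functional", "connectivity"),
                             fold_size = NULL,
                             python = Sys.which("python")) {
  invariants <- match.arg(invariants)
  stopifnot(radius >= 0)
  if (!is.null(fold_size)) {
    if (fold_size < 1024 || bitwAnd(as.integer(fold_size), as.integer(fold_size) - 1L) != 0L)
      stop("featurize_smiles: fold_size must be a power of two >= 1024")
  }
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  if (!nzchar(python)) stop("featurize_smiles: no python interpreter found")
  script <- system.file("python", "fcfp.py", package = "cytobayes")
  if (!nzchar(script)) stop("featurize_smiles: bundled fcfp.py not found")
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(data.frame(id = ids, smiles = smiles),
                     fin, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  status <- system2(python,
                    c(script, fin, fout, as.integer(radius), invariants,
                      if (is.null(fold_size)) "0" else as.integer(fold_size)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
    stop("featurize_smiles: rdkit featurizer failed:\n",
         paste(status, collapse = "\n"))
  out <- utils::read.table(fout, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          status = "character",
                                          features = "character"))
  errs <- out[out$status != "ok", c("id", "status"), drop = FALSE]
  errors <- data.frame(id = errs$id,
                       smiles = smiles[match(errs$id, ids)],
                       message = errs$status, stringsAsFactors = FALSE)
  ok <- out[out$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) return(list(compounds = NULL, errors = errors))
  feats <- strsplit(ok$features, " ", fixed = TRUE)
  feats <- lapply(feats, function(f) f[nzchar(f)])
  cs <- compound_set(ok$id, features = feats,
                     smiles = smiles[match(ok$id, ids)],
                     descriptors = ok[, c("alogp", "mw", "hbd", "hba",
                                          "rotb", "fpsa")])
  list(compounds = cs, errors = errors)
}

#' Read a SMILES file
#'
#' One molecule per line: SMILES first, optional id after whitespace
#' (`mol<line>` when absent). Blank lines and lines starting with `#` are
#' skipped.
#' @param path file path.
#' @return data.frame with `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("mol", i)
  }, character(1))
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write / read a portable feature table
#'
#' The feature table is the package's structure-free interchange format: a
#' TSV with columns `id`, `features` (space-separated feature ids; empty
#' string for none) and one column per descriptor. The simulator and the
#' RDKit featurizer emit the same format, so simulated and real compounds
#' are interchangeable downstream.
#'
#' @param cs a [compound_set()].
#' @param path file path.
#' @return `path` invisibly ([write_feature_table()]); a [compound_set()]
#'   ([read_feature_table()]).
#' @export
write_feature_table <- function(cs, path) {
  stopifnot(inherits(cs, "compound_set"))
  df <- data.frame(id = cs$id,
                   features = vapply(cs$features, paste, character(1),
                                     collapse = " "),
                   stringsAsFactors = FALSE)
  for (nm in descriptor_names(cs)) df[[nm]] <- cs[[nm]]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = c(id = "character",
                                         features = "character"),
                          na.strings = "NA")
  if (!all(c("id", "features") %in% names(df)))
    stop("read_feature_table: need 'id' and 'features' columns")
  df$features[is.na(df$features)] <- ""
  feats <- strsplit(df$features, " ", fixed = TRUE)
  feats <- lapply(feats, function(f) f[nzchar(f)])
  desc_cols <- setdiff(names(df), c("id", "features"))
  compound_set(df$id, features = feats,
               descriptors = if (length(desc_cols)) df[, desc_cols, drop = FALSE])
}
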