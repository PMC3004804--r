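# Independent oracles and small fixture builders shared across tests.

# Labelled set straight from a named logical vector.
make_labels <- function(labels, rule = list(kind = "test")) {
  cytobayes:::new_labelled_set(labels, rule)
}

# Brute-force AUC: concordant active/inactive pairs, ties count one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force Laplacian-corrected score of one molecule: log of the product
# over its features of P_corr(active|D) / P(active), with each per-feature
# probability computed directly from the class counts.
brute_force_score <- function(mol_feats, train_feats, train_labels) {
  p <- mean(train_labels)
  total <- 1
  vocab <- unique(unlist(train_feats))
  for (f in intersect(mol_feats, vocab)) {
    has <- vapply(train_feats, function(x) f %in% x, logical(1))
    a_d <- sum(has & train_labels)
    t_d <- sum(has)
    p_corr <- (a_d + p * (1 / p)) / (t_d + 1 / p)
    total <- total * (p_corr / p)
  }
  log(total)
}

# Tiny compound set with explicit features and no descriptors.
toy_compounds <- function(feats, ids = paste0("m", seq_along(feats))) {
  compound_set(ids, features = feats)
}

# Shuffle values under a local seed (names reassigned by the caller).
with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

# Assay over given ids/values.
toy_assay <- function(values, ids = paste0("m", seq_along(values)),
                      readout = "percent_inhibition") {
  assay_dataset("toy", stats::setNames(values, ids), readout = readout)
}
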