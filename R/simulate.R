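#' Generate a synthetic compound universe with planted SAR series
#'
#' Builds an abstract compound collection organised as structure-activity
#' (SAR) series: every molecule's sparse feature set is the union of its
#' series' shared scaffold features and its own random decoration
#' features, so within-series Tanimoto similarity is high and
#' between-series similarity is near zero. A fraction of series is
#' cytotoxic; each toxic series acts through one of `n_mechanisms`
#' mechanisms and its members carry a latent potency drawn uniformly from
#' `potency_range` (series whose members span weak to potent, as real SAR
#' series do). Continuous descriptors are drawn per molecule; by default
#' lipophilicity (and weight) are mildly shifted upward for toxic-series
#' molecules, emulating the well-known lipophilicity-cytotoxicity
#' correlation (`lipo_tox_shift = 0` turns this off).
#'
#' Features are abstract integers (as strings), not real chemistry: the
#' learner and network machinery are structure-agnostic, and abstract
#' features make the generator fast and fully deterministic under `seed`.
#'
#' @param seed integer seed; a fixed seed gives an identical universe.
#' @param n_series number of series (default 40).
#' @param series_size molecules per series (default 25).
#' @param n_mechanisms number of distinct toxicity mechanisms (default 3).
#' @param p_toxic_series probability a series is toxic (default 0.3, the
#'   enriched-panel regime typical of selectivity/confirmation screens).
#' @param toxic_series optional explicit integer vector of toxic series
#'   indices (overrides `p_toxic_series`; used by fixtures).
#' @param scaffold_features_per_series shared features per series (30).
#' @param decoration_features_per_molecule random features per molecule (40).
#' @param feature_space_size hashed feature universe size (2^20).
#' @param potency_range latent potency range for toxic-series members,
#'   default c(0.3, 0.95) (percent-inhibition signal = 100 x potency).
#' @param lipo_tox_shift additive AlogP shift for toxic-series molecules,
#'   default 1.2 log units.
#' @return object of class `sim_universe`: list with `compounds` (a
#'   [compound_set()] with descriptors) and `truth` (data.frame `id`,
#'   `series`, `toxic_series`, `mechanism` (NA for clean series),
#'   `potency`).
#' @export
generate_universe <- function(seed = 0L, n_series = 40L, series_size = 25L,
                              n_mechanisms = 3L, p_toxic_series = 0.3,
                              toxic_series = NULL,
                              scaffold_features_per_series = 30L,
                              decoration_features_per_molecule = 40L,
                              feature_space_size = 2^20,
                              potency_range = c(0.3, 0.95),
                              lipo_tox_shift = 1.2) {
  stopifnot(n_series >= 1, series_size >= 1, n_mechanisms >= 1)
  with_seed(seed, {
    if (is.null(toxic_series)) {
      toxic_series <- which(stats::runif(n_series) < p_toxic_series)
    } else {
      toxic_series <- as.integer(toxic_series)
      stopifnot(all(toxic_series %in% seq_len(n_series)))
    }
    mech_of_series <- rep(NA_integer_, n_series)
    if (length(toxic_series))
      mech_of_series[toxic_series] <-
        sample(seq_len(n_mechanisms), length(toxic_series), replace = TRUE)
    # distinct scaffold features across all series: no cross-series collisions
    scaff <- matrix(sample.int(feature_space_size,
                               n_series * scaffold_features_per_series),
                    nrow = n_series)
    n <- n_series * series_size
    series <- rep(seq_len(n_series), each = series_size)
    id <- sprintf("s%02d_m%03d", series, rep(seq_len(series_size), n_series))
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      deco <- sample.int(feature_space_size, decoration_features_per_molecule)
      feats[[i]] <- as.character(c(scaff[series[i], ], deco))
    }
    is_tox <- series %in% toxic_series
    potency <- ifelse(is_tox,
                      stats::runif(n, potency_range[1], potency_range[2]), 0)
    desc <- data.frame(
      alogp = stats::rnorm(n, 2.2, 1.2) + lipo_tox_shift * is_tox,
      mw = stats::rnorm(n, 380, 70) + 25 * lipo_tox_shift * is_tox,
      hbd = stats::rpois(n, 1.5),
      hba = stats::rpois(n, 4),
      rotb = stats::rpois(n, 5),
      fpsa = stats::plogis(stats::rnorm(n, -1, 0.6)))
    structure(list(
      compounds = compound_set(id, features = feats, descriptors = desc),
      truth = data.frame(id = id, series = series, toxic_series = is_tox,
                         mechanism = mech_of_series[series],
                         potency = potency, stringsAsFactors = FALSE)),
      class = "sim_universe")
  })
}

#' @export
print.sim_universe <- function(x, ...) {
  cat(sprintf("<sim_universe> %d molecules, %d series (%d toxic)\n",
              nrow(x$truth), length(unique(x$truth$series)),
              length(unique(x$truth$series[x$truth$toxic_series]))))
  invisible(x)
}

#' Simulate a single-concentration cytotoxicity screen
#'
#' Percent inhibition is `baseline + 100 * potency * [mechanism detected] +
#' Gaussian noise`, clipped to \[-20, 100\]. The default baseline (1.2%)
#' and noise SD (9.8%) are the observed moments of a large public
#' percent-inhibition screen. Only molecules from the footprint series are
#' measured, and only mechanisms in `sensitivity` produce signal, so
#' assays can have partially overlapping chemical-space footprints and
#' detect different subsets of the toxicity mechanisms.
#'
#' @param universe a `sim_universe`.
#' @param assay_id assay identifier.
#' @param footprint integer vector of series measured (default all).
#' @param sensitivity integer vector of mechanisms the assay detects
#'   (default all).
#' @param baseline mean response of inactive compounds (%), default 1.2.
#' @param noise_sd Gaussian noise SD (%), default 9.8.
#' @param seed integer seed.
#' @param metadata extra metadata entries (cell_line, species, ...).
#' @return an [assay_dataset()] (percent inhibition); the generating spec
#'   is recorded in its metadata.
#' @export
generate_assay <- function(universe, assay_id, footprint = NULL,
                           sensitivity = NULL, baseline = 1.2,
                           noise_sd = 9.8, seed = 0L, metadata = list()) {
  stopifnot(inherits(universe, "sim_universe"), noise_sd >= 0)
  tr <- universe$truth
  if (is.null(footprint)) footprint <- sort(unique(tr$series))
  if (is.null(sensitivity)) sensitivity <- sort(unique(stats::na.omit(tr$mechanism)))
  if (length(footprint) == 0L) stop("generate_assay: empty footprint")
  sel <- tr$series %in% footprint
  tr <- tr[sel, , drop = FALSE]
  with_seed(seed, {
    detected <- !is.na(tr$mechanism) & tr$mechanism %in% sensitivity
    v <- baseline + 100 * tr$potency * detected +
      stats::rnorm(nrow(tr), 0, noise_sd)
    v <- pmin(pmax(v, -20), 100)
    assay_dataset(assay_id, stats::setNames(v, tr$id),
                  readout = "percent_inhibition",
                  metadata = utils::modifyList(
                    list(simulated = TRUE, footprint = footprint,
                         sensitivity = sensitivity, baseline = baseline,
                         noise_sd = noise_sd), metadata))
  })
}

#' Simulate an IC50 follow-up of a primary screen
#'
#' The `top_n` compounds by primary percent inhibition, plus `filler_n`
#' random other primary compounds (mirroring the practice of topping up a
#' confirmation assay with less active compounds when hits are
#' unavailable), are "submitted" to a potency assay: pIC50 = intercept +
#' slope * detected potency + Gaussian noise. The follow-up is therefore
#' enriched in actives relative to the primary screen; the two hit rates
#' (at the `pIC50 > 5.5` rule) are recorded in the metadata.
#'
#' @param assay the primary [assay_dataset()] from [generate_assay()].
#' @param universe the `sim_universe` the assay came from.
#' @param top_n number of top primary compounds submitted (default 150).
#' @param filler_n number of random additional compounds (default 50).
#' @param intercept baseline pIC50 of inactive compounds (default 4.0).
#' @param slope pIC50 units per unit potency (default 3.0).
#' @param noise_sd pIC50 noise SD (default 0.15).
#' @param seed integer seed.
#' @return an [assay_dataset()] with pIC50 readout.
#' @export
generate_ic50_followup <- function(assay, universe, top_n = 150L,
                                   filler_n = 50L, intercept = 4.0,
                                   slope = 3.0, noise_sd = 0.15, seed = 0L) {
  stopifnot(inherits(assay, "assay_dataset"),
            inherits(universe, "sim_universe"))
  ids <- names(assay$values)
  if (top_n > length(ids)) {
    warning("generate_ic50_followup: top_n exceeds assay size; truncated")
    top_n <- length(ids)
  }
  ord <- ids[order(-assay$values, ids)]
  top <- ord[seq_len(top_n)]
  with_seed(seed, {
    rest <- setdiff(ids, top)
    filler <- if (filler_n > 0L && length(rest))
      sample(rest, min(filler_n, length(rest))) else character(0)
    sub <- c(top, filler)
    tr <- universe$truth[match(sub, universe$truth$id), , drop = FALSE]
    sens <- assay$metadata$sensitivity
    detected <- !is.na(tr$mechanism) &
      (if (is.null(sens)) TRUE else tr$mechanism %in% sens)
    pic50 <- intercept + slope * tr$potency * detected +
      stats::rnorm(nrow(tr), 0, noise_sd)
    ds <- assay_dataset(paste0(assay$assay_id, "_ic50"),
                        stats::setNames(pic50, sub), readout = "pIC50",
                        metadata = list(
                          simulated = TRUE, parent = assay$assay_id,
                          top_n = top_n, filler_n = length(filler),
                          parent_hit_rate = mean(assay$values > 30),
                          followup_hit_rate = mean(pic50 > 5.5)))
    ds
  })
}

#' The default follow-up scenario
#'
#' One full-footprint primary percent-inhibition screen plus its IC50
#' follow-up — the setting for the cutoff optimisation scan (confirmed
#' actives = follow-up compounds with pIC50 above 5.5). Unlike the
#' default enriched-panel universe, the primary screen here is a diverse
#' HTS with a low toxic fraction (50 series of 30, 12% of series toxic,
#' i.e. most measurements are baseline noise), the regime in which
#' primary screens are actually run and in which the near-flat
#' ROC-versus-cutoff curve is observed; the follow-up is strongly
#' hit-enriched relative to the primary.
#'
#' @param seed integer seed.
#' @return list with `universe`, `primary` (percent-inhibition
#'   [assay_dataset()]), `followup` (pIC50 [assay_dataset()]), and
#'   `confirmed_actives` (character ids).
#' @export
scenario_followup <- function(seed = 0L) {
  uni <- generate_universe(seed = seed, n_series = 50L, series_size = 30L,
                           p_toxic_series = 0.12)
  primary <- generate_assay(uni, "primary", seed = seed + 1L)
  followup <- generate_ic50_followup(primary, uni, top_n = 150L,
                                     filler_n = 50L, seed = seed + 2L)
  confirmed <- names(followup$values)[followup$values > 5.5]
  list(universe = uni, primary = primary, followup = followup,
       confirmed_actives = confirmed)
}

#' The A-B-C chain scenario (cross-prediction non-transitivity)
#'
#' Three percent-inhibition assays over one 20-series universe: A measures
#' series 1-10, B series 6-15, C series 11-20. A and B overlap in series
#' 6-10, B and C in series 11-15, while A and C share no series. Every
#' even-numbered series is toxic through a single mechanism, so each
#' overlap region contains toxic series. Models trained on A and B (and B
#' and C) are mutually predictive through their shared series, but A and C
#' are too far apart in the feature space to predict each other — the
#' planted non-transitive chain. The descriptor-toxicity correlation is
#' disabled here so that transfer is fingerprint-driven only.
#'
#' @param seed integer seed.
#' @param label_cutoff percent-inhibition cutoff used to label each assay
#'   (default 30, a mean-plus-3-SD-scale hit rule).
#' @return list with `universe`, `panel` (named list of
#'   `list(dataset, labels)` for A, B, C), and `compounds`.
#' @export
scenario_chain <- function(seed = 0L, label_cutoff = 30) {
  uni <- generate_universe(seed = seed, n_series = 20L, series_size = 25L,
                           n_mechanisms = 1L,
                           toxic_series = seq(2L, 20L, by = 2L),
                           potency_range = c(0.4, 0.95),
                           lipo_tox_shift = 0)
  spans <- list(A = 1:10, B = 6:15, C = 11:20)
  panel <- lapply(names(spans), function(nm) {
    ds <- generate_assay(uni, nm, footprint = spans[[nm]],
                         seed = seed + match(nm, names(spans)))
    list(dataset = ds, labels = label_fixed(ds, label_cutoff))
  })
  names(panel) <- names(spans)
  list(universe = uni, panel = panel, compounds = uni$compounds)
}

#' Simulated percent-inhibition and IC50 assay panels
#'
#' A small heterogeneous panel over one universe, for exercising the whole
#' network-and-merge pipeline: three primary percent-inhibition screens
#' with overlapping footprints and differing mechanism sensitivities
#' (labelled by the top-20% rule), and three IC50 confirmation assays
#' arising from separate screening campaigns — each is the follow-up of
#' its own (unreported) primary screen over a partially different
#' footprint, so the IC50 panel is hit-enriched, smaller, and covers
#' chemistry the percent-inhibition panel does not fully share (labelled
#' by pIC50 > 5.5).
#'
#' @param seed integer seed.
#' @return list with `universe`, `compounds`, `panel_pi` and `panel_ic50`
#'   (named lists of `list(dataset, labels)`).
#' @export
scenario_panels <- function(seed = 0L) {
  uni <- generate_universe(seed = seed)
  pi_specs <- list(
    PI1 = list(footprint = 1:20, sensitivity = c(1L, 2L, 3L)),
    PI2 = list(footprint = 6:25, sensitivity = c(1L, 2L)),
    PI3 = list(footprint = c(1:12, 14:25), sensitivity = c(2L, 3L)))
  ic_specs <- list(
    IC1 = list(footprint = 16:40, sensitivity = c(1L, 2L, 3L)),
    IC2 = list(footprint = 16:32, sensitivity = c(1L, 3L)),
    IC3 = list(footprint = 24:40, sensitivity = c(2L, 3L)))
  panel_pi <- list()
  for (i in seq_along(pi_specs)) {
    nm <- names(pi_specs)[i]
    ds <- generate_assay(uni, nm, footprint = pi_specs[[i]]$footprint,
                         sensitivity = pi_specs[[i]]$sensitivity,
                         seed = seed + 10L * i)
    panel_pi[[nm]] <- list(dataset = ds, labels = label_top_fraction(ds, 0.20))
  }
  panel_ic50 <- list()
  for (i in seq_along(ic_specs)) {
    nm <- names(ic_specs)[i]
    hidden <- generate_assay(uni, paste0(nm, "_primary"),
                             footprint = ic_specs[[i]]$footprint,
                             sensitivity = ic_specs[[i]]$sensitivity,
                             seed = seed + 100L * i)
    fu <- generate_ic50_followup(hidden, uni, top_n = 150L, filler_n = 100L,
                                 seed = seed + 100L * i + 1L)
    fu$assay_id <- nm
    panel_ic50[[nm]] <- list(dataset = fu, labels = label_fixed(fu, 5.5))
  }
  list(universe = uni, compounds = uni$compounds,
       panel_pi = panel_pi, panel_ic50 = panel_ic50)
}
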