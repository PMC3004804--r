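mat2 <- function(ab, ba, ids = c("i", "j")) {
  m <- matrix(NA_real_, 2, 2, dimnames = list(ids, ids))
  m[1, 2] <- ab; m[2, 1] <- ba
  m
}

test_that("edges require bidirectional ROC at or above the threshold", {
  expect_equal(nrow(build_network(mat2(0.65, 0.62))$edges), 1L)
  expect_equal(nrow(build_network(mat2(0.65, 0.58))$edges), 0L)
  # boundary: >= by default, > in strict mode
  expect_equal(nrow(build_network(mat2(0.60, 0.60))$edges), 1L)
  expect_equal(nrow(build_network(mat2(0.60, 0.60), strict = TRUE)$edges), 0L)
})

test_that("chains form one component without the missing transitive edge", {
  ids <- c("A", "B", "C")
  m <- matrix(0.5, 3, 3, dimnames = list(ids, ids))
  diag(m) <- NA
  m["A", "B"] <- m["B", "A"] <- 0.8
  m["B", "C"] <- m["C", "B"] <- 0.7
  net <- build_network(m)
  expect_equal(nrow(net$edges), 2L)
  expect_false(any(net$edges$a == "A" & net$edges$b == "C"))
  comp <- network_components(net)
  expect_length(comp, 1L)
  expect_setequal(comp[[1]], ids)
})

test_that("raising the threshold only removes edges and splits components", {
  set.seed(71)
  ids <- paste0("a", 1:8)
  for (rep in 1:10) {
    m <- matrix(stats::runif(64, 0.3, 0.9), 8, 8, dimnames = list(ids, ids))
    diag(m) <- NA
    prev_edges <- NULL
    prev_comp <- NULL
    for (th in c(0.4, 0.55, 0.7, 0.85)) {
      net <- build_network(m, threshold = th)
      ekey <- paste(net$edges$a, net$edges$b)
      if (!is.null(prev_edges)) {
        expect_true(all(ekey %in% prev_edges))
        # components only split as the threshold rises: any two assays
        # together now were together at the lower threshold
        for (cmp in network_components(net)) {
          if (length(cmp) < 2) next
          expect_length(unique(prev_comp[cmp]), 1L)
        }
      }
      prev_edges <- ekey
      prev_comp <- net$components
    }
  }
})

test_that("cross-prediction recovers mutual predictivity and its absence", {
  uni <- generate_universe(seed = 81, n_series = 12L, series_size = 15L,
                           n_mechanisms = 1L, toxic_series = c(2, 4, 6, 8, 10, 12),
                           potency_range = c(0.4, 0.95), lipo_tox_shift = 0)
  mk <- function(nm, fp, seed) {
    ds <- generate_assay(uni, nm, footprint = fp, seed = seed)
    list(dataset = ds, labels = label_fixed(ds, 30))
  }
  panel <- list(X = mk("X", 1:6, 82), Xcopy = mk("Xcopy", 1:6, 83),
                Far = mk("Far", 7:12, 84))
  res <- cross_roc_matrix(panel, uni$compounds)
  # same underlying assay measured twice: strongly mutually predictive
  expect_gte(res$roc["X", "Xcopy"], 0.9)
  expect_gte(res$roc["Xcopy", "X"], 0.9)
  # disjoint chemical space: near-random transfer
  expect_lt(res$roc["X", "Far"], 0.6)
  expect_lt(res$roc["Far", "X"], 0.6)
})

test_that("assays that cannot be modelled are excluded with a reason", {
  uni <- generate_universe(seed = 91, n_series = 8L, series_size = 12L)
  mk <- function(nm, seed) {
    ds <- generate_assay(uni, nm, seed = seed)
    list(dataset = ds, labels = label_top_fraction(ds, 0.25))
  }
  panel <- list(A = mk("A", 92), B = mk("B", 93))
  # C has too few actives
  dsC <- generate_assay(uni, "C", seed = 94)
  labC <- make_labels(stats::setNames(
    seq_along(dsC$values) <= 3, names(dsC$values)))
  panel$C <- list(dataset = dsC, labels = labC)
  res <- cross_roc_matrix(panel, uni$compounds)
  expect_equal(res$excluded$assay_id, "C")
  expect_match(res$excluded$reason, "toxic compounds")
  expect_setequal(rownames(res$roc), c("A", "B"))
})

test_that("merging components honours the label policies", {
  csA <- toy_compounds(rep(list("f"), 4), ids = paste0("a", 1:4))
  csB <- toy_compounds(rep(list("g"), 4), ids = paste0("b", 1:4))
  store <- cs_union(csA, csB)
  dsA <- toy_assay(c(9, 8, 1, 1), ids = csA$id)
  dsB <- toy_assay(c(9, 8, 1, 1), ids = csB$id)
  panel <- list(A = list(dataset = dsA, labels = label_fixed(dsA, 5)),
                B = list(dataset = dsB, labels = label_fixed(dsB, 5)))
  ids <- c("A", "B")
  m <- matrix(0.9, 2, 2, dimnames = list(ids, ids)); diag(m) <- NA
  net <- build_network(m)
  merged <- merge_component(net, panel, store)
  expect_equal(nrow(merged$compounds), 8L)       # disjoint union
  expect_equal(sum(merged$labels$labels), 4L)

  # conflicting labels for a shared compound
  ds1 <- toy_assay(c(9, 1), ids = c("s", "x1"))
  ds2 <- toy_assay(c(1, 9, 1), ids = c("s", "x2", "x3"))
  store2 <- toy_compounds(rep(list("f"), 4), ids = c("s", "x1", "x2", "x3"))
  pan2 <- list(P = list(dataset = ds1, labels = label_fixed(ds1, 5)),
               Q = list(dataset = ds2, labels = label_fixed(ds2, 5)))
  merged_any <- merge_component(net, pan2, store2, component = c("P", "Q"),
                                policy = "any_toxic")
  expect_true(merged_any$labels$labels[["s"]])     # toxic in P wins
  merged_maj <- merge_component(net, pan2, store2, component = c("P", "Q"),
                                policy = "majority")
  expect_false(merged_maj$labels$labels[["s"]])    # 1 of 2 votes is not majority
  merged_dup <- merge_component(net, pan2, store2, component = c("P", "Q"),
                                policy = "keep_duplicates")
  expect_equal(nrow(merged_dup$compounds), 5L)     # sum of measurements
  # any_toxic is order-independent
  merged_rev <- merge_component(net, pan2, store2, component = c("Q", "P"),
                                policy = "any_toxic")
  expect_equal(merged_any$labels$labels[sort(names(merged_any$labels$labels))],
               merged_rev$labels$labels[sort(names(merged_rev$labels$labels))])
})

test_that("network exports cover TSV, SIF, GraphML and survive read-back", {
  ids <- c("A", "B", "C")
  m <- matrix(c(NA, 0.7, 0.4, 0.8, NA, 0.5, 0.45, 0.55, NA), 3, 3,
              byrow = TRUE, dimnames = list(ids, ids))
  net <- build_network(m)
  expect_equal(nrow(net$edges), 1L)   # only A-B is bidirectional
  prefix <- file.path(withr::local_tempdir(), "net")
  files <- export_network(net, prefix)
  tsv <- read.delim(files[["tsv"]])
  expect_named(tsv, c("training_set", "test_set", "roc"))
  expect_equal(nrow(tsv), 6L)         # all directed pairs
  expect_equal(tsv$roc[tsv$training_set == "A" & tsv$test_set == "B"], 0.7)
  sif <- readLines(files[["sif"]])
  expect_length(sif, 2L)              # one edge line + isolated node C
  expect_true(any(grepl("^A\tpp\tB$", sif)))
  expect_true("C" %in% sif)
  g <- igraph::read_graph(files[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(g), 1L)
  expect_setequal(igraph::V(g)$name, ids)
  js <- jsonlite::read_json(files[["json"]], simplifyVector = TRUE)
  expect_equal(js$threshold, 0.6)

  # empty edge set still yields valid files with isolated nodes
  m0 <- matrix(0.2, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  diag(m0) <- NA
  files0 <- export_network(build_network(m0), paste0(prefix, "0"))
  expect_length(readLines(files0[["sif"]]), 2L)
})
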