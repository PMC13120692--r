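# Synthetic-world generator: reproducibility, structural validity, the
# text-similarity structure of definitions, planted motifs and zero-shot
# scenarios.

small_cfg <- function(seed = 7, ...) {
  synthetic_config(terms_per_aspect = 15, n_proteins = 25,
                   length_range = c(30L, 60L), seed = seed, ...)
}

test_that("generation is bit-reproducible from (config, seed)", {
  d1 <- simulate_dataset(small_cfg())
  d2 <- simulate_dataset(small_cfg())
  expect_identical(object_checksum(d1$graph), object_checksum(d2$graph))
  expect_identical(object_checksum(d1$proteins),
                   object_checksum(d2$proteins))
  expect_identical(d1$annotations, d2$annotations)
  d3 <- simulate_dataset(small_cfg(seed = 8))
  expect_false(identical(object_checksum(d1$proteins),
                         object_checksum(d3$proteins)))
})

test_that("generated ontologies satisfy parse-level invariants", {
  g <- generate_ontology(small_cfg())
  expect_s3_class(g, "go_graph")
  expect_equal(sort(names(g$roots)), c("BP", "CC", "MF"))
  # round-trips through the OBO writer/parser
  f <- tempfile(fileext = ".obo")
  write_obo(g, f)
  g2 <- parse_obo(f)
  expect_equal(active_terms(g2), active_terms(g))
  expect_equal(g2$parents[active_terms(g2)], g$parents[active_terms(g)])
  expect_equal(unname(g2$definitions[active_terms(g2)]),
               unname(g$definitions[active_terms(g)]))
  # every non-root term reaches exactly its aspect root (parse would fail
  # otherwise), and the DAG admits a topological order per aspect
  for (a in c("MF", "BP", "CC")) {
    ord <- topological_order(g, a)
    r <- setNames(seq_along(ord), as.character(ord))
    e <- g$edges[g$edges$child %in% names(r), ]
    expect_true(all(r[e$parent] < r[e$child]))
  }
})

test_that("definition similarity tracks ontology proximity", {
  g <- generate_ontology(synthetic_config(terms_per_aspect = 40, seed = 9))
  enc <- text_encoder_spec(dim = 128, seed = 9)
  X <- embed_definitions(g, enc)
  Xn <- unclass(X) / sqrt(rowSums(unclass(X)^2))
  ids <- rownames(X)
  set.seed(10)
  child_parent <- c()
  random_pair <- c()
  for (rep in 1:250) {
    ch <- sample(names(Filter(length, g$parents)), 1)
    pa <- sample(g$parents[[ch]], 1)
    child_parent <- c(child_parent, sum(Xn[ch, ] * Xn[pa, ]))
    ab <- sample(ids, 2)
    random_pair <- c(random_pair, sum(Xn[ab[1], ] * Xn[ab[2], ]))
  }
  expect_gt(mean(child_parent), mean(random_pair) + 0.1)
})

test_that("planted windows carry the signatures and masks align", {
  cfg <- small_cfg(snr = Inf)
  ds <- simulate_dataset(cfg)
  S <- ds$signatures
  for (k in seq_len(min(10, nrow(ds$masks)))) {
    row <- ds$masks[k, ]
    X <- ds$proteins[[row$protein_id]]
    win <- X[(row$start + 1):row$end, , drop = FALSE]
    # noiseless limit: window rows are exactly the signature
    expect_equal(win, matrix(S[row$term_id, ], nrow(win), ncol(S),
                             byrow = TRUE), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(row$end - row$start, cfg$motif_len)
  }
  # windows of one protein never overlap
  for (p in unique(ds$masks$protein_id)) {
    iv <- ds$masks[ds$masks$protein_id == p, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1) {
      expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
    }
  }
})

test_that("annotations are upward-closed under the closure oracle", {
  ds <- simulate_dataset(small_cfg())
  for (p in unique(ds$annotations$protein_id)) {
    raw <- ds$annotations_raw$term_id[ds$annotations_raw$protein_id == p]
    got <- sort(ds$annotations$term_id[ds$annotations$protein_id == p])
    expect_equal(got, oracle_closure(ds$graph$parents, unique(raw)))
  }
})

test_that("zero-shot scenarios strip held-out terms and derange controls", {
  ds <- simulate_dataset(synthetic_config(terms_per_aspect = 20,
                                          n_proteins = 60,
                                          length_range = c(30L, 60L),
                                          seed = 11))
  sc <- make_zero_shot_scenario(ds, n_held_out = 3, seed = 2)
  expect_length(sc$held_out, 3)
  # held-out terms appear in no training record
  expect_false(any(sc$train_annotations$term_id %in% sc$held_out))
  # test split keeps their proteins and labels
  expect_true(any(sc$test_annotations$term_id %in% sc$held_out))
  # splits partition the proteins
  expect_setequal(c(sc$train, sc$val, sc$test), names(ds$proteins))
  expect_length(intersect(sc$train, sc$test), 0)
  # control definitions are a derangement of the originals
  orig <- ds$graph$definitions[sc$held_out]
  ctrl <- sc$control_definitions[sc$held_out]
  expect_setequal(unname(ctrl), unname(orig))
  expect_true(all(ctrl != orig))
  # same seed reproduces the scenario exactly
  sc2 <- make_zero_shot_scenario(ds, n_held_out = 3, seed = 2)
  expect_identical(sc[names(sc) != "seed"], sc2[names(sc2) != "seed"])
})

test_that("dataset writes to plain-text files with a manifest", {
  ds <- simulate_dataset(small_cfg())
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "ontology.obo")))
  g2 <- parse_obo(file.path(dir, "ontology.obo"))
  expect_equal(active_terms(g2), active_terms(ds$graph))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(ann), nrow(ds$annotations_raw))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, ds$config$seed)
  X <- as.matrix(read.delim(
    file.path(dir, "proteins", "prot0001.tsv"), header = FALSE))
  expect_equal(dim(X), dim(ds$proteins[["prot0001"]]))
})
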