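# OBO parsing, ancestor closure, true-path propagation, orderings and
# zero-shot splits, each checked against naive oracles.

chain_obo <- c(
  "[Term]", "id: R:1", "name: root", "namespace: molecular_function", "",
  "[Term]", "id: A:1", "name: a", "is_a: R:1", "",
  "[Term]", "id: C:1", "name: c", "is_a: A:1", ""
)

test_that("parse_obo builds the expected small graphs", {
  g <- parse_obo(c("[Term]", "id: R:1", "name: r",
                   "namespace: molecular_function",
                   "[Term]", "id: A:1", "name: a", "is_a: R:1",
                   "[Term]", "id: B:1", "name: b", "is_a: A:1"))
  expect_equal(nrow(g$terms), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(unname(g$roots), "R:1")
  expect_equal(g$terms$aspect[match("B:1", g$terms$id)], "MF")

  # obsolete terms keep their row but lose all edges and index membership
  g2 <- parse_obo(c(chain_obo,
                    "[Term]", "id: X:1", "name: gone", "is_a: A:1",
                    "is_obsolete: true"))
  expect_true("X:1" %in% g2$terms$id)
  expect_false("X:1" %in% g2$edges$child)
  expect_false("X:1" %in% ancestor_index(g2)$term_ids)

  # relationship lines honour the retained-relation filter
  g3 <- parse_obo(c(chain_obo,
                    "[Term]", "id: P:1", "name: p",
                    "relationship: part_of A:1",
                    "relationship: regulates R:1"))
  e <- g3$edges[g3$edges$child == "P:1", ]
  expect_equal(e$relation, "part_of")
})

test_that("parse_obo rejects cycles and unknown parents", {
  cyc <- c("[Term]", "id: A:1", "name: a", "is_a: B:1",
           "[Term]", "id: B:1", "name: b", "is_a: A:1")
  expect_error(parse_obo(cyc), "cycle")
  expect_error(parse_obo(c("[Term]", "id: A:1", "name: a", "is_a: NOPE:9")),
               "unknown")
})

test_that("ancestor_index matches DFS reachability on random DAGs", {
  g <- parse_obo(chain_obo)
  idx <- ancestor_index(g, include_self = FALSE)
  expect_equal(idx$ancestors[["C:1"]], c("A:1", "R:1"))
  idx_s <- ancestor_index(g, include_self = TRUE)
  expect_equal(idx_s$ancestors[["C:1"]], c("A:1", "C:1", "R:1"))
  expect_length(idx$ancestors[["R:1"]], 0L)

  for (seed in c(11, 12, 13)) {
    gr <- parse_obo(rand_dag_obo(50, seed))
    idx <- ancestor_index(gr)
    for (id in idx$term_ids) {
      expect_equal(idx$ancestors[[id]], oracle_ancestors(gr$parents, id))
    }
  }
})

test_that("true-path propagation equals the closure oracle and is idempotent", {
  g <- parse_obo(chain_obo)
  idx <- ancestor_index(g)
  ann <- data.frame(protein_id = "p1", term_id = "C:1")
  out <- propagate_true_path(ann, idx)
  expect_setequal(out$term_id, c("C:1", "A:1", "R:1"))
  expect_identical(propagate_true_path(out, idx), out)

  set.seed(21)
  gr <- parse_obo(rand_dag_obo(60, 21))
  ids <- active_terms(gr)
  ann <- data.frame(
    protein_id = rep(sprintf("p%02d", 1:15), each = 3),
    term_id = sample(ids, 45, replace = TRUE))
  out <- propagate_true_path(ann, ancestor_index(gr))
  for (p in unique(ann$protein_id)) {
    expect_equal(sort(out$term_id[out$protein_id == p]),
                 oracle_closure(gr$parents,
                                unique(ann$term_id[ann$protein_id == p])))
  }
  # monotone: adding records never removes outputs
  extra <- rbind(ann, data.frame(protein_id = "p01",
                                 term_id = sample(ids, 1)))
  out2 <- propagate_true_path(extra, ancestor_index(gr))
  expect_true(all(paste(out$protein_id, out$term_id) %in%
                    paste(out2$protein_id, out2$term_id)))

  expect_error(propagate_true_path(
    data.frame(protein_id = "p", term_id = "GHOST:1"), ancestor_index(gr)),
    "missing")
})

test_that("topological orderings are valid, deterministic linear extensions", {
  diamond <- c(
    "[Term]", "id: R:1", "name: r", "namespace: molecular_function",
    "[Term]", "id: A:1", "name: a", "is_a: R:1",
    "[Term]", "id: B:1", "name: b", "is_a: R:1",
    "[Term]", "id: C:1", "name: c", "is_a: A:1", "is_a: B:1")
  g <- parse_obo(diamond)
  expect_equal(as.character(topological_order(g, "MF")),
               c("R:1", "A:1", "B:1", "C:1"))
  expect_equal(as.character(topological_order(g, "MF", mode = "go_id")),
               c("A:1", "B:1", "C:1", "R:1"))

  for (seed in 31:40) {
    gr <- parse_obo(rand_dag_obo(40, seed))
    ord <- topological_order(gr, "MF")
    r <- setNames(seq_along(ord), as.character(ord))
    ok <- all(r[gr$edges$parent] < r[gr$edges$child])
    expect_true(ok, info = paste("seed", seed))
    expect_identical(as.character(topological_order(gr, "MF")),
                     as.character(ord))
  }
})

test_that("zero-shot splits remove held-out associations before propagation", {
  g <- parse_obo(c(chain_obo,
                   "[Term]", "id: D:1", "name: d", "is_a: R:1"))
  idx <- ancestor_index(g)

  # protein annotated only with the held-out leaf ends up with nothing
  ann <- data.frame(protein_id = "p1", term_id = "C:1")
  zs <- make_zero_shot_split(ann, "C:1", idx)
  expect_equal(nrow(zs$train), 0L)

  # unrelated annotations survive and propagate normally
  ann2 <- data.frame(protein_id = c("p1", "p1"), term_id = c("C:1", "D:1"))
  zs2 <- make_zero_shot_split(ann2, "C:1", idx)
  expect_setequal(zs2$train$term_id, c("D:1", "R:1"))

  # empty holdout is plain propagation
  zs3 <- make_zero_shot_split(ann2, character(), idx)
  expect_identical(zs3$train, propagate_true_path(ann2, idx))

  expect_error(make_zero_shot_split(ann2, "GHOST:1", idx), "absent")
  expect_error(make_zero_shot_split(propagate_true_path(ann2, idx),
                                    "C:1", idx), "unpropagated")
})

test_that("annotation IO round-trips and reads GAF by position", {
  ann <- data.frame(protein_id = c("p1", "p2"), term_id = c("A:1", "C:1"),
                    aspect = c("MF", "MF"))
  f <- tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  expect_equal(read_annotations(f), ann)

  gaf <- c("!gaf-version: 2.1",
           paste(c("DB", "P007", "SYMB", "", "GO:0001", "REF", "IEA", "",
                   "F", "", "", "", "", "", "", "", ""), collapse = "\t"))
  f2 <- tempfile(fileext = ".gaf")
  writeLines(gaf, f2)
  got <- read_annotations(f2)
  expect_equal(got$protein_id, "P007")
  expect_equal(got$term_id, "GO:0001")
  expect_equal(got$aspect, "MF")
})

test_that("subsumption ranking scores parent recovery", {
  g <- parse_obo(c("[Term]", "id: R:1", "name: r",
                   "namespace: molecular_function",
                   "[Term]", "id: A:1", "name: a", "is_a: R:1"))
  E <- matrix(rnorm(2 * 8), 2, 8, dimnames = list(c("A:1", "R:1"), NULL))
  res <- subsumption_ranking_eval(E, g)
  expect_equal(res$mrr, 1)  # single candidate is the true parent

  # children built as parent means + tiny noise are near-perfectly ranked
  set.seed(5)
  gr <- parse_obo(rand_dag_obo(30, 77))
  ids <- active_terms(gr)
  d <- 16
  E <- matrix(0, length(ids), d, dimnames = list(ids, NULL))
  ord <- as.character(topological_order(gr, "MF"))
  for (v in ord) {
    ps <- gr$parents[[v]]
    E[v, ] <- if (!length(ps)) rnorm(d) else
      colMeans(E[ps, , drop = FALSE]) + rnorm(d, sd = 1e-3)
  }
  res <- subsumption_ranking_eval(E, gr)
  # descendants of a child sit as close as its parents under this
  # construction, so MRR stays below 1 while parents dominate the top ranks
  expect_gt(res$mrr, 0.6)
  expect_gt(res$hits[["hits@5"]], 0.9)
  expect_gt(res$auc, 0.9)

  # orthogonal random embeddings: hits@1 near the 1/(n-1) chance level
  set.seed(6)
  gr2 <- parse_obo(rand_dag_obo(100, 78))
  ids2 <- active_terms(gr2)
  E2 <- matrix(rnorm(length(ids2) * 256), length(ids2),
               dimnames = list(ids2, NULL))
  res2 <- subsumption_ranking_eval(E2, gr2)
  expect_lt(res2$hits[["hits@1"]], 0.15)

  expect_error(subsumption_ranking_eval(E2[-1, , drop = FALSE], gr2),
               "missing")
})
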