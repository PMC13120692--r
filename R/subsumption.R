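# Subsumption-prediction evaluation of term embeddings: how well does
# cosine similarity in the embedding space rank a child's true parents
# among all candidate terms? Reported as mean reciprocal rank (of the
# best-ranked true parent), hits@k, and the ROC AUC of parents versus
# non-parents, averaged over children.

#' Rank true parents by embedding cosine similarity
#'
#' For every non-root term, all other terms are ranked by cosine similarity
#' to the child's embedding and the child's true parents are scored.
#'
#' @param embeddings Matrix with one row per term (rownames = term ids);
#'   e.g. a `term_embedding` or autoencoder latents.
#' @param graph The `go_graph` providing parent edges.
#' @param ks Cutoffs for hits@k.
#' @return List with `mrr`, `hits` (named by k), `auc`, and a `per_child`
#'   data frame.
#' @export
subsumption_ranking_eval <- function(embeddings, graph, ks = c(1L, 5L, 10L)) {
  ids <- active_terms(graph)
  missing <- setdiff(ids, rownames(embeddings))
  if (length(missing)) {
    stop_hiergo("embedding rows missing for: ",
                paste(utils::head(missing, 5), collapse = ", "),
                class = "hiergo_validation_error")
  }
  X <- as.matrix(embeddings)[ids, , drop = FALSE]
  norms <- sqrt(rowSums(X^2))
  norms[norms == 0] <- 1
  Xn <- X / norms
  children <- ids[lengths(graph$parents[ids]) > 0L]

  rows <- lapply(children, function(ch) {
    sims <- drop(Xn %*% Xn[ch, ])
    names(sims) <- ids
    cand <- sims[setdiff(ids, ch)]
    parents <- graph$parents[[ch]]
    r <- rank(-cand, ties.method = "average")
    is_par <- names(cand) %in% parents
    best <- min(r[is_par])
    data.frame(child = ch,
               best_parent_rank = best,
               rr = 1 / best,
               auc = roc_auc(cand, as.numeric(is_par)),
               stringsAsFactors = FALSE)
  })
  per_child <- do.call(rbind, rows)
  hits <- vapply(ks, function(k) mean(per_child$best_parent_rank <= k), 0)
  names(hits) <- paste0("hits@", ks)
  list(mrr = mean(per_child$rr), hits = hits,
       auc = mean(per_child$auc, na.rm = TRUE), per_child = per_child)
}
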