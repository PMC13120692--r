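# Independent oracles used throughout the suite. These deliberately use
# naive algorithms (per-node DFS, explicit threshold loops, O(n^2) pair
# counts) so they share no code with the package implementations they
# check.

# Per-node DFS reachability over child->parent adjacency lists.
oracle_ancestors <- function(parents, id) {
  seen <- character()
  stack <- parents[[id]]
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, parents[[v]])
  }
  sort(seen)
}

# Union-of-ancestors closure of one protein's term set.
oracle_closure <- function(parents, terms) {
  sort(unique(c(terms, unlist(lapply(terms, oracle_ancestors,
                                     parents = parents)))))
}

# CAFA Fmax by explicit recomputation from counts at every threshold.
oracle_fmax <- function(P, Y, taus = seq(0.01, 1, by = 0.01)) {
  best <- 0
  best_tau <- taus[1]
  for (tau in taus) {
    precs <- c()
    recs <- c()
    for (i in seq_len(nrow(P))) {
      called <- which(P[i, ] >= tau)
      true <- which(Y[i, ] > 0)
      if (length(called)) {
        precs <- c(precs, sum(called %in% true) / length(called))
      }
      if (length(true)) {
        recs <- c(recs, sum(called %in% true) / length(true))
      }
    }
    if (!length(precs) || !length(recs)) next
    p <- mean(precs)
    r <- mean(recs)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    if (f > best + 1e-12) {
      best <- f
      best_tau <- tau
    }
  }
  list(fmax = best, threshold = best_tau)
}

# Step-interpolated AUPR by looping over distinct thresholds.
oracle_aupr <- function(scores, labels) {
  n_pos <- sum(labels > 0)
  if (n_pos == 0) return(NA_real_)
  taus <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (tau in taus) {
    called <- scores >= tau
    tp <- sum(called & labels > 0)
    prec <- tp / sum(called)
    rec <- tp / n_pos
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# ROC AUC by exhaustive pair comparison (ties half credit).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Closed-form rollout: R = sum_l w_l Abar(l), with w_1 = 2^-(N-1) and
# w_l = 2^-(N-l+1) for l >= 2 (the unique convex weights the recursion
# R(l) = (Abar(l) + R(l-1)) / 2 unrolls to; they sum to 1).
oracle_rollout <- function(abar_list) {
  N <- length(abar_list)
  w <- c(2^-(N - 1), if (N >= 2) 2^-(N - seq(2, N) + 1))
  stopifnot(abs(sum(w) - 1) < 1e-12)
  Reduce(`+`, Map(`*`, w, abar_list))
}

# Random DAG as OBO text: one root, each later node picks 1-2 parents among
# earlier nodes; ids shuffled so lexicographic order is unrelated to depth.
rand_dag_obo <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T:%04d", sample(9999, n))
  lines <- c("format-version: 1.2", "",
             "[Term]", paste0("id: ", ids[1]), "name: root",
             "namespace: molecular_function", "")
  for (i in seq(2, n)) {
    k <- sample(1:min(2, i - 1), 1)
    ps <- sample(ids[seq_len(i - 1)], k)
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: node ", i), paste0("is_a: ", ps), "")
  }
  lines
}

row_stochastic <- function(n, m) {
  A <- matrix(stats::runif(n * m), n, m)
  A / rowSums(A)
}
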