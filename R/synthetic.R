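# Download-free synthetic world with the statistical structure the method
# assumes: a random three-aspect DAG ontology whose templated definitions
# carry signature tokens (so text similarity tracks ontology proximity),
# proteins as residue-embedding matrices with planted term-specific motif
# windows, upward-closed annotations, and zero-shot scenarios in which the
# text-to-motif mapping is linearly recoverable -- the property that lets a
# trained model score terms it never saw annotated.

#' Synthetic dataset configuration
#'
#' Defaults are the desk-scale world used throughout the test suite: 70
#' terms per aspect (about 50 of them leaves), 300 proteins of 40-120
#' residues, 32-dimensional residue embeddings, 8-residue motif windows at
#' signal-to-noise ratio 3.
#'
#' @param terms_per_aspect Terms per subontology (including the root).
#' @param max_depth Maximum DAG depth below the root.
#' @param max_parents Maximum parents drawn per non-root term.
#' @param n_proteins Number of proteins.
#' @param length_range Min/max residue counts.
#' @param d_seq Residue embedding dimension.
#' @param d_t Definition text embedding dimension (hash encoder).
#' @param motif_len Planted motif window length (residues).
#' @param snr Signal-to-noise ratio inside motif windows (signal norm over
#'   expected noise norm; `Inf` plants noiseless motifs).
#' @param annot_aspects Aspects whose leaves annotate proteins.
#' @param max_leaves_per_protein Each protein draws 1..this many leaf terms.
#' @param signature_mode `"text_linked"` (motif vectors are a fixed random
#'   linear image of each leaf's definition embedding, so the text-to-motif
#'   map is learnable and transfers to unseen terms) or `"orthonormal"`
#'   (motifs are a random orthonormal set unrelated to the text; a negative
#'   control under which zero-shot transfer has no signal to exploit).
#' @param seed Master seed; regeneration from (config, seed) is
#'   bit-reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(terms_per_aspect = 70L, max_depth = 4L,
                             max_parents = 2L, n_proteins = 300L,
                             length_range = c(40L, 120L), d_seq = 32L,
                             d_t = 64L, motif_len = 8L, snr = 3,
                             annot_aspects = "MF",
                             max_leaves_per_protein = 3L,
                             signature_mode = c("text_linked", "orthonormal"),
                             seed = 1L) {
  stopifnot(terms_per_aspect >= 2, max_depth >= 1, max_parents >= 1,
            n_proteins >= 1, length_range[1] >= 1,
            length_range[2] >= length_range[1],
            motif_len >= 1, snr > 0,
            length_range[1] >= max_leaves_per_protein * motif_len)
  structure(list(
    terms_per_aspect = as.integer(terms_per_aspect),
    max_depth = as.integer(max_depth),
    max_parents = as.integer(max_parents),
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    d_seq = as.integer(d_seq), d_t = as.integer(d_t),
    motif_len = as.integer(motif_len), snr = snr,
    annot_aspects = annot_aspects,
    max_leaves_per_protein = as.integer(max_leaves_per_protein),
    signature_mode = match.arg(signature_mode),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

ASPECT_PHRASES <- c(MF = "molecular activity", BP = "biological process",
                    CC = "cellular location")

#' @noRd
sig_token <- function(id) paste0("sig_", sub(":", "_", id))

#' Generate a random rooted DAG ontology with templated definitions
#'
#' Three aspects, one root each. Every non-root term draws 1 to
#' `max_parents` parents from strictly shallower levels of the same aspect
#' (always at least one from the level directly above, so assigned depths
#' are realized). Term ids are assigned in a seeded random permutation, so
#' lexicographic id order is uncorrelated with the hierarchy (which is what
#' makes the flat "go_id" ordering a genuine ablation). Definitions embed a
#' unique signature token per term plus the parents' tokens; internal terms
#' additionally aggregate all descendants' tokens, giving definition-text
#' similarity a hierarchical structure a text encoder can exploit.
#'
#' @param config A [synthetic_config()].
#' @return A `go_graph` with populated `definitions`.
#' @export
generate_ontology <- function(config) {
  with_seed(derive_seed(config$seed, 41L), {
    n_total <- 3L * config$terms_per_aspect
    ids_pool <- sprintf("SYN:%07d", sample(n_total))
    aspects <- c("MF", "BP", "CC")

    terms <- list()
    edges <- list()
    idx <- 0L
    for (a in aspects) {
      n <- config$terms_per_aspect
      aspect_ids <- ids_pool[idx + seq_len(n)]
      idx <- idx + n
      root <- aspect_ids[1]
      others <- aspect_ids[-1]
      depth <- stats::setNames(integer(n), aspect_ids)
      depth[root] <- 0L
      n_oth <- length(others)
      # depth distribution widens toward the leaves (weight 3^(d-1)),
      # mirroring real ontologies; with the defaults roughly 50 of 70
      # terms end up as leaves
      d_assign <- c(seq_len(min(config$max_depth, n_oth)),
                    if (n_oth > config$max_depth) {
                      sample(config$max_depth, n_oth - config$max_depth,
                             replace = TRUE,
                             prob = 3^(seq_len(config$max_depth) - 1))
                    })
      d_assign <- sort(d_assign)
      depth[others] <- d_assign
      for (i in seq_along(others)) {
        t_id <- others[i]
        d <- d_assign[i]
        above <- aspect_ids[depth[aspect_ids] == d - 1L &
                              aspect_ids != t_id]
        shallower <- aspect_ids[depth[aspect_ids] < d - 1L]
        # first parent one level up (realizes the assigned depth)
        p1 <- if (length(above) == 1L) above else sample(above, 1L)
        extra <- sample.int(config$max_parents, 1L) - 1L
        pool <- setdiff(c(above, shallower), p1)
        ps <- c(p1, if (extra > 0L && length(pool) > 0L) {
          pool[sample.int(length(pool), min(extra, length(pool)))]
        })
        edges[[length(edges) + 1L]] <- data.frame(
          child = t_id, parent = ps, relation = "is_a",
          stringsAsFactors = FALSE)
      }
      for (t_id in aspect_ids) {
        terms[[length(terms) + 1L]] <- data.frame(
          id = t_id,
          name = if (t_id == root) paste0("synthetic ", a, " root")
                 else paste0("synthetic term ", t_id),
          aspect = a, obsolete = FALSE, stringsAsFactors = FALSE)
      }
    }
    term_tab <- do.call(rbind, terms)
    term_tab <- term_tab[order(term_tab$id), , drop = FALSE]
    rownames(term_tab) <- NULL
    edge_tab <- do.call(rbind, edges)

    ids <- term_tab$id
    parents <- split(edge_tab$parent, factor(edge_tab$child, levels = ids))
    children <- split(edge_tab$child, factor(edge_tab$parent, levels = ids))
    parents <- lapply(parents, function(p) sort(unique(p)))
    children <- lapply(children, function(p) sort(unique(p)))
    roots <- stats::setNames(
      vapply(aspects, function(a) {
        term_tab$id[term_tab$aspect == a][
          which(lengths(parents[term_tab$id[term_tab$aspect == a]]) == 0L)]
      }, ""), aspects)

    graph <- structure(
      list(terms = term_tab, definitions = NULL, parents = parents,
           children = children, edges = edge_tab, roots = roots,
           retained_relations = "is_a"),
      class = "go_graph")

    # definitions need the descendant closure
    idx_anc <- ancestor_index(graph, include_self = FALSE)
    descendants <- stats::setNames(vector("list", length(ids)), ids)
    for (v in ids) {
      for (anc in idx_anc$ancestors[[v]]) {
        descendants[[anc]] <- c(descendants[[anc]], v)
      }
    }
    # definitions are deliberately dense in signature tokens (the term's
    # own token emphasized, then its parents', then its descendants'): a
    # mean-pooling text encoder keeps a usable fraction of term-specific
    # signal, as in real GO definitions where most words are informative
    defs <- vapply(ids, function(v) {
      a <- term_tab$aspect[match(v, ids)]
      ps <- parents[[v]]
      ds <- sort(unique(descendants[[v]]))
      own <- sig_token(v)
      paste0(
        "A synthetic ", ASPECT_PHRASES[[a]], " characterized by ",
        own,
        if (length(ps)) paste0(" within ",
                               paste(rep(vapply(ps, sig_token, ""), 3),
                                     collapse = " ")),
        if (length(ds)) paste0(" encompassing ",
                               paste(vapply(ds, sig_token, ""),
                                     collapse = " ")),
        "."
      )
    }, "")
    graph$definitions <- defs
    graph
  })
}

#' Leaf terms of a graph
#' @noRd
leaf_terms <- function(graph, aspect = NULL) {
  ids <- active_terms(graph, aspect)
  ids[lengths(graph$children[ids]) == 0L]
}

#' Motif signature vectors for leaf terms
#'
#' In `"text_linked"` mode each leaf's motif vector is the unit-normalized
#' image of its definition embedding under one fixed seeded Gaussian map,
#' making the text-to-motif relation a single linear map shared by all
#' terms (seen or unseen). In `"orthonormal"` mode motifs are a random
#' orthonormal set carrying no relation to the text.
#'
#' @param graph Synthetic `go_graph`.
#' @param config [synthetic_config()].
#' @param leaves Leaf term ids.
#' @return Matrix `length(leaves)` x `d_seq`, rows unit-norm, named.
#' @export
leaf_signatures <- function(graph, config,
                            leaves = leaf_terms(graph, config$annot_aspects)) {
  d <- config$d_seq
  if (config$signature_mode == "orthonormal") {
    if (length(leaves) > d) {
      stop_hiergo("orthonormal signatures need d_seq >= number of leaves",
                  class = "hiergo_config_error")
    }
    S <- with_seed(derive_seed(config$seed, 43L), {
      M <- matrix(stats::rnorm(d * d), d, d)
      t(qr.Q(qr(M))[, seq_along(leaves), drop = FALSE])
    })
  } else {
    enc <- text_encoder_spec("hash", dim = config$d_t, seed = config$seed)
    X <- t(vapply(leaves, function(v) {
      encode_text(graph$definitions[[v]], enc)
    }, numeric(config$d_t)))
    P <- with_seed(derive_seed(config$seed, 43L), {
      matrix(stats::rnorm(config$d_t * d, sd = 1 / sqrt(config$d_t)),
             config$d_t, d)
    })
    S <- X %*% P
    S <- S / sqrt(rowSums(S^2))
  }
  rownames(S) <- leaves
  S
}

#' Generate proteins with planted motif windows
#'
#' Each protein draws a length, 1 to `max_leaves_per_protein` leaf-term
#' annotations, and disjoint motif windows (one per annotated leaf) whose
#' rows are the leaf's signature vector plus Gaussian noise at the
#' configured SNR; background residues are pure noise of matching scale.
#' Annotations are then true-path-propagated. Binding masks record the
#' planted windows as 0-based half-open intervals.
#'
#' @param config [synthetic_config()].
#' @param graph Graph from [generate_ontology()].
#' @return List with `proteins` (named list of L x d_seq matrices),
#'   `annotations_raw`, `annotations` (propagated), `masks` (data frame:
#'   protein_id, term_id, start, end), `signatures`, `index`.
#' @export
generate_proteins <- function(config, graph) {
  leaves <- leaf_terms(graph, config$annot_aspects)
  S <- leaf_signatures(graph, config, leaves)
  index <- ancestor_index(graph, include_self = FALSE)
  d <- config$d_seq
  w <- config$motif_len
  sd_bg <- 1 / sqrt(d)
  sd_win <- if (is.finite(config$snr)) 1 / (config$snr * sqrt(d)) else 0

  with_seed(derive_seed(config$seed, 47L), {
    proteins <- vector("list", config$n_proteins)
    names(proteins) <- sprintf("prot%04d", seq_len(config$n_proteins))
    ann <- list()
    masks <- list()
    for (i in seq_len(config$n_proteins)) {
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      k <- sample.int(config$max_leaves_per_protein, 1L)
      picks <- sample(leaves, k)
      X <- matrix(stats::rnorm(L * d, sd = sd_bg), L, d)
      # k disjoint windows, placed uniformly at random
      slack <- L - k * w
      offs <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
      starts <- offs + (seq_len(k) - 1L) * w + 1L
      for (j in seq_len(k)) {
        rows <- starts[j]:(starts[j] + w - 1L)
        noise <- if (sd_win > 0) {
          matrix(stats::rnorm(w * d, sd = sd_win), w, d)
        } else 0
        X[rows, ] <- matrix(S[picks[j], ], w, d, byrow = TRUE) + noise
        masks[[length(masks) + 1L]] <- data.frame(
          protein_id = names(proteins)[i], term_id = picks[j],
          start = starts[j] - 1L, end = starts[j] + w - 1L,
          stringsAsFactors = FALSE)
      }
      proteins[[i]] <- X
      ann[[i]] <- data.frame(protein_id = names(proteins)[i],
                             term_id = picks, stringsAsFactors = FALSE)
    }
    annotations_raw <- do.call(rbind, ann)
    list(proteins = proteins,
         annotations_raw = annotations_raw,
         annotations = propagate_true_path(annotations_raw, index),
         masks = do.call(rbind, masks),
         signatures = S, index = index)
  })
}

#' Generate a complete synthetic dataset
#'
#' Ontology, frozen definition-text embeddings, proteins, annotations and
#' binding masks, plus a manifest with the seed and a config checksum.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  graph <- generate_ontology(config)
  encoder <- text_encoder_spec("hash", dim = config$d_t, seed = config$seed)
  embeddings <- embed_definitions(graph, encoder)
  prot <- generate_proteins(config, graph)
  structure(
    c(list(graph = graph, encoder = encoder, term_embeddings = embeddings,
           config = config,
           manifest = list(seed = config$seed,
                           config_checksum = object_checksum(config))),
      prot),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$proteins), "proteins,",
      sum(!x$graph$terms$obsolete), "terms,",
      nrow(x$annotations), "propagated annotations\n")
  invisible(x)
}

#' Build a zero-shot scenario from a synthetic dataset
#'
#' Splits proteins into train/validation/test, removes every association of
#' the held-out leaf terms from the training annotations before true-path
#' propagation, and prepares a shuffled-definition negative control: the
#' held-out terms' definition texts are deranged among themselves, so each
#' held-out term's textual signal points at the wrong motif.
#'
#' @param dataset A `synthetic_dataset`.
#' @param held_out Held-out leaf term ids; if `NULL`, `n_held_out` annotated
#'   leaves (with at least `min_annotations` annotated proteins) are drawn
#'   at random under the scenario seed.
#' @param n_held_out Number of terms to hold out when `held_out` is `NULL`.
#' @param split Train/validation/test protein fractions (sums to 1).
#' @param min_annotations Minimum annotated proteins for an auto-picked
#'   held-out leaf.
#' @param seed Scenario seed (protein split, term pick, derangement).
#' @return Object of class `zero_shot_scenario`: protein id vectors
#'   (`train`, `val`, `test`), `train_annotations` (propagated, without
#'   held-out associations), `test_annotations` (fully propagated),
#'   `held_out`, `control_definitions` (named deranged texts).
#' @export
make_zero_shot_scenario <- function(dataset, held_out = NULL,
                                    n_held_out = 3L,
                                    split = c(0.8, 0.1, 0.1),
                                    min_annotations = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  raw <- dataset$annotations_raw
  counts <- table(raw$term_id)
  leaves <- leaf_terms(dataset$graph, dataset$config$annot_aspects)

  with_seed(derive_seed(seed, 53L), {
    if (is.null(held_out)) {
      eligible <- intersect(names(counts)[counts >= min_annotations], leaves)
      if (length(eligible) < n_held_out) {
        stop_hiergo("not enough well-annotated leaves to hold out",
                    class = "hiergo_validation_error")
      }
      # draw from distinct branches (no shared parent): held-out terms
      # should be functionally distinct, and a shuffled-definition control
      # only destroys the signal if the deranged text points elsewhere
      held_out <- character()
      pool <- sample(eligible)
      for (cand in pool) {
        if (length(held_out) == n_held_out) break
        shared <- any(vapply(held_out, function(h) {
          length(intersect(dataset$graph$parents[[h]],
                           dataset$graph$parents[[cand]])) > 0
        }, TRUE))
        if (!shared) held_out <- c(held_out, cand)
      }
      if (length(held_out) < n_held_out) {
        stop_hiergo("not enough branch-distinct leaves to hold out",
                    class = "hiergo_validation_error")
      }
    } else {
      bad <- setdiff(held_out, leaves)
      if (length(bad)) {
        stop_hiergo("held-out terms must be annotated leaves: ",
                    paste(bad, collapse = ", "),
                    class = "hiergo_validation_error")
      }
    }

    ids <- names(dataset$proteins)
    n <- length(ids)
    perm <- sample(ids)
    n_train <- round(split[1] * n)
    n_val <- round(split[2] * n)
    train <- perm[seq_len(n_train)]
    val <- perm[n_train + seq_len(n_val)]
    test <- perm[(n_train + n_val + 1):n]

    if (!any(raw$protein_id %in% test & raw$term_id %in% held_out)) {
      warning("no test protein is annotated with a held-out term")
    }

    trainval_raw <- raw[raw$protein_id %in% c(train, val), , drop = FALSE]
    zs <- make_zero_shot_split(trainval_raw, held_out, dataset$index)

    defs <- dataset$graph$definitions[held_out]
    perm_d <- derangement(length(held_out))
    control <- stats::setNames(unname(defs)[perm_d], held_out)

    structure(list(train = train, val = val, test = test,
                   train_annotations = zs$train,
                   test_annotations = propagate_true_path(
                     raw[raw$protein_id %in% test, , drop = FALSE],
                     dataset$index),
                   held_out = held_out,
                   control_definitions = control,
                   seed = seed),
              class = "zero_shot_scenario")
  })
}

# A uniformly sampled permutation with no fixed point.
#' @noRd
derangement <- function(n) {
  if (n < 2L) {
    stop_hiergo("derangement needs n >= 2", class = "hiergo_validation_error")
  }
  repeat {
    p <- sample(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Binary target matrix from an annotation table
#'
#' @param annotations Annotation data frame (usually propagated).
#' @param protein_ids Row order.
#' @param term_ids Column order (decoding order).
#' @return Binary matrix with the requested dimnames.
#' @export
targets_matrix <- function(annotations, protein_ids, term_ids) {
  M <- matrix(0, length(protein_ids), length(term_ids),
              dimnames = list(protein_ids, term_ids))
  keep <- annotations$protein_id %in% protein_ids &
    annotations$term_id %in% term_ids
  a <- annotations[keep, , drop = FALSE]
  M[cbind(match(a$protein_id, protein_ids), match(a$term_id, term_ids))] <- 1
  M
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `ontology.obo`, `annotations.tsv`, `masks.tsv`, one TSV of
#' residue embeddings per protein under `proteins/`, and `manifest.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(dataset$graph, file.path(dir, "ontology.obo"))
  write_annotations(dataset$annotations_raw,
                    file.path(dir, "annotations.tsv"))
  utils::write.table(dataset$masks, file.path(dir, "masks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pdir <- file.path(dir, "proteins")
  dir.create(pdir, showWarnings = FALSE)
  for (nm in names(dataset$proteins)) {
    utils::write.table(dataset$proteins[[nm]],
                       file.path(pdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = dataset$config$seed,
         config_checksum = dataset$manifest$config_checksum,
         n_proteins = length(dataset$proteins)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
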