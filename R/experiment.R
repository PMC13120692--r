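# End-to-end experiment engine: assemble GO latents for a chosen embedding
# configuration, train one model per subontology, and evaluate -- including
# the zero-shot path where held-out terms are excluded from the training
# sequence and re-inserted at their topological ranks at test time (no
# positional parameters are tied to ranks, so insertion is well-defined).

#' GO latents for an embedding configuration
#'
#' @param dataset A `synthetic_dataset` (or any list with `graph`,
#'   `term_embeddings`, `encoder`).
#' @param embedding `"combined"` (autoencoder latents), `"textual"` (raw
#'   definition-text embeddings), `"structural"` (self-inclusive ancestor
#'   indicator vectors, the desk-scale stand-in for structure-only
#'   embeddings) or `"none"` (trainable; returns NULL).
#' @param term_ids Row set and order.
#' @param ae Fitted `go_autoencoder` (required for `"combined"`).
#' @return Latent matrix (rows = `term_ids`) or NULL.
#' @export
go_latents <- function(dataset, embedding, term_ids, ae = NULL) {
  switch(embedding,
    combined = {
      if (is.null(ae)) {
        stop_hiergo("combined embeddings need a fitted autoencoder",
                    class = "hiergo_config_error")
      }
      ae$latents[term_ids, , drop = FALSE]
    },
    textual = unclass(dataset$term_embeddings)[term_ids, , drop = FALSE],
    structural = {
      idx <- ancestor_index(dataset$graph, include_self = TRUE)
      M <- matrix(0, length(term_ids), length(term_ids),
                  dimnames = list(term_ids, term_ids))
      for (t in term_ids) {
        on <- intersect(idx$ancestors[[t]], term_ids)
        M[t, on] <- 1
      }
      M
    },
    none = NULL,
    stop_hiergo("unknown embedding configuration: ", embedding,
                class = "hiergo_config_error")
  )
}

#' Plain protein split (no zero-shot holdout)
#'
#' @param dataset A `synthetic_dataset`.
#' @param split Train/validation/test fractions.
#' @param seed Split seed.
#' @return List with `train`, `val`, `test`, `train_annotations`,
#'   `test_annotations`, `held_out = character()`.
#' @export
make_protein_split <- function(dataset, split = c(0.8, 0.1, 0.1), seed = 1L) {
  ids <- names(dataset$proteins)
  with_seed(derive_seed(seed, 59L), {
    perm <- sample(ids)
    n_train <- round(split[1] * length(ids))
    n_val <- round(split[2] * length(ids))
    train <- perm[seq_len(n_train)]
    val <- perm[n_train + seq_len(n_val)]
    test <- perm[(n_train + n_val + 1):length(ids)]
    raw <- dataset$annotations_raw
    list(train = train, val = val, test = test,
         train_annotations = propagate_true_path(
           raw[raw$protein_id %in% c(train, val), , drop = FALSE],
           dataset$index),
         test_annotations = propagate_true_path(
           raw[raw$protein_id %in% test, , drop = FALSE], dataset$index),
         held_out = character())
  })
}

#' Run one training-and-evaluation experiment
#'
#' The workhorse behind [run_pipeline()] and [run_ablation_grid()]:
#' orders the aspect's terms, builds GO latents for the requested embedding
#' configuration (fitting the autoencoder if needed), trains the chosen
#' architecture on the training proteins (held-out zero-shot terms removed
#' from the decoding sequence), and evaluates on test proteins over the
#' full term sequence -- so held-out terms are scored purely zero-shot.
#'
#' @param dataset A `synthetic_dataset`.
#' @param scenario Optional `zero_shot_scenario`; when NULL a plain split
#'   is used.
#' @param aspect Subontology to model.
#' @param embedding,architecture,ordering Configuration axes (see
#'   [go_latents()] and [transformer_config()]).
#' @param config [transformer_config()]; its `ordering`/`architecture` are
#'   overridden by the axis arguments.
#' @param tc [train_config()].
#' @param ae Optionally a pre-fitted autoencoder (re-used across an
#'   ablation grid); fitted on demand otherwise.
#' @param d_z,ae_epochs,ae_lr Autoencoder settings when fitted on demand.
#' @param with_control Also evaluate the shuffled-definition negative
#'   control (zero-shot scenarios only).
#' @return List: `model`, `ae`, `order`, `report` (an `eval_report`),
#'   `preds`, `truth`, `held_out_auc` (per-term table for held-out terms),
#'   `control_auc` (under the deranged definitions), `scenario`, `E_full`.
#' @export
run_experiment <- function(dataset, scenario = NULL, aspect = "MF",
                           embedding = "combined",
                           architecture = "decoder",
                           ordering = "hierarchical",
                           config = transformer_config(),
                           tc = train_config(), ae = NULL, d_z = 64L,
                           ae_epochs = 150L, ae_lr = 5e-3,
                           with_control = TRUE) {
  graph <- dataset$graph
  config$ordering <- ordering
  config$architecture <- architecture
  if (is.null(scenario)) {
    scenario <- make_protein_split(dataset, seed = tc$seed)
  }
  held_out <- scenario$held_out %||% character()

  order_full <- topological_order(graph, aspect, ordering)
  term_ids_full <- as.character(order_full)
  train_terms <- setdiff(term_ids_full, held_out)

  if (embedding == "combined" && is.null(ae)) {
    ae <- fit_autoencoder(dataset$term_embeddings, graph, d_z = d_z,
                          epochs = ae_epochs, lr = ae_lr, seed = tc$seed)
  }
  E_full <- go_latents(dataset, embedding, term_ids_full, ae)
  E_train <- if (is.null(E_full)) NULL else
    E_full[train_terms, , drop = FALSE]

  trainval <- c(scenario$train, scenario$val)
  targets <- targets_matrix(scenario$train_annotations, trainval,
                            train_terms)
  model <- train_model(dataset$proteins[trainval], targets, E_train,
                       config = config, tc = tc,
                       val_proteins = scenario$val)

  zero_shot_possible <- length(held_out) > 0 && !is.null(E_full)
  pred_terms <- if (zero_shot_possible) term_ids_full else train_terms
  E_pred <- if (is.null(E_full)) NULL else
    E_full[pred_terms, , drop = FALSE]
  preds <- predict_proteins(model, dataset$proteins[scenario$test], E_pred)
  truth <- targets_matrix(scenario$test_annotations, scenario$test,
                          pred_terms)
  root_id <- graph$roots[[aspect]]
  report <- evaluate_predictions(preds, truth, exclude_roots = root_id)

  held_out_auc <- NULL
  control_auc <- NULL
  if (zero_shot_possible) {
    tab <- per_term_auc(preds, truth)
    held_out_auc <- tab[tab$term_id %in% held_out, , drop = FALSE]
    if (with_control && !is.null(scenario$control_definitions) &&
        embedding %in% c("combined", "textual")) {
      E_ctrl <- E_pred
      for (t in held_out) {
        x <- encode_text(scenario$control_definitions[[t]], dataset$encoder)
        E_ctrl[t, ] <- if (embedding == "combined") encode_term(x, ae) else x
      }
      preds_ctrl <- predict_proteins(model, dataset$proteins[scenario$test],
                                     E_ctrl)
      tab_ctrl <- per_term_auc(preds_ctrl, truth)
      control_auc <- tab_ctrl[tab_ctrl$term_id %in% held_out, , drop = FALSE]
    }
  }

  list(model = model, ae = ae, order = order_full, report = report,
       preds = preds, truth = truth, held_out_auc = held_out_auc,
       control_auc = control_auc, scenario = scenario, E_full = E_full,
       aspect = aspect, embedding = embedding,
       architecture = architecture, ordering = ordering)
}

#' Rollout localization report against planted windows
#'
#' For each requested (protein, term) pair with a recorded binding mask,
#' computes the attention-rollout residue profile and its AUROC against the
#' planted motif window.
#'
#' @param exp Result of [run_experiment()] (decoder or encoder
#'   architecture).
#' @param dataset The `synthetic_dataset`.
#' @param protein_ids Proteins to analyse (default: the test split).
#' @param terms Term filter (default: all terms with masks on those
#'   proteins).
#' @return Data frame: `protein_id`, `term_id`, `auroc`.
#' @export
rollout_report <- function(exp, dataset, protein_ids = exp$scenario$test,
                           terms = NULL) {
  if (exp$architecture == "mlp") {
    stop_hiergo("the MLP ablation has no cross-attention to roll out",
                class = "hiergo_config_error")
  }
  masks <- dataset$masks
  masks <- masks[masks$protein_id %in% protein_ids, , drop = FALSE]
  if (!is.null(terms)) {
    masks <- masks[masks$term_id %in% terms, , drop = FALSE]
  }
  pred_terms <- rownames(exp$E_full %||% matrix(ncol = 0, nrow = 0)) %||%
    exp$model$term_ids
  masks <- masks[masks$term_id %in% pred_terms, , drop = FALSE]
  rows <- list()
  for (pid in unique(masks$protein_id)) {
    X <- dataset$proteins[[pid]]
    E_pred <- if (is.null(exp$E_full)) NULL else
      exp$E_full[pred_terms, , drop = FALSE]
    fwd <- hg_forward(X, E_pred, exp$model$params, exp$model$config)
    R <- rollout_from_record(fwd$attn)
    m_p <- masks[masks$protein_id == pid, , drop = FALSE]
    for (j in seq_len(nrow(m_p))) {
      term <- m_p$term_id[j]
      prof <- R[match(term, pred_terms), ]
      mv <- mask_vector(m_p[j, , drop = FALSE], nrow(X))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, term_id = term,
        auroc = rollout_auroc(prof, mv), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||%
    data.frame(protein_id = character(), term_id = character(),
               auroc = numeric())
}
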