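# Attention-rollout residue attribution.
#
# Cross-attention weights indicate which residues each GO term attended to.
# Signals are aggregated across heads by averaging and across decoder
# layers by the recursion R(1) = Abar(1), R(l) = (A bar(l) + R(l-1)) / 2 --
# an equal weighting of the current layer and the accumulated score. Rows
# stay probability distributions over residues by convexity.

#' Head-averaged cross-attention at one decoder layer
#'
#' @param attn Attention record from [hg_forward()] (list over layers of
#'   lists over heads).
#' @param layer Decoder layer index.
#' @return T x L row-stochastic matrix.
#' @export
head_average <- function(attn, layer) {
  if (layer < 1L || layer > length(attn)) {
    stop_hiergo("no attention recorded for layer ", layer,
                class = "hiergo_validation_error")
  }
  Reduce(`+`, attn[[layer]]) / length(attn[[layer]])
}

#' Recursive attention rollout
#'
#' @param abar_list List of head-averaged T x L matrices, one per decoder
#'   layer in order.
#' @return The final rollout matrix R (T x L), with per-layer intermediates
#'   attached as attribute `layers`.
#' @export
attention_rollout <- function(abar_list) {
  if (length(abar_list) == 0L) {
    stop_hiergo("empty attention stack", class = "hiergo_validation_error")
  }
  dims <- dim(abar_list[[1]])
  for (A in abar_list) {
    if (!all(dim(A) == dims)) {
      stop_hiergo("attention matrices differ in shape",
                  class = "hiergo_validation_error")
    }
  }
  R <- abar_list[[1]]
  layers <- list(R)
  for (l in seq_along(abar_list)[-1]) {
    R <- (abar_list[[l]] + R) / 2
    layers[[l]] <- R
  }
  structure(R, layers = layers)
}

#' Rollout of a model's recorded cross-attention
#'
#' @param attn Attention record from [hg_forward()].
#' @return Rollout matrix as in [attention_rollout()].
#' @export
rollout_from_record <- function(attn) {
  attention_rollout(lapply(seq_along(attn), function(l) {
    head_average(attn, l)
  }))
}

#' Per-residue attention profile of one GO term
#'
#' @param R Rollout matrix (T x L, rows ordered by the term ordering).
#' @param term Term id.
#' @param order The `topo_order` the decoder ran with.
#' @param key_keep Logical residue mask; padding positions are dropped.
#' @return Numeric vector over real residues.
#' @export
residue_profile <- function(R, term, order, key_keep = NULL) {
  r <- R[topo_rank(order, term), ]
  if (!is.null(key_keep)) r <- r[key_keep]
  r
}

#' AUROC of an attention profile against a binding mask
#'
#' @param profile Per-residue scores.
#' @param mask Binary vector, 1 = known relevant residue (e.g. DNA-contact
#'   site). Must contain both classes.
#' @return AUROC in [0, 1] (ties get half credit).
#' @export
rollout_auroc <- function(profile, mask) {
  if (length(profile) != length(mask)) {
    stop_hiergo("profile and mask lengths differ",
                class = "hiergo_validation_error")
  }
  if (all(mask > 0) || all(mask <= 0)) {
    stop_hiergo("binding mask must contain both classes",
                class = "hiergo_validation_error")
  }
  roc_auc(profile, mask)
}

#' Read binding masks from BED-like TSV
#'
#' Columns: `protein_id`, `start`, `end` (0-based half-open residue
#' intervals), optionally `term_id`.
#'
#' @param path TSV path.
#' @return Data frame of intervals.
#' @export
read_binding_masks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop_hiergo("binding mask file must have columns protein_id, start, end",
                class = "hiergo_validation_error")
  }
  df
}

#' Expand interval masks to a per-residue binary vector
#'
#' @param intervals Data frame rows for one protein (`start`, `end`,
#'   0-based half-open).
#' @param length Protein length.
#' @return Binary vector of `length`.
#' @export
mask_vector <- function(intervals, length) {
  v <- integer(length)
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals$start[i] + 1L
    hi <- min(intervals$end[i], length)
    if (hi >= lo) v[lo:hi] <- 1L
  }
  v
}
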