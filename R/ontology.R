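# GO DAG operations: ancestor closure, true-path-rule propagation,
# topological orderings and zero-shot splits.

#' Transitive ancestor closure of a GO graph
#'
#' Computes, for every non-obsolete term, the set of all terms reachable by
#' following retained child-to-parent relations. Computed by dynamic
#' programming over a topological order, so it is exact transitive closure
#' (equal to per-node DFS reachability).
#'
#' @param graph A `go_graph`.
#' @param include_self If `TRUE` (convention used for ancestor-recovery
#'   training targets), each term is a member of its own ancestor set.
#' @return An object of class `ancestor_index`: list with `ancestors`
#'   (named list of id-sorted character vectors), `include_self`, and
#'   `term_ids` (all indexed ids, sorted).
#' @export
ancestor_index <- function(graph, include_self = FALSE) {
  ids <- active_terms(graph)
  order <- ids[order(topo_depth(graph, ids))]  # parents before children
  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (v in order) {
    ps <- graph$parents[[v]]
    anc[[v]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  if (include_self) {
    anc <- stats::setNames(lapply(ids, function(v) sort(c(v, anc[[v]]))), ids)
  }
  structure(list(ancestors = anc, include_self = include_self,
                 term_ids = ids),
            class = "ancestor_index")
}

# Longest-path depth from the aspect root (root = 0). Guarantees that a
# parent's depth is strictly smaller than every child's.
#' @noRd
topo_depth <- function(graph, ids = active_terms(graph)) {
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  visit <- function(v) {
    if (!is.na(depth[[v]])) return(depth[[v]])
    ps <- graph$parents[[v]]
    d <- if (length(ps) == 0L) 0 else 1 + max(vapply(ps, visit, 0))
    depth[[v]] <<- d
    d
  }
  for (v in ids) visit(v)
  depth
}

#' @export
print.ancestor_index <- function(x, ...) {
  cat("ancestor_index over", length(x$term_ids), "terms (include_self =",
      x$include_self, ")\n")
  invisible(x)
}

#' Propagate annotations by the true path rule
#'
#' A protein annotated with a term is implicitly annotated with every
#' ancestor of that term; propagation makes that explicit so annotation sets
#' are upward-closed under the ontology. The operation never removes
#' records and is idempotent.
#'
#' @param annotations Data frame with columns `protein_id` and `term_id`
#'   (an extra `aspect` column, if present, is recomputed from the index's
#'   graph terms by the caller if needed).
#' @param index An [ancestor_index()].
#' @return Annotation data frame, upward-closed, deduplicated and sorted,
#'   with attribute `propagated = TRUE`.
#' @export
propagate_true_path <- function(annotations, index) {
  check_annotations(annotations)
  unknown <- setdiff(unique(annotations$term_id), index$term_ids)
  if (length(unknown)) {
    stop_hiergo("annotation term ids missing from ancestor index: ",
                paste(utils::head(unknown, 10), collapse = ", "),
                class = "hiergo_validation_error")
  }
  by_protein <- split(annotations$term_id, annotations$protein_id)
  rows <- lapply(names(by_protein), function(p) {
    ts <- unique(by_protein[[p]])
    closed <- unique(c(ts, unlist(index$ancestors[ts], use.names = FALSE)))
    data.frame(protein_id = p, term_id = sort(closed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), term_id = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$protein_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "propagated") <- TRUE
  out
}

#' @noRd
check_annotations <- function(annotations) {
  if (!is.data.frame(annotations) ||
      !all(c("protein_id", "term_id") %in% names(annotations))) {
    stop_hiergo("annotations must be a data frame with columns ",
                "protein_id and term_id", class = "hiergo_validation_error")
  }
  invisible(TRUE)
}

#' Deterministic topological ordering of one subontology
#'
#' In `"hierarchical"` mode terms are ordered root-to-leaves by depth level
#' (the longest-path distance from the aspect root, so every parent strictly
#' precedes all of its children), with ties inside a level broken by
#' lexicographic term id. This is the breadth-first general-to-specific
#' ordering the causal decoder mask is built over. `"go_id"` mode is the
#' flat ablation: a plain lexicographic id sort that ignores the hierarchy.
#'
#' @param graph A `go_graph`.
#' @param aspect Which subontology to order (`"MF"`, `"BP"`, `"CC"`).
#' @param mode `"hierarchical"` or `"go_id"`.
#' @return Object of class `topo_order`: character vector of term ids in
#'   rank order with attributes `mode` and `aspect`.
#' @export
topological_order <- function(graph, aspect, mode = c("hierarchical", "go_id")) {
  mode <- match.arg(mode)
  if (!aspect %in% names(graph$roots)) {
    stop_hiergo("unknown aspect: ", aspect,
                class = "hiergo_validation_error")
  }
  ids <- active_terms(graph, aspect)
  disconnected <- ids[is.na(graph$terms$aspect[match(ids, graph$terms$id)])]
  if (length(disconnected)) {
    stop_hiergo("terms without a path to the aspect root: ",
                paste(disconnected, collapse = ", "),
                class = "hiergo_validation_error")
  }
  ordered <- if (mode == "go_id") {
    sort(ids)
  } else {
    depth <- topo_depth(graph, ids)
    ids[order(depth[ids], ids)]
  }
  structure(ordered, mode = mode, aspect = aspect, class = "topo_order")
}

#' Rank lookup for a topological order
#'
#' @param order A `topo_order`.
#' @param term_ids Term ids to rank.
#' @return Integer ranks (1-based).
#' @export
topo_rank <- function(order, term_ids) {
  r <- match(term_ids, unclass(order))
  if (anyNA(r)) {
    stop_hiergo("terms absent from ordering: ",
                paste(term_ids[is.na(r)], collapse = ", "),
                class = "hiergo_validation_error")
  }
  r
}

#' Build a zero-shot annotation split
#'
#' Removes every record naming a held-out term from the (unpropagated)
#' annotation table and only then applies the true path rule. Held-out
#' terms can therefore still appear in the propagated training table, but
#' only as ancestors reached from retained annotations, never via their own
#' removed records.
#'
#' @param annotations Unpropagated annotation data frame.
#' @param held_out_terms Character vector of term ids to hold out.
#' @param index An [ancestor_index()] covering the ontology.
#' @return List with `train` (propagated annotation table without the
#'   held-out associations) and `held_out` (the term id set).
#' @export
make_zero_shot_split <- function(annotations, held_out_terms, index) {
  check_annotations(annotations)
  if (isTRUE(attr(annotations, "propagated"))) {
    stop_hiergo("zero-shot splits must be built from unpropagated ",
                "annotations", class = "hiergo_validation_error")
  }
  missing <- setdiff(held_out_terms, index$term_ids)
  if (length(missing)) {
    stop_hiergo("held-out terms absent from ontology: ",
                paste(missing, collapse = ", "),
                class = "hiergo_validation_error")
  }
  kept <- annotations[!(annotations$term_id %in% held_out_terms), ,
                      drop = FALSE]
  list(train = propagate_true_path(kept, index),
       held_out = unique(held_out_terms))
}

#' Read protein-to-term annotations
#'
#' Accepts either the package's native GAF-like TSV (header row with columns
#' `protein_id`, `term_id` and optionally `aspect`) or GAF 2.x by column
#' position (column 2 = object id, column 5 = term id, column 9 = aspect;
#' `!` comment lines and evidence columns ignored).
#'
#' @param path TSV/GAF file path.
#' @return Data frame with columns `protein_id`, `term_id` (and `aspect`
#'   when available).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(c("protein_id", "term_id") %in% header)) {
    body <- fields[-1]
    get <- function(col) {
      j <- match(col, header)
      vapply(body, function(x) x[j] %||% NA_character_, "")
    }
    out <- data.frame(protein_id = get("protein_id"),
                      term_id = get("term_id"), stringsAsFactors = FALSE)
    if ("aspect" %in% header) out$aspect <- get("aspect")
  } else {
    aspect_map <- c(F = "MF", P = "BP", C = "CC")
    out <- data.frame(
      protein_id = vapply(fields, `[`, "", 2L),
      term_id = vapply(fields, `[`, "", 5L),
      aspect = unname(aspect_map[vapply(fields, `[`, "", 9L)]),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Write annotations as GAF-like TSV
#'
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  check_annotations(annotations)
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
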