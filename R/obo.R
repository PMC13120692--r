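# OBO parsing and construction of the GO DAG.
#
# The graph container is deliberately plain: a term table plus child->parent
# adjacency lists over the retained relations. Everything downstream
# (ancestor closure, orderings, propagation) works off this structure.

OBO_NAMESPACE_ASPECT <- c(
  molecular_function = "MF",
  biological_process = "BP",
  cellular_component = "CC"
)

#' Parse an OBO ontology into a GO DAG
#'
#' Reads an OBO 1.2/1.4 document stanza by stanza and builds a directed
#' acyclic graph of terms. Only `[Term]` stanzas are considered; fields used
#' are `id`, `name`, `namespace`, `def`, `is_a`, `relationship` and
#' `is_obsolete`. Obsolete terms are kept in the term table but carry no
#' edges and are excluded from ancestor indices and orderings.
#'
#' Edges are retained only for the requested relation labels (`is_a` and
#' `part_of` by default; regulates-type relations are dropped unless asked
#' for). Acyclicity is verified at parse time and each term is assigned to
#' the aspect (subontology) whose root it reaches; a term reaching more than
#' one root is rejected.
#'
#' @param obo Path to an OBO file, or a character vector of OBO lines.
#' @param retained_relations Relation labels that become edges.
#' @return An object of class `go_graph`: a list with elements
#'   `terms` (data.frame: id, name, aspect, obsolete), `definitions`
#'   (named character), `parents`/`children` (named lists of character
#'   vectors over non-obsolete terms), `edges` (data.frame: child, parent,
#'   relation) and `roots` (named character, aspect -> root id).
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "namespace: molecular_function",
#'          "[Term]", "id: T:2", "name: child", "is_a: T:1")
#' g <- parse_obo(obo)
#' g$roots
#' @export
parse_obo <- function(obo, retained_relations = c("is_a", "part_of")) {
  lines <- if (length(obo) == 1L && !grepl("\n", obo) && file.exists(obo)) {
    readLines(obo, warn = FALSE)
  } else {
    unlist(strsplit(obo, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0L) {
    stop_hiergo("no stanzas found in OBO input", class = "hiergo_parse_error")
  }
  stanza_ends <- c(stanza_starts[-1] - 1L, length(lines))
  is_term <- lines[stanza_starts] == "[Term]"

  terms <- list()
  for (k in which(is_term)) {
    body <- lines[seq(stanza_starts[k] + 1L, stanza_ends[k])]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    keys <- sub(":.*$", "", body)
    vals <- sub("^[^:]+:\\s*", "", body)
    vals <- sub("\\s+!.*$", "", vals)  # trailing comments

    id <- vals[match("id", keys)]
    if (is.na(id)) {
      stop_hiergo("[Term] stanza without id", class = "hiergo_parse_error")
    }
    rel_vals <- vals[keys == "relationship"]
    rel_split <- strsplit(rel_vals, "\\s+")
    parents <- data.frame(
      parent = c(vals[keys == "is_a"],
                 vapply(rel_split, function(x) x[2] %||% NA_character_, "")),
      relation = c(rep("is_a", sum(keys == "is_a")),
                   vapply(rel_split, `[`, "", 1L)),
      stringsAsFactors = FALSE
    )
    terms[[length(terms) + 1L]] <- list(
      id = id,
      name = vals[match("name", keys)],
      namespace = vals[match("namespace", keys)],
      def = vals[match("def", keys)],
      obsolete = identical(vals[match("is_obsolete", keys)], "true"),
      parents = parents
    )
  }

  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop_hiergo("duplicate term ids: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "),
                class = "hiergo_parse_error")
  }

  obsolete <- vapply(terms, `[[`, TRUE, "obsolete")
  defs <- vapply(terms, function(t) t$def %||% NA_character_, "")
  # OBO def fields look like: "text" [citation, citation]; keep the text.
  defs <- ifelse(is.na(defs), NA_character_, clean_obo_def(defs))
  names(defs) <- ids

  edges <- do.call(rbind, lapply(terms, function(t) {
    if (t$obsolete || nrow(t$parents) == 0L) return(NULL)
    keep <- t$parents$relation %in% retained_relations
    if (!any(keep)) return(NULL)
    data.frame(child = t$id, parent = t$parents$parent[keep],
               relation = t$parents$relation[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }

  unknown <- setdiff(edges$parent, ids)
  if (length(unknown)) {
    stop_hiergo("edges reference unknown terms: ",
                paste(utils::head(unknown, 5), collapse = ", "),
                class = "hiergo_parse_error")
  }
  # edges into obsolete parents are dropped (obsolete terms carry no edges)
  edges <- edges[!(edges$parent %in% ids[obsolete]), , drop = FALSE]

  active <- ids[!obsolete]
  parents <- split(edges$parent, factor(edges$child, levels = active))
  children <- split(edges$child, factor(edges$parent, levels = active))
  parents <- lapply(parents, function(p) sort(unique(p)))
  children <- lapply(children, function(p) sort(unique(p)))

  check_acyclic(active, parents)

  namespaces <- vapply(terms, function(t) t$namespace %||% NA_character_, "")
  names(namespaces) <- ids
  aspect <- assign_aspects(active, parents, namespaces)

  term_tab <- data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name %||% NA_character_, ""),
    aspect = aspect[ids],
    obsolete = obsolete,
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  roots <- active[lengths(parents[active]) == 0L]
  root_aspect <- aspect[roots]
  if (anyDuplicated(root_aspect)) {
    stop_hiergo("multiple roots within one aspect: ",
                paste(roots[duplicated(root_aspect) |
                              duplicated(root_aspect, fromLast = TRUE)],
                      collapse = ", "),
                class = "hiergo_structure_error")
  }
  roots <- stats::setNames(roots, root_aspect)

  structure(
    list(terms = term_tab, definitions = defs, parents = parents,
         children = children, edges = edges, roots = roots,
         retained_relations = retained_relations),
    class = "go_graph"
  )
}

#' @noRd
clean_obo_def <- function(def) {
  out <- sub('^\\s*"', "", def)
  out <- sub('"\\s*(\\[[^]]*\\])?\\s*$', "", out)
  out
}

# Kahn's algorithm; names a cycle member on failure.
#' @noRd
check_acyclic <- function(ids, parents) {
  indeg <- lengths(parents[ids])
  names(indeg) <- ids
  queue <- ids[indeg == 0L]
  seen <- 0L
  children <- invert_adjacency(parents, ids)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (c in children[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids)) {
    member <- ids[indeg > 0L][1L]
    stop_hiergo("ontology graph contains a directed cycle (e.g. through ",
                member, ")", class = "hiergo_structure_error")
  }
  invisible(TRUE)
}

#' @noRd
invert_adjacency <- function(adj, ids) {
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (v in ids) out[[v]] <- character()
  for (v in names(adj)) {
    for (p in adj[[v]]) out[[p]] <- c(out[[p]], v)
  }
  out
}

# Aspect = namespace of the unique reachable root. Terms reaching several
# roots are rejected; namespace labels on non-root terms are ignored.
#' @noRd
assign_aspects <- function(active, parents, namespaces) {
  roots <- active[lengths(parents[active]) == 0L]
  root_ns <- namespaces[roots]
  bad <- roots[is.na(root_ns) | !(root_ns %in% names(OBO_NAMESPACE_ASPECT))]
  if (length(bad)) {
    stop_hiergo("root term(s) without a recognized namespace: ",
                paste(bad, collapse = ", "), class = "hiergo_parse_error")
  }
  root_aspect <- OBO_NAMESPACE_ASPECT[root_ns]
  names(root_aspect) <- roots

  aspect <- stats::setNames(rep(NA_character_, length(namespaces)),
                            names(namespaces))
  memo <- new.env(parent = emptyenv())
  reach_roots <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    ps <- parents[[v]]
    r <- if (length(ps) == 0L) v else
      sort(unique(unlist(lapply(ps, reach_roots), use.names = FALSE)))
    memo[[v]] <- r
    r
  }
  for (v in active) {
    r <- reach_roots(v)
    if (length(r) > 1L) {
      stop_hiergo("term ", v, " reaches multiple subontology roots: ",
                  paste(r, collapse = ", "),
                  class = "hiergo_structure_error")
    }
    aspect[[v]] <- root_aspect[[r]]
  }
  aspect
}

#' @export
print.go_graph <- function(x, ...) {
  n_active <- sum(!x$terms$obsolete)
  cat("go_graph:", n_active, "active terms (",
      sum(x$terms$obsolete), "obsolete ),", nrow(x$edges), "edges\n")
  cat("roots:", paste(names(x$roots), x$roots, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Active (non-obsolete) term ids of a GO graph
#'
#' @param graph A `go_graph`.
#' @param aspect Optional aspect filter (`"MF"`, `"BP"` or `"CC"`).
#' @return Character vector of term ids, id-sorted.
#' @export
active_terms <- function(graph, aspect = NULL) {
  tt <- graph$terms[!graph$terms$obsolete, , drop = FALSE]
  if (!is.null(aspect)) tt <- tt[tt$aspect %in% aspect, , drop = FALSE]
  sort(tt$id)
}

#' Serialize a GO graph back to OBO
#'
#' Writes a minimal OBO 1.2 document (id, name, namespace, def, is_a /
#' relationship lines) sufficient to round-trip graphs produced by
#' [generate_ontology()].
#'
#' @param graph A `go_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  ns_of <- stats::setNames(names(OBO_NAMESPACE_ASPECT), OBO_NAMESPACE_ASPECT)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(graph$terms))) {
    row <- graph$terms[i, ]
    stanza <- c("[Term]", paste0("id: ", row$id), paste0("name: ", row$name))
    if (!is.na(row$aspect)) {
      stanza <- c(stanza, paste0("namespace: ", ns_of[[row$aspect]]))
    }
    def <- graph$definitions[[row$id]]
    if (!is.na(def)) stanza <- c(stanza, paste0('def: "', def, '" []'))
    if (row$obsolete) stanza <- c(stanza, "is_obsolete: true")
    e <- graph$edges[graph$edges$child == row$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      stanza <- c(stanza, if (e$relation[j] == "is_a") {
        paste0("is_a: ", e$parent[j])
      } else {
        paste0("relationship: ", e$relation[j], " ", e$parent[j])
      })
    }
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}
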