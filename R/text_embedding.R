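# Frozen sentence embeddings of GO term definitions.
#
# Real deployments plug in a sentence encoder (e.g. a biomedical SBERT) via
# the same interface; the package ships a deterministic hash encoder so the
# whole stack runs and is testable without any model download. Both produce
# mean-pooled token vectors, which is the pooling contract downstream code
# relies on.

#' Describe a text encoder
#'
#' @param name Encoder name. `"hash"` selects the built-in deterministic
#'   hash encoder; any other name requires `encode_tokens`, a function
#'   `(tokens, dim) -> token-by-dim matrix`, to be supplied (adapter hook
#'   for real sentence encoders).
#' @param dim Output embedding dimension `d_t`.
#' @param seed Seed for the hash encoder's token vectors.
#' @param encode_tokens Optional adapter function (see `name`).
#' @return A `text_encoder_spec` list (`name`, `dim`, `seed`,
#'   `pooling = "mean"`, `deterministic`).
#' @export
text_encoder_spec <- function(name = "hash", dim = 64L, seed = 1L,
                              encode_tokens = NULL) {
  if (dim < 8L) {
    stop_hiergo("encoder dimension must be >= 8",
                class = "hiergo_config_error")
  }
  if (name != "hash" && !is.function(encode_tokens)) {
    stop_hiergo("non-hash encoders need an encode_tokens adapter",
                class = "hiergo_config_error")
  }
  structure(list(name = name, dim = as.integer(dim), seed = as.integer(seed),
                 pooling = "mean",
                 deterministic = is.null(encode_tokens) || name == "hash",
                 encode_tokens = encode_tokens),
            class = "text_encoder_spec")
}

#' @noRd
tokenize_definition <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9:_]+")[[1]]
  toks[nzchar(toks)]
}

# FNV-1a over UTF-8 bytes, folded to a valid 31-bit R seed. Pure integer
# arithmetic via doubles so it is platform-stable.
#' @noRd
fnv1a_hash <- function(token, seed = 0L) {
  bytes <- as.integer(charToRaw(token))
  h <- (2166136261 + as.numeric(seed) * 16777619) %% 2147483647
  for (b in bytes) {
    h <- ((h + b) * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Deterministic hash embedding of one text
#'
#' Stand-in for a pretrained sentence encoder: each token gets a unit-norm
#' pseudo-random vector seeded by a stable hash of the token (and the
#' encoder seed), and the text embedding is the mean over token vectors.
#' Identical texts embed identically on any platform; cosine similarity
#' grows with token overlap.
#'
#' @param text Non-empty character scalar.
#' @param dim Embedding dimension (>= 8).
#' @param seed Encoder seed.
#' @return Numeric vector of length `dim`.
#' @export
hash_test_encoder <- function(text, dim = 64L, seed = 1L) {
  m <- hash_token_matrix(text, dim, seed)
  colMeans(m)
}

#' @noRd
hash_token_matrix <- function(text, dim, seed) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop_hiergo("cannot embed empty text", class = "hiergo_validation_error")
  }
  if (dim < 8L) {
    stop_hiergo("encoder dimension must be >= 8",
                class = "hiergo_config_error")
  }
  toks <- tokenize_definition(text)
  if (length(toks) == 0L) {
    stop_hiergo("text contains no tokens", class = "hiergo_validation_error")
  }
  rows <- vapply(toks, function(tok) {
    with_seed(fnv1a_hash(tok, seed), {
      v <- stats::rnorm(dim)
      v / sqrt(sum(v^2))
    })
  }, numeric(dim))
  t(rows)
}

#' Embed GO term definitions into a frozen matrix
#'
#' Applies a text encoder to each term's definition (falling back to the
#' term name when the definition is missing) and stacks the mean-pooled
#' vectors into one matrix, row order = id-sorted terms. The matrix is
#' flagged frozen: downstream training treats it as fixed input and the
#' package's fitting routines verify its checksum is unchanged.
#'
#' @param graph A `go_graph` (obsolete terms are skipped).
#' @param encoder A [text_encoder_spec()].
#' @param term_ids Optional subset of term ids.
#' @return A `term_embedding` matrix (terms x dim, rownames = term ids)
#'   with attributes `frozen = TRUE` and `encoder` name/dim/seed.
#' @export
embed_definitions <- function(graph, encoder = text_encoder_spec(),
                              term_ids = NULL) {
  ids <- sort(term_ids %||% active_terms(graph))
  defs <- graph$definitions[ids]
  names_ <- graph$terms$name[match(ids, graph$terms$id)]
  texts <- ifelse(is.na(defs) | !nzchar(defs), names_, defs)
  bad <- ids[is.na(texts) | !nzchar(texts)]
  if (length(bad)) {
    stop_hiergo("terms with neither definition nor name: ",
                paste(bad, collapse = ", "),
                class = "hiergo_validation_error")
  }
  X <- t(vapply(texts, function(txt) encode_text(txt, encoder),
                numeric(encoder$dim)))
  rownames(X) <- ids
  if (any(!is.finite(X))) {
    stop_hiergo("non-finite entries in embedding matrix",
                class = "hiergo_validation_error")
  }
  structure(X, frozen = TRUE,
            encoder = encoder[c("name", "dim", "seed")],
            class = c("term_embedding", "matrix", "array"))
}

#' Embed a single free text with an encoder spec
#'
#' @param text Character scalar.
#' @param encoder A [text_encoder_spec()].
#' @return Numeric vector of length `encoder$dim` (mean-pooled).
#' @export
encode_text <- function(text, encoder) {
  if (encoder$name == "hash") {
    hash_test_encoder(text, encoder$dim, encoder$seed)
  } else {
    toks <- tokenize_definition(text)
    m <- encoder$encode_tokens(toks, encoder$dim)
    if (!is.matrix(m) || ncol(m) != encoder$dim) {
      stop_hiergo("encoder adapter returned wrong dimension",
                  class = "hiergo_config_error")
    }
    colMeans(m)
  }
}

#' Write a term embedding matrix as TSV
#'
#' Plain-text export: header row of dimension labels, one id-keyed row per
#' term.
#' @param embeddings A `term_embedding` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_embeddings <- function(embeddings, path) {
  df <- data.frame(term_id = rownames(embeddings),
                   as.data.frame(unclass(embeddings), row.names = NULL),
                   check.names = FALSE)
  names(df)[-1] <- paste0("d", seq_len(ncol(embeddings)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term embedding matrix written by [write_term_embeddings()]
#'
#' @param path TSV path.
#' @return A `term_embedding` matrix.
#' @export
read_term_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$term_id
  structure(X, frozen = TRUE, class = c("term_embedding", "matrix", "array"))
}
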