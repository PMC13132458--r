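# Encoding module: SMILES -> pooled drug vector, disease texts -> fused and
# projected disease vector.
#
# Drugs: an adapter emits a token-level embedding matrix (<= 512 rows); a
# two-layer tanh MLP scores each token and a stabilized softmax turns scores
# into pooling weights, so the drug vector is a learned convex combination of
# its token embeddings. Diseases: each available text field (name, synonyms,
# definition) is encoded to a fixed-width vector, the fields are combined by
# a normalized weighted average, and the result is projected to a compact
# space by a seeded linear map.

#' Encode a drug's SMILES string into a token embedding matrix
#'
#' @param record a list or one-row data.frame with `drug_id` and `smiles`.
#' @param enc a `dda_adapter`.
#' @return an L x token_dim numeric matrix, L <= 512, rows in token order.
#' @export
encode_drug_tokens <- function(record, enc) {
  stopifnot(inherits(enc, "dda_adapter"))
  record <- as.list(record)
  if (is.null(record$smiles) || !nzchar(record$smiles)) {
    stop(sprintf("empty SMILES for drug '%s'", record$drug_id %||% "<unknown>"),
         call. = FALSE)
  }
  M <- tryCatch(
    enc$encode_drug(record),
    error = function(e) {
      stop(sprintf("encoder failure for drug '%s': %s",
                   record$drug_id %||% "<unknown>", conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (!is_finite_matrix(M)) stop("adapter returned non-finite token matrix", call. = FALSE)
  if (nrow(M) > MAX_TOKENS) M <- M[seq_len(MAX_TOKENS), , drop = FALSE]
  M
}

#' Initialize attention-pooling parameters
#'
#' Two-layer feedforward scorer: `e_j = W2 tanh(W1 m_j + b1) + b2`. Weights
#' are drawn from seeded scaled Gaussians; biases start at zero.
#'
#' @param d_tok token embedding width.
#' @param h hidden width of the scoring MLP (default 128).
#' @param seed integer seed.
#' @return an object of class `attn_pool_params`.
#' @export
attn_pool_params <- function(d_tok, h = 128L, seed = 1L) {
  stopifnot(d_tok >= 1, h >= 1)
  p <- with_seed(derive_seed(seed, 21L), list(
    W1 = matrix(stats::rnorm(h * d_tok, sd = 1 / sqrt(d_tok)), h, d_tok),
    b1 = numeric(h),
    W2 = matrix(stats::rnorm(h, sd = 1 / sqrt(h)), 1L, h),
    b2 = 0
  ))
  structure(p, class = "attn_pool_params")
}

#' Compute per-token attention scores
#'
#' @param M an L x d_tok token matrix.
#' @param P `attn_pool_params`.
#' @return numeric vector of L scores.
#' @export
attention_scores <- function(M, P) {
  stopifnot(inherits(P, "attn_pool_params"))
  M <- as.matrix(M)
  if (ncol(M) != ncol(P$W1)) {
    stop(sprintf("attention shape mismatch: tokens have width %d, W1 expects %d",
                 ncol(M), ncol(P$W1)), call. = FALSE)
  }
  H <- tanh(M %*% t(P$W1) + matrix(P$b1, nrow(M), length(P$b1), byrow = TRUE))
  drop(H %*% t(P$W2)) + P$b2
}

#' Pool a token matrix into a drug-level vector by softmax attention
#'
#' Weights use max-subtracted softmax for numerical stability; the pooled
#' vector is the weight-averaged token embedding and therefore lies in the
#' convex hull of the token rows.
#'
#' @param M an L x d_tok token matrix (L >= 1).
#' @param P `attn_pool_params`, or `NULL` for uniform (mean) pooling.
#' @return a list of class `pooled_drug` with `values` (d_tok vector) and
#'   `attn_weights` (L vector summing to 1).
#' @export
attention_pool <- function(M, P = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 1L) stop("token matrix must have at least one row", call. = FALSE)
  if (is.null(P)) {
    w <- rep(1 / nrow(M), nrow(M))
  } else {
    e <- attention_scores(M, P)
    if (any(!is.finite(e))) stop("non-finite attention scores", call. = FALSE)
    z <- exp(e - max(e))
    w <- z / sum(z)
  }
  structure(list(values = drop(crossprod(M, w)), attn_weights = w),
            class = "pooled_drug")
}

#' Encode one disease text field
#'
#' Empty text yields the adapter's defined empty-text vector (all zeros for
#' the offline adapters); this is logged as a message, not an error.
#'
#' @param text character scalar.
#' @param enc a `dda_adapter`.
#' @return numeric vector of length `enc$text_dim`.
#' @export
encode_disease_field <- function(text, enc) {
  stopifnot(inherits(enc, "dda_adapter"))
  if (is.na(text)) text <- ""
  v <- enc$encode_text(text)
  if (any(!is.finite(v))) stop("adapter returned non-finite text vector", call. = FALSE)
  v
}

#' Construct field-fusion weights
#'
#' @param name,synonymous,definition nonnegative field weights, not all zero.
#' @return an object of class `field_weights`.
#' @export
field_weights <- function(name = 1, synonymous = 1, definition = 1) {
  w <- c(name = name, synonymous = synonymous, definition = definition)
  if (any(w < 0) || any(!is.finite(w))) {
    stop("field weights must be finite and nonnegative", call. = FALSE)
  }
  if (sum(w) <= 0) stop("field weights must not all be zero", call. = FALSE)
  structure(w, class = "field_weights")
}

#' Fuse per-field disease vectors by normalized weighted average
#'
#' Missing fields (`NULL` entries) are dropped and the weights renormalized
#' over the fields that are present.
#'
#' @param vs named list of per-field vectors (`name`, `synonymous`,
#'   `definition`); absent fields may be `NULL`.
#' @param w a [field_weights()] object (or named nonnegative vector).
#' @return the fused vector.
#' @export
fuse_fields <- function(vs, w = field_weights()) {
  fields <- names(vs)[!vapply(vs, is.null, logical(1))]
  if (length(fields) == 0L) stop("at least one field must be present", call. = FALSE)
  wv <- as.numeric(w[fields])
  if (any(is.na(wv))) stop("weights missing for fields: ",
                           paste(fields[is.na(wv)], collapse = ", "), call. = FALSE)
  if (sum(wv) <= 0) stop("all present-field weights are zero", call. = FALSE)
  acc <- 0
  for (i in seq_along(fields)) acc <- acc + wv[i] * vs[[fields[i]]]
  acc / sum(wv)
}

#' Initialize the disease projection map
#'
#' Seeded random linear map from the fused-text width to a compact space
#' (default 768 -> 128).
#'
#' @param in_dim input width.
#' @param out_dim output width (default 128).
#' @param seed integer seed.
#' @return an object of class `disease_projection`.
#' @export
disease_projection <- function(in_dim, out_dim = 128L, seed = 1L) {
  W <- with_seed(derive_seed(seed, 22L),
                 matrix(stats::rnorm(in_dim * out_dim, sd = 1 / sqrt(in_dim)),
                        in_dim, out_dim))
  structure(list(W = W, in_dim = as.integer(in_dim), out_dim = as.integer(out_dim)),
            class = "disease_projection")
}

#' Project a fused disease vector
#'
#' @param fused fused-text vector.
#' @param map a [disease_projection()].
#' @return a list of class `disease_vector` with `fused` and `projected`.
#' @export
project_disease <- function(fused, map) {
  stopifnot(inherits(map, "disease_projection"))
  if (length(fused) != map$in_dim) {
    stop(sprintf("projection expects length %d, got %d", map$in_dim, length(fused)),
         call. = FALSE)
  }
  structure(list(fused = fused, projected = drop(fused %*% map$W)),
            class = "disease_vector")
}

# ---- batch helpers -------------------------------------------------------

#' Encode and pool all drugs in a table
#'
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param enc a `dda_adapter`.
#' @param pool `attn_pool_params` or `NULL` for mean pooling.
#' @return matrix (n_drugs x token_dim) with drug_id rownames; pooling
#'   weights attached as attribute `attn_weights` (named list).
#' @export
encode_drugs <- function(drugs, enc, pool = NULL) {
  n <- nrow(drugs)
  out <- matrix(0, n, enc$token_dim, dimnames = list(drugs$drug_id, NULL))
  wts <- vector("list", n)
  names(wts) <- drugs$drug_id
  for (i in seq_len(n)) {
    M <- encode_drug_tokens(drugs[i, ], enc)
    p <- attention_pool(M, pool)
    out[i, ] <- p$values
    wts[[i]] <- p$attn_weights
  }
  attr(out, "attn_weights") <- wts
  out
}

#' Encode, fuse and project all diseases in a table
#'
#' Fields that are empty strings are treated as absent and dropped from the
#' fusion for that disease.
#'
#' @param diseases data.frame with `disease_id`, `name`, `synonymous`,
#'   `definition`.
#' @param enc a `dda_adapter`.
#' @param w [field_weights()].
#' @param map a [disease_projection()] matching `enc$text_dim`, or `NULL` to
#'   create one from `seed`.
#' @param seed seed used when `map` is `NULL`.
#' @return list with `fused` (n x text_dim) and `projected` (n x out_dim)
#'   matrices, disease_id rownames, and the `projection` used.
#' @export
encode_diseases <- function(diseases, enc, w = field_weights(), map = NULL, seed = 1L) {
  if (is.null(map)) map <- disease_projection(enc$text_dim, seed = seed)
  n <- nrow(diseases)
  fused <- matrix(0, n, enc$text_dim, dimnames = list(diseases$disease_id, NULL))
  projected <- matrix(0, n, map$out_dim, dimnames = list(diseases$disease_id, NULL))
  for (i in seq_len(n)) {
    vs <- list()
    for (f in c("name", "synonymous", "definition")) {
      txt <- diseases[[f]][i]
      if (!is.na(txt) && nzchar(txt)) vs[[f]] <- encode_disease_field(txt, enc)
    }
    dv <- project_disease(fuse_fields(vs, w), map)
    fused[i, ] <- dv$fused
    projected[i, ] <- dv$projected
  }
  list(fused = fused, projected = projected, projection = map)
}

#' Export per-token attention weights to TSV
#'
#' Writes columns `drug_id`, `token_index`, `token_text`, `weight` for each
#' drug, using the adapter's tokenizer for token texts.
#'
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param enc a `dda_adapter`.
#' @param pool `attn_pool_params` (or `NULL` for uniform weights).
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_attention_weights <- function(drugs, enc, pool, path) {
  rows <- vector("list", nrow(drugs))
  for (i in seq_len(nrow(drugs))) {
    M <- encode_drug_tokens(drugs[i, ], enc)
    p <- attention_pool(M, pool)
    toks <- enc$tokenize(drugs$smiles[i])
    L <- nrow(M)
    if (length(toks) != L) toks <- rep_len(toks, L)
    rows[[i]] <- data.frame(
      drug_id = drugs$drug_id[i], token_index = seq_len(L),
      token_text = toks, weight = p$attn_weights,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
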