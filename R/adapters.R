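# Encoder adapters: pluggable back-ends that turn strings into embeddings.
#
# Real deployments plug in pretrained transformer encoders (a SMILES language
# model emitting 384-dimensional token embeddings and a biomedical text
# encoder emitting a 768-dimensional first-position vector). The adapters
# shipped here are fully offline:
#   * mock-hash    — deterministic pseudo-random embeddings keyed on the input
#                    string; carries no association signal by construction.
#   * oracle-latent — embeds the ground-truth latents of a synthetic dataset,
#                    so the planted signal is recoverable downstream.
#   * one-hot      — entity-identity indicator vectors (ablation tier).

MAX_TOKENS <- 512L

#' Create a hash-based mock encoder adapter
#'
#' Tokenizes character-by-character and emits, per token, unit-variance
#' Gaussian pseudo-random entries seeded from a stable digest of the full
#' input string, the token position and the token itself. Identical inputs
#' give bitwise-identical output; the embeddings carry no chemical or
#' semantic signal.
#'
#' @param token_dim width of drug token embeddings (default 384).
#' @param text_dim width of text vectors (default 768).
#' @return an object of class `dda_adapter`.
#' @export
adapter_mock_hash <- function(token_dim = 384L, text_dim = 768L) {
  hash_vec <- function(string, dim, salt) {
    if (!nzchar(string)) return(numeric(dim))
    with_seed(derive_seed(hash_string(string), salt), stats::rnorm(dim))
  }
  enc <- list(
    kind = "mock-hash",
    token_dim = as.integer(token_dim),
    text_dim = as.integer(text_dim),
    encode_drug = function(record) {
      smiles <- record$smiles
      chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
      L <- min(length(chars), MAX_TOKENS)
      chars <- chars[seq_len(L)]
      base <- hash_string(smiles)
      M <- matrix(0, nrow = L, ncol = token_dim)
      for (j in seq_len(L)) {
        M[j, ] <- with_seed(
          derive_seed(base, j, utf8ToInt(chars[j])),
          stats::rnorm(token_dim)
        )
      }
      M
    },
    encode_text = function(text) hash_vec(substr(text, 1L, MAX_TOKENS), text_dim, 2L),
    tokenize = function(string) {
      chars <- strsplit(string, "", fixed = TRUE)[[1]]
      chars[seq_len(min(length(chars), MAX_TOKENS))]
    }
  )
  structure(enc, class = "dda_adapter")
}

#' Create an oracle adapter over a synthetic dataset
#'
#' Embeds each entity's ground-truth latent through a fixed seeded linear map
#' and adds independent Gaussian noise, so attention pooling (drugs) or field
#' fusion (diseases) can recover the latent. Disease field texts are resolved
#' back to their entity by exact string lookup.
#'
#' @param dataset a `synth_dataset` from [generate_benchmark()].
#' @param noise_sd per-entry Gaussian noise SD (default: the dataset's
#'   configured `noise_sd`).
#' @param seed adapter seed controlling the embedding maps and noise.
#' @param token_dim,text_dim embedding widths (defaults 384 and 768).
#' @return an object of class `dda_adapter`.
#' @export
adapter_oracle <- function(dataset, noise_sd = NULL, seed = 1L,
                           token_dim = 384L, text_dim = 768L) {
  stopifnot(inherits(dataset, "synth_dataset"))
  noise_sd <- noise_sd %||% dataset$config$noise_sd
  k <- ncol(dataset$U)
  E_drug <- with_seed(derive_seed(seed, 11L),
                      matrix(stats::rnorm(k * token_dim, sd = 1 / sqrt(k)), k, token_dim))
  E_dis <- with_seed(derive_seed(seed, 12L),
                     matrix(stats::rnorm(k * text_dim, sd = 1 / sqrt(k)), k, text_dim))

  drug_idx <- stats::setNames(seq_len(nrow(dataset$drugs)), dataset$drugs$drug_id)
  # Disease field texts are unique per (disease, field); map text -> latent row.
  text_map <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dataset$diseases))) {
    for (f in c("name", "synonymous", "definition")) {
      txt <- dataset$diseases[[f]][i]
      if (nzchar(txt)) assign(txt, c(i = i, f = match(f, c("name", "synonymous", "definition"))), envir = text_map)
    }
  }

  enc <- list(
    kind = "oracle-latent",
    token_dim = as.integer(token_dim),
    text_dim = as.integer(text_dim),
    noise_sd = noise_sd,
    encode_drug = function(record) {
      idx <- drug_idx[[record$drug_id]]
      if (is.null(idx)) {
        stop(sprintf("oracle adapter: unknown drug '%s'", record$drug_id), call. = FALSE)
      }
      L <- min(nchar(record$smiles), MAX_TOKENS)
      base <- drop(dataset$U[idx, , drop = FALSE] %*% E_drug)
      M <- matrix(base, nrow = L, ncol = token_dim, byrow = TRUE)
      if (noise_sd > 0) {
        M <- M + with_seed(derive_seed(seed, 1L, idx),
                           matrix(stats::rnorm(L * token_dim, sd = noise_sd), L, token_dim))
      }
      M
    },
    encode_text = function(text) {
      if (!nzchar(text)) return(numeric(text_dim))
      key <- substr(text, 1L, MAX_TOKENS)
      hit <- if (exists(key, envir = text_map, inherits = FALSE)) get(key, envir = text_map) else NULL
      if (is.null(hit)) stop("oracle adapter: unknown disease text", call. = FALSE)
      v <- drop(dataset$V[hit[["i"]], , drop = FALSE] %*% E_dis)
      if (noise_sd > 0) {
        v <- v + with_seed(derive_seed(seed, 2L, hit[["i"]], hit[["f"]]),
                           stats::rnorm(text_dim, sd = noise_sd))
      }
      v
    },
    tokenize = function(string) {
      chars <- strsplit(string, "", fixed = TRUE)[[1]]
      chars[seq_len(min(length(chars), MAX_TOKENS))]
    }
  )
  structure(enc, class = "dda_adapter")
}

#' Create a one-hot entity-identity adapter
#'
#' Drugs map to a single-token matrix holding the drug's indicator vector;
#' disease texts map to the disease's indicator vector. Used for the
#' one-hot ablation tier: features identify entities but carry no content.
#'
#' @param dataset a `synth_dataset` (provides the entity universe).
#' @return an object of class `dda_adapter`.
#' @export
adapter_onehot <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  nd <- nrow(dataset$drugs)
  ni <- nrow(dataset$diseases)
  drug_idx <- stats::setNames(seq_len(nd), dataset$drugs$drug_id)
  text_map <- new.env(parent = emptyenv())
  for (i in seq_len(ni)) {
    for (f in c("name", "synonymous", "definition")) {
      txt <- dataset$diseases[[f]][i]
      if (nzchar(txt)) assign(txt, i, envir = text_map)
    }
  }
  enc <- list(
    kind = "one-hot",
    token_dim = nd,
    text_dim = ni,
    encode_drug = function(record) {
      idx <- drug_idx[[record$drug_id]]
      if (is.null(idx)) stop(sprintf("one-hot adapter: unknown drug '%s'", record$drug_id), call. = FALSE)
      M <- matrix(0, nrow = 1L, ncol = nd)
      M[1L, idx] <- 1
      M
    },
    encode_text = function(text) {
      v <- numeric(ni)
      if (!nzchar(text)) return(v)
      key <- substr(text, 1L, MAX_TOKENS)
      if (!exists(key, envir = text_map, inherits = FALSE)) {
        stop("one-hot adapter: unknown disease text", call. = FALSE)
      }
      v[get(key, envir = text_map)] <- 1
      v
    },
    tokenize = function(string) "<entity>"
  )
  structure(enc, class = "dda_adapter")
}

#' @export
print.dda_adapter <- function(x, ...) {
  cat(sprintf("<dda_adapter: %s | token_dim=%d, text_dim=%d>\n",
              x$kind, x$token_dim, x$text_dim))
  invisible(x)
}
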