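# Synthetic benchmark generator.
#
# Emulates the structure of a curated drug-disease association benchmark:
# a sparse bipartite association table driven by a low-rank latent signal,
# SMILES-like drug strings from a small guaranteed-valid grammar, and
# templated multi-field disease texts with category labels. Ground-truth
# latents are recorded so oracle adapters can expose a recoverable signal.

#' Synthetic benchmark configuration
#'
#' @param n_drugs,n_diseases entity counts.
#' @param latent_dim latent factor dimension (default 8).
#' @param target_density expected fraction of positive pairs, in (0, 1).
#' @param noise_sd encoder noise SD recorded for the oracle adapters; also
#'   sets the floor on category centroid separation (>= 3 * noise_sd).
#' @param n_categories disease categories (default 6, mirroring six primary
#'   disease classes used for clustering diagnostics).
#' @param within_sd within-category latent spread (default 0.5).
#' @param latent_scale multiplier on the latent factors; 0 suppresses the
#'   association signal entirely (every pair then has probability
#'   `target_density`).
#' @param seed integer seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 200L, n_diseases = 150L, latent_dim = 8L,
                         target_density = 0.05, noise_sd = 0.3,
                         n_categories = 6L, within_sd = 0.5, latent_scale = 1,
                         seed = 0L) {
  stopifnot(target_density > 0, target_density < 1, latent_dim >= 1,
            n_categories >= 1)
  structure(list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
                 latent_dim = as.integer(latent_dim), target_density = target_density,
                 noise_sd = noise_sd, n_categories = as.integer(n_categories),
                 within_sd = within_sd, latent_scale = latent_scale,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# SMILES-like string from a tiny guaranteed-valid grammar: a chain of atoms
# with optional short branches and at most one aromatic ring.
random_smiles <- function() {
  atoms <- c("C", "C", "C", "N", "O", "S", "F")
  n <- sample(8:36, 1L)
  parts <- character(0)
  i <- 0L
  ring_used <- FALSE
  while (i < n) {
    if (!ring_used && stats::runif(1) < 0.15) {
      parts <- c(parts, "c1ccccc1")
      ring_used <- TRUE
      i <- i + 6L
    } else if (stats::runif(1) < 0.15 && i > 0L) {
      parts <- c(parts, paste0("(", paste(sample(atoms, sample(1:2, 1L), replace = TRUE),
                                          collapse = ""), ")"))
      i <- i + 1L
    } else {
      parts <- c(parts, sample(atoms, 1L))
      i <- i + 1L
    }
  }
  paste(parts, collapse = "")
}

category_vocab <- function(k) {
  terms <- c("infection", "neoplasm", "neuropathy", "carditis", "dermatosis",
             "syndrome", "myopathy", "nephropathy", "hepatopathy", "arthritis")
  rep_len(terms, k)
}

#' Generate a synthetic drug-disease benchmark
#'
#' Drug latents are standard normal; disease latents sit around one of
#' `n_categories` centroids placed on scaled coordinate axes (pairwise
#' separation at least `3 * noise_sd`). Each pair is positive independently
#' with probability `plogis(u . v + b)`, where the bias `b` is solved by
#' bisection so the expected density equals `target_density`.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `synth_dataset`: `drugs`, `diseases` (with
#'   `category`), `pairs` (positives), latents `U`, `V`, bias `b`, `config`.
#' @export
generate_benchmark <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    k <- cfg$latent_dim
    U <- matrix(stats::rnorm(cfg$n_drugs * k), cfg$n_drugs, k) * cfg$latent_scale
    categories <- sample.int(cfg$n_categories, cfg$n_diseases, replace = TRUE)
    sep <- max(3 * cfg$noise_sd, 3)
    centroids <- matrix(0, cfg$n_categories, k)
    for (g in seq_len(cfg$n_categories)) {
      # axes reused with growing magnitude keep pairwise separation >= sep
      centroids[g, ((g - 1L) %% k) + 1L] <- sep * (1 + (g - 1L) %/% k)
    }
    V <- (centroids[categories, , drop = FALSE] +
            matrix(stats::rnorm(cfg$n_diseases * k, sd = cfg$within_sd),
                   cfg$n_diseases, k)) * cfg$latent_scale

    logits <- U %*% t(V)
    f <- function(b) mean(stats::plogis(logits + b)) - cfg$target_density
    lo <- -60; hi <- 60
    if (f(lo) > 0 || f(hi) < 0) stop("density bisection failed to bracket", call. = FALSE)
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    b <- (lo + hi) / 2

    P <- stats::plogis(logits + b)
    A <- matrix(stats::rbinom(length(P), 1L, P), nrow(P), ncol(P))

    smiles <- character(cfg$n_drugs)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(cfg$n_drugs)) {
      repeat {
        s <- random_smiles()
        if (!exists(s, envir = seen, inherits = FALSE)) {
          assign(s, TRUE, envir = seen)
          smiles[i] <- s
          break
        }
      }
    }
    drugs <- data.frame(drug_id = sprintf("DR%04d", seq_len(cfg$n_drugs)),
                        smiles = smiles, stringsAsFactors = FALSE)

    vocab <- category_vocab(cfg$n_categories)
    dis_id <- sprintf("DI%04d", seq_len(cfg$n_diseases))
    name <- sprintf("%s disorder %s", vocab[categories], dis_id)
    synonymous <- ifelse(stats::runif(cfg$n_diseases) < 0.8,
                         sprintf("chronic %s %s; %s variant", vocab[categories],
                                 tolower(dis_id), vocab[categories]),
                         "")
    definition <- ifelse(stats::runif(cfg$n_diseases) < 0.8,
                         sprintf("A condition of the %s class, presenting as %s with progressive course (%s).",
                                 vocab[categories], vocab[categories], dis_id),
                         "")
    diseases <- data.frame(disease_id = dis_id, name = name,
                           synonymous = synonymous, definition = definition,
                           category = categories, stringsAsFactors = FALSE)

    pos <- which(A == 1L, arr.ind = TRUE)
    pairs <- data.frame(drug_id = drugs$drug_id[pos[, 1L]],
                        disease_id = diseases$disease_id[pos[, 2L]],
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$drug_id, pairs$disease_id), , drop = FALSE]
    rownames(pairs) <- NULL

    rownames(U) <- drugs$drug_id
    rownames(V) <- diseases$disease_id
    structure(list(drugs = drugs, diseases = diseases, pairs = pairs,
                   U = U, V = V, b = b, config = cfg),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset: %d drugs x %d diseases, %d positives (density %.4f)>\n",
              nrow(x$drugs), nrow(x$diseases), nrow(x$pairs),
              nrow(x$pairs) / (nrow(x$drugs) * nrow(x$diseases))))
  invisible(x)
}

#' Write a synthetic dataset to CSV tables plus a ground-truth JSON
#'
#' Emits `drugs.csv`, `diseases.csv`, `associations.csv` (the formats the
#' readers accept) and `ground_truth.json` with latents, categories and the
#' density bias.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  utils::write.csv(dataset$diseases[, c("disease_id", "name", "synonymous", "definition")],
                   file.path(dir, "diseases.csv"), row.names = FALSE)
  utils::write.csv(dataset$pairs, file.path(dir, "associations.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(format = "ddapred-ground-truth", version = 1L,
         b = dataset$b,
         categories = stats::setNames(as.list(dataset$diseases$category),
                                      dataset$diseases$disease_id),
         U = apply(dataset$U, 1L, identity, simplify = FALSE),
         V = apply(dataset$V, 1L, identity, simplify = FALSE),
         config = unclass(dataset$config)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
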