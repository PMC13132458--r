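# Shared fixtures and independent brute-force oracles.

# Small benchmark used across module tests.
tiny_dataset <- function(seed = 1L) {
  generate_benchmark(synth_config(n_drugs = 60L, n_diseases = 40L, latent_dim = 6L,
                                  target_density = 0.08, noise_sd = 0.3, seed = seed))
}

# Mid-size benchmark for pipeline-level diagnostics (cold-start ordering,
# noise trend, null runs).
diag_dataset <- function(seed = 1L) {
  generate_benchmark(synth_config(n_drugs = 120L, n_diseases = 90L, latent_dim = 8L,
                                  target_density = 0.06, noise_sd = 0.3, seed = seed))
}

# Scaled pipeline configuration matching diag_dataset-sized problems.
diag_config <- function(adapter, seed = 1L, noise = NULL) {
  pipeline_config(adapter,
                  enhancer = enhancer_config(proj_dim = 64L, epochs = 25L,
                                             batch_size = 128L),
                  forest = forest_config(n_estimators = 120L),
                  disease_proj_dim = 64L, noise = noise, seed = seed)
}

diag_oracle <- function(ds, seed = 1L) {
  adapter_oracle(ds, seed = derive_seed(seed, 3L), token_dim = 96L, text_dim = 192L)
}

run_diag <- function(seed, mode = "cv5", rho = NULL, adapter = NULL) {
  ds <- diag_dataset(seed)
  ad <- adapter %||% diag_oracle(ds, seed)
  ns <- if (!is.null(rho) && rho > 0) noise_spec(rho, seed = derive_seed(seed, 4L)) else NULL
  pc <- diag_config(ad, seed = seed, noise = ns)
  pairs <- build_labeled_pairs(ds, seed = derive_seed(seed, 5L))
  data <- list(drugs = ds$drugs, diseases = ds$diseases, pairs = pairs)
  split <- if (mode == "cv5") {
    make_cv_folds(pairs, seed = derive_seed(seed, 8L))
  } else {
    make_coldstart_split(pairs, mode = mode, seed = derive_seed(seed, 9L))
  }
  run_cv_experiment(data, pc, split)
}

# ---- independent oracles --------------------------------------------------

# Unstabilized InfoNCE: explicit exponentials, mean over positives.
brute_infonce <- function(S, positives) {
  per <- apply(positives, 1L, function(p) {
    -log(exp(S[p[1L], p[2L]]) / sum(exp(S[p[1L], ])))
  })
  list(value = mean(per), per_pair = per)
}

# Exhaustive Youden scan over every candidate threshold.
brute_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  J <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & labels == 1) / sum(labels == 1) - sum(pred & labels == 0) / sum(labels == 0)
  }, numeric(1))
  best <- which(J > max(J) - 1e-12)[1L]  # smallest threshold among ties
  list(theta_star = cand[best], J_star = J[best])
}

# AUROC by trapezoidal integration of the ROC curve.
trapezoid_auroc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1)))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Brute-force Top-K metrics for a single-query score table.
brute_ranking_one <- function(scores, relevant, K, ndcg_k = 10L) {
  ord <- order(-scores)
  rel <- relevant[ord]
  n_rel <- sum(rel)
  p_at <- vapply(K, function(k) sum(rel[seq_len(min(k, length(rel)))]) / k, numeric(1))
  r_at <- vapply(K, function(k) sum(rel[seq_len(min(k, length(rel)))]) / n_rel, numeric(1))
  rr <- 1 / min(which(rel == 1))
  k <- min(ndcg_k, length(rel))
  dcg <- sum(ifelse(rel[seq_len(k)] == 1, 1 / log2(seq_len(k) + 1), 0))
  idcg <- sum(1 / log2(seq_len(min(n_rel, k)) + 1))
  list(p_at = p_at, r_at = r_at, rr = rr, ndcg = dcg / idcg)
}

# Session-level cache for the expensive reference-benchmark computations so
# several acceptance properties can share one run.
.ref_cache <- new.env(parent = emptyenv())

ref_benchmark <- function() {
  if (is.null(.ref_cache$ds)) {
    .ref_cache$ds <- generate_benchmark(synth_config(
      n_drugs = 200L, n_diseases = 150L, latent_dim = 8L,
      target_density = 0.05, noise_sd = 0.3, seed = 0L))
    .ref_cache$adapter <- adapter_oracle(.ref_cache$ds, seed = derive_seed(0L, 3L))
    .ref_cache$pairs <- build_labeled_pairs(.ref_cache$ds, seed = derive_seed(0L, 5L))
  }
  list(ds = .ref_cache$ds, adapter = .ref_cache$adapter, pairs = .ref_cache$pairs)
}

ref_entities <- function() {
  if (is.null(.ref_cache$emb)) {
    rb <- ref_benchmark()
    .ref_cache$config <- pipeline_config(rb$adapter, seed = 0L)
    .ref_cache$emb <- encode_entities(list(drugs = rb$ds$drugs,
                                           diseases = rb$ds$diseases),
                                      .ref_cache$config)
  }
  list(emb = .ref_cache$emb, config = .ref_cache$config)
}
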