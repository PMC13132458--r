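# Evaluation protocol: balanced negative sampling, stratified five-fold CV,
# C1/C2/C3 cold-start splits, classification and Top-K ranking metrics,
# Gaussian noise injection, feature-separability and clustering diagnostics,
# and the end-to-end cross-validated experiment driver.

#' Sample balanced negatives from the unknown pairs
#'
#' Draws exactly `n` (default: as many as there are positives) drug-disease
#' pairs uniformly without replacement from the universe minus the known
#' positives.
#'
#' @param positives data.frame with `drug_id`, `disease_id`.
#' @param drugs,diseases entity tables (or character id vectors).
#' @param seed integer seed.
#' @param n number of negatives (default `nrow(positives)`).
#' @return data.frame of sampled pairs with `drug_id`, `disease_id`.
#' @export
balanced_negatives <- function(positives, drugs, diseases, seed = 1L,
                               n = nrow(positives)) {
  drug_ids <- if (is.data.frame(drugs)) drugs$drug_id else drugs
  disease_ids <- if (is.data.frame(diseases)) diseases$disease_id else diseases
  universe <- length(drug_ids) * length(disease_ids)
  if (universe - nrow(positives) < n) {
    stop("not enough unknown pairs to sample negatives", call. = FALSE)
  }
  known <- new.env(parent = emptyenv())
  for (k in paste(positives$drug_id, positives$disease_id, sep = "\r")) {
    assign(k, TRUE, envir = known)
  }
  with_seed(seed, {
    out_d <- character(0)
    out_i <- character(0)
    while (length(out_d) < n) {
      m <- max(64L, 2L * (n - length(out_d)))
      cd <- drug_ids[sample.int(length(drug_ids), m, replace = TRUE)]
      ci <- disease_ids[sample.int(length(disease_ids), m, replace = TRUE)]
      keys <- paste(cd, ci, sep = "\r")
      for (j in seq_len(m)) {
        if (length(out_d) >= n) break
        if (!exists(keys[j], envir = known, inherits = FALSE)) {
          assign(keys[j], TRUE, envir = known)
          out_d <- c(out_d, cd[j])
          out_i <- c(out_i, ci[j])
        }
      }
    }
    data.frame(drug_id = out_d, disease_id = out_i, stringsAsFactors = FALSE)
  })
}

#' Build the balanced labeled pair set for a dataset
#'
#' Positives (label 1) are the dataset's association table; negatives
#' (label 0) are balanced-sampled once, before any splitting, so all folds
#' share the same universe.
#'
#' @param dataset a `synth_dataset`, or a list with `drugs`, `diseases`,
#'   `pairs`.
#' @param seed negative-sampling seed.
#' @return data.frame with `drug_id`, `disease_id`, `label`.
#' @export
build_labeled_pairs <- function(dataset, seed = 1L) {
  neg <- balanced_negatives(dataset$pairs, dataset$drugs, dataset$diseases, seed = seed)
  rbind(
    data.frame(dataset$pairs[, c("drug_id", "disease_id")], label = 1L),
    data.frame(neg, label = 0L)
  )
}

#' Stratified k-fold assignment of labeled pairs
#'
#' Shuffles within each label stratum and deals pairs to folds so that fold
#' sizes differ by at most one and each fold preserves the label balance.
#'
#' @param pairs labeled pair data.frame (`label` column used for strata).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return an object of class `split_spec` with `mode = "cv5"` and a per-pair
#'   `fold` vector.
#' @export
make_cv_folds <- function(pairs, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  n <- nrow(pairs)
  if (n < k) stop("fewer pairs than folds", call. = FALSE)
  fold <- integer(n)
  offset <- 0L
  with_seed(seed, {
    for (lv in sort(unique(pairs$label))) {
      idx <- which(pairs$label == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(mode = "cv5", k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "split_spec")
}

#' Cold-start train/test partition of labeled pairs
#'
#' C1 holds out a fraction of drugs: every pair touching a held-out drug is
#' test, the rest train. C2 mirrors this for diseases. C3 holds out both:
#' test pairs have both entities held out; pairs touching exactly one
#' held-out entity are discarded (neither split), the strictest leak-free
#' reading. If C3 yields an empty test set the split is retried with a
#' derived seed up to `max_attempts` times.
#'
#' @param pairs labeled pair data.frame.
#' @param mode `"C1"`, `"C2"` or `"C3"`.
#' @param fraction fraction of entities held out (default 0.2).
#' @param seed integer seed.
#' @param max_attempts bounded retries for degenerate C3 draws.
#' @return an object of class `split_spec` with a per-pair `role` vector in
#'   `{"train", "test", "drop"}` and the held-out entity sets.
#' @export
make_coldstart_split <- function(pairs, mode = c("C1", "C2", "C3"),
                                 fraction = 0.2, seed = 1L, max_attempts = 20L) {
  mode <- match.arg(mode)
  drugs <- sort(unique(pairs$drug_id))
  diseases <- sort(unique(pairs$disease_id))
  for (attempt in seq_len(max_attempts)) {
    s <- if (attempt == 1L) seed else derive_seed(seed, 7000L, attempt)
    test_drugs <- character(0)
    test_diseases <- character(0)
    role <- rep("train", nrow(pairs))
    if (mode %in% c("C1", "C3")) {
      nt <- max(1L, round(fraction * length(drugs)))
      test_drugs <- with_seed(derive_seed(s, 1L), sample(drugs, nt))
    }
    if (mode %in% c("C2", "C3")) {
      nt <- max(1L, round(fraction * length(diseases)))
      test_diseases <- with_seed(derive_seed(s, 2L), sample(diseases, nt))
    }
    d_hit <- pairs$drug_id %in% test_drugs
    i_hit <- pairs$disease_id %in% test_diseases
    if (mode == "C1") {
      role[d_hit] <- "test"
    } else if (mode == "C2") {
      role[i_hit] <- "test"
    } else {
      role[d_hit & i_hit] <- "test"
      role[xor(d_hit, i_hit)] <- "drop"
    }
    ok <- sum(role == "test") > 0L && sum(role == "train") > 0L &&
      length(unique(pairs$label[role == "test"])) == 2L &&
      length(unique(pairs$label[role == "train"])) == 2L
    if (ok) {
      if (attempt > 1L) {
        message(sprintf("cold-start %s: degenerate draw, reseeded (attempt %d)",
                        mode, attempt))
      }
      return(structure(list(mode = mode, role = role, test_drugs = test_drugs,
                            test_diseases = test_diseases, fraction = fraction,
                            seed = as.integer(seed), attempts = attempt),
                       class = "split_spec"))
    }
  }
  stop(sprintf("cold-start %s produced a degenerate split after %d attempts",
               mode, max_attempts), call. = FALSE)
}

#' Write / read a split specification as TSV
#'
#' One row per pair: `pair_index`, `drug_id`, `disease_id`, `label`, and
#' `fold` (CV) or `role` (cold-start), sufficient for exact reruns.
#'
#' @param split a `split_spec`.
#' @param pairs the labeled pairs the split refers to.
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
write_split <- function(split, pairs, path) {
  df <- data.frame(pair_index = seq_len(nrow(pairs)),
                   drug_id = pairs$drug_id, disease_id = pairs$disease_id,
                   label = pairs$label, stringsAsFactors = FALSE)
  if (split$mode == "cv5") df$fold <- split$fold else df$role <- split$role
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Gaussian noise specification
#'
#' @param rho noise level: the SD of the injected Gaussian noise relative to
#'   each feature column's SD.
#' @param seed integer seed.
#' @param apply_to `"both"`, `"embeddings"` or `"enhanced"`.
#' @param phases `"both"`, `"train"` or `"test"`.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(rho, seed = 1L, apply_to = c("both", "embeddings", "enhanced"),
                       phases = c("both", "train", "test")) {
  stopifnot(rho >= 0)
  structure(list(rho = rho, seed = as.integer(seed),
                 apply_to = match.arg(apply_to), phases = match.arg(phases)),
            class = "noise_spec")
}

#' Inject column-scaled Gaussian noise into a feature matrix
#'
#' Adds independent `Normal(0, (rho * sigma_c)^2)` noise to each column,
#' where `sigma_c` is the column SD of the reference (clean training)
#' features. Zero-variance columns are left untouched.
#'
#' @param X feature matrix.
#' @param spec a [noise_spec()].
#' @param ref_sd reference per-column SDs (default: column SDs of `X`).
#' @return the noised matrix.
#' @export
inject_noise <- function(X, spec, ref_sd = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  X <- as.matrix(X)
  if (spec$rho == 0) return(X)
  if (is.null(ref_sd)) ref_sd <- apply(X, 2L, stats::sd)
  ref_sd[!is.finite(ref_sd)] <- 0
  E <- with_seed(spec$seed, matrix(stats::rnorm(length(X)), nrow(X), ncol(X)))
  X + E * rep(spec$rho * ref_sd, each = nrow(X))
}

#' Feature separability diagnostics
#'
#' Samples positive and negative pairs, computes the cosine similarity of
#' each pair's drug and disease vectors, and reports the class means,
#' pooled-SD Cohen's d, and the AUROC of similarity used as a classifier.
#'
#' @param pos_pairs,neg_pairs pair data.frames (`drug_id`, `disease_id`).
#' @param drug_vecs,disease_vecs embedding matrices with id rownames (same
#'   width; project first if needed).
#' @param n_sample pairs sampled per class (default 1000).
#' @param seed integer seed.
#' @return an object of class `quality_report`.
#' @export
feature_quality <- function(pos_pairs, neg_pairs, drug_vecs, disease_vecs,
                            n_sample = 1000L, seed = 1L) {
  take <- function(df, n, salt) {
    if (nrow(df) <= n) return(df)
    df[with_seed(derive_seed(seed, salt), sample.int(nrow(df), n)), , drop = FALSE]
  }
  pos <- take(pos_pairs, n_sample, 1L)
  neg <- take(neg_pairs, n_sample, 2L)
  sims <- function(df) {
    vapply(seq_len(nrow(df)), function(j) {
      cosine_sim(drug_vecs[df$drug_id[j], ], disease_vecs[df$disease_id[j], ])
    }, numeric(1))
  }
  ps <- sims(pos)
  ns <- sims(neg)
  structure(list(mean_pos_sim = mean(ps), mean_neg_sim = mean(ns),
                 sd_pos = stats::sd(ps), sd_neg = stats::sd(ns),
                 cohens_d = cohens_d(ps, ns),
                 sim_auc = auroc(c(ps, ns), c(rep(1L, length(ps)), rep(0L, length(ns)))),
                 n_pos = length(ps), n_neg = length(ns)),
            class = "quality_report")
}

#' Clustering agreement diagnostics for disease embeddings
#'
#' Seeded KMeans on the embeddings, compared with the reference category
#' labels via NMI and ARI; silhouette is computed on the cluster assignment
#' (NA when k = 1).
#'
#' @param embeddings numeric matrix (diseases x features).
#' @param labels reference category labels.
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param nstart KMeans restarts (default 10).
#' @return list with `nmi`, `ari`, `silhouette`, `cluster`.
#' @export
clustering_quality <- function(embeddings, labels, k = 6L, seed = 1L, nstart = 10L) {
  embeddings <- as.matrix(embeddings)
  if (k > nrow(embeddings)) stop("k exceeds the number of points", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("labels cover fewer than 2 categories", call. = FALSE)
  cl <- with_seed(derive_seed(seed, 41L),
                  stats::kmeans(embeddings, centers = k, nstart = nstart,
                                iter.max = 50L)$cluster)
  sil <- if (k >= 2L && length(unique(cl)) >= 2L) {
    mean(cluster::silhouette(cl, stats::dist(embeddings))[, "sil_width"])
  } else {
    NA_real_
  }
  list(nmi = nmi(cl, labels), ari = ari(cl, labels), silhouette = sil, cluster = cl)
}

#' Pipeline configuration for an experiment run
#'
#' @param adapter a `dda_adapter` used for both drugs and disease texts.
#' @param weights [field_weights()] for disease field fusion.
#' @param attn_h attention MLP hidden width (default 128).
#' @param no_att ablation: replace attention pooling by mean pooling.
#' @param no_cl ablation: skip contrastive enhancement (features are the
#'   original blocks only).
#' @param enhancer an [enhancer_config()].
#' @param forest a [forest_config()].
#' @param noise optional [noise_spec()].
#' @param disease_proj_dim disease projection width (default 128).
#' @param ranking compute Top-K ranking metrics on test folds (per-drug
#'   queries).
#' @param K Precision/Recall cutoffs (default `c(1, 3)`).
#' @param seed global seed; all stage seeds derive from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(adapter, weights = field_weights(), attn_h = 128L,
                            no_att = FALSE, no_cl = FALSE,
                            enhancer = enhancer_config(), forest = forest_config(),
                            noise = NULL, disease_proj_dim = 128L, ranking = FALSE,
                            K = c(1L, 3L), seed = 0L) {
  stopifnot(inherits(adapter, "dda_adapter"))
  structure(list(adapter = adapter, weights = weights, attn_h = as.integer(attn_h),
                 no_att = isTRUE(no_att), no_cl = isTRUE(no_cl), enhancer = enhancer,
                 forest = forest, noise = noise,
                 disease_proj_dim = as.integer(disease_proj_dim),
                 ranking = isTRUE(ranking), K = as.integer(K),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Encode all entities under a pipeline configuration
#'
#' @param data list with `drugs` and `diseases` tables.
#' @param config a [pipeline_config()].
#' @return list with `drug_vecs` (pooled) and `disease_vecs` (projected),
#'   plus the attention parameters and projection used.
#' @export
encode_entities <- function(data, config) {
  pool <- if (config$no_att) NULL else {
    attn_pool_params(config$adapter$token_dim, h = config$attn_h,
                     seed = derive_seed(config$seed, 51L))
  }
  drug_vecs <- encode_drugs(data$drugs, config$adapter, pool)
  dis <- encode_diseases(data$diseases, config$adapter, config$weights,
                         map = disease_projection(config$adapter$text_dim,
                                                  config$disease_proj_dim,
                                                  seed = derive_seed(config$seed, 52L)))
  list(drug_vecs = drug_vecs, disease_vecs = dis$projected,
       disease_fused = dis$fused, pool = pool, projection = dis$projection)
}

# One train/test evaluation: enhancer + forest on train, threshold on train
# scores, metrics on test. Embedding/enhanced noise handled per the spec.
evaluate_fold <- function(train_pairs, test_pairs, drug_vecs, disease_vecs,
                          config, fold_id = 1L) {
  ns <- config$noise
  noise_on <- function(phase, target) {
    !is.null(ns) && ns$rho > 0 &&
      (ns$apply_to == "both" || ns$apply_to == target) &&
      (ns$phases == "both" || ns$phases == phase)
  }
  noised <- function(X, phase, target, salt) {
    if (!noise_on(phase, target)) return(X)
    spec <- noise_spec(ns$rho, seed = derive_seed(ns$seed, fold_id, salt),
                       apply_to = ns$apply_to, phases = ns$phases)
    inject_noise(X, spec, ref_sd = apply(X, 2L, stats::sd))
  }
  dv_train <- noised(drug_vecs, "train", "embeddings", 1L)
  iv_train <- noised(disease_vecs, "train", "embeddings", 2L)
  dv_test <- noised(drug_vecs, "test", "embeddings", 3L)
  iv_test <- noised(disease_vecs, "test", "embeddings", 4L)

  fit <- if (config$no_cl) NULL else {
    cfg <- config$enhancer
    cfg$seed <- derive_seed(config$seed, 100L, fold_id)
    train_enhancer(train_pairs, dv_train, iv_train, cfg)
  }
  X_train <- enhanced_matrix(train_pairs, dv_train, iv_train, fit)
  X_test <- enhanced_matrix(test_pairs, dv_test, iv_test, fit)
  clean_sd <- apply(X_train, 2L, stats::sd)
  if (!is.null(ns) && noise_on("train", "enhanced")) {
    spec <- noise_spec(ns$rho, seed = derive_seed(ns$seed, fold_id, 5L))
    X_train <- inject_noise(X_train, spec, ref_sd = clean_sd)
  }
  if (!is.null(ns) && noise_on("test", "enhanced")) {
    spec <- noise_spec(ns$rho, seed = derive_seed(ns$seed, fold_id, 6L))
    X_test <- inject_noise(X_test, spec, ref_sd = clean_sd)
  }

  fcfg <- config$forest
  fcfg$seed <- derive_seed(config$seed, 200L, fold_id)
  model <- fit_forest(X_train, train_pairs$label, fcfg)
  train_scores <- predict_scores(model, X_train)
  thr <- youden_threshold(train_scores, train_pairs$label)
  test_scores <- predict_scores(model, X_test)
  cm <- classification_metrics(test_scores, test_pairs$label, thr$theta_star)
  list(metrics = cm, threshold = thr, scores = test_scores, fit = fit,
       model = model)
}

#' Run the cross-validated (or cold-start) association experiment
#'
#' For every fold: train the contrastive enhancer and the forest on training
#' pairs only, select the Youden threshold on training-fold scores, then
#' score the test fold. Reports per-fold and mean AUROC, AUPR, F1 and
#' accuracy, and (optionally) Top-K ranking metrics with drugs as queries
#' over their test-fold candidate diseases.
#'
#' @param data list with `drugs`, `diseases`, and labeled `pairs`.
#' @param config a [pipeline_config()].
#' @param split a `split_spec` from [make_cv_folds()] or
#'   [make_coldstart_split()]; default: stratified 5-fold CV seeded from the
#'   config seed.
#' @return an object of class `metrics_report`.
#' @export
run_cv_experiment <- function(data, config, split = NULL) {
  pairs <- data$pairs
  if (is.null(split)) split <- make_cv_folds(pairs, seed = derive_seed(config$seed, 61L))
  emb <- encode_entities(data, config)

  fold_sets <- if (split$mode == "cv5") {
    lapply(seq_len(split$k), function(f) {
      list(train = which(split$fold != f), test = which(split$fold == f))
    })
  } else {
    list(list(train = which(split$role == "train"), test = which(split$role == "test")))
  }

  per_fold <- vector("list", length(fold_sets))
  rank_tables <- vector("list", length(fold_sets))
  for (f in seq_along(fold_sets)) {
    tr <- pairs[fold_sets[[f]]$train, , drop = FALSE]
    te <- pairs[fold_sets[[f]]$test, , drop = FALSE]
    res <- tryCatch(
      evaluate_fold(tr, te, emb$drug_vecs, emb$disease_vecs, config, fold_id = f),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE)
    )
    per_fold[[f]] <- data.frame(fold = f, auroc = res$metrics$auroc,
                                aupr = res$metrics$aupr, f1 = res$metrics$f1,
                                accuracy = res$metrics$accuracy,
                                theta = res$threshold$theta_star,
                                J = res$threshold$J_star)
    if (config$ranking) {
      rank_tables[[f]] <- data.frame(query = te$drug_id, candidate = te$disease_id,
                                     score = res$scores, relevant = te$label,
                                     stringsAsFactors = FALSE)
    }
  }
  fold_df <- do.call(rbind, per_fold)
  means <- colMeans(fold_df[, c("auroc", "aupr", "f1", "accuracy")])

  ranking <- NULL
  if (config$ranking) {
    per_rank <- lapply(rank_tables, function(tb) {
      suppressWarnings(ranking_metrics(tb, K = config$K))
    })
    ranking <- list(
      p_at = colMeans(do.call(rbind, lapply(per_rank, `[[`, "p_at"))),
      r_at = colMeans(do.call(rbind, lapply(per_rank, `[[`, "r_at"))),
      mrr = mean(vapply(per_rank, `[[`, numeric(1), "mrr")),
      ndcg = mean(vapply(per_rank, `[[`, numeric(1), "ndcg"))
    )
  }

  structure(list(mode = split$mode, per_fold = fold_df, means = as.list(means),
                 ranking = ranking, split = split, seed = config$seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %s, %d fold(s)>\n", x$mode, nrow(x$per_fold)))
  cat(sprintf("  mean AUROC %.4f | AUPR %.4f | F1 %.4f | accuracy %.4f\n",
              x$means$auroc, x$means$aupr, x$means$f1, x$means$accuracy))
  if (!is.null(x$ranking)) {
    cat(sprintf("  ranking: MRR %.4f | NDCG@10 %.4f | %s | %s\n", x$ranking$mrr,
                x$ranking$ndcg,
                paste(names(x$ranking$p_at), sprintf("%.4f", x$ranking$p_at),
                      collapse = " ", sep = "="),
                paste(names(x$ranking$r_at), sprintf("%.4f", x$ranking$r_at),
                      collapse = " ", sep = "=")))
  }
  invisible(x)
}

#' Write a metrics report as JSON plus a per-fold TSV
#'
#' @param report a `metrics_report`.
#' @param dir output directory.
#' @param name file stem (default `"report"`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, name = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_fold, file.path(dir, paste0(name, "_folds.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(mode = report$mode, means = report$means, seed = report$seed)
  if (!is.null(report$ranking)) {
    out$ranking <- list(p_at = as.list(report$ranking$p_at),
                        r_at = as.list(report$ranking$r_at),
                        mrr = report$ranking$mrr, ndcg = report$ranking$ndcg)
  }
  jsonlite::write_json(out, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
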