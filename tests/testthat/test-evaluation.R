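# Negative sampling, splits, noise injection, quality diagnostics, and the
# experiment driver.

test_that("balanced negatives are disjoint, sized and seed-reproducible", {
  ds <- tiny_dataset(4L)
  pos <- ds$pairs[1:10, ]
  neg <- balanced_negatives(pos, ds$drugs, ds$diseases, seed = 5L)
  expect_equal(nrow(neg), 10L)
  expect_false(any(paste(neg$drug_id, neg$disease_id) %in%
                     paste(pos$drug_id, pos$disease_id)))
  expect_false(any(duplicated(paste(neg$drug_id, neg$disease_id))))
  expect_identical(neg, balanced_negatives(pos, ds$drugs, ds$diseases, seed = 5L))
})

test_that("negative sampling is uniform over the unknown pairs", {
  # 3x3 universe with 2 positives: each of the 7 unknown pairs should be
  # drawn with probability 2/7 per 2-negative sample
  drugs <- paste0("d", 1:3)
  diseases <- paste0("i", 1:3)
  pos <- data.frame(drug_id = c("d1", "d2"), disease_id = c("i1", "i2"))
  counts <- new.env(parent = emptyenv())
  n_draws <- 300L
  for (s in seq_len(n_draws)) {
    neg <- balanced_negatives(pos, drugs, diseases, seed = s)
    for (k in paste(neg$drug_id, neg$disease_id)) {
      assign(k, (get0(k, envir = counts) %||% 0) + 1, envir = counts)
    }
  }
  freqs <- unlist(as.list(counts)) / n_draws
  expect_length(freqs, 7L)
  expect_true(all(abs(freqs - 2 / 7) < 0.1))

  expect_error(balanced_negatives(pos, drugs[1], diseases[1:2], seed = 1L),
               "not enough")
})

test_that("stratified CV folds cover every pair exactly once", {
  ds <- tiny_dataset(6L)
  pairs <- build_labeled_pairs(ds, seed = 2L)
  sp <- make_cv_folds(pairs, k = 5L, seed = 3L)
  expect_identical(sp, make_cv_folds(pairs, k = 5L, seed = 3L))
  sizes <- table(sp$fold)
  expect_length(sizes, 5L)
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(sizes), nrow(pairs))
  # stratification: per-fold positive counts within 1 of each other
  pos_sizes <- table(sp$fold[pairs$label == 1])
  expect_lte(diff(range(pos_sizes)), 1L)
  # 100 pairs over 5 folds: 20 each
  sp100 <- make_cv_folds(pairs[1:100, ], k = 5L, seed = 1L)
  expect_true(all(table(sp100$fold) == 20L))
  expect_error(make_cv_folds(pairs, k = 1L), "at least 2")
})

test_that("cold-start splits satisfy their entity-exclusion invariants", {
  ds <- tiny_dataset(7L)
  pairs <- build_labeled_pairs(ds, seed = 2L)
  for (seed in 1:15) {
    for (mode in c("C1", "C2", "C3")) {
      sp <- make_coldstart_split(pairs, mode = mode, seed = seed)
      tr <- pairs[sp$role == "train", ]
      te <- pairs[sp$role == "test", ]
      expect_gt(nrow(te), 0L)
      expect_gt(nrow(tr), 0L)
      if (mode %in% c("C1", "C3")) {
        expect_length(intersect(te$drug_id, tr$drug_id), 0L)
        n_drugs <- length(unique(pairs$drug_id))
        expect_lte(abs(length(sp$test_drugs) - 0.2 * n_drugs), 1)
      }
      if (mode %in% c("C2", "C3")) {
        expect_length(intersect(te$disease_id, tr$disease_id), 0L)
      }
      if (mode == "C3") {
        # discarded pairs touch exactly one held-out entity
        dr <- pairs[sp$role == "drop", ]
        expect_true(all(xor(dr$drug_id %in% sp$test_drugs,
                            dr$disease_id %in% sp$test_diseases)))
        expect_true(all(te$drug_id %in% sp$test_drugs))
        expect_true(all(te$disease_id %in% sp$test_diseases))
      } else {
        expect_equal(sum(sp$role == "drop"), 0L)
      }
    }
  }
})

test_that("noise injection scales with the reference column SD", {
  X <- matrix(rnorm(50 * 4), 50, 4)
  expect_identical(inject_noise(X, noise_spec(0, seed = 1L)), X)
  n1 <- inject_noise(X, noise_spec(0.3, seed = 2L))
  expect_identical(n1, inject_noise(X, noise_spec(0.3, seed = 2L)))
  expect_false(identical(n1, inject_noise(X, noise_spec(0.3, seed = 3L))))

  # law of large numbers: empirical noise SD within 2% of rho * sigma_c
  Xc <- matrix(rnorm(1e5, sd = 2), ncol = 1)
  sig <- sd(Xc)
  noisy <- inject_noise(Xc, noise_spec(0.5, seed = 4L))
  expect_lt(abs(sd(noisy - Xc) / (0.5 * sig) - 1), 0.02)

  # zero-variance columns stay untouched
  Xz <- cbind(rep(3, 50), rnorm(50))
  nz <- inject_noise(Xz, noise_spec(0.5, seed = 5L))
  expect_equal(nz[, 1], rep(3, 50))
  expect_false(all(nz[, 2] == Xz[, 2]))
})

test_that("feature quality reports cosine separability", {
  # two drugs/diseases with known geometry
  dv <- rbind(d1 = c(1, 0), d2 = c(0, 1))
  iv <- rbind(i1 = c(1, 0), i2 = c(1, 0))
  pos <- data.frame(drug_id = "d1", disease_id = "i1")
  neg <- data.frame(drug_id = "d2", disease_id = "i2")
  q <- feature_quality(pos, neg, dv, iv, seed = 1L)
  expect_equal(q$mean_pos_sim, 1)
  expect_equal(q$mean_neg_sim, 0)
  expect_equal(q$sim_auc, 1)

  # null case: similarities from one distribution give sim_auc near 0.5
  set.seed(41)
  n <- 400L
  dvn <- matrix(rnorm(2 * n * 8), 2 * n, 8)
  rownames(dvn) <- paste0("d", seq_len(2 * n))
  ivn <- matrix(rnorm(2 * n * 8), 2 * n, 8)
  rownames(ivn) <- paste0("i", seq_len(2 * n))
  posn <- data.frame(drug_id = paste0("d", 1:n), disease_id = paste0("i", 1:n))
  negn <- data.frame(drug_id = paste0("d", n + 1:n), disease_id = paste0("i", n + 1:n))
  qn <- feature_quality(posn, negn, dvn, ivn, seed = 2L)
  expect_lt(abs(qn$sim_auc - 0.5), 0.08)
  expect_lt(abs(qn$cohens_d), 0.25)
})

test_that("clustering diagnostics recover planted structure", {
  set.seed(42)
  centers <- diag(3) * 10
  emb <- centers[rep(1:3, each = 20), ] + matrix(rnorm(180, sd = 0.1), 60, 3)
  lab <- rep(1:3, each = 20)
  q <- clustering_quality(emb, lab, k = 3L, seed = 1L)
  expect_equal(q$nmi, 1)
  expect_equal(q$ari, 1)
  expect_gt(q$silhouette, 0.8)
  expect_error(clustering_quality(emb[1:2, ], lab[1:2], k = 3L), "exceeds")
})

test_that("the experiment driver recovers planted signal and respects nulls", {
  ds <- tiny_dataset(8L)
  ad <- adapter_oracle(ds, seed = 5L, token_dim = 48L, text_dim = 96L)
  pc <- pipeline_config(ad, enhancer = enhancer_config(proj_dim = 32L, epochs = 15L,
                                                       batch_size = 128L),
                        forest = forest_config(n_estimators = 80L),
                        disease_proj_dim = 24L, ranking = TRUE, seed = 3L)
  pairs <- build_labeled_pairs(ds, seed = 4L)
  data <- list(drugs = ds$drugs, diseases = ds$diseases, pairs = pairs)
  rep1 <- run_cv_experiment(data, pc)
  expect_gt(rep1$means$auroc, 0.75)
  expect_equal(nrow(rep1$per_fold), 5L)
  expect_true(all(rep1$per_fold$auroc >= 0 & rep1$per_fold$auroc <= 1))
  expect_false(is.null(rep1$ranking))
  expect_true(rep1$ranking$mrr >= 0 && rep1$ranking$mrr <= 1)

  # determinism of the full driver
  rep2 <- run_cv_experiment(data, pc)
  expect_identical(rep1$per_fold, rep2$per_fold)

  # shuffled labels destroy the signal
  sh <- data
  sh$pairs$label <- with_seed(9L, sample(sh$pairs$label))
  rep0 <- run_cv_experiment(sh, pc)
  expect_lt(abs(rep0$means$auroc - 0.5), 0.12)
})
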