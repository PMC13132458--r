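# Projection heads, interaction, enhanced-feature assembly, InfoNCE loss,
# contrastive training.

test_that("projection heads are deterministic with the configured output width", {
  head <- projection_head(10L, 6L, seed = 4L)
  v <- rnorm(10)
  expect_length(project(v, head), 6L)
  expect_identical(project(v, head), project(v, head))
  expect_identical(project(v, projection_head(10L, 6L, seed = 4L)), project(v, head))
  # zero input through a zero-bias head: layer-norm of the zero vector is zero
  expect_equal(project(numeric(10), head), numeric(6))
  expect_error(project(rnorm(5), head), "width")
})

test_that("interaction depends only on the concatenated projections", {
  p <- 4L
  # identity-on-concatenation head returns [a ; b] (nonnegative inputs)
  ident <- structure(list(W = diag(2 * p), b = numeric(2 * p), proj_dim = p,
                          interact_dim = 2L * p, activation = "relu"),
                     class = "interaction_head")
  a <- abs(rnorm(p)); b <- abs(rnorm(p))
  expect_equal(interact(a, b, ident), c(a, b))

  head <- interaction_head(p, seed = 9L)
  expect_false(isTRUE(all.equal(interact(a, b, head), interact(b, a, head))))
  # zero inputs through the linear zero-bias head give zero output
  expect_equal(interact(numeric(p), numeric(p), head), numeric(p))
  expect_error(interact(rnorm(3), rnorm(4), head), "width")
})

test_that("enhanced features concatenate blocks in fixed order", {
  f <- assemble_enhanced(rnorm(384), rnorm(128), rnorm(128), rnorm(128), rnorm(128))
  expect_equal(sum(f$block_dims), 896L)
  expect_length(f$values, 896L)
  expect_named(f$block_dims, c("M_d", "D_i", "Z_drug", "Z_disease", "Z_interact"))

  # round trip: splitting by block_dims reproduces the inputs
  M_d <- rnorm(5); D_i <- rnorm(3); zd <- rnorm(2); zi <- rnorm(2); zint <- rnorm(4)
  f2 <- assemble_enhanced(M_d, D_i, zd, zi, zint)
  ends <- cumsum(f2$block_dims)
  starts <- c(1L, head(ends, -1) + 1L)
  expect_equal(f2$values[starts[1]:ends[1]], M_d)
  expect_equal(f2$values[starts[5]:ends[5]], zint)

  # no-contrastive ablation keeps only the two original blocks
  f3 <- assemble_enhanced(M_d, D_i)
  expect_length(f3$block_dims, 2L)
  expect_equal(f3$values, c(M_d, D_i))

  expect_error(assemble_enhanced(M_d, D_i, zd, NULL, zint), "Z_disease")
})

test_that("similarity matrix is the temperature-scaled dot-product table", {
  Z <- diag(2)
  S <- similarity_matrix(Z, Z, tau = 0.25)
  expect_equal(S$values, matrix(c(4, 0, 0, 4), 2, 2))
  expect_equal(similarity_matrix(Z, Z, tau = 1)$values, diag(2))
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(12), 3, 4)
  expect_equal(similarity_matrix(A, B, tau = 0.5)$values,
               2 * similarity_matrix(A, B, tau = 1)$values)
  expect_error(similarity_matrix(A, B, tau = 0), "positive")
})

test_that("InfoNCE matches hand-computed values and softmax invariances", {
  expect_equal(infonce_loss(matrix(3.7, 1, 1))$value, 0)

  S <- similarity_matrix(diag(2), diag(2), tau = 1)
  l <- infonce_loss(S)
  expect_equal(l$value, log(1 + exp(-1)), tolerance = 1e-12)
  expect_equal(l$per_pair, rep(log(1 + exp(-1)), 2), tolerance = 1e-12)

  # uniform row: loss is log B
  B <- 6L
  expect_equal(infonce_loss(matrix(2, B, B))$value, log(B))

  # row-shift invariance and permutation equivariance
  M <- matrix(rnorm(25), 5, 5)
  l0 <- infonce_loss(M)$value
  M2 <- M; M2[3, ] <- M2[3, ] + 11
  expect_equal(infonce_loss(M2)$value, l0, tolerance = 1e-9)
  p <- sample(5)
  expect_equal(infonce_loss(M[p, p])$value, l0, tolerance = 1e-12)
})

test_that("InfoNCE agrees with the brute-force unstabilized oracle", {
  set.seed(11)
  for (i in 1:100) {
    B <- sample(2:8, 1)
    S <- matrix(runif(B * B, -20, 20), B, B)
    rows <- sort(sample(B, sample(B, 1)))
    pos <- cbind(rows, sample(B, length(rows), replace = TRUE))
    got <- infonce_loss(S, pos)
    want <- brute_infonce(S, pos)
    expect_equal(got$value, want$value, tolerance = 1e-6)
    expect_equal(got$per_pair, unname(want$per_pair), tolerance = 1e-6)
  }
})

test_that("contrastive training reduces the loss and is seed-reproducible", {
  ds <- tiny_dataset(2L)
  ad <- adapter_oracle(ds, seed = 5L, token_dim = 32L, text_dim = 48L)
  pc <- pipeline_config(ad, disease_proj_dim = 24L, seed = 2L)
  pairs <- build_labeled_pairs(ds, seed = 3L)
  emb <- encode_entities(list(drugs = ds$drugs, diseases = ds$diseases), pc)
  cfg <- enhancer_config(proj_dim = 16L, epochs = 12L, batch_size = 64L, seed = 6L)
  fit1 <- train_enhancer(pairs, emb$drug_vecs, emb$disease_vecs, cfg)
  fit2 <- train_enhancer(pairs, emb$drug_vecs, emb$disease_vecs, cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_gt(length(fit1$loss_history), 0L)
  expect_lt(tail(fit1$loss_history, 1), fit1$loss_history[1])

  expect_error(train_enhancer(pairs[pairs$label == 0, ],
                              emb$drug_vecs, emb$disease_vecs, cfg),
               "no positive")
})

test_that("enhancer checkpoints round-trip through disk", {
  ds <- tiny_dataset(3L)
  ad <- adapter_oracle(ds, seed = 5L, token_dim = 16L, text_dim = 24L)
  pc <- pipeline_config(ad, disease_proj_dim = 12L, seed = 2L)
  pairs <- build_labeled_pairs(ds, seed = 3L)
  emb <- encode_entities(list(drugs = ds$drugs, diseases = ds$diseases), pc)
  fit <- train_enhancer(pairs, emb$drug_vecs, emb$disease_vecs,
                        enhancer_config(proj_dim = 8L, epochs = 3L, seed = 1L))
  dir <- withr::local_tempdir()
  save_enhancer(fit, dir)
  back <- load_enhancer(dir)
  v <- rnorm(ncol(emb$drug_vecs))
  expect_equal(project(v, back$drug_head), project(v, fit$drug_head))
  expect_true(file.exists(file.path(dir, "enhancer.json")))
  expect_error(load_enhancer(withr::local_tempdir()), "enhancer.rds")
})
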