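# Drug token encoding, attention pooling, disease field fusion/projection.

test_that("mock-hash drug encoding is deterministic, input-sensitive and truncated", {
  enc <- adapter_mock_hash(token_dim = 16L, text_dim = 24L)
  rec <- list(drug_id = "d1", smiles = "CC(N)CO")
  M1 <- encode_drug_tokens(rec, enc)
  M2 <- encode_drug_tokens(rec, enc)
  expect_identical(M1, M2)
  expect_equal(dim(M1), c(nchar(rec$smiles), 16L))

  other <- encode_drug_tokens(list(drug_id = "d2", smiles = "CC(N)CS"), enc)
  expect_true(any(M1 != other))

  long <- list(drug_id = "d3", smiles = strrep("C", 600))
  expect_equal(nrow(encode_drug_tokens(long, enc)), 512L)

  expect_error(encode_drug_tokens(list(drug_id = "d4", smiles = ""), enc), "empty SMILES")
  expect_error(encode_drug_tokens(list(drug_id = "d4", smiles = ""), enc), "d4")
})

test_that("attention scores follow the two-layer tanh formula", {
  P <- structure(list(W1 = matrix(c(1, 0), 1, 2), b1 = 0,
                      W2 = matrix(1, 1, 1), b2 = 0),
                 class = "attn_pool_params")
  expect_equal(attention_scores(matrix(c(0.5, 9), 1, 2), P), tanh(0.5),
               tolerance = 1e-12)

  # constant map: W2 = 0 makes every score equal b2
  Pc <- structure(list(W1 = matrix(rnorm(6), 3, 2), b1 = rnorm(3),
                       W2 = matrix(0, 1, 3), b2 = 1.7),
                  class = "attn_pool_params")
  M <- matrix(rnorm(10), 5, 2)
  expect_equal(attention_scores(M, Pc), rep(1.7, 5))

  # zero-padding invariance: appending a zero column of W1 and a matching
  # input coordinate leaves scores unchanged
  P3 <- Pc
  P3$W1 <- cbind(Pc$W1, 0)
  expect_equal(attention_scores(cbind(M, rnorm(5)), P3), attention_scores(M, Pc))

  expect_error(attention_scores(matrix(0, 2, 5), Pc), "shape mismatch")
})

test_that("attention pooling is a softmax-weighted convex combination", {
  P <- attn_pool_params(3L, h = 4L, seed = 7L)
  m1 <- matrix(rnorm(3), 1, 3)
  p1 <- attention_pool(m1, P)
  expect_equal(p1$values, drop(m1))
  expect_equal(p1$attn_weights, 1)

  # equal scores (constant scorer) -> arithmetic mean, uniform weights
  Pc <- structure(list(W1 = matrix(0, 2, 3), b1 = c(0, 0),
                       W2 = matrix(1, 1, 2), b2 = 0),
                  class = "attn_pool_params")
  M <- matrix(rnorm(12), 4, 3)
  pc <- attention_pool(M, Pc)
  expect_equal(pc$attn_weights, rep(0.25, 4))
  expect_equal(pc$values, colMeans(M))

  # frozen softmax: scores (0, log 3) give weights (1/4, 3/4)
  M2 <- matrix(c(1, 0, 0, 1), 2, 2)
  w <- exp(c(0, log(3)) - log(3))
  expect_equal(w / sum(w), c(0.25, 0.75))
  # via the public surface: a scorer reproducing those scores
  Ps <- structure(list(W1 = matrix(c(20, 0), 1, 2), b1 = 0,
                       W2 = matrix(log(3), 1, 1), b2 = 0),
                  class = "attn_pool_params")
  # tanh(20) ~ 1, tanh(0) = 0 -> scores ~ (log 3, 0)
  ps <- attention_pool(M2, Ps)
  expect_equal(ps$attn_weights, c(0.75, 0.25), tolerance = 1e-8)
  expect_equal(ps$values, 0.75 * M2[1, ] + 0.25 * M2[2, ], tolerance = 1e-8)
})

test_that("pooling weights sum to one and respect score-shift invariance", {
  for (i in 1:50) {
    L <- sample(1:20, 1)
    d <- sample(2:8, 1)
    M <- matrix(rnorm(L * d), L, d)
    P <- attn_pool_params(d, h = 5L, seed = i)
    p <- attention_pool(M, P)
    expect_true(all(p$attn_weights >= 0))
    expect_lt(abs(sum(p$attn_weights) - 1), 1e-9)
    # convex hull: each pooled coordinate within the token range
    expect_true(all(p$values >= apply(M, 2, min) - 1e-12))
    expect_true(all(p$values <= apply(M, 2, max) + 1e-12))
    # adding a constant to b2 shifts all scores, leaving the pool unchanged
    P2 <- P
    P2$b2 <- P$b2 + rnorm(1, sd = 5)
    expect_equal(attention_pool(M, P2)$values, p$values, tolerance = 1e-9)
  }
})

test_that("disease field encoding and fusion behave as a weighted mean", {
  enc <- adapter_mock_hash(text_dim = 32L)
  v1 <- encode_disease_field("chronic carditis", enc)
  expect_identical(v1, encode_disease_field("chronic carditis", enc))
  expect_length(v1, 32L)
  expect_identical(encode_disease_field("", enc), numeric(32L))
  expect_length(encode_disease_field("x", adapter_mock_hash()), 768L)

  vs <- list(name = c(1, 1), synonymous = c(2, 2), definition = c(3, 3))
  expect_equal(fuse_fields(vs, field_weights(1, 1, 1)), c(2, 2))
  expect_equal(fuse_fields(vs, field_weights(2, 1, 1)), c(1.75, 1.75))
  # single present field: any positive weight returns it unchanged
  expect_equal(fuse_fields(list(name = c(4, 5)), field_weights(0.3, 1, 1)), c(4, 5))
  # weight scale invariance
  expect_equal(fuse_fields(vs, field_weights(0.4, 0.2, 0.2)),
               fuse_fields(vs, field_weights(2, 1, 1)))
  # missing fields dropped with renormalization
  expect_equal(fuse_fields(list(name = c(1, 1), definition = c(3, 3)),
                           field_weights(1, 1, 1)), c(2, 2))
  expect_error(fuse_fields(list(name = c(1, 1)), field_weights(0, 1, 1)),
               "zero")
  expect_error(field_weights(0, 0, 0), "zero")
})

test_that("disease projection applies the linear map deterministically", {
  fused <- rnorm(20)
  ident <- structure(list(W = diag(20)[, 1:8], in_dim = 20L, out_dim = 8L),
                     class = "disease_projection")
  expect_equal(project_disease(fused, ident)$projected, fused[1:8])

  zero <- structure(list(W = matrix(0, 20, 8), in_dim = 20L, out_dim = 8L),
                    class = "disease_projection")
  expect_equal(project_disease(fused, zero)$projected, numeric(8))

  m1 <- disease_projection(20L, 8L, seed = 3L)
  m2 <- disease_projection(20L, 8L, seed = 3L)
  expect_identical(project_disease(fused, m1)$projected,
                   project_disease(fused, m2)$projected)
  expect_error(project_disease(rnorm(10), m1), "length 20")
})

test_that("attention export writes one weighted row per token", {
  ds <- tiny_dataset(5L)
  enc <- adapter_mock_hash(token_dim = 12L, text_dim = 12L)
  P <- attn_pool_params(12L, h = 6L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_attention_weights(ds$drugs[1:3, ], enc, P, path)
  back <- read.delim(path)
  expect_named(back, c("drug_id", "token_index", "token_text", "weight"))
  expect_equal(nrow(back), sum(pmin(nchar(ds$drugs$smiles[1:3]), 512)))
  for (id in unique(back$drug_id)) {
    expect_lt(abs(sum(back$weight[back$drug_id == id]) - 1), 1e-9)
  }
})
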