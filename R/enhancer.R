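# Contrastive enhancement module.
#
# Two projection heads (linear -> ReLU -> linear -> layer norm) map pooled
# drug vectors and projected disease vectors into a shared space. Heads are
# trained with a temperature-scaled InfoNCE objective over batches of known
# positive pairs, each batch's other diseases serving as in-batch negatives.
# The enhanced feature for a pair concatenates the original vectors, both
# projections, and an interaction vector computed from the concatenated
# projections.

#' Initialize a projection head
#'
#' Architecture: affine -> ReLU -> affine -> layer normalization (no affine
#' layer-norm parameters; eps 1e-5, so a zero pre-norm row maps to zero).
#'
#' @param input_dim input width.
#' @param proj_dim output width.
#' @param seed integer seed (He-scaled Gaussian weights, zero biases).
#' @return an object of class `projection_head`.
#' @export
projection_head <- function(input_dim, proj_dim = 256L, seed = 1L) {
  stopifnot(input_dim >= 1, proj_dim >= 1)
  p <- with_seed(derive_seed(seed, 31L), list(
    W1 = matrix(stats::rnorm(input_dim * proj_dim, sd = sqrt(2 / input_dim)),
                input_dim, proj_dim),
    b1 = numeric(proj_dim),
    W2 = matrix(stats::rnorm(proj_dim * proj_dim, sd = sqrt(2 / proj_dim)),
                proj_dim, proj_dim),
    b2 = numeric(proj_dim)
  ))
  p$input_dim <- as.integer(input_dim)
  p$proj_dim <- as.integer(proj_dim)
  structure(p, class = "projection_head")
}

# Forward pass for a batch; optionally keeps intermediates for backprop.
head_forward <- function(head, X, keep = FALSE) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  if (ncol(X) != head$input_dim) {
    stop(sprintf("projection head expects width %d, got %d", head$input_dim, ncol(X)),
         call. = FALSE)
  }
  A1 <- X %*% head$W1 + matrix(head$b1, nrow(X), head$proj_dim, byrow = TRUE)
  H1 <- relu(A1)
  Z0 <- H1 %*% head$W2 + matrix(head$b2, nrow(X), head$proj_dim, byrow = TRUE)
  Z <- layernorm_rows(Z0)
  if (keep) list(Z = Z, Z0 = Z0, H1 = H1, X = X) else Z
}

#' Apply a projection head to a vector or matrix
#'
#' @param v input vector (or matrix of row vectors).
#' @param head a [projection_head()].
#' @return projected vector (or matrix of row vectors).
#' @export
project <- function(v, head) {
  stopifnot(inherits(head, "projection_head"))
  Z <- head_forward(head, v)
  if (is.matrix(v)) Z else drop(Z)
}

#' Initialize an interaction head
#'
#' Single affine layer with ReLU over the concatenated projected pair.
#'
#' @param proj_dim width of each projected input.
#' @param interact_dim output width (default `proj_dim`).
#' @param seed integer seed.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return an object of class `interaction_head`.
#' @export
interaction_head <- function(proj_dim, interact_dim = proj_dim, seed = 1L,
                             activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  W <- with_seed(derive_seed(seed, 32L),
                 matrix(stats::rnorm(2 * proj_dim * interact_dim, sd = sqrt(1 / proj_dim)),
                        2L * proj_dim, interact_dim))
  structure(list(W = W, b = numeric(interact_dim), proj_dim = as.integer(proj_dim),
                 interact_dim = as.integer(interact_dim), activation = activation),
            class = "interaction_head")
}

#' Compute the cross-modal interaction vector
#'
#' Depends on the inputs only through the concatenation `[zd ; zi]`.
#'
#' @param zd,zi projected drug and disease vectors (or matrices of rows).
#' @param head an [interaction_head()].
#' @return interaction vector (or matrix).
#' @export
interact <- function(zd, zi, head) {
  stopifnot(inherits(head, "interaction_head"))
  mat_in <- is.matrix(zd)
  if (!mat_in) { zd <- matrix(zd, 1L); zi <- matrix(zi, 1L) }
  if (ncol(zd) != head$proj_dim || ncol(zi) != head$proj_dim) {
    stop(sprintf("interaction head expects two inputs of width %d", head$proj_dim),
         call. = FALSE)
  }
  A <- cbind(zd, zi) %*% head$W + matrix(head$b, nrow(zd), head$interact_dim, byrow = TRUE)
  Z <- if (head$activation == "relu") relu(A) else A
  if (mat_in) Z else drop(Z)
}

#' Assemble the enhanced feature for one pair
#'
#' Fixed block order: pooled drug vector, projected disease vector, projected
#' drug, projected disease, interaction. Under the no-contrastive-learning
#' ablation pass `zd = zi = zint = NULL`: the feature is then just the two
#' original blocks.
#'
#' @param M_d pooled drug vector.
#' @param D_i projected disease vector.
#' @param zd,zi,zint projected and interaction vectors (all present or all
#'   `NULL`).
#' @return an object of class `enhanced_feature` with `values` and
#'   `block_dims`.
#' @export
assemble_enhanced <- function(M_d, D_i, zd = NULL, zi = NULL, zint = NULL) {
  blocks <- list(M_d = M_d, D_i = D_i, Z_drug = zd, Z_disease = zi, Z_interact = zint)
  proj_blocks <- blocks[3:5]
  missing <- names(proj_blocks)[vapply(proj_blocks, is.null, logical(1))]
  if (length(missing) > 0L && length(missing) < 3L) {
    stop("missing enhanced-feature block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(M_d) || is.null(D_i)) {
    stop("missing enhanced-feature block(s): ",
         paste(c("M_d", "D_i")[c(is.null(M_d), is.null(D_i))], collapse = ", "),
         call. = FALSE)
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  vals <- unlist(blocks, use.names = FALSE)
  if (any(!is.finite(vals))) stop("non-finite values in enhanced feature", call. = FALSE)
  structure(list(values = vals,
                 block_dims = vapply(blocks, length, integer(1))),
            class = "enhanced_feature")
}

#' Temperature-scaled similarity matrix
#'
#' @param Zd,Zi B x p matrices of projected drug / disease rows.
#' @param tau positive temperature.
#' @return an object of class `sim_matrix` with `values` (B x B) and `tau`;
#'   entry (i, j) is the dot product of drug row i and disease row j over
#'   `tau`.
#' @export
similarity_matrix <- function(Zd, Zi, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("temperature tau must be a positive scalar", call. = FALSE)
  }
  Zd <- as.matrix(Zd); Zi <- as.matrix(Zi)
  if (nrow(Zd) != nrow(Zi)) stop("batch sizes differ", call. = FALSE)
  structure(list(values = tcrossprod(Zd, Zi) / tau, tau = tau), class = "sim_matrix")
}

#' InfoNCE contrastive loss over a similarity matrix
#'
#' Per positive pair (d, i): `-log( exp(S[d,i]) / sum_j exp(S[d,j]) )`,
#' computed with max-subtraction stabilization; the reported value is the
#' mean over positives (batch-size independent reduction).
#'
#' @param S a [similarity_matrix()] result, or a plain numeric matrix.
#' @param positives two-column integer matrix of (row, col) positive indices;
#'   default: the diagonal.
#' @return an object of class `contrastive_loss` with `value` and `per_pair`.
#' @export
infonce_loss <- function(S, positives = NULL) {
  M <- if (inherits(S, "sim_matrix")) S$values else as.matrix(S)
  if (is.null(positives)) positives <- cbind(seq_len(nrow(M)), seq_len(nrow(M)))
  positives <- matrix(as.integer(positives), ncol = 2L)
  if (any(positives[, 1L] < 1L | positives[, 1L] > nrow(M) |
          positives[, 2L] < 1L | positives[, 2L] > ncol(M))) {
    stop("positive index out of range", call. = FALSE)
  }
  per <- numeric(nrow(positives))
  for (k in seq_len(nrow(positives))) {
    row <- M[positives[k, 1L], ]
    if (all(!is.finite(row))) stop("similarity row has no finite entries", call. = FALSE)
    per[k] <- logsumexp(row) - row[positives[k, 2L]]
  }
  structure(list(value = mean(per), per_pair = per), class = "contrastive_loss")
}

#' Enhancer training configuration
#'
#' @param proj_dim projection width (default 256, the tuned value).
#' @param interact_dim interaction width (default `proj_dim`).
#' @param tau InfoNCE temperature (default 0.25).
#' @param batch_size positives per batch (default 256).
#' @param epochs maximum epochs (default 60).
#' @param learning_rate Adam step size (default 5e-4).
#' @param early_stopping_patience epochs without held-out improvement before
#'   stopping (default 5).
#' @param val_fraction fraction of positives held out for early stopping
#'   (default 0.1).
#' @param seed integer seed.
#' @return an object of class `enhancer_config`.
#' @export
enhancer_config <- function(proj_dim = 256L, interact_dim = proj_dim, tau = 0.25,
                            batch_size = 256L, epochs = 60L, learning_rate = 5e-4,
                            early_stopping_patience = 5L, val_fraction = 0.1,
                            seed = 1L) {
  stopifnot(tau > 0, proj_dim >= 1, learning_rate > 0, epochs >= 1)
  structure(list(proj_dim = as.integer(proj_dim), interact_dim = as.integer(interact_dim),
                 tau = tau, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "enhancer_config")
}

# Backward pass of row-wise layer normalization (no affine parameters).
layernorm_backward <- function(dZ, Z0, eps = 1e-5) {
  mu <- rowMeans(Z0)
  Xc <- Z0 - mu
  sd_ <- sqrt(rowMeans(Xc^2) + eps)
  Y <- Xc / sd_
  (dZ - rowMeans(dZ) - Y * rowMeans(dZ * Y)) / sd_
}

# Gradients of the diagonal-positive InfoNCE loss for one head's batch.
head_backward <- function(head, fw, dZ) {
  dZ0 <- layernorm_backward(dZ, fw$Z0)
  dW2 <- crossprod(fw$H1, dZ0)
  db2 <- colSums(dZ0)
  dH1 <- dZ0 %*% t(head$W2)
  dH1[fw$H1 <= 0] <- 0
  dW1 <- crossprod(fw$X, dH1)
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the contrastive enhancer
#'
#' Optimizes both projection heads with Adam on the InfoNCE loss over batches
#' of positive pairs, the rest of each batch acting as negatives. A fraction
#' of positives is held out; training stops early when the held-out loss has
#' not improved for `early_stopping_patience` epochs. The interaction head is
#' initialized from the same seed and left at initialization (it is not part
#' of the contrastive objective).
#'
#' @param pairs data.frame of labeled pairs (`drug_id`, `disease_id`,
#'   `label`); only `label == 1` rows are used for training.
#' @param drug_vecs matrix of pooled drug vectors with drug_id rownames.
#' @param disease_vecs matrix of projected disease vectors with disease_id
#'   rownames.
#' @param cfg an [enhancer_config()].
#' @return an object of class `enhancer_fit`: both heads, the interaction
#'   head, per-epoch training and validation loss histories, and the config.
#' @export
train_enhancer <- function(pairs, drug_vecs, disease_vecs, cfg = enhancer_config()) {
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive pairs to train on", call. = FALSE)
  di <- match(pos$drug_id, rownames(drug_vecs))
  ii <- match(pos$disease_id, rownames(disease_vecs))
  if (anyNA(di) || anyNA(ii)) stop("pair references entity without an embedding", call. = FALSE)

  drug_head <- projection_head(ncol(drug_vecs), cfg$proj_dim, seed = derive_seed(cfg$seed, 1L))
  dis_head <- projection_head(ncol(disease_vecs), cfg$proj_dim, seed = derive_seed(cfg$seed, 2L))
  int_head <- interaction_head(cfg$proj_dim, cfg$interact_dim, seed = derive_seed(cfg$seed, 3L))

  n <- nrow(pos)
  n_val <- if (n >= 10L) max(1L, floor(cfg$val_fraction * n)) else 0L
  idx <- with_seed(derive_seed(cfg$seed, 4L), sample.int(n))
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)

  pnames <- c("W1", "b1", "W2", "b2")
  st_d <- adam_new(drug_head[pnames])
  st_i <- adam_new(dis_head[pnames])

  batch_loss_grad <- function(bd, bi, update) {
    Xd <- drug_vecs[bd, , drop = FALSE]
    Xi <- disease_vecs[bi, , drop = FALSE]
    fd <- head_forward(drug_head, Xd, keep = TRUE)
    fi <- head_forward(dis_head, Xi, keep = TRUE)
    S <- tcrossprod(fd$Z, fi$Z) / cfg$tau
    B <- nrow(S)
    rowmax <- apply(S, 1L, max)
    P <- exp(S - rowmax)
    P <- P / rowSums(P)
    loss <- mean(log(rowSums(exp(S - rowmax))) + rowmax - diag(S))
    if (!update) return(list(loss = loss))
    dS <- (P - diag(B)) / B
    dZd <- (dS %*% fi$Z) / cfg$tau
    dZi <- (crossprod(dS, fd$Z)) / cfg$tau
    list(loss = loss,
         gd = head_backward(drug_head, fd, dZd),
         gi = head_backward(dis_head, fi, dZi))
  }

  train_hist <- numeric(0)
  val_hist <- numeric(0)
  best_val <- Inf
  best <- list(drug_head = drug_head, dis_head = dis_head)
  stall <- 0L
  t_step <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 5L, epoch), sample(tr_idx))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      b <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      if (length(b) < 2L) next  # a singleton batch has no negatives
      r <- batch_loss_grad(di[b], ii[b], update = TRUE)
      t_step <- t_step + 1L
      up_d <- adam_step(drug_head[pnames], r$gd, st_d, cfg$learning_rate, t_step)
      drug_head[pnames] <- up_d$params; st_d <- up_d$state
      up_i <- adam_step(dis_head[pnames], r$gi, st_i, cfg$learning_rate, t_step)
      dis_head[pnames] <- up_i$params; st_i <- up_i$state
      losses <- c(losses, r$loss)
    }
    train_hist <- c(train_hist, mean(losses))
    if (n_val > 1L) {
      vl <- batch_loss_grad(di[val_idx], ii[val_idx], update = FALSE)$loss
      val_hist <- c(val_hist, vl)
      if (vl < best_val - 1e-6) {
        best_val <- vl
        best <- list(drug_head = drug_head, dis_head = dis_head)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stopping_patience) break
      }
    } else {
      best <- list(drug_head = drug_head, dis_head = dis_head)
    }
  }
  if (n_val > 1L) {
    drug_head <- best$drug_head
    dis_head <- best$dis_head
  }

  structure(list(drug_head = drug_head, disease_head = dis_head,
                 interaction_head = int_head, loss_history = train_hist,
                 val_history = val_hist, config = cfg, epochs_run = length(train_hist)),
            class = "enhancer_fit")
}

#' Build the enhanced feature matrix for a set of pairs
#'
#' @param pairs data.frame with `drug_id`, `disease_id`.
#' @param drug_vecs,disease_vecs embedding matrices with id rownames.
#' @param fit an `enhancer_fit`, or `NULL` for the no-contrastive ablation
#'   (original blocks only).
#' @return numeric matrix, one row per pair, with attribute `block_dims`.
#' @export
enhanced_matrix <- function(pairs, drug_vecs, disease_vecs, fit = NULL) {
  di <- match(pairs$drug_id, rownames(drug_vecs))
  ii <- match(pairs$disease_id, rownames(disease_vecs))
  if (anyNA(di) || anyNA(ii)) stop("pair references entity without an embedding", call. = FALSE)
  Md <- drug_vecs[di, , drop = FALSE]
  Di <- disease_vecs[ii, , drop = FALSE]
  if (is.null(fit)) {
    X <- cbind(Md, Di)
    attr(X, "block_dims") <- c(M_d = ncol(Md), D_i = ncol(Di))
    return(X)
  }
  Zd <- head_forward(fit$drug_head, Md)
  Zi <- head_forward(fit$disease_head, Di)
  Zint <- interact(Zd, Zi, fit$interaction_head)
  X <- cbind(Md, Di, Zd, Zi, Zint)
  attr(X, "block_dims") <- c(M_d = ncol(Md), D_i = ncol(Di), Z_drug = ncol(Zd),
                             Z_disease = ncol(Zi), Z_interact = ncol(Zint))
  X
}

#' Save / load an enhancer checkpoint
#'
#' Writes the fitted heads to a binary checkpoint beside a JSON manifest
#' (format version, dimensions, temperature, seed, epochs run).
#'
#' @param fit an `enhancer_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_enhancer <- function(fit, dir) {
  stopifnot(inherits(fit, "enhancer_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(fit, file.path(dir, "enhancer.rds"))
  manifest <- list(format = "ddapred-enhancer", version = 1L,
                   input_dim_drug = fit$drug_head$input_dim,
                   input_dim_disease = fit$disease_head$input_dim,
                   proj_dim = fit$config$proj_dim, interact_dim = fit$config$interact_dim,
                   tau = fit$config$tau, seed = fit$config$seed,
                   epochs_run = fit$epochs_run)
  jsonlite::write_json(manifest, file.path(dir, "enhancer.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_enhancer
#' @export
load_enhancer <- function(dir) {
  path <- file.path(dir, "enhancer.rds")
  if (!file.exists(path)) {
    stop(sprintf("no enhancer checkpoint at '%s' (expected enhancer.rds)", dir),
         call. = FALSE)
  }
  readRDS(path)
}
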