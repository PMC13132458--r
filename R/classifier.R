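# Association scoring: a Random Forest over enhanced pair features, scored
# as the mean of per-tree class votes (a soft vote, which is what ranked
# metrics require), binarized at the Youden-optimal threshold selected on
# training-fold scores only.

#' Random Forest configuration
#'
#' Defaults follow the tuned configuration: 250 trees, depth cap 25, at
#' least 5 samples to split a node and 2 per leaf, square-root feature
#' subsampling, balanced class weights.
#'
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param min_samples_leaf minimum terminal node size.
#' @param max_features `"sqrt"`, `"all"`, or a fraction in (0, 1].
#' @param class_weight `"balanced"` or `"none"`.
#' @param bootstrap sample with replacement per tree (disable for exact
#'   single-tree checks).
#' @param seed integer seed.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_estimators = 250L, max_depth = 25L,
                          min_samples_split = 5L, min_samples_leaf = 2L,
                          max_features = "sqrt", class_weight = "balanced",
                          bootstrap = TRUE, seed = 1L) {
  stopifnot(n_estimators >= 1, max_depth >= 1, min_samples_split >= 1,
            min_samples_leaf >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_features = max_features, class_weight = class_weight,
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "forest_config")
}

#' Fit the Random Forest association scorer
#'
#' @param X numeric feature matrix (one row per pair).
#' @param y binary labels (0/1).
#' @param cfg a [forest_config()].
#' @return an object of class `forest_model`.
#' @export
fit_forest <- function(X, y, cfg = forest_config()) {
  X <- as.matrix(X)
  bad <- which(rowSums(!is.finite(X)) > 0)
  if (length(bad) > 0L) {
    stop("non-finite feature rows: ", paste(utils::head(bad, 10L), collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class", call. = FALSE)
  mtry <- switch(as.character(cfg$max_features),
    sqrt = max(1L, floor(sqrt(ncol(X)))),
    all = ncol(X),
    {
      fr <- suppressWarnings(as.numeric(cfg$max_features))
      if (is.na(fr) || fr <= 0 || fr > 1) stop("invalid max_features rule", call. = FALSE)
      max(1L, floor(fr * ncol(X)))
    }
  )
  yf <- factor(y, levels = c(0L, 1L))
  cw <- if (identical(cfg$class_weight, "balanced")) {
    tab <- table(yf)
    as.numeric(length(yf) / (2 * tab))
  } else {
    NULL
  }
  df <- data.frame(X)
  df$.label <- yf
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = cfg$n_estimators, mtry = mtry, max.depth = cfg$max_depth,
    min.node.size = cfg$min_samples_split, min.bucket = cfg$min_samples_leaf,
    replace = cfg$bootstrap, sample.fraction = 1,
    class.weights = cw, probability = TRUE, seed = cfg$seed, num.threads = 1L,
    verbose = FALSE
  )
  structure(list(fit = fit, feature_dim = ncol(X), config = cfg,
                 n_train = nrow(X)), class = "forest_model")
}

#' Predict association scores
#'
#' Scores are the forest's mean per-tree vote for the positive class, so they
#' lie in \[0, 1\] and each row is scored independently.
#'
#' @param m a `forest_model`.
#' @param X feature matrix with `m$feature_dim` columns.
#' @return numeric score vector.
#' @export
predict_scores <- function(m, X) {
  stopifnot(inherits(m, "forest_model"))
  X <- as.matrix(X)
  if (ncol(X) != m$feature_dim) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(X), m$feature_dim), call. = FALSE)
  }
  pred <- stats::predict(m$fit, data = data.frame(X), num.threads = 1L)
  unname(pred$predictions[, "1"])
}

#' Select the Youden-optimal threshold
#'
#' Scans all candidate thresholds (midpoints between adjacent distinct sorted
#' scores, plus -Inf/+Inf sentinels) and maximizes J = TPR - FPR, with a
#' prediction rule of `score >= theta`. Ties are broken toward the smallest
#' threshold, favoring sensitivity.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @return an object of class `threshold_result` with `theta_star`, `J_star`,
#'   `tpr_at`, `fpr_at`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to select a threshold", call. = FALSE)
  }
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  best <- NULL
  for (th in candidates) {
    pred <- scores >= th
    tpr <- sum(pred & labels == 1L) / n_pos
    fpr <- sum(pred & labels == 0L) / n_neg
    J <- tpr - fpr
    if (is.null(best) || J > best$J_star + 1e-12) {
      best <- list(theta_star = th, J_star = J, tpr_at = tpr, fpr_at = fpr)
    }
  }
  structure(best, class = "threshold_result")
}

#' Binarize scores at a threshold
#'
#' The interval is closed at the threshold: a score equal to `theta` is
#' called positive.
#'
#' @param scores numeric scores.
#' @param theta threshold (may be -Inf / +Inf sentinels).
#' @return integer 0/1 vector.
#' @export
binarize <- function(scores, theta) {
  as.integer(scores >= theta)
}

#' Save / load a forest checkpoint
#'
#' @param m a `forest_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_forest <- function(m, dir) {
  stopifnot(inherits(m, "forest_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(m, file.path(dir, "forest.rds"))
  jsonlite::write_json(
    list(format = "ddapred-forest", version = 1L, feature_dim = m$feature_dim,
         n_train = m$n_train, config = unclass(m$config)),
    file.path(dir, "forest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_forest
#' @export
load_forest <- function(dir) {
  path <- file.path(dir, "forest.rds")
  if (!file.exists(path)) {
    stop(sprintf("no forest checkpoint at '%s' (expected forest.rds)", dir),
         call. = FALSE)
  }
  readRDS(path)
}
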