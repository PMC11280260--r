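#' Train/validation/test split specification
#'
#' @param train,val,test positive fractions summing to 1 (defaults
#'   0.7/0.1/0.2).
#' @param seed integer seed for the shuffle.
#' @param stratified stratify the split by label (default `TRUE`).
#' @return A `split_spec` object.
#' @export
split_spec <- function(train = 0.7, val = 0.1, test = 0.2, seed = 1L,
                       stratified = TRUE) {
  stopifnot(train > 0, val > 0, test > 0,
            abs(train + val + test - 1) < 1e-9)
  structure(list(fractions = c(train = train, val = val, test = test),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Allocate n items to k groups with target fractions, by largest remainder.
.allocate <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    bump <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[bump] <- base[bump] + 1L
  }
  as.integer(base)
}

# Class-by-group allocation matrix: group totals are hit exactly while each
# class is spread proportionally (Hamilton apportionment per class, then a
# repair pass to reconcile column sums with the exact group targets).
.stratified_counts <- function(class_sizes, group_sizes) {
  k <- length(group_sizes)
  n <- sum(class_sizes)
  counts <- t(vapply(class_sizes, function(nc) .allocate(nc, group_sizes / n),
                     integer(k)))
  repeat {
    excess <- colSums(counts) - group_sizes
    over <- which(excess > 0)
    under <- which(excess < 0)
    if (length(over) == 0L) break
    s1 <- over[1L]
    s2 <- under[1L]
    c_move <- which.max(counts[, s1])
    counts[c_move, s1] <- counts[c_move, s1] - 1L
    counts[c_move, s2] <- counts[c_move, s2] + 1L
  }
  counts
}

# Seeded assignment of indices to groups with exact group sizes, stratified
# on y when requested.
.assign_groups <- function(y, group_sizes, seed, stratified = TRUE) {
  n <- length(y)
  stopifnot(sum(group_sizes) == n)
  assign <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (stratified) {
    groups <- split(seq_len(n), y)
    counts <- .stratified_counts(lengths(groups), group_sizes)
    for (ci in seq_along(groups)) {
      idx <- groups[[ci]][sample.int(length(groups[[ci]]))]
      assign[idx] <- rep(seq_along(group_sizes), times = counts[ci, ])
    }
  } else {
    idx <- sample.int(n)
    assign[idx] <- rep(seq_along(group_sizes), times = group_sizes)
  }
  assign
}

# Seeded, optionally stratified validation mask covering ~val_fraction of y.
.val_mask <- function(y, val_fraction, seed, stratified = TRUE) {
  n <- length(y)
  mask <- logical(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
  for (idx in groups) {
    take <- round(length(idx) * val_fraction)
    if (take > 0L) mask[sample(idx, take)] <- TRUE
  }
  mask
}

# Assign each index to a split id (1=train, 2=val, 3=test), seeded,
# optionally stratified on y. Split sizes are exact for the whole set.
.split_indices <- function(y, spec) {
  sizes <- .allocate(length(y), spec$fractions)
  .assign_groups(y, sizes, spec$seed, spec$stratified)
}

#' Split a tensor set into train/validation/test parts
#'
#' Disjoint, exhaustive and reproducible by seed; stratified on labels by
#' default so each part keeps the overall prevalence.
#'
#' @param ts a `pair_tensor_set` with at least 10 pairs.
#' @param spec a [split_spec()].
#' @return Named list of `pair_tensor_set`s: `train`, `val`, `test`.
#' @export
split_pairs <- function(ts, spec = split_spec()) {
  stopifnot(inherits(ts, "pair_tensor_set"), inherits(spec, "split_spec"))
  n <- ts_n(ts)
  if (n < 10L) stop("need at least 10 pairs to split, have ", n)
  assign <- .split_indices(ts$y, spec)
  if (any(tabulate(assign, 3L) == 0L)) {
    stop("a split part would be empty at n=", n)
  }
  list(
    train = ts_subset(ts, which(assign == 1L)),
    val = ts_subset(ts, which(assign == 2L)),
    test = ts_subset(ts, which(assign == 3L))
  )
}

# Scale both input blocks of a tensor set with the model's stored scalers.
.scale_ts <- function(model, ts) {
  list(
    X_cell = apply_scaler(model$scaler_cell, ts$X_cell),
    X_drug = apply_scaler(model$scaler_drug, ts$X_drug)
  )
}

#' Predicted sensitivity scores for a tensor set
#'
#' Applies the training-data scalers stored in the model, then the forward
#' pass.
#'
#' @param model a trained `deepdra_model`.
#' @param ts a `pair_tensor_set` on the raw (unscaled) feature scale.
#' @param chunk_size rows scored per forward pass (memory control).
#' @return Numeric vector of probabilities, one per pair.
#' @export
predict_scores <- function(model, ts, chunk_size = 2048L) {
  stopifnot(inherits(model, "deepdra_model"), inherits(ts, "pair_tensor_set"))
  if (is.null(model$scaler_cell)) {
    stop("model has no stored scalers; train it (or load a checkpoint) first")
  }
  sc <- .scale_ts(model, ts)
  n <- ts_n(ts)
  out <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    out[s:e] <- forward(model,
                        sc$X_cell[s:e, , drop = FALSE],
                        sc$X_drug[s:e, , drop = FALSE])$p
  }
  out
}

#' Train the multi-task model on labeled pairs
#'
#' Fits feature scalers on the training pairs only, initializes the model
#' from the config seed, then runs `cfg$epochs` epochs of shuffled
#' mini-batch optimization of the composite loss. No early stopping by
#' default; set `cfg$early_stopping_patience` to stop on stalled validation
#' AUPRC.
#'
#' @param cfg a `deepdra_config` whose input dims match the tensor sets.
#' @param train training `pair_tensor_set` (raw feature scale).
#' @param val optional validation `pair_tensor_set`; enables per-epoch
#'   validation metrics in the history.
#' @param verbose print per-epoch progress.
#' @return List with `model` (trained, scalers and training keys attached)
#'   and `history` (one row per epoch: loss components and validation
#'   metrics).
#' @export
train_model <- function(cfg, train, val = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "deepdra_config"), inherits(train, "pair_tensor_set"))
  if (ncol(train$X_cell) != cfg$cell_input_dim ||
      ncol(train$X_drug) != cfg$drug_input_dim) {
    stop("tensor set dims (", ncol(train$X_cell), ", ", ncol(train$X_drug),
         ") do not match config (", cfg$cell_input_dim, ", ",
         cfg$drug_input_dim, ")")
  }
  model <- init_model(cfg)
  model$scaler_cell <- fit_scaler(train$X_cell, cfg$scaling)
  model$scaler_drug <- fit_scaler(train$X_drug, cfg$scaling)
  model$training_keys <- unique(paste(train$pair_keys$cell_line_id,
                                      train$pair_keys$drug_id, sep = "\r"))
  Xc <- apply_scaler(model$scaler_cell, train$X_cell)
  Xd <- apply_scaler(model$scaler_drug, train$X_drug)
  y <- train$y
  n <- length(y)
  opt <- .opt_init(model$params, cfg)

  val_sc <- if (!is.null(val)) .scale_ts(model, val)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  hist_rows <- vector("list", cfg$epochs)
  best_val <- -Inf
  stall <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    acc <- c(l_cell_ae = 0, l_drug_ae = 0, l_classifier = 0, total = 0)
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      xc <- Xc[idx, , drop = FALSE]
      xd <- Xd[idx, , drop = FALSE]
      yb <- y[idx]
      cache <- .forward_cache(model, xc, xd)
      lb <- composite_loss(model, xc, xd, yb, cache)
      if (!is.finite(lb$total)) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (drug AE %g, cell AE %g, classifier %g); lower the learning rate",
          epoch, lb$l_drug_ae, lb$l_cell_ae, lb$l_classifier
        ))
      }
      w_batch <- length(idx) / n
      acc <- acc + w_batch * c(lb$l_cell_ae, lb$l_drug_ae, lb$l_classifier, lb$total)
      grads <- .backward(model, cache, xc, xd, yb)
      opt <- .opt_step(opt, model$params, grads)
    }
    row <- data.frame(epoch = epoch, l_cell_ae = acc[[1]], l_drug_ae = acc[[2]],
                      l_classifier = acc[[3]], total = acc[[4]],
                      val_auprc = NA_real_, val_auc = NA_real_,
                      val_accuracy = NA_real_)
    if (!is.null(val)) {
      vp <- drop(.forward_cache(model, val_sc$X_cell, val_sc$X_drug)$prob)
      row$val_auprc <- auprc_step(val$y, vp)
      row$val_auc <- auc_concordance(val$y, vp)
      row$val_accuracy <- mean((vp > 0.5) == (val$y == 1))
    }
    hist_rows[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %2d  loss %.5f  val AUPRC %s",
                      epoch, acc[[4]], .fmt(row$val_auprc)))
    }
    if (!is.null(cfg$early_stopping_patience) && !is.null(val) &&
        !is.na(row$val_auprc)) {
      if (row$val_auprc > best_val + 1e-9) {
        best_val <- row$val_auprc
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stopping_patience) {
          hist_rows <- hist_rows[seq_len(epoch)]
          break
        }
      }
    }
  }
  list(model = model, history = do.call(rbind, hist_rows))
}

#' Evaluate a trained model on a tensor set
#'
#' @param model a trained `deepdra_model`.
#' @param ts a nonempty `pair_tensor_set` (raw feature scale).
#' @param threshold classification cutoff (default 0.5).
#' @return A `metrics_report` (see [compute_metrics()]); rank metrics are
#'   `NA` when only one class is present.
#' @export
evaluate <- function(model, ts, threshold = 0.5) {
  stopifnot(ts_n(ts) > 0L)
  compute_metrics(ts$y, predict_scores(model, ts), threshold)
}

#' Stratified k-fold cross-validation
#'
#' Each fold serves once as the test part; the remaining pairs are split
#' 7:1 into training and validation (so the overall proportions mirror the
#' 0.7/0.1/0.2 design), the model is trained from scratch, and the held-out
#' fold is evaluated.
#'
#' @param cfg a `deepdra_config`.
#' @param ts a `pair_tensor_set` with at least `k` pairs.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment (default: `cfg$seed`).
#' @param stratified stratify folds by label (default `TRUE`).
#' @param verbose print per-fold progress.
#' @return List with `folds` (one `metrics_report` per fold), `summary`
#'   (data.frame of per-metric mean and sd), and `assignments` (fold id per
#'   pair).
#' @export
kfold_cv <- function(cfg, ts, k = 5L, seed = cfg$seed, stratified = TRUE,
                     verbose = FALSE) {
  stopifnot(inherits(cfg, "deepdra_config"), inherits(ts, "pair_tensor_set"),
            k >= 2L, ts_n(ts) >= k)
  n <- ts_n(ts)
  fold_sizes <- .allocate(n, rep(1 / k, k))
  fold <- .assign_groups(ts$y, fold_sizes, seed, stratified)

  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_ts <- ts_subset(ts, which(fold == f))
    rest <- ts_subset(ts, which(fold != f))
    # carve a 1/8 validation slice out of the non-test side (7:1 train:val,
    # mirroring the 0.7/0.1 proportions)
    vm <- .val_mask(rest$y, 1 / 8, seed + f, stratified)
    tr <- ts_subset(rest, which(!vm))
    va <- ts_subset(rest, which(vm))
    fit <- train_model(cfg, tr, va)
    reports[[f]] <- evaluate(fit$model, test_ts)
    if (verbose) message(sprintf("fold %d/%d  AUPRC %s", f, k,
                                 .fmt(reports[[f]]$auprc)))
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc", "auprc")
  vals <- vapply(reports, function(r) unlist(r[metric_names]),
                 numeric(length(metric_names)))
  summary <- data.frame(
    metric = metric_names,
    mean = rowMeans(vals, na.rm = TRUE),
    sd = apply(vals, 1L, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  list(folds = reports, summary = summary, assignments = fold)
}

#' Train on one cohort, test on another
#'
#' The cross-cohort generalization harness: the model (and its feature
#' scalers) are fit only on `train_ts`; `test_ts` is scored once. Both
#' tensor sets must be built over identical feature spaces.
#'
#' @param cfg a `deepdra_config`.
#' @param train_ts training-cohort `pair_tensor_set`.
#' @param test_ts test-cohort `pair_tensor_set` on the same features.
#' @param val_fraction fraction of the training cohort carved out as the
#'   validation slice (default 1/8, mirroring the 0.7/0.1 design).
#' @return A `metrics_report` on `test_ts`.
#' @export
cross_cohort_eval <- function(cfg, train_ts, test_ts, val_fraction = 1 / 8) {
  stopifnot(inherits(train_ts, "pair_tensor_set"),
            inherits(test_ts, "pair_tensor_set"))
  if (ncol(train_ts$X_cell) != ncol(test_ts$X_cell)) {
    stop("cell feature spaces differ: ", ncol(train_ts$X_cell), " vs ",
         ncol(test_ts$X_cell), " features")
  }
  if (!identical(train_ts$cell_feature_ids, test_ts$cell_feature_ids)) {
    stop("cell feature IDs differ between cohorts; intersect features first")
  }
  if (ncol(train_ts$X_drug) != ncol(test_ts$X_drug)) {
    stop("drug feature spaces differ: ", ncol(train_ts$X_drug), " vs ",
         ncol(test_ts$X_drug), " features")
  }
  vm <- .val_mask(train_ts$y, val_fraction, cfg$seed, stratified = TRUE)
  tr <- ts_subset(train_ts, which(!vm))
  va <- ts_subset(train_ts, which(vm))
  fit <- train_model(cfg, tr, va)
  evaluate(fit$model, test_ts)
}
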