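.VARIANTS <- c("full", "cell_ae_only", "drug_ae_only", "no_ae")

#' Model configuration
#'
#' Hyperparameters of the multi-task model. Defaults follow the reference
#' architecture: autoencoder hidden layer of 256 ReLU units, latent layer of
#' 50 units, classifier hidden layer of 128 ReLU units with a sigmoid output,
#' composite-loss weights a = b = c = 1, 25 training epochs, learning rate
#' 0.01 with the Adadelta optimizer.
#'
#' @param cell_input_dim width of the concatenated cell-line vector.
#' @param drug_input_dim width of the drug feature vector.
#' @param seed integer seed governing parameter initialization and batch
#'   shuffling; mandatory for reproducibility.
#' @param ae_hidden autoencoder hidden width (default 256).
#' @param ae_latent autoencoder latent width (default 50).
#' @param mlp_hidden classifier hidden width (default 128).
#' @param loss_weights named numeric `c(drug=, cell=, classifier=)`:
#'   non-negative weights of the drug-AE, cell-AE and classifier loss terms.
#' @param epochs training epochs (default 25).
#' @param learning_rate optimizer learning rate (default 0.01).
#' @param optimizer `"adam"` (default) or `"adadelta"`. The default learning
#'   rate of 0.01 is a conventional Adam setting; Adadelta users will usually
#'   want a much larger `learning_rate` (its canonical value is 1).
#' @param batch_size mini-batch size (default 128; at the default Adam
#'   learning rate, substantially smaller batches make late-epoch training
#'   visibly unstable on data of the bundled synthetic scale).
#' @param latent_activation activation of the autoencoder bottleneck:
#'   `"linear"` (default) or `"relu"`. The hidden layers are always ReLU;
#'   a linear bottleneck is the standard autoencoder design and preserves
#'   the sign of latent factors, which a rectified bottleneck discards.
#' @param variant which components are present: `"full"` (both
#'   autoencoders), `"cell_ae_only"`, `"drug_ae_only"` (the other side's raw
#'   vector is passed straight to the classifier), or `"no_ae"` (plain MLP on
#'   the concatenated raw inputs).
#' @param scaling feature scaling fit on training data: `"zscore"`
#'   (default), `"minmax"` or `"none"`.
#' @param early_stopping_patience optional integer; if set, training stops
#'   once validation AUPRC has not improved for this many epochs. `NULL`
#'   (default) trains the fixed number of epochs.
#' @return A `deepdra_config` object.
#' @export
deepdra_config <- function(cell_input_dim, drug_input_dim, seed,
                           ae_hidden = 256L, ae_latent = 50L, mlp_hidden = 128L,
                           loss_weights = c(drug = 1, cell = 1, classifier = 1),
                           epochs = 25L, learning_rate = 0.01,
                           optimizer = c("adam", "adadelta"),
                           batch_size = 128L,
                           latent_activation = c("linear", "relu"),
                           variant = c("full", "cell_ae_only", "drug_ae_only", "no_ae"),
                           scaling = c("zscore", "minmax", "none"),
                           early_stopping_patience = NULL) {
  optimizer <- match.arg(optimizer)
  latent_activation <- match.arg(latent_activation)
  variant <- match.arg(variant)
  scaling <- match.arg(scaling)
  stopifnot(
    length(cell_input_dim) == 1L, cell_input_dim >= 1L,
    length(drug_input_dim) == 1L, drug_input_dim >= 1L,
    ae_hidden >= 1L, ae_latent >= 1L, mlp_hidden >= 1L,
    epochs >= 1L, learning_rate > 0, batch_size >= 1L,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  lw <- loss_weights
  if (is.null(names(lw))) names(lw) <- c("drug", "cell", "classifier")
  stopifnot(all(c("drug", "cell", "classifier") %in% names(lw)),
            all(lw >= 0))
  if (!is.null(early_stopping_patience)) {
    stopifnot(early_stopping_patience >= 1L)
  }
  structure(
    list(
      cell_input_dim = as.integer(cell_input_dim),
      drug_input_dim = as.integer(drug_input_dim),
      ae_hidden = as.integer(ae_hidden),
      ae_latent = as.integer(ae_latent),
      mlp_hidden = as.integer(mlp_hidden),
      loss_weights = lw[c("drug", "cell", "classifier")],
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      optimizer = optimizer,
      batch_size = as.integer(batch_size),
      seed = as.integer(seed),
      latent_activation = latent_activation,
      variant = variant,
      scaling = scaling,
      early_stopping_patience = early_stopping_patience
    ),
    class = "deepdra_config"
  )
}

#' @export
print.deepdra_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "deepdra_config [%s]: cell %d, drug %d -> AE %d/%d, MLP %d\n",
      "  weights a=%g b=%g c=%g; %d epochs, lr %g (%s), batch %d, scaling %s, seed %d\n"
    ),
    x$variant, x$cell_input_dim, x$drug_input_dim, x$ae_hidden, x$ae_latent,
    x$mlp_hidden, x$loss_weights["drug"], x$loss_weights["cell"],
    x$loss_weights["classifier"], x$epochs, x$learning_rate, x$optimizer,
    x$batch_size, x$scaling, x$seed
  ))
  invisible(x)
}

# ---- layer primitives -------------------------------------------------------

# Glorot-uniform initialization; biases start at zero.
.init_dense <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  list(
    W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
    b = numeric(fan_out)
  )
}

.affine <- function(X, W, b) {
  Z <- X %*% W
  Z + rep(b, each = nrow(Z))
}

.relu <- function(Z) Z * (Z > 0)

.sigmoid <- function(z) 1 / (1 + exp(-z))

# classifier input width per variant
.cls_input_dim <- function(cfg) {
  switch(cfg$variant,
    full = 2L * cfg$ae_latent,
    cell_ae_only = cfg$ae_latent + cfg$drug_input_dim,
    drug_ae_only = cfg$cell_input_dim + cfg$ae_latent,
    no_ae = cfg$cell_input_dim + cfg$drug_input_dim
  )
}

.has_cell_ae <- function(cfg) cfg$variant %in% c("full", "cell_ae_only")
.has_drug_ae <- function(cfg) cfg$variant %in% c("full", "drug_ae_only")

#' Initialize a model from a configuration
#'
#' Parameters are drawn from a seeded Glorot-uniform scheme; two calls with
#' the same config produce identical parameters. Variants lacking an
#' autoencoder contain no parameters for it.
#'
#' @param cfg a `deepdra_config`.
#' @return A `deepdra_model` (config, parameter list, empty scaler slots).
#' @export
init_model <- function(cfg) {
  stopifnot(inherits(cfg, "deepdra_config"))
  params <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  if (.has_cell_ae(cfg)) {
    params$cell_enc1 <- .init_dense(cfg$cell_input_dim, cfg$ae_hidden)
    params$cell_enc2 <- .init_dense(cfg$ae_hidden, cfg$ae_latent)
    params$cell_dec1 <- .init_dense(cfg$ae_latent, cfg$ae_hidden)
    params$cell_dec2 <- .init_dense(cfg$ae_hidden, cfg$cell_input_dim)
  }
  if (.has_drug_ae(cfg)) {
    params$drug_enc1 <- .init_dense(cfg$drug_input_dim, cfg$ae_hidden)
    params$drug_enc2 <- .init_dense(cfg$ae_hidden, cfg$ae_latent)
    params$drug_dec1 <- .init_dense(cfg$ae_latent, cfg$ae_hidden)
    params$drug_dec2 <- .init_dense(cfg$ae_hidden, cfg$drug_input_dim)
  }
  params$cls1 <- .init_dense(.cls_input_dim(cfg), cfg$mlp_hidden)
  params$cls2 <- .init_dense(cfg$mlp_hidden, 1L)
  structure(
    list(cfg = cfg, params = params, scaler_cell = NULL, scaler_drug = NULL,
         training_keys = NULL),
    class = "deepdra_model"
  )
}

#' @export
print.deepdra_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("deepdra_model [%s]: %s parameters%s\n",
              x$cfg$variant, format(np, big.mark = ","),
              if (is.null(x$scaler_cell)) " (untrained)" else ""))
  invisible(x)
}

# save/restore the global RNG state so seeded model operations do not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- forward / backward -----------------------------------------------------

# Full forward pass keeping intermediate activations for backprop.
.forward_cache <- function(model, x_cell, x_drug) {
  cfg <- model$cfg
  p <- model$params
  if (ncol(x_cell) != cfg$cell_input_dim) {
    stop("cell input width ", ncol(x_cell), " != config ", cfg$cell_input_dim)
  }
  if (ncol(x_drug) != cfg$drug_input_dim) {
    stop("drug input width ", ncol(x_drug), " != config ", cfg$drug_input_dim)
  }
  act_z <- if (identical(cfg$latent_activation, "relu")) .relu else identity
  cache <- list()
  if (.has_cell_ae(cfg)) {
    cache$c_h1 <- .relu(.affine(x_cell, p$cell_enc1$W, p$cell_enc1$b))
    cache$c_z <- act_z(.affine(cache$c_h1, p$cell_enc2$W, p$cell_enc2$b))
    cache$c_d1 <- .relu(.affine(cache$c_z, p$cell_dec1$W, p$cell_dec1$b))
    cache$c_rec <- .affine(cache$c_d1, p$cell_dec2$W, p$cell_dec2$b) # linear output
    cell_repr <- cache$c_z
  } else {
    cell_repr <- x_cell
  }
  if (.has_drug_ae(cfg)) {
    cache$d_h1 <- .relu(.affine(x_drug, p$drug_enc1$W, p$drug_enc1$b))
    cache$d_z <- act_z(.affine(cache$d_h1, p$drug_enc2$W, p$drug_enc2$b))
    cache$d_d1 <- .relu(.affine(cache$d_z, p$drug_dec1$W, p$drug_dec1$b))
    cache$d_rec <- .affine(cache$d_d1, p$drug_dec2$W, p$drug_dec2$b)
    drug_repr <- cache$d_z
  } else {
    drug_repr <- x_drug
  }
  cache$cls_in <- cbind(cell_repr, drug_repr)
  cache$m1 <- .relu(.affine(cache$cls_in, p$cls1$W, p$cls1$b))
  cache$logit <- .affine(cache$m1, p$cls2$W, p$cls2$b)
  cache$prob <- .sigmoid(cache$logit)
  cache
}

#' Forward pass of the model
#'
#' @param model a `deepdra_model`.
#' @param x_cell numeric matrix, batch x cell_input_dim. Inputs are assumed
#'   to be on the scale the model was trained on; use [predict_scores()] for
#'   automatic application of the stored training scalers.
#' @param x_drug numeric matrix, batch x drug_input_dim.
#' @return List with `p` (probabilities in \[0, 1\]), `recon_cell` and
#'   `recon_drug` (reconstructions; `NULL` for variants lacking that
#'   autoencoder), and `latent_cell`/`latent_drug` (`NULL` likewise).
#' @export
forward <- function(model, x_cell, x_drug) {
  stopifnot(inherits(model, "deepdra_model"))
  if (!is.matrix(x_cell)) x_cell <- matrix(x_cell, nrow = 1L)
  if (!is.matrix(x_drug)) x_drug <- matrix(x_drug, nrow = 1L)
  cache <- .forward_cache(model, x_cell, x_drug)
  list(
    p = drop(cache$prob),
    recon_cell = cache$c_rec,
    recon_drug = cache$d_rec,
    latent_cell = cache$c_z,
    latent_drug = cache$d_z
  )
}

#' Mean squared error over all matrix elements
#'
#' The autoencoder reconstruction loss.
#'
#' @param y,y_hat numeric matrices (or vectors) of identical shape.
#' @return Non-negative scalar; 0 iff the inputs are equal.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat) ||
      (is.matrix(y) && is.matrix(y_hat) && !all(dim(y) == dim(y_hat)))) {
    stop("mse_loss: shape mismatch")
  }
  mean((y - y_hat)^2)
}

#' Binary cross-entropy of predicted probabilities
#'
#' The classifier loss. Probabilities are clamped to
#' \[1e-7, 1 - 1e-7\] to avoid log(0).
#'
#' @param y 0/1 vector of true labels.
#' @param p predicted probabilities of the same length.
#' @param eps clamping bound (default 1e-7).
#' @return Non-negative scalar: `-mean(y*log(p) + (1-y)*log(1-p))`.
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) stop("bce_loss: length mismatch")
  stopifnot(all(y %in% c(0, 1)))
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Composite multi-task loss of a batch
#'
#' Weighted sum `a * drug-AE MSE + b * cell-AE MSE + c * classifier BCE`,
#' with weights from `cfg$loss_weights`. Components absent from the variant
#' are exactly 0.
#'
#' @param model a `deepdra_model`.
#' @param x_cell,x_drug input batch (already on model scale).
#' @param y 0/1 labels of the batch.
#' @param cache optional precomputed result of an internal forward pass;
#'   recomputed when missing.
#' @return A `loss_breakdown`: `l_cell_ae`, `l_drug_ae`, `l_classifier`,
#'   `total`, `weights`.
#' @export
composite_loss <- function(model, x_cell, x_drug, y, cache = NULL) {
  stopifnot(inherits(model, "deepdra_model"))
  if (!is.matrix(x_cell)) x_cell <- matrix(x_cell, nrow = 1L)
  if (!is.matrix(x_drug)) x_drug <- matrix(x_drug, nrow = 1L)
  if (is.null(cache)) cache <- .forward_cache(model, x_cell, x_drug)
  w <- model$cfg$loss_weights
  l_cell <- if (.has_cell_ae(model$cfg)) mse_loss(x_cell, cache$c_rec) else 0
  l_drug <- if (.has_drug_ae(model$cfg)) mse_loss(x_drug, cache$d_rec) else 0
  l_cls <- bce_loss(y, drop(cache$prob))
  structure(
    list(
      l_cell_ae = l_cell,
      l_drug_ae = l_drug,
      l_classifier = l_cls,
      total = w[["drug"]] * l_drug + w[["cell"]] * l_cell + w[["classifier"]] * l_cls,
      weights = w
    ),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.6f (drug AE %.6f, cell AE %.6f, classifier %.6f)\n",
    x$total, x$l_drug_ae, x$l_cell_ae, x$l_classifier
  ))
  invisible(x)
}

# Gradients of the composite loss w.r.t. every parameter, by backprop.
# Returns a list parallel to model$params with $W and $b entries.
.backward <- function(model, cache, x_cell, x_drug, y) {
  cfg <- model$cfg
  p <- model$params
  w <- cfg$loss_weights
  n <- nrow(x_cell)
  g <- list()

  # classifier head: BCE through sigmoid
  dlogit <- w[["classifier"]] * (cache$prob - y) / n # n x 1
  g$cls2 <- list(W = crossprod(cache$m1, dlogit), b = colSums(dlogit))
  dm1 <- tcrossprod(dlogit, p$cls2$W) * (cache$m1 > 0)
  g$cls1 <- list(W = crossprod(cache$cls_in, dm1), b = colSums(dm1))
  dcls_in <- tcrossprod(dm1, p$cls1$W)

  left_dim <- if (.has_cell_ae(cfg)) cfg$ae_latent else cfg$cell_input_dim
  d_cell_repr <- dcls_in[, seq_len(left_dim), drop = FALSE]
  d_drug_repr <- dcls_in[, -seq_len(left_dim), drop = FALSE]

  relu_z <- identical(cfg$latent_activation, "relu")
  if (.has_cell_ae(cfg)) {
    drec <- (2 * w[["cell"]] / (n * cfg$cell_input_dim)) * (cache$c_rec - x_cell)
    g$cell_dec2 <- list(W = crossprod(cache$c_d1, drec), b = colSums(drec))
    dd1 <- tcrossprod(drec, p$cell_dec2$W) * (cache$c_d1 > 0)
    g$cell_dec1 <- list(W = crossprod(cache$c_z, dd1), b = colSums(dd1))
    dz <- tcrossprod(dd1, p$cell_dec1$W) + d_cell_repr
    if (relu_z) dz <- dz * (cache$c_z > 0)
    g$cell_enc2 <- list(W = crossprod(cache$c_h1, dz), b = colSums(dz))
    dh1 <- tcrossprod(dz, p$cell_enc2$W) * (cache$c_h1 > 0)
    g$cell_enc1 <- list(W = crossprod(x_cell, dh1), b = colSums(dh1))
  }
  if (.has_drug_ae(cfg)) {
    drec <- (2 * w[["drug"]] / (n * cfg$drug_input_dim)) * (cache$d_rec - x_drug)
    g$drug_dec2 <- list(W = crossprod(cache$d_d1, drec), b = colSums(drec))
    dd1 <- tcrossprod(drec, p$drug_dec2$W) * (cache$d_d1 > 0)
    g$drug_dec1 <- list(W = crossprod(cache$d_z, dd1), b = colSums(dd1))
    dz <- tcrossprod(dd1, p$drug_dec1$W) + d_drug_repr
    if (relu_z) dz <- dz * (cache$d_z > 0)
    g$drug_enc2 <- list(W = crossprod(cache$d_h1, dz), b = colSums(dz))
    dh1 <- tcrossprod(dz, p$drug_enc2$W) * (cache$d_h1 > 0)
    g$drug_enc1 <- list(W = crossprod(x_drug, dh1), b = colSums(dh1))
  }
  g
}

# ---- optimizers -------------------------------------------------------------

.opt_init <- function(params, cfg) {
  # state buffers are mutated in place by the compiled kernels, so each slot
  # needs its own freshly allocated zeros
  zeros <- function() lapply(params, function(pr) list(
    W = array(0, dim = dim(pr$W)), b = numeric(length(pr$b))
  ))
  switch(cfg$optimizer,
    adadelta = list(kind = "adadelta", lr = cfg$learning_rate,
                    rho = 0.95, eps = 1e-6, Eg = zeros(), Ed = zeros()),
    adam = list(kind = "adam", lr = cfg$learning_rate,
                beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                m = zeros(), v = zeros(), t = 0L)
  )
}

# One optimizer step. Parameters and optimizer state are mutated in place by
# the compiled kernels (both are freshly allocated and owned by the training
# loop); returns the updated opt bookkeeping.
.opt_step <- function(opt, params, grads) {
  if (opt$kind == "adadelta") {
    for (nm in names(grads)) {
      for (s in c("W", "b")) {
        adadelta_update_(params[[nm]][[s]], grads[[nm]][[s]],
                         opt$Eg[[nm]][[s]], opt$Ed[[nm]][[s]],
                         opt$lr, opt$rho, opt$eps)
      }
    }
  } else {
    opt$t <- opt$t + 1L
    for (nm in names(grads)) {
      for (s in c("W", "b")) {
        adam_update_(params[[nm]][[s]], grads[[nm]][[s]],
                     opt$m[[nm]][[s]], opt$v[[nm]][[s]],
                     opt$lr, opt$beta1, opt$beta2, opt$eps, opt$t)
      }
    }
  }
  opt
}

# ---- checkpointing ----------------------------------------------------------

.CHECKPOINT_FORMAT <- "deepdra-checkpoint"
.CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' The checkpoint is a single self-describing file (RDS archive) embedding
#' the full configuration, all parameters, the training-data scalers and the
#' training pair keys; [load_model()] reproduces predictions bit-exactly.
#'
#' @param model a `deepdra_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deepdra_model"))
  saveRDS(list(
    format = .CHECKPOINT_FORMAT,
    version = .CHECKPOINT_VERSION,
    config = unclass(model$cfg),
    params = model$params,
    scaler_cell = model$scaler_cell,
    scaler_drug = model$scaler_drug,
    training_keys = model$training_keys
  ), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_model()].
#' @param cell_input_dim,drug_input_dim optional expected input widths;
#'   loading fails if the checkpoint declares different ones.
#' @return A `deepdra_model`.
#' @export
load_model <- function(path, cell_input_dim = NULL, drug_input_dim = NULL) {
  ck <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read checkpoint ", path, ": ", conditionMessage(e))
  })
  if (!is.list(ck) || !identical(ck$format, .CHECKPOINT_FORMAT)) {
    stop("not a deepdra checkpoint: ", path)
  }
  if (!identical(ck$version, .CHECKPOINT_VERSION)) {
    stop("unsupported checkpoint version: ", ck$version)
  }
  cfg <- structure(ck$config, class = "deepdra_config")
  if (!is.null(cell_input_dim) && cfg$cell_input_dim != cell_input_dim) {
    stop("checkpoint cell_input_dim ", cfg$cell_input_dim,
         " != expected ", cell_input_dim)
  }
  if (!is.null(drug_input_dim) && cfg$drug_input_dim != drug_input_dim) {
    stop("checkpoint drug_input_dim ", cfg$drug_input_dim,
         " != expected ", drug_input_dim)
  }
  structure(
    list(cfg = cfg, params = ck$params, scaler_cell = ck$scaler_cell,
         scaler_drug = ck$scaler_drug, training_keys = ck$training_keys),
    class = "deepdra_model"
  )
}
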