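# Small random batch on a small model, for loss/gradient checks.
toy_batch <- function(n = 6L, dc = 7L, dd = 5L, seed = 4L) {
  set.seed(seed)
  list(
    xc = matrix(rnorm(n * dc), n, dc),
    xd = matrix(rnorm(n * dd), n, dd),
    y = rbinom(n, 1, 0.5)
  )
}

toy_config <- function(variant = "full", ...) {
  deepdra_config(7L, 5L, seed = 3L, ae_hidden = 6L, ae_latent = 3L,
                 mlp_hidden = 4L, variant = variant, ...)
}

test_that("elementary losses match their closed forms", {
  expect_equal(mse_loss(c(1, 0), c(0, 0)), 0.5)
  expect_equal(mse_loss(c(2), c(0)), 4)
  expect_equal(mse_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_error(mse_loss(1:3, 1:2), "shape mismatch")
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_lt(bce_loss(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  expect_error(bce_loss(c(1, 0), 0.5), "length mismatch")
})

test_that("bce_loss equals the hand-computed per-sample average", {
  y <- c(1, 0, 1, 0)
  p <- c(0.8, 0.3, 0.6, 0.9)
  by_hand <- -(log(0.8) + log(0.7) + log(0.6) + log(0.1)) / 4
  expect_equal(bce_loss(y, p), by_hand, tolerance = 1e-12)
})

test_that("model initialization is seeded and dimension-checked", {
  m1 <- init_model(toy_config())
  m2 <- init_model(toy_config())
  expect_identical(m1$params, m2$params)
  b <- toy_batch()
  l1 <- composite_loss(m1, b$xc, b$xd, b$y)
  l2 <- composite_loss(m2, b$xc, b$xd, b$y)
  expect_identical(l1$total, l2$total)
  expect_error(deepdra_config(7L, 5L, seed = 1L, ae_latent = 0L))
  expect_error(deepdra_config(0L, 5L, seed = 1L))
})

test_that("forward yields probabilities and respects batch independence", {
  m <- init_model(toy_config())
  b <- toy_batch(n = 12L)
  out <- forward(m, b$xc, b$xd)
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_equal(dim(out$recon_cell), dim(b$xc))
  expect_equal(dim(out$recon_drug), dim(b$xd))
  # a row scored alone equals the same row inside a batch
  solo <- forward(m, b$xc[3, , drop = FALSE], b$xd[3, , drop = FALSE])
  expect_equal(solo$p, out$p[3])
  expect_error(forward(m, b$xc[, 1:3], b$xd), "cell input width")
  expect_error(forward(m, b$xc, b$xd[, 1:2]), "drug input width")
})

test_that("variants carry exactly the advertised components", {
  b <- toy_batch()
  m_no <- init_model(toy_config("no_ae"))
  expect_false(any(grepl("enc|dec", names(m_no$params))))
  out <- forward(m_no, b$xc, b$xd)
  expect_null(out$recon_cell)
  expect_null(out$recon_drug)
  lb <- composite_loss(m_no, b$xc, b$xd, b$y)
  expect_identical(lb$l_cell_ae, 0)
  expect_identical(lb$l_drug_ae, 0)

  m_cell <- init_model(toy_config("cell_ae_only"))
  expect_true(any(grepl("cell_enc", names(m_cell$params))))
  expect_false(any(grepl("drug_enc", names(m_cell$params))))
  lbc <- composite_loss(m_cell, b$xc, b$xd, b$y)
  expect_identical(lbc$l_drug_ae, 0)
  expect_gt(lbc$l_cell_ae, 0)
  # classifier input width adapts: latent + raw drug width
  expect_equal(nrow(m_cell$params$cls1$W), 3L + 5L)
})

test_that("composite loss is the weighted sum of its components", {
  b <- toy_batch()
  w <- c(drug = 2, cell = 1, classifier = 0.5)
  m <- init_model(toy_config(loss_weights = w))
  lb <- composite_loss(m, b$xc, b$xd, b$y)
  expect_equal(lb$total,
               2 * lb$l_drug_ae + 1 * lb$l_cell_ae + 0.5 * lb$l_classifier,
               tolerance = 1e-12)
  # components themselves equal direct mse/bce on the forward outputs
  out <- forward(m, b$xc, b$xd)
  expect_equal(lb$l_cell_ae, mse_loss(b$xc, out$recon_cell))
  expect_equal(lb$l_drug_ae, mse_loss(b$xd, out$recon_drug))
  expect_equal(lb$l_classifier, bce_loss(b$y, out$p))
})

test_that("total equals component sum under default weights across random batches", {
  for (i in 1:25) {
    b <- toy_batch(seed = i)
    m <- init_model(toy_config())
    lb <- composite_loss(m, b$xc, b$xd, b$y)
    expect_equal(lb$total, lb$l_cell_ae + lb$l_drug_ae + lb$l_classifier,
                 tolerance = 1e-6 * max(1, abs(lb$total)))
  }
})

test_that("backprop gradients match finite differences on every parameter group", {
  b <- toy_batch()
  cases <- list(
    list(variant = "full", latent = "linear"),
    list(variant = "full", latent = "relu"),
    list(variant = "cell_ae_only", latent = "linear"),
    list(variant = "no_ae", latent = "linear")
  )
  for (case in cases) {
    variant <- case$variant
    m <- init_model(toy_config(variant, latent_activation = case$latent,
                               loss_weights = c(drug = 1.5, cell = 0.8,
                                                classifier = 1.2)))
    # jitter every parameter so no ReLU pre-activation sits exactly at the
    # kink, where central differences straddle the subgradient
    set.seed(99)
    m$params <- lapply(m$params, function(pr) list(
      W = pr$W + matrix(runif(length(pr$W), 0.01, 0.2) *
                          sign(runif(length(pr$W), -1, 1)), nrow(pr$W)),
      b = pr$b + runif(length(pr$b), 0.01, 0.1)
    ))
    cache <- deepdra:::.forward_cache(m, b$xc, b$xd)
    g <- deepdra:::.backward(m, cache, b$xc, b$xd, b$y)
    expect_setequal(names(g), names(m$params))
    eps <- 1e-6
    for (nm in names(m$params)) {
      for (s in c("W", "b")) {
        P <- m$params[[nm]][[s]]
        for (i in seq_len(min(length(P), 4L))) {
          m2 <- m
          m2$params[[nm]][[s]][i] <- P[i] + eps
          up <- composite_loss(m2, b$xc, b$xd, b$y)$total
          m2$params[[nm]][[s]][i] <- P[i] - eps
          dn <- composite_loss(m2, b$xc, b$xd, b$y)$total
          fd <- (up - dn) / (2 * eps)
          expect_equal(g[[nm]][[s]][i], fd, tolerance = 1e-4,
                       info = sprintf("%s/%s/%s[%d]", variant, nm, s, i))
        }
      }
    }
  }
})

test_that("one optimizer step on a fixed batch decreases the loss", {
  b <- toy_batch(n = 16L)
  for (optname in c("adadelta", "adam")) {
    cfg <- toy_config(learning_rate = 1e-3, optimizer = optname)
    m <- init_model(cfg)
    before <- composite_loss(m, b$xc, b$xd, b$y)$total
    cache <- deepdra:::.forward_cache(m, b$xc, b$xd)
    g <- deepdra:::.backward(m, cache, b$xc, b$xd, b$y)
    opt <- deepdra:::.opt_init(m$params, cfg)
    deepdra:::.opt_step(opt, m$params, g)
    after <- composite_loss(m, b$xc, b$xd, b$y)$total
    expect_lt(after, before)
  }
})

test_that("checkpoint round-trip reproduces predictions bit-exactly", {
  co <- generate_cohort(small_cohort_config())
  ts <- cohort_tensorset(co)$ts
  sp <- split_pairs(ts, split_spec(seed = 2L))
  cfg <- small_model_config(ts, epochs = 2L)
  fit <- train_model(cfg, sp$train, sp$val)
  f <- tempfile(fileext = ".rds")
  save_model(fit$model, f)
  m2 <- load_model(f)
  expect_identical(predict_scores(m2, sp$test), predict_scores(fit$model, sp$test))
  # checkpoint is self-describing
  expect_identical(m2$cfg$variant, cfg$variant)
  expect_identical(m2$cfg$loss_weights, cfg$loss_weights)
  expect_identical(m2$scaler_cell, fit$model$scaler_cell)
  # declared-dimension mismatch and corrupt files are rejected
  expect_error(load_model(f, cell_input_dim = 1L), "cell_input_dim")
  expect_error(load_model(f, drug_input_dim = 1L), "drug_input_dim")
  junk <- tempfile()
  saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "not a deepdra checkpoint")
})
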