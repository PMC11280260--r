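# A quickly trained small model plus its cohort, shared across tests.
repurposing_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(small_cohort_config(seed = 51L))
      cts <- cohort_tensorset(co)
      sp <- split_pairs(cts$ts, split_spec(seed = 51L))
      cfg <- small_model_config(cts$ts, seed = 51L, epochs = 8L)
      fit <- train_model(cfg, sp$train, sp$val)
      panel <- co$panel
      panel$modalities <- lapply(panel$modalities, impute_missing)
      cache <<- list(co = co, panel = panel, model = fit$model,
                     train_keys = sp$train$pair_keys, test = sp$test)
    }
    cache
  }
})

test_that("score_pairs scores the full cell x drug grid with ranks and flags", {
  fx <- repurposing_fixture()
  cells <- fx$panel$cell_line_ids[1:2]
  res <- score_pairs(fx$model, fx$panel, fx$co$drug_table, cells)
  n_drugs <- length(fx$co$drug_table$drug_ids)
  expect_equal(nrow(res), 2L * n_drugs)
  expect_true(all(res$score >= 0 & res$score <= 1))
  # per cell line: ranks are a permutation and ordered by descending score
  for (cl in cells) {
    sub <- res[res$cell_line_id == cl, ]
    expect_equal(sort(sub$rank), seq_len(n_drugs))
    expect_true(all(diff(sub$score[order(sub$rank)]) <= 0))
  }
  # candidates are exactly the rows strictly above the cutoff
  expect_equal(res$candidate, res$score > 0.5)
  expect_equal(candidates(res)$drug_id, res$drug_id[res$score > 0.5])
})

test_that("seen-in-training annotation keys on (cell, drug) ignoring source", {
  fx <- repurposing_fixture()
  cells <- unique(fx$train_keys$cell_line_id)[1]
  res <- score_pairs(fx$model, fx$panel, fx$co$drug_table, cells)
  seen_drugs <- fx$train_keys$drug_id[fx$train_keys$cell_line_id == cells]
  expect_setequal(res$drug_id[res$seen_in_training], unique(seen_drugs))
  # explicit keys override the checkpoint's
  res2 <- score_pairs(fx$model, fx$panel, fx$co$drug_table, cells,
                      training_keys = data.frame(cell_line_id = cells,
                                                 drug_id = res$drug_id[1]))
  expect_equal(sum(res2$seen_in_training), 1L)
})

test_that("repurposing scores agree bit-exactly with the model forward pass", {
  fx <- repurposing_fixture()
  cl <- fx$panel$cell_line_ids[3]
  res <- score_pairs(fx$model, fx$panel, fx$co$drug_table, cl)
  # the identically assembled batch (sorted drug order, as score_pairs
  # builds it) through forward() reproduces the scores bitwise
  ids <- sort(res$drug_id)
  xc <- apply_scaler(fx$model$scaler_cell, panel_matrix(fx$panel, rep(cl, length(ids))))
  xd <- apply_scaler(fx$model$scaler_drug, drug_matrix(fx$co$drug_table, ids, "both"))
  expect_identical(res$score[match(ids, res$drug_id)],
                   unname(forward(fx$model, xc, xd)$p))
  # a pair scored on its own agrees to floating-point noise
  solo <- unname(forward(fx$model, xc[7, , drop = FALSE], xd[7, , drop = FALSE])$p)
  expect_equal(res$score[match(ids, res$drug_id)][7], solo, tolerance = 1e-12)
})

test_that("candidate set and ranking are invariant to drug table order", {
  fx <- repurposing_fixture()
  cl <- fx$panel$cell_line_ids[1]
  tab <- fx$co$drug_table
  perm <- rev(seq_along(tab$drug_ids))
  tab2 <- drug_feature_table(tab$drug_ids[perm],
                             tab$descriptors[perm, , drop = FALSE],
                             tab$fingerprints[perm, , drop = FALSE])
  r1 <- score_pairs(fx$model, fx$panel, tab, cl)
  r2 <- score_pairs(fx$model, fx$panel, tab2, cl)
  expect_equal(r1$drug_id, r2$drug_id)
  expect_equal(r1$score, r2$score)
  expect_equal(candidates(r1)$drug_id, candidates(r2)$drug_id)
})

test_that("ranking follows the documented sort with lexicographic tie-break", {
  # synthetic result exercising the documented 3-drug example: duplicate a
  # drug's features so its scores tie exactly
  fx <- repurposing_fixture()
  tab <- fx$co$drug_table
  ids <- tab$drug_ids[1:3]
  dup <- drug_feature_table(
    c(ids, "ZZdup"),
    rbind(tab$descriptors[ids, ], tab$descriptors[ids[2], , drop = FALSE]),
    rbind(tab$fingerprints[ids, ], tab$fingerprints[ids[2], , drop = FALSE])
  )
  cl <- fx$panel$cell_line_ids[1]
  res <- score_pairs(fx$model, fx$panel, dup, cl)
  s2 <- res$score[res$drug_id == ids[2]]
  expect_identical(res$score[res$drug_id == "ZZdup"], s2)
  # the tied pair is ordered lexicographically
  r_tied <- res$rank[res$drug_id %in% c(ids[2], "ZZdup")]
  expect_equal(diff(r_tied[order(c(ids[2], "ZZdup"))]), 1)
  expect_lt(res$rank[res$drug_id == ids[2]], res$rank[res$drug_id == "ZZdup"])
})

test_that("rank_report returns the top-k per cell line, clipped to drug count", {
  fx <- repurposing_fixture()
  cells <- fx$panel$cell_line_ids[1:2]
  res <- score_pairs(fx$model, fx$panel, fx$co$drug_table, cells)
  top2 <- rank_report(res, 2L)
  expect_equal(nrow(top2), 4L)
  expect_equal(top2$rank, c(1, 2, 1, 2))
  # top_k beyond the drug count returns everything
  all_rows <- rank_report(res, 10000L)
  expect_equal(nrow(all_rows), nrow(res))
  expect_error(rank_report(res, 0L))
})

test_that("held-out sensitive pairs outscore resistant ones across seeds", {
  for (seed in c(61L, 62L, 63L)) {
    co <- generate_cohort(small_cohort_config(seed = seed, n_pairs = 900L))
    cts <- cohort_tensorset(co)
    sp <- split_pairs(cts$ts, split_spec(seed = seed))
    cfg <- small_model_config(cts$ts, seed = seed, epochs = 10L)
    fit <- train_model(cfg, sp$train, sp$val)
    scores <- predict_scores(fit$model, sp$test)
    expect_gt(mean(scores[sp$test$y == 1]), mean(scores[sp$test$y == 0]),
              label = sprintf("seed %d: mean sensitive score", seed))
  }
})

test_that("unknown cells or empty subsets are rejected", {
  fx <- repurposing_fixture()
  expect_error(score_pairs(fx$model, fx$panel, fx$co$drug_table, character(0)))
  expect_error(score_pairs(fx$model, fx$panel, fx$co$drug_table, "NOPE"),
               "unknown cell-line")
})
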