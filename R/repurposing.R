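#' Score all drug candidates against selected cell lines
#'
#' Scores the full cartesian product of `cell_subset` x drugs with a trained
#' model, ranks drugs per cell line by descending score (ties broken
#' lexicographically by drug ID), and flags candidates whose score is
#' strictly above the sensitivity cutoff. Pairs present in the training set
#' are annotated so novel (unseen) candidates can be distinguished.
#'
#' @param model a trained `deepdra_model`.
#' @param panel a `cell_line_panel` on the model's cell feature space.
#' @param drugs a `drug_feature_table` on the model's drug feature space.
#' @param cell_subset cell-line IDs to score (must resolve in the panel).
#' @param training_keys training pairs as a data.frame with columns
#'   `cell_line_id`, `drug_id`, or `NULL` (default) to use the keys stored
#'   in the model checkpoint. Matching ignores the source cohort.
#' @param drug_mode drug feature block, see [drug_matrix()]; must match how
#'   the model was trained.
#' @param cutoff sensitivity cutoff (default 0.5, strict).
#' @return A `repurposing_result` data.frame with columns `cell_line_id`,
#'   `drug_id`, `score`, `rank` (within cell line), `seen_in_training`,
#'   `candidate`.
#' @export
score_pairs <- function(model, panel, drugs, cell_subset,
                        training_keys = NULL,
                        drug_mode = c("both", "descriptors", "fingerprints"),
                        cutoff = 0.5) {
  drug_mode <- match.arg(drug_mode)
  stopifnot(inherits(model, "deepdra_model"),
            inherits(panel, "cell_line_panel"),
            inherits(drugs, "drug_feature_table"),
            length(cell_subset) >= 1L)
  if (is.null(training_keys)) {
    seen_keys <- model$training_keys %||% character(0)
  } else {
    stopifnot(all(c("cell_line_id", "drug_id") %in% names(training_keys)))
    seen_keys <- unique(paste(training_keys$cell_line_id,
                              training_keys$drug_id, sep = "\r"))
  }
  # sort drugs once so scoring order (and tie-broken ranks) cannot depend on
  # table order
  drug_ids <- sort(drugs$drug_ids)
  grid <- expand.grid(drug_id = drug_ids, cell_line_id = cell_subset,
                      stringsAsFactors = FALSE)[, c("cell_line_id", "drug_id")]
  ts <- structure(
    list(
      X_cell = panel_matrix(panel, grid$cell_line_id),
      X_drug = drug_matrix(drugs, grid$drug_id, drug_mode),
      y = rep(0, nrow(grid)),
      pair_keys = data.frame(grid, source = NA_character_),
      cell_feature_ids = panel_feature_ids(panel),
      drug_mode = drug_mode,
      n_dropped = 0L
    ),
    class = "pair_tensor_set"
  )
  scores <- predict_scores(model, ts)
  out <- data.frame(
    cell_line_id = grid$cell_line_id,
    drug_id = grid$drug_id,
    score = scores,
    stringsAsFactors = FALSE
  )
  # per-cell-line rank: descending score, lexicographic drug_id tie-break
  out <- out[order(out$cell_line_id, -out$score, out$drug_id), , drop = FALSE]
  out$rank <- stats::ave(out$score, out$cell_line_id,
                         FUN = function(s) seq_along(s))
  out$seen_in_training <- paste(out$cell_line_id, out$drug_id,
                                sep = "\r") %in% seen_keys
  out$candidate <- out$score > cutoff
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("repurposing_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-ranked drugs per cell line
#'
#' @param result a `repurposing_result` from [score_pairs()].
#' @param top_k number of top-ranked drugs to keep per cell line (clipped to
#'   the number of drugs available).
#' @return Data.frame of the top rows per cell line, ordered by cell line
#'   then rank.
#' @export
rank_report <- function(result, top_k) {
  stopifnot(inherits(result, "repurposing_result"), nrow(result) > 0L,
            length(top_k) == 1L, top_k >= 1L)
  out <- result[result$rank <= top_k, , drop = FALSE]
  out <- out[order(out$cell_line_id, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate drugs above the sensitivity cutoff
#'
#' @param result a `repurposing_result`.
#' @return The candidate subset (score strictly above the cutoff), ranked.
#' @export
candidates <- function(result) {
  stopifnot(inherits(result, "repurposing_result"))
  out <- result[result$candidate, , drop = FALSE]
  rownames(out) <- NULL
  out
}
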