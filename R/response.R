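#' Default binarization thresholds per response measure
#'
#' Each cohort reports a different continuous response summary, binarized
#' with cohort-specific cutoffs:
#' \itemize{
#'   \item `ctrp_auc` — dose-response AUC; low values mean the drug worked.
#'     `< 6` sensitive, `> 16` resistant.
#'   \item `gdsc_norm` — normalized IC50-derived response in \[0, 1\]; low
#'     values mean sensitive. `< 0.2` sensitive, `> 0.99` resistant.
#'   \item `ccle_actarea` — activity area; high values mean the drug worked.
#'     `> 2` sensitive, `< 0.5` resistant.
#' }
#' All inequalities are strict: values in between (including values exactly
#' at a cutoff) are `undefined` and dropped from training.
#'
#' @return Named list of `c(sensitive = ..., resistant = ...)` cutoffs with a
#'   per-measure `direction` attribute (`"low_sensitive"`/`"high_sensitive"`).
#' @export
response_thresholds <- function() {
  list(
    ctrp_auc = list(sensitive = 6, resistant = 16, direction = "low_sensitive"),
    gdsc_norm = list(sensitive = 0.2, resistant = 0.99, direction = "low_sensitive"),
    ccle_actarea = list(sensitive = 2, resistant = 0.5, direction = "high_sensitive")
  )
}

#' Binarize continuous drug-response values
#'
#' Vectorized over `value` and `measure`. Strict inequalities; boundary
#' values fall in the undefined band.
#'
#' @param value numeric vector of continuous response values.
#' @param measure character vector (recycled) naming the measure of each
#'   value; must be names of `thresholds`.
#' @param thresholds threshold set, see [response_thresholds()].
#' @return Character vector in `{"sensitive", "resistant", "undefined"}`.
#' @export
binarize_response <- function(value, measure, thresholds = response_thresholds()) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  measure <- as.character(measure)
  if (length(measure) == 1L) measure <- rep(measure, length(value))
  stopifnot(length(measure) == length(value))
  unknown <- setdiff(unique(measure), names(thresholds))
  if (length(unknown) > 0L) {
    stop("unknown response measure(s): ", paste(unknown, collapse = ", "))
  }
  out <- rep("undefined", length(value))
  for (ms in unique(measure)) {
    th <- thresholds[[ms]]
    i <- measure == ms
    if (th$direction == "low_sensitive") {
      out[i & value < th$sensitive] <- "sensitive"
      out[i & value > th$resistant] <- "resistant"
    } else {
      out[i & value > th$sensitive] <- "sensitive"
      out[i & value < th$resistant] <- "resistant"
    }
  }
  out
}

#' Read a drug-response table from delimited text
#'
#' @param path file with columns `cell_line_id`, `drug_id`, `value`,
#'   `measure`, `source`.
#' @return data.frame of response records.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("cannot read response file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("cell_line_id", "drug_id", "value", "measure", "source")
  if (!all(need %in% names(dt))) {
    stop("response file must have columns: ", paste(need, collapse = ", "))
  }
  dt[, need]
}

#' Binarize response records into labeled training pairs
#'
#' Records falling in the undefined band are dropped. Duplicate
#' (cell line, drug) keys within one source collapse to a single pair when
#' their labels agree and are dropped entirely when they conflict. The same
#' pair occurring in two different sources is kept as two distinct labeled
#' pairs (cohorts are merged, not deduplicated across sources).
#'
#' @param records data.frame of response records, see [read_response_table()].
#' @param thresholds see [response_thresholds()].
#' @return List with `pairs` (data.frame `cell_line_id`, `drug_id`, `label`
#'   1 = sensitive / 0 = resistant, `source`) and `report` (input/output/drop
#'   counts, per-source label table).
#' @export
build_labeled_pairs <- function(records, thresholds = response_thresholds()) {
  need <- c("cell_line_id", "drug_id", "value", "measure", "source")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  n_in <- nrow(records)
  cls <- if (n_in > 0L) {
    binarize_response(records$value, records$measure, thresholds)
  } else {
    character(0)
  }
  n_undefined <- sum(cls == "undefined")
  keep <- records[cls != "undefined", c("cell_line_id", "drug_id", "source"), drop = FALSE]
  keep$label <- as.integer(cls[cls != "undefined"] == "sensitive")

  n_conflict <- 0L
  n_collapsed <- 0L
  if (nrow(keep) > 0L) {
    key <- paste(keep$cell_line_id, keep$drug_id, keep$source, sep = "\r")
    grp_lab <- tapply(keep$label, key, function(l) {
      if (length(unique(l)) > 1L) NA_integer_ else l[1L]
    })
    sizes <- table(key)
    conflict_keys <- names(grp_lab)[is.na(grp_lab)]
    n_conflict <- sum(sizes[conflict_keys])               # all rows of conflicting groups
    n_collapsed <- sum(sizes) - length(sizes) - n_conflict +
      length(conflict_keys)                               # extra rows merged into keepers
    sel <- !duplicated(key) & !(key %in% conflict_keys)
    keep <- keep[sel, , drop = FALSE]
  }
  if (nrow(keep) == 0L) {
    warning("no labeled pairs survive binarization")
  }
  rownames(keep) <- NULL
  per_source <- if (nrow(keep) > 0L) {
    as.data.frame(table(source = keep$source,
                        label = ifelse(keep$label == 1L, "sensitive", "resistant")))
  } else {
    data.frame(source = character(0), label = character(0), Freq = integer(0))
  }
  report <- list(
    n_input = n_in,
    n_sensitive = sum(keep$label == 1L),
    n_resistant = sum(keep$label == 0L),
    n_undefined_dropped = n_undefined,
    n_conflict_dropped = n_conflict,
    n_duplicates_collapsed = n_collapsed,
    n_dropped_total = n_undefined + n_conflict + n_collapsed,
    per_source = per_source
  )
  list(pairs = keep[, c("cell_line_id", "drug_id", "label", "source")],
       report = report)
}

#' Materialize labeled pairs into aligned model tensors
#'
#' Looks every pair up in the cell-line panel and drug table; pairs whose
#' cell line or drug is absent are dropped with a count. Surviving rows keep
#' their input order.
#'
#' @param pairs data.frame of labeled pairs, see [build_labeled_pairs()].
#' @param panel a `cell_line_panel` (impute before assembling).
#' @param drugs a `drug_feature_table`.
#' @param drug_mode drug feature block to use, see [drug_matrix()].
#' @return A `pair_tensor_set`: `X_cell` (n x combined_dim), `X_drug`
#'   (n x drug width), `y` (0/1), `pair_keys` (data.frame), plus feature
#'   bookkeeping and an `n_dropped` attribute.
#' @export
assemble_tensorset <- function(pairs, panel, drugs,
                               drug_mode = c("both", "descriptors", "fingerprints")) {
  drug_mode <- match.arg(drug_mode)
  stopifnot(is.data.frame(pairs),
            all(c("cell_line_id", "drug_id", "label") %in% names(pairs)),
            inherits(panel, "cell_line_panel"),
            inherits(drugs, "drug_feature_table"))
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  ok <- pairs$cell_line_id %in% panel$cell_line_ids &
    pairs$drug_id %in% drugs$drug_ids
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("assemble_tensorset: dropped ", n_dropped,
            " pair(s) with unknown cell line or drug")
  }
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no pairs resolve against the panel and drug table")
  X_cell <- panel_matrix(panel, pairs$cell_line_id)
  X_drug <- drug_matrix(drugs, pairs$drug_id, drug_mode)
  rownames(X_cell) <- NULL
  rownames(X_drug) <- NULL
  structure(
    list(
      X_cell = X_cell,
      X_drug = X_drug,
      y = as.numeric(pairs$label),
      pair_keys = data.frame(
        cell_line_id = pairs$cell_line_id,
        drug_id = pairs$drug_id,
        source = pairs$source,
        row.names = NULL
      ),
      cell_feature_ids = panel_feature_ids(panel),
      drug_feature_ids = colnames(drug_matrix(drugs, drugs$drug_ids[1L], drug_mode)),
      drug_mode = drug_mode,
      n_dropped = n_dropped
    ),
    class = "pair_tensor_set"
  )
}

#' @export
print.pair_tensor_set <- function(x, ...) {
  cat(sprintf(
    "pair_tensor_set: n=%d pairs, cell dim %d, drug dim %d (%s), prevalence %.3f\n",
    length(x$y), ncol(x$X_cell), ncol(x$X_drug), x$drug_mode, mean(x$y)
  ))
  invisible(x)
}

#' Number of pairs in a tensor set
#' @param ts a `pair_tensor_set`.
#' @return Integer count.
#' @export
ts_n <- function(ts) {
  stopifnot(inherits(ts, "pair_tensor_set"))
  length(ts$y)
}

#' Subset a tensor set by row index
#' @param ts a `pair_tensor_set`.
#' @param idx integer (or logical) row indices.
#' @return A `pair_tensor_set` over the selected rows, order preserved.
#' @export
ts_subset <- function(ts, idx) {
  stopifnot(inherits(ts, "pair_tensor_set"))
  out <- ts
  out$X_cell <- ts$X_cell[idx, , drop = FALSE]
  out$X_drug <- ts$X_drug[idx, , drop = FALSE]
  out$y <- ts$y[idx]
  out$pair_keys <- ts$pair_keys[idx, , drop = FALSE]
  rownames(out$pair_keys) <- NULL
  out
}
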