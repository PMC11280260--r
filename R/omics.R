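#' @import methods
NULL

.MODALITIES <- c("expression", "mutation", "methylation", "cnv")
.MISSING_TOKENS <- c("", "NA", "NaN", "nan")

#' Construct an omics matrix for one modality
#'
#' One modality of a cell-line panel: a dense numeric matrix with cell lines
#' as rows and named features as columns. Feature IDs are prefixed with the
#' modality tag (e.g. `expression:TP53`) so that no two modalities can share
#' a feature ID after concatenation.
#'
#' @param values numeric matrix with unique rownames (cell-line IDs) and
#'   unique colnames (feature IDs).
#' @param modality one of `"expression"`, `"mutation"`, `"methylation"`,
#'   `"cnv"`.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, modality) {
  modality <- match.arg(modality, .MODALITIES)
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry cell-line rownames and feature colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate cell-line IDs in ", modality, " matrix")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature IDs in ", modality, " matrix")
  }
  tag <- paste0(modality, ":")
  untagged <- !startsWith(colnames(values), tag)
  colnames(values)[untagged] <- paste0(tag, colnames(values)[untagged])
  structure(list(modality = modality, values = values), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix [%s]: %d cell lines x %d features (%d missing entries)\n",
    x$modality, nrow(x$values), ncol(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' Cell-line IDs of an omics matrix or panel
#' @param x an `omics_matrix` or `cell_line_panel`.
#' @return Character vector of cell-line IDs, in storage order.
#' @export
cell_line_ids <- function(x) {
  if (inherits(x, "omics_matrix")) {
    return(rownames(x$values))
  }
  if (inherits(x, "cell_line_panel")) {
    return(x$cell_line_ids)
  }
  stop("unsupported type")
}

#' Feature IDs of an omics matrix (modality-prefixed)
#' @param x an `omics_matrix`.
#' @return Character vector of prefixed feature IDs.
#' @export
feature_ids <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  colnames(x$values)
}

#' Read an omics matrix from a delimited text file
#'
#' Expects a header row of feature names and a first column of cell-line IDs.
#' Empty fields, `NA`, `NaN` and `nan` are read as missing; imputation is a
#' separate explicit step ([impute_missing()]).
#'
#' @param path file path.
#' @param modality modality tag, see [omics_matrix()].
#' @param delimiter field delimiter (default tab; comma accepted).
#' @return An `omics_matrix` (possibly containing missing values).
#' @export
read_omics_matrix <- function(path, modality, delimiter = "\t") {
  if (!file.exists(path)) stop("cannot read omics file: ", path)
  dt <- data.table::fread(
    path,
    sep = delimiter, header = TRUE, na.strings = .MISSING_TOKENS,
    colClasses = list(character = 1L), data.table = FALSE
  )
  if (ncol(dt) < 2L) stop("omics table needs an ID column plus >=1 feature")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate cell-line IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in omics table ", path)
  rownames(vals) <- ids
  omics_matrix(vals, modality)
}

#' Write an omics matrix to TSV
#'
#' Values are written with 6 significant digits; missing entries as `NA`.
#'
#' @param m an `omics_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  vals <- signif(m$values, 6L)
  dt <- data.table::data.table(cell_line_id = rownames(vals))
  dt <- cbind(dt, data.table::as.data.table(vals))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Replace missing omics entries with zero
#'
#' Missing measurements are imputed to 0, the convention used throughout the
#' pipeline; all observed entries are left untouched. Idempotent.
#'
#' @param m an `omics_matrix`.
#' @return The imputed `omics_matrix`.
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  m$values[is.na(m$values)] <- 0
  m
}

#' Restrict two same-modality matrices to their shared features
#'
#' Both outputs are reordered to the lexicographically sorted shared feature
#' set, so the result is independent of input column order. Used to align
#' panels from different cohorts onto a common feature space.
#'
#' @param a,b `omics_matrix` objects of the same modality.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   features in identical order.
#' @export
intersect_features <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  if (a$modality != b$modality) {
    stop("cannot intersect features across modalities (",
         a$modality, " vs ", b$modality, ")")
  }
  shared <- sort(intersect(feature_ids(a), feature_ids(b)))
  if (length(shared) == 0L) {
    stop("no shared ", a$modality, " features between the two panels")
  }
  a$values <- a$values[, shared, drop = FALSE]
  b$values <- b$values[, shared, drop = FALSE]
  list(a = a, b = b)
}

#' Assemble aligned modalities into a cell-line panel
#'
#' Restricts all matrices to the cell lines present in every modality (and in
#' `cell_line_subset`, if given), in one shared order, and fixes the modality
#' concatenation order used by [cell_vector()].
#'
#' @param matrices list of `omics_matrix` objects with pairwise-distinct
#'   modalities.
#' @param cell_line_subset optional character vector restricting the panel.
#' @return A `cell_line_panel`: aligned matrices, `cell_line_ids`,
#'   `combined_dim` (sum of modality widths) and `concat_order`.
#' @export
assemble_panel <- function(matrices, cell_line_subset = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  for (m in matrices) stopifnot(inherits(m, "omics_matrix"))
  mods <- vapply(matrices, function(m) m$modality, character(1))
  if (anyDuplicated(mods)) stop("duplicate modalities in panel: ",
                                paste(mods[duplicated(mods)], collapse = ", "))
  names(matrices) <- mods
  common <- Reduce(intersect, lapply(matrices, cell_line_ids))
  if (!is.null(cell_line_subset)) common <- intersect(common, cell_line_subset)
  if (length(common) == 0L) stop("no cell lines shared by all modalities")
  # keep modalities in their canonical order for reproducible concatenation
  order_ <- intersect(.MODALITIES, mods)
  matrices <- matrices[order_]
  matrices <- lapply(matrices, function(m) {
    m$values <- m$values[common, , drop = FALSE]
    m
  })
  structure(
    list(
      modalities = matrices,
      cell_line_ids = common,
      combined_dim = sum(vapply(matrices, function(m) ncol(m$values), integer(1))),
      concat_order = order_
    ),
    class = "cell_line_panel"
  )
}

#' @export
print.cell_line_panel <- function(x, ...) {
  widths <- vapply(x$modalities, function(m) ncol(m$values), integer(1))
  cat(sprintf(
    "cell_line_panel: %d cell lines, %d combined features (%s)\n",
    length(x$cell_line_ids), x$combined_dim,
    paste(sprintf("%s=%d", x$concat_order, widths), collapse = ", ")
  ))
  invisible(x)
}

#' Combined feature IDs of a panel, in concatenation order
#' @param panel a `cell_line_panel`.
#' @return Character vector of length `combined_dim`.
#' @export
panel_feature_ids <- function(panel) {
  stopifnot(inherits(panel, "cell_line_panel"))
  unlist(lapply(panel$modalities, feature_ids), use.names = FALSE)
}

#' Model-ready matrix of a panel
#'
#' Concatenates all modalities column-wise in `concat_order`, one row per
#' cell line.
#'
#' @param panel a `cell_line_panel`.
#' @param ids optional cell-line IDs to extract (default: all, panel order).
#' @return Numeric matrix `length(ids) x combined_dim`.
#' @export
panel_matrix <- function(panel, ids = NULL) {
  stopifnot(inherits(panel, "cell_line_panel"))
  if (is.null(ids)) ids <- panel$cell_line_ids
  unknown <- setdiff(ids, panel$cell_line_ids)
  if (length(unknown) > 0L) {
    stop("unknown cell-line ID(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  out <- do.call(cbind, lapply(panel$modalities, function(m) {
    m$values[ids, , drop = FALSE]
  }))
  rownames(out) <- ids
  out
}

#' Concatenated feature vector of one cell line
#'
#' The model input for one cell line: its rows across all modalities,
#' concatenated in `concat_order`.
#'
#' @param panel a `cell_line_panel`.
#' @param cell_line_id a single cell-line ID present in the panel.
#' @return Named numeric vector of length `combined_dim`.
#' @export
cell_vector <- function(panel, cell_line_id) {
  stopifnot(length(cell_line_id) == 1L)
  m <- panel_matrix(panel, cell_line_id)
  stats::setNames(drop(m), colnames(m))
}
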