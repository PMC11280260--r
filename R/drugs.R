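.DESCRIPTOR_NAMES <- c(
  "HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA",
  "n_atoms", "n_bonds"
)

#' Names of the molecular descriptors computed from SMILES
#'
#' The 2-D physicochemical property set of the OpenBabel/ChemmineR toolkit
#' (hydrogen-bond acceptor counts, donors, logP, molar refractivity,
#' molecular weight, fluorine count, topological polar surface area) plus
#' heavy-atom and bond counts from the parsed connection table.
#'
#' @return Character vector of descriptor names, in column order.
#' @export
drug_descriptor_names <- function() .DESCRIPTOR_NAMES

# Parse one SMILES into an SDFset; stop with a drug-tagged error on failure.
.parse_smiles <- function(smiles, drug_id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("featurization failed for drug '", drug_id, "': empty SMILES")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, drug_id))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != 1L ||
      !isTRUE(tryCatch(ChemmineR::validSDF(sdf), error = function(e) FALSE))) {
    stop("featurization failed for drug '", drug_id,
         "': SMILES does not parse: ", smiles)
  }
  sdf
}

# Fold an OpenBabel ECFP bit matrix (4096 bits) down to n_bits by OR-ing
# bit i into slot i mod n_bits. Standard hashed-fingerprint folding.
.fold_bits <- function(bits, n_bits) {
  idx <- (seq_along(bits) - 1L) %% n_bits
  out <- integer(n_bits)
  set <- tapply(bits, idx, max)
  out[as.integer(names(set)) + 1L] <- as.integer(set)
  out
}

#' Featurize one drug from its SMILES string
#'
#' Computes a molecular-descriptor vector and a binary circular
#' (Morgan-type, ECFP) fingerprint. Fingerprints use neighborhoods up to
#' `radius` bonds and are hashed/folded to `n_bits`; they are invariant to
#' the atom ordering of the input SMILES. Non-finite descriptor values are
#' imputed to 0, mirroring the missing-data rule used for omics features.
#'
#' @param smiles a single SMILES string.
#' @param radius circular-fingerprint radius in bonds (default 2, i.e. ECFP4).
#' @param n_bits fingerprint length after folding (default 2048, max 4096).
#' @param drug_id identifier used in error messages (default: the SMILES).
#' @param descriptor_set descriptor names to compute, a subset of
#'   [drug_descriptor_names()] (default: all of them).
#' @return List with `descriptors` (named numeric, in `descriptor_set`
#'   order) and `fingerprint` (integer 0/1 of length `n_bits`).
#' @export
featurize_drug <- function(smiles, radius = 2L, n_bits = 2048L,
                           drug_id = smiles,
                           descriptor_set = drug_descriptor_names()) {
  stopifnot(radius %in% 0:5, n_bits >= 1L, n_bits <= 4096L,
            length(descriptor_set) >= 1L,
            all(descriptor_set %in% .DESCRIPTOR_NAMES))
  sdf <- .parse_smiles(smiles, drug_id)
  props <- ChemmineR::propOB(sdf)
  atomb <- ChemmineR::atomblock(sdf[[1]])
  bondb <- ChemmineR::bondblock(sdf[[1]])
  desc <- c(
    HBA1 = props$HBA1, HBA2 = props$HBA2, HBD = props$HBD,
    logP = props$logP, MR = props$MR, MW = props$MW,
    nF = props$nF, TPSA = props$TPSA,
    n_atoms = nrow(atomb), n_bonds = nrow(bondb)
  )
  desc <- vapply(desc, as.numeric, numeric(1))[descriptor_set]
  desc[!is.finite(desc)] <- 0
  fp_raw <- ChemmineR::fingerprintOB(sdf, sprintf("ECFP%d", 2L * radius))
  bits <- as.integer(methods::slot(fp_raw, "fpma")[1L, ])
  list(descriptors = desc, fingerprint = .fold_bits(bits, n_bits))
}

#' Construct a drug feature table from precomputed matrices
#'
#' Low-level constructor used both by [build_drug_table()] and by the
#' synthetic-cohort generator (whose drug features are drawn from latent
#' factors rather than computed from structures).
#'
#' @param drug_ids unique drug identifiers, one per row.
#' @param descriptors numeric matrix drugs x D, finite everywhere.
#' @param fingerprints 0/1 matrix drugs x B.
#' @param radius,n_bits fingerprint settings recorded for provenance
#'   (`NA` for synthetic features).
#' @param dropped character vector of drug IDs that failed featurization.
#' @return A `drug_feature_table`.
#' @export
drug_feature_table <- function(drug_ids, descriptors, fingerprints,
                               radius = NA_integer_, n_bits = ncol(fingerprints),
                               dropped = character(0)) {
  drug_ids <- as.character(drug_ids)
  stopifnot(
    !anyDuplicated(drug_ids),
    is.matrix(descriptors), is.matrix(fingerprints),
    nrow(descriptors) == length(drug_ids),
    nrow(fingerprints) == length(drug_ids)
  )
  if (!all(is.finite(descriptors))) stop("descriptors contain non-finite values")
  if (!all(fingerprints %in% c(0, 1))) stop("fingerprints must be 0/1")
  storage.mode(descriptors) <- "double"
  storage.mode(fingerprints) <- "double"
  rownames(descriptors) <- drug_ids
  rownames(fingerprints) <- drug_ids
  if (is.null(colnames(descriptors))) {
    colnames(descriptors) <- paste0("desc:", seq_len(ncol(descriptors)))
  }
  if (is.null(colnames(fingerprints))) {
    colnames(fingerprints) <- paste0("fp:", seq_len(ncol(fingerprints)))
  }
  structure(
    list(
      drug_ids = drug_ids,
      descriptor_names = colnames(descriptors),
      descriptors = descriptors,
      fingerprints = fingerprints,
      fingerprint_radius = as.integer(radius),
      fingerprint_bits = as.integer(n_bits),
      dropped = dropped
    ),
    class = "drug_feature_table"
  )
}

#' @export
print.drug_feature_table <- function(x, ...) {
  cat(sprintf(
    "drug_feature_table: %d drugs, %d descriptors + %d fingerprint bits (radius %s)%s\n",
    length(x$drug_ids), ncol(x$descriptors), ncol(x$fingerprints),
    ifelse(is.na(x$fingerprint_radius), "NA", x$fingerprint_radius),
    if (length(x$dropped)) sprintf(" [%d dropped]", length(x$dropped)) else ""
  ))
  invisible(x)
}

#' Featurize a table of drugs from SMILES
#'
#' @param records data.frame with columns `drug_id` (unique) and `smiles`.
#' @param radius,n_bits,descriptor_set see [featurize_drug()].
#' @param on_error `"drop"` skips drugs whose SMILES fail to parse (logged in
#'   the returned table's `dropped` field and as a message); `"abort"` stops
#'   on the first failure.
#' @return A `drug_feature_table`; row order follows the input order of the
#'   surviving drugs.
#' @export
build_drug_table <- function(records, radius = 2L, n_bits = 2048L,
                             on_error = c("drop", "abort"),
                             descriptor_set = drug_descriptor_names()) {
  on_error <- match.arg(on_error)
  stopifnot(is.data.frame(records), all(c("drug_id", "smiles") %in% names(records)),
            nrow(records) >= 1L)
  ids <- as.character(records$drug_id)
  if (anyDuplicated(ids)) {
    stop("duplicate drug_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feats <- vector("list", nrow(records))
  failed <- character(0)
  for (i in seq_len(nrow(records))) {
    # note [i] <- list(...): assigning NULL via [[<- would delete the element
    feats[i] <- list(tryCatch(
      featurize_drug(records$smiles[i], radius, n_bits, drug_id = ids[i],
                     descriptor_set = descriptor_set),
      error = function(e) {
        if (on_error == "abort") stop(e)
        failed <<- c(failed, ids[i])
        NULL
      }
    ))
  }
  keep <- !vapply(feats, is.null, logical(1))
  if (!any(keep)) stop("all ", nrow(records), " drug records failed featurization")
  if (length(failed) > 0L) {
    message("dropped ", length(failed), " unfeaturizable drug(s): ",
            paste(utils::head(failed, 10L), collapse = ", "))
  }
  desc <- do.call(rbind, lapply(feats[keep], `[[`, "descriptors"))
  fp <- do.call(rbind, lapply(feats[keep], `[[`, "fingerprint"))
  colnames(desc) <- paste0("desc:", descriptor_set)
  colnames(fp) <- paste0("fp:", seq_len(n_bits))
  drug_feature_table(ids[keep], desc, fp,
                     radius = radius, n_bits = n_bits, dropped = failed)
}

#' Feature matrix for a set of drugs
#'
#' @param table a `drug_feature_table`.
#' @param ids drug IDs (default: all, table order).
#' @param mode `"descriptors"`, `"fingerprints"`, or `"both"` (descriptors
#'   first). The mode switch supports descriptor-only / fingerprint-only
#'   ablation experiments.
#' @return Numeric matrix `length(ids) x (D, B, or D+B)`.
#' @export
drug_matrix <- function(table, ids = NULL,
                        mode = c("both", "descriptors", "fingerprints")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "drug_feature_table"))
  if (is.null(ids)) ids <- table$drug_ids
  unknown <- setdiff(ids, table$drug_ids)
  if (length(unknown) > 0L) {
    stop("unknown drug ID(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  out <- switch(mode,
    descriptors = table$descriptors[ids, , drop = FALSE],
    fingerprints = table$fingerprints[ids, , drop = FALSE],
    both = cbind(table$descriptors[ids, , drop = FALSE],
                 table$fingerprints[ids, , drop = FALSE])
  )
  rownames(out) <- ids
  out
}

#' Feature vector of one drug
#'
#' @inheritParams drug_matrix
#' @param drug_id a single drug ID present in the table.
#' @return Named numeric vector.
#' @export
drug_vector <- function(table, drug_id,
                        mode = c("both", "descriptors", "fingerprints")) {
  stopifnot(length(drug_id) == 1L)
  m <- drug_matrix(table, drug_id, mode)
  stats::setNames(drop(m), colnames(m))
}

#' Read a drug table (drug_id, smiles) from delimited text
#'
#' @param path file path; delimiter is auto-detected by `fread`.
#' @return data.frame with character columns `drug_id` and `smiles`.
#' @export
read_drug_records <- function(path) {
  if (!file.exists(path)) stop("cannot read drug file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (!all(c("drug_id", "smiles") %in% names(dt))) {
    stop("drug file must have columns drug_id, smiles")
  }
  dt[, c("drug_id", "smiles")]
}

#' Write a drug feature table as TSV plus a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the fingerprint radius, bit count and
#' descriptor names so the table can be rebuilt reproducibly.
#'
#' @param table a `drug_feature_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(table, path) {
  stopifnot(inherits(table, "drug_feature_table"))
  m <- cbind(table$descriptors, table$fingerprints)
  dt <- data.table::data.table(drug_id = table$drug_ids)
  dt <- cbind(dt, data.table::as.data.table(signif(m, 6L)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  meta <- list(
    fingerprint_radius = table$fingerprint_radius,
    fingerprint_bits = table$fingerprint_bits,
    descriptor_names = table$descriptor_names,
    dropped = table$dropped
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
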