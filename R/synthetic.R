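# Valid small-molecule SMILES (common drugs and simple organics) cycled onto
# synthetic drug IDs so the SMILES featurization path can run end-to-end on
# generated cohorts.
.BUILTIN_SMILES <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "c1ccccc1O", "CC(=O)Oc1ccccc1C(=O)O",
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CC(=O)Nc1ccc(O)cc1", "Clc1ccccc1", "OCC(O)CO",
  "C1CCCCC1", "c1ccc2ccccc2c1", "CCN(CC)CC", "CC(C)O", "CCOC(=O)C",
  "Nc1ccc(cc1)S(=O)(=O)N", "OC(=O)c1ccccc1O", "CCCCCC", "C=CC=C",
  "N#Cc1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "OC(=O)C(N)Cc1ccccc1",
  "CSCC", "O=C(O)CCC(=O)O", "c1ccsc1", "c1ccoc1", "c1ccncc1",
  "CC1=CC(=O)CC(C)(C)C1", "COc1ccccc1", "CC(N)C(=O)O",
  "OC(=O)c1cccnc1", "CCCCO", "CC(C)(C)O", "FC(F)(F)c1ccccc1",
  "Brc1ccccc1", "Ic1ccccc1", "OCc1ccccc1", "NCCc1ccccc1",
  "CC(=O)C", "CCC(=O)C", "O=Cc1ccccc1", "CC#N", "CCOCC",
  "C1CCOC1", "C1CCNC1", "O=S(=O)(O)O", "NC(=O)c1ccccc1",
  "Oc1ccc(O)cc1", "Cc1ccc(C)cc1", "Cc1ccccc1C"
)

#' Configuration of the synthetic cohort generator
#'
#' The generator draws cell-line latents U (n x k) and drug latents V
#' (m x k) from a standard normal; continuous omics blocks and drug
#' descriptors are noisy linear maps of the latents, binary blocks
#' (mutations, fingerprints) are thresholded linear maps, and the
#' sensitivity label of a (cell, drug) pair is Bernoulli with probability
#' `plogis(interaction_scale * <u_i, v_j> + label_bias)`. Continuous
#' response values are then drawn so that binarization recovers the true
#' label for `1 - undefined_fraction` of pairs and falls in the undefined
#' band for the rest.
#'
#' Defaults give a cohort of 200 cell lines, 100 drugs, 2,000 omics features
#' (1,000 expression + 500 mutation + 500 CNV), ~5,000 response records and
#' ~35% sensitive prevalence with a near-ceiling Bayes oracle.
#'
#' @param n_cell_lines,n_drugs cohort sizes.
#' @param latent_dim latent factor dimension k.
#' @param n_expression,n_mutation,n_cnv per-modality feature counts.
#' @param n_descriptors,n_fingerprint_bits drug feature widths.
#' @param noise_sd feature noise standard deviation.
#' @param interaction_scale signal strength s of the label logit.
#' @param label_bias intercept b0 of the label logit (controls prevalence).
#' @param n_pairs number of (cell, drug) response records drawn.
#' @param undefined_fraction fraction of records whose continuous value
#'   lands in the undefined binarization band.
#' @param missing_rate per-entry omics missingness probability.
#' @param measure response measure used for the continuous values.
#' @param shift additive mean offset applied to continuous features
#'   (models cross-cohort covariate shift; 0 for an in-distribution cohort).
#' @param source cohort name stamped on the response records.
#' @param seed integer seed; cohorts are byte-identical given a config.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_lines = 200L, n_drugs = 100L,
                             latent_dim = 8L,
                             n_expression = 1000L, n_mutation = 500L,
                             n_cnv = 500L,
                             n_descriptors = 40L, n_fingerprint_bits = 128L,
                             noise_sd = 0.3, interaction_scale = 2.5,
                             label_bias = -2.7,
                             n_pairs = 5000L, undefined_fraction = 0.1,
                             missing_rate = 0.02,
                             measure = c("ctrp_auc", "gdsc_norm", "ccle_actarea"),
                             shift = 0, source = "synthetic", seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(
    n_cell_lines >= 2L, n_drugs >= 2L, latent_dim >= 1L,
    n_expression >= 1L, n_mutation >= 1L, n_cnv >= 1L,
    n_descriptors >= 1L, n_fingerprint_bits >= 1L,
    noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
    undefined_fraction >= 0, undefined_fraction < 1,
    n_pairs >= 1L, n_pairs <= n_cell_lines * n_drugs,
    is.finite(shift), is.finite(interaction_scale), is.finite(label_bias)
  )
  if (latent_dim > min(n_expression, n_mutation, n_cnv, n_descriptors,
                       n_fingerprint_bits)) {
    stop("latent_dim exceeds the smallest feature block")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Latent-to-feature loading matrices; depend only on map_seed so that two
# cohorts can share one generative process.
.synth_maps <- function(cfg, map_seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(map_seed)
  k <- cfg$latent_dim
  load_mat <- function(p) matrix(stats::rnorm(k * p, sd = 1 / sqrt(k)), k, p)
  list(
    expression = load_mat(cfg$n_expression),
    mutation = load_mat(cfg$n_mutation),
    cnv = load_mat(cfg$n_cnv),
    descriptors = load_mat(cfg$n_descriptors),
    fingerprints = load_mat(cfg$n_fingerprint_bits)
  )
}

.with_missing <- function(x, rate) {
  if (rate <= 0) {
    return(x)
  }
  x[stats::runif(length(x)) < rate] <- NA_real_
  x
}

# Draw continuous response values that binarize to the intended class.
.response_values <- function(class, measure) {
  n <- length(class)
  v <- numeric(n)
  s <- class == "sensitive"
  r <- class == "resistant"
  u <- class == "undefined"
  draw <- function(m, lo, hi) stats::runif(m, lo, hi)
  if (measure == "ctrp_auc") {
    v[s] <- draw(sum(s), 2, 5.5)
    v[r] <- draw(sum(r), 16.5, 20)
    v[u] <- draw(sum(u), 7, 15)
  } else if (measure == "gdsc_norm") {
    v[s] <- draw(sum(s), 0.01, 0.15)
    v[r] <- draw(sum(r), 0.991, 1)
    v[u] <- draw(sum(u), 0.3, 0.9)
  } else {
    v[s] <- draw(sum(s), 2.5, 6)
    v[r] <- draw(sum(r), 0.05, 0.4)
    v[u] <- draw(sum(u), 0.7, 1.8)
  }
  v
}

#' Generate a synthetic cohort with known latent structure
#'
#' Produces everything the rest of the pipeline consumes — a multi-omics
#' panel (with missingness, pre-imputation), drug records with valid SMILES,
#' a latent-driven drug feature table, and continuous response records —
#' plus the generating truth (latents and true pair probabilities) for
#' oracle checks.
#'
#' @param cfg a [synthetic_config()].
#' @param map_seed seed of the latent-to-feature maps (default `cfg$seed`);
#'   pass a shared value to generate multiple cohorts from one generative
#'   process (see [make_shifted_pair()]).
#' @return A `synthetic_cohort`: `panel`, `drug_records`, `drug_table`,
#'   `responses`, and `truth` (`U`, `V`, `pair_prob`, `true_label`,
#'   `prevalence`).
#' @export
generate_cohort <- function(cfg, map_seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  maps <- .synth_maps(cfg, map_seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  n <- cfg$n_cell_lines
  m <- cfg$n_drugs
  k <- cfg$latent_dim
  cells <- sprintf("CL%04d", seq_len(n))
  drugs <- sprintf("D%04d", seq_len(m))

  U <- matrix(stats::rnorm(n * k), n, k, dimnames = list(cells, NULL))
  V <- matrix(stats::rnorm(m * k), m, k, dimnames = list(drugs, NULL))

  noise <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = cfg$noise_sd), nr, nc)
  feat <- function(base, prefix, p) {
    colnames(base) <- sprintf("%s%04d", prefix, seq_len(p))
    rownames(base) <- cells
    base
  }
  expr <- feat(U %*% maps$expression + noise(n, cfg$n_expression) + cfg$shift,
               "g", cfg$n_expression)
  cnv <- feat(U %*% maps$cnv + noise(n, cfg$n_cnv) + cfg$shift,
              "c", cfg$n_cnv)
  mut <- feat((U %*% maps$mutation + noise(n, cfg$n_mutation) >
                 stats::qnorm(0.8)) * 1, "m", cfg$n_mutation)

  expr <- .with_missing(expr, cfg$missing_rate)
  cnv <- .with_missing(cnv, cfg$missing_rate)
  mut <- .with_missing(mut, cfg$missing_rate)

  panel <- assemble_panel(list(
    omics_matrix(expr, "expression"),
    omics_matrix(mut, "mutation"),
    omics_matrix(cnv, "cnv")
  ))

  desc <- V %*% maps$descriptors + noise(m, cfg$n_descriptors) + cfg$shift
  colnames(desc) <- sprintf("desc:s%03d", seq_len(cfg$n_descriptors))
  fp <- (V %*% maps$fingerprints + noise(m, cfg$n_fingerprint_bits) >
           stats::qnorm(0.7)) * 1
  colnames(fp) <- sprintf("fp:%d", seq_len(cfg$n_fingerprint_bits))
  drug_table <- drug_feature_table(drugs, desc, fp)
  drug_records <- data.frame(
    drug_id = drugs,
    smiles = rep_len(.BUILTIN_SMILES, m),
    stringsAsFactors = FALSE
  )

  # sample distinct (cell, drug) pairs and their true labels
  pair_idx <- sample.int(n * m, cfg$n_pairs)
  ci <- ((pair_idx - 1L) %% n) + 1L
  di <- ((pair_idx - 1L) %/% n) + 1L
  logit <- cfg$interaction_scale * rowSums(U[ci, , drop = FALSE] *
                                           V[di, , drop = FALSE]) + cfg$label_bias
  prob <- stats::plogis(logit)
  label <- stats::rbinom(cfg$n_pairs, 1L, prob)
  class <- ifelse(label == 1L, "sensitive", "resistant")
  class[stats::runif(cfg$n_pairs) < cfg$undefined_fraction] <- "undefined"
  responses <- data.frame(
    cell_line_id = cells[ci],
    drug_id = drugs[di],
    value = .response_values(class, cfg$measure),
    measure = cfg$measure,
    source = cfg$source,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      panel = panel,
      drug_records = drug_records,
      drug_table = drug_table,
      responses = responses,
      truth = list(U = U, V = V, pair_prob = prob, true_label = label,
                   assigned_class = class, prevalence = mean(label)),
      cfg = cfg,
      map_seed = map_seed
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d cell lines x %d drugs, %d response records (prevalence %.3f, shift %g)\n",
    x$cfg$n_cell_lines, x$cfg$n_drugs, nrow(x$responses),
    x$truth$prevalence, x$cfg$shift
  ))
  invisible(x)
}

#' Generate two cohorts sharing one generative process
#'
#' Cohort A uses the config as given (shift forced to 0); cohort B is an
#' independent draw from the same latent-to-feature maps with its continuous
#' features offset by `cfg$shift`. This is the fixture for the
#' train-on-one-cohort / test-on-another harness.
#'
#' @param cfg a [synthetic_config()]; `cfg$shift` is the offset applied to
#'   cohort B.
#' @return List with cohorts `a` and `b` (identical feature IDs).
#' @export
make_shifted_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg_a <- cfg
  cfg_a$shift <- 0
  cfg_a$source <- paste0(cfg$source, "_A")
  cfg_b <- cfg
  cfg_b$seed <- cfg$seed + 1000L
  cfg_b$source <- paste0(cfg$source, "_B")
  list(
    a = generate_cohort(cfg_a, map_seed = cfg$seed),
    b = generate_cohort(cfg_b, map_seed = cfg$seed)
  )
}

#' Model-ready tensor set of a synthetic cohort
#'
#' Convenience wrapper: imputes the panel, binarizes the responses and
#' assembles the labeled pairs against the cohort's latent-driven drug
#' feature table.
#'
#' @param cohort a `synthetic_cohort`.
#' @param drug_mode drug feature block, see [drug_matrix()].
#' @return List with `ts` (the `pair_tensor_set`), `pairs` and `report`
#'   (from [build_labeled_pairs()]).
#' @export
cohort_tensorset <- function(cohort,
                             drug_mode = c("both", "descriptors", "fingerprints")) {
  drug_mode <- match.arg(drug_mode)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  panel <- cohort$panel
  panel$modalities <- lapply(panel$modalities, impute_missing)
  lp <- build_labeled_pairs(cohort$responses)
  ts <- assemble_tensorset(lp$pairs, panel, cohort$drug_table, drug_mode)
  list(ts = ts, pairs = lp$pairs, report = lp$report)
}
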