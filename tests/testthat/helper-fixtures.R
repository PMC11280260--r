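# Shared in-code fixtures for the unit tests. Everything is generated
# programmatically; sizes are kept small so each file runs in seconds.

# A tiny omics matrix with controllable missingness.
tiny_omics <- function(modality = "expression", n = 3L, p = 2L,
                       cells = sprintf("CL%02d", seq_len(n)),
                       genes = sprintf("g%d", seq_len(p)), seed = 1L) {
  n <- length(cells)
  p <- length(genes)
  set.seed(seed)
  m <- matrix(round(stats::rnorm(n * p), 3), n, p,
              dimnames = list(cells, genes))
  omics_matrix(m, modality)
}

# A small synthetic cohort config for fast end-to-end tests.
small_cohort_config <- function(seed = 7L, n_pairs = 700L, ...) {
  synthetic_config(
    n_cell_lines = 60L, n_drugs = 30L, latent_dim = 4L,
    n_expression = 60L, n_mutation = 30L, n_cnv = 30L,
    n_descriptors = 10L, n_fingerprint_bits = 32L,
    n_pairs = n_pairs, seed = seed, ...
  )
}

# A small model config matched to the small cohort.
small_model_config <- function(ts, seed = 5L, epochs = 10L, ...) {
  deepdra_config(
    cell_input_dim = ncol(ts$X_cell), drug_input_dim = ncol(ts$X_drug),
    seed = seed, ae_hidden = 32L, ae_latent = 8L, mlp_hidden = 16L,
    epochs = epochs, ...
  )
}

# Write a delimited omics table to a temp file, returning its path.
write_omics_text <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}
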