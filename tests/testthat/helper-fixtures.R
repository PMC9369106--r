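# Small in-code fixtures shared across test files.

# Minimal counts tibble from a probe/class/values specification.
make_counts <- function(probe_name, probe_class, values) {
  m <- matrix(values, nrow = length(probe_name))
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(probe_name = probe_name, probe_class = probe_class),
    tibble::as_tibble(m))
}

make_labels <- function(entities) {
  tibble::tibble(sample_id = sprintf("S%02d", seq_along(entities)),
                 entity = entities)
}

# A compact panel with the tree marker genes plus filler, for fast tree fits.
small_tree_panel <- function(n_filler = 50) {
  build_panel(3 + n_filler, n_housekeeping = 4L, n_negative = 4L,
              n_positive = 2L,
              required_genes = c("PLA2G2A", "RBM47", "AQP1"))
}

# Random raw counts matrix for normalization oracle checks:
# 13 endogenous + 3 housekeeping + 4 negative probes, 6 samples.
random_norm_instance <- function() {
  n_s <- 6
  probe_name <- c(sprintf("G%02d", 1:13), sprintf("HK%02d", 1:3),
                  sprintf("NEG%02d", 1:4))
  probe_class <- c(rep("Endogenous", 13), rep("Housekeeping", 3),
                   rep("Negative", 4))
  vals <- c(rpois(13 * n_s, 300), rpois(3 * n_s, 800) + 1, rpois(4 * n_s, 6))
  m <- matrix(NA_real_, 20, n_s)
  m[1:13, ] <- vals[1:(13 * n_s)]
  m[14:16, ] <- vals[(13 * n_s + 1):(16 * n_s)]
  m[17:20, ] <- vals[(16 * n_s + 1):(20 * n_s)]
  make_counts(probe_name, probe_class, m)
}
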