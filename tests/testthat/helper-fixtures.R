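# Shared fixtures, all generated in code.

tiny_samples <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:16),
    strain = rep(c("Gaighatta", "Nadia", "SH", "TM1"), each = 4),
    domestication = rep(c("wild", "wild", "domesticated", "domesticated"),
                        each = 4),
    sex = rep(c("F", "F", "M", "M"), times = 4),
    pool_size = 4L,
    stringsAsFactors = FALSE)
}

# A hand-built 2-probe-set dataset (3 and 4 probe pairs) with valid structure.
tiny_dataset <- function(seed = 1) {
  set.seed(seed)
  samples <- tiny_samples()
  probe_ids <- c(paste0("psA:", 1:3), paste0("psB:", 1:4))
  pm <- matrix(exp(rnorm(7 * 16, log(500), 0.3)), 7, 16,
               dimnames = list(probe_ids, samples$sample_id))
  mm <- matrix(exp(rnorm(7 * 16, log(120), 0.3)), 7, 16,
               dimnames = list(probe_ids, samples$sample_id))
  probe_level_dataset(pm, mm, samples)
}

small_sim <- function(n = 400, seed = 1, ...) {
  generate_probe_level_dataset(sim_config(n_probesets = n, seed = seed, ...))
}

# Expression-level simulator for differential-expression properties: planted
# per-strain mean shifts plus iid Gaussian noise, bypassing the probe level.
sim_expression <- function(n_genes, effects = NULL, noise_sd = 0.25,
                           samples = tiny_samples()) {
  strains <- sort(unique(samples$strain))
  mu <- matrix(8, n_genes, length(strains),
               dimnames = list(sprintf("g%04d", seq_len(n_genes)), strains))
  if (!is.null(effects)) mu <- mu + effects
  expr <- mu[, samples$strain, drop = FALSE] +
    matrix(rnorm(n_genes * nrow(samples), 0, noise_sd), n_genes)
  colnames(expr) <- samples$sample_id
  expr
}
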