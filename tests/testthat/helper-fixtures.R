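# Small fixtures built in code, shared across test files.

toy_shape <- function(n_sites = 60) dataset_shape(11, 2, n_sites)

# a scenario draw with fixed, hand-set values (no RNG)
fixed_params <- function(model_id, ct = 0.5, founder_ratio = 0.05,
                         growth_ratio = 0.5) {
  tibble::tibble(model_id = as.integer(model_id), ne = 1e5,
                 dt = ct * 4e5, g = 1, theta = 5e-4, ct = ct,
                 founder_ratio = if (model_id %in% 3:4) founder_ratio
                                 else NA_real_,
                 growth_ratio = if (model_id %in% 3:4) growth_ratio
                                else NA_real_)
}

# genotype matrix with two populations at controlled allele frequencies
toy_genotypes <- function(n_per_pop = c(A = 10, B = 10), n_loci = 100,
                          p1 = 0.5, p2 = 0.5, seed = 1) {
  set.seed(seed)
  n <- sum(n_per_pop)
  pops <- rep(names(n_per_pop), n_per_pop)
  g <- matrix(NA_integer_, n, n_loci)
  g[pops == "A", ] <- stats::rbinom(sum(pops == "A") * n_loci, 2, p1)
  g[pops == "B", ] <- stats::rbinom(sum(pops == "B") * n_loci, 2, p2)
  genotype_matrix(g, pops)
}

# constant-image tensor set for separable toy classification
toy_tensor_set <- function(values, n_each, rows = 12, cols = 16) {
  cols_list <- lapply(seq_along(values), function(i) {
    matrix(as.raw(round(values[i] * 200)), rows * cols, n_each)
  })
  arowana:::new_tensor_set(do.call(cbind, cols_list), rows, cols, 1L,
                           rep(seq_along(values), each = n_each),
                           NULL, NULL)
}
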