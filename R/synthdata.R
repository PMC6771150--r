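#' Configuration of the synthetic genotype generator
#'
#' Describes an empirical-like SNP dataset generated under a hierarchical
#' Balding--Nichols model: ancestral allele frequencies are drawn uniformly,
#' basin-level frequencies diverge from them at `fst_between_basins`, and
#' locality frequencies diverge from their basin at `fst_within_basin`;
#' genotypes are then binomial draws (Hardy--Weinberg within locality) and a
#' uniform fraction of entries is masked as missing. Defaults emulate the
#' silver-arowana dataset: 6 + 5 Tocantins-Araguaia and 2 Amazon diploids,
#' 1661 loci, 0.95% missing data, basin-level differentiation around 0.49 and
#' within-basin differentiation 0.059.
#'
#' @param n_per_pop Named diploid counts per locality.
#' @param basins Basin assignment of each locality (same length as
#'   `n_per_pop`).
#' @param n_loci Number of biallelic loci.
#' @param fst_between_basins Target differentiation between basins.
#' @param fst_within_basin Target differentiation between localities of the
#'   same basin.
#' @param missing_rate Fraction of masked genotypes.
#' @param freq_range Uniform range of ancestral allele frequencies.
#' @param rng_seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_pop = c("TAb-Luciara" = 6, "TAb-Loroti" = 5,
                                       "AMb-Catalao" = 2),
                         basins = c("TAb", "TAb", "AMb"),
                         n_loci = 1661,
                         fst_between_basins = 0.49,
                         fst_within_basin = 0.059,
                         missing_rate = 0.0095,
                         freq_range = c(0.05, 0.95),
                         rng_seed = NULL) {
  if (any(n_per_pop < 1)) stop("`n_per_pop` must be >= 1", call. = FALSE)
  if (length(basins) != length(n_per_pop)) {
    stop("`basins` must match `n_per_pop`", call. = FALSE)
  }
  if (fst_between_basins < 0 || fst_between_basins >= 1 ||
      fst_within_basin < 0 || fst_within_basin >= 1) {
    stop("FST targets must lie in [0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_per_pop = n_per_pop, basins = basins,
                 n_loci = as.integer(n_loci),
                 fst_between_basins = fst_between_basins,
                 fst_within_basin = fst_within_basin,
                 missing_rate = missing_rate,
                 freq_range = freq_range, rng_seed = rng_seed),
            class = "synth_config")
}

#' Named presets emulating the two study datasets
#'
#' `"bicirrhosum"`: 13 diploids in three localities across two basins, 1661
#' loci, 0.95% missing. `"ferreirai"`: 20 diploids in one locality, 433 loci,
#' 3.77% missing (a single population, so the differentiation dials are
#' irrelevant).
#'
#' @param name Preset name.
#' @param rng_seed Integer seed stored in the config.
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("bicirrhosum", "ferreirai"),
                         rng_seed = NULL) {
  name <- match.arg(name)
  if (name == "bicirrhosum") {
    synth_config(rng_seed = rng_seed)
  } else {
    synth_config(n_per_pop = c("AMb-Taruma" = 20), basins = "AMb",
                 n_loci = 433, missing_rate = 0.0377, rng_seed = rng_seed)
  }
}

# Balding-Nichols draw: frequencies around p at divergence F
bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  lambda <- (1 - f) / f
  stats::rbeta(length(p), p * lambda, (1 - p) * lambda)
}

#' Generate an empirical-like genotype dataset
#'
#' Draws a structured genotype matrix under the hierarchical Balding--Nichols
#' model described in [synth_config()]. Loci monomorphic across the whole
#' dataset are redrawn so every column is a SNP; missing entries are masked
#' uniformly at the configured rate. Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @param rng_seed Overrides the config seed.
#' @return A `genotype_matrix` with localities as populations.
#' @export
generate_dataset <- function(config = synth_config(), rng_seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- if (!is.null(rng_seed)) rng_seed else config$rng_seed
  if (!is.null(seed)) set.seed(seed)
  n_ind <- sum(config$n_per_pop)
  pops <- rep(names(config$n_per_pop), config$n_per_pop)
  basins <- unique(config$basins)
  g <- matrix(NA_integer_, n_ind, 0)
  while (ncol(g) < config$n_loci) {
    todo <- config$n_loci - ncol(g)
    p0 <- stats::runif(todo, config$freq_range[1], config$freq_range[2])
    p_basin <- lapply(basins, function(b) {
      bn_draw(p0, config$fst_between_basins)
    })
    names(p_basin) <- basins
    cols <- matrix(NA_integer_, n_ind, todo)
    for (k in seq_along(config$n_per_pop)) {
      rows <- which(pops == names(config$n_per_pop)[k])
      p_loc <- bn_draw(p_basin[[config$basins[k]]],
                       config$fst_within_basin)
      cols[rows, ] <- vapply(p_loc, function(pl) {
        stats::rbinom(length(rows), 2L, pl)
      }, integer(length(rows)))
    }
    keep <- colSums(cols) > 0 & colSums(cols) < 2 * n_ind
    g <- cbind(g, cols[, keep, drop = FALSE])
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(g)) < config$missing_rate
    g[mask] <- NA_integer_
  }
  colnames(g) <- paste0("L", seq_len(ncol(g)))
  genotype_matrix(g, pops)
}

#' Convert a coalescent simulation into empirical format
#'
#' Bridges the simulator to the empirical-data representation: haplotypes are
#' paired into diploids within each deme, recoded as 0/1/2 genotype counts, and
#' missing entries are injected uniformly. The result passes every
#' `genotype_matrix` reader/writer and can be fed to the full inference
#' pipeline for self-consistency experiments.
#'
#' @param params One scenario draw (see [draw_priors()]).
#' @param shape A [dataset_shape()].
#' @param missing_rate Fraction of masked genotypes.
#' @param rng_seed Integer seed.
#' @param pop_names Population labels of the two demes.
#' @return A `genotype_matrix`.
#' @export
generate_pseudo_empirical <- function(params, shape = dataset_shape(),
                                      missing_rate = 0.0095, rng_seed = NULL,
                                      pop_names = c("TAb", "AMb")) {
  ds <- simulate_dataset(params, shape, rng_seed = rng_seed)
  m <- ds$matrix
  pair <- collapse_diploids(m, ds$deme_labels)
  g <- as.matrix(pair$m * 2)
  storage.mode(g) <- "integer"
  if (missing_rate > 0) {
    mask <- stats::runif(length(g)) < missing_rate
    g[mask] <- NA_integer_
  }
  colnames(g) <- paste0("L", seq_len(ncol(g)))
  genotype_matrix(g, pop_names[pair$groups])
}
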