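#' Prior configuration for the demographic scenarios
#'
#' Bundles the uniform priors used when drawing demographic parameters for the
#' four two-basin scenarios: effective population size \eqn{N_e}, divergence
#' time DT (years), generation time G (years/generation), the per-site per-year
#' mutation rate \eqn{\mu}, and the founder and growth size ratios used by the
#' colonization scenarios.
#'
#' The coalescent machinery works in scaled units: the population-scaled
#' mutation rate is \eqn{\theta = 4 N_e \mu_{gen}} per site and the divergence
#' time in coalescent units is \eqn{CT = DT / (4 N_e G)}. By default the
#' per-generation mutation rate is \eqn{\mu_{gen} = \mu G}, keeping \eqn{\theta}
#' and CT in consistent generation units; set `theta_per_generation = FALSE` for
#' the literal \eqn{\theta = 4 N_e \mu} reading with \eqn{\mu} per year.
#'
#' @param ne_range Uniform bounds for \eqn{N_e} (diploid individuals).
#' @param dt_range Uniform bounds for the divergence time DT (years).
#' @param g_range Uniform bounds for the generation time G (years/generation).
#' @param mu Mutation rate per site per year.
#' @param founder_ratio_range Uniform bounds for the founder size ratio
#'   \eqn{\theta rF\mbox{-}A} (founding size of the colonized deme relative to
#'   the ancestral size).
#' @param growth_ratio_range Uniform bounds for the growth ratio
#'   \eqn{\theta rC\mbox{-}A} (present size of the colonized deme relative to
#'   the ancestral size).
#' @param theta_per_generation Use \eqn{\mu_{gen} = \mu G} when computing
#'   \eqn{\theta} (default) rather than the per-year \eqn{\mu}.
#' @return An object of class `prior_config`.
#' @examples
#' cfg <- prior_config()
#' draw_priors(cfg, model_id = 3, n = 2, rng_seed = 1)
#' @export
prior_config <- function(ne_range = c(1e4, 1e6),
                         dt_range = c(0, 2e6),
                         g_range = c(1, 2),
                         mu = 1.25e-9,
                         founder_ratio_range = c(0.01, 0.1),
                         growth_ratio_range = c(0.1, 1.0),
                         theta_per_generation = TRUE) {
  check_range <- function(x, nm, positive_low = FALSE) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x)) {
      stop(sprintf("`%s` must be a numeric vector of two finite bounds", nm),
           call. = FALSE)
    }
    if (x[1] > x[2]) {
      stop(sprintf("`%s`: lower bound exceeds upper bound", nm), call. = FALSE)
    }
    if (positive_low && x[1] <= 0) {
      stop(sprintf("`%s`: lower bound must be > 0", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  cfg <- list(
    ne_range = check_range(ne_range, "ne_range", positive_low = TRUE),
    dt_range = check_range(dt_range, "dt_range"),
    g_range = check_range(g_range, "g_range", positive_low = TRUE),
    mu = mu,
    founder_ratio_range = check_range(founder_ratio_range,
                                      "founder_ratio_range",
                                      positive_low = TRUE),
    growth_ratio_range = check_range(growth_ratio_range,
                                     "growth_ratio_range",
                                     positive_low = TRUE),
    theta_per_generation = isTRUE(theta_per_generation)
  )
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a single positive number", call. = FALSE)
  }
  structure(cfg, class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat("<prior_config>\n")
  cat(sprintf("  Ne ~ U(%g, %g)   DT ~ U(%g, %g) yr   G ~ U(%g, %g) yr/gen\n",
              x$ne_range[1], x$ne_range[2], x$dt_range[1], x$dt_range[2],
              x$g_range[1], x$g_range[2]))
  cat(sprintf("  mu = %g /site/yr (theta uses mu %s)\n", x$mu,
              if (x$theta_per_generation) "* G" else "per year"))
  cat(sprintf("  founder ratio ~ U(%g, %g)   growth ratio ~ U(%g, %g)\n",
              x$founder_ratio_range[1], x$founder_ratio_range[2],
              x$growth_ratio_range[1], x$growth_ratio_range[2]))
  invisible(x)
}

#' Draw demographic parameters from the priors
#'
#' Samples one or more parameter sets for a given scenario and derives the
#' coalescent quantities: \eqn{\theta = 4 N_e \mu_{gen}} per site and
#' \eqn{CT = DT/(4 N_e G)}. Under the panmictic scenario (model 1) the
#' divergence time is fixed at 0, so CT = 0. The founder and growth ratios are
#' drawn only for the colonization scenarios (models 3 and 4) and are `NA`
#' otherwise.
#'
#' @param config A [prior_config()].
#' @param model_id Scenario id: 1 panmixia, 2 vicariance, 3 colonization of the
#'   Tocantins-Araguaia deme from the Amazon deme, 4 the mirror colonization.
#' @param n Number of independent draws.
#' @param rng_seed Optional integer seed; draws are reproducible given a seed.
#' @return A tibble with one row per draw and columns `model_id`, `ne`, `dt`,
#'   `g`, `theta`, `ct`, `founder_ratio`, `growth_ratio`.
#' @export
draw_priors <- function(config = prior_config(), model_id, n = 1,
                        rng_seed = NULL) {
  stopifnot(inherits(config, "prior_config"))
  if (length(model_id) != 1L || !model_id %in% 1:4) {
    stop("`model_id` must be one of 1, 2, 3, 4", call. = FALSE)
  }
  model_id <- as.integer(model_id)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ne <- stats::runif(n, config$ne_range[1], config$ne_range[2])
  g <- stats::runif(n, config$g_range[1], config$g_range[2])
  dt <- if (model_id == 1L) {
    rep(0, n)
  } else {
    stats::runif(n, config$dt_range[1], config$dt_range[2])
  }
  if (model_id %in% 3:4) {
    founder_ratio <- stats::runif(n, config$founder_ratio_range[1],
                                  config$founder_ratio_range[2])
    growth_ratio <- stats::runif(n, config$growth_ratio_range[1],
                                 config$growth_ratio_range[2])
  } else {
    founder_ratio <- rep(NA_real_, n)
    growth_ratio <- rep(NA_real_, n)
  }
  mu_gen <- if (config$theta_per_generation) config$mu * g else config$mu
  tibble::tibble(
    model_id = model_id,
    ne = ne,
    dt = dt,
    g = g,
    theta = 4 * ne * mu_gen,
    ct = dt / (4 * ne * g),
    founder_ratio = founder_ratio,
    growth_ratio = growth_ratio
  )
}
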