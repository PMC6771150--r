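#' Sample-size and site configuration for simulated datasets
#'
#' Describes the shape of each simulated SNP dataset: diploid sample sizes of
#' the two demes and the number of segregating sites. Defaults match the
#' silver-arowana study system: 11 Tocantins-Araguaia (deme 1) and 2 Amazon
#' (deme 2) diploids genotyped at 1661 biallelic SNPs.
#'
#' @param n_dip_deme1,n_dip_deme2 Diploid sample sizes (deme 1 and deme 2).
#' @param n_sites Number of segregating sites S in fixed-S mode.
#' @return An object of class `dataset_shape`.
#' @export
dataset_shape <- function(n_dip_deme1 = 11, n_dip_deme2 = 2, n_sites = 1661) {
  if (n_dip_deme1 < 1 || n_dip_deme2 < 1 || n_sites < 1) {
    stop("diploid counts and `n_sites` must all be >= 1", call. = FALSE)
  }
  structure(list(n_dip_deme1 = as.integer(n_dip_deme1),
                 n_dip_deme2 = as.integer(n_dip_deme2),
                 n_sites = as.integer(n_sites)),
            class = "dataset_shape")
}

# Hudson-style genealogy of n1h + n2h haploid tips under one of the four
# two-deme scenarios. Time runs backward in units of 4*Ne generations; deme
# sizes are relative to the ancestral/reference Ne. Returns parent pointers and
# node times; node ids always increase with coalescence time within a lineage,
# so children have smaller ids than their parents.
sim_genealogy <- function(model_id, ct, founder_ratio, growth_ratio,
                          n1h, n2h) {
  ntips <- n1h + n2h
  n_nodes_max <- 2L * ntips - 1L
  parent <- integer(n_nodes_max)
  node_time <- numeric(n_nodes_max)
  nxt <- ntips + 1L

  # Coalesce `active` lineages between absolute times t0 and tmax in a deme of
  # relative size x(t) = x0 * exp(-alpha * t); pair rate is k(k-1)/x(t).
  coalesce_in <- function(active, t0, tmax, x0, alpha) {
    t <- t0
    while (length(active) > 1L) {
      k <- length(active)
      rate <- k * (k - 1)
      e <- stats::rexp(1)
      s <- if (alpha == 0) {
        e * x0 / rate
      } else {
        log1p(e * alpha * x0 * exp(-alpha * t) / rate) / alpha
      }
      if (t + s > tmax) return(list(active = active))
      t <- t + s
      pick <- sample.int(k, 2L)
      node <- nxt
      nxt <<- nxt + 1L
      parent[active[pick]] <<- node
      node_time[node] <<- t
      active <- c(active[-pick], node)
    }
    list(active = active)
  }

  tips1 <- seq_len(n1h)
  tips2 <- n1h + seq_len(n2h)
  eps <- 1e-12

  if (model_id == 1L || ct <= eps) {
    coalesce_in(seq_len(ntips), 0, Inf, 1, 0)
  } else if (model_id == 2L) {
    r1 <- coalesce_in(tips1, 0, ct, 1, 0)
    r2 <- coalesce_in(tips2, 0, ct, 1, 0)
    coalesce_in(c(r1$active, r2$active), ct, Inf, 1, 0)
  } else {
    # colonization: the founded deme shrinks backward in time from
    # growth_ratio * Ne at present to founder_ratio * Ne at ct
    alpha <- log(growth_ratio / founder_ratio) / ct
    founded <- if (model_id == 3L) tips1 else tips2
    source_ <- if (model_id == 3L) tips2 else tips1
    rf <- coalesce_in(founded, 0, ct, growth_ratio, alpha)
    rs <- coalesce_in(source_, 0, ct, 1, 0)
    coalesce_in(c(rf$active, rs$active), ct, Inf, 1, 0)
  }

  list(parent = parent, node_time = node_time,
       n_nodes = nxt - 1L, ntips = ntips)
}

# Descendant tip sets for every node of a genealogy (children precede parents).
genealogy_descendants <- function(gen) {
  desc <- vector("list", gen$n_nodes)
  for (i in seq_len(gen$ntips)) desc[[i]] <- i
  if (gen$n_nodes > gen$ntips) {
    for (i in seq_len(gen$n_nodes)) {
      p <- gen$parent[i]
      if (p > 0L) desc[[p]] <- c(desc[[p]], desc[[i]])
    }
  }
  desc
}

#' Watterson's expected number of segregating sites
#'
#' \eqn{E[S] = \theta \sum_{i=1}^{n-1} 1/i} for a sample of `n` haploids from a
#' constant-size panmictic population with locus-wide scaled mutation rate
#' `theta`.
#'
#' @param n Haploid sample size.
#' @param theta Locus-wide population-scaled mutation rate \eqn{4 N_e \mu L}.
#' @return Expected number of segregating sites.
#' @export
watterson_s <- function(n, theta) theta * sum(1 / seq_len(n - 1))

#' Simulate one SNP dataset under a demographic scenario
#'
#' Generates a binary haplotype matrix from a single nonrecombining coalescent
#' genealogy under one of the four scenarios: (1) panmixia, (2) vicariance of
#' two equal-size demes at CT, (3) colonization of deme 1 from deme 2 at CT with
#' a founder bottleneck followed by exponential growth, (4) the mirror
#' colonization. Mutations are placed by the infinite-sites model: each site is
#' assigned to a branch with probability proportional to branch length, so every
#' column is polymorphic.
#'
#' In `"fixed_s"` mode (default) exactly `shape$n_sites` sites are produced,
#' matching the width of the empirical SNP matrix. In `"fixed_theta"` mode the
#' number of sites is Poisson with mean `locus_theta` times the total tree
#' length (in units of \eqn{4 N_e} generations), giving Watterson's
#' \eqn{E[S] = \theta \sum 1/i}; this mode exists for analytic validation.
#'
#' Linkage: reduced-representation SNP panels keep one SNP per scattered
#' locus, so the markers are quasi-independent; the default in fixed-S mode is
#' therefore `"unlinked"` -- every site gets its own genealogy. The
#' `"linked"` mode (all sites on one nonrecombining genealogy, the classical
#' single-locus `ms` layout) remains available and is always used in
#' fixed-theta mode, whose closed-form expectations assume a single locus.
#'
#' @param params One draw from [draw_priors()] (a one-row data frame or list
#'   with `model_id`, `ct`, `founder_ratio`, `growth_ratio`).
#' @param shape A [dataset_shape()].
#' @param rng_seed Optional integer seed.
#' @param mode `"fixed_s"` or `"fixed_theta"`.
#' @param locus_theta Locus-wide scaled mutation rate; required in
#'   `"fixed_theta"` mode.
#' @param linkage `"auto"` (unlinked in fixed-S mode, linked in fixed-theta
#'   mode), `"unlinked"` (one genealogy per SNP; fixed-S only) or `"linked"`
#'   (one shared genealogy).
#' @return An object of class `haplotype_dataset`: a list with the binary
#'   `matrix` (rows = haploid sequences), `deme_labels`, `positions` in
#'   \eqn{[0,1)} and the generating `params`.
#' @export
simulate_dataset <- function(params, shape = dataset_shape(), rng_seed = NULL,
                             mode = c("fixed_s", "fixed_theta"),
                             locus_theta = NULL,
                             linkage = c("auto", "unlinked", "linked")) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  if (linkage == "auto") {
    linkage <- if (mode == "fixed_s") "unlinked" else "linked"
  }
  if (linkage == "unlinked" && mode != "fixed_s") {
    stop("unlinked sites are only available in fixed-S mode", call. = FALSE)
  }
  stopifnot(inherits(shape, "dataset_shape"))
  p <- as.list(params)[c("model_id", "ct", "founder_ratio", "growth_ratio")]
  if (is.null(p$model_id) || !p$model_id %in% 1:4) {
    stop("`params` must carry a `model_id` in 1..4", call. = FALSE)
  }
  if (p$model_id %in% 3:4 &&
      (is.null(p$founder_ratio) || is.na(p$founder_ratio) ||
       is.null(p$growth_ratio) || is.na(p$growth_ratio))) {
    stop("models 3 and 4 require `founder_ratio` and `growth_ratio`",
         call. = FALSE)
  }
  n1h <- 2L * shape$n_dip_deme1
  n2h <- 2L * shape$n_dip_deme2
  ntips <- n1h + n2h
  if (ntips < 2L) stop("need at least 2 haploid samples", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  one_genealogy <- function() {
    gen <- sim_genealogy(p$model_id, p$ct, p$founder_ratio, p$growth_ratio,
                         n1h, n2h)
    branch <- which(gen$parent > 0L)
    blen <- gen$node_time[gen$parent[branch]] - gen$node_time[branch]
    list(gen = gen, branch = branch, blen = blen)
  }

  if (linkage == "unlinked") {
    s <- shape$n_sites
    if (ntips <= 31L) {
      cpp_seed <- floor(stats::runif(1) * 2147483646) + 1
      m <- .sim_unlinked(as.integer(p$model_id), p$ct,
                         if (is.null(p$founder_ratio)) NA_real_
                         else p$founder_ratio,
                         if (is.null(p$growth_ratio)) NA_real_
                         else p$growth_ratio,
                         n1h, n2h, s, cpp_seed)
    } else {
      m <- matrix(0L, ntips, s)
      for (j in seq_len(s)) {
        g <- one_genealogy()
        desc <- genealogy_descendants(g$gen)
        b <- g$branch[sample.int(length(g$branch), 1L, prob = g$blen)]
        m[desc[[b]], j] <- 1L
      }
    }
  } else {
    g <- one_genealogy()
    s <- if (mode == "fixed_s") {
      shape$n_sites
    } else {
      if (is.null(locus_theta)) {
        stop("`locus_theta` is required in fixed-theta mode", call. = FALSE)
      }
      stats::rpois(1, locus_theta * sum(g$blen))
    }
    m <- matrix(0L, ntips, s)
    if (s > 0L) {
      desc <- genealogy_descendants(g$gen)
      hit <- sample.int(length(g$branch), s, replace = TRUE, prob = g$blen)
      # columns grouped by branch for vectorized assignment
      idx <- split(seq_len(s), hit)
      for (k in names(idx)) {
        b <- g$branch[as.integer(k)]
        m[desc[[b]], idx[[k]]] <- 1L
      }
    }
  }
  structure(list(matrix = m,
                 deme_labels = rep(1:2, c(n1h, n2h)),
                 positions = sort(stats::runif(ncol(m))),
                 params = tibble::as_tibble(as.list(params))),
            class = "haplotype_dataset")
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat(sprintf("<haplotype_dataset> %d haploids x %d sites (model %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$params$model_id)) x$params$model_id else "?"))
  invisible(x)
}

#' Summary statistics of a haplotype dataset
#'
#' Segregating sites, mean pairwise nucleotide diversity (locus-wide, i.e. mean
#' number of pairwise differences) overall and within each deme, and Hudson's
#' \eqn{F_{ST}} (\eqn{1 - \pi_{within}/\pi_{total}}). Used to validate the
#' simulator against closed forms and independent implementations.
#'
#' @param ds A `haplotype_dataset`.
#' @return A one-row tibble with `s`, `pi`, `pi_deme1`, `pi_deme2`,
#'   `fst_hudson`.
#' @export
haplotype_stats <- function(ds) {
  stopifnot(inherits(ds, "haplotype_dataset"))
  m <- ds$matrix
  pi_of <- function(mm) {
    n <- nrow(mm)
    if (n < 2L || ncol(mm) == 0L) return(0)
    k <- colSums(mm)
    sum(k * (n - k)) / (n * (n - 1) / 2)
  }
  m1 <- m[ds$deme_labels == 1L, , drop = FALSE]
  m2 <- m[ds$deme_labels == 2L, , drop = FALSE]
  pi_t <- pi_of(m)
  pi_1 <- pi_of(m1)
  pi_2 <- pi_of(m2)
  pi_w <- (pi_1 + pi_2) / 2
  tibble::tibble(s = ncol(m), pi = pi_t, pi_deme1 = pi_1, pi_deme2 = pi_2,
                 fst_hudson = ifelse(pi_t > 0, 1 - pi_w / pi_t, NA_real_))
}

#' Simulate a labeled batch of datasets
#'
#' Draws `n_per_model` parameter sets per requested scenario and simulates one
#' dataset per draw. The batch manifest (one row per dataset: scenario label,
#' all drawn and derived parameters, and the per-dataset RNG seed) is always
#' returned; the datasets themselves are either kept in a `data` list-column or
#' streamed one at a time to `sink(dataset, index)` so that large batches never
#' have to be held in memory at once.
#'
#' @param config A [prior_config()].
#' @param shape A [dataset_shape()].
#' @param n_per_model Datasets per scenario.
#' @param models Scenario ids to simulate (subset of 1:4).
#' @param rng_seed Integer seed; the whole batch is reproducible given it.
#' @param mode,locus_theta,linkage Passed to [simulate_dataset()].
#' @param sink Optional `function(dataset, index)` consuming datasets as they
#'   are produced; when supplied, datasets are not retained.
#' @return The manifest tibble, with a `data` list-column unless `sink` is
#'   given.
#' @export
simulate_batch <- function(config = prior_config(), shape = dataset_shape(),
                           n_per_model, models = 1:4, rng_seed = NULL,
                           mode = c("fixed_s", "fixed_theta"),
                           locus_theta = NULL,
                           linkage = c("auto", "unlinked", "linked"),
                           sink = NULL) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  models <- as.integer(models)
  if (length(models) == 0L) stop("`models` must be non-empty", call. = FALSE)
  if (!all(models %in% 1:4)) stop("`models` must be within 1..4", call. = FALSE)
  if (n_per_model < 1L) stop("`n_per_model` must be >= 1", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  manifest <- dplyr::bind_rows(lapply(models, function(m) {
    draw_priors(config, m, n = n_per_model)
  }))
  manifest$seed <- sample.int(.Machine$integer.max, nrow(manifest))
  keep <- is.null(sink)
  out <- if (keep) vector("list", nrow(manifest)) else NULL
  for (i in seq_len(nrow(manifest))) {
    ds <- simulate_dataset(manifest[i, ], shape, rng_seed = manifest$seed[i],
                           mode = mode, locus_theta = locus_theta,
                           linkage = linkage)
    if (keep) out[[i]] <- ds else sink(ds, i)
  }
  if (keep) manifest$data <- out
  manifest
}

#' Write and read ms-style text
#'
#' Serializes a haplotype dataset as one ms-style block: `//`, `segsites: S`,
#' `positions: ...`, then one 0/1 row per haplotype. `read_ms_text()` is the
#' companion reader; positions are written with full precision so the pair
#' round-trips exactly.
#'
#' @param dataset A `haplotype_dataset`.
#' @param path File path or connection to write to.
#' @return `write_ms_text()` returns `path` invisibly; `read_ms_text()` returns
#'   a `haplotype_dataset` (deme labels from `deme_haploids` if supplied,
#'   otherwise a single deme).
#' @export
write_ms_text <- function(dataset, path) {
  stopifnot(inherits(dataset, "haplotype_dataset"))
  m <- dataset$matrix
  if (ncol(m) == 0L || nrow(m) == 0L) {
    stop("cannot write an empty haplotype matrix", call. = FALSE)
  }
  lines <- c(
    "//",
    sprintf("segsites: %d", ncol(m)),
    paste("positions:", paste(sprintf("%.17g", dataset$positions),
                              collapse = " ")),
    apply(m, 1, paste0, collapse = "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ms_text
#' @param deme_haploids Optional integer vector of haploid counts per deme used
#'   to reconstruct deme labels.
#' @export
read_ms_text <- function(path, deme_haploids = NULL) {
  lines <- readLines(path)
  i <- which(lines == "//")[1]
  if (is.na(i)) stop("not an ms-style block: no `//` line", call. = FALSE)
  s <- as.integer(sub("^segsites:\\s*", "", lines[i + 1]))
  pos <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[i + 2]),
                             "\\s+")[[1]])
  rows <- lines[-seq_len(i + 2)]
  rows <- rows[nzchar(rows)]
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  if (ncol(m) != s) stop("segsites does not match row width", call. = FALSE)
  labels <- if (is.null(deme_haploids)) {
    rep(1L, nrow(m))
  } else {
    rep(seq_along(deme_haploids), deme_haploids)
  }
  structure(list(matrix = m, deme_labels = labels, positions = pos,
                 params = NULL),
            class = "haplotype_dataset")
}
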