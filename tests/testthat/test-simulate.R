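test_that("tiny panmictic datasets are well-formed and deterministic", {
  p <- draw_priors(prior_config(), 1, rng_seed = 1)
  ds <- simulate_dataset(p, dataset_shape(1, 1, 5), rng_seed = 2)
  expect_equal(dim(ds$matrix), c(4L, 5L))
  ds2 <- simulate_dataset(p, dataset_shape(1, 1, 5), rng_seed = 2)
  expect_identical(ds$matrix, ds2$matrix)
  # with exactly two haploid tips every segregating site separates the pair:
  # both branches of the 2-tip genealogy subtend a single tip
  set.seed(3)
  gen <- arowana:::sim_genealogy(1L, 0, NA, NA, 1L, 1L)
  expect_equal(gen$n_nodes, 3L)
  desc <- arowana:::genealogy_descendants(gen)
  expect_identical(desc[[1]], 1L)
  expect_identical(desc[[2]], 2L)
  expect_setequal(desc[[3]], 1:2)
})

test_that("every column is polymorphic and fixed-S width is exact", {
  for (m in 1:4) {
    ds <- simulate_dataset(fixed_params(m), toy_shape(80), rng_seed = 10 + m)
    cs <- colSums(ds$matrix)
    expect_equal(ncol(ds$matrix), 80L)
    expect_true(all(cs > 0 & cs < nrow(ds$matrix)))
    expect_true(all(diff(ds$positions) >= 0))
    expect_true(all(ds$positions >= 0 & ds$positions < 1))
  }
})

test_that("fixed-theta mode matches Watterson's expectation within 1%", {
  p <- draw_priors(prior_config(), 1, rng_seed = 5)
  sh <- toy_shape()
  set.seed(99)
  s <- replicate(1e4, ncol(simulate_dataset(p, sh, mode = "fixed_theta",
                                            locus_theta = 10)$matrix))
  expect_equal(mean(s), watterson_s(26, 10), tolerance = 0.01)
})

test_that("pairwise diversity under panmixia matches theta", {
  p <- draw_priors(prior_config(), 1, rng_seed = 5)
  sh <- toy_shape()
  set.seed(7)
  pis <- replicate(2000, haplotype_stats(
    simulate_dataset(p, sh, mode = "fixed_theta", locus_theta = 10))$pi)
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 10), 3 * se)
})

test_that("a vicariance split at time zero is panmixia", {
  sh <- toy_shape()
  p1 <- draw_priors(prior_config(), 1, rng_seed = 5)
  p2 <- fixed_params(2, ct = 0)
  set.seed(11)
  stat <- function(p) {
    replicate(1500, {
      d <- simulate_dataset(p, sh, mode = "fixed_theta", locus_theta = 8)
      c(ncol(d$matrix), haplotype_stats(d)$pi)
    })
  }
  a <- stat(p1)
  b <- stat(p2)
  expect_gt(suppressWarnings(stats::ks.test(a[1, ], b[1, ]))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(a[2, ], b[2, ]))$p.value, 0.01)
})

test_that("the founder bottleneck strips diversity from the colonized deme", {
  sh <- toy_shape()
  p <- fixed_params(3, ct = 0.5, founder_ratio = 0.01, growth_ratio = 0.5)
  set.seed(21)
  st <- purrr::map_dfr(1:300, function(i) {
    haplotype_stats(simulate_dataset(p, sh))
  })
  expect_lt(mean(st$pi_deme1), mean(st$pi_deme2))
})

test_that("models 3 and 4 are mirror images under deme-label swap", {
  # swap both the scenario direction and the sample sizes: the joint
  # distribution of (pi_founded, pi_source, fst) must agree
  set.seed(31)
  sh34 <- dataset_shape(11, 2, 60)
  sh43 <- dataset_shape(2, 11, 60)
  p3 <- fixed_params(3)
  p4 <- fixed_params(4)
  a <- purrr::map_dfr(1:400, function(i) {
    haplotype_stats(simulate_dataset(p3, sh34))
  })
  b <- purrr::map_dfr(1:400, function(i) {
    haplotype_stats(simulate_dataset(p4, sh43))
  })
  expect_gt(suppressWarnings(
    stats::ks.test(a$pi_deme1, b$pi_deme2))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(a$pi_deme2, b$pi_deme1))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(a$fst_hudson, b$fst_hudson))$p.value, 0.01)
})

test_that("between-deme differentiation increases with divergence time", {
  sh <- toy_shape()
  set.seed(41)
  mean_fst <- vapply(c(0.05, 0.2, 0.8, 3), function(ct) {
    mean(vapply(1:300, function(i) {
      haplotype_stats(simulate_dataset(fixed_params(2, ct = ct),
                                       sh))$fst_hudson
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})

test_that("unlinked sites match the reference genealogy-per-site sampler", {
  # reference implementation in plain R: one genealogy per site, derived
  # allele on a branch chosen proportionally to branch length
  ref_counts <- function(p, n1h, n2h, n) {
    vapply(seq_len(n), function(i) {
      gen <- arowana:::sim_genealogy(p$model_id, p$ct, p$founder_ratio,
                                     p$growth_ratio, n1h, n2h)
      desc <- arowana:::genealogy_descendants(gen)
      branch <- which(gen$parent > 0L)
      blen <- gen$node_time[gen$parent[branch]] - gen$node_time[branch]
      length(desc[[branch[sample.int(length(branch), 1L, prob = blen)]]])
    }, integer(1))
  }
  p <- fixed_params(3, ct = 0.5)
  set.seed(61)
  ref <- ref_counts(as.list(p), 22L, 4L, 4000)
  got <- integer(0)
  for (i in 1:10) {
    got <- c(got, colSums(simulate_dataset(p, toy_shape(400),
                                           rng_seed = 600 + i)$matrix))
  }
  tab <- rbind(tabulate(ref, 25) + 1, tabulate(got, 25) + 1)
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)

  # columns of an unlinked dataset are uncorrelated, unlike linked ones
  un <- simulate_dataset(p, toy_shape(300), rng_seed = 62)
  li <- simulate_dataset(p, toy_shape(300), rng_seed = 62,
                         linkage = "linked")
  mean_abs_cor <- function(m) {
    k <- colSums(m)
    mean(abs(stats::cor(m[, k > 2 & k < 22, drop = FALSE]))[upper.tri(
      diag(sum(k > 2 & k < 22)))], na.rm = TRUE)
  }
  expect_lt(mean_abs_cor(un$matrix), mean_abs_cor(li$matrix))
  expect_error(simulate_dataset(p, toy_shape(10), mode = "fixed_theta",
                                locus_theta = 5, linkage = "unlinked"),
               "fixed-S")
})

test_that("batches are reproducible, labeled and streamable", {
  cfg <- prior_config()
  sh <- toy_shape(20)
  b1 <- simulate_batch(cfg, sh, n_per_model = 3, models = c(2, 3),
                       rng_seed = 77)
  b2 <- simulate_batch(cfg, sh, n_per_model = 3, models = c(2, 3),
                       rng_seed = 77)
  expect_equal(nrow(b1), 6L)
  expect_equal(as.integer(table(b1$model_id)), c(3L, 3L))
  expect_identical(b1$data[[5]]$matrix, b2$data[[5]]$matrix)
  seen <- integer(0)
  b3 <- simulate_batch(cfg, sh, n_per_model = 3, models = c(2, 3),
                       rng_seed = 77,
                       sink = function(ds, i) seen <<- c(seen, i))
  expect_false("data" %in% names(b3))
  expect_equal(seen, 1:6)
  expect_error(simulate_batch(cfg, sh, 3, models = integer(0)), "non-empty")
  expect_error(simulate_batch(cfg, sh, 0), ">= 1")
})

test_that("ms-style text round-trips exactly", {
  ds <- simulate_dataset(fixed_params(3), toy_shape(25), rng_seed = 9)
  f <- withr::local_tempfile(fileext = ".txt")
  write_ms_text(ds, f)
  back <- read_ms_text(f, deme_haploids = c(22, 4))
  expect_identical(back$matrix, ds$matrix)
  expect_equal(back$positions, ds$positions)
  expect_identical(back$deme_labels, ds$deme_labels)
  txt <- readLines(f)
  expect_identical(txt[1], "//")
  expect_identical(txt[2], "segsites: 25")
  empty <- ds
  empty$matrix <- ds$matrix[, integer(0)]
  expect_error(write_ms_text(empty, f), "empty")
})

test_that("simulated distributions match an independent coalescent oracle", {
  # msprime (python) as the independent simulator: compare S, pi and Hudson
  # FST distributions for a panmictic and a structured scenario
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".csv")
  writeLines(c(
    "import msprime, sys",
    "n_rep = 1500",
    "rows = []",
    "# panmixia: 26 haploids, locus theta = 8 (msprime time unit = 2N here)",
    "for i in range(n_rep):",
    "    ts = msprime.sim_ancestry(samples=26, ploidy=1, population_size=1,",
    "                              random_seed=1 + i)",
    "    mt = msprime.sim_mutations(ts, rate=4.0, random_seed=90001 + i,",
    "                               discrete_genome=False)",
    "    pi = mt.diversity(span_normalise=False)",
    "    rows.append(('pan', mt.num_sites, float(pi), 0.0, 0.0))",
    "# vicariance at ct=0.4 coalescent units (= 0.8 msprime time units)",
    "dem = msprime.Demography()",
    "dem.add_population(name='A', initial_size=1)",
    "dem.add_population(name='B', initial_size=1)",
    "dem.add_population(name='anc', initial_size=1)",
    "dem.add_population_split(time=0.8, derived=['A', 'B'], ancestral='anc')",
    "for i in range(n_rep):",
    "    ts = msprime.sim_ancestry(samples={'A': 22, 'B': 4}, ploidy=1,",
    "                              demography=dem, random_seed=200001 + i)",
    "    mt = msprime.sim_mutations(ts, rate=4.0, random_seed=300001 + i,",
    "                               discrete_genome=False)",
    "    pi = mt.diversity(span_normalise=False)",
    "    sets = [list(range(22)), list(range(22, 26))]",
    "    piw = mt.diversity(sample_sets=sets, span_normalise=False)",
    "    rows.append(('vic', mt.num_sites, float(pi), float(piw[0]),",
    "                 float(piw[1])))",
    "with open(sys.argv[1], 'w') as f:",
    "    f.write('scen,s,pi,pi1,pi2\\n')",
    "    for r in rows:",
    "        f.write(','.join(map(str, r)) + '\\n')"
  ), script)
  res <- system2("python", c(script, out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.size(out) > 0,
              info = paste(res, collapse = "\n"))
  ora <- utils::read.csv(out)

  sh <- toy_shape()
  set.seed(51)
  mine_pan <- purrr::map_dfr(1:1500, function(i) {
    haplotype_stats(simulate_dataset(draw_priors(prior_config(), 1), sh,
                                     mode = "fixed_theta", locus_theta = 8))
  })
  o <- ora[ora$scen == "pan", ]
  expect_gt(suppressWarnings(stats::ks.test(mine_pan$s, o$s))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(mine_pan$pi, o$pi))$p.value, 0.01)

  mine_vic <- purrr::map_dfr(1:1500, function(i) {
    haplotype_stats(simulate_dataset(fixed_params(2, ct = 0.4), sh,
                                     mode = "fixed_theta", locus_theta = 8))
  })
  o <- ora[ora$scen == "vic", ]
  fst_o <- 1 - ((o$pi1 + o$pi2) / 2) / o$pi
  expect_gt(suppressWarnings(stats::ks.test(mine_vic$s, o$s))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(mine_vic$pi, o$pi))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(mine_vic$fst_hudson, fst_o))$p.value, 0.01)
})
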