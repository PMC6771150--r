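test_that("readers agree across VCF, DArT two-row and matrix formats", {
  g <- rbind(ind1 = c(0L, 1L, 2L), ind2 = c(2L, 1L, NA), ind3 = c(1L, 0L, 0L),
             ind4 = c(0L, 2L, 1L))
  colnames(g) <- paste0("L", 1:3)
  pm <- data.frame(id = paste0("ind", 1:4), pop = c("A", "A", "B", "B"))
  gm <- genotype_matrix(g, pm)

  fm <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gm, fm, "matrix")
  back <- read_genotypes(fm, "matrix", pm)
  expect_equal(unname(back$genotypes), unname(g))

  fd <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gm, fd, "dart2row")
  backd <- read_genotypes(fd, "dart2row", pm)
  expect_equal(unname(backd$genotypes), unname(g))

  fv <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(gm, fv, "vcf")
  backv <- read_genotypes(fv, "vcf", pm)
  expect_equal(unname(backv$genotypes), unname(g))

  # the two-row convention: (1,0) hom ref, (1,1) het, (0,1) hom alt, (0,0) NA
  d <- utils::read.csv(fd)
  l2 <- d[d$locus == "L2", paste0("ind", 1:4)]
  expect_equal(unname(as.integer(l2[1, ])), c(1L, 1L, 1L, 0L))
  expect_equal(unname(as.integer(l2[2, ])), c(1L, 1L, 0L, 1L))

  expect_error(genotype_matrix(matrix(3L, 2, 2), c("A", "A")), "codes")
  expect_error(genotype_matrix(g, pm[1:3, ]), "absent")
})

test_that("diversity matches the hand-worked single-locus examples", {
  # genotypes {AA, Aa, Aa, aa}: p = 0.5, Ho = 0.5, He = (8/7) * 0.5 = 0.5714
  gm <- genotype_matrix(cbind(c(0L, 1L, 1L, 2L)), rep("P", 4))
  d <- diversity(gm)
  expect_equal(d$ho, 0.5)
  expect_equal(d$he, 4 / 7, tolerance = 1e-12)
  expect_equal(d$gis, 1 - 0.5 / (4 / 7), tolerance = 1e-12)
  expect_equal(d$gis, 0.125)
  expect_equal(d$a, 2)

  # all heterozygotes: Ho = 1, He unchanged, Gis negative
  gm2 <- genotype_matrix(cbind(rep(1L, 4)), rep("P", 4))
  d2 <- diversity(gm2)
  expect_equal(d2$ho, 1)
  expect_equal(d2$he, 4 / 7)
  expect_lt(d2$gis, 0)

  # a dataset-monomorphic locus is excluded from the across-locus means
  gm3 <- genotype_matrix(cbind(c(0L, 1L, 1L, 2L), c(0L, 0L, 0L, 0L)),
                         rep("P", 4))
  expect_equal(diversity(gm3)$ho, 0.5)
  expect_error(diversity(genotype_matrix(cbind(c(0L, 1L)), c("P", "Q"))),
               "fewer than 2")
})

test_that("expected equals observed heterozygosity under Hardy-Weinberg", {
  set.seed(12)
  n <- 40
  p <- stats::runif(5000, 0.1, 0.9)
  g <- vapply(p, function(pp) stats::rbinom(n, 2, pp), integer(n))
  gm <- genotype_matrix(g, rep("P", n))
  ho <- colMeans(g == 1L)
  he <- (2 * n / (2 * n - 1)) * 2 * colMeans(g) / 2 * (1 - colMeans(g) / 2)
  expect_gt(stats::t.test(ho - he)$p.value, 0.01)
  # and the aggregated table reflects it
  d <- diversity(gm)
  expect_equal(d$ho, d$he, tolerance = 0.01)
})

test_that("Weir-Cockerham theta hits its analytic anchor points", {
  # identical allele frequencies, many loci: theta near 0
  gm0 <- toy_genotypes(c(A = 30, B = 30), n_loci = 1000, p1 = 0.5, p2 = 0.5,
                       seed = 3)
  f0 <- pairwise_fst(gm0)
  expect_lt(abs(f0["A", "B"]), 0.02)
  expect_equal(unclass(f0)[cbind(1:2, 1:2)], c(0, 0), ignore_attr = TRUE)
  expect_equal(f0["A", "B"], f0["B", "A"])

  # fixed difference at every locus: theta = 1
  gm1 <- genotype_matrix(rbind(matrix(0L, 5, 50), matrix(2L, 5, 50)),
                         rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(gm1)["A", "B"], 1)

  # Balding-Nichols populations at F = 0.5 recover theta in (0.45, 0.55)
  set.seed(31)
  n <- 50
  p0 <- stats::runif(2000, 0.1, 0.9)
  draw_pop <- function() {
    p <- stats::rbeta(length(p0), p0, 1 - p0)  # lambda = (1-F)/F = 1
    vapply(p, function(pp) stats::rbinom(n, 2, pp), integer(n))
  }
  gmbn <- genotype_matrix(rbind(draw_pop(), draw_pop()),
                          rep(c("A", "B"), each = n))
  th <- pairwise_fst(gmbn)["A", "B"]
  expect_gt(th, 0.45)
  expect_lt(th, 0.55)
})

test_that("theta increases with divergence time and is centred at 0 at ct=0", {
  set.seed(17)
  sh <- toy_shape(200)
  theta_at <- function(ct, reps = 60) {
    mean(vapply(seq_len(reps), function(i) {
      gm <- generate_pseudo_empirical(fixed_params(2, ct = ct), sh,
                                      missing_rate = 0)
      pairwise_fst(gm)["TAb", "AMb"]
    }, numeric(1)))
  }
  t0 <- theta_at(0)
  t1 <- theta_at(0.3)
  t2 <- theta_at(1.5)
  expect_lt(abs(t0), 0.05)
  expect_lt(t0, t1)
  expect_lt(t1, t2)
})

test_that("PCoA reconstructs distances and orders eigenvalues", {
  # three collinear points: d(1,2) = d(1,3) = 1, d(2,3) = 2
  g <- rbind(a = rep(1L, 8), b = rep(c(0L, 1L), each = 4),
             c = rep(c(2L, 1L), each = 4))
  gm <- genotype_matrix(g, rep("P", 3))
  res <- suppressWarnings(pcoa(gm, n_axes = 2))
  got <- as.matrix(stats::dist(res$coordinates$axis1))
  expect_equal(got[1, 2], 0.25, tolerance = 1e-9)
  expect_equal(got[1, 3], 0.25, tolerance = 1e-9)
  expect_equal(got[2, 3], 0.5, tolerance = 1e-9)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))

  # identical individuals are coincident
  g2 <- rbind(matrix(rep(c(0L, 2L, 1L, 0L), 3), 3, byrow = TRUE),
              c(2L, 0L, 1L, 2L))
  res2 <- suppressWarnings(pcoa(genotype_matrix(g2, rep("P", 4)), 1))
  expect_equal(res2$coordinates$axis1[1], res2$coordinates$axis1[2])
})

test_that("PCoA separates differentiated populations along axis 1", {
  set.seed(23)
  ok <- vapply(1:100, function(i) {
    cfg <- synth_config(n_per_pop = c(A = 10, B = 10), basins = c("a", "b"),
                        n_loci = 150, fst_between_basins = 0.25,
                        fst_within_basin = 0, missing_rate = 0)
    gm <- generate_dataset(cfg)
    co <- pcoa(gm, 1)$coordinates
    x <- split(co$axis1, co$pop)
    # positive silhouette-like separation: group means further apart than
    # within-group spread
    abs(mean(x$A) - mean(x$B)) >
      (stats::sd(x$A) + stats::sd(x$B)) / 2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("dataset summaries count individuals, loci and missingness", {
  g <- matrix(0L, 2, 4)
  g[1, 2] <- NA
  gm <- genotype_matrix(g, c("A", "A"))
  s <- summarize_dataset(gm)
  expect_equal(s$n_individuals, 2L)
  expect_equal(s$n_loci, 4L)
  expect_equal(s$missing_fraction, 0.125)
  expect_equal(summarize_dataset(toy_genotypes())$missing_fraction, 0)
})
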