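# helper: encoder with positional column order, isolating row-sort semantics
cfg_pos <- function(...) encoder_config(..., col_sort = "none")

test_that("row sorting is canonical and invariant to within-deme permutation", {
  # hand example: rows {110, 011, 110, 000} sort to {000, 011, 110, 110}
  ds <- structure(list(
    matrix = rbind(c(1, 1, 0), c(0, 1, 1), c(1, 1, 0), c(0, 0, 0)),
    deme_labels = rep(1L, 4), positions = c(0.1, 0.5, 0.9),
    params = NULL), class = "haplotype_dataset")
  cfg <- cfg_pos(rows_fixed = 4, cols_fixed = 3)
  img <- matrix_to_image(ds, cfg)
  expect_equal(unclass(img)[, ],
               rbind(c(0, 0, 0), c(0, 1, 1), c(1, 1, 0), c(1, 1, 0)),
               ignore_attr = TRUE)
  perm <- ds
  perm$matrix <- ds$matrix[c(3, 1, 4, 2), ]
  expect_equal(matrix_to_image(perm, cfg)[, ], img[, ])

  # within-deme permutations leave the tensor fixed under either column order
  sim <- simulate_dataset(fixed_params(3), toy_shape(30), rng_seed = 4)
  set.seed(8)
  shuffled <- sim
  shuffled$matrix <- sim$matrix[c(sample(1:22), 22 + sample(1:4)), ]
  for (cs in c("frequency", "none")) {
    cfg2 <- encoder_config(rows_fixed = 26, cols_fixed = 30, col_sort = cs)
    expect_equal(matrix_to_image(shuffled, cfg2)[, ],
                 matrix_to_image(sim, cfg2)[, ])
  }
})

test_that("frequency column sort orders sites by allele counts", {
  ds <- structure(list(
    matrix = rbind(c(1, 1, 0), c(0, 1, 0), c(1, 1, 1), c(0, 1, 0)),
    deme_labels = c(1L, 1L, 2L, 2L), positions = c(0.1, 0.5, 0.9),
    params = NULL), class = "haplotype_dataset")
  img <- matrix_to_image(ds, encoder_config(rows_fixed = 4, cols_fixed = 3))
  # column totals (2, 4, 1) -> order: site3, site1, site2
  expect_equal(colSums(decode_image(img)), c(1, 2, 4))
  expect_equal(attr(img, "positions"), c(0.9, 0.1, 0.5))
  # the value multiset is only rearranged
  expect_equal(sum(img), sum(ds$matrix))
})

test_that("padding, truncation and the decode round trip behave", {
  ds <- structure(list(matrix = rbind(c(0, 1), c(1, 0)),
                       deme_labels = rep(1L, 2),
                       positions = c(0.2, 0.7), params = NULL),
                  class = "haplotype_dataset")
  img <- matrix_to_image(ds, cfg_pos(rows_fixed = 2, cols_fixed = 4))
  expect_equal(img[, 3:4], matrix(0, 2, 2))
  expect_equal(decode_image(img), rbind(c(0, 1), c(1, 0)),
               ignore_attr = TRUE)

  sim <- simulate_dataset(fixed_params(2), toy_shape(50), rng_seed = 5)
  cfg <- encoder_config(rows_fixed = 26, cols_fixed = 20)
  a <- matrix_to_image(sim, cfg, rng_seed = 1)
  b <- matrix_to_image(sim, cfg, rng_seed = 1)
  expect_equal(a[, ], b[, ])           # seeded truncation is deterministic
  expect_equal(attr(a, "n_cols_data"), 20L)

  # binary haploid data with no padding decode to the sorted matrix exactly
  full <- matrix_to_image(sim, encoder_config(rows_fixed = 26,
                                              cols_fixed = 50))
  dec <- decode_image(full)
  expect_true(all(dec %in% c(0, 1)))
  expect_equal(sort(colSums(dec)), sort(colSums(sim$matrix)))

  expect_error(matrix_to_image(sim, encoder_config(rows_fixed = 10,
                                                   cols_fixed = 50)),
               "rows")
})

test_that("deme swap moves blocks, diploid collapse averages pairs", {
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 1))
  ds12 <- structure(list(matrix = m, deme_labels = c(1L, 1L, 2L, 2L),
                         positions = 1:3 / 3, params = NULL),
                    class = "haplotype_dataset")
  ds21 <- structure(list(matrix = m[c(3, 4, 1, 2), ],
                         deme_labels = c(1L, 1L, 2L, 2L),
                         positions = 1:3 / 3, params = NULL),
                    class = "haplotype_dataset")
  cfg <- cfg_pos(rows_fixed = 4, cols_fixed = 3)
  a <- matrix_to_image(ds12, cfg)
  b <- matrix_to_image(ds21, cfg)
  expect_equal(a[1:2, ], b[3:4, ])
  expect_equal(a[3:4, ], b[1:2, ])

  dip <- matrix_to_image(ds12, cfg_pos(rows_fixed = 2, cols_fixed = 3,
                                       ploidy_mode = "diploid_collapsed"))
  expect_equal(sort(unique(as.numeric(dip))), c(0, 0.5, 1))
  expect_equal(dip[1, ], c(1, 0.5, 0))  # (110 + 100)/2
})

test_that("genotype matrices encode with missing-value imputation", {
  g <- rbind(c(0L, 1L, 2L), c(2L, NA, 0L), c(1L, 1L, 1L), c(0L, 2L, NA))
  gm <- genotype_matrix(g, c("A", "A", "B", "B"))
  img <- matrix_to_image(gm, encoder_config(rows_fixed = 4, cols_fixed = 3,
                                            missing_value = 0.5))
  vals <- as.numeric(img)
  expect_true(all(vals %in% c(0, 0.5, 1)))
  expect_equal(sum(vals == 0.5), 4 + 2)  # four heterozygotes plus two NAs
})

test_that("training tensors split stratified, disjoint and reproducible", {
  b <- simulate_batch(prior_config(), toy_shape(15), n_per_model = 25,
                      models = 1:4, rng_seed = 3)
  cfg <- encoder_config(rows_fixed = 26, cols_fixed = 15)
  sp <- make_training_tensors(b, cfg, train_n = 80, test_n = 20,
                              rng_seed = 10)
  expect_equal(n_images(sp$train), 80L)
  expect_equal(n_images(sp$test), 20L)
  expect_equal(as.integer(table(sp$train$labels)), rep(20L, 4))
  expect_equal(as.integer(table(sp$test$labels)), rep(5L, 4))
  sp2 <- make_training_tensors(b, cfg, train_n = 80, test_n = 20,
                               rng_seed = 10)
  expect_identical(sp$train$x, sp2$train$x)
  ts <- encode_batch(b, cfg)
  expect_error(split_tensors(ts, 120, 40, rng_seed = 1), "available")
  # quantized storage reproduces image values exactly
  img <- matrix_to_image(b$data[[7]], cfg)
  expect_equal(tensor_image(ts, 7), img[, ], ignore_attr = TRUE)
})

test_that("streaming simulate_tensors matches simulate_batch + encode_batch", {
  cfg <- encoder_config(rows_fixed = 26, cols_fixed = 15)
  a <- simulate_tensors(prior_config(), toy_shape(15), n_per_model = 4,
                        models = c(1, 3), rng_seed = 5, encoder = cfg)
  b <- encode_batch(simulate_batch(prior_config(), toy_shape(15),
                                   n_per_model = 4, models = c(1, 3),
                                   rng_seed = 5), cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$labels, b$labels)
})

test_that("tensor sets round-trip through the binary container", {
  cfg <- encoder_config(rows_fixed = 26, cols_fixed = 15)
  ts <- simulate_tensors(prior_config(), toy_shape(15), n_per_model = 5,
                         models = c(1, 3), rng_seed = 9, encoder = cfg)
  f <- withr::local_tempfile(fileext = ".bin")
  write_tensors(ts, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- read_tensors(f)
  expect_identical(back$x, ts$x)
  expect_identical(back$labels, ts$labels)
  expect_equal(back$rows, ts$rows)
  expect_equal(back$config$cols_fixed, 15)
  expect_equal(back$params$ne, ts$params$ne)
})
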