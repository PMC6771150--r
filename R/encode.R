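#' Encoder configuration
#'
#' Controls how a haplotype or genotype matrix is converted into the
#' fixed-shape image tensor consumed by the network. Rows are sorted
#' lexicographically within each deme block (the usual matrix-as-image
#' treatment, removing haplotype label-switching noise); columns beyond the
#' data width are zero-padded and wider matrices are randomly column-subsampled
#' (seeded) down to `cols_fixed`.
#'
#' @param rows_fixed Image height; defaults to the 26 haploids of the default
#'   [dataset_shape()].
#' @param cols_fixed Image width; defaults to the 1661 empirical SNPs.
#' @param sort_scope Sort rows `"within_deme"` (default) or `"global"`.
#' @param ploidy_mode `"haploid"` keeps one row per haplotype (values 0/1);
#'   `"diploid_collapsed"` averages the two haplotypes of each individual
#'   (values 0, 0.5, 1), the encoding used for unphased empirical genotypes.
#' @param missing_value Value imputed for missing genotypes (default 0.5).
#' @param position_channel If `TRUE`, append a second channel holding each
#'   site's relative position.
#' @param sort_method `"lexicographic"` (default) or `"similarity"`
#'   (hierarchical-clustering leaf order).
#' @param col_sort `"frequency"` (default) reorders site columns by total
#'   allele count with per-deme counts as tie-breakers, canonicalizing the
#'   exchangeable site order into a joint-frequency-spectrum-like image;
#'   `"none"` keeps positional order.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(rows_fixed = 26, cols_fixed = 1661,
                           sort_scope = c("within_deme", "global"),
                           ploidy_mode = c("haploid", "diploid_collapsed"),
                           missing_value = 0.5, position_channel = FALSE,
                           sort_method = c("lexicographic", "similarity"),
                           col_sort = c("frequency", "none")) {
  if (rows_fixed < 2 || cols_fixed < 1) {
    stop("`rows_fixed` must be >= 2 and `cols_fixed` >= 1", call. = FALSE)
  }
  structure(list(rows_fixed = as.integer(rows_fixed),
                 cols_fixed = as.integer(cols_fixed),
                 sort_scope = match.arg(sort_scope),
                 ploidy_mode = match.arg(ploidy_mode),
                 missing_value = missing_value,
                 position_channel = isTRUE(position_channel),
                 sort_method = match.arg(sort_method),
                 col_sort = match.arg(col_sort)),
            class = "encoder_config")
}

# Lexicographic row order. For the {0, 0.5, 1} alphabet, columns are packed
# 32 at a time into base-3 integer keys (fits a double exactly) and ordered by
# multi-key radix sort; other alphabets fall back to string keys.
row_order <- function(m, method) {
  if (method == "similarity" && nrow(m) > 2) {
    return(stats::hclust(stats::dist(m, method = "manhattan"),
                         "average")$order)
  }
  v <- m * 2
  if (all(v %in% c(0, 1, 2))) {
    nb <- ncol(v)
    k <- ceiling(nb / 32)
    keys <- vector("list", k)
    for (j in seq_len(k)) {
      cols <- ((j - 1) * 32 + 1):min(j * 32, nb)
      keys[[j]] <- as.vector(v[, cols, drop = FALSE] %*%
                               3^((length(cols) - 1):0))
    }
    do.call(order, c(keys, list(method = "radix")))
  } else {
    order(apply(m, 1, paste, collapse = ","), method = "radix")
  }
}

#' Convert a dataset to a fixed-shape image
#'
#' Produces a numeric `rows_fixed x cols_fixed` matrix with values in `[0, 1]`:
#' 0/1 for haploid data, 0/0.5/1 for collapsed diploids, `missing_value` for
#' missing genotypes. Rows are sorted within their deme/population block
#' (deme 1 block on top); extra columns are zero padding and, when the data are
#' wider than `cols_fixed`, a seeded random subsample of columns (order
#' preserved) is taken.
#'
#' @param x A `haplotype_dataset` or `genotype_matrix`.
#' @param config An [encoder_config()].
#' @param rng_seed Seed for the column subsample when truncating.
#' @return A matrix of class `snp_image` with attributes `deme_sizes`,
#'   `n_rows_data`, `n_cols_data`, `label` and `positions` (if a position
#'   channel is requested the result is a `rows x cols x 2` array).
#' @export
matrix_to_image <- function(x, config = encoder_config(), rng_seed = NULL) {
  stopifnot(inherits(config, "encoder_config"))
  if (inherits(x, "haplotype_dataset")) {
    m <- x$matrix
    groups <- x$deme_labels
    positions <- x$positions
    label <- if (!is.null(x$params)) x$params$model_id else NA_integer_
    if (config$ploidy_mode == "diploid_collapsed") {
      collapsed <- collapse_diploids(m, groups)
      m <- collapsed$m
      groups <- collapsed$groups
    } else {
      m <- m * 1.0
    }
  } else if (inherits(x, "genotype_matrix")) {
    m <- x$genotypes / 2
    m[is.na(m)] <- config$missing_value
    groups <- match(x$popmap$pop, unique(x$popmap$pop))
    positions <- seq_len(ncol(m)) / ncol(m)
    label <- NA_integer_
  } else {
    stop("`x` must be a haplotype_dataset or genotype_matrix", call. = FALSE)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("cannot encode an empty matrix", call. = FALSE)
  }
  if (nrow(m) > config$rows_fixed) {
    stop(sprintf("matrix has %d rows but `rows_fixed` is %d", nrow(m),
                 config$rows_fixed), call. = FALSE)
  }
  if (ncol(m) > config$cols_fixed) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    keep <- sort(sample.int(ncol(m), config$cols_fixed))
    m <- m[, keep, drop = FALSE]
    positions <- positions[keep]
  }
  blocks <- split(seq_len(nrow(m)), groups)
  # canonical column order first (keys are invariant to row permutations
  # within blocks), then row sort within blocks (deterministic afterwards)
  if (is.null(config$col_sort) || config$col_sort == "frequency") {
    keys <- c(list(colSums(m)),
              lapply(blocks, function(ix) {
                colSums(m[ix, , drop = FALSE])
              }))
    co <- do.call(order, c(keys, list(method = "radix")))
    m <- m[, co, drop = FALSE]
    positions <- positions[co]
  }
  if (config$sort_scope == "global") blocks <- list(seq_len(nrow(m)))
  ord <- unlist(lapply(blocks, function(ix) {
    ix[row_order(m[ix, , drop = FALSE], config$sort_method)]
  }), use.names = FALSE)
  m <- m[ord, , drop = FALSE]
  out <- matrix(0, config$rows_fixed, config$cols_fixed)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  if (config$position_channel) {
    pos <- matrix(0, config$rows_fixed, config$cols_fixed)
    pos[, seq_len(ncol(m))] <- matrix(positions, config$rows_fixed, ncol(m),
                                      byrow = TRUE)
    out <- array(c(out, pos), dim = c(dim(pos), 2L))
  }
  structure(out, class = "snp_image",
            deme_sizes = lengths(blocks),
            n_rows_data = nrow(m), n_cols_data = ncol(m),
            label = label, positions = positions)
}

# Average haplotype pairs into pseudo-diploid rows (consecutive haplotypes
# within each deme form an individual).
collapse_diploids <- function(m, groups) {
  out <- NULL
  gout <- integer(0)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) %% 2L != 0L) {
      stop("odd haploid count in a deme cannot be paired into diploids",
           call. = FALSE)
    }
    a <- m[rows[c(TRUE, FALSE)], , drop = FALSE]
    b <- m[rows[c(FALSE, TRUE)], , drop = FALSE]
    out <- rbind(out, (a + b) / 2)
    gout <- c(gout, rep(g, length(rows) / 2L))
  }
  list(m = out, groups = gout)
}

#' Recover the data region of an encoded image
#'
#' Inverse of [matrix_to_image()] up to row sorting: returns the sorted data
#' block without padding.
#'
#' @param img An `snp_image`.
#' @return A numeric matrix of the encoded (sorted) data values.
#' @export
decode_image <- function(img) {
  stopifnot(inherits(img, "snp_image"))
  v <- if (length(dim(img)) == 3L) img[, , 1L] else unclass(img)
  v[seq_len(attr(img, "n_rows_data")), seq_len(attr(img, "n_cols_data")),
    drop = FALSE]
}

# ---- tensor sets ---------------------------------------------------------
# Images are stored quantized: byte = round(200 * value), value = byte / 200,
# exact for the {0, 0.5, 1} genotype alphabet and 0.005-resolution for the
# optional position channel. One column of `x` per image.

new_tensor_set <- function(x, rows, cols, channels, labels, params, config) {
  structure(list(x = x, rows = as.integer(rows), cols = as.integer(cols),
                 channels = as.integer(channels), labels = labels,
                 params = params, config = config),
            class = "tensor_set")
}

#' @export
print.tensor_set <- function(x, ...) {
  cat(sprintf("<tensor_set> %d images of %d x %d x %d\n",
              ncol(x$x), x$rows, x$cols, x$channels))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Number of images in a tensor set
#' @param ts A `tensor_set`.
#' @return Integer count.
#' @export
n_images <- function(ts) ncol(ts$x)

quantize_image <- function(img) as.raw(round(as.numeric(img) * 200))

#' Extract one image from a tensor set
#' @param ts A `tensor_set`.
#' @param i Image index.
#' @return A numeric matrix (or array, with a position channel) of the stored
#'   image values.
#' @export
tensor_image <- function(ts, i) {
  v <- as.integer(ts$x[, i]) / 200
  if (ts$channels > 1L) {
    array(v, dim = c(ts$rows, ts$cols, ts$channels))
  } else {
    matrix(v, ts$rows, ts$cols)
  }
}

#' Subset a tensor set
#' @param ts A `tensor_set`.
#' @param idx Image indices to keep.
#' @return A `tensor_set` with the selected images.
#' @export
tensor_subset <- function(ts, idx) {
  new_tensor_set(ts$x[, idx, drop = FALSE], ts$rows, ts$cols, ts$channels,
                 if (!is.null(ts$labels)) ts$labels[idx] else NULL,
                 if (!is.null(ts$params)) ts$params[idx, , drop = FALSE]
                 else NULL,
                 ts$config)
}

#' Encode a simulated batch into a tensor set
#'
#' @param batch A manifest with a `data` list-column from [simulate_batch()].
#' @param config An [encoder_config()].
#' @param rng_seed Seed for any column truncation.
#' @return A `tensor_set` whose labels are the scenario ids and whose `params`
#'   slot keeps the manifest (without the data column).
#' @export
encode_batch <- function(batch, config = encoder_config(), rng_seed = NULL) {
  if (is.null(batch$data)) {
    stop("`batch` must carry a `data` list-column (use simulate_batch)",
         call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  channels <- if (config$position_channel) 2L else 1L
  d <- config$rows_fixed * config$cols_fixed * channels
  x <- matrix(as.raw(0), d, nrow(batch))
  for (i in seq_len(nrow(batch))) {
    x[, i] <- quantize_image(matrix_to_image(batch$data[[i]], config))
  }
  new_tensor_set(x, config$rows_fixed, config$cols_fixed, channels,
                 as.integer(batch$model_id),
                 batch[setdiff(names(batch), "data")], config)
}

#' Simulate and encode a training tensor set in one streaming pass
#'
#' Equivalent to [simulate_batch()] followed by [encode_batch()] but encodes
#' each dataset as soon as it is simulated, so only the packed tensors are ever
#' held in memory. This is the path used for large training runs.
#'
#' @inheritParams simulate_batch
#' @param encoder An [encoder_config()].
#' @return A `tensor_set` (labels = scenario ids, `params` = batch manifest).
#' @export
simulate_tensors <- function(config = prior_config(), shape = dataset_shape(),
                             n_per_model, models = 1:4, rng_seed = NULL,
                             encoder = encoder_config(),
                             mode = c("fixed_s", "fixed_theta"),
                             locus_theta = NULL,
                             linkage = c("auto", "unlinked", "linked")) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  channels <- if (encoder$position_channel) 2L else 1L
  d <- encoder$rows_fixed * encoder$cols_fixed * channels
  n_total <- n_per_model * length(models)
  x <- matrix(as.raw(0), d, n_total)
  sink <- function(ds, i) x[, i] <<- quantize_image(matrix_to_image(ds, encoder))
  manifest <- simulate_batch(config, shape, n_per_model, models,
                             rng_seed = rng_seed, mode = mode,
                             locus_theta = locus_theta, linkage = linkage,
                             sink = sink)
  new_tensor_set(x, encoder$rows_fixed, encoder$cols_fixed, channels,
                 as.integer(manifest$model_id), manifest, encoder)
}

#' Stratified train/test split of a tensor set
#'
#' Splits a labeled tensor set into disjoint, shuffled, class-balanced train
#' and test partitions. `train_n` and `test_n` are total counts and must be
#' divisible by the number of classes; unlabeled sets are split by simple
#' random sampling.
#'
#' @param ts A `tensor_set`.
#' @param train_n,test_n Total images in each partition.
#' @param rng_seed Integer seed; the same seed reproduces the same split.
#' @return A list with elements `train` and `test`.
#' @export
split_tensors <- function(ts, train_n, test_n, rng_seed = NULL) {
  stopifnot(inherits(ts, "tensor_set"))
  n <- n_images(ts)
  if (train_n + test_n > n) {
    stop(sprintf("requested %d train + %d test but only %d images available",
                 train_n, test_n, n), call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(ts$labels)) {
    sh <- sample.int(n)
    return(list(train = tensor_subset(ts, sh[seq_len(train_n)]),
                test = tensor_subset(ts, sh[train_n + seq_len(test_n)])))
  }
  classes <- sort(unique(ts$labels))
  k <- length(classes)
  if (train_n %% k != 0L || test_n %% k != 0L) {
    stop(sprintf("`train_n` and `test_n` must be divisible by %d classes", k),
         call. = FALSE)
  }
  per_tr <- train_n %/% k
  per_te <- test_n %/% k
  tr_idx <- te_idx <- integer(0)
  for (cl in classes) {
    ix <- which(ts$labels == cl)
    if (length(ix) < per_tr + per_te) {
      stop(sprintf("class %s has %d images; %d needed", cl, length(ix),
                   per_tr + per_te), call. = FALSE)
    }
    ix <- sample(ix)
    tr_idx <- c(tr_idx, ix[seq_len(per_tr)])
    te_idx <- c(te_idx, ix[per_tr + seq_len(per_te)])
  }
  list(train = tensor_subset(ts, sample(tr_idx)),
       test = tensor_subset(ts, sample(te_idx)))
}

#' Encode a batch and split it into training and test tensors
#'
#' Convenience wrapper: [encode_batch()] then [split_tensors()].
#'
#' @inheritParams encode_batch
#' @inheritParams split_tensors
#' @param batch A manifest with `data` list-column.
#' @return A list with `train` and `test` tensor sets.
#' @export
make_training_tensors <- function(batch, config = encoder_config(),
                                  train_n, test_n, rng_seed = NULL) {
  ts <- encode_batch(batch, config, rng_seed = rng_seed)
  split_tensors(ts, train_n, test_n, rng_seed = rng_seed)
}

#' Serialize and restore tensor sets
#'
#' Writes the packed image bytes to `<path>` and a JSON sidecar
#' (`<path>.json`) holding the shape, labels, encoder configuration and any
#' parameter table, so a training set can be regenerated once and reused
#' across sessions. `read_tensors()` restores the `tensor_set`.
#'
#' @param ts A `tensor_set`.
#' @param path Output file for the raw image bytes.
#' @return `path` (`write_tensors`) or a `tensor_set` (`read_tensors`),
#'   invisibly for the writer.
#' @export
write_tensors <- function(ts, path) {
  stopifnot(inherits(ts, "tensor_set"))
  writeBin(as.vector(ts$x), path)
  meta <- list(rows = ts$rows, cols = ts$cols, channels = ts$channels,
               n = n_images(ts), labels = ts$labels,
               config = ts$config[!vapply(ts$config, is.function,
                                          logical(1))],
               params = ts$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tensors
#' @export
read_tensors <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- meta$rows * meta$cols * meta$channels
  x <- matrix(readBin(path, "raw", n = d * meta$n), d, meta$n)
  config <- if (!is.null(meta$config)) {
    structure(as.list(meta$config), class = "encoder_config")
  }
  params <- if (!is.null(meta$params)) tibble::as_tibble(meta$params)
  new_tensor_set(x, meta$rows, meta$cols, meta$channels,
                 if (!is.null(meta$labels)) as.integer(meta$labels),
                 params, config)
}
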