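#' Construct a genotype matrix
#'
#' The empirical-data container: a per-individual, per-locus matrix of diploid
#' genotype codes (0, 1, 2 copies of the alternate allele, `NA` missing) plus a
#' population map. All loci are biallelic.
#'
#' @param genotypes Integer matrix, individuals in rows, loci in columns.
#' @param pops Population label per individual (character), or a data frame
#'   with columns `id` and `pop`.
#' @param ids Individual ids; defaults to the matrix rownames or `ind1..n`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, pops, ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(ids)) {
    ids <- rownames(genotypes)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(genotypes)))
  }
  if (is.data.frame(pops)) {
    m <- match(ids, pops$id)
    if (anyNA(m)) {
      stop(sprintf("individuals absent from popmap: %s",
                   paste(ids[is.na(m)], collapse = ", ")), call. = FALSE)
    }
    pops <- pops$pop[m]
  }
  if (length(pops) != nrow(genotypes)) {
    stop("`pops` must provide one label per individual", call. = FALSE)
  }
  if (any(table(pops) < 1)) stop("empty population", call. = FALSE)
  rownames(genotypes) <- ids
  structure(list(genotypes = genotypes,
                 popmap = tibble::tibble(id = ids, pop = as.character(pops))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci, %d populations\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$popmap$pop))))
  invisible(x)
}

#' Read genotype data from standard formats
#'
#' Readers for three SNP formats: VCF (biallelic SNP records, genotypes taken
#' from the GT field), DArT two-row CSV (two rows per locus -- reference-allele
#' presence then alternate-allele presence, one column per individual; (1,0) is
#' homozygous reference, (0,1) homozygous alternate, (1,1) heterozygous, (0,0)
#' missing) and a plain matrix CSV of 0/1/2 codes (individuals in rows).
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"`, `"dart2row"` or `"matrix"`.
#' @param popmap A data frame with columns `id` and `pop`, or the path of a
#'   tab-separated file with those two columns (no header).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "dart2row", "matrix"),
                           popmap) {
  format <- match.arg(format)
  if (is.character(popmap)) {
    popmap <- utils::read.table(popmap, header = FALSE,
                                col.names = c("id", "pop"),
                                colClasses = "character")
  }
  g <- switch(format,
    vcf = read_vcf_genotypes(path),
    dart2row = read_dart2row(path),
    matrix = {
      d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
      as.matrix(d)
    })
  genotype_matrix(g, popmap)
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    stop("multi-allelic VCF records are not supported; split or filter them",
         call. = FALSE)
  }
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  m <- apply(gt, 2, code)
  rn <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  t(matrix(m, nrow = nrow(gt), dimnames = list(rn, colnames(gt))))
}

read_dart2row <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("locus", "allele") %in% names(d))) {
    stop("DArT two-row CSV needs `locus` and `allele` columns", call. = FALSE)
  }
  ind <- setdiff(names(d), c("locus", "allele"))
  loci <- unique(d$locus)
  g <- matrix(NA_integer_, length(ind), length(loci),
              dimnames = list(ind, loci))
  for (j in seq_along(loci)) {
    rows <- which(d$locus == loci[j])
    if (length(rows) != 2L) {
      stop(sprintf("locus %s: expected 2 rows, found %d (row %s)",
                   loci[j], length(rows), paste(rows, collapse = ",")),
           call. = FALSE)
    }
    ref <- as.integer(d[rows[1], ind])
    alt <- as.integer(d[rows[2], ind])
    gj <- rep(NA_integer_, length(ind))
    gj[ref == 1 & alt == 0] <- 0L
    gj[ref == 1 & alt == 1] <- 1L
    gj[ref == 0 & alt == 1] <- 2L
    g[, j] <- gj
  }
  g
}

#' Write a genotype matrix
#'
#' Writers mirroring [read_genotypes()]: plain matrix CSV, DArT two-row CSV or
#' a minimal VCF (v4.2, unphased diploid GT), plus [write_popmap()] for the
#' population map.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @param format `"matrix"`, `"dart2row"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path,
                            format = c("matrix", "dart2row", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  if (format == "matrix") {
    utils::write.csv(as.data.frame(g), path, row.names = TRUE)
  } else if (format == "dart2row") {
    loci <- colnames(g)
    if (is.null(loci)) loci <- paste0("L", seq_len(ncol(g)))
    ref <- ifelse(is.na(g), 0L, ifelse(g <= 1L, 1L, 0L))
    alt <- ifelse(is.na(g), 0L, ifelse(g >= 1L, 1L, 0L))
    rows <- vector("list", 2L * ncol(g))
    for (j in seq_len(ncol(g))) {
      rows[[2 * j - 1]] <- data.frame(locus = loci[j], allele = "ref",
                                      t(ref[, j]), check.names = FALSE)
      rows[[2 * j]] <- data.frame(locus = loci[j], allele = "alt",
                                  t(alt[, j]), check.names = FALSE)
    }
    d <- do.call(rbind, rows)
    names(d) <- c("locus", "allele", rownames(g))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    gt <- t(g)
    gtxt <- matrix("./.", nrow(gt), ncol(gt))
    gtxt[gt == 0L] <- "0/0"
    gtxt[gt == 1L] <- "0/1"
    gtxt[gt == 2L] <- "1/1"
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t"),
               vapply(seq_len(nrow(gt)), function(j) {
                 paste(c("1", j, paste0("snp", j), "A", "T", ".", "PASS",
                         ".", "GT", gtxt[j, ]), collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_popmap <- function(gm, path) {
  utils::write.table(gm$popmap, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-population diversity statistics
#'
#' For each population: mean number of alleles per locus (A), observed
#' heterozygosity \eqn{H_O} (fraction of heterozygotes among non-missing
#' genotypes), unbiased expected heterozygosity
#' \eqn{H_E = \frac{2n}{2n-1}(1 - \sum p^2)} with `n` the genotyped diploids at
#' the locus, and the inbreeding coefficient
#' \eqn{G_{IS} = 1 - \bar{H_O}/\bar{H_E}} computed from across-locus means
#' (ratio of averages, over loci with \eqn{H_E > 0} in that population).
#' Across-locus means run over loci polymorphic in the dataset.
#'
#' @param gm A `genotype_matrix`.
#' @return A tibble with one row per population: `pop`, `n`, `a`, `ho`, `he`,
#'   `gis`.
#' @export
diversity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  pops <- unique(gm$popmap$pop)
  # loci polymorphic in the whole dataset
  p_all <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p_all) & p_all > 0 & p_all < 1
  out <- lapply(pops, function(pp) {
    rows <- which(gm$popmap$pop == pp)
    if (length(rows) < 2L) {
      stop(sprintf("population %s has fewer than 2 individuals", pp),
           call. = FALSE)
    }
    sub <- g[rows, poly, drop = FALSE]
    n <- colSums(!is.na(sub))
    ok <- n >= 2L
    sub <- sub[, ok, drop = FALSE]
    n <- n[ok]
    if (ncol(sub) == 0L) {
      stop(sprintf("population %s has no loci with 2+ genotyped individuals",
                   pp), call. = FALSE)
    }
    p <- colMeans(sub, na.rm = TRUE) / 2
    ho <- colMeans(sub == 1L, na.rm = TRUE)
    he <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
    a <- ifelse(p > 0 & p < 1, 2, 1)
    seg <- he > 0
    gis <- 1 - mean(ho[seg]) / mean(he[seg])
    tibble::tibble(pop = pp, n = length(rows), a = mean(a), ho = mean(ho),
                   he = mean(he), gis = gis)
  })
  dplyr::bind_rows(out)
}

# Weir & Cockerham (1984) variance components for one biallelic locus across
# r = 2 populations; ni = genotyped diploids, pi = alt allele frequency,
# hi = observed heterozygote fraction.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir--Cockerham FST
#'
#' Multi-locus Weir & Cockerham (1984) \eqn{\theta} between every pair of
#' populations, using the ratio-of-sums estimator over loci
#' (\eqn{\hat\theta = \sum_l a_l / \sum_l (a_l+b_l+c_l)}). Loci are used
#' pairwise-complete: a locus enters a pair's estimate when both populations
#' have at least two genotyped individuals at it. A pair with no usable locus
#' is reported as `NA`.
#'
#' @param gm A `genotype_matrix` with at least two populations.
#' @return A symmetric matrix of class `fst_matrix` with zero diagonal.
#' @export
pairwise_fst <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  pops <- unique(gm$popmap$pop)
  if (length(pops) < 2L) stop("need at least 2 populations", call. = FALSE)
  fst <- matrix(0, length(pops), length(pops),
                dimnames = list(pops, pops))
  stats_of <- function(rows) {
    sub <- g[rows, , drop = FALSE]
    list(n = colSums(!is.na(sub)),
         p = colMeans(sub, na.rm = TRUE) / 2,
         h = colMeans(sub == 1L, na.rm = TRUE))
  }
  st <- lapply(pops, function(pp) stats_of(which(gm$popmap$pop == pp)))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (j <= i) next
      s1 <- st[[i]]; s2 <- st[[j]]
      ok <- s1$n >= 2L & s2$n >= 2L
      ok[ok] <- {
        pb <- (s1$n[ok] * s1$p[ok] + s2$n[ok] * s2$p[ok]) /
          (s1$n[ok] + s2$n[ok])
        pb > 0 & pb < 1   # monomorphic-in-pair loci carry no information
      }
      if (!any(ok)) {
        fst[i, j] <- fst[j, i] <- NA_real_
        next
      }
      comp <- mapply(wc_components, s1$n[ok], s2$n[ok], s1$p[ok], s2$p[ok],
                     s1$h[ok], s2$h[ok])
      fst[i, j] <- fst[j, i] <- sum(comp["a", ]) / sum(colSums(comp))
    }
  }
  structure(fst, class = c("fst_matrix", "matrix"))
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> pairwise Weir-Cockerham theta\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Principal coordinates analysis of genetic distances
#'
#' Classical metric scaling ([stats::cmdscale()]) of the allele-sharing
#' distance `1 - IBS`, where IBS between two individuals is the mean over
#' co-genotyped loci of \eqn{1 - |g_i - g_j|/2}.
#'
#' @param gm A `genotype_matrix` with at least 3 individuals.
#' @param n_axes Number of axes to return (truncated to the available rank,
#'   with a warning).
#' @return An object of class `pcoa_result`: a list with `coordinates` (a
#'   tibble with `id`, `pop` and `axis1..k`), `eigenvalues` and the proportion
#'   of (positive) eigenvalue sum per axis.
#' @export
pcoa <- function(gm, n_axes = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  n <- nrow(g)
  if (n < 3L) stop("need at least 3 individuals", call. = FALSE)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- !is.na(g[i, ]) & !is.na(g[j, ])
      d[i, j] <- d[j, i] <- if (any(co)) {
        mean(abs(g[i, co] - g[j, co]) / 2)
      } else NA_real_
    }
  }
  if (anyNA(d)) stop("some individual pairs share no genotyped locus",
                     call. = FALSE)
  # rank < n-1 is normal (duplicated individuals, double-centering); the
  # positive-eigenvalue axes are extracted below, so cmdscale's warning about
  # non-positive eigenvalues carries no information here
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  pos <- which(mds$eig > 1e-12)
  avail <- max(1L, length(pos))
  if (n_axes > avail) {
    warning(sprintf("only %d positive axes available; truncating", avail))
    n_axes <- avail
  }
  pts <- mds$points[, seq_len(n_axes), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(n_axes))
  coords <- dplyr::bind_cols(gm$popmap, tibble::as_tibble(pts))
  structure(list(coordinates = coords,
                 eigenvalues = mds$eig,
                 explained = pmax(mds$eig, 0) / sum(pmax(mds$eig, 0))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d individuals, axis 1 explains %.1f%%\n",
              nrow(x$coordinates), 100 * x$explained[1]))
  invisible(x)
}

#' Dataset dimensions and missingness
#'
#' @param gm A `genotype_matrix`.
#' @return A one-row tibble: `n_individuals`, `n_loci`, `n_populations`,
#'   `missing_fraction`.
#' @export
summarize_dataset <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  tibble::tibble(n_individuals = nrow(g), n_loci = ncol(g),
                 n_populations = length(unique(gm$popmap$pop)),
                 missing_fraction = mean(is.na(g)))
}
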