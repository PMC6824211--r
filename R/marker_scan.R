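# Simplified single-marker trait association with permutation thresholds,
# plus the +1/0/-1 coded correlation test.
#
# This is deliberately NOT a reimplementation of multiparent mixed-model or
# hidden-Markov interval mapping: each marker is tested by a single-marker
# regression of the trait on genotype dosage, which is sufficient to
# validate synthetic data with known causal loci.

# dosage coding: AA = 0, AB = 1, BB = 2
.dosage <- function(calls) {
  d <- match(.normalize_call(calls), .call_alphabet) - 1
  as.numeric(d)
}

# per-marker two-sided p-values for trait ~ dosage via the Pearson-r t-test
# (equivalent to the simple-regression slope test); monomorphic -> NA
.scan_p <- function(trait, D) {
  n <- length(trait)
  sy <- sd(trait)
  r <- suppressWarnings(as.numeric(stats::cor(trait, D,
                                              use = "pairwise.complete.obs")))
  r[!is.finite(r)] <- NA_real_
  r2 <- pmin(r^2, 1 - 1e-15)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  list(p = p, r = r, sy = sy)
}

#' Simplified single-marker association scan
#'
#' Regresses a presence/absence trait (from [encode_traits()]; `NA`s are
#' dropped listwise per trait) on genotype dosage `{0, 1, 2}` at every
#' marker, with a genome-wide permutation threshold: trait labels are
#' permuted jointly across all markers (preserving LD), the genome-wide
#' minimum p-value is recorded per permutation, and the threshold is the
#' `alpha`-quantile of those minima. Monomorphic markers are recorded with
#' p = 1 and flagged.
#'
#' @param trait Numeric vector (1/0/`NA`), one value per line, named or in
#'   the order of the marker table's samples.
#' @param genotypes A [marker_table()] whose samples are the lines.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `"scan_result"`: data frame `scan` (marker,
#'   chrom, bp, effect, p, neg_log10_p, monomorphic), `threshold`
#'   (permutation p-value threshold), `alpha`, `n_perm`, `n_lines`, and
#'   `significant` (marker ids with p <= threshold).
#' @export
single_marker_scan <- function(trait, genotypes, n_perm = 1000L,
                               alpha = 0.05, seed = NULL) {
  stopifnot(inherits(genotypes, "marker_table"))
  samples <- mt_samples(genotypes)
  if (!is.null(names(trait))) {
    shared <- intersect(names(trait), samples)
    if (!length(shared))
      stop("no lines shared between trait and genotypes", call. = FALSE)
    trait <- trait[shared]
    samples <- shared
  } else if (length(trait) != length(samples)) {
    stop("unnamed trait vector must have one value per sample",
         call. = FALSE)
  }
  keep <- !is.na(trait)
  trait <- as.numeric(trait[keep])
  samples <- samples[keep]
  n <- length(trait)
  if (n < 3L) stop("need at least 3 scored lines", call. = FALSE)
  if (var(trait) == 0)
    stop("trait has zero variance among scored lines", call. = FALSE)
  D <- vapply(samples, function(s) .dosage(genotypes[[s]]),
              numeric(nrow(genotypes)))
  D <- t(D) # lines x markers
  mono <- apply(D, 2L, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) < 2L
  })
  obs <- .scan_p(trait, D)
  p <- obs$p
  p[mono] <- 1
  sx <- apply(D, 2L, sd, na.rm = TRUE)
  effect <- obs$r * obs$sy / sx
  effect[mono] <- 0
  minp <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pp <- .scan_p(sample(trait), D)$p
    min(pp[!mono], na.rm = TRUE)
  }, 0))
  threshold <- unname(quantile(minp, alpha, names = FALSE))
  scan <- data.frame(marker = genotypes$marker, chrom = genotypes$chrom,
                     bp = genotypes$bp, effect = effect, p = p,
                     neg_log10_p = -log10(p), monomorphic = mono,
                     stringsAsFactors = FALSE)
  structure(list(scan = scan, threshold = threshold, alpha = alpha,
                 n_perm = n_perm, n_lines = n,
                 significant = scan$marker[!mono & p <= threshold]),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>", nrow(x$scan), "markers,", x$n_lines, "lines;",
      "threshold p =", format(x$threshold, digits = 3),
      paste0("(alpha = ", x$alpha, ", ", x$n_perm, " permutations)\n"))
  if (length(x$significant))
    cat("  significant:", paste(x$significant, collapse = ", "), "\n")
  else cat("  no significant markers\n")
  invisible(x)
}

#' Coded genotype/phenotype correlation test
#'
#' Pearson correlation between a phenotype coded +1/-1 (trait present or
#' absent) and a genotype coded +1/0/-1 (reference homozygote /
#' heterozygote / alternate homozygote), with the two-sided t-distribution
#' p-value on n - 2 degrees of freedom. Pairs with a missing value are
#' dropped listwise.
#'
#' @param phenotype Numeric vector of +1/-1 codes.
#' @param genotype Numeric vector of +1/0/-1 codes, same length.
#' @return List with `estimate` (r), `p_value`, `n`.
#' @export
coded_correlation <- function(phenotype, genotype) {
  if (length(phenotype) != length(genotype))
    stop("phenotype and genotype vectors must have equal length",
         call. = FALSE)
  keep <- !is.na(phenotype) & !is.na(genotype)
  x <- as.numeric(phenotype[keep])
  y <- as.numeric(genotype[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (!all(x %in% c(-1, 1)))
    stop("phenotype codes must be +1/-1", call. = FALSE)
  if (!all(y %in% c(-1, 0, 1)))
    stop("genotype codes must be +1/0/-1", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in coded vector", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(estimate = r, p_value = p, n = n)
}
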