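# Forward simulation of F2, RIL (single-seed descent) and 8-founder MAGIC
# populations over a genetic map, under the Haldane map function (no
# interference); chromosomes assort independently. Haplotypes are stored as
# founder-origin labels, so allele content at any marker (including the
# multi-allelic pattern loci) is a lookup into the founder allele matrix.

#' Construct a genetic map
#'
#' @param markers Data frame with columns `marker`, `chrom`, `cM`, `bp`.
#'   Within each chromosome both cM and bp must be nondecreasing; marker
#'   ids must be unique.
#' @return The validated data frame with class `"genetic_map"`, sorted by
#'   chromosome then position.
#' @export
genetic_map <- function(markers) {
  req <- c("marker", "chrom", "cM", "bp")
  if (!all(req %in% names(markers)))
    stop("map needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(markers) == 0L) stop("map has no markers", call. = FALSE)
  if (anyDuplicated(markers$marker))
    stop("marker ids must be unique", call. = FALSE)
  markers$chrom <- as.character(markers$chrom)
  markers <- markers[order(markers$chrom, markers$cM, markers$bp), ,
                     drop = FALSE]
  for (ch in unique(markers$chrom)) {
    sub <- markers[markers$chrom == ch, ]
    if (is.unsorted(sub$cM) || is.unsorted(sub$bp))
      stop("cM and bp must be nondecreasing within chromosome ", ch,
           call. = FALSE)
  }
  rownames(markers) <- NULL
  class(markers) <- c("genetic_map", "data.frame")
  markers
}

#' Haldane map function
#'
#' Converts a genetic distance d (cM) to a recombination fraction,
#' \eqn{r = (1 - e^{-2d/100}) / 2}, assuming no crossover interference.
#'
#' @param d_cM Genetic distance(s) in centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# recombination fraction between consecutive map rows; 0.5 across
# chromosome boundaries (independent assortment)
.map_recomb <- function(map) {
  m <- nrow(map)
  if (m == 1L) return(numeric(0L))
  r <- haldane(diff(map$cM))
  r[map$chrom[-1L] != map$chrom[-m]] <- 0.5
  r
}

# one gamete per row of the parent haplotype matrices (n x m), vectorized
# across individuals; r = recombination fractions between adjacent markers
.meiose <- function(H1, H2, r) {
  n <- nrow(H1)
  m <- ncol(H1)
  G <- H1
  s <- runif(n) < 0.5 # which haplotype the gamete starts on
  if (any(s)) G[s, 1L] <- H2[s, 1L]
  for (j in seq_len(m - 1L)) {
    s <- xor(s, runif(n) < r[j])
    G[s, j + 1L] <- H2[s, j + 1L]
  }
  G
}

#' Simulate one meiosis
#'
#' Draws a single recombinant gamete from a diploid parent under the
#' Haldane map function.
#'
#' @param parent List with haplotype vectors `h1`, `h2` (one entry per map
#'   marker).
#' @param map A [genetic_map()].
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return A gamete: vector of length `nrow(map)`.
#' @export
meiosis <- function(parent, map, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  h1 <- parent$h1
  h2 <- parent$h2
  if (length(h1) != nrow(map) || length(h2) != nrow(map))
    stop("haplotype length must equal map length", call. = FALSE)
  with_seed(seed,
            drop(.meiose(matrix(h1, 1L), matrix(h2, 1L), .map_recomb(map))))
}

.new_population <- function(founders, h1, h2) {
  structure(list(founders = founders, h1 = h1, h2 = h2),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population>", nrow(x$h1), "lines x", ncol(x$h1), "markers,",
      length(x$founders$names), "founders\n")
  invisible(x)
}

#' Number of lines in a simulated population
#' @param pop A `"sim_population"`.
#' @return Integer.
#' @export
n_lines <- function(pop) nrow(pop$h1)

#' Per-line heterozygosity of a simulated population
#'
#' Fraction of markers at which the two haplotypes carry different alleles
#' (by allele content, not founder origin).
#'
#' @param pop A `"sim_population"`.
#' @return Numeric vector, one value per line.
#' @export
heterozygosity <- function(pop) {
  a <- .allele_content(pop)
  rowMeans(a$a1 != a$a2)
}

# allele content of both haplotypes as n x m character matrices
.allele_content <- function(pop) {
  A <- pop$founders$alleles
  n <- nrow(pop$h1)
  m <- ncol(pop$h1)
  mk <- rep(seq_len(m), each = n)
  list(a1 = matrix(A[cbind(mk, as.vector(pop$h1))], n, m),
       a2 = matrix(A[cbind(mk, as.vector(pop$h2))], n, m))
}

# self a population k generations by single-seed descent (one offspring
# per line per generation)
.self_ssd <- function(h1, h2, r, k) {
  for (i in seq_len(k)) {
    g1 <- .meiose(h1, h2, r)
    g2 <- .meiose(h1, h2, r)
    h1 <- g1
    h2 <- g2
  }
  list(h1 = h1, h2 = h2)
}

.founder_idx <- function(founders, which) {
  if (is.character(which)) {
    i <- match(which, founders$names)
    if (anyNA(i)) stop("unknown founder: ",
                       paste(which[is.na(i)], collapse = ", "), call. = FALSE)
    i
  } else as.integer(which)
}

#' Simulate an F2 population
#'
#' Crosses two homozygous founders, then selfs the F1 once; each F2
#' individual is formed from two independent F1 gametes.
#'
#' @param founders A `"founder_set"` from [make_founders()].
#' @param n Number of individuals.
#' @param parents The two founders (names or indices); default the first
#'   two.
#' @param seed Optional integer seed.
#' @return A `"sim_population"`.
#' @export
make_f2 <- function(founders, n, parents = c(1L, 2L), seed = NULL) {
  stopifnot(inherits(founders, "founder_set"), n >= 1)
  p <- .founder_idx(founders, parents)
  stopifnot(length(p) == 2L)
  m <- nrow(founders$map)
  r <- .map_recomb(founders$map)
  with_seed(seed, {
    F1_h1 <- matrix(p[1L], n, m)
    F1_h2 <- matrix(p[2L], n, m)
    .new_population(founders,
                    .meiose(F1_h1, F1_h2, r),
                    .meiose(F1_h1, F1_h2, r))
  })
}

#' Simulate a RIL population by single-seed descent
#'
#' Crosses two homozygous founders and selfs the F1 for `k_selfing`
#' generations, one offspring per line per generation (k = 7 gives F8
#' lines with expected residual heterozygosity 1/128 per marker).
#'
#' @inheritParams make_f2
#' @param k_selfing Selfing generations after the F1 (default 7).
#' @return A `"sim_population"`.
#' @export
make_ril <- function(founders, n, k_selfing = 7, parents = c(1L, 2L),
                     seed = NULL) {
  stopifnot(inherits(founders, "founder_set"), n >= 1, k_selfing >= 1)
  p <- .founder_idx(founders, parents)
  stopifnot(length(p) == 2L)
  m <- nrow(founders$map)
  r <- .map_recomb(founders$map)
  with_seed(seed, {
    h <- .self_ssd(matrix(p[1L], n, m), matrix(p[2L], n, m), r, k_selfing)
    .new_population(founders, h$h1, h$h2)
  })
}

#' Simulate an eight-founder MAGIC population
#'
#' Each line descends from its own funnel: four 2-way crosses, two 4-way
#' crosses, one 8-way cross, then `k_selfing` generations of single-seed
#' descent. Founder order in the funnel is randomized per line unless a
#' fixed `pedigree` is supplied.
#'
#' @param founders A `"founder_set"` with exactly 8 founders.
#' @param n Number of lines.
#' @param k_selfing Selfing generations after the 8-way F1 (default 7).
#' @param pedigree Optional n x 8 integer matrix of founder orderings (one
#'   funnel per row; every founder exactly once per row).
#' @param seed Optional integer seed.
#' @return A `"sim_population"`.
#' @export
make_magic <- function(founders, n, k_selfing = 7, pedigree = NULL,
                       seed = NULL) {
  stopifnot(inherits(founders, "founder_set"), n >= 1)
  if (length(founders$names) != 8L)
    stop("MAGIC requires exactly 8 founders", call. = FALSE)
  m <- nrow(founders$map)
  r <- .map_recomb(founders$map)
  with_seed(seed, {
    if (is.null(pedigree)) {
      pedigree <- t(vapply(seq_len(n), function(i) sample.int(8L),
                           integer(8L)))
    } else {
      pedigree <- as.matrix(pedigree)
      if (!all(dim(pedigree) == c(n, 8L)) ||
          !all(apply(pedigree, 1L, function(x) setequal(x, 1:8))))
        stop("pedigree must be n x 8 with every founder once per funnel",
             call. = FALSE)
    }
    const <- function(k) matrix(pedigree[, k], n, m)
    # founders are homozygous, so a 2-way F1 is (founder_a, founder_b);
    # a gamete of a 4-way cross is a meiosis of that F1 pair, etc.
    g_ab <- .meiose(const(1L), const(2L), r)
    g_cd <- .meiose(const(3L), const(4L), r)
    g_ef <- .meiose(const(5L), const(6L), r)
    g_gh <- .meiose(const(7L), const(8L), r)
    h1 <- .meiose(g_ab, g_cd, r)
    h2 <- .meiose(g_ef, g_gh, r)
    h <- .self_ssd(h1, h2, r, k_selfing)
    .new_population(founders, h$h1, h$h2)
  })
}

#' Genotype of each line at the pattern loci
#'
#' @param pop A `"sim_population"`.
#' @return Data frame, one row per line, two columns per pattern locus
#'   (`<locus>.a1`, `<locus>.a2`).
#' @export
pattern_genotypes <- function(pop) {
  pl <- pop$founders$pattern_loci
  A <- pop$founders$alleles
  out <- data.frame(row.names = seq_len(nrow(pop$h1)))
  for (i in seq_len(nrow(pl))) {
    j <- pl$row[i]
    out[[paste0(pl$locus[i], ".a1")]] <- A[j, pop$h1[, j]]
    out[[paste0(pl$locus[i], ".a2")]] <- A[j, pop$h2[, j]]
  }
  out
}

#' Assign pattern phenotypes to simulated lines
#'
#' Applies [phenotype_of()] to each line's genotype at the pattern loci.
#'
#' @param pop A `"sim_population"` whose founder set carries pattern loci.
#' @param model A [phenotype_model()].
#' @return Character vector of pattern classes, one per line.
#' @export
assign_phenotypes <- function(pop, model) {
  pg <- pattern_genotypes(pop)
  loci <- pop$founders$pattern_loci$locus
  key <- do.call(paste, c(pg, sep = "|"))
  uk <- unique(key)
  map_class <- vapply(uk, function(k) {
    row <- pg[match(k, key), , drop = FALSE]
    pairs <- lapply(loci, function(ln)
      sort(c(row[[paste0(ln, ".a1")]], row[[paste0(ln, ".a2")]])))
    names(pairs) <- loci
    phenotype_of(do.call(multilocus_genotype, pairs), model)
  }, "")
  unname(map_class[match(key, uk)])
}

#' Biallelic marker calls of a simulated population
#'
#' Collapses the two founder-origin haplotypes to calls in `{AA, AB, BB}`
#' by the allele content of the founder matrix. Pattern-locus markers with
#' more than two alleles are reported as `AA`/`BB` by reference allele
#' (first founder's allele = `A`), heterozygote = `AB`.
#'
#' @param pop A `"sim_population"`.
#' @param line_names Optional sample names (default `L001`...).
#' @return A `"marker_table"` (see [marker_table()]).
#' @export
as_marker_table <- function(pop, line_names = NULL) {
  fs <- pop$founders
  n <- nrow(pop$h1)
  m <- nrow(fs$map)
  if (is.null(line_names))
    line_names <- sprintf("L%03d", seq_len(n))
  a <- .allele_content(pop)
  ref <- matrix(fs$alleles[, 1L], n, m, byrow = TRUE)
  calls <- t(ifelse(a$a1 != a$a2, "AB", ifelse(a$a1 == ref, "AA", "BB")))
  colnames(calls) <- line_names
  marker_table(data.frame(marker = fs$map$marker, chrom = fs$map$chrom,
                          bp = fs$map$bp, calls, check.names = FALSE))
}
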