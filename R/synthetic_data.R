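# Generators for every fixture the other modules need: genetic maps,
# homozygous founders (including the eight named MAGIC founders), noisy
# populations and phenotype bulks. Everything is reproducible from
# (spec, seed); nothing is downloaded.

#' Specification for synthetic fixtures
#'
#' Defaults describe a desk-scale stand-in for a cowpea genotyping
#' experiment: 11 chromosomes named Vu01..Vu11, 45 ordinary markers per
#' chromosome (~500 genome-wide, standing in for a ~50k SNP array), 100 cM
#' chromosomes at 400 kb/cM, pattern loci C/W/H placed at 50 cM on
#' Vu07/Vu09/Vu10, a 0.5% genotyping error rate, a 5% Eye1/Watson
#' phenotype-confusion rate (the two patterns are hard to tell apart on
#' pale seeds), and 20-individual bulks.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chrom Ordinary markers per chromosome.
#' @param chrom_length_cM Chromosome length in cM.
#' @param bp_per_cM Physical scale in bp per cM.
#' @param pattern_loci Named character vector locus -> chromosome.
#' @param pattern_pos_cM Position of each pattern locus (cM).
#' @param polymorphic_fraction Fraction of ordinary markers polymorphic
#'   among founders.
#' @param error_rate Per-call genotyping error rate.
#' @param confusion_rate Probability that an Eye1/Watson phenotype is
#'   recorded as the other.
#' @param bulk_size Individuals pooled per phenotype bulk.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_chromosomes = 11L, markers_per_chrom = 45L,
                         chrom_length_cM = 100, bp_per_cM = 4e5,
                         pattern_loci = c(C = "Vu07", W = "Vu09", H = "Vu10"),
                         pattern_pos_cM = 50,
                         polymorphic_fraction = 0.8,
                         error_rate = 0.005, confusion_rate = 0.05,
                         bulk_size = 20L) {
  stopifnot(n_chromosomes >= 1L, markers_per_chrom >= 1L,
            chrom_length_cM > 0, bp_per_cM > 0,
            polymorphic_fraction >= 0, polymorphic_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            confusion_rate >= 0, confusion_rate <= 1, bulk_size >= 1L)
  chroms <- sprintf("Vu%02d", seq_len(n_chromosomes))
  if (!all(pattern_loci %in% chroms))
    stop("pattern loci must be placed on valid chromosomes", call. = FALSE)
  if (anyDuplicated(pattern_loci))
    stop("analytic ratios need pattern loci on distinct chromosomes",
         call. = FALSE)
  pattern_pos_cM <- rep_len(pattern_pos_cM, length(pattern_loci))
  if (any(pattern_pos_cM < 0 | pattern_pos_cM > chrom_length_cM))
    stop("pattern locus position outside chromosome", call. = FALSE)
  structure(list(n_chromosomes = n_chromosomes, chroms = chroms,
                 markers_per_chrom = markers_per_chrom,
                 chrom_length_cM = chrom_length_cM, bp_per_cM = bp_per_cM,
                 pattern_loci = pattern_loci,
                 pattern_pos_cM = pattern_pos_cM,
                 polymorphic_fraction = polymorphic_fraction,
                 error_rate = error_rate, confusion_rate = confusion_rate,
                 bulk_size = bulk_size),
            class = "fixture_spec")
}

.make_map <- function(spec) {
  rows <- list()
  for (ci in seq_along(spec$chroms)) {
    ch <- spec$chroms[ci]
    cm <- seq(0, spec$chrom_length_cM, length.out = spec$markers_per_chrom)
    df <- data.frame(marker = sprintf("%s_%03d", ch,
                                      seq_len(spec$markers_per_chrom)),
                     chrom = ch, cM = cm,
                     bp = round(cm * spec$bp_per_cM) + 1,
                     stringsAsFactors = FALSE)
    li <- which(spec$pattern_loci == ch)
    for (l in li) {
      df <- rbind(df, data.frame(
        marker = paste0(ch, "_", names(spec$pattern_loci)[l], "locus"),
        chrom = ch, cM = spec$pattern_pos_cM[l],
        bp = round(spec$pattern_pos_cM[l] * spec$bp_per_cM) + 1,
        stringsAsFactors = FALSE))
    }
    rows[[ci]] <- df
  }
  map <- do.call(rbind, rows)
  map <- map[order(map$chrom, map$cM, map$bp), , drop = FALSE]
  # guard against float ties between a pattern locus and a grid marker:
  # force strictly increasing bp and monotone cM within each chromosome
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    map$cM[ix] <- cummax(map$cM[ix])
    bp <- map$bp[ix]
    for (i in seq_along(bp)[-1L])
      if (bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1
    map$bp[ix] <- bp
  }
  genetic_map(map)
}

#' Generate homozygous founders and their genetic map
#'
#' Builds a [genetic_map()] from the spec and a founder allele matrix:
#' every founder is fully homozygous; each ordinary marker is polymorphic
#' among the founders with probability `polymorphic_fraction` (for two
#' founders the two carry opposite alleles; for more, each founder draws
#' A or B); pattern-locus markers carry the allele symbols of the supplied
#' C/W/H genotypes.
#'
#' @param spec A [fixture_spec()].
#' @param genotypes Named list of fully homozygous [multilocus_genotype()]
#'   objects, one per founder (e.g. [magic_founders()] or two entries of
#'   [cowpea_parents()]).
#' @param seed Optional integer seed.
#' @return An object of class `"founder_set"`: `map`, `alleles` (marker x
#'   founder character matrix), `names`, `genotypes`, and `pattern_loci`
#'   (data frame locus/marker/row).
#' @examples
#' fs <- make_founders(fixture_spec(), magic_founders(), seed = 1)
#' @export
make_founders <- function(spec, genotypes, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(names(genotypes)))
    names(genotypes) <- paste0("F", seq_along(genotypes))
  genotypes <- lapply(genotypes, function(g)
    if (inherits(g, "multilocus_genotype")) g else multilocus_genotype(g))
  for (g in genotypes)
    if (!is_homozygous(g))
      stop("founders must be fully homozygous", call. = FALSE)
  loci <- names(spec$pattern_loci)
  for (g in genotypes)
    if (!all(loci %in% names(g)))
      stop("founder genotypes must cover loci ",
           paste(loci, collapse = ", "), call. = FALSE)
  map <- .make_map(spec)
  nf <- length(genotypes)
  with_seed(seed, {
    A <- matrix("A", nrow(map), nf,
                dimnames = list(map$marker, names(genotypes)))
    poly <- runif(nrow(map)) < spec$polymorphic_fraction
    if (nf == 2L) {
      A[poly, 2L] <- "B"
    } else {
      for (j in which(poly)) {
        draw <- sample(c("A", "B"), nf, replace = TRUE)
        if (length(unique(draw)) == 1L) # force polymorphism
          draw[sample.int(nf, 1L)] <- setdiff(c("A", "B"), draw[1L])
        A[j, ] <- draw
      }
    }
    pl_marker <- paste0(spec$pattern_loci, "_", loci, "locus")
    pl_row <- match(pl_marker, map$marker)
    for (i in seq_along(loci))
      A[pl_row[i], ] <- vapply(genotypes, function(g)
        g[[loci[i]]][1L], "")
    structure(list(map = map, alleles = A, names = names(genotypes),
                   genotypes = genotypes,
                   pattern_loci = data.frame(locus = loci,
                                             marker = pl_marker,
                                             row = pl_row,
                                             chrom = as.character(spec$pattern_loci),
                                             bp = map$bp[pl_row],
                                             stringsAsFactors = FALSE)),
              class = "founder_set")
  })
}

#' @export
print.founder_set <- function(x, ...) {
  cat("<founder_set>", length(x$names), "founders,", nrow(x$map),
      "markers on", length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

#' Marker calls of the founders themselves
#'
#' Useful as parent columns for [filter_polymorphic()].
#'
#' @param founders A `"founder_set"`.
#' @return A [marker_table()] with one column per founder (`AA`/`BB` by
#'   reference = first founder's allele).
#' @export
founder_calls <- function(founders) {
  A <- founders$alleles
  ref <- A[, 1L]
  df <- data.frame(marker = founders$map$marker, chrom = founders$map$chrom,
                   bp = founders$map$bp, stringsAsFactors = FALSE)
  for (f in seq_along(founders$names))
    df[[founders$names[f]]] <- ifelse(A[, f] == ref, "AA", "BB")
  marker_table(df)
}

#' Score a simulated population (calls + phenotypes)
#'
#' @param pop A `"sim_population"`.
#' @param model A [phenotype_model()].
#' @param line_names Optional line names.
#' @return An object of class `"scored_population"`: `tab` (a
#'   [marker_table()]) and `phenotype` (named character vector).
#' @export
score_population <- function(pop, model, line_names = NULL) {
  tab <- as_marker_table(pop, line_names)
  ph <- setNames(assign_phenotypes(pop, model), mt_samples(tab))
  structure(list(tab = tab, phenotype = ph), class = "scored_population")
}

#' Corrupt a scored population with genotyping error and phenotype confusion
#'
#' Each genotype call is flipped, with probability `error_rate`, to one of
#' the other two calls uniformly; each Eye1 or Watson phenotype is swapped
#' to the other, with probability `confusion_rate` (pale-seed scoring
#' confusion). Other phenotypes are never touched. Rates of zero return
#' the input unchanged.
#'
#' @param scored A `"scored_population"` from [score_population()].
#' @param error_rate Per-call flip probability.
#' @param confusion_rate Eye1/Watson swap probability.
#' @param seed Optional integer seed.
#' @return A `"scored_population"`.
#' @export
corrupt_population <- function(scored, error_rate = 0.005,
                               confusion_rate = 0.05, seed = NULL) {
  stopifnot(inherits(scored, "scored_population"),
            error_rate >= 0, error_rate <= 1,
            confusion_rate >= 0, confusion_rate <= 1)
  with_seed(seed, {
    tab <- corrupt_calls(scored$tab, error_rate)
    ph <- scored$phenotype
    if (confusion_rate > 0) {
      swp <- ph %in% c("Eye1", "Watson") & runif(length(ph)) < confusion_rate
      ph[swp] <- ifelse(ph[swp] == "Eye1", "Watson", "Eye1")
    }
    structure(list(tab = tab, phenotype = ph), class = "scored_population")
  })
}

#' Add genotyping error to a marker table
#'
#' Flips each non-missing call, with probability `error_rate`, to one of
#' the other two calls uniformly. Applies to whatever was genotyped as one
#' DNA sample — an individual line, or a 20-individual bulk (pooled DNA is
#' assayed once, so array error hits the pool call, not each individual).
#'
#' @param tab A [marker_table()].
#' @param error_rate Per-call flip probability.
#' @param seed Optional integer seed.
#' @return The corrupted [marker_table()].
#' @export
corrupt_calls <- function(tab, error_rate, seed = NULL) {
  stopifnot(inherits(tab, "marker_table"), error_rate >= 0, error_rate <= 1)
  if (error_rate == 0) return(tab)
  with_seed(seed, {
    for (s in mt_samples(tab)) {
      calls <- tab[[s]]
      hit <- !is.na(calls) & runif(length(calls)) < error_rate
      if (any(hit)) {
        calls[hit] <- vapply(calls[hit], function(cc)
          sample(setdiff(.call_alphabet, cc), 1L), "")
        tab[[s]] <- calls
      }
    }
    tab
  })
}

#' Build phenotype bulks from a scored F2 population
#'
#' Samples `bulk_size` individuals from each of two phenotype classes and
#' genotypes each pool with [bulk_call()], emulating bulked-DNA genotyping.
#'
#' @param scored A `"scored_population"`.
#' @param classes Length-2 character vector: the recessive-class and the
#'   dominant-class phenotype, in that order.
#' @param bulk_size Individuals per bulk (default 20).
#' @param seed Optional integer seed.
#' @return A [marker_table()] with samples `recessive_bulk` and
#'   `dominant_bulk` (roles attribute set accordingly).
#' @export
make_bulks <- function(scored, classes, bulk_size = 20L, seed = NULL) {
  stopifnot(inherits(scored, "scored_population"), length(classes) == 2L)
  ph <- scored$phenotype
  tab <- scored$tab
  picks <- with_seed(seed, lapply(classes, function(cl) {
    lines <- names(ph)[ph == cl]
    if (length(lines) < bulk_size)
      stop("only ", length(lines), " lines with phenotype '", cl,
           "' (need ", bulk_size, ")", call. = FALSE)
    sample(lines, bulk_size)
  }))
  pool <- function(cols) {
    # vectorized bulk_call over markers: pool is a homozygote only when
    # every non-missing individual is that same homozygote
    M <- as.matrix(as.data.frame(tab)[, cols, drop = FALSE])
    all_aa <- rowSums(M != "AA", na.rm = TRUE) == 0
    all_bb <- rowSums(M != "BB", na.rm = TRUE) == 0
    none <- rowSums(!is.na(M)) == 0
    ifelse(none, NA_character_,
           ifelse(all_aa, "AA", ifelse(all_bb, "BB", "AB")))
  }
  out <- data.frame(marker = tab$marker, chrom = tab$chrom, bp = tab$bp,
                    recessive_bulk = pool(picks[[1L]]),
                    dominant_bulk = pool(picks[[2L]]),
                    stringsAsFactors = FALSE)
  marker_table(out, roles = c(recessive_bulk = "recessive_bulk",
                              dominant_bulk = "dominant_bulk"))
}

#' Simulate a bulked-segregant experiment and scan it
#'
#' End-to-end pipeline: build founders, simulate an F2, score phenotypes
#' (with the spec's Eye1/Watson confusion rate), pool `bulk_size`
#' individuals per phenotype class, apply the spec's genotyping error to
#' the two bulk calls (pooled DNA is assayed as one sample), filter to
#' parent-polymorphic markers and run [bsa_scan()].
#'
#' @param spec A [fixture_spec()].
#' @param genotypes Two named founder genotypes (see [make_founders()]).
#' @param classes Length-2 vector: recessive-class then dominant-class
#'   phenotype.
#' @param n F2 population size.
#' @param min_run,max_gap Passed to [bsa_scan()].
#' @param model A [phenotype_model()].
#' @param seed Optional integer seed for the whole pipeline.
#' @return List: `regions` (scan result), `causal` (pattern-locus
#'   positions), `n_scored` (class counts).
#' @export
simulate_bulk_scan <- function(spec, genotypes, classes, n = 150L,
                               min_run = 5L, max_gap = 1L,
                               model = cwh_model(), seed = NULL) {
  with_seed(seed, {
    fs <- make_founders(spec, genotypes)
    f2 <- make_f2(fs, n)
    sc <- score_population(f2, model)
    sc <- corrupt_population(sc, error_rate = 0,
                             confusion_rate = spec$confusion_rate)
    bt <- make_bulks(sc, classes, spec$bulk_size)
    bt <- corrupt_calls(bt, spec$error_rate)
    fc <- founder_calls(fs)
    parents <- names(fs$genotypes)[1:2]
    merged <- cbind(as.data.frame(bt),
                    as.data.frame(fc)[match(bt$marker, fc$marker), parents,
                                      drop = FALSE])
    pol <- filter_polymorphic(marker_table(merged), parents[1L], parents[2L])
    list(regions = bsa_scan(pol, "recessive_bulk", "dominant_bulk",
                            min_run = min_run, max_gap = max_gap),
         causal = fs$pattern_loci,
         n_scored = table(sc$phenotype))
  })
}

#' Write a complete fixture directory
#'
#' Writes the genetic map, founder calls, population calls + phenotypes,
#' and (for F2 designs with both classes populous enough) the two bulks,
#' all as TSV.
#'
#' @param spec A [fixture_spec()].
#' @param genotypes Founder genotypes (see [make_founders()]).
#' @param design `"F2"`, `"RIL"` or `"MAGIC"`.
#' @param n Number of lines.
#' @param out_dir Output directory (created if needed).
#' @param model A [phenotype_model()] (default [cwh_model()]).
#' @param bulk_classes Optional length-2 classes for bulking.
#' @param seed Integer seed (required: fixtures are reproducible from
#'   spec + seed).
#' @return Invisibly, the list of written file paths.
#' @export
write_fixtures <- function(spec, genotypes, design, n, out_dir,
                           model = cwh_model(), bulk_classes = NULL,
                           seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fs <- make_founders(spec, genotypes, seed = seed)
  pop <- switch(design,
                F2 = make_f2(fs, n, seed = seed + 1L),
                RIL = make_ril(fs, n, seed = seed + 1L),
                MAGIC = make_magic(fs, n, seed = seed + 1L),
                stop("unknown design '", design, "'", call. = FALSE))
  scored <- score_population(pop, model)
  scored <- corrupt_population(scored, spec$error_rate,
                               spec$confusion_rate, seed = seed + 2L)
  paths <- list(map = file.path(out_dir, "map.tsv"),
                founders = file.path(out_dir, "founders.tsv"),
                population = file.path(out_dir, "population.tsv"),
                phenotypes = file.path(out_dir, "phenotypes.tsv"))
  write.table(as.data.frame(fs$map), paths$map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_marker_table(founder_calls(fs), paths$founders)
  write_marker_table(scored$tab, paths$population)
  write.table(data.frame(line = names(scored$phenotype),
                         phenotype = scored$phenotype),
              paths$phenotypes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bulk_classes)) {
    bt <- make_bulks(scored, bulk_classes, spec$bulk_size, seed = seed + 3L)
    paths$bulks <- file.path(out_dir, "bulks.tsv")
    write_marker_table(bt, paths$bulks)
  }
  invisible(paths)
}
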