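# Bulked-segregant region scan and minimal-haplotype-block intersection.
# All genomic coordinates are 1-based inclusive; interval length is
# end - start + 1 bp. BED export converts to 0-based half-open.

.call_alphabet <- c("AA", "AB", "BB")

# normalize call dialects ({hom_ref, het, hom_alt, missing}, VCF-ish
# {0/0, 0/1, 1/1, ./.}, presence/absence {present, absent}) to {AA, AB, BB}
.normalize_call <- function(x) {
  x <- as.character(x)
  dict <- c(AA = "AA", AB = "AB", BA = "AB", BB = "BB",
            hom_ref = "AA", het = "AB", hom_alt = "BB", missing = NA,
            "0/0" = "AA", "0/1" = "AB", "1/0" = "AB", "1/1" = "BB",
            "0|0" = "AA", "0|1" = "AB", "1|0" = "AB", "1|1" = "BB",
            "./." = NA, ".|." = NA, "." = NA,
            present = "AA", absent = "BB")
  out <- unname(dict[x])
  bad <- !is.na(x) & !(x %in% names(dict))
  if (any(bad))
    stop("unrecognized genotype call(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Construct a marker table
#'
#' A marker table holds markers (rows) by samples (columns) with calls in
#' `{AA, AB, BB, NA}`. Several call dialects are accepted and normalized:
#' `hom_ref/het/hom_alt/missing`, VCF-style `0/0, 0/1, 1/1, ./.` and
#' presence/absence `present/absent`. Rows are sorted by chromosome and
#' physical position.
#'
#' @param df Data frame with columns `marker`, `chrom`, `bp` followed by
#'   one column per sample.
#' @param roles Optional named character vector of sample roles (e.g.
#'   `c(P1 = "parent", bulkR = "recessive_bulk")`), kept as an attribute.
#' @return An object of class `"marker_table"` (a data frame).
#' @export
marker_table <- function(df, roles = NULL) {
  req <- c("marker", "chrom", "bp")
  if (!all(req %in% names(df)))
    stop("marker table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  samples <- setdiff(names(df), req)
  if (anyDuplicated(samples))
    stop("sample names must be unique", call. = FALSE)
  if (anyDuplicated(df$marker))
    stop("marker ids must be unique", call. = FALSE)
  df$chrom <- as.character(df$chrom)
  df$bp <- as.numeric(df$bp)
  for (s in samples) df[[s]] <- .normalize_call(df[[s]])
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "roles") <- roles
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Sample names of a marker table
#' @param tab A [marker_table()].
#' @return Character vector.
#' @export
mt_samples <- function(tab) setdiff(names(tab), c("marker", "chrom", "bp"))

#' Pooled-DNA genotype call for a bulk
#'
#' Models genotyping of pooled DNA: if every non-missing individual is the
#' same homozygote the pool reads as that homozygote; any heterozygote, or
#' a mixture of the two homozygotes, contributes both alleles and the pool
#' reads as heterozygous. All-missing input yields `NA`.
#'
#' @param calls Character vector of individual calls (any accepted dialect).
#' @return One call: `"AA"`, `"AB"`, `"BB"` or `NA`.
#' @examples
#' bulk_call(rep("AA", 20))                # "AA"
#' bulk_call(c(rep("AA", 19), "BB"))       # "AB"
#' @export
bulk_call <- function(calls) {
  calls <- .normalize_call(calls)
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA_character_)
  u <- unique(calls)
  if (length(u) == 1L && u != "AB") return(u)
  "AB"
}

#' Keep only markers polymorphic between two parents
#'
#' Retains markers at which the two parent samples have opposite homozygous
#' calls; markers missing in either parent are dropped (no imputation — a
#' missing parent call cannot be phased).
#'
#' @param tab A [marker_table()].
#' @param parent_a,parent_b Parent sample names.
#' @return The filtered marker table.
#' @export
filter_polymorphic <- function(tab, parent_a, parent_b) {
  stopifnot(inherits(tab, "marker_table"))
  for (p in c(parent_a, parent_b))
    if (!p %in% mt_samples(tab))
      stop("parent column '", p, "' not present", call. = FALSE)
  a <- tab[[parent_a]]
  b <- tab[[parent_b]]
  keep <- !is.na(a) & !is.na(b) & a != "AB" & b != "AB" & a != b
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.region_df <- function(chrom = character(), start = numeric(),
                       end = numeric(), flank_left = character(),
                       flank_right = character(), n_markers = integer()) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       flank_left = flank_left, flank_right = flank_right,
                       n_markers = n_markers, stringsAsFactors = FALSE),
            class = c("regions", "data.frame"))
}

#' Bulked-segregant zygosity scan
#'
#' Scans a polymorphic, position-sorted marker table for the causal-region
#' signature of a dominant/recessive contrast between phenotype bulks: runs
#' of consecutive markers at which the recessive bulk is homozygous (for a
#' constant parental allele within the run) while the dominant bulk is
#' heterozygous. Runs of at least `min_run` supporting markers are
#' reported; up to `max_gap` consecutive discordant markers inside a run
#' are tolerated (genotyping-error slack) and do not split it.
#'
#' @param tab A [marker_table()] already filtered with
#'   [filter_polymorphic()].
#' @param recessive_bulk,dominant_bulk Bulk sample names.
#' @param min_run Minimum number of supporting markers per region
#'   (default 5).
#' @param max_gap Maximum run of discordant markers bridged within a region
#'   (default 1).
#' @return A `"regions"` data frame: `chrom`, `start`, `end` (1-based
#'   inclusive bp), flanking supporting marker ids and the count of
#'   supporting markers.
#' @export
bsa_scan <- function(tab, recessive_bulk, dominant_bulk, min_run = 5L,
                     max_gap = 1L) {
  stopifnot(inherits(tab, "marker_table"))
  for (s in c(recessive_bulk, dominant_bulk))
    if (!s %in% mt_samples(tab))
      stop("bulk sample '", s, "' not present in table", call. = FALSE)
  tab <- tab[order(tab$chrom, tab$bp), , drop = FALSE]
  rec <- tab[[recessive_bulk]]
  dom <- tab[[dominant_bulk]]
  out <- .region_df()
  for (ch in unique(tab$chrom)) {
    ix <- which(tab$chrom == ch)
    # scan once per recessive allele: markers discordant for that allele
    # (wrong zygosity, wrong allele, or missing) may be bridged in runs of
    # up to max_gap, so an isolated miscalled marker does not split a block
    for (allele in c("AA", "BB")) {
      sup <- which(!is.na(rec[ix]) & !is.na(dom[ix]) &
                     rec[ix] == allele & dom[ix] == "AB")
      if (!length(sup)) next
      grp <- cumsum(c(TRUE, diff(sup) > max_gap + 1L))
      for (g in unique(grp)) {
        s <- sup[grp == g]
        if (length(s) < min_run) next
        rows <- ix[s]
        out <- rbind(out, .region_df(
          chrom = ch, start = tab$bp[rows[1L]],
          end = tab$bp[rows[length(rows)]],
          flank_left = tab$marker[rows[1L]],
          flank_right = tab$marker[rows[length(rows)]],
          n_markers = length(s)))
      }
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  class(out) <- c("regions", "data.frame")
  rownames(out) <- NULL
  out
}

#' Haplotype blocks cosegregating with a phenotype contrast in lines
#'
#' For inbred-line populations (RILs), a phenotype-associated haplotype
#' block is a run of markers whose calls separate two phenotype groups:
#' one group homozygous for one parent's allele, the other for the other's.
#' A marker is concordant when, under one of the two orientations, at most
#' `max_mismatch` lines (heterozygous, missing, or carrying the wrong
#' allele) disagree — slack for genotyping error. Maximal runs of at least
#' `min_run` concordant markers, bridging up to `max_gap` discordant ones,
#' are reported.
#'
#' @param tab A [marker_table()] of line genotypes.
#' @param group_a,group_b Character vectors of sample names (the two
#'   phenotype groups; e.g. Holstein-patterned vs not, Eye 1 lines
#'   excluded).
#' @param max_mismatch Maximum disagreeing lines per concordant marker
#'   (default 2).
#' @param min_run Minimum concordant markers per block (default 3).
#' @param max_gap Maximum bridged discordant markers (default 1).
#' @return A `"regions"` data frame (see [bsa_scan()]).
#' @export
haplotype_block <- function(tab, group_a, group_b, max_mismatch = 2L,
                            min_run = 3L, max_gap = 1L) {
  stopifnot(inherits(tab, "marker_table"))
  miss <- setdiff(c(group_a, group_b), mt_samples(tab))
  if (length(miss))
    stop("samples not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- tab[order(tab$chrom, tab$bp), , drop = FALSE]
  A <- as.matrix(as.data.frame(tab)[, group_a, drop = FALSE])
  B <- as.matrix(as.data.frame(tab)[, group_b, drop = FALSE])
  mism <- function(M, call) rowSums(M != call | is.na(M))
  m1 <- mism(A, "AA") + mism(B, "BB")
  m2 <- mism(A, "BB") + mism(B, "AA")
  conc <- pmin(m1, m2) <= max_mismatch
  out <- .region_df()
  for (ch in unique(tab$chrom)) {
    ix <- which(tab$chrom == ch)
    sup <- which(conc[ix])
    if (!length(sup)) next
    grp <- cumsum(c(TRUE, diff(sup) > max_gap + 1L))
    for (g in unique(grp)) {
      s <- sup[grp == g]
      if (length(s) < min_run) next
      rows <- ix[s]
      out <- rbind(out, .region_df(
        chrom = ch, start = tab$bp[rows[1L]],
        end = tab$bp[rows[length(rows)]],
        flank_left = tab$marker[rows[1L]],
        flank_right = tab$marker[rows[length(rows)]],
        n_markers = length(s)))
    }
  }
  class(out) <- c("regions", "data.frame")
  rownames(out) <- NULL
  out
}

#' Intersect haplotype blocks across populations
#'
#' The minimal shared haplotype block across populations is the
#' intersection of one region per population: `[max(starts), min(ends)]`.
#' Associative and commutative in population order; errors if any pair of
#' regions is disjoint or the regions span several chromosomes.
#'
#' @param regions List of single-row `"regions"` data frames (or a single
#'   `"regions"` data frame with one row per population).
#' @return A one-row `"regions"` data frame with an extra `length_bp`
#'   column (`end - start + 1`).
#' @examples
#' r <- lapply(list(c(1000, 5000), c(2000, 6000), c(1500, 5500),
#'                  c(2500, 4500)),
#'             function(x) data.frame(chrom = "Vu07", start = x[1],
#'                                    end = x[2]))
#' intersect_blocks(r) # 2500..4500, 2001 bp
#' @export
intersect_blocks <- function(regions) {
  if (is.data.frame(regions)) {
    df <- regions
  } else {
    df <- do.call(rbind, lapply(regions, function(r)
      as.data.frame(r)[, c("chrom", "start", "end")]))
  }
  if (nrow(df) == 0L) stop("no regions supplied", call. = FALSE)
  if (length(unique(df$chrom)) != 1L)
    stop("all regions must be on one chromosome", call. = FALSE)
  start <- max(df$start)
  end <- min(df$end)
  if (start > end)
    stop("no shared block: region intersection is empty", call. = FALSE)
  out <- .region_df(chrom = df$chrom[1L], start = start, end = end,
                    flank_left = NA_character_, flank_right = NA_character_,
                    n_markers = NA_integer_)
  out$length_bp <- end - start + 1
  out
}

# ---- I/O ---------------------------------------------------------------

#' Write regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start` is decremented by one and `end` kept.
#'
#' @param regions A `"regions"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1,
                    end = regions$end,
                    name = ifelse(is.na(regions$flank_left), ".",
                                  paste0(regions$flank_left, "..",
                                         regions$flank_right)))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into 1-based inclusive regions
#'
#' @param path BED file path.
#' @return A `"regions"` data frame.
#' @export
read_regions_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  flanks <- if (ncol(bed) >= 4L) {
    t(vapply(strsplit(as.character(bed[[4L]]), "..", fixed = TRUE),
             function(x) if (length(x) == 2L) x
             else rep(NA_character_, 2L),
             character(2L)))
  } else {
    matrix(NA_character_, nrow(bed), 2L)
  }
  .region_df(chrom = as.character(bed[[1L]]), start = bed[[2L]] + 1,
             end = bed[[3L]], flank_left = flanks[, 1L],
             flank_right = flanks[, 2L],
             n_markers = rep(NA_integer_, nrow(bed)))
}

#' Write regions as TSV (with flanking marker ids)
#' @param regions A `"regions"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a marker table as TSV
#'
#' Wide format with a 2-line header: sample names, then sample roles
#' (`.` for the three coordinate columns and for samples without a role).
#'
#' @param tab A [marker_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(tab, path) {
  stopifnot(inherits(tab, "marker_table"))
  roles <- attr(tab, "roles")
  samples <- mt_samples(tab)
  role_line <- c(".", ".", ".",
                 vapply(samples, function(s)
                   if (!is.null(roles) && s %in% names(roles)) roles[[s]]
                   else ".", ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker", "chrom", "bp", samples), collapse = "\t"), con)
  writeLines(paste(role_line, collapse = "\t"), con)
  body <- as.data.frame(tab)
  body[is.na(body)] <- "missing"
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a marker table from TSV
#'
#' Expects the 2-line header written by [write_marker_table()].
#'
#' @param path TSV path.
#' @return A [marker_table()].
#' @export
read_marker_table <- function(path) {
  header <- readLines(path, n = 2L)
  cols <- strsplit(header[1L], "\t")[[1L]]
  roles_raw <- strsplit(header[2L], "\t")[[1L]]
  df <- read.delim(path, skip = 2L, header = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA"))
  names(df) <- cols
  samples <- setdiff(cols, c("marker", "chrom", "bp"))
  roles <- setNames(roles_raw[match(samples, cols)], samples)
  roles <- roles[roles != "."]
  marker_table(df, roles = if (length(roles)) roles else NULL)
}

#' Import marker calls from a VCF file
#'
#' Maps diploid GT fields to the `{AA, AB, BB, NA}` call alphabet. Requires
#' the VariantAnnotation package (Suggests).
#'
#' @param path Path to a VCF file.
#' @return A [marker_table()] with one column per VCF sample.
#' @export
read_vcf_calls <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_calls() requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  df <- data.frame(
    marker = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    bp = GenomicRanges::start(rr),
    stringsAsFactors = FALSE)
  for (s in colnames(gt)) df[[s]] <- .normalize_call(gt[, s])
  marker_table(df)
}
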