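test_that("bulk_call models pooled-DNA genotyping", {
  expect_identical(bulk_call(rep("AA", 20)), "AA")
  expect_identical(bulk_call(rep("hom_alt", 20)), "BB")
  expect_identical(bulk_call(c(rep("AA", 19), "BB")), "AB")
  expect_identical(bulk_call(c(rep("het", 10), rep("hom_ref", 10))), "AB")
  expect_identical(bulk_call(c("AA", NA, "AA", "missing")), "AA")
  expect_identical(bulk_call(c(NA, "missing")), NA_character_)
  expect_error(bulk_call(c("AA", "XX")), "unrecognized")
})

test_that("marker_table normalizes dialects and sorts by position", {
  df <- data.frame(marker = c("m2", "m1"), chrom = "Vu01", bp = c(200, 100),
                   s1 = c("hom_ref", "0/1"), s2 = c("1|1", "./."),
                   stringsAsFactors = FALSE)
  tab <- marker_table(df)
  expect_identical(tab$marker, c("m1", "m2"))
  expect_identical(tab$s1, c("AB", "AA"))
  expect_identical(tab$s2, c(NA, "BB"))
  expect_identical(mt_samples(tab), c("s1", "s2"))
  expect_error(marker_table(df[, -1]), "needs columns")
})

test_that("filter_polymorphic keeps opposite homozygotes only", {
  df <- data.frame(marker = paste0("m", 1:5), chrom = "Vu01",
                   bp = 1:5 * 100,
                   pa = c("AA", "AA", "AB", NA, "BB"),
                   pb = c("BB", "AA", "BB", "BB", "AA"),
                   stringsAsFactors = FALSE)
  tab <- marker_table(df)
  out <- filter_polymorphic(tab, "pa", "pb")
  expect_identical(out$marker, c("m1", "m5"))
  expect_error(filter_polymorphic(tab, "pa", "nope"), "not present")
})

# deterministic synthetic table: causal run embedded among non-qualifying
# markers
.make_scan_fixture <- function(n = 500, run_at = 201:212, chrom = "Vu03",
                               rec_allele = "BB") {
  set.seed(4242)
  df <- data.frame(marker = sprintf("mk%04d", 1:n), chrom = chrom,
                   bp = (1:n) * 1000,
                   rec = sample(c("AA", "AB", "BB"), n, TRUE,
                                prob = c(0.25, 0.5, 0.25)),
                   dom = sample(c("AA", "AB", "BB"), n, TRUE,
                                prob = c(0.25, 0.5, 0.25)),
                   stringsAsFactors = FALSE)
  # ensure no accidental qualifying run outside the causal one
  spurious <- df$rec != "AB" & df$dom == "AB"
  df$dom[spurious] <- "AA"
  df$rec[run_at] <- rec_allele
  df$dom[run_at] <- "AB"
  df
}

test_that("bsa_scan finds exactly the planted causal run", {
  df <- .make_scan_fixture()
  reg <- bsa_scan(marker_table(df), "rec", "dom", min_run = 5)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 201 * 1000)
  expect_equal(reg$end, 212 * 1000)
  expect_equal(reg$n_markers, 12)
  expect_identical(reg$flank_left, "mk0201")
  expect_identical(reg$flank_right, "mk0212")
  # no qualifying marker at all -> empty result
  df2 <- df
  df2$dom <- "AA"
  expect_equal(nrow(bsa_scan(marker_table(df2), "rec", "dom")), 0)
  expect_error(bsa_scan(marker_table(df), "rec", "nope"), "not present")
})

test_that("bsa_scan bridges up to max_gap discordant markers", {
  df <- .make_scan_fixture()
  df$rec[206] <- "AB" # one discordant marker splits the run in two
  reg1 <- bsa_scan(marker_table(df), "rec", "dom", min_run = 5, max_gap = 1)
  expect_equal(nrow(reg1), 1)
  expect_equal(reg1$n_markers, 11)
  expect_equal(c(reg1$start, reg1$end), c(201000, 212000))
  reg0 <- bsa_scan(marker_table(df), "rec", "dom", min_run = 5, max_gap = 0)
  expect_equal(nrow(reg0), 2) # no bridging: both halves pass min_run
  expect_equal(reg0$start, c(201000, 207000))
  expect_equal(reg0$end, c(205000, 212000))
  # a single opposite-homozygote call (array error) is also bridged
  df2 <- .make_scan_fixture()
  df2$rec[206] <- "AA"
  reg2 <- bsa_scan(marker_table(df2), "rec", "dom", min_run = 5, max_gap = 1)
  expect_equal(nrow(reg2), 1)
  expect_equal(c(reg2$start, reg2$end), c(201000, 212000))
})

test_that("bsa_scan is invariant to marker row order and re-verifies", {
  df <- .make_scan_fixture()
  set.seed(1)
  shuffled <- df[sample(nrow(df)), ]
  expect_equal(as.data.frame(bsa_scan(marker_table(shuffled), "rec", "dom")),
               as.data.frame(bsa_scan(marker_table(df), "rec", "dom")))
  # every supporting marker inside the reported region satisfies the
  # zygosity contrast (with the known bridged exceptions)
  tab <- marker_table(df)
  reg <- bsa_scan(tab, "rec", "dom")
  inside <- tab$bp >= reg$start & tab$bp <= reg$end
  expect_true(all(tab$rec[inside] == "BB" & tab$dom[inside] == "AB"))
})

test_that("intersect_blocks computes the minimal shared block", {
  mk <- function(x) data.frame(chrom = "Vu07", start = x[1], end = x[2])
  r <- lapply(list(c(1000, 5000), c(2000, 6000), c(1500, 5500),
                   c(2500, 4500)), mk)
  out <- intersect_blocks(r)
  expect_equal(c(out$start, out$end, out$length_bp), c(2500, 4500, 2001))
  # identity on a single population
  one <- intersect_blocks(r[4])
  expect_equal(c(one$start, one$end), c(2500, 4500))
  # associative + commutative over population order
  set.seed(2)
  for (i in 1:5) {
    perm <- sample(4)
    expect_equal(intersect_blocks(r[perm])$length_bp, 2001)
  }
  expect_equal(intersect_blocks(list(intersect_blocks(r[1:2]),
                                     intersect_blocks(r[3:4])))$length_bp,
               2001)
  expect_error(intersect_blocks(list(mk(c(1, 10)), mk(c(20, 30)))),
               "no shared block")
  expect_error(intersect_blocks(list(mk(c(1, 10)),
                                     data.frame(chrom = "Vu08", start = 1,
                                                end = 10))),
               "one chromosome")
})

test_that("haplotype_block finds runs of phenotype-concordant markers", {
  n_lines <- 40
  lines <- sprintf("L%02d", 1:n_lines)
  grp_a <- lines[1:20]
  grp_b <- lines[21:40]
  set.seed(31)
  calls <- matrix(sample(c("AA", "BB"), 300 * n_lines, TRUE), 300, n_lines,
                  dimnames = list(NULL, lines))
  block <- 140:151
  calls[block, grp_a] <- "AA"
  calls[block, grp_b] <- "BB"
  calls[145, grp_a[1]] <- "AB" # one mis-genotyped line is tolerated
  df <- data.frame(marker = sprintf("m%03d", 1:300), chrom = "Vu10",
                   bp = (1:300) * 500, calls, stringsAsFactors = FALSE,
                   check.names = FALSE)
  reg <- haplotype_block(marker_table(df), grp_a, grp_b, min_run = 5)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(140 * 500, 151 * 500))
  expect_equal(reg$n_markers, 12)
})

test_that("BED round-trip preserves 1-based inclusive coordinates", {
  df <- .make_scan_fixture()
  reg <- bsa_scan(marker_table(df), "rec", "dom")
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(reg, bed)
  raw <- read.delim(bed, header = FALSE)
  expect_equal(raw$V2, reg$start - 1) # 0-based half-open on disk
  expect_equal(raw$V3, reg$end)
  back <- read_regions_bed(bed)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_identical(back$flank_left, reg$flank_left)
  tsv <- tempfile(fileext = ".tsv")
  write_regions_tsv(reg, tsv)
  expect_equal(read.delim(tsv)$start, reg$start)
})

test_that("marker table TSV round-trips with sample roles", {
  df <- data.frame(marker = c("m1", "m2"), chrom = "Vu01", bp = c(1, 2),
                   bulkR = c("AA", NA), bulkD = c("AB", "BB"),
                   stringsAsFactors = FALSE)
  tab <- marker_table(df, roles = c(bulkR = "recessive_bulk",
                                    bulkD = "dominant_bulk"))
  tmp <- tempfile(fileext = ".tsv")
  write_marker_table(tab, tmp)
  back <- read_marker_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "roles"),
               c(bulkR = "recessive_bulk", bulkD = "dominant_bulk"))
})

test_that("VCF import maps GT fields to the call alphabet", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=Vu07,length=40000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("Vu07", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t"),
    paste("Vu07", "200", "snp2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "./.", sep = "\t")), vcf)
  tab <- read_vcf_calls(vcf)
  expect_identical(tab$s1, c("AA", "BB"))
  expect_identical(tab$s2, c("AB", NA))
  expect_equal(tab$bp, c(100, 200))
})
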