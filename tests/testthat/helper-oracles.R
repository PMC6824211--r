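# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: brute-force enumeration and
# transition-matrix iteration only.

# Selfing Markov chain on genotype states (AA, Aa, aa), starting from the
# F1 heterozygote; k steps of selfing.
oracle_selfing_probs <- function(k) {
  T <- rbind(AA = c(1, 0, 0),
             Aa = c(0.25, 0.5, 0.25),
             aa = c(0, 0, 1))
  v <- c(AA = 0, Aa = 1, aa = 0)
  for (i in seq_len(k)) v <- as.numeric(v %*% T)
  setNames(v, c("AA", "Aa", "aa"))
}

# Brute-force phenotype ratio under the complete-fixation idealization:
# enumerate every equally likely atomic outcome per locus and tabulate
# phenotype classes.
#  F2    : the 4 ordered gamete pairs per locus
#  RIL   : fixation to either parent per locus (2 outcomes)
#  MAGIC : each founder's homozygote per locus (8 outcomes)
oracle_idealized_ratio <- function(design, model) {
  loci <- design$loci
  atoms_per_locus <- lapply(loci, function(ln) {
    al <- vapply(design$parents, function(p) p[[ln]][1L], "")
    switch(design$kind,
           F2 = {
             g <- expand.grid(a = al, b = al, stringsAsFactors = FALSE)
             lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i]))
           },
           RIL = lapply(al, function(a) c(a, a)),
           MAGIC = lapply(al, function(a) c(a, a)))
  })
  names(atoms_per_locus) <- loci
  grid <- expand.grid(lapply(atoms_per_locus, seq_along))
  counts <- setNames(rep(0, length(model$classes)), model$classes)
  for (i in seq_len(nrow(grid))) {
    pairs <- lapply(loci, function(ln)
      atoms_per_locus[[ln]][[grid[i, ln]]])
    names(pairs) <- loci
    cl <- phenotype_of(do.call(multilocus_genotype, pairs), model)
    counts[cl] <- counts[cl] + 1
  }
  counts[counts > 0] / sum(counts)
}

# 3-SE binomial band check for observed class frequencies
expect_within_3se <- function(freq, expected, n) {
  for (cl in names(expected)) {
    se <- sqrt(expected[[cl]] * (1 - expected[[cl]]) / n)
    obs <- if (cl %in% names(freq)) freq[[cl]] else 0
    expect_lt(abs(obs - expected[[cl]]), 3 * se + 1e-12,
              label = paste0("class ", cl, ": |", signif(obs, 4), " - ",
                             signif(expected[[cl]], 4), "|"))
  }
}

# expected proportions (numeric) of a ratio_prediction as a named vector
pred_props <- function(pred) setNames(pred$proportions, pred$classes)
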