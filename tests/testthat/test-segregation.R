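model <- cwh_model()
parents <- cowpea_parents()

test_that("per-locus distributions: F2, RIL (selfing oracle), MAGIC", {
  f2 <- population_design("F2", parents[c("CB27", "B21")])
  d <- per_locus_genotype_probs(f2, "C")
  expect_equal(attr(d, "den"), 4)
  expect_equal(d$num[d$a1 == "C0" & d$a2 == "C0"], 1)
  expect_equal(d$num[d$a1 == "C0" & d$a2 == "C2"], 2)
  expect_equal(d$num[d$a1 == "C2" & d$a2 == "C2"], 1)
  # monomorphic locus collapses to a point mass
  dW <- per_locus_genotype_probs(f2, "W")
  expect_equal(nrow(dW), 1)
  expect_equal(dW$num / attr(dW, "den"), 1)

  # RIL residual heterozygosity vs the independent selfing-chain oracle
  for (k in c(1, 3, 7)) {
    ril <- population_design("RIL", parents[c("CB27", "IT82E-18")],
                             selfing_generations = k)
    d <- per_locus_genotype_probs(ril, "H")
    oracle <- oracle_selfing_probs(k)
    expect_equal(d$num[d$a1 == "H0" & d$a2 == "H1"] / attr(d, "den"),
                 unname(oracle["Aa"]))
    expect_equal(d$num[d$a1 == "H0" & d$a2 == "H0"] / attr(d, "den"),
                 unname(oracle["AA"]))
  }
  d7 <- per_locus_genotype_probs(
    population_design("RIL", parents[c("CB27", "IT82E-18")]), "H")
  expect_equal(attr(d7, "den"), 256)
  expect_equal(d7$num, c(127, 2, 127))

  # MAGIC idealization: 3 of 8 founders carry C1
  dm <- per_locus_genotype_probs(magic_design(), "C")
  expect_equal(attr(dm, "den"), 8)
  expect_equal(dm$num[dm$a1 == "C1"], 3)
  expect_equal(dm$num[dm$a1 == "C2"], 5)

  expect_error(per_locus_genotype_probs(f2, "Z"), "not covered")
  het_parent <- list(multilocus_genotype(C = c("C2", "C0")),
                     multilocus_genotype(C = c("C0", "C0")))
  expect_error(population_design("F2", het_parent), "homozygous")
})

test_that("finite-k MAGIC model: distinct-founder pairs plus selfing residue", {
  dm <- per_locus_genotype_probs(magic_design(), "C", idealized = FALSE)
  den <- attr(dm, "den")
  # haplotypes trace two distinct founders: P(both alleles C1) = 3*2/56
  # = 3/28; het pairs (one C1, one C2) = 30/56 = 15/28, residue (1/2)^7;
  # P(C1C1) = 3/28 + (15/28)(1 - 1/128)/2 = 2673/7168
  expect_equal(dm$num[dm$a1 == "C1" & dm$a2 == "C1"] / den, 2673 / 7168)
  expect_equal(dm$num[dm$a1 == "C1" & dm$a2 == "C2"] / den,
               (15 / 28) / 128)
  expect_equal(sum(dm$num) / den, 1)
  # complete fixation recovers the idealized marginals exactly
  dinf <- per_locus_genotype_probs(magic_design(selfing_generations = Inf),
                                   "C", idealized = FALSE)
  expect_equal(dinf$num / attr(dinf, "den"), c(3, 5) / 8)
})

test_that("joint distribution is the product over unlinked loci", {
  jt <- joint_genotype_probs(magic_design(), model)
  expect_equal(sum(jt$num) / attr(jt, "den"), 1)
  # Holstein genotype C2C2 H1H1 W0W0: (5/8)(7/8)(1/8) = 35/512
  row <- jt$num[jt$C.a1 == "C2" & jt$C.a2 == "C2" &
                jt$W.a1 == "W0" & jt$W.a2 == "W0" &
                jt$H.a1 == "H1" & jt$H.a2 == "H1"]
  expect_equal(row / attr(jt, "den"), 35 / 512)
  # single-locus case matches per_locus_genotype_probs
  f2 <- population_design("F2", parents[c("CB27", "B21")])
  jt1 <- joint_genotype_probs(f2, model)
  d1 <- per_locus_genotype_probs(f2, "C")
  expect_equal(sum(jt1$num) / attr(jt1, "den"), 1)
  agg <- tapply(jt1$num, paste(jt1$C.a1, jt1$C.a2), sum)
  expect_equal(as.numeric(agg[paste(d1$a1, d1$a2)]) / attr(jt1, "den"),
               d1$num / attr(d1, "den"))
  # linked loci are refused with a pointer to the simulator
  linked <- phenotype_model(
    list(C = model$series$C,
         W = allelic_series(locus("W", "Vu07", c("W0", "W1")),
                            list(c("W1", "W0"))),
         H = model$series$H),
    model$rules)
  expect_error(joint_genotype_probs(magic_design(), linked), "simulator")
})

test_that("joint distribution always sums to 1 (property)", {
  alleles <- list(C = c("C0", "C1", "C2"), W = c("W0", "W1"),
                  H = c("H0", "H1"))
  set.seed(99)
  for (rep in 1:20) {
    kind <- sample(c("F2", "RIL", "MAGIC"), 1)
    np <- if (kind == "MAGIC") 8 else 2
    ps <- replicate(np, multilocus_genotype(
      C = rep(sample(alleles$C, 1), 2),
      W = rep(sample(alleles$W, 1), 2),
      H = rep(sample(alleles$H, 1), 2)), simplify = FALSE)
    des <- population_design(kind, ps,
                             selfing_generations = sample(1:9, 1))
    for (ideal in c(TRUE, FALSE)) {
      jt <- joint_genotype_probs(des, model, idealized = ideal)
      expect_equal(sum(jt$num) / attr(jt, "den"), 1)
      expect_true(all(jt$num > 0))
    }
  }
})

test_that("idealized ratio predictions match the printed expectations", {
  pred <- expected_phenotype_ratio(magic_design(), model)
  expect_identical(pred$classes,
                   c("Eye1", "Eye2", "Holstein", "Watson", "FullCoat"))
  expect_equal(unname(pred$integer_ratio), c(192, 5, 35, 35, 245))
  expect_equal(pred$den, 512)
  expect_equal(sum(pred$proportions), 1)

  ril <- population_design("RIL", parents[c("CB46", "IT93K-503-1")])
  expect_equal(unname(expected_phenotype_ratio(ril, model)$integer_ratio),
               c(4, 1, 1, 1, 1))
  ril2 <- population_design("RIL", parents[c("CB27", "IT82E-18")])
  expect_equal(unname(expected_phenotype_ratio(ril2, model)$integer_ratio),
               c(1, 1, 1, 1))
  f2a <- population_design("F2", parents[c("CB27", "B21")])
  pa <- expected_phenotype_ratio(f2a, model)
  expect_equal(setNames(unname(pa$integer_ratio), pa$classes),
               c(NoColor = 1, Eye2 = 3))
  f2b <- population_design("F2", parents[c("Tvu-15426", "MAGIC014")])
  pb <- expected_phenotype_ratio(f2b, model)
  expect_equal(setNames(unname(pb$integer_ratio), pb$classes),
               c(Watson = 1, FullCoat = 3))
})

test_that("finite-k ratios collapse residual heterozygotes by dominance", {
  ril <- population_design("RIL", parents[c("CB46", "IT93K-503-1")])
  pred <- expected_phenotype_ratio(ril, model, idealized = FALSE)
  props <- pred_props(pred)
  # Eye1 requires fixation to C1C1: (2^7 - 1)/2^8 = 127/256
  expect_equal(unname(props["Eye1"]), 127 / 256)
  # FullCoat needs expressed C2, W1 and H1; heterozygotes express the
  # dominant allele, so each factor is (127 + 2)/256
  expect_equal(unname(props["FullCoat"]), (129 / 256)^3)
  expect_equal(sum(pred$proportions), 1)
  # an unresolved heterozygote reachable with nonzero probability errors
  f2bad <- population_design("F2", list(
    multilocus_genotype(C = c("C1", "C1"), W = c("W0", "W0"),
                        H = c("H0", "H0")),
    multilocus_genotype(C = c("C0", "C0"), W = c("W0", "W0"),
                        H = c("H0", "H0"))))
  expect_error(expected_phenotype_ratio(f2bad, model),
               "unresolved dominance")
})

test_that("chi-square reproduces all ten published values", {
  printed_x2 <- c(6.41, 3.53, 7.30, 3.73, 5.82, 0.27, 4.89, 0.84, 0.0019,
                  0.40)
  printed_p <- c(0.17, 0.32, 0.06, 0.44, 0.21, 0.60, 0.027, 0.36, 0.97,
                 0.53)
  dat <- cowpea_segregation_data()
  expect_length(dat, 10)
  for (i in seq_along(dat)) {
    g <- chi_square_gof(dat[[i]]$observed, dat[[i]]$ratio)
    digits <- if (printed_x2[i] < 0.01) 4 else 2
    expect_equal(round(g$statistic, digits), printed_x2[i],
                 label = paste(names(dat)[i], "statistic"))
    p_digits <- if (printed_p[i] == 0.027) 3 else 2
    expect_equal(round(g$p_value, p_digits), printed_p[i],
                 label = paste(names(dat)[i], "p-value"))
    expect_equal(g$df, length(dat[[i]]$observed) - 1)
    expect_equal(sum(g$expected), sum(g$observed))
    # the predicted ratio is also what the genetic model derives
    pred <- expected_phenotype_ratio(dat[[i]]$design, model)
    expect_equal(pred$integer_ratio[names(dat[[i]]$ratio)], dat[[i]]$ratio,
                 label = paste(names(dat)[i], "derived ratio"))
  }
})

test_that("chi-square matches stats::chisq.test and is scale-invariant", {
  obs <- c(Eye2 = 20, Holstein = 28, Watson = 16, FullCoat = 23)
  g1 <- chi_square_gof(obs, c(Eye2 = 1, Holstein = 1, Watson = 1,
                              FullCoat = 1))
  ref <- stats::chisq.test(obs, p = rep(1 / 4, 4))
  expect_equal(g1$statistic, unname(ref$statistic))
  expect_equal(g1$p_value, unname(ref$p.value))
  g2 <- chi_square_gof(obs, c(Eye2 = 17, Holstein = 17, Watson = 17,
                              FullCoat = 17))
  expect_equal(g2$statistic, g1$statistic)
  # exact proportionality gives statistic 0, p 1
  g0 <- chi_square_gof(c(A = 30, B = 10), c(A = 3, B = 1))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)
})

test_that("chi-square input validation", {
  expect_error(chi_square_gof(c(A = 5, B = 1), c(A = 1)), "zero expected")
  expect_error(chi_square_gof(c(A = 5), c(A = 3, B = 1)), "missing")
  expect_error(chi_square_gof(c(A = -1, B = 1), c(A = 1, B = 1)), ">= 0")
  expect_error(chi_square_gof(c(5, 1), c(A = 1, B = 1)), "named")
  # zero-expected class with zero observed count is silently dropped
  g <- chi_square_gof(c(A = 5, B = 7, C = 0), c(A = 1, B = 1))
  expect_equal(g$df, 1)
})
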