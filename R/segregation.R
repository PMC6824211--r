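# Exact segregation-ratio prediction and chi-square goodness of fit.
#
# All analytic class proportions are carried as integer numerators over a
# common integer denominator (exact in doubles up to 2^53), so ratios like
# 192:5:35:35:245 come out exact; floating point enters only inside the
# chi-square.

.gcd2 <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

.gcd <- function(x) Reduce(.gcd2, x[x > 0], accumulate = FALSE)

# ---- population designs ------------------------------------------------

#' Declare a cross design (F2, RIL or MAGIC)
#'
#' @param kind `"F2"`, `"RIL"` or `"MAGIC"`.
#' @param parents Named list of fully homozygous [multilocus_genotype()]
#'   objects: 2 for F2/RIL, 8 for MAGIC.
#' @param selfing_generations Number of selfing generations after the F1
#'   (RIL and MAGIC); the default 7 corresponds to F8 lines. `Inf` means
#'   complete fixation.
#' @param founder_weights Integer founder weights (MAGIC only); the default
#'   `rep(1, 8)` is the canonical "each founder passes its genotype with
#'   probability 1/8" idealization.
#' @return An object of class `"population_design"`.
#' @examples
#' p <- cowpea_parents()
#' population_design("RIL", p[c("CB46", "IT93K-503-1")])
#' @export
population_design <- function(kind = c("F2", "RIL", "MAGIC"), parents,
                              selfing_generations = 7,
                              founder_weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(parents), length(parents) >= 2L)
  parents <- lapply(parents, function(p)
    if (inherits(p, "multilocus_genotype")) p else multilocus_genotype(p))
  n_expect <- if (kind == "MAGIC") 8L else 2L
  if (length(parents) != n_expect)
    stop(kind, " design needs exactly ", n_expect, " parents", call. = FALSE)
  loci <- names(parents[[1L]])
  for (p in parents) {
    if (!identical(sort(names(p)), sort(loci)))
      stop("all parents must cover the same loci", call. = FALSE)
    if (!is_homozygous(p))
      stop("design parents must be fully homozygous at every locus",
           call. = FALSE)
  }
  if (is.null(names(parents)))
    names(parents) <- paste0("P", seq_along(parents))
  if (kind == "MAGIC") {
    if (is.null(founder_weights)) founder_weights <- rep(1L, 8L)
    founder_weights <- as.numeric(founder_weights)
    if (length(founder_weights) != 8L || any(founder_weights < 0) ||
        sum(founder_weights) <= 0 ||
        any(founder_weights != round(founder_weights)))
      stop("founder_weights must be 8 nonnegative integer weights",
           call. = FALSE)
  } else {
    founder_weights <- NULL
  }
  if (!(is.infinite(selfing_generations) ||
        (selfing_generations == round(selfing_generations) &&
         selfing_generations >= 1)))
    stop("selfing_generations must be a positive integer or Inf",
         call. = FALSE)
  structure(list(kind = kind, parents = parents, loci = loci,
                 selfing_generations = selfing_generations,
                 founder_weights = founder_weights),
            class = "population_design")
}

#' @export
print.population_design <- function(x, ...) {
  cat("<population_design>", x$kind, "with", length(x$parents), "parents")
  if (x$kind != "F2") cat(", k =", x$selfing_generations, "selfing generations")
  cat("\n")
  for (nm in names(x$parents))
    cat("  ", nm, ": ", format(x$parents[[nm]]), "\n", sep = "")
  invisible(x)
}

# a genotype distribution: data.frame(a1, a2, num) + common denominator
.gdist <- function(a1, a2, num, den) {
  sw <- a1 > a2
  tmp <- a1[sw]
  a1[sw] <- a2[sw]
  a2[sw] <- tmp
  d <- data.frame(a1 = a1, a2 = a2, num = num, stringsAsFactors = FALSE)
  d <- stats::aggregate(num ~ a1 + a2, data = d, FUN = sum)
  d <- d[d$num > 0, , drop = FALSE]
  g <- .gcd(c(d$num, den))
  d$num <- d$num / g
  attr(d, "den") <- den / g
  rownames(d) <- NULL
  d
}

#' Per-locus genotype distribution under a design
#'
#' Exact genotype-pair probabilities at one locus:
#' \itemize{
#'   \item F2: 1/4, 1/2, 1/4 over (AA, Aa, aa);
#'   \item RIL with k selfing generations: residual heterozygosity
#'     \eqn{h = (1/2)^k} from the F1, homozygotes \eqn{(1-h)/2} each;
#'   \item MAGIC (default, `idealized = TRUE`): each founder's homozygote
#'     with its founder weight, aggregated over founders sharing an allele;
#'   \item MAGIC with `idealized = FALSE`: the finite-k funnel model — the
#'     line's two haplotypes trace two distinct founders (uniform over the
#'     56 ordered pairs under a random funnel), then k selfing generations
#'     leave heterozygote residue \eqn{(1/2)^k}. Equal founder weights only.
#' }
#'
#' @param design A [population_design()].
#' @param locus_name Name of a locus covered by the design's parents.
#' @param idealized MAGIC only: complete-fixation idealization (default)
#'   versus the finite-k funnel model.
#' @return Data frame with columns `a1`, `a2` (unordered pair) and `num`,
#'   plus attribute `"den"`: probabilities are `num / den`, exactly.
#' @examples
#' p <- cowpea_parents()
#' d <- population_design("RIL", p[c("CB27", "IT82E-18")])
#' per_locus_genotype_probs(d, "W") # 127:2:127 over 256
#' @export
per_locus_genotype_probs <- function(design, locus_name, idealized = TRUE) {
  stopifnot(inherits(design, "population_design"))
  if (!locus_name %in% design$loci)
    stop("locus '", locus_name, "' not covered by the design", call. = FALSE)
  al <- vapply(design$parents, function(p) p[[locus_name]][1L], "")
  k <- design$selfing_generations
  if (design$kind == "F2") {
    a <- al[1L]
    b <- al[2L]
    if (a == b) return(.gdist(a, b, 1, 1))
    return(.gdist(c(a, a, b), c(a, b, b), c(1, 2, 1), 4))
  }
  if (design$kind == "RIL") {
    a <- al[1L]
    b <- al[2L]
    if (a == b) return(.gdist(a, b, 1, 1))
    if (is.infinite(k)) return(.gdist(c(a, b), c(a, b), c(1, 1), 2))
    # selfing from the F1: het residue 2 / 2^(k+1), homozygotes (2^k - 1) each
    den <- 2^(k + 1)
    return(.gdist(c(a, a, b), c(a, b, b), c(2^k - 1, 2, 2^k - 1), den))
  }
  # MAGIC
  w <- design$founder_weights
  if (idealized || is.infinite(k)) {
    return(.gdist(al, al, w, sum(w)))
  }
  if (length(unique(w)) != 1L)
    stop("finite-k MAGIC model supports equal founder weights only",
         call. = FALSE)
  # ordered distinct founder pairs, 1/56 each; selfing residue 2^-k
  pairs <- expand.grid(i = 1:8, j = 1:8)
  pairs <- pairs[pairs$i != pairs$j, ]
  a1 <- al[pairs$i]
  a2 <- al[pairs$j]
  den <- 56 * 2^(k + 1)
  hom <- a1 == a2
  out_a1 <- c(a1[hom], a1[!hom], a1[!hom], a2[!hom])
  out_a2 <- c(a2[hom], a2[!hom], a1[!hom], a2[!hom])
  out_num <- c(rep(2^(k + 1), sum(hom)),
               rep(2, sum(!hom)),          # still heterozygous
               rep(2^k - 1, sum(!hom)),    # fixed to first allele
               rep(2^k - 1, sum(!hom)))    # fixed to second allele
  .gdist(out_a1, out_a2, out_num, den)
}

#' Joint multi-locus genotype distribution
#'
#' Product of per-locus distributions, valid only for unlinked loci (the
#' model's loci must sit on distinct chromosomes; linked loci are the
#' simulator's job, see [make_f2()] and friends).
#'
#' @param design A [population_design()].
#' @param model A [phenotype_model()] (supplies locus chromosomes), or a
#'   named list of [locus()] objects.
#' @param idealized Passed to [per_locus_genotype_probs()].
#' @return Data frame with two columns per locus (`<locus>.a1`,
#'   `<locus>.a2`) and `num`, plus attribute `"den"`; probabilities sum to 1.
#' @export
joint_genotype_probs <- function(design, model, idealized = TRUE) {
  stopifnot(inherits(design, "population_design"))
  loci <- if (inherits(model, "phenotype_model")) {
    lapply(model$series, `[[`, "locus")
  } else {
    model
  }
  loci <- loci[design$loci]
  if (any(vapply(loci, is.null, TRUE)))
    stop("model does not cover all design loci", call. = FALSE)
  chroms <- vapply(loci, `[[`, "", "chromosome")
  if (anyDuplicated(chroms))
    stop("loci ", paste(design$loci[duplicated(chroms) |
                                    duplicated(chroms, fromLast = TRUE)],
                        collapse = ", "),
         " share a chromosome; analytic ratios assume unlinked loci - ",
         "use the cross simulator for linked loci", call. = FALSE)
  dists <- lapply(design$loci, per_locus_genotype_probs, design = design,
                  idealized = idealized)
  names(dists) <- design$loci
  out <- NULL
  den <- 1
  for (ln in design$loci) {
    d <- dists[[ln]]
    den <- den * attr(d, "den")
    block <- d
    names(block) <- c(paste0(ln, ".a1"), paste0(ln, ".a2"), ".num")
    if (is.null(out)) {
      out <- block
      names(out)[names(out) == ".num"] <- "num"
    } else {
      idx <- expand.grid(i = seq_len(nrow(out)), j = seq_len(nrow(block)))
      new <- cbind(out[idx$i, setdiff(names(out), "num"), drop = FALSE],
                   block[idx$j, setdiff(names(block), ".num"), drop = FALSE])
      new$num <- out$num[idx$i] * block$.num[idx$j]
      out <- new
    }
  }
  rownames(out) <- NULL
  g <- .gcd(c(out$num, den))
  out$num <- out$num / g
  attr(out, "den") <- den / g
  out
}

# ---- ratio prediction --------------------------------------------------

#' Expected phenotype-class ratio for a design
#'
#' Sums the joint genotype distribution by phenotype class under the model.
#' With `idealized = TRUE` (default) RIL and MAGIC lines are treated as
#' fully inbred, reproducing the canonical printed predictions (e.g.
#' 192:5:35:35:245 for the eight-founder MAGIC, 4:1:1:1:1 and 1:1:1:1 for
#' RILs, 3:1 and 1:3 for F2s). With `idealized = FALSE` the finite-k
#' residual heterozygosity is kept and heterozygotes are collapsed into
#' classes via dominance (errors if an unresolved-dominance heterozygote is
#' reachable with nonzero probability).
#'
#' @param design A [population_design()].
#' @param model A [phenotype_model()].
#' @param idealized Complete-fixation idealization for RIL/MAGIC designs.
#' @return An object of class `"ratio_prediction"`: classes (nonzero ones,
#'   in model order), exact `num`/`den`, `proportions`, and the
#'   smallest-integer `integer_ratio`.
#' @examples
#' expected_phenotype_ratio(magic_design(), cwh_model())
#' @export
expected_phenotype_ratio <- function(design, model, idealized = TRUE) {
  stopifnot(inherits(model, "phenotype_model"))
  d2 <- design
  if (idealized && design$kind %in% c("RIL", "MAGIC"))
    d2$selfing_generations <- Inf
  jt <- joint_genotype_probs(d2, model, idealized = idealized)
  den <- attr(jt, "den")
  cls <- character(nrow(jt))
  for (i in seq_len(nrow(jt))) {
    pairs <- lapply(design$loci, function(ln)
      c(jt[i, paste0(ln, ".a1")], jt[i, paste0(ln, ".a2")]))
    names(pairs) <- design$loci
    cls[i] <- phenotype_of(do.call(multilocus_genotype, pairs), model)
  }
  num <- vapply(model$classes, function(cl) sum(jt$num[cls == cl]), 0)
  keep <- num > 0
  num <- num[keep]
  classes <- model$classes[keep]
  g <- .gcd(c(num, den))
  structure(list(classes = classes, num = num / g, den = den / g,
                 proportions = num / sum(num),
                 integer_ratio = setNames(num / .gcd(num), classes)),
            class = "ratio_prediction")
}

#' Build a ratio prediction directly from an integer ratio
#'
#' Convenience for testing observed counts against a stated ratio such as
#' `c(Eye2 = 3, NoColor = 1)`.
#'
#' @param ratio Named nonnegative numeric vector.
#' @return A `"ratio_prediction"`.
#' @export
ratio_prediction <- function(ratio) {
  stopifnot(!is.null(names(ratio)), all(ratio >= 0), sum(ratio) > 0)
  keep <- ratio > 0
  num <- as.numeric(ratio[keep])
  g <- if (all(num == round(num))) .gcd(num) else 1
  structure(list(classes = names(ratio)[keep], num = num / g,
                 den = sum(num / g), proportions = num / sum(num),
                 integer_ratio = setNames(num / g, names(ratio)[keep])),
            class = "ratio_prediction")
}

#' @export
print.ratio_prediction <- function(x, ...) {
  cat("<ratio_prediction> ",
      paste(x$classes, collapse = ":"), " = ",
      paste(format(x$integer_ratio, trim = TRUE), collapse = ":"),
      "  (den ", format(x$den), ")\n", sep = "")
  invisible(x)
}

# ---- chi-square goodness of fit ----------------------------------------

#' Chi-square goodness of fit of observed class counts
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} with expected counts scaled
#' to the *observed* total (lines expressing classes outside the prediction,
#' e.g. Eye 1 lines masked from a W/H contrast, are simply absent from the
#' observed counts), df = number of classes with nonzero expectation minus
#' one, upper-tail p-value, and no continuity correction.
#'
#' @param observed Named nonnegative counts per class.
#' @param prediction A `"ratio_prediction"` or a named numeric ratio.
#' @return An object of class `"gof_result"` with fields `statistic`, `df`,
#'   `p_value`, `observed`, `expected`.
#' @examples
#' chi_square_gof(c(Eye1 = 121, Eye2 = 0, Holstein = 21, Watson = 13,
#'                  FullCoat = 141),
#'                c(Eye1 = 192, Eye2 = 5, Holstein = 35, Watson = 35,
#'                  FullCoat = 245)) # X2 = 6.41
#' @export
chi_square_gof <- function(observed, prediction) {
  if (!inherits(prediction, "ratio_prediction"))
    prediction <- ratio_prediction(prediction)
  if (is.null(names(observed)))
    stop("observed counts must be named by class", call. = FALSE)
  if (any(observed < 0)) stop("observed counts must be >= 0", call. = FALSE)
  extra <- setdiff(names(observed), prediction$classes)
  if (any(observed[extra] > 0))
    stop("nonzero observed count for class(es) with zero expected ",
         "proportion: ", paste(extra[observed[extra] > 0], collapse = ", "),
         call. = FALSE)
  miss <- setdiff(prediction$classes, names(observed))
  if (length(miss))
    stop("observed counts missing for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs <- as.numeric(observed[prediction$classes])
  names(obs) <- prediction$classes
  expected <- prediction$proportions * sum(obs)
  names(expected) <- prediction$classes
  statistic <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 observed = obs, expected = expected),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, digits = 4, ...) {
  cat("<gof_result> X-squared = ", format(x$statistic, digits = digits),
      ", df = ", x$df, ", p = ", format(x$p_value, digits = digits),
      "\n", sep = "")
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}

# ---- named parental genotypes and published counts ---------------------

#' Proposed C/W/H genotypes of named cowpea accessions
#'
#' The fully homozygous three-locus genotypes proposed for the parents of
#' the ten mapping populations (one 8-founder MAGIC, four biparental RIL,
#' five F2).
#'
#' @return Named list of [multilocus_genotype()] objects.
#' @export
cowpea_parents <- function() {
  g <- function(c, w, h)
    multilocus_genotype(C = rep(c, 2L), W = rep(w, 2L), H = rep(h, 2L))
  list(
    "CB27"        = g("C2", "W0", "H0"),
    "IT00K-1263"  = g("C2", "W1", "H1"),
    "IT82E-18"    = g("C2", "W1", "H1"),
    "IT84S-2049"  = g("C1", "W1", "H1"),
    "IT84S-2246"  = g("C2", "W1", "H1"),
    "IT89KD-288"  = g("C1", "W1", "H1"),
    "IT93K-503-1" = g("C1", "W1", "H1"),
    "SuVita-2"    = g("C2", "W1", "H1"),
    "IT97K-556-6" = g("C2", "W1", "H1"),
    "CB46"        = g("C2", "W0", "H0"),
    "524B"        = g("C2", "W0", "H0"),
    "B21"         = g("C0", "W0", "H0"),
    "CB50"        = g("C2", "W0", "H0"),
    "Tvu-15426"   = g("C2", "W1", "H1"),
    "MAGIC014"    = g("C2", "W1", "H0")
  )
}

#' The eight MAGIC founder genotypes
#'
#' CB27 (Eye 2, C2 W0 H0), three Eye 1 founders (IT84S-2049, IT89KD-288,
#' IT93K-503-1; C1 W1 H1) and four Full Coat founders (IT00K-1263,
#' IT82E-18, IT84S-2246, SuVita-2; C2 W1 H1).
#'
#' @return Named list of 8 [multilocus_genotype()] objects.
#' @export
magic_founders <- function() {
  cowpea_parents()[c("CB27", "IT00K-1263", "IT82E-18", "IT84S-2049",
                     "IT84S-2246", "IT89KD-288", "IT93K-503-1", "SuVita-2")]
}

#' The eight-founder MAGIC design
#'
#' @param selfing_generations Selfing generations after the 8-way F1
#'   (default 7, i.e. F8-equivalent lines).
#' @return A [population_design()].
#' @export
magic_design <- function(selfing_generations = 7) {
  population_design("MAGIC", magic_founders(),
                    selfing_generations = selfing_generations)
}

#' Published class counts and predicted ratios for the ten populations
#'
#' Observed phenotype class counts, the stated predicted segregation ratio
#' and the population design for each of the ten cowpea mapping populations
#' (dashes in the source table are classes that were not scored and are
#' omitted here).
#'
#' @return Named list; each element has `n_lines`, `observed` (named
#'   counts), `ratio` (named integer ratio) and `design` (a
#'   [population_design()]).
#' @export
cowpea_segregation_data <- function() {
  p <- cowpea_parents()
  ril <- function(a, b) population_design("RIL", p[c(a, b)])
  f2 <- function(a, b) population_design("F2", p[c(a, b)])
  list(
    "MAGIC" = list(
      n_lines = 305,
      observed = c(Eye1 = 121, Eye2 = 0, Holstein = 21, Watson = 13,
                   FullCoat = 141),
      ratio = c(Eye1 = 192, Eye2 = 5, Holstein = 35, Watson = 35,
                FullCoat = 245),
      design = magic_design()),
    "CB27 by BB" = list(
      n_lines = 87,
      observed = c(Eye2 = 20, Holstein = 28, Watson = 16, FullCoat = 23),
      ratio = c(Eye2 = 1, Holstein = 1, Watson = 1, FullCoat = 1),
      design = ril("CB27", "IT82E-18")),
    "CB27 by 556" = list(
      n_lines = 80,
      observed = c(Eye2 = 14, Holstein = 30, Watson = 17, FullCoat = 19),
      ratio = c(Eye2 = 1, Holstein = 1, Watson = 1, FullCoat = 1),
      design = ril("CB27", "IT97K-556-6")),
    "CB46 by 503" = list(
      n_lines = 101,
      observed = c(Eye1 = 49, Eye2 = 12, Holstein = 17, Watson = 8,
                   FullCoat = 15),
      ratio = c(Eye1 = 4, Eye2 = 1, Holstein = 1, Watson = 1, FullCoat = 1),
      design = ril("CB46", "IT93K-503-1")),
    "524B by 2049" = list(
      n_lines = 76,
      observed = c(Eye1 = 47, Eye2 = 5, Holstein = 8, Watson = 6,
                   FullCoat = 10),
      ratio = c(Eye1 = 4, Eye2 = 1, Holstein = 1, Watson = 1, FullCoat = 1),
      design = ril("524B", "IT84S-2049")),
    "CB27 by B21 A" = list(
      n_lines = 176,
      observed = c(Eye2 = 129, NoColor = 47),
      ratio = c(Eye2 = 3, NoColor = 1),
      design = f2("CB27", "B21")),
    "CB27 by B21 B" = list(
      n_lines = 132,
      observed = c(Eye2 = 88, NoColor = 44),
      ratio = c(Eye2 = 3, NoColor = 1),
      design = f2("CB27", "B21")),
    "B21 by CB50" = list(
      n_lines = 143,
      observed = c(Eye2 = 112, NoColor = 31),
      ratio = c(Eye2 = 3, NoColor = 1),
      design = f2("B21", "CB50")),
    "Tvu-15426 by MAGIC014 A" = list(
      n_lines = 175,
      observed = c(Watson = 44, FullCoat = 131),
      ratio = c(Watson = 1, FullCoat = 3),
      design = f2("Tvu-15426", "MAGIC014")),
    "Tvu-15426 by MAGIC014 B" = list(
      n_lines = 120,
      observed = c(Watson = 27, FullCoat = 93),
      ratio = c(Watson = 1, FullCoat = 3),
      design = f2("Tvu-15426", "MAGIC014"))
  )
}
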