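#' The six canonical seed-coat pattern classes
#'
#' No Color (no pigment), Eye 1 (loose teardrop eye), Eye 2 (tight winged
#' eye), Holstein (eye plus spots), Watson (indefinite-edge eye) and Full
#' Coat (complete pigmentation). Models may extend this set but always
#' include these six.
#'
#' @export
pattern_classes <- c("NoColor", "Eye1", "Eye2", "Holstein", "Watson", "FullCoat")

#' Define a pattern locus
#'
#' @param name Short locus identifier, e.g. `"C"`.
#' @param chromosome Chromosome label, e.g. `"Vu07"`.
#' @param alleles Character vector of at least two unique allele symbols,
#'   e.g. `c("C0", "C1", "C2")`.
#' @return An object of class `"locus"`.
#' @examples
#' locus("C", "Vu07", c("C0", "C1", "C2"))
#' @export
locus <- function(name, chromosome, alleles) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  alleles <- as.character(alleles)
  if (length(alleles) < 2L)
    stop("locus '", name, "' needs at least 2 alleles", call. = FALSE)
  if (anyDuplicated(alleles))
    stop("allele symbols must be unique within locus '", name, "'", call. = FALSE)
  structure(list(name = name, chromosome = as.character(chromosome),
                 alleles = alleles),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus>", x$name, "on", x$chromosome,
      "alleles:", paste(x$alleles, collapse = ", "), "\n")
  invisible(x)
}

#' Define an allelic series (dominance ranking) for a locus
#'
#' The dominance relation is a partial order given as dominant -> recessive
#' pairs. Pairs whose relative dominance is unknown are listed in
#' `unresolved`; a heterozygote of such a pair cannot be resolved and
#' [expressed_allele()] raises an error rather than guessing.
#'
#' @param locus A [locus()].
#' @param dominance List of character pairs `c(dominant, recessive)`.
#' @param unresolved List of character pairs with unknown relative dominance.
#' @return An object of class `"allelic_series"`.
#' @examples
#' Cl <- locus("C", "Vu07", c("C0", "C1", "C2"))
#' allelic_series(Cl, dominance = list(c("C2", "C0"), c("C2", "C1")),
#'                unresolved = list(c("C1", "C0")))
#' @export
allelic_series <- function(locus, dominance, unresolved = list()) {
  stopifnot(inherits(locus, "locus"))
  chk_pair <- function(p) {
    if (length(p) != 2L || !all(p %in% locus$alleles))
      stop("allelic series pair must be two alleles of locus '",
           locus$name, "'", call. = FALSE)
  }
  lapply(dominance, chk_pair)
  lapply(unresolved, chk_pair)
  # transitive closure of the dominance relation; also detects cycles
  n <- length(locus$alleles)
  M <- matrix(FALSE, n, n, dimnames = list(locus$alleles, locus$alleles))
  for (p in dominance) M[p[1L], p[2L]] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n))
    if (M[i, k]) M[i, ] <- M[i, ] | M[k, ]
  if (any(diag(M)))
    stop("dominance relation for locus '", locus$name, "' is cyclic",
         call. = FALSE)
  mentioned <- unique(unlist(c(dominance, unresolved)))
  if (!all(locus$alleles %in% mentioned))
    stop("every allele of locus '", locus$name,
         "' must appear in the series", call. = FALSE)
  structure(list(locus = locus, dominance = dominance,
                 unresolved = unresolved, closure = M),
            class = "allelic_series")
}

#' Expressed allele of an unordered genotype pair
#'
#' Returns the allele expressed by a diploid pair under an allelic series:
#' a homozygote expresses its allele, a heterozygote expresses the dominant
#' one. Heterozygotes of an unresolved pair raise an "unresolved dominance"
#' error; no silent choice is ever made.
#'
#' @param pair Character vector of two allele symbols (unordered).
#' @param series An [allelic_series()].
#' @return A single allele symbol.
#' @examples
#' Cl <- locus("C", "Vu07", c("C0", "C1", "C2"))
#' ser <- allelic_series(Cl, list(c("C2", "C0"), c("C2", "C1")),
#'                       list(c("C1", "C0")))
#' expressed_allele(c("C2", "C0"), ser) # "C2"
#' @export
expressed_allele <- function(pair, series) {
  stopifnot(inherits(series, "allelic_series"))
  pair <- as.character(pair)
  if (length(pair) != 2L || !all(pair %in% series$locus$alleles))
    stop("genotype pair must be two alleles of locus '",
         series$locus$name, "'", call. = FALSE)
  if (pair[1L] == pair[2L]) return(pair[1L])
  if (series$closure[pair[1L], pair[2L]]) return(pair[1L])
  if (series$closure[pair[2L], pair[1L]]) return(pair[2L])
  stop("unresolved dominance between alleles '", pair[1L], "' and '",
       pair[2L], "' at locus '", series$locus$name, "'", call. = FALSE)
}

#' Construct a multi-locus genotype
#'
#' Unordered allele pairs keyed by locus name (no parent-of-origin effect).
#'
#' @param ... Named length-2 character vectors, e.g.
#'   `C = c("C2", "C2"), W = c("W0", "W1")`.
#' @return An object of class `"multilocus_genotype"`.
#' @examples
#' multilocus_genotype(C = c("C2", "C2"), W = c("W0", "W0"), H = c("H0", "H0"))
#' @export
multilocus_genotype <- function(...) {
  g <- list(...)
  if (length(g) == 1L && is.null(names(g)) && is.list(g[[1L]]))
    g <- g[[1L]] # allow multilocus_genotype(list(C = ..., W = ...))
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("genotype pairs must be named by locus", call. = FALSE)
  for (nm in names(g)) {
    g[[nm]] <- as.character(g[[nm]])
    if (length(g[[nm]]) != 2L)
      stop("locus '", nm, "': a genotype is an unordered pair of 2 alleles",
           call. = FALSE)
  }
  structure(g, class = "multilocus_genotype")
}

#' @export
format.multilocus_genotype <- function(x, ...) {
  paste(vapply(unclass(x), paste0, "", collapse = ""), collapse = " ")
}

#' @export
print.multilocus_genotype <- function(x, ...) {
  cat("<genotype>", format(x), "\n")
  invisible(x)
}

is_homozygous <- function(g) {
  all(vapply(unclass(g), function(p) p[1L] == p[2L], TRUE))
}

#' Construct a genotype-to-phenotype model
#'
#' A phenotype model couples one [allelic_series()] per locus with an
#' ordered list of epistasis rules. Each rule is a condition on the
#' *expressed* per-locus alleles mapped to a pattern class; the first
#' matching rule wins, so extensions (e.g. a hypothetical Blue-grey Ring
#' allele) can be prepended without rewriting the core rules. Rules are
#' required to be exhaustive over all resolvable genotypes (checked by
#' enumeration in [check_exhaustive()]).
#'
#' @param series Named list of [allelic_series()] objects (names = loci).
#' @param rules List of rules, each `list(when = c(<locus> = <allele>, ...),
#'   class = <pattern class>)`.
#' @param classes Character vector of known pattern classes; must contain
#'   the six canonical [pattern_classes].
#' @return An object of class `"phenotype_model"`.
#' @seealso [cwh_model()] for the default cowpea C/W/H model.
#' @export
phenotype_model <- function(series, rules, classes = pattern_classes) {
  stopifnot(is.list(series), length(series) >= 1L)
  if (is.null(names(series)))
    names(series) <- vapply(series, function(s) s$locus$name, "")
  for (s in series) stopifnot(inherits(s, "allelic_series"))
  classes <- as.character(classes)
  if (anyDuplicated(classes))
    stop("pattern class names must be unique", call. = FALSE)
  if (!all(pattern_classes %in% classes))
    stop("the six canonical pattern classes must always be present",
         call. = FALSE)
  for (r in rules) {
    if (!all(c("when", "class") %in% names(r)))
      stop("each rule needs 'when' and 'class'", call. = FALSE)
    if (!r$class %in% classes)
      stop("rule maps to unknown class '", r$class, "'", call. = FALSE)
    for (ln in names(r$when)) {
      if (!ln %in% names(series))
        stop("rule conditions on unknown locus '", ln, "'", call. = FALSE)
      if (!r$when[[ln]] %in% series[[ln]]$locus$alleles)
        stop("rule conditions on unknown allele '", r$when[[ln]], "'",
             call. = FALSE)
    }
  }
  structure(list(series = series, rules = rules, classes = classes),
            class = "phenotype_model")
}

#' Default cowpea C/W/H pattern model
#'
#' Encodes the three-locus system: C (Vu07; alleles C0 < C2, C1 < C2, C0/C1
#' unresolved), W (Vu09; W1 > W0) and H (Vu10; H1 > H0), with epistasis
#' rules: expressed C0 gives No Color and expressed C1 gives Eye 1, both
#' regardless of W and H ("constriction"); expressed C2 reveals the
#' "expansion" loci, with (W0,H0) = Eye 2, (W0,H1) = Holstein,
#' (W1,H0) = Watson and (W1,H1) = Full Coat.
#'
#' @return A [phenotype_model()].
#' @examples
#' m <- cwh_model()
#' phenotype_of(multilocus_genotype(C = c("C2", "C2"), W = c("W1", "W1"),
#'                                  H = c("H0", "H0")), m) # "Watson"
#' @export
cwh_model <- function() {
  C <- locus("C", "Vu07", c("C0", "C1", "C2"))
  W <- locus("W", "Vu09", c("W0", "W1"))
  H <- locus("H", "Vu10", c("H0", "H1"))
  series <- list(
    C = allelic_series(C, dominance = list(c("C2", "C0"), c("C2", "C1")),
                       unresolved = list(c("C1", "C0"))),
    W = allelic_series(W, dominance = list(c("W1", "W0"))),
    H = allelic_series(H, dominance = list(c("H1", "H0")))
  )
  rules <- list(
    list(when = c(C = "C0"), class = "NoColor"),
    list(when = c(C = "C1"), class = "Eye1"),
    list(when = c(C = "C2", W = "W0", H = "H0"), class = "Eye2"),
    list(when = c(C = "C2", W = "W0", H = "H1"), class = "Holstein"),
    list(when = c(C = "C2", W = "W1", H = "H0"), class = "Watson"),
    list(when = c(C = "C2", W = "W1", H = "H1"), class = "FullCoat")
  )
  phenotype_model(series, rules)
}

#' Phenotype of a multi-locus genotype
#'
#' Applies the model's ordered epistasis rules to the expressed allele at
#' each locus; the first matching rule gives the pattern class. Expressed
#' alleles are computed lazily, so a genotype masked by C never needs W or H
#' resolved. "Unresolved dominance" errors from [expressed_allele()]
#' propagate.
#'
#' @param g A [multilocus_genotype()] covering the model's loci.
#' @param model A [phenotype_model()].
#' @return A pattern class name.
#' @export
phenotype_of <- function(g, model) {
  stopifnot(inherits(model, "phenotype_model"))
  if (!inherits(g, "multilocus_genotype")) g <- multilocus_genotype(g)
  expressed <- list()
  for (r in model$rules) {
    ok <- TRUE
    for (ln in names(r$when)) {
      if (is.null(g[[ln]]))
        stop("genotype does not cover locus '", ln, "'", call. = FALSE)
      if (is.null(expressed[[ln]]))
        expressed[[ln]] <- expressed_allele(g[[ln]], model$series[[ln]])
      if (!identical(expressed[[ln]], unname(r$when[[ln]]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(r$class)
  }
  stop("no rule matched genotype ", format(g),
       " - model rules are not exhaustive", call. = FALSE)
}

#' Enumerate all genotypes of a model and check rule exhaustiveness
#'
#' Enumerates every unordered multi-locus genotype combination (for the
#' default model, 6 x 3 x 3 = 54) and classifies each. Genotypes containing
#' a heterozygote with unresolved dominance are returned with class `NA` and
#' counted separately; every resolvable genotype must map to exactly one
#' class or an error is raised.
#'
#' @param model A [phenotype_model()].
#' @return Data frame with one row per genotype: one column per locus
#'   (genotype written `"a/b"`) and a `class` column (`NA` = unresolvable).
#' @export
check_exhaustive <- function(model) {
  stopifnot(inherits(model, "phenotype_model"))
  per_locus <- lapply(model$series, function(s) {
    a <- s$locus$alleles
    idx <- which(upper.tri(diag(length(a)), diag = TRUE), arr.ind = TRUE)
    apply(idx, 1L, function(ij) sort(c(a[ij[1L]], a[ij[2L]])),
          simplify = FALSE)
  })
  grid <- expand.grid(lapply(per_locus, seq_along))
  out <- data.frame(matrix("", nrow(grid), length(per_locus)),
                    stringsAsFactors = FALSE)
  names(out) <- names(per_locus)
  out$class <- NA_character_
  for (i in seq_len(nrow(grid))) {
    pairs <- lapply(names(per_locus),
                    function(ln) per_locus[[ln]][[grid[i, ln]]])
    names(pairs) <- names(per_locus)
    g <- do.call(multilocus_genotype, pairs)
    for (ln in names(pairs)) out[i, ln] <- paste(pairs[[ln]], collapse = "/")
    out$class[i] <- tryCatch(phenotype_of(g, model), error = function(e) {
      if (grepl("unresolved dominance", conditionMessage(e)))
        return(NA_character_)
      stop(e)
    })
  }
  out
}

#' Encode a pattern phenotype as mapping-ready presence/absence scores
#'
#' Each trait in `trait_list` is scored 1 (present) or 0 (absent); pattern
#' phenotypes are mutually exclusive, so at most one trait is 1. Because
#' Eye 1 is epistatic towards the W and H loci, an Eye 1 line is scored as
#' missing (`NA`) for all other traits in `"strict"` mode (avoids biasing
#' biparental mapping) and as 0 in `"magic"` mode (multiparent software
#' cannot tolerate that much missing data).
#'
#' @param pattern A pattern class name.
#' @param trait_list Character vector of traits to score.
#' @param mode `"strict"` or `"magic"`.
#' @param classes Known classes (for validating `pattern`).
#' @return Named numeric vector over `trait_list` with values 1, 0 or `NA`.
#' @examples
#' encode_traits("Eye1", c("Eye1", "Eye2", "Holstein", "Watson", "FullCoat"))
#' @export
encode_traits <- function(pattern, trait_list, mode = c("strict", "magic"),
                          classes = pattern_classes) {
  mode <- match.arg(mode)
  if (length(pattern) != 1L || !pattern %in% classes)
    stop("unknown pattern class '", paste(pattern, collapse = ","), "'",
         call. = FALSE)
  v <- setNames(rep(0, length(trait_list)), trait_list)
  if (pattern %in% trait_list) v[pattern] <- 1
  if (identical(pattern, "Eye1") && mode == "strict")
    v[setdiff(trait_list, "Eye1")] <- NA_real_
  v
}

#' Encode phenotypes of many lines as a trait score matrix
#'
#' @param patterns Character vector of pattern classes (one per line).
#' @param trait_list Traits to score; default the five mapped patterns.
#' @param mode See [encode_traits()].
#' @return Numeric matrix, lines x traits.
#' @export
encode_trait_matrix <- function(patterns,
                                trait_list = setdiff(pattern_classes, "NoColor"),
                                mode = c("strict", "magic")) {
  mode <- match.arg(mode)
  m <- t(vapply(as.character(patterns), encode_traits,
                numeric(length(trait_list)),
                trait_list = trait_list, mode = mode))
  if (!is.null(names(patterns))) rownames(m) <- names(patterns)
  m
}

# ---- model serialization (JSON) ----------------------------------------

#' Write a phenotype model to a JSON file
#'
#' @param model A [phenotype_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]; the packaged default model is at
#'   `system.file("extdata", "cwh_default.json", package = "seedcoat")`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "phenotype_model"))
  obj <- list(
    classes = model$classes,
    loci = lapply(unname(model$series), function(s)
      list(name = s$locus$name, chromosome = s$locus$chromosome,
           alleles = s$locus$alleles)),
    series = lapply(unname(model$series), function(s)
      list(locus = s$locus$name, dominance = s$dominance,
           unresolved = s$unresolved)),
    rules = lapply(model$rules, function(r)
      list(when = as.list(r$when), class = r$class))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a phenotype model from a JSON file
#'
#' @param path Path to a JSON file written by [write_model()].
#' @return A [phenotype_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  loci <- lapply(obj$loci, function(l)
    locus(l$name, l$chromosome, unlist(l$alleles)))
  names(loci) <- vapply(obj$loci, `[[`, "", "name")
  series <- lapply(obj$series, function(s)
    allelic_series(loci[[s$locus]],
                   dominance = lapply(s$dominance, unlist),
                   unresolved = lapply(s$unresolved, unlist)))
  names(series) <- vapply(obj$series, `[[`, "", "locus")
  rules <- lapply(obj$rules, function(r)
    list(when = unlist(r$when), class = r$class))
  phenotype_model(series, rules, classes = unlist(obj$classes))
}
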