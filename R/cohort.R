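#' Specification of a synthetic Hardy-Weinberg cohort
#'
#' Describes a cohort to be drawn under Hardy-Weinberg equilibrium: size, sex
#' ratio, per-locus allele frequencies and a reproducibility seed. Defaults
#' are the published unaffected-cohort conditions: allele frequencies of the
#' five modelled variants and a female fraction of 92/140.
#'
#' @param n number of individuals.
#' @param female_fraction proportion of females in `[0, 1]`.
#' @param allele_freqs named list, locus id to named vector of allele
#'   frequencies (must sum to 1 per locus). Defaults to the frequencies in
#'   `defs`.
#' @param seed optional integer seed; cohorts drawn with the same spec and
#'   seed are identical.
#' @param group_label group label attached to every individual.
#' @param defs a [variantDefs()] table.
#' @return A list of class `serodyn_cohort_spec`.
#' @export
#' @examples
#' cohortSpec(n = 140, seed = 1)
cohortSpec <- function(n, female_fraction = 92 / 140, allele_freqs = NULL,
                       seed = NULL, group_label = "unaffected",
                       defs = variantDefs()) {
  if (n < 1) stop("cohort size must be at least 1")
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must be in [0, 1]")
  }
  default_freqs <- lapply(split(defs, defs$locus), function(sub) {
    stats::setNames(sub$freq, sub$allele)
  })[lociNames(defs)]
  if (is.null(allele_freqs)) {
    allele_freqs <- default_freqs
  } else {
    # partial overrides merge over the defaults
    bad_loci <- setdiff(names(allele_freqs), lociNames(defs))
    if (length(bad_loci) > 0) {
      stop("allele frequencies given for undefined locus ",
           paste(bad_loci, collapse = ", "))
    }
    merged <- default_freqs
    merged[names(allele_freqs)] <- allele_freqs
    allele_freqs <- merged
  }
  for (loc in names(allele_freqs)) {
    f <- allele_freqs[[loc]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop("allele frequencies for locus ", loc,
           " must be non-negative and sum to 1")
    }
    sub <- defs[defs$locus == loc, ]
    bad <- setdiff(names(f), sub$allele)
    if (length(bad) > 0) {
      stop("locus ", loc, ": frequency given for undefined allele ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 allele_freqs = allele_freqs, seed = seed,
                 group_label = group_label),
            class = "serodyn_cohort_spec")
}

#' Draw a synthetic genotype cohort under Hardy-Weinberg equilibrium
#'
#' Autosomal loci receive two independent allele draws per individual; the
#' X-linked MAOA uVNTR receives one draw for males and two for females. Sex
#' is drawn from the spec's female fraction. Loci are sampled independently
#' (no linkage disequilibrium between the three TPH2 SNVs; see the methods
#' vignette for this limitation).
#'
#' @param spec a [cohortSpec()].
#' @param defs a [variantDefs()] table.
#' @return A genotype table (`data.frame`, class `serodyn_genotypes`) with
#'   columns `sample_id`, `sex`, `group` and one column per locus; genotype
#'   cells are `"X/Y"`, male uVNTR cells a single allele.
#' @export
#' @examples
#' head(sampleCohort(cohortSpec(n = 5, seed = 1)))
sampleCohort <- function(spec, defs = variantDefs()) {
  stopifnot(inherits(spec, "serodyn_cohort_spec"))
  if (!is.null(spec$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(spec$seed)
  }
  n <- spec$n
  sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)), sex = sex,
                    group = spec$group_label, stringsAsFactors = FALSE)
  for (loc in lociNames(defs)) {
    f <- spec$allele_freqs[[loc]]
    xlinked <- defs$chromosome[defs$locus == loc][1] == "X-linked"
    a1 <- sample(names(f), n, replace = TRUE, prob = f)
    a2 <- sample(names(f), n, replace = TRUE, prob = f)
    out[[loc]] <- if (xlinked) {
      ifelse(sex == "male", a1, paste(a1, a2, sep = "/"))
    } else {
      paste(a1, a2, sep = "/")
    }
  }
  class(out) <- c("serodyn_genotypes", "data.frame")
  out
}

#' Convert one genotype-table row to a genotype record
#'
#' @param genotypes a genotype table ([sampleCohort()] or
#'   [readGenotypeTable()]).
#' @param i row index.
#' @param defs a [variantDefs()] table.
#' @return A [genotypeRecord()].
#' @export
asGenotypeRecord <- function(genotypes, i, defs = variantDefs()) {
  row <- genotypes[i, ]
  g <- lapply(lociNames(defs), function(loc) {
    strsplit(as.character(row[[loc]]), "/", fixed = TRUE)[[1]]
  })
  names(g) <- lociNames(defs)
  genotypeRecord(row$sample_id, row$sex, row$group, g, defs = defs)
}

#' Biallelic genotype counts for a Hardy-Weinberg test
#'
#' Tabulates genotype counts at one locus in the three-class biallelic form
#' (reference homozygote, heterozygote, alternate homozygote) expected by
#' [hweChi2()]. For the multi-allelic uVNTR, alleles are first grouped into
#' their Low/High expression classes and, the locus being X-linked, only
#' females are counted.
#'
#' @param genotypes a genotype table.
#' @param locus locus id.
#' @param defs a [variantDefs()] table.
#' @return Named integer vector of length 3 (`hom_ref`, `het`, `hom_alt`).
#' @export
hweCounts <- function(genotypes, locus, defs = variantDefs()) {
  sub <- defs[defs$locus == locus, ]
  xlinked <- sub$chromosome[1] == "X-linked"
  rows <- if (xlinked) genotypes$sex == "female" else rep(TRUE, nrow(genotypes))
  cells <- as.character(genotypes[[locus]][rows])
  al <- strsplit(cells, "/", fixed = TRUE)
  if (any(lengths(al) != 2)) stop("expected two alleles per genotype cell")
  if (locus == "uVNTR") {
    al <- lapply(al, groupUvntrAllele, defs = defs)
    ref <- "High"
    alt <- "Low"
  } else {
    ref <- sub$allele[sub$effect == 1][1]
    alt <- setdiff(sub$allele, ref)
    if (length(alt) != 1) stop("locus ", locus, " is not biallelic")
  }
  nref <- vapply(al, function(a) sum(a == ref), integer(1))
  c(hom_ref = sum(nref == 2L), het = sum(nref == 1L), hom_alt = sum(nref == 0L))
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed biallelic genotype counts to the Hardy-Weinberg
#' expectation (p^2, 2pq, q^2 at the observed allele frequency) with a
#' 1-degree-of-freedom Pearson chi-square statistic.
#'
#' @param counts integer vector of length 3: reference homozygotes,
#'   heterozygotes, alternate homozygotes.
#' @return List with `chi2`, `df` (1) and `p_value`.
#' @export
#' @examples
#' hweChi2(c(25, 50, 25))  # chi2 = 0
hweChi2 <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts")
  }
  n <- sum(counts)
  if (n == 0) stop("no genotypes to test")
  p <- (2 * counts[[1]] + counts[[2]]) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expd == 0)) {
    # monomorphic sample: observed equals expected by construction
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expd)^2 / expd)
  }
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
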