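#' Variant definitions: loci, allelic effects and allele frequencies
#'
#' Loads the definition table of the five regulatory variants the model
#' integrates: three TPH2 SNVs (rs11178998, rs4290270, rs7305115), the
#' SLC6A4 promoter repeat 5-HTTLPR (L/S) and the MAOA promoter uVNTR
#' (3R/3.5R/4R/5R, X-linked). Each allele carries a normalised effect on mRNA
#' expression (reference allele = 1) and a population allele frequency. The
#' packaged defaults are the published values; pass `path` to override with a
#' user table in the same tab-separated layout.
#'
#' The uVNTR reference is the high-expression allele class (3.5R, 4R), so the
#' low-expression alleles (3R, 5R) have effect 0.2. The rare 2R allele has no
#' established expression effect and is rejected by the parsers unless a user
#' table supplies one.
#'
#' @param path optional path to a tab-separated definition table with columns
#'   `locus`, `gene`, `chromosome` (`autosomal`/`X-linked`), `inheritance`
#'   (`additive`/`dominant`), `allele`, `effect`, `freq`.
#' @return A `data.frame` of class `serodyn_variants`.
#' @export
#' @examples
#' defs <- variantDefs()
#' subset(defs, locus == "uVNTR")
variantDefs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variant_effects.tsv", package = "serodyn",
                        mustWork = TRUE)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "gene", "chromosome", "inheritance", "allele", "effect",
            "freq")
  if (!all(need %in% names(d))) {
    stop("variant definition table must have columns: ",
         paste(need, collapse = ", "))
  }
  for (loc in unique(d$locus)) {
    sub <- d[d$locus == loc, ]
    if (anyDuplicated(sub$allele)) {
      stop("duplicate allele definitions for locus ", loc)
    }
    if (!any(sub$effect == 1)) {
      stop("locus ", loc, " has no reference allele (effect 1)")
    }
    if (abs(sum(sub$freq) - 1) > 1e-9) {
      stop("allele frequencies for locus ", loc, " do not sum to 1")
    }
  }
  class(d) <- c("serodyn_variants", "data.frame")
  d
}

#' Locus identifiers in canonical order
#' @param defs a [variantDefs()] table.
#' @return Character vector of locus ids.
#' @export
lociNames <- function(defs = variantDefs()) unique(defs$locus)

#' Group a MAOA uVNTR allele into its expression class
#'
#' The promoter repeat alleles are grouped by their effect on mRNA
#' expression: 3R and 5R are low-expression (`"Low"`), 3.5R and 4R
#' high-expression (`"High"`). The 2R allele has no established effect and is
#' rejected unless the supplied definitions assign it one.
#'
#' @param allele repeat label, e.g. `"4R"`.
#' @param defs a [variantDefs()] table.
#' @return `"Low"` or `"High"`.
#' @export
#' @examples
#' groupUvntrAllele("4R")  # "High"
groupUvntrAllele <- function(allele, defs = variantDefs()) {
  sub <- defs[defs$locus == "uVNTR", ]
  out <- character(length(allele))
  for (i in seq_along(allele)) {
    j <- match(allele[i], sub$allele)
    if (is.na(j)) {
      if (allele[i] == "2R") {
        stop("uVNTR allele 2R has no defined expression effect; ",
             "supply one via a custom variant definition table")
      }
      stop("unknown uVNTR allele: ", allele[i])
    }
    out[i] <- if (sub$effect[j] == 1) "High" else "Low"
  }
  out
}

#' Protein expression and turnover table
#'
#' Normalised brain-stem mRNA expression (NX units) and catalytic turnover
#' numbers for the three genotype-dependent proteins. The enzyme
#' concentration entering the maximal-rate law is derived from expression as
#' E = NX/1000 (uM), and the turnover number is converted to hourly units as
#' kcat/h = 3600 x kcat/s. SERT has no measured kcat; its value is the
#' published back-calculation from transporter maximal rate and expression.
#'
#' @return `data.frame` with columns `gene`, `nx`, `kcat_per_s`, `kcat_per_h`
#'   and `e_nx_uM`.
#' @export
#' @examples
#' proteinExpression()
proteinExpression <- function() {
  d <- data.frame(gene = c("TPH2", "SLC6A4", "MAOA"),
                  nx = c(46.2, 11.2, 18.6),
                  kcat_per_s = c(5.03, 198.4, 18.6),
                  stringsAsFactors = FALSE)
  d$kcat_per_h <- kcatToPerHour(d$kcat_per_s)
  d$e_nx_uM <- nxToConcentration(d$nx)
  d
}

#' Convert a turnover number from per-second to per-hour
#' @param kcat_per_s turnover number in 1/s, > 0.
#' @return kcat in 1/h (3600 x input).
#' @export
#' @examples
#' kcatToPerHour(5.03)  # 18108
kcatToPerHour <- function(kcat_per_s) {
  if (any(kcat_per_s <= 0)) stop("kcat must be positive")
  3600 * kcat_per_s
}

#' Enzyme concentration from maximal rate and turnover
#'
#' E = Vmax / kcat, the protein concentration consistent with a given maximal
#' rate.
#'
#' @param vmax maximal rate (uM/h), > 0.
#' @param kcat_per_h turnover number (1/h), > 0.
#' @return Enzyme concentration in uM.
#' @export
#' @examples
#' enzymeConcFromVmax(400, 18108)  # 0.0221 (TPH2)
enzymeConcFromVmax <- function(vmax, kcat_per_h) {
  if (any(vmax <= 0)) stop("vmax must be positive")
  if (any(kcat_per_h <= 0)) stop("kcat must be positive")
  vmax / kcat_per_h
}

#' Map normalised expression (NX) to enzyme concentration
#'
#' The model's expression-to-concentration rule: E = NX/1000, interpreted in
#' uM (i.e. NX units approximate nanomolar protein concentration).
#'
#' @param nx normalised expression units, >= 0.
#' @return Concentration in uM.
#' @export
#' @examples
#' nxToConcentration(46.2)  # 0.0462
nxToConcentration <- function(nx) {
  if (any(nx < 0)) stop("NX must be non-negative")
  nx / 1000
}

#' Construct and validate one individual's genotype record
#'
#' @param sample_id sample identifier.
#' @param sex `"male"` or `"female"`.
#' @param group group label (e.g. `"unaffected"`).
#' @param genotype named list, one entry per locus in `defs`: a character
#'   vector of two alleles for autosomal loci, and for the X-linked uVNTR one
#'   allele for males, two for females. Allele order is irrelevant.
#' @param defs a [variantDefs()] table.
#' @return A list of class `serodyn_genotype`.
#' @export
#' @examples
#' genotypeRecord("S1", "female", "unaffected",
#'   list(rs11178998 = c("A", "A"), rs4290270 = c("T", "T"),
#'        rs7305115 = c("G", "G"), HTTLPR = c("L", "S"),
#'        uVNTR = c("4R", "3R")))
genotypeRecord <- function(sample_id, sex, group, genotype,
                           defs = variantDefs()) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  loci <- lociNames(defs)
  missing_loci <- setdiff(loci, names(genotype))
  if (length(missing_loci) > 0) {
    stop("sample ", sample_id, ": missing genotype for locus ",
         paste(missing_loci, collapse = ", "))
  }
  for (loc in loci) {
    al <- genotype[[loc]]
    sub <- defs[defs$locus == loc, ]
    xlinked <- sub$chromosome[1] == "X-linked"
    expected <- if (xlinked && sex == "male") 1L else 2L
    if (length(al) != expected) {
      stop("sample ", sample_id, ", locus ", loc, ": expected ", expected,
           " allele(s) for ", sex, ", got ", length(al))
    }
    bad <- setdiff(al, sub$allele)
    if (length(bad) > 0) {
      extra <- if (loc == "uVNTR" && "2R" %in% bad) {
        " (2R has no defined expression effect)"
      } else ""
      stop("sample ", sample_id, ", locus ", loc, ": unsupported allele ",
           paste(bad, collapse = "/"), extra)
    }
  }
  structure(list(sample_id = sample_id, sex = sex, group = group,
                 genotype = genotype[loci]),
            class = "serodyn_genotype")
}

#' Genotype correction factors per gene
#'
#' Computes the dimensionless genotype correction C_genotype that multiplies
#' each protein's effective concentration. TPH2 uses an additive model
#' averaged over its three loci: C = mean over loci of (a1 + a2). SLC6A4
#' (SERT) uses a dominant model for 5-HTTLPR in which the short allele
#' dominates: genotypes SS and LS give S + S, LL gives L + L. MAOA is
#' additive (a1 + a2); hemizygous males are counted as homozygotes (2 x a).
#' The all-reference genotype therefore has C = 2 at every gene.
#'
#' @param record a [genotypeRecord()].
#' @param defs a [variantDefs()] table.
#' @return Named numeric vector `c(tph2 = , sert = , maoa = )`.
#' @export
#' @examples
#' r <- genotypeRecord("S1", "male", "unaffected",
#'   list(rs11178998 = c("A", "A"), rs4290270 = c("T", "T"),
#'        rs7305115 = c("G", "G"), HTTLPR = c("L", "L"), uVNTR = "3R"))
#' cGenotype(r)  # tph2 2, sert 2, maoa 0.4
cGenotype <- function(record, defs = variantDefs()) {
  eff <- function(loc, alleles) {
    sub <- defs[defs$locus == loc, ]
    sub$effect[match(alleles, sub$allele)]
  }
  g <- record$genotype
  tph2_loci <- unique(defs$locus[defs$gene == "TPH2"])
  c_tph2 <- mean(vapply(tph2_loci, function(loc) sum(eff(loc, g[[loc]])),
                        numeric(1)))
  e_sert <- eff("HTTLPR", g[["HTTLPR"]])
  # dominant model: the lower-expression allele sets both contributions
  c_sert <- 2 * min(e_sert)
  e_maoa <- eff("uVNTR", g[["uVNTR"]])
  c_maoa <- if (record$sex == "male") 2 * e_maoa else sum(e_maoa)
  c(tph2 = c_tph2, sert = c_sert, maoa = c_maoa)
}

#' Per-gene maximal-rate scale multipliers
#'
#' Dimensionless multipliers applied to the literal maximal-rate law
#' Vmax = E_NX x C_genotype x kcat. With all three set to 1 the literal law
#' is used. The defaults are the package's frozen calibration of the
#' absolute rate scale against the published baseline mean concentrations of
#' an unaffected cohort (see the methods vignette): the literal products for
#' SERT and MAOA, taken at face value, pin extracellular serotonin near 2 nM
#' and overshoot degradation, far from the published 70 nM / 0.6 uM
#' baselines, so the absolute scale is fixed once here and never revisited.
#'
#' @param tph2,sert,maoa positive multipliers.
#' @return Named numeric vector `c(tph2 = , sert = , maoa = )`.
#' @export
vmaxScale <- function(tph2 = .serodyn_calibrated_scale[["tph2"]],
                      sert = .serodyn_calibrated_scale[["sert"]],
                      maoa = .serodyn_calibrated_scale[["maoa"]]) {
  s <- c(tph2 = tph2, sert = sert, maoa = maoa)
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("scale multipliers must be positive")
  }
  s
}

# Frozen calibration of the absolute Vmax scale (see vmaxScale docs and the
# methods vignette for the procedure): the literal law for TPH2; SERT and
# MAOA multipliers fixed once by rooting the expected extracellular-5-HT
# mean (70.5 nM) and the 5-HIAA/fc5-HT ratio (0.67) over the exact
# Hardy-Weinberg genotype-class distribution.
.serodyn_calibrated_scale <- c(tph2 = 1, sert = 0.01219, maoa = 0.03667)

#' Genotype-dependent maximal rates for one individual
#'
#' The maximal-rate law: for each of TPH2, SERT and MAOA,
#' Vmax = E_NX x C_genotype x kcat x scale, where E_NX is the NX-derived
#' protein concentration (uM), C_genotype the genotype correction of
#' [cGenotype()], kcat the hourly turnover number and `scale` the per-gene
#' calibration multiplier of [vmaxScale()].
#'
#' @param record a [genotypeRecord()].
#' @param expr a [proteinExpression()] table.
#' @param defs a [variantDefs()] table.
#' @param scale a [vmaxScale()] vector.
#' @return A [vmaxSet()] (uM/h).
#' @export
vmaxFromGenotype <- function(record, expr = proteinExpression(),
                             defs = variantDefs(), scale = vmaxScale()) {
  cg <- cGenotype(record, defs)
  row <- function(gene) expr[expr$gene == gene, ]
  t2 <- row("TPH2"); s4 <- row("SLC6A4"); ma <- row("MAOA")
  vmaxSet(tph2 = t2$e_nx_uM * cg[["tph2"]] * t2$kcat_per_h * scale[["tph2"]],
          sert = s4$e_nx_uM * cg[["sert"]] * s4$kcat_per_h * scale[["sert"]],
          maoa = ma$e_nx_uM * cg[["maoa"]] * ma$kcat_per_h * scale[["maoa"]])
}
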