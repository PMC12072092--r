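test_that("turnover conversion and enzyme-concentration identities hold", {
  expect_equal(kcatToPerHour(5.03), 18108)
  expect_equal(kcatToPerHour(18.6), 66960)
  expect_equal(kcatToPerHour(1), 3600)
  expect_error(kcatToPerHour(0), "positive")

  expect_equal(enzymeConcFromVmax(400, 18108), 400 / 18108)
  expect_equal(round(enzymeConcFromVmax(400, 18108), 3), 0.022)
  expect_equal(enzymeConcFromVmax(1000, 66960), 1000 / 66960)
  expect_equal(round(enzymeConcFromVmax(8000, 714285.7), 4), 0.0112)
  expect_error(enzymeConcFromVmax(400, 0), "positive")

  expect_equal(nxToConcentration(46.2), 0.0462)
  expect_equal(nxToConcentration(11.2), 0.0112)
  expect_equal(nxToConcentration(0), 0)
  expect_error(nxToConcentration(-1), "non-negative")

  expr <- proteinExpression()
  expect_equal(expr$kcat_per_h, 3600 * expr$kcat_per_s)
  expect_equal(expr$e_nx_uM, expr$nx / 1000)
})

test_that("uVNTR alleles group into expression classes; 2R is rejected", {
  expect_equal(groupUvntrAllele(c("4R", "3.5R")), c("High", "High"))
  expect_equal(groupUvntrAllele(c("3R", "5R")), c("Low", "Low"))
  expect_error(groupUvntrAllele("2R"), "no defined expression effect")
  expect_error(groupUvntrAllele("7R"), "unknown")
})

test_that("genotype corrections follow the per-gene inheritance models", {
  # all-reference genotype: C = 2 everywhere
  expect_equal(cGenotype(refRecord()), c(tph2 = 2, sert = 2, maoa = 2))
  # the worked examples
  r <- mixedRecord()  # A/G, T/A, G/A, L/S, 4R/3R
  cg <- cGenotype(r)
  expect_equal(unname(cg[["tph2"]]), ((1 + 3) + (1 + 0.7) + (1 + 1.7)) / 3)
  expect_equal(unname(cg[["sert"]]), 0.6)   # dominant: LS behaves as SS
  expect_equal(unname(cg[["maoa"]]), 1.2)   # female High/Low
  # maximal-effect TPH2 genotype
  hi <- genotypeRecord("HI", "female", "u",
                       list(rs11178998 = c("G", "G"), rs4290270 = c("A", "A"),
                            rs7305115 = c("A", "A"), HTTLPR = c("L", "L"),
                            uVNTR = c("4R", "4R")))
  expect_equal(unname(cGenotype(hi)[["tph2"]]), (6 + 1.4 + 3.4) / 3)
  # hemizygous male counted as homozygote
  m <- genotypeRecord("M", "male", "u",
                      list(rs11178998 = c("A", "A"), rs4290270 = c("T", "T"),
                           rs7305115 = c("G", "G"), HTTLPR = c("L", "L"),
                           uVNTR = "3R"))
  expect_equal(unname(cGenotype(m)[["maoa"]]), 0.4)
})

test_that("genotype corrections are invariant to allele order", {
  a <- genotypeRecord("A", "female", "u",
                      list(rs11178998 = c("A", "G"), rs4290270 = c("A", "T"),
                           rs7305115 = c("A", "G"), HTTLPR = c("S", "L"),
                           uVNTR = c("3R", "4R")))
  b <- genotypeRecord("B", "female", "u",
                      list(rs11178998 = c("G", "A"), rs4290270 = c("T", "A"),
                           rs7305115 = c("G", "A"), HTTLPR = c("L", "S"),
                           uVNTR = c("4R", "3R")))
  expect_equal(cGenotype(a), cGenotype(b))
})

test_that("replacing an allele with a higher-effect allele never lowers Vmax", {
  base <- list(rs11178998 = c("A", "A"), rs4290270 = c("A", "T"),
               rs7305115 = c("G", "G"), HTTLPR = c("L", "L"),
               uVNTR = c("3R", "3R"))
  v0 <- vmaxFromGenotype(genotypeRecord("X", "female", "u", base))
  ups <- list(list(locus = "rs11178998", to = c("G", "A")),
              list(locus = "rs4290270", to = c("T", "T")),
              list(locus = "rs7305115", to = c("A", "G")),
              list(locus = "uVNTR", to = c("4R", "3R")))
  for (up in ups) {
    g <- base
    g[[up$locus]] <- up$to
    v1 <- vmaxFromGenotype(genotypeRecord("X", "female", "u", g))
    expect_true(all(v1 >= v0 - 1e-12))
  }
})

test_that("the maximal-rate law composes concentration, correction, turnover", {
  expr <- proteinExpression()
  # literal law (scale 1): TPH2 reference genotype
  v <- vmaxFromGenotype(refRecord(), scale = vmaxScale(1, 1, 1))
  expect_equal(unname(v[["tph2"]]), 0.0462 * 2 * 18108, tolerance = 1e-12)
  expect_equal(unname(v[["tph2"]]), 1673.18, tolerance = 1e-5)
  expect_equal(unname(v[["maoa"]]), 0.0186 * 2 * 66960, tolerance = 1e-12)
  # round trip back to the NX-derived enzyme concentration
  cg <- cGenotype(mixedRecord())
  v2 <- vmaxFromGenotype(mixedRecord(), scale = vmaxScale(1, 1, 1))
  for (g in c("tph2", "maoa")) {
    gene <- c(tph2 = "TPH2", maoa = "MAOA")[[g]]
    kc <- expr$kcat_per_h[expr$gene == gene]
    expect_equal(enzymeConcFromVmax(v2[[g]] / cg[[g]], kc),
                 expr$e_nx_uM[expr$gene == gene], tolerance = 1e-12)
  }
  # calibration multipliers act multiplicatively
  v3 <- vmaxFromGenotype(refRecord(), scale = vmaxScale(0.5, 2, 1))
  expect_equal(unname(v3[["tph2"]]), unname(v[["tph2"]]) * 0.5)
  expect_equal(unname(v3[["sert"]]), unname(v[["sert"]]) * 2)
})

test_that("genotype records are validated against the variant definitions", {
  g <- list(rs11178998 = c("A", "A"), rs4290270 = c("T", "T"),
            rs7305115 = c("G", "G"), HTTLPR = c("L", "L"),
            uVNTR = c("4R", "4R"))
  # male with two uVNTR alleles
  expect_error(genotypeRecord("S", "male", "u", g), "expected 1 allele")
  # unsupported allele
  g2 <- g; g2$uVNTR <- c("2R", "4R")
  expect_error(genotypeRecord("S", "female", "u", g2), "2R")
  # missing locus
  expect_error(genotypeRecord("S", "female", "u", g[-1]), "missing genotype")
  # single allele at an autosomal locus
  g3 <- g; g3$HTTLPR <- "L"
  expect_error(genotypeRecord("S", "female", "u", g3), "expected 2 allele")
})

test_that("variant definitions carry the published effects and frequencies", {
  defs <- variantDefs()
  eff <- function(loc, al) defs$effect[defs$locus == loc & defs$allele == al]
  expect_equal(eff("rs11178998", "G"), 3)
  expect_equal(eff("rs4290270", "A"), 0.7)
  expect_equal(eff("rs7305115", "A"), 1.7)
  expect_equal(eff("HTTLPR", "S"), 0.3)
  expect_equal(eff("uVNTR", "3R"), 0.2)
  expect_equal(eff("uVNTR", "4R"), 1)
  for (loc in lociNames(defs)) {
    expect_equal(sum(defs$freq[defs$locus == loc]), 1, tolerance = 1e-9)
  }
})
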