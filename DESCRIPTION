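Package: serodyn
Title: Dynamic Model of the Serotonin Presynapse with Genotype-Dependent
    Enzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic model of serotonin (5-HT) metabolism in the presynapse:
    eight coupled differential equations describing tryptophan transport,
    5-HT synthesis (TPH2, AADC), vesicular storage (VMAT), release, reuptake
    (SERT) and degradation (MAOA), with per-individual maximal reaction rates
    derived from common regulatory variants in TPH2, SLC6A4 and MAOA
    (three SNVs, 5-HTTLPR, the MAOA uVNTR). Includes a Hardy-Weinberg
    synthetic cohort generator at published allele frequencies, stiff ODE
    simulation of whole cohorts with per-individual time-averaged species
    concentrations, and a nonparametric group-comparison battery
    (Mann-Whitney U, Kruskal-Wallis, Dunn's post hoc test with Bonferroni
    correction, Cohen's d, post hoc power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
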