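#' Published baseline concentrations for an unaffected cohort
#'
#' The baseline mean (and SD) time-averaged concentrations of the five
#' serotonin-branch species reported for a 140-individual unaffected cohort,
#' in uM. These are the values the package's maximal-rate scale calibration
#' was frozen against (see [vmaxScale()] and the methods vignette), and the
#' yardstick used by [baselineReport()].
#'
#' @return `data.frame` with columns `species`, `mean_uM`, `sd_uM`.
#' @export
baselineReference <- function() {
  data.frame(species = c("htp5", "fc5ht", "v5ht", "e5ht", "hiaa5"),
             mean_uM = c(13.6265, 0.8869, 2.4925, 0.0705, 0.6115),
             sd_uM = c(0.2259, 0.2600, 0.6752, 0.0013, 0.2453),
             stringsAsFactors = FALSE)
}

#' Compare a cohort run against the published baseline
#'
#' Draws a synthetic Hardy-Weinberg cohort at the default allele frequencies,
#' simulates it, and tabulates the cohort mean of each serotonin-branch
#' species next to the published baseline with a within-one-SD verdict.
#'
#' @param n cohort size.
#' @param seed reproducibility seed.
#' @param params,defs,scale model configuration (defaults as shipped).
#' @param ... passed to [simulateCohort()].
#' @return `data.frame` with columns `species`, `simulated_mean_uM`,
#'   `simulated_sd_uM`, `reference_mean_uM`, `reference_sd_uM`,
#'   `within_one_sd`.
#' @export
baselineReport <- function(n = 140, seed = 1, params = modelParameters(),
                           defs = variantDefs(), scale = vmaxScale(), ...) {
  cohort <- sampleCohort(cohortSpec(n = n, seed = seed, defs = defs),
                         defs = defs)
  summ <- simulateCohort(cohort, params = params, defs = defs,
                         scale = scale, ...)
  ref <- baselineReference()
  sim_mean <- vapply(ref$species,
                     function(sp) mean(summ[[paste0(sp, "_mean")]]),
                     numeric(1))
  sim_sd <- vapply(ref$species,
                   function(sp) stats::sd(summ[[paste0(sp, "_mean")]]),
                   numeric(1))
  data.frame(species = ref$species,
             simulated_mean_uM = unname(sim_mean),
             simulated_sd_uM = unname(sim_sd),
             reference_mean_uM = ref$mean_uM,
             reference_sd_uM = ref$sd_uM,
             within_one_sd = abs(sim_mean - ref$mean_uM) <= ref$sd_uM,
             stringsAsFactors = FALSE)
}
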