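#' Read a genotype table
#'
#' Reads the delimited genotype format: header columns `sample_id`, `sex`,
#' `group`, `rs11178998`, `rs4290270`, `rs7305115`, `HTTLPR`, `uVNTR`;
#' genotype cells `"X/Y"` (allele order irrelevant), male uVNTR cells a
#' single allele. Tab-separated by default; `.csv` files are read
#' comma-separated. Every row is validated against the variant definitions;
#' errors name the offending row and column.
#'
#' @param path file path.
#' @param defs a [variantDefs()] table.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return Validated genotype table of class `serodyn_genotypes`.
#' @export
readGenotypeTable <- function(path, defs = variantDefs(), sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "sex", "group", lociNames(defs))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("genotype table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(d))) {
    tryCatch(asGenotypeRecord(d, i, defs = defs),
             error = function(e) {
               stop("row ", i, " of ", path, ": ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  d <- d[need]
  class(d) <- c("serodyn_genotypes", "data.frame")
  d
}

#' Write a genotype table
#'
#' Inverse of [readGenotypeTable()]; prepends provenance header comments
#' (package version, optional seed, configuration hash).
#'
#' @param genotypes a genotype table.
#' @param path output path (`.csv` switches to comma separation).
#' @param seed optional seed recorded in the header.
#' @param config optional configuration list hashed into the header.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(genotypes, path, seed = NULL, config = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  writeWithProvenance(genotypes, path, sep = sep, seed = seed,
                      config = config)
}

#' Read a run configuration (YAML or JSON)
#'
#' Flat keys override [modelParameters()] fields; the `scale` block (keys
#' `tph2`, `sert`, `maoa`) overrides [vmaxScale()]; the `cohort` block (keys
#' of [cohortSpec()] except `defs`) overrides the cohort specification;
#' `variant_effects` names a custom [variantDefs()] table; `grid` (keys
#' `t_max`, `dt`) sets the simulation grid. Unknown keys are rejected with an
#' error naming the key, so a fully default configuration is the empty file.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with elements `params`, `scale`, `defs`, `cohort` (a list of
#'   [cohortSpec()] arguments or `NULL`), `grid` and `seed`.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON, got .", ext)
  }
  if (is.null(cfg)) cfg <- list()
  param_keys <- setdiff(names(formals(modelParameters)), character(0))
  known <- c(param_keys, "scale", "cohort", "variant_effects", "grid", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defs <- if (!is.null(cfg$variant_effects)) {
    variantDefs(cfg$variant_effects)
  } else {
    variantDefs()
  }
  params <- do.call(modelParameters, cfg[intersect(names(cfg), param_keys)])
  scale <- vmaxScale()
  if (!is.null(cfg$scale)) {
    bad <- setdiff(names(cfg$scale), c("tph2", "sert", "maoa"))
    if (length(bad) > 0) stop("unknown scale key(s): ",
                              paste(bad, collapse = ", "))
    scale <- do.call(vmaxScale, as.list(cfg$scale))
  }
  grid <- list(t_max = 3, dt = 0.01)
  if (!is.null(cfg$grid)) {
    bad <- setdiff(names(cfg$grid), c("t_max", "dt"))
    if (length(bad) > 0) stop("unknown grid key(s): ",
                              paste(bad, collapse = ", "))
    grid[names(cfg$grid)] <- cfg$grid
  }
  cohort <- NULL
  if (!is.null(cfg$cohort)) {
    allowed <- setdiff(names(formals(cohortSpec)), "defs")
    bad <- setdiff(names(cfg$cohort), allowed)
    if (length(bad) > 0) stop("unknown cohort key(s): ",
                              paste(bad, collapse = ", "))
    cohort <- cfg$cohort
  }
  list(params = params, scale = scale, defs = defs, cohort = cohort,
       grid = grid, seed = cfg$seed)
}

# djb2 string hash, rendered in hex; used only to make reruns attributable.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

writeWithProvenance <- function(d, path, sep = "\t", seed = NULL,
                                config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("serodyn")),
                  error = function(e) "dev")
  hdr <- c(paste0("# serodyn ", ver),
           paste0("# seed: ", if (is.null(seed)) "none" else seed),
           paste0("# config_hash: ", configHash(config)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(d, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Columns `time_h` plus the eight species (uM) in fixed order, preceded by
#' provenance header comments.
#'
#' @param traj a `serodyn_trajectory`.
#' @param path output path.
#' @param seed,config recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path, seed = NULL, config = NULL) {
  d <- data.frame(time_h = traj$times, traj$conc, check.names = FALSE)
  writeWithProvenance(d, path, sep = ",", seed = seed, config = config)
}

#' Write cohort species-mean summaries as CSV
#'
#' One row per individual with the per-species time means in uM and, for the
#' five serotonin-branch species, additional nanomolar columns
#' (`<species>_mean_nM`).
#'
#' @param summaries output of [simulateCohort()].
#' @param path output path.
#' @param seed,config recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeSummaryCSV <- function(summaries, path, seed = NULL, config = NULL) {
  d <- summaries
  for (sp in c("htp5", "fc5ht", "v5ht", "e5ht", "hiaa5")) {
    d[[paste0(sp, "_mean_nM")]] <- 1000 * d[[paste0(sp, "_mean")]]
  }
  writeWithProvenance(d, path, sep = ",", seed = seed, config = config)
}

#' Write a group-comparison table as CSV
#'
#' @param comparisons output of [compareGroups()].
#' @param path output path.
#' @param seed,config recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeComparisonCSV <- function(comparisons, path, seed = NULL,
                               config = NULL) {
  writeWithProvenance(comparisons, path, sep = ",", seed = seed,
                      config = config)
}
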