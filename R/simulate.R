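# Fast unchecked right-hand side used inside the integrator. Clamps tiny
# solver undershoots below zero before evaluating the rate laws; must agree
# with odeRHS() on non-negative states (asserted in the test suite).
.rhsDeSolve <- function(t, y, parms) {
  p <- parms$p
  v <- parms$v
  y <- pmax(y, 0)
  trp_serum <- y[[1L]]; trp <- y[[2L]]; trp_pool <- y[[3L]]
  htp5 <- y[[4L]]; fc5ht <- y[[5L]]; v5ht <- y[[6L]]
  e5ht <- y[[7L]]; hiaa5 <- y[[8L]]
  v_trpin <- p$vmax_trpin * trp_serum / (p$km_trpin + trp_serum)
  v_pool_forward <- p$k1 * trp
  v_pool_reverse <- p$k_minus1 *
    (if (p$pool_reverse_substrate == "trp") trp else trp_pool)
  v_tph2 <- v[[1L]] * trp / (p$km_tph2 + trp)
  v_aadc <- p$vmax_aadc * htp5 / (p$km_aadc + htp5)
  v_vmat <- p$vmax_vmat * fc5ht / (p$km_vmat + fc5ht)
  v_release <- if (p$release_kinetics == "first_order") {
    p$k_release * v5ht
  } else if (v5ht > 0) p$k_release else 0
  v_sert <- v[[2L]] * e5ht / (p$km_sert + e5ht)
  v_maoa <- v[[3L]] * fc5ht / (p$km_maoa + fc5ht)
  leak <- p$k_out * v5ht
  list(c(-v_trpin,
         v_trpin - v_pool_forward + v_pool_reverse -
           p$k_trp_removal * trp - v_tph2,
         v_pool_forward - v_pool_reverse - p$k_pool_removal * trp_pool,
         v_tph2 - v_aadc,
         v_aadc - v_vmat + leak + v_sert - v_maoa,
         v_vmat - leak - v_release,
         v_release - v_sert - p$k_5ht_removal * e5ht,
         v_maoa - p$k_hiaa_removal * hiaa5))
}

#' Integrate the model for one individual
#'
#' Solves the eight differential equations from the initial condition (all
#' species zero except serum tryptophan at `params$trp_serum_init`) over a
#' fixed output grid, by default 0 to 3 hours in steps of 0.01 h. The default
#' integrator is lsoda, a stiff-capable adaptive solver; the output grid only
#' sets where the solution is reported, not the internal step. Species values
#' above -1e-9 uM (solver noise near zero) are clipped to 0; anything more
#' negative raises an integration error.
#'
#' @param vmaxes a [vmaxSet()] of genotype-dependent maximal rates.
#' @param params a [modelParameters()] object.
#' @param t_max simulation horizon in hours.
#' @param dt output grid spacing in hours.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param method integration method passed to [deSolve::ode()] (`"lsoda"` by
#'   default; `"rk4"` gives a fixed-step 4th-order explicit reference
#'   integration when combined with a small `dt`).
#' @param sample_id optional identifier carried into error messages.
#' @return Object of class `serodyn_trajectory`: list with `times` (hours)
#'   and `conc` (matrix, time by the eight species of [speciesNames()], uM).
#' @export
#' @examples
#' traj <- simulateIndividual(vmaxSet(1700, 100, 60))
#' head(traj$conc)
simulateIndividual <- function(vmaxes, params = modelParameters(),
                               t_max = 3, dt = 0.01,
                               rtol = 1e-8, atol = 1e-12,
                               method = "lsoda", sample_id = NULL) {
  if (t_max <= 0 || dt <= 0) stop("t_max and dt must be positive")
  validateParameters(params)
  times <- seq(0, t_max, by = dt)
  y0 <- stats::setNames(c(params$trp_serum_init, rep(0, 7)), speciesNames())
  v <- c(vmaxes[["tph2"]], vmaxes[["sert"]], vmaxes[["maoa"]])
  sol <- try(deSolve::ode(y = y0, times = times, func = .rhsDeSolve,
                          parms = list(p = params, v = v),
                          method = method, rtol = rtol, atol = atol),
             silent = TRUE)
  id <- if (is.null(sample_id)) "" else paste0(" for sample ", sample_id)
  if (inherits(sol, "try-error") || nrow(sol) < length(times)) {
    stop("ODE integration failed", id)
  }
  conc <- unclass(sol)[, speciesNames(), drop = FALSE]
  if (min(conc) < -1e-9) {
    stop("integration produced concentrations below -1e-9 uM", id,
         " (min ", format(min(conc)), "); tighten tolerances")
  }
  conc[conc < 0] <- 0
  structure(list(times = times, conc = conc, params = params,
                 vmaxes = vmaxes, method = method, rtol = rtol, atol = atol),
            class = "serodyn_trajectory")
}

#' @export
print.serodyn_trajectory <- function(x, ...) {
  cat("serodyn trajectory:", length(x$times), "time points on [",
      min(x$times), ",", max(x$times), "] h\n")
  cat("final concentrations (uM):\n")
  print(round(x$conc[nrow(x$conc), ], 6))
  invisible(x)
}

#' Reduce a trajectory to per-species time-mean concentrations
#'
#' Arithmetic mean of each species over all output grid rows, the
#' individual-level summary the group comparisons operate on. The t = 0 row
#' is included by default ("across all time points"); excluding it shifts
#' each mean by at most 1/n of the species range.
#'
#' @param traj a `serodyn_trajectory`.
#' @param include_t0 include the initial-condition row in the mean.
#' @return Named numeric vector `<species>_mean` (uM) over the eight species.
#' @export
summarizeTrajectory <- function(traj, include_t0 = TRUE) {
  stopifnot(inherits(traj, "serodyn_trajectory"))
  conc <- traj$conc
  if (nrow(conc) == 0) stop("empty trajectory")
  if (!include_t0 && nrow(conc) > 1) conc <- conc[-1, , drop = FALSE]
  m <- colMeans(conc)
  stats::setNames(m, paste0(speciesNames(), "_mean"))
}

#' Simulate a whole cohort and summarise each individual
#'
#' Maps each genotype to its maximal rates, integrates the model and reduces
#' each trajectory to per-species time means. Individuals are independent;
#' the result is a pure function of genotypes and parameters (identical
#' genotypes give identical rows). Integrations are cached per distinct
#' maximal-rate triple, so large cohorts cost one solve per distinct
#' genotype class.
#'
#' @param genotypes a genotype table ([sampleCohort()] /
#'   [readGenotypeTable()]) or a list of [genotypeRecord()]s.
#' @param params a [modelParameters()] object.
#' @param defs a [variantDefs()] table.
#' @param expr a [proteinExpression()] table.
#' @param scale a [vmaxScale()] vector.
#' @param include_t0 passed to [summarizeTrajectory()].
#' @param ... further arguments to [simulateIndividual()].
#' @return `data.frame` with `sample_id`, `sex`, `group`, the three maximal
#'   rates and one `<species>_mean` column (uM) per species. If some
#'   individuals fail to integrate, their ids are attached as
#'   `attr(, "failures")` and a warning is raised; the remaining rows are
#'   returned.
#' @export
simulateCohort <- function(genotypes, params = modelParameters(),
                           defs = variantDefs(), expr = proteinExpression(),
                           scale = vmaxScale(), include_t0 = TRUE, ...) {
  records <- if (inherits(genotypes, "data.frame")) {
    lapply(seq_len(nrow(genotypes)), function(i) {
      asGenotypeRecord(genotypes, i, defs = defs)
    })
  } else {
    genotypes
  }
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(records))
  failures <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    res <- tryCatch({
      v <- vmaxFromGenotype(rec, expr = expr, defs = defs, scale = scale)
      key <- paste(format(v, digits = 15), collapse = "|")
      means <- if (!is.null(cache[[key]])) {
        cache[[key]]
      } else {
        traj <- simulateIndividual(v, params = params,
                                   sample_id = rec$sample_id, ...)
        m <- summarizeTrajectory(traj, include_t0 = include_t0)
        cache[[key]] <- m
        m
      }
      cbind(data.frame(sample_id = rec$sample_id, sex = rec$sex,
                       group = rec$group,
                       vmax_tph2 = v[["tph2"]], vmax_sert = v[["sert"]],
                       vmax_maoa = v[["maoa"]], stringsAsFactors = FALSE),
            as.data.frame(as.list(means)))
    }, error = function(e) {
      structure(conditionMessage(e), class = "serodyn_failure")
    })
    if (inherits(res, "serodyn_failure")) {
      failures <- c(failures, stats::setNames(unclass(res), rec$sample_id))
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(failures) > 0) {
    warning(length(failures), " individual(s) failed to integrate: ",
            paste(names(failures), collapse = ", "))
    attr(out, "failures") <- failures
  }
  out
}

#' Mass-balance audit of a trajectory
#'
#' All transfer fluxes cancel pairwise, so at every time the current total
#' concentration plus the cumulative removal (time integral of the four
#' removal fluxes, trapezoidal rule on the output grid) must equal the
#' initial serum tryptophan input. Returns the worst relative discrepancy
#' over the grid.
#'
#' @param traj a `serodyn_trajectory`.
#' @param params the [modelParameters()] used for the simulation (defaults to
#'   those stored in the trajectory).
#' @return Maximum absolute relative closure error (dimensionless).
#' @export
massAudit <- function(traj, params = traj$params) {
  conc <- traj$conc
  removal <- params$k_trp_removal * conc[, "trp"] +
    params$k_pool_removal * conc[, "trp_pool"] +
    params$k_5ht_removal * conc[, "e5ht"] +
    params$k_hiaa_removal * conc[, "hiaa5"]
  dtimes <- diff(traj$times)
  cum <- c(0, cumsum(dtimes * (removal[-1] + removal[-length(removal)]) / 2))
  closure <- rowSums(conc) + cum
  max(abs(closure / params$trp_serum_init - 1))
}

#' The all-reference genotype record
#'
#' Convenience constructor for the individual homozygous for the reference
#' allele at every locus (A/A, T/T, G/G, L/L, 4R high-expression); every
#' genotype correction equals 2 for this record.
#'
#' @param sex `"female"` (default) or `"male"`.
#' @param group group label.
#' @param defs a [variantDefs()] table.
#' @return A [genotypeRecord()].
#' @export
referenceGenotype <- function(sex = "female", group = "unaffected",
                              defs = variantDefs()) {
  uv <- if (identical(sex, "male")) "4R" else c("4R", "4R")
  genotypeRecord("reference", sex, group,
                 list(rs11178998 = c("A", "A"), rs4290270 = c("T", "T"),
                      rs7305115 = c("G", "G"), HTTLPR = c("L", "L"),
                      uVNTR = uv),
                 defs = defs)
}
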