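#' Fixed species ordering of the model
#'
#' The eight molecular species tracked by the presynapse model, in the order
#' used everywhere (state vectors, trajectory columns, summaries): serum
#' tryptophan, tryptophan available for synthesis, the cellular tryptophan
#' pool, 5-hydroxytryptophan, free cellular serotonin, vesicular serotonin,
#' extracellular serotonin, and 5-hydroxy-3-indolacetic acid.
#'
#' @return Character vector of the eight species names.
#' @export
speciesNames <- function() {
  c("trp_serum", "trp", "trp_pool", "htp5", "fc5ht", "v5ht", "e5ht", "hiaa5")
}

#' Construct a model state vector
#'
#' A named non-negative concentration vector (micromolar) over the eight
#' species in the fixed order of [speciesNames()].
#'
#' @param trp_serum,trp,trp_pool,htp5,fc5ht,v5ht,e5ht,hiaa5 concentrations in
#'   micromolar; all must be finite and non-negative.
#' @return Named numeric vector of length 8, class `serodyn_state`.
#' @export
#' @examples
#' stateVector(trp_serum = 100)
stateVector <- function(trp_serum = 0, trp = 0, trp_pool = 0, htp5 = 0,
                        fc5ht = 0, v5ht = 0, e5ht = 0, hiaa5 = 0) {
  s <- c(trp_serum = trp_serum, trp = trp, trp_pool = trp_pool, htp5 = htp5,
         fc5ht = fc5ht, v5ht = v5ht, e5ht = e5ht, hiaa5 = hiaa5)
  if (any(!is.finite(s))) stop("state concentrations must be finite")
  if (any(s < 0)) stop("state concentrations must be non-negative")
  class(s) <- c("serodyn_state", "numeric")
  s
}

#' Kinetic parameters of the presynaptic serotonin model
#'
#' All fixed kinetic constants of the model. Defaults are the published
#' constants of the presynapse model: Michaelis constants (Km, uM), fixed
#' maximal rates (Vmax, uM/h) for the tryptophan transporter, AADC and VMAT,
#' and first-order mass-action constants (1/h) for pool exchange, vesicular
#' leak, exocytosis and the removal processes. The maximal rates of TPH2,
#' SERT and MAOA are genotype-dependent and live in a [vmaxSet()], not here.
#'
#' Two structural switches cover ambiguities of the source model:
#' `pool_reverse_substrate` selects the substrate of the pool-leak flux
#' (`"trp"`, the literal published rate law, or `"trp_pool"`, the
#' mass-balance-intuitive alternative), and `release_kinetics` selects
#' first-order exocytosis (`"first_order"`, the published rate law
#' V = k_release x [v5-HT]) or a constant-flux alternative (`"zero_order"`,
#' k_release uM/h while vesicular serotonin is present).
#'
#' @param km_trpin,vmax_trpin Trp transporter Michaelis constant (uM) and
#'   maximal rate (uM/h).
#' @param k1,k_minus1 forward/reverse tryptophan-pool exchange constants (1/h).
#' @param k_pool_removal,k_trp_removal first-order removal of pool and free
#'   tryptophan (1/h).
#' @param km_tph2 TPH2 Michaelis constant for tryptophan (uM).
#' @param km_aadc,vmax_aadc AADC Michaelis constant (uM) and maximal rate
#'   (uM/h).
#' @param km_vmat,vmax_vmat VMAT Michaelis constant (uM) and maximal rate
#'   (uM/h).
#' @param k_out vesicular leak constant (1/h).
#' @param k_release exocytosis constant (1/h first-order; uM/h if
#'   `release_kinetics = "zero_order"`).
#' @param km_sert SERT Michaelis constant (uM; sex-averaged).
#' @param km_maoa MAOA Michaelis constant (uM).
#' @param k_5ht_removal first-order removal of extracellular serotonin (1/h).
#' @param k_hiaa_removal first-order removal of 5-HIAA (1/h).
#' @param trp_serum_init initial serum tryptophan input (uM).
#' @param pool_reverse_substrate substrate of the pool-leak flux.
#' @param release_kinetics exocytosis rate-law form.
#' @return Named list of class `serodyn_params`.
#' @export
#' @examples
#' p <- modelParameters()
#' p$km_tph2
modelParameters <- function(km_trpin = 64, vmax_trpin = 400,
                            k1 = 6, k_minus1 = 0.6,
                            k_pool_removal = 0.2, k_trp_removal = 0.2,
                            km_tph2 = 44,
                            km_aadc = 160, vmax_aadc = 400,
                            km_vmat = 19, vmax_vmat = 3500,
                            k_out = 40, k_release = 20,
                            km_sert = 0.2605, km_maoa = 86,
                            k_5ht_removal = 400, k_hiaa_removal = 1,
                            trp_serum_init = 100,
                            pool_reverse_substrate = c("trp", "trp_pool"),
                            release_kinetics = c("first_order", "zero_order")) {
  p <- list(km_trpin = km_trpin, vmax_trpin = vmax_trpin,
            k1 = k1, k_minus1 = k_minus1,
            k_pool_removal = k_pool_removal, k_trp_removal = k_trp_removal,
            km_tph2 = km_tph2,
            km_aadc = km_aadc, vmax_aadc = vmax_aadc,
            km_vmat = km_vmat, vmax_vmat = vmax_vmat,
            k_out = k_out, k_release = k_release,
            km_sert = km_sert, km_maoa = km_maoa,
            k_5ht_removal = k_5ht_removal, k_hiaa_removal = k_hiaa_removal,
            trp_serum_init = trp_serum_init,
            pool_reverse_substrate = match.arg(pool_reverse_substrate),
            release_kinetics = match.arg(release_kinetics))
  validateParameters(p)
  class(p) <- "serodyn_params"
  p
}

validateParameters <- function(p) {
  kms <- c("km_trpin", "km_tph2", "km_aadc", "km_vmat", "km_sert", "km_maoa")
  rates <- c("vmax_trpin", "k1", "k_minus1", "k_pool_removal",
             "k_trp_removal", "vmax_aadc", "vmax_vmat", "k_out", "k_release",
             "k_5ht_removal", "k_hiaa_removal")
  num <- unlist(p[c(kms, rates, "trp_serum_init")])
  if (any(!is.finite(num))) stop("all kinetic parameters must be finite")
  if (any(unlist(p[kms]) <= 0)) stop("all Km values must be > 0")
  if (any(unlist(p[rates]) < 0)) stop("all rate constants must be >= 0")
  if (p$trp_serum_init <= 0) stop("trp_serum_init must be > 0")
  invisible(p)
}

#' @export
print.serodyn_params <- function(x, ...) {
  cat("Presynaptic serotonin model parameters\n")
  num <- x[vapply(x, is.numeric, logical(1))]
  cat(paste0("  ", format(names(num), width = 16), format(unlist(num)),
             collapse = "\n"), "\n")
  cat("  pool reverse substrate:", x$pool_reverse_substrate,
      "| release kinetics:", x$release_kinetics, "\n")
  invisible(x)
}

#' Genotype-dependent maximal rates
#'
#' Bundles the three maximal reaction rates (uM/h) that depend on an
#' individual's genotype: serotonin synthesis (TPH2), reuptake (SERT) and
#' degradation (MAOA).
#'
#' @param tph2,sert,maoa maximal rates in uM/h, each >= 0.
#' @return Named numeric vector of class `serodyn_vmax`.
#' @export
vmaxSet <- function(tph2, sert, maoa) {
  v <- c(tph2 = tph2, sert = sert, maoa = maoa)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("maximal rates must be finite and non-negative")
  }
  class(v) <- c("serodyn_vmax", "numeric")
  v
}
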