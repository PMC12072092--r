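#' Michaelis-Menten rate law
#'
#' V = Vmax * S / (Km + S). Bounded above by `vmax`, monotone non-decreasing
#' in the substrate concentration.
#'
#' @param vmax maximal rate (uM/h), >= 0.
#' @param km Michaelis constant (uM), > 0.
#' @param s substrate concentration (uM), >= 0. Vectorised.
#' @return Flux in uM/h.
#' @export
#' @examples
#' michaelisMentenRate(400, 64, 100)  # 243.9024
michaelisMentenRate <- function(vmax, km, s) {
  if (any(vmax < 0)) stop("vmax must be non-negative")
  if (any(km <= 0)) stop("km must be positive")
  if (any(s < 0)) stop("substrate concentration must be non-negative")
  vmax * s / (km + s)
}

#' Mass-action (first-order) rate law
#'
#' V = k * S.
#'
#' @param k rate constant (1/h), >= 0.
#' @param s substrate concentration (uM), >= 0. Vectorised.
#' @return Flux in uM/h.
#' @export
#' @examples
#' massActionRate(20, 2.5)  # 50
massActionRate <- function(k, s) {
  if (any(k < 0)) stop("rate constant must be non-negative")
  if (any(s < 0)) stop("substrate concentration must be non-negative")
  k * s
}

#' Evaluate all reaction and removal fluxes at one state
#'
#' Computes every flux of the model at a given state: tryptophan transport
#' (Michaelis-Menten on serum Trp), pool exchange (first-order), TPH2, AADC,
#' VMAT, SERT and MAOA (Michaelis-Menten), exocytotic release (first-order by
#' default) and the four removal fluxes.
#'
#' Note the published pool-leak rate law is first-order in free tryptophan,
#' not in the pool itself; `params$pool_reverse_substrate` switches between
#' the two readings.
#'
#' @param state non-negative state vector over [speciesNames()].
#' @param params a [modelParameters()] object.
#' @param vmaxes a [vmaxSet()] of genotype-dependent maximal rates.
#' @return Named numeric vector of fluxes (uM/h): `v_trpin`,
#'   `v_pool_forward`, `v_pool_reverse`, `v_tph2`, `v_aadc`, `v_vmat`,
#'   `v_release`, `v_sert`, `v_maoa`, `r_trp`, `r_pool`, `r_e5ht`, `r_hiaa`.
#' @export
reactionRates <- function(state, params, vmaxes) {
  s <- state[speciesNames()]
  if (any(is.na(s))) stop("state must be named over speciesNames()")
  rev_sub <- if (params$pool_reverse_substrate == "trp") {
    s[["trp"]]
  } else {
    s[["trp_pool"]]
  }
  v_release <- if (params$release_kinetics == "first_order") {
    massActionRate(params$k_release, s[["v5ht"]])
  } else {
    if (s[["v5ht"]] > 0) params$k_release else 0
  }
  c(v_trpin = michaelisMentenRate(params$vmax_trpin, params$km_trpin,
                                  s[["trp_serum"]]),
    v_pool_forward = massActionRate(params$k1, s[["trp"]]),
    v_pool_reverse = massActionRate(params$k_minus1, rev_sub),
    v_tph2 = michaelisMentenRate(vmaxes[["tph2"]], params$km_tph2,
                                 s[["trp"]]),
    v_aadc = michaelisMentenRate(params$vmax_aadc, params$km_aadc,
                                 s[["htp5"]]),
    v_vmat = michaelisMentenRate(params$vmax_vmat, params$km_vmat,
                                 s[["fc5ht"]]),
    v_release = v_release,
    v_sert = michaelisMentenRate(vmaxes[["sert"]], params$km_sert,
                                 s[["e5ht"]]),
    v_maoa = michaelisMentenRate(vmaxes[["maoa"]], params$km_maoa,
                                 s[["fc5ht"]]),
    r_trp = massActionRate(params$k_trp_removal, s[["trp"]]),
    r_pool = massActionRate(params$k_pool_removal, s[["trp_pool"]]),
    r_e5ht = massActionRate(params$k_5ht_removal, s[["e5ht"]]),
    r_hiaa = massActionRate(params$k_hiaa_removal, s[["hiaa5"]]))
}

#' Right-hand side of the eight model differential equations
#'
#' Time derivatives (uM/h) of the eight species. Every non-removal flux is a
#' pairwise transfer between species, so the derivatives sum to minus the
#' total removal flux (mass conservation with sinks).
#'
#' @inheritParams reactionRates
#' @return Named numeric vector of length 8 (d concentration / dt, uM/h) in
#'   the order of [speciesNames()].
#' @export
#' @examples
#' odeRHS(stateVector(trp_serum = 100), modelParameters(), vmaxSet(1, 1, 1))
odeRHS <- function(state, params, vmaxes) {
  v <- reactionRates(state, params, vmaxes)
  leak <- params$k_out * state[["v5ht"]]
  c(trp_serum = -v[["v_trpin"]],
    trp = v[["v_trpin"]] - v[["v_pool_forward"]] + v[["v_pool_reverse"]] -
      v[["r_trp"]] - v[["v_tph2"]],
    trp_pool = v[["v_pool_forward"]] - v[["v_pool_reverse"]] - v[["r_pool"]],
    htp5 = v[["v_tph2"]] - v[["v_aadc"]],
    fc5ht = v[["v_aadc"]] - v[["v_vmat"]] + leak + v[["v_sert"]] -
      v[["v_maoa"]],
    v5ht = v[["v_vmat"]] - leak - v[["v_release"]],
    e5ht = v[["v_release"]] - v[["v_sert"]] - v[["r_e5ht"]],
    hiaa5 = v[["v_maoa"]] - v[["r_hiaa"]])
}
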