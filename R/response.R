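# Dose-response assembly: endpoint probability, TD50 and iso-effect
# solvers, the TD50-ratio dose-rate correction factor, and the three RBE
# definitions (fixed-reference, dose-rate adapted, no-repair).

#' Photon survival under selectable engine
#'
#' Dispatches to the exact per-domain expectation (deterministic) or the
#' Monte Carlo engine (with a per-evaluation seed, giving common random
#' numbers across iso-effect solves).
#'
#' @param dose Dose, Gy.
#' @param dose_rate Dose rate, Gy/min (`Inf` = acute).
#' @param params,nucleus Model inputs.
#' @param engine `"exact"` or `"mc"`.
#' @param n_iter MC iterations (engine `"mc"`).
#' @param seed Seed applied before each MC evaluation.
#' @param n_timesteps Delivery time-steps.
#' @return Mean survival (scalar).
#' @export
photon_survival <- function(dose, dose_rate, params, nucleus,
                            engine = c("exact", "mc"), n_iter = 1e4,
                            seed = NULL, n_timesteps = 100) {
  engine <- match.arg(engine)
  if (engine == "exact")
    return(photon_survival_timed_exact(dose, dose_rate, params, nucleus,
                                       n_timesteps = n_timesteps))
  if (!is.finite(dose_rate))
    return(simulate_photon_acute(dose, params, nucleus, n_iter,
                                 seed = seed)$mean)
  simulate_photon_timed(
    irradiation_protocol(dose, dose_rate, n_timesteps = n_timesteps),
    params, nucleus, n_iter, seed = seed)$mean
}

#' Endpoint probability of a fractionated delivery
#'
#' Fractions are simulated independently with equal doses and survivals
#' multiplied (complete inter-fraction damage resolution), and the
#' endpoint probability is `P = 1 - S_total`: the lethality parameters
#' are read as per-damage probabilities of triggering the endpoint.
#'
#' @param total_dose Total dose over all fractions, Gy.
#' @param protocol An [irradiation_protocol()] supplying dose rate,
#'   fraction count, time-steps and (optionally) the particle; its `dose`
#'   field is ignored in favour of `total_dose`.
#' @param params,nucleus Model inputs.
#' @param engine Photon engine selector (`"exact"` or `"mc"`); ion
#'   protocols always use the MC engines.
#' @param n_iter MC iterations per fraction simulation.
#' @param seed Seed applied before each stochastic evaluation.
#' @param setup Optional [ion_track_setup()] for ion protocols.
#' @return Endpoint probability in \[0, 1\].
#' @export
endpoint_probability <- function(total_dose, protocol, params, nucleus,
                                 engine = c("exact", "mc"), n_iter = 1e4,
                                 seed = NULL, setup = NULL) {
  stopifnot(inherits(protocol, "irradiation_protocol"))
  engine <- match.arg(engine)
  if (total_dose < 0) stop("total_dose must be >= 0")
  if (total_dose == 0) return(0)
  d_frac <- total_dose / protocol$n_fractions
  if (is.null(protocol$particle)) {
    s_frac <- photon_survival(d_frac, protocol$dose_rate, params, nucleus,
                              engine = engine, n_iter = n_iter,
                              seed = seed,
                              n_timesteps = protocol$n_timesteps)
  } else {
    frac_proto <- irradiation_protocol(d_frac, protocol$dose_rate,
                                       n_timesteps = protocol$n_timesteps,
                                       particle = protocol$particle)
    s_frac <- if (is.finite(protocol$dose_rate))
      simulate_ion_timed(frac_proto, params, nucleus, n_iter,
                         seed = seed, setup = setup)$mean
    else
      simulate_ion_acute(frac_proto, params, nucleus, n_iter,
                         seed = seed, setup = setup)$mean
  }
  1 - s_frac^protocol$n_fractions
}

#' Solve the TD50 of a photon protocol
#'
#' Bisection on total dose for the 50% endpoint-probability level. With
#' the MC engine every evaluation reuses the same seed (common random
#' numbers) so the bisected function is deterministic; the initial
#' bracket is expanded (up to 60 doublings) until it straddles 0.5.
#'
#' @param params,nucleus Model inputs.
#' @param dose_rate Dose rate, Gy/min (`Inf` = acute).
#' @param n_fractions Number of equal fractions; the TD50 is a total dose.
#' @param engine,n_iter,seed Passed to [endpoint_probability()].
#' @param n_timesteps Delivery time-steps per fraction.
#' @param tol Bracket width at which bisection stops, Gy (default 0.05).
#' @param bracket Initial dose bracket, Gy.
#' @return A `td50_result`.
#' @export
solve_td50 <- function(params, nucleus, dose_rate = Inf, n_fractions = 1,
                       engine = c("exact", "mc"), n_iter = 1e4,
                       seed = NULL, n_timesteps = 100, tol = 0.05,
                       bracket = c(1, 30)) {
  engine <- match.arg(engine)
  if (tol <= 0) stop("tol must be > 0")
  proto <- irradiation_protocol(1, dose_rate, n_fractions = n_fractions,
                                n_timesteps = n_timesteps)
  pfun <- function(d) endpoint_probability(d, proto, params, nucleus,
                                           engine = engine,
                                           n_iter = n_iter, seed = seed)
  lo <- bracket[1]; hi <- bracket[2]
  p_lo <- pfun(lo); p_hi <- pfun(hi)
  n_dbl <- 0
  while (p_hi < 0.5) {
    lo <- hi; p_lo <- p_hi
    hi <- hi * 2; p_hi <- pfun(hi)
    n_dbl <- n_dbl + 1
    if (n_dbl > 60) stop("could not bracket the 50% effect level from above")
  }
  while (p_lo > 0.5) {
    hi <- lo; p_hi <- p_lo
    lo <- lo / 2; p_lo <- pfun(lo)
    n_dbl <- n_dbl + 1
    if (n_dbl > 60) stop("could not bracket the 50% effect level from below")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pfun(mid) < 0.5) lo <- mid else hi <- mid
  }
  structure(
    list(td50 = (lo + hi) / 2, dose_rate = dose_rate,
         n_fractions = as.integer(n_fractions), tol = tol,
         engine = engine, n_iter = if (engine == "mc") as.integer(n_iter)
                                   else NA_integer_,
         n_timesteps = as.integer(n_timesteps), seed = seed),
    class = "td50_result")
}

#' @export
print.td50_result <- function(x, ...) {
  cat(sprintf(
    "TD50 = %.4g Gy total (%d fraction(s), %s Gy/min, +/- %.3g Gy bracket, %s engine)\n",
    x$td50, x$n_fractions, format(x$dose_rate), x$tol / 2, x$engine))
  invisible(x)
}

#' TD50 ratio between a reference and a given photon dose rate
#'
#' The dose-rate correction factor `R_TD50 =
#' TD50(ref_rate) / TD50(dose_rate)` of the photon reference radiation at
#' matched fractionation: delivering faster leaves less time for repair,
#' lowers the TD50, and pushes the ratio above 1.
#'
#' @param dose_rate Dose rate of interest, Gy/min.
#' @param ref_rate Reference dose rate, Gy/min (default 3.75).
#' @param n_fractions Number of equal fractions.
#' @param params,nucleus Model inputs.
#' @param ... Engine settings handed to [solve_td50()] (both solves share
#'   them, including the seed: common random numbers).
#' @return Dimensionless ratio.
#' @export
r_td50 <- function(dose_rate, ref_rate = 3.75, n_fractions = 1, params,
                   nucleus, ...) {
  if (dose_rate <= 0 || ref_rate <= 0) stop("dose rates must be > 0")
  ref <- solve_td50(params, nucleus, dose_rate = ref_rate,
                    n_fractions = n_fractions, ...)
  cur <- solve_td50(params, nucleus, dose_rate = dose_rate,
                    n_fractions = n_fractions, ...)
  ref$td50 / cur$td50
}

# solve the photon dose reproducing a target survival at a given rate
photon_isoeffect_dose <- function(target_survival, dose_rate, params,
                                  nucleus, engine = "exact", n_iter = 1e4,
                                  seed = NULL, n_timesteps = 100,
                                  tol = 0.02) {
  if (!is.finite(target_survival) || target_survival <= 0 ||
      target_survival >= 1)
    stop("effect level outside the achievable photon range (0 < S < 1)")
  sfun <- function(d) photon_survival(d, dose_rate, params, nucleus,
                                      engine = engine, n_iter = n_iter,
                                      seed = seed,
                                      n_timesteps = n_timesteps)
  lo <- 0; hi <- 2
  s_hi <- sfun(hi)
  n_dbl <- 0
  while (s_hi > target_survival) {
    lo <- hi
    hi <- hi * 2; s_hi <- sfun(hi)
    n_dbl <- n_dbl + 1
    if (n_dbl > 60)
      stop("effect level outside the achievable photon range")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sfun(mid) > target_survival) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

new_rbe_result <- function(value, definition, ion_dose, ion_rate,
                           ref_rate, effect_level, photon_dose) {
  structure(list(value = value, definition = definition,
                 ion_dose = ion_dose, ion_rate = ion_rate,
                 ref_rate = ref_rate, effect_level = effect_level,
                 photon_dose = photon_dose),
            class = "rbe_result")
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("RBE (%s) = %.4g\n", x$definition, x$value))
  cat(sprintf("  ion: %.4g Gy at %s Gy/min; photon iso-dose %.4g Gy at %s Gy/min; effect level %.4g\n",
              x$ion_dose, format(x$ion_rate), x$photon_dose,
              format(x$ref_rate), x$effect_level))
  invisible(x)
}

rbe_generic <- function(ion_dose, ion_rate, ref_rate, particle, params,
                        nucleus, definition, n_iter, seed, setup,
                        photon_engine, n_timesteps, tol, sigma,
                        enhancement) {
  if (ion_dose <= 0) stop("ion_dose must be > 0")
  if (is.null(setup))
    setup <- ion_track_setup(particle, nucleus, sigma = sigma,
                             enhancement = enhancement)
  proto <- irradiation_protocol(ion_dose, ion_rate,
                                n_timesteps = n_timesteps,
                                particle = setup$particle)
  est <- if (is.finite(ion_rate))
    simulate_ion_timed(proto, params, nucleus, n_iter, seed = seed,
                       setup = setup)
  else
    simulate_ion_acute(proto, params, nucleus, n_iter, seed = seed,
                       setup = setup)
  s_ion <- est$mean
  if (s_ion <= 0 || s_ion >= 1)
    stop("ion effect level outside the achievable photon range; ",
         "increase n_iter or adjust the dose")
  d_gamma <- photon_isoeffect_dose(s_ion, ref_rate, params, nucleus,
                                   engine = photon_engine,
                                   n_iter = n_iter, seed = seed,
                                   n_timesteps = n_timesteps, tol = tol)
  new_rbe_result(d_gamma / ion_dose, definition, ion_dose, ion_rate,
                 ref_rate, 1 - s_ion, d_gamma)
}

#' Fixed-reference RBE
#'
#' Ratio of the photon dose at a fixed reference dose rate to the ion
#' dose at its own dose rate producing the same effect level — the
#' situation of most RBE measurements, where the reference irradiation
#' runs at a constant (usually low) dose rate.
#'
#' @param ion_dose Ion dose, Gy.
#' @param ion_rate Ion dose rate, Gy/min (`Inf` = acute).
#' @param ref_rate Photon reference dose rate, Gy/min (default 2).
#' @param particle A [particle_state()] (ignored when `setup` given).
#' @param params,nucleus Model inputs.
#' @param n_iter MC iterations for the ion simulation (default 1e4).
#' @param seed Optional integer seed.
#' @param setup Optional [ion_track_setup()].
#' @param photon_engine `"exact"` (deterministic iso-effect solve,
#'   default) or `"mc"`.
#' @param n_timesteps Delivery time-steps.
#' @param tol Photon iso-dose bisection tolerance, Gy.
#' @param sigma,enhancement Track setup options when `setup` is absent.
#' @return An `rbe_result` tagged `fixed_reference`.
#' @export
rbe_fixed_reference <- function(ion_dose, ion_rate, ref_rate = 2,
                                particle = NULL, params, nucleus,
                                n_iter = 1e4, seed = NULL, setup = NULL,
                                photon_engine = "exact",
                                n_timesteps = 100, tol = 0.02,
                                sigma = 0.004,
                                enhancement = enhancement_ssb_pairing()) {
  if (ref_rate <= 0) stop("ref_rate must be > 0")
  rbe_generic(ion_dose, ion_rate, ref_rate, particle, params, nucleus,
              "fixed_reference", n_iter, seed, setup, photon_engine,
              n_timesteps, tol, sigma, enhancement)
}

#' Dose-rate adapted RBE
#'
#' As [rbe_fixed_reference()], but the photon reference is delivered at
#' the same dose rate as the ion beam: the "intrinsic" relative efficacy
#' of the ion at that dose rate.
#'
#' @inheritParams rbe_fixed_reference
#' @return An `rbe_result` tagged `dose_rate_adapted`.
#' @export
rbe_dose_rate_adapted <- function(ion_dose, ion_rate, particle = NULL,
                                  params, nucleus, n_iter = 1e4,
                                  seed = NULL, setup = NULL,
                                  photon_engine = "exact",
                                  n_timesteps = 100, tol = 0.02,
                                  sigma = 0.004,
                                  enhancement = enhancement_ssb_pairing()) {
  rbe_generic(ion_dose, ion_rate, ion_rate, particle, params, nucleus,
              "dose_rate_adapted", n_iter, seed, setup, photon_engine,
              n_timesteps, tol, sigma, enhancement)
}

#' No-repair RBE
#'
#' Both modalities delivered acutely (instantaneously): the RBE expected
#' at infinite dose rates, where repair during irradiation is negligible.
#'
#' @inheritParams rbe_fixed_reference
#' @return An `rbe_result` tagged `no_repair`.
#' @export
rbe_no_repair <- function(ion_dose, particle = NULL, params, nucleus,
                          n_iter = 1e4, seed = NULL, setup = NULL,
                          photon_engine = "exact", n_timesteps = 100,
                          tol = 0.02, sigma = 0.004,
                          enhancement = enhancement_ssb_pairing()) {
  rbe_generic(ion_dose, Inf, Inf, particle, params, nucleus, "no_repair",
              n_iter, seed, setup, photon_engine, n_timesteps, tol,
              sigma, enhancement)
}

#' Mixed-field RBE approximation for SOBP positions
#'
#' The dose-rate dependent RBE at a spread-out-Bragg-peak position is
#' approximated as the no-repair RBE times the photon TD50 ratio
#' `R_TD50` — valid where the dose-rate adapted RBE is close to the
#' no-repair RBE (high dose rates).
#'
#' @param no_repair_rbe No-repair RBE (number or `rbe_result`).
#' @param r_td50 TD50 ratio (number).
#' @return An `rbe_result` tagged `sobp_approx`.
#' @export
rbe_sobp_approx <- function(no_repair_rbe, r_td50) {
  v <- if (inherits(no_repair_rbe, "rbe_result")) no_repair_rbe$value
       else no_repair_rbe
  if (v <= 0 || r_td50 <= 0) stop("both factors must be > 0")
  new_rbe_result(v * r_td50, "sobp_approx",
                 if (inherits(no_repair_rbe, "rbe_result"))
                   no_repair_rbe$ion_dose else NA,
                 Inf, NA, NA, NA)
}

#' Linear-quadratic parameter set
#'
#' @param alpha Linear coefficient, 1/Gy (>= 0).
#' @param beta Quadratic coefficient, 1/Gy^2 (>= 0).
#' @param dose_rate Dose rate tag, Gy/min (`Inf` for acute).
#' @return An object of class `lq_params`.
#' @export
lq_params <- function(alpha, beta, dose_rate = Inf) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, dose_rate = dose_rate),
            class = "lq_params")
}

#' Does the RBE of an acute vs. protracted comparison fall with dose?
#'
#' Within the linear-quadratic model the RBE of radiation delivered at an
#' infinite dose rate relative to the same quality at a fixed finite rate
#' decreases with increasing dose if and only if
#' `alpha_inf / alpha_ref > beta_inf / beta_ref`.
#'
#' @param lq_ref `lq_params` of the reference (finite) dose rate.
#' @param lq_inf `lq_params` of the acute limit.
#' @return `TRUE` if the RBE decreases with dose (strict inequality).
#' @export
lq_decreasing_rbe <- function(lq_ref, lq_inf) {
  stopifnot(inherits(lq_ref, "lq_params"), inherits(lq_inf, "lq_params"))
  if (lq_ref$alpha == 0 || lq_ref$beta == 0)
    stop("reference alpha and beta must be nonzero")
  (lq_inf$alpha / lq_ref$alpha) > (lq_inf$beta / lq_ref$beta)
}
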