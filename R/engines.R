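# Monte Carlo survival engines (R surface over the compiled cores) and
# the exact photon expectations used as oracles and fast solvers.

new_survival_estimate <- function(surv, n_iter, seed, protocol, engine) {
  structure(
    list(mean = mean(surv),
         se = stats::sd(surv) / sqrt(length(surv)),
         n_iter = as.integer(n_iter), seed = seed,
         protocol = protocol, engine = engine),
    class = "survival_estimate")
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat(sprintf("Survival estimate (%s): %.6g +/- %.2g (SE), %d iterations\n",
              x$engine, x$mean, x$se, x$n_iter))
  if (!is.null(x$protocol)) print(x$protocol)
  invisible(x)
}

#' Exact acute photon survival
#'
#' Closed-form expectation of the survival law under the acute photon
#' model: the total DSB count is Poisson with mean `alpha_dsb * dose`, and
#' uniform allocation makes per-domain counts iid Poisson with mean
#' `mu = alpha_dsb * dose / n_domains`, so
#' `E(S) = f^n_domains` with
#' `f = e^-mu + mu e^-mu (1-k_idsb) + (1 - e^-mu - mu e^-mu)(1-k_cdsb)`.
#'
#' @param dose Dose, Gy (>= 0); vectorised.
#' @param params An [endpoint_params()].
#' @param nucleus A [nucleus_model()] or domain count.
#' @return Expected survival in \[0, 1\].
#' @export
photon_survival_closed_form <- function(dose, params, nucleus) {
  stopifnot(inherits(params, "endpoint_params"))
  if (any(dose < 0)) stop("dose must be >= 0")
  n_dom <- if (inherits(nucleus, "nucleus_model")) nucleus$n_domains
           else as.integer(nucleus)
  mu <- params$alpha_dsb * dose / n_dom
  p0 <- exp(-mu)
  p1 <- mu * exp(-mu)
  f <- p0 + p1 * (1 - params$k_idsb) + (1 - p0 - p1) * (1 - params$k_cdsb)
  f^n_dom
}

#' Exact timed photon survival (per-domain recursion)
#'
#' Deterministic expectation of the time-resolved photon engine. Because
#' DSB are allocated uniformly, the domains evolve as independent,
#' identically distributed birth-death processes (Poisson arrivals per
#' tranche; exponential, memoryless repair; domain-local misrepair), so
#' the population survival is the per-domain expected survival factor
#' raised to the number of domains. The per-domain factor is propagated
#' through the `n_timesteps` deposit/repair steps over a truncated
#' occupancy state space. Serves both as the oracle for the Monte Carlo
#' timed engine and as a noise-free iso-effect solver.
#'
#' @param dose Dose, Gy.
#' @param dose_rate Dose rate, Gy/min; `Inf` falls back to
#'   [photon_survival_closed_form()].
#' @param params An [endpoint_params()].
#' @param nucleus A [nucleus_model()] or domain count.
#' @param n_timesteps Number of deposit/repair steps (default 100).
#' @return Expected survival in \[0, 1\].
#' @export
photon_survival_timed_exact <- function(dose, dose_rate, params, nucleus,
                                        n_timesteps = 100) {
  stopifnot(inherits(params, "endpoint_params"))
  if (dose < 0) stop("dose must be >= 0")
  n_dom <- if (inherits(nucleus, "nucleus_model")) nucleus$n_domains
           else as.integer(nucleus)
  if (dose == 0) return(1)
  if (!is.finite(dose_rate))
    return(photon_survival_closed_form(dose, params, nucleus))
  dt <- (dose / dose_rate) / n_timesteps
  mu_dom_part <- params$alpha_dsb * dose / (n_timesteps * n_dom)
  cpp_photon_timed_exact(n_dom, mu_dom_part, n_timesteps, dt,
                         params$k_idsb, params$k_cdsb,
                         params$t_half_idsb, params$t_half_cdsb)
}

#' Monte Carlo acute photon survival
#'
#' Samples the total DSB count from a Poisson distribution, allocates the
#' breaks uniformly over domains, scores isolated/clustered damages and
#' averages the survival law over iterations.
#'
#' @param dose Dose, Gy.
#' @param params An [endpoint_params()].
#' @param nucleus A [nucleus_model()] or domain count.
#' @param n_iter Iterations (default 1e4).
#' @param seed Optional integer seed (applied via `set.seed`).
#' @return A `survival_estimate`.
#' @export
simulate_photon_acute <- function(dose, params, nucleus, n_iter = 1e4,
                                  seed = NULL) {
  stopifnot(inherits(params, "endpoint_params"), n_iter >= 1)
  if (dose < 0) stop("dose must be >= 0")
  n_dom <- if (inherits(nucleus, "nucleus_model")) nucleus$n_domains
           else as.integer(nucleus)
  if (!is.null(seed)) set.seed(seed)
  surv <- cpp_photon_acute(as.integer(n_iter), n_dom,
                           params$alpha_dsb * dose,
                           params$k_idsb, params$k_cdsb)
  new_survival_estimate(surv, n_iter, seed,
                        irradiation_protocol(dose), "photon_acute")
}

#' Monte Carlo time-resolved photon survival
#'
#' Splits the delivery into `n_timesteps` equal sub-intervals, deposits
#' the partial dose at the start of each and advances exponential repair
#' (with misrepair) in between. Misrepair zeroes an iteration's survival;
#' otherwise the survival law is applied to the damage remaining at the
#' end of the irradiation time.
#'
#' @param protocol An [irradiation_protocol()] with finite dose rate (or a
#'   plain dose when `dose_rate` is given).
#' @param params An [endpoint_params()].
#' @param nucleus A [nucleus_model()] or domain count.
#' @param n_iter Iterations (default 1e4).
#' @param seed Optional integer seed.
#' @param dose_rate Dose rate, Gy/min, when `protocol` is a plain dose.
#' @return A `survival_estimate`.
#' @export
simulate_photon_timed <- function(protocol, params, nucleus, n_iter = 1e4,
                                  seed = NULL, dose_rate = NULL) {
  if (!inherits(protocol, "irradiation_protocol")) {
    if (is.null(dose_rate)) stop("dose_rate required with a plain dose")
    protocol <- irradiation_protocol(protocol, dose_rate)
  }
  stopifnot(inherits(params, "endpoint_params"), n_iter >= 1)
  if (!is.finite(protocol$dose_rate))
    stop("timed engine requires a finite dose rate; use the acute engine")
  n_dom <- if (inherits(nucleus, "nucleus_model")) nucleus$n_domains
           else as.integer(nucleus)
  dt <- (protocol$dose / protocol$dose_rate) / protocol$n_timesteps
  if (!is.null(seed)) set.seed(seed)
  surv <- cpp_photon_timed(as.integer(n_iter), n_dom,
                           params$alpha_dsb * protocol$dose,
                           protocol$n_timesteps, dt,
                           params$k_idsb, params$k_cdsb,
                           params$t_half_idsb, params$t_half_cdsb)
  new_survival_estimate(surv, n_iter, seed, protocol, "photon_timed")
}

# ---- ion engines -----------------------------------------------------------

#' Expected number of tracks through the sampling area
#'
#' Fluence-dose relation `D = 1.602e-9 * LET * Phi / rho` (Phi per cm^2)
#' rearranged for the expected track count through `sampling_area`
#' (conventionally `pi (nucleus radius + r_max)^2`).
#'
#' @param dose Macroscopic dose, Gy (>= 0).
#' @param let LET, keV/um (> 0).
#' @param sampling_area Area, um^2 (> 0).
#' @param rho Density, g/cm^3.
#' @return Expected track count (Poisson mean).
#' @export
expected_track_count <- function(dose, let, sampling_area, rho = 1) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (let <= 0 || sampling_area <= 0) stop("let and area must be > 0")
  dose * rho * sampling_area / (KEV_TO_GY_UM3 * let)
}

#' Per-domain dose deposited by one track
#'
#' Midpoint rule: every domain receives the three-step profile evaluated
#' at the radial distance between the track axis and the domain column's
#' centre line (tracks travel parallel to the cylinder axis, so all
#' domains of a column receive the same dose).
#'
#' @param x,y Track position, um, relative to the nucleus axis.
#' @param step_profile A `step_profile` from [three_step_profile()].
#' @param nucleus A [nucleus_model()].
#' @param effective Use yield-weighted levels.
#' @return Numeric vector of per-domain dose increments (Gy), domain index
#'   running column-major (`(column - 1) * n_z + z`).
#' @export
deposit_track <- function(x, y, step_profile, nucleus, effective = FALSE) {
  stopifnot(inherits(step_profile, "step_profile"),
            inherits(nucleus, "nucleus_model"))
  r <- sqrt((x - nucleus$col_x)^2 + (y - nucleus$col_y)^2)
  rep(step_dose(step_profile, r, effective = effective),
      each = nucleus$n_z)
}

#' Precompute the track-structure inputs of the ion engines
#'
#' Builds the raw radial dose profile of the particle, applies radical
#' diffusion, reduces it to the three-step parametrization (with
#' yield-weighted levels for the DSB induction enhancement) and derives
#' the track sampling geometry for a nucleus.
#'
#' @param particle A [particle_state()].
#' @param nucleus A [nucleus_model()].
#' @param sigma Radical diffusion length, um (default 0.004).
#' @param enhancement A `dsb_enhancement` (default the SSB-pairing
#'   local-dose model; use [enhancement_identity()] for oracle work).
#' @param rho Density, g/cm^3.
#' @return A list with the `step_profile`, the sampling radius and the
#'   per-Gy expected track count.
#' @export
ion_track_setup <- function(particle, nucleus, sigma = 0.004,
                            enhancement = enhancement_ssb_pairing(),
                            rho = 1) {
  stopifnot(inherits(particle, "particle_state"),
            inherits(nucleus, "nucleus_model"))
  prof <- build_profile(particle, rho = rho)
  if (sigma > 0) prof <- diffuse_profile(prof, sigma)
  step <- three_step_profile(prof, enhancement = enhancement,
                             footprint = nucleus$domain_side / sqrt(pi))
  r_samp <- nucleus$radius + step$r_bounds[3]
  lambda_per_gy <- expected_track_count(1, particle$let,
                                        pi * r_samp^2, rho = rho)
  list(particle = particle, nucleus = nucleus, step = step,
       sigma = sigma, enhancement = enhancement$label,
       r_samp = r_samp, lambda_per_gy = lambda_per_gy)
}

#' Monte Carlo acute ion survival
#'
#' Per iteration: Poisson track count through the sampling disk, uniform
#' track positions, per-domain doses by [deposit_track()] semantics,
#' per-domain Poisson DSB counts with the (enhancement-weighted) yield,
#' survival by the damage-classification law; averaged over iterations.
#'
#' @param protocol An [irradiation_protocol()] carrying a particle (or a
#'   plain dose with `setup` supplied).
#' @param params An [endpoint_params()].
#' @param nucleus A [nucleus_model()].
#' @param n_iter Iterations (default 1e4).
#' @param seed Optional integer seed.
#' @param setup Optional precomputed [ion_track_setup()] (built on the
#'   fly otherwise).
#' @param sigma,enhancement Passed to [ion_track_setup()] when `setup` is
#'   not given.
#' @return A `survival_estimate`.
#' @export
simulate_ion_acute <- function(protocol, params, nucleus, n_iter = 1e4,
                               seed = NULL, setup = NULL, sigma = 0.004,
                               enhancement = enhancement_ssb_pairing()) {
  if (!inherits(protocol, "irradiation_protocol"))
    protocol <- irradiation_protocol(protocol,
                                     particle = setup$particle)
  stopifnot(inherits(params, "endpoint_params"), n_iter >= 1)
  if (is.null(setup)) {
    if (is.null(protocol$particle))
      stop("ion engine needs a particle in the protocol or a setup")
    setup <- ion_track_setup(protocol$particle, nucleus, sigma = sigma,
                             enhancement = enhancement)
  }
  if (!is.null(seed)) set.seed(seed)
  surv <- cpp_ion_acute(as.integer(n_iter), nucleus$col_x, nucleus$col_y,
                        nucleus$n_z,
                        setup$lambda_per_gy * protocol$dose, setup$r_samp,
                        setup$step$r_bounds, setup$step$levels_eff,
                        params$alpha_dsb / nucleus$n_domains,
                        params$k_idsb, params$k_cdsb)
  new_survival_estimate(surv, n_iter, seed, protocol, "ion_acute")
}

#' Monte Carlo time-resolved ion survival
#'
#' As [simulate_ion_acute()], but the delivery is split into
#' `n_timesteps` tranches: each tranche draws a fresh, independent set of
#' tracks carrying the partial dose, adds the induced DSB to the standing
#' damage distribution, and repair is advanced between tranches.
#'
#' @inheritParams simulate_ion_acute
#' @return A `survival_estimate`.
#' @export
simulate_ion_timed <- function(protocol, params, nucleus, n_iter = 1e4,
                               seed = NULL, setup = NULL, sigma = 0.004,
                               enhancement = enhancement_ssb_pairing()) {
  stopifnot(inherits(protocol, "irradiation_protocol"),
            inherits(params, "endpoint_params"), n_iter >= 1)
  if (!is.finite(protocol$dose_rate))
    stop("timed engine requires a finite dose rate; use the acute engine")
  if (is.null(setup)) {
    if (is.null(protocol$particle))
      stop("ion engine needs a particle in the protocol or a setup")
    setup <- ion_track_setup(protocol$particle, nucleus, sigma = sigma,
                             enhancement = enhancement)
  }
  dt <- (protocol$dose / protocol$dose_rate) / protocol$n_timesteps
  if (!is.null(seed)) set.seed(seed)
  surv <- cpp_ion_timed(as.integer(n_iter), nucleus$col_x, nucleus$col_y,
                        nucleus$n_z,
                        setup$lambda_per_gy * protocol$dose, setup$r_samp,
                        setup$step$r_bounds, setup$step$levels_eff,
                        params$alpha_dsb / nucleus$n_domains,
                        protocol$n_timesteps, dt,
                        params$k_idsb, params$k_cdsb,
                        params$t_half_idsb, params$t_half_cdsb)
  new_survival_estimate(surv, n_iter, seed, protocol, "ion_timed")
}
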