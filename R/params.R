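#' Endpoint-dependent lethality and repair parameters
#'
#' Bundles the per-damage lethality probabilities and repair half-lives that
#' characterise one cell line or biological endpoint. A domain containing a
#' single DSB ("isolated", iDSB) triggers the endpoint with probability
#' `k_idsb` per damage; a domain containing two or more DSB ("clustered",
#' cDSB) with probability `k_cdsb`. Repair lifetimes are drawn from
#' exponential distributions whose *medians* equal the half-lives.
#'
#' @param k_idsb Lethality (endpoint-trigger) probability per isolated DSB,
#'   in \[0, 1\].
#' @param k_cdsb Lethality probability per clustered DSB, in \[0, 1\].
#' @param t_half_idsb Repair half-life of isolated DSB, minutes (> 0).
#' @param t_half_cdsb Repair half-life of clustered DSB, minutes
#'   (>= `t_half_idsb`).
#' @param alpha_dsb DSB induction yield, DSB per Gy per cell (default 30).
#' @param label Free-text label for printing and output headers.
#' @return An object of class `endpoint_params`.
#' @seealso [endpoint_preset()] for the parameter sets shipped with the
#'   package.
#' @export
#' @examples
#' endpoint_params(5.9e-3, 0.17, 4, 100, label = "DU145")
endpoint_params <- function(k_idsb, k_cdsb, t_half_idsb, t_half_cdsb,
                            alpha_dsb = 30, label = "") {
  stopifnot(is.numeric(k_idsb), length(k_idsb) == 1L,
            is.numeric(k_cdsb), length(k_cdsb) == 1L)
  if (k_idsb < 0 || k_idsb > 1) stop("k_idsb must lie in [0, 1]")
  if (k_cdsb < 0 || k_cdsb > 1) stop("k_cdsb must lie in [0, 1]")
  if (!is.numeric(t_half_idsb) || t_half_idsb <= 0)
    stop("t_half_idsb must be > 0")
  if (!is.numeric(t_half_cdsb) || t_half_cdsb < t_half_idsb)
    stop("t_half_cdsb must be >= t_half_idsb")
  if (!is.numeric(alpha_dsb) || alpha_dsb <= 0)
    stop("alpha_dsb must be > 0")
  structure(
    list(k_idsb = as.numeric(k_idsb), k_cdsb = as.numeric(k_cdsb),
         t_half_idsb = as.numeric(t_half_idsb),
         t_half_cdsb = as.numeric(t_half_cdsb),
         alpha_dsb = as.numeric(alpha_dsb), label = as.character(label)),
    class = "endpoint_params")
}

#' Named endpoint parameter presets
#'
#' Published parameter sets for the DU145 prostate-carcinoma cell line and
#' for the rat-spinal-cord paresis endpoint (fitted with and without repair
#' kinetics). Half-lives for the no-repair fit are not defined; nominal
#' values are carried so that the object validates, and engines run such
#' protocols acutely.
#'
#' @param name One of `"DU145"`, `"RSC_repair"`, `"RSC_norepair"`.
#' @return An `endpoint_params` object.
#' @export
endpoint_preset <- function(name = c("DU145", "RSC_repair", "RSC_norepair")) {
  name <- match.arg(name)
  switch(name,
    DU145 = endpoint_params(5.9e-3, 0.17, 4, 100, label = "DU145"),
    RSC_repair = endpoint_params(3.5e-5, 9.8e-3, 11.4, 129.6,
                                 label = "RSC_repair"),
    # half-lives undefined for this fit; repair is not meant to be simulated
    RSC_norepair = endpoint_params(6.5e-3, 8.5e-3, 11.4, 129.6,
                                   label = "RSC_norepair"))
}

#' @export
print.endpoint_params <- function(x, ...) {
  cat("Endpoint parameters", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  K_iDSB = %.3g   K_cDSB = %.3g\n", x$k_idsb, x$k_cdsb))
  cat(sprintf("  T1/2 iDSB = %.4g min   T1/2 cDSB = %.4g min\n",
              x$t_half_idsb, x$t_half_cdsb))
  cat(sprintf("  alpha_DSB = %.4g DSB/(Gy cell)\n", x$alpha_dsb))
  invisible(x)
}

#' Cylindrical nucleus with cubic chromatin domains
#'
#' The cell nucleus is a cylinder of radius `radius` and height `height`
#' (particles traverse parallel to the height axis) packed with cubic
#' domains of ~2 Mbp of DNA each, the "giant-loop" chromatin substructures
#' over which DSB clustering is scored. The domain edge length is derived
#' from the requested domain count; the realised grid (square lattice of
#' domain columns whose centres fall inside the cylinder cross-section,
#' times full layers along the axis) defines the domain count actually
#' used, which is stored back into `n_domains`.
#'
#' @param radius Nucleus radius, micrometres.
#' @param height Nucleus height, micrometres.
#' @param n_domains Target number of chromatin domains (default 3000,
#'   approximately a 6 Gbp diploid genome at 2 Mbp per domain).
#' @param dna_per_domain DNA content per domain, Mbp (nominal 2).
#' @param domain_side Optional explicit domain edge length, micrometres.
#'   By default derived as `(pi r^2 h / n_domains)^(1/3)`.
#' @return An object of class `nucleus_model` with the realised geometry:
#'   `n_domains`, `domain_side`, `n_z` (layers along the axis), and
#'   `col_x`/`col_y` (column centre coordinates).
#' @export
#' @examples
#' nucleus_model()           # default ~3000-domain nucleus
#' nucleus_model(n_domains = 1)  # single-domain nucleus for small oracles
nucleus_model <- function(radius = 5, height = 10, n_domains = 3000,
                          dna_per_domain = 2, domain_side = NULL) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(height) || height <= 0) stop("height must be > 0")
  if (!is.numeric(n_domains) || n_domains < 1)
    stop("n_domains must be >= 1")
  vol <- pi * radius^2 * height
  if (is.null(domain_side)) {
    domain_side <- (vol / n_domains)^(1 / 3)
  }
  if (domain_side <= 0) stop("domain_side must be > 0")
  # packing feasibility; 5% slack for lattice discretisation at the rim
  if (n_domains * domain_side^3 > vol * 1.05)
    stop("n_domains * domain_side^3 exceeds the cylinder volume: ",
         "domains do not pack into the nucleus")
  if (n_domains == 1L) {
    col_x <- 0; col_y <- 0; n_z <- 1L
  } else {
    n_z <- max(1L, as.integer(round(height / domain_side)))
    half <- ceiling(radius / domain_side)
    centres <- (seq(-half, half) + 0.5) * domain_side
    grid <- expand.grid(x = centres, y = centres)
    keep <- grid$x^2 + grid$y^2 <= radius^2
    col_x <- grid$x[keep]
    col_y <- grid$y[keep]
  }
  realised <- length(col_x) * n_z
  structure(
    list(n_domains = as.integer(realised), radius = radius, height = height,
         domain_side = domain_side, dna_per_domain = dna_per_domain,
         n_z = as.integer(n_z), col_x = as.numeric(col_x),
         col_y = as.numeric(col_y)),
    class = "nucleus_model")
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf(
    "Nucleus: cylinder r = %.3g um, h = %.3g um\n  %d cubic domains (side %.4g um, %d columns x %d layers, %.3g Mbp each)\n",
    x$radius, x$height, x$n_domains, x$domain_side,
    length(x$col_x), x$n_z, x$dna_per_domain))
  invisible(x)
}

#' Irradiation protocol
#'
#' Describes one delivery: total dose, dose rate (`Inf` means acute,
#' i.e. instantaneous delivery with no repair during irradiation), number
#' of equal fractions, the time-step count of the delivery discretisation,
#' and the particle (NULL for sparsely ionizing / photon irradiation).
#'
#' @param dose Total dose over all fractions, Gy (>= 0).
#' @param dose_rate Dose rate, Gy/min; `Inf` for acute delivery.
#' @param n_fractions Number of equal fractions (>= 1). Fractions are
#'   simulated independently and survivals multiplied (complete
#'   inter-fraction damage resolution).
#' @param n_timesteps Number of time-steps the irradiation time is divided
#'   into (default 100).
#' @param particle A [particle_state()] for ion protocols, or `NULL` for
#'   photons.
#' @return An object of class `irradiation_protocol`.
#' @export
irradiation_protocol <- function(dose, dose_rate = Inf, n_fractions = 1,
                                 n_timesteps = 100, particle = NULL) {
  if (!is.numeric(dose) || dose < 0) stop("dose must be >= 0")
  if (!is.numeric(dose_rate) || dose_rate <= 0)
    stop("dose_rate must be > 0 (Inf for acute delivery)")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (n_timesteps < 1) stop("n_timesteps must be >= 1")
  if (!is.null(particle) && !inherits(particle, "particle_state"))
    stop("particle must be a particle_state or NULL")
  structure(
    list(dose = dose, dose_rate = dose_rate,
         n_fractions = as.integer(n_fractions),
         n_timesteps = as.integer(n_timesteps), particle = particle),
    class = "irradiation_protocol")
}

#' @export
print.irradiation_protocol <- function(x, ...) {
  mod <- if (is.null(x$particle)) "photon" else
    sprintf("ion (z = %d, %.3g MeV/u, LET %.3g keV/um)",
            x$particle$z_ion, x$particle$e_kin, x$particle$let)
  cat(sprintf("Protocol: %.4g Gy at %s Gy/min, %d fraction(s), %d time-steps, %s\n",
              x$dose, format(x$dose_rate), x$n_fractions, x$n_timesteps, mod))
  invisible(x)
}
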