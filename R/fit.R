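# Least-squares fitting of the per-damage lethality parameters to
# TD50-versus-fractionation data, and the synthetic TD50 generator.

#' Fit lethality parameters to TD50-vs-fractionation data
#'
#' Estimates the per-damage endpoint-trigger probabilities `k_idsb` and
#' `k_cdsb` by least squares on measured TD50 values over the number of
#' fractions, with the repair half-lives held fixed. The model TD50 is
#' obtained from the photon engine at the reference dose rate (with
#' repair kinetics on, or acutely when `repair = FALSE`). Optimisation is
#' derivative-free (Nelder-Mead) on `log10(k)` with box `[1e-8, 1]`,
#' started from the best point of a coarse log-grid scan; with the
#' `"mc"` engine every objective evaluation reuses the same seed so the
#' objective is deterministic.
#'
#' @param formula Model formula, `td50 ~ n_fractions`.
#' @param data A data frame holding the variables of `formula`; at least
#'   two rows.
#' @param ref_rate Reference photon dose rate, Gy/min (default 3.75).
#' @param repair Simulate repair kinetics during delivery (`TRUE`), or
#'   fit the acute (no-repair) model.
#' @param t_half Fixed repair half-lives `c(idsb, cdsb)`, minutes.
#' @param nucleus A [nucleus_model()].
#' @param alpha_dsb DSB yield, per Gy per cell.
#' @param engine `"exact"` (deterministic, default) or `"mc"`.
#' @param n_iter MC iterations per TD50 solve (engine `"mc"`).
#' @param seed Seed reused across MC evaluations.
#' @param tol TD50 bisection tolerance, Gy.
#' @param start Optional starting values `c(k_idsb, k_cdsb)`.
#' @param control Passed to [stats::optim()] (Nelder-Mead); sensible
#'   defaults applied.
#' @return An object of class `lethality_fit` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot`
#'   methods.
#' @export
#' @examples
#' \donttest{
#' truth <- endpoint_preset("RSC_repair")
#' nuc <- nucleus_model(n_domains = 500)
#' syn <- make_synthetic_td50(truth, fractions = c(1, 4, 16),
#'                            nucleus = nuc, seed = 1)
#' fit <- fit_lethality(td50_gy ~ n_fractions, syn$table, nucleus = nuc)
#' coef(fit)
#' }
fit_lethality <- function(formula = td50_gy ~ n_fractions, data,
                          ref_rate = 3.75, repair = TRUE,
                          t_half = c(11.4, 129.6),
                          nucleus = nucleus_model(), alpha_dsb = 30,
                          engine = c("exact", "mc"), n_iter = 2000,
                          seed = NULL, tol = 0.02, start = NULL,
                          control = list()) {
  engine <- match.arg(engine)
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  td50_obs <- stats::model.response(mf)
  n_frac <- mf[[2L]]
  if (length(td50_obs) < 2)
    stop("need at least two (n_fractions, td50) points to fit two parameters")
  if (any(td50_obs <= 0) || any(n_frac < 1))
    stop("td50 values must be positive and fraction counts >= 1")
  dose_rate <- if (repair) ref_rate else Inf

  model_td50 <- function(k_i, k_c) {
    params <- endpoint_params(k_i, k_c, t_half[1], t_half[2],
                              alpha_dsb = alpha_dsb)
    vapply(n_frac, function(nf)
      solve_td50(params, nucleus, dose_rate = dose_rate,
                 n_fractions = nf, engine = engine, n_iter = n_iter,
                 seed = seed, tol = tol)$td50,
      numeric(1))
  }
  obj <- function(theta) {
    pen <- sum(pmax(0, theta - 0)^2 + pmax(0, -8 - theta)^2) * 1e4
    th <- pmin(pmax(theta, -8), 0)
    pred <- model_td50(10^th[1], 10^th[2])
    sum((pred - td50_obs)^2) + pen
  }

  if (is.null(start)) {
    grid <- expand.grid(li = c(-6, -4.5, -3, -1.8),
                        lc = c(-4, -3, -2, -1))
    vals <- apply(grid, 1, obj)
    start_theta <- as.numeric(grid[which.min(vals), ])
  } else {
    start_theta <- log10(start)
  }
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 500), control)
  opt <- stats::optim(start_theta, obj, method = "Nelder-Mead",
                      control = ctrl)
  theta <- pmin(pmax(opt$par, -8), 0)
  k_hat <- 10^theta
  names(k_hat) <- c("k_idsb", "k_cdsb")
  boundary <- any(abs(theta - (-8)) < 1e-6) || any(abs(theta) < 1e-6)
  if (boundary)
    warning("estimate pinned at a box boundary [1e-8, 1]; ",
            "the data may not identify both parameters")
  if (opt$convergence != 0)
    warning("optimiser reported non-convergence (code ",
            opt$convergence, ")")
  fitted_td50 <- model_td50(k_hat[1], k_hat[2])

  structure(
    list(coefficients = k_hat, fitted.values = fitted_td50,
         residuals = td50_obs - fitted_td50,
         data = data.frame(n_fractions = n_frac, td50 = td50_obs),
         rss = sum((td50_obs - fitted_td50)^2),
         convergence = opt$convergence, boundary = boundary,
         counts = opt$counts,
         settings = list(ref_rate = ref_rate, repair = repair,
                         t_half = t_half, alpha_dsb = alpha_dsb,
                         engine = engine, n_iter = n_iter, seed = seed,
                         tol = tol, n_domains = nucleus$n_domains),
         nucleus = nucleus, call = cl),
    class = "lethality_fit")
}

#' @export
print.lethality_fit <- function(x, ...) {
  cat("Lethality-parameter fit to TD50 data\n")
  cat(sprintf("  k_idsb = %.4g   k_cdsb = %.4g\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  %d points, RSS = %.4g Gy^2, repair %s at %.3g Gy/min\n",
              nrow(x$data), x$rss,
              if (x$settings$repair) "on" else "off",
              x$settings$ref_rate))
  invisible(x)
}

#' @export
summary.lethality_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              residuals = object$residuals, rss = object$rss,
              data = object$data, fitted = object$fitted.values,
              settings = object$settings, boundary = object$boundary,
              convergence = object$convergence)
  class(out) <- "summary.lethality_fit"
  out
}

#' @export
print.summary.lethality_fit <- function(x, ...) {
  cat("Lethality-parameter fit\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nRSS: %.4g Gy^2 over %d points\n", x$rss, nrow(x$data)))
  tab <- cbind(x$data, fitted = x$fitted, residual = x$residuals)
  print(tab, row.names = FALSE)
  cat(sprintf("\nSettings: repair %s, ref %.3g Gy/min, T1/2 = %.4g/%.4g min, %s engine, %d domains\n",
              if (x$settings$repair) "on" else "off",
              x$settings$ref_rate, x$settings$t_half[1],
              x$settings$t_half[2], x$settings$engine,
              x$settings$n_domains))
  if (x$boundary) cat("Warning: estimate pinned at the parameter box\n")
  invisible(x)
}

#' Predict TD50 for new fraction numbers
#'
#' @param object A `lethality_fit`.
#' @param newdata Data frame with column `n_fractions` (defaults to the
#'   fitted data).
#' @param ... Unused.
#' @return Numeric vector of model TD50 values, Gy.
#' @export
predict.lethality_fit <- function(object, newdata = NULL, ...) {
  nf <- if (is.null(newdata)) object$data$n_fractions
        else newdata$n_fractions
  s <- object$settings
  params <- endpoint_params(object$coefficients[1], object$coefficients[2],
                            s$t_half[1], s$t_half[2],
                            alpha_dsb = s$alpha_dsb)
  dose_rate <- if (s$repair) s$ref_rate else Inf
  vapply(nf, function(n)
    solve_td50(params, object$nucleus, dose_rate = dose_rate,
               n_fractions = n, engine = s$engine, n_iter = s$n_iter,
               seed = s$seed, tol = s$tol)$td50,
    numeric(1))
}

#' Simulate synthetic TD50 datasets from a fitted model
#'
#' @param object A `lethality_fit`.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param noise_sd Relative (lognormal) noise standard deviation.
#' @param ... Unused.
#' @return A list of data frames with columns `n_fractions`, `td50_gy`.
#' @export
simulate.lethality_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_sd = 0.03, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$fitted.values
  nf <- object$data$n_fractions
  lapply(seq_len(nsim), function(i)
    data.frame(n_fractions = nf,
               td50_gy = base * exp(stats::rnorm(length(base), 0,
                                                 noise_sd))))
}

#' @export
plot.lethality_fit <- function(x, ...) {
  nf <- x$data$n_fractions
  graphics::plot(nf, x$data$td50, log = "x", pch = 19,
                 xlab = "number of fractions", ylab = "TD50 [Gy]",
                 main = "TD50 vs fractionation", ...)
  o <- order(nf)
  graphics::lines(nf[o], x$fitted.values[o], col = "steelblue")
  graphics::legend("topleft", legend = c("data", "fit"), pch = c(19, NA),
                   lty = c(NA, 1), col = c("black", "steelblue"),
                   bty = "n")
  invisible(x)
}

#' Generate a synthetic TD50-vs-fractionation dataset
#'
#' Computes the model TD50 for each fraction number at the reference
#' photon dose rate and perturbs it with multiplicative lognormal noise
#' `exp(N(0, noise_sd))` — a stand-in for measured photon tolerance-dose
#' series. Regeneration from the same parameters and seed is
#' bit-identical.
#'
#' @param params An [endpoint_params()] (the generating truth).
#' @param fractions Fraction numbers (default `c(1, 2, 4, 8, 16, 32)`).
#' @param ref_rate Reference dose rate, Gy/min (default 3.75).
#' @param noise_sd Relative noise standard deviation (>= 0; default 0).
#' @param seed Optional integer seed.
#' @param nucleus A [nucleus_model()].
#' @param repair Simulate repair during delivery (default TRUE).
#' @param engine,n_iter,tol TD50 solver settings.
#' @return An object of class `synthetic_td50`: list with the generating
#'   settings and `$table`, a data frame of `n_fractions`, `td50_gy`.
#' @export
make_synthetic_td50 <- function(params, fractions = c(1, 2, 4, 8, 16, 32),
                                ref_rate = 3.75, noise_sd = 0,
                                seed = NULL, nucleus = nucleus_model(),
                                repair = TRUE,
                                engine = c("exact", "mc"), n_iter = 2000,
                                tol = 0.02) {
  stopifnot(inherits(params, "endpoint_params"))
  engine <- match.arg(engine)
  if (length(fractions) == 0) stop("fractions must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dose_rate <- if (repair) ref_rate else Inf
  base <- vapply(fractions, function(nf)
    solve_td50(params, nucleus, dose_rate = dose_rate, n_fractions = nf,
               engine = engine, n_iter = n_iter, seed = seed,
               tol = tol)$td50,
    numeric(1))
  noise <- if (noise_sd > 0)
    exp(stats::rnorm(length(base), 0, noise_sd)) else rep(1, length(base))
  structure(
    list(table = data.frame(n_fractions = as.integer(fractions),
                            td50_gy = base * noise),
         params = params, ref_rate = ref_rate, noise_sd = noise_sd,
         seed = seed, repair = repair, engine = engine,
         n_domains = nucleus$n_domains),
    class = "synthetic_td50")
}

#' @export
print.synthetic_td50 <- function(x, ...) {
  cat(sprintf(
    "Synthetic TD50 dataset (ref %.3g Gy/min, noise sd %.3g, seed %s)\n",
    x$ref_rate, x$noise_sd,
    if (is.null(x$seed)) "none" else format(x$seed)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
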