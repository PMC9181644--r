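#' Create an empty per-domain damage state
#'
#' Book-keeping container for the DSB present in a nucleus at a given time.
#' Each active DSB carries the domain it sits in and an absolute expiry
#' time (elapsed time at which its repair completes); storing expiry times
#' rather than decremented lifetimes makes time-stepping order-independent
#' within a step. Domains holding exactly one DSB are classified isolated
#' (iDSB), domains with two or more clustered (cDSB).
#'
#' @param n_domains Number of chromatin domains.
#' @return An object of class `damage_state` with fields `dom` (domain
#'   index per active DSB), `expiry` (absolute repair time, minutes),
#'   `ctype` (whether the lifetime was drawn from the clustered-DSB
#'   distribution), `elapsed_time` and `misrepair`.
#' @export
damage_state <- function(n_domains) {
  stopifnot(n_domains >= 1)
  structure(
    list(n_domains = as.integer(n_domains), dom = integer(0),
         expiry = numeric(0), ctype = logical(0),
         elapsed_time = 0, misrepair = FALSE),
    class = "damage_state")
}

#' @export
print.damage_state <- function(x, ...) {
  cl <- classify_domains(x)
  cat(sprintf(
    "Damage state: %d DSB in %d domains (%d iDSB, %d cDSB), t = %.3g min%s\n",
    length(x$dom), x$n_domains, cl[["n_idsb"]], cl[["n_cdsb"]],
    x$elapsed_time, if (x$misrepair) ", MISREPAIR" else ""))
  invisible(x)
}

domain_counts <- function(state) {
  tabulate(state$dom, nbins = state$n_domains)
}

#' Count isolated and clustered DSB domains
#'
#' Scores the number of domains containing exactly one DSB (isolated) and
#' two or more DSB (clustered).
#'
#' @param state A [damage_state()].
#' @return Named numeric vector `c(n_idsb, n_cdsb)`.
#' @export
classify_domains <- function(state) {
  stopifnot(inherits(state, "damage_state"))
  if (length(state$dom) == 0L)
    return(c(n_idsb = 0L, n_cdsb = 0L))
  counts <- domain_counts(state)
  c(n_idsb = sum(counts == 1L), n_cdsb = sum(counts >= 2L))
}

#' Cell survival probability from the damage pattern
#'
#' The survival law of the damage-clustering model: each isolated DSB
#' independently inactivates the cell with probability `k_idsb`, each
#' clustered DSB with probability `k_cdsb`, so
#' `S = (1 - k_idsb)^n_idsb * (1 - k_cdsb)^n_cdsb`.
#'
#' @param n_idsb Number of domains holding exactly one DSB.
#' @param n_cdsb Number of domains holding two or more DSB.
#' @param params An [endpoint_params()].
#' @return Survival probability in \[0, 1\].
#' @export
#' @examples
#' p <- endpoint_params(0.1, 0.5, 4, 100)
#' survival_probability(2, 1, p)  # 0.9^2 * 0.5 = 0.405
survival_probability <- function(n_idsb, n_cdsb, params) {
  stopifnot(inherits(params, "endpoint_params"))
  if (any(n_idsb < 0) || any(n_cdsb < 0))
    stop("DSB counts must be non-negative")
  (1 - params$k_idsb)^n_idsb * (1 - params$k_cdsb)^n_cdsb
}

#' Allocate DSB uniformly over domains
#'
#' Assigns each of `n_dsb` double-strand breaks to a domain with equal
#' probability (multinomial allocation), the homogeneous-dose assumption
#' for sparsely ionizing radiation.
#'
#' @param n_dsb Number of DSB to allocate (>= 0).
#' @param nucleus A [nucleus_model()] or a plain domain count.
#' @return Integer vector of per-domain DSB counts summing to `n_dsb`.
#' @export
allocate_dsb_uniform <- function(n_dsb, nucleus) {
  n_dom <- if (inherits(nucleus, "nucleus_model")) nucleus$n_domains
           else as.integer(nucleus)
  stopifnot(n_dsb >= 0, n_dom >= 1)
  if (n_dsb == 0) return(integer(n_dom))
  tabulate(sample.int(n_dom, size = n_dsb, replace = TRUE), nbins = n_dom)
}

#' Sample repair lifetimes
#'
#' Lifetimes are exponential with *median* equal to the repair half-life,
#' i.e. rate `log(2) / t_half` and mean `t_half / log(2)`.
#'
#' @param n Number of lifetimes to draw.
#' @param t_half Repair half-life, minutes (> 0).
#' @return Numeric vector of lifetimes, minutes.
#' @export
sample_lifetime <- function(n, t_half) {
  if (!is.numeric(t_half) || t_half <= 0) stop("t_half must be > 0")
  stats::rexp(n, rate = log(2) / t_half)
}

#' Add newly induced DSB to a damage state
#'
#' New DSB landing in an empty domain become isolated and draw a lifetime
#' from the isolated-DSB distribution. DSB landing in or forming a cluster
#' draw clustered-DSB lifetimes, and a previously isolated DSB whose
#' domain gains a DSB is upgraded: its lifetime is redrawn from the
#' clustered-DSB distribution.
#'
#' @param state A [damage_state()].
#' @param new_dsb Integer vector of per-domain DSB counts to add (length
#'   `state$n_domains`).
#' @param params An [endpoint_params()].
#' @return The updated `damage_state`.
#' @export
add_damage <- function(state, new_dsb, params) {
  stopifnot(inherits(state, "damage_state"),
            inherits(params, "endpoint_params"),
            length(new_dsb) == state$n_domains)
  if (any(new_dsb < 0)) stop("new_dsb counts must be non-negative")
  if (sum(new_dsb) == 0) return(state)
  counts <- domain_counts(state)
  hit <- which(new_dsb > 0L)
  for (d in hit) {
    k <- new_dsb[d]
    pre <- counts[d]
    if (pre == 0L && k == 1L) {
      # lone DSB in an empty domain: isolated
      state$dom <- c(state$dom, d)
      state$expiry <- c(state$expiry,
                        state$elapsed_time + sample_lifetime(1, params$t_half_idsb))
      state$ctype <- c(state$ctype, FALSE)
    } else {
      if (pre == 1L) {
        # upgrade: the pre-existing isolated DSB redraws a clustered lifetime
        j <- which(state$dom == d)
        state$expiry[j] <- state$elapsed_time +
          sample_lifetime(1, params$t_half_cdsb)
        state$ctype[j] <- TRUE
      }
      state$dom <- c(state$dom, rep.int(d, k))
      state$expiry <- c(state$expiry,
                        state$elapsed_time + sample_lifetime(k, params$t_half_cdsb))
      state$ctype <- c(state$ctype, rep(TRUE, k))
    }
  }
  state
}

#' Advance a damage state in time
#'
#' Moves the clock forward by `dt` minutes. Every DSB whose expiry falls
#' within the interval is repaired (removed). Each removal fails
#' ("misrepair") with probability `k_idsb` if the damage sat isolated at
#' the start of the removal pass, `k_cdsb` if clustered; any misrepair
#' sets the state's misrepair flag permanently. Declassification (a
#' cluster dropping to a single DSB) applies after the removals of the
#' pass; the surviving damage keeps its current lifetime.
#'
#' @param state A [damage_state()].
#' @param dt Time increment, minutes (>= 0).
#' @param params An [endpoint_params()].
#' @return The updated `damage_state`.
#' @export
advance_state <- function(state, dt, params) {
  stopifnot(inherits(state, "damage_state"),
            inherits(params, "endpoint_params"))
  if (!is.numeric(dt) || dt < 0) stop("dt must be >= 0")
  t_end <- state$elapsed_time + dt
  if (length(state$dom)) {
    expired <- state$expiry <= t_end
    if (any(expired)) {
      counts <- domain_counts(state)   # classification before removals
      clustered <- counts[state$dom] >= 2L
      for (j in which(expired)) {
        k <- if (clustered[j]) params$k_cdsb else params$k_idsb
        if (stats::runif(1) < k) state$misrepair <- TRUE
      }
      keep <- !expired
      state$dom <- state$dom[keep]
      state$expiry <- state$expiry[keep]
      state$ctype <- state$ctype[keep]
    }
  }
  state$elapsed_time <- t_end
  state
}

#' Final survival of a damage state
#'
#' Zero if a misrepair occurred; otherwise the survival law applied to the
#' isolated/clustered DSB counts present in the state.
#'
#' @param state A [damage_state()].
#' @param params An [endpoint_params()].
#' @return Survival probability in \[0, 1\].
#' @export
finalize_survival <- function(state, params) {
  if (state$misrepair) return(0)
  cl <- classify_domains(state)
  survival_probability(cl[["n_idsb"]], cl[["n_cdsb"]], params)
}
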