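# Shared fixtures: small parameter sets and nuclei sized for fast tests.

par_mid <- function() endpoint_params(0.1, 0.5, 4, 100, label = "mid")
par_du <- function() endpoint_preset("DU145")
par_rsc <- function() endpoint_preset("RSC_repair")

nuc_small <- function(n = 50) nucleus_model(n_domains = n)
nuc_one <- function() nucleus_model(n_domains = 1)

# brute-force expectation of the survival law under acute photon damage:
# enumerate total DSB counts (Poisson) and allocate multinomially over a
# handful of domains by exhaustive composition enumeration
enum_photon_survival <- function(mu_total, n_dom, k_i, k_c, n_cap = 25) {
  comps <- function(n, k) {
    if (k == 1) return(matrix(n, ncol = 1))
    out <- NULL
    for (i in 0:n) out <- rbind(out, cbind(i, comps(n - i, k - 1)))
    out
  }
  total <- 0
  for (n in 0:n_cap) {
    pn <- stats::dpois(n, mu_total)
    cc <- comps(n, n_dom)
    lp <- lfactorial(n) - rowSums(lfactorial(cc)) - n * log(n_dom)
    s <- (1 - k_i)^rowSums(cc == 1) * (1 - k_c)^rowSums(cc >= 2)
    total <- total + pn * sum(exp(lp) * s)
  }
  total
}
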