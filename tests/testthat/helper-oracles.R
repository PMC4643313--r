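# Independent oracles used across the suite. Each deliberately takes a naive
# route (direct enumeration / quadrature) distinct from the package's code
# paths.

# Variance-stabilizing integral by quadrature: int_0^x dm / sqrt(m + a m^2).
vst_quadrature <- function(x, alpha) {
  if (x == 0) return(0)
  stats::integrate(function(m) 1 / sqrt(m + alpha * m^2), 0, x,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Brute-force conditional NB split test: plain probability loop, no logs.
nb_brute_pval <- function(ka, kb, sa, sb, alpha) {
  total <- ka + kb
  if (total == 0) return(1)
  SA <- sum(sa); SB <- sum(sb)
  q <- total / (SA + SB)
  prob_of <- function(a) {
    if (alpha <= 1e-12) {
      stats::dpois(a, q * SA) * stats::dpois(total - a, q * SB)
    } else {
      stats::dnbinom(a, mu = q * SA, size = SA^2 / (alpha * sum(sa^2))) *
        stats::dnbinom(total - a, mu = q * SB,
                       size = SB^2 / (alpha * sum(sb^2)))
    }
  }
  probs <- vapply(0:total, prob_of, numeric(1))
  obs <- probs[ka + 1]
  sum(probs[probs <= obs * (1 + 1e-7)]) / sum(probs)
}

# Hypergeometric upper tail by explicit enumeration of binomial coefficients.
hyper_enum_pval <- function(k, K, N, n) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  total <- choose(N, n)
  sum(vapply(k:jmax, function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, numeric(1))) / total
}

# Studentized-range CDF by nested quadrature:
# P(Q <= q) = int f_s(s) * k * int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where s = sqrt(chisq_df / df).
srange_cdf <- function(q, k, df) {
  inner <- function(s) {
    stats::integrate(function(z) {
      k * stats::dnorm(z) *
        pmax(stats::pnorm(z) - stats::pnorm(z - q * s), 0)^(k - 1)
    }, -8, 8, rel.tol = 1e-9)$value
  }
  dens_s <- function(s) {
    # density of sqrt(chisq_df/df)
    2 * s * df * stats::dchisq(s^2 * df, df)
  }
  stats::integrate(function(s) {
    vapply(s, function(si) dens_s(si) * inner(si), numeric(1))
  }, 1e-6, 6, rel.tol = 1e-7)$value
}

# Small standard simulation used by several recovery tests.
recovery_sim <- function(seed, n_genes = 2000, profiles = NULL) {
  sim_config(n_genes = n_genes,
             stages = c("E2.5", "E3.5", "E4.5", "E5.5"),
             replicates_per_stage = 4, frac_dynamic = 0.1, n_modules = 10,
             module_profiles = profiles, dispersion = 0.1, seed = seed)
}
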