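# Independent oracles used by the tests.  Everything here is computed
# from closed forms or numerical quadrature, never through the package's
# own transport code.

# Henyey-Greenstein density of the deflection cosine.
hg_pdf <- function(x, g) {
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * x)^1.5
}

# Quantile of the HG deflection cosine by numerically inverting the CDF
# (quadrature + root bracketing; independent of the sampler's algebra).
hg_quantile_numeric <- function(p, g) {
  cdf <- function(x) integrate(hg_pdf, -1, x, g = g,
                               rel.tol = 1e-10)$value
  vapply(p, function(pp) {
    uniroot(function(x) cdf(x) - pp, c(-1 + 1e-12, 1 - 1e-12),
            tol = 1e-10)$root
  }, numeric(1))
}

# Steady-state diffuse reflectance R(rho) of a semi-infinite medium:
# dipole solution with extrapolated boundary.  A = 1 corresponds to a
# refractive-index-matched boundary.
diffusion_R_rho <- function(rho, mu_a, mu_s_prime, A = 1) {
  mu_t <- mu_a + mu_s_prime
  z0 <- 1 / mu_t
  D <- 1 / (3 * mu_t)
  zb <- 2 * A * D
  mu_eff <- sqrt(mu_a / D)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
     (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2) / (4 * pi)
}

# Total diffuse reflectance: integral of R(rho) over the surface.
diffusion_total_reflectance <- function(mu_a, mu_s_prime, A = 1) {
  integrate(function(r) 2 * pi * r * diffusion_R_rho(r, mu_a, mu_s_prime, A),
            0, Inf, rel.tol = 1e-8)$value
}

# Semi-infinite diffusion intensity used for slope-chain checks:
# I(rho) proportional to exp(-mu_eff * rho) / rho^2.
diffusion_intensity <- function(rho, mu_a, mu_s_prime) {
  mu_eff <- sqrt(3 * mu_a * mu_s_prime)
  exp(-mu_eff * rho) / rho^2
}

# Generic 2x2 linear solve of the extinction system (cross-check for
# the explicit hemoglobin formulas).
solve_hb_2x2 <- function(mu_a_770, mu_a_830, eps) {
  E <- matrix(c(eps$eps_o2hb_770, eps$eps_hhb_770,
                eps$eps_o2hb_830, eps$eps_hhb_830),
              nrow = 2, byrow = TRUE)
  drop(solve(E, c(mu_a_770, mu_a_830)))
}
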