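# shared helpers for the test suite

# compact configuration for fast replicate loops
small_config <- function(n = 800, rho = -0.4, delta = 1, gamma_iv = 1,
                         seed = 101, ...) {
  sim_config(n = n, rho = rho, delta = delta, gamma_iv = gamma_iv,
             seed = seed, ...)
}

# covariate set used in speed-sensitive fits
fast_covs <- c("residence", "wealth_quintile")

# generated table with both dimension columns attached
sim_table <- function(cfg) {
  sim <- generate_dataset(cfg)
  tab <- sim$data
  tab$d1 <- compute_visit_dimension(tab$anc_visits)
  list(tab = tab, truth = sim$truth)
}

# brute-force 2-D quadrature oracle for the bivariate normal CDF:
# iterated adaptive integration of the joint density over (-9, x] x (-9, y]
bvn_oracle <- function(x, y, rho) {
  inner <- function(u) {
    vapply(u, function(ui) {
      stats::integrate(function(v) .bvn_pdf_oracle(ui, v, rho),
                       -9, y, rel.tol = 1e-12, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  stats::integrate(inner, -9, x, rel.tol = 1e-11, abs.tol = 1e-11)$value
}

.bvn_pdf_oracle <- function(u, v, rho) {
  omr2 <- 1 - rho^2
  exp(-(u^2 - 2 * rho * u * v + v^2) / (2 * omr2)) / (2 * pi * sqrt(omr2))
}
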