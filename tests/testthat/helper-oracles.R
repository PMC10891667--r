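# Independent oracle for the JZS paired Bayes factor: the marginal likelihood
# under H1 written as a Cauchy mixture of noncentral-t densities and computed
# by brute-force midpoint-Riemann integration over the effect size. This path
# shares no code with the package's g-parameterized adaptive quadrature.
bf10_oracle <- function(t, n, r, half_width = 30, h = 0.002) {
  delta <- seq(-half_width, half_width, by = h) + h / 2
  m1 <- sum(stats::dt(t, df = n - 1, ncp = delta * sqrt(n)) *
              stats::dcauchy(delta, 0, r)) * h
  m0 <- stats::dt(t, df = n - 1)
  m1 / m0
}
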