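# Independent oracles used by the energy and observables tests.

# Madelung constant of the rocksalt lattice by direct summation with Evjen
# boundary weights (fractional weights 1/2, 1/4, 1/8 on faces/edges/corners
# of the truncation cube). Converges rapidly and independently of Ewald.
evjen_madelung <- function(n = 8) {
  idx <- -n:n
  g <- expand.grid(i = idx, j = idx, k = idx)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  r <- sqrt(g$i^2 + g$j^2 + g$k^2)
  sgn <- (-1)^(g$i + g$j + g$k)
  w <- (ifelse(abs(g$i) == n, 0.5, 1) *
        ifelse(abs(g$j) == n, 0.5, 1) *
        ifelse(abs(g$k) == n, 0.5, 1))
  -sum(sgn * w / r)   # positive convention: energy per ion = -M / a
}

# AR(1) series with marginal sd 1: x_t = phi x_{t-1} + sqrt(1-phi^2) eps
ar1_series <- function(n, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n) * sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t]
  x
}

# build a bare ion core (no bodies) directly; positions as an n x 3 matrix
bare_ion_core <- function(L, species, q, pos, lB = 0.71, accuracy = 1e-3,
                          use_wca = FALSE, use_coulomb = TRUE,
                          sigma = 0.355) {
  off <- patchtitrate:::.offset_matrix(1.42, sigma, sigma)
  patchtitrate:::core_new(L, as.integer(species), as.numeric(q),
                          pos, rep(-1L, length(species)), 0L, off, sigma, 1,
                          lB, accuracy, use_wca, use_coulomb)
}
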