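# Reference parameter sets used across the suite: r0 = 2, i0 = 1e-4 with an
# infectious period of 2 days, and the symmetric SEIR case sigma = gamma.
fig_sir <- function(i0 = 1e-4) epi_params(r0 = 2, gamma = 0.5, i0 = i0)
fig_seir <- function(sigma = 0.5, gamma = 0.5, r0 = 2, i0 = 1e-4, e0 = 0) {
  epi_params(r0 = r0, gamma = gamma, sigma = sigma, i0 = i0, e0 = e0)
}

# Frozen calibration constants for the R''' = 0 approximation (see R/ package
# internals and the methods vignette).
tol <- seirshape:::.approx_tol
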