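# shared fixtures: the standard experiment geometry and the published
# expected hydration levels it is calibrated against

standard_mo <- 132
standard_spec <- function(d = 1) droplet_spec(450, 450, dilution_factor = d)

caption_levels <- data.frame(dilution = c(1, 2, 4, 7),
                             hydration = c(75, 60, 43, 30))

# independent minimax oracle for phi: brute-force grid search
phi_grid_oracle <- function(obs, screen_volume, mo_mass,
                            grid = seq(0.5, 1.1, by = 0.001)) {
  fwd <- function(phi, d) {
    w <- phi * screen_volume / d
    100 * w / (w + mo_mass)
  }
  worst <- vapply(grid, function(phi) {
    max(abs(fwd(phi, obs$dilution) - obs$hydration))
  }, numeric(1))
  grid[which.min(worst)]
}

# independent mole-conservation oracle for the incorporated fraction:
# numerically solve C_aq * W + K * C_aq * M = P for C_aq, then f
fraction_oracle <- function(K, M, W, P = 1) {
  if (K == 0) return(0)
  if (W == 0) return(1)
  g <- function(caq) caq * W + K * caq * M - P
  caq <- uniroot(g, lower = 0, upper = P / W, tol = 1e-15)$root
  1 - caq * W / P
}
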