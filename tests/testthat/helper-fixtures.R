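# Shared fixtures: everything is generated in code at test time.

# A small standardized 8-covariate stack on a 40x40 grid.
small_stack <- function(seed = 101, n = 40, smoothness = 2) {
  g <- make_grid(-62, -62 + n * 0.1, -52, -52 + n * 0.1, 0.1)
  make_synthetic_stack(g, seed = seed, smoothness = smoothness)
}

# The recovery-study fixture: 125x125 grid, true model BAT+, SST-, CHLa+
# at |beta| = 1, intercept calibrated to an expected 600 presence cells.
recovery_study <- function(seed) {
  g <- make_grid(-70, -60, -60, -50, 0.08)
  st <- make_synthetic_stack(g, seed = seed)
  truth <- calibrate_intercept(habitat_model(c(BAT = 1, SST = -1, CHLa = 1)),
                               st, 600)
  pres <- presence_set(sample_presence_cells(truth, st, seed = seed + 1),
                       colony = "SIM")
  list(grid = g, stack = st, truth = truth, presences = pres)
}

# Simulate a simple logistic-regression data frame with known coefficients.
sim_logistic_df <- function(n, beta, seed) {
  set.seed(seed)
  p <- length(beta) - 1
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("x", seq_len(p))
  eta <- beta[1] + x %*% beta[-1]
  data.frame(occ = rbinom(n, 1, plogis(eta)), x)
}
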