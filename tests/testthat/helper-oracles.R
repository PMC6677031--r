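# Independent oracles used across the suite.

# OLS slope via the normal equations, written independently of
# fit_parameter_slope()
oracle_ols_slope <- function(y, x = seq_along(y)) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# partial correlation by inverting the correlation matrix of
# (x, y, covariates): r_xy.z = -P_xy / sqrt(P_xx * P_yy)
oracle_partial_cor <- function(x, y, covs) {
  m <- cbind(x, y, as.matrix(covs))
  prec <- solve(cor(m))
  -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
}

# noiseless raised-cosine tap train analysis used by several tests
analyze_clean_train <- function(amplitude = 60, frequency = 3,
                                duration = 15, ...) {
  rec <- generate_tap_waveform(amplitude, frequency, duration,
                               noise_sd = 0, sampling_rate = 200, ...)
  tap_kinematics(rec)
}

# minimal six-parameter normative model with given population stats
population_model <- function(mean = 0, sd = 1) {
  grid <- expand.grid(parameter = c("amplitude", "open_speed",
                                    "close_speed"),
                      side = c("L", "R"), stringsAsFactors = FALSE)
  normative_model(data.frame(grid, mean = mean, sd = sd))
}
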