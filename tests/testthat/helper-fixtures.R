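# Shared fixtures: built once per test file, in code.

# standard two-ratio phantom volume (right 8:1, left 4:1, background 5 kBq/mL)
fixture_phantom_84 <- function(voxel = 2) {
  rasterize_phantom(build_phantom_spec(8, 4, 5), voxel)
}

# cohort lying exactly on the normative planes (no residual noise)
fixture_exact_cohort <- function(n = 200, seed = 11) {
  generate_cohort(n, residual_sd = 0, ai_residual_sd = 0, seed = seed)
}

# normal-equations OLS oracle, independent of lm()
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# brute-force Eq-style SBR oracle: explicit voxel loops
sbr_loop_oracle <- function(data, str_mask, ref_mask, vol_str_vox) {
  c_ref <- 0; n_ref <- 0; c_str <- 0; n_str <- 0
  d <- dim(data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (ref_mask[i, j, k]) { c_ref <- c_ref + data[i, j, k]; n_ref <- n_ref + 1 }
    if (str_mask[i, j, k]) { c_str <- c_str + data[i, j, k]; n_str <- n_str + 1 }
  }
  c_bg <- c_ref / n_ref
  (c_str - c_bg * n_str) / (c_bg * vol_str_vox)
}

# ICC mean squares through R's aov machinery (independent of the package's
# hand-computed sums of squares)
icc21_aov_oracle <- function(x, y) {
  n <- length(x)
  long <- data.frame(value = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}
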