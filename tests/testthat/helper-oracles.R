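# independent oracles, written as plain loops so they share no code with the
# package implementations they check

# Davies-Bouldin by direct definition
dbi_brute <- function(X, g) {
  X <- as.matrix(X)
  ids <- sort(unique(g))
  k <- length(ids)
  cent <- list(); S <- numeric(k)
  for (i in seq_len(k)) {
    pts <- X[g == ids[i], , drop = FALSE]
    cent[[i]] <- colMeans(pts)
    d <- 0
    for (r in seq_len(nrow(pts))) d <- d + sqrt(sum((pts[r, ] - cent[[i]])^2))
    S[i] <- d / nrow(pts)
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / k
}

# OLS line + confidence interval of the mean at x0, via the closed-form
# normal equations on centred predictors
ols_oracle <- function(x, y, x0, level = 0.95) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  fit <- intercept + slope * x0
  se <- sqrt(s2 * (1 / n + (x0 - xbar)^2 / sxx))
  tq <- qt(1 - (1 - level) / 2, df = n - 2)
  list(intercept = intercept, slope = slope, fit = fit,
       lwr = fit - tq * se, upr = fit + tq * se)
}

# input level for a target surplus, by 1e-4-step grid search with linear
# interpolation between the bracketing cells
required_input_grid_search <- function(c_coef, target) {
  hi <- target + sqrt(target^2 + 4 * c_coef * target)  # generous upper bound
  grid <- seq(0, hi, by = hi * 1e-4)
  surp <- grid^2 / (c_coef + grid)
  idx <- which(surp >= target)[1]
  f <- (target - surp[idx - 1]) / (surp[idx] - surp[idx - 1])
  grid[idx - 1] + f * (grid[idx] - grid[idx - 1])
}
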