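# Independent oracle: posterior of the pooled log HR by 2-D grid
# quadrature over (theta, tau), integrating each site's profile likelihood
# against the Normal(theta, tau^2) random-effects kernel and the priors.
quadrature_theta_median <- function(profiles, theta_prior_sd = 2,
                                    tau_prior_sd = 0.5,
                                    theta_grid = seq(-2, 2, by = 0.005),
                                    tau_grid = seq(0, 1.5, by = 0.025)) {
  xg <- profiles[[1]]$log_hr
  dx <- xg[2] - xg[1]
  liks <- lapply(profiles, function(p) exp(p$log_lik))
  post <- numeric(length(theta_grid))
  for (tau in tau_grid) {
    site <- matrix(0, length(profiles), length(theta_grid))
    if (tau == 0) {
      for (d in seq_along(profiles)) {
        site[d, ] <- approx(xg, liks[[d]], xout = theta_grid,
                            yleft = 0, yright = 0)$y
      }
    } else {
      k <- outer(xg, theta_grid, function(x, th) dnorm(x - th, 0, tau)) * dx
      for (d in seq_along(profiles)) site[d, ] <- as.vector(liks[[d]] %*% k)
    }
    post <- post + apply(site, 2, prod) *
      dnorm(theta_grid, 0, theta_prior_sd) *
      exp(-tau^2 / (2 * tau_prior_sd^2))
  }
  cdf <- cumsum(post) / sum(post)
  theta_grid[which.max(cdf >= 0.5)]
}

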