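# Independent oracles used across the test files.

# Penalized log-likelihood evaluated from its definition, independently
# of the package's fitting code: binomial log-likelihood plus half the
# log-determinant of X' W X.
oracle_pll <- function(beta, x, y) {
  p <- 1 / (1 + exp(-drop(x %*% beta)))
  if (any(p <= 0) || any(p >= 1)) {
    ll <- sum(y * drop(x %*% beta) - log(1 + exp(drop(x %*% beta))))
  } else {
    ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
  }
  w <- p * (1 - p)
  info <- t(x) %*% (x * w)
  dt <- det(info)
  if (dt <= 0) return(-Inf)
  ll + 0.5 * log(dt)
}

# Dense grid search maximizer of the penalized log-likelihood, zooming
# around the best point until the grid step falls below `step_tol`.
# Works for designs with up to 3 columns.
oracle_firth_grid <- function(x, y, half_width = 6, n_grid = 13,
                              step_tol = 1e-5, max_zoom = 12) {
  d <- ncol(x)
  center <- rep(0, d)
  width <- half_width
  for (zoom in seq_len(max_zoom)) {
    axes <- lapply(seq_len(d), function(j) {
      seq(center[j] - width, center[j] + width, length.out = n_grid)
    })
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, oracle_pll, x = x, y = y)
    center <- grid[which.max(vals), ]
    step <- 2 * width / (n_grid - 1)
    if (step < step_tol) break
    width <- 2 * step  # keep the previous best strictly interior
  }
  unname(center)
}

# Simulate one triple analysis dataset from the logistic interaction
# model: independent Bernoulli exposures and covariates, outcome from
# plogis(b0 + b1 A + b2 B + b3 AB + covariate effects).
simulate_triple <- function(n, b0, b1, b2, b3, p_a = 0.3, p_b = 0.3,
                            cov_eff = c(age65 = 0.3, male = 0.1,
                              bin3_4 = 0.15, bin_ge5 = 0.3)) {
  xa <- rbinom(n, 1, p_a)
  xb <- rbinom(n, 1, p_b)
  age65 <- rbinom(n, 1, 0.46)
  male <- rbinom(n, 1, 0.53)
  nbin <- sample(0:3, n, replace = TRUE)
  bin3_4 <- as.integer(nbin == 1)
  bin_ge5 <- as.integer(nbin >= 2)
  eta <- b0 + b1 * xa + b2 * xb + b3 * xa * xb +
    cov_eff[["age65"]] * age65 + cov_eff[["male"]] * male +
    cov_eff[["bin3_4"]] * bin3_4 + cov_eff[["bin_ge5"]] * bin_ge5
  y <- as.integer(runif(n) < plogis(eta))
  triple_dataset("drugA", "drugB", "eventE", data.frame(
    report_id = sprintf("r%05d", seq_len(n)),
    exposed_a = xa, exposed_b = xb, outcome = y,
    age65 = age65, male = male, bin3_4 = bin3_4, bin_ge5 = bin_ge5,
    stringsAsFactors = FALSE
  ))
}

# Build a firth_fit-shaped object from given coefficients/covariance,
# for closed-form checks of the interaction measures.
fake_fit <- function(beta, cov = NULL) {
  nm <- names(beta)
  if (is.null(cov)) {
    cov <- diag(1e-4, length(beta))
    dimnames(cov) <- list(nm, nm)
  }
  structure(
    list(beta = beta, cov = cov, converged = TRUE, n_iter = 1,
      penalized_loglik = 0, max_score = 0, n = 0, n_events = 0,
      dropped = character(0)),
    class = "firth_fit"
  )
}
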