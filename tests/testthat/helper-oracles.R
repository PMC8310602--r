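# Independent numerical oracles and small fixture builders used across the
# test files.  Everything here is deliberately naive (dense, loop-based):
# the oracles must not share code paths with the implementation they check.

# Central finite-difference gradient of a scalar function.
num_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, 0)
}

# Dense central finite-difference Hessian of a scalar function.
num_hess <- function(fn, x, h = 1e-5) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    ei <- replace(numeric(d), i, h)
    ej <- replace(numeric(d), j, h)
    H[i, j] <- H[j, i] <-
      (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
         fn(x - ei - ej)) / (4 * h * h)
  }
  H
}

# Textbook natural cubic spline basis (truncated-power construction with
# the natural constraint solved by hand; ESL 5.2.1): dimension = number of
# knots, spanning the full natural-spline space including the constant.
truncated_power_natural_basis <- function(x, knots) {
  K <- length(knots)
  d <- function(k, x) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  out <- cbind(1, x)
  for (k in seq_len(K - 2))
    out <- cbind(out, d(k, x) - d(K - 1, x))
  out
}

# Exact Gaussian marginal log-density of a LMM: Y ~ N(X beta + offset,
# phi I + Z G Z').
gaussian_marginal_loglik <- function(data, beta, sigma, phi) {
  n <- length(data$y)
  sizes <- vapply(data$groups, function(g) length(g$levels), 1L)
  sd_u <- rep(sigma, times = sizes)
  Zd <- as.matrix(data$Z)
  V <- phi * diag(n) + Zd %*% (sd_u^2 * t(Zd))
  r <- data$y - as.numeric(data$X %*% beta) - data$offset
  -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
            sum(r * solve(V, r)))
}

# Small mixed toy datasets ---------------------------------------------

# Crossed poisson toy: n_pat patients x n_fac facilities, every cell
# observed `rep` times.
toy_crossed_data <- function(family = "poisson", n_pat = 2, n_fac = 2,
                             rep = 2, beta = 0.2, sigma = c(0.5, 0.3),
                             seed = 42) {
  grid <- expand.grid(pat = seq_len(n_pat), fac = seq_len(n_fac),
                      k = seq_len(rep))
  n <- nrow(grid)
  set.seed(seed)
  u_pat <- rnorm(n_pat, 0, sigma[1])
  u_fac <- rnorm(n_fac, 0, sigma[2])
  X <- cbind(1, runif(n, -1, 1))
  eta <- X %*% c(beta, 0.5) + u_pat[grid$pat] + u_fac[grid$fac]
  y <- switch(family,
              poisson = rpois(n, exp(eta)),
              bernoulli = rbinom(n, 1, plogis(eta)),
              gaussian = rnorm(n, eta, 1))
  glmm_data(y = y, X = X, family = family,
            groups = list(
              pat = list(name = "pat", levels = as.character(seq_len(n_pat)),
                         index = grid$pat),
              fac = list(name = "fac", levels = as.character(seq_len(n_fac)),
                         index = grid$fac)))
}

# Single-factor toy with n_group groups of size m.
toy_single_factor <- function(family = "poisson", n_group = 50, m = 5,
                              beta = c(-0.5, 0.4), sigma = 0.7, seed = 7) {
  n <- n_group * m
  g <- rep(seq_len(n_group), each = m)
  set.seed(seed)
  u <- rnorm(n_group, 0, sigma)
  X <- cbind(1, rnorm(n))
  eta <- as.numeric(X %*% beta) + u[g]
  y <- switch(family,
              poisson = rpois(n, exp(eta)),
              bernoulli = rbinom(n, 1, plogis(eta)),
              gaussian = rnorm(n, eta, 1))
  glmm_data(y = y, X = X, family = family,
            groups = list(g = list(name = "g",
                                   levels = as.character(seq_len(n_group)),
                                   index = g)))
}

# One-observation poisson fixture used for the closed-form spot checks.
toy_pois1 <- function() {
  glmm_data(y = 1, X = matrix(1, 1, 1), family = "poisson",
            groups = list(g = list(name = "g", levels = "a", index = 1L)))
}
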