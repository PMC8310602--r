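# Gauss-Hermite rules (physicists' convention, weight exp(-x^2)), cached
# per order.
.gh_cache <- new.env(parent = emptyenv())

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the weight function \eqn{e^{-x^2}}; an order-m
#' rule integrates polynomials of degree 2m - 1 against that kernel
#' exactly.  The \eqn{\sqrt 2} rescaling to Gaussian densities is absorbed
#' into the adaptive transform at the point of use.
#'
#' @param m Order (>= 1).
#' @return List with `x` (nodes, symmetric about 0) and `w` (positive
#'   weights summing to \eqn{\sqrt\pi}).
#' @export
gh_rule <- function(m) {
  key <- as.character(m)
  if (is.null(.gh_cache[[key]])) {
    if (m < 1) stop("quadrature order must be >= 1")
    .gh_cache[[key]] <- if (m == 1) list(x = 0, w = sqrt(pi)) else
      pracma::gaussHermite(m)
  }
  .gh_cache[[key]]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-group 1-D inner mode of the conditional h contribution by Newton.
group_mode_1d <- function(y, eta_base, family, sigma, phi,
                          tol = 1e-11, max_iter = 100L) {
  u <- 0
  h_of <- function(u) {
    mu <- family$linkinv(eta_base + u)
    sum(family$logdens(y, mu, phi)) + stats::dnorm(u, 0, sigma, log = TRUE)
  }
  h <- h_of(u)
  for (it in seq_len(max_iter)) {
    mu <- family$linkinv(eta_base + u)
    g <- sum(family$score_eta(y, mu, phi)) - u / sigma^2
    curv <- sum(family$weight_eta(y, mu, phi)) + 1 / sigma^2
    if (abs(g) <= tol) break
    step <- g / curv
    repeat {
      h_new <- h_of(u + step)
      if (is.finite(h_new) && h_new >= h - 1e-14) break
      step <- step / 2
      if (abs(step) < 1e-15) break
    }
    u <- u + step
    h <- h_of(u)
  }
  mu <- family$linkinv(eta_base + u)
  list(mode = u, h = h,
       curv = sum(family$weight_eta(y, mu, phi)) + 1 / sigma^2)
}

#' Adaptive Gauss-Hermite marginal log-likelihood (single grouping factor)
#'
#' For models with one grouping factor the marginal likelihood factorizes
#' into independent univariate integrals per group; each is computed by an
#' order-m Gauss-Hermite rule centered at the group's conditional mode and
#' scaled by the curvature of h there (full adaptivity: centers and scales
#' are recomputed at every parameter value).  `m = 1` reproduces the
#' Laplace approximation exactly.
#'
#' @param data A [glmm_data()] with exactly one grouping factor.
#' @param params Parameter values: list with `beta`, `sigma` (scalar),
#'   `phi`.
#' @param m Quadrature order.
#' @return The marginal log-likelihood of `beta, sigma, phi`.
#' @export
agh_loglik <- function(data, params, m = 25) {
  if (length(data$groups) != 1L)
    stop("unsupported structure: AGH requires exactly one grouping factor")
  rule <- gh_rule(m)
  g <- data$groups[[1]]
  eta0 <- as.numeric(data$X %*% params$beta + data$offset)
  fam <- data$family
  sigma <- params$sigma[1]
  phi <- params$phi %||% 1
  total <- 0
  for (k in seq_along(g$levels)) {
    rows <- which(g$index == k)
    y_k <- data$y[rows]
    eta_k <- eta0[rows]
    md <- group_mode_1d(y_k, eta_k, fam, sigma, phi)
    s <- 1 / sqrt(md$curv)
    u_nodes <- md$mode + sqrt(2) * s * rule$x
    lt <- vapply(seq_len(m), function(j) {
      mu <- fam$linkinv(eta_k + u_nodes[j])
      sum(fam$logdens(y_k, mu, phi)) +
        stats::dnorm(u_nodes[j], 0, sigma, log = TRUE) + rule$x[j]^2 +
        log(rule$w[j])
    }, 0)
    if (any(!is.finite(lt) & rule$w > 0) && all(!is.finite(lt)))
      stop("numerical error: non-finite integrand in group ", k)
    total <- total + log(sqrt(2) * s) + logsumexp(lt)
  }
  total
}

#' Maximum-likelihood fit by adaptive Gauss-Hermite quadrature
#'
#' Verification-grade ML estimation for single-grouping-factor models:
#' maximizes [agh_loglik()] over `(beta, log sigma[, log phi])` by
#' quasi-Newton.  Intended as an independent oracle for the Laplace-based
#' estimators, not as a production fitting route.
#'
#' @inheritParams agh_loglik
#' @param control An [hlik_control()] (starting values only).
#' @return List with `beta`, `sigma`, `phi`, `se_beta` (from the numerical
#'   Hessian), `loglik`, `convergence`.
#' @export
fit_agh <- function(data, m = 25, control = hlik_control()) {
  p <- ncol(data$X)
  est_phi <- !data$family$dispersion_known
  theta_fun <- function(par)
    list(beta = par[seq_len(p)], sigma = exp(par[p + 1]),
         phi = if (est_phi) exp(par[p + 2]) else 1)
  fn <- function(par) agh_loglik(data, theta_fun(par), m)
  par0 <- c(unname(beta_init_glm(data)), log(control$sigma_init),
            if (est_phi) log(stats::var(data$y) / 2 + 1e-8))
  opt <- stats::optim(par0, function(p_) -fn(p_), method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  ses <- standard_errors(fn, opt$par, step = 1e-3)
  th <- theta_fun(opt$par)
  list(beta = th$beta, sigma = th$sigma, phi = th$phi,
       se_beta = ses$se[seq_len(p)], loglik = -opt$value,
       convergence = opt$convergence)
}

#' Exact marginal log-likelihood of a Gaussian linear mixed model
#'
#' Dense evaluation of the Gaussian marginal, `V = phi I + Z G Z'`, with
#' the fixed effects profiled out by generalized least squares.  For
#' `criterion = "REML"` the returned objective is the log of the marginal
#' likelihood additionally integrated over beta (flat prior), which equals
#' the Laplace adjusted profile \eqn{p_{\beta,u}(h)} exactly in the
#' Gaussian case.
#'
#' @param data A Gaussian [glmm_data()]; N capped (default 2000) since this
#'   is a test oracle.
#' @param sigma,phi Variance parameters at which to evaluate.
#' @param criterion `"ML"` or `"REML"`.
#' @return Scalar log-likelihood (profiled over beta).
#' @export
lmm_marginal_loglik <- function(data, sigma, phi, criterion = c("ML", "REML")) {
  criterion <- match.arg(criterion)
  n <- length(data$y)
  if (n > 2000) stop("size error: dense Gaussian oracle capped at N = 2000")
  sd_u <- expand_sigma(data, sigma)
  Zd <- as.matrix(data$Z)
  V <- phi * diag(n) + Zd %*% (sd_u^2 * t(Zd))
  R <- chol(V)
  Xw <- backsolve(R, data$X, transpose = TRUE)
  yw <- backsolve(R, data$y - data$offset, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  ld_V <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi) + ld_V + sum(resid^2))
  if (criterion == "REML") {
    p <- ncol(data$X)
    ll <- ll + 0.5 * p * log(2 * pi) - 0.5 * determinant(XtX)$modulus[1]
  }
  as.numeric(ll)
}

#' Closed-form Gaussian LMM estimates (verification oracle)
#'
#' Maximizes the exact Gaussian marginal likelihood (or its REML variant)
#' over the variance parameters by quasi-Newton on the log scale, with the
#' fixed effects profiled out by GLS.
#'
#' @param data A Gaussian [glmm_data()].
#' @param criterion `"ML"` or `"REML"`.
#' @param sigma_floor Lower clamp for the SDs.
#' @return List with `beta`, `sigma`, `phi`, `loglik`, `boundary`.
#' @export
lmm_closed_form <- function(data, criterion = c("ML", "REML"),
                            sigma_floor = 1e-4) {
  criterion <- match.arg(criterion)
  if (data$family$name != "gaussian") stop("gaussian family required")
  r <- length(data$groups)
  fn <- function(par) lmm_marginal_loglik(data, exp(par[seq_len(r)]),
                                          exp(par[r + 1]), criterion)
  par0 <- c(rep(log(0.5), r), log(stats::var(data$y) / 2 + 1e-8))
  lower <- c(rep(log(sigma_floor), r), -20)
  opt <- stats::optim(par0, function(p_) -fn(p_), method = "L-BFGS-B",
                      lower = lower, control = list(factr = 1e2,
                                                    maxit = 500))
  sigma <- exp(opt$par[seq_len(r)])
  phi <- exp(opt$par[r + 1])
  sd_u <- expand_sigma(data, sigma)
  n <- length(data$y)
  Zd <- as.matrix(data$Z)
  V <- phi * diag(n) + Zd %*% (sd_u^2 * t(Zd))
  R <- chol(V)
  Xw <- backsolve(R, data$X, transpose = TRUE)
  yw <- backsolve(R, data$y - data$offset, transpose = TRUE)
  beta <- as.numeric(solve(crossprod(Xw), crossprod(Xw, yw)))
  list(beta = beta, sigma = sigma, phi = phi, loglik = -opt$value,
       boundary = any(opt$par[seq_len(r)] <= log(sigma_floor) + 1e-8))
}

#' Tensor-grid marginal log-likelihood for tiny crossed models
#'
#' Brute-force verification oracle: a full tensor product of Gauss-Hermite
#' nodes over all random effects jointly (at most q = 4), centered at the
#' joint conditional mode and scaled by the Cholesky factor of the negative
#' Hessian there.  Converges to the exact marginal as `nodes_per_dim`
#' grows.
#'
#' @param data A [glmm_data()] with `ncol(Z) <= 4`.
#' @param params List with `beta`, `sigma`, `phi`.
#' @param nodes_per_dim Nodes per dimension of the tensor grid.
#' @return The marginal log-likelihood of the supplied parameters.
#' @export
bruteforce_marginal_loglik <- function(data, params, nodes_per_dim = 40) {
  q <- ncol(data$Z)
  if (q > 4) stop("size error: tensor-grid oracle limited to q <= 4")
  theta <- list(beta = params$beta, sigma = params$sigma,
                phi = params$phi %||% 1)
  sol <- inner_mode(data, theta, elim = "u", tol = 1e-12)
  negH <- as.matrix(sol$negH)
  R <- chol(negH)                       # t(R) %*% R = -H
  ld <- 2 * sum(log(diag(R)))
  rule <- gh_rule(nodes_per_dim)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes_per_dim)), q)))
  # u = mode + sqrt(2) * R^{-1} x  (Jacobian 2^{q/2} exp(-ld/2))
  X_nodes <- matrix(rule$x[grid], ncol = q)
  logw <- rowSums(matrix(log(rule$w)[grid], ncol = q))
  U <- t(sol$w + sqrt(2) * backsolve(R, t(X_nodes)))
  eta0 <- as.numeric(data$X %*% theta$beta + data$offset)
  sd_u <- expand_sigma(data, theta$sigma)
  fam <- data$family
  n_grid <- nrow(U)
  lt <- numeric(n_grid)
  chunk <- 200000L
  for (s in seq(1L, n_grid, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n_grid)
    Eta <- eta0 + tcrossprod(as.matrix(data$Z), U[idx, , drop = FALSE])
    Mu <- fam$linkinv(Eta)
    ll_y <- colSums(matrix(fam$logdens(data$y, Mu, theta$phi), nrow = length(data$y)))
    ll_u <- colSums(matrix(stats::dnorm(t(U[idx, , drop = FALSE]), 0, sd_u,
                                        log = TRUE), nrow = q))
    lt[idx] <- ll_y + ll_u + rowSums(X_nodes[idx, , drop = FALSE]^2) +
      logw[idx]
  }
  0.5 * q * log(2) - 0.5 * ld + logsumexp(lt)
}
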