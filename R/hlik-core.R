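#' Parameter state for a GLMM
#'
#' Bundles fixed effects, random effects, variance-component standard
#' deviations (one per grouping factor) and the dispersion into a single
#' validated object.
#'
#' @param beta Fixed-effect coefficients (length p).
#' @param u Random effects (length q, concatenated over grouping-factor
#'   blocks in the order of `data$groups`).
#' @param sigma Random-intercept standard deviations, one per grouping
#'   factor, strictly positive.
#' @param phi Dispersion (> 0); fixed at 1 for Poisson and Bernoulli.
#' @return A list of class `hlik_params`.
#' @export
hlik_params <- function(beta, u, sigma, phi = 1) {
  if (any(sigma <= 0)) stop("domain error: sigma must be strictly positive")
  if (phi <= 0) stop("domain error: phi must be strictly positive")
  structure(list(beta = as.numeric(beta), u = as.numeric(u),
                 sigma = as.numeric(sigma), phi = as.numeric(phi)),
            class = "hlik_params")
}

# Expand per-factor SDs to the length-q vector of per-coefficient SDs.
expand_sigma <- function(data, sigma) {
  sizes <- group_sizes(data)
  if (length(sigma) != length(sizes))
    stop("contract error: one sigma per grouping factor required")
  rep(sigma, times = sizes)
}

#' Linear predictor of a GLMM
#'
#' @param data A [glmm_data()] object.
#' @param params An [hlik_params()] state.
#' @return `eta = X beta + Z u + offset`, length N.
#' @export
linear_predictor <- function(data, params) {
  if (length(params$beta) != ncol(data$X) || length(params$u) != ncol(data$Z))
    stop("contract error: parameter dimensions do not match the design")
  as.numeric(data$X %*% params$beta + data$Z %*% params$u + data$offset)
}

#' Hierarchical log-likelihood
#'
#' The joint log-density of data and random effects,
#' \eqn{h = \log f(Y | \beta, u, \phi) + \log f(u | \gamma)},
#' with the random effects normal with mean zero and block-diagonal
#' covariance \eqn{\sigma_k^2 I} within grouping factor k.
#'
#' @inheritParams linear_predictor
#' @return Scalar value of h.
#' @export
h_loglik <- function(data, params) {
  eta <- linear_predictor(data, params)
  mu <- data$family$linkinv(eta)
  sd_u <- expand_sigma(data, params$sigma)
  sum(data$family$logdens(data$y, mu, params$phi)) +
    sum(stats::dnorm(params$u, 0, sd_u, log = TRUE))
}

# Columns of the elimination-set design [X | Z] or [Z], plus the prior
# precision of each eliminated coordinate (0 for beta).  The sparse design
# is assembled once per data object and cached.
elim_design <- function(data, params, elim = c("u", "beta_u")) {
  elim <- match.arg(elim)
  cache <- data$cache %||% new.env(parent = emptyenv())
  key <- paste0("A_", elim)
  if (is.null(cache[[key]])) {
    cache[[key]] <- if (elim == "beta_u")
      cbind(methods::as(methods::as(data$X, "CsparseMatrix"),
                        "generalMatrix"), data$Z)
    else data$Z
  }
  sd_u <- expand_sigma(data, params$sigma)
  prec <- if (elim == "beta_u") c(rep(0, ncol(data$X)), 1 / sd_u^2)
          else 1 / sd_u^2
  list(A = cache[[key]], prec = prec)
}

#' Gradient of the hierarchical log-likelihood
#'
#' Exact analytic score of h with respect to the eliminated coordinates:
#' `t(A) %*% score_eta` minus the Gaussian penalty score `u / sigma^2` for
#' the random-effect coordinates (A is `[X | Z]` or `[Z]`).
#'
#' @inheritParams linear_predictor
#' @param elim `"u"` (random effects only) or `"beta_u"` (fixed and random
#'   effects jointly).
#' @return Numeric gradient vector over the elimination set (beta
#'   coordinates first when included).
#' @export
h_gradient <- function(data, params, elim = c("u", "beta_u")) {
  elim <- match.arg(elim)
  eta <- linear_predictor(data, params)
  mu <- data$family$linkinv(eta)
  s <- data$family$score_eta(data$y, mu, params$phi)
  d <- elim_design(data, params, elim)
  w <- if (elim == "beta_u") c(params$beta, params$u) else params$u
  as.numeric(Matrix::crossprod(d$A, s)) - d$prec * w
}

#' Sparse negative Hessian of the hierarchical log-likelihood
#'
#' Returns \eqn{-H(h, w) = A' W A + \mathrm{diag}(prec)} where W holds the
#' family curvature weights and prec the random-effect prior precisions
#' (zero for fixed-effect coordinates).  The sparsity pattern follows
#' directly from the grouping structure; no numerical thresholding is
#' applied.
#'
#' @inheritParams h_gradient
#' @return A sparse symmetric matrix (`dsCMatrix`), the negative Hessian.
#' @export
h_hessian <- function(data, params, elim = c("u", "beta_u")) {
  elim <- match.arg(elim)
  eta <- linear_predictor(data, params)
  mu <- data$family$linkinv(eta)
  w <- data$family$weight_eta(data$y, mu, params$phi)
  d <- elim_design(data, params, elim)
  M <- Matrix::crossprod(d$A, d$A * w) + Matrix::Diagonal(x = d$prec)
  Matrix::forceSymmetric(methods::as(M, "CsparseMatrix"))
}

#' Log-determinant of a sparse symmetric positive-definite matrix
#'
#' Computed from a sparse Cholesky factorization with a fill-reducing
#' permutation.
#'
#' @param M Sparse (or dense) symmetric positive-definite matrix.
#' @return `log det(M)`.
#' @export
logdet_spd <- function(M) {
  if (is.matrix(M)) M <- methods::as(M, "CsparseMatrix")
  M <- Matrix::forceSymmetric(M)
  ch <- tryCatch(suppressWarnings(Matrix::Cholesky(M, LDL = FALSE,
                                                   perm = TRUE)),
                 error = function(e)
                   stop("factorization error: matrix is not positive definite"))
  2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
}

# Assemble a full parameter state from theta (the retained parameters) and
# w (the eliminated coordinates).
params_from_w <- function(data, theta, w, elim) {
  p <- ncol(data$X)
  if (elim == "beta_u")
    hlik_params(beta = w[seq_len(p)], u = w[-seq_len(p)],
                sigma = theta$sigma, phi = theta$phi)
  else
    hlik_params(beta = theta$beta, u = w, sigma = theta$sigma,
                phi = theta$phi)
}

#' Inner Newton optimization of the hierarchical log-likelihood
#'
#' Maximizes h over the elimination set w (the random effects, or fixed
#' and random effects jointly) at fixed variance components and dispersion,
#' using Newton's method with sparse Cholesky solves and a step-halving
#' line search that never accepts a decrease in h.
#'
#' @inheritParams h_gradient
#' @param theta List of retained parameters: `sigma`, `phi`, and `beta`
#'   when only `u` is eliminated.
#' @param init Starting value for w (defaults to zeros).
#' @param tol Convergence tolerance on the sup-norm of the gradient.
#' @param max_iter Maximum Newton iterations.
#' @param chol Optional cached Cholesky factor (CHMfactor) with the
#'   pattern of the negative Hessian; reused via a numeric update.
#' @return An `inner_solution`: list with `w` (the mode), `params` (full
#'   parameter state at the mode), `negH` (sparse negative Hessian at the
#'   mode), `chol` (its Cholesky factor), `h_value`, `grad_norm`,
#'   `iterations`, `converged`, and `h_trace` (h after each accepted step).
#' @export
inner_mode <- function(data, theta, elim = c("u", "beta_u"), init = NULL,
                       tol = 1e-8, max_iter = 100L, chol = NULL) {
  elim <- match.arg(elim)
  p <- ncol(data$X)
  dim_w <- ncol(data$Z) + if (elim == "beta_u") p else 0L
  w <- if (is.null(init)) rep(0, dim_w) else as.numeric(init)
  if (length(w) != dim_w) stop("contract error: init has wrong length")

  d <- elim_design(data, theta_for_design(data, theta, elim), elim)
  A <- d$A; prec <- d$prec
  fam <- data$family
  phi <- theta$phi %||% 1
  y <- data$y
  # log-normalization of the Gaussian random-effect density (w-independent)
  pen_const <- -sum(0.5 * log(2 * pi / prec[prec > 0]))
  eta_fixed <- if (elim == "beta_u") data$offset else
    as.numeric(data$X %*% theta$beta + data$offset)
  # augmented design folds the prior precision into a single crossprod:
  # -H = A' W A + diag(prec) = [A; I]' diag(w, prec) [A; I]
  Aaug <- rbind(A, Matrix::Diagonal(dim_w))

  h_of <- function(eta, w) {
    mu <- fam$linkinv(eta)
    sum(fam$logdens(y, mu, phi)) - 0.5 * sum(prec * w^2) + pen_const
  }

  eta <- eta_fixed + as.numeric(A %*% w)
  h <- h_of(eta, w)
  if (!is.finite(h)) stop("optimization error: non-finite h at the start")
  h_trace <- h
  converged <- FALSE
  iter <- 0L
  mu <- fam$linkinv(eta)
  g <- as.numeric(Matrix::crossprod(A, fam$score_eta(y, mu, phi))) - prec * w

  while (iter < max_iter) {
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
    iter <- iter + 1L
    wgt <- fam$weight_eta(y, mu, phi)
    negH <- Matrix::crossprod(Aaug * sqrt(c(wgt, prec)))
    ch_ok <- tryCatch(suppressWarnings({
      chol <- if (is.null(chol)) Matrix::Cholesky(negH, LDL = FALSE, perm = TRUE)
              else Matrix::update(chol, negH)
      TRUE
    }), error = function(e) FALSE)
    if (!ch_ok)
      stop("optimization error: negative Hessian not positive definite ",
           "(iteration ", iter, ")")
    delta <- as.numeric(Matrix::solve(chol, g))
    Adelta <- as.numeric(A %*% delta)

    step <- 1
    accepted <- FALSE
    # near the mode a Newton step moves h by less than its floating-point
    # resolution; allow rounding-level slack in the monotonicity test
    slack <- 1e-12 * (1 + abs(h))
    for (half in 0:30) {
      w_new <- w + step * delta
      eta_new <- eta + step * Adelta
      h_new <- suppressWarnings(h_of(eta_new, w_new))
      if (is.finite(h_new) && h_new >= h - slack) {
        w <- w_new; eta <- eta_new; h <- h_new
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted)
      stop("optimization error: line search failed after 30 halvings ",
           "(iteration ", iter, ", |grad| = ", format(max(abs(g))), ")")
    h_trace <- c(h_trace, h)
    mu <- fam$linkinv(eta)
    g <- as.numeric(Matrix::crossprod(A, fam$score_eta(y, mu, phi))) -
      prec * w
  }

  # factor at the accepted mode (also covers the 0-iteration case)
  wgt <- fam$weight_eta(y, mu, phi)
  negH <- Matrix::crossprod(Aaug * sqrt(c(wgt, prec)))
  chol <- suppressWarnings(
    if (is.null(chol)) Matrix::Cholesky(negH, LDL = FALSE, perm = TRUE)
    else Matrix::update(chol, negH))

  params <- params_from_w(data, theta, w, elim)
  structure(list(w = w, params = params, negH = negH, chol = chol,
                 h_value = h, grad_norm = max(abs(g)), iterations = iter,
                 converged = converged, h_trace = h_trace, elim = elim),
            class = "inner_solution")
}

# Minimal parameter list needed by elim_design (sigma only).
theta_for_design <- function(data, theta, elim) {
  list(sigma = theta$sigma, phi = theta$phi %||% 1,
       beta = theta$beta %||% rep(0, ncol(data$X)))
}

#' Adjusted profile log-likelihood (Laplace approximation)
#'
#' Evaluates \eqn{p_w(h) = h(\theta, \hat w_\theta) - \tfrac12 \log | -H(h,
#' \hat w_\theta) / 2\pi |}, the Laplace approximation to the log of the
#' integral of exp(h) over the eliminated coordinates.  Eliminating `u`
#' gives the (approximate) marginal log-likelihood in \eqn{(\beta, \gamma,
#' \phi)}; eliminating `(beta, u)` gives the REML criterion in
#' \eqn{(\gamma, \phi)}.
#'
#' @inheritParams inner_mode
#' @return List with `value` (the adjusted profile log-likelihood) and
#'   `solution` (the [inner_mode()] result, reusable as a warm start).
#' @export
adjusted_profile_loglik <- function(data, theta, elim = c("u", "beta_u"),
                                    init = NULL, tol = 1e-8, chol = NULL) {
  elim <- match.arg(elim)
  sol <- inner_mode(data, theta, elim, init = init, tol = tol, chol = chol)
  d <- length(sol$w)
  ld <- 2 * as.numeric(Matrix::determinant(sol$chol, sqrt = TRUE)$modulus)
  list(value = sol$h_value - 0.5 * (ld - d * log(2 * pi)), solution = sol)
}
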