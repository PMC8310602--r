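#' Control parameters for the h-likelihood estimators
#'
#' @param sigma_init Starting value for every random-intercept SD.
#' @param outer_maxit Maximum quasi-Newton iterations of the outer
#'   optimization.
#' @param outer_reltol Relative objective-change convergence tolerance of
#'   the outer optimization.
#' @param fd_step Central finite-difference step for outer gradients
#'   (log scale for variance parameters).
#' @param hess_step Central finite-difference step for the numerical
#'   Hessians used for standard errors.
#' @param inner_tol Sup-norm gradient tolerance of the inner Newton solver.
#' @param sigma_floor Lower clamp for the SDs when the bound-constrained
#'   fallback is triggered.
#' @return A list of class `hlik_control`.
#' @export
hlik_control <- function(sigma_init = 0.5, outer_maxit = 200,
                         outer_reltol = 1e-8, fd_step = 1e-4,
                         hess_step = 1e-3, inner_tol = 1e-8,
                         sigma_floor = 1e-4) {
  structure(as.list(environment()), class = "hlik_control")
}

# Warm-started closure evaluating the adjusted profile log-likelihood for a
# given elimination set.  `theta_fun` maps the outer parameter vector to
# list(beta, sigma, phi).  The previous inner mode and Cholesky pattern are
# reused between calls.
apl_closure <- function(data, elim, theta_fun, control) {
  env <- new.env(parent = emptyenv())
  env$sol <- NULL
  fn <- function(par) {
    theta <- theta_fun(par)
    res <- tryCatch(adjusted_profile_loglik(
      data, theta, elim,
      init = if (!is.null(env$sol)) env$sol$w else NULL,
      tol = control$inner_tol,
      chol = if (!is.null(env$sol)) env$sol$chol else NULL),
      error = function(e) NULL)
    # overflow or an indefinite Hessian far from the optimum: report a
    # deep objective value so the outer line search backtracks
    if (is.null(res) || !is.finite(res$value)) return(-1e10)
    env$sol <- res$solution
    res$value
  }
  list(fn = fn, env = env)
}

# Central finite-difference gradient.
fd_gradient <- function(fn, x, step) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + step
    xm <- x; xm[i] <- x[i] - step
    (fn(xp) - fn(xm)) / (2 * step)
  }, 0)
}

# One or two finite-difference Newton polish steps after quasi-Newton
# termination: drives the outer parameters to a projected gradient near
# zero (quadratic local convergence), which BFGS's objective-change rule
# alone does not guarantee.
polish_newton <- function(fn, par, fd_step, hess_step, lower = NULL,
                          iters = 2L) {
  f0 <- fn(par)
  for (it in seq_len(iters)) {
    g <- fd_gradient(fn, par, fd_step)
    H <- fd_hessian(fn, par, hess_step)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- par + step
    if (!is.null(lower)) cand <- pmax(cand, lower)
    f1 <- fn(cand)
    if (is.finite(f1) && f1 >= f0 - 1e-10 * (1 + abs(f0))) {
      par <- cand
      f0 <- f1
    } else break
  }
  list(par = par, value = f0)
}

# Central finite-difference Hessian (symmetric).
fd_hessian <- function(fn, x, step) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  hs <- step * pmax(1, abs(x))
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, hs[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hs[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, hs[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * hs[i] * hs[j])
    }
  }
  H
}

#' Standard errors from a numerical Hessian at an optimum
#'
#' Computes the central-difference Hessian of a scalar log-likelihood-type
#' objective at a converged maximizer, inverts its negative to a covariance
#' matrix, and (for parameters optimized on the log scale) applies the
#' delta-method transform back to the natural scale.
#'
#' @param objective Scalar function being maximized.
#' @param optimum The maximizer.
#' @param scale `"natural"` or `"log"`; with `"log"` the returned SEs are
#'   `exp(optimum) * se_log` (SD-scale standard errors).
#' @param step Finite-difference step.
#' @return List with `se` (per coordinate; `NA` with `ok = FALSE` when the
#'   numerical Hessian is not negative definite), `cov` (covariance on the
#'   optimization scale) and `ok`.
#' @export
standard_errors <- function(objective, optimum, scale = c("natural", "log"),
                            step = 1e-3) {
  scale <- match.arg(scale)
  H <- fd_hessian(objective, optimum, step)
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0))
    return(list(se = rep(NA_real_, length(optimum)), cov = NULL, ok = FALSE))
  se <- sqrt(diag(cov))
  if (scale == "log") se <- exp(optimum) * se
  list(se = se, cov = cov, ok = TRUE)
}

# Starting fixed effects from an unpenalized GLM fit (random effects
# ignored); falls back to zeros on failure.
beta_init_glm <- function(data) {
  fam <- switch(data$family$name,
                poisson = stats::poisson(),
                bernoulli = stats::binomial(),
                gaussian = stats::gaussian())
  tryCatch({
    fit <- suppressWarnings(
      stats::glm.fit(x = data$X, y = data$y, family = fam,
                     offset = data$offset))
    b <- fit$coefficients
    b[!is.finite(b)] <- 0
    b
  }, error = function(e) rep(0, ncol(data$X)))
}

# Shared stage 1: REML-type maximization of p_{beta,u}(h) over log-sigma
# (and log-phi for gaussian).  Returns estimates, SEs, the final joint
# inner solution, and diagnostics.
stage1_reml <- function(data, control, se = TRUE) {
  r <- length(data$groups)
  if (r < 1) stop("at least one grouping factor is required")
  few <- vapply(data$groups, function(g) length(g$levels) < 2, TRUE)
  if (any(few))
    warning("grouping factor(s) with fewer than 2 levels: ",
            paste(names(data$groups)[few], collapse = ", "))
  est_phi <- !data$family$dispersion_known
  theta_fun <- function(par)
    list(sigma = exp(par[seq_len(r)]),
         phi = if (est_phi) exp(par[r + 1]) else 1)
  obj <- apl_closure(data, "beta_u", theta_fun, control)
  par0 <- c(rep(log(control$sigma_init), r),
            if (est_phi) log(stats::var(data$y) / 2 + 1e-8))

  negfn <- function(par) -obj$fn(par)
  neggr <- function(par) -fd_gradient(obj$fn, par, control$fd_step)
  opt <- stats::optim(par0, negfn, neggr, method = "BFGS",
                      control = list(maxit = control$outer_maxit,
                                     reltol = control$outer_reltol))
  boundary <- FALSE
  lb <- log(control$sigma_floor)
  if (any(opt$par[seq_len(r)] < lb)) {
    lower <- c(rep(lb, r), if (est_phi) -Inf)
    opt <- stats::optim(pmax(opt$par, lower), negfn, neggr,
                        method = "L-BFGS-B", lower = lower,
                        control = list(maxit = control$outer_maxit,
                                       factr = 1e4))
    boundary <- any(opt$par[seq_len(r)] <= lb + 1e-8)
  }
  if (se && !boundary) {
    # polish only in precision mode: benchmark loops (se = FALSE) do not
    # need the last 1e-4 of the outer parameters
    pol <- polish_newton(obj$fn, opt$par, control$fd_step,
                         control$hess_step)
    opt$par <- pol$par
  }
  theta_hat <- theta_fun(opt$par)
  value <- obj$fn(opt$par)          # refresh warm cache at the optimum
  ses <- if (se) standard_errors(obj$fn, opt$par, scale = "log",
                                 step = control$hess_step)
         else list(se = rep(NA_real_, length(opt$par)), ok = NA)
  if (se) value <- obj$fn(opt$par)  # re-anchor the inner mode at the optimum
  list(sigma = theta_hat$sigma, phi = theta_hat$phi,
       se_sigma = ses$se[seq_len(r)],
       se_phi = if (est_phi) ses$se[r + 1] else NA_real_,
       se_ok = ses$ok, objective = value, par = opt$par,
       solution = obj$env$sol, boundary = boundary,
       convergence = opt$convergence, counts = opt$counts)
}

# Stage 2: with (sigma, phi) fixed, maximize p_u(h) over beta.
stage2_beta <- function(data, sigma, phi, control, se = TRUE) {
  p <- ncol(data$X)
  theta_fun <- function(par) list(beta = par, sigma = sigma, phi = phi)
  obj <- apl_closure(data, "u", theta_fun, control)
  par0 <- unname(beta_init_glm(data))
  negfn <- function(par) -obj$fn(par)
  neggr <- function(par) -fd_gradient(obj$fn, par, control$fd_step)
  opt <- stats::optim(par0, negfn, neggr, method = "BFGS",
                      control = list(maxit = control$outer_maxit,
                                     reltol = control$outer_reltol))
  if (se)
    opt$par <- polish_newton(obj$fn, opt$par, control$fd_step,
                             control$hess_step)$par
  value <- obj$fn(opt$par)
  ses <- if (se) standard_errors(obj$fn, opt$par, step = control$hess_step)
         else list(se = rep(NA_real_, length(opt$par)), cov = NULL, ok = NA)
  if (se) value <- obj$fn(opt$par)
  list(beta = opt$par, se_beta = ses$se, vcov_beta = ses$cov,
       se_ok = ses$ok, objective = value, solution = obj$env$sol,
       convergence = opt$convergence, counts = opt$counts)
}

new_hlik_fit <- function(method, data, beta, se_beta, vcov_beta, sigma,
                         se_sigma, phi, se_phi, u, objectives, diagnostics) {
  names(beta) <- colnames(data$X)
  if (!is.null(se_beta)) names(se_beta) <- colnames(data$X)
  if (!is.null(vcov_beta) && nrow(vcov_beta) == ncol(data$X))
    dimnames(vcov_beta) <- list(colnames(data$X), colnames(data$X))
  names(sigma) <- names(data$groups)
  if (!is.null(se_sigma)) names(se_sigma) <- names(data$groups)
  names(u) <- unlist(lapply(data$groups, function(g)
    paste(g$name, g$levels, sep = ":")), use.names = FALSE)
  structure(
    list(method = method, beta = beta, se_beta = se_beta,
         vcov_beta = vcov_beta, sigma = sigma, se_sigma = se_sigma,
         phi = phi, se_phi = se_phi, u = u, objectives = objectives,
         diagnostics = diagnostics, terms = data$terms,
         groups = lapply(data$groups, function(g)
           list(name = g$name, levels = g$levels)),
         dims = c(n = length(data$y), p = ncol(data$X), q = ncol(data$Z))),
    class = "hlik_fit")
}

#' Fit a GLMM by the two-stage HL(1,1) hierarchical-likelihood procedure
#'
#' Stage 1 maximizes the REML-type adjusted profile likelihood
#' \eqn{p_{\beta,u}(h)} over the log variance-component SDs (and the log
#' dispersion for Gaussian responses) by quasi-Newton with warm-started
#' finite-difference gradients, yielding \eqn{\hat\gamma, \hat\phi} with
#' standard errors from the numerical Hessian of the stage-1 objective.
#' Stage 2 fixes them and maximizes \eqn{p_u(h)} over the fixed effects
#' \eqn{\beta}.  The random-effect predictions are read from the stage-2
#' inner mode; a third conditional optimization is available separately as
#' [refit_random_effects()].
#'
#' @param data A [glmm_data()] object.
#' @param control An [hlik_control()] list.
#' @return An object of class `hlik_fit` with elements `method`
#'   (`"HL11"`), `beta`, `se_beta`, `vcov_beta`, `sigma` (SD scale),
#'   `se_sigma`, `phi`, `se_phi`, `u`, `objectives` (stage-1 and stage-2
#'   optima of the adjusted profiles) and `diagnostics`.
#' @seealso [fit_hl01()], [fit_ml_laplace()]
#' @export
fit_hl11 <- function(data, control = hlik_control(), se = TRUE) {
  s1 <- stage1_reml(data, control, se = se)
  s2 <- stage2_beta(data, s1$sigma, s1$phi, control, se = se)
  u_hat <- s2$solution$w
  new_hlik_fit(
    "HL11", data,
    beta = s2$beta, se_beta = s2$se_beta, vcov_beta = s2$vcov_beta,
    sigma = s1$sigma, se_sigma = s1$se_sigma, phi = s1$phi,
    se_phi = s1$se_phi, u = u_hat,
    objectives = list(stage1 = s1$objective, stage2 = s2$objective),
    diagnostics = list(
      converged = s1$convergence == 0 && s2$convergence == 0 &&
        s1$solution$converged && s2$solution$converged,
      boundary = s1$boundary, se_ok = s1$se_ok && s2$se_ok,
      stage1 = list(convergence = s1$convergence, counts = s1$counts),
      stage2 = list(convergence = s2$convergence, counts = s2$counts)))
}

#' Fit a GLMM by the HL(0,1) joint shortcut
#'
#' Runs only stage 1 of the HL(1,1) procedure (identical variance
#' components, same optimizer trace) and reads the fixed and random effects
#' from the final joint inner mode of \eqn{p_{\beta,u}(h)}, skipping the
#' second optimization.  Standard errors for \eqn{\beta} come from the
#' corresponding diagonal block of the inverse joint curvature at the mode.
#' This shortcut can be visibly biased for sparse binary outcomes with few
#' observations per cluster.
#'
#' @inheritParams fit_hl11
#' @return An `hlik_fit` with `method = "HL01"`.
#' @export
fit_hl01 <- function(data, control = hlik_control(), se = TRUE) {
  s1 <- stage1_reml(data, control, se = se)
  p <- ncol(data$X)
  w <- s1$solution$w
  beta_hat <- w[seq_len(p)]
  u_hat <- w[-seq_len(p)]
  Ep <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(nrow(s1$solution$negH), p))
  cov_beta <- as.matrix(Matrix::solve(s1$solution$negH, Ep))[seq_len(p), ,
                                                             drop = FALSE]
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  new_hlik_fit(
    "HL01", data,
    beta = beta_hat, se_beta = sqrt(pmax(diag(cov_beta), 0)),
    vcov_beta = cov_beta,
    sigma = s1$sigma, se_sigma = s1$se_sigma, phi = s1$phi,
    se_phi = s1$se_phi, u = u_hat,
    objectives = list(stage1 = s1$objective, stage2 = NA_real_),
    diagnostics = list(
      converged = s1$convergence == 0 && s1$solution$converged,
      boundary = s1$boundary, se_ok = s1$se_ok,
      stage1 = list(convergence = s1$convergence, counts = s1$counts)))
}

#' Fit a GLMM by maximum likelihood with the Laplace approximation
#'
#' Maximizes the Laplace-approximated marginal log-likelihood
#' \eqn{p_u(h)} jointly over \eqn{(\beta, \log\gamma[, \log\phi])} — the
#' classical ML route, equivalent to adaptive Gauss-Hermite quadrature with
#' a single node.  Standard errors come from the numerical Hessian at the
#' optimum.
#'
#' @inheritParams fit_hl11
#' @return An `hlik_fit` with `method = "ML"`.
#' @export
fit_ml_laplace <- function(data, control = hlik_control(), se = TRUE) {
  p <- ncol(data$X)
  r <- length(data$groups)
  if (r < 1) stop("at least one grouping factor is required")
  est_phi <- !data$family$dispersion_known
  theta_fun <- function(par)
    list(beta = par[seq_len(p)],
         sigma = exp(par[p + seq_len(r)]),
         phi = if (est_phi) exp(par[p + r + 1]) else 1)
  obj <- apl_closure(data, "u", theta_fun, control)
  par0 <- c(unname(beta_init_glm(data)), rep(log(control$sigma_init), r),
            if (est_phi) log(stats::var(data$y) / 2 + 1e-8))
  negfn <- function(par) -obj$fn(par)
  neggr <- function(par) -fd_gradient(obj$fn, par, control$fd_step)
  opt <- stats::optim(par0, negfn, neggr, method = "BFGS",
                      control = list(maxit = control$outer_maxit,
                                     reltol = control$outer_reltol))
  boundary <- FALSE
  lb <- log(control$sigma_floor)
  if (any(opt$par[p + seq_len(r)] < lb)) {
    lower <- c(rep(-Inf, p), rep(lb, r), if (est_phi) -Inf)
    opt <- stats::optim(pmax(opt$par, lower), negfn, neggr,
                        method = "L-BFGS-B", lower = lower,
                        control = list(maxit = control$outer_maxit,
                                       factr = 1e4))
    boundary <- any(opt$par[p + seq_len(r)] <= lb + 1e-8)
  }
  if (se && !boundary) {
    pol <- polish_newton(obj$fn, opt$par, control$fd_step,
                         control$hess_step)
    opt$par <- pol$par
  }
  theta_hat <- theta_fun(opt$par)
  value <- obj$fn(opt$par)
  ses <- if (se) standard_errors(obj$fn, opt$par, step = control$hess_step)
         else list(se = rep(NA_real_, p + r + est_phi), cov = NULL, ok = NA)
  if (se) value <- obj$fn(opt$par)
  se_sigma <- if (isTRUE(ses$ok)) theta_hat$sigma * ses$se[p + seq_len(r)]
              else rep(NA_real_, r)
  new_hlik_fit(
    "ML", data,
    beta = theta_hat$beta,
    se_beta = ses$se[seq_len(p)],
    vcov_beta = if (isTRUE(ses$ok)) ses$cov[seq_len(p), seq_len(p),
                                            drop = FALSE] else NULL,
    sigma = theta_hat$sigma, se_sigma = se_sigma,
    phi = theta_hat$phi,
    se_phi = if (est_phi && isTRUE(ses$ok))
      theta_hat$phi * ses$se[p + r + 1] else NA_real_,
    u = obj$env$sol$w,
    objectives = list(stage1 = NA_real_, stage2 = value),
    diagnostics = list(
      converged = opt$convergence == 0 && obj$env$sol$converged,
      boundary = boundary, se_ok = ses$ok,
      stage1 = list(convergence = opt$convergence, counts = opt$counts)))
}

#' Third-stage conditional refit of the random effects
#'
#' Maximizes the hierarchical log-likelihood
#' \eqn{h(\hat\beta, u, \hat\gamma, \hat\phi)} over `u` alone, with all
#' other parameters fixed at their estimates.  The default fits instead
#' reuse the stage-2 (or joint stage-1) inner mode, which is typically very
#' close; this function makes the conditional mode available for
#' comparison.
#'
#' @param data The [glmm_data()] the fit was computed from.
#' @param fit An `hlik_fit`.
#' @return Numeric vector of refitted random effects (same naming as
#'   `fit$u`).
#' @export
refit_random_effects <- function(data, fit) {
  sol <- inner_mode(data,
                    theta = list(beta = unname(fit$beta),
                                 sigma = unname(fit$sigma), phi = fit$phi),
                    elim = "u", init = unname(fit$u))
  u3 <- sol$w
  names(u3) <- names(fit$u)
  u3
}

#' @export
print.hlik_fit <- function(x, digits = 4, ...) {
  cat("Hierarchical-likelihood GLMM fit  [", x$method, "]\n", sep = "")
  cat("  n = ", x$dims["n"], ", p = ", x$dims["p"], ", q = ", x$dims["q"],
      if (!isTRUE(x$diagnostics$converged)) "  ** NOT CONVERGED **",
      "\n\nFixed effects:\n", sep = "")
  print(round(cbind(estimate = x$beta, se = x$se_beta), digits))
  cat("\nRandom-intercept SDs:\n")
  print(round(cbind(sd = x$sigma, se = x$se_sigma), digits))
  if (!is.na(x$se_phi) || x$phi != 1)
    cat("\nDispersion:", format(x$phi, digits = digits),
        "(se", format(x$se_phi, digits = digits), ")\n")
  invisible(x)
}

#' Serialize a fit to JSON plus a random-effects CSV
#'
#' @param fit An `hlik_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param meta Optional named list of reproducibility metadata (seed,
#'   configuration hash, ...) embedded in the JSON.
#' @return Path of the JSON file, invisibly.
#' @export
write_fit_json <- function(fit, dir, prefix = "fit", meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranef_path <- file.path(dir, paste0(prefix, "_ranef.csv"))
  parts <- strsplit(names(fit$u), ":", fixed = TRUE)
  utils::write.csv(data.frame(
    factor = vapply(parts, `[[`, "", 1),
    level = vapply(parts, function(p) paste(p[-1], collapse = ":"), ""),
    estimate = unname(fit$u)), ranef_path, row.names = FALSE)
  out <- list(
    method = fit$method,
    coefficients = data.frame(name = names(fit$beta),
                              estimate = unname(fit$beta),
                              se = unname(fit$se_beta)),
    variance_components = data.frame(factor = names(fit$sigma),
                                     sd = unname(fit$sigma),
                                     se = unname(fit$se_sigma)),
    dispersion = fit$phi,
    random_effects = ranef_path,
    objectives = fit$objectives,
    diagnostics = fit$diagnostics[c("converged", "boundary", "se_ok")],
    metadata = c(meta, list(package_version =
                              as.character(utils::packageVersion("hlik")),
                            timestamp = format(Sys.time(), usetz = TRUE))))
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
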