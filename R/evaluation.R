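#' Absolute standardized bias of replicate estimates
#'
#' `100 * |mean(estimates) - truth| / sd(estimates)`, the bias of a
#' simulation estimator expressed in percent of the empirical replicate
#' standard deviation.
#'
#' @param estimates Numeric vector of estimates over replicates (>= 2).
#' @param truth True parameter value.
#' @return The absolute standardized bias in percent.
#' @export
standardized_bias <- function(estimates, truth) {
  if (length(estimates) < 2) stop("contract error: need >= 2 replicates")
  s <- stats::sd(estimates)
  if (s == 0) stop("undefined metric: zero replicate standard deviation")
  100 * abs(mean(estimates) - truth) / s
}

#' Mean squared error of replicate estimates
#'
#' @inheritParams standardized_bias
#' @return `mean((estimates - truth)^2)`.
#' @export
mse <- function(estimates, truth) {
  if (length(estimates) < 1) stop("contract error: empty estimate vector")
  mean((estimates - truth)^2)
}

# Extract the (beta, sigma) estimate vector of a fit, named consistently.
fit_param_vector <- function(fit) {
  c(fit$beta, stats::setNames(fit$sigma, paste0("sd_", names(fit$sigma))))
}

#' Compare estimation methods over replicate fits
#'
#' Computes per-parameter absolute standardized bias and MSE for each
#' method, and the pairwise between-method differences in standardized
#' bias (maximized over parameters) that summarize method agreement.
#'
#' @param fits Named list: method tag -> list of `hlik_fit` objects, all
#'   fitted to the same replicate datasets (equal lengths required).
#' @param truth Named true values covering the fixed effects (by
#'   coefficient name) and the variance components (as
#'   `sd_<factor name>`); parameters missing from `truth` are skipped.
#' @return An object of class `method_comparison`: list with `table`
#'   (parameter x method data frame of mean, sd, std_bias, mse),
#'   `pairwise` (symmetric matrix of max-over-parameters |delta
#'   std_bias|), and `max_pairwise`.
#' @export
compare_methods <- function(fits, truth) {
  stopifnot(is.list(fits), length(fits) >= 1)
  lens <- vapply(fits, length, 1L)
  if (length(unique(lens)) != 1)
    stop("contract error: methods fitted to different replicate sets")
  methods_ <- names(fits)
  est <- lapply(fits, function(fl)
    do.call(rbind, lapply(fl, fit_param_vector)))
  params <- intersect(colnames(est[[1]]), names(truth))
  if (!length(params)) stop("no parameters with declared truth")

  tab <- do.call(rbind, lapply(methods_, function(m) {
    do.call(rbind, lapply(params, function(p) {
      e <- est[[m]][, p]
      data.frame(parameter = p, method = m, mean = mean(e),
                 sd = stats::sd(e),
                 std_bias = standardized_bias(e, truth[[p]]),
                 mse = mse(e, truth[[p]]))
    }))
  }))
  rownames(tab) <- NULL

  sb <- matrix(tab$std_bias, nrow = length(params),
               dimnames = list(params, methods_))
  pw <- matrix(0, length(methods_), length(methods_),
               dimnames = list(methods_, methods_))
  for (a in methods_) for (b in methods_)
    pw[a, b] <- max(abs(sb[, a] - sb[, b]))
  structure(list(table = tab, pairwise = pw,
                 max_pairwise = max(pw)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 3, ...) {
  cat("Method comparison over", sum(x$table$method == x$table$method[1]),
      "parameters\n\n")
  print(cbind(x$table[1:2],
              round(x$table[c("mean", "sd", "std_bias", "mse")], digits)))
  cat("\nMax pairwise |delta standardized bias| (percentage points):",
      round(x$max_pairwise, digits), "\n")
  invisible(x)
}

#' Agreement between two sets of random-effect predictions
#'
#' Bland-Altman-style numerical summary for the random effects of two fits
#' of the same dataset: Pearson correlation, mean difference, and the
#' +/- 1.96 SD limits of agreement.
#'
#' @param fit1,fit2 `hlik_fit` objects sharing random-effect names.
#' @return List with `correlation`, `mean_difference`, `loa`
#'   (length-2 limits of agreement), `n`.
#' @export
ranef_agreement <- function(fit1, fit2) {
  common <- intersect(names(fit1$u), names(fit2$u))
  if (!length(common)) stop("contract error: no shared random effects")
  a <- fit1$u[common]; b <- fit2$u[common]
  d <- a - b
  list(correlation = stats::cor(a, b), mean_difference = mean(d),
       loa = mean(d) + c(-1, 1) * 1.96 * stats::sd(d), n = length(common))
}

#' Relative-risk curve from a fitted spline term
#'
#' Builds the curve `RR(v) = exp([B(v) - B(ref)] beta_spline)` over a grid
#' of covariate values, with 95 percent pointwise confidence bands from
#' the delta method applied to the spline-block covariance.  At the
#' reference value the relative risk is exactly 1 with a zero-width band.
#' Values beyond the boundary knots follow the linear tails of the natural
#' spline (a warning is raised).
#'
#' @param fit An `hlik_fit` whose model contained a spline term for `var`.
#' @param var Name of the spline covariate.
#' @param grid Numeric grid of covariate values.
#' @param reference Reference value (RR = 1 anchor).
#' @return Data frame with columns `value`, `rr`, `lower`, `upper`.
#' @export
rr_curve <- function(fit, var, grid, reference = 4.0) {
  term <- NULL
  for (t_ in fit$terms) if (t_$name == var && t_$type == "spline") term <- t_
  if (is.null(term)) stop("no spline term for '", var, "' in the fit")
  if (is.null(fit$vcov_beta))
    stop("fit carries no coefficient covariance; bands unavailable")
  basis <- term$basis
  if (any(grid < basis$boundary[1] | grid > basis$boundary[2]))
    warning("extrapolation warning: grid extends beyond the boundary ",
            "knots; linear tails apply")
  D <- eval_spline_basis(basis, grid) -
    matrix(eval_spline_basis(basis, reference), nrow = length(grid),
           ncol = basis$df, byrow = TRUE)
  cols <- term$columns
  b <- fit$beta[cols]
  V <- fit$vcov_beta[cols, cols, drop = FALSE]
  log_rr <- as.numeric(D %*% b)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  data.frame(value = grid, rr = exp(log_rr),
             lower = exp(log_rr - 1.96 * se),
             upper = exp(log_rr + 1.96 * se))
}
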