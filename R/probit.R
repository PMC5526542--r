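#' Probit log-likelihood
#'
#' \deqn{\ell(\beta) = \sum_i y_i \log\Phi(x_i'\beta) +
#'   (1 - y_i)\log(1 - \Phi(x_i'\beta))}
#' evaluated through `pnorm(log.p = TRUE)` so large \eqn{|x_i'\beta|} do not
#' underflow.
#'
#' @param beta coefficient vector.
#' @param y 0/1 outcome vector.
#' @param X design matrix (a [build_design_matrix()] result or numeric
#'   matrix) conforming with `beta`.
#' @return scalar log-likelihood.
#' @export
probit_loglik <- function(beta, y, X) {
  X <- .design_X(X)
  if (!all(y %in% c(0, 1))) stop("'y' must be 0/1", call. = FALSE)
  q <- 2 * y - 1
  sum(stats::pnorm(q * drop(X %*% beta), log.p = TRUE))
}

# phi(u)/Phi(u), stable in the lower tail
.mills <- function(u) {
  exp(stats::dnorm(u, log = TRUE) - stats::pnorm(u, log.p = TRUE))
}

# gradient of the probit log-likelihood
.probit_grad <- function(beta, y, X) {
  q <- 2 * y - 1
  u <- q * drop(X %*% beta)
  drop(crossprod(X, q * .mills(u)))
}

# observed information (negative Hessian) of the probit log-likelihood
.probit_info <- function(beta, y, X) {
  q <- 2 * y - 1
  u <- q * drop(X %*% beta)
  l <- .mills(u)
  crossprod(X * sqrt(l * (l + u)), X)
}

#' Fit a probit model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of [probit_loglik()] with analytic
#' gradient from a zero start; standard errors from the inverse observed
#' information. Complete separation and one-class outcomes raise explicit
#' errors.
#'
#' @param y 0/1 outcome vector.
#' @param X design matrix ([build_design_matrix()] result or numeric
#'   matrix) with full column rank.
#' @param tol gradient-norm convergence tolerance.
#' @param maxit maximum BFGS iterations.
#' @return object of class `probit_fit`: coefficients, `vcov`, `se`,
#'   `loglik`, `converged`, `n`, plus the design metadata.
#' @export
fit_probit <- function(y, X, tol = 1e-8, maxit = 200) {
  dm <- if (inherits(X, "design_matrix")) X else NULL
  X <- .design_X(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; probit is not estimable",
         call. = FALSE)
  }
  p <- ncol(X)
  opt <- stats::optim(rep(0, p),
                      fn = function(b) -probit_loglik(b, y, X),
                      gr = function(b) -.probit_grad(b, y, X),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  beta <- opt$par
  ll <- -opt$value
  # Newton polish: the probit log-likelihood is concave, so a few damped
  # Newton steps drive the gradient to the stated tolerance
  for (it in seq_len(25)) {
    g <- .probit_grad(beta, y, X)
    if (sqrt(sum(g^2)) <= tol * max(1, abs(ll))) break
    step <- tryCatch(solve(.probit_info(beta, y, X), g),
                     error = function(e) g * 0)
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- probit_loglik(cand, y, X)
      if (llc >= ll || h < 1e-8) break
      h <- h / 2
    }
    if (llc < ll) break
    beta <- cand
    ll <- llc
  }
  opt$value <- -ll
  g <- .probit_grad(beta, y, X)
  eta <- drop(X %*% beta)
  # complete separation: the fitted index splits the classes exactly
  if (min(eta[y == 1]) > max(eta[y == 0]) ||
      max(abs(beta)) > 1e2) {
    stop("perfect separation detected; probit estimates diverge",
         call. = FALSE)
  }
  if (sqrt(sum(g^2)) > tol * max(1, abs(opt$value))) {
    stop("probit estimation did not converge (gradient norm ",
         format(sqrt(sum(g^2))), ")", call. = FALSE)
  }
  info <- .probit_info(beta, y, X)
  vc <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix", call. = FALSE))
  vc <- (vc + t(vc)) / 2
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
    loglik = -opt$value, converged = TRUE, n = length(y),
    gradient_norm = sqrt(sum(g^2)),
    dimension = if (!is.null(dm)) dm$dimension else NULL,
    X = X, y = y
  ), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit: n = %d, logLik = %.3f\n", x$n, x$loglik))
  print(coef_table(x))
  invisible(x)
}

#' Coefficient table with z statistics and significance stars
#'
#' @param fit a `probit_fit` or `biprobit_fit`.
#' @param equation for biprobit fits, `"outcome"` or `"treatment"`.
#' @return data.frame with estimate, se, z, p and stars
#'   (* p<0.05, ** p<0.01, *** p<0.001).
#' @export
coef_table <- function(fit, equation = "outcome") {
  if (inherits(fit, "biprobit_fit")) {
    idx <- if (equation == "outcome") fit$idx_outcome else fit$idx_treatment
    est <- fit$coefficients[idx]
    se <- fit$se[idx]
  } else {
    est <- fit$coefficients
    se <- fit$se
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                  ifelse(p < 0.05, "*", "")))
  data.frame(estimate = est, se = se, z = z, p = p, stars = stars)
}

#' Counterfactual average predicted probability (probit)
#'
#' Average structural function: the dimension column is set to `d` for
#' every row and \eqn{\mathrm{mean}_i\,\Phi(x_i(d)'\hat\beta)} is returned.
#' Subgroup means over rows observed at the given dimension value are
#' available via `type = "subgroup"`.
#'
#' @param fit a `probit_fit` whose design includes a dimension column.
#' @param X design matrix used for the fit (defaults to the stored one).
#' @param d counterfactual dimension value, 0 or 1.
#' @param dimension name of the dimension column (defaults to the one
#'   recorded at fit time).
#' @param type `"counterfactual"` (default) or `"subgroup"`.
#' @return scalar probability.
#' @export
average_predicted_probability <- function(fit, X = NULL, d,
                                          dimension = NULL,
                                          type = c("counterfactual",
                                                   "subgroup")) {
  type <- match.arg(type)
  if (!d %in% c(0, 1)) stop("'d' must be 0 or 1", call. = FALSE)
  X <- if (is.null(X)) fit$X else .design_X(X)
  dimension <- if (is.null(dimension)) fit$dimension else dimension
  if (is.null(dimension) || !dimension %in% colnames(X)) {
    # no dimension column: the counterfactual is the plain average
    return(mean(stats::pnorm(drop(X %*% fit$coefficients))))
  }
  if (type == "subgroup") {
    rows <- X[, dimension] == d
    return(mean(stats::pnorm(drop(X[rows, , drop = FALSE] %*%
                                    fit$coefficients))))
  }
  Xd <- X
  Xd[, dimension] <- d
  mean(stats::pnorm(drop(Xd %*% fit$coefficients)))
}
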