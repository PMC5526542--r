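#' Default covariate specification for the DHS-like generator
#'
#' Categorical covariates mirroring those commonly controlled for in
#' South / South-East Asian DHS analyses of institutional delivery:
#' residence, parental education, mother's age group, working status,
#' birth order, children ever born (CEB), say in health-care decisions,
#' wealth quintile, media exposure (newspaper, radio, television),
#' religion and caste. The first label of each covariate is its
#' reference category in the design matrix.
#'
#' @return named list; each element has `labels` and `probs` (summing to 1).
#' @export
default_covariate_spec <- function() {
  list(
    residence        = list(labels = c("rural", "urban"),
                            probs  = c(0.65, 0.35)),
    mother_education = list(labels = c("none", "primary", "secondary", "higher"),
                            probs  = c(0.35, 0.25, 0.30, 0.10)),
    husband_education = list(labels = c("none", "primary", "secondary", "higher"),
                             probs  = c(0.25, 0.25, 0.35, 0.15)),
    mother_age_group = list(labels = c("<18", "19-24", "25-29", "30+"),
                            probs  = c(0.05, 0.40, 0.30, 0.25)),
    working_status   = list(labels = c("unemployed", "employed"),
                            probs  = c(0.60, 0.40)),
    birth_order      = list(labels = c("1", "2-3", "4-5", "6+"),
                            probs  = c(0.30, 0.40, 0.20, 0.10)),
    ceb              = list(labels = c("1", "2-3", "4-5", "6+"),
                            probs  = c(0.25, 0.40, 0.22, 0.13)),
    health_decision  = list(labels = c("others", "joint", "respondent"),
                            probs  = c(0.30, 0.40, 0.30)),
    wealth_quintile  = list(labels = c("poorest", "poorer", "middle",
                                       "richer", "richest"),
                            probs  = rep(0.2, 5)),
    newspaper        = list(labels = c("no", "weekly"),
                            probs  = c(0.60, 0.40)),
    radio            = list(labels = c("no", "weekly"),
                            probs  = c(0.50, 0.50)),
    television       = list(labels = c("no", "weekly"),
                            probs  = c(0.40, 0.60)),
    religion         = list(labels = c("hindu", "muslim", "others"),
                            probs  = c(0.60, 0.30, 0.10)),
    caste            = list(labels = c("others", "obc", "sc", "st"),
                            probs  = c(0.35, 0.35, 0.20, 0.10))
  )
}

# default per-level structural effects (non-reference dummies, in label order)
.default_effects <- function(scale = 1) {
  lapply(list(
    residence        = 0.20,
    mother_education = c(0.15, 0.30, 0.45),
    husband_education = c(0.10, 0.20, 0.30),
    mother_age_group = c(0.05, 0.05, 0.00),
    working_status   = 0.05,
    birth_order      = c(-0.10, -0.20, -0.30),
    ceb              = c(0.00, 0.00, 0.00),
    health_decision  = c(0.10, 0.15),
    wealth_quintile  = c(0.10, 0.20, 0.30, 0.40),
    newspaper        = 0.10,
    radio            = 0.05,
    television       = 0.15,
    religion         = c(0.00, 0.00),
    caste            = c(0.00, 0.00, 0.00)
  ), function(b) b * scale)
}

#' Configuration of the synthetic DHS-like structural model
#'
#' Bundles every parameter of the data-generating process: the recursive
#' bivariate probit structure linking a binary ANC exposure to institutional
#' delivery, the instrument (first ANC visit in the first trimester), the
#' visit-count mechanism, the one-factor model for the eight ANC service
#' items, and the covariate distribution.
#'
#' The latent structure is
#' \deqn{E_i = 1\{\gamma_{IV} Z_i + x_i'\beta_E + \epsilon'_i > 0\},\qquad
#'       O_i = 1\{\delta E_i + x_i'\beta_O + \epsilon_i > 0\},}
#' with \eqn{(\epsilon_i, \epsilon'_i)} standard bivariate normal with
#' correlation \code{rho} and \eqn{Z_i \sim} Bernoulli(\code{p_instrument})
#' independent of the errors (the exclusion restriction holds by
#' construction). Visit counts are drawn so that the 3-or-more-visits
#' indicator reproduces \eqn{E_i} exactly: truncated Poisson on \{3..12\}
#' (mean \code{visit_rate_params$lambda_high}) when \eqn{E_i = 1}, truncated
#' Poisson on \{0..2\} (mean \code{visit_rate_params$lambda_low}) otherwise.
#' Service item \eqn{j} is Bernoulli\eqn{(\Phi(a_j + b_j U_i))} with
#' \eqn{U_i} the standardized treatment-equation latent index (a one-factor
#' binary-item model, so the PCA score and reliability have known structure).
#'
#' @param n number of women (rows).
#' @param rho latent error correlation in \[-1, 1\]; nonzero values make the
#'   exposure endogenous in the outcome equation.
#' @param delta structural effect of the exposure on the outcome latent index.
#' @param gamma_iv instrument coefficient in the exposure equation
#'   (1.0 = strong; 0.1 is a conventional weak-instrument setting).
#' @param p_instrument Bernoulli rate of the instrument.
#' @param intercept_outcome,intercept_treatment equation intercepts.
#' @param effects_outcome,effects_treatment named lists of per-level effects
#'   on the non-reference dummies of each covariate (label order).
#' @param item_loadings,item_intercepts length-8 vectors \eqn{b_j}, \eqn{a_j}
#'   of the service-item factor model.
#' @param covariate_spec as [default_covariate_spec()].
#' @param visit_rate_params list with `lambda_high`, `lambda_low`.
#' @param seed root seed; all generator sub-streams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n = 5000,
                       rho = -0.4,
                       delta = 1.0,
                       gamma_iv = 1.0,
                       p_instrument = 0.4,
                       intercept_outcome = -1.6,
                       intercept_treatment = -0.9,
                       effects_outcome = .default_effects(1),
                       effects_treatment = .default_effects(0.8),
                       item_loadings = c(0.8, 1.0, 0.9, 1.1, 1.0, 1.2, 0.7, 0.6),
                       item_intercepts = c(0.8, 0.3, -0.1, 0.5, 0.2, 0.1, -0.4, -0.6),
                       covariate_spec = default_covariate_spec(),
                       visit_rate_params = list(lambda_high = 4, lambda_low = 1),
                       seed = 20170725) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]", call. = FALSE)
  if (length(item_loadings) != 8 || length(item_intercepts) != 8) {
    stop("exactly 8 item loadings and 8 item intercepts are required",
         call. = FALSE)
  }
  for (nm in names(covariate_spec)) {
    cv <- covariate_spec[[nm]]
    if (length(cv$labels) != length(cv$probs)) {
      stop(sprintf("covariate '%s': labels and probs differ in length", nm),
           call. = FALSE)
    }
    if (abs(sum(cv$probs) - 1) > 1e-9) {
      stop(sprintf("covariate '%s': frequencies must sum to 1", nm),
           call. = FALSE)
    }
    if (any(cv$probs < 0)) {
      stop(sprintf("covariate '%s': negative frequency", nm), call. = FALSE)
    }
  }
  structure(list(
    n = as.integer(n), rho = rho, delta = delta, gamma_iv = gamma_iv,
    p_instrument = p_instrument,
    intercept_outcome = intercept_outcome,
    intercept_treatment = intercept_treatment,
    effects_outcome = effects_outcome,
    effects_treatment = effects_treatment,
    item_loadings = item_loadings, item_intercepts = item_intercepts,
    covariate_spec = covariate_spec,
    visit_rate_params = visit_rate_params,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic DHS-like structural model configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  rho = %.3f, delta = %.3f, gamma_iv = %.3f, P(Z=1) = %.2f\n",
              x$rho, x$delta, x$gamma_iv, x$p_instrument))
  cat(sprintf("  covariates: %s\n",
              paste(names(x$covariate_spec), collapse = ", ")))
  invisible(x)
}

# zero out structural effects outside a covariate subset (used by the
# Monte Carlo driver so the fitted compact model is correctly specified)
.restrict_effects <- function(effects, covariates) {
  for (nm in setdiff(names(effects), covariates)) {
    effects[[nm]] <- effects[[nm]] * 0
  }
  effects
}

# population mean of the covariate contribution to a latent index
.mean_structural_index <- function(spec, effects) {
  tot <- 0
  for (nm in names(spec)) {
    eff <- effects[[nm]]
    if (is.null(eff)) next
    tot <- tot + sum(spec[[nm]]$probs * c(0, eff))
  }
  tot
}

# deterministic sub-stream seed from root seed and a tag; keeps every
# component's draws invariant to the presence of other components
.sub_seed <- function(root, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 100003
  as.integer((as.numeric(root) %% 1000003 * 100003 + h) %% 2147483647)
}

#' Draw the categorical covariates
#'
#' Each covariate is sampled independently from its configured category
#' frequencies on its own seed sub-stream, so adding or removing a covariate
#' never perturbs the draws of the others.
#'
#' @param config a [sim_config()].
#' @return data.frame of factor columns, `config$n` rows.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(names(config$covariate_spec), function(nm) {
    cv <- config$covariate_spec[[nm]]
    seed <- .sub_seed(config$seed, paste0("cov:", nm))
    withr_seed(seed)
    factor(sample(cv$labels, config$n, replace = TRUE, prob = cv$probs),
           levels = cv$labels)
  })
  names(out) <- names(config$covariate_spec)
  as.data.frame(out, stringsAsFactors = FALSE)
}

# set.seed without touching the caller's RNG state on exit
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# structural design matrix (intercept + covariate dummies) and linear
# predictor contribution of the covariates under a named effects list
.structural_index <- function(covariates, effects, spec) {
  idx <- numeric(nrow(covariates))
  for (nm in names(spec)) {
    eff <- effects[[nm]]
    labs <- spec[[nm]]$labels
    if (is.null(eff)) eff <- rep(0, length(labs) - 1)
    if (length(eff) != length(labs) - 1) {
      stop(sprintf("effects for '%s' must have %d values", nm,
                   length(labs) - 1), call. = FALSE)
    }
    idx <- idx + c(0, eff)[as.integer(covariates[[nm]])]
  }
  idx
}

#' Draw exposure, outcome, instrument and visit count
#'
#' Implements the recursive latent structure described in [sim_config()].
#' The instrument is drawn independently of the latent errors, enforcing the
#' exclusion restriction by construction; the visit count is drawn so the
#' 3+ indicator equals the exposure bit for every row.
#'
#' @param config a [sim_config()].
#' @param covariates data.frame from [generate_covariates()].
#' @return list with `columns` (data.frame: `first_trimester`, `anc_visits`,
#'   `place_of_delivery`) and `latents` (data.frame: `eps_outcome`,
#'   `eps_treatment`, `index_treatment`, `treatment`).
#' @export
generate_exposure_outcome <- function(config, covariates) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  if (nrow(covariates) != n) stop("covariates do not match config$n",
                                  call. = FALSE)
  xb_out <- config$intercept_outcome +
    .structural_index(covariates, config$effects_outcome, config$covariate_spec)
  xb_trt <- config$intercept_treatment +
    .structural_index(covariates, config$effects_treatment, config$covariate_spec)

  withr_seed(.sub_seed(config$seed, "errors"))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  eps_trt <- z1
  eps_out <- config$rho * z1 + sqrt(1 - config$rho^2) * z2

  withr_seed(.sub_seed(config$seed, "instrument"))
  z <- stats::rbinom(n, 1, config$p_instrument)

  index_trt <- config$gamma_iv * z + xb_trt + eps_trt
  e <- as.integer(index_trt > 0)
  o <- as.integer(config$delta * e + xb_out + eps_out > 0)

  withr_seed(.sub_seed(config$seed, "visits"))
  visits <- integer(n)
  hi <- e == 1
  visits[hi] <- .rtrunc_pois(sum(hi), config$visit_rate_params$lambda_high,
                             3L, 12L)
  visits[!hi] <- .rtrunc_pois(sum(!hi), config$visit_rate_params$lambda_low,
                              0L, 2L)
  list(
    columns = data.frame(first_trimester = z, anc_visits = visits,
                         place_of_delivery = o),
    latents = data.frame(eps_outcome = eps_out, eps_treatment = eps_trt,
                         index_treatment = index_trt, treatment = e)
  )
}

# truncated Poisson sampler on {lo..hi}
.rtrunc_pois <- function(n, lambda, lo, hi) {
  if (n == 0L) return(integer(0))
  support <- lo:hi
  p <- stats::dpois(support, lambda)
  sample(support, n, replace = TRUE, prob = p / sum(p))
}

#' Draw the eight binary ANC service items
#'
#' One-factor binary-item model: item \eqn{j} is Bernoulli
#' \eqn{(\Phi(a_j + b_j U))} where \eqn{U} is a per-woman latent
#' care-quality value (by default the standardized treatment-equation
#' latent index, so women with more intensive contact also receive more
#' procedures).
#'
#' @param config a [sim_config()].
#' @param latent numeric vector of latent care-quality values, length `n`.
#' @return data.frame of 8 binary columns: `tetanus`, `weight`, `height`,
#'   `blood_pressure`, `urine`, `blood`, `breastfeeding_counsel`,
#'   `complication_signs`.
#' @export
generate_service_items <- function(config, latent) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$item_loadings) != 8) {
    stop("exactly 8 item loadings are required", call. = FALSE)
  }
  n <- length(latent)
  withr_seed(.sub_seed(config$seed, "items"))
  nm <- anc_item_names()
  out <- vector("list", 8)
  for (j in 1:8) {
    p <- stats::pnorm(config$item_intercepts[j] +
                        config$item_loadings[j] * latent)
    out[[j]] <- stats::rbinom(n, 1, p)
  }
  names(out) <- nm
  as.data.frame(out)
}

#' Names of the eight ANC service items
#'
#' Tetanus vaccination plus the seven procedure items (weight, height and
#' blood-pressure measurement, urine and blood samples, breastfeeding
#' counselling, information on complication signs).
#' @return character vector of length 8.
#' @export
anc_item_names <- function() {
  c("tetanus", "weight", "height", "blood_pressure", "urine", "blood",
    "breastfeeding_counsel", "complication_signs")
}

#' Generate a complete synthetic DHS-like dataset
#'
#' Composes [generate_covariates()], [generate_exposure_outcome()] and
#' [generate_service_items()] and returns both the observable microdata
#' table and the ground truth needed for parameter-recovery experiments.
#'
#' @param config a [sim_config()].
#' @param csv optional path; when given the observable table is written as
#'   CSV (deterministic bytes for a fixed config).
#' @return list with `data` (data.frame: outcome, visits, instrument, the
#'   8 items, covariates) and `truth` (config parameters plus the latent
#'   draws).
#' @export
generate_dataset <- function(config, csv = NULL) {
  stopifnot(inherits(config, "sim_config"))
  covs <- generate_covariates(config)
  eo <- generate_exposure_outcome(config, covs)
  u <- scale(eo$latents$index_treatment)[, 1]
  items <- generate_service_items(config, u)
  dat <- cbind(eo$columns["place_of_delivery"], eo$columns["anc_visits"],
               eo$columns["first_trimester"], items, covs)
  stopifnot(!anyNA(dat), nrow(dat) == config$n)
  if (!is.null(csv)) {
    utils::write.csv(dat, csv, row.names = FALSE, quote = FALSE)
  }
  list(
    data = dat,
    truth = list(config = config, latents = eo$latents,
                 treatment = eo$latents$treatment)
  )
}
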