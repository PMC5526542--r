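#' Visits dimension of antenatal care
#'
#' Dichotomizes the ANC visit count at the conventional three-visit
#' threshold: 1 for three or more visits, 0 otherwise. This dimension is
#' independent of the health-care delivery system.
#'
#' @param anc_visits vector of non-negative integer visit counts.
#' @return integer 0/1 vector.
#' @export
compute_visit_dimension <- function(anc_visits) {
  if (any(!is.finite(anc_visits)) || any(anc_visits < 0)) {
    stop("'anc_visits' must be non-negative counts", call. = FALSE)
  }
  as.integer(anc_visits >= 3)
}

#' PCA-based care-intensity score
#'
#' First principal component of the covariance matrix of the eight binary
#' service items (raw 0/1 coding, mirroring the DHS wealth-index
#' convention). Scores are centered at zero and sign-oriented so that the
#' loading sum is positive: a woman receiving every service scores highest.
#'
#' @param items data.frame or matrix of 8 binary columns.
#' @return numeric score vector with attributes `loadings` (PC1 loadings)
#'   and `var_share` (share of total variance on PC1).
#' @export
compute_care_score <- function(items) {
  x <- as.matrix(items)
  if (nrow(x) < 2) stop("at least 2 rows are required", call. = FALSE)
  if (anyNA(x)) stop("missing item values are not allowed", call. = FALSE)
  if (all(apply(x, 2, stats::var) == 0)) {
    stop("degenerate input: all items are constant", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  s <- if (sum(load1) < 0) -1 else 1
  score <- s * pc$x[, 1]
  attr(score, "loadings") <- s * load1
  attr(score, "var_share") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  score
}

#' Classify care scores into ordered levels
#'
#' Equal-probability quantile cut into `L` levels (median split for L = 2,
#' tertiles for L = 3). A tied block of scores straddling a cutpoint is
#' assigned in full to the lower level, so level sizes can differ by the
#' size of a tie block.
#'
#' @param care_score numeric vector.
#' @param L number of levels, 2 or 3.
#' @return integer vector of levels in 1..L (L = most intensive care).
#' @export
classify_care_level <- function(care_score, L = 3) {
  if (!L %in% c(2, 3)) stop("'L' must be 2 or 3", call. = FALSE)
  if (length(unique(care_score)) == 1) {
    stop("degenerate input: all scores identical", call. = FALSE)
  }
  cuts <- stats::quantile(care_score, probs = seq_len(L - 1) / L,
                          type = 1, names = FALSE)
  # a tie block straddling two cuts would otherwise empty a level:
  # bump coincident cutpoints to the next distinct score
  distinct <- sort(unique(care_score))
  for (j in seq_along(cuts)[-1]) {
    if (cuts[j] <= cuts[j - 1]) {
      above <- distinct[distinct > cuts[j - 1]]
      cuts[j] <- if (length(above)) above[1] else Inf
    }
  }
  lev <- rep.int(1L, length(care_score))
  for (c_ in cuts) lev <- lev + (care_score > c_)
  as.integer(lev)
}

#' Care-intensity dimension of antenatal care
#'
#' Indicator of the highest care level: 1 when `care_level == L`, 0
#' otherwise. This dimension depends on the health-care delivery system.
#'
#' @param care_level integer levels in 1..L.
#' @param L number of levels.
#' @return integer 0/1 vector.
#' @export
compute_care_dimension <- function(care_level, L = 3) {
  if (any(care_level < 1 | care_level > L)) {
    stop("care levels out of range 1..L", call. = FALSE)
  }
  as.integer(care_level == L)
}

#' Both ANC dimensions for a microdata table
#'
#' Convenience wrapper: computes the visits dimension `d1`, the PCA care
#' score, the care level and the care dimension `d2` for a table holding
#' `anc_visits` and the eight service items.
#'
#' @param table microdata data.frame.
#' @param L number of care levels (2 or 3).
#' @return data.frame with columns `d1`, `care_score`, `care_level`, `d2`;
#'   attributes `L`, `pc1_loadings`, `pc1_var_share`.
#' @export
compute_anc_dimensions <- function(table, L = 3) {
  score <- compute_care_score(table[, anc_item_names()])
  lev <- classify_care_level(score, L)
  out <- data.frame(
    d1 = compute_visit_dimension(table$anc_visits),
    care_score = as.numeric(score),
    care_level = lev,
    d2 = compute_care_dimension(lev, L)
  )
  attr(out, "L") <- L
  attr(out, "pc1_loadings") <- attr(score, "loadings")
  attr(out, "pc1_var_share") <- attr(score, "var_share")
  out
}

#' Cronbach's alpha for the service-item scale
#'
#' Internal-consistency reliability
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_j \sigma^2_j}
#'   {\sigma^2_{total}}\Big)}
#' with sample variances of the `k` items and of their row sum.
#'
#' @param items data.frame or matrix of binary (or numeric) item columns.
#' @return list of class `reliability_result` with `alpha`, `k`,
#'   `item_variances`, `total_variance`.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x)
  if (k < 2 || nrow(x) < 2) {
    stop("at least 2 items and 2 rows are required", call. = FALSE)
  }
  iv <- apply(x, 2, stats::var)
  tv <- stats::var(rowSums(x))
  if (tv == 0) stop("degenerate input: total score has zero variance",
                    call. = FALSE)
  structure(list(alpha = k / (k - 1) * (1 - sum(iv) / tv),
                 k = k, item_variances = iv, total_variance = tv),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items)\n", x$alpha, x$k))
  invisible(x)
}
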