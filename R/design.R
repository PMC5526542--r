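#' Build a probit design matrix
#'
#' Intercept plus reference-cell dummy coding of the requested categorical
#' covariates (the first factor level is the omitted reference), with the
#' 0/1 dimension column appended last. Constant covariates are dropped with
#' a warning; a rank-deficient result is rejected with the offending
#' columns named.
#'
#' @param table microdata data.frame.
#' @param dimension name of the 0/1 dimension column in `table`
#'   (e.g. `"d1"` or `"d2"`), or `NULL` for covariates only.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @return object of class `design_matrix`: list with `X` (numeric matrix),
#'   `dimension` (appended column name or `NULL`), `reference` (named list
#'   of omitted categories).
#' @export
build_design_matrix <- function(table, dimension = NULL,
                                covariates = character()) {
  missing_cols <- setdiff(c(covariates, dimension), names(table))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- character()
  reference <- list()
  for (cv in covariates) {
    col <- table[[cv]]
    if (!is.factor(col)) col <- factor(col)
    if (nlevels(droplevels(col)) < 2) {
      warning(sprintf("covariate '%s' is constant and was dropped", cv),
              call. = FALSE)
      next
    }
    table[[cv]] <- droplevels(col)
    reference[[cv]] <- levels(table[[cv]])[1]
    keep <- c(keep, cv)
  }
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = table)
  if (!is.null(dimension)) {
    d <- table[[dimension]]
    if (!all(d %in% c(0, 1))) {
      stop(sprintf("dimension column '%s' must be 0/1", dimension),
           call. = FALSE)
    }
    X <- cbind(X, as.numeric(d))
    colnames(X)[ncol(X)] <- dimension
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, dimension = dimension, reference = reference),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows x %d columns\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$dimension)) cat("  dimension column:", x$dimension, "\n")
  invisible(x)
}

# accept either a design_matrix or a bare numeric matrix
.design_X <- function(X) {
  if (inherits(X, "design_matrix")) X$X else as.matrix(X)
}
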