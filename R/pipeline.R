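#' Cross-tabulation of place of delivery by the ANC dimensions
#'
#' Row percentages of home versus institutional delivery within each
#' category of each ANC dimension, with unweighted counts, plus the
#' aggregate rates (share with 3+ visits, share with a first-trimester
#' first visit, share delivering in an institution).
#'
#' @param table microdata data.frame with `place_of_delivery`,
#'   `anc_visits`, `first_trimester`.
#' @param dims result of [compute_anc_dimensions()].
#' @return list of class `crosstab_report`: `rows` (data.frame with
#'   dimension, category, pct_home, pct_institutional, total) and
#'   `aggregates`.
#' @export
crosstab_by_dimension <- function(table, dims) {
  o <- table$place_of_delivery
  one_dim <- function(values, dimension, labels) {
    do.call(rbind, lapply(sort(unique(values)), function(v) {
      rows <- values == v
      tot <- sum(rows)
      data.frame(
        dimension = dimension,
        category = labels[as.character(v)],
        pct_home = if (tot) 100 * mean(o[rows] == 0) else NA_real_,
        pct_institutional = if (tot) 100 * mean(o[rows] == 1) else NA_real_,
        total = tot
      )
    }))
  }
  L <- attr(dims, "L")
  rows <- rbind(
    one_dim(dims$d1, "visits",
            c("0" = "<3 visits", "1" = "3+ visits")),
    one_dim(dims$d2, "care",
            stats::setNames(c(sprintf("level < %d", L), sprintf("level %d", L)),
                            c("0", "1")))
  )
  structure(list(
    rows = rows,
    aggregates = c(
      pct_3plus_visits = 100 * mean(dims$d1 == 1),
      pct_first_trimester = 100 * mean(table$first_trimester == 1),
      pct_institutional = 100 * mean(o == 1)
    )
  ), class = "crosstab_report")
}

#' @export
print.crosstab_report <- function(x, ...) {
  cat("Place of delivery by ANC dimension (row %)\n")
  print(x$rows, row.names = FALSE, digits = 4)
  cat(sprintf("3+ visits: %.1f%%  first trimester: %.1f%%  institutional: %.1f%%\n",
              x$aggregates["pct_3plus_visits"],
              x$aggregates["pct_first_trimester"],
              x$aggregates["pct_institutional"]))
  invisible(x)
}

#' Paired probit / biprobit analysis of both ANC dimensions
#'
#' The full estimation pipeline: computes both ANC dimensions, then for
#' each one fits the naive probit and the instrument-identified recursive
#' bivariate probit, runs the Wald test of exogeneity, and assembles a
#' side-by-side comparison of coefficients and counterfactual average
#' predicted probabilities, together with the reliability and PCA metadata
#' of the care scale.
#'
#' @param table microdata data.frame (as produced by [generate_dataset()]
#'   or read via [read_microdata()]).
#' @param covariates character vector of covariate columns to control for.
#' @param L number of care levels (2 or 3).
#' @param instrument name of the 0/1 instrument column.
#' @param verbose emit one structured log line per fitted model.
#' @return object of class `anc_comparison`: `comparison` data.frame (one
#'   row per dimension), `fits` (the four model objects), `alpha`,
#'   `pc1_var_share`, `crosstab`, `meta`.
#' @export
run_analysis <- function(table,
                         covariates = names(default_covariate_spec()),
                         L = 3, instrument = "first_trimester",
                         verbose = FALSE) {
  covariates <- intersect(covariates, names(table))
  dims <- compute_anc_dimensions(table, L = L)
  tab <- cbind(table, dims[, c("d1", "d2")])
  rel <- cronbach_alpha(table[, anc_item_names()])
  O <- tab$place_of_delivery
  Z <- tab[[instrument]]
  Xcov <- build_design_matrix(tab, dimension = NULL, covariates = covariates)

  fit_pair <- function(dim_name) {
    Xd <- build_design_matrix(tab, dimension = dim_name,
                              covariates = covariates)
    pr <- fit_probit(O, Xd)
    bp <- fit_biprobit(O, tab[[dim_name]], Xcov, Z)
    if (verbose) {
      message(sprintf(
        "model=%s n=%d probit.ll=%.2f biprobit.ll=%.2f iters=%d grad=%.2e",
        dim_name, pr$n, pr$loglik, bp$loglik, bp$iterations,
        pr$gradient_norm))
    }
    w <- wald_exogeneity_test(bp)
    pr_tab <- coef_table(pr)
    bp_tab <- coef_table(bp, "outcome")
    delta_row <- nrow(bp_tab)                 # E is the last outcome column
    data.frame(
      dimension = dim_name,
      probit_coef = pr_tab[dim_name, "estimate"],
      probit_stars = pr_tab[dim_name, "stars"],
      probit_p0 = average_predicted_probability(pr, d = 0),
      probit_p1 = average_predicted_probability(pr, d = 1),
      biprobit_coef = bp_tab[delta_row, "estimate"],
      biprobit_stars = bp_tab[delta_row, "stars"],
      biprobit_p0 = average_predicted_probability_biprobit(bp, d = 0),
      biprobit_p1 = average_predicted_probability_biprobit(bp, d = 1),
      rho = bp$rho,
      rho_behaviour = w$label,
      wald_stat = w$statistic,
      wald_p = w$p_value
    )
  }
  comp_d1 <- fit_pair("d1")
  comp_d2 <- fit_pair("d2")
  comparison <- rbind(comp_d1, comp_d2)
  rownames(comparison) <- NULL
  structure(list(
    comparison = comparison,
    alpha = rel$alpha,
    pc1_var_share = attr(dims, "pc1_var_share"),
    crosstab = crosstab_by_dimension(tab, dims),
    meta = list(n = nrow(tab), L = L, covariates = covariates,
                instrument = instrument,
                level_rule = "equal-probability quantile cut, ties to lower")
  ), class = "anc_comparison")
}

#' @export
print.anc_comparison <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Probit vs biprobit comparison (n = %d, L = %d, alpha = %.3f)\n",
    x$meta$n, x$meta$L, x$alpha))
  cols <- c("dimension", "probit_coef", "probit_stars", "probit_p0",
            "probit_p1", "biprobit_coef", "biprobit_stars", "biprobit_p0",
            "biprobit_p1", "rho", "rho_behaviour")
  print(format(x$comparison[, cols], digits = digits), row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report an `anc_comparison`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_comparison_json <- function(report, path) {
  jsonlite::write_json(
    list(comparison = report$comparison,
         alpha = report$alpha,
         pc1_var_share = report$pc1_var_share,
         crosstab = report$crosstab$rows,
         aggregates = as.list(report$crosstab$aggregates),
         meta = report$meta),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read microdata from CSV with an optional column mapping
#'
#' Complete-case reader for externally supplied extracts: columns are
#' renamed through `mapping` (names = canonical names used by the package,
#' values = names in the file), then rows with missing values in the
#' analysis columns are dropped with a logged count.
#'
#' @param path CSV file.
#' @param mapping named character vector, or `NULL` when the file already
#'   uses the canonical snake_case names.
#' @return data.frame.
#' @export
read_microdata <- function(path, mapping = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(dat)) {
        stop(sprintf("mapped column '%s' not found", src), call. = FALSE)
      }
      names(dat)[names(dat) == src] <- canon
    }
  }
  core <- c("place_of_delivery", "anc_visits", "first_trimester",
            anc_item_names())
  missing_cols <- setdiff(core, names(dat))
  if (length(missing_cols)) {
    stop("required columns missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(dat)
  if (any(!keep)) {
    message(sprintf("dropped %d incomplete rows of %d", sum(!keep),
                    nrow(dat)))
  }
  dat[keep, , drop = FALSE]
}
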