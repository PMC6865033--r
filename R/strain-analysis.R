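#' Read a strain parameter table
#'
#' Loads a TSV of per-strain fitted parameters: one row per strain with at
#' least `strain`, `avg_rls`, `net_R`, `t0`, `n`, `gomp_R` and `gomp_G`
#' columns (optionally their `_sd` companions and per-model AIC columns).
#' All parameter entries must be positive and `n > 1`.
#'
#' @param path path to a tab-delimited table; defaults to the bundled
#'   wild-isolate table (see [wild_isolates()]).
#' @return A data frame of class `"strain_table"`.
#' @export
read_strain_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "wild_isolates.tsv", package = "netaging",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("strain", "avg_rls", "net_R", "t0", "n", "gomp_R", "gomp_G")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop("strain table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$strain))
    stop("strain table has duplicated strain labels")
  num <- setdiff(needed, "strain")
  for (col in num) {
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]]) || any(tab[[col]] <= 0))
      stop(sprintf("column `%s` must be positive and complete", col))
  }
  if (any(tab$n <= 1))
    stop("column `n` must exceed 1 for every strain")
  class(tab) <- c("strain_table", "data.frame")
  tab
}

#' Bundled parameter table for 15 wild yeast isolates
#'
#' Network (`R`, `t0`, `n`) and Gompertz (`R`, `G`) parameters fitted to
#' replicative lifespans of 15 natural isolates of *Saccharomyces
#' cerevisiae*, with bootstrap standard deviations (100 resamples) and
#' per-model AICs. Ships with the package and is the default input of the
#' cross-strain analyses.
#'
#' @return A `"strain_table"` data frame with 15 rows.
#' @examples
#' column_summary(wild_isolates())
#' @export
wild_isolates <- function() read_strain_table()

# ---- correlation machinery --------------------------------------------------

new_correlation_result <- function(fit, x, y, x_name, y_name, degenerate) {
  if (degenerate) {
    out <- list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, p_value = NA_real_,
                n_strains = length(x), x = x_name, y = y_name,
                degenerate = TRUE)
  } else {
    sm <- summary(fit)
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r = stats::cor(x, y),
                r_squared = sm$r.squared,
                p_value = sm$coefficients[2, 4],
                n_strains = length(x), x = x_name, y = y_name,
                degenerate = FALSE)
  }
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Correlation %s ~ %s: degenerate (zero variance), %d strains\n",
                x$y, x$x, x$n_strains))
  } else {
    cat(sprintf("Correlation %s ~ %s over %d strains\n", x$y, x$x,
                x$n_strains))
    cat(sprintf("  slope %.4g, intercept %.4g\n", x$slope, x$intercept))
    cat(sprintf("  r = %.3f, R^2 = %.3f, p = %.4g\n", x$r, x$r_squared,
                x$p_value))
  }
  invisible(x)
}

#' Correlation between two strain-table columns
#'
#' Ordinary least squares of `y` on `x` across strains, with Pearson r,
#' R-squared and the two-sided p-value of the slope. Optional transforms
#' are applied to each column before regression.
#'
#' @param table a `"strain_table"` (see [read_strain_table()]).
#' @param x,y column names.
#' @param transform_x,transform_y functions applied to the columns before
#'   the regression (default identity).
#' @return A `"correlation_result"`. If either transformed column has zero
#'   variance the result is flagged `degenerate` with `r = NA`.
#' @examples
#' parameter_correlation(wild_isolates(), "gomp_R", "t0",
#'                       transform_x = log10)
#' @export
parameter_correlation <- function(table, x, y, transform_x = identity,
                                  transform_y = identity) {
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) < 3)
    stop("at least 3 strains are required for a correlation")
  for (col in c(x, y))
    if (!col %in% names(table))
      stop(sprintf("column `%s` not found in the strain table", col))
  xv <- transform_x(table[[x]])
  yv <- transform_y(table[[y]])
  if (anyNA(xv) || anyNA(yv) || any(!is.finite(c(xv, yv))))
    stop("transformed columns contain non-finite values")
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    return(new_correlation_result(NULL, xv, yv, x, y, degenerate = TRUE))
  fit <- stats::lm(yv ~ xv)
  new_correlation_result(fit, xv, yv, x, y, degenerate = FALSE)
}

#' Strehler-Mildvan correlation across strains
#'
#' Regresses the Gompertz coefficient `G` on `log10(R)` across strains —
#' the classical Strehler-Mildvan relation, in which populations with a
#' higher initial mortality rate age more slowly. `which_R` selects whether
#' the Gompertz-fitted or network-fitted `R` column is used (Gompertz by
#' convention).
#'
#' @param table a `"strain_table"`.
#' @param which_R `"gompertz"` (default) or `"network"`.
#' @return A `"correlation_result"` for `G ~ log10(R)`.
#' @examples
#' strehler_mildvan(wild_isolates())
#' @export
strehler_mildvan <- function(table, which_R = c("gompertz", "network")) {
  which_R <- match.arg(which_R)
  r_col <- if (which_R == "gompertz") "gomp_R" else "net_R"
  parameter_correlation(table, x = r_col, y = "gomp_G",
                        transform_x = log10)
}

#' Mediation test across strains
#'
#' Classical product-of-coefficients mediation with a percentile bootstrap
#' over strains. Three regressions are fitted: outcome on exposure (total
#' effect `c`), outcome on exposure plus mediator (direct effect `c'`,
#' mediator slope `b`) and mediator on exposure (`a`). The indirect effect
#' is `a*b`, and the proportion mediated is `a*b / (a*b + c')`; in these
#' linear models `c = c' + a*b`. Defaults probe whether the initial
#' virtual age `t0` transmits the Strehler-Mildvan association between
#' `log10(R)` and `G`.
#'
#' @param table a `"strain_table"` with at least 5 rows.
#' @param exposure,mediator,outcome column names (defaults `gomp_R`, `t0`,
#'   `gomp_G`).
#' @param log10_exposure apply `log10` to the exposure column (default
#'   `TRUE`, matching the Strehler-Mildvan convention).
#' @param B bootstrap resamples, >= 100 (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return An object of class `"mediation_result"`: `total`, `direct`,
#'   `indirect`, `prop_mediated`, percentile `ci` for the proportion
#'   mediated, `B`, `n_strains` and `seed`.
#' @examples
#' mediation_test(wild_isolates(), B = 200, seed = 1)
#' @export
mediation_test <- function(table, exposure = "gomp_R", mediator = "t0",
                           outcome = "gomp_G", log10_exposure = TRUE,
                           B = 1000, seed = NULL, conf = 0.95) {
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) < 5)
    stop("at least 5 strains are required for the mediation test")
  if (B < 100) stop("B must be >= 100")
  for (col in c(exposure, mediator, outcome))
    if (!col %in% names(table))
      stop(sprintf("column `%s` not found in the strain table", col))
  x <- table[[exposure]]
  if (log10_exposure) x <- log10(x)
  m <- table[[mediator]]
  y <- table[[outcome]]
  if (stats::var(x) == 0 || stats::var(m) == 0 || stats::var(y) == 0)
    stop("degenerate mediation input: a column has zero variance")

  point <- mediation_coefs(x, m, y)

  if (!is.null(seed)) set.seed(seed)
  nr <- length(x)
  boot <- vapply(seq_len(B), function(b) {
    i <- sample.int(nr, nr, replace = TRUE)
    if (stats::var(x[i]) == 0 || stats::var(m[i]) == 0) return(NA_real_)
    mediation_coefs(x[i], m[i], y[i])["prop_mediated"]
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))

  structure(list(total = unname(point["total"]),
                 direct = unname(point["direct"]),
                 indirect = unname(point["indirect"]),
                 prop_mediated = unname(point["prop_mediated"]),
                 ci = ci, conf = conf, B = B,
                 n_boot_used = length(boot),
                 n_strains = nr,
                 exposure = exposure, mediator = mediator, outcome = outcome,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "mediation_result")
}

mediation_coefs <- function(x, m, y) {
  a <- unname(stats::coef(stats::lm(m ~ x))[2])
  fit_y <- stats::coef(stats::lm(y ~ x + m))
  b <- unname(fit_y["m"]); direct <- unname(fit_y["x"])
  indirect <- a * b
  c(total = direct + indirect, direct = direct, indirect = indirect,
    prop_mediated = indirect / (direct + indirect))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation of %s -> %s through %s (%d strains)\n",
              x$exposure, x$outcome, x$mediator, x$n_strains))
  cat(sprintf("  total %.4g = direct %.4g + indirect %.4g\n",
              x$total, x$direct, x$indirect))
  cat(sprintf("  proportion mediated %.1f%% (%d%% CI %.1f%%-%.1f%%, B = %d)\n",
              100 * x$prop_mediated, round(100 * x$conf),
              100 * x$ci[1], 100 * x$ci[2], x$B))
  invisible(x)
}

#' Interaction decay-time summary across strains
#'
#' Back-calculates the mean interaction survival time `1/lambda =
#' p * t0 / (1 - p)` per strain under an assumed activation probability,
#' and summarizes it across the table. Checks whether the working
#' assumption `t << 1/lambda` holds for observed lifespans.
#'
#' @param table a `"strain_table"`.
#' @param p_assumed assumed activation probability, in (0, 1).
#' @return A list with `mean`, `min` and `max` of `1/lambda` (rounded to
#'   whole cell divisions), `p_assumed` and the unrounded `per_strain`
#'   vector (named by strain).
#' @examples
#' decay_summary(wild_isolates(), p_assumed = 0.7)
#' @export
decay_summary <- function(table, p_assumed) {
  stopifnot(inherits(table, "data.frame"))
  check_scalar(p_assumed, "p_assumed", lower = 0, upper = 1,
               strict = TRUE, strict_upper = TRUE)
  inv_lambda <- vapply(table$t0,
                       function(t0) decay_rate_from_t0(t0, p_assumed)$inv_lambda,
                       numeric(1))
  names(inv_lambda) <- table$strain
  list(mean = round(mean(inv_lambda)),
       min = round(min(inv_lambda)),
       max = round(max(inv_lambda)),
       p_assumed = p_assumed,
       per_strain = inv_lambda)
}

#' Cross-strain parameter summaries
#'
#' Arithmetic mean and range of the fitted initial virtual age `t0`, the
#' interaction count `n` and the average replicative lifespan across the
#' strains of a table, rounded to one decimal.
#'
#' @param table a non-empty `"strain_table"`.
#' @return A data frame with rows `t0`, `n`, `avg_rls` and columns `mean`,
#'   `min`, `max`.
#' @export
column_summary <- function(table) {
  stopifnot(inherits(table, "data.frame"), nrow(table) >= 1)
  cols <- c("t0", "n", "avg_rls")
  out <- data.frame(
    mean = vapply(cols, function(c) round(mean(table[[c]]), 1), numeric(1)),
    min = vapply(cols, function(c) round(min(table[[c]]), 1), numeric(1)),
    max = vapply(cols, function(c) round(max(table[[c]]), 1), numeric(1)),
    row.names = cols)
  out
}
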