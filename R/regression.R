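# Predictor screening, Pearson correlations and automatic backward multiple
# regression on standardized scores. Model fitting itself is ordinary least
# squares via stats::lm on z-scored variables; the elimination procedure and
# reporting follow the study design: remove the single worst predictor
# (largest p) while its p exceeds p_remove, refit, repeat.

check_numeric_cols <- function(data, cols) {
  for (col in cols) {
    v <- data[[col]]
    if (is.null(v)) abort(sprintf("column '%s' not found", col), "adaptaaf_invalid_config")
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      abort(sprintf("column '%s' must be numeric with no missing values", col),
            "adaptaaf_invalid_config")
  }
  invisible(data)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation and its two-sided p-value from the t transform
#' with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with non-zero
#'   variance.
#' @return List: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) || length(x) < 3L)
    abort("x and y must be numeric vectors of equal length >= 3", "adaptaaf_invalid_input")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    abort("x and y must be finite with no missing values", "adaptaaf_invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("zero variance: correlation undefined", "adaptaaf_degenerate_input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standardized multiple regression
#'
#' Ordinary least-squares fit of a z-scored outcome on z-scored predictors
#' (standardized beta weights; the intercept is retained and is zero by
#' construction). Reports per-predictor beta, t and two-sided p, the adjusted
#' and unadjusted R-squared, the overall F statistic with (k, n - k - 1)
#' degrees of freedom, and the residual standard error of the standardized fit.
#'
#' @param data Data frame with no missing cells.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names (may be empty:
#'   intercept-only model).
#' @return Object of class `aaf_regression`.
#' @export
fit_standardized <- function(data, outcome,
                             predictors = setdiff(names(data), outcome)) {
  check_numeric_cols(data, c(outcome, predictors))
  n <- nrow(data)
  k <- length(predictors)
  if (n <= k + 1L)
    abort("need more participants than predictors + 1", "adaptaaf_invalid_config")
  if (stats::sd(data[[outcome]]) == 0)
    abort("outcome has zero variance", "adaptaaf_degenerate_input")
  degenerate <- predictors[vapply(predictors, function(p)
    stats::sd(data[[p]]) == 0, logical(1L))]
  if (length(degenerate))
    abort(sprintf("zero-variance predictor(s): %s", paste(degenerate, collapse = ", ")),
          "adaptaaf_degenerate_input")

  z <- as.data.frame(lapply(data[c(outcome, predictors)], function(v) as.numeric(scale(v))))
  names(z) <- c(".outcome", predictors)

  if (k > 0L) {
    q <- qr(as.matrix(z[predictors]))
    if (q$rank < k) {
      bad <- predictors[q$pivot[(q$rank + 1L):k]]
      abort(sprintf("collinear predictor(s): %s", paste(bad, collapse = ", ")),
            "adaptaaf_collinearity")
    }
  }

  fml <- if (k > 0L) stats::reformulate(predictors, ".outcome") else .outcome ~ 1
  fit <- stats::lm(fml, data = z)
  s <- summary(fit)
  if (k > 0L) {
    co <- s$coefficients[predictors, , drop = FALSE]
    betas <- stats::setNames(co[, 1L], predictors)
    tval <- stats::setNames(co[, 3L], predictors)
    pval <- stats::setNames(co[, 4L], predictors)
    fstat <- list(value = unname(s$fstatistic[1L]),
                  df1 = unname(s$fstatistic[2L]), df2 = unname(s$fstatistic[3L]))
    p_model <- stats::pf(fstat$value, fstat$df1, fstat$df2, lower.tail = FALSE)
  } else {
    betas <- tval <- pval <- stats::setNames(numeric(0L), character(0L))
    fstat <- NULL
    p_model <- NA_real_
  }
  structure(list(standardized_betas = betas, t_values = tval, p_values = pval,
                 r_squared = if (k > 0L) s$r.squared else 0,
                 adjusted_r2 = if (k > 0L) s$adj.r.squared else 0,
                 f_statistic = fstat, p_model = p_model,
                 residual_std_error = s$sigma,
                 n = n, outcome = outcome, predictors = predictors,
                 fit = fit),
            class = "aaf_regression")
}

#' @export
print.aaf_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Standardized regression of %s (n = %d, %d predictor%s)\n",
              x$outcome, x$n, length(x$predictors),
              if (length(x$predictors) == 1L) "" else "s"))
  if (length(x$predictors)) {
    tab <- data.frame(beta = round(x$standardized_betas, digits),
                      t = round(x$t_values, digits),
                      p = signif(x$p_values, digits))
    print(tab)
    cat(sprintf("adjusted R^2 = %.3f; F(%d, %d) = %.2f, p = %.3g; residual SE = %.3f\n",
                x$adjusted_r2, x$f_statistic$df1, x$f_statistic$df2,
                x$f_statistic$value, x$p_model, x$residual_std_error))
  } else {
    cat("(intercept-only model)\n")
  }
  invisible(x)
}

#' Automatic backward elimination
#'
#' Fits the full standardized model, then repeatedly removes the single
#' predictor with the largest p-value while that p exceeds `p_remove`
#' (one-at-a-time removal), refitting after each removal. Terminates when every
#' surviving predictor has p <= `p_remove` or the model is empty. The final
#' model is a fixed point: re-running elimination on it removes nothing.
#'
#' @param data Data frame with no missing cells.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of candidate predictors.
#' @param p_remove Removal threshold (default 0.10).
#' @return Object of class `aaf_elimination`: `initial` and `final`
#'   [fit_standardized()] models and `steps`, a data frame recording each
#'   removed predictor and its p at removal.
#' @export
backward_eliminate <- function(data, outcome,
                               predictors = setdiff(names(data), outcome),
                               p_remove = 0.10) {
  if (!is_number(p_remove) || p_remove <= 0 || p_remove >= 1)
    abort("p_remove must be in (0, 1)", "adaptaaf_invalid_config")
  remaining <- predictors
  initial <- fit_standardized(data, outcome, remaining)
  model <- initial
  removed <- character(0L)
  p_at_removal <- numeric(0L)
  while (length(remaining) > 0L) {
    p <- model$p_values
    worst <- which.max(p)
    if (p[[worst]] <= p_remove) break
    removed <- c(removed, names(p)[[worst]])
    p_at_removal <- c(p_at_removal, p[[worst]])
    remaining <- setdiff(remaining, names(p)[[worst]])
    model <- fit_standardized(data, outcome, remaining)
  }
  structure(list(initial = initial, final = model,
                 steps = data.frame(step = seq_along(removed),
                                    removed = removed, p_at_removal = p_at_removal)),
            class = "aaf_elimination")
}

#' @export
print.aaf_elimination <- function(x, ...) {
  cat("Backward elimination\n--- initial model ---\n")
  print(x$initial)
  if (nrow(x$steps)) {
    cat("--- removals ---\n")
    for (i in seq_len(nrow(x$steps)))
      cat(sprintf("  step %d: removed %s (p = %.3f)\n", x$steps$step[i],
                  x$steps$removed[i], x$steps$p_at_removal[i]))
  } else cat("--- no removals ---\n")
  cat("--- final model ---\n")
  print(x$final)
  invisible(x)
}

#' Combine melody-task percent-correct scores
#'
#' The combined score is the percentage of correct responses over both melody
#' tasks pooled: total correct divided by total trials.
#'
#' @param simple_pct,transposed_pct Percent-correct in the simple and
#'   transposed melody tasks.
#' @param n_simple,n_transposed Trial counts per task (default 60 each).
#' @return Combined percent-correct.
#' @export
combine_melody_scores <- function(simple_pct, transposed_pct,
                                  n_simple = 60L, n_transposed = 60L) {
  if (!is_count(n_simple) || !is_count(n_transposed))
    abort("trial counts must be positive whole numbers", "adaptaaf_invalid_config")
  (simple_pct * n_simple + transposed_pct * n_transposed) / (n_simple + n_transposed)
}

#' Screen candidate predictors for mutual correlation
#'
#' Reports all pairwise Pearson correlations (r, r-squared, two-sided p) among
#' the candidate predictors. If the two melody percent-correct scores are
#' significantly correlated at `p_corr` they are merged into a single combined
#' score ([combine_melody_scores()]), mirroring the study's treatment of the
#' simple/transposed melody pair.
#'
#' @param data Data frame of candidate predictors (numeric, no missing cells).
#' @param melody_cols Names of the two melody score columns (both must be
#'   present for the merge rule to be evaluated).
#' @param melody_trials Trial counts for the two melody tasks.
#' @param p_corr Significance threshold for the merge (default 0.05).
#' @param combined_name Column name for the merged melody score.
#' @return List of class `aaf_screen`: `data` (possibly with the melody pair
#'   replaced by the combined score), `correlations` (pairwise report),
#'   `melody` (list: `merged`, `r`, `r2`, `p`).
#' @export
screen_predictors <- function(data,
                              melody_cols = c("melody_simple_pct", "melody_transposed_pct"),
                              melody_trials = c(60L, 60L),
                              p_corr = 0.05,
                              combined_name = "melody_pct") {
  cols <- names(data)
  check_numeric_cols(data, cols)
  pairs <- utils::combn(cols, 2L)
  correlations <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    pr <- pearson(data[[a]], data[[b]])
    data.frame(var1 = a, var2 = b, r = pr$r, r2 = pr$r^2, p = pr$p)
  }))

  melody <- list(merged = FALSE, r = NA_real_, r2 = NA_real_, p = NA_real_)
  if (all(melody_cols %in% cols)) {
    pr <- pearson(data[[melody_cols[1L]]], data[[melody_cols[2L]]])
    melody <- list(merged = pr$p <= p_corr, r = pr$r, r2 = pr$r^2, p = pr$p)
    if (melody$merged) {
      data[[combined_name]] <- combine_melody_scores(
        data[[melody_cols[1L]]], data[[melody_cols[2L]]],
        melody_trials[1L], melody_trials[2L])
      data <- data[setdiff(names(data), melody_cols)]
    }
  }
  structure(list(data = data, correlations = correlations, melody = melody),
            class = "aaf_screen")
}

#' @export
print.aaf_screen <- function(x, ...) {
  cat(sprintf("Predictor screen: %d predictors", ncol(x$data)))
  if (x$melody$merged)
    cat(sprintf(" (melody scores merged: r = %.2f, r^2 = %.2f, p = %.3f)",
                x$melody$r, x$melody$r2, x$melody$p))
  cat("\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
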