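test_that("pearson matches closed-form values and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  pr <- pearson(x, c(1, 3, 2, 4))
  expect_equal(pr$r, 0.8)
  expect_equal(pr$n, 4)
  # p from the t transform with n - 2 df
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(pr$p, 2 * pt(tstat, df = 2, lower.tail = FALSE))
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), class = "adaptaaf_degenerate_input")
  expect_error(pearson(1:2, 1:2), class = "adaptaaf_invalid_input")
})

test_that("standardized fit reports betas, t, p, R2 and F consistently", {
  set.seed(20)
  x <- rnorm(31)
  d <- data.frame(y = 3 * x - 2, x = x)
  fit <- suppressWarnings(fit_standardized(d, "y"))  # exact fit by design
  expect_equal(unname(fit$standardized_betas["x"]), 1)
  expect_equal(fit$adjusted_r2, 1)

  d2 <- data.frame(y = rnorm(31), x1 = rnorm(31), x2 = rnorm(31))
  f2 <- fit_standardized(d2, "y")
  expect_lte(f2$adjusted_r2, f2$r_squared)
  expect_true(all(f2$p_values >= 0 & f2$p_values <= 1))
  expect_equal(f2$f_statistic$df1, 2)
  expect_equal(f2$f_statistic$df2, 28)

  dup <- d2
  dup$x3 <- dup$x1
  expect_error(fit_standardized(dup, "y"), class = "adaptaaf_collinearity")
  expect_error(fit_standardized(dup, "y"), "x3")
  small <- d2[1:3, ]
  expect_error(fit_standardized(small, "y"), class = "adaptaaf_invalid_config")
  const <- transform(d2, x1 = 1)
  expect_error(fit_standardized(const, "y"), class = "adaptaaf_degenerate_input")
})

test_that("standardized betas are invariant to affine rescaling", {
  set.seed(21)
  d <- data.frame(y = rnorm(40), a = rnorm(40), b = rnorm(40))
  d$y <- d$a - 0.5 * d$b + rnorm(40, 0, 0.5)
  base <- fit_standardized(d, "y")
  resc <- data.frame(y = 7 * d$y - 3, a = d$a / 100 + 2, b = -0 + 1000 * d$b)
  alt <- fit_standardized(resc, "y")
  expect_equal(alt$standardized_betas, base$standardized_betas)
  expect_equal(alt$t_values, base$t_values)
  expect_equal(alt$adjusted_r2, base$adjusted_r2)
})

test_that("null-model adjusted R-squared is centred on zero", {
  set.seed(22)
  ar <- replicate(1000, {
    d <- as.data.frame(matrix(rnorm(31 * 7), 31))
    names(d) <- c("y", paste0("x", 1:6))
    fit_standardized(d, "y")$adjusted_r2
  })
  expect_lt(abs(mean(ar)), 0.02)
})

test_that("backward elimination removes one worst predictor at a time", {
  set.seed(23)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  d <- data.frame(y = x1 - x2 + rnorm(n, 0, 0.3), x1, x2, x3)
  el <- backward_eliminate(d, "y")
  # strong predictors all significant at the first fit in this regime
  expect_setequal(el$final$predictors, c("x1", "x2"))
  expect_equal(el$steps$removed, "x3")
  expect_true(all(el$final$p_values <= 0.10))
  # a model whose predictors all pass produces zero removals
  el2 <- backward_eliminate(d[c("y", "x1", "x2")], "y")
  expect_equal(nrow(el2$steps), 0)
  # the final model is a fixed point of the procedure
  refit <- backward_eliminate(cbind(el$final$fit$model[-1],
                                    y = d$y)[c("y", el$final$predictors)], "y")
  expect_equal(nrow(refit$steps), 0)
  expect_error(backward_eliminate(d, "y", p_remove = 1.5), class = "adaptaaf_invalid_config")
})

test_that("elimination keeps a strong predictor and usually drops pure noise", {
  set.seed(24)
  keep_strong <- 0L
  drop_noise <- 0L
  for (s in 1:300) {
    x1 <- rnorm(200); x2 <- rnorm(200)
    d <- data.frame(y = 0.8 * x1 + rnorm(200, 0, 0.6), x1, x2)
    fin <- backward_eliminate(d, "y")$final$predictors
    keep_strong <- keep_strong + ("x1" %in% fin)
    drop_noise <- drop_noise + !("x2" %in% fin)
  }
  expect_gte(keep_strong, 297)            # essentially always
  # the noise predictor survives with ~p_remove probability by construction,
  # so the drop rate sits near 1 - p_remove, not at 1
  expect_gte(drop_noise, 240)
})

test_that("elimination on pure noise usually empties the model", {
  # each null predictor survives with ~p_remove probability, so the modal
  # outcome is the empty model (~half of seeds) and few predictors remain
  set.seed(25)
  empty <- 0L
  retained <- 0L
  n_sims <- 150L
  for (s in seq_len(n_sims)) {
    d <- as.data.frame(matrix(rnorm(31 * 7), 31))
    names(d) <- c("y", paste0("x", 1:6))
    fin <- backward_eliminate(d, "y")$final$predictors
    if (length(fin) == 0L) empty <- empty + 1L
    retained <- retained + length(fin)
  }
  expect_gt(empty / n_sims, 0.4)
  expect_lt(retained / n_sims, 1.2)
})

test_that("melody scores are pooled as total correct over total trials", {
  expect_equal(combine_melody_scores(80, 70), 75)
  expect_equal(combine_melody_scores(80, 70, n_simple = 90, n_transposed = 30), 77.5)
  expect_equal(combine_melody_scores(77, 77), 77)
})

test_that("screening merges correlated melody scores and reports correlations", {
  set.seed(26)
  n <- 31
  shared <- rnorm(n)
  d <- data.frame(interference_stroop = rnorm(n),
                  interference_simon = rnorm(n),
                  melody_simple_pct = 75 + 5 * shared + rnorm(n, 0, 2),
                  melody_transposed_pct = 72 + 5 * shared + rnorm(n, 0, 2))
  # oracle: the direct correlation test on the melody pair decides the merge
  pr <- pearson(d$melody_simple_pct, d$melody_transposed_pct)
  scr <- screen_predictors(d)
  expect_equal(scr$melody$merged, pr$p <= 0.05)
  expect_true(scr$melody$merged)
  expect_true("melody_pct" %in% names(scr$data))
  expect_false(any(c("melody_simple_pct", "melody_transposed_pct") %in% names(scr$data)))
  expect_equal(scr$data$melody_pct,
               combine_melody_scores(d$melody_simple_pct, d$melody_transposed_pct))
  expect_equal(nrow(scr$correlations), choose(4, 2))
  expect_equal(scr$correlations$r2, scr$correlations$r^2)

  # identical melody scores merge to the same values
  d2 <- d
  d2$melody_transposed_pct <- d2$melody_simple_pct
  scr2 <- screen_predictors(d2)
  expect_equal(scr2$data$melody_pct, d2$melody_simple_pct)

  # without a melody pair the matrix passes through unchanged
  d3 <- as.data.frame(matrix(rnorm(n * 6), n))
  names(d3) <- paste0("v", 1:6)
  scr3 <- screen_predictors(d3)
  expect_identical(scr3$data, d3)
  expect_false(scr3$melody$merged)
})
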