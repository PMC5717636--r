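test_that("within/between decomposition reconstructs the predictor", {
  wb <- within_between(c(1, 2, 3), rep("a", 3))
  expect_equal(wb$within, c(-1, 0, 1))
  expect_equal(wb$between, c(2, 2, 2))
  wb2 <- within_between(c(1, 3, 8, 12), c("a", "a", "b", "b"))
  expect_equal(wb2$between, c(2, 2, 10, 10))
  set.seed(8)
  x <- rnorm(100); g <- sample(letters[1:5], 100, replace = TRUE)
  wb3 <- within_between(x, g)
  expect_equal(wb3$within + wb3$between, x, tolerance = 1e-12)
  expect_true(all(abs(tapply(wb3$within, g, mean)) < 1e-12))
})

test_that("autocorrelation term is a kernel-weighted residual mean", {
  rows <- data.frame(group = c("a", "a", "a", "b"),
                     date = as.Date("2012-10-01") + c(0, 1, 30, 0),
                     cell_i = c(0, 0, 5, 2), cell_j = c(0, 0, 5, 2))
  g <- toy_grid()
  # zero residuals give zero everywhere
  expect_equal(autocorrelation_term(rows, rep(0, 4), 3, 500, g), rep(0, 4))
  # single-row group gets zero
  res <- c(1, -1, 2, 5)
  expect_equal(autocorrelation_term(rows, res, 3, 500, g)[4], 0)
  # huge scales: unweighted mean of the other same-group residuals
  a <- autocorrelation_term(rows, res, 1e9, 1e12, g)
  expect_equal(a[1], mean(res[2:3]), tolerance = 1e-6)
  expect_equal(a[2], mean(res[c(1, 3)]), tolerance = 1e-6)
  # tiny temporal scale: only the 1-day-apart same-cell row matters
  b <- autocorrelation_term(rows, res, 1, 500, g)
  expect_equal(b[1], res[2], tolerance = 1e-3)
  expect_error(autocorrelation_term(rows, res, -1, 500, g), "> 0")
})

test_that("utilization tables decompose transformed predictors per group", {
  g <- toy_grid()
  f <- toy_field(g)
  set.seed(2)
  vis <- data.frame(group = rep(c("A", "B"), each = 15),
                    cell_i = sample(0:9, 30, TRUE),
                    cell_j = sample(0:9, 30, TRUE),
                    date = as.Date("2012-10-01") + sample(0:60, 30, TRUE),
                    distance_m = c(rexp(28, 1 / 400), 0, 0))
  led <- toy_ledger(vis)
  tab <- build_utilization_table(vis, f, led)
  expect_equal(nrow(tab), 28)  # zero-distance rows dropped
  expect_equal(tab$response, log(vis$distance_m[vis$distance_m > 0]))
  for (p in c("food", "self", "nbr")) {
    w <- tab[[paste0(p, "_within")]]
    expect_true(all(abs(tapply(w, tab$group, mean)) < 1e-10))
  }
})

test_that("with zero variance components the LMM equals OLS", {
  rows <- simulate_utilization_rows(n_groups = 8, n_per_group = 30,
                                    beta = c(food_within = 0.3),
                                    sd_group = 0, sd_cell = 0, sd_gcell = 0,
                                    sd_resid = 1, seed = 21)
  fit <- fit_utilization_model(rows)
  ols <- lm(response ~ food_within + food_between + self_within +
              self_between + nbr_within + nbr_between + autocor,
            data = data.frame(rows))
  # all variance components estimated at (or near) the boundary
  expect_lt(sum(fit$varcor[c("group", "cell", "group:cell")]), 1e-3)
  keep <- intersect(rownames(fit$coefficients), names(coef(ols)))
  expect_equal(fit$coefficients[keep, "Est"], coef(ols)[keep],
               tolerance = 1e-3)
})

test_that("the full model never has lower likelihood than the null", {
  for (s in 1:3) {
    rows <- simulate_utilization_rows(n_groups = 6, n_per_group = 20,
                                      seed = 100 + s)
    full <- fit_utilization_model(rows)
    null <- fit_utilization_model(rows, null = TRUE)
    lrt <- likelihood_ratio_full_null(full, null)
    expect_gte(full$logLik, null$logLik - 1e-6)
    expect_equal(lrt$df, 6)
    expect_gte(lrt$p_value, 0)
  }
})

test_that("an injected effect is estimated with the right magnitude", {
  rows <- simulate_utilization_rows(n_groups = 10, n_per_group = 60,
                                    beta = c(nbr_between = -0.4,
                                             self_within = 0.2), seed = 33)
  fit <- fit_utilization_model(rows)
  est <- fit$coefficients[, "Est"]
  se <- fit$coefficients[, "s.e."]
  expect_lt(abs(est["nbr_between"] + 0.4), 3 * se["nbr_between"])
  expect_lt(abs(est["self_within"] - 0.2), 3 * se["self_within"])
})

test_that("profile selection of autocorrelation scales returns a grid optimum", {
  g <- toy_grid()
  rows <- simulate_utilization_rows(n_groups = 5, n_per_group = 25, seed = 5)
  rows$cell_i <- rows$cell_i %% 10; rows$cell_j <- rows$cell_j %% 10
  sel <- select_autocor_sigma(rows, g, sigma_t_grid = c(3, 14),
                              sigma_s_grid = c(500, 1500))
  expect_true(sel$sigma_t %in% c(3, 14))
  expect_true(sel$sigma_s %in% c(500, 1500))
  expect_equal(max(sel$table$logLik), sel$logLik)
})

test_that("the full-null LRT reaches nominal level with many groups", {
  # with few groups the chi-squared reference for the three group-level
  # (between) terms is optimistic; this check shows the test calibrates as
  # the number of groups grows, i.e. the inflation is a small-sample
  # property of the reference distribution, not an implementation defect
  n_rep <- 150
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    rows <- simulate_utilization_rows(n_groups = 30, n_per_group = 40,
                                      seed = 20000 + r)
    full <- fit_utilization_model(rows)
    null <- fit_utilization_model(rows, null = TRUE)
    pvals[r] <- likelihood_ratio_full_null(full, null)$p_value
  }
  rate <- mean(pvals <= 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.09)
})
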