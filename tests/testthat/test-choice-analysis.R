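test_that("log-z transform standardizes, preserves order, handles zeros", {
  set.seed(3)
  x <- rexp(200, 1 / 50)
  tr <- log_z_transform(x)
  expect_equal(mean(tr$values), 0, tolerance = 1e-12)
  expect_equal(sd(tr$values), 1, tolerance = 1e-12)
  expect_equal(order(tr$values), order(x))
  # zeros map to a finite value via the half-minimum shift
  x0 <- c(0, 1, 10, 100)
  tr0 <- log_z_transform(x0)
  expect_true(all(is.finite(tr0$values)))
  expect_equal(tr0$state$shift, 0.5)
  # a fitted state reapplies identically on new data
  tr2 <- log_z_transform(x[1:50], tr$state)
  expect_equal(tr2$values, tr$values[1:50])
  expect_error(log_z_transform(rep(2, 5)), "zero variance")
  expect_error(log_z_transform(c(-1, 2)), ">= 0")
})

toy_decisions <- function() {
  data.frame(group = "A", date = as.Date("2012-10-05"),
             origin_i = c(2, 0), origin_j = c(2, 0),
             chosen_i = c(3, 1), chosen_j = c(2, 1),
             n_candidates = NA)
}

test_that("choice tables carry offsets, chosen flags and predictors", {
  g <- toy_grid()
  f <- toy_field(g)
  led <- toy_ledger(data.frame(group = c("A", "B"), cell_i = 3, cell_j = 2,
                               date = as.Date("2012-10-01"),
                               distance_m = c(120, 300)))
  tab <- build_choice_table(toy_decisions(), f, led)
  # interior origin: 8 candidates, offset log(1/8); corner origin: 3
  expect_equal(sum(tab$choice_id == 1), 8)
  expect_equal(unique(tab$offset[tab$choice_id == 1]), log(1 / 8))
  expect_equal(sum(tab$choice_id == 2), 3)
  expect_equal(unique(tab$offset[tab$choice_id == 2]), log(1 / 3))
  expect_equal(as.vector(rowsum(tab$chosen, tab$choice_id)), c(1, 1))
  # previous-use predictors evaluated at (cell, date): 4 days after visit
  row <- tab[tab$cell_i == 3 & tab$cell_j == 2 & tab$choice_id == 1, ]
  expect_equal(row$prev_self_raw, 10 / 4 * 120)
  expect_equal(row$prev_nbr_raw, 10 / 4 * 300)
  expect_equal(row$food_raw, 100 * 4 + 10 * 3)  # gradient field at (3,2)
})

test_that("beta = 0 log-likelihood is the uniform-choice null exactly", {
  tab <- simulate_choice_sets(100, beta = c(0.4, 0, 0), seed = 2)
  fit <- fit_choice_model(tab)
  expect_equal(fit$null_logLik, -100 * log(8))
  expect_equal(clogit_ll_bruteforce(tab, c(0, 0, 0)), -100 * log(8))
  expect_gte(fit$logLik, fit$null_logLik)
})

test_that("Newton MLE agrees with a brute-force grid search", {
  tab <- simulate_choice_sets(50, beta = c(0.6, -0.4, 0.2), seed = 9,
                              n_candidates = 2)
  fit <- fit_choice_model(tab)
  # coarse-to-fine grid search over the three coefficients
  centre <- c(0, 0, 0); width <- 2
  for (round in 1:6) {
    gr <- expand.grid(b1 = centre[1] + seq(-width, width, length.out = 11),
                      b2 = centre[2] + seq(-width, width, length.out = 11),
                      b3 = centre[3] + seq(-width, width, length.out = 11))
    ll <- apply(gr, 1, function(b) clogit_ll_bruteforce(tab, b))
    centre <- as.numeric(gr[which.max(ll), ])
    width <- width / 4
  }
  expect_lt(max(abs(fit$coefficients - centre)), 1e-3)
})

test_that("conditional logit matches the survival package on shared data", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  tab <- simulate_choice_sets(300, beta = c(0.5, -0.3, 0.2), seed = 5)
  fit <- fit_choice_model(tab)
  cf <- survival::clogit(chosen ~ food + prev_self + prev_nbr +
                           strata(choice_id), data = as.data.frame(tab))
  expect_equal(unname(fit$coefficients), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cf)))), tolerance = 1e-5)
})

test_that("likelihood is invariant to set-constant predictor shifts", {
  tab <- simulate_choice_sets(80, beta = c(0.5, 0.2, -0.2), seed = 4)
  fit <- fit_choice_model(tab)
  shifted <- tab
  shifts <- rnorm(length(unique(tab$choice_id)))
  shifted$food <- shifted$food + shifts[shifted$choice_id]
  fit2 <- fit_choice_model(shifted)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-6)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-4)
})

test_that("complete separation is flagged as non-converged", {
  tab <- simulate_choice_sets(30, beta = c(0, 0, 0), seed = 6,
                              n_candidates = 2)
  # make food perfectly predict the choice
  tab$food <- ifelse(tab$chosen == 1, 5, -5)
  fit <- fit_choice_model(tab, predictors = "food")
  expect_false(fit$converged)
})

test_that("permutations are deterministic, weighted and structure-preserving", {
  tab <- simulate_choice_sets(120, beta = c(0.5, 0.3, 0), seed = 10)
  p1 <- permutation_full_null(tab, n_perm = 50, seed = 77)
  p2 <- permutation_full_null(tab, n_perm = 50, seed = 77)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$null_stats, p2$null_stats)
  expect_gte(p1$observed_stat, 0)
  expect_true(all(p1$null_stats >= -1e-8))
  expect_equal(p1$p_value,
               (1 + sum(p1$null_stats >= p1$observed_stat)) / (1 + 50))
  expect_error(permutation_full_null(tab, n_perm = 0), "n_perm")
  # user-supplied edge/corner weights are honoured
  p3 <- permutation_full_null(tab, n_perm = 10, seed = 1,
                              weights = c(edge = 2, corner = 1))
  expect_equal(unname(p3$weights), c(2, 1))
})

test_that("a strong effect is detected by the permutation test", {
  tab <- simulate_choice_sets(300, beta = c(0.8, 0, 0), seed = 12)
  p <- permutation_full_null(tab, n_perm = 99, seed = 3)
  expect_equal(p$p_value, 1 / 100)
})
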