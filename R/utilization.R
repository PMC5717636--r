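#' Within-/between-group decomposition of a predictor
#'
#' Splits a predictor into the group mean (between-groups variation) and the
#' deviation from the group mean (within-groups variation), so a model can
#' carry possibly different effects at the two levels. The parts reconstruct
#' the original exactly: \code{within + between == x}.
#'
#' @param x Numeric vector.
#' @param group Group labels, same length as \code{x}.
#' @return List with numeric vectors \code{within} and \code{between}.
#' @export
within_between <- function(x, group) {
  stopifnot(length(x) == length(group))
  gm <- stats::ave(x, group, FUN = mean)
  list(within = x - gm, between = gm)
}

#' Build the model frame for the utilization-of-a-chosen-area model
#'
#' One row per (group, date, cell) visit with positive travel distance. The
#' response is the log of the distance travelled in the cell that day; the
#' three test predictors (food energy density, previous use by the group,
#' previous use by the neighbours) are evaluated at the visit's cell and
#' date, log- and z-transformed, and split into within- and between-group
#' parts. Zero-distance visits are dropped: a visit without measurable
#' travel carries no utilization signal.
#'
#' @param visits Cell-visit data frame from \code{\link{distance_per_cell}}
#'   (after \code{\link{apply_burn_in}}).
#' @param field An \code{energy_field}; visits to masked cells are dropped.
#' @param ledger A \code{\link{usage_ledger}}.
#' @param transforms Optional named list of transform states (as in
#'   \code{\link{build_choice_table}}).
#' @return Data frame with columns \code{group}, \code{date}, \code{cell_i},
#'   \code{cell_j}, \code{response}, \code{food_within}, \code{food_between},
#'   \code{self_within}, \code{self_between}, \code{nbr_within},
#'   \code{nbr_between} and an \code{autocor} column initialised to 0;
#'   transform states attached as attribute \code{"transforms"}.
#' @export
build_utilization_table <- function(visits, field, ledger, transforms = NULL) {
  visits <- visits[visits$distance_m > 0, , drop = FALSE]
  food <- energy_at(field, cbind(visits$cell_i, visits$cell_j))
  visits <- visits[!is.na(food), , drop = FALSE]
  food <- food[!is.na(food)]
  if (!nrow(visits)) stop("no usable utilization rows")
  n <- nrow(visits)
  ps <- pn <- numeric(n)
  gcodes <- match(visits$group, ledger$groups)
  all_codes <- seq_along(ledger$groups)
  ref <- as.integer(as.Date(visits$date))
  for (r in seq_len(n)) {
    mat <- get0(cell_key(visits$cell_i[r], visits$cell_j[r]),
                envir = ledger$index)
    ps[r] <- pu_sum(mat, gcodes[r], ref[r])
    pn[r] <- pu_sum(mat, setdiff(all_codes, gcodes[r]), ref[r])
  }
  raw <- list(food = food, prev_self = ps, prev_nbr = pn)
  tf <- list()
  z <- list()
  for (p in names(raw)) {
    tr <- log_z_transform(raw[[p]], transforms[[p]])
    z[[p]] <- tr$values
    tf[[p]] <- tr$state
  }
  out <- data.frame(group = visits$group, date = as.Date(visits$date),
                    cell_i = visits$cell_i, cell_j = visits$cell_j,
                    response = log(visits$distance_m))
  map <- c(food = "food", self = "prev_self", nbr = "prev_nbr")
  for (short in names(map)) {
    wb <- within_between(z[[map[[short]]]], out$group)
    out[[paste0(short, "_within")]] <- wb$within
    out[[paste0(short, "_between")]] <- wb$between
  }
  out$autocor <- 0
  rownames(out) <- NULL
  structure(out, transforms = tf, class = c("utilization_table",
                                            "data.frame"))
}

#' Spatio-temporal autocorrelation term
#'
#' For each row, a Gaussian-weighted mean of the residuals of all other rows
#' of the same group, with weight
#' \code{exp(-dt^2 / (2 sigma_t^2)) * exp(-dx^2 / (2 sigma_s^2))} where
#' \code{dt} is the difference in days and \code{dx} the distance between
#' cell centres. Rows in single-row groups (or with zero total weight) get
#' 0. Including the term as a covariate absorbs residual temporal and
#' spatial autocorrelation left by the random-intercept structure.
#'
#' @param rows A \code{utilization_table} (needs \code{group}, \code{date},
#'   \code{cell_i}, \code{cell_j}).
#' @param residuals Residuals of a prior fit of the model without the term.
#' @param sigma_t Temporal scale, days (> 0).
#' @param sigma_s Spatial scale, metres (> 0).
#' @param grid A \code{space_grid} giving cell-centre geometry.
#' @return Numeric vector, one value per row.
#' @export
autocorrelation_term <- function(rows, residuals, sigma_t, sigma_s, grid) {
  if (sigma_t <= 0 || sigma_s <= 0) stop("sigma_t and sigma_s must be > 0")
  stopifnot(length(residuals) == nrow(rows))
  cc <- cell_centre(cbind(rows$cell_i, rows$cell_j), grid)
  day <- as.numeric(as.Date(rows$date))
  out <- numeric(nrow(rows))
  for (g in unique(rows$group)) {
    w <- which(rows$group == g)
    if (length(w) < 2) next
    dt2 <- outer(day[w], day[w], "-")^2
    dx2 <- outer(cc[w, 1], cc[w, 1], "-")^2 + outer(cc[w, 2], cc[w, 2], "-")^2
    W <- exp(-dt2 / (2 * sigma_t^2)) * exp(-dx2 / (2 * sigma_s^2))
    diag(W) <- 0
    tw <- rowSums(W)
    val <- as.vector(W %*% residuals[w])
    out[w] <- ifelse(tw > 0, val / tw, 0)
  }
  out
}

# internal: the utilization model formulas
util_formula <- function(full = TRUE) {
  fixed <- if (full)
    "response ~ food_within + food_between + self_within + self_between + nbr_within + nbr_between + autocor"
  else
    "response ~ autocor"
  stats::as.formula(paste(fixed,
    "+ (1 | group) + (1 | cell) + (1 | group:cell)"))
}

#' Fit the linear mixed model for utilization of a chosen area
#'
#' Gaussian LMM (fitted by maximum likelihood so that full and null models
#' are comparable by a likelihood-ratio test) of log distance travelled in a
#' chosen cell on the six within/between predictor terms plus the
#' autocorrelation term, with random intercepts for group, cell and
#' group-by-cell.
#'
#' @param rows A \code{utilization_table}. If \code{autocor_sigma} is given,
#'   the autocorrelation term is (re)computed from the residuals of a fit
#'   without it before the final fit.
#' @param null If \code{TRUE} fit the null model (intercept + autocorrelation
#'   term + random intercepts; the six test-predictor terms dropped).
#' @param autocor_sigma Optional \code{c(sigma_t, sigma_s)}; when \code{NULL}
#'   the \code{autocor} column is used as supplied.
#' @param grid Required when \code{autocor_sigma} is given.
#' @return Object of class \code{util_fit}: \code{coefficients} table
#'   (Est, s.e.), \code{logLik} (ML), \code{varcor} (random-intercept
#'   variances), \code{fit} (the \code{lmerMod}), \code{rows}.
#' @export
fit_utilization_model <- function(rows, null = FALSE, autocor_sigma = NULL,
                                  grid = NULL) {
  rows <- as.data.frame(rows)
  rows$cell <- cell_key(rows$cell_i, rows$cell_j)
  if (!is.null(autocor_sigma)) {
    if (is.null(grid)) stop("grid is required to recompute the autocor term")
    rows$autocor <- 0
    base <- suppressMessages(suppressWarnings(
      lme4::lmer(util_formula(!null), data = rows, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    rows$autocor <- autocorrelation_term(rows, stats::residuals(base),
                                         autocor_sigma[1], autocor_sigma[2],
                                         grid)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(util_formula(!null), data = rows, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = cbind(Est = co, s.e. = se),
                 logLik = as.numeric(stats::logLik(fit)),
                 varcor = stats::setNames(vc$vcov, vc$grp),
                 fit = fit, rows = rows, null = null),
            class = "util_fit")
}

#' @export
print.util_fit <- function(x, ...) {
  cat(sprintf("<util_fit> %s model, logLik %.3f\n",
              if (x$null) "null" else "full", x$logLik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Select autocorrelation scales by profile likelihood
#'
#' Fits the model without the autocorrelation term, then for every
#' (sigma_t, sigma_s) pair on the grid computes the term from the base
#' residuals, refits, and returns the pair maximizing the ML likelihood.
#'
#' @param rows A \code{utilization_table}.
#' @param grid A \code{space_grid}.
#' @param sigma_t_grid,sigma_s_grid Candidate scales (days; metres).
#' @return List: \code{sigma_t}, \code{sigma_s}, \code{logLik}, and the full
#'   search \code{table}.
#' @export
select_autocor_sigma <- function(rows, grid,
                                 sigma_t_grid = c(1, 3, 7, 14, 30),
                                 sigma_s_grid = c(250, 500, 1000, 2000)) {
  rows <- as.data.frame(rows)
  rows$cell <- cell_key(rows$cell_i, rows$cell_j)
  rows$autocor <- 0
  base <- suppressMessages(suppressWarnings(
    lme4::lmer(util_formula(TRUE), data = rows, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  res <- stats::residuals(base)
  cand <- expand.grid(sigma_t = sigma_t_grid, sigma_s = sigma_s_grid)
  cand$logLik <- NA_real_
  for (r in seq_len(nrow(cand))) {
    rows$autocor <- autocorrelation_term(rows, res, cand$sigma_t[r],
                                         cand$sigma_s[r], grid)
    f <- suppressMessages(suppressWarnings(
      lme4::lmer(util_formula(TRUE), data = rows, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    cand$logLik[r] <- as.numeric(stats::logLik(f))
  }
  best <- cand[which.max(cand$logLik), ]
  list(sigma_t = best$sigma_t, sigma_s = best$sigma_s,
       logLik = best$logLik, table = cand)
}

#' Likelihood-ratio test of the full against the null utilization model
#'
#' Both models share the random-effect structure and the autocorrelation
#' term; the test concerns the six fixed test-predictor terms, so the
#' statistic \eqn{2(LL_{full} - LL_{null})} is referred to a chi-squared
#' distribution with 6 degrees of freedom.
#'
#' @param full,null \code{util_fit} objects (ML fits).
#' @return List: \code{chisq}, \code{df}, \code{p_value}.
#' @export
likelihood_ratio_full_null <- function(full, null) {
  stat <- 2 * (full$logLik - null$logLik)
  df <- nrow(full$coefficients) - nrow(null$coefficients)
  list(chisq = max(stat, 0), df = df,
       p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}
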