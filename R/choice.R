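#' Log- then z-transform a non-negative predictor
#'
#' Computes \code{(log(x + c) - mean) / sd}, the transformation applied to
#' every test predictor before model fitting: the log makes right-skewed
#' availability/previous-use distributions approximately symmetric, the
#' z-scaling puts coefficients on a per-standard-deviation scale. The shift
#' constant \code{c} is half the smallest positive value (1 if all values are
#' zero) so that zeros map to a finite value. A fitted \code{TransformState}
#' can be re-applied to new data.
#'
#' @param x Non-negative numeric vector.
#' @param state Optional transform state from a previous call; when supplied,
#'   its shift/mean/sd are applied unchanged.
#' @return List with \code{values} (transformed vector) and \code{state}
#'   (class \code{log_z_state}: \code{shift}, \code{mean}, \code{sd}).
#' @export
log_z_transform <- function(x, state = NULL) {
  if (any(x < 0, na.rm = TRUE)) stop("values must be >= 0")
  if (is.null(state)) {
    pos <- x[x > 0 & !is.na(x)]
    shift <- if (length(pos)) min(pos) / 2 else 1
    y <- log(x + shift)
    m <- mean(y, na.rm = TRUE); s <- stats::sd(y, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero variance after log transform")
    state <- structure(list(shift = shift, mean = m, sd = s),
                       class = "log_z_state")
  }
  list(values = (log(x + state$shift) - state$mean) / state$sd,
       state = state)
}

#' Build the choice table for the movement-choice model
#'
#' Expands each cell-entry decision into one row per candidate cell (the
#' origin's neighbours with food data), evaluating the three test predictors
#' at that cell and date: herbaceous food energy density, previous use by the
#' group, and previous use by the neighbouring groups collectively. Each
#' predictor is then log- and z-transformed over all rows (or with supplied
#' transform states). The offset \code{log(1/n_candidates)} controls for the
#' varying number of surrounding cells. Decisions whose chosen cell lacks
#' food data have already been dropped upstream.
#'
#' @param decisions Data frame from \code{\link{extract_entry_decisions}}
#'   (after \code{\link{apply_burn_in}}).
#' @param field An \code{energy_field}.
#' @param ledger A \code{\link{usage_ledger}}.
#' @param transforms Optional named list of \code{log_z_state} objects
#'   (\code{food}, \code{prev_self}, \code{prev_nbr}), e.g. the truth record
#'   of a simulation.
#' @return Data frame of class \code{choice_table}: \code{choice_id},
#'   \code{group}, \code{date}, \code{cell_i}, \code{cell_j}, \code{corner}
#'   (1 if the candidate touches the origin only at a corner), transformed
#'   \code{food}, \code{prev_self}, \code{prev_nbr}, raw \code{*_raw}
#'   columns, \code{chosen} (0/1, exactly one per set) and \code{offset}.
#'   The fitted transform states are attached as attribute
#'   \code{"transforms"}.
#' @export
build_choice_table <- function(decisions, field, ledger, transforms = NULL) {
  grid <- field$grid
  n <- nrow(decisions)
  if (!n) stop("no decisions supplied")
  rows <- vector("list", n)
  gcodes <- match(decisions$group, ledger$groups)
  all_codes <- seq_along(ledger$groups)
  for (r in seq_len(n)) {
    nb <- neighbour_cells(decisions$origin_i[r], decisions$origin_j[r], grid)
    keep <- !is.na(energy_at(field, nb[, 1:2, drop = FALSE]))
    nb <- nb[keep, , drop = FALSE]
    m <- nrow(nb)
    ref <- as.integer(as.Date(decisions$date[r]))
    ps <- pn <- numeric(m)
    for (q in seq_len(m)) {
      mat <- get0(cell_key(nb[q, 1], nb[q, 2]), envir = ledger$index)
      ps[q] <- pu_sum(mat, gcodes[r], ref)
      pn[q] <- pu_sum(mat, setdiff(all_codes, gcodes[r]), ref)
    }
    rows[[r]] <- data.frame(
      choice_id = r, group = decisions$group[r], date = decisions$date[r],
      cell_i = nb[, 1], cell_j = nb[, 2], corner = nb[, "corner"],
      food_raw = energy_at(field, nb[, 1:2, drop = FALSE]),
      prev_self_raw = ps, prev_nbr_raw = pn,
      chosen = as.integer(nb[, 1] == decisions$chosen_i[r] &
                          nb[, 2] == decisions$chosen_j[r]),
      offset = -log(m))
  }
  tab <- do.call(rbind, rows)
  # a set with a single candidate carries no information (and breaks the
  # 2..8-candidate contract); drop it
  sizes <- table(tab$choice_id)
  tab <- tab[tab$choice_id %in% names(sizes)[sizes >= 2], , drop = FALSE]
  if (!nrow(tab)) stop("no informative choice sets")
  stopifnot(all(rowsum(tab$chosen, tab$choice_id) == 1))
  tf <- list()
  for (p in c("food", "prev_self", "prev_nbr")) {
    tr <- log_z_transform(tab[[paste0(p, "_raw")]], transforms[[p]])
    tab[[p]] <- tr$values
    tf[[p]] <- tr$state
  }
  rownames(tab) <- NULL
  structure(tab, transforms = tf, class = c("choice_table", "data.frame"))
}

# internal: Newton-Raphson conditional-logit fit.
# X: model matrix, set: integer set ids 1..K, y: logical chosen.
clogit_newton <- function(X, set, y, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  K <- max(set)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -500), 500)
    e <- exp(eta)
    denom <- rowsum(e, set)[, 1]
    pr <- e / denom[set]
    ll <- sum(eta[y]) - sum(log(denom))
    grad <- drop(crossprod(X, y - pr))
    G <- rowsum(pr * X, set)
    info <- crossprod(X, pr * X) - crossprod(G)
    step <- tryCatch(solve(info + diag(1e-10, p), grad),
                     error = function(e) rep(NA_real_, p))
    if (anyNA(step)) break
    beta <- beta + step
    if (max(abs(grad)) < tol || max(abs(step)) < 1e-12) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- pmin(pmax(drop(X %*% beta), -500), 500)
  denom <- rowsum(exp(eta), set)[, 1]
  ll <- sum(eta[y]) - sum(log(denom))
  pr <- exp(eta) / denom[set]
  G <- rowsum(pr * X, set)
  info <- crossprod(X, pr * X) - crossprod(G)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  # separation: the likelihood flattens out, so either beta runs away or the
  # information matrix collapses and standard errors explode
  if (max(abs(beta)) > 15 || anyNA(diag(vcov)) ||
      any(diag(vcov) < 0) || max(sqrt(pmax(diag(vcov), 0))) > 100)
    converged <- FALSE
  list(coefficients = beta, logLik = ll, vcov = vcov, converged = converged,
       iterations = it)
}

#' Fit the conditional-logit movement-choice model
#'
#' Maximum-likelihood fit of the discrete-choice model in which the
#' probability that candidate cell \eqn{k} of a choice set is entered is
#' \eqn{\exp(x_k \beta) / \sum_j \exp(x_j \beta)}. The set-constant offset
#' \code{log(1/n_candidates)} cancels from this likelihood but defines the
#' null model: under \eqn{\beta = 0} the log-likelihood is
#' \eqn{\sum_{sets} \log(1/n_i)}, i.e. uniform choice among candidates.
#'
#' @param tab A \code{choice_table}.
#' @param predictors Character vector of predictor columns (default the three
#'   transformed test predictors).
#' @return Object of class \code{choice_fit}: \code{coefficients} (named,
#'   per-sd log-odds), \code{se}, \code{vcov}, \code{logLik},
#'   \code{null_logLik}, \code{converged}, \code{n_sets}.
#' @export
fit_choice_model <- function(tab,
                             predictors = c("food", "prev_self", "prev_nbr")) {
  set <- match(tab$choice_id, unique(tab$choice_id))
  X <- as.matrix(tab[, predictors, drop = FALSE])
  y <- tab$chosen == 1
  if (!all(rowsum(as.integer(y), set) == 1))
    stop("each choice set must have exactly one chosen row")
  fit <- clogit_newton(X, set, y)
  nn <- tabulate(set)
  names(fit$coefficients) <- predictors
  se <- sqrt(diag(fit$vcov)); names(se) <- predictors
  structure(list(coefficients = fit$coefficients, se = se, vcov = fit$vcov,
                 logLik = fit$logLik, null_logLik = -sum(log(nn)),
                 converged = fit$converged, n_sets = max(set),
                 predictors = predictors),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("<choice_fit> conditional logit, %d choice sets%s\n", x$n_sets,
              if (!x$converged) " (NOT converged)" else ""))
  print(round(cbind(Est = x$coefficients, s.e. = x$se), 4))
  cat(sprintf("logLik %.3f (null %.3f)\n", x$logLik, x$null_logLik))
  invisible(x)
}

# internal: estimate relative per-candidate choice rates for edge- vs
# corner-adjacent cells from the observed data
edge_corner_weights <- function(tab) {
  chosen <- tab$chosen == 1
  rate_edge <- sum(chosen & tab$corner == 0) / max(sum(tab$corner == 0), 1)
  rate_corner <- sum(chosen & tab$corner == 1) / max(sum(tab$corner == 1), 1)
  if (rate_edge <= 0) rate_edge <- 1e-8
  if (rate_corner <= 0) rate_corner <- 1e-8
  c(edge = rate_edge, corner = rate_corner) / rate_edge
}

#' Weighted permutation full-null test for the choice model
#'
#' Tests the three predictors as a whole. The observed statistic is the
#' full-null deviance \eqn{2(LL_{full} - LL_{null})} with the null the
#' uniform-choice model. Each permutation reassigns every set's chosen flag
#' to one candidate drawn with weights reflecting that edge-adjacent cells
#' are entered more readily than corner-adjacent ones (weights estimated
#' from the observed per-candidate choice rates unless supplied),
#' renormalized within the set; the model is refitted and the statistic
#' recomputed. The p-value uses the add-one estimator
#' \eqn{(1 + \#\{null \ge obs\}) / (1 + n_{perm})}.
#'
#' @param tab A \code{choice_table}.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; fixes the permutation stream.
#' @param weights Optional numeric \code{c(edge =, corner =)} relative
#'   weights overriding the empirical estimate.
#' @param predictors Passed to \code{\link{fit_choice_model}}.
#' @return Object of class \code{perm_test}: \code{observed_stat},
#'   \code{null_stats}, \code{p_value}, \code{n_perm}, \code{seed},
#'   \code{weights}, \code{fit} (the observed \code{choice_fit}).
#' @export
permutation_full_null <- function(tab, n_perm = 1000, seed = 1,
                                  weights = NULL,
                                  predictors = c("food", "prev_self",
                                                 "prev_nbr")) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  fit <- fit_choice_model(tab, predictors)
  obs <- 2 * (fit$logLik - fit$null_logLik)
  if (is.null(weights)) weights <- edge_corner_weights(tab)

  set <- match(tab$choice_id, unique(tab$choice_id))
  ord <- order(set)
  X <- as.matrix(tab[, predictors, drop = FALSE])[ord, , drop = FALSE]
  seto <- set[ord]
  K <- max(seto)
  w <- ifelse(tab$corner[ord] == 1, weights["corner"], weights["edge"])
  tot <- rowsum(w, seto)[, 1]
  wn <- w / tot[seto]
  cw <- stats::ave(wn, seto, FUN = cumsum)
  last <- !duplicated(seto, fromLast = TRUE)
  cw[last] <- 1                      # guard against rounding at the set end
  Cglob <- cw + (seto - 1)           # strictly increasing over all rows
  nn <- tabulate(seto)
  ll_null <- -sum(log(nn))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    u <- stats::runif(K)
    pos <- findInterval(u + (seq_len(K) - 1), Cglob, left.open = TRUE) + 1L
    yb <- logical(length(seto)); yb[pos] <- TRUE
    fb <- clogit_newton(X, seto, yb)
    null_stats[b] <- 2 * (fb$logLik - ll_null)
  }
  p <- (1 + sum(null_stats >= obs)) / (1 + n_perm)
  structure(list(observed_stat = obs, null_stats = null_stats, p_value = p,
                 n_perm = n_perm, seed = seed, weights = weights, fit = fit),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> chi^2 = %.3f, p = %.4g (%d weighted permutations)\n",
    x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' Write a choice table to CSV
#'
#' @param tab A \code{choice_table}.
#' @param file CSV path.
#' @export
write_choice_csv <- function(tab, file) {
  utils::write.csv(as.data.frame(tab), file, row.names = FALSE)
  invisible(file)
}
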