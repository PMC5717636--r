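# Small in-code fixtures shared across test files.

# a 10 x 10 grid of 500 m cells at the origin
toy_grid <- function() make_grid(0, 0, 500, 10, 10)

# energy field with a known gradient; optionally mask some cells
toy_field <- function(grid = toy_grid(), masked = NULL) {
  e <- outer(seq_len(grid$n_cols), seq_len(grid$n_rows),
             function(i, j) 100 * i + 10 * j)
  if (!is.null(masked)) e[masked] <- NA
  energy_field(grid, e)
}

# a fix table built from waypoints: one group-day straight-line walk
fixes_from_points <- function(pts, group = "A", date = "2012-10-01",
                              t0 = 6 * 3600) {
  data.frame(group = group, date = as.Date(date),
             time = t0 + 30 * (seq_len(nrow(pts)) - 1),
             x = pts[, 1], y = pts[, 2])
}

# minimal ledger: visits data frame and constant group sizes
toy_ledger <- function(visits, sizes = NULL) {
  if (is.null(sizes)) {
    g <- unique(visits$group)
    sizes <- expand.grid(group = g, year = 2012, month = 1:12,
                         stringsAsFactors = FALSE)
    sizes$size <- 10
  }
  usage_ledger(visits, sizes)
}

# brute-force conditional-logit log-likelihood for a choice table
clogit_ll_bruteforce <- function(tab, beta) {
  ll <- 0
  for (id in unique(tab$choice_id)) {
    s <- tab[tab$choice_id == id, ]
    eta <- as.matrix(s[, c("food", "prev_self", "prev_nbr")]) %*% beta
    ll <- ll + eta[s$chosen == 1] - log(sum(exp(eta)))
  }
  as.numeric(ll)
}

# independent exact Wilcoxon oracle: enumerate all 2^n sign assignments
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  tt <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    tt[m + 1] <- sum(r[signs])
  }
  p_le <- mean(tt <= t_obs + 1e-9)
  p_ge <- mean(tt >= t_obs - 1e-9)
  list(T_plus = t_obs, p = min(1, 2 * min(p_le, p_ge)), n_used = n)
}

# count 4-connected components of a logical raster mask
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (s0 in which(mask)) {
    if (lab[s0] != 0L) next
    comp <- comp + 1L
    stack <- s0
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- comp
      i <- (p - 1) %% nrow(mask) + 1; j <- (p - 1) %/% nrow(mask) + 1
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L)
          stack <- c(stack, (jj - 1) * nrow(mask) + ii)
      }
    }
  }
  comp
}
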