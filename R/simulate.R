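#' Configuration for the multi-group movement simulator
#'
#' Bundles every tunable of the synthetic landscape and movement generator.
#' Defaults emulate the study system the package was built around: ten
#' neighbouring groups of 4-13 weaned individuals tracked for many months
#' with roughly half of all days observed, daily travel averaging 808 m on a
#' 500 m grid whose cell energy densities span 0-13054 kcal per square
#' metre, and movement choices driven by food, site fidelity and neighbour
#' avoidance.
#'
#' @param seed Integer; fixes all randomness of landscape and movement.
#' @param n_cols,n_rows,cell_size,origin_x,origin_y Grid geometry (metres).
#' @param smoothness Gaussian smoothing scale of the energy field, in cells.
#' @param energy_max Maximum cell energy density (kcal per square metre).
#' @param n_groups Number of groups.
#' @param group_sizes Optional integer vector of per-group sizes; by default
#'   drawn uniformly from \code{4:13}.
#' @param n_days Study length in days.
#' @param observed_fraction Fraction of group-days with GPS data, in (0, 1].
#' @param beta_food,beta_self,beta_nbr True choice-model coefficients on the
#'   z-scale (log-odds per sd of transformed food, own previous use,
#'   neighbours' previous use).
#' @param util_loadings Named numeric \code{c(food=, self=, nbr=)}: loadings
#'   of the transformed predictors on log within-cell travel (the
#'   utilization process); default a negative neighbour loading.
#' @param util_intercept_log_m,util_sd Intercept and sd of log within-cell
#'   wander length (metres).
#' @param daily_travel_m Mean target daily path length (metres).
#' @param daily_travel_sdlog Lognormal sdlog of the daily target length.
#' @param fix_spacing_m Distance between successive simulated GPS fixes.
#' @param fix_jitter_sd GPS noise sd (metres) added to each fix coordinate.
#' @param start_date First study day.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_cols = 15, n_rows = 15, cell_size = 500,
                       origin_x = 0, origin_y = 0,
                       smoothness = 2, energy_max = 13054,
                       n_groups = 10, group_sizes = NULL,
                       n_days = 300, observed_fraction = 0.5,
                       beta_food = 0.5, beta_self = 0.5, beta_nbr = 0,
                       util_loadings = c(food = 0, self = 0.15, nbr = -0.25),
                       util_intercept_log_m = log(150), util_sd = 0.4,
                       daily_travel_m = 808, daily_travel_sdlog = 0.3,
                       fix_spacing_m = 25, fix_jitter_sd = 5,
                       start_date = "2012-05-01") {
  stopifnot(observed_fraction > 0, observed_fraction <= 1,
            n_groups >= 1, n_days >= 2)
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a smooth synthetic energy landscape
#'
#' White noise on the grid is convolved with a Gaussian of the configured
#' smoothness and linearly rescaled to \code{[0, energy_max]}, giving a
#' positively autocorrelated field like a patchy herbaceous vegetation map.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An \code{\link{energy_field}} with no masked cells.
#' @export
generate_landscape <- function(config) {
  g <- make_grid(config$origin_x, config$origin_y, config$cell_size,
                 config$n_cols, config$n_rows)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  z <- matrix(stats::rnorm(config$n_cols * config$n_rows),
              config$n_cols, config$n_rows)
  kmat <- function(n, s) {
    k <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * s^2))
    k / rowSums(k)
  }
  sm <- kmat(config$n_cols, config$smoothness) %*% z %*%
        t(kmat(config$n_rows, config$smoothness))
  sm <- (sm - min(sm)) / (max(sm) - min(sm)) * config$energy_max
  energy_field(g, sm)
}

# internal: interpolate a waypoint polyline at fixed spacing
interpolate_path <- function(wp, spacing) {
  if (nrow(wp) < 2) return(wp)
  seg <- sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2)
  cl <- c(0, cumsum(seg))
  total <- cl[length(cl)]
  at <- unique(c(seq(0, total, by = spacing), total))
  i <- findInterval(at, cl, rightmost.closed = TRUE)
  i[i >= nrow(wp)] <- nrow(wp) - 1
  f <- (at - cl[i]) / pmax(cl[i + 1] - cl[i], 1e-12)
  cbind(wp[i, 1] + f * (wp[i + 1, 1] - wp[i, 1]),
        wp[i, 2] + f * (wp[i + 1, 2] - wp[i, 2]))
}

# internal: random wander inside a cell, inset from the boundary; returns
# waypoints (excluding the start point) with total length exactly target_len
wander_in_cell <- function(pos, cell, grid, target_len) {
  s <- grid$cell_size
  lo <- grid$origin + c(cell[1], cell[2]) * s + 60
  hi <- grid$origin + c(cell[1] + 1, cell[2] + 1) * s - 60
  pts <- list()
  len <- 0
  p <- pos
  while (len < target_len) {
    q <- pmin(pmax(p + stats::rnorm(2, 0, 50), lo), hi)
    step <- sqrt(sum((q - p)^2))
    if (step < 1) next
    if (len + step > target_len) {      # truncate the final leg exactly
      q <- p + (q - p) * (target_len - len) / step
      step <- target_len - len
    }
    len <- len + step
    pts[[length(pts) + 1]] <- q
    p <- q
  }
  do.call(rbind, pts)
}

#' Simulate multi-group daily movement on an energy landscape
#'
#' Each group walks from day to day on the grid. A day draws a lognormal
#' target path length (mean \code{daily_travel_m}); the group wanders within
#' its current cell (within-cell wander length lognormal with the
#' configured loadings on the transformed predictors - the utilization
#' process) and, while the target is not exhausted, steps into one of the
#' up-to-eight neighbouring cells drawn with probability proportional to
#' \code{exp(beta_food z(food) + beta_self z(prev self) + beta_nbr z(prev
#' nbr))}, where previous use is computed from the running usage ledger
#' exactly as the analysis defines it. GPS fixes are interpolated along the
#' daily waypoint path at fixed spacing with Gaussian jitter, and group-days
#' are thinned to the observed fraction.
#'
#' Simulation operates directly on the z-scale: the fixed transform states
#' used for the previous-use predictors (and the food state fitted to the
#' landscape) are exported with the truth record, so an analysis can be run
#' in exactly the generating parameterization.
#'
#' @param config A \code{\link{sim_config}}.
#' @param field Optional \code{energy_field}; by default
#'   \code{\link{generate_landscape}(config)}.
#' @return Object of class \code{sim_output}: \code{fixes} (observed
#'   group-days only), \code{decisions} (true transitions, all days, with
#'   \code{observed} flag), \code{visits} (true per-day per-cell distances),
#'   \code{group_sizes}, \code{transforms}, \code{truth} (true
#'   coefficients), \code{field}, \code{grid}, \code{config}.
#' @export
simulate_movement <- function(config, field = generate_landscape(config)) {
  grid <- field$grid
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)

  prev_state <- structure(list(shift = 1, mean = 2, sd = 2),
                          class = "log_z_state")
  food_state <- log_z_transform(as.vector(field$energy))$state
  zfood <- matrix(log_z_transform(as.vector(field$energy),
                                  food_state)$values,
                  grid$n_cols, grid$n_rows)
  zprev <- function(x) (log(x + prev_state$shift) - prev_state$mean) /
    prev_state$sd

  ng <- config$n_groups
  sizes <- config$group_sizes
  if (is.null(sizes)) sizes <- sample(4:13, ng, replace = TRUE)
  stopifnot(length(sizes) == ng)
  groups <- sprintf("G%02d", seq_len(ng))

  # start cells spread over the central part of the grid
  cand_start <- expand.grid(
    i = round(seq(2, grid$n_cols - 3, length.out = ceiling(sqrt(ng)))),
    j = round(seq(2, grid$n_rows - 3, length.out = ceiling(sqrt(ng)))))
  start_cells <- cand_start[sample.int(nrow(cand_start), ng), , drop = FALSE]

  ledger <- new.env(parent = emptyenv())
  cur_cell <- as.matrix(start_cells)
  pos <- cell_centre(cur_cell, grid)

  fixes <- list(); decisions <- list(); visits <- list()
  util <- config$util_loadings

  for (day in seq_len(config$n_days)) {
    date <- config$start_date + day - 1
    for (g in seq_len(ng)) {
      target <- stats::rlnorm(1, log(config$daily_travel_m) -
                                 config$daily_travel_sdlog^2 / 2,
                              config$daily_travel_sdlog)
      wp <- matrix(pos[g, ], 1)
      len <- 0
      repeat {
        cell <- cur_cell[g, ]
        # within-cell wander, length set by the utilization process but
        # capped at the remaining daily budget
        mat <- get0(cell_key(cell[1], cell[2]), envir = ledger)
        zs <- zprev(pu_sum(mat, g, day))
        zn <- zprev(pu_sum(mat, setdiff(seq_len(ng), g), day))
        zf <- zfood[cell[1] + 1, cell[2] + 1]
        wlen <- exp(config$util_intercept_log_m + util["food"] * zf +
                    util["self"] * zs + util["nbr"] * zn +
                    stats::rnorm(1, 0, config$util_sd))
        wlen <- min(wlen, max(target - len, 0))
        if (wlen > 1) {
          ww <- wander_in_cell(wp[nrow(wp), ], cell, grid, wlen)
          if (!is.null(ww)) wp <- rbind(wp, ww)
          len <- len + wlen
        }
        # stop the day when the remaining budget cannot fund a typical
        # crossing (~350 m from a wander position to 100 m past the shared
        # edge); the rule must not look at any candidate, otherwise it
        # would select on the chosen cell and bias the choice process
        if (target - len < 350) break
        nb <- neighbour_cells(cell[1], cell[2], grid)
        keep <- !is.na(energy_at(field, nb[, 1:2, drop = FALSE]))
        nb <- nb[keep, , drop = FALSE]
        if (!nrow(nb)) break
        eta <- numeric(nrow(nb))
        for (q in seq_len(nrow(nb))) {
          mq <- get0(cell_key(nb[q, 1], nb[q, 2]), envir = ledger)
          eta[q] <- config$beta_food * zfood[nb[q, 1] + 1, nb[q, 2] + 1] +
            config$beta_self * zprev(pu_sum(mq, g, day)) +
            config$beta_nbr * zprev(pu_sum(mq, setdiff(seq_len(ng), g), day))
        }
        pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
        pick <- sample.int(nrow(nb), 1, prob = pr)
        # cross into the chosen cell through the shared edge midpoint, or
        # exactly through the shared corner for a diagonal move, so the path
        # never clips a third cell; the entry point sits 100 m inside
        dcell <- nb[pick, 1:2] - cell
        s <- grid$cell_size
        if (sum(abs(dcell)) == 2) {
          corner <- grid$origin + (cell + (dcell + 1) / 2) * s
          new_pts <- rbind(corner - 60 * dcell, corner + 100 * dcell)
        } else {
          ocen <- cell_centre(matrix(cell, 1), grid)
          mid <- ocen + dcell * s / 2          # shared edge midpoint
          new_pts <- rbind(mid, mid + dcell * 100)
        }
        step_len <- sum(sqrt(rowSums(
          (rbind(wp[nrow(wp), ], new_pts)[-(nrow(new_pts) + 1), , drop = FALSE] -
             new_pts)^2)))
        decisions[[length(decisions) + 1]] <- data.frame(
          group = groups[g], date = date,
          origin_i = cell[1], origin_j = cell[2],
          chosen_i = nb[pick, 1], chosen_j = nb[pick, 2],
          n_candidates = nrow(nb))
        len <- len + step_len
        wp <- rbind(wp, new_pts)
        cur_cell[g, ] <- nb[pick, 1:2]
      }
      if (target - len > 20) {
        # walk out the unspent budget in place so daily totals match the
        # drawn target
        wf <- wander_in_cell(wp[nrow(wp), ], cur_cell[g, ], grid,
                             target - len)
        if (!is.null(wf)) wp <- rbind(wp, wf)
      }
      pos[g, ] <- wp[nrow(wp), ]
      # true per-cell distances from the waypoint polyline itself
      day_visits <- polyline_cell_distances(wp, grid)
      if (nrow(day_visits)) {
        day_visits$group <- groups[g]; day_visits$date <- date
        visits[[length(visits) + 1]] <- day_visits
        for (r in seq_len(nrow(day_visits))) {
          k <- cell_key(day_visits$cell_i[r], day_visits$cell_j[r])
          assign(k, rbind(get0(k, envir = ledger),
                          c(day = day, dist = day_visits$distance_m[r],
                            size = sizes[g], gcode = g)), envir = ledger)
        }
      }
      if (stats::runif(1) <= config$observed_fraction) {
        fx <- interpolate_path(wp, config$fix_spacing_m)
        fx <- fx + matrix(stats::rnorm(length(fx), 0, config$fix_jitter_sd),
                          nrow(fx))
        fixes[[length(fixes) + 1]] <- data.frame(
          group = groups[g], date = date,
          time = 6 * 3600 + 30 * (seq_len(nrow(fx)) - 1),
          x = fx[, 1], y = fx[, 2])
      }
    }
  }

  dec <- do.call(rbind, decisions)
  fix_df <- do.call(rbind, fixes)
  obs_days <- unique(paste(fix_df$group, fix_df$date))
  dec$observed <- paste(dec$group, dec$date) %in% obs_days

  months <- unique(format(seq(config$start_date,
                              config$start_date + config$n_days - 1,
                              by = "day"), "%Y-%m"))
  gs <- expand.grid(group = groups, ym = months, stringsAsFactors = FALSE)
  gs$year <- as.integer(substr(gs$ym, 1, 4))
  gs$month <- as.integer(substr(gs$ym, 6, 7))
  gs$size <- sizes[match(gs$group, groups)]
  gs$ym <- NULL

  structure(list(fixes = fix_df, decisions = dec,
                 visits = do.call(rbind, visits),
                 group_sizes = gs,
                 transforms = list(food = food_state,
                                   prev_self = prev_state,
                                   prev_nbr = prev_state),
                 truth = c(food = config$beta_food,
                           self = config$beta_self,
                           nbr = config$beta_nbr),
                 field = field, grid = grid, config = config),
            class = "sim_output")
}

# internal: per-cell distances of one polyline (no group/date bookkeeping)
polyline_cell_distances <- function(wp, grid) {
  if (nrow(wp) < 2) {
    cc <- cell_of(wp, grid)
    return(data.frame(cell_i = cc[1], cell_j = cc[2], distance_m = 0))
  }
  cells <- cell_of(wp, grid)
  acc_key <- character(0); acc_len <- numeric(0)
  for (t in seq_len(nrow(wp) - 1)) {
    if (all(cells[t, ] == cells[t + 1, ])) {
      acc_key <- c(acc_key, cell_key(cells[t, 1], cells[t, 2]))
      acc_len <- c(acc_len, sqrt(sum((wp[t + 1, ] - wp[t, ])^2)))
    } else {
      pc <- split_segment(wp[t, ], wp[t + 1, ], grid)
      acc_key <- c(acc_key, cell_key(pc[, "i"], pc[, "j"]))
      acc_len <- c(acc_len, pc[, "length"])
    }
  }
  tot <- rowsum(acc_len, acc_key)
  ij <- do.call(rbind, strsplit(rownames(tot), "_", fixed = TRUE))
  data.frame(cell_i = as.integer(ij[, 1]), cell_j = as.integer(ij[, 2]),
             distance_m = tot[, 1], row.names = NULL)
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %d groups, %d days; %d true decisions (%d observed), %d fixes\n",
    x$config$n_groups, x$config$n_days, nrow(x$decisions),
    sum(x$decisions$observed), nrow(x$fixes)))
  invisible(x)
}

#' Write the simulator outputs as analysis-ready CSVs
#'
#' Emits the same fix / group-size tables the real pipeline reads, plus the
#' truth record as JSON.
#'
#' @param sim A \code{sim_output}.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_sim_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fixes = file.path(dir, "fixes.csv"),
             sizes = file.path(dir, "group_sizes.csv"),
             energy = file.path(dir, "energy.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$fixes, paths["fixes"], row.names = FALSE)
  utils::write.csv(sim$group_sizes, paths["sizes"], row.names = FALSE)
  write_energy_csv(sim$field, paths["energy"])
  jsonlite::write_json(
    list(beta = as.list(sim$truth),
         transforms = lapply(sim$transforms, unclass),
         grid = list(origin_x = sim$grid$origin[[1]],
                     origin_y = sim$grid$origin[[2]],
                     cell_size = sim$grid$cell_size,
                     n_cols = sim$grid$n_cols, n_rows = sim$grid$n_rows),
         config = lapply(unclass(sim$config), function(v)
           if (inherits(v, "Date")) format(v) else v)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Directly simulate choice sets on the z-scale
#'
#' A lightweight generator for calibration studies of the choice model and
#' its permutation test: each set has eight candidates with the usual
#' four-edge/four-corner geometry, standard-normal predictors, and a chosen
#' cell drawn from the conditional-logit probabilities at the supplied
#' coefficients (uniform when all are zero). Bypasses landscapes and
#' ledgers entirely.
#'
#' @param n_sets Number of choice sets.
#' @param beta Named or length-3 numeric: coefficients for \code{food},
#'   \code{prev_self}, \code{prev_nbr}.
#' @param seed Integer seed.
#' @param n_candidates Candidates per set (default 8; 4 edge then corners).
#' @return A \code{choice_table}-compatible data frame.
#' @export
simulate_choice_sets <- function(n_sets, beta = c(0, 0, 0), seed = 1,
                                 n_candidates = 8) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- n_candidates
  n <- n_sets * m
  corner <- rep(c(rep(0, min(4, m)), rep(1, max(m - 4, 0))), n_sets)
  X <- matrix(stats::rnorm(3 * n), n, 3,
              dimnames = list(NULL, c("food", "prev_self", "prev_nbr")))
  set <- rep(seq_len(n_sets), each = m)
  eta <- drop(X %*% as.numeric(beta))
  e <- exp(eta - stats::ave(eta, set, FUN = max))
  pr <- e / rowsum(e, set)[set, 1]
  cw <- stats::ave(pr, set, FUN = cumsum)
  cw[!duplicated(set, fromLast = TRUE)] <- 1
  u <- stats::runif(n_sets)
  pos <- findInterval(u + (seq_len(n_sets) - 1), cw + (set - 1),
                      left.open = TRUE) + 1L
  chosen <- integer(n); chosen[pos] <- 1L
  tab <- data.frame(choice_id = set, group = "G01",
                    date = as.Date("2012-10-01") + (set - 1) %% 200,
                    cell_i = 0L, cell_j = 0L, corner = corner,
                    food_raw = NA_real_, prev_self_raw = NA_real_,
                    prev_nbr_raw = NA_real_,
                    food = X[, 1], prev_self = X[, 2], prev_nbr = X[, 3],
                    chosen = chosen, offset = -log(m))
  structure(tab, class = c("choice_table", "data.frame"))
}

#' Directly simulate utilization-model rows
#'
#' Generates the Gaussian mixed-model data the utilization analysis assumes:
#' group/cell/group-by-cell random intercepts, standard-normal predictors
#' with genuine between-group variation (predictor = group mean + deviation),
#' and a linear response on the within/between parts. Used for calibration
#' (type-I error) and sign-recovery studies of the utilization model.
#'
#' @param n_groups,n_per_group Design size.
#' @param beta Named numeric of effects on the six terms
#'   \code{food_within}, \code{food_between}, \code{self_within},
#'   \code{self_between}, \code{nbr_within}, \code{nbr_between} (missing
#'   names default to 0).
#' @param sd_group,sd_cell,sd_gcell,sd_resid Random-effect and residual sds.
#' @param n_cells_per_group Cells available to each group.
#' @param seed Integer seed.
#' @return A \code{utilization_table}-compatible data frame (with
#'   \code{autocor} set to 0).
#' @export
simulate_utilization_rows <- function(n_groups = 10, n_per_group = 40,
                                      beta = c(), sd_group = 0.3,
                                      sd_cell = 0.3, sd_gcell = 0.2,
                                      sd_resid = 0.6,
                                      n_cells_per_group = 12, seed = 1) {
  terms <- c("food_within", "food_between", "self_within", "self_between",
             "nbr_within", "nbr_between")
  b <- stats::setNames(numeric(6), terms)
  b[names(beta)] <- beta
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- n_groups * n_per_group
  group <- rep(sprintf("G%02d", seq_len(n_groups)), each = n_per_group)
  # each group works a small cluster of cells around its own centre
  gi <- rep(sample.int(20, n_groups, replace = TRUE), each = n_per_group)
  gj <- rep(sample.int(20, n_groups, replace = TRUE), each = n_per_group)
  pick <- sample.int(n_cells_per_group, n, replace = TRUE)
  cell_i <- gi + pick %% 4L
  cell_j <- gj + pick %/% 4L
  date <- as.Date("2012-10-01") + sample.int(150, n, replace = TRUE)
  raw <- lapply(1:3, function(k)
    rep(stats::rnorm(n_groups), each = n_per_group) + stats::rnorm(n))
  u <- rep(stats::rnorm(n_groups, 0, sd_group), each = n_per_group)
  ckey <- cell_key(cell_i, cell_j)
  v <- stats::rnorm(length(unique(ckey)), 0, sd_cell)[match(ckey, unique(ckey))]
  gck <- paste(group, ckey)
  w <- stats::rnorm(length(unique(gck)), 0, sd_gcell)[match(gck, unique(gck))]
  out <- data.frame(group = group, date = date,
                    cell_i = cell_i, cell_j = cell_j, response = 0)
  lin <- 0
  for (k in 1:3) {
    short <- c("food", "self", "nbr")[k]
    wb <- within_between(raw[[k]], group)
    out[[paste0(short, "_within")]] <- wb$within
    out[[paste0(short, "_between")]] <- wb$between
    lin <- lin + b[paste0(short, "_within")] * wb$within +
      b[paste0(short, "_between")] * wb$between
  }
  out$response <- 5 + lin + u + v + w + stats::rnorm(n, 0, sd_resid)
  out$autocor <- 0
  structure(out, class = c("utilization_table", "data.frame"))
}
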