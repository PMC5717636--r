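#' Published Bwindi annual overlap table
#'
#' The published per-group annual kernel home-range statistics of the ten
#' Bwindi mountain-gorilla study groups (2012-2013): 90\% home-range and
#' 50\% core-area sizes (km^2), the exclusively used part of the core, per
#' cent overlap of home range and core area with all habituated neighbours,
#' and the number of daily locations used. These published percentages are
#' the inputs of the exact signed-rank comparison of home-range versus
#' core-area overlap.
#'
#' @return Data frame with one row per group.
#' @export
bwindi_overlap_table <- function() {
  utils::read.csv(system.file("extdata", "bwindi_overlap_table1.csv",
                              package = "spacepart"))
}

# internal: read a config from a list or YAML file
load_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  config
}

#' Run the full space-partitioning analysis
#'
#' One-command orchestration from input tables to a report bundle:
#' \enumerate{
#'   \item energy field from a per-cell energy CSV (or transects +
#'     calibrations);
#'   \item per-day per-cell travel distances and cell-entry decisions from
#'     the fix table; usage ledger; burn-in filter;
#'   \item conditional-logit choice model with the weighted permutation
#'     full-null test;
#'   \item utilization mixed model (within/between decomposition,
#'     autocorrelation term) with the full-null likelihood-ratio test;
#'   \item kernel home ranges (one location per day) on a common raster,
#'     50\%/90\% contours, overlap report, exclusive cores, area-weighted
#'     energy densities;
#'   \item exact signed-rank comparisons (home-range vs core overlap;
#'     core vs rest-of-range energy density).
#' }
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \code{fixes_csv}, \code{sizes_csv}, \code{energy_csv} (or
#'   \code{transects_csv} + \code{calibrations_csv}), \code{grid} (list:
#'   \code{origin_x}, \code{origin_y}, \code{cell_size}, \code{n_cols},
#'   \code{n_rows}), \code{burn_in_date}, and optionally \code{h} (200),
#'   \code{resolution} (50), \code{levels} (c(0.5, 0.9)), \code{n_perm}
#'   (1000), \code{seed} (1), \code{autocor_sigma} (c(7, 1000) or
#'   \code{"select"}), \code{out_dir} (write nothing when \code{NULL}).
#' @return A list with components \code{choice} (fit + permutation),
#'   \code{utilization} (full/null fits + LRT), \code{overlap} (per-level
#'   reports and the assembled summary table), \code{wilcoxon} (exact
#'   tests), \code{energy} (core vs rest densities), \code{counts} (row
#'   counts at each filtering step), invisibly written to \code{out_dir}.
#' @export
run_analysis <- function(config) {
  cfg <- load_config(config)
  for (k in c("fixes_csv", "sizes_csv", "grid", "burn_in_date"))
    if (is.null(cfg[[k]])) stop("config is missing '", k, "'")
  h <- cfg$h %||% 200
  resolution <- cfg$resolution %||% 50
  levels <- cfg$levels %||% c(0.5, 0.9)
  n_perm <- cfg$n_perm %||% 1000
  seed <- cfg$seed %||% 1
  counts <- list()

  g <- cfg$grid
  grid <- make_grid(g$origin_x %||% 0, g$origin_y %||% 0,
                    g$cell_size %||% 500, g$n_cols, g$n_rows)
  field <- if (!is.null(cfg$energy_csv)) {
    read_energy_csv(cfg$energy_csv, grid)
  } else if (!is.null(cfg$transects_csv)) {
    estimate_cell_energy_density(utils::read.csv(cfg$transects_csv),
                                 utils::read.csv(cfg$calibrations_csv), grid)
  } else stop("config needs energy_csv or transects_csv + calibrations_csv")

  fixes <- read_fixes_csv(cfg$fixes_csv)
  sizes <- utils::read.csv(cfg$sizes_csv)
  counts$fixes <- nrow(fixes)

  min_visit <- cfg$min_visit_m %||% 50
  visits <- distance_per_cell(fixes, grid)
  visits <- visits[visits$distance_m >= min_visit, , drop = FALSE]
  ledger <- usage_ledger(visits, sizes)
  decisions <- extract_entry_decisions(fixes, grid, field)
  counts$visits <- nrow(visits); counts$decisions <- nrow(decisions)

  dec_a <- apply_burn_in(decisions, cfg$burn_in_date)
  vis_a <- apply_burn_in(visits, cfg$burn_in_date)
  counts$decisions_post_burn_in <- nrow(dec_a)
  counts$visits_post_burn_in <- nrow(vis_a)

  tab <- build_choice_table(dec_a, field, ledger)
  counts$choice_rows <- nrow(tab)
  perm <- permutation_full_null(tab, n_perm = n_perm, seed = seed)

  util_tab <- build_utilization_table(vis_a, field, ledger)
  counts$utilization_rows <- nrow(util_tab)
  sig <- cfg$autocor_sigma %||% c(7, 1000)
  if (identical(sig, "select")) {
    sel <- select_autocor_sigma(util_tab, grid)
    sig <- c(sel$sigma_t, sel$sigma_s)
  }
  util_full <- fit_utilization_model(util_tab, null = FALSE,
                                     autocor_sigma = sig, grid = grid)
  util_null <- fit_utilization_model(util_full$rows, null = TRUE)
  lrt <- likelihood_ratio_full_null(util_full, util_null)

  daily <- first_fix_per_day(fixes)
  counts$daily_locations <- nrow(daily)
  ext <- c(min(daily$x) - 4 * h, max(daily$x) + 4 * h,
           min(daily$y) - 4 * h, max(daily$y) + 4 * h)
  by_group <- split(daily, daily$group)
  uds <- lapply(by_group, function(d)
    kde_ud(cbind(d$x, d$y), h = h, resolution = resolution, extent = ext))
  contours <- lapply(sort(levels), function(lv)
    lapply(uds, volume_contour, level = lv))
  names(contours) <- sprintf("level_%g", sort(levels))
  reports <- lapply(contours, overlap_report)

  core <- contours[[1]]; hr <- contours[[length(contours)]]
  summary_tab <- data.frame(
    group = reports[[1]]$group,
    hr_km2 = reports[[length(reports)]]$area_km2,
    core_km2 = reports[[1]]$area_km2,
    exclusive_core_km2 = reports[[1]]$exclusive_km2,
    pct_overlap_hr = reports[[length(reports)]]$pct_overlap,
    pct_overlap_core = reports[[1]]$pct_overlap,
    n_points = vapply(uds, `[[`, 0, "n_points")[reports[[1]]$group])

  wil_overlap <- wilcoxon_signed_rank_exact(summary_tab$pct_overlap_hr,
                                            summary_tab$pct_overlap_core)
  core_energy <- vapply(summary_tab$group, function(gr)
    weighted_energy_density(core[[gr]], field), numeric(1))
  rest_energy <- vapply(summary_tab$group, function(gr)
    weighted_energy_density(region_difference(hr[[gr]], core[[gr]]), field),
    numeric(1))
  wil_energy <- wilcoxon_signed_rank_exact(core_energy, rest_energy)

  out <- list(
    choice = list(fit = perm$fit, permutation = perm,
                  transforms = attr(tab, "transforms")),
    utilization = list(full = util_full, null = util_null, lrt = lrt,
                       autocor_sigma = sig),
    overlap = list(reports = reports, summary = summary_tab,
                   contours = contours),
    wilcoxon = list(
      overlap = wil_overlap,
      energy = wil_energy,
      overlap_median_hr = median_range(summary_tab$pct_overlap_hr),
      overlap_median_core = median_range(summary_tab$pct_overlap_core)),
    energy = data.frame(group = summary_tab$group, core = core_energy,
                        rest = rest_energy),
    counts = counts, config = cfg)

  if (!is.null(cfg$out_dir)) write_report_bundle(out, cfg$out_dir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: serialize the run_analysis result into the bundle directory
write_report_bundle <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$overlap$summary,
                   file.path(dir, "overlap_table.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    choice_model = list(
      coefficients = as.list(out$choice$fit$coefficients),
      se = as.list(out$choice$fit$se),
      logLik = out$choice$fit$logLik,
      null_logLik = out$choice$fit$null_logLik,
      converged = out$choice$fit$converged,
      n_sets = out$choice$fit$n_sets),
    permutation = list(chisq = out$choice$permutation$observed_stat,
                       p = out$choice$permutation$p_value,
                       n_perm = out$choice$permutation$n_perm,
                       weights = as.list(out$choice$permutation$weights)),
    utilization = list(
      coefficients = apply(out$utilization$full$coefficients, 1, as.list),
      lrt = out$utilization$lrt,
      autocor_sigma = out$utilization$autocor_sigma),
    wilcoxon = list(
      overlap = unclass(out$wilcoxon$overlap),
      energy = unclass(out$wilcoxon$energy),
      median_hr = as.list(out$wilcoxon$overlap_median_hr),
      median_core = as.list(out$wilcoxon$overlap_median_core)),
    counts = out$counts),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (lv in names(out$overlap$contours))
    for (gr in names(out$overlap$contours[[lv]]))
      contour_to_geojson(out$overlap$contours[[lv]][[gr]],
                         file.path(dir, sprintf("%s_%s.geojson", gr, lv)),
                         name = gr)
  invisible(dir)
}

#' Simulate-and-refit calibration study
#'
#' Repeatedly simulates movement with known coefficients, reruns the
#' analysis, and tabulates recovery: true and estimated choice coefficients,
#' their standard errors, the permutation p-value and the utilization LRT
#' p-value per replicate, with bias / RMSE / 2-se coverage summaries.
#'
#' @param config List (or YAML path): \code{n_replicates}, \code{seed},
#'   \code{n_perm} (default 200), plus any \code{\link{sim_config}}
#'   overrides under \code{sim}.
#' @return List with \code{replicates} (data frame) and \code{summary}.
#' @export
run_simulation_study <- function(config) {
  cfg <- load_config(config)
  n_rep <- cfg$n_replicates %||% 10
  n_perm <- cfg$n_perm %||% 200
  base_seed <- cfg$seed %||% 1
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sc <- do.call(sim_config, utils::modifyList(
      list(seed = base_seed + r), as.list(cfg$sim %||% list())))
    sim <- simulate_movement(sc)
    res <- refit_simulation(sim, n_perm = n_perm, seed = base_seed + r,
                            burn_in_days = cfg$burn_in_days %||% 60)
    rows[[r]] <- cbind(data.frame(replicate = r), res)
  }
  reps <- do.call(rbind, rows)
  est <- as.matrix(reps[, c("est_food", "est_self", "est_nbr")])
  tru <- as.matrix(reps[, c("true_food", "true_self", "true_nbr")])
  se <- as.matrix(reps[, c("se_food", "se_self", "se_nbr")])
  summary <- data.frame(
    term = c("food", "self", "nbr"),
    bias = colMeans(est - tru),
    rmse = sqrt(colMeans((est - tru)^2)),
    coverage_2se = colMeans(abs(est - tru) <= 2 * se))
  list(replicates = reps, summary = summary)
}

#' Rerun the estimation pipeline on one simulation
#'
#' Feeds the simulated fixes through track processing, ledger construction,
#' choice-table building (with the simulation's exported transform states)
#' and model fitting; runs the weighted permutation test.
#'
#' @param sim A \code{\link{simulate_movement}} output.
#' @param n_perm Permutations for the full-null test (0 to skip).
#' @param seed Seed for the permutation stream.
#' @param burn_in_days Days of history excluded from analysis rows
#'   (default 60).
#' @param dedup Deduplication rule passed to
#'   \code{\link{extract_entry_decisions}}; default \code{"none"} because
#'   every simulated transition is an independent draw from the generating
#'   choice model.
#' @return One-row data frame: true/estimated coefficients, ses,
#'   permutation p, decision recovery rate.
#' @export
refit_simulation <- function(sim, n_perm = 200, seed = 1,
                             burn_in_days = 60, dedup = "none") {
  grid <- sim$grid
  visits <- distance_per_cell(sim$fixes, grid)
  visits <- visits[visits$distance_m >= 50, , drop = FALSE]
  ledger <- usage_ledger(visits, sim$group_sizes)
  decisions <- extract_entry_decisions(sim$fixes, grid, sim$field,
                                       dedup = dedup)
  burn <- sim$config$start_date + burn_in_days
  dec_a <- apply_burn_in(decisions, burn)
  tab <- build_choice_table(dec_a, sim$field, ledger,
                            transforms = sim$transforms)
  fit <- fit_choice_model(tab)
  p <- NA_real_; stat <- NA_real_
  if (n_perm > 0) {
    pm <- permutation_full_null(tab, n_perm = n_perm, seed = seed)
    p <- pm$p_value; stat <- pm$observed_stat
  }
  truth_dec <- sim$decisions[sim$decisions$observed, ]
  tk <- unique(paste(truth_dec$group, truth_dec$date, truth_dec$origin_i,
                     truth_dec$origin_j, truth_dec$chosen_i,
                     truth_dec$chosen_j))
  dk <- paste(decisions$group, decisions$date, decisions$origin_i,
              decisions$origin_j, decisions$chosen_i, decisions$chosen_j)
  data.frame(true_food = sim$truth[["food"]], true_self = sim$truth[["self"]],
             true_nbr = sim$truth[["nbr"]],
             est_food = fit$coefficients[["food"]],
             est_self = fit$coefficients[["prev_self"]],
             est_nbr = fit$coefficients[["prev_nbr"]],
             se_food = fit$se[["food"]], se_self = fit$se[["prev_self"]],
             se_nbr = fit$se[["prev_nbr"]],
             perm_chisq = stat, perm_p = p,
             n_sets = fit$n_sets, converged = fit$converged,
             decision_recovery = mean(tk %in% dk))
}
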