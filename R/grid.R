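#' Define a square analysis grid
#'
#' The analysis lattice onto which tracks, transects and energy densities are
#' projected. Cell \code{(i, j)} (0-based) covers the half-open square
#' \code{[origin_x + i*s, origin_x + (i+1)*s) x [origin_y + j*s, origin_y + (j+1)*s)}
#' so that every planar point maps to exactly one cell.
#'
#' @param origin_x,origin_y Coordinates of the lower-left grid corner, in
#'   metres of a projected planar CRS. No reprojection is performed.
#' @param cell_size Cell edge length in metres (default 500).
#' @param n_cols,n_rows Number of columns (x direction) and rows (y direction).
#' @return An object of class \code{space_grid}.
#' @examples
#' g <- make_grid(0, 0, 500, 10, 10)
#' cell_of(cbind(1250, 760), g)  # cell (2, 1)
#' @export
make_grid <- function(origin_x = 0, origin_y = 0, cell_size = 500,
                      n_cols, n_rows) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            n_cols >= 1, n_rows >= 1)
  structure(list(origin = c(x = origin_x, y = origin_y),
                 cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "space_grid")
}

#' @export
print.space_grid <- function(x, ...) {
  cat(sprintf("<space_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Map planar points to grid cells
#'
#' @param points Two-column matrix or data frame of x, y coordinates (metres).
#' @param grid A \code{space_grid}.
#' @param strict If \code{TRUE} (default) points outside the grid extent raise
#'   an error; otherwise their rows are \code{NA}.
#' @return Integer matrix with columns \code{i}, \code{j} (0-based indices),
#'   assigned by half-open floor division.
#' @export
cell_of <- function(points, grid, strict = TRUE) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  i <- floor((points[, 1] - grid$origin[1]) / grid$cell_size)
  j <- floor((points[, 2] - grid$origin[2]) / grid$cell_size)
  bad <- i < 0 | i >= grid$n_cols | j < 0 | j >= grid$n_rows
  if (any(bad, na.rm = TRUE)) {
    if (strict)
      stop("point(s) outside grid extent: row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    i[bad] <- NA_integer_; j[bad] <- NA_integer_
  }
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Cell centres in planar coordinates
#'
#' @param cells Two-column matrix of 0-based \code{i}, \code{j} indices.
#' @param grid A \code{space_grid}.
#' @return Matrix with columns \code{x}, \code{y} (metres).
#' @export
cell_centre <- function(cells, grid) {
  cells <- as.matrix(cells)[, 1:2, drop = FALSE]
  cbind(x = grid$origin[1] + (cells[, 1] + 0.5) * grid$cell_size,
        y = grid$origin[2] + (cells[, 2] + 0.5) * grid$cell_size)
}

# internal: "i_j" string keys used by ledgers and lookup tables
cell_key <- function(i, j) paste(i, j, sep = "_")

#' Fit a species dry-weight calibration
#'
#' Ordinary least-squares regression of specimen dry weight (g) on a field
#' measure (stem length in m, or leaf count). The fitted line converts plot
#' measurements into dry biomass; negative predictions are clamped to zero at
#' prediction time.
#'
#' @param measure_value Numeric vector of field measures.
#' @param dry_weight_g Numeric vector of oven-dry weights (g).
#' @param species,measure_kind Labels stored with the calibration.
#' @param energy_kcal_g Metabolizable energy content (kcal per g dry weight).
#' @return A one-row data frame with class \code{species_calibration}:
#'   \code{species}, \code{measure_kind}, \code{slope}, \code{intercept},
#'   \code{energy_kcal_g}.
#' @export
fit_species_calibration <- function(measure_value, dry_weight_g,
                                    species = "species",
                                    measure_kind = c("stem_length_m",
                                                     "leaf_count"),
                                    energy_kcal_g = NA_real_) {
  measure_kind <- match.arg(measure_kind)
  stopifnot(length(measure_value) == length(dry_weight_g),
            length(measure_value) >= 2)
  if (stats::var(measure_value) == 0)
    stop("singular fit: measure values are constant")
  if (!is.na(energy_kcal_g) && energy_kcal_g < 0)
    stop("energy_kcal_g must be >= 0")
  fit <- stats::lm.fit(cbind(1, measure_value), dry_weight_g)
  out <- data.frame(species = species, measure_kind = measure_kind,
                    slope = fit$coefficients[2], intercept = fit$coefficients[1],
                    energy_kcal_g = energy_kcal_g, row.names = NULL)
  class(out) <- c("species_calibration", "data.frame")
  out
}

#' Construct an energy field directly from per-cell values
#'
#' @param grid A \code{space_grid}.
#' @param energy Matrix of dimension \code{n_cols x n_rows} (indexed
#'   \code{[i + 1, j + 1]}) of kcal per square metre; \code{NA} marks cells
#'   with no food-availability data (masked).
#' @return An \code{energy_field} object.
#' @export
energy_field <- function(grid, energy) {
  energy <- as.matrix(energy)
  stopifnot(nrow(energy) == grid$n_cols, ncol(energy) == grid$n_rows)
  if (any(energy < 0, na.rm = TRUE)) stop("energy densities must be >= 0")
  structure(list(grid = grid, energy = energy), class = "energy_field")
}

#' @export
print.energy_field <- function(x, ...) {
  v <- x$energy[!is.na(x$energy)]
  cat(sprintf(
    "<energy_field> %d x %d cells; %d with data; range %.0f-%.0f kcal/m^2\n",
    x$grid$n_cols, x$grid$n_rows, length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# internal: energy at 0-based cells, NA outside grid or masked
energy_at <- function(field, cells) {
  cells <- as.matrix(cells)
  ok <- !is.na(cells[, 1]) & !is.na(cells[, 2]) &
        cells[, 1] >= 0 & cells[, 1] < field$grid$n_cols &
        cells[, 2] >= 0 & cells[, 2] < field$grid$n_rows
  out <- rep(NA_real_, nrow(cells))
  out[ok] <- field$energy[cbind(cells[ok, 1] + 1L, cells[ok, 2] + 1L)]
  out
}

#' Per-cell herbaceous energy density from vegetation transects
#'
#' For every grid cell with at least one sampled plot, the predicted dry
#' biomass of each species is averaged over all of that cell's 1 m^2 plots
#' (plots where the species was not recorded contribute zero), multiplied by
#' the species' energy content (kcal/g) and summed over species, yielding
#' kcal per square metre. Cells without plots are masked (\code{NA}), not
#' treated as zero.
#'
#' @param plots Data frame of transect plot records with columns
#'   \code{cell_i}, \code{cell_j} (0-based grid indices), \code{transect_id},
#'   \code{plot_id}, \code{species}, \code{measure_kind},
#'   \code{measure_value}. One row per species recorded in a plot.
#' @param calibrations Data frame with columns \code{species},
#'   \code{measure_kind}, \code{slope}, \code{intercept},
#'   \code{energy_kcal_g} (e.g. stacked \code{\link{fit_species_calibration}}
#'   results). Every species present in \code{plots} must have a calibration
#'   for its measure kind.
#' @param grid A \code{space_grid}.
#' @return An \code{\link{energy_field}}.
#' @export
estimate_cell_energy_density <- function(plots, calibrations, grid) {
  req <- c("cell_i", "cell_j", "transect_id", "plot_id", "species",
           "measure_kind", "measure_value")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stop("plots is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(plots$measure_value < 0)) stop("measure_value must be >= 0")
  key <- paste(plots$species, plots$measure_kind)
  ckey <- paste(calibrations$species, calibrations$measure_kind)
  m <- match(key, ckey)
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("no calibration for: ", paste(bad, collapse = "; "))
  }
  pred <- calibrations$intercept[m] + calibrations$slope[m] * plots$measure_value
  pred <- pmax(pred, 0)                      # biomass cannot be negative
  kcal <- pred * calibrations$energy_kcal_g[m]

  cellk <- cell_key(plots$cell_i, plots$cell_j)
  plotk <- paste(cellk, plots$transect_id, plots$plot_id)
  # number of distinct plots per cell (denominator of the per-species mean)
  n_plots <- tapply(!duplicated(plotk), cellk, sum)
  kcal_sum <- tapply(kcal, cellk, sum)       # summed over species and plots

  energy <- matrix(NA_real_, grid$n_cols, grid$n_rows)
  ij <- do.call(rbind, strsplit(names(kcal_sum), "_", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  if (any(i < 0 | i >= grid$n_cols | j < 0 | j >= grid$n_rows))
    stop("plot cell index outside grid")
  energy[cbind(i + 1L, j + 1L)] <- as.numeric(kcal_sum / n_plots[names(kcal_sum)])
  energy_field(grid, energy)
}

#' Read/write an energy field as CSV
#'
#' The CSV has columns \code{i}, \code{j} (0-based cell indices) and
#' \code{kcal_per_m2}; masked cells are omitted.
#'
#' @param field An \code{energy_field}.
#' @param file Path to a CSV file.
#' @param grid A \code{space_grid} describing the lattice the CSV refers to.
#' @return \code{write_energy_csv} returns \code{file} invisibly;
#'   \code{read_energy_csv} returns an \code{energy_field}.
#' @export
write_energy_csv <- function(field, file) {
  idx <- which(!is.na(field$energy), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   kcal_per_m2 = field$energy[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_energy_csv
#' @export
read_energy_csv <- function(file, grid) {
  df <- utils::read.csv(file)
  energy <- matrix(NA_real_, grid$n_cols, grid$n_rows)
  energy[cbind(df$i + 1L, df$j + 1L)] <- df$kcal_per_m2
  energy_field(grid, energy)
}
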