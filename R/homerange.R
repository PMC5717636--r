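#' Fixed-bandwidth kernel utilization distribution
#'
#' Bivariate isotropic Gaussian kernel density estimate over a raster of
#' pixel centres, normalized so the pixel masses sum to one. The bandwidth
#' is the kernel standard deviation in metres and is fixed (not data-driven)
#' so that estimates are comparable across groups.
#'
#' @param points Two-column matrix or data frame of planar x, y (metres);
#'   conventionally one location per day.
#' @param h Bandwidth in metres (default 200).
#' @param resolution Pixel edge length in metres (default 50).
#' @param extent Optional \code{c(xmin, xmax, ymin, ymax)}; by default the
#'   point bounding box padded by \code{4 * h}. Supply a common extent when
#'   several groups' distributions must share a raster (see
#'   \code{\link{overlap_report}}).
#' @return Object of class \code{kde_ud}: pixel-centre coordinate vectors
#'   \code{x}, \code{y}, the \code{mass} matrix (\code{length(x)} by
#'   \code{length(y)}), \code{resolution}, \code{h}, \code{n_points}.
#' @export
kde_ud <- function(points, h = 200, resolution = 50, extent = NULL) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 5)
    stop("kernel estimation needs at least 5 points; supply more data")
  if (h <= 0 || resolution <= 0) stop("h and resolution must be > 0")
  if (is.null(extent))
    extent <- c(min(points[, 1]) - 4 * h, max(points[, 1]) + 4 * h,
                min(points[, 2]) - 4 * h, max(points[, 2]) + 4 * h)
  x <- seq(extent[1] + resolution / 2, extent[2], by = resolution)
  y <- seq(extent[3] + resolution / 2, extent[4], by = resolution)
  # separable Gaussian: density(x_i, y_j) = sum_k A[i,k] * B[j,k]
  A <- exp(-outer(x, points[, 1], "-")^2 / (2 * h^2))
  B <- exp(-outer(y, points[, 2], "-")^2 / (2 * h^2))
  dens <- A %*% t(B)
  mass <- dens / sum(dens)
  structure(list(x = x, y = y, mass = mass, resolution = resolution, h = h,
                 n_points = nrow(points), extent = extent),
            class = "kde_ud")
}

#' @export
print.kde_ud <- function(x, ...) {
  cat(sprintf("<kde_ud> %d x %d pixels of %g m, h = %g m, %d points\n",
              length(x$x), length(x$y), x$resolution, x$h, x$n_points))
  invisible(x)
}

#' Percent-volume contour of a utilization distribution
#'
#' Selects pixels in decreasing order of probability mass until the
#' cumulative mass reaches \code{level}; the union of the selected pixel
#' squares is the contour region (no smoothing, so regions are exactly
#' reproducible). The 90\% contour is the conventional home range, the 50\%
#' contour the core area.
#'
#' @param ud A \code{\link{kde_ud}}.
#' @param level Fraction of total mass to capture, in (0, 1).
#' @return Object of class \code{range_contour}: logical \code{mask} matrix
#'   over the UD raster, \code{level}, \code{area_km2},
#'   \code{mass_captured}, plus the raster geometry (\code{x}, \code{y},
#'   \code{resolution}).
#' @export
volume_contour <- function(ud, level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  o <- order(ud$mass, decreasing = TRUE)
  cum <- cumsum(ud$mass[o])
  k <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(ud$mass), ncol(ud$mass))
  mask[o[seq_len(k)]] <- TRUE
  structure(list(mask = mask, level = level,
                 area_km2 = k * ud$resolution^2 / 1e6,
                 mass_captured = cum[k],
                 x = ud$x, y = ud$y, resolution = ud$resolution),
            class = "range_contour")
}

#' @export
print.range_contour <- function(x, ...) {
  cat(sprintf("<range_contour> %.0f%% contour, %.2f km^2 (mass %.4f)\n",
              100 * x$level, x$area_km2, x$mass_captured))
  invisible(x)
}

# internal: check two contours share a raster
same_raster <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
}

#' Home-range / core-area overlap report
#'
#' For each group \eqn{i} with contour region \eqn{P_i}: the area
#' \eqn{A_i}, the shared area
#' \eqn{S_i = area(P_i \cap \bigcup_{j \ne i} P_j)} with all other groups
#' collectively, the percentage \eqn{100 S_i / A_i}, and the exclusively
#' used remainder \eqn{A_i - S_i}. All contours must be built on one common
#' raster (pass a shared \code{extent} to \code{\link{kde_ud}}). A pairwise
#' shared-area percentage matrix (\code{pct[i, j]} = per cent of group i's
#' area covered by group j) is attached as attribute \code{"pairwise"};
#' shared areas themselves are symmetric.
#'
#' @param contours Named list of \code{range_contour} objects, one per
#'   group, all at the same level and raster.
#' @return Data frame: \code{group}, \code{area_km2}, \code{shared_km2},
#'   \code{pct_overlap}, \code{exclusive_km2}.
#' @export
overlap_report <- function(contours) {
  if (length(contours) < 2) stop("need at least 2 groups")
  if (is.null(names(contours)))
    names(contours) <- paste0("G", seq_along(contours))
  for (k in seq_along(contours)[-1])
    if (!same_raster(contours[[1]], contours[[k]]))
      stop("all contours must share one raster; rebuild the UDs on a ",
           "common extent")
  if (any(!vapply(contours, function(cc) any(cc$mask), TRUE)))
    stop("degenerate (empty) contour region")
  px_km2 <- contours[[1]]$resolution^2 / 1e6
  masks <- lapply(contours, `[[`, "mask")
  n <- length(masks)
  out <- data.frame(group = names(contours),
                    area_km2 = NA_real_, shared_km2 = NA_real_,
                    pct_overlap = NA_real_, exclusive_km2 = NA_real_)
  pw <- matrix(0, n, n, dimnames = list(names(contours), names(contours)))
  for (i in seq_len(n)) {
    others <- Reduce(`|`, masks[-i])
    a <- sum(masks[[i]])
    s <- sum(masks[[i]] & others)
    out$area_km2[i] <- a * px_km2
    out$shared_km2[i] <- s * px_km2
    out$pct_overlap[i] <- 100 * s / a
    out$exclusive_km2[i] <- (a - s) * px_km2
    for (j in seq_len(n)[-i])
      pw[i, j] <- 100 * sum(masks[[i]] & masks[[j]]) / a
  }
  attr(out, "pairwise") <- pw
  out
}

#' Area-weighted energy density of a contour region
#'
#' Mean energy density over the region, weighting each grid cell by the area
#' of its intersection with the region (computed from the pixel
#' decomposition): \eqn{\sum_c energy(c) \, area(P \cap c) / area(P)}. Cells
#' without food data are excluded from both numerator and denominator, so
#' the result is the mean over the surveyed part of the region.
#'
#' @param contour A \code{range_contour} (or a bare logical mask with the
#'   raster attached, as produced by \code{\link{region_difference}}).
#' @param field An \code{energy_field}.
#' @return Energy density in kcal per square metre.
#' @export
weighted_energy_density <- function(contour, field) {
  idx <- which(contour$mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty region")
  px <- cbind(contour$x[idx[, 1]], contour$y[idx[, 2]])
  e <- energy_at(field, cell_of(px, field$grid, strict = FALSE))
  if (all(is.na(e))) stop("region lies entirely over cells without food data")
  mean(e, na.rm = TRUE)
}

#' Difference of two contour regions on the same raster
#'
#' Pixelwise set difference (e.g. home range minus core area = the rest of
#' the range). Returns a contour-like object usable with
#' \code{\link{weighted_energy_density}}.
#'
#' @param a,b \code{range_contour} objects on the same raster.
#' @return A \code{range_contour} with \code{level = NA}.
#' @export
region_difference <- function(a, b) {
  if (!same_raster(a, b)) stop("contours are on different rasters")
  mask <- a$mask & !b$mask
  structure(list(mask = mask, level = NA_real_,
                 area_km2 = sum(mask) * a$resolution^2 / 1e6,
                 mass_captured = NA_real_,
                 x = a$x, y = a$y, resolution = a$resolution),
            class = "range_contour")
}

#' Home-range area sensitivity to location subsampling
#'
#' Repeatedly subsamples the daily locations without replacement and
#' recomputes the home-range contour area, summarizing how stable the area
#' estimate is as data are thinned.
#'
#' @param points Two-column matrix of locations.
#' @param fractions Subsampling fractions in (0, 1].
#' @param n_rep Replicates per fraction.
#' @param seed Integer seed.
#' @param h,resolution,level Passed to the kernel estimator and contour.
#' @return Data frame: \code{fraction}, \code{n_points}, \code{mean_km2},
#'   \code{sd_km2}, \code{n_rep_used}.
#' @export
subsample_sensitivity <- function(points, fractions = c(0.5, 0.75, 1),
                                  n_rep = 50, seed = 1, h = 200,
                                  resolution = 50, level = 0.9) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  if (n_rep < 1) stop("n_rep must be >= 1")
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(points)
  full_area <- volume_contour(kde_ud(points, h, resolution), level)$area_km2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- lapply(sort(fractions), function(f) {
    m <- floor(f * n)
    if (m < 5) {
      warning(sprintf("fraction %.2f gives %d < 5 points; skipped", f, m))
      return(NULL)
    }
    if (m == n) {
      areas <- full_area          # no sampling variability at fraction 1
      reps <- 1L
    } else {
      areas <- vapply(seq_len(n_rep), function(b) {
        sub <- points[sample.int(n, m), , drop = FALSE]
        volume_contour(kde_ud(sub, h, resolution), level)$area_km2
      }, numeric(1))
      reps <- n_rep
    }
    data.frame(fraction = f, n_points = m, mean_km2 = mean(areas),
               sd_km2 = if (reps > 1) stats::sd(areas) else 0,
               n_rep_used = reps)
  })
  do.call(rbind, out)
}

#' Export a contour region as GeoJSON
#'
#' The pixel union is encoded as a MultiPolygon of maximal horizontal pixel
#' runs (axis-aligned rectangles), a lossless representation of the raster
#' region.
#'
#' @param contour A \code{range_contour}.
#' @param file Output path.
#' @param name Feature name property.
#' @return \code{file}, invisibly.
#' @export
contour_to_geojson <- function(contour, file, name = "region") {
  res <- contour$resolution
  polys <- list()
  for (j in seq_along(contour$y)) {
    col <- contour$mask[, j]
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      x0 <- contour$x[starts[k]] - res / 2; x1 <- contour$x[ends[k]] + res / 2
      y0 <- contour$y[j] - res / 2; y1 <- contour$y[j] + res / 2
      ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      polys[[length(polys) + 1]] <- list(ring)
    }
  }
  gj <- list(type = "Feature",
             properties = list(name = name, level = contour$level,
                               area_km2 = contour$area_km2),
             geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(gj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
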