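#' Build a usage ledger
#'
#' The ledger holds every group's dated visits to grid cells (with the track
#' length of each visit) together with monthly mean group sizes (weaned
#' individuals), and backs the composite previous-use statistic. Visits are
#' aggregated to one record per (group, cell, day), summing distances, so
#' that elapsed time enters the statistic as an integer number of calendar
#' days (same-day earlier passes do not contribute).
#'
#' @param visits Data frame with columns \code{group}, \code{cell_i},
#'   \code{cell_j}, \code{date}, \code{distance_m}
#'   (e.g. from \code{\link{distance_per_cell}}).
#' @param group_sizes Data frame with columns \code{group}, \code{year},
#'   \code{month}, \code{size} (mean number of weaned individuals that
#'   month). A visit in a month with no size record falls back to the
#'   group's mean size.
#' @param min_visit_m Visits with less track length (metres) than this are
#'   discarded before aggregation (default 0 = keep all). Useful to strip
#'   boundary-overhang artefacts of GPS noise, which otherwise register as
#'   metre-scale visits to cells that were never entered.
#' @return An object of class \code{usage_ledger}.
#' @export
usage_ledger <- function(visits, group_sizes, min_visit_m = 0) {
  req <- c("group", "cell_i", "cell_j", "date", "distance_m")
  miss <- setdiff(req, names(visits))
  if (length(miss)) stop("visits missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(visits$date, "Date")) visits$date <- as.Date(visits$date)
  if (any(visits$distance_m < 0)) stop("distance_m must be >= 0")
  if (any(group_sizes$size <= 0)) stop("group sizes must be > 0")
  if (min_visit_m > 0)
    visits <- visits[visits$distance_m >= min_visit_m, , drop = FALSE]
  if (!nrow(visits)) stop("no visits remain")

  k <- paste(visits$group, visits$cell_i, visits$cell_j, visits$date, sep = "|")
  agg <- rowsum(visits$distance_m, k)
  first <- !duplicated(k)
  vv <- visits[first, c("group", "cell_i", "cell_j", "date")]
  vv$distance_m <- agg[k[first], 1]

  # attach the group size in force at each visit's month
  ym <- format(vv$date, "%Y-%m")
  sk <- sprintf("%s|%04d-%02d", group_sizes$group, group_sizes$year,
                group_sizes$month)
  m <- match(paste(vv$group, ym, sep = "|"), sk)
  vv$size <- group_sizes$size[m]
  if (anyNA(vv$size)) {
    mean_size <- tapply(group_sizes$size, group_sizes$group, mean)
    vv$size[is.na(vv$size)] <- mean_size[vv$group[is.na(vv$size)]]
    if (anyNA(vv$size))
      stop("no size record at all for group(s): ",
           paste(unique(vv$group[is.na(vv$size)]), collapse = ", "))
  }
  rownames(vv) <- NULL

  # per-cell index: matrix of (day, distance, size, group code) for fast sums
  groups <- sort(unique(vv$group))
  gcode <- match(vv$group, groups)
  day <- as.integer(vv$date)
  idx <- new.env(parent = emptyenv())
  ck <- cell_key(vv$cell_i, vv$cell_j)
  for (k2 in unique(ck)) {
    w <- which(ck == k2)
    assign(k2, cbind(day = day[w], dist = vv$distance_m[w],
                     size = vv$size[w], gcode = gcode[w]), envir = idx)
  }
  structure(list(visits = vv, groups = groups, index = idx,
                 group_sizes = group_sizes,
                 start_date = min(vv$date)),
            class = "usage_ledger")
}

#' @export
print.usage_ledger <- function(x, ...) {
  cat(sprintf("<usage_ledger> %d visits, %d groups, %s to %s\n",
              nrow(x$visits), length(x$groups),
              format(min(x$visits$date)), format(max(x$visits$date))))
  invisible(x)
}

# internal: sum of size/(ref_day - day) * dist over rows of a cell index
# matrix, restricted to gcode %in% codes and day < ref_day
pu_sum <- function(mat, codes, ref_day) {
  if (is.null(mat)) return(0)
  w <- mat[, "day"] < ref_day & mat[, "gcode"] %in% codes
  if (!any(w)) return(0)
  sum(mat[w, "size"] / (ref_day - mat[w, "day"]) * mat[w, "dist"])
}

#' Composite previous use of a cell by a group
#'
#' Sums, over all of the group's visits to the cell strictly before
#' \code{ref_date}, the quantity (group size at the visit's month) divided by
#' the days elapsed since the visit, multiplied by the track length of the
#' visit. Units: individuals x metres / day. Zero when there are no
#' qualifying prior visits.
#'
#' @param ledger A \code{\link{usage_ledger}}.
#' @param group Group identifier.
#' @param cell Length-2 vector (or 1-row matrix) of 0-based cell indices.
#' @param ref_date Reference date (\code{Date} or ISO string); visits on
#'   \code{ref_date} itself are excluded.
#' @return A single non-negative number.
#' @export
previous_use_value <- function(ledger, group, cell, ref_date) {
  ref_date <- as.Date(ref_date)
  if (ref_date < ledger$start_date)
    warning("ref_date precedes all ledger data; previous use is 0")
  cell <- as.integer(cell)
  code <- match(group, ledger$groups)
  if (is.na(code)) return(0)
  mat <- get0(cell_key(cell[1], cell[2]), envir = ledger$index)
  pu_sum(mat, code, as.integer(ref_date))
}

#' Collective previous use of a cell by all neighbouring groups
#'
#' Same statistic as \code{\link{previous_use_value}} but summed over every
#' ledger group except the focal group.
#'
#' @inheritParams previous_use_value
#' @param focal_group Group whose own visits are excluded.
#' @return A single non-negative number.
#' @export
neighbour_previous_use <- function(ledger, focal_group, cell, ref_date) {
  ref_date <- as.Date(ref_date)
  cell <- as.integer(cell)
  codes <- setdiff(seq_along(ledger$groups), match(focal_group, ledger$groups))
  if (!length(codes)) return(0)
  mat <- get0(cell_key(cell[1], cell[2]), envir = ledger$index)
  pu_sum(mat, codes, as.integer(ref_date))
}

#' Remove the burn-in period from analysis records
#'
#' Drops rows dated before \code{burn_in_date} from a table of analysis
#' records (decisions, cell visits, model rows). The usage ledger itself is
#' never filtered: pre-burn-in visits remain available as history for the
#' previous-use statistic.
#'
#' @param records Data frame with a \code{date} column.
#' @param burn_in_date First date retained for analysis.
#' @return The filtered data frame.
#' @export
apply_burn_in <- function(records, burn_in_date) {
  burn_in_date <- as.Date(burn_in_date)
  d <- as.Date(records$date)
  out <- records[d >= burn_in_date, , drop = FALSE]
  if (!nrow(out))
    stop("burn-in date ", format(burn_in_date),
         " is after the last record; no analysis rows remain")
  rownames(out) <- NULL
  out
}

#' Read/write a usage ledger's visit table
#'
#' @param ledger A \code{usage_ledger}.
#' @param visits_file,sizes_file CSV paths for the visit table
#'   (\code{group,cell_i,cell_j,date,distance_m}) and the group-size table
#'   (\code{group,year,month,size}).
#' @return \code{read_ledger_csv} returns a \code{usage_ledger}.
#' @export
write_ledger_csv <- function(ledger, visits_file, sizes_file) {
  utils::write.csv(ledger$visits[, c("group", "cell_i", "cell_j", "date",
                                     "distance_m")],
                   visits_file, row.names = FALSE)
  utils::write.csv(ledger$group_sizes, sizes_file, row.names = FALSE)
  invisible(visits_file)
}

#' @rdname write_ledger_csv
#' @export
read_ledger_csv <- function(visits_file, sizes_file) {
  usage_ledger(utils::read.csv(visits_file),
               utils::read.csv(sizes_file))
}
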