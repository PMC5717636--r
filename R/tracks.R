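#' Read a GPS fix table
#'
#' Expects columns \code{group}, \code{date} (ISO yyyy-mm-dd), \code{time}
#' (seconds of day or hh:mm:ss) and projected metric \code{x}, \code{y}.
#' Fixes are sorted by group, date and time; fixes sharing a timestamp within
#' a group-day keep the first record and drop the rest with a warning.
#'
#' @param file CSV path.
#' @return A data frame of fixes with \code{date} as \code{Date} and
#'   \code{time} numeric seconds.
#' @export
read_fixes_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_fixes(df)
}

#' @rdname read_fixes_csv
#' @param fixes A data frame with the columns described above.
#' @export
validate_fixes <- function(fixes) {
  req <- c("group", "date", "time", "x", "y")
  miss <- setdiff(req, names(fixes))
  if (length(miss)) stop("fix table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!inherits(fixes$date, "Date")) fixes$date <- as.Date(fixes$date)
  if (is.character(fixes$time)) {
    hms <- strsplit(fixes$time, ":", fixed = TRUE)
    fixes$time <- vapply(hms, function(p)
      sum(as.numeric(p) * c(3600, 60, 1)[seq_along(p)]), numeric(1))
  }
  o <- order(fixes$group, fixes$date, fixes$time)
  fixes <- fixes[o, , drop = FALSE]
  dup <- duplicated(fixes[, c("group", "date", "time")])
  if (any(dup)) {
    warning(sum(dup), " fix(es) with duplicated timestamps dropped")
    fixes <- fixes[!dup, , drop = FALSE]
  }
  rownames(fixes) <- NULL
  fixes
}

# internal: split one segment (p0 -> p1, cells differ) at grid boundary lines;
# returns matrix of (length, i, j) pieces assigned by piece-midpoint cell.
split_segment <- function(p0, p1, grid) {
  s <- grid$cell_size
  ts <- numeric(0)
  for (k in 1:2) {
    o <- grid$origin[k]
    a <- p0[k]; b <- p1[k]
    if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      # boundary coordinates strictly inside the open interval (lo, hi]
      f <- o + s * seq(ceiling((lo - o) / s), floor((hi - o) / s))
      f <- f[f > lo & f < hi]
      if (length(f)) ts <- c(ts, (f - a) / (b - a))
    }
  }
  ts <- sort(unique(c(0, ts, 1)))
  len <- sqrt(sum((p1 - p0)^2))
  mid <- (ts[-length(ts)] + ts[-1]) / 2
  px <- p0[1] + mid * (p1[1] - p0[1])
  py <- p0[2] + mid * (p1[2] - p0[2])
  cells <- cell_of(cbind(px, py), grid)
  cbind(length = diff(ts) * len, cells)
}

#' Distance travelled per grid cell per group-day
#'
#' Sums the lengths of consecutive-fix segments within each cell. Segments
#' that cross one or more cell boundaries are split at the boundary by linear
#' interpolation, so each segment's pieces sum exactly to its length; a piece
#' is assigned to the cell containing its midpoint. A single-fix day yields
#' one zero-distance visit to the cell of that fix.
#'
#' @param fixes Fix data frame (see \code{\link{read_fixes_csv}}); may contain
#'   any number of groups and days.
#' @param grid A \code{space_grid}.
#' @return Data frame of cell visits: \code{group}, \code{date},
#'   \code{cell_i}, \code{cell_j}, \code{distance_m}, one row per
#'   (group, date, cell).
#' @export
distance_per_cell <- function(fixes, grid) {
  fixes <- validate_fixes(fixes)
  cells <- cell_of(fixes[, c("x", "y")], grid)
  gd <- paste(fixes$group, fixes$date)
  n <- nrow(fixes)
  same_day <- gd[-n] == gd[-1]
  same_cell <- cells[-n, 1] == cells[-1, 1] & cells[-n, 2] == cells[-1, 2]
  seg_len <- sqrt((fixes$x[-1] - fixes$x[-n])^2 + (fixes$y[-1] - fixes$y[-n])^2)

  acc_key <- character(0); acc_len <- numeric(0)
  # within-cell segments, accumulated vectorised
  w <- which(same_day & same_cell)
  if (length(w)) {
    k <- paste(gd[w], cells[w, 1], cells[w, 2], sep = "|")
    sums <- rowsum(seg_len[w], k)
    acc_key <- rownames(sums); acc_len <- sums[, 1]
  }
  # boundary-crossing segments, split individually
  for (w in which(same_day & !same_cell)) {
    pieces <- split_segment(c(fixes$x[w], fixes$y[w]),
                            c(fixes$x[w + 1], fixes$y[w + 1]), grid)
    k <- paste(gd[w], pieces[, "i"], pieces[, "j"], sep = "|")
    acc_key <- c(acc_key, k); acc_len <- c(acc_len, pieces[, "length"])
  }
  # every visited cell appears, even if only touched by a single fix
  k0 <- paste(gd, cells[, 1], cells[, 2], sep = "|")
  acc_key <- c(acc_key, unique(k0)); acc_len <- c(acc_len, numeric(length(unique(k0))))

  tot <- rowsum(acc_len, acc_key)
  parts <- strsplit(rownames(tot), "|", fixed = TRUE)
  gdp <- vapply(parts, `[`, "", 1L)
  sp <- regexpr(" ", gdp, fixed = TRUE)
  grp_day <- t(vapply(gdp, function(z) {
    p <- regexpr(" \\d{4}-\\d{2}-\\d{2}$", z)
    c(substr(z, 1, p - 1), substr(z, p + 1, nchar(z)))
  }, character(2)))
  out <- data.frame(group = grp_day[, 1],
                    date = as.Date(grp_day[, 2]),
                    cell_i = as.integer(vapply(parts, `[`, "", 2L)),
                    cell_j = as.integer(vapply(parts, `[`, "", 3L)),
                    distance_m = tot[, 1], row.names = NULL)
  out[order(out$group, out$date, out$cell_i, out$cell_j), , drop = FALSE]
}

# internal: merge cell runs shorter than min_run fixes into the preceding
# run, per group-day (a leading short run merges forward instead)
despike_cells <- function(cells, gd, min_run) {
  key <- cell_key(cells[, 1], cells[, 2])
  for (d in unique(gd)) {
    w <- which(gd == d)
    k <- key[w]
    repeat {
      r <- rle(k)
      if (length(r$lengths) < 2) break
      short <- which(r$lengths < min_run)
      if (!length(short)) break
      s <- short[1]
      if (s == 1) r$values[1] <- r$values[2]
      else r$values[s] <- r$values[s - 1]
      k <- inverse.rle(r)
    }
    key[w] <- k
  }
  ij <- do.call(rbind, strsplit(key, "_", fixed = TRUE))
  cbind(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
}

# internal: the 8 neighbours of a cell, clipped to the grid
neighbour_cells <- function(i, j, grid) {
  d <- expand.grid(di = -1:1, dj = -1:1)
  d <- d[!(d$di == 0 & d$dj == 0), ]
  ni <- i + d$di; nj <- j + d$dj
  ok <- ni >= 0 & ni < grid$n_cols & nj >= 0 & nj < grid$n_rows
  cbind(i = ni[ok], j = nj[ok], corner = as.integer(abs(d$di[ok]) + abs(d$dj[ok]) == 2))
}

#' Extract daily cell-entry decisions from fixes
#'
#' A decision is a transition from the current (origin) cell into one of its
#' up-to-eight surrounding cells. Multiple entries into the same cell on the
#' same day count as one decision: by default the deduplication key is the
#' (origin, chosen) pair within a group-day; set \code{dedup = "chosen"} to
#' keep only the first entry into each cell per day regardless of origin.
#' Candidate cells are the origin's neighbours with unmasked food data;
#' decisions whose chosen cell is masked, or whose transition skips a cell
#' (non-adjacent jump between consecutive fixes), are dropped and counted in
#' the \code{"dropped"} attribute of the result.
#'
#' @param fixes Fix data frame.
#' @param grid A \code{space_grid}.
#' @param field An \code{energy_field} providing the food-data mask.
#' @param dedup \code{"pair"} (default), \code{"chosen"}, or \code{"none"}
#'   to keep every transition as its own decision (appropriate when each
#'   transition is known to be an independent choice, as in simulator
#'   output).
#' @param include_return Count a move back into the day's earlier origin cell
#'   as a decision (default \code{TRUE}).
#' @param min_run Minimum number of consecutive fixes in a cell for the cell
#'   to count as entered (default 2). GPS noise of a few metres flips fixes
#'   across a cell boundary for a single epoch; runs shorter than
#'   \code{min_run} are treated as such spikes and merged into the
#'   preceding cell. Set to 1 to disable cleaning.
#' @return Data frame of decisions: \code{group}, \code{date},
#'   \code{origin_i}, \code{origin_j}, \code{chosen_i}, \code{chosen_j},
#'   \code{n_candidates}.
#' @export
extract_entry_decisions <- function(fixes, grid, field,
                                    dedup = c("pair", "chosen", "none"),
                                    include_return = TRUE, min_run = 2) {
  dedup <- match.arg(dedup)
  fixes <- validate_fixes(fixes)
  cells <- cell_of(fixes[, c("x", "y")], grid)
  gd <- paste(fixes$group, fixes$date)
  if (min_run > 1) cells <- despike_cells(cells, gd, min_run)
  n <- nrow(fixes)
  chg <- which(gd[-n] == gd[-1] &
               (cells[-n, 1] != cells[-1, 1] | cells[-n, 2] != cells[-1, 2]))
  dropped <- c(nonadjacent = 0L, masked_chosen = 0L, duplicate = 0L,
               returns = 0L)
  rows <- vector("list", length(chg))
  seen <- character(0); seen_day <- ""
  for (t in chg) {
    oi <- cells[t, 1]; oj <- cells[t, 2]
    ci <- cells[t + 1, 1]; cj <- cells[t + 1, 2]
    day <- gd[t]
    if (day != seen_day) { seen <- character(0); day_cells <- character(0); seen_day <- day }
    if (max(abs(ci - oi), abs(cj - oj)) != 1) {
      dropped["nonadjacent"] <- dropped["nonadjacent"] + 1L
      next
    }
    if (!include_return && cell_key(ci, cj) %in% day_cells) {
      dropped["returns"] <- dropped["returns"] + 1L
      day_cells <- c(day_cells, cell_key(ci, cj))
      next
    }
    key <- switch(dedup, pair = paste(oi, oj, ci, cj), chosen = paste(ci, cj),
                  none = NULL)
    if (!is.null(key)) {
      if (key %in% seen) {
        dropped["duplicate"] <- dropped["duplicate"] + 1L
        next
      }
      seen <- c(seen, key)
    }
    day_cells <- c(day_cells, cell_key(oi, oj), cell_key(ci, cj))
    nb <- neighbour_cells(oi, oj, grid)
    nb <- nb[!is.na(energy_at(field, nb[, 1:2, drop = FALSE])), , drop = FALSE]
    if (!nrow(nb) || !any(nb[, 1] == ci & nb[, 2] == cj)) {
      dropped["masked_chosen"] <- dropped["masked_chosen"] + 1L
      next
    }
    rows[[t]] <- data.frame(group = fixes$group[t], date = fixes$date[t],
                            origin_i = oi, origin_j = oj,
                            chosen_i = ci, chosen_j = cj,
                            n_candidates = nrow(nb))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(group = character(0), date = as.Date(character(0)),
                      origin_i = integer(0), origin_j = integer(0),
                      chosen_i = integer(0), chosen_j = integer(0),
                      n_candidates = integer(0))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' First recorded fix per group-day
#'
#' Used to thin trail-based all-day tracks to one point per day for kernel
#' home-range estimation.
#'
#' @param fixes Fix data frame.
#' @return One row per (group, date): the earliest fix.
#' @export
first_fix_per_day <- function(fixes) {
  fixes <- validate_fixes(fixes)
  keep <- !duplicated(paste(fixes$group, fixes$date))
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
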