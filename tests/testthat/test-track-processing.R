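test_that("distance per cell handles whole, split and degenerate segments", {
  g <- toy_grid()
  v1 <- distance_per_cell(fixes_from_points(cbind(c(100, 400), c(250, 250))), g)
  expect_equal(nrow(v1), 1)
  expect_equal(v1$distance_m, 300)
  expect_equal(c(v1$cell_i, v1$cell_j), c(0, 0))

  v2 <- distance_per_cell(fixes_from_points(cbind(c(400, 600), c(250, 250))), g)
  expect_equal(v2$distance_m[order(v2$cell_i)], c(100, 100))
  expect_equal(sort(v2$cell_i), c(0, 1))

  v3 <- distance_per_cell(fixes_from_points(cbind(700, 800)), g)
  expect_equal(v3$distance_m, 0)
  expect_equal(c(v3$cell_i, v3$cell_j), c(1, 1))
})

test_that("cell distances sum to the day's polyline length", {
  g <- toy_grid()
  set.seed(7)
  for (rep in 1:5) {
    pts <- cbind(cumsum(rnorm(40, 0, 180)) + 2500,
                 cumsum(rnorm(40, 0, 180)) + 2500)
    pts <- pmin(pmax(pts, 1), 4999)
    v <- distance_per_cell(fixes_from_points(pts), g)
    expect_equal(sum(v$distance_m),
                 sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)),
                 tolerance = 1e-6)
  }
})

test_that("diagonal corner-crossing segments keep full length", {
  g <- toy_grid()
  # crosses near the 4-corner point of cells (0,0),(1,0),(0,1),(1,1)
  pts <- cbind(c(480, 530), c(470, 520))
  v <- distance_per_cell(fixes_from_points(pts), g)
  expect_equal(sum(v$distance_m), sqrt(50^2 + 50^2), tolerance = 1e-9)
})

test_that("entry decisions are deduplicated and candidate-aware", {
  g <- toy_grid()
  f <- toy_field(g)
  ctr <- function(i, j) cell_centre(cbind(i, j), g)
  # stay in one cell all day: no decisions (3 fixes per cell for min_run)
  stay <- fixes_from_points(ctr(2, 2)[rep(1, 5), ] + seq(-20, 20, 10))
  expect_equal(nrow(extract_entry_decisions(stay, g, f)), 0)

  # A -> B -> A -> B: second A->B is a duplicate under pair dedup
  path <- rbind(ctr(2, 2), ctr(2, 2), ctr(3, 2), ctr(3, 2), ctr(2, 2),
                ctr(2, 2), ctr(3, 2), ctr(3, 2))
  d <- extract_entry_decisions(fixes_from_points(path), g, f, min_run = 1)
  expect_equal(nrow(d), 2)
  expect_setequal(paste(d$origin_i, d$chosen_i), c("2 3", "3 2"))
  expect_equal(unname(attr(d, "dropped")["duplicate"]), 1L)
  # without dedup all three transitions are decisions
  d3 <- extract_entry_decisions(fixes_from_points(path), g, f,
                                dedup = "none", min_run = 1)
  expect_equal(nrow(d3), 3)
  # returns can be excluded
  d2 <- extract_entry_decisions(fixes_from_points(path), g, f,
                                include_return = FALSE, min_run = 1)
  expect_equal(nrow(d2), 1)

  # interior origin: 8 candidates
  move <- rbind(ctr(2, 2), ctr(2, 2), ctr(3, 2), ctr(3, 2))
  d4 <- extract_entry_decisions(fixes_from_points(move), g, f, min_run = 1)
  expect_equal(d4$n_candidates, 8)
})

test_that("masked neighbours shrink the candidate set", {
  g <- toy_grid()
  # origin (1,1); mask 3 of its 8 neighbours
  f <- toy_field(g, masked = cbind(c(1, 2, 3), c(1, 1, 1)))  # cells (0,0),(1,0),(2,0)
  ctr <- function(i, j) cell_centre(cbind(i, j), g)
  move <- rbind(ctr(1, 1), ctr(1, 1), ctr(2, 1), ctr(2, 1))
  d <- extract_entry_decisions(fixes_from_points(move), g, f, min_run = 1)
  expect_equal(d$n_candidates, 5)
  # a move into a masked cell is dropped
  move2 <- rbind(ctr(1, 1), ctr(1, 1), ctr(1, 0), ctr(1, 0))
  d2 <- extract_entry_decisions(fixes_from_points(move2), g, f, min_run = 1)
  expect_equal(nrow(d2), 0)
  expect_equal(unname(attr(d2, "dropped")["masked_chosen"]), 1L)
})

test_that("single-fix cell spikes are despiked", {
  g <- toy_grid()
  f <- toy_field(g)
  ctr <- function(i, j) cell_centre(cbind(i, j), g)
  # one stray fix in (3,2) sandwiched inside a (2,2) run
  path <- rbind(ctr(2, 2), ctr(2, 2), ctr(3, 2), ctr(2, 2), ctr(2, 2))
  expect_equal(nrow(extract_entry_decisions(fixes_from_points(path), g, f)), 0)
  expect_equal(nrow(extract_entry_decisions(fixes_from_points(path), g, f,
                                            min_run = 1)), 2)
})

test_that("first fix per day picks the earliest record", {
  fx <- rbind(fixes_from_points(cbind(c(10, 20, 30), c(5, 5, 5)), date = "2012-10-01"),
              fixes_from_points(cbind(55, 44), date = "2012-10-02"))
  # shuffle rows; validate_fixes must re-sort
  fx <- fx[c(3, 1, 4, 2), ]
  ff <- first_fix_per_day(fx)
  expect_equal(nrow(ff), 2)
  expect_equal(ff$x, c(10, 55))
  expect_equal(ff$time[1], 6 * 3600)
})

test_that("transitions per day bound the number of decisions", {
  g <- toy_grid()
  f <- toy_field(g)
  set.seed(11)
  pts <- cbind(cumsum(rnorm(60, 30, 120)) + 1500,
               cumsum(rnorm(60, 30, 120)) + 1500)
  pts <- pmin(pmax(pts, 1), 4999)
  cells <- cell_of(pts, g)
  n_trans <- sum(cells[-1, 1] != cells[-60, 1] | cells[-1, 2] != cells[-60, 2])
  d <- extract_entry_decisions(fixes_from_points(pts), g, f, min_run = 1)
  expect_lte(nrow(d), n_trans)
})
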