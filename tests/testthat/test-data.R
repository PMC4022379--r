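# Time-series containers, inconsistency breaking, noise injection,
# discretization, and file I/O.

two_series <- function(a, b, n = 2) {
  time_series_set(list(time_series(a, label = "t1"),
                       time_series(b, label = "t2")))
}

test_that("inconsistencies are found over pooled transitions", {
  s <- c(0, 0); a <- c(1, 0); b <- c(0, 1)
  tss <- two_series(rbind(s, a), rbind(s, b))
  inc <- find_inconsistencies(tss)
  expect_length(inc, 1L)
  expect_identical(inc[[1]]$state, c(0L, 0L))
  expect_equal(nrow(inc[[1]]$successors), 2L)

  # a single deterministic trajectory is consistent
  f <- canned_fixtures()$toggle3$model
  traj <- simulate_model(f, c(1, 0, 0), 8)
  expect_length(find_inconsistencies(
    time_series_set(list(time_series(traj)))), 0L)

  # repeated visits with diverging successors within one series
  u <- c(0, 0); v <- c(1, 0); w <- c(0, 1)
  tss2 <- time_series_set(list(time_series(rbind(u, v, u, w))))
  inc2 <- find_inconsistencies(tss2)
  expect_length(inc2, 1L)
  expect_identical(inc2[[1]]$state, c(0L, 0L))
})

test_that("knock-out targets pool separately from wildtype", {
  s <- c(0, 0); a <- c(1, 0); b <- c(0, 1)
  tss <- time_series_set(list(
    time_series(rbind(s, a), label = "wt"),
    time_series(rbind(s, b), kind = "knockout", ko_target = 1, label = "ko")))
  # same predecessor, different successors, but different pools: consistent
  expect_length(find_inconsistencies(tss), 0L)
})

test_that("breaking removes all transitions out of inconsistent states", {
  u <- c(0, 0); v <- c(1, 0); w <- c(0, 1)
  tss <- time_series_set(list(time_series(rbind(u, v, u, w))))
  broken <- break_inconsistencies(tss)
  lens <- vapply(broken$series, function(s) nrow(s$points), integer(1))
  expect_identical(sort(lens), c(1L, 1L, 2L))   # [u], [v,u], [w]
  expect_identical(total_length(lens), 1L)      # only v -> u survives
  frag2 <- broken$series[[which(lens == 2L)]]
  expect_identical(unname(frag2$points), rbind(c(1L, 0L), c(0L, 0L)))
  # idempotent
  again <- break_inconsistencies(broken)
  expect_identical(vapply(again$series, function(s) nrow(s$points), integer(1)),
                   lens)
  expect_length(find_inconsistencies(broken), 0L)

  # consistent input is returned unchanged
  f <- canned_fixtures()$toggle3$model
  ok <- time_series_set(list(time_series(simulate_model(f, c(1, 1, 0), 6))))
  expect_identical(break_inconsistencies(ok), ok)

  # fully conflicting pair: all transitions removed, m = 0
  s <- c(0, 0); a <- c(1, 0); b <- c(0, 1)
  gone <- break_inconsistencies(two_series(rbind(s, a), rbind(s, b)))
  expect_identical(total_length(vapply(gone$series, function(x)
    nrow(x$points), integer(1))), 0L)
  expect_error(evolve(gone), "m = 0|no transitions")
})

test_that("noise injection flips exactly the rounded bit count, reproducibly", {
  f <- canned_fixtures()$toggle3$model
  tss <- time_series_set(list(time_series(simulate_model(f, c(1, 0, 0), 10)),
                              time_series(simulate_model(f, c(0, 1, 0), 10))))
  ni0 <- inject_noise(tss, 0, seed = 5)
  expect_equal(nrow(ni0$flips), 0L)
  expect_identical(ni0$tss$series[[1]]$points, tss$series[[1]]$points)

  ni <- inject_noise(tss, 0.05, seed = 5)
  expected <- floor(0.05 * 20 * 3 + 0.5)
  expect_equal(nrow(ni$flips), expected)
  ham <- sum(ni$tss$series[[1]]$points != tss$series[[1]]$points) +
    sum(ni$tss$series[[2]]$points != tss$series[[2]]$points)
  expect_equal(ham, expected)

  ni2 <- inject_noise(tss, 0.05, seed = 5)
  expect_identical(ni$flips, ni2$flips)
  ni3 <- inject_noise(tss, 0.05, seed = 6)
  expect_false(identical(ni$flips, ni3$flips))
  expect_error(inject_noise(tss, 1, seed = 1), "xi")
})

test_that("the validation protocol's bit count comes out to 212 flips", {
  # 202 time points on 21 variables at xi = 0.05
  set.seed(2)
  pts <- matrix(sample(c(0L, 1L), 202 * 21, replace = TRUE), ncol = 21)
  tss <- time_series_set(list(time_series(pts)))
  ni <- inject_noise(tss, 0.05, seed = 9)
  expect_equal(nrow(ni$flips), 212L)
})

test_that("quantile discretization thresholds per column with ties going down", {
  ts <- time_series(matrix(c(1, 2, 3, 4), ncol = 1), continuous = TRUE)
  d <- discretize_quantile(time_series_set(list(ts)), 2)
  expect_identical(unname(d$series[[1]]$points[, 1]), c(0L, 0L, 1L, 1L))

  ts3 <- time_series(matrix(c(0, 10, 20, 30, 40, 50), ncol = 1),
                     continuous = TRUE)
  d3 <- discretize_quantile(time_series_set(list(ts3)), 3)
  expect_identical(unname(d3$series[[1]]$points[, 1]),
                   c(0, 0, 1, 1, 2, 2))

  const <- time_series(matrix(rep(7, 4), ncol = 1), continuous = TRUE)
  expect_warning(dc <- discretize_quantile(time_series_set(list(const)), 2),
                 "constant")
  expect_true(all(dc$series[[1]]$points == 0L))
  expect_error(discretize_quantile(time_series_set(list(ts)), 1), "at least 2")
})

test_that("quantile discretization is invariant under monotone transforms", {
  set.seed(3)
  pts <- matrix(rnorm(30), ncol = 3)
  tss <- time_series_set(list(time_series(pts, continuous = TRUE)))
  tss_t <- time_series_set(list(time_series(exp(pts), continuous = TRUE)))
  expect_identical(discretize_quantile(tss, 2)$series[[1]]$points,
                   discretize_quantile(tss_t, 2)$series[[1]]$points)
})

test_that("interval discretization uses equal-width bins on [min, max]", {
  ts <- time_series(matrix(c(0, 1, 2, 3), ncol = 1), continuous = TRUE)
  d <- discretize_interval(time_series_set(list(ts)), 2)
  expect_identical(unname(d$series[[1]]$points[, 1]), c(0L, 0L, 1L, 1L))
  ts2 <- time_series(matrix(c(0, 0.4, 2), ncol = 1), continuous = TRUE)
  d2 <- discretize_interval(time_series_set(list(ts2)), 2)
  expect_identical(unname(d2$series[[1]]$points[, 1]), c(0L, 0L, 1L))
  const <- time_series(matrix(rep(1, 3), ncol = 1), continuous = TRUE)
  expect_warning(dc <- discretize_interval(time_series_set(list(const)), 2),
                 "constant")
  expect_true(all(dc$series[[1]]$points == 0L))
})

test_that("time-series TSV + manifest round-trips byte-identically", {
  f <- canned_fixtures()$irma5$model
  wt <- time_series(simulate_model(f, c(1, 0, 0, 1, 0), 6), label = "wt1")
  ko <- time_series(simulate_model(knockout_model(f, 3), c(1, 1, 0, 0, 1), 5),
                    kind = "knockout", ko_target = 3, label = "ko_SWI5")
  cases <- list(
    wildtype_only = time_series_set(list(wt), xi = 0, variables = f$variables),
    mixed = time_series_set(list(wt, ko), xi = 0.05,
                            variables = f$variables),
    fragments = break_inconsistencies(time_series_set(
      list(time_series(rbind(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
                             c(0, 0, 0, 0, 0), c(0, 1, 0, 0, 0)))),
      variables = f$variables)))
  for (nm in names(cases)) {
    p1 <- withr::local_tempfile(fileext = ".tsv")
    p2 <- withr::local_tempfile(fileext = ".tsv")
    write_timeseries(cases[[nm]], p1)
    back <- read_timeseries(p1)
    expect_equal(back$xi, cases[[nm]]$xi)
    write_timeseries(back, p2)
    expect_identical(readLines(p1), readLines(p2))
    for (s in seq_along(back$series))
      expect_identical(unname(back$series[[s]]$points),
                       unname(cases[[nm]]$series[[s]]$points))
  }
})

test_that("prior matrices round-trip and validate their entries", {
  rho <- matrix(runif(9), 3, 3)
  pr <- prior_matrix(rho, "bio")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prior(pr, path)
  back <- read_prior(path)
  expect_equal(unname(back$rho), unname(rho), tolerance = 1e-12)
  expect_error(prior_matrix(matrix(2, 2, 2)), "\\[0, 1\\]")
  expect_error(prior_matrix(matrix(0.5, 2, 3)), "square")
})
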