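# deterministic fan panel: exponential trends with distinct slopes, pairwise
# divergent by construction
fan_panel <- function(slopes, T = 30, base = 5) {
  v <- t(vapply(seq_along(slopes),
                function(i) base * (1 + 0.5 * i) * exp(slopes[i] * (0:(T - 1))),
                numeric(T)))
  panel(v, sprintf("fan%02d", seq_along(slopes)), 1990 + 0:(T - 1))
}

test_that("units are ordered by final-window mean, ties lexicographic", {
  T <- 20
  v <- rbind(rep(30, T), rep(21, T), rep(2, T))
  p <- panel(v, c("high", "mid", "low"), 2000 + 1:T)
  expect_identical(order_units(p), c("high", "mid", "low"))
  p_tie <- panel(matrix(rep(c(4, 4, 1), each = T), 3, T, byrow = TRUE),
                 c("bb", "aa", "cc"), 2000 + 1:T)
  expect_identical(order_units(p_tie), c("aa", "bb", "cc"))
  # random panel against an independent sort
  p <- random_panel(15, 20, seed = 77)
  x <- t(apply(log(p$values), 1, hp_smooth, lambda = 400))
  m <- rowMeans(x[, 11:20])
  expect_identical(order_units(p), p$unit_ids[order(-m, p$unit_ids)])
})

test_that("two identical units form a core with the perfect-convergence sentinel", {
  v <- matrix(rep(exp(seq(1, 2, length.out = 15)), each = 2), 2, 15)
  p <- panel(v, c("a", "b"), 2001:2015)
  core <- find_core_group(p)
  expect_setequal(core, c("a", "b"))
  res <- logt_regression(relative_transition(p))
  expect_identical(res$t_stat, Inf)
})

test_that("a pairwise-divergent fan yields an empty core and all-divergent partition", {
  p <- fan_panel(c(0.02, 0.05, 0.09, 0.14))
  expect_identical(find_core_group(p), character(0))
  part <- form_clubs(p)
  expect_length(part$clubs, 0)
  expect_setequal(part$divergent, p$unit_ids)
})

test_that("the sieve admits a twin of a core member and rejects a diverging trend", {
  set.seed(30)
  sim <- simulate_panel(sim_config(n_units_per_club = 10, club_deltas = 1.5,
                                   n_divergent = 0, seed = 30))
  base <- sim$panel
  twin <- base$values[1, , drop = FALSE]
  rownames(twin) <- "zz_twin"
  # starts at the club's level and drifts away at 8%/yr on top of the trend
  diverger <- matrix(15 * exp(0.08 * (0:29)), 1, 30, dimnames = list("zz_div", NULL))
  p <- panel(rbind(base$values, twin, diverger),
             c(base$unit_ids, "zz_twin", "zz_div"), base$years)
  core <- base$unit_ids
  sv <- sieve_members(p, core, c("zz_twin", "zz_div"))
  expect_true("zz_twin" %in% sv$club)
  expect_false("zz_div" %in% sv$club)
  expect_true(sv$result$converged)
})

test_that("a fully convergent panel returns a single all-units club", {
  sim <- simulate_panel(sim_config(n_units_per_club = 20, club_deltas = 1,
                                   seed = 4))
  part <- form_clubs(sim$panel)
  expect_length(part$clubs, 1)
  expect_setequal(part$clubs[[1]], sim$panel$unit_ids)
  expect_length(part$divergent, 0)
})

test_that("partitions are disjoint, exhaustive, and clubs pass their own test", {
  for (seed in 1:5) {
    sim <- simulate_panel(sim_config(n_units_per_club = c(15, 15),
                                     club_deltas = c(2, 1), n_divergent = 2,
                                     seed = 100 + seed))
    part <- form_clubs(sim$panel)
    all_ids <- c(unlist(part$clubs, use.names = FALSE), part$divergent)
    expect_setequal(all_ids, sim$panel$unit_ids)
    expect_identical(anyDuplicated(all_ids), 0L)
    for (r in part$club_results) expect_gte(r$t_stat, -1.65)
    expect_true(all(lengths(part$clubs) >= 2))
  }
})

test_that("clustering is deterministic: identical inputs give identical partitions", {
  sim <- simulate_panel(sim_config(n_units_per_club = c(20, 20),
                                   club_deltas = c(2, 1), n_divergent = 2,
                                   seed = 55))
  expect_identical(form_clubs(sim$panel), form_clubs(sim$panel))
})

test_that("re-clustering a single club's members returns that club intact", {
  sim <- simulate_panel(sim_config(n_units_per_club = c(20, 20),
                                   club_deltas = c(2, 1), seed = 61))
  part <- form_clubs(sim$panel)
  expect_length(part$clubs, 2)
  sub <- subset_panel(sim$panel, part$clubs[["Club 1"]])
  part2 <- form_clubs(sub)
  expect_length(part2$clubs, 1)
  expect_setequal(part2$clubs[[1]], part$clubs[["Club 1"]])
})

test_that("club-level statistics equal the standalone pipeline on the subpanel", {
  sim <- simulate_panel(sim_config(n_units_per_club = c(15, 15),
                                   club_deltas = c(2, 1), seed = 13))
  part <- form_clubs(sim$panel)
  for (nm in names(part$clubs)) {
    sub <- subset_panel(sim$panel, part$clubs[[nm]])
    standalone <- logt_regression(relative_transition(sub))
    expect_equal(part$club_results[[nm]]$t_stat, standalone$t_stat,
                 tolerance = 1e-6)
  }
})

test_that("an artificially split club is merged back into one", {
  sim <- simulate_panel(sim_config(n_units_per_club = 30, club_deltas = 1.5,
                                   seed = 88))
  p <- sim$panel
  halves <- list(p$unit_ids[1:15], p$unit_ids[16:30])
  results <- lapply(halves, function(ids)
    logt_regression(relative_transition(subset_panel(p, ids))))
  fake <- structure(list(clubs = setNames(halves, c("Club 1", "Club 2")),
                         divergent = character(0),
                         club_results = setNames(results, c("Club 1", "Club 2")),
                         merge_log = data.frame(),
                         config = club_config()),
                    class = "club_partition")
  merged <- merge_clubs(fake, p)
  expect_length(merged$clubs, 1)
  expect_setequal(merged$clubs[[1]], p$unit_ids)
  expect_true(any(merged$merge_log$merged))
})

test_that("well-separated clubs refuse to merge and the attempt is logged", {
  sim <- simulate_panel(sim_config(n_units_per_club = c(20, 20),
                                   club_deltas = c(2, 1), seed = 90))
  part <- form_clubs(sim$panel)
  expect_length(part$clubs, 2)
  expect_true(nrow(part$merge_log) >= 1)
  expect_false(any(part$merge_log$merged))
  expect_true(all(part$merge_log$t_stat[!part$merge_log$merged] < -1.65))
  # single-club partition has no pairs to merge
  single <- form_clubs(subset_panel(sim$panel, part$clubs[["Club 1"]]))
  expect_identical(merge_clubs(single, subset_panel(sim$panel, part$clubs[["Club 1"]]))$clubs,
                   single$clubs)
})

test_that("modest two-club panels with fans are recovered across seeds", {
  ok_clubs <- ok_fans <- logical(30)
  for (s in 1:30) {
    sim <- simulate_panel(sim_config(n_units_per_club = c(25, 25),
                                     club_deltas = c(2, 1), n_divergent = 3,
                                     seed = 700 + s))
    part <- form_clubs(sim$panel)
    lab <- partition_labels(part, sim$truth$labels$unit_id)
    tru <- truth_labels(sim$truth)
    fans <- names(tru)[tru == 0]
    ok_fans[s] <- all(fans %in% part$divergent)
    # Club 1 = high-density club by convention on both sides, so labels align
    ok_clubs[s] <- length(part$clubs) == 2 &&
      mean(lab[tru != 0] == tru[tru != 0]) >= 0.9
  }
  expect_gte(mean(ok_clubs), 0.9)
  expect_gte(mean(ok_fans), 0.9)
})

test_that("membership CSV lists every unit exactly once with its club label", {
  sim <- simulate_panel(sim_config(n_units_per_club = c(15, 15),
                                   club_deltas = c(2, 1), n_divergent = 2,
                                   seed = 17))
  part <- form_clubs(sim$panel)
  f <- withr::local_tempfile(fileext = ".csv")
  write_membership(part, f)
  df <- read.csv(f)
  expect_setequal(df$location, sim$panel$unit_ids)
  expect_identical(anyDuplicated(df$location), 0L)
  expect_true(all(df$club %in% c(names(part$clubs), "Divergent")))
})
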