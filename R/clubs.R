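# Endogenous club clustering. Four stages on the transformed panel x
# (log + HP-smoothed by default):
#   1. order units by the mean of the final window of x, decreasing;
#   2. core search: scan prefixes of the ordering, keep the prefix maximizing
#      the log-t statistic among those passing the test; drop the top unit and
#      restart when even the top pair fails;
#   3. sieve: admit each remaining unit whose one-unit-augmented log-t
#      statistic exceeds c*; if the assembled club then fails its own test,
#      raise c* and sieve again;
#   4. remove the club, recurse on the remainder; leftovers that form no club
#      are divergent; finally adjacent clubs are merged while their union
#      passes the log-t test, and clubs are renumbered by final density.
#
# Every subset log-t statistic only needs the column sums S_t and sums of
# squares Q_t of the subset's rows of x, because
#   H_t = n Q_t / S_t^2 - 1
# when h is formed against the subset mean. Prefix scans and one-unit
# augmentations therefore update S and Q incrementally.

#' Clustering configuration
#'
#' Collects every knob of the club-clustering procedure so a whole analysis is
#' reproducible from its configuration echo.
#'
#' @param transform `"log"` (default) or `"levels"`: scale on which transition
#'   paths are computed.
#' @param hp_lambda Hodrick-Prescott smoothing weight applied per unit before
#'   the transition paths (`NULL` disables; default 400, the annual-data
#'   convention).
#' @param trim Trim fraction r of the log-t regression (default 0.3).
#' @param crit One-sided critical value of the convergence test (default -1.65).
#' @param bandwidth Newey-West lag truncation (`NULL` = automatic rule).
#' @param order_fraction Fraction of final periods averaged when ordering
#'   units (default 0.5; robust to terminal-year noise).
#' @param cstar Initial sieve criterion c* (default 0, the conservative choice
#'   for short panels).
#' @param cstar_step Increment by which c* is raised when an assembled club
#'   fails its own log-t test (default 0.05).
#' @return A list of class `club_config`.
#' @export
club_config <- function(transform = "log", hp_lambda = 400, trim = 0.3,
                        crit = -1.65, bandwidth = NULL, order_fraction = 0.5,
                        cstar = 0, cstar_step = 0.05) {
  transform <- match.arg(transform, c("log", "levels"))
  stopifnot(trim > 0, trim < 0.5, order_fraction > 0, order_fraction <= 1,
            cstar_step > 0)
  structure(list(transform = transform, hp_lambda = hp_lambda, trim = trim,
                 crit = crit, bandwidth = bandwidth,
                 order_fraction = order_fraction, cstar = cstar,
                 cstar_step = cstar_step),
            class = "club_config")
}

# log-t result from subset column sums/sums of squares of x. A subset whose
# transformed cross-sectional mean is not positive at some t (possible on the
# log scale when densities sit below 1 per 10,000) has no well-defined
# transition paths; inside the clustering search such a subset simply carries
# no evidence of convergence, so it is scored as a rejection (t = -Inf)
# rather than an error, keeping the search total and deterministic.
.logt_from_SQ <- function(S, Q, n, cfg) {
  if (any(S <= 0)) {
    return(.logt_result(NA_real_, NA_real_, NA_real_, -Inf, cfg$trim, n,
                        length(S), length(S) - floor(cfg$trim * length(S)),
                        NA_integer_, cfg$crit))
  }
  H <- .snap_H(pmax(n * Q / (S * S) - 1, 0))
  logt_regression(H, trim_fraction = cfg$trim, bandwidth = cfg$bandwidth,
                  crit = cfg$crit, n_units = n)
}

.logt_subset <- function(x, ids, cfg) {
  xs <- x[ids, , drop = FALSE]
  .logt_from_SQ(colSums(xs), colSums(xs * xs), length(ids), cfg)
}

# decreasing mean over the final window, ties broken lexicographically
.order_ids <- function(x, ids, order_fraction) {
  Tn <- ncol(x)
  win <- (Tn - floor(order_fraction * Tn) + 1):Tn
  m <- rowMeans(x[ids, win, drop = FALSE])
  ids[order(-m, ids, method = "radix")]
}

.find_core <- function(x, ordered, cfg) {
  s <- 1
  n_all <- length(ordered)
  while (n_all - s + 1 >= 2) {
    avail <- ordered[s:n_all]
    S <- x[avail[1], ]
    Q <- S * S
    best_k <- 0L
    best_t <- -Inf
    for (k in 2:length(avail)) {
      xi <- x[avail[k], ]
      S <- S + xi
      Q <- Q + xi * xi
      t_k <- .logt_from_SQ(S, Q, k, cfg)$t_stat
      if (!(t_k < cfg$crit)) {
        if (t_k > best_t) { best_t <- t_k; best_k <- k }
      } else break   # statistic fell below the critical value: stop the scan
    }
    if (best_k > 0) return(avail[seq_len(best_k)])
    s <- s + 1       # even the top pair diverges: drop the top unit
  }
  character(0)
}

.sieve <- function(x, core, candidates, cfg, cstar = cfg$cstar) {
  xc <- x[core, , drop = FALSE]
  Sc <- colSums(xc)
  Qc <- colSums(xc * xc)
  nc <- length(core)
  repeat {
    keep <- character(0)
    for (cand in candidates) {
      xi <- x[cand, ]
      t_aug <- .logt_from_SQ(Sc + xi, Qc + xi * xi, nc + 1, cfg)$t_stat
      if (t_aug > cstar) keep <- c(keep, cand)
    }
    club <- c(core, keep)
    res <- .logt_subset(x, club, cfg)
    if (!(res$t_stat < cfg$crit))
      return(list(club = club, result = res, cstar = cstar))
    if (length(keep) == 0) {
      # no candidate survives even this c*: the club is the core itself,
      # which passed the test during the core search
      return(list(club = core, result = .logt_subset(x, core, cfg),
                  cstar = cstar))
    }
    cstar <- cstar + cfg$cstar_step
  }
}

.new_partition <- function(clubs, results, divergent, merge_log, cfg) {
  structure(list(clubs = clubs, divergent = sort(divergent, method = "radix"),
                 club_results = results, merge_log = merge_log, config = cfg),
            class = "club_partition")
}

.empty_merge_log <- function() {
  data.frame(club_a = integer(0), club_b = integer(0), t_stat = numeric(0),
             merged = logical(0))
}

.merge_pass <- function(x, clubs, results, cfg) {
  log <- .empty_merge_log()
  i <- 1
  while (i < length(clubs)) {
    union_ids <- c(clubs[[i]], clubs[[i + 1]])
    res <- .logt_subset(x, union_ids, cfg)
    merged <- !(res$t_stat < cfg$crit)
    log <- rbind(log, data.frame(club_a = i, club_b = i + 1,
                                 t_stat = res$t_stat, merged = merged))
    if (merged) {
      clubs[[i]] <- union_ids
      results[[i]] <- res
      clubs[[i + 1]] <- NULL
      results[[i + 1]] <- NULL
      i <- 1                      # restart the scan after any merge
    } else {
      i <- i + 1
    }
  }
  list(clubs = clubs, results = results, log = log)
}

# renumber clubs by decreasing mean raw density over the final window;
# Club 1 = highest density
.rank_clubs <- function(p, clubs, results, order_fraction) {
  if (!length(clubs)) return(list(clubs = clubs, results = results))
  Tn <- length(p$years)
  win <- (Tn - floor(order_fraction * Tn) + 1):Tn
  m <- vapply(clubs, function(ids) mean(p$values[ids, win]), numeric(1))
  ord <- order(-m, vapply(clubs, function(ids) min(ids), character(1)),
               method = "radix")
  clubs <- lapply(clubs[ord], function(ids) sort(ids, method = "radix"))
  results <- results[ord]
  names(clubs) <- paste("Club", seq_along(clubs))
  names(results) <- names(clubs)
  list(clubs = clubs, results = results)
}

#' Order units for the club search
#'
#' Sorts units in decreasing order of the mean of their transformed (log,
#' smoothed) series over the final window of periods, ties broken
#' lexicographically by unit id.
#'
#' @param p A `conv_panel`.
#' @param config A [club_config()].
#' @return Character vector of unit ids, most-advanced unit first.
#' @export
order_units <- function(p, config = club_config()) {
  x <- .transform_values(p, config$transform, config$hp_lambda)
  .order_ids(x, p$unit_ids, config$order_fraction)
}

#' Find the core group seeding a club
#'
#' Scans prefixes of the unit ordering with the log-t test: the core is the
#' prefix maximizing the t-statistic among prefixes that pass the test. When
#' no prefix starting from the current top passes, the top unit is set aside
#' and the search restarts on the remainder. An empty set (no pair of units
#' converges) is a valid outcome meaning "all divergent".
#'
#' @param p A `conv_panel`.
#' @param ordered_units Optional explicit ordering; defaults to
#'   [order_units()].
#' @param config A [club_config()].
#' @return Character vector of core unit ids (possibly empty).
#' @export
find_core_group <- function(p, ordered_units = NULL, config = club_config()) {
  x <- .transform_values(p, config$transform, config$hp_lambda)
  if (is.null(ordered_units))
    ordered_units <- .order_ids(x, p$unit_ids, config$order_fraction)
  .find_core(x, ordered_units, config)
}

#' Sieve candidate members into a club
#'
#' Each candidate in turn is provisionally added to the core; it is kept when
#' the one-unit-augmented log-t statistic exceeds the sieve criterion `c_star`.
#' If the assembled club then fails its own log-t test, `c_star` is raised by
#' `config$cstar_step` and the sieve repeats; in the limit the club shrinks
#' back to the core, which passed by construction.
#'
#' @param p A `conv_panel`.
#' @param core Non-empty character vector of core unit ids.
#' @param candidates Character vector of candidate unit ids, in search order.
#' @param config A [club_config()].
#' @param c_star Initial sieve criterion (defaults to `config$cstar`).
#' @return List with `club` (unit ids), `result` (the club's `logt_result`)
#'   and `cstar` (the criterion finally used).
#' @export
sieve_members <- function(p, core, candidates, config = club_config(),
                          c_star = config$cstar) {
  if (!length(core)) .err("core group is empty", "logtclub_domain_error")
  x <- .transform_values(p, config$transform, config$hp_lambda)
  .sieve(x, core, candidates, config, cstar = c_star)
}

#' Identify convergence clubs
#'
#' Runs the full endogenous clustering: full-sample log-t first (if
#' convergence is not rejected a single all-units club is returned), then
#' repeated order / core / sieve rounds on the shrinking remainder, divergent
#' assignment of leftovers, adjacent-club merging, and renumbering so Club 1
#' has the highest final-window density.
#'
#' @param p A `conv_panel`.
#' @param config A [club_config()].
#' @return An object of class `club_partition`: `clubs` (named list of unit-id
#'   vectors), `divergent` (unit ids in no club), `club_results` (per-club
#'   `logt_result`), `merge_log` (every attempted merge with its t-statistic)
#'   and the `config` echo. Clubs always have at least two members; every
#'   reported club passes the log-t test.
#' @export
form_clubs <- function(p, config = club_config()) {
  .check_inference_dims(p)
  x <- .transform_values(p, config$transform, config$hp_lambda)
  full <- .logt_subset(x, p$unit_ids, config)
  if (full$converged) {
    ranked <- .rank_clubs(p, list(p$unit_ids), list(full), config$order_fraction)
    return(.new_partition(ranked$clubs, ranked$results, character(0),
                          .empty_merge_log(), config))
  }
  clubs <- list()
  results <- list()
  divergent <- character(0)
  remaining <- p$unit_ids
  while (length(remaining) >= 2) {
    res_all <- .logt_subset(x, remaining, config)
    if (!(res_all$t_stat < config$crit)) {
      clubs <- c(clubs, list(remaining))
      results <- c(results, list(res_all))
      remaining <- character(0)
      break
    }
    ordered <- .order_ids(x, remaining, config$order_fraction)
    core <- .find_core(x, ordered, config)
    if (!length(core)) break                   # nothing converges: all divergent
    sv <- .sieve(x, core, setdiff(ordered, core), config)
    clubs <- c(clubs, list(sv$club))
    results <- c(results, list(sv$result))
    remaining <- setdiff(remaining, sv$club)
  }
  divergent <- c(divergent, remaining)
  mp <- .merge_pass(x, clubs, results, config)
  ranked <- .rank_clubs(p, mp$clubs, mp$results, config$order_fraction)
  .new_partition(ranked$clubs, ranked$results, divergent, mp$log, config)
}

#' Merge adjacent clubs that jointly converge
#'
#' For each adjacent pair of clubs (by rank) the log-t test is run on their
#' union; a passing pair is merged and the scan restarts, until no adjacent
#' pair merges. Every attempt is recorded in the merge log. Clubs surviving
#' this step are "strong" clubs.
#'
#' @param partition A `club_partition`.
#' @param p The `conv_panel` the partition was formed on.
#' @param config A [club_config()] (defaults to the partition's own).
#' @return A `club_partition` with merged, re-ranked clubs and an appended
#'   merge log.
#' @export
merge_clubs <- function(partition, p, config = partition$config) {
  x <- .transform_values(p, config$transform, config$hp_lambda)
  mp <- .merge_pass(x, unname(partition$clubs), unname(partition$club_results),
                    config)
  ranked <- .rank_clubs(p, mp$clubs, mp$results, config$order_fraction)
  .new_partition(ranked$clubs, ranked$results, partition$divergent,
                 rbind(partition$merge_log, mp$log), config)
}

#' @export
print.club_partition <- function(x, ...) {
  cat(sprintf("Club partition: %d club(s), %d divergent unit(s)\n",
              length(x$clubs), length(x$divergent)))
  for (nm in names(x$clubs)) {
    r <- x$club_results[[nm]]
    cat(sprintf("  %s: %3d members, beta_hat = %s, t = %s\n", nm,
                length(x$clubs[[nm]]),
                if (is.finite(r$t_stat)) sprintf("%.3f", r$beta_hat) else "--",
                if (is.finite(r$t_stat)) sprintf("%.3f", r$t_stat) else "+Inf"))
  }
  invisible(x)
}

#' Write club membership as a two-column CSV
#'
#' Emits `location, club` rows (club labels `"Club 1"`, ..., or
#' `"Divergent"`), the layout of a published membership table.
#'
#' @param partition A `club_partition`.
#' @param file Destination path.
#' @return The file path, invisibly.
#' @export
write_membership <- function(partition, file) {
  rows <- do.call(rbind, c(
    lapply(names(partition$clubs), function(nm)
      data.frame(location = partition$clubs[[nm]], club = nm,
                 stringsAsFactors = FALSE)),
    if (length(partition$divergent))
      list(data.frame(location = partition$divergent, club = "Divergent",
                      stringsAsFactors = FALSE))
  ))
  rows <- rows[order(rows$location, method = "radix"), , drop = FALSE]
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

# partition -> plain list for the JSON report
.partition_as_list <- function(x) {
  list(clubs = lapply(unname(x$clubs), as.list),
       club_results = lapply(unname(x$club_results), .logt_as_list),
       divergent = as.list(x$divergent),
       merge_log = if (nrow(x$merge_log)) x$merge_log else NULL)
}
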