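#' Glicko-1 configuration
#'
#' Classic Glicko: each individual carries a rating and a rating deviation
#' (RD). Ratings start at 2200 points (the convention of the rating software
#' used throughout mouse dominance work), RD starts at its ceiling of 300
#' points, shrinks with every contest and grows again during idle rating
#' periods at rate `c` per square-root period. The default `c` is calibrated
#' so that an RD of `rd_ref` returns to the ceiling after
#' `idle_return_periods` idle periods:
#' `c = sqrt((rd_max^2 - rd_ref^2) / idle_return_periods)`.
#'
#' @param init_rating initial rating, default 2200.
#' @param init_rd initial rating deviation, default 300.
#' @param rd_max RD ceiling, default 300.
#' @param c uncertainty growth constant; if `NULL`, calibrated as above.
#' @param rd_ref,idle_return_periods calibration anchors for `c`
#'   (defaults 50 and 100).
#' @param period `"day"` (one rating period per observation day, default) or
#'   `"event"` (each contest is its own period, a sequential sensitivity
#'   mode).
#' @return An object of class `glicko_config`.
#' @export
glicko_config <- function(init_rating = 2200, init_rd = 300, rd_max = 300,
                          c = NULL, rd_ref = 50, idle_return_periods = 100,
                          period = c("day", "event")) {
  period <- match.arg(period)
  stopifnot(init_rd > 0, init_rd <= rd_max)
  if (is.null(c)) c <- sqrt((rd_max^2 - rd_ref^2) / idle_return_periods)
  stopifnot(c >= 0)
  structure(list(init_rating = init_rating, init_rd = init_rd,
                 rd_max = rd_max, c = c, q = log(10) / 400, period = period),
            class = "glicko_config")
}

#' Glicko attenuation factor g(RD)
#'
#' Down-weights opponents whose ratings are uncertain:
#' `g = 1 / sqrt(1 + 3 q^2 RD^2 / pi^2)` with `q = ln(10)/400`. Tends to 1 as
#' RD tends to 0 and decreases strictly in RD.
#'
#' @param rd rating deviation(s), must be positive.
#' @param q Glicko scale constant.
#' @return attenuation in `(0, 1]`.
#' @export
glicko_g <- function(rd, q = log(10) / 400) {
  if (any(rd <= 0)) stop("rd must be positive", call. = FALSE)
  1 / sqrt(1 + 3 * q^2 * rd^2 / pi^2)
}

#' Glicko expected score
#'
#' Probability that a player rated `r_i` beats an opponent rated `r_j` whose
#' uncertainty is `rd_j`:
#' `E = 1 / (1 + 10^(-g(rd_j) (r_i - r_j) / 400))`. Beating a much
#' lower-rated opponent is near-certain and so earns few points.
#'
#' @param r_i player rating.
#' @param r_j opponent rating.
#' @param rd_j opponent rating deviation.
#' @param q Glicko scale constant.
#' @return expected score in `(0, 1)`.
#' @export
glicko_expected <- function(r_i, r_j, rd_j, q = log(10) / 400) {
  1 / (1 + 10^(-glicko_g(rd_j, q) * (r_i - r_j) / 400))
}

new_glicko_states <- function(roster, config) {
  data.frame(mouse = as.character(roster),
             rating = config$init_rating, rd = config$init_rd,
             n_contests = 0L, stringsAsFactors = FALSE)
}

#' One Glicko-1 rating-period update
#'
#' Applies the simultaneous Glicko-1 update to all individuals for one rating
#' period. Opponent ratings and RDs are the pre-period values. For a player
#' with period opponents `j`, outcomes `s_j` in `{0, 1}`:
#' `d^2 = 1 / (q^2 sum g(RD_j)^2 E_j (1 - E_j))`,
#' `r' = r + q / (1/RD^2 + 1/d^2) * sum g(RD_j) (s_j - E_j)`,
#' `RD' = sqrt(1 / (1/RD^2 + 1/d^2))`.
#' Individuals with no contests keep their rating. RD inflation for idle time
#' (`RD <- min(sqrt(RD^2 + c^2 t), rd_max)`) is applied before the update.
#'
#' @param states data.frame with columns `mouse,rating,rd,n_contests`.
#' @param contests contests in this period (columns `winner`, `loser`).
#' @param config [glicko_config()].
#' @param t_idle periods elapsed since the previous update (default 1).
#' @return updated states data.frame.
#' @export
glicko_update_period <- function(states, contests, config = glicko_config(),
                                 t_idle = 1) {
  q <- config$q
  parts <- c(contests$winner, contests$loser)
  unknown <- setdiff(unique(parts), states$mouse)
  if (length(unknown))
    stop("contest participant(s) without a rating state: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # pre-period RD inflation, capped at the ceiling
  states$rd <- pmin(sqrt(states$rd^2 + config$c^2 * t_idle), config$rd_max)
  if (!nrow(contests)) return(states)
  r0 <- stats::setNames(states$rating, states$mouse)
  rd0 <- stats::setNames(states$rd, states$mouse)
  for (i in seq_len(nrow(states))) {
    m <- states$mouse[i]
    w <- contests$winner == m
    l <- contests$loser == m
    opp <- c(contests$loser[w], contests$winner[l])
    if (!length(opp)) next
    s <- c(rep(1, sum(w)), rep(0, sum(l)))
    gj <- glicko_g(rd0[opp], q)
    Ej <- glicko_expected(r0[m], r0[opp], rd0[opp], q)
    d2 <- 1 / (q^2 * sum(gj^2 * Ej * (1 - Ej)))
    denom <- 1 / rd0[m]^2 + 1 / d2
    states$rating[i] <- r0[m] + q / denom * sum(gj * (s - Ej))
    states$rd[i] <- sqrt(1 / denom)
    states$n_contests[i] <- states$n_contests[i] + length(opp)
  }
  states
}

#' Rate a time-ordered contest stream
#'
#' Runs the Glicko-1 engine over a full contest stream, one rating period per
#' observation day by default (`period = "event"` treats each contest as its
#' own period). Idle days between observed days inflate RD. Returns final
#' states plus each mouse's net change in rating from the 2200 baseline; a
#' mouse with no contests has net change exactly 0.
#'
#' @param contests data.frame with columns `day,t,winner,loser`, sorted by
#'   `(day, t)`.
#' @param roster character vector of all mouse ids to rate.
#' @param config [glicko_config()].
#' @return An object of class `glicko_history`: list with `states` (final
#'   data.frame incl. `net_change`), `snapshots` (per-period states) and
#'   `config`.
#' @export
glicko_rate <- function(contests, roster, config = glicko_config()) {
  if (nrow(contests)) {
    key <- contests$day * 1e7 + contests$t
    if (is.unsorted(key))
      stop("contests must be sorted by (day, t)", call. = FALSE)
  }
  states <- new_glicko_states(roster, config)
  snapshots <- list()
  if (nrow(contests)) {
    if (config$period == "day") {
      days <- sort(unique(contests$day))
      prev <- days[1]
      for (d in days) {
        batch <- contests[contests$day == d, , drop = FALSE]
        states <- glicko_update_period(states, batch, config,
                                       t_idle = max(d - prev, 1))
        snapshots[[as.character(d)]] <- states
        prev <- d
      }
    } else {
      for (k in seq_len(nrow(contests))) {
        states <- glicko_update_period(states, contests[k, , drop = FALSE],
                                       config, t_idle = 1)
      }
      snapshots[["final"]] <- states
    }
  }
  states$net_change <- states$rating - config$init_rating
  states$net_change[states$n_contests == 0] <- 0
  structure(list(states = states, snapshots = snapshots, config = config),
            class = "glicko_history")
}

#' @export
print.glicko_history <- function(x, ...) {
  cat("<glicko_history> ", nrow(x$states), " mice, period = ",
      x$config$period, "\n", sep = "")
  print(x$states[order(-x$states$net_change), ], row.names = FALSE)
  invisible(x)
}

#' Aggression- and submission-based Glicko net changes
#'
#' Computes both rating variants for one cage: Glicko-Agg from aggression
#' contests (winner = attacker) and Glicko-Sub from submission events
#' (winner = mouse submitted to). The mouse receiving the most submission ends
#' up with the top Glicko-Sub net change and is the cage's dominant under the
#' submission criterion.
#'
#' @param events validated events data.frame for one cage.
#' @param roster cage roster.
#' @param config [glicko_config()].
#' @return list with elements `agg` and `sub`, each a `glicko_history`, and
#'   `net` — a data.frame `mouse, glicko_agg_net, glicko_sub_net`.
#' @export
glicko_variants <- function(events, roster, config = glicko_config()) {
  agg <- glicko_rate(contests_from_aggression(events), roster, config)
  sub <- glicko_rate(contests_from_submission(events), roster, config)
  net <- data.frame(mouse = agg$states$mouse,
                    glicko_agg_net = agg$states$net_change,
                    glicko_sub_net = sub$states$net_change,
                    stringsAsFactors = FALSE)
  list(agg = agg, sub = sub, net = net)
}
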