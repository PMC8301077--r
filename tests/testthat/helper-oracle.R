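# Independent straight-line transcription of the Glicko-1 one-period update,
# used as the oracle against the engine. Deliberately naive: per-mouse loops,
# no shared code with the package internals.
oracle_glicko_period <- function(ratings, rds, contests) {
  q <- log(10) / 400
  g <- function(rd) 1 / sqrt(1 + 3 * q^2 * rd^2 / pi^2)
  E <- function(r, rj, rdj) 1 / (1 + 10^(-g(rdj) * (r - rj) / 400))
  out_r <- ratings
  out_rd <- rds
  for (m in names(ratings)) {
    opp <- character(0)
    s <- numeric(0)
    for (k in seq_len(nrow(contests))) {
      if (contests$winner[k] == m) {
        opp <- c(opp, contests$loser[k]); s <- c(s, 1)
      } else if (contests$loser[k] == m) {
        opp <- c(opp, contests$winner[k]); s <- c(s, 0)
      }
    }
    if (!length(opp)) next
    gs <- vapply(opp, function(o) g(rds[[o]]), numeric(1))
    Es <- vapply(opp, function(o) E(ratings[[m]], ratings[[o]], rds[[o]]),
                 numeric(1))
    d2 <- 1 / (q^2 * sum(gs^2 * Es * (1 - Es)))
    denom <- 1 / rds[[m]]^2 + 1 / d2
    out_r[[m]] <- ratings[[m]] + q / denom * sum(gs * (s - Es))
    out_rd[[m]] <- sqrt(1 / denom)
  }
  list(rating = out_r, rd = out_rd)
}

# minimal event-table builder for unit tests
make_events <- function(day, t, actor, recipient, category) {
  data.frame(day = rep(day, length.out = length(category)),
             t = rep(t, length.out = length(category)),
             actor = actor, recipient = recipient,
             category = category,
             subtype = rep(NA_character_, length(category)),
             stringsAsFactors = FALSE)
}

# small contest table
make_contests <- function(winner, loser, day = 2, t = seq_along(winner)) {
  data.frame(day = rep(day, length.out = length(winner)),
             t = rep(t, length.out = length(winner)),
             winner = winner, loser = loser,
             source = rep("aggression", length(winner)),
             stringsAsFactors = FALSE)
}

# a lightweight sim config for tests that only need event streams
fast_sim_config <- function(...) {
  defaults <- list(investigation_rate = 0.5, allogroom_rate = 0.2,
                   include_scans = FALSE)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
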