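test_that("attenuation and expected score match the closed forms", {
  expect_equal(glicko_g(1e-9), 1, tolerance = 1e-6)
  expect_equal(glicko_g(300), 0.724235, tolerance = 1e-6)
  rds <- seq(10, 300, by = 10)
  expect_true(all(diff(glicko_g(rds)) < 0))
  expect_error(glicko_g(0), "positive")

  expect_equal(glicko_expected(2200, 2200, 300), 0.5)
  expect_gt(glicko_expected(5000, 2200, 300), 0.999)
  expect_equal(glicko_expected(2300, 2100, 150) +
                 glicko_expected(2100, 2300, 150), 1)
})

test_that("a single contest between fresh mice gives the derived update", {
  states <- data.frame(mouse = c("A", "B"), rating = 2200, rd = 300,
                       n_contests = 0L)
  out <- glicko_update_period(states, make_contests("A", "B"),
                              glicko_config(c = 0))
  expect_equal(out$rating[out$mouse == "A"], 2334.8650, tolerance = 1e-4)
  expect_equal(out$rating[out$mouse == "B"], 2065.1350, tolerance = 1e-4)
  expect_equal(out$rd, c(254.3589, 254.3589), tolerance = 1e-4)
  # winner's gain equals loser's loss from identical starting states
  expect_equal(out$rating[1] - 2200, 2200 - out$rating[2])
  expect_error(glicko_update_period(states, make_contests("A", "Z"),
                                    glicko_config()), "Z")
})

test_that("one-period engine output matches the oracle transcription", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    ids <- paste0("m", seq_len(n))
    ratings <- setNames(rnorm(n, 2200, 150), ids)
    rds <- setNames(runif(n, 60, 300), ids)
    k <- sample(1:20, 1)
    w <- sample(ids, k, replace = TRUE)
    l <- vapply(w, function(x) sample(setdiff(ids, x), 1), character(1))
    contests <- make_contests(w, l)
    states <- data.frame(mouse = ids, rating = unname(ratings),
                         rd = unname(rds), n_contests = 0L)
    got <- glicko_update_period(states, contests, glicko_config(c = 0))
    want <- oracle_glicko_period(ratings, rds, contests)
    expect_equal(got$rating, unname(want$rating[got$mouse]),
                 tolerance = 1e-9)
    expect_equal(got$rd, unname(want$rd[got$mouse]), tolerance = 1e-9)
  }
})

test_that("zero-contest mice keep the 2200 baseline and full RD", {
  co <- make_contests(c("A", "A"), c("B", "B"))
  h <- glicko_rate(co, c("A", "B", "C"))
  s <- h$states
  expect_equal(s$net_change[s$mouse == "C"], 0)
  expect_equal(s$rating[s$mouse == "C"], 2200)
  expect_equal(s$rd[s$mouse == "C"], 300)
  expect_gt(s$net_change[s$mouse == "A"], 0)
  expect_lt(s$net_change[s$mouse == "B"], 0)
})

test_that("a despot tops the net-change ranking and mirroring negates it", {
  ids <- c("A", "B", "C", "D")
  set.seed(13)
  w <- rep("A", 30)
  l <- sample(c("B", "C", "D"), 30, replace = TRUE)
  # interleave some contests among subordinates
  w2 <- sample(c("B", "C"), 10, replace = TRUE)
  l2 <- ifelse(w2 == "B", "D", "B")
  co <- make_contests(c(w, w2), c(l, l2), day = rep(c(2, 7), 20))
  co <- co[order(co$day, co$t), ]
  h <- glicko_rate(co, ids)
  expect_equal(h$states$mouse[which.max(h$states$net_change)], "A")

  mirrored <- co
  mirrored$winner <- co$loser
  mirrored$loser <- co$winner
  hm <- glicko_rate(mirrored, ids)
  # outcome reversal negates every net change, so the order flips exactly
  expect_equal(hm$states$net_change, -h$states$net_change, tolerance = 1e-9)
  expect_equal(order(hm$states$net_change), rev(order(h$states$net_change)))
})

test_that("RD shrinks over consecutive active periods", {
  co <- make_contests(rep("A", 12), rep(c("B", "C"), 6),
                      day = rep(c(2, 3, 7), each = 4),
                      t = rep(1:4, 3))
  h <- glicko_rate(co, c("A", "B", "C"))
  rd_a <- vapply(h$snapshots, function(s) s$rd[s$mouse == "A"], numeric(1))
  expect_true(all(diff(rd_a) < 0))
})

test_that("round-robin sweeps put the sweeper on top in every ordering", {
  ids <- c("A", "B", "C")
  base <- expand.grid(l = c("B", "C"), rep = 1:4,
                      stringsAsFactors = FALSE)
  set.seed(2)
  for (i in 1:20) {
    o <- sample(nrow(base))
    co <- make_contests(rep("A", nrow(base)), base$l[o])
    h <- glicko_rate(co, ids, glicko_config(period = "event"))
    expect_equal(h$states$mouse[which.max(h$states$net_change)], "A")
  }
})

test_that("unsorted contest streams are rejected", {
  co <- make_contests(c("A", "A"), c("B", "B"), day = c(7, 2))
  expect_error(glicko_rate(co, c("A", "B")), "sorted")
})

test_that("glicko variants agree on coupled streams", {
  ev <- rbind(
    make_events(2, 1:6, "A", rep(c("B", "C"), 3),
                rep("escalated_aggression", 6)),
    make_events(2, 1:6 + 0.5, rep(c("B", "C"), 3), "A", rep("submission", 6)))
  ev <- ev[order(ev$day, ev$t), ]
  v <- glicko_variants(ev, c("A", "B", "C"))
  expect_equal(v$net$mouse[which.max(v$net$glicko_agg_net)], "A")
  expect_equal(v$net$mouse[which.max(v$net$glicko_sub_net)], "A")

  no_sub <- make_events(2, 1:3, "A", c("B", "C", "B"),
                        rep("mediated_aggression", 3))
  v2 <- glicko_variants(no_sub, c("A", "B", "C"))
  expect_true(all(v2$net$glicko_sub_net == 0))

  # coupled generation: the two variants correlate strongly across mice
  set.seed(31)
  nets <- do.call(rbind, lapply(1:10, function(i) {
    cage <- simulate_cage(fast_sim_config(investigation_rate = 1.5),
                          cage_meta("C01", "SJL", paste0("m", 1:5)))
    glicko_variants(cage$events, cage$meta$mouse_ids)$net
  }))
  expect_gt(cor(nets$glicko_agg_net, nets$glicko_sub_net), 0.5)
})
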