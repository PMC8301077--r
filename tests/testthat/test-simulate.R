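test_that("sampling emulation keeps the half-open observation windows", {
  ev <- data.frame(t = c(0, 59.9, 60, 299, 300, 360.5), day = 2)
  kept <- emulate_sampling(ev, sampling_scheme())
  expect_equal(kept$t, c(0, 59.9, 300))  # boundary event at k*period kept

  # window == period keeps everything
  all_kept <- emulate_sampling(ev, sampling_scheme(window_s = 300))
  expect_equal(nrow(all_kept), nrow(ev))

  # thinning a homogeneous stream retains ~ window/period
  set.seed(61)
  big <- data.frame(t = runif(10000, 0, 86400), day = 2)
  frac <- nrow(emulate_sampling(big, sampling_scheme())) / 10000
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("full despotism makes the alpha the only aggressor", {
  set.seed(67)
  cage <- simulate_cage(fast_sim_config(despotism = 1),
                        cage_meta("C01", "SJL", paste0("m", 1:5)))
  agg <- cage$events_continuous[cage$events_continuous$category %in%
    c("mediated_aggression", "escalated_aggression"), ]
  alpha <- cage$truth$mouse[cage$truth$true_rank == 1]
  expect_gt(nrow(agg), 0)
  expect_true(all(agg$actor == alpha))
})

test_that("certain submission makes every attack scorable in the window", {
  set.seed(71)
  cfg <- fast_sim_config(
    p_submit_given_attack = matrix(1, 2, 2,
                                   dimnames = list(strains, c("2", "7"))))
  cage <- simulate_cage(cfg, cage_meta("C01", "albinoB6", paste0("m", 1:3)))
  ev <- cage$events_continuous
  agg <- ev[ev$category %in% c("mediated_aggression",
                               "escalated_aggression"), ]
  sub <- ev[ev$category == "submission", ]
  ok <- vapply(seq_len(nrow(agg)), function(i) {
    any(sub$day == agg$day[i] & sub$actor == agg$recipient[i] &
          sub$t > agg$t[i] & sub$t <= agg$t[i] + 5)
  }, logical(1))
  # the only unscorable attacks are those whose response would cross
  # midnight (dropped by construction)
  expect_gte(mean(ok), 0.99)
})

test_that("the scanner recovers the configured response probability", {
  set.seed(73)
  # attack-triggered submissions off: they would contaminate the window
  cfg <- fast_sim_config(
    investigation_rate = 3,
    p_submit_given_attack = matrix(0, 2, 2,
                                   dimnames = list(strains, c("2", "7"))))
  p_cfg <- cfg$p_submit_given_investigation["SJL", "2"]
  hits <- n_inv <- 0
  for (i in 1:6) {
    cage <- simulate_cage(cfg, cage_meta("C01", "SJL", paste0("m", 1:5)))
    ev <- cage$events_continuous
    out <- submission_response_scan(ev[ev$day == 2, ])
    hits <- hits + sum(out$responded)
    n_inv <- n_inv + nrow(out)
  }
  ci <- binom.test(hits, n_inv)$conf.int
  expect_true(ci[1] <= p_cfg && p_cfg <= ci[2])
})

test_that("study layout, attrition and darcin missingness are as configured", {
  study <- simulate_study(sim_config(seed = 5))
  expect_equal(length(study$cages), 24)
  gs <- vapply(study$metas, function(m) m$group_size, integer(1))
  st <- vapply(study$metas, function(m) m$strain, character(1))
  expect_equal(sum(gs == 3), 12)
  expect_equal(sum(gs == 5), 12)
  expect_equal(as.integer(table(st)[strains]), c(12L, 12L))
  expect_equal(length(study$analysis_cages), 19)
  expect_equal(nrow(study$selected), 38)
  expect_equal(sum(is.na(study$measures$darcin)), 2)
  expect_equal(sum(complete.cases(study$measures[c(
    "darcin", "preputial_ratio", "posterior_pals",
    "tube_r1", "tube_r2", "tube_r3")])), 36)
})

test_that("identical seeds reproduce the study byte-for-byte", {
  a <- simulate_study(sim_config(seed = 77, n_cages_per_arm = 1L,
                                 attrition = c()))
  b <- simulate_study(sim_config(seed = 77, n_cages_per_arm = 1L,
                                 attrition = c()))
  expect_identical(a$events, b$events)
  expect_identical(a$scans, b$scans)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$measures, b$measures)
})

test_that("investigation out-strength tracks its implied coupling", {
  set.seed(79)
  study <- simulate_study(fast_sim_config(seed = 79))
  truth <- do.call(rbind, lapply(study$cages, function(cg) cg$truth))
  ev <- do.call(rbind, lapply(study$cages,
                              function(cg) cg$events_continuous))
  agg_out <- vapply(truth$mouse, function(m) sum(ev$actor == m &
    ev$category %in% c("mediated_aggression", "escalated_aggression")),
    numeric(1))
  inv_out <- vapply(truth$mouse, function(m) sum(ev$actor == m &
    ev$category == "investigation"), numeric(1))
  implied <- cor(truth$w_aggression, truth$w_investigation)
  expect_lt(abs(cor(agg_out, inv_out) - implied), 0.1)
})

test_that("strong tube coupling merges the factor blocks", {
  separated <- function(seed, rho) {
    st <- simulate_study(fast_sim_config(seed = seed, tube_coupling = rho))
    fa <- tryCatch(
      suppressWarnings(validity_analysis(st$measures))$factor_solution,
      error = function(e) NULL)
    if (is.null(fa) || fa$n_factors < 2) return(FALSE)
    m <- fa$membership
    f_g <- which(m["darcin", ] & m["preputial_ratio", ])
    f_t <- which(m["tube_r1", ] & m["tube_r2", ] & m["tube_r3", ])
    length(f_g) >= 1 && length(f_t) >= 1 && !any(f_g %in% f_t)
  }
  merged <- vapply(1:8, function(s) separated(s, 0.9), logical(1))
  expect_lt(mean(merged), 0.5)
})

test_that("a simulated study writes and re-reads as a CSV bundle", {
  study <- simulate_study(sim_config(seed = 83, n_cages_per_arm = 1L,
                                     attrition = c()))
  dir <- tempfile()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "events.csv", "scans.csv", "cages.csv", "phenotypes.csv",
    "pals_grids.csv", "manifest.json")))))
  back <- read_study(dir)
  expect_equal(length(back$metas), 4)
  expect_equal(nrow(back$events), nrow(study$events))
  expect_equal(sort(back$analysis_cages), sort(study$analysis_cages))
})
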