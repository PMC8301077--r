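#' Configuration of a synthetic cage study
#'
#' Parameterizes the generative model of a 2 x 2 (strain x group size)
#' home-cage study. Defaults state a despotic world: the alpha performs 90%
#' of cage aggression, dyads are strongly unidirectional, investigation
#' propensity tracks aggression propensity (emulating their high observed
#' correlation), darcin and preputial ratio are higher in albino B6 and track
#' dominance, wounding is higher in SJL and accumulates on attack victims,
#' the tube-test latent is decoupled from home-cage dominance, and open-field
#' measures are independent of everything (the discriminant-validity null).
#' Continuous event streams are thinned by the 1-min-in-5 observation scheme
#' over 24-h days 2 and 7.
#'
#' @param n_cages_per_arm cages per strain x group-size arm (default 6, i.e.
#'   24 cages).
#' @param group_sizes the two housing densities (default `c(3L, 5L)`).
#' @param despotism share of cage aggression performed by the alpha, in
#'   `[0, 1]` (default 0.9).
#' @param aggression_rate continuous aggression events per mouse-hour
#'   (default 0.5; about one fifth are observed under the default scheme).
#' @param investigation_rate,allogroom_rate continuous rates per mouse-hour.
#' @param p_escalated probability an aggression event is escalated (bite or
#'   fight) rather than mediated.
#' @param p_down_rank probability a non-alpha aggressor targets a
#'   lower-ranked mouse (keeps dyads unidirectional).
#' @param p_submit_given_attack 2 x 2 matrix (rows SJL, albinoB6; columns
#'   day 2, day 7) of submission-response probabilities after an attack.
#' @param p_submit_given_investigation same layout, response to social
#'   investigation; default elevates SJL on day 2.
#' @param investigation_coupling mixing weight of aggression propensity in
#'   investigation propensity, in `[0, 1]`.
#' @param tube_coupling correlation of the tube-test latent with the
#'   dominance latent, in `[-1, 1]`; 0 reproduces the observed two-factor
#'   separation.
#' @param beta_darcin,beta_preputial,beta_pals additive strain shifts (darcin
#'   and preputial higher in albino B6, wounding higher in SJL).
#' @param gamma_darcin,gamma_preputial dominance effects (per SD of the
#'   within-cage dominance score).
#' @param sigma_darcin,sigma_preputial,sigma_pals residual noise SDs.
#' @param sigma_cage SD of cage-level random shifts shared by cage mates in
#'   darcin, preputial, wounding and the tube latent (CageID was a
#'   significant variance component in the source data; default 0.4).
#' @param response_window_s submission-response window in seconds (5).
#' @param submission_latency `"uniform"` over the window (default) or
#'   `"exponential"` with mean `window/2` (longer-tailed, to probe window
#'   misspecification).
#' @param tube_timeout_p probability a tube trial times out (loss for both).
#' @param tube_steepness logistic slope of the tube-latent difference.
#' @param tube_replicates replicates per pairing per round (default 4).
#' @param ofm_coupled couple open-field distance to dominance (default
#'   `FALSE`, the discriminant null).
#' @param attrition named integer vector of cages dropped before the
#'   validity stage, emulating the realized study (defaults drop 5 of 24,
#'   leaving 19 validation cages).
#' @param n_missing_darcin_selected number of selected (dominant or
#'   subordinate) mice with missing darcin (default 2, the realized count).
#' @param p_missing_darcin missingness probability for non-selected mice.
#' @param scheme [sampling_scheme()].
#' @param include_scans generate scan records (default `TRUE`); replicate
#'   simulations that only exercise the event-based stages can skip them.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cages_per_arm = 6L,
                       group_sizes = c(3L, 5L),
                       despotism = 0.9,
                       aggression_rate = 0.5,
                       investigation_rate = 2.5,
                       allogroom_rate = 0.4,
                       p_escalated = 0.3,
                       p_down_rank = 0.9,
                       p_submit_given_attack =
                         matrix(c(0.5, 0.6, 0.6, 0.75), 2, 2,
                                dimnames = list(strains, c("2", "7"))),
                       p_submit_given_investigation =
                         matrix(c(0.25, 0.10, 0.10, 0.10), 2, 2,
                                dimnames = list(strains, c("2", "7"))),
                       investigation_coupling = 0.8,
                       tube_coupling = 0,
                       beta_darcin = 1.5, beta_preputial = 0.8,
                       beta_pals = 1.2,
                       gamma_darcin = 1.0, gamma_preputial = 1.0,
                       sigma_darcin = 0.6, sigma_preputial = 0.6,
                       sigma_pals = 0.5,
                       sigma_cage = 0.4,
                       response_window_s = 5,
                       submission_latency = c("uniform", "exponential"),
                       tube_timeout_p = 0.05,
                       tube_steepness = 2,
                       tube_replicates = 4L,
                       ofm_coupled = FALSE,
                       attrition = c(SJL_3 = 1L, albinoB6_3 = 3L,
                                     albinoB6_5 = 1L),
                       n_missing_darcin_selected = 2L,
                       p_missing_darcin = 0.15,
                       scheme = sampling_scheme(),
                       include_scans = TRUE,
                       seed = 1L) {
  submission_latency <- match.arg(submission_latency)
  cfg <- as.list(environment())
  probs <- c(despotism, p_down_rank, p_escalated, p_submit_given_attack,
             p_submit_given_investigation, investigation_coupling,
             tube_timeout_p, p_missing_darcin)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(tube_coupling) > 1)
    stop("tube_coupling must lie in [-1, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Thin a continuous event stream to the observed sampling windows
#'
#' All-occurrence coding watches the first `window_s` seconds of every
#' `period_s`-second block, so an event is observed iff
#' `t %% period_s < window_s` (half-open window: an event exactly at a window
#' start is retained). Expected retention fraction is `window_s / period_s`.
#'
#' @param events events data.frame with column `t` (seconds from day start).
#' @param scheme [sampling_scheme()].
#' @return the observed subset of `events`.
#' @export
emulate_sampling <- function(events, scheme = sampling_scheme()) {
  keep <- (events$t %% scheme$period_s) < scheme$window_s
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# draw submission latencies per the configured latency model
r_latency <- function(n, config) {
  w <- config$response_window_s
  if (config$submission_latency == "uniform") stats::runif(n, 0, w)
  else stats::rexp(n, rate = 2 / w)
}

# vectorized down-rank-biased target choice; actor_i indexes into ids
pick_targets <- function(actor_i, ids, rank, p_down) {
  recip <- character(length(actor_i))
  for (a in unique(actor_i)) {
    sel <- which(actor_i == a)
    lower <- ids[rank > rank[a]]
    higher <- ids[rank < rank[a]]
    down <- if (!length(higher)) rep(TRUE, length(sel))
            else if (!length(lower)) rep(FALSE, length(sel))
            else stats::runif(length(sel)) < p_down
    if (any(down))
      recip[sel[down]] <- sample(lower, sum(down), replace = TRUE)
    if (any(!down))
      recip[sel[!down]] <- sample(higher, sum(!down), replace = TRUE)
  }
  recip
}

# vectorized uniform choice among cage mates
pick_others <- function(actor_i, ids) {
  recip <- character(length(actor_i))
  for (a in unique(actor_i)) {
    sel <- which(actor_i == a)
    recip[sel] <- sample(ids[-a], length(sel), replace = TRUE)
  }
  recip
}

#' Simulate one cage
#'
#' Generates a cage's ground truth (ranks, propensities, latents), its
#' continuous and observed behavior event streams, scan records and
#' phenotypes under a [sim_config()]. See the package vignette for the
#' generative model. RNG state is taken as-is: callers seed once per study.
#'
#' @param config [sim_config()].
#' @param meta [cage_meta()] for the cage.
#' @return object of class `sim_cage`: list with `meta`, `truth` (data.frame
#'   incl. `true_rank`, dominance scores and latents), `events_continuous`,
#'   `events` (observed), `scans`, `phenotypes` (one row per mouse),
#'   `pals_grids` (long data.frame), `tube_trials`.
#' @export
simulate_cage <- function(config, meta) {
  n <- meta$group_size
  ids <- meta$mouse_ids
  days <- config$scheme$days
  strain <- meta$strain

  rank <- sample(n)                       # 1 = alpha
  dom <- (n - rank) / (n - 1)             # 1 alpha .. 0 bottom
  dom_z <- as.numeric(scale(dom))
  w_agg <- ifelse(rank == 1, config$despotism,
                  (1 - config$despotism) / (n - 1))
  u <- stats::runif(n); u <- u / sum(u)
  rho <- config$investigation_coupling
  w_inv <- rho * w_agg + (1 - rho) * u

  sec_day <- 86400
  gen_day <- function(day) {
    day_chr <- as.character(day)
    ev <- list()
    # aggression: Poisson stream, actor by despotic weights, target mostly
    # down-rank so dyads stay unidirectional
    n_agg <- stats::rpois(1, config$aggression_rate * n * 24)
    if (n_agg > 0) {
      t_agg <- sort(stats::runif(n_agg, 0, sec_day))
      actor_i <- sample.int(n, n_agg, replace = TRUE, prob = w_agg)
      actor <- ids[actor_i]
      recip <- pick_targets(actor_i, ids, rank, config$p_down_rank)
      cat_agg <- ifelse(stats::runif(n_agg) < config$p_escalated,
                        "escalated_aggression", "mediated_aggression")
      ev$agg <- data.frame(day = day, t = t_agg, actor = actor,
                           recipient = recip, category = cat_agg,
                           stringsAsFactors = FALSE)
      resp <- stats::runif(n_agg) <
        config$p_submit_given_attack[strain, day_chr]
      if (any(resp)) {
        t_sub <- t_agg[resp] + r_latency(sum(resp), config)
        keep <- t_sub < sec_day
        ev$sub_agg <- data.frame(day = day, t = t_sub[keep],
                                 actor = recip[resp][keep],
                                 recipient = actor[resp][keep],
                                 category = "submission",
                                 stringsAsFactors = FALSE)
      }
    }
    # investigation, with its own submission responses
    n_inv <- stats::rpois(1, config$investigation_rate * n * 24)
    if (n_inv > 0) {
      t_inv <- sort(stats::runif(n_inv, 0, sec_day))
      actor_i <- sample.int(n, n_inv, replace = TRUE, prob = w_inv)
      actor <- ids[actor_i]
      recip <- pick_others(actor_i, ids)
      ev$inv <- data.frame(day = day, t = t_inv, actor = actor,
                           recipient = recip, category = "investigation",
                           stringsAsFactors = FALSE)
      resp <- stats::runif(n_inv) <
        config$p_submit_given_investigation[strain, day_chr]
      if (any(resp)) {
        t_sub <- t_inv[resp] + r_latency(sum(resp), config)
        keep <- t_sub < sec_day
        ev$sub_inv <- data.frame(day = day, t = t_sub[keep],
                                 actor = recip[resp][keep],
                                 recipient = actor[resp][keep],
                                 category = "submission",
                                 stringsAsFactors = FALSE)
      }
    }
    # allogrooming, independent of rank
    n_allo <- stats::rpois(1, config$allogroom_rate * n * 24)
    if (n_allo > 0) {
      actor_i <- sample.int(n, n_allo, replace = TRUE)
      actor <- ids[actor_i]
      recip <- pick_others(actor_i, ids)
      ev$allo <- data.frame(day = day, t = stats::runif(n_allo, 0, sec_day),
                            actor = actor, recipient = recip,
                            category = "allogroom", stringsAsFactors = FALSE)
    }
    do.call(rbind, ev)
  }
  events <- do.call(rbind, lapply(days, gen_day))
  if (is.null(events))
    events <- data.frame(day = integer(0), t = numeric(0),
                         actor = character(0), recipient = character(0),
                         category = character(0), stringsAsFactors = FALSE)
  events <- events[order(events$day, events$t), , drop = FALSE]
  events$subtype <- NA_character_
  rownames(events) <- NULL
  observed <- emulate_sampling(events, config$scheme)

  # scans: sticky Markov chains whose stationary state probabilities shift
  # with dominance (more active, more solitary sleep); group sleepers share
  # the nest cell
  p_active <- 0.30 + 0.15 * dom
  p_sol <- 0.05 + 0.10 * dom
  persist <- 0.7
  scan_t <- seq(0, sec_day - config$scheme$period_s,
                by = config$scheme$period_s)
  scans <- if (!config$include_scans) NULL else
    do.call(rbind, lapply(days, function(day) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      pr <- c(p_active[i], 1 - p_active[i] - p_sol[i], p_sol[i])
      K <- length(scan_t)
      # sticky chain: resample from the stationary law w.p. 1 - persist,
      # else repeat; vectorized via the index of the latest resample
      draws <- sample(scan_states, K, replace = TRUE, prob = pr)
      fresh <- stats::runif(K) >= persist
      fresh[1] <- TRUE
      st <- draws[cummax(seq_len(K) * fresh)]
      in_nest <- st == "group_sleep"
      row <- ifelse(in_nest, 1L, sample(1:2, length(st), replace = TRUE))
      col <- ifelse(in_nest, 1L, sample(1:4, length(st), replace = TRUE))
      # solitary sleepers rest away from the nest cell
      away <- st == "solitary_sleep" & row == 1L & col == 1L
      col[away] <- 2L
      data.frame(day = day, t = scan_t, mouse = ids[i], state = st,
                 row = row, col = col, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(scans)) rownames(scans) <- NULL

  # cage-level shifts shared by cage mates (CageID variance component)
  cage_fx <- stats::rnorm(4, 0, config$sigma_cage)

  # tube tests: Bradley-Terry on a latent optionally coupled to dominance
  rho_t <- config$tube_coupling
  tube_latent <- cage_fx[4] + rho_t * dom_z +
    sqrt(1 - rho_t^2) * stats::rnorm(n)
  pairs <- utils::combn(n, 2)
  tube_trials <- do.call(rbind, lapply(1:3, function(r) {
    lat_r <- tube_latent + stats::rnorm(n, 0, 0.3)
    i <- rep(pairs[1, ], each = config$tube_replicates)
    j <- rep(pairs[2, ], each = config$tube_replicates)
    p_i <- stats::plogis(config$tube_steepness * (lat_r[i] - lat_r[j]))
    winner <- ifelse(stats::runif(length(i)) < p_i, ids[i], ids[j])
    winner[stats::runif(length(i)) < config$tube_timeout_p] <- NA_character_
    data.frame(round = r, mouse_a = ids[i], mouse_b = ids[j],
               winner = winner, stringsAsFactors = FALSE)
  }))
  tube_scores <- sapply(1:3, function(r) {
    tr <- tube_trials[tube_trials$round == r, ]
    vapply(ids, function(m) {
      competed <- sum(tr$mouse_a == m | tr$mouse_b == m)
      wins <- sum(tr$winner == m, na.rm = TRUE)
      tube_test_score(wins, competed)
    }, numeric(1))
  })
  colnames(tube_scores) <- paste0("tube_r", 1:3)

  # wounding accumulates on attack victims; grids are generated and then
  # scored through the same PALS functions the pipeline uses
  recv <- vapply(ids, function(m) sum(events$recipient == m &
    events$category %in% c("mediated_aggression", "escalated_aggression")),
    numeric(1))
  recv_z <- if (stats::sd(recv) > 0) (recv - mean(recv)) / stats::sd(recv)
            else recv * 0
  pals_latent <- -1 + cage_fx[3] + 0.9 * recv_z +
    config$beta_pals * (strain == "SJL") +
    stats::rnorm(n, 0, config$sigma_pals)
  grids <- lapply(seq_len(n), function(i) {
    p_hit <- stats::plogis(pals_latent[i])
    sev <- matrix(0L, 9, 9)
    area <- matrix(0, 9, 9)
    band_w <- c(0.1, 0.3, 1.0)   # anterior, mid, posterior exposure
    for (b in 1:3) {
      rows <- (b - 1) * 3 + 1:3
      hit <- matrix(stats::runif(27) < p_hit * band_w[b], 3, 9)
      sev[rows, ][hit] <- sample(1:4, sum(hit), replace = TRUE,
                                 prob = c(0.4, 0.3, 0.2, 0.1))
      area[rows, ][hit] <- stats::runif(sum(hit), 5, 60)
    }
    list(severity = sev, area_pct = area)
  })
  pals <- t(vapply(grids, function(g)
    pals_region_scores(g$severity, g$area_pct), numeric(3)))
  pals_long <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- grids[[i]]
    data.frame(mouse = ids[i],
               row = rep(1:9, 9), col = rep(1:9, each = 9),
               severity = as.integer(g$severity),
               area_pct = round(as.numeric(g$area_pct), 2),
               stringsAsFactors = FALSE)
  }))

  # dominance-correlated morphometrics with strain shifts
  is_b6 <- strain == "albinoB6"
  darcin <- cage_fx[1] + config$beta_darcin * is_b6 +
    config$gamma_darcin * dom_z + stats::rnorm(n, 0, config$sigma_darcin)
  body_length_mm <- stats::rnorm(n, 95, 3)
  preputial_mg <- pmax(10, 60 + 10 * (cage_fx[2] +
    config$beta_preputial * is_b6 + config$gamma_preputial * dom_z +
    stats::rnorm(n, 0, config$sigma_preputial)))
  ofm_distance <- stats::rnorm(n, 3000, 500) +
    if (config$ofm_coupled) 400 * dom_z else 0
  ofm_center <- pmin(100, pmax(0, stats::rnorm(n, 15, 5)))
  ofm_boli <- stats::rpois(n, 3)

  if (!is.null(scans)) {
    tb <- t(vapply(ids, function(m) time_budget(scans, m), numeric(3)))
    p_alone <- proportion_alone(scans)[ids]
  } else {
    tb <- matrix(NA_real_, n, 3, dimnames = list(NULL, scan_states))
    p_alone <- rep(NA_real_, n)
  }

  phen <- data.frame(
    mouse = ids, cage_id = meta$cage_id, strain = strain,
    group_size = n, batch = meta$batch,
    posterior_pals = pals[, "posterior"], mid_pals = pals[, "mid"],
    anterior_pals = pals[, "anterior"],
    tube_r1 = tube_scores[, 1], tube_r2 = tube_scores[, 2],
    tube_r3 = tube_scores[, 3],
    preputial_mg = preputial_mg, body_length_mm = body_length_mm,
    preputial_ratio = preputial_ratio(preputial_mg, body_length_mm),
    darcin = darcin,
    ofm_distance_cm = ofm_distance, ofm_center_pct = ofm_center,
    ofm_boli = ofm_boli,
    p_active = tb[, "active"], p_group_sleep = tb[, "group_sleep"],
    p_solitary_sleep = tb[, "solitary_sleep"], p_alone = as.numeric(p_alone),
    stringsAsFactors = FALSE)
  rownames(phen) <- NULL

  truth <- data.frame(mouse = ids, true_rank = rank, dominance = dom,
                      dominance_z = dom_z, w_aggression = w_agg,
                      w_investigation = w_inv, tube_latent = tube_latent,
                      received_attacks = recv, stringsAsFactors = FALSE)
  structure(list(meta = meta, truth = truth, events_continuous = events,
                 events = observed, scans = scans, phenotypes = phen,
                 pals_grids = pals_long, tube_trials = tube_trials),
            class = "sim_cage")
}

#' Simulate a full 2 x 2 cage study
#'
#' Builds the balanced strain x group-size design, simulates every cage,
#' applies the configured attrition (dropping whole cages before the validity
#' stage), computes both Glicko variants per cage from the observed events,
#' selects dominant/subordinate mice, and applies darcin missingness (exactly
#' `n_missing_darcin_selected` of the selected mice, probability
#' `p_missing_darcin` elsewhere). Seeded once from `config$seed`: identical
#' configs give identical studies.
#'
#' @param config [sim_config()].
#' @return object of class `sim_study`: list with `cages` (named list of
#'   `sim_cage`), `metas`, pooled `events`/`scans`/`phenotypes`/`pals_grids`
#'   tables (with `cage_id`), `net` (Glicko net changes), `selected`,
#'   `measures` (validity-stage table), `analysis_cages`, `manifest`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  arms <- expand.grid(strain = strains, group_size = config$group_sizes,
                      stringsAsFactors = FALSE)
  metas <- list()
  idx <- 0
  for (a in seq_len(nrow(arms))) {
    for (k in seq_len(config$n_cages_per_arm)) {
      idx <- idx + 1
      cid <- sprintf("C%02d", idx)
      ids <- sprintf("%s_m%d", cid, seq_len(arms$group_size[a]))
      metas[[cid]] <- cage_meta(cid, arms$strain[a], ids,
                                batch = ((idx - 1) %% 4) + 1)
    }
  }
  cages <- lapply(metas, function(m) simulate_cage(config, m))

  # attrition: drop whole cages from the analysis set (names like "SJL_3")
  analysis_cages <- names(cages)
  for (arm in names(config$attrition)) {
    parts <- strsplit(arm, "_", fixed = TRUE)[[1]]
    pool <- Filter(function(cid) {
      m <- metas[[cid]]
      m$strain == parts[1] && m$group_size == as.integer(parts[2])
    }, analysis_cages)
    drop_n <- min(config$attrition[[arm]], length(pool))
    if (drop_n > 0)
      analysis_cages <- setdiff(analysis_cages,
                                sample(pool, drop_n))
  }

  bind_with_cage <- function(field) {
    do.call(rbind, lapply(names(cages), function(cid) {
      x <- cages[[cid]][[field]]
      if (is.null(x) || !nrow(x)) return(NULL)
      if (!"cage_id" %in% names(x)) x <- cbind(cage_id = cid, x)
      x
    }))
  }
  events <- bind_with_cage("events")
  scans <- bind_with_cage("scans")
  phen <- bind_with_cage("phenotypes")
  grids <- bind_with_cage("pals_grids")

  net <- do.call(rbind, lapply(names(cages), function(cid) {
    v <- glicko_variants(cages[[cid]]$events, metas[[cid]]$mouse_ids)
    cbind(cage_id = cid, v$net)
  }))
  rownames(net) <- NULL

  selected <- select_dominant_subordinate(
    net[net$cage_id %in% analysis_cages, ])

  # darcin missingness: the realized-study world — exactly
  # n_missing_darcin_selected among selected mice, p_missing_darcin elsewhere
  phen$darcin_missing <- FALSE
  sel_idx <- which(phen$mouse %in% selected$mouse)
  n_miss <- min(config$n_missing_darcin_selected, length(sel_idx))
  if (n_miss > 0)
    phen$darcin_missing[sample(sel_idx, n_miss)] <- TRUE
  other <- setdiff(seq_len(nrow(phen)), sel_idx)
  phen$darcin_missing[other] <-
    stats::runif(length(other)) < config$p_missing_darcin
  phen$darcin[phen$darcin_missing] <- NA_real_

  measures <- merge(selected, phen[c(
    "mouse", "darcin", "preputial_ratio", "posterior_pals",
    "tube_r1", "tube_r2", "tube_r3",
    "ofm_boli", "ofm_center_pct", "ofm_distance_cm",
    "strain", "group_size")], by = "mouse", sort = FALSE)
  measures <- measures[order(measures$cage_id, measures$role), ]
  rownames(measures) <- NULL

  manifest <- list(seed = config$seed, n_cages = length(cages),
                   analysis_cages = sort(analysis_cages),
                   arms = arms, generated = unclass(Sys.time()))
  structure(list(cages = cages, metas = metas, events = events,
                 scans = scans, phenotypes = phen, pals_grids = grids,
                 net = net, selected = selected, measures = measures,
                 analysis_cages = sort(analysis_cages),
                 config = config, manifest = manifest),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> ", length(x$cages), " cages (",
      length(x$analysis_cages), " in analysis set), ",
      nrow(x$events), " observed events, seed = ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write a simulated study as a CSV bundle
#'
#' Emits `events.csv`, `scans.csv`, `cages.csv`, `phenotypes.csv`,
#' `pals_grids.csv` and `manifest.json` into `dir`, the interchange format
#' consumed by the ingest stage.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$events, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$scans, file.path(dir, "scans.csv"),
                   row.names = FALSE, quote = FALSE)
  write_cages(study$metas, file.path(dir, "cages.csv"))
  utils::write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$pals_grids, file.path(dir, "pals_grids.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- study$manifest
  manifest$config <- study$config[!vapply(study$config, is.function,
                                          logical(1))]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
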