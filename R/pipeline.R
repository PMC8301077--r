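#' Pipeline configuration
#'
#' Bundles the inputs and the statistical constants of a full run. Either a
#' [sim_config()] (synthetic study) or an input directory holding the CSV
#' bundle (`events.csv`, `scans.csv`, `cages.csv`, `phenotypes.csv`,
#' optionally `pals_grids.csv`) must be given — not neither. Every analysis
#' constant is a named key so no stage hides a magic number.
#'
#' @param sim optional [sim_config()].
#' @param input_dir optional directory with the CSV bundle.
#' @param out_dir output directory.
#' @param seed integer seed (overrides `sim$seed` when given).
#' @param alpha family-wise error rate for the contrast family (0.05).
#' @param contrast_family_size number of post-hoc contrasts (6).
#' @param loading_threshold factor-membership threshold (0.45).
#' @param eigenvalue_cutoff component/factor retention cutoff (1.0).
#' @param response_window_s submission-response window, seconds (5).
#' @param glicko [glicko_config()].
#' @param residual_method `"random"` or `"fixed"`, see [residualize()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, out_dir = tempfile(),
                            seed = NULL, alpha = 0.05,
                            contrast_family_size = 6L,
                            loading_threshold = 0.45,
                            eigenvalue_cutoff = 1.0,
                            response_window_s = 5,
                            glicko = glicko_config(),
                            residual_method = "random") {
  if (is.null(sim) && is.null(input_dir))
    stop("either a sim config or an input directory is required",
         call. = FALSE)
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 seed = seed, alpha = alpha,
                 contrast_family_size = contrast_family_size,
                 loading_threshold = loading_threshold,
                 eigenvalue_cutoff = eigenvalue_cutoff,
                 response_window_s = response_window_s, glicko = glicko,
                 residual_method = residual_method),
            class = "pipeline_config")
}

#' Read a study CSV bundle
#'
#' Ingests the interchange bundle written by [write_study()] (or hand-coded
#' data in the same layout) into the structure the downstream stages consume.
#'
#' @param dir directory with `events.csv`, `scans.csv`, `cages.csv`,
#'   `phenotypes.csv` and optionally `pals_grids.csv`, `manifest.json`.
#' @return list with `metas`, `events`, `scans`, `phenotypes`, `pals_grids`
#'   (or `NULL`), `analysis_cages`.
#' @export
read_study <- function(dir) {
  need <- c("events.csv", "scans.csv", "cages.csv", "phenotypes.csv")
  missing_f <- need[!file.exists(file.path(dir, need))]
  if (length(missing_f))
    stop("input bundle is missing: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  metas <- read_cages(file.path(dir, "cages.csv"))
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  events <- validate_events(events)
  scans <- read_scans(file.path(dir, "scans.csv"))
  phen <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                          stringsAsFactors = FALSE)
  grids <- NULL
  if (file.exists(file.path(dir, "pals_grids.csv")))
    grids <- utils::read.csv(file.path(dir, "pals_grids.csv"),
                             stringsAsFactors = FALSE)
  analysis_cages <- names(metas)
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!is.null(manifest$analysis_cages))
      analysis_cages <- manifest$analysis_cages
  }
  list(metas = metas, events = events, scans = scans, phenotypes = phen,
       pals_grids = grids, analysis_cages = analysis_cages)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest -> network -> ratings -> phenotypes ->
#' validity -> report. Deterministic given the seed. Writes per-cage
#' aggression sociomatrices, a tidy network-metric table, a ratings table,
#' the assembled per-mouse phenotype table, the validity report (JSON and
#' CSV tables) and a run manifest into `config$out_dir`.
#'
#' @param config [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return list (invisibly returned components also written to disk):
#'   `study`, `metrics`, `ratings`, `phenotypes`, `validity`,
#'   `response_model`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[cagedom] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim)) {
    say("simulate: ", config$sim$n_cages_per_arm * 4, " cages, seed ",
        config$sim$seed)
    study <- simulate_study(config$sim)
  } else {
    say("ingest: ", config$input_dir)
    study <- read_study(config$input_dir)
  }
  metas <- study$metas
  events <- study$events
  say("events: ", nrow(events), " observed rows, ", length(metas), " cages")

  # network stage: pooled-day aggression sociomatrices and global metrics
  metrics <- list(); mats <- list()
  for (cid in names(metas)) {
    ev <- events[events$cage_id == cid, , drop = FALSE]
    contests <- contests_from_aggression(ev)
    M <- frequency_sociomatrix(contests, metas[[cid]]$mouse_ids,
                               "aggression")
    mats[[cid]] <- M
    dc <- suppressWarnings(directional_consistency(M))
    metrics[[cid]] <- data.frame(
      cage_id = cid, behavior_scope = "aggression",
      metric = c("density", "directional_consistency", "n_contests"),
      value = c(sociomatrix_density(binarize(M)), dc, sum(M)))
    write_sociomatrix(M, file.path(config$out_dir,
                                   paste0("sociomatrix_", cid, ".csv")))
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(config$out_dir, "network_metrics.csv"),
                   row.names = FALSE)
  say("network: metrics for ", length(mats), " cages")

  # rating stage: both Glicko variants per cage
  ratings <- list(); net <- list()
  for (cid in names(metas)) {
    ev <- events[events$cage_id == cid, , drop = FALSE]
    v <- glicko_variants(ev, metas[[cid]]$mouse_ids, config$glicko)
    for (variant in c("agg", "sub")) {
      s <- v[[variant]]$states
      ratings[[paste(cid, variant)]] <- data.frame(
        cage_id = cid, mouse = s$mouse, variant = variant,
        rating_final = s$rating, rd_final = s$rd,
        n_contests = s$n_contests, net_change = s$net_change)
    }
    net[[cid]] <- cbind(cage_id = cid, v$net)
  }
  ratings <- do.call(rbind, ratings); rownames(ratings) <- NULL
  net <- do.call(rbind, net); rownames(net) <- NULL
  utils::write.csv(ratings, file.path(config$out_dir, "ratings.csv"),
                   row.names = FALSE)
  say("ratings: ", nrow(ratings), " rows")

  # phenotype stage: recompute PALS regions from grids when available,
  # time budgets and solitary occupancy from scans
  phen <- study$phenotypes
  if (!is.null(study$pals_grids)) {
    for (m in unique(study$pals_grids$mouse)) {
      g <- study$pals_grids[study$pals_grids$mouse == m, ]
      sev <- matrix(0L, max(g$row), max(g$col))
      area <- matrix(0, max(g$row), max(g$col))
      sev[cbind(g$row, g$col)] <- g$severity
      area[cbind(g$row, g$col)] <- g$area_pct
      reg <- pals_region_scores(sev, area)
      i <- phen$mouse == m
      phen$posterior_pals[i] <- reg[["posterior"]]
      phen$mid_pals[i] <- reg[["mid"]]
      phen$anterior_pals[i] <- reg[["anterior"]]
    }
  }
  sc <- study$scans
  for (cid in names(metas)) {
    s_c <- sc[sc$cage_id == cid, , drop = FALSE]
    if (!nrow(s_c)) next
    pa <- proportion_alone(s_c)
    for (m in metas[[cid]]$mouse_ids) {
      tb <- time_budget(s_c, m)
      i <- phen$mouse == m
      phen$p_active[i] <- tb[["active"]]
      phen$p_group_sleep[i] <- tb[["group_sleep"]]
      phen$p_solitary_sleep[i] <- tb[["solitary_sleep"]]
      phen$p_alone[i] <- as.numeric(pa[m])
    }
  }
  utils::write.csv(phen, file.path(config$out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  say("phenotypes: ", nrow(phen), " mice")

  # validity stage on the analysis cages
  analysis_cages <- study$analysis_cages
  sel <- select_dominant_subordinate(net[net$cage_id %in% analysis_cages, ])
  measures <- merge(sel, phen[c(
    "mouse", "darcin", "preputial_ratio", "posterior_pals",
    "tube_r1", "tube_r2", "tube_r3",
    "ofm_boli", "ofm_center_pct", "ofm_distance_cm",
    "strain", "group_size")], by = "mouse", sort = FALSE)
  validity <- validity_analysis(measures,
                                loading_threshold = config$loading_threshold,
                                eigen_cutoff = config$eigenvalue_cutoff,
                                residual_method = config$residual_method)
  say("validity: n = ", validity$n_complete, " complete mice, ",
      validity$factor_solution$n_factors, " factor(s)")

  # submission-response analysis over investigation occurrences
  ev_strain <- events
  ev_strain$strain <- vapply(ev_strain$cage_id,
                             function(cid) metas[[cid]]$strain, character(1))
  outcomes <- do.call(rbind, lapply(names(metas), function(cid) {
    o <- submission_response_scan(
      ev_strain[ev_strain$cage_id == cid, , drop = FALSE],
      window_s = config$response_window_s)
    if (nrow(o)) cbind(cage_id = cid, o) else NULL
  }))
  response <- NULL
  if (!is.null(outcomes) && length(unique(outcomes$strain)) == 2 &&
      length(unique(outcomes$day)) == 2) {
    response <- response_logistic(outcomes, alpha = config$alpha,
                                  family_size = config$contrast_family_size)
    say("response model: ", nrow(outcomes), " investigations, threshold ",
        signif(response$threshold, 3))
  }

  fa <- validity$factor_solution
  report <- list(
    constants = list(alpha = config$alpha,
                     contrast_family_size = config$contrast_family_size,
                     loading_threshold = config$loading_threshold,
                     eigenvalue_cutoff = config$eigenvalue_cutoff,
                     response_window_s = config$response_window_s,
                     glicko_init_rating = config$glicko$init_rating,
                     glicko_init_rd = config$glicko$init_rd),
    factor_analysis = list(
      n_subjects = fa$n_subjects, n_variables = ncol(fa$loadings),
      subjects_per_variable = fa$subjects_per_variable,
      n_factors = fa$n_factors,
      loadings = as.data.frame(fa$loadings),
      eigenvalues = fa$eigenvalues, pct_variance = fa$pct_variance),
    convergent = list(glicko_agg = validity$convergent$glicko_agg$table,
                      glicko_sub = validity$convergent$glicko_sub$table),
    glicko_correlation = validity$glicko_correlation,
    discriminant = if (!is.null(validity$discriminant))
      validity$discriminant$table,
    response_contrasts = if (!is.null(response))
      list(threshold = response$threshold,
           interaction = response$interaction,
           contrasts = response$contrasts))
  jsonlite::write_json(report, file.path(config$out_dir,
                                         "validity_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(data.frame(variable = rownames(fa$loadings),
                              fa$loadings, check.names = FALSE),
                   file.path(config$out_dir, "factor_loadings.csv"),
                   row.names = FALSE)
  if (!is.null(response))
    utils::write.csv(response$contrasts,
                     file.path(config$out_dir, "response_contrasts.csv"),
                     row.names = FALSE)

  manifest <- list(seed = if (!is.null(config$sim)) config$sim$seed
                   else config$seed,
                   n_cages = length(metas),
                   analysis_cages = analysis_cages,
                   n_events = nrow(events),
                   package_version =
                     as.character(utils::packageVersion("cagedom")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("report written to ", config$out_dir)
  invisible(list(study = study, metrics = metrics, ratings = ratings, net = net,
                 phenotypes = phen, measures = measures, validity = validity,
                 response_model = response, report = report,
                 manifest = manifest))
}
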