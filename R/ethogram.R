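#' Behavior categories of the home-cage ethogram
#'
#' Coded social behaviors: two aggression classes (mediated, e.g. chasing and
#' mounting, and escalated, i.e. biting and fighting), submission, allogrooming
#' and social investigation. The first mouse to perform a submissive behavior in
#' an agonistic interaction is the loser, so every recorded aggression event
#' carries a winner (the actor) and a loser (the recipient).
#'
#' @export
behavior_categories <- c("mediated_aggression", "escalated_aggression",
                         "submission", "allogroom", "investigation")

#' Scan states of the time-budget ethogram
#' @export
scan_states <- c("active", "group_sleep", "solitary_sleep")

#' Strains used in the study design
#' @export
strains <- c("SJL", "albinoB6")

#' Cage metadata
#'
#' Describes one cage: identity, strain, group size and roster. Group sizes of
#' three or five mice are the two levels of the housing-density factor.
#'
#' @param cage_id character scalar.
#' @param strain one of `"SJL"`, `"albinoB6"`.
#' @param mouse_ids character vector of unique mouse identifiers; its length is
#'   the group size.
#' @param batch integer batch index (husbandry cohort), default 1.
#' @return An object of class `cage_meta`.
#' @examples
#' cage_meta("C01", "SJL", c("m1", "m2", "m3"))
#' @export
cage_meta <- function(cage_id, strain, mouse_ids, batch = 1L) {
  strain <- match.arg(strain, strains)
  mouse_ids <- as.character(mouse_ids)
  if (anyDuplicated(mouse_ids))
    stop("mouse_ids must be unique within a cage", call. = FALSE)
  if (!length(mouse_ids) %in% c(3L, 5L))
    warning("group size ", length(mouse_ids), " is outside the 3/5 design")
  structure(
    list(cage_id = as.character(cage_id), strain = strain,
         group_size = length(mouse_ids), mouse_ids = mouse_ids,
         batch = as.integer(batch)),
    class = "cage_meta")
}

#' @export
print.cage_meta <- function(x, ...) {
  cat("<cage_meta> ", x$cage_id, ": ", x$strain, ", n = ", x$group_size,
      " [", paste(x$mouse_ids, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Observational sampling scheme
#'
#' All-occurrence coding is done for `window_s` seconds at the start of every
#' `period_s`-second block (1 min in every 5 min by default), on each listed
#' observation day.
#'
#' @param window_s observed window length in seconds (default 60).
#' @param period_s sampling period in seconds (default 300).
#' @param days integer vector of observation days (default `c(2L, 7L)`).
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(window_s = 60, period_s = 300, days = c(2L, 7L)) {
  stopifnot(window_s > 0, window_s <= period_s)
  structure(list(window_s = window_s, period_s = period_s,
                 days = as.integer(days)),
            class = "sampling_scheme")
}

event_columns <- c("day", "t", "actor", "recipient", "category")

validate_events <- function(events, meta = NULL, scheme = NULL) {
  missing_cols <- setdiff(event_columns, names(events))
  if (length(missing_cols))
    stop("events table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"subtype" %in% names(events)) events$subtype <- NA_character_
  events$subtype <- as.character(events$subtype)
  events$category <- as.character(events$category)
  bad_cat <- !events$category %in% behavior_categories
  if (any(bad_cat))
    stop("unknown behavior category in row(s) ",
         paste(which(bad_cat), collapse = ", "), call. = FALSE)
  self_dir <- events$actor == events$recipient
  if (any(self_dir))
    stop("actor == recipient in row(s) ",
         paste(which(self_dir), collapse = ", "), call. = FALSE)
  if (!is.null(meta)) {
    known <- c(meta$mouse_ids)
    bad_id <- !(events$actor %in% known & events$recipient %in% known)
    if (any(bad_id))
      stop("mouse id outside cage roster in row(s) ",
           paste(which(bad_id), collapse = ", "), call. = FALSE)
  }
  if (!is.null(scheme)) {
    off <- (events$t %% scheme$period_s) >= scheme$window_s
    if (any(off))
      warning(sum(off), " event(s) fall outside the sampled windows ",
              "(kept; partially coded data are expected)", call. = FALSE)
  }
  events <- events[order(events$day, events$t), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Read coded behavior events from CSV
#'
#' Expected columns: `day,t,actor,recipient,category` and optionally
#' `subtype` and `cage_id`. Events are validated (known categories, roster
#' membership, no self-directed rows) and returned sorted by `(day, t)`.
#' Events timestamped outside the sampled observation windows raise a warning
#' but are kept, so partially coded data still load.
#'
#' @param path CSV file path.
#' @param meta optional [cage_meta()] used to check roster membership.
#' @param scheme optional [sampling_scheme()] used to warn about events outside
#'   observed windows.
#' @return data.frame of events sorted by `(day, t)`.
#' @export
read_events <- function(path, meta = NULL, scheme = NULL) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(ev) == 0) {
    missing_cols <- setdiff(event_columns, names(ev))
    if (length(missing_cols))
      stop("events table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (!"subtype" %in% names(ev)) ev$subtype <- character(0)
    return(ev)
  }
  validate_events(ev, meta = meta, scheme = scheme)
}

#' Write coded behavior events to CSV
#'
#' Inverse of [read_events()]: `read_events(write_events(ev, f))` reproduces
#' the event table field for field.
#'
#' @param events validated events data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read instantaneous scan records from CSV
#'
#' Expected columns: `day,t,mouse,state,row,col` (and optionally `cage_id`).
#' `state` must be one of `active`, `group_sleep`, `solitary_sleep`; `row` in
#' 1..2 and `col` in 1..4 index the 4 x 2 grid overlaid on the cage.
#'
#' @param path CSV file path.
#' @return data.frame of scan records.
#' @export
read_scans <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "t", "mouse", "state", "row", "col")
  missing_cols <- setdiff(need, names(sc))
  if (length(missing_cols))
    stop("scans table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !sc$state %in% scan_states
  if (any(bad))
    stop("unknown scan state in row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  sc
}

#' Read cage metadata table from CSV
#'
#' Expected columns: `cage_id,strain,group_size,batch,mouse_ids` with
#' `mouse_ids` semicolon-joined.
#'
#' @param path CSV file path.
#' @return named list of [cage_meta()] objects keyed by cage id.
#' @export
read_cages <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cage_id", "strain", "group_size", "batch", "mouse_ids")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("cages table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  metas <- lapply(seq_len(nrow(tab)), function(i) {
    ids <- strsplit(tab$mouse_ids[i], ";", fixed = TRUE)[[1]]
    if (length(ids) != tab$group_size[i])
      stop("cage ", tab$cage_id[i], ": group_size does not match mouse_ids",
           call. = FALSE)
    cage_meta(tab$cage_id[i], tab$strain[i], ids, tab$batch[i])
  })
  names(metas) <- tab$cage_id
  metas
}

#' Write cage metadata to CSV
#' @param metas list of [cage_meta()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cages <- function(metas, path) {
  tab <- do.call(rbind, lapply(metas, function(m)
    data.frame(cage_id = m$cage_id, strain = m$strain,
               group_size = m$group_size, batch = m$batch,
               mouse_ids = paste(m$mouse_ids, collapse = ";"))))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract dominance contests from aggression events
#'
#' Every mediated- or escalated-aggression event is a decided contest: in
#' home-cage coding the initiating mouse always wins (the recipient is the
#' first to flee or posture submissively), so winner = actor and
#' loser = recipient. Other categories are ignored.
#'
#' @param events validated events data.frame.
#' @return data.frame with columns `day,t,winner,loser,source`
#'   (`source = "aggression"`), one row per aggression event.
#' @export
contests_from_aggression <- function(events) {
  keep <- events$category %in% c("mediated_aggression", "escalated_aggression")
  ev <- events[keep, , drop = FALSE]
  out <- data.frame(day = ev$day, t = ev$t, winner = ev$actor,
                    loser = ev$recipient, source = rep("aggression", nrow(ev)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract dominance contests from submission events
#'
#' For the submission-based rating variant, each submission event is a contest
#' won by the mouse submitted to: winner = recipient, loser = actor (the
#' submitter). All submission events count, regardless of what triggered them,
#' because only the submission itself carries an observable direction.
#'
#' @param events validated events data.frame.
#' @return data.frame with columns `day,t,winner,loser,source`
#'   (`source = "submission_response"`).
#' @export
contests_from_submission <- function(events) {
  ev <- events[events$category == "submission", , drop = FALSE]
  out <- data.frame(day = ev$day, t = ev$t, winner = ev$recipient,
                    loser = ev$actor,
                    source = rep("submission_response", nrow(ev)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohen's kappa for inter-coder agreement
#'
#' Chance-corrected agreement between two coders' category sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is observed agreement and
#' `p_e` expected agreement from the coders' marginal label frequencies. If
#' both coders are constant and identical (`p_e == 1`), 1 is returned by
#' convention.
#'
#' @param labels_1,labels_2 equal-length category vectors.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c("a", "a", "b"), c("a", "a", "b"))  # 1
#' @export
cohens_kappa <- function(labels_1, labels_2) {
  if (length(labels_1) != length(labels_2))
    stop("label sequences differ in length", call. = FALSE)
  if (length(labels_1) < 1) stop("need at least one label", call. = FALSE)
  labels_1 <- as.character(labels_1)
  labels_2 <- as.character(labels_2)
  n <- length(labels_1)
  p_o <- mean(labels_1 == labels_2)
  lev <- union(labels_1, labels_2)
  p1 <- tabulate(factor(labels_1, lev), nbins = length(lev)) / n
  p2 <- tabulate(factor(labels_2, lev), nbins = length(lev)) / n
  p_e <- sum(p1 * p2)
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Audit scan records against the sampling design
#'
#' Report-only quality control: lists missing mouse-by-scan slots, off-grid
#' cells, off-schedule timestamps and duplicate `(mouse, day, t)` records.
#' The data are never mutated.
#'
#' @param scans scan records data.frame (see [read_scans()]).
#' @param meta [cage_meta()] for the cage.
#' @param scheme [sampling_scheme()]; scans are expected every `period_s`
#'   seconds over each 24-h day.
#' @return list with data.frames `missing`, `off_grid`, `off_schedule`,
#'   `duplicates` and the integer `n_issues`.
#' @export
validate_scans <- function(scans, meta, scheme = sampling_scheme()) {
  expected_t <- seq(0, 86400 - scheme$period_s, by = scheme$period_s)
  grid_ok <- scans$row %in% 1:2 & scans$col %in% 1:4
  off_grid <- scans[!grid_ok, c("day", "t", "mouse", "row", "col")]
  on_time <- (scans$t %% scheme$period_s) == 0
  off_schedule <- scans[!on_time, c("day", "t", "mouse")]
  key <- paste(scans$mouse, scans$day, scans$t, sep = "\r")
  duplicates <- scans[duplicated(key), c("day", "t", "mouse")]

  full <- expand.grid(mouse = meta$mouse_ids, day = scheme$days,
                      t = expected_t, stringsAsFactors = FALSE)
  have <- unique(key)
  full_key <- paste(full$mouse, full$day, full$t, sep = "\r")
  missing <- full[!full_key %in% have, c("day", "t", "mouse")]
  missing <- missing[order(missing$day, missing$t, missing$mouse), ,
                     drop = FALSE]
  rownames(missing) <- NULL
  res <- list(missing = missing, off_grid = off_grid,
              off_schedule = off_schedule, duplicates = duplicates)
  res$n_issues <- sum(vapply(res, nrow, integer(1)))
  res
}
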