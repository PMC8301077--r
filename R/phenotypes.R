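#' Pelt aggression lesion scale (PALS) grid-cell score
#'
#' Each cell of the grid overlaid on a pelt image is scored for wound
#' severity (0-4 ordinal: 0 none, 1 five or fewer bites, up to 4 full
#' thickness wounding over >25% of the square) and for the percent of visible
#' area impacted. The cell score is `severity * area_pct * 0.25`, so a cell
#' maxes out at `4 * 100 * 0.25 = 100`.
#'
#' @param severity integer(s) in 0..4.
#' @param area_pct percent area impacted, in `[0, 100]`.
#' @return numeric grid score(s) in `[0, 100]`.
#' @export
pals_grid_score <- function(severity, area_pct) {
  if (any(!severity %in% 0:4))
    stop("severity must be an integer in 0..4", call. = FALSE)
  if (any(area_pct < 0 | area_pct > 100))
    stop("area_pct must be in [0, 100]", call. = FALSE)
  severity * area_pct * 0.25
}

#' PALS region averages (anterior, mid, posterior)
#'
#' The pelt grid runs from base of neck (row 1) to base of tail (last row).
#' Rows are split into three equal bands — anterior, mid, posterior — and each
#' region's score is the mean of its cells' grid scores. On the standard
#' 9 x 9 grid each band holds 27 cells; a 3 x 3 summary grid (one score per
#' cell, three per region) is also accepted, since the row count only needs to
#' be divisible by three. The posterior average is the analysis value, being
#' most predictive of aggression-related wounding.
#'
#' @param severity matrix of severity codes (rows = head-to-tail axis).
#' @param area_pct matrix of percent areas, same shape.
#' @return named numeric vector `c(anterior, mid, posterior)`.
#' @export
pals_region_scores <- function(severity, area_pct) {
  severity <- as.matrix(severity); area_pct <- as.matrix(area_pct)
  if (!all(dim(severity) == dim(area_pct)))
    stop("severity and area_pct shapes differ", call. = FALSE)
  if (nrow(severity) %% 3 != 0)
    stop("row count must be divisible by 3 to form regions", call. = FALSE)
  g <- pals_grid_score(severity, area_pct)
  band <- nrow(g) / 3
  c(anterior = mean(g[seq_len(band), ]),
    mid = mean(g[band + seq_len(band), ]),
    posterior = mean(g[2 * band + seq_len(band), ]))
}

#' Tube-test dominance score
#'
#' Wins out of trials competed. A 2-minute stalemate is a loss for both mice:
#' it counts in `competed` for both contestants and in `wins` for neither.
#'
#' @param wins trials won.
#' @param competed trials competed (including timed-out trials).
#' @return proportion in `[0, 1]`, or `NA` with a warning when
#'   `competed == 0`.
#' @export
tube_test_score <- function(wins, competed) {
  if (any(wins < 0) || any(competed < 0) || any(wins > competed, na.rm = TRUE))
    stop("need 0 <= wins <= competed", call. = FALSE)
  out <- wins / competed
  if (any(competed == 0)) {
    warning("competed == 0: tube-test score undefined, returning NA")
    out[competed == 0] <- NA_real_
  }
  out
}

#' Expected tube-test trials per round
#'
#' Round-robin within a cage: every unordered pair meets
#' `replicates_per_pairing` times, so a round has
#' `choose(group_size, 2) * replicates_per_pairing` trials — 40 in cages of
#' five and 12 in cages of three at the standard four replicates.
#'
#' @param group_size number of mice (>= 2).
#' @param replicates_per_pairing replicates per pair (default 4).
#' @return integer trial count.
#' @examples
#' expected_trials(5, 4)  # 40
#' expected_trials(3, 4)  # 12
#' @export
expected_trials <- function(group_size, replicates_per_pairing = 4) {
  stopifnot(group_size >= 2, replicates_per_pairing >= 1)
  as.integer(choose(group_size, 2) * replicates_per_pairing)
}

#' Preputial gland to body length ratio
#'
#' Combined preputial gland mass (mg) over body length (mm, nose tip to tail
#' base); a testosterone-dependent dominance correlate.
#'
#' @param preputial_mg gland mass in milligrams (> 0).
#' @param body_length_mm body length in millimeters (> 0).
#' @return ratio in mg/mm.
#' @export
preputial_ratio <- function(preputial_mg, body_length_mm) {
  if (any(body_length_mm <= 0))
    stop("body_length_mm must be positive", call. = FALSE)
  if (any(preputial_mg <= 0))
    stop("preputial_mg must be positive", call. = FALSE)
  preputial_mg / body_length_mm
}

#' Time budget from scan records
#'
#' Proportion of instantaneous scans a mouse spent active, in group sleep and
#' in solitary sleep. Proportions are over non-missing scans and sum to 1.
#'
#' @param scans scan records for one mouse (column `state`), or for a cage if
#'   `mouse` is given.
#' @param mouse optional mouse id to filter on.
#' @return named numeric vector over [scan_states], or `NA`s if no scans.
#' @export
time_budget <- function(scans, mouse = NULL) {
  if (!is.null(mouse)) scans <- scans[scans$mouse == mouse, , drop = FALSE]
  st <- scans$state[!is.na(scans$state)]
  if (!length(st)) {
    warning("no scans: time budget undefined")
    return(stats::setNames(rep(NA_real_, 3), scan_states))
  }
  counts <- tabulate(factor(st, scan_states), nbins = 3)
  stats::setNames(counts / length(st), scan_states)
}

#' Proportion of scans observed alone
#'
#' A mouse is alone at a scan if no cage mate occupies the same grid cell at
#' that `(day, t)`. Scans where a mouse is missing are excluded pairwise: the
#' mouse itself gets no observation and absent cage mates simply do not block
#' a cell.
#'
#' @param scans scan records for one cage (columns `day,t,mouse,row,col`).
#' @return named numeric vector: per-mouse proportion of its scans alone.
#' @export
proportion_alone <- function(scans) {
  slot <- paste(scans$day, scans$t, sep = "\r")
  cell <- paste(slot, scans$row, scans$col, sep = "\r")
  occupancy <- table(cell)
  alone <- occupancy[cell] == 1
  tapply(as.logical(alone), scans$mouse, mean)
}
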