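#' Build a directed frequency sociomatrix
#'
#' Tallies directed occurrences into an n x n matrix over the cage roster:
#' `M[i, j]` is the number of times mouse `i` directed the behavior at mouse
#' `j`. For aggression contests this is the number of times `i` won an attack
#' over `j` (the initiator always wins). The grand sum equals the number of
#' input records; the diagonal is structurally zero.
#'
#' @param x either a contests data.frame (columns `winner`, `loser`) or an
#'   events data.frame (columns `actor`, `recipient`); for contests the
#'   winner is the actor.
#' @param roster ordered character vector of mouse ids.
#' @param behavior_scope label describing what was counted, e.g.
#'   `"aggression"`.
#' @return integer matrix with `dimnames = list(roster, roster)` and
#'   attributes `behavior_scope` and class `sociomatrix`.
#' @export
frequency_sociomatrix <- function(x, roster, behavior_scope = "aggression") {
  roster <- as.character(roster)
  if (all(c("winner", "loser") %in% names(x))) {
    from <- x$winner; to <- x$loser
  } else if (all(c("actor", "recipient") %in% names(x))) {
    from <- x$actor; to <- x$recipient
  } else {
    stop("x must have winner/loser or actor/recipient columns", call. = FALSE)
  }
  unknown <- setdiff(unique(c(from, to)), roster)
  if (length(unknown))
    stop("participant(s) not in roster: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- length(roster)
  M <- matrix(0L, n, n, dimnames = list(roster, roster))
  if (length(from)) {
    tab <- table(factor(from, roster), factor(to, roster))
    M[] <- as.integer(tab)
  }
  structure(M, behavior_scope = behavior_scope,
            class = c("sociomatrix", class(M)))
}

assert_sociomatrix <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("expected a square sociomatrix", call. = FALSE)
  invisible(M)
}

#' Binarize a frequency sociomatrix
#'
#' Presence/absence version: `B[i, j] = 1` iff `i` was ever observed directing
#' the behavior at `j`. Idempotent on 0/1 matrices.
#'
#' @param M frequency sociomatrix.
#' @return 0/1 integer matrix with the same dimnames.
#' @export
binarize <- function(M) {
  assert_sociomatrix(M)
  B <- matrix(as.integer(M > 0), nrow(M), ncol(M), dimnames = dimnames(M))
  structure(B, behavior_scope = attr(M, "behavior_scope"),
            class = c("sociomatrix", class(B)))
}

#' Sociomatrix density
#'
#' Proportion of possible directed relationships in which at least one
#' interaction was observed: off-diagonal nonzero entries out of `n * (n - 1)`
#' ordered pairs. With `directed = FALSE`, a dyad counts once if either
#' direction was observed, out of `n * (n - 1) / 2` unordered pairs.
#'
#' @param M sociomatrix (frequency or binary; positivity is what counts).
#' @param directed count ordered pairs (default) or unordered dyads.
#' @return density in `[0, 1]`.
#' @export
sociomatrix_density <- function(M, directed = TRUE) {
  assert_sociomatrix(M)
  n <- nrow(M)
  if (n < 2) stop("density needs at least 2 individuals", call. = FALSE)
  B <- M > 0
  diag(B) <- FALSE
  if (directed) sum(B) / (n * (n - 1))
  else sum(B | t(B)) / 2 / (n * (n - 1) / 2)
}

#' Directional consistency of a frequency sociomatrix
#'
#' For each unordered dyad let `H` be the count in its more frequent direction
#' and `L` the count in the other; DC is `sum(H - L) / sum(H + L)` over dyads
#' with any interaction. 1 means fully unidirectional relationships, 0 fully
#' reciprocated ones. Computed from the frequency matrix: a binary variant
#' (`binary = TRUE`, positivity only) is exposed for auditing but collapses
#' dyad asymmetry to mutual-edge presence and is not the default.
#'
#' @param M frequency sociomatrix.
#' @param binary compute on the binarized matrix instead (default `FALSE`).
#' @return DC in `[0, 1]`, or `NA` with a warning if the matrix is all zero.
#' @export
directional_consistency <- function(M, binary = FALSE) {
  assert_sociomatrix(M)
  if (binary) M <- binarize(M)
  up <- upper.tri(M)
  a <- M[up]; b <- t(M)[up]
  tot <- sum(a) + sum(b)
  if (tot == 0) {
    warning("no interactions: directional consistency undefined")
    return(NA_real_)
  }
  sum(abs(a - b)) / tot
}

#' Individual out-strength and in-strength
#'
#' Row sum (behaviors performed) and column sum (behaviors received) of the
#' frequency sociomatrix for one mouse, or for all mice when `mouse` is
#' omitted.
#'
#' @param M frequency sociomatrix.
#' @param mouse mouse id (must be in the roster); if `NULL`, a named vector
#'   for the full roster is returned.
#' @return numeric count(s).
#' @export
out_strength <- function(M, mouse = NULL) {
  assert_sociomatrix(M)
  s <- rowSums(M)
  if (is.null(mouse)) return(s)
  if (!mouse %in% rownames(M)) stop("unknown mouse: ", mouse, call. = FALSE)
  s[[mouse]]
}

#' @rdname out_strength
#' @export
in_strength <- function(M, mouse = NULL) {
  assert_sociomatrix(M)
  s <- colSums(M)
  if (is.null(mouse)) return(s)
  if (!mouse %in% colnames(M)) stop("unknown mouse: ", mouse, call. = FALSE)
  s[[mouse]]
}

#' Write a sociomatrix as labeled CSV
#' @param M sociomatrix.
#' @param path output path; roster appears as header row and first column.
#' @return `path`, invisibly.
#' @export
write_sociomatrix <- function(M, path) {
  df <- data.frame(mouse = rownames(M), as.data.frame(unclass(M)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sociomatrix written by [write_sociomatrix()]
#' @param path CSV path.
#' @return sociomatrix (integer matrix with roster dimnames).
#' @export
read_sociomatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "integer"
  structure(M, class = c("sociomatrix", class(M)))
}
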