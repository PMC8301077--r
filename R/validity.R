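#' Standardize a measure to z-scores
#'
#' Centers and scales to mean 0, sd 1 over non-missing values; missing values
#' are preserved. Errors on fewer than two non-missing values or zero
#' variance.
#'
#' @param x numeric vector.
#' @param name measure name used in error messages.
#' @return z-scored vector, same length and missingness as `x`.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2)
    stop("standardize(", name, "): need >= 2 non-missing values",
         call. = FALSE)
  s <- stats::sd(x[ok])
  if (s == 0)
    stop("standardize(", name, "): zero variance", call. = FALSE)
  (x - mean(x[ok])) / s
}

#' Residualize a measure on the housing design
#'
#' Removes strain, group-size and their interaction from a (standardized)
#' measure by fitting a mixed model with a random cage intercept and taking
#' the conditional residuals; these feed the validity factor analysis so that
#' the factors reflect dominance structure rather than the 2 x 2 design.
#' When the random-intercept fit is singular — or `method = "fixed"` — cage
#' enters as a fixed factor instead (cage is nested in strain x group size, so
#' the fixed model absorbs the design through cage means).
#'
#' @param y numeric measure (missing allowed; preserved in the output).
#' @param design data.frame with columns `strain`, `group_size`, `cage_id`,
#'   one row per element of `y`.
#' @param method `"random"` (default) or `"fixed"`.
#' @return residual vector aligned with `y`.
#' @export
residualize <- function(y, design, method = c("random", "fixed")) {
  method <- match.arg(method)
  stopifnot(nrow(design) == length(y))
  d <- data.frame(y = y, strain = factor(design$strain),
                  group_size = factor(design$group_size),
                  cage_id = factor(design$cage_id))
  ok <- stats::complete.cases(d)
  res <- rep(NA_real_, length(y))
  dd <- d[ok, , drop = FALSE]
  dd[] <- lapply(dd, function(v) if (is.factor(v)) droplevels(v) else v)
  # constant design factors (e.g. a single-strain subset) drop out
  fx <- c("strain", "group_size")[c(nlevels(dd$strain) > 1,
                                    nlevels(dd$group_size) > 1)]
  fixed <- if (length(fx)) paste(fx, collapse = " * ") else "1"
  if (method == "random") {
    form <- stats::as.formula(paste("y ~", fixed, "+ (1 | cage_id)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dd,
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC("ignore", 1e-4)))))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-intercept fit; falling back to fixed cage",
              call. = FALSE)
      return(residualize(y, design, method = "fixed"))
    }
    res[ok] <- stats::residuals(fit)
  } else {
    fit <- stats::lm(y ~ cage_id, data = dd)
    res[ok] <- stats::residuals(fit)
  }
  res
}

#' Principal component analysis with eigenvalue-rule retention
#'
#' PCA of the correlation matrix; components with eigenvalue above `cutoff`
#' (Kaiser rule, 1.0) are retained. Used to condense the three time-budget
#' behaviors into a Budget PC and the three tube-test rounds into a tube-test
#' PC. Loadings are eigenvector scaled by the singular value (component-
#' variable correlations); each component is oriented so its largest-magnitude
#' loading is positive.
#'
#' @param X numeric matrix or data.frame (rows = subjects).
#' @param cutoff eigenvalue retention threshold (default 1.0).
#' @return list with `eigenvalues`, `loadings`, `scores`, `retained`
#'   (indices), `pct_variance`.
#' @export
pca_retain <- function(X, cutoff = 1.0) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 variables", call. = FALSE)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 complete rows", call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant column in PCA input", call. = FALSE)
  if (nrow(X) < ncol(X)) warning("fewer rows than variables in PCA")
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  load <- sweep(p$rotation, 2, p$sdev, `*`)
  flip <- apply(load, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(p$x, 2, p$sdev * flip, `/`) # unit-variance scores
  list(eigenvalues = ev, loadings = load, scores = scores,
       retained = which(ev > cutoff), pct_variance = 100 * ev / sum(ev))
}

#' Maximum-likelihood factor analysis with varimax rotation
#'
#' Exploratory factor analysis of the residualized dominance measures:
#' maximum-likelihood factoring of the correlation matrix, varimax-rotated
#' loadings, regression (Thomson) factor scores. The number of factors
#' defaults to the count of correlation-matrix eigenvalues above
#' `eigen_cutoff`. A variable "belongs" to a factor when the magnitude of its
#' rotated loading reaches `loading_threshold` (0.45). Each factor is
#' oriented so its largest-magnitude loading is positive; with orthogonal
#' rotation, orientation and factor order are conventions, the membership
#' pattern is the reproducible structure. Rows with any missing value are
#' dropped (listwise deletion) before fitting.
#'
#' @param X matrix/data.frame of measures (rows = subjects).
#' @param n_factors number of factors; `NULL` (default) applies the
#'   eigenvalue rule.
#' @param loading_threshold membership threshold on `|loading|` (default
#'   0.45).
#' @param eigen_cutoff eigenvalue cutoff for factor-count selection (1.0).
#' @return list of class `factor_solution`: `loadings`, `eigenvalues`
#'   (rotated sum-of-squares loadings), `pct_variance`, `scores`,
#'   `membership` (logical variables x factors), `n_factors`, `n_subjects`,
#'   `subjects_per_variable`, `uniquenesses`.
#' @export
ml_factor_analysis <- function(X, n_factors = NULL, loading_threshold = 0.45,
                               eigen_cutoff = 1.0) {
  X <- as.data.frame(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1) stop("too few complete rows for factor analysis",
                      call. = FALSE)
  if (n < 5 * p)
    warning("subject-to-variable ratio below 5:1 (", round(n / p, 2), ")")
  R <- stats::cor(X)
  if (is.null(n_factors)) n_factors <- sum(eigen(R, TRUE)$values > eigen_cutoff)
  n_factors <- max(1L, as.integer(n_factors))
  fit <- tryCatch(
    stats::factanal(~ ., data = X, factors = n_factors, rotation = "varimax",
                    scores = "regression", lower = 0.005),
    error = function(e) stop("factor analysis failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  if (any(fit$uniquenesses <= 0.0051))
    warning("Heywood case: communality bounded at 1", call. = FALSE)
  L <- unclass(fit$loadings)
  flip <- apply(L, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, `*`)
  scores <- sweep(fit$scores, 2, flip, `*`)
  ss <- colSums(L^2)
  structure(list(loadings = L, eigenvalues = ss,
                 pct_variance = 100 * ss / p, scores = scores,
                 membership = abs(L) >= loading_threshold,
                 n_factors = n_factors, n_subjects = n,
                 subjects_per_variable = n / p,
                 uniquenesses = fit$uniquenesses),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("<factor_solution> ", x$n_factors, " factor(s), n = ", x$n_subjects,
      " (", round(x$subjects_per_variable, 2), " subjects/variable)\n",
      sep = "")
  print(round(x$loadings, 3))
  cat("eigenvalues:", round(x$eigenvalues, 2),
      " | % variance:", round(x$pct_variance, 2), "\n")
  invisible(x)
}

#' Regress a Glicko net change on factor scores
#'
#' Convergent-validity test: ordinary linear model of a rating net change on
#' the retained factor scores, with per-term F tests and partial eta squared.
#'
#' @param y numeric response (Glicko-Agg or Glicko-Sub net change).
#' @param scores matrix of factor scores (columns = factors).
#' @return list with `model` (lm fit) and `table` (term, df, F, p,
#'   partial_eta_sq).
#' @export
convergent_regression <- function(y, scores) {
  d <- data.frame(y = y, as.data.frame(scores))
  fit <- stats::lm(y ~ ., data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design in convergent regression", call. = FALSE)
  dr <- stats::drop1(fit, test = "F")
  ss_res <- sum(stats::residuals(fit)^2)
  terms <- rownames(dr)[-1]
  tab <- data.frame(term = terms, df = dr$Df[-1], F = dr$`F value`[-1],
                    p = dr$`Pr(>F)`[-1],
                    partial_eta_sq = dr$`Sum of Sq`[-1] /
                      (dr$`Sum of Sq`[-1] + ss_res))
  list(model = fit, table = tab)
}

#' Discriminant-validity model for the tube-test PC
#'
#' Mixed linear model of the tube-test principal component on the open-field
#' measures (fecal boli, percent time in the center, distance traveled) plus
#' strain, group size and their interaction, with a random cage intercept
#' (cage is nested in strain x group size). Discriminant validity holds when
#' none of the three open-field terms is significant. F statistics use
#' residual-based approximate denominator degrees of freedom. A singular
#' random-effects fit falls back to a fixed-cage model with a warning (design
#' terms are then absorbed by cage).
#'
#' @param data data.frame with columns `tube_pc`, `boli`, `center_pct`,
#'   `distance`, `strain`, `group_size`, `cage_id`.
#' @return list with `model` and `table` (term, F, df1, df2, p).
#' @export
discriminant_model <- function(data) {
  d <- data
  d$strain <- factor(d$strain); d$group_size <- factor(d$group_size)
  d$cage_id <- factor(d$cage_id)
  d <- d[stats::complete.cases(d[c("tube_pc", "boli", "center_pct",
                                   "distance")]), , drop = FALSE]
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(tube_pc ~ boli + center_pct + distance +
                 strain * group_size + (1 | cage_id), data = d,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC("ignore", 1e-4)))))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular random-effects fit; using fixed-cage fallback",
            call. = FALSE)
    fit <- stats::lm(tube_pc ~ boli + center_pct + distance + cage_id,
                     data = d)
    an <- stats::drop1(fit, test = "F")
    terms <- rownames(an)[-1]
    tab <- data.frame(term = terms, F = an$`F value`[-1], df1 = an$Df[-1],
                      df2 = stats::df.residual(fit), p = an$`Pr(>F)`[-1])
    return(list(model = fit, table = tab))
  }
  an <- stats::anova(fit)
  df2 <- nrow(d) - length(lme4::fixef(fit))
  tab <- data.frame(term = rownames(an), F = an$`F value`,
                    df1 = an$npar, df2 = df2,
                    p = stats::pf(an$`F value`, an$npar, df2,
                                  lower.tail = FALSE))
  list(model = fit, table = tab)
}

#' Pearson correlation with confidence interval
#'
#' Pearson's r, two-sided t-test p-value and a Fisher-z confidence interval.
#'
#' @param x,y numeric vectors (pairwise complete values are used).
#' @param level confidence level (default 0.95).
#' @return list with `r`, `p`, `ci` (length 2), `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], conf.level = level)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = sum(ok))
}

#' Scan investigations for submission responses
#'
#' For every social-investigation event, scores 1 if the investigated mouse
#' (the recipient) performs a submission within `window_s` seconds after the
#' investigation on the same day, else 0. A submission by any other mouse in
#' the window does not count.
#'
#' @param events validated events data.frame for one cage (may carry extra
#'   columns such as `cage_id`).
#' @param window_s response window in seconds (default 5).
#' @return data.frame with one row per investigation: `day,t,actor,recipient,
#'   responded` plus `strain` if present in `events`.
#' @export
submission_response_scan <- function(events, window_s = 5) {
  inv <- events[events$category == "investigation", , drop = FALSE]
  sub <- events[events$category == "submission", , drop = FALSE]
  responded <- vapply(seq_len(nrow(inv)), function(i) {
    hit <- sub$day == inv$day[i] & sub$actor == inv$recipient[i] &
      sub$t > inv$t[i] & sub$t <= inv$t[i] + window_s
    as.integer(any(hit))
  }, integer(1))
  out <- data.frame(day = inv$day, t = inv$t, actor = inv$actor,
                    recipient = inv$recipient, responded = responded,
                    stringsAsFactors = FALSE)
  if ("strain" %in% names(inv)) out$strain <- inv$strain
  rownames(out) <- NULL
  out
}

#' Logistic model of submission following investigation
#'
#' Binomial-logit model `responded ~ strain * day` over investigation
#' occurrences, with all six pairwise contrasts among the four strain x day
#' cells on the log-odds scale. Contrast p-values are compared to the
#' Bonferroni-corrected threshold `alpha / 6` (0.05 / 6 = 0.0083). Under
#' complete separation the model is refit with half a success and half a
#' failure added per cell (an empirical-logit style penalty) and a warning is
#' issued.
#'
#' @param outcomes data.frame with columns `responded` (0/1), `strain`,
#'   `day`.
#' @param alpha family-wise error rate (default 0.05).
#' @param family_size number of contrasts in the family (default 6).
#' @return list with `model`, `interaction` (LR chi-square test of
#'   strain:day), `contrasts` (data.frame: cells, estimate (log-odds
#'   difference), se, z, p, significant), `threshold`.
#' @export
response_logistic <- function(outcomes, alpha = 0.05, family_size = 6L) {
  d <- data.frame(responded = outcomes$responded,
                  strain = factor(outcomes$strain),
                  day = factor(outcomes$day))
  if (nlevels(d$strain) < 2 || nlevels(d$day) < 2)
    stop("need two strains and two days represented", call. = FALSE)
  d$.w <- 1
  fit <- suppressWarnings(stats::glm(responded ~ strain * day,
                                     family = stats::binomial(), data = d,
                                     weights = .w))
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    warning("possible complete separation: refitting with cell pseudo-counts",
            call. = FALSE)
    cells <- unique(d[c("strain", "day")])
    aug <- rbind(transform(cells, responded = 1L, .w = 0.5),
                 transform(cells, responded = 0L, .w = 0.5))
    d <- rbind(d, aug[names(d)])
    fit <- suppressWarnings(stats::glm(responded ~ strain * day,
                                       family = stats::binomial(),
                                       data = d, weights = .w))
  }
  V <- stats::vcov(fit)
  cells <- expand.grid(strain = levels(d$strain), day = levels(d$day),
                       KEEP.OUT.ATTRS = FALSE)
  Xc <- stats::model.matrix(~ strain * day, cells)
  pairs <- utils::combn(nrow(cells), 2)
  est <- se <- numeric(ncol(pairs)); lab <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    L <- Xc[i, ] - Xc[j, ]
    est[k] <- sum(L * stats::coef(fit))
    se[k] <- sqrt(drop(t(L) %*% V %*% L))
    lab[k] <- paste0(cells$strain[i], ":day", cells$day[i], " - ",
                     cells$strain[j], ":day", cells$day[j])
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  threshold <- alpha / family_size
  fit0 <- suppressWarnings(stats::glm(responded ~ strain + day,
                                      family = stats::binomial(), data = d,
                                      weights = .w))
  lr <- stats::anova(fit0, fit, test = "Chisq")
  list(model = fit,
       interaction = list(chisq = lr$Deviance[2], df = lr$Df[2],
                          p = lr$`Pr(>Chi)`[2]),
       contrasts = data.frame(contrast = lab, estimate = est, se = se,
                              z = z, p = p, significant = p < threshold),
       threshold = threshold)
}

#' Select the dominant and subordinate mouse of each cage
#'
#' The per-cage maximum and minimum of the Glicko-Sub net change designate
#' the dominant (received the most submission) and subordinate (received the
#' least). Ties break on Glicko-Agg net change, then roster order.
#'
#' @param net data.frame with columns `cage_id,mouse,glicko_agg_net,
#'   glicko_sub_net`.
#' @return `net` rows for the selected mice with an added `role` column
#'   (`"dominant"`/`"subordinate"`).
#' @export
select_dominant_subordinate <- function(net) {
  pick <- function(d) {
    o <- order(-d$glicko_sub_net, -d$glicko_agg_net)
    top <- d[o[1], , drop = FALSE]; bot <- d[o[nrow(d)], , drop = FALSE]
    top$role <- "dominant"; bot$role <- "subordinate"
    rbind(top, bot)
  }
  out <- do.call(rbind, lapply(split(net, net$cage_id), pick))
  rownames(out) <- NULL
  out
}

#' Run the full dominance-measure validity analysis
#'
#' The convergent/discriminant validity stage over a study-wide measure
#' table: (1) standardize darcin, preputial ratio, posterior PALS and the
#' three tube-test round scores; (2) residualize each on strain, group size
#' and cage; (3) maximum-likelihood factor analysis with varimax rotation on
#' the residuals (listwise deletion of mice with missing darcin); (4) regress
#' Glicko-Agg and Glicko-Sub net change on the factor scores; (5) Pearson
#' correlation between the two Glicko variants; (6) condense the tube rounds
#' with PCA and test the open-field measures against the tube-test PC.
#'
#' @param measures data.frame, one row per selected mouse, with columns
#'   `mouse,cage_id,strain,group_size,darcin,preputial_ratio,posterior_pals,
#'   tube_r1,tube_r2,tube_r3,glicko_agg_net,glicko_sub_net` and (for the
#'   discriminant model) `ofm_boli,ofm_center_pct,ofm_distance_cm`.
#' @param loading_threshold factor-membership threshold (default 0.45).
#' @param eigen_cutoff eigenvalue retention cutoff (default 1.0).
#' @param residual_method passed to [residualize()].
#' @return list of class `validity_report`: `factor_solution`,
#'   `convergent` (per Glicko variant), `glicko_correlation`,
#'   `discriminant`, `n_complete`, `subjects_per_variable`, `residuals`.
#' @export
validity_analysis <- function(measures, loading_threshold = 0.45,
                              eigen_cutoff = 1.0,
                              residual_method = "random") {
  vars <- c("darcin", "preputial_ratio", "posterior_pals",
            "tube_r1", "tube_r2", "tube_r3")
  design <- measures[c("strain", "group_size", "cage_id")]
  resid_tab <- as.data.frame(lapply(stats::setNames(vars, vars), function(v)
    residualize(standardize(measures[[v]], v), design,
                method = residual_method)))
  ok <- stats::complete.cases(resid_tab)
  fa <- ml_factor_analysis(resid_tab[ok, ], loading_threshold =
                             loading_threshold, eigen_cutoff = eigen_cutoff)
  conv <- list(
    glicko_agg = convergent_regression(measures$glicko_agg_net[ok],
                                       fa$scores),
    glicko_sub = convergent_regression(measures$glicko_sub_net[ok],
                                       fa$scores))
  gcor <- pearson_ci(measures$glicko_agg_net, measures$glicko_sub_net)
  tube_pca <- pca_retain(measures[c("tube_r1", "tube_r2", "tube_r3")],
                         cutoff = eigen_cutoff)
  disc <- NULL
  if (all(c("ofm_boli", "ofm_center_pct", "ofm_distance_cm") %in%
          names(measures))) {
    tube_ok <- stats::complete.cases(
      measures[c("tube_r1", "tube_r2", "tube_r3")])
    dd <- data.frame(tube_pc = tube_pca$scores[, 1],
                     boli = measures$ofm_boli[tube_ok],
                     center_pct = measures$ofm_center_pct[tube_ok],
                     distance = measures$ofm_distance_cm[tube_ok],
                     strain = measures$strain[tube_ok],
                     group_size = measures$group_size[tube_ok],
                     cage_id = measures$cage_id[tube_ok])
    disc <- discriminant_model(dd)
  }
  structure(list(factor_solution = fa, convergent = conv,
                 glicko_correlation = gcor, tube_pca = tube_pca,
                 discriminant = disc, n_complete = sum(ok),
                 subjects_per_variable = sum(ok) / length(vars),
                 residuals = resid_tab),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report> n =", x$n_complete, "complete mice (",
      round(x$subjects_per_variable, 2), "subjects/variable )\n")
  print(x$factor_solution)
  cat("\nGlicko-Agg ~ factors:\n"); print(x$convergent$glicko_agg$table)
  cat("Glicko-Sub ~ factors:\n"); print(x$convergent$glicko_sub$table)
  cat("\nGlicko-Agg vs Glicko-Sub: r =",
      round(x$glicko_correlation$r, 3), " 95% CI",
      round(x$glicko_correlation$ci, 3), "\n")
  if (!is.null(x$discriminant)) {
    cat("\nDiscriminant model (tube PC ~ OFM + design):\n")
    print(x$discriminant$table)
  }
  invisible(x)
}
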