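# design helper: n_cages cages of group size 5, strains alternating
make_design <- function(n_cages = 40, per_cage = 5) {
  data.frame(
    cage_id = rep(sprintf("C%02d", seq_len(n_cages)), each = per_cage),
    strain = rep(rep(strains, length.out = n_cages), each = per_cage),
    group_size = per_cage)
}

test_that("standardize gives exact z-scores and rejects degenerate input", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(c(2, 2, 2)), "zero variance")
  expect_error(standardize(c(1, NA, NA)), "non-missing")
  x <- rnorm(20)
  z <- standardize(x)
  expect_equal(standardize(z), z)
  xm <- c(x, NA)
  expect_true(is.na(standardize(xm)[21]))
})

test_that("residualize removes strain structure", {
  set.seed(17)
  des <- make_design(40)
  strain_ind <- as.numeric(des$strain == "albinoB6")
  y <- 1.5 * strain_ind + rnorm(nrow(des))
  r <- suppressWarnings(residualize(standardize(y), des))
  expect_lt(abs(cor(r, strain_ind)), 0.05)
  expect_lt(abs(mean(r)), 1e-8)

  # measure independent of the design: residuals track the centered values
  y2 <- rnorm(nrow(des))
  r2 <- suppressWarnings(residualize(y2, des))
  expect_gt(cor(r2, y2 - mean(y2)), 0.9)

  # missingness is preserved in place
  y3 <- y; y3[c(4, 9)] <- NA
  r3 <- suppressWarnings(residualize(y3, des))
  expect_true(all(is.na(r3[c(4, 9)])))
  expect_false(anyNA(r3[-c(4, 9)]))
})

test_that("correlation PCA retains by the eigenvalue rule", {
  set.seed(6)
  x <- rnorm(100)
  two <- cbind(a = x, b = 2 * x + 1e-8 * rnorm(100))
  p <- pca_retain(two)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-6)
  expect_equal(p$retained, 1L)
  expect_equal(sum(p$eigenvalues), 2)  # trace conservation

  three <- matrix(rnorm(300), ncol = 3)
  p3 <- pca_retain(three)
  expect_equal(sum(p3$eigenvalues), 3, tolerance = 1e-10)
  expect_error(pca_retain(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

# two-block generative model mirroring the published loading structure:
# darcin + preputial share one latent, tube rounds (+ weak PALS) the other
make_two_block <- function(n = 36, noise = 0.5) {
  L1 <- rnorm(n); L2 <- rnorm(n)
  data.frame(darcin = L2 + noise * rnorm(n),
             preputial_ratio = L2 + noise * rnorm(n),
             posterior_pals = 0.45 * L1 + rnorm(n),
             tube_r1 = L1 + noise * rnorm(n),
             tube_r2 = L1 + noise * rnorm(n),
             tube_r3 = L1 + noise * rnorm(n))
}

blocks_separated <- function(fa) {
  if (fa$n_factors < 2) return(FALSE)
  m <- fa$membership
  f_gland <- which(m["darcin", ] & m["preputial_ratio", ])
  f_tube <- which(m["tube_r1", ] & m["tube_r2", ] & m["tube_r3", ])
  length(f_gland) >= 1 && length(f_tube) >= 1 &&
    !any(f_gland %in% f_tube)
}

test_that("ML factor analysis recovers the two-block structure", {
  set.seed(23)
  fa <- suppressWarnings(ml_factor_analysis(make_two_block()))
  expect_equal(fa$n_factors, 2L)
  expect_true(blocks_separated(fa))
  expect_equal(fa$n_subjects, 36L)
  expect_equal(fa$subjects_per_variable, 6)
  # rotation preserves communalities: SS of loadings + uniqueness = 1
  expect_equal(unname(rowSums(fa$loadings^2) + fa$uniquenesses),
               rep(1, 6), tolerance = 0.02)
})

test_that("single-factor data retain exactly one factor", {
  set.seed(29)
  L <- rnorm(60)
  X <- as.data.frame(replicate(5, L + 0.6 * rnorm(60)))
  fa <- ml_factor_analysis(X)
  expect_equal(fa$n_factors, 1L)
  expect_true(all(fa$membership[, 1]))
})

test_that("convergent regression: exact fit, calibrated power, type I", {
  set.seed(37)
  scores <- matrix(rnorm(72), ncol = 2,
                   dimnames = list(NULL, c("Factor1", "Factor2")))
  y <- 2 * scores[, 2] + 1
  cr <- suppressWarnings(convergent_regression(y, scores))
  expect_equal(suppressWarnings(summary(cr$model))$r.squared, 1,
               tolerance = 1e-9)
  expect_equal(cr$table$term, c("Factor1", "Factor2"))

  # power: slope calibrated a priori for ~0.95 power at n = 36, alpha 0.05
  n <- 36
  ncp <- uniroot(function(l) pf(qf(0.95, 1, n - 3), 1, n - 3, ncp = l,
                                lower.tail = FALSE) - 0.95,
                 c(1, 50))$root
  beta <- sqrt(ncp / n)
  hits <- 0
  for (i in 1:200) {
    s <- matrix(rnorm(2 * n), ncol = 2,
                dimnames = list(NULL, c("Factor1", "Factor2")))
    yy <- beta * s[, 2] + rnorm(n)
    hits <- hits + (convergent_regression(yy, s)$table$p[2] < 0.05)
  }
  expect_gte(hits / 200, 0.9)

  # type-I control within 2 Monte-Carlo SEs of nominal
  rej <- 0
  reps <- 600
  for (i in seq_len(reps)) {
    s <- matrix(rnorm(2 * n), ncol = 2,
                dimnames = list(NULL, c("Factor1", "Factor2")))
    rej <- rej + (convergent_regression(rnorm(n), s)$table$p[2] < 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 2 * sqrt(0.05 * 0.95 / reps))
})

make_disc_data <- function(beta_dist = 0) {
  cages <- sprintf("C%02d", 1:19)
  strain <- rep(strains, length.out = 19)
  gs <- rep(c(3, 5), length.out = 19)
  d <- data.frame(cage_id = rep(cages, each = 2),
                  strain = rep(strain, each = 2),
                  group_size = rep(gs, each = 2))
  d$boli <- rpois(nrow(d), 3)
  d$center_pct <- pmax(0, rnorm(nrow(d), 15, 5))
  d$distance <- rnorm(nrow(d), 3000, 500)
  cage_fx <- rnorm(19, 0, 0.5)
  d$tube_pc <- cage_fx[match(d$cage_id, cages)] + rnorm(nrow(d)) +
    beta_dist * scale(d$distance)
  d
}

test_that("discriminant model is translation invariant and null-calibrated", {
  set.seed(41)
  d <- make_disc_data()
  m1 <- suppressWarnings(discriminant_model(d))
  d2 <- d; d2$tube_pc <- d$tube_pc + 100
  m2 <- suppressWarnings(discriminant_model(d2))
  ofm <- c("boli", "center_pct", "distance")
  expect_equal(m1$table$F[m1$table$term %in% ofm],
               m2$table$F[m2$table$term %in% ofm], tolerance = 1e-6)

  reps <- 300
  rej <- matrix(0, reps, 3, dimnames = list(NULL, ofm))
  for (i in seq_len(reps)) {
    m <- suppressWarnings(discriminant_model(make_disc_data()))
    rej[i, ] <- m$table$p[match(ofm, m$table$term)] < 0.05
  }
  for (term in ofm)
    expect_lt(abs(mean(rej[, term]) - 0.05),
              2 * sqrt(0.05 * 0.95 / reps) + 0.01)

  # a real coupling is picked up
  set.seed(43)
  hits <- 0
  for (i in 1:50) {
    m <- suppressWarnings(discriminant_model(make_disc_data(beta_dist = 0.8)))
    hits <- hits + (m$table$p[m$table$term == "distance"] < 0.05)
  }
  expect_gt(hits / 50, 0.8)
})

test_that("pearson_ci matches limits and achieves nominal coverage", {
  x <- rnorm(30)
  expect_equal(pearson_ci(x, x)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
  expect_error(pearson_ci(x, rep(1, 30)), "zero variance")
  expect_error(pearson_ci(1:3, 3:1), "n >= 4")

  set.seed(47)
  rho <- 0.79; n <- 96
  cover <- 0
  for (i in 1:1000) {
    z <- rnorm(n)
    x <- z + rnorm(n) * sqrt(1 / rho^2 - 1)
    ci <- pearson_ci(z, x)$ci
    cover <- cover + (ci[1] <= rho && rho <= ci[2])
  }
  expect_lt(abs(cover / 1000 - 0.95), 2 * sqrt(0.95 * 0.05 / 1000) + 0.005)
})

test_that("submission response scan honors the 5-s window and actor", {
  ev <- rbind(
    make_events(2, 10, "A", "B", "investigation"),
    make_events(2, 13, "B", "A", "submission"),      # within window
    make_events(2, 40, "A", "B", "investigation"),
    make_events(2, 46, "B", "A", "submission"),      # 6 s late
    make_events(2, 70, "A", "B", "investigation"),
    make_events(2, 72, "C", "A", "submission"),      # wrong mouse
    make_events(7, 10, "C", "A", "investigation"))   # no response at all
  ev <- ev[order(ev$day, ev$t), ]
  out <- submission_response_scan(ev)
  expect_equal(nrow(out), 4)  # one row per investigation, exactly
  expect_equal(out$responded[out$day == 2 & out$t == 10], 1)
  expect_equal(out$responded[out$day == 2 & out$t == 40], 0)
  expect_equal(out$responded[out$day == 2 & out$t == 70], 0)
  expect_equal(out$responded[out$day == 7], 0)
})

make_outcomes <- function(p_cells, n_per_cell = 400) {
  cells <- expand.grid(strain = strains, day = c(2L, 7L),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(strain = cells$strain[i], day = cells$day[i],
               responded = rbinom(n_per_cell, 1, p_cells[i]))
  }))
}

test_that("response logistic reports the corrected threshold and contrasts", {
  set.seed(53)
  # SJL day 2 elevated, everything else at baseline
  out <- make_outcomes(c(0.6, 0.2, 0.2, 0.2))
  res <- response_logistic(out)
  expect_equal(res$threshold, 0.05 / 6)
  sig <- res$contrasts$significant
  involves <- grepl("SJL:day2", res$contrasts$contrast)
  expect_true(all(sig[involves]))
  expect_false(any(sig[!involves]))
  expect_lt(res$interaction$p, 0.05)
})

test_that("separation triggers the penalized fallback", {
  set.seed(59)
  out <- make_outcomes(c(1, 0.3, 0.3, 0.3), n_per_cell = 60)
  expect_warning(res <- response_logistic(out), "separation")
  expect_true(all(is.finite(res$contrasts$estimate)))
  expect_true(all(is.finite(res$contrasts$se)))
})
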