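test_that("Mann-Whitney U follows the larger-rank convention", {
  # complete separation, n = (3, 3): U = 9, exact two-sided p = 2/20
  mw <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw$U, 9)
  expect_equal(mw$p, 0.1)

  # reversed separation gives U = 0
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)

  # identical constant samples: all ties, U = n1 n2 / 2
  expect_equal(mann_whitney(rep(1, 4), rep(1, 5))$U, 10)

  expect_error(mann_whitney(numeric(), 1:3),
               class = "taplab_invalid_argument")
})

test_that("the AUC-U identity holds exactly and against brute force", {
  expect_equal(auc_from_u(297.5, 32, 10), 0.9296875)
  expect_equal(auc_from_u(160, 32, 10), 0.5)
  expect_error(auc_from_u(321, 32, 10), class = "taplab_invalid_argument")

  # on random data (with and without ties), U/(n1 n2), the pairwise
  # oracle, and the DeLong AUC all agree
  for (seed in 1:6) {
    set.seed(seed)
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    x <- if (seed %% 2) rnorm(n1) else sample(1:8, n1, replace = TRUE)
    y <- if (seed %% 2) rnorm(n2, 0.5) else sample(1:8, n2, replace = TRUE)
    ora <- oracle_auc(x, y)
    expect_equal(auc_from_u(mann_whitney(x, y)$U, n1, n2), ora)
    r <- roc_analysis(c(x, y), rep(c(TRUE, FALSE), c(n1, n2)))
    expect_equal(r$auc, ora)
  }
})

test_that("ROC analysis reports DeLong inference and the operating point", {
  set.seed(42)
  pos <- rnorm(30, 1.5); neg <- rnorm(20)
  r <- roc_analysis(c(pos, neg), rep(c("case", "control"), c(30, 20)),
                    positive = "case")
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  expect_gt(r$auc, 0.5)
  expect_lt(r$p_vs_half, 0.05)
  expect_equal(r$accuracy,
               (r$sensitivity * 30 + r$specificity * 20) / 50)

  # perfectly separating scores
  rp <- roc_analysis(c(2, 3, 4, 0, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(rp$auc, 1)
  expect_equal(rp$ci95[2], 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)

  # scores below chance are reported as-is, not flipped
  rl <- roc_analysis(c(0, 1, 5, 6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rl$auc, 0)

  # label-independent scores: AUC ~ 0.5 across replicates
  aucs <- vapply(1:50, function(s) {
    set.seed(100 + s)
    roc_analysis(rnorm(40), rep(c(TRUE, FALSE), 20))$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)

  expect_error(roc_analysis(1:4, rep(TRUE, 4)),
               class = "taplab_invalid_argument")
})

test_that("Youden cutoffs match the exhaustive threshold scan", {
  # hand-checkable example
  y <- youden_cutoff(c(0.1, 0.3, 0.2, 0.4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(y$youden_j,
               oracle_youden_j(c(0.1, 0.3, 0.2, 0.4),
                               c(FALSE, FALSE, TRUE, TRUE)))

  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(20:200, 1)
    pos <- rbinom(n, 1, 0.4) == 1
    sc <- round(rnorm(n, ifelse(pos, 0.8, 0)), 2)  # ties likely
    yj <- youden_cutoff(sc, pos)
    expect_equal(yj$youden_j, oracle_youden_j(sc, pos))
    # accuracy identity at the reported cutoff
    expect_equal(yj$accuracy,
                 (yj$sensitivity * sum(pos) + yj$specificity * sum(!pos)) / n)
    # reported sens/spec are realized at the cutoff
    expect_equal(yj$sensitivity, mean(sc[pos] >= yj$cutoff))
    expect_equal(yj$specificity, mean(sc[!pos] < yj$cutoff))
  }

  # separable data reach sensitivity = specificity = 1
  ys <- youden_cutoff(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(ys$sensitivity, 1)
  expect_equal(ys$specificity, 1)
})

test_that("logistic regression reproduces closed forms and diagnostics", {
  # single binary predictor: beta equals the 2x2 table log odds ratio
  x <- rep(c(0, 1), c(10, 10))
  y <- c(rep(c(TRUE, FALSE), c(3, 7)), rep(c(TRUE, FALSE), c(8, 2)))
  fit <- logistic_fit(data.frame(x = x), y)
  lor <- log((8 / 2) / (3 / 7))
  expect_equal(fit$coefficients$estimate[2], lor, tolerance = 1e-6)
  expect_equal(fit$coefficients$odds_ratio[2], exp(lor), tolerance = 1e-6)
  expect_true(fit$nagelkerke_r2 >= fit$cox_snell_r2)
  expect_true(fit$converged)

  # labels independent of features: omnibus ~ 0, both R2 ~ 0
  set.seed(8)
  xr <- data.frame(a = rnorm(60), b = rnorm(60))
  yr <- rep(c(TRUE, FALSE), 30)
  fr <- logistic_fit(xr, yr)
  expect_lt(fr$omnibus_chi2, qchisq(0.999, df = 2))
  expect_lt(fr$cox_snell_r2, 0.15)
  expect_gt(fr$omnibus_p, 0.001)
  expect_true(fr$nagelkerke_r2 >= fr$cox_snell_r2)

  # perfect separation is flagged, not silent
  xs <- data.frame(v = c(1:5, 11:15))
  ys <- rep(c(FALSE, TRUE), c(5, 5))
  fs <- logistic_fit(xs, ys)
  expect_true(fs$separation)

  expect_error(logistic_fit(data.frame(k = rep(1, 10)),
                            rep(c(TRUE, FALSE), 5)),
               class = "taplab_invalid_argument")
})

test_that("Spearman bootstrap is tie-aware, seeded and calibrated", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_bootstrap(x, exp(x), seed = 1)$rho, 1)
  expect_equal(spearman_bootstrap(x, rev(x), seed = 1)$rho, -1)

  # tie-aware oracle: explicit Pearson formula on average ranks
  xt <- c(1, 2, 2, 3, 5, 7)
  yt <- c(2, 1, 4, 4, 5, 5)
  rx <- rank(xt); ry <- rank(yt)
  ora <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman_bootstrap(xt, yt, seed = 2)
  expect_equal(res$rho, ora)

  # seeded CIs are reproducible and contain the point estimate
  set.seed(99)
  xx <- rnorm(30); yy <- 0.6 * xx + rnorm(30, 0, 0.8)
  r1 <- spearman_bootstrap(xx, yy, seed = 7)
  r2 <- spearman_bootstrap(xx, yy, seed = 7)
  expect_identical(r1$ci95, r2$ci95)
  expect_true(r1$ci95[1] <= r1$rho && r1$rho <= r1$ci95[2])

  expect_error(spearman_bootstrap(rep(1, 10), rnorm(10)),
               class = "taplab_invalid_argument")
  expect_error(spearman_bootstrap(1:4, 4:1),
               class = "taplab_invalid_argument")
})

test_that("BH adjustment implements the step-up rule", {
  # hand application: p = (.01,.02,.03,.04), m = 4 ->
  # q4 = .04, q3 = min(4*.03/3, .04) = .04, q2 = .04, q1 = .04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)

  set.seed(5)
  p <- runif(20)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # permutation equivariance
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), q[perm])

  expect_error(bh_adjust(c(0.1, 1.2)), class = "taplab_invalid_argument")
})

test_that("group comparisons gate on normality and adjust the family", {
  set.seed(12)
  cohort <- data.frame(
    group = rep(c("PD", "HC"), c(20, 12)),
    gaussian_var = c(rnorm(20, 1), rnorm(12)),
    skewed_var = c(rlnorm(20, 0, 1), rlnorm(12, 1.2, 1)),
    sex = sample(c("F", "M"), 32, replace = TRUE))
  out <- group_compare_suite(cohort, vars = c("gaussian_var", "skewed_var"),
                             sex_col = "sex")
  expect_equal(out$test[out$variable == "gaussian_var"], "welch_t")
  expect_equal(out$test[out$variable == "skewed_var"], "mann_whitney")
  expect_equal(out$q, bh_adjust(out$p))

  # a perfectly proportional 2x2 sex table has chi-square statistic 0
  coh2 <- data.frame(group = rep(c("A", "B"), c(20, 10)),
                     sex = c(rep(c("F", "M"), c(10, 10)),
                             rep(c("F", "M"), c(5, 5))),
                     x = rnorm(30))
  out2 <- group_compare_suite(coh2, vars = "x", sex_col = "sex")
  expect_equal(out2$statistic[out2$variable == "sex"], 0)

  # degenerate variables are skipped with a message
  coh3 <- data.frame(group = rep(c("A", "B"), each = 6),
                     flat = 1, x = rnorm(12))
  expect_message(out3 <- group_compare_suite(coh3, vars = c("flat", "x")),
                 "degenerate")
  expect_false("flat" %in% out3$variable)
})

test_that("SBR follows the background-ratio definition", {
  expect_equal(compute_sbr(2, 1), 1)
  expect_equal(compute_sbr(1.5, 1.5), 0)
  expect_equal(compute_sbr(1.8, 1.2), 0.5)
  expect_error(compute_sbr(1, 0), class = "taplab_invalid_argument")
  expect_equal(log_sbr(exp(2)), 2)
  expect_error(log_sbr(-0.1), class = "taplab_invalid_argument")
})
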