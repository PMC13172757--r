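#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic follows
#' the larger-rank convention for the first sample, so that
#' `U / (n1 * n2)` estimates `P(X > Y) + 0.5 P(X = Y)` — the identity
#' linking U to the empirical ROC AUC. The p-value is exact (by
#' enumeration) when `n1 * n2 <= 400` and the data are tie-free, and a
#' tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y Numeric samples (the first group carries the convention).
#' @param two_tailed Two-sided p-value (default `TRUE`; otherwise the
#'   alternative is `x` stochastically greater).
#' @return List with `U`, `p`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(4, 5, 6), c(1, 2, 3))  # complete separation: U = 9, p = 0.1
#' @export
mann_whitney <- function(x, y, two_tailed = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L)
    stop_taplab("both groups must be non-empty", "taplab_invalid_argument")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && n1 * n2 <= 400
  p <- suppressWarnings(wilcox.test(
    x, y, exact = exact, correct = TRUE,
    alternative = if (two_tailed) "two.sided" else "greater")$p.value)
  list(U = unname(U), p = p, n1 = n1, n2 = n2)
}

#' AUC from the Mann-Whitney U statistic
#'
#' The empirical ROC AUC equals `U / (n1 * n2)` when U follows the
#' larger-rank convention of [mann_whitney()]. This identity lets AUCs be
#' checked directly against published U statistics.
#'
#' @param U Mann-Whitney U for the positive group.
#' @param n1,n2 Group sizes.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_from_u(297.5, 32, 10)  # 0.9297
#' @export
auc_from_u <- function(U, n1, n2) {
  if (any(U < 0) || any(U > n1 * n2))
    stop_taplab("U must lie in [0, n1 * n2]", "taplab_invalid_argument")
  U / (n1 * n2)
}

resolve_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    pos <- if (is.null(positive)) TRUE else positive
    return(labels == pos)
  }
  f <- as.factor(labels)
  if (nlevels(f) != 2L)
    stop_taplab("labels must have exactly 2 classes", "taplab_invalid_argument")
  pos <- if (is.null(positive)) levels(f)[2] else as.character(positive)
  if (!pos %in% levels(f))
    stop_taplab("`positive` is not a label level", "taplab_invalid_argument")
  as.character(f) == pos
}

#' ROC analysis with DeLong inference
#'
#' Empirical (tie-aware) ROC AUC in the fixed orientation "higher score
#' indicates the positive class" — an AUC below 0.5 is reported as-is
#' rather than flipped. Standard error and 95% CI come from DeLong's
#' method, the p-value from the DeLong z test against AUC = 0.5, and the
#' operating point from the Youden cutoff. On any dataset the AUC equals
#' `auc_from_u(mann_whitney(pos, neg)$U, n1, n2)`.
#'
#' @param scores Numeric classifier scores or feature values.
#' @param labels Two-class labels.
#' @param positive Label value treated as positive (default: `TRUE` for
#'   logical labels, the second factor level otherwise).
#' @return A `tap_roc` list: `auc`, `se`, `ci95`, `p_vs_half`, `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  pos <- resolve_labels(labels, positive)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  if (!any(pos) || all(pos))
    stop_taplab("both classes must be present", "taplab_invalid_argument")
  r <- pROC::roc(response = pos, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # pROC warns that a degenerate (AUC = 1) curve has zero DeLong variance;
  # the Inf z-score and p = 0 are the intended limits here
  se <- suppressWarnings(sqrt(as.numeric(pROC::var(r, method = "delong"))))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  z <- (auc - 0.5) / se
  yj <- youden_cutoff(scores, pos)
  structure(
    list(auc = auc, se = se, ci95 = c(max(ci[1], 0), min(ci[2], 1)),
         p_vs_half = 2 * pnorm(-abs(z)),
         cutoff = yj$cutoff, sensitivity = yj$sensitivity,
         specificity = yj$specificity, accuracy = yj$accuracy,
         n_pos = sum(pos), n_neg = sum(!pos)),
    class = "tap_roc")
}

#' @export
print.tap_roc <- function(x, ...) {
  cat(sprintf(
    "<tap_roc> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f, p = %.4g)\n",
    x$auc, x$se, x$ci95[1], x$ci95[2], x$p_vs_half))
  cat(sprintf(
    "  Youden cutoff %.4g: sens %.1f%%, spec %.1f%%, accuracy %.1f%%\n",
    x$cutoff, 100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Optimal cutoff by the Youden index
#'
#' Scans all midpoints between adjacent sorted unique scores and returns
#' the threshold maximizing sensitivity + specificity - 1 under the rule
#' "score >= cutoff is positive". Ties are broken toward higher
#' specificity, then toward the lower cutoff.
#'
#' @inheritParams roc_analysis
#' @return List with `cutoff`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden_j`.
#' @export
youden_cutoff <- function(scores, labels, positive = NULL) {
  pos <- resolve_labels(labels, positive)
  if (!any(pos) || all(pos))
    stop_taplab("both classes must be present", "taplab_invalid_argument")
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop_taplab("scores are constant", "taplab_invalid_argument")
  cand <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cand, function(c) mean(scores[pos] >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(scores[!pos] < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-spec[best], cand[best])][1]
  n1 <- sum(pos); n2 <- sum(!pos)
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best],
       accuracy = (sens[best] * n1 + spec[best] * n2) / (n1 + n2),
       youden_j = j[best])
}

#' Binary logistic regression with classification diagnostics
#'
#' Maximum-likelihood logistic fit (IRLS, convergence tolerance 1e-8, at
#' most 100 iterations) of class membership on an untransformed feature
#' matrix, reporting per-feature Wald statistics `(beta/se)^2` with
#' chi-square p-values and odds ratios, the omnibus likelihood-ratio test
#' against the intercept-only model, Cox-Snell and Nagelkerke pseudo-R2,
#' and the fraction correctly classified at probability 0.5. Perfect
#' separation or non-convergence is flagged, not silently ignored.
#'
#' @param x Data frame or matrix of predictors.
#' @param labels Two-class labels.
#' @param positive Label value modelled as 1.
#' @return A `tap_logistic` list: `coefficients` (data frame with
#'   `estimate`, `se`, `wald`, `p`, `odds_ratio`), `omnibus_chi2`,
#'   `omnibus_df`, `omnibus_p`, `cox_snell_r2`, `nagelkerke_r2`,
#'   `pct_correct`, `converged`, `separation`, `n`.
#' @export
logistic_fit <- function(x, labels, positive = NULL) {
  y <- resolve_labels(labels, positive)
  x <- as.data.frame(x)
  n <- nrow(x)
  if (n != length(y))
    stop_taplab("x and labels lengths differ", "taplab_invalid_argument")
  if (n <= ncol(x) + 1L)
    stop_taplab("need n > p + 1 observations", "taplab_invalid_argument")
  if (any(vapply(x, function(col) var(as.numeric(col)) == 0, logical(1))))
    stop_taplab("constant predictor column", "taplab_invalid_argument")
  dat <- cbind(.y = as.integer(y), x)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = dat,
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  null <- glm(.y ~ 1, family = binomial(), data = dat)
  sm <- summary(fit)$coefficients
  ll_full <- as.numeric(logLik(fit))
  ll_null <- as.numeric(logLik(null))
  omnibus <- 2 * (ll_full - ll_null)
  df <- ncol(x)
  cs <- 1 - exp(2 * (ll_null - ll_full) / n)
  nk <- cs / (1 - exp(2 * ll_null / n))
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    wald = (sm[, 1] / sm[, 2])^2,
    p = pchisq((sm[, 1] / sm[, 2])^2, df = 1, lower.tail = FALSE),
    odds_ratio = exp(sm[, 1]), row.names = NULL)
  structure(
    list(coefficients = coefs, omnibus_chi2 = omnibus, omnibus_df = df,
         omnibus_p = pchisq(omnibus, df, lower.tail = FALSE),
         cox_snell_r2 = cs, nagelkerke_r2 = nk,
         pct_correct = mean((fitted(fit) >= 0.5) == y),
         converged = fit$converged, separation = sep, n = n),
    class = "tap_logistic")
}

#' @export
print.tap_logistic <- function(x, ...) {
  cat(sprintf(
    "<tap_logistic> omnibus chi2(%d) = %.3f, p = %.4g | Cox-Snell R2 %.3f | Nagelkerke R2 %.3f | %.1f%% correct\n",
    x$omnibus_df, x$omnibus_chi2, x$omnibus_p, x$cox_snell_r2,
    x$nagelkerke_r2, 100 * x$pct_correct))
  if (x$separation) cat("  warning: (quasi-)separation detected\n")
  if (!x$converged) cat("  warning: IRLS did not converge\n")
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 4), wald = signif(wald, 4),
                  p = signif(p, 4), odds_ratio = signif(odds_ratio, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Spearman correlation with a bootstrap confidence interval
#'
#' Tie-aware Spearman rho (Pearson correlation of average ranks), p-value
#' from the t approximation on n - 2 degrees of freedom, and a percentile
#' 95% CI from seeded non-parametric bootstrap resampling of subject
#' pairs (default 1000 iterations).
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return A `tap_correlation` list: `rho`, `p`, `ci95`, `n`, `n_boot`.
#'   The `q` slot is filled by [bh_adjust()] at the family level.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 1000, seed = NULL, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L)
    stop_taplab("need at least 5 paired observations", "taplab_invalid_argument")
  if (sd(x) == 0 || sd(y) == 0)
    stop_taplab("correlation undefined for constant input",
                "taplab_invalid_argument")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
    cor(rank(x[i]), rank(y[i]))
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(rho = rho, p = p, ci95 = ci, n = n, n_boot = n_boot,
                 q = NA_real_),
            class = "tap_correlation")
}

#' @export
print.tap_correlation <- function(x, ...) {
  cat(sprintf(
    "<tap_correlation> rho = %.3f (95%% CI %.3f-%.3f), p = %.4g%s, n = %d\n",
    x$rho, x$ci95[1], x$ci95[2], x$p,
    if (is.na(x$q)) "" else sprintf(", q = %.4g", x$q), x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and mapped back to
#' input order. Invariant to permutation of the input.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_taplab("p-values must lie in [0, 1]", "taplab_invalid_argument")
  p.adjust(p, method = "BH")
}

#' Two-group comparison suite with normality-gated test choice
#'
#' For each variable: Shapiro-Wilk within each group decides the test —
#' Welch's t when both groups look normal (p > `alpha_normal`),
#' Mann-Whitney otherwise. A sex column, if named, is compared with a
#' Pearson chi-square test. All tests are two-tailed and the family is
#' BH-adjusted.
#'
#' @param cohort Data frame of subject rows.
#' @param vars Character vector of numeric columns to compare.
#' @param group_col Name of the two-level group column (default
#'   `"group"`).
#' @param sex_col Optional name of a categorical sex column.
#' @param alpha_normal Shapiro-Wilk threshold (default 0.05).
#' @return Data frame: `variable`, `test`, `statistic`, `p`, `q`.
#'   Degenerate (constant or near-empty) variables are skipped with a
#'   message.
#' @export
group_compare_suite <- function(cohort, vars, group_col = "group",
                                sex_col = NULL, alpha_normal = 0.05) {
  g <- as.factor(cohort[[group_col]])
  if (nlevels(g) != 2L)
    stop_taplab("exactly two groups required", "taplab_invalid_argument")
  lv <- levels(g)
  rows <- list()
  for (v in vars) {
    a <- cohort[[v]][g == lv[1]]
    b <- cohort[[v]][g == lv[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L || sd(a) == 0 || sd(b) == 0) {
      message("skipping degenerate variable: ", v)
      next
    }
    normal <- shapiro.test(a)$p.value > alpha_normal &&
      shapiro.test(b)$p.value > alpha_normal
    if (normal) {
      tt <- t.test(a, b)  # Welch by default
      rows[[v]] <- data.frame(variable = v, test = "welch_t",
                              statistic = unname(tt$statistic),
                              p = tt$p.value)
    } else {
      mw <- mann_whitney(a, b)
      rows[[v]] <- data.frame(variable = v, test = "mann_whitney",
                              statistic = mw$U, p = mw$p)
    }
  }
  if (!is.null(sex_col)) {
    tab <- table(cohort[[sex_col]], g)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[sex_col]] <- data.frame(variable = sex_col, test = "chi_square",
                                  statistic = unname(ct$statistic),
                                  p = ct$p.value)
  }
  if (!length(rows))
    stop_taplab("no testable variables", "taplab_invalid_argument")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Striatal binding ratio
#'
#' `SBR = (roi_mean - background_mean) / background_mean`, the
#' semi-quantitative DAT-SPECT uptake ratio of a striatal region against
#' the occipital background. `log_sbr()` gives the log transform used for
#' hemispheric modelling and is defined only for positive SBR.
#'
#' @param roi_mean Mean tracer uptake in the region of interest.
#' @param background_mean Mean occipital background uptake (> 0).
#' @return Scalar (or vector) SBR.
#' @examples
#' compute_sbr(1.8, 1.2)  # 0.5
#' @export
compute_sbr <- function(roi_mean, background_mean) {
  if (any(background_mean <= 0))
    stop_taplab("background_mean must be > 0", "taplab_invalid_argument")
  (roi_mean - background_mean) / background_mean
}

#' @rdname compute_sbr
#' @param sbr A striatal binding ratio (> 0).
#' @export
log_sbr <- function(sbr) {
  if (any(sbr <= 0))
    stop_taplab("log(SBR) defined only for SBR > 0", "taplab_invalid_argument")
  log(sbr)
}
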