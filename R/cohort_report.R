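#' Sequential participant-selection flow accounting
#'
#' Applies the study's exclusion chain in its narrative order — duplicate
#' records, non-qualifying diagnosis, imaging-to-video window exceeded,
#' low recording quality — and returns the per-stage bookkeeping of a
#' selection flow diagram. A record failing several criteria is counted
#' once, at the earliest matching stage; conflicting flags are therefore
#' resolved by stage precedence. Flow is conserved: at every stage
#' `n_out = n_in - n_excluded`, and stages chain.
#'
#' @param records Data frame with one row per candidate and logical flag
#'   columns `duplicate`, `non_pd`, `dat_window_exceeded`, `low_quality`
#'   (missing flags are treated as all-`FALSE`).
#' @return A `selection_flow` data frame with columns `stage`, `n_in`,
#'   `n_excluded`, `exclusion_reason`, `n_out`; the attribute `final`
#'   holds the retained records.
#' @examples
#' rec <- data.frame(duplicate = c(TRUE, FALSE, FALSE),
#'                   non_pd = c(TRUE, TRUE, FALSE),
#'                   dat_window_exceeded = FALSE, low_quality = FALSE)
#' apply_selection_flow(rec)  # 1 duplicate, then 1 non-PD, final n = 1
#' @export
apply_selection_flow <- function(records) {
  stages <- c(duplicate = "duplicates",
              non_pd = "diagnosis",
              dat_window_exceeded = "dat_window",
              low_quality = "quality")
  for (flag in names(stages)) {
    if (!flag %in% names(records)) records[[flag]] <- FALSE
    records[[flag]][is.na(records[[flag]])] <- FALSE
  }
  out <- list()
  current <- records
  for (flag in names(stages)) {
    n_in <- nrow(current)
    drop <- as.logical(current[[flag]])
    out[[flag]] <- data.frame(
      stage = stages[[flag]], n_in = n_in, n_excluded = sum(drop),
      exclusion_reason = flag, n_out = n_in - sum(drop))
    current <- current[!drop, , drop = FALSE]
  }
  flow <- do.call(rbind, out)
  rownames(flow) <- NULL
  structure(flow, class = c("selection_flow", "data.frame"), final = current)
}

#' Final cohort retained by a selection flow
#'
#' @param flow A `selection_flow` from [apply_selection_flow()].
#' @return The data frame of retained records.
#' @export
selection_final <- function(flow) attr(flow, "final")

#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end orchestration: simulate a labelled cohort (waveform
#' generation, conditioning, tap detection, feature extraction), drop
#' subjects failing cycle QC, and compute the cohort statistics — group
#' comparisons, per-feature ROC with Youden cutoffs, multivariable
#' logistic classification, and Spearman correlations (with bootstrap
#' CIs and BH adjustment) of each feature against each clinical anchor.
#' All tables are written as CSV under `out_dir` together with a JSON run
#' manifest recording the seed and parameters; re-running with the same
#' config reproduces identical tables.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `seed` (integer), `groups` (list of lists with `label`,
#'   `n_subjects`, `acov`, `ifcov`, `v` quartile triples), and optional
#'   `fps`, `duration_s`, `mean_frequency`, `noise_sd`, `n_boot`,
#'   `disease_label`, `clinical` (logical, default `TRUE`).
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `cohort`, `features`, `group_tests`,
#'   `roc`, `logistic`, `correlations`, `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_taplab("reading YAML configs requires the yaml package",
                  "taplab_invalid_argument")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$groups) || length(config$groups) < 2L)
    stop_taplab("config must define at least 2 groups", "taplab_invalid_argument")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  groups <- lapply(config$groups, function(g)
    group_spec(g$label, g$n_subjects, unlist(g$acov), unlist(g$ifcov),
               unlist(g$v)))
  args <- list(groups = groups, seed = seed)
  for (nm in c("fps", "duration_s", "mean_frequency", "noise_sd"))
    if (!is.null(config[[nm]])) args[[nm]] <- config[[nm]]
  cohort <- do.call(simulate_cohort, args)
  disease <- if (is.null(config$disease_label)) groups[[1]]$label
             else config$disease_label
  if (!identical(config$clinical, FALSE))
    cohort <- attach_synthetic_clinical(cohort, disease_label = disease,
                                        seed = seed + 1L)

  excluded <- cohort[!cohort$qc_pass, , drop = FALSE]
  kept <- cohort[cohort$qc_pass, , drop = FALSE]
  feats <- c("V", "delta_a", "aCoV", "ifCoV")
  group_tests <- group_compare_suite(kept, vars = feats)

  roc_rows <- lapply(feats, function(f) {
    r <- roc_analysis(kept[[f]], kept$group == disease)
    data.frame(feature = f, auc = r$auc, se = r$se,
               ci_lo = r$ci95[1], ci_hi = r$ci95[2], p = r$p_vs_half,
               cutoff = r$cutoff, sensitivity = r$sensitivity,
               specificity = r$specificity, accuracy = r$accuracy)
  })
  roc_tab <- do.call(rbind, roc_rows)

  logit <- tryCatch(logistic_fit(kept[feats], kept$group == disease),
                    taplab_error = function(e) NULL)

  n_boot <- if (is.null(config$n_boot)) 1000L else as.integer(config$n_boot)
  anchors <- intersect(c("updrs3_total", "item_3_4", "duration_y",
                         "sbr_striatum", "sbr_putamen", "sbr_caudate"),
                       names(kept))
  cor_tab <- NULL
  if (length(anchors)) {
    pd <- kept[kept$group == disease, , drop = FALSE]
    rows <- list()
    k <- 0L
    for (an in anchors) {
      fam <- list()
      for (f in feats) {
        res <- tryCatch(
          spearman_bootstrap(pd[[f]], pd[[an]], n_boot = n_boot,
                             seed = seed + 100L + k),
          taplab_error = function(e) NULL)
        k <- k + 1L
        if (!is.null(res))
          fam[[f]] <- data.frame(anchor = an, feature = f, rho = res$rho,
                                 p = res$p, ci_lo = res$ci95[1],
                                 ci_hi = res$ci95[2], n = res$n)
      }
      if (length(fam)) {
        fam <- do.call(rbind, fam)
        # BH family: all feature correlations against one clinical anchor
        fam$q <- bh_adjust(fam$p)
        rows[[an]] <- fam
      }
    }
    if (length(rows)) cor_tab <- do.call(rbind, rows)
  }

  manifest <- list(
    package = "taplab",
    version = as.character(utils::packageVersion("taplab")),
    seed = seed, n_boot = n_boot,
    groups = lapply(groups, function(g)
      list(label = g$label, n_subjects = g$n_subjects,
           acov = g$acov, ifcov = g$ifcov, v = g$v)),
    generator = args[setdiff(names(args), c("groups", "seed"))],
    n_simulated = nrow(cohort), n_analyzed = nrow(kept),
    n_excluded_qc = nrow(excluded))

  result <- list(cohort = cohort, features = kept, group_tests = group_tests,
                 roc = roc_tab, logistic = logit, exclusions = excluded,
                 correlations = cor_tab, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) if (!is.null(df))
      write.csv(df, file.path(out_dir, nm), row.names = FALSE)
    wr(kept, "features.csv")
    wr(group_tests, "group_tests.csv")
    wr(roc_tab, "roc.csv")
    wr(cor_tab, "correlations.csv")
    wr(excluded, "exclusions.csv")
    if (!is.null(logit)) wr(logit$coefficients, "logistic.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summ <- c(
      "taplab pipeline summary",
      sprintf("subjects simulated: %d; analyzed: %d; excluded by QC: %d",
              nrow(cohort), nrow(kept), nrow(excluded)),
      sprintf("group sizes: %s",
              paste(names(table(kept$group)), table(kept$group),
                    sep = "=", collapse = ", ")),
      sprintf("best AUC: %s = %.3f",
              roc_tab$feature[which.max(roc_tab$auc)], max(roc_tab$auc)))
    writeLines(summ, file.path(out_dir, "summary.txt"))
  }
  invisible(result)
}
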