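#  Cohort-level statistics: normality-gated summaries and tests, 95% cohort
#  ranges (normal values), bootstrap confidence intervals of the median, and
#  the seven-table normative report.

#  Shapiro-Wilk p-value with the gate's edge cases handled: constant samples
#  are treated as non-normal (p = 0); samples beyond the test's 5000-value
#  limit are subsampled deterministically.
normality_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  if (length(x) > 5000) {
    x <- with_seed(1L, sample(x, 5000))
  }
  stats::shapiro.test(x)$p.value
}

#' Summary statistics, normal range and median CI for one metric
#'
#' Computes n, mean, SD, median, IQR (Q3 - Q1, linear-interpolation
#' quantiles), the 95% cohort range (2.5th-97.5th percentiles, used as the
#' normal range), a bootstrap percentile CI of the median, and the
#' Shapiro-Wilk normality p-value that decides whether mean +/- SD or
#' median +/- IQR is the canonical presentation.
#'
#' @param x numeric sample (n >= 2 after NA removal).
#' @param boot bootstrap resamples for the median CI (default 2000).
#' @param boot_seed RNG seed for the bootstrap (fixed for reproducibility).
#' @param conf confidence level for the median CI.
#' @param alpha significance level of the normality gate.
#' @return one-row tibble with fields `n, mean, sd, median, iqr,
#'   normal_range_low, normal_range_high, ci_low, ci_high, normality_p,
#'   normal`.
#' @export
summarize_metric <- function(x, boot = 2000, boot_seed = 1, conf = 0.95,
                             alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop_tp("need at least 2 values to summarize a metric")
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                       type = 7)
  ci <- with_seed(boot_seed, {
    meds <- vapply(seq_len(boot), function(i) {
      stats::median(x[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  p_norm <- normality_p(x)
  tibble::tibble(n = n, mean = mean(x), sd = stats::sd(x),
                 median = q[3], iqr = q[4] - q[2],
                 normal_range_low = q[1], normal_range_high = q[5],
                 ci_low = ci[1], ci_high = ci[2],
                 normality_p = p_norm, normal = p_norm >= alpha)
}

#' Two-group comparison with a normality gate
#'
#' Selects the test from the Shapiro-Wilk gate and the pairing flag:
#' independent t-test / Mann-Whitney U for unpaired data, paired t-test /
#' Wilcoxon signed-rank for paired data (gated on the paired differences).
#'
#' @param values_a,values_b numeric samples (n >= 3 each; equal length when
#'   paired).
#' @param paired logical.
#' @param alpha significance level of the normality gate.
#' @return list with `test`, `statistic`, `p_value`, `direction` (sign of
#'   a's central tendency minus b's) and `normal` (gate decision).
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE, alpha = 0.05) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (paired) {
    if (length(values_a) != length(values_b)) {
      stop_tp("paired comparison requires samples of equal length")
    }
    keep <- !is.na(values_a) & !is.na(values_b)
    a <- values_a[keep]; b <- values_b[keep]
  }
  if (length(a) < 3 || length(b) < 3) {
    stop_tp("need at least 3 values per group")
  }
  normal <- if (paired) {
    normality_p(a - b) >= alpha
  } else {
    normality_p(a) >= alpha && normality_p(b) >= alpha
  }
  res <- if (normal) {
    ht <- stats::t.test(a, b, paired = paired)
    list(test = if (paired) "paired t-test" else "independent t-test",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    list(test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  delta <- if (paired) stats::median(a - b) else
    stats::median(a) - stats::median(b)
  c(res, list(direction = sign(delta), normal = normal))
}

#' Comparison across three or more paired conditions
#'
#' The >= 3-condition analogue of [compare_groups()]: Friedman's two-way
#' analysis of variance by ranks when any condition fails the normality
#' gate, otherwise one-way repeated-measures ANOVA. Pairwise contrasts are
#' reported with Bonferroni-adjusted p-values (the adjustment used for slice
#' contrasts).
#'
#' @param values numeric matrix, subjects x conditions (named columns).
#' @param alpha significance level of the normality gate.
#' @param p_adjust adjustment method for pairwise contrasts.
#' @return list with `test`, `statistic`, `p_value`, and a `pairwise` tibble.
#' @export
compare_conditions <- function(values, alpha = 0.05, p_adjust = "bonferroni") {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  if (ncol(values) < 3 || nrow(values) < 3) {
    stop_tp("need >= 3 conditions and >= 3 complete subjects")
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(ncol(values)))
  normal <- all(apply(values, 2, normality_p) >= alpha)
  if (normal) {
    long <- data.frame(
      y = as.vector(values),
      cond = factor(rep(colnames(values), each = nrow(values))),
      id = factor(rep(seq_len(nrow(values)), ncol(values))))
    fit <- stats::aov(y ~ cond + Error(id), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    omnibus <- list(test = "repeated-measures ANOVA",
                    statistic = tab["cond", "F value"],
                    p_value = tab["cond", "Pr(>F)"])
  } else {
    ht <- stats::friedman.test(values)
    omnibus <- list(test = "Friedman",
                    statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  pairs <- utils::combn(colnames(values), 2, simplify = FALSE)
  pw <- dplyr::bind_rows(lapply(pairs, function(pr) {
    cg <- compare_groups(values[, pr[1]], values[, pr[2]], paired = TRUE,
                         alpha = alpha)
    tibble::tibble(a = pr[1], b = pr[2], test = cg$test,
                   p_value = cg$p_value, direction = cg$direction)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = p_adjust)
  c(omnibus, list(normal = normal, pairwise = pw))
}

#' Correlation of a metric with age
#'
#' Pearson when both variables pass the Shapiro-Wilk gate, Spearman rank
#' correlation otherwise.
#'
#' @param values metric sample.
#' @param ages ages in years, same length.
#' @param method `"auto"` (gate-selected), `"pearson"` or `"spearman"`.
#' @param alpha significance level of the normality gate.
#' @return list with `r`, `p_value`, `method`, `n`.
#' @export
correlate_age <- function(values, ages, method = c("auto", "pearson", "spearman"),
                          alpha = 0.05) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(ages)
  values <- values[keep]; ages <- ages[keep]
  if (length(values) < 10) stop_tp("need at least 10 complete pairs")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
    stop_tp("correlation undefined for a constant input")
  }
  if (method == "auto") {
    method <- if (normality_p(values) >= alpha && normality_p(ages) >= alpha) {
      "pearson"
    } else "spearman"
  }
  ht <- suppressWarnings(stats::cor.test(values, ages, method = method,
                                         exact = FALSE))
  list(r = unname(ht$estimate), p_value = ht$p.value, method = method,
       n = length(values))
}

#  One report table: per-parameter overall and by-sex summaries plus the
#  female-vs-male comparison. Single-sex cohorts yield NA comparison columns.
report_table <- function(df, params, boot_seed = 1) {
  params <- intersect(params, names(df))
  rows <- lapply(params, function(p) {
    x <- df[[p]]
    all_s <- summarize_metric(x, boot_seed = boot_seed)
    out <- tibble::tibble(parameter = p)
    add <- function(s, tag) {
      s <- stats::setNames(s, paste0(names(s), "_", tag))
      tibble::as_tibble(s)
    }
    out <- dplyr::bind_cols(out, add(all_s, "all"))
    f <- x[df$sex == "female"]; m <- x[df$sex == "male"]
    if (sum(!is.na(f)) >= 2 && sum(!is.na(m)) >= 2) {
      out <- dplyr::bind_cols(out, add(summarize_metric(f, boot_seed = boot_seed), "female"),
                              add(summarize_metric(m, boot_seed = boot_seed), "male"))
      if (sum(!is.na(f)) >= 3 && sum(!is.na(m)) >= 3 &&
          (stats::sd(f, na.rm = TRUE) > 0 || stats::sd(m, na.rm = TRUE) > 0)) {
        cg <- compare_groups(f, m)
        out$p_sex <- cg$p_value
        out$test_sex <- cg$test
      } else {
        out$p_sex <- NA_real_; out$test_sex <- NA_character_
      }
    } else {
      out$p_sex <- NA_real_; out$test_sex <- NA_character_
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Normative report for a cohort of subject records
#'
#' Builds the seven-table normative report from a metrics table
#' ([cohort_metrics()] output): demographics/hemodynamics, global and
#' regional wall MBF/MPR, global layer MBF/MPR, slice-specific layer MPR,
#' global and regional transmural gradients, slice-specific gradients, and
#' slice-specific normal values (median, IQR, 95% CI of the median and the
#' 95% cohort range). Each table reports the whole cohort and the two sexes
#' with a gate-selected comparison p-value; slice tables add
#' Bonferroni-adjusted pairwise slice contrasts. Subjects flagged
#' `qc_excluded` are dropped and counted.
#'
#' @param metrics tibble from [cohort_metrics()] with `sex` and
#'   `qc_excluded` columns.
#' @param boot_seed seed for all bootstrap CIs.
#' @return object of class `cohort_report`: `$tables` (named list of seven
#'   tibbles), `$slice_contrasts`, `$n_total`, `$n_excluded`, `$n_used`.
#' @export
build_report <- function(metrics, boot_seed = 1) {
  n_total <- nrow(metrics)
  excl <- metrics$qc_excluded %||% rep(FALSE, n_total)
  df <- metrics[!excl, , drop = FALSE]
  if (nrow(df) < 2) {
    stop_tp("fewer than 2 subjects remain after QC exclusion")
  }
  df <- df[order(df$subject_id), , drop = FALSE]
  df$hr_change <- df$hr_stress - df$hr_rest
  df$sbp_change <- df$sbp_stress - df$sbp_rest
  df$rpp_change <- df$rpp_stress - df$rpp_rest

  tables <- list(
    demographics = report_table(df, c("age", "hr_rest", "sbp_rest", "rpp_rest",
                                      "hr_stress", "sbp_stress", "rpp_stress",
                                      "hr_change", "sbp_change", "rpp_change"),
                                boot_seed),
    global_mbf = report_table(df, c("rmbf_wall_global", "rmbf_c",
                                    "smbf_wall_global", "mpr_global", "mpr_c",
                                    paste0("rmbf_wall_", c("lad", "lcx", "rca")),
                                    paste0("smbf_wall_", c("lad", "lcx", "rca")),
                                    paste0("mpr_", c("lad", "lcx", "rca"))),
                              boot_seed),
    layer_mbf = report_table(df, c("rmbf_endo_global", "rmbf_epi_global",
                                   "smbf_endo_global", "smbf_epi_global",
                                   "mpr_endo_global", "mpr_epi_global"),
                             boot_seed),
    slice_mpr = report_table(df, c(paste0("mpr_endo_", c("basal", "mid", "apical")),
                                   paste0("mpr_epi_", c("basal", "mid", "apical"))),
                             boot_seed),
    gradients = report_table(df, c("sgrad_global", "rgrad_global",
                                   paste0("sgrad_", c("lad", "lcx", "rca")),
                                   paste0("rgrad_", c("lad", "lcx", "rca"))),
                             boot_seed),
    slice_gradients = report_table(df, c(paste0("sgrad_", c("basal", "mid", "apical")),
                                         paste0("rgrad_", c("basal", "mid", "apical"))),
                                   boot_seed))
  # Table 7 analogue: slice-specific normal values
  nv_rows <- list()
  for (mt in c("mpr_endo", "mpr_epi", "sgrad", "rgrad")) {
    for (sl in c("basal", "mid", "apical")) {
      cl <- paste(mt, sl, sep = "_")
      if (!cl %in% names(df)) next
      s <- summarize_metric(df[[cl]], boot_seed = boot_seed)
      nv_rows[[length(nv_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(metric = mt, slice = sl), s)
    }
  }
  tables$slice_normal_values <- dplyr::bind_rows(nv_rows)

  slice_contrasts <- list()
  for (mt in c("mpr_endo", "mpr_epi", "sgrad", "rgrad")) {
    cls <- paste(mt, c("basal", "mid", "apical"), sep = "_")
    if (all(cls %in% names(df))) {
      m <- as.matrix(df[cls])
      colnames(m) <- c("basal", "mid", "apical")
      slice_contrasts[[mt]] <- compare_conditions(m)
    }
  }

  structure(list(tables = tables, slice_contrasts = slice_contrasts,
                 n_total = n_total, n_excluded = sum(excl),
                 n_used = nrow(df)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects used (%d excluded of %d)\n",
              x$n_used, x$n_excluded, x$n_total))
  for (nm in names(x$tables)) {
    cat(sprintf("  $tables$%s: %d parameters\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Structure-recovery check over replicate simulated cohorts
#'
#' Simulates `n_rep` cohorts under a specification and records, per
#' replicate, whether the expected physiological structure is recovered:
#' median MPR_ENDO below MPR_EPI, median sGRAD below rGRAD, a significant
#' negative stress-MBF/age correlation together with a non-significant
#' rest-MBF/age correlation, a significant female > male rest-MBF
#' difference, and the mid-slice MPR_ENDO median below both basal and
#' apical.
#'
#' @param n_rep number of replicate cohorts.
#' @param spec a [cohort_spec()].
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @return tibble of logicals (one row per replicate) with an `all_ok`
#'   column.
#' @export
cohort_structure_replicates <- function(n_rep = 200, spec = cohort_spec(),
                                        seed = 1) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_rep))
  rows <- lapply(seq_len(n_rep), function(i) {
    co <- cohort_metrics(make_cohort(spec, seed = seeds[i]))
    age_s <- correlate_age(co$smbf_endo_global, co$age)
    age_r <- correlate_age(co$rmbf_endo_global, co$age)
    sexcmp <- compare_groups(co$rmbf_wall_global[co$sex == "female"],
                             co$rmbf_wall_global[co$sex == "male"])
    tibble::tibble(
      mpr_layer_order = stats::median(co$mpr_endo_global) <
        stats::median(co$mpr_epi_global),
      grad_order = stats::median(co$sgrad_global) <
        stats::median(co$rgrad_global),
      stress_age_negative = age_s$r < 0 && age_s$p_value < 0.05,
      rest_age_ns = age_r$p_value >= 0.05,
      sex_rest_mbf = sexcmp$p_value < 0.05 && sexcmp$direction > 0,
      mid_slice_lowest = stats::median(co$mpr_endo_mid) <
        stats::median(co$mpr_endo_basal) &&
        stats::median(co$mpr_endo_mid) < stats::median(co$mpr_endo_apical))
  })
  out <- dplyr::bind_rows(rows)
  out$all_ok <- Reduce(`&`, out)
  out
}
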