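# Cohort-level statistics: normality screening, equal-variance Student t
# comparisons by sex and age group (independent) and laterality (paired),
# and the a-priori sample-size calculation via the noncentral-t power
# function.

#' Shapiro-Wilk normality p-value
#'
#' @param values Numeric vector, n >= 3.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    rlang::abort("normality test needs at least 3 values",
                 class = "coronoid_precondition_error")
  }
  stats::shapiro.test(values)$p.value
}

#' Independent two-sample Student t-test
#'
#' Classic equal-variance form (df = n_a + n_b - 2, not Welch), used for
#' the sex and age-group comparisons.
#'
#' @param a,b Numeric vectors.
#' @return Tibble with `t`, `df`, `p`, group means and SDs.
#' @export
independent_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    rlang::abort("each group needs at least 2 values",
                 class = "coronoid_precondition_error")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b))
}

#' Paired two-sample Student t-test
#'
#' One-sample t on the paired differences (df = n - 1), used for the
#' bilateral (laterality) comparisons.
#'
#' @param a,b Numeric vectors of equal length (pairs in matching order).
#' @return Tibble with `t`, `df`, `p`, group means and SDs.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("paired test needs equal-length vectors",
                 class = "coronoid_precondition_error")
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) {
    rlang::abort("paired test needs at least 2 complete pairs",
                 class = "coronoid_precondition_error")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    # identical pairs: no variance in the differences; t is 0 when the
    # shift is 0 and unbounded otherwise
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble::tibble(t = tt, df = length(a) - 1,
                          p = if (mean(d) == 0) 1 else 0,
                          mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                          mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b))
}

# power of the two-sided two-sample equal-variance t at level alpha,
# standardized effect d, n per group (noncentral-t)
two_sample_t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Sample size per group for the two-sample t-test
#'
#' Smallest per-group n whose noncentral-t power reaches `1 - beta` for a
#' two-sided equal-variance two-sample t at level `alpha`.
#'
#' @param effect_size Standardised effect size d (> 0).
#' @param alpha Type-I error level.
#' @param beta Type-II error level (power = 1 - beta).
#' @return Integer sample size per group (>= 2).
#' @export
sample_size_two_sample <- function(effect_size, alpha = 0.05, beta = 0.2) {
  if (!is.finite(effect_size) || effect_size <= 0) {
    rlang::abort("effect size must be positive (power unachievable at d = 0)",
                 class = "coronoid_precondition_error")
  }
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  target <- 1 - beta
  n <- 2L
  while (two_sample_t_power(n, effect_size, alpha) < target) {
    n <- n + 1L
    if (n > 1e7) rlang::abort("sample size search did not converge",
                              class = "coronoid_degenerate_error")
  }
  n
}

#' Cohort comparison report
#'
#' For each of the six parameters (the five fragment measurements plus the
#' covering percentage) runs the sex and age-group (> 40 vs <= 40 years)
#' independent Student t comparisons, and for the five side-wise
#' measurements the laterality paired t comparison. Covering percentage is
#' a per-subject (not per-side) quantity, so it has no laterality row.
#' Each row carries the Shapiro-Wilk normality p-value of the pooled
#' values entering the comparison.
#'
#' @param table Cohort tibble with one row per subject-side: columns
#'   `subject_id`, `sex`, `age`, `side`, the five `*_mm` measurements and
#'   optionally `covering_pct`.
#' @return Tibble of class `cohort_comparisons`: one row per parameter x
#'   grouping with group means, SDs, t, df, p, the test type and the
#'   normality p-value.
#' @export
build_report <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    rlang::abort("cohort table is empty", class = "coronoid_precondition_error")
  }
  params <- c("height_mm", "length_mm", "width_mm", "r_medial_mm", "r_lateral_mm")
  have_cov <- "covering_pct" %in% names(table)
  needed <- c("subject_id", "sex", "age", "side", params)
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    rlang::abort(paste("cohort table lacks columns:", paste(missing, collapse = ", ")),
                 class = "coronoid_precondition_error")
  }
  # subject-level view: side-averaged measurements, subject covering
  subj <- table |>
    dplyr::group_by(.data$subject_id, .data$sex, .data$age) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c(params,
                                                   if (have_cov) "covering_pct")),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  all_params <- c(params, if (have_cov) "covering_pct")
  rows <- list()
  for (pm in all_params) {
    vals <- subj[[pm]]
    norm_p <- tryCatch(normality_test(vals), error = function(e) NA_real_)
    for (grouping in c("sex", "age_40")) {
      if (grouping == "sex") {
        ga <- subj[[pm]][subj$sex == "male"]
        gb <- subj[[pm]][subj$sex == "female"]
        g1 <- "male"; g2 <- "female"
      } else {
        ga <- subj[[pm]][subj$age > 40]
        gb <- subj[[pm]][subj$age <= 40]
        g1 <- ">40y"; g2 <- "<=40y"
      }
      res <- tryCatch(independent_t(ga, gb), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(parameter = pm, grouping = grouping,
                       group1 = g1, group2 = g2,
                       test_type = "independent", normality_p = norm_p),
        res)
    }
    if (pm != "covering_pct") {
      wide <- table |>
        dplyr::select(dplyr::all_of(c("subject_id", "side", pm))) |>
        tidyr::pivot_wider(names_from = "side", values_from = dplyr::all_of(pm))
      if (all(c("left", "right") %in% names(wide))) {
        res <- tryCatch(paired_t(wide$left, wide$right), error = function(e) NULL)
        if (!is.null(res)) {
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(parameter = pm, grouping = "laterality",
                           group1 = "left", group2 = "right",
                           test_type = "paired", normality_p = norm_p),
            res)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cohort_comparisons", class(out))
  out
}

#' @export
glance.cohort_comparisons <- function(x, ...) {
  tibble::tibble(n_comparisons = nrow(x),
                 n_significant = sum(x$p < 0.05, na.rm = TRUE),
                 min_p = min(x$p, na.rm = TRUE))
}

#' Render a comparison report as aligned plain text
#'
#' Results-style table: one line per comparison with group means +/- SD,
#' t and p.
#'
#' @param report A [build_report()] result.
#' @return Character vector of lines, invisibly printed.
#' @export
format_report_text <- function(report) {
  lines <- sprintf("%-14s %-10s %18s %18s  t = %5.2f  P = %.3f",
                   report$parameter, report$grouping,
                   sprintf("%s %.2f +/- %.2f", report$group1, report$mean_a, report$sd_a),
                   sprintf("%s %.2f +/- %.2f", report$group2, report$mean_b, report$sd_b),
                   report$t, report$p)
  lines
}
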