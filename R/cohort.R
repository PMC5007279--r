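#' Dichotomize values at the fifth decile
#'
#' Splits a set of whole-cord NSUVs at their fifth decile (the median,
#' computed with the lower-interpolation convention, `quantile type 1`):
#' the low group takes values `<= threshold`, the high group values
#' `> threshold`.  With heavily tied data one group can be empty, which
#' raises a warning.
#'
#' @param values numeric vector, at least 2 values.
#' @return List with `threshold`, `low`, `high`.
#' @export
dichotomize_fifth_decile <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 values to dichotomize", call. = FALSE)
  thr <- unname(stats::quantile(values, 0.5, type = 1))
  low <- values[values <= thr]
  high <- values[values > thr]
  if (length(low) == 0L || length(high) == 0L)
    warning("degenerate dichotomization: one group is empty")
  list(threshold = thr, low = low, high = high)
}

#' Mortality rate as a rounded percentage
#'
#' @param deaths number of deaths, `0 <= deaths <= n`.
#' @param n group size, `> 0`.
#' @return `round(100 * deaths / n)`, an integer percent.
#' @export
mortality_rate <- function(deaths, n) {
  if (n <= 0) stop("group size must be > 0", call. = FALSE)
  if (deaths < 0 || deaths > n)
    stop("deaths must lie in [0, n]", call. = FALSE)
  round(100 * deaths / n)
}

#' Two-group comparison of a continuous measure
#'
#' Means +/- SD per group and an unpaired two-sample t test (Welch by
#' default), returned as a one-row tibble.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param var_equal passed to [stats::t.test()].
#' @return Tibble: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(tibble::tibble(mean_a = mean(a), sd_a = 0, n_a = length(a),
                          mean_b = mean(b), sd_b = 0, n_b = length(b),
                          statistic = 0, df = NA_real_, p_value = 1))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Contingency summary of deaths by NSUV group
#'
#' Dichotomizes subjects at the fifth-decile NSUV and tabulates deaths
#' and mortality rates per group plus the overall rate -- the desk-scale
#' contingency arithmetic of a survival read-out.
#'
#' @param cohort a cohort table (see [read_cohort_table()]) with columns
#'   `sc_nsuv` and `death` (0/1).
#' @return Tibble with rows `low`, `high`, `overall`: `n`, `deaths`,
#'   `mortality_pct`, and the `threshold` used.
#' @export
mortality_by_nsuv_group <- function(cohort) {
  stopifnot(all(c("sc_nsuv", "death") %in% names(cohort)))
  d <- dichotomize_fifth_decile(cohort$sc_nsuv)
  lowi <- cohort$sc_nsuv <= d$threshold
  row <- function(label, sel) tibble::tibble(
    group = label, n = sum(sel), deaths = sum(cohort$death[sel]),
    mortality_pct = mortality_rate(sum(cohort$death[sel]), sum(sel)),
    threshold = d$threshold)
  rbind(row("low", lowi), row("high", !lowi),
        row("overall", rep(TRUE, nrow(cohort))))
}

cohort_columns <- c("id", "group", "sc_nsuv", "survival_months", "death",
                    "age", "sex", "alsfrs_r", "months_to_pet", "riluzole")

#' Read or write a cohort table
#'
#' Tab-delimited table with a documented header: `id`, `group`,
#' `sc_nsuv`, `survival_months`, `death` (0/1), and the covariates
#' `age`, `sex`, `alsfrs_r`, `months_to_pet`, `riluzole`.  Missing
#' covariate columns are tolerated on read; `sc_nsuv` must be positive
#' and `survival_months` non-negative.
#'
#' @param path file path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sc_nsuv")
  if (!all(need %in% names(tab)))
    stop("cohort table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tab$sc_nsuv <= 0))
    stop("sc_nsuv must be > 0", call. = FALSE)
  if ("survival_months" %in% names(tab) && any(tab$survival_months < 0))
    stop("survival_months must be >= 0", call. = FALSE)
  tibble::as_tibble(tab)
}

#' @rdname read_cohort_table
#' @param cohort the table to write.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Survival read-outs over a cohort table
#'
#' Thin hooks over the standard survival routines for exploratory use:
#' Kaplan-Meier fit and log-rank test across the fifth-decile NSUV
#' groups.  Requires the `survival` package; these are validation
#' statistics around the method, not part of it.
#'
#' @param cohort cohort table with `sc_nsuv`, `survival_months`, `death`.
#' @return List with `km` (a `survfit`) and `logrank` (a `survdiff`).
#' @export
survival_by_nsuv_group <- function(cohort) {
  if (!requireNamespace("survival", quietly = TRUE))
    stop("the 'survival' package is required", call. = FALSE)
  d <- dichotomize_fifth_decile(cohort$sc_nsuv)
  grp <- factor(ifelse(cohort$sc_nsuv <= d$threshold, "low", "high"),
                levels = c("low", "high"))
  s <- survival::Surv(cohort$survival_months, cohort$death)
  list(km = survival::survfit(s ~ grp),
       logrank = survival::survdiff(s ~ grp))
}
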