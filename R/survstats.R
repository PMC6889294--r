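#' Pearson chi-square test on a contingency table
#'
#' Association test for categorical variables (mutation status against
#' histology, grade, stage, ...): the Pearson statistic
#' \eqn{\sum (O-E)^2 / E} with expectations from the margins,
#' `df = (r-1)(c-1)` and the upper chi-square tail. No continuity correction
#' by default; Yates' correction is available for 2x2 tables.
#'
#' @param counts Matrix or data frame of non-negative integer counts,
#'   at least 2x2.
#' @param correction `"none"` (default) or `"yates"`.
#' @return Tibble `statistic`, `df`, `p_value`, `method`.
#' @examples
#' chi_square_test(matrix(c(24, 8, 59, 5), 2, 2, byrow = TRUE))
#' @export
chi_square_test <- function(counts, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  m <- as.matrix(counts)
  if (any(m < 0) || nrow(m) < 2 || ncol(m) < 2) {
    abort("`counts` must be a non-negative table of at least 2x2.")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) {
    abort(sprintf("Row %s has a zero margin.", which(rs == 0)[1]))
  }
  if (any(cs == 0)) {
    abort(sprintf("Column %s has a zero margin.", which(cs == 0)[1]))
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = correction == "yates"))
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = unname(fit$p.value),
         method = if (correction == "yates") "pearson_yates" else "pearson")
}

#' Rank tests for mutational load across groups
#'
#' Nonparametric comparison of per-sample loads: Wilcoxon rank-sum for two
#' groups and Kruskal-Wallis for more, both tie-corrected. The two-group test
#' uses the exact null distribution for small untied samples and the normal
#' approximation otherwise; the k-group test uses the chi-square
#' approximation.
#'
#' @param data Tibble with a numeric value column and a group column.
#' @param value,group Column names (strings).
#' @return Tibble `statistic`, `df` (NA for two groups), `p_value`, `method`.
#' @export
rank_test <- function(data, value = "load", group = "group") {
  data <- as_tibble(data)
  stopifnot_cols(data, c(value, group), "Rank-test input")
  g <- factor(data[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2) {
    abort("Need at least two non-empty groups.")
  }
  x <- data[[value]]
  if (nlevels(g) == 2) {
    fit <- suppressWarnings(
      stats::wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]]))
    tibble(statistic = unname(fit$statistic), df = NA_real_,
           p_value = fit$p.value, method = "wilcoxon_rank_sum")
  } else {
    fit <- stats::kruskal.test(x, g)
    tibble(statistic = unname(fit$statistic),
           df = unname(fit$parameter), p_value = fit$p.value,
           method = "kruskal_wallis")
  }
}

check_survival <- function(records) {
  records <- as_tibble(records)
  stopifnot_cols(records, c("time", "event"), "Survival records")
  if (nrow(records) == 0) abort("Empty survival table.")
  if (any(records$time <= 0)) abort("Survival times must be positive.")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0/1.")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival curve estimation for time-to-event endpoints (DFS/OS in months).
#' Subjects censored at an event time are handled after the events at that
#' time, as in the standard product-limit construction. The median survival
#' is the earliest time at which the estimate drops to 0.5 or below (absent
#' when never reached).
#'
#' @param records Tibble with `time` (> 0), `event` (1 event / 0 censored)
#'   and optionally a grouping column.
#' @param by Optional grouping column name.
#' @return An `ec_km` tibble: `group` (when `by` given), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records, by = NULL) {
  records <- check_survival(records)
  one <- function(d, label) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    tibble(group = label, time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
  }
  out <- if (is.null(by)) {
    one(records, NA_character_)
  } else {
    stopifnot_cols(records, by, "Survival records")
    records |>
      group_by(group = .data[[by]]) |>
      group_map(~ one(.x, .y$group)) |>
      purrr::list_rbind()
  }
  structure(out, class = c("ec_km", class(out)))
}

#' @rdname km_estimate
#' @param km An `ec_km` tibble.
#' @return For `km_median()`: tibble `group`, `median` (NA when the curve
#'   never reaches 0.5).
#' @export
km_median <- function(km) {
  km |>
    group_by(.data$group) |>
    summarise(median = {
      hit <- .data$time[.data$surv <= 0.5]
      if (length(hit) == 0) NA_real_ else min(hit)
    }, .groups = "drop")
}

#' K-group log-rank test
#'
#' Compares event-time distributions across groups using hypergeometric
#' expectations at each distinct event time; `df = k - 1`. With no events at
#' all the statistic is 0 and p = 1 (with a warning).
#'
#' @param records Tibble with `time`, `event` and a grouping column.
#' @param by Grouping column name (default `"group"`).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records, by = "group") {
  records <- check_survival(records)
  stopifnot_cols(records, by, "Survival records")
  g <- factor(records[[by]])
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    abort("Need at least two non-empty groups.")
  }
  if (sum(records$event) == 0) {
    warn("All subjects censored; log-rank statistic is 0.")
    return(tibble(statistic = 0, df = nlevels(g) - 1, p_value = 1))
  }
  fit <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = tibble(time = records$time, event = records$event, g = g))
  df <- length(fit$n) - 1
  tibble(statistic = unname(fit$chisq), df = df,
         p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}
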