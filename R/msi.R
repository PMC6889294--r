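#' The 8-marker microsatellite panel
#'
#' Default short-tandem-repeat loci assayed by fluorescent PCR and capillary
#' electrophoresis for MSI typing.
#'
#' @param markers Character vector of locus names (>= 1, unique).
#' @return Character vector of marker names.
#' @export
marker_set <- function(markers = c("NR27", "NR21", "NR24", "BAT26", "BAT25",
                                   "D5S346", "D2S123", "D17S250")) {
  if (length(markers) < 1 || anyDuplicated(markers)) {
    abort("`markers` must be a non-empty vector of unique names.")
  }
  markers
}

#' Marker-level instability parameters
#'
#' A deterministic surrogate for expert electropherogram reading. A marker is
#' `failed` when either the tumor or the normal trace carries total signal
#' below `min_signal`; `unstable` when the tumor trace contains a dominant
#' allele (peak height at least `rel_peak_frac` of the tallest tumor peak)
#' whose fragment length differs from every dominant normal allele by more
#' than `shift_tol` base pairs; `stable` otherwise.
#'
#' @param shift_tol Allele-length tolerance in bp (default 2).
#' @param rel_peak_frac Fraction of the tallest peak that defines a dominant
#'   allele (default 0.2).
#' @param min_signal Minimum total peak height per trace (default 100).
#' @return An `ec_msi_params` list.
#' @export
msi_params <- function(shift_tol = 2, rel_peak_frac = 0.2, min_signal = 100) {
  if (shift_tol < 0 || rel_peak_frac <= 0 || rel_peak_frac > 1 || min_signal < 0) {
    abort("Invalid MSI parameters.")
  }
  structure(list(shift_tol = shift_tol, rel_peak_frac = rel_peak_frac,
                 min_signal = min_signal), class = "ec_msi_params")
}

as_histogram <- function(x) {
  if (is.data.frame(x)) {
    stopifnot_cols(x, c("length_bp", "height"), "Histogram")
    h <- x$height
    names(h) <- as.character(x$length_bp)
    x <- h
  }
  if (length(x) == 0) return(numeric(0))
  if (is.null(names(x))) abort("Histograms need fragment lengths as names.")
  if (any(x < 0)) abort("Peak heights must be non-negative.")
  x
}

#' Call one marker's instability from paired tumor/normal traces
#'
#' @param tumor,normal Peak histograms: named numeric vectors (names =
#'   fragment length in bp, values = peak height) or two-column data frames
#'   `length_bp`, `height`.
#' @param params An [msi_params()] object.
#' @return `"stable"`, `"unstable"` or `"failed"`.
#' @examples
#' call_marker_instability(c(`100` = 900, `97` = 850), c(`100` = 1000))
#' @export
call_marker_instability <- function(tumor, normal, params = msi_params()) {
  tumor <- as_histogram(tumor)
  normal <- as_histogram(normal)
  if (sum(tumor) < params$min_signal || sum(normal) < params$min_signal) {
    return("failed")
  }
  t_len <- as.numeric(names(tumor))
  n_len <- as.numeric(names(normal))
  t_dom <- t_len[tumor >= params$rel_peak_frac * max(tumor)]
  n_dom <- n_len[normal >= params$rel_peak_frac * max(normal)]
  novel <- vapply(t_dom, function(l) all(abs(l - n_dom) > params$shift_tol),
                  logical(1))
  if (any(novel)) "unstable" else "stable"
}

#' Call all markers for all samples from a long trace table
#'
#' @param traces Long tibble with columns `sample_id`, `marker`,
#'   `tissue` (`"tumor"`/`"normal"`), `length_bp`, `height`.
#' @param markers Marker names to evaluate (default [marker_set()]). Markers
#'   with no rows for a sample are called `failed`.
#' @param params An [msi_params()] object.
#' @return Tibble `sample_id`, `marker`, `call`.
#' @export
call_marker_profiles <- function(traces, markers = marker_set(),
                                 params = msi_params()) {
  traces <- as_tibble(traces)
  stopifnot_cols(traces, c("sample_id", "marker", "tissue", "length_bp",
                           "height"), "Trace table")
  called <- traces |>
    filter(.data$marker %in% markers) |>
    group_by(.data$sample_id, .data$marker) |>
    summarise(call = {
      tum <- stats::setNames(.data$height[.data$tissue == "tumor"],
                             .data$length_bp[.data$tissue == "tumor"])
      nor <- stats::setNames(.data$height[.data$tissue == "normal"],
                             .data$length_bp[.data$tissue == "normal"])
      call_marker_instability(tum, nor, params)
    }, .groups = "drop")
  # markers absent from a sample's table are uncallable, i.e. failed
  tidyr::expand_grid(sample_id = unique(traces$sample_id), marker = markers) |>
    left_join(called, by = c("sample_id", "marker")) |>
    mutate(call = tidyr::replace_na(.data$call, "failed"))
}

#' Sample-level MSI status from per-marker calls
#'
#' MSI-High is called when at least `threshold` (default 30%) of the
#' evaluable markers show an unstable pattern; with all 8 default markers
#' evaluable this means 3 or more unstable (2/8 = 0.25 falls below the 30%
#' cut). Failed markers are removed from the denominator, and a sample with
#' fewer than `min_evaluable` evaluable markers is `indeterminate` rather
#' than MSS.
#'
#' @param calls Tibble `sample_id`, `marker`, `call` (from
#'   [call_marker_profiles()] or a pre-called lab export).
#' @param threshold Unstable fraction for MSI-H (default 0.30).
#' @param min_evaluable Minimum evaluable markers (default 5).
#' @return Tibble `sample_id`, `n_unstable`, `n_evaluable`,
#'   `unstable_fraction`, `msi_status`.
#' @export
call_msi_status <- function(calls, threshold = 0.30, min_evaluable = 5) {
  calls <- as_tibble(calls)
  stopifnot_cols(calls, c("sample_id", "marker", "call"), "Marker call table")
  bad <- setdiff(unique(calls$call), c("stable", "unstable", "failed"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown marker call value(s): %s", paste(bad, collapse = ", ")))
  }
  calls |>
    group_by(.data$sample_id) |>
    summarise(
      n_unstable = sum(.data$call == "unstable"),
      n_evaluable = sum(.data$call != "failed"),
      .groups = "drop"
    ) |>
    mutate(
      unstable_fraction = ifelse(.data$n_evaluable > 0,
                                 .data$n_unstable / .data$n_evaluable, NA_real_),
      msi_status = dplyr::case_when(
        .data$n_evaluable < min_evaluable ~ "indeterminate",
        .data$unstable_fraction >= threshold ~ "MSI-H",
        .default = "MSS"
      )
    )
}

#' Cohort MSI summary
#'
#' @param status Tibble with `msi_status` (from [call_msi_status()]).
#' @return Tibble `msi_status`, `n`, `fraction`, `percent` (1 decimal).
#' @export
msi_cohort_summary <- function(status) {
  status <- as_tibble(status)
  if (nrow(status) == 0) abort("Empty cohort: no MSI statuses supplied.")
  stopifnot_cols(status, "msi_status", "MSI status table")
  status |>
    count(.data$msi_status, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n),
           percent = round(100 * .data$fraction, 1))
}
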