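#' Run the molecular profiling stages of a cohort
#'
#' Applies pathogenicity and quality filters to the cohort's variant rows,
#' dichotomizes genes into per-sample profiles, and calls MSI status from the
#' paired tumor/normal traces.
#'
#' @param cohort An `ec_cohort` (or any list with `variants` and `markers`).
#' @param policy An [filter_policy()].
#' @param panel An [gene_panel()].
#' @param msi_params An [msi_params()].
#' @return List with `profiles`, `msi`, `filtered` (retained variant rows).
#' @export
cohort_profiles <- function(cohort, policy = filter_policy(),
                            panel = gene_panel(), msi_params = ecbiotype::msi_params()) {
  filtered <- apply_quality_filters(cohort$variants, policy)
  profiles <- suppressWarnings(suppressMessages(
    dichotomize_genes(filtered, panel, raw = cohort$variants,
                      samples = unique(cohort$variants$sample_id))))
  msi <- call_msi_status(call_marker_profiles(cohort$markers, params = msi_params))
  list(profiles = profiles, msi = msi, filtered = filtered)
}

#' Per-gene mutation frequencies
#'
#' @param profiles Profile tibble from [dichotomize_genes()].
#' @param panel An [gene_panel()].
#' @return Tibble `gene`, `n_mutated`, `n`, `fraction`, `percent`.
#' @export
gene_frequencies <- function(profiles, panel = gene_panel()) {
  profiles <- as_tibble(profiles)
  purrr::map_dfr(panel$genes, function(g) {
    tibble(gene = g, n_mutated = sum(profiles[[g]]), n = nrow(profiles))
  }) |>
    mutate(fraction = .data$n_mutated / .data$n,
           percent = round(100 * .data$fraction, 1)) |>
    arrange(desc(.data$fraction))
}

#' End-to-end cohort report
#'
#' Wires the whole workflow: filters, dichotomization, MSI calling, the
#' hierarchical four-group classification, per-gene frequencies, mutational
#' load by group, and Kaplan-Meier/log-rank survival analyses of the
#' resulting groups for both endpoints. Deterministic given the cohort and
#' model.
#'
#' @param cohort An `ec_cohort` with `variants`, `markers`, `clinical`.
#' @param model An [train_rf()] model for the CNL/CNH branch, unless
#'   `use_truth_cn`.
#' @param use_truth_cn Use the cohort's generative truth labels for the CN
#'   branch instead of a forest (fixtures and oracle runs).
#' @param policy,panel,msi_params Stage parameters.
#' @return An `ec_report` list of tibbles: `groups`, `assignments`,
#'   `gene_freq`, `load_by_group`, `load_summary`, `msi_summary`,
#'   `survival` (log-rank per endpoint), `km_medians`, and `provenance`.
#' @export
run_cohort_report <- function(cohort, model = NULL, use_truth_cn = FALSE,
                              policy = filter_policy(), panel = gene_panel(),
                              msi_params = ecbiotype::msi_params()) {
  if (is.null(cohort$variants) || nrow(cohort$variants) == 0) {
    abort("Validation: cohort has no variant rows.")
  }
  if (is.null(cohort$markers) || is.null(cohort$clinical)) {
    abort("Validation: cohort needs `markers` and `clinical` tables.")
  }
  prof <- cohort_profiles(cohort, policy, panel, msi_params)
  cn_labels <- NULL
  if (use_truth_cn) {
    if (is.null(cohort$truth)) abort("`use_truth_cn` needs a `truth` table.")
    cn_labels <- cohort$truth |>
      filter(.data$group %in% c("CNL", "CNH")) |>
      transmute(sample_id = .data$sample_id, cn_label = .data$group)
  }
  assignments <- suppressWarnings(
    assign_subgroups(prof$profiles, prof$msi, model = model,
                     cn_labels = cn_labels, panel = panel))
  loads <- mutational_load(prof$profiles, by = "retained") |>
    left_join(assignments |> select("sample_id", "group"), by = "sample_id")
  surv_long <- cohort$clinical |>
    left_join(assignments |> select("sample_id", "group"), by = "sample_id")
  survival <- purrr::map_dfr(c(DFS = "dfs", OS = "os"), function(ep) {
    rec <- tibble(sample_id = surv_long$sample_id,
                  time = surv_long[[paste0(ep, "_time")]],
                  event = surv_long[[paste0(ep, "_event")]],
                  group = surv_long$group)
    logrank_test(rec) |> mutate(endpoint = toupper(ep), .before = 1)
  })
  km_medians <- purrr::map_dfr(c("dfs", "os"), function(ep) {
    rec <- tibble(time = surv_long[[paste0(ep, "_time")]],
                  event = surv_long[[paste0(ep, "_event")]],
                  group = surv_long$group)
    km_median(km_estimate(rec, by = "group")) |>
      mutate(endpoint = toupper(ep), .before = 1)
  })
  structure(list(
    groups = subgroup_summary(assignments),
    assignments = assignments,
    gene_freq = gene_frequencies(prof$profiles, panel),
    load_by_group = loads |> group_by(.data$group) |>
      summarise(n = dplyr::n(), median = stats::median(.data$load),
                min = min(.data$load), max = max(.data$load), .groups = "drop"),
    load_summary = load_summary(loads),
    msi_summary = msi_cohort_summary(prof$msi),
    survival = survival,
    km_medians = km_medians,
    provenance = tibble(
      n_samples = nrow(prof$profiles),
      n_variant_rows = nrow(cohort$variants),
      n_retained_rows = nrow(prof$filtered),
      cohort_seed = cohort$seed %||% NA_integer_,
      cn_branch = if (use_truth_cn) "truth_labels" else "random_forest"
    )
  ), class = "ec_report")
}

#' @export
print.ec_report <- function(x, ...) {
  cat("<ec_report>\nGroups:\n")
  print(x$groups)
  cat("Log-rank:\n")
  print(x$survival)
  invisible(x)
}
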