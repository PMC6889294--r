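#' POLE exonuclease-domain rule
#'
#' Tumors with a retained mutation inside the POLE proofreading (exonuclease)
#' domain define the ultramutated POLE group. The domain bounds default to
#' protein residues 268-471, the standard literature convention, and the
#' recurrent hotspots to p.P286R and p.V411L.
#'
#' @param domain_start,domain_end 1-based protein residue bounds.
#' @param hotspots HGVS-p strings matched exactly.
#' @return An `ec_pole_rule` list.
#' @export
pole_rule <- function(domain_start = 268, domain_end = 471,
                      hotspots = c("p.P286R", "p.V411L")) {
  if (domain_start >= domain_end) abort("`domain_start` must be < `domain_end`.")
  res <- hgvs_residue(hotspots)
  if (any(is.na(res) | res < domain_start | res > domain_end)) {
    abort("Hotspots must be parseable HGVS-p inside the domain.")
  }
  structure(list(domain_start = domain_start, domain_end = domain_end,
                 hotspots = hotspots), class = "ec_pole_rule")
}

# Residue number from an HGVS-p string like "p.P286R"; NA when unparseable.
hgvs_residue <- function(x) {
  m <- regmatches(x, regexec("^p\\.[A-Za-z*]{1,3}([0-9]+)", x))
  vapply(m, function(g) if (length(g) < 2) NA_real_ else as.numeric(g[2]),
         numeric(1))
}

#' Detect POLE exonuclease-domain mutations per sample
#'
#' Evaluates retained POLE variants against an [pole_rule()]: `pole_domain`
#' is true when at least one variant's protein residue lies inside the
#' domain; `pole_hotspot` when such a variant matches a hotspot exactly.
#' POLE variants without a parseable residue number are excluded from the
#' domain test (counted in a message).
#'
#' @param variants Tibble of retained variant records.
#' @param rule An [pole_rule()].
#' @param samples Optional sample set for the output (defaults to the samples
#'   present in `variants`).
#' @param pole_gene Gene symbol holding the polymerase (default `"POLE"`).
#' @return Tibble `sample_id`, `pole_domain`, `pole_hotspot`.
#' @export
detect_pole_domain_mutation <- function(variants, rule = pole_rule(),
                                        samples = NULL, pole_gene = "POLE") {
  variants <- as_tibble(variants)
  stopifnot_cols(variants, c("sample_id", "gene", "protein_change"),
                 "Variant table")
  ids <- samples %||% unique(variants$sample_id)
  pv <- variants[variants$gene == pole_gene, , drop = FALSE]
  res <- hgvs_residue(pv$protein_change)
  unparsed <- sum(is.na(res) & nzchar(pv$protein_change %||% ""))
  if (unparsed > 0) {
    inform(sprintf(
      "%d POLE variant(s) without parseable HGVS-p excluded from the domain test.",
      unparsed))
  }
  in_domain <- !is.na(res) & res >= rule$domain_start & res <= rule$domain_end
  hot <- in_domain & pv$protein_change %in% rule$hotspots
  flags <- tibble(sample_id = pv$sample_id, dom = in_domain, hot = hot) |>
    group_by(.data$sample_id) |>
    summarise(pole_domain = any(.data$dom), pole_hotspot = any(.data$hot),
              .groups = "drop")
  tibble(sample_id = ids) |>
    left_join(flags, by = "sample_id") |>
    mutate(pole_domain = tidyr::replace_na(.data$pole_domain, FALSE),
           pole_hotspot = tidyr::replace_na(.data$pole_hotspot, FALSE))
}

#' Assign samples to the four prognostic biotypes
#'
#' The hierarchy of the molecular classification: a sample with a POLE
#' exonuclease-domain mutation is POLE regardless of its MSI status (MSI may
#' co-occur in POLE tumors); otherwise an MSI-H sample is MSI; the remaining
#' samples are split CNL/CNH by the random-forest surrogate (or by
#' caller-supplied copy-number labels). Samples with indeterminate MSI fall
#' through to the copy-number branch with a warning.
#'
#' @param profiles Profile tibble from [dichotomize_genes()] (needs
#'   `sample_id`, `pole_domain` and the 12 RF genes when a model is used).
#' @param msi Tibble `sample_id`, `msi_status` (from [call_msi_status()]).
#' @param model An [train_rf()] model, required unless `cn_labels` given.
#' @param cn_labels Optional tibble `sample_id`, `cn_label` (`"CNL"`/`"CNH"`)
#'   bypassing the forest (e.g. generative truth labels).
#' @param panel An [gene_panel()].
#' @return Tibble `sample_id`, `group`, `rule_fired`, `rf_vote_fraction`
#'   (vote share of the predicted class; `NA` for rule-based branches).
#' @export
assign_subgroups <- function(profiles, msi, model = NULL, cn_labels = NULL,
                             panel = gene_panel()) {
  profiles <- as_tibble(profiles)
  stopifnot_cols(profiles, c("sample_id", "pole_domain"), "Profile table")
  msi <- as_tibble(msi)
  stopifnot_cols(msi, c("sample_id", "msi_status"), "MSI table")
  joined <- profiles |> left_join(msi |> select("sample_id", "msi_status"),
                                  by = "sample_id")
  if (anyNA(joined$msi_status)) {
    abort(sprintf("Missing MSI status for sample(s): %s",
                  paste(utils::head(
                    joined$sample_id[is.na(joined$msi_status)], 5),
                    collapse = ", ")))
  }
  n_ind <- sum(joined$msi_status == "indeterminate" & !joined$pole_domain)
  if (n_ind > 0) {
    warn(sprintf(
      "%d sample(s) with indeterminate MSI fall through to the CN branch.",
      n_ind))
  }
  cn_needed <- joined |>
    filter(!.data$pole_domain, .data$msi_status != "MSI-H")
  if (nrow(cn_needed) > 0) {
    if (!is.null(cn_labels)) {
      cn_labels <- as_tibble(cn_labels)
      stopifnot_cols(cn_labels, c("sample_id", "cn_label"), "CN label table")
      cn <- cn_needed |> left_join(cn_labels, by = "sample_id") |>
        transmute(sample_id = .data$sample_id, group = .data$cn_label,
                  rf_vote_fraction = NA_real_)
      if (anyNA(cn$group)) abort("`cn_labels` does not cover every CN-branch sample.")
    } else {
      if (is.null(model)) {
        abort("A trained CN model (or `cn_labels`) is required for CN-branch samples.")
      }
      pred <- stats::predict(model, cn_needed)
      cn <- tibble(sample_id = cn_needed$sample_id,
                   group = pred$label, rf_vote_fraction = pred$vote_fraction)
    }
  } else {
    cn <- tibble(sample_id = character(), group = character(),
                 rf_vote_fraction = double())
  }
  joined |>
    left_join(cn, by = "sample_id") |>
    transmute(
      sample_id = .data$sample_id,
      group = dplyr::case_when(
        .data$pole_domain ~ "POLE",
        .data$msi_status == "MSI-H" ~ "MSI",
        .default = .data$group
      ),
      rule_fired = dplyr::case_when(
        .data$pole_domain ~ "pole_domain",
        .data$msi_status == "MSI-H" ~ "msi_high",
        .data$group == "CNL" ~ "rf_cnl",
        .default = "rf_cnh"
      ),
      rf_vote_fraction = .data$rf_vote_fraction
    )
}

#' Classify a whole cohort and summarise group sizes
#'
#' @param cohort An `ec_cohort` (from [simulate_cohort()] or
#'   [build_reference_fixture()]) or a list with `profiles` and `msi` tibbles.
#' @param model,cn_labels,panel Passed to [assign_subgroups()].
#' @return List with `assignments` (per-sample tibble) and `summary`
#'   (group `n` and `percent`).
#' @export
classify_cohort <- function(cohort, model = NULL, cn_labels = NULL,
                            panel = gene_panel()) {
  if (is.null(cohort$profiles) || is.null(cohort$msi)) {
    abort("`cohort` must carry `profiles` and `msi` tables.")
  }
  assignments <- assign_subgroups(cohort$profiles, cohort$msi, model = model,
                                  cn_labels = cn_labels, panel = panel)
  list(assignments = assignments, summary = subgroup_summary(assignments))
}

#' @rdname classify_cohort
#' @param assignments Tibble from [assign_subgroups()].
#' @export
subgroup_summary <- function(assignments) {
  assignments |>
    count(group = factor(.data$group, c("POLE", "MSI", "CNL", "CNH")),
          name = "n", .drop = FALSE) |>
    mutate(fraction = .data$n / sum(.data$n),
           percent = round(100 * .data$fraction, 1))
}
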