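#' The 13-gene endometrial cancer panel
#'
#' The targeted panel interrogates the coding regions of 13 genes chosen for
#' their discriminating mutation frequencies across the four TCGA prognostic
#' biotypes. The copy-number surrogate model uses the 12-gene subset that
#' excludes `POLE` (the POLE group is assigned upstream by the
#' exonuclease-domain rule, so `POLE` carries no information for the
#' CNL/CNH decision).
#'
#' @param genes Character vector of 13 unique, uppercase gene symbols.
#'   Defaults to the published panel.
#' @param pole_gene Symbol excluded from the random-forest feature set.
#'
#' @return An object of class `ec_panel`: a list with elements `genes`
#'   (length 13) and `rf_genes` (length 12).
#' @examples
#' gene_panel()$rf_genes
#' @export
gene_panel <- function(genes = c("POLE", "PTEN", "TP53", "ARID1A", "ARID5B",
                                 "FBXW7", "PPP2R1A", "CTCF", "CTNNB1",
                                 "RPL22", "KRAS", "PIK3CA", "PIK3R1"),
                       pole_gene = "POLE") {
  genes <- toupper(genes)
  if (anyDuplicated(genes)) abort("Panel gene symbols must be unique.")
  if (length(genes) != 13) abort("The panel must contain exactly 13 genes.")
  if (!pole_gene %in% genes) abort("`pole_gene` must be one of the panel genes.")
  structure(
    list(genes = genes, rf_genes = setdiff(genes, pole_gene),
         pole_gene = pole_gene),
    class = "ec_panel"
  )
}

#' @export
print.ec_panel <- function(x, ...) {
  cat("<ec_panel> 13 genes:", paste(x$genes, collapse = ", "), "\n")
  cat("RF feature set (12):", paste(x$rf_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Variant retention policy
#'
#' Quality and pathogenicity thresholds applied to annotated somatic variants
#' before gene-level dichotomization: a minimum sequencing depth of 600 reads,
#' a minimum variant allele fraction of 5%, and retention of variants
#' classified pathogenic, likely pathogenic or of unknown significance (VUS).
#' Benign and likely benign variants are excluded. Both numeric thresholds are
#' closed bounds (a depth of exactly 600 and a VAF of exactly 0.05 pass).
#'
#' @param min_depth Minimum read depth (default 600).
#' @param min_vaf Minimum variant allele fraction in `[0, 1]` (default 0.05).
#' @param retained_classes ClinVar-style classes retained outright.
#' @return An `ec_filter_policy` list.
#' @export
filter_policy <- function(min_depth = 600, min_vaf = 0.05,
                          retained_classes = c("pathogenic",
                                               "likely_pathogenic", "vus")) {
  if (min_depth < 0) abort("`min_depth` must be >= 0.")
  if (min_vaf < 0 || min_vaf > 1) abort("`min_vaf` must lie in [0, 1].")
  if (length(retained_classes) == 0) abort("`retained_classes` must be non-empty.")
  structure(list(min_depth = min_depth, min_vaf = min_vaf,
                 retained_classes = retained_classes),
            class = "ec_filter_policy")
}

.variant_cols <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                   "protein_change", "consequence", "depth", "vaf",
                   "clinvar_class", "polyphen_call", "sift_call")

.consequences <- c("missense", "nonsense", "frameshift", "inframe",
                   "splicing", "synonymous", "intronic", "regulatory")
.protein_altering <- c("missense", "nonsense", "frameshift", "inframe",
                       "splicing")

# Canonicalize annotation vocabularies; unknown values map to
# unreported/unknown rather than being dropped.
normalize_variants <- function(variants) {
  variants <- as_tibble(variants)
  stopifnot_cols(variants, .variant_cols, "Variant table")
  bad_depth <- which(is.na(variants$depth) | variants$depth < 0)
  if (length(bad_depth) > 0) {
    abort(sprintf("Invalid depth at row(s) %s.",
                  paste(utils::head(bad_depth, 5), collapse = ", ")))
  }
  bad_vaf <- which(is.na(variants$vaf) | variants$vaf < 0 | variants$vaf > 1)
  if (length(bad_vaf) > 0) {
    abort(sprintf("VAF outside [0, 1] at row(s) %s.",
                  paste(utils::head(bad_vaf, 5), collapse = ", ")))
  }
  clin_ok <- c("pathogenic", "likely_pathogenic", "vus", "benign",
               "likely_benign", "unreported")
  variants |>
    mutate(
      gene = toupper(.data$gene),
      clinvar_class = ifelse(tolower(.data$clinvar_class) %in% clin_ok,
                             tolower(.data$clinvar_class), "unreported"),
      polyphen_call = ifelse(tolower(.data$polyphen_call) %in%
                               c("damaging", "benign"),
                             tolower(.data$polyphen_call), "unknown"),
      sift_call = ifelse(tolower(.data$sift_call) %in%
                           c("deleterious", "tolerated"),
                         tolower(.data$sift_call), "unknown"),
      consequence = ifelse(tolower(.data$consequence) %in% .consequences,
                           tolower(.data$consequence), "missense")
    )
}

#' Read an annotated somatic variant table
#'
#' Reads per-sample annotated variants from either a documented TSV dialect
#' (header columns `sample_id, gene, chrom, pos, ref, alt, hgvs_p,
#' consequence, depth, vaf, clinvar, polyphen, sift`) or a VCF in which the
#' annotations live in INFO keys. Multi-allelic VCF records are split into one
#' row per ALT allele, with per-allele VAF taken positionally from a
#' comma-separated `AF`. Coordinates stay 1-based. Unknown annotation values
#' are mapped to `unreported`/`unknown`, never silently dropped.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param info_keys Named character vector mapping canonical fields to VCF
#'   INFO keys (VCF dialect only).
#' @return A tibble of variant records, one row per sample/allele.
#' @export
read_variant_table <- function(path,
                               dialect = c("tsv", "vcf"),
                               info_keys = c(sample_id = "SAMPLE",
                                             gene = "GENE",
                                             protein_change = "HGVSP",
                                             consequence = "CSQ",
                                             depth = "DP", vaf = "AF",
                                             clinvar_class = "CLNSIG",
                                             polyphen_call = "POLYPHEN",
                                             sift_call = "SIFT")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "tsv") {
    tsv_cols <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "hgvs_p",
                  "consequence", "depth", "vaf", "clinvar", "polyphen", "sift")
    raw <- suppressWarnings(
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(
                        pos = readr::col_double(),
                        depth = readr::col_double(),
                        vaf = readr::col_double(),
                        .default = readr::col_character())))
    stopifnot_cols(raw, tsv_cols, sprintf("'%s'", path))
    probs <- readr::problems(raw)
    if (nrow(probs) > 0) {
      abort(sprintf("Malformed row(s) in '%s' at line(s) %s; file rejected.",
                    path, paste(unique(probs$row) + 1, collapse = ", ")))
    }
    out <- raw |>
      rename(protein_change = "hgvs_p", clinvar_class = "clinvar",
             polyphen_call = "polyphen", sift_call = "sift") |>
      mutate(protein_change = ifelse(is.na(.data$protein_change), "",
                                     .data$protein_change))
  } else {
    out <- read_variant_vcf(path, info_keys)
  }
  out <- normalize_variants(out)
  inform(sprintf("Read %d variant record(s) from '%s' (%d sample(s)).",
                 nrow(out), path, length(unique(out$sample_id))))
  out
}

# Minimal VCF-dialect reader: fixed columns plus the named INFO keys.
read_variant_vcf <- function(path, info_keys) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble(sample_id = character(), gene = character(),
                  chrom = character(), pos = double(), ref = character(),
                  alt = character(), protein_change = character(),
                  consequence = character(), depth = double(), vaf = double(),
                  clinvar_class = character(), polyphen_call = character(),
                  sift_call = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad) > 0) {
    abort(sprintf("Malformed VCF row at line %d; file rejected.",
                  which(!startsWith(lines, "#"))[bad[1]]))
  }
  grab <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  rows <- purrr::map(fields, function(f) {
    info <- f[8]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    afs <- strsplit(grab(info, info_keys[["vaf"]]) %||% "", ",", fixed = TRUE)[[1]]
    purrr::imap(alts, function(alt, i) {
      tibble(
        sample_id = grab(info, info_keys[["sample_id"]]) %||% NA_character_,
        gene = grab(info, info_keys[["gene"]]) %||% NA_character_,
        chrom = f[1], pos = as.numeric(f[2]), ref = f[4], alt = alt,
        protein_change = grab(info, info_keys[["protein_change"]]) %||% "",
        consequence = grab(info, info_keys[["consequence"]]) %||% "missense",
        depth = as.numeric(grab(info, info_keys[["depth"]])),
        vaf = as.numeric(if (i <= length(afs)) afs[i] else NA),
        clinvar_class = grab(info, info_keys[["clinvar_class"]]) %||% "unreported",
        polyphen_call = grab(info, info_keys[["polyphen_call"]]) %||% "unknown",
        sift_call = grab(info, info_keys[["sift_call"]]) %||% "unknown"
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows$protein_change[is.na(rows$protein_change)] <- ""
  rows
}

#' Pathogenicity triage of annotated variants
#'
#' Retains variants reported in ClinVar as pathogenic, likely pathogenic or
#' VUS; discards (likely) benign ones, with the ClinVar classification taking
#' precedence over in-silico predictors. For variants unreported in ClinVar,
#' a damaging PolyPhen or deleterious SIFT call retains the variant; when both
#' predictors are uninformative, a protein-altering consequence (missense,
#' nonsense, frameshift, inframe, splicing) is kept as a VUS and
#' synonymous/intronic/regulatory changes are dropped.
#'
#' @param variants Tibble of variant records (see [read_variant_table()]).
#' @return The input with an added `pathogenicity_call` column
#'   (`"retain"`/`"discard"`).
#' @export
classify_pathogenicity <- function(variants) {
  variants <- normalize_variants(variants)
  clin <- variants$clinvar_class
  predicted <- variants$polyphen_call == "damaging" |
    variants$sift_call == "deleterious"
  both_unknown <- variants$polyphen_call == "unknown" &
    variants$sift_call == "unknown"
  retain <- dplyr::case_when(
    clin %in% c("pathogenic", "likely_pathogenic", "vus") ~ TRUE,
    clin %in% c("benign", "likely_benign") ~ FALSE,
    predicted ~ TRUE,
    both_unknown ~ variants$consequence %in% .protein_altering,
    .default = FALSE
  )
  variants$pathogenicity_call <- ifelse(retain, "retain", "discard")
  variants
}

#' Apply depth, VAF and pathogenicity filters
#'
#' Retains exactly the records with `depth >= min_depth`, `vaf >= min_vaf`
#' (both closed bounds) and a `retain` pathogenicity triage. Row order is
#' stable. Rejection reasons are counted and attached as the `"filter_log"`
#' attribute (retrievable with [filter_log()]), so samples filtered to zero
#' remain auditable.
#'
#' @param variants Tibble of variant records.
#' @param policy An [filter_policy()] object.
#' @return Tibble of retained records with a `filter_log` attribute.
#' @export
apply_quality_filters <- function(variants, policy = filter_policy()) {
  if (!inherits(policy, "ec_filter_policy")) abort("`policy` must be an ec_filter_policy.")
  variants <- classify_pathogenicity(variants)
  low_depth <- variants$depth < policy$min_depth
  low_vaf <- variants$vaf < policy$min_vaf
  not_path <- variants$pathogenicity_call != "retain"
  keep <- !low_depth & !low_vaf & !not_path
  log <- tibble(
    reason = c("low_depth", "low_vaf", "pathogenicity", "retained"),
    n = c(sum(low_depth), sum(low_vaf & !low_depth),
          sum(not_path & !low_depth & !low_vaf), sum(keep))
  )
  out <- variants[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' @rdname apply_quality_filters
#' @param x A filtered variant tibble.
#' @export
filter_log <- function(x) attr(x, "filter_log")

#' Collapse filtered variants to binary per-gene mutation profiles
#'
#' The presence of mutation is treated as a dichotomous variable: a panel gene
#' scores 1 for a sample when at least one retained variant falls in it.
#' Off-panel records are ignored (their count is reported in a message).
#' Samples present in `raw` (or `samples`) but with no retained variants get
#' an all-zero profile, distinguishable from absent data through the
#' `raw_n`/`retained_n` columns. POLE exonuclease-domain and hotspot flags are
#' computed from the retained POLE variants via [detect_pole_domain_mutation()].
#'
#' @param variants Tibble of *filtered* variant records.
#' @param panel An [gene_panel()] object.
#' @param raw Optional unfiltered variant tibble (used for `raw_n`).
#' @param samples Optional character vector forcing the output sample set.
#' @param pole_rule An [pole_rule()] for the POLE flags.
#' @return A tibble with one row per sample: `sample_id`, one 0/1 column per
#'   panel gene, `pole_domain`, `pole_hotspot`, `raw_n`, `retained_n`.
#' @export
dichotomize_genes <- function(variants, panel = gene_panel(), raw = NULL,
                              samples = NULL, pole_rule = ecbiotype::pole_rule()) {
  variants <- as_tibble(variants)
  stopifnot_cols(variants, c("sample_id", "gene"), "Filtered variant table")
  off_panel <- sum(!variants$gene %in% panel$genes)
  if (off_panel > 0) {
    inform(sprintf("Ignoring %d off-panel variant record(s).", off_panel))
  }
  ids <- unique(c(variants$sample_id,
                  if (!is.null(raw)) unique(raw$sample_id), samples))
  if (length(ids) == 0) abort("No samples to profile.")
  on_panel <- variants[variants$gene %in% panel$genes, , drop = FALSE]

  status <- tidyr::expand_grid(sample_id = ids, gene = panel$genes) |>
    left_join(on_panel |> distinct(.data$sample_id, .data$gene) |>
                mutate(hit = 1L),
              by = c("sample_id", "gene")) |>
    mutate(hit = tidyr::replace_na(.data$hit, 0L)) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "hit")

  pole <- detect_pole_domain_mutation(on_panel, rule = pole_rule,
                                      samples = ids,
                                      pole_gene = panel$pole_gene)
  counts <- tibble(sample_id = ids) |>
    left_join(count(variants, .data$sample_id, name = "retained_n"),
              by = "sample_id") |>
    mutate(retained_n = tidyr::replace_na(.data$retained_n, 0L))
  raw_counts <- if (is.null(raw)) {
    counts |> rename(raw_n = "retained_n")
  } else {
    tibble(sample_id = ids) |>
      left_join(count(as_tibble(raw), .data$sample_id, name = "raw_n"),
                by = "sample_id") |>
      mutate(raw_n = tidyr::replace_na(.data$raw_n, 0L))
  }
  no_rows <- counts$sample_id[counts$retained_n == 0]
  if (length(no_rows) > 0) {
    warn(sprintf("%d sample(s) have an all-zero mutation profile.",
                 length(no_rows)))
  }
  status |>
    left_join(pole, by = "sample_id") |>
    left_join(raw_counts, by = "sample_id") |>
    left_join(counts, by = "sample_id") |>
    arrange(match(.data$sample_id, ids))
}

#' Per-sample mutational load
#'
#' Counts variants per sample, either raw annotated rows (`by = "raw"`) or
#' filter-passing rows (`by = "retained"`), from a profile table produced by
#' [dichotomize_genes()].
#'
#' @param profiles Profile tibble with `raw_n`/`retained_n` columns.
#' @param by `"retained"` or `"raw"`.
#' @return Tibble `sample_id`, `load`.
#' @export
mutational_load <- function(profiles, by = c("retained", "raw")) {
  by <- match.arg(by)
  profiles <- as_tibble(profiles)
  if (nrow(profiles) == 0) abort("Empty cohort: no profiles supplied.")
  col <- if (by == "retained") "retained_n" else "raw_n"
  stopifnot_cols(profiles, c("sample_id", col), "Profile table")
  tibble(sample_id = profiles$sample_id, load = profiles[[col]])
}

#' @rdname mutational_load
#' @param loads A tibble from [mutational_load()].
#' @return For `load_summary()`: a one-row tibble `n`, `median`, `min`, `max`
#'   (median is the mean of the two central order statistics for even `n`).
#' @export
load_summary <- function(loads) {
  if (nrow(loads) == 0) abort("Empty cohort: no loads supplied.")
  tibble(n = nrow(loads),
         median = stats::median(loads$load),
         min = min(loads$load), max = max(loads$load))
}
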