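# Rough genomic anchors per panel gene; variant coordinates are synthetic
# offsets from these (gene assignment is always taken from the annotation
# column, never recomputed from coordinates).
.gene_loci <- list(
  POLE = c("chr12", 132620000), PTEN = c("chr10", 89620000),
  TP53 = c("chr17", 7570000), ARID1A = c("chr1", 27020000),
  ARID5B = c("chr10", 63660000), FBXW7 = c("chr4", 153240000),
  PPP2R1A = c("chr19", 52690000), CTCF = c("chr16", 67590000),
  CTNNB1 = c("chr3", 41240000), RPL22 = c("chr1", 6250000),
  KRAS = c("chr12", 25360000), PIK3CA = c("chr3", 178860000),
  PIK3R1 = c("chr5", 67510000)
)

.marker_lengths <- c(NR27 = 87, NR21 = 103, NR24 = 132, BAT26 = 120,
                     BAT25 = 124, D5S346 = 110, D2S123 = 150, D17S250 = 140)

#' Group-level generative specification
#'
#' Describes one prognostic group for the synthetic-cohort generator:
#' per-gene Bernoulli mutation probabilities, the raw mutational-load
#' distribution (median and observed range of annotated variants per case),
#' survival medians per endpoint (months) and the censoring fraction.
#'
#' @param name Group name (`"POLE"`, `"MSI"`, `"CNL"`, `"CNH"`).
#' @param proportion Cohort proportion in `[0, 1]`.
#' @param gene_probs Named numeric vector of mutation probabilities.
#' @param load_median,load_range Median and `(min, max)` of raw variants/case.
#' @param dfs_median,os_median Median survival (months).
#' @param censoring Censoring fraction (default 0.15).
#' @return An `ec_group_spec` list.
#' @export
group_spec <- function(name, proportion, gene_probs, load_median, load_range,
                       dfs_median, os_median, censoring = 0.15) {
  if (any(gene_probs < 0 | gene_probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (proportion <= 0) abort("`proportion` must be positive.")
  if (dfs_median <= 0 || os_median <= 0) abort("Survival medians must be positive.")
  structure(list(name = name, proportion = proportion,
                 gene_probs = gene_probs, load_median = load_median,
                 load_range = load_range, dfs_median = dfs_median,
                 os_median = os_median, censoring = censoring),
            class = "ec_group_spec")
}

#' Default group specifications
#'
#' The study conditions of the synthetic generator. Stated quantities (group
#' proportions 16/12/48/20 of 96; MSI-group PTEN 0.75 / ARID1A 0.583 /
#' RPL22 0.833; CNH TP53 0.75 / PTEN 0.05 / PPP2R1A 0.45; CNL PTEN 0.604 /
#' TP53 0.146 / PIK3R1 0.354 / ARID5B 0.417 / CTCF 0.313 / RPL22 0.396;
#' raw-load medians 94/40/37/32 with their observed ranges; DFS medians
#' 55.40/38.33/34.43/27.70 and OS medians 55.40/38.6/42.57/30.53 months) are
#' fixed; the remaining gene frequencies are filled once with TCGA-typical
#' endometrial values (see the methods vignette).
#'
#' @return Named list of four [group_spec()] objects.
#' @export
default_group_specs <- function() {
  list(
    POLE = group_spec("POLE", 16 / 96, c(
      POLE = 1, PTEN = 0.875, TP53 = 0.50, ARID1A = 0.625, ARID5B = 0.75,
      FBXW7 = 0.19, PPP2R1A = 0.125, CTCF = 0.44, CTNNB1 = 0.31,
      RPL22 = 0.625, KRAS = 0.19, PIK3CA = 0.625, PIK3R1 = 0.375),
      load_median = 94, load_range = c(31, 171),
      dfs_median = 55.40, os_median = 55.40),
    MSI = group_spec("MSI", 12 / 96, c(
      POLE = 0, PTEN = 0.75, TP53 = 0.17, ARID1A = 0.583, ARID5B = 0.50,
      FBXW7 = 0.08, PPP2R1A = 0.08, CTCF = 0.25, CTNNB1 = 0.25,
      RPL22 = 0.833, KRAS = 0.17, PIK3CA = 0.50, PIK3R1 = 0.33),
      load_median = 40, load_range = c(19, 93),
      dfs_median = 38.33, os_median = 38.6),
    CNL = group_spec("CNL", 48 / 96, c(
      POLE = 0, PTEN = 0.604, TP53 = 0.146, ARID1A = 0.50, ARID5B = 0.417,
      FBXW7 = 0.08, PPP2R1A = 0.06, CTCF = 0.313, CTNNB1 = 0.30,
      RPL22 = 0.396, KRAS = 0.06, PIK3CA = 0.46, PIK3R1 = 0.354),
      load_median = 37, load_range = c(13, 138),
      dfs_median = 34.43, os_median = 42.57),
    CNH = group_spec("CNH", 20 / 96, c(
      POLE = 0, PTEN = 0.05, TP53 = 0.75, ARID1A = 0.30, ARID5B = 0.20,
      FBXW7 = 0.20, PPP2R1A = 0.45, CTCF = 0.05, CTNNB1 = 0.05,
      RPL22 = 0.10, KRAS = 0.05, PIK3CA = 0.40, PIK3R1 = 0.10),
      load_median = 32, load_range = c(19, 96),
      dfs_median = 27.70, os_median = 30.53)
  )
}

#' Simulate a TCGA-like CNL/CNH training matrix
#'
#' Independent Bernoulli draws per gene per sample from each copy-number
#' group's probability map, with labels attached; emulates the 148-case
#' labeled training resource (roughly 40% CNH among CNL/CNH cases).
#'
#' @param n Number of samples (default 148).
#' @param cnh_fraction CNH proportion (default 0.4).
#' @param specs List with `CNL` and `CNH` [group_spec()]s.
#' @param seed Integer seed.
#' @param features Feature genes (default the 12 RF panel genes).
#' @return Tibble `sample_id`, one 0/1 column per feature, `label`.
#' @export
simulate_training_set <- function(n = 148, cnh_fraction = 0.4,
                                  specs = default_group_specs()[c("CNL", "CNH")],
                                  seed = 1,
                                  features = gene_panel()$rf_genes) {
  if (n <= 0) abort("`n` must be positive.")
  n_cnh <- round(n * cnh_fraction)
  if (n_cnh == 0 || n_cnh == n) abort("`cnh_fraction` leaves a class empty.")
  labels <- rep(c("CNL", "CNH"), c(n - n_cnh, n_cnh))
  with_seed(seed, {
    draws <- purrr::map(labels, function(lb) {
      p <- specs[[lb]]$gene_probs[features]
      stats::rbinom(length(features), 1, p)
    })
    mat <- do.call(rbind, draws)
    colnames(mat) <- features
    bind_cols(tibble(sample_id = sprintf("T%03d", seq_len(n))),
              as_tibble(mat), tibble(label = labels))
  })
}

# --- deterministic variant-row construction (shared by the simulator and
# the reference fixture; all quality fields are functions of the row salt) ---

.gene_chrom <- vapply(.gene_loci, `[`, character(1), 1)
.gene_base <- vapply(.gene_loci, function(x) as.numeric(x[2]), numeric(1))

# Vectorized retained-grade rows (all pass depth/VAF/pathogenicity filters);
# the quality fields are deterministic functions of the per-row salt.
retained_rows <- function(sample_id, genes, salts, protein_change = NULL) {
  clin_cycle <- c("vus", "pathogenic", "unreported", "likely_pathogenic", "vus")
  cons_cycle <- c("missense", "missense", "nonsense", "frameshift", "missense",
                  "splicing", "inframe", "missense")
  clin <- clin_cycle[salts %% 5 + 1]
  tibble(
    sample_id = sample_id, gene = genes,
    chrom = unname(.gene_chrom[genes]),
    pos = unname(.gene_base[genes]) + 13 * salts %% 9973,
    ref = c("A", "C", "G", "T")[salts %% 4 + 1],
    alt = c("T", "G", "C", "A")[(salts + 1) %% 4 + 1],
    protein_change = protein_change %||% sprintf("p.A%dT", 500 + salts %% 400),
    consequence = cons_cycle[salts %% 8 + 1],
    depth = 600 + (37 * salts) %% 1400,
    vaf = round(0.05 + ((7 * salts) %% 56) / 100, 3),
    clinvar_class = clin,
    polyphen_call = ifelse(clin == "unreported", "damaging", "unknown"),
    sift_call = "unknown"
  )
}

# Vectorized sub-threshold rows; each cycles one rejection mode (low depth,
# low VAF, benign, likely benign, or non-protein-altering unreported).
filler_rows <- function(sample_id, genes, salts) {
  mode <- salts %% 5
  tibble(
    sample_id = sample_id, gene = genes,
    chrom = unname(.gene_chrom[genes]),
    pos = unname(.gene_base[genes]) + 17 * salts %% 9973 + 1,
    ref = "G", alt = "A",
    protein_change = ifelse(mode == 4, "", sprintf("p.G%dS", 100 + salts %% 300)),
    consequence = ifelse(mode == 4, "synonymous", "missense"),
    depth = ifelse(mode == 0, 300 + salts %% 299, 700 + salts %% 500),
    vaf = ifelse(mode == 1, round(0.01 + (salts %% 4) / 100, 3), 0.30),
    clinvar_class = c("vus", "vus", "benign", "likely_benign",
                      "unreported")[mode + 1],
    polyphen_call = "unknown", sift_call = "unknown"
  )
}

# Variant rows for one sample: >= 1 retained-grade row per mutated gene,
# extras round-robin, then raw_n - retained_n filler rows failing the filters.
sample_variant_rows <- function(sample_id, genes, retained_n, raw_n, salt0,
                                pole_hgvs = NULL, all_genes = gene_panel()$genes) {
  out <- list()
  if (length(genes) > 0) {
    retained_n <- max(retained_n, length(genes))
    alloc <- rep(1L, length(genes))
    extra <- retained_n - length(genes)
    if (extra > 0) {
      alloc <- alloc + tabulate((seq_len(extra) - 1) %% length(genes) + 1,
                                nbins = length(genes))
    }
    gene_per_row <- rep(genes, alloc)
    salts <- salt0 + seq_along(gene_per_row)
    ret <- retained_rows(sample_id, gene_per_row, salts)
    pole_first <- which(gene_per_row == "POLE")
    if (length(pole_first) > 0) {
      # extra POLE rows sit outside the exonuclease domain; the first row
      # carries the domain (possibly hotspot) mutation when requested
      ret$protein_change[pole_first] <-
        sprintf("p.R%dQ", 600 + seq_along(pole_first) %% 300)
      if (!is.null(pole_hgvs)) {
        ret$protein_change[pole_first[1]] <- pole_hgvs
        ret$clinvar_class[pole_first[1]] <- "pathogenic"
        ret$polyphen_call[pole_first[1]] <- "unknown"
      }
    }
    out <- list(ret)
  } else {
    retained_n <- 0
  }
  n_fill <- max(raw_n - retained_n, 0)
  if (n_fill > 0) {
    j <- seq_len(n_fill)
    out <- c(out, list(filler_rows(
      sample_id, all_genes[(salt0 + j) %% length(all_genes) + 1],
      salt0 + 31 * j)))
  }
  purrr::list_rbind(out)
}

# Electropherogram traces for one sample; `unstable` names the markers whose
# tumor trace gains a novel dominant allele shifted 5 bp down.
sample_marker_traces <- function(sample_id, unstable = character(),
                                 markers = marker_set()) {
  L <- unname(.marker_lengths[markers])
  L[is.na(L)] <- 100
  base <- tibble(
    marker = rep(markers, each = 3),
    length_bp = as.vector(rbind(L, L - 1, L + 1)),
    height = rep(c(1000, 450, 300), length(markers))
  )
  novel <- tibble(marker = unstable,
                  length_bp = unname(L[match(unstable, markers)]) - 5,
                  height = 900)
  bind_rows(base |> mutate(tissue = "tumor"),
            novel |> mutate(tissue = "tumor"),
            base |> mutate(tissue = "normal")) |>
    mutate(sample_id = sample_id) |>
    select("sample_id", "marker", "tissue", "length_bp", "height")
}

#' Draw survival times with a given median
#'
#' Weibull event times parameterised by their median, the generator's model
#' for DFS/OS. `shape = 1` is the exponential special case; the default
#' `shape = 2` (increasing hazard) matches the dispersion needed for cohorts
#' whose group medians alone carry prognostic separation. Censoring is an
#' independent Bernoulli event indicator. Draws from the current RNG state.
#'
#' @param n Number of subjects.
#' @param median_months Median survival (months).
#' @param shape Weibull shape (default 2).
#' @param censoring Fraction of censored subjects (default 0.15).
#' @return Tibble `time`, `event`.
#' @export
simulate_survival_times <- function(n, median_months, shape = 2,
                                    censoring = 0.15) {
  if (median_months <= 0 || shape <= 0) abort("Invalid survival parameters.")
  scale <- median_months / log(2)^(1 / shape)
  tibble(time = pmax(stats::rweibull(n, shape, scale), 0.1),
         event = stats::rbinom(n, 1, 1 - censoring))
}

#' Simulate a full synthetic endometrial-cancer cohort
#'
#' Draws each sample's group, gene mutations (group-specific Bernoulli), raw
#' mutational load (discretized log-normal matched to the group's median and
#' clipped to its observed range), annotated variant rows (each mutated gene
#' realized as at least one filter-passing row, the remainder as sub-threshold
#' filler rows), paired tumor/normal microsatellite traces (MSI-group samples
#' and a POLE subset forced to at least 3 unstable markers of 8), clinical
#' covariates and exponential survival times with the group's median and
#' censoring fraction.
#'
#' @param n Cohort size (default 96).
#' @param specs Named list of four [group_spec()]s (default
#'   [default_group_specs()]).
#' @param seed Integer seed.
#' @param pole_msi_prob Probability that a POLE sample also shows MSI
#'   (default 3/16, the observed overlap).
#' @param pole_hotspot_prob Probability that a POLE domain mutation is a
#'   hotspot (default 5/16).
#' @param survival_shape Weibull shape for survival times (default 2; 1 is
#'   exponential). See [simulate_survival_times()].
#' @return An `ec_cohort` list: tibbles `variants`, `markers`, `clinical`,
#'   `truth`, plus `seed`.
#' @export
simulate_cohort <- function(n = 96, specs = default_group_specs(), seed = 1,
                            pole_msi_prob = 3 / 16,
                            pole_hotspot_prob = 5 / 16,
                            survival_shape = 2) {
  props <- vapply(specs, function(s) s$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-8) abort("Group proportions must sum to 1.")
  panel <- gene_panel()
  with_seed(seed, {
    groups <- sample(names(specs), n, replace = TRUE, prob = props)
    ids <- sprintf("SIM%03d", seq_len(n))
    per_sample <- purrr::map(seq_len(n), function(i) {
      sp <- specs[[groups[i]]]
      p <- sp$gene_probs[panel$genes]
      status <- stats::rbinom(length(p), 1, p)
      genes <- panel$genes[status == 1]
      if (groups[i] == "POLE" && !"POLE" %in% genes) genes <- c("POLE", genes)
      raw_n <- round(stats::rlnorm(1, log(sp$load_median), 0.45))
      raw_n <- min(max(raw_n, sp$load_range[1]), sp$load_range[2])
      retained_n <- length(genes) + stats::rpois(1, 0.8 * length(genes))
      pole_hgvs <- NULL
      if (groups[i] == "POLE") {
        pole_hgvs <- if (stats::runif(1) < pole_hotspot_prob) {
          sample(c("p.P286R", "p.V411L"), 1)
        } else {
          sprintf("p.S%dF", sample(270:470, 1))
        }
      }
      msi_h <- groups[i] == "MSI" ||
        (groups[i] == "POLE" && stats::runif(1) < pole_msi_prob)
      unstable <- if (msi_h) {
        sample(marker_set(), sample(3:6, 1))
      } else {
        character()
      }
      dfs <- simulate_survival_times(1, sp$dfs_median, survival_shape,
                                     sp$censoring)
      os <- simulate_survival_times(1, sp$os_median, survival_shape,
                                    sp$censoring)
      list(
        variants = sample_variant_rows(ids[i], genes, retained_n, raw_n,
                                       salt0 = 1000 * i, pole_hgvs = pole_hgvs),
        markers = sample_marker_traces(ids[i], unstable),
        clinical = tibble(
          sample_id = ids[i],
          histology = if (stats::runif(1) < 0.135) "serous" else "endometrioid",
          stage = if (stats::runif(1) < 0.18) "advanced" else "early",
          grade = sample(c("I", "II", "III"), 1, prob = c(45, 28, 23)),
          dfs_time = dfs$time, dfs_event = dfs$event,
          os_time = os$time, os_event = os$event
        )
      )
    })
    structure(list(
      variants = purrr::list_rbind(purrr::map(per_sample, "variants")),
      markers = purrr::list_rbind(purrr::map(per_sample, "markers")),
      clinical = purrr::list_rbind(purrr::map(per_sample, "clinical")),
      truth = tibble(sample_id = ids, group = groups),
      seed = seed
    ), class = "ec_cohort")
  })
}

#' @export
print.ec_cohort <- function(x, ...) {
  cat(sprintf("<ec_cohort> %d samples, %d variant rows, %d trace rows\n",
              nrow(x$truth), nrow(x$variants), nrow(x$markers)))
  print(count(x$truth, .data$group))
  invisible(x)
}

#' Write a cohort's tables to disk
#'
#' Emits the cohort in the package's input dialects: `variants.tsv` (readable
#' by [read_variant_table()]), `msi_traces.tsv`, `clinical.tsv`, `truth.tsv`
#' and, for fixtures, `manifest.json`.
#'
#' @param cohort An `ec_cohort` or `ec_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- cohort$variants |>
    rename(hgvs_p = "protein_change", clinvar = "clinvar_class",
           polyphen = "polyphen_call", sift = "sift_call")
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    markers = file.path(dir, "msi_traces.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(v, paths["variants"])
  readr::write_tsv(cohort$markers, paths["markers"])
  readr::write_tsv(cohort$clinical, paths["clinical"])
  readr::write_tsv(cohort$truth, paths["truth"])
  if (!is.null(cohort$manifest)) {
    paths <- c(paths, manifest = file.path(dir, "manifest.json"))
    jsonlite::write_json(cohort$manifest, paths["manifest"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
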