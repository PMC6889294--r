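# Per-group gene-positive counts of the reference fixture. Stated
# group-conditional frequencies and cohort totals are hit exactly; the
# remaining cells are free parameters fixed once at TCGA-typical values and
# recorded in the fixture manifest.
.fixture_gene_counts <- local({
  genes <- c("POLE", "PTEN", "TP53", "ARID1A", "ARID5B", "FBXW7", "PPP2R1A",
             "CTCF", "CTNNB1", "RPL22", "KRAS", "PIK3CA", "PIK3R1")
  m <- cbind(
    POLE = c(16, 14, 8, 10, 12, 3, 2, 7, 5, 10, 3, 10, 6),
    MSI  = c(0, 9, 2, 7, 6, 1, 1, 3, 3, 10, 2, 6, 4),
    CNL  = c(0, 29, 7, 24, 20, 4, 3, 15, 25, 19, 3, 22, 17),
    CNH  = c(0, 1, 15, 6, 4, 4, 9, 1, 1, 2, 1, 8, 2)
  )
  rownames(m) <- genes
  m
})

.fixture_group_sizes <- c(POLE = 16, MSI = 12, CNL = 48, CNH = 20)

# Per-sample retained (filter-passing) variant counts, descending within each
# group; jointly these give a cohort median of 9.5 (range 2-64).
.fixture_retained <- list(
  POLE = c(64, 60, 54, 48, 44, 40, 36, 34, 32, 30, 28, 26, 24, 22, 20, 18),
  MSI = c(24, 20, 18, 16, 14, 13, 12, 11, 10, 9, 8, 7),
  CNL = rev(c(2, 2, 3, 3, 3, 4, 4, 4, 4, 5, 5, 5, 5, 5, 6, 6, 6, 6, 6, 7, 7,
              7, 7, 7, 8, 8, 8, 8, 8, 8, 9, 9, 10, 10, 11, 11, 12, 12, 13,
              13, 14, 15, 16, 17, 18, 20, 22, 25)),
  CNH = c(16, 14, 13, 12, 11, 10, 10, 9, 9, 8, 8, 7, 7, 6, 6, 5, 5, 4, 4, 3)
)

# Per-sample raw annotated-variant counts (same descending order), giving
# group medians 94/40/37/32 and a cohort median of 40 (range 13-171).
.fixture_raw <- list(
  POLE = c(171, 155, 140, 130, 120, 110, 100, 96, 92, 90, 85, 75, 65, 55,
           45, 31),
  MSI = c(93, 75, 60, 52, 45, 41, 39, 38, 34, 30, 25, 19),
  CNL = rev(c(13, 15, 17, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31,
              32, 33, 34, 35, 35, 36, 36, 36, 38, 38, 40, 40, 41, 42, 43, 44,
              45, 46, 48, 50, 52, 55, 58, 62, 66, 70, 75, 80, 90, 100, 120,
              138)),
  CNH = c(96, 80, 65, 55, 45, 40, 36, 34, 33, 32, 32, 31, 31, 30, 29, 27,
          25, 23, 21, 19)
)

# Assign each gene's positives to group samples by a greedy degree
# realization: capacities are the per-sample retained counts, and each gene
# (largest first) takes the samples with the most remaining slack. A repair
# pass guarantees every sample at least one mutated gene. Errors if any
# capacity would be exceeded.
assign_group_genes <- function(counts, capacity, force_gene = NULL) {
  n <- length(capacity)
  genes <- names(counts)
  assigned <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  if (!is.null(force_gene)) {
    assigned[, force_gene] <- ifelse(seq_len(n) <= counts[force_gene], 1L, 0L)
  }
  todo <- setdiff(genes[counts > 0], force_gene)
  for (g in todo[order(counts[todo], decreasing = TRUE)]) {
    slack <- capacity - rowSums(assigned)
    pick <- order(-slack, seq_len(n))[seq_len(counts[g])]
    assigned[pick, g] <- 1L
  }
  # every sample needs a mutated gene to anchor its retained variants
  for (i in which(rowSums(assigned) == 0)) {
    moved <- FALSE
    for (g in genes[order(counts[genes], decreasing = TRUE)]) {
      donors <- which(assigned[, g] == 1L & rowSums(assigned) >= 2)
      if (length(donors) > 0) {
        donor <- donors[which.max(capacity[donors] - rowSums(assigned)[donors])]
        assigned[donor, g] <- 0L
        assigned[i, g] <- 1L
        moved <- TRUE
        break
      }
    }
    if (!moved) abort("Fixture builder: cannot give every sample a mutation.")
  }
  if (any(rowSums(assigned) > capacity)) {
    abort("Fixture builder: gene count exceeds a sample's retained capacity.")
  }
  if (!all(colSums(assigned) == counts)) {
    abort("Fixture builder: per-gene counts not realized.")
  }
  assigned
}

# Deterministic within-group survival times hitting the printed median, min
# and max exactly (even group sizes: the two central values equal the median).
survival_quantiles <- function(n, min, med, max) {
  c(seq(min, med, length.out = n / 2), seq(med, max, length.out = n / 2))
}

.fixture_survival <- list(
  dfs = list(POLE = c(24.27, 55.40, 77.43), MSI = c(11.9, 38.33, 74.93),
             CNL = c(2.067, 34.43, 91.00), CNH = c(4.87, 27.70, 91.2)),
  os = list(POLE = c(24.27, 55.40, 77.43), MSI = c(11.9, 38.6, 74.93),
            CNL = c(2.067, 42.57, 91.00), CNH = c(6.30, 30.53, 91.2))
)

#' Build the deterministic 96-sample reference fixture
#'
#' Constructs a fully synthetic cohort that reproduces the published cohort's
#' printed marginals exactly: truth-group sizes 16/12/48/20; MSI-H in 15
#' samples (3 inside the POLE group); per-gene positives PTEN 53, TP53 32,
#' POLE 16, KRAS 9, CTCF 26, RPL22 41, ARID1A 47, ARID5B 42; the stated
#' group-conditional counts; retained-mutation cohort median 9.5 (range
#' 2-64) and raw median 40 (range 13-171) with group medians 94/40/37/32;
#' 5 POLE hotspot cases; covariate margins (endometrioid 83 / serous 13,
#' early 79 / advanced 17, grades 45/28/23) and deterministic survival times
#' hitting each group's printed median and range. The build is verified by
#' the independent [check_fixture()] recount and aborts if any exact
#' constraint is violated.
#'
#' @param seed Recorded in the manifest for provenance; the construction is
#'   fully deterministic, so any seed yields byte-identical output.
#' @return An `ec_fixture` (an `ec_cohort` with a `manifest`).
#' @export
build_reference_fixture <- function(seed = 0) {
  panel <- gene_panel()
  groups <- rep(names(.fixture_group_sizes), .fixture_group_sizes)
  ids <- sprintf("EC%03d", seq_along(groups))
  gene_mat <- matrix(0L, length(ids), length(panel$genes),
                     dimnames = list(ids, panel$genes))
  for (grp in names(.fixture_group_sizes)) {
    rows <- which(groups == grp)
    gene_mat[rows, ] <- assign_group_genes(
      .fixture_gene_counts[, grp], .fixture_retained[[grp]],
      force_gene = if (grp == "POLE") "POLE" else NULL)
  }
  retained <- unlist(.fixture_retained, use.names = FALSE)
  raw <- unlist(.fixture_raw, use.names = FALSE)

  pole_rows <- which(groups == "POLE")
  hotspot_rows <- pole_rows[c(2, 5, 8, 11, 14)]
  pole_hgvs <- stats::setNames(rep(NA_character_, length(ids)), ids)
  pole_hgvs[pole_rows] <- sprintf("p.S%dF", 280 + 11 * seq_along(pole_rows))
  pole_hgvs[hotspot_rows] <- rep(c("p.P286R", "p.V411L"), length.out = 5)

  variants <- purrr::map(seq_along(ids), function(i) {
    sample_variant_rows(
      ids[i], panel$genes[gene_mat[i, ] == 1L], retained[i], raw[i],
      salt0 = 997L * i,
      pole_hgvs = if (!is.na(pole_hgvs[i])) pole_hgvs[[i]] else NULL)
  }) |> purrr::list_rbind()

  msi_h_rows <- c(pole_rows[1:3], which(groups == "MSI"))
  n_unstable <- 3 + (seq_along(msi_h_rows) - 1) %% 4
  markers <- purrr::map(seq_along(ids), function(i) {
    j <- match(i, msi_h_rows)
    unstable <- if (!is.na(j)) {
      marker_set()[((j - 1 + seq_len(n_unstable[j]) - 1) %% 8) + 1]
    } else {
      character()
    }
    sample_marker_traces(ids[i], unstable)
  }) |> purrr::list_rbind()

  grade <- character(length(ids))
  grade_plan <- list(POLE = c(5, 6, 5), MSI = c(6, 4, 2),
                     CNL = c(32, 12, 4), CNH = c(2, 6, 12))
  for (grp in names(grade_plan)) {
    grade[groups == grp] <- rep(c("I", "II", "III"), grade_plan[[grp]])
  }
  stage <- rep("early", length(ids))
  stage[which(groups == "MSI")[9:12]] <- "advanced"
  stage[which(groups == "CNH")[1:7]] <- "advanced"
  stage[which(groups == "CNL")[1:6]] <- "advanced"

  pick <- function(grp, k, predicates) {
    rows <- which(groups == grp)
    for (pred in predicates) {
      hit <- rows[pred(rows)]
      if (length(hit) >= k) return(hit[seq_len(k)])
    }
    abort(sprintf("Fixture builder: no serous candidate in group %s.", grp))
  }
  serous <- c(
    pick("CNH", 8, list(function(r) gene_mat[r, "TP53"] == 1 &
                          gene_mat[r, "PTEN"] == 0 & gene_mat[r, "RPL22"] == 0)),
    pick("POLE", 1, list(
      function(r) gene_mat[r, "PTEN"] == 0 & gene_mat[r, "TP53"] == 0 &
        gene_mat[r, "RPL22"] == 0,
      function(r) gene_mat[r, "PTEN"] == 0 & gene_mat[r, "TP53"] == 0,
      function(r) gene_mat[r, "PTEN"] == 0)),
    pick("MSI", 1, list(
      function(r) gene_mat[r, "PTEN"] == 0 & gene_mat[r, "TP53"] == 0 &
        gene_mat[r, "RPL22"] == 1,
      function(r) gene_mat[r, "PTEN"] == 0 & gene_mat[r, "RPL22"] == 1,
      function(r) gene_mat[r, "PTEN"] == 0)),
    pick("CNL", 3, list(
      function(r) gene_mat[r, "PTEN"] == 0 & gene_mat[r, "TP53"] == 0 &
        gene_mat[r, "RPL22"] == 0,
      function(r) gene_mat[r, "PTEN"] == 0 & gene_mat[r, "TP53"] == 0))
  )
  histology <- ifelse(seq_along(ids) %in% serous, "serous", "endometrioid")

  surv <- purrr::map(c(dfs = "dfs", os = "os"), function(ep) {
    out <- numeric(length(ids))
    for (grp in names(.fixture_group_sizes)) {
      q <- .fixture_survival[[ep]][[grp]]
      out[groups == grp] <- survival_quantiles(sum(groups == grp),
                                               q[1], q[2], q[3])
    }
    out
  })
  event <- as.integer(seq_along(ids) %% 7 != 0)

  clinical <- tibble(
    sample_id = ids, histology = histology, stage = stage, grade = grade,
    dfs_time = surv$dfs, dfs_event = event,
    os_time = surv$os, os_event = event
  )
  fixture <- structure(list(
    variants = variants, markers = markers, clinical = clinical,
    truth = tibble(sample_id = ids, group = groups), seed = seed
  ), class = c("ec_fixture", "ec_cohort"))

  constraints <- check_fixture(fixture)
  exact_bad <- constraints |>
    filter(.data$class == "exact", !.data$satisfied)
  if (nrow(exact_bad) > 0) {
    abort(paste0("Fixture violates exact constraint(s):\n",
                 paste("-", exact_bad$description, collapse = "\n")))
  }
  fixture$manifest <- list(
    seed = seed,
    n_samples = length(ids),
    free_parameters = paste(
      "Cohort-wide frequencies unstated for PIK3CA, CTNNB1, FBXW7 and for",
      "PPP2R1A/PIK3R1 outside their highlighted groups were fixed once at",
      "TCGA-typical endometrial values; see the per-group count table."),
    gene_counts_by_group = as.data.frame(.fixture_gene_counts),
    constraints = as.data.frame(constraints)
  )
  fixture
}

#' Independently verify the reference fixture
#'
#' Re-derives every constrained quantity from the fixture's emitted tables by
#' running the package pipeline (pathogenicity + quality filters, gene
#' dichotomization, trace-level MSI calling, hierarchical classification)
#' rather than trusting the builder's bookkeeping.
#'
#' @param fixture An `ec_fixture` or `ec_cohort`.
#' @return Tibble `class` (`"exact"`/`"best_effort"`), `description`,
#'   `expected`, `observed`, `satisfied`.
#' @export
check_fixture <- function(fixture) {
  panel <- gene_panel()
  filtered <- apply_quality_filters(fixture$variants)
  profiles <- suppressWarnings(suppressMessages(
    dichotomize_genes(filtered, panel, raw = fixture$variants,
                      samples = fixture$truth$sample_id)))
  msi <- call_msi_status(call_marker_profiles(fixture$markers))
  truth <- fixture$truth
  cn_labels <- truth |>
    filter(.data$group %in% c("CNL", "CNH")) |>
    transmute(sample_id = .data$sample_id, cn_label = .data$group)
  assignments <- suppressWarnings(
    assign_subgroups(profiles, msi, cn_labels = cn_labels, panel = panel))
  joined <- profiles |>
    left_join(truth, by = "sample_id") |>
    left_join(msi |> select("sample_id", "msi_status"), by = "sample_id")

  gene_total <- function(g) sum(joined[[g]])
  gene_in <- function(g, grp) sum(joined[[g]][joined$group == grp])
  cl <- joined$group
  con <- function(class, description, expected, observed) {
    tibble(class = class, description = description,
           expected = expected, observed = observed)
  }
  rows <- bind_rows(
    con("exact", "truth group sizes POLE/MSI/CNL/CNH", "16/12/48/20",
        paste(sum(cl == "POLE"), sum(cl == "MSI"), sum(cl == "CNL"),
              sum(cl == "CNH"), sep = "/")),
    con("exact", "MSI-H total", "15", as.character(sum(joined$msi_status == "MSI-H"))),
    con("exact", "MSI-H inside POLE truth group", "3",
        as.character(sum(joined$msi_status == "MSI-H" & cl == "POLE"))),
    purrr::map2_dfr(
      c("POLE", "PTEN", "TP53", "KRAS", "CTCF", "RPL22", "ARID1A", "ARID5B"),
      c(16, 53, 32, 9, 26, 41, 47, 42),
      function(g, k) con("exact", sprintf("%s positives (cohort)", g),
                         as.character(k), as.character(gene_total(g)))),
    purrr::pmap_dfr(
      list(g = c("PTEN", "ARID1A", "RPL22", "TP53", "PTEN", "PPP2R1A",
                 "PTEN", "TP53", "PIK3R1", "ARID5B", "CTCF", "RPL22"),
           grp = c("MSI", "MSI", "MSI", "CNH", "CNH", "CNH",
                   "CNL", "CNL", "CNL", "CNL", "CNL", "CNL"),
           k = c(9, 7, 10, 15, 1, 9, 29, 7, 17, 20, 15, 19)),
      function(g, grp, k) con("exact", sprintf("%s positives in %s", g, grp),
                              as.character(k), as.character(gene_in(g, grp)))),
    con("exact", "retained load median (range)", "9.5 (2-64)",
        sprintf("%s (%s-%s)", stats::median(joined$retained_n),
                min(joined$retained_n), max(joined$retained_n))),
    con("exact", "raw load median (range)", "40 (13-171)",
        sprintf("%s (%s-%s)", stats::median(joined$raw_n),
                min(joined$raw_n), max(joined$raw_n))),
    con("exact", "hierarchy POLE group", "16",
        as.character(sum(assignments$group == "POLE"))),
    con("exact", "hierarchy MSI group", "12",
        as.character(sum(assignments$group == "MSI"))),
    con("exact", "POLE hotspot cases", "5",
        as.character(sum(joined$pole_hotspot))),
    con("exact", "histology endometrioid/serous", "83/13",
        paste(sum(fixture$clinical$histology == "endometrioid"),
              sum(fixture$clinical$histology == "serous"), sep = "/")),
    con("exact", "stage early/advanced", "79/17",
        paste(sum(fixture$clinical$stage == "early"),
              sum(fixture$clinical$stage == "advanced"), sep = "/")),
    con("exact", "grade I/II/III", "45/28/23",
        paste(sum(fixture$clinical$grade == "I"),
              sum(fixture$clinical$grade == "II"),
              sum(fixture$clinical$grade == "III"), sep = "/")),
    purrr::map2_dfr(names(.fixture_group_sizes), c(94, 40, 37, 32),
                    function(grp, k) {
                      con("best_effort", sprintf("%s raw-load median", grp),
                          as.character(k),
                          as.character(stats::median(joined$raw_n[cl == grp])))
                    }),
    con("best_effort", "serous PTEN-mutated", "0",
        as.character(sum(joined$PTEN == 1 &
                           fixture$clinical$histology == "serous"))),
    con("best_effort", "serous TP53-mutated", "8",
        as.character(sum(joined$TP53 == 1 &
                           fixture$clinical$histology == "serous"))),
    con("best_effort", "serous RPL22-mutated", "1",
        as.character(sum(joined$RPL22 == 1 &
                           fixture$clinical$histology == "serous"))),
    con("best_effort", "POLE-mutated advanced stage", "0",
        as.character(sum(joined$POLE == 1 &
                           fixture$clinical$stage == "advanced")))
  )
  rows |> mutate(satisfied = .data$expected == .data$observed)
}
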