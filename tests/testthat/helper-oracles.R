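# Independent oracles: deliberately naive re-derivations used to check the
# package's statistics, kept free of any package code path.

# Pearson chi-square by direct sum over cells.
oracle_chisq <- function(m) {
  m <- as.matrix(m)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Two-group log-rank by explicit O-E summation over distinct event times.
oracle_logrank2 <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o - e)^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Exact two-sided rank-sum p by enumeration of all rank assignments.
oracle_ranksum_enum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  all_sums <- apply(utils::combn(length(pooled), n1), 2,
                    function(idx) sum(r[idx]))
  ew <- mean(all_sums)
  mean(abs(all_sums - ew) >= abs(obs - ew) - 1e-12)
}

# Minimal variant-row builder with retained-grade defaults.
variant_row <- function(sample_id = "S1", gene = "PTEN", depth = 1000,
                        vaf = 0.3, clinvar = "pathogenic",
                        polyphen = "unknown", sift = "unknown",
                        consequence = "missense", protein_change = "p.A123T",
                        chrom = "chr10", pos = 1e6, ref = "A", alt = "T") {
  tibble::tibble(sample_id = sample_id, gene = gene, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, protein_change = protein_change,
                 consequence = consequence, depth = depth, vaf = vaf,
                 clinvar_class = clinvar, polyphen_call = polyphen,
                 sift_call = sift)
}

# Long-format electropherogram rows for one sample/marker pair.
trace_rows <- function(sample_id, marker, tumor, normal) {
  dplyr::bind_rows(
    tibble::tibble(sample_id = sample_id, marker = marker, tissue = "tumor",
                   length_bp = as.numeric(names(tumor)),
                   height = unname(tumor)),
    tibble::tibble(sample_id = sample_id, marker = marker, tissue = "normal",
                   length_bp = as.numeric(names(normal)),
                   height = unname(normal))
  )
}

# Traces for a sample with `k` markers forced unstable (5 bp shift).
sample_traces <- function(sample_id, k = 0) {
  mk <- marker_set()
  purrr::map_dfr(seq_along(mk), function(i) {
    normal <- c(`100` = 1000, `99` = 450)
    tumor <- if (i <= k) c(normal, `95` = 900) else normal
    trace_rows(sample_id, mk[i], tumor, normal)
  })
}

# A perfectly separable 12-gene training set: TP53 equals the label.
separable_training_set <- function(n = 60) {
  genes <- gene_panel()$rf_genes
  label <- rep(c("CNH", "CNL"), length.out = n)
  m <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  m[, "TP53"] <- as.integer(label == "CNH")
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("P%02d", 1:n)),
                   tibble::as_tibble(m), tibble::tibble(label = label))
}
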