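test_that("TSV variant tables round-trip, including threshold boundary values", {
  tsv <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"), gene = c("PTEN", "TP53", "KRAS"),
    chrom = c("chr10", "chr17", "chr12"), pos = c(100, 200, 300),
    ref = c("A", "C", "G"), alt = c("T", "G", "A"),
    hgvs_p = c("p.R130Q", "p.R175H", "p.G12D"),
    consequence = c("missense", "missense", "missense"),
    depth = c(600, 1200, 800), vaf = c(0.05, 0.31, 0.22),
    clinvar = c("pathogenic", "vus", "unreported"),
    polyphen = c("damaging", "unknown", "damaging"),
    sift = c("deleterious", "unknown", "unknown"))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tsv, path)
  got <- suppressMessages(read_variant_table(path, "tsv"))
  expect_equal(nrow(got), 3)
  expect_equal(got$depth[1], 600)
  expect_equal(got$vaf[1], 0.05)
  expect_equal(got$protein_change, tsv$hgvs_p)
  expect_equal(got$clinvar_class, tsv$clinvar)

  readr::write_tsv(tsv[setdiff(names(tsv), "vaf")], path)
  expect_error(suppressMessages(read_variant_table(path, "tsv")), "vaf")
})

test_that("multi-allelic VCF records split into one row per ALT with per-allele VAF", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr10\t89620100\t.\tA\tT,G\t.\tPASS\t",
           "SAMPLE=S1;GENE=PTEN;HGVSP=p.R130Q;CSQ=missense;DP=900;AF=0.30,0.10;",
           "CLNSIG=pathogenic;POLYPHEN=damaging;SIFT=deleterious"),
    paste0("chr17\t7578000\t.\tC\tG\t.\tPASS\t",
           "SAMPLE=S1;GENE=TP53;HGVSP=p.R175H;CSQ=missense;DP=700;AF=0.25;",
           "CLNSIG=vus;POLYPHEN=unknown;SIFT=unknown"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  got <- suppressMessages(read_variant_table(path, "vcf"))
  # hand expansion: the biallelic row contributes two records at one position
  expect_equal(nrow(got), 3)
  split_rows <- got[got$gene == "PTEN", ]
  expect_equal(split_rows$pos, c(89620100, 89620100))
  expect_equal(split_rows$alt, c("T", "G"))
  expect_equal(split_rows$vaf, c(0.30, 0.10))
  expect_equal(split_rows$depth, c(900, 900))
})

test_that("pathogenicity triage follows ClinVar precedence and predictor fallback", {
  cases <- list(
    list(clinvar = "pathogenic", polyphen = "benign", sift = "tolerated",
         consequence = "missense", want = "retain"),
    list(clinvar = "likely_benign", polyphen = "damaging", sift = "deleterious",
         consequence = "missense", want = "discard"),
    list(clinvar = "benign", polyphen = "damaging", sift = "unknown",
         consequence = "nonsense", want = "discard"),
    list(clinvar = "unreported", polyphen = "unknown", sift = "deleterious",
         consequence = "missense", want = "retain"),
    list(clinvar = "unreported", polyphen = "damaging", sift = "tolerated",
         consequence = "missense", want = "retain"),
    list(clinvar = "unreported", polyphen = "unknown", sift = "unknown",
         consequence = "frameshift", want = "retain"),
    list(clinvar = "unreported", polyphen = "unknown", sift = "unknown",
         consequence = "synonymous", want = "discard"),
    list(clinvar = "unreported", polyphen = "benign", sift = "unknown",
         consequence = "missense", want = "discard"),
    list(clinvar = "vus", polyphen = "benign", sift = "tolerated",
         consequence = "synonymous", want = "retain")
  )
  for (cs in cases) {
    v <- variant_row(clinvar = cs$clinvar, polyphen = cs$polyphen,
                     sift = cs$sift, consequence = cs$consequence)
    got <- classify_pathogenicity(v)$pathogenicity_call
    expect_equal(got, cs$want,
                 info = paste(cs$clinvar, cs$polyphen, cs$sift, cs$consequence))
  }
})

test_that("quality filters use closed 600X / 5% bounds and log rejections", {
  v <- dplyr::bind_rows(
    variant_row(depth = 599, vaf = 0.40),                 # low depth
    variant_row(depth = 600, vaf = 0.05, clinvar = "vus"),# boundary keeps
    variant_row(depth = 5000, vaf = 0.04),                # low VAF
    variant_row(depth = 900, vaf = 0.30, clinvar = "benign"))
  kept <- apply_quality_filters(v)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$depth, 600)
  log <- filter_log(kept)
  expect_equal(log$n[log$reason == "low_depth"], 1)
  expect_equal(log$n[log$reason == "low_vaf"], 1)
  expect_equal(log$n[log$reason == "pathogenicity"], 1)
})

test_that("filtering is idempotent and monotone in the thresholds", {
  set.seed(11)
  v <- purrr::map_dfr(1:120, function(i) {
    variant_row(sample_id = sprintf("S%d", i %% 7),
                depth = sample(200:2500, 1), vaf = runif(1, 0, 0.6),
                clinvar = sample(c("pathogenic", "vus", "benign",
                                   "unreported"), 1),
                polyphen = sample(c("damaging", "benign", "unknown"), 1),
                consequence = sample(c("missense", "synonymous"), 1))
  })
  once <- apply_quality_filters(v)
  twice <- apply_quality_filters(once)
  expect_equal(twice, once, ignore_attr = TRUE)
  expect_equal(filter_log(twice)$n[filter_log(twice)$reason == "retained"],
               nrow(once))
  keyed <- function(d) paste(d$sample_id, d$pos, d$depth, d$vaf)
  for (pol in list(filter_policy(min_depth = 900),
                   filter_policy(min_vaf = 0.2),
                   filter_policy(min_depth = 1500, min_vaf = 0.3))) {
    stricter <- apply_quality_filters(v, pol)
    expect_true(all(keyed(stricter) %in% keyed(once)))
  }
})

test_that("dichotomization gives indicator semantics invariant to order and duplication", {
  v <- dplyr::bind_rows(
    variant_row("S1", "PTEN", pos = 1), variant_row("S1", "PTEN", pos = 2),
    variant_row("S1", "PTEN", pos = 3), variant_row("S1", "TP53", pos = 4))
  prof <- suppressWarnings(dichotomize_genes(v))
  expect_equal(prof$PTEN, 1L)
  expect_equal(prof$TP53, 1L)
  expect_equal(sum(dplyr::select(prof, dplyr::all_of(gene_panel()$genes))), 2)
  expect_equal(prof$retained_n, 4L)

  shuffled <- suppressWarnings(dichotomize_genes(v[c(3, 1, 4, 2), ]))
  duplicated <- suppressWarnings(dichotomize_genes(dplyr::bind_rows(v, v[1, ])))
  cols <- gene_panel()$genes
  expect_equal(shuffled[cols], prof[cols])
  expect_equal(duplicated[cols], prof[cols])
})

test_that("samples filtered to zero keep an auditable all-zero profile", {
  raw <- variant_row("S9", "PTEN", depth = 100)
  filtered <- apply_quality_filters(raw)
  expect_warning(
    prof <- dichotomize_genes(filtered, raw = raw, samples = "S9"),
    "all-zero")
  expect_equal(prof$retained_n, 0L)
  expect_equal(prof$raw_n, 1L)
  expect_equal(sum(dplyr::select(prof, dplyr::all_of(gene_panel()$genes))), 0)
})

test_that("mutational load uses the even-n central-mean median", {
  prof <- tibble::tibble(sample_id = paste0("S", 1:4),
                         retained_n = c(2L, 9L, 10L, 64L),
                         raw_n = c(10L, 20L, 30L, 100L))
  loads <- mutational_load(prof, by = "retained")
  s <- load_summary(loads)
  expect_equal(s$median, 9.5)
  expect_equal(c(s$min, s$max), c(2, 64))
  expect_error(mutational_load(prof[0, ]), "Empty")
})
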