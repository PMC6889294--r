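test_that("POLE exonuclease-domain detection parses residues against 268-471", {
  hot <- detect_pole_domain_mutation(
    variant_row(gene = "POLE", protein_change = "p.P286R"))
  expect_true(hot$pole_domain)
  expect_true(hot$pole_hotspot)

  out <- detect_pole_domain_mutation(
    variant_row(gene = "POLE", protein_change = "p.S500F"))
  expect_false(out$pole_domain)
  expect_false(out$pole_hotspot)

  none <- detect_pole_domain_mutation(variant_row(gene = "PTEN"),
                                      samples = "S1")
  expect_false(none$pole_domain)

  # unparseable HGVS-p is excluded from the domain test, not an error
  expect_message(
    bad <- detect_pole_domain_mutation(
      variant_row(gene = "POLE", protein_change = "c.858+1G>A")),
    "parseable")
  expect_false(bad$pole_domain)

  expect_error(pole_rule(domain_start = 500, domain_end = 400), "<")
})

profile_row <- function(id, pole = FALSE, tp53 = 0) {
  p <- tibble::tibble(sample_id = id, pole_domain = pole, pole_hotspot = FALSE)
  for (g in gene_panel()$genes) p[[g]] <- 0L
  p$TP53 <- tp53
  p
}

test_that("the hierarchy gives POLE precedence over MSI, then MSI, then CN", {
  profiles <- dplyr::bind_rows(
    profile_row("A", pole = TRUE), profile_row("B"), profile_row("C", tp53 = 1L))
  msi <- tibble::tibble(sample_id = c("A", "B", "C"),
                        msi_status = c("MSI-H", "MSI-H", "MSS"))
  model <- train_rf(separable_training_set(), mtry = 4, n_trees = 201, seed = 1)
  got <- assign_subgroups(profiles, msi, model = model)
  expect_equal(got$group, c("POLE", "MSI", "CNH"))
  expect_equal(got$rule_fired, c("pole_domain", "msi_high", "rf_cnh"))
  expect_true(is.na(got$rf_vote_fraction[1]))
  expect_gte(got$rf_vote_fraction[3], 0.9)
})

test_that("indeterminate MSI falls through to the CN branch with a warning", {
  profiles <- profile_row("X")
  msi <- tibble::tibble(sample_id = "X", msi_status = "indeterminate")
  cn <- tibble::tibble(sample_id = "X", cn_label = "CNL")
  expect_warning(got <- assign_subgroups(profiles, msi, cn_labels = cn),
                 "indeterminate")
  expect_equal(got$group, "CNL")
})

test_that("classification is a total partition and POLE precedence is absolute", {
  set.seed(21)
  n <- 40
  profiles <- purrr::map_dfr(1:n, function(i) {
    profile_row(sprintf("S%02d", i), pole = runif(1) < 0.2,
                tp53 = rbinom(1, 1, 0.5))
  })
  msi <- tibble::tibble(
    sample_id = profiles$sample_id,
    msi_status = sample(c("MSI-H", "MSS"), n, replace = TRUE))
  cn <- tibble::tibble(sample_id = profiles$sample_id, cn_label = "CNL")
  got <- assign_subgroups(profiles, msi, cn_labels = cn)
  expect_equal(sum(subgroup_summary(got)$n), n)
  expect_setequal(got$sample_id, profiles$sample_id)
  # flipping any CN sample's POLE-domain flag must move it to POLE
  cn_ids <- got$sample_id[got$group %in% c("CNL", "CNH")]
  for (id in utils::head(cn_ids, 5)) {
    flipped <- profiles
    flipped$pole_domain[flipped$sample_id == id] <- TRUE
    regot <- assign_subgroups(flipped, msi, cn_labels = cn)
    expect_equal(regot$group[regot$sample_id == id], "POLE")
  }
})

test_that("missing MSI status and missing CN model are explicit errors", {
  profiles <- profile_row("S1")
  expect_error(
    assign_subgroups(profiles,
                     tibble::tibble(sample_id = "S2", msi_status = "MSS")),
    "S1")
  expect_error(
    assign_subgroups(profiles,
                     tibble::tibble(sample_id = "S1", msi_status = "MSS")),
    "model")
})

test_that("on the fixture the MSI group is total MSI-H minus the POLE overlap", {
  fx <- build_reference_fixture()
  prof <- cohort_profiles(fx)
  n_msih <- sum(prof$msi$msi_status == "MSI-H")
  res <- classify_cohort(
    list(profiles = prof$profiles, msi = prof$msi),
    cn_labels = dplyr::transmute(
      dplyr::filter(fx$truth, group %in% c("CNL", "CNH")),
      sample_id = sample_id, cn_label = group))
  sizes <- res$summary
  overlap <- sum(prof$msi$msi_status == "MSI-H" &
                   prof$profiles$pole_domain)
  expect_equal(n_msih, 15)
  expect_equal(overlap, 3)
  expect_equal(sizes$n[sizes$group == "MSI"], n_msih - overlap)
})
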