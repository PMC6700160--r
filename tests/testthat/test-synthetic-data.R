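test_that("design generation honours group sizes and the paired fraction", {
  d <- generate_design(12, 12, 10, paired_fraction = 1, seed = 1)
  expect_equal(sum(d$dataset_id == "CD4"), 34)
  expect_equal(sum(d$dataset_id == "CD8"), 34)
  both <- d |> dplyr::count(individual_id) |> dplyr::filter(n == 2)
  expect_equal(nrow(both), 34)

  d0 <- generate_design(2, 2, 2, paired_fraction = 0, seed = 5)
  both0 <- d0 |> dplyr::count(individual_id) |> dplyr::filter(n == 2)
  expect_equal(nrow(both0), 0)

  # paired-individual count equals the sum of per-group rounded targets
  d7 <- generate_design(10, 10, 8, paired_fraction = 0.7, seed = 3)
  both7 <- d7 |> dplyr::count(individual_id) |> dplyr::filter(n == 2)
  expect_equal(nrow(both7), round(0.7 * 10) + round(0.7 * 10) + round(0.7 * 8))
  expect_silent(validate_design(d7))

  expect_error(generate_design(1, 5, 5, seed = 1),
               class = "npcomb_invalid_design")
})

test_that("individuals keep identical covariates across datasets", {
  d <- generate_design(6, 6, 5, paired_fraction = 0.8, seed = 11)
  per_ind <- d |> dplyr::distinct(individual_id, group, age, sex)
  expect_equal(anyDuplicated(per_ind$individual_id), 0L)
})

test_that("annotations respect strand-aware TSS and planted cis probes", {
  ann <- generate_annotations(30, 25, n_cis_pairs = 4, promoter_offset = 500,
                              seed = 2)
  expect_equal(nrow(ann$cis_links), 4)
  tss <- compute_tss(ann$annotations)
  linked <- dplyr::left_join(ann$cis_links,
                             dplyr::rename(tss, gene_id = feature_id),
                             by = "gene_id")
  probes <- dplyr::filter(ann$annotations, feature_type == "probe")
  pos <- probes$start[match(linked$probe_id, probes$feature_id)]
  expect_true(all(abs(pos - linked$tss) <= 500))
  # probes are single positions; genes are proper intervals
  expect_true(all(probes$start == probes$end))
  genes <- dplyr::filter(ann$annotations, feature_type == "gene")
  expect_true(all(genes$end > genes$start))

  expect_error(generate_annotations(3, 10, n_cis_pairs = 5, seed = 1),
               class = "npcomb_invalid_annotation")
})

test_that("generators are deterministic given the master seed", {
  a <- simulate_study(n_genes = 60, n_probes = 40, n_cis_pairs = 3, seed = 9)
  b <- simulate_study(n_genes = 60, n_probes = 40, n_cis_pairs = 3, seed = 9)
  expect_identical(a$expression$CD4$values, b$expression$CD4$values)
  expect_identical(a$expression$CD8$counts, b$expression$CD8$counts)
  expect_identical(a$methylation$CD4$values, b$methylation$CD4$values)
  expect_identical(a$design, b$design)
})

test_that("expression filter drops genes at or below 1 CPM in any sample", {
  st <- simulate_study(n_genes = 300, n_probes = 0, seed = 4,
                       expr_spec = expression_spec(
                         baseline_cpm_range = c(0.5, 100)))
  for (d in names(st$expression)) {
    counts <- st$expression[[d]]$counts
    cpm <- t(t(counts) / colSums(counts)) * 1e6
    expect_true(all(cpm > 1))
  }
  expect_gt(length(st$dropped_genes), 0)
  expect_false(any(st$dropped_genes %in% rownames(st$expression$CD4$values)))
})

test_that("methylation betas are strictly inside (0, 1)", {
  st <- simulate_study(n_genes = 20, n_probes = 150, seed = 6,
                       meth_spec = methylation_spec(noise_sd = 2))
  for (d in names(st$methylation)) {
    v <- st$methylation[[d]]$values
    expect_true(all(v > 0 & v < 1))
  }
})

test_that("generator rejects invalid specifications", {
  expect_error(expression_spec(dispersion = 0), class = "npcomb_invalid_spec")
  expect_error(methylation_spec(cis_target_rho = -1),
               class = "npcomb_invalid_spec")
  d <- generate_design(3, 3, 2, seed = 1)
  ann <- generate_annotations(5, 5, n_cis_pairs = 2, seed = 1)
  expect_error(generate_methylation(d, ann, seed = 1),
               class = "npcomb_invalid_spec")
})

test_that("shared fraction 1 flags every DE gene as shared in both datasets", {
  st <- simulate_study(n_genes = 200, n_probes = 0, seed = 8,
                       expr_spec = expression_spec(n_de = 30,
                                                   shared_fraction = 1))
  de <- dplyr::filter(st$truth$expression, de_hc_rr | de_rr_sp)
  expect_true(all(de$shared))
  per_ds <- de |> dplyr::count(feature_id)
  expect_true(all(per_ds$n == 2))

  st0 <- simulate_study(n_genes = 100, n_probes = 0, seed = 8,
                        expr_spec = expression_spec(n_de = 0))
  expect_false(any(st0$truth$expression$de_hc_rr))
  expect_false(any(st0$truth$expression$de_rr_sp))
})

test_that("parametric F p-values are uniform under the global null", {
  # 3 seeds x 2 datasets; a single marginal KS draw is allowed (at 5200
  # features the test detects sub-percent deviations, so under exact
  # uniformity one of six p-values still dips below 0.01 now and then)
  ks <- unlist(lapply(1:3, function(s) {
    st <- simulate_study(10, 10, 8, paired_fraction = 0.7,
                         n_genes = 5200, n_probes = 0, seed = s)
    purrr::imap_dbl(st$expression, function(ds, d) {
      dm <- build_design_matrix(dplyr::filter(st$design, dataset_id == d))
      pv <- group_f_statistics(fit_feature_models(ds, dm))$p.value
      suppressWarnings(ks.test(pv, "punif")$p.value)
    })
  }))
  expect_gte(sum(ks > 0.01), 5)
  expect_gt(median(ks), 0.05)
})

test_that("planted cis pairs carry the target anti-correlation", {
  rhos <- unlist(lapply(1:15, function(s) {
    st <- simulate_study(9, 9, 7, paired_fraction = 1, n_genes = 6,
                         n_probes = 6, n_cis_pairs = 3, seed = s)
    corr <- correlate_pairs(
      pair_within_distance(st$cis_links$gene_id, st$cis_links$probe_id,
                           st$annotations),
      st$expression, st$methylation, st$design)
    dplyr::semi_join(corr, st$cis_links,
                     by = c("gene_id", "probe_id"))$rho
  }))
  expect_gt(mean(rhos > -0.99 & rhos < -0.6), 0.9)
  expect_lt(median(rhos), -0.8)
})
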