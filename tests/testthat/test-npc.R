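test_that("constrained permutations broadcast labels to paired samples", {
  d <- generate_design(4, 4, 3, paired_fraction = 0.6, seed = 2)
  ps <- constrained_permutations(d, B = 50, seed = 1)
  assert_pairing_constraint(ps)
  # every sample of a shared individual carries that individual's label
  lab_cd4 <- npcomb:::sample_labels_for(ps, "CD4")
  lab_cd8 <- npcomb:::sample_labels_for(ps, "CD8")
  shared <- intersect(
    d$individual_id[d$dataset_id == "CD4"],
    d$individual_id[d$dataset_id == "CD8"])
  for (ind in shared) {
    expect_identical(lab_cd4[paste0(ind, "_CD4"), ],
                     lab_cd8[paste0(ind, "_CD8"), ])
  }
})

test_that("label shuffles preserve the observed multiset per permutation", {
  d <- generate_design(5, 4, 3, paired_fraction = 0.5, seed = 7)
  ps <- constrained_permutations(d, B = 200, seed = 3)
  obs <- table(ps$observed)
  for (b in c(1, 57, 200)) {
    expect_equal(as.vector(table(factor(ps$labels[, b],
                                        levels = names(obs)))),
                 as.vector(obs))
  }
  expect_silent(assert_pairing_constraint(ps))
})

test_that("enumeration yields the exact multinomial number of assignments", {
  d <- tibble::tibble(
    individual_id = c("A", "B", "C", "D"),
    group = c("HC", "HC", "RR", "RR"),
    age = c(30, 40, 35, 45), sex = c("F", "M", "F", "M"),
    dataset_id = "CD4",
    sample_id = paste0(individual_id, "_CD4")
  )
  ps <- enumerate_label_permutations(d)
  expect_equal(ps$B, 6)  # 4! / (2! 2!)
  keys <- apply(ps$labels, 2, paste, collapse = "|")
  expect_equal(length(unique(keys)), 6)
  # sampling more than the distinct assignments is allowed but announced
  expect_message(constrained_permutations(d, B = 10, seed = 1),
                 "replacement")
})

test_that("an unpaired individual's permuted label is independent of others", {
  d <- generate_design(6, 6, 6, paired_fraction = 0.5, seed = 2)
  ps <- constrained_permutations(d, B = 1000, seed = 7)
  tab <- d |> dplyr::count(individual_id)
  single <- tab$individual_id[tab$n == 1][1]
  paired <- tab$individual_id[tab$n == 2][1]
  ct <- suppressWarnings(
    chisq.test(table(ps$labels[single, ], ps$labels[paired, ])))
  expect_gt(ct$p.value, 0.01)
})

test_that("partial p-values follow the pseudocount-with-ties rule", {
  expect_equal(partial_pvalues(5, matrix(1:99 / 100, 1)), 0.01)
  expect_equal(partial_pvalues(0, matrix(1:99, 1)), 1)
  # 3 ties + 6 smaller out of 9 permutations: p = (1 + 3) / (1 + 9)
  expect_equal(partial_pvalues(2, matrix(c(2, 2, 2, rep(1, 6)), 1)), 0.4)
  expect_warning(p_na <- partial_pvalues(NA_real_, matrix(1:9, 1)),
                 "undefined")
  expect_equal(p_na, 1)
})

test_that("Liptak combination matches hand-computed quantile sums", {
  expect_equal(liptak_combine(cbind(0.5, 0.5)), 0, tolerance = 1e-12)
  expect_equal(liptak_combine(cbind(0.05, 0.05)), 3.2897, tolerance = 1e-4)
  expect_equal(liptak_combine(cbind(0.2)), 0.8416, tolerance = 1e-4)
  expect_equal(liptak_combine(cbind(0.05, 0.05), weights = c(2, 0)),
               2 * qnorm(0.95))
  expect_error(liptak_combine(cbind(0.5, 0.5), weights = c(-1, 1)),
               class = "npcomb_invalid_data")
  expect_error(liptak_combine(cbind(0, 0.5)), class = "npcomb_invalid_data")
  # monotone: decreasing any partial p never decreases T
  p <- cbind(runif(50, 0.1, 0.9), runif(50, 0.1, 0.9))
  t1 <- liptak_combine(p)
  p2 <- p
  p2[, 1] <- p2[, 1] / 2
  expect_true(all(liptak_combine(p2) >= t1))
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(23, {
    for (i in 1:5) {
      p <- runif(40)
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("npc_global is deterministic and monotone in its bookkeeping", {
  st <- simulate_study(n_genes = 80, n_probes = 0, seed = 2)
  r1 <- npc_global(st$expression, st$design, B = 99, seed = 5)
  r2 <- npc_global(st$expression, st$design, B = 99, seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  tab <- tidy(r1)
  expect_true(all(tab$global_p >= 1 / (r1$B + 1)))
  expect_true(all(tab$global_p <= 1))
  expect_true(all(tab$q >= tab$global_p - 1e-12))
  expect_true(all(tab$q <= 1))
  # BH never reorders significance
  ord <- order(tab$global_p)
  expect_true(all(diff(tab$q[ord]) >= -1e-12))
})

test_that("duplicated fully paired datasets collapse to the partial test", {
  d <- generate_design(5, 5, 4, paired_fraction = 1, seed = 3)
  y_cd4 <- random_values(d, "CD4", 60, seed = 11)
  y_cd8 <- y_cd4
  colnames(y_cd8) <- paste0(sub("_CD4", "", colnames(y_cd4)), "_CD8")
  res <- npc_global(list(CD4 = y_cd4, CD8 = y_cd8), d, B = 199, seed = 9)
  tab <- tidy(res)
  expect_true(all(abs(tab$global_p - tab$partial_p_CD4) <= 1 / (res$B + 1)))
  expect_equal(tab$partial_p_CD4, tab$partial_p_CD8)
})

test_that("exhaustive NPC matches the brute-force enumeration oracle", {
  d <- tiny_paired_design()
  y_cd4 <- random_values(d, "CD4", 12, seed = 71, sd = 1)
  y_cd8 <- random_values(d, "CD8", 12, seed = 72, sd = 1)
  ps <- enumerate_label_permutations(d)
  expect_equal(ps$B, 90)  # 6! / (2! 2! 2!)
  res <- npc_global(list(CD4 = y_cd4, CD8 = y_cd8), d, permutations = ps)
  oracle <- oracle_npc_exhaustive(list(CD4 = y_cd4, CD8 = y_cd8), d)
  tab <- tidy(res)
  expect_equal(tab$global_p, unname(oracle$global_p), tolerance = 1e-12)
  expect_equal(tab$partial_p_CD4, unname(oracle$partial_p[, 1]),
               tolerance = 1e-12)
  expect_equal(tab$partial_p_CD8, unname(oracle$partial_p[, 2]),
               tolerance = 1e-12)
})

test_that("feature selection applies both thresholds and sorts by p", {
  tab <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    global_p = c(0.0005, 0.0005, 0.01, 0.2),
    q = c(0.05, 0.2, 0.05, 0.9)
  )
  expect_equal(select_features(tab, 0.001, 0.1), "a")
  expect_equal(select_features(tab, 1, 1), c("a", "b", "c", "d"))
  empty <- tab[0, ]
  expect_equal(select_features(empty), character(0))
})

test_that("disjoint feature universes are rejected", {
  d <- tiny_paired_design()
  y1 <- random_values(d, "CD4", 5, seed = 1)
  y2 <- random_values(d, "CD8", 5, seed = 2)
  rownames(y2) <- paste0("other", 1:5)
  expect_error(npc_global(list(CD4 = y1, CD8 = y2), d, B = 9, seed = 1),
               class = "npcomb_invalid_data")
})
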