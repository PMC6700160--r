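test_that("design matrix has the expected columns and treatment coding", {
  d <- tiny_paired_design() |> dplyr::filter(dataset_id == "CD4")
  dm <- build_design_matrix(d)
  expect_equal(colnames(dm),
               c("(Intercept)", "groupRR", "groupSP", "age", "sexM"))
  expect_equal(attr(dm, "group_cols"), c("groupRR", "groupSP"))
  expect_equal(unname(colSums(dm[, c("groupRR", "groupSP")])), c(2, 2))
  expect_equal(mean(dm[, "age"]), 0)  # centered

  # single-level group is rejected
  expect_error(build_design_matrix(dplyr::mutate(d, group = "HC")),
               class = "npcomb_invalid_design")
  # constant age is dropped with a warning
  expect_warning(dm2 <- build_design_matrix(dplyr::mutate(d, age = 40)),
                 "age")
  expect_false("age" %in% colnames(dm2))
  # sex confounded with group triggers a rank error naming the column
  d3 <- dplyr::mutate(d, sex = ifelse(group == "HC", "F", "M"),
                      group = ifelse(group == "SP", "RR", group))
  expect_error(build_design_matrix(d3), "sexM",
               class = "npcomb_rank_error")
})

test_that("OLS fits recover exact and hand-computed solutions", {
  d <- tiny_paired_design() |> dplyr::filter(dataset_id == "CD4")
  dm <- build_design_matrix(d)
  beta <- c(2, 1, -1, 0.05, 0.5)
  y_exact <- rbind(f1 = drop(dm %*% beta))
  fits <- fit_feature_models(y_exact, dm)
  expect_equal(unname(fits$coefficients["f1", ]), beta, tolerance = 1e-10)
  expect_equal(unname(fits$sigma2), 0, tolerance = 1e-18)

  # intercept-only model: residual variance is the sample variance
  x1 <- matrix(1, 4, 1, dimnames = list(paste0("s", 1:4), "(Intercept)"))
  y <- rbind(f1 = c(1, 2, 3, 4))
  colnames(y) <- rownames(x1)
  f1 <- fit_feature_models(y, x1)
  expect_equal(unname(f1$sigma2), 5 / 3)
})

test_that("coefficients match an independent normal-equations solve", {
  d <- tiny_paired_design()
  dd <- d |> dplyr::filter(dataset_id == "CD8")
  dm <- build_design_matrix(dd)
  y <- random_values(d, "CD8", 20, seed = 21)
  fits <- fit_feature_models(y, dm)
  for (i in c(1, 7, 20)) {
    b <- solve(crossprod(dm), crossprod(dm, y[i, rownames(dm)]))
    expect_equal(unname(fits$coefficients[i, ]), unname(drop(b)),
                 tolerance = 1e-9)
    r <- y[i, rownames(dm)] - drop(dm %*% b)
    expect_equal(unname(fits$sigma2[i]),
                 sum(r^2) / (nrow(dm) - ncol(dm)), tolerance = 1e-9)
  }
})

test_that("variance moderation behaves at the boundaries and recovers d0", {
  d <- tiny_paired_design() |> dplyr::filter(dataset_id == "CD4")
  dm <- build_design_matrix(d)
  y <- random_values(tiny_paired_design(), "CD4", 100, seed = 3)
  fits <- fit_feature_models(y, dm)

  expect_identical(moderate_variances(fits, enabled = FALSE), fits)

  same <- fits
  same$sigma2 <- same$s2_post <- rep(2, 100)
  mod_same <- moderate_variances(same)
  expect_identical(mod_same$s2_post, same$s2_post)

  mod <- moderate_variances(fits)
  expect_true(all(mod$s2_post >= pmin(fits$sigma2, mod$s2_prior) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(fits$sigma2, mod$s2_prior) + 1e-12))

  # d0 recovery from simulated scaled-inverse-chi-square variances
  withr::with_seed(17, {
    d0 <- 4; df <- 10
    s2 <- (d0 / rchisq(5000, d0)) * rchisq(5000, df) / df
  })
  sim <- structure(list(sigma2 = s2, df_residual = 10, s2_post = s2,
                        df_prior = 0, s2_prior = NA_real_),
                   class = "feature_fits")
  est <- moderate_variances(sim)
  expect_gt(est$df_prior, 2.5)
  expect_lt(est$df_prior, 6.5)
  # same moment estimator as the established empirical-Bayes implementation
  skip_if_not_installed("limma")
  sq <- limma::squeezeVar(s2, 10)
  expect_equal(est$df_prior, sq$df.prior, tolerance = 1e-6)
  expect_equal(unname(est$s2_post), unname(sq$var.post), tolerance = 1e-6)
})

test_that("F statistics match the full-vs-reduced RSS brute force", {
  d <- tiny_paired_design()
  dd <- d |> dplyr::filter(dataset_id == "CD4")
  dm <- build_design_matrix(dd)
  y <- random_values(d, "CD4", 15, seed = 31)
  fits <- fit_feature_models(y, dm)
  f_pkg <- group_f_statistics(fits)
  f_oracle <- apply(y[, rownames(dm)], 1, oracle_f_lm, dd = dd)
  expect_equal(f_pkg$statistic, unname(f_oracle), tolerance = 1e-9)

  # zero group effect with zero noise: F is exactly 0
  beta <- c(1, 0, 0, 0.1, -0.3)
  y0 <- rbind(f1 = drop(dm %*% beta))
  f0 <- group_f_statistics(fit_feature_models(y0, dm))
  expect_equal(f0$statistic, 0)
})

test_that("with two groups F equals the squared t of the group coefficient", {
  d <- tibble::tibble(
    individual_id = sprintf("I%02d", 1:10),
    group = rep(c("HC", "RR"), each = 5),
    age = c(30, 35, 42, 50, 55, 33, 38, 45, 52, 60),
    sex = rep(c("F", "M"), 5),
    dataset_id = "CD4",
    sample_id = paste0(individual_id, "_CD4")
  )
  dm <- build_design_matrix(d)
  y <- withr::with_seed(61, matrix(rnorm(8 * nrow(dm)), 8,
              dimnames = list(paste0("f", 1:8), d$sample_id)))
  fits <- fit_feature_models(y, dm)
  f <- group_f_statistics(fits)$statistic
  t1 <- contrast_t_statistics(fits, "HC-RR")$statistic
  expect_equal(f, t1^2, tolerance = 1e-9)
  expect_error(contrast_t_statistics(fits, "RR-SP"),
               class = "npcomb_invalid_design")
})

test_that("contrast t statistics follow the later-stage sign convention", {
  d <- tiny_paired_design() |> dplyr::filter(dataset_id == "CD4")
  dm <- build_design_matrix(d)
  withr::with_seed(5, {
    up_rr <- drop(dm %*% c(5, 1, 1, 0, 0)) + rnorm(nrow(dm), 0, 0.01)
  })
  fits <- fit_feature_models(rbind(f1 = up_rr), dm)
  t_rr <- contrast_t_statistics(fits, "HC-RR")
  t_sp <- contrast_t_statistics(fits, "RR-SP")
  expect_gt(t_rr$statistic, 10)       # upregulated in RR
  expect_equal(t_sp$estimate, 0, tolerance = 0.05)  # SP == RR

  # brute-force contrast oracle
  y <- random_values(tiny_paired_design(), "CD4", 10, seed = 41)
  fits2 <- fit_feature_models(y, dm)
  cvec <- c(0, -1, 1, 0, 0)
  xtxi <- solve(crossprod(dm))
  for (i in c(2, 9)) {
    b <- solve(crossprod(dm), crossprod(dm, y[i, rownames(dm)]))
    r <- y[i, rownames(dm)] - drop(dm %*% b)
    s2 <- sum(r^2) / (nrow(dm) - ncol(dm))
    t_manual <- sum(cvec * b) / sqrt(s2 * drop(t(cvec) %*% xtxi %*% cvec))
    expect_equal(contrast_t_statistics(fits2, "RR-SP")$statistic[i],
                 t_manual, tolerance = 1e-9)
  }
})

test_that("statistics are invariant to constant shifts and row reordering", {
  d <- tiny_paired_design() |> dplyr::filter(dataset_id == "CD4")
  dm <- build_design_matrix(d)
  y <- random_values(tiny_paired_design(), "CD4", 6, seed = 51)
  f1 <- group_f_statistics(fit_feature_models(y, dm))$statistic
  f2 <- group_f_statistics(fit_feature_models(y + 100, dm))$statistic
  expect_equal(f1, f2, tolerance = 1e-8)

  perm <- withr::with_seed(8, sample(nrow(d)))
  d_perm <- d[perm, ]
  dm_perm <- build_design_matrix(d_perm)
  f3 <- group_f_statistics(fit_feature_models(y, dm_perm))$statistic
  expect_equal(f1, f3, tolerance = 1e-8)
})

test_that("direction-pattern groups map shared signs to G1-G4, else G5", {
  make <- function(id, cd4, cd8) {
    tibble::tibble(
      feature_id = id,
      dataset_id = rep(c("CD4", "CD8"), each = 2),
      contrast = rep(c("HC-RR", "RR-SP"), 2),
      statistic = c(cd4, cd8)
    )
  }
  cases <- dplyr::bind_rows(
    make("up_up", c(2, 3), c(1, 2)),        # G1
    make("up_down", c(2, -3), c(1, -2)),    # G2
    make("down_up", c(-2, 3), c(-1, 2)),    # G3
    make("down_down", c(-2, -3), c(-1, -2)),# G4
    make("discordant", c(2, 3), c(-1, 2))   # G5
  )
  g <- assign_expression_groups(cases)
  expect_equal(g$pattern_group[match(
    c("up_up", "up_down", "down_up", "down_down", "discordant"),
    g$feature_id)], c("G1", "G2", "G3", "G4", "G5"))

  zero <- make("zt", c(0, 3), c(2, 2))
  expect_message(gz <- assign_expression_groups(zero), "G5")
  expect_equal(gz$pattern_group, "G5")
})
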