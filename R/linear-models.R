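#' Build the per-dataset design matrix for differential testing
#'
#' Treatment-coded design with the healthy-control group as baseline:
#' intercept, disease-group indicators, mean-centered age and a male
#' indicator. Zero-variance covariates are dropped with a warning; a
#' rank-deficient matrix (e.g. sex confounded with group) is an error that
#' names the collinear columns.
#'
#' @param design Design tibble restricted to one dataset (rows define the
#'   sample order of the matrix).
#' @param reference_group Baseline group label, default `"HC"`.
#' @return A numeric matrix with rownames `sample_id` and attributes
#'   `group_cols` (names of the group indicator columns) and
#'   `reference_group`.
#' @examples
#' d <- generate_design(4, 4, 3, seed = 1)
#' dm <- build_design_matrix(dplyr::filter(d, dataset_id == "CD4"))
#' colnames(dm)
#' @export
build_design_matrix <- function(design, reference_group = "HC") {
  groups <- unique(design$group)
  if (length(groups) < 2) {
    abort("design matrix needs >= 2 disease groups",
          class = "npcomb_invalid_design")
  }
  if (!reference_group %in% groups) {
    abort(sprintf("reference group '%s' absent from design", reference_group),
          class = "npcomb_invalid_design")
  }
  grp <- factor(design$group,
                levels = c(reference_group,
                           sort(setdiff(groups, reference_group))))
  x <- model.matrix(~grp)
  colnames(x) <- sub("^grp", "group", colnames(x))
  group_cols <- colnames(x)[-1]

  if (length(unique(design$age)) > 1) {
    x <- cbind(x, age = design$age - mean(design$age))
  } else {
    warn("age has zero variance; age column dropped from the design matrix")
  }
  if (length(unique(design$sex)) > 1) {
    x <- cbind(x, sexM = as.numeric(design$sex == "M"))
  } else {
    warn("sex has zero variance; sex column dropped from the design matrix")
  }
  rownames(x) <- design$sample_id

  if (nrow(x) <= ncol(x)) {
    abort("fewer samples than design-matrix columns (no residual df)",
          class = "npcomb_rank_error")
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "npcomb_rank_error")
  }
  attr(x, "group_cols") <- group_cols
  attr(x, "reference_group") <- reference_group
  x
}

#' Fit per-feature ordinary least squares models
#'
#' Vectorized OLS of every feature on a shared design matrix; the fit stores
#' coefficients, residual variances and the unscaled coefficient covariance
#' so F and t statistics can be formed without refitting.
#'
#' @param data An [omics_dataset()] or a feature x sample numeric matrix.
#' @param dm Design matrix from [build_design_matrix()]; its rownames select
#'   and order the sample columns used.
#' @return An object of class `feature_fits` with elements `coefficients`
#'   (features x terms), `sigma2`, `df_residual`, `xtx_inv`, `s2_post`
#'   (moderated variance, equal to `sigma2` until [moderate_variances()] is
#'   applied), `df_prior`, and `design`.
#' @export
fit_feature_models <- function(data, dm) {
  y <- if (inherits(data, "omics_dataset")) data$values else data
  stopifnot(is.matrix(y))
  if (!all(rownames(dm) %in% colnames(y))) {
    abort("design-matrix samples missing from the data matrix",
          class = "npcomb_invalid_data")
  }
  y <- y[, rownames(dm), drop = FALSE]
  n <- nrow(dm)
  p <- ncol(dm)
  df <- n - p
  if (df <= 0) {
    abort("no residual degrees of freedom", class = "npcomb_rank_error")
  }
  qx <- qr(dm)
  coefs <- t(qr.coef(qx, t(y)))
  res <- t(qr.resid(qx, t(y)))
  s2 <- rowSums(res^2) / df
  structure(list(coefficients = coefs,
                 yss = rowSums(y^2),
                 sigma2 = s2,
                 df_residual = df,
                 xtx_inv = solve(crossprod(dm)),
                 s2_post = s2,
                 df_prior = 0,
                 s2_prior = NA_real_,
                 feature_ids = rownames(y),
                 design = dm),
            class = "feature_fits")
}

#' @export
print.feature_fits <- function(x, ...) {
  cat(sprintf("<feature_fits> %d features, %d terms, %d residual df%s\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df_residual,
              if (x$df_prior > 0) sprintf(" (moderated, d0 = %.2f)",
                                          x$df_prior) else ""))
  invisible(x)
}

## Newton inversion of the trigamma function (y = trigamma(x) -> x).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances toward a common prior under a
#' scaled-inverse-chi-square model, with prior df `d0` and prior variance
#' `s0^2` estimated by method of moments on `log(s^2)` (trigamma inversion
#' for `d0`). The moderated variance is the usual posterior mean
#' `(d0 s0^2 + d s^2) / (d0 + d)`. With no excess dispersion in `log(s^2)`
#' the prior df is infinite and all variances collapse to `s0^2`; exactly
#' identical input variances are returned unchanged.
#'
#' @param fits A `feature_fits` object.
#' @param enabled If `FALSE`, returns `fits` unchanged.
#' @return `fits` with updated `s2_post`, `df_prior`, `s2_prior`.
#' @export
moderate_variances <- function(fits, enabled = TRUE) {
  stopifnot(inherits(fits, "feature_fits"))
  if (!enabled) return(fits)
  s2 <- fits$sigma2
  if (length(s2) < 50) {
    abort("variance moderation needs >= 50 features",
          class = "npcomb_invalid_data")
  }
  d <- fits$df_residual
  z <- log(s2)
  if (!all(is.finite(z))) {
    warn("non-finite log-variances; moderation skipped (identity)")
    return(fits)
  }
  if (var(z) < 1e-12) return(fits)  # degenerate: nothing to shrink
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar)) {
    warn("moment estimates non-finite; moderation skipped (identity)")
    return(fits)
  }
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    fits$s2_post <- (d0 * s0 + d * s2) / (d0 + d)
    fits$df_prior <- d0
  } else {
    s0 <- exp(mean(e))
    fits$s2_post <- rep(s0, length(s2))
    fits$df_prior <- Inf
  }
  fits$s2_prior <- s0
  fits
}

## Bare F vector for the joint group effect (internal fast path).
.group_f <- function(fits) {
  gc <- attr(fits$design, "group_cols")
  b <- fits$coefficients[, gc, drop = FALSE]
  v_inv <- solve(fits$xtx_inv[gc, gc])
  q <- rowSums((b %*% v_inv) * b)
  f <- q / (length(gc) * fits$s2_post)
  # a group sum of squares that is zero up to floating-point residue means
  # no group signal: F = 0 even when the residual variance is also zero
  yss <- fits$yss %||% rep(1, length(q))
  f[q <= 1e-20 * pmax(yss, .Machine$double.xmin)] <- 0
  f
}

#' Partial F statistics for the disease-group factor
#'
#' Tests the joint nullity of the group coefficients given the covariates,
#' using the (possibly moderated) residual variance. This is the partial-test
#' statistic fed to the permutation NPC.
#'
#' @param fits A `feature_fits` object.
#' @return A tibble with `feature_id`, `statistic` (F), `df1`, `df2` and the
#'   parametric `p.value` (permutation p-values are the job of [npc_global()]).
#' @export
group_f_statistics <- function(fits) {
  f <- .group_f(fits)
  k <- length(attr(fits$design, "group_cols"))
  df2 <- fits$df_residual + fits$df_prior
  tibble::tibble(feature_id = fits$feature_ids,
                 statistic = unname(f),
                 df1 = k, df2 = df2,
                 p.value = pf(f, k, df2, lower.tail = FALSE))
}

#' Per-contrast t statistics and effect sizes
#'
#' Contrast `"HC-RR"` is the RR coefficient (positive = higher in RR than in
#' HC); `"RR-SP"` is the SP minus RR coefficient (positive = higher in SP).
#' Positive t therefore always means upregulation in the later disease stage.
#'
#' @param fits A `feature_fits` object.
#' @param contrast `"HC-RR"` or `"RR-SP"`.
#' @return A tibble with `feature_id`, `contrast`, `estimate` (log-scale
#'   effect), `statistic` (t) and two-sided `p.value`.
#' @export
contrast_t_statistics <- function(fits, contrast = c("HC-RR", "RR-SP")) {
  contrast <- match.arg(contrast)
  cols <- colnames(fits$coefficients)
  cvec <- setNames(numeric(length(cols)), cols)
  if (contrast == "HC-RR") {
    if (!"groupRR" %in% cols) abort("contrast HC-RR not estimable (no RR)",
                                    class = "npcomb_invalid_design")
    cvec["groupRR"] <- 1
  } else {
    if (!all(c("groupRR", "groupSP") %in% cols)) {
      abort("contrast RR-SP not estimable", class = "npcomb_invalid_design")
    }
    cvec["groupSP"] <- 1
    cvec["groupRR"] <- -1
  }
  est <- drop(fits$coefficients %*% cvec)
  se <- sqrt(fits$s2_post * drop(t(cvec) %*% fits$xtx_inv %*% cvec))
  tstat <- est / se
  df <- fits$df_residual + fits$df_prior
  tibble::tibble(feature_id = fits$feature_ids,
                 contrast = contrast,
                 estimate = unname(est),
                 statistic = unname(tstat),
                 p.value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' Assign direction-pattern groups across datasets
#'
#' Classifies features by the signs of their per-contrast t statistics across
#' datasets: if the sign agrees across all datasets for *both* contrasts, the
#' shared sign pattern maps to `G1` (+,+), `G2` (+,-), `G3` (-,+) or `G4`
#' (-,-) over the (HC-RR, RR-SP) contrasts; any discordance (or an exactly
#' zero t, which carries no direction) yields `G5`.
#'
#' @param t_stats A tibble with columns `feature_id`, `dataset_id`,
#'   `contrast` (`"HC-RR"`/`"RR-SP"`) and `statistic`, e.g. row-bound outputs
#'   of [contrast_t_statistics()] over datasets.
#' @return A tibble `feature_id`, `pattern_group`.
#' @export
assign_expression_groups <- function(t_stats) {
  if (nrow(t_stats) == 0) {
    return(tibble::tibble(feature_id = character(),
                          pattern_group = character()))
  }
  need <- c("HC-RR", "RR-SP")
  if (!all(need %in% t_stats$contrast)) {
    abort("t statistics for both contrasts (HC-RR, RR-SP) are required",
          class = "npcomb_invalid_data")
  }
  n_zero <- sum(t_stats$statistic == 0)
  if (n_zero > 0) {
    inform(sprintf("%d zero t statistic(s): affected features assigned G5",
                   n_zero))
  }
  wide <- t_stats |>
    dplyr::mutate(sgn = sign(.data$statistic)) |>
    dplyr::summarise(
      concordant = dplyr::n_distinct(.data$sgn) == 1 && all(.data$sgn != 0),
      shared_sign = .data$sgn[1],
      .by = c("feature_id", "contrast")
    ) |>
    tidyr::pivot_wider(names_from = "contrast",
                       values_from = c("concordant", "shared_sign"))
  key <- function(s1, s2) {
    dplyr::case_when(s1 > 0 & s2 > 0 ~ "G1",
                     s1 > 0 & s2 < 0 ~ "G2",
                     s1 < 0 & s2 > 0 ~ "G3",
                     s1 < 0 & s2 < 0 ~ "G4",
                     TRUE ~ "G5")
  }
  wide |>
    dplyr::mutate(
      pattern_group = dplyr::if_else(
        .data$`concordant_HC-RR` & .data$`concordant_RR-SP`,
        key(.data$`shared_sign_HC-RR`, .data$`shared_sign_RR-SP`),
        "G5")
    ) |>
    dplyr::select("feature_id", "pattern_group") |>
    dplyr::arrange(.data$feature_id)
}
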