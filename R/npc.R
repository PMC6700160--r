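#' Pairing-constrained permutations of disease labels
#'
#' Permutes the observed disease labels at the *individual* level: the label
#' multiset over distinct individuals is shuffled, and each individual's
#' permuted label is broadcast to every sample that individual contributes.
#' Individuals present in several datasets therefore always receive one and
#' the same permuted label (preserving the cross-dataset correlation
#' structure under the null), while covariates stay attached to samples.
#'
#' @param design Design tibble ([generate_design()]).
#' @param dataset_ids Datasets to permute over; defaults to all present.
#' @param B Number of permutations (>= 1). If `B` exceeds the number of
#'   distinct label assignments, permutations are sampled with replacement
#'   and a message is emitted.
#' @param seed Integer seed.
#' @return An object of class `permutation_set`: `individual_ids`,
#'   `observed` (labels over individuals), `labels` (individuals x B
#'   character matrix), `B`, `design`, `dataset_ids`, `seed`.
#' @examples
#' d <- generate_design(3, 3, 2, seed = 1)
#' ps <- constrained_permutations(d, B = 10, seed = 1)
#' dim(ps$labels)
#' @export
constrained_permutations <- function(design, dataset_ids = NULL, B = 1000,
                                     seed = 1L) {
  validate_design(design)
  stopifnot(B >= 1)
  dataset_ids <- dataset_ids %||% sort(unique(design$dataset_id))
  design <- dplyr::filter(design, .data$dataset_id %in% dataset_ids)
  ind <- design |>
    dplyr::distinct(.data$individual_id, .data$group) |>
    dplyr::arrange(.data$individual_id)
  obs <- setNames(ind$group, ind$individual_id)
  n_assign <- exp(lgamma(length(obs) + 1) -
                    sum(lgamma(table(obs) + 1)))
  if (B > n_assign) {
    inform(sprintf(paste0("B = %d exceeds the %.0f distinct label ",
                          "assignments; permutations are sampled with ",
                          "replacement"), B, n_assign))
  }
  labels <- withr::with_seed(stage_seed(seed, "permutations"), {
    vapply(seq_len(B), function(b) sample(unname(obs)),
           character(length(obs)))
  })
  rownames(labels) <- names(obs)
  structure(list(individual_ids = names(obs), observed = obs,
                 labels = labels, B = B, design = design,
                 dataset_ids = dataset_ids, seed = seed,
                 enumerated = FALSE),
            class = "permutation_set")
}

## All distinct multiset permutations of x (lexicographic).
multiset_permutations <- function(x) {
  n <- length(x)
  ux <- sort(unique(x))
  counts <- table(factor(x, levels = ux))
  out <- list()
  recurse <- function(prefix, counts) {
    if (sum(counts) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (u in ux[counts[ux] > 0]) {
      counts2 <- counts
      counts2[u] <- counts2[u] - 1
      recurse(c(prefix, u), counts2)
    }
  }
  recurse(character(0), counts)
  out
}

#' Enumerate every distinct label assignment as a permutation set
#'
#' For small designs this yields the exact permutation null: all distinct
#' rearrangements of the observed label multiset over individuals (the
#' observed assignment is one of them).
#'
#' @inheritParams constrained_permutations
#' @param max_assignments Guard against combinatorial explosion.
#' @return A `permutation_set` with `B` equal to the number of distinct
#'   assignments and `enumerated = TRUE`.
#' @export
enumerate_label_permutations <- function(design, dataset_ids = NULL,
                                         max_assignments = 1e5) {
  validate_design(design)
  dataset_ids <- dataset_ids %||% sort(unique(design$dataset_id))
  design <- dplyr::filter(design, .data$dataset_id %in% dataset_ids)
  ind <- design |>
    dplyr::distinct(.data$individual_id, .data$group) |>
    dplyr::arrange(.data$individual_id)
  obs <- setNames(ind$group, ind$individual_id)
  n_assign <- exp(lgamma(length(obs) + 1) - sum(lgamma(table(obs) + 1)))
  if (n_assign > max_assignments) {
    abort(sprintf("%.0f distinct assignments exceed max_assignments = %g",
                  n_assign, max_assignments),
          class = "npcomb_invalid_data")
  }
  perms <- multiset_permutations(unname(obs))
  labels <- do.call(cbind, perms)
  rownames(labels) <- names(obs)
  structure(list(individual_ids = names(obs), observed = obs,
                 labels = labels, B = ncol(labels), design = design,
                 dataset_ids = dataset_ids, seed = NA_integer_,
                 enumerated = TRUE),
            class = "permutation_set")
}

#' @export
print.permutation_set <- function(x, ...) {
  cat(sprintf("<permutation_set> %d individuals x %d permutations%s\n",
              length(x$individual_ids), x$B,
              if (isTRUE(x$enumerated)) " (exhaustive)" else ""))
  invisible(x)
}

## Sample-level label matrix (n_samples x B) for one dataset.
sample_labels_for <- function(pset, dataset_id) {
  dd <- dplyr::filter(pset$design, .data$dataset_id == !!dataset_id)
  idx <- match(dd$individual_id, pset$individual_ids)
  m <- pset$labels[idx, , drop = FALSE]
  rownames(m) <- dd$sample_id
  m
}

## #{pool >= x} with a small relative tolerance: statistics that are
## mathematically tied (e.g. permutations spanning the same group subspace)
## count as ties no matter which floating-point path produced them. The
## tolerance (1e-6 relative) sits far below any genuine gap between distinct
## permutation statistics of continuous data, yet above the cancellation
## noise of near-degenerate statistics (rss_full close to zero).
.ge_count <- function(pool, x, tol = 1e-6) {
  s <- sort(pool)
  length(pool) - findInterval(x - tol * pmax(1, abs(x)), s)
}

#' Permutation partial p-values with pseudocount
#'
#' `p = (1 + #[perm >= obs]) / (1 + B)`; ties count as exceedances
#' (conservative, assessed with a 1e-6 relative numerical tolerance), so p
#' can never be 0 and the permutation test stays valid. Features with a
#' non-finite observed statistic get `p = 1` with a warning.
#'
#' @param obs Per-feature observed statistics (larger = more significant).
#' @param perm_stats Feature x B matrix of permuted statistics.
#' @return Numeric vector of partial p-values in `(0, 1]`.
#' @export
partial_pvalues <- function(obs, perm_stats) {
  stopifnot(length(obs) == nrow(perm_stats))
  bad <- is.na(obs)  # NA/NaN: undefined statistic (+-Inf still orders)
  if (any(bad)) {
    warn(sprintf("%d feature(s) with undefined statistics: p set to 1",
                 sum(bad)))
    obs[bad] <- Inf
  }
  b <- ncol(perm_stats)
  counts <- vapply(seq_along(obs), function(i) {
    .ge_count(perm_stats[i, ], obs[i])
  }, numeric(1))
  p <- (1 + counts) / (1 + b)
  p[bad] <- 1
  p
}

#' Liptak (Stouffer) combination of partial p-values
#'
#' `T = sum_d w_d * qnorm(1 - p_d)`; larger T means more significant. Before
#' the transform, p-values are clipped to at most `1 - 1/(2(B+1))` so the
#' normal quantile stays finite.
#'
#' @param partial_p Feature x dataset matrix (or vector) of p-values in
#'   `(0, 1]`.
#' @param weights Non-negative weights, default all 1.
#' @param B The permutation count governing the upper clip; defaults to a
#'   clip at `1 - 1e-12`.
#' @return Per-feature combined statistic T.
#' @examples
#' liptak_combine(cbind(0.05, 0.05))  # ~ 3.2897
#' @export
liptak_combine <- function(partial_p, weights = NULL, B = NULL) {
  p <- as.matrix(partial_p)
  weights <- weights %||% rep(1, ncol(p))
  if (length(weights) != ncol(p)) {
    abort("one weight per dataset is required", class = "npcomb_invalid_data")
  }
  if (any(weights < 0)) {
    abort("Liptak weights must be non-negative",
          class = "npcomb_invalid_data")
  }
  if (any(p <= 0 | p > 1)) {
    abort("partial p-values must lie in (0, 1]",
          class = "npcomb_invalid_data")
  }
  clip <- if (is.null(B)) 1 - 1e-12 else 1 - 1 / (2 * (B + 1))
  drop(qnorm(1 - pmin(p, clip)) %*% weights)
}

## F statistics for one dataset under a vector of label assignments.
## Frisch-Waugh: covariates (and intercept) are projected out of both the
## response and the group dummies once; each permutation then only costs a
## tiny QR of the residualized dummies. Rank-safe for degenerate label
## draws (e.g. a dataset ending up single-group under the constrained
## shuffle): the explained sum of squares uses the realized rank while k and
## df stay nominal, matching a projection-based full-vs-reduced computation.
.f_machine <- function(y, dm) {
  gc <- attr(dm, "group_cols")
  x_cov <- dm[, setdiff(colnames(dm), gc), drop = FALSE]
  qc <- qr(x_cov)
  yt <- t(y[, rownames(dm), drop = FALSE])       # n x G
  yss <- pmax(colSums(yt^2), .Machine$double.xmin)
  w <- qr.resid(qc, yt)                          # response, covariates out
  rss_red <- colSums(w^2)
  lvl <- c(attr(dm, "reference_group"),
           sub("^group", "", gc))
  k <- length(gc)
  df <- nrow(dm) - ncol(dm)
  list(
    f_for_labels = function(labels) {
      z <- vapply(lvl[-1], function(g) as.numeric(labels == g),
                  numeric(length(labels)))
      zr <- qr.resid(qc, z)
      qz <- qr(zr)
      r <- qz$rank
      qss <- if (r > 0) {
        qw <- qr.qty(qz, w)[seq_len(r), , drop = FALSE]
        if (r > 1) colSums(qw^2) else qw[1, ]^2
      } else rep(0, ncol(w))
      rss_full <- pmax(rss_red - qss, 0)
      f <- (qss / k) / (rss_full / df)
      # zero group signal (up to floating residue) is F = 0 even with zero
      # residual variance
      f[qss <= 1e-20 * yss] <- 0
      list(f = f, s2 = rss_full / df, qss = qss)
    },
    rss_red = rss_red, k = k, df = df
  )
}

#' Global NPC p-values across datasets
#'
#' The core procedure: (i) observed per-dataset partial F statistics for the
#' disease-group factor given covariates; (ii) `B` pairing-constrained label
#' permutations, recomputing every dataset's F with covariates fixed to
#' samples; (iii) permutation partial p-values for the observed statistics
#' *and* for every permutation (each scored against the full B-permutation
#' pool, itself included); (iv) Liptak combination of observed and permuted
#' partial p-vectors; (v) global p as the permutation exceedance probability
#' of the combined statistic; (vi) Benjamini-Hochberg q-values over features.
#'
#' @param datasets Named list of [omics_dataset()] objects (or feature x
#'   sample matrices) — one per dataset. Features are intersected across
#'   datasets; dropped ids are recorded.
#' @param design Design tibble covering all datasets' samples.
#' @param B Number of permutations (ignored when `permutations` is given).
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional [constrained_permutations()] /
#'   [enumerate_label_permutations()] result to reuse.
#' @param moderate Apply [moderate_variances()] to observed and permuted
#'   fits (default `FALSE`: permutation nulls do not need moderation for
#'   validity).
#' @param weights Liptak weights, default equal.
#' @return An object of class `npc_result`; its `$table` tibble holds per
#'   feature the per-dataset F (`stat_<d>`) and partial p
#'   (`partial_p_<d>`), the combined statistic, `global_p` and `q`.
#' @examples
#' st <- simulate_study(n_genes = 40, n_probes = 0, seed = 1)
#' res <- npc_global(st$expression, st$design, B = 99, seed = 1)
#' res
#' @export
npc_global <- function(datasets, design, B = 1000, seed = 1L,
                       permutations = NULL, moderate = FALSE,
                       weights = NULL) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  mats <- purrr::map(datasets, function(d) {
    if (inherits(d, "omics_dataset")) d$values else d
  })
  features <- Reduce(intersect, purrr::map(mats, rownames))
  if (length(features) == 0) {
    abort("datasets share no features", class = "npcomb_invalid_data")
  }
  dropped <- purrr::map(mats, ~setdiff(rownames(.x), features))
  validate_design(design)

  pset <- permutations %||%
    constrained_permutations(design, names(datasets), B, seed)
  assert_pairing_constraint(pset)
  B <- pset$B

  per_ds <- purrr::imap(mats, function(y, d) {
    y <- y[features, , drop = FALSE]
    dd <- dplyr::filter(design, .data$dataset_id == d,
                        .data$sample_id %in% colnames(y))
    dm <- build_design_matrix(dd)
    machine <- .f_machine(y, dm)
    moderate_f <- function(raw) {
      if (!moderate) return(raw$f)
      fake <- structure(list(sigma2 = raw$s2, df_residual = machine$df,
                             s2_post = raw$s2, df_prior = 0,
                             s2_prior = NA_real_),
                        class = "feature_fits")
      (raw$qss / machine$k) / moderate_variances(fake)$s2_post
    }
    labels_mat <- sample_labels_for(pset, d)[rownames(dm), , drop = FALSE]
    f_obs <- moderate_f(machine$f_for_labels(
      setNames(dd$group, dd$sample_id)[rownames(dm)]))
    f_perm <- matrix(0, length(features), B)
    for (b in seq_len(B)) {
      f_perm[, b] <- moderate_f(machine$f_for_labels(labels_mat[, b]))
    }
    p_obs <- partial_pvalues(f_obs, f_perm)
    # each permutation scored against the whole pool, itself included
    p_perm <- t(vapply(seq_len(length(features)), function(i) {
      (1 + .ge_count(f_perm[i, ], f_perm[i, ])) / (1 + B)
    }, numeric(B)))
    if (B == 1) p_perm <- matrix(p_perm, ncol = 1)
    list(f_obs = f_obs, p_obs = p_obs, p_perm = p_perm,
         n_samples = nrow(dm))
  })

  p_obs_mat <- do.call(cbind, purrr::map(per_ds, "p_obs"))
  t_obs <- liptak_combine(p_obs_mat, weights, B = B)
  t_perm <- matrix(0, length(features), B)
  w <- weights %||% rep(1, length(per_ds))
  for (i in seq_along(per_ds)) {
    clip <- 1 - 1 / (2 * (B + 1))
    t_perm <- t_perm + w[i] * qnorm(1 - pmin(per_ds[[i]]$p_perm, clip))
  }
  global_counts <- vapply(seq_along(t_obs), function(i) {
    .ge_count(t_perm[i, ], t_obs[i])
  }, numeric(1))
  global_p <- (1 + global_counts) / (1 + B)
  q <- bh_fdr(global_p)

  tab <- tibble::tibble(feature_id = features)
  for (d in names(per_ds)) {
    tab[[paste0("stat_", d)]] <- unname(per_ds[[d]]$f_obs)
    tab[[paste0("partial_p_", d)]] <- unname(per_ds[[d]]$p_obs)
  }
  tab$combined_stat <- unname(t_obs)
  tab$global_p <- unname(global_p)
  tab$q <- unname(q)

  structure(list(table = tab, B = B, seed = seed,
                 dataset_ids = names(datasets),
                 moderate = moderate, weights = w,
                 dropped_features = dropped,
                 n_samples = purrr::map_int(per_ds, "n_samples")),
            class = "npc_result")
}

#' @export
print.npc_result <- function(x, ...) {
  cat(sprintf(paste0("<npc_result> %d features, datasets: %s, B = %d\n",
                     "  global p range: [%.3g, %.3g]; ",
                     "features with q <= 0.1: %d\n"),
              nrow(x$table), paste(x$dataset_ids, collapse = ", "), x$B,
              min(x$table$global_p), max(x$table$global_p),
              sum(x$table$q <= 0.1)))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (a thin wrapper over [stats::p.adjust()] with
#' `method = "BH"`), kept as a named surface so downstream stages share one
#' FDR convention.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Select significant features from an NPC result
#'
#' @param result An `npc_result` (or its `$table`).
#' @param p_max Global p-value threshold (inclusive).
#' @param q_max BH q-value threshold (inclusive).
#' @return Character vector of feature ids sorted by (global p, feature id).
#' @export
select_features <- function(result, p_max = 0.001, q_max = 0.1) {
  tab <- if (inherits(result, "npc_result")) result$table else result
  tab |>
    dplyr::filter(.data$global_p <= p_max, .data$q <= q_max) |>
    dplyr::arrange(.data$global_p, .data$feature_id) |>
    dplyr::pull("feature_id")
}

#' Audit the pairing constraint of a permutation set
#'
#' Asserts that (a) every individual has exactly one label per permutation —
#' guaranteed structurally, since labels live on individuals and are
#' broadcast to samples — and (b) each permutation's label multiset over
#' individuals equals the observed multiset (shuffle, not resample).
#'
#' @param pset A `permutation_set`.
#' @return `pset`, invisibly, or an error.
#' @export
assert_pairing_constraint <- function(pset) {
  stopifnot(inherits(pset, "permutation_set"))
  lv <- sort(unique(as.vector(pset$observed)))
  obs_counts <- as.vector(table(factor(pset$observed, levels = lv)))
  ok <- apply(pset$labels, 2, function(l) {
    all(l %in% lv) &&
      identical(as.vector(table(factor(l, levels = lv))), obs_counts)
  })
  if (!all(ok)) {
    abort("permutation label multiset differs from the observed multiset",
          class = "npcomb_invalid_permutations")
  }
  invisible(pset)
}
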