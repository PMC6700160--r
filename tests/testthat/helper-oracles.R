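# Hand-built 6-individual fully paired design: balanced sexes within group
# so the design matrix is always full rank, ages spread out.
tiny_paired_design <- function(datasets = c("CD4", "CD8")) {
  ind <- tibble::tibble(
    individual_id = c("HC01", "HC02", "RR01", "RR02", "SP01", "SP02"),
    group = rep(c("HC", "RR", "SP"), each = 2),
    age = c(31, 44, 37, 52, 48, 59),
    sex = c("F", "M", "F", "M", "M", "F")
  )
  tidyr::crossing(ind, dataset_id = datasets) |>
    dplyr::mutate(sample_id = paste(individual_id, dataset_id, sep = "_")) |>
    dplyr::select(sample_id, individual_id, dataset_id, group, age, sex)
}

# Random feature x sample matrix aligned to one dataset of a design.
random_values <- function(design, dataset, n_features, seed, sd = 1) {
  dd <- design[design$dataset_id == dataset, ]
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_features * nrow(dd), sd = sd), n_features,
                dimnames = list(sprintf("f%03d", seq_len(n_features)),
                                dd$sample_id))
    m
  })
}

# Brute-force BH step-up straight from the definition:
# q_i = min over {j : p_j >= p_i} of min(1, m * p_j / rank(j)).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(1, min(m * p[j] / r[j]))
  }, numeric(1))
}

# Classical rank-distance Spearman formula (untied data only).
oracle_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Full-vs-reduced F through lm(), one feature at a time.
oracle_f_lm <- function(y, dd, labels = NULL) {
  if (is.null(labels)) labels <- stats::setNames(dd$group, dd$individual_id)
  dat <- data.frame(
    y = y,
    g = factor(labels[dd$individual_id], levels = c("HC", "RR", "SP")),
    age = dd$age,
    sexM = as.numeric(dd$sex == "M")
  )
  full <- stats::lm(y ~ g + age + sexM, data = dat)
  red <- stats::lm(y ~ age + sexM, data = dat)
  rss_f <- sum(stats::resid(full)^2)
  rss_r <- sum(stats::resid(red)^2)
  k <- 2
  df <- nrow(dat) - 5
  f <- ((rss_r - rss_f) / k) / (rss_f / df)
  # convention shared with the package: no group signal means F = 0
  if (abs(rss_r - rss_f) < 1e-12 && rss_f < 1e-12) f <- 0
  f
}

# Independent enumeration of all distinct label assignments: full recursive
# permutations of the label vector, then deduplication.
oracle_enumerate_assignments <- function(labels) {
  gen <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  perms <- gen(unname(labels))
  keys <- vapply(perms, paste, collapse = "|", FUN.VALUE = "")
  perms[!duplicated(keys)]
}

# Brute-force exhaustive NPC: enumerate assignments, compute every F through
# lm(), count exceedances, Liptak-combine, count again. Fully independent of
# the package's vectorized Frisch-Waugh machinery.
oracle_npc_exhaustive <- function(values_list, design) {
  ind <- design |>
    dplyr::distinct(individual_id, group) |>
    dplyr::arrange(individual_id)
  obs_labels <- stats::setNames(ind$group, ind$individual_id)
  assignments <- oracle_enumerate_assignments(obs_labels)
  assignments <- lapply(assignments, stats::setNames, names(obs_labels))
  M <- length(assignments)
  clip <- 1 - 1 / (2 * (M + 1))

  per_ds <- lapply(names(values_list), function(d) {
    y <- values_list[[d]]
    dd <- design[design$dataset_id == d, ]
    y <- y[, dd$sample_id, drop = FALSE]
    # same tie convention as the package: exceedance with 1e-6 relative
    # tolerance, so mathematically tied assignments count as ties
    ge_count <- function(pool, x) {
      vapply(x, function(xi) {
        sum(pool >= xi - 1e-6 * max(1, abs(xi)))
      }, numeric(1))
    }
    f_obs <- apply(y, 1, oracle_f_lm, dd = dd, labels = obs_labels)
    f_perm <- sapply(assignments, function(a) {
      apply(y, 1, oracle_f_lm, dd = dd, labels = a)
    })
    p_obs <- vapply(seq_along(f_obs), function(i) {
      (1 + ge_count(f_perm[i, ], f_obs[i])) / (1 + M)
    }, numeric(1))
    p_perm <- t(vapply(seq_along(f_obs), function(i) {
      (1 + ge_count(f_perm[i, ], f_perm[i, ])) / (1 + M)
    }, numeric(M)))
    list(p_obs = p_obs, p_perm = p_perm)
  })
  t_obs <- Reduce(`+`, lapply(per_ds, function(x) {
    qnorm(1 - pmin(x$p_obs, clip))
  }))
  t_perm <- Reduce(`+`, lapply(per_ds, function(x) {
    qnorm(1 - pmin(x$p_perm, clip))
  }))
  global_p <- vapply(seq_along(t_obs), function(i) {
    cnt <- sum(t_perm[i, ] >= t_obs[i] - 1e-6 * max(1, abs(t_obs[i])))
    (1 + cnt) / (1 + M)
  }, numeric(1))
  list(global_p = global_p,
       partial_p = do.call(cbind, lapply(per_ds, `[[`, "p_obs")),
       M = M)
}

# Recall of a truth set within a selection.
recall_of <- function(selected, truth_ids) {
  if (length(truth_ids) == 0) return(NA_real_)
  mean(truth_ids %in% selected)
}

# Single-dataset selection at matched thresholds from an NPC table.
single_dataset_selection <- function(tab, dataset, p_max = 0.001,
                                     q_max = 0.1) {
  pp <- tab[[paste0("partial_p_", dataset)]]
  tab$feature_id[pp <= p_max & bh_fdr(pp) <= q_max]
}
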