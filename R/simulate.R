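#' Simulate the design of a partially paired multi-dataset cohort
#'
#' Generates a sample/individual table for a study in which each individual
#' belongs to one disease group (`HC`, `RR`, `SP`) and contributes a sample to
#' either one dataset (e.g. one sorted T-cell population) or to all of them.
#' A configurable fraction of each group is *paired*, i.e. measured in every
#' dataset; the remaining individuals are split across datasets as evenly as
#' possible, at random.
#'
#' @param n_hc,n_rr,n_sp Number of individuals per disease group (each >= 2).
#' @param paired_fraction Fraction of each group measured in all datasets
#'   (rounded to the nearest integer count per group).
#' @param dataset_ids Character vector of dataset labels, default
#'   `c("CD4", "CD8")`.
#' @param age_ranges Named list of `c(min, max)` age ranges (years) per group;
#'   ages are drawn uniformly.
#' @param sex_ratio Probability that an individual is female.
#' @param seed Integer master seed.
#'
#' @return A tibble with columns `sample_id`, `individual_id`, `dataset_id`,
#'   `group`, `age`, `sex`, one row per sample.
#' @examples
#' d <- generate_design(4, 4, 3, paired_fraction = 0.5, seed = 1)
#' table(d$dataset_id, d$group)
#' @export
generate_design <- function(n_hc, n_rr, n_sp, paired_fraction = 0.7,
                            dataset_ids = c("CD4", "CD8"),
                            age_ranges = list(HC = c(25, 55), RR = c(25, 55),
                                              SP = c(35, 65)),
                            sex_ratio = 0.65, seed = 1L) {
  sizes <- c(HC = n_hc, RR = n_rr, SP = n_sp)
  if (any(sizes < 2)) {
    abort("invalid design: every group needs at least 2 individuals",
          class = "npcomb_invalid_design")
  }
  stopifnot(paired_fraction >= 0, paired_fraction <= 1,
            length(dataset_ids) >= 1, !anyDuplicated(dataset_ids))

  withr::with_seed(stage_seed(seed, "design"), {
    per_group <- purrr::imap(as.list(sizes), function(n_g, g) {
      ind <- sprintf("%s%02d", g, seq_len(n_g))
      n_paired <- round(paired_fraction * n_g)
      paired <- logical(n_g)
      if (n_paired > 0) paired[sample.int(n_g, n_paired)] <- TRUE
      # unpaired individuals get exactly one dataset, split evenly at random
      single_ds <- sample(rep_len(sample(dataset_ids), sum(!paired)))
      ds_list <- vector("list", n_g)
      ds_list[paired] <- list(dataset_ids)
      ds_list[!paired] <- as.list(single_ds)
      rng <- age_ranges[[g]] %||% c(25, 65)
      tibble::tibble(
        individual_id = ind,
        group = g,
        age = round(runif(n_g, rng[1], rng[2]), 1),
        sex = ifelse(rbinom(n_g, 1, sex_ratio) == 1, "F", "M"),
        datasets = ds_list
      )
    })
    design <- dplyr::bind_rows(per_group) |>
      tidyr::unnest_longer(col = "datasets", values_to = "dataset_id") |>
      dplyr::mutate(sample_id = paste(.data$individual_id, .data$dataset_id,
                                      sep = "_")) |>
      dplyr::select("sample_id", "individual_id", "dataset_id", "group",
                    "age", "sex") |>
      dplyr::arrange(.data$dataset_id, .data$group, .data$individual_id)
    validate_design(design)
  })
}

#' Validate a study design table
#'
#' Checks the invariants the permutation machinery relies on: unique sample
#' ids, at most one sample per individual per dataset, identical group/age/sex
#' for an individual across datasets, and at least two groups with samples in
#' every dataset.
#'
#' @param design A design tibble as produced by [generate_design()].
#' @return The design, invisibly unchanged, or an error.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "individual_id", "dataset_id", "group", "age", "sex")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(paste("design is missing columns:",
                paste(missing_cols, collapse = ", ")),
          class = "npcomb_invalid_design")
  }
  if (anyDuplicated(design$sample_id)) {
    abort("sample_id values must be unique", class = "npcomb_invalid_design")
  }
  if (anyDuplicated(design[c("individual_id", "dataset_id")])) {
    abort("an individual may contribute at most one sample per dataset",
          class = "npcomb_invalid_design")
  }
  if (!all(design$group %in% c("HC", "RR", "SP"))) {
    abort("group must be one of HC, RR, SP", class = "npcomb_invalid_design")
  }
  if (!all(design$sex %in% c("F", "M"))) {
    abort("sex must be F or M", class = "npcomb_invalid_design")
  }
  consistent <- design |>
    dplyr::distinct(.data$individual_id, .data$group, .data$age, .data$sex)
  if (anyDuplicated(consistent$individual_id)) {
    abort("individuals must carry identical group/age/sex in all datasets",
          class = "npcomb_invalid_design")
  }
  per_ds <- design |>
    dplyr::summarise(n_groups = dplyr::n_distinct(.data$group),
                     n = dplyr::n(), .by = "dataset_id")
  if (any(per_ds$n < 2) || any(per_ds$n_groups < 2)) {
    abort("every dataset needs >= 2 samples spanning >= 2 groups",
          class = "npcomb_invalid_design")
  }
  invisible(design)
}

#' Simulate gene and probe annotations with optional cis pairs
#'
#' Places genes (with strand) and single-position methylation probes on one or
#' more chromosomes. For each requested cis pair a probe is planted within
#' `promoter_offset` bases of a gene's strand-aware transcription start site,
#' emulating promoter CpGs; remaining probes are uniform. Coordinates are
#' 0-based half-open internally (probes carry `start == end`).
#'
#' @param n_genes,n_probes Numbers of features to place.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bases).
#' @param n_cis_pairs Number of gene-probe promoter pairs to plant.
#' @param promoter_offset Maximum distance (bases) of a planted probe from its
#'   gene's TSS.
#' @param gene_length_range Range of gene lengths (bases).
#' @param seed Integer master seed.
#'
#' @return A list with `annotations` (tibble: `feature_id`, `feature_type`,
#'   `chrom`, `start`, `end`, `strand`) and `cis_links` (tibble: `gene_id`,
#'   `probe_id`, `offset`).
#' @export
generate_annotations <- function(n_genes, n_probes,
                                 chrom_lengths = c(chr1 = 2.49e8),
                                 n_cis_pairs = 0, promoter_offset = 1500,
                                 gene_length_range = c(2e3, 2e5), seed = 1L) {
  if (n_cis_pairs > min(n_genes, n_probes)) {
    abort("more cis pairs requested than genes (or probes) available",
          class = "npcomb_invalid_annotation")
  }
  if (any(chrom_lengths < max(gene_length_range) + 1)) {
    abort("chromosomes too short to place genes",
          class = "npcomb_invalid_annotation")
  }
  withr::with_seed(stage_seed(seed, "annotations"), {
    chroms <- names(chrom_lengths)
    g_chrom <- sample(chroms, n_genes, replace = TRUE,
                      prob = chrom_lengths / sum(chrom_lengths))
    g_len <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
    g_start <- floor(runif(n_genes) * (chrom_lengths[g_chrom] - g_len))
    genes <- tibble::tibble(
      feature_id = sprintf("gene%04d", seq_len(n_genes)),
      feature_type = "gene",
      chrom = g_chrom,
      start = as.numeric(g_start),
      end = as.numeric(g_start + g_len),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)

    probe_id <- sprintf("cg%07d", seq_len(max(n_probes, 0)))
    cis_links <- tibble::tibble(gene_id = character(), probe_id = character(),
                                offset = numeric())
    p_chrom <- character(0)
    p_pos <- numeric(0)
    if (n_probes > 0) {
      cis_gene_idx <- if (n_cis_pairs > 0) sample.int(n_genes, n_cis_pairs)
                      else integer(0)
      offs <- if (n_cis_pairs > 0)
        sample(seq(-promoter_offset, promoter_offset), n_cis_pairs,
               replace = TRUE) else numeric(0)
      cis_pos <- pmin(pmax(tss[cis_gene_idx] + offs, 0),
                      chrom_lengths[genes$chrom[cis_gene_idx]] - 1)
      n_rest <- n_probes - n_cis_pairs
      rest_chrom <- sample(chroms, n_rest, replace = TRUE,
                           prob = chrom_lengths / sum(chrom_lengths))
      rest_pos <- floor(runif(n_rest) * chrom_lengths[rest_chrom])
      p_chrom <- c(genes$chrom[cis_gene_idx], rest_chrom)
      p_pos <- as.numeric(c(cis_pos, rest_pos))
      if (n_cis_pairs > 0) {
        cis_links <- tibble::tibble(
          gene_id = genes$feature_id[cis_gene_idx],
          probe_id = probe_id[seq_len(n_cis_pairs)],
          offset = as.numeric(cis_pos) - tss[cis_gene_idx]
        )
      }
    }
    probes <- tibble::tibble(
      feature_id = probe_id[seq_len(n_probes)],
      feature_type = "probe",
      chrom = p_chrom,
      start = p_pos,
      end = p_pos,
      strand = "."
    )
    list(annotations = dplyr::bind_rows(genes, probes), cis_links = cis_links)
  })
}

#' Settings for the synthetic expression generator
#'
#' @param n_de Number of differentially expressed genes.
#' @param effect_size Log2 shift per disease-stage step for DE genes (the
#'   injected pattern is monotone: `HC -> RR -> SP` shifts by `effect_size`
#'   at each step, with random direction per gene).
#' @param shared_fraction Fraction of DE genes whose effect is present in all
#'   datasets; the rest are perturbed in one randomly chosen dataset.
#' @param age_effect_sd,sex_effect_sd SDs of per-gene log2 covariate effects
#'   (per year of age / for male vs female).
#' @param dispersion Negative-binomial dispersion (1/size); must be > 0.
#' @param baseline_cpm_range Range of per-gene mean CPM (log-uniform draw).
#' @param libsize_range Range of per-sample library sizes (reads).
#' @param indiv_var_share Share of non-group log-scale variation attributable
#'   to the individual effect shared across datasets for paired individuals.
#' @param cpm_filter Features must exceed this CPM in every sample to be kept.
#' @return A list of class `expression_spec`.
#' @export
expression_spec <- function(n_de = 0, effect_size = 1, shared_fraction = 1,
                            age_effect_sd = 0.005, sex_effect_sd = 0.05,
                            dispersion = 0.05,
                            baseline_cpm_range = c(10, 1000),
                            libsize_range = c(8e5, 1.2e6),
                            indiv_var_share = 0.3, cpm_filter = 1) {
  if (dispersion <= 0) {
    abort("dispersion must be > 0", class = "npcomb_invalid_spec")
  }
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            indiv_var_share >= 0, indiv_var_share < 1)
  structure(as.list(environment()), class = "expression_spec")
}

## Draw per-feature group coefficient tables (per dataset), monotone pattern.
.draw_effects <- function(feature_ids, dataset_ids, n_de, effect_size,
                          shared_fraction) {
  n <- length(feature_ids)
  n_de <- min(n_de, n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  dir <- sample(c(-1, 1), n_de, replace = TRUE)
  n_shared <- round(shared_fraction * n_de)
  shared <- logical(n_de)
  if (n_shared > 0) shared[seq_len(n_shared)] <- TRUE
  only_ds <- sample(dataset_ids, n_de, replace = TRUE)
  purrr::map(setNames(dataset_ids, dataset_ids), function(d) {
    beta_rr <- beta_sp <- numeric(n)
    active <- shared | only_ds == d
    beta_rr[de_idx[active]] <- dir[active] * effect_size
    beta_sp[de_idx[active]] <- 2 * dir[active] * effect_size
    tibble::tibble(
      feature_id = feature_ids, dataset_id = d,
      beta_rr = beta_rr, beta_sp = beta_sp,
      de_hc_rr = beta_rr != 0,
      de_rr_sp = (beta_sp - beta_rr) != 0,
      shared = feature_ids %in% feature_ids[de_idx[shared]]
    )
  }) |> dplyr::bind_rows()
}

## Linear predictor shared by both generators: group + covariates.
.effect_matrix <- function(dd, beta_rr, beta_sp, beta_age, beta_sex) {
  age_c <- dd$age - mean(dd$age)
  outer(beta_rr, as.numeric(dd$group == "RR")) +
    outer(beta_sp, as.numeric(dd$group == "SP")) +
    outer(beta_age, age_c) +
    outer(beta_sex, as.numeric(dd$sex == "M"))
}

#' Simulate expression counts and log2 CPM for every dataset
#'
#' Counts follow a negative-binomial log-linear model: per-gene baseline,
#' monotone disease-group shifts for DE genes, small per-gene age and sex
#' effects, and a per-individual random effect shared across datasets for
#' paired individuals (the mechanism behind cross-dataset correlation).
#' Genes not exceeding `cpm_filter` counts per million in every sample of
#' every dataset are dropped and reported.
#'
#' @param design A design tibble ([generate_design()]).
#' @param annotations Annotation tibble (or the list from
#'   [generate_annotations()]); only `feature_type == "gene"` rows are used.
#' @param spec An [expression_spec()].
#' @param seed Integer master seed.
#' @return A list with `datasets` (named list of [omics_dataset()] objects
#'   carrying log2 CPM `values` and raw `counts`), `truth` (per-gene,
#'   per-dataset effect table), and `dropped` (filtered-out gene ids).
#' @export
generate_expression <- function(design, annotations,
                                spec = expression_spec(), seed = 1L) {
  validate_design(design)
  stopifnot(inherits(spec, "expression_spec"))
  ann <- if (is.list(annotations) && !is.data.frame(annotations))
    annotations$annotations else annotations
  genes <- dplyr::filter(ann, .data$feature_type == "gene")
  g_ids <- genes$feature_id
  n_g <- length(g_ids)
  dataset_ids <- sort(unique(design$dataset_id))
  individuals <- sort(unique(design$individual_id))

  withr::with_seed(stage_seed(seed, "expression"), {
    base_cpm <- exp(runif(n_g, log(spec$baseline_cpm_range[1]),
                          log(spec$baseline_cpm_range[2])))
    beta_age <- rnorm(n_g, 0, spec$age_effect_sd)
    beta_sex <- rnorm(n_g, 0, spec$sex_effect_sd)
    truth <- .draw_effects(g_ids, dataset_ids, spec$n_de, spec$effect_size,
                           spec$shared_fraction)
    # individual effect on the natural-log scale, shared across datasets;
    # scaled so it contributes ~indiv_var_share of the non-group variation
    ivs <- spec$indiv_var_share
    tau <- sqrt(ivs / (1 - ivs) * (1 / base_cpm + spec$dispersion))
    indiv_eff <- matrix(rnorm(n_g * length(individuals)), n_g,
                        length(individuals)) * tau
    colnames(indiv_eff) <- individuals

    datasets <- purrr::map(setNames(dataset_ids, dataset_ids), function(d) {
      dd <- dplyr::filter(design, .data$dataset_id == d)
      lib <- runif(nrow(dd), spec$libsize_range[1], spec$libsize_range[2])
      tr <- dplyr::filter(truth, .data$dataset_id == d)
      eff <- .effect_matrix(dd, tr$beta_rr, tr$beta_sp, beta_age, beta_sex)
      log_mu <- log(outer(base_cpm, lib / 1e6)) + log(2) * eff +
        indiv_eff[, dd$individual_id, drop = FALSE]
      counts <- matrix(rnbinom(length(log_mu), mu = exp(log_mu),
                               size = 1 / spec$dispersion),
                       nrow = n_g,
                       dimnames = list(g_ids, dd$sample_id))
      omics_dataset(d, "expression",
                    values = .log2_cpm(counts), counts = counts)
    })

    keep <- Reduce(`&`, purrr::map(datasets, function(ds) {
      cpm <- t(t(ds$counts) / colSums(ds$counts)) * 1e6
      rowSums(cpm > spec$cpm_filter) == ncol(cpm)
    }))
    dropped <- g_ids[!keep]
    datasets <- purrr::map(datasets, function(ds) {
      omics_dataset(ds$dataset_id, "expression",
                    values = ds$values[keep, , drop = FALSE],
                    counts = ds$counts[keep, , drop = FALSE])
    })
    list(datasets = datasets,
         truth = dplyr::filter(truth, !.data$feature_id %in% dropped),
         dropped = dropped)
  })
}

.log2_cpm <- function(counts) {
  log2(t(t(counts + 0.5) / (colSums(counts) + 1)) * 1e6)
}

#' Settings for the synthetic methylation generator
#'
#' @param n_dm Number of differentially methylated probes.
#' @param effect_size M-value shift per disease-stage step for DM probes.
#' @param shared_fraction Fraction of DM probes perturbed in all datasets.
#' @param age_effect_sd,sex_effect_sd SDs of per-probe M-value covariate
#'   effects.
#' @param noise_sd Residual M-value SD.
#' @param indiv_var_share Share of non-group M-value variation carried by the
#'   cross-dataset individual effect.
#' @param cis_target_rho Target Spearman correlation between a planted cis
#'   probe's methylation and its gene's expression (typically negative for
#'   promoter probes); must satisfy `abs(rho) < 1`.
#' @param clip_eps Betas are clipped to `(clip_eps, 1 - clip_eps)`.
#' @return A list of class `methylation_spec`.
#' @export
methylation_spec <- function(n_dm = 0, effect_size = 0.8, shared_fraction = 1,
                             age_effect_sd = 0.005, sex_effect_sd = 0.05,
                             noise_sd = 0.5, indiv_var_share = 0.3,
                             cis_target_rho = -0.9, clip_eps = 1e-6) {
  if (any(abs(cis_target_rho) >= 1)) {
    abort("abs(cis_target_rho) must be < 1", class = "npcomb_invalid_spec")
  }
  stopifnot(noise_sd > 0, indiv_var_share >= 0, indiv_var_share < 1)
  structure(as.list(environment()), class = "methylation_spec")
}

#' Simulate methylation beta values for every dataset
#'
#' Probe M-values (logit2 of beta) are Gaussian with a bimodal baseline,
#' group shifts for DM probes, covariate effects, a cross-dataset individual
#' effect, and residual noise. For every cis link in `annotations$cis_links`
#' the probe's M-value is coupled to the *realized* standardized log2-CPM
#' expression of the linked gene within each dataset, with loading chosen so
#' the expression-methylation Spearman correlation targets
#' `spec$cis_target_rho` (the Pearson target is `2 sin(pi rho / 6)`).
#' Betas are the inverse logit2 of M, clipped strictly inside (0, 1).
#'
#' @param design A design tibble.
#' @param annotations The list from [generate_annotations()] (or a bare
#'   annotation tibble, in which case no cis links are planted).
#' @param spec A [methylation_spec()].
#' @param expression The list returned by [generate_expression()]; required
#'   when cis links are present.
#' @param seed Integer master seed.
#' @return A list with `datasets` (named list of [omics_dataset()] with beta
#'   `values` and an `mvalues` matrix), `truth`, and `cis_links` (with
#'   `target_rho` filled in).
#' @export
generate_methylation <- function(design, annotations,
                                 spec = methylation_spec(),
                                 expression = NULL, seed = 1L) {
  validate_design(design)
  stopifnot(inherits(spec, "methylation_spec"))
  ann <- if (is.list(annotations) && !is.data.frame(annotations))
    annotations$annotations else annotations
  cis_links <- if (is.list(annotations) && !is.data.frame(annotations))
    annotations$cis_links else
      tibble::tibble(gene_id = character(), probe_id = character())
  probes <- dplyr::filter(ann, .data$feature_type == "probe")
  p_ids <- probes$feature_id
  n_p <- length(p_ids)
  dataset_ids <- sort(unique(design$dataset_id))
  individuals <- sort(unique(design$individual_id))
  if (nrow(cis_links) > 0 && is.null(expression)) {
    abort("cis links requested but no expression data supplied",
          class = "npcomb_invalid_spec")
  }

  withr::with_seed(stage_seed(seed, "methylation"), {
    # bimodal baseline: mostly clearly methylated or unmethylated probes
    m0 <- sample(c(-1, 1), n_p, replace = TRUE) * runif(n_p, 1, 3.5)
    beta_age <- rnorm(n_p, 0, spec$age_effect_sd)
    beta_sex <- rnorm(n_p, 0, spec$sex_effect_sd)
    truth <- .draw_effects(p_ids, dataset_ids, spec$n_dm, spec$effect_size,
                           spec$shared_fraction)
    ivs <- spec$indiv_var_share
    tau <- spec$noise_sd * sqrt(ivs / (1 - ivs))
    indiv_eff <- matrix(rnorm(n_p * length(individuals), 0, tau), n_p,
                        length(individuals))
    colnames(indiv_eff) <- individuals

    target <- rep_len(spec$cis_target_rho, nrow(cis_links))
    r_pearson <- 2 * sin(pi * target / 6)
    loading <- abs(r_pearson) / sqrt(1 - r_pearson^2)

    datasets <- purrr::map(setNames(dataset_ids, dataset_ids), function(d) {
      dd <- dplyr::filter(design, .data$dataset_id == d)
      n_s <- nrow(dd)
      tr <- dplyr::filter(truth, .data$dataset_id == d)
      m <- outer(m0, rep(1, n_s)) +
        .effect_matrix(dd, tr$beta_rr, tr$beta_sp, beta_age, beta_sex) +
        indiv_eff[, dd$individual_id, drop = FALSE] +
        matrix(rnorm(n_p * n_s, 0, spec$noise_sd), n_p, n_s)
      dimnames(m) <- list(p_ids, dd$sample_id)
      if (nrow(cis_links) > 0) {
        expr <- expression$datasets[[d]]
        for (k in seq_len(nrow(cis_links))) {
          g <- cis_links$gene_id[k]
          p <- cis_links$probe_id[k]
          if (!g %in% rownames(expr$values)) next  # gene lost to CPM filter
          z <- drop(scale(expr$values[g, dd$sample_id]))
          m[p, ] <- m0[match(p, p_ids)] + spec$noise_sd *
            (sign(target[k]) * loading[k] * z + rnorm(n_s))
        }
      }
      beta <- 1 / (1 + 2^(-m))
      beta <- pmin(pmax(beta, spec$clip_eps), 1 - spec$clip_eps)
      dimnames(beta) <- list(p_ids, dd$sample_id)
      ds <- omics_dataset(d, "methylation", values = beta)
      ds$mvalues <- m
      ds
    })
    cis_links$target_rho <- target
    list(datasets = datasets, truth = truth, cis_links = cis_links)
  })
}

#' A single feature-by-sample omics matrix tied to a study design
#'
#' @param dataset_id Dataset label (e.g. `"CD4"`).
#' @param modality `"expression"` or `"methylation"`.
#' @param values Numeric feature x sample matrix with dimnames; methylation
#'   values must lie in `[0, 1]`, and no missing values are allowed.
#' @param counts Optional raw count matrix (expression only).
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(dataset_id, modality = c("expression", "methylation"),
                          values, counts = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(values),
            nrow(values) == 0 || !is.null(rownames(values)),
            ncol(values) == 0 || !is.null(colnames(values)))
  if (anyNA(values)) abort("omics values must not contain missing entries",
                           class = "npcomb_invalid_data")
  if (modality == "methylation" && length(values) > 0 &&
      (min(values) < 0 || max(values) > 1)) {
    abort("methylation values must lie in [0, 1]",
          class = "npcomb_invalid_data")
  }
  structure(list(dataset_id = dataset_id, modality = modality,
                 values = values, counts = counts),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %s [%s]: %d features x %d samples\n",
              x$dataset_id, x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate a complete paired multi-omics study with ground truth
#'
#' Convenience wrapper chaining [generate_design()],
#' [generate_annotations()], [generate_expression()] and
#' [generate_methylation()] under one master seed with independent per-stage
#' substreams.
#'
#' @inheritParams generate_design
#' @inheritParams generate_annotations
#' @param expr_spec,meth_spec Generator settings, see [expression_spec()] and
#'   [methylation_spec()].
#' @param seed Integer master seed.
#' @return A list of class `npc_study`: `design`, `annotations`, `cis_links`,
#'   `expression`, `methylation` (each a named list of [omics_dataset()]),
#'   `truth` (list with `expression`, `methylation`, `cis_links`), and
#'   `dropped_genes`.
#' @examples
#' st <- simulate_study(n_genes = 50, n_probes = 50, seed = 1)
#' st$expression$CD4
#' @export
simulate_study <- function(n_hc = 10, n_rr = 10, n_sp = 8,
                           paired_fraction = 0.7,
                           dataset_ids = c("CD4", "CD8"),
                           n_genes = 1000, n_probes = 1000, n_cis_pairs = 0,
                           chrom_lengths = c(chr1 = 2.49e8),
                           promoter_offset = 1500,
                           expr_spec = expression_spec(),
                           meth_spec = methylation_spec(),
                           seed = 1L) {
  design <- generate_design(n_hc, n_rr, n_sp, paired_fraction, dataset_ids,
                            seed = seed)
  ann <- generate_annotations(n_genes, n_probes, chrom_lengths, n_cis_pairs,
                              promoter_offset, seed = seed)
  expr <- generate_expression(design, ann, expr_spec, seed = seed)
  meth <- generate_methylation(design, ann, meth_spec, expression = expr,
                               seed = seed)
  structure(list(design = design,
                 annotations = ann$annotations,
                 cis_links = meth$cis_links,
                 expression = expr$datasets,
                 methylation = meth$datasets,
                 truth = list(expression = expr$truth,
                              methylation = meth$truth,
                              cis_links = meth$cis_links),
                 dropped_genes = expr$dropped),
            class = "npc_study")
}

#' @export
print.npc_study <- function(x, ...) {
  cat(sprintf(paste0("<npc_study> %d samples, %d individuals, datasets: %s\n",
                     "  expression: %d genes; methylation: %d probes; ",
                     "cis links: %d\n"),
              nrow(x$design), dplyr::n_distinct(x$design$individual_id),
              paste(names(x$expression), collapse = ", "),
              nrow(x$expression[[1]]$values),
              nrow(x$methylation[[1]]$values),
              nrow(x$cis_links)))
  invisible(x)
}
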