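#' Strand-aware transcription start sites
#'
#' `+` strand genes start at `start`, `-` strand genes at `end`; an unknown
#' strand falls back to `start` with a warning.
#'
#' @param genes Annotation tibble rows with `feature_type == "gene"`.
#' @return A tibble `feature_id`, `chrom`, `tss`.
#' @export
compute_tss <- function(genes) {
  genes <- dplyr::filter(genes, .data$feature_type == "gene")
  unknown <- !genes$strand %in% c("+", "-")
  if (any(unknown)) {
    warn(sprintf("%d gene(s) with unknown strand: TSS set to start",
                 sum(unknown)))
  }
  tibble::tibble(
    feature_id = genes$feature_id,
    chrom = genes$chrom,
    tss = ifelse(genes$strand == "-", genes$end, genes$start)
  )
}

#' Pair genes and probes within a cis window of the TSS
#'
#' Same-chromosome gene-probe pairs with `|probe position - TSS| < max_dist`
#' (strictly less than; the canonical window is 1 Mb). Selected features
#' lacking an annotation are skipped with a warning.
#'
#' @param gene_ids,probe_ids Character vectors of selected features.
#' @param annotations Annotation tibble covering both feature types.
#' @param max_dist Window size in bases (strict upper bound), default 1e6.
#' @return A tibble `gene_id`, `probe_id`, `chrom`, `tss`, `probe_pos`,
#'   `distance`, deduplicated and sorted by (gene, distance).
#' @export
pair_within_distance <- function(gene_ids, probe_ids, annotations,
                                 max_dist = 1e6) {
  genes <- dplyr::filter(annotations, .data$feature_type == "gene",
                         .data$feature_id %in% gene_ids)
  probes <- dplyr::filter(annotations, .data$feature_type == "probe",
                          .data$feature_id %in% probe_ids)
  missing <- c(setdiff(gene_ids, genes$feature_id),
               setdiff(probe_ids, probes$feature_id))
  if (length(missing)) {
    warn(sprintf("%d selected feature(s) lack annotation and were skipped",
                 length(missing)))
  }
  tss <- compute_tss(genes)
  probe_tab <- tibble::tibble(probe_id = probes$feature_id,
                              chrom = probes$chrom,
                              probe_pos = probes$start)
  tss |>
    dplyr::rename(gene_id = "feature_id") |>
    dplyr::inner_join(probe_tab, by = "chrom",
                      relationship = "many-to-many") |>
    dplyr::mutate(distance = abs(.data$probe_pos - .data$tss)) |>
    dplyr::filter(.data$distance < max_dist) |>
    dplyr::distinct(.data$gene_id, .data$probe_id, .keep_all = TRUE) |>
    dplyr::select("gene_id", "probe_id", "chrom", "tss", "probe_pos",
                  "distance") |>
    dplyr::arrange(.data$gene_id, .data$distance)
}

## Spearman rho (average ranks) plus a two-sided p-value: exact enumeration
## of rank permutations up to n = exact_limit, t-approximation above.
.spearman_test <- function(x, y, exact_limit = 7) {
  n <- length(x)
  rho <- cor(x, y, method = "spearman")
  if (!is.finite(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (n <= exact_limit) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- multiset_permutations(as.character(seq_len(n)))
    rhos <- vapply(perms, function(p) cor(rx, ry[as.integer(p)]),
                   numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Correlate paired expression and methylation across shared samples
#'
#' For every gene-probe pair and every dataset, the Spearman correlation
#' between the gene's expression and the probe's methylation is computed over
#' the samples (matched by individual) present in both matrices, pooling all
#' disease groups. Ranks use averages for ties; p-values are two-sided
#' (exact rank-permutation enumeration for very small n, t-approximation
#' otherwise). Pairs with fewer than `min_n` shared samples are flagged
#' untested rather than erroring.
#'
#' @param pairs Output of [pair_within_distance()].
#' @param expression,methylation Named lists of [omics_dataset()] objects
#'   keyed by dataset id (the shared names define the datasets tested).
#' @param design Design tibble used to match samples via `individual_id`.
#' @param min_n Minimum shared samples for a pair to be tested (default 5).
#' @param exact_limit Largest n for exact permutation p-values (default 7).
#' @return A tibble in long format: `gene_id`, `probe_id`, `distance`,
#'   `dataset_id`, `rho`, `p`, `n`, `tested`.
#' @export
correlate_pairs <- function(pairs, expression, methylation, design,
                            min_n = 5, exact_limit = 7) {
  dataset_ids <- intersect(names(expression), names(methylation))
  if (length(dataset_ids) == 0) {
    abort("expression and methylation share no datasets",
          class = "npcomb_invalid_data")
  }
  empty <- tibble::tibble(gene_id = character(), probe_id = character(),
                          distance = numeric(), dataset_id = character(),
                          rho = numeric(), p = numeric(), n = integer(),
                          tested = logical())
  if (nrow(pairs) == 0) return(empty)
  purrr::map(dataset_ids, function(d) {
    ev <- expression[[d]]$values
    mv <- methylation[[d]]$values
    dd <- dplyr::filter(design, .data$dataset_id == d)
    e_ind <- setNames(dd$sample_id, dd$individual_id)[
      dd$sample_id %in% colnames(ev)]
    m_ind <- setNames(dd$sample_id, dd$individual_id)[
      dd$sample_id %in% colnames(mv)]
    shared <- intersect(names(e_ind), names(m_ind))
    purrr::pmap(pairs[c("gene_id", "probe_id", "distance")],
                function(gene_id, probe_id, distance) {
      ok <- gene_id %in% rownames(ev) && probe_id %in% rownames(mv) &&
        length(shared) >= min_n
      if (!ok) {
        return(tibble::tibble(gene_id = gene_id, probe_id = probe_id,
                              distance = distance, dataset_id = d,
                              rho = NA_real_, p = NA_real_,
                              n = length(shared), tested = FALSE))
      }
      st <- .spearman_test(ev[gene_id, e_ind[shared]],
                           mv[probe_id, m_ind[shared]], exact_limit)
      tibble::tibble(gene_id = gene_id, probe_id = probe_id,
                     distance = distance, dataset_id = d,
                     rho = st$rho, p = st$p, n = length(shared),
                     tested = is.finite(st$rho))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Rank per-dataset correlations and intersect across datasets
#'
#' Per dataset, keeps tested pairs with `|rho| > rho_min` and `p < p_max`
#' and ranks them by ascending p; the returned table holds the pairs passing
#' in *every* dataset, with per-dataset rank, rho and p spread into columns
#' and ordered by the best combined rank.
#'
#' @param results Long tibble from [correlate_pairs()].
#' @param rho_min Absolute-correlation threshold (strict), default 0.5.
#' @param p_max P-value threshold (strict), default 0.05.
#' @return A wide tibble, one row per intersected pair.
#' @export
rank_and_intersect <- function(results, rho_min = 0.5, p_max = 0.05) {
  kept <- results |>
    dplyr::filter(.data$tested, abs(.data$rho) > rho_min,
                  .data$p < p_max) |>
    dplyr::mutate(rank = rank(.data$p, ties.method = "min"),
                  .by = "dataset_id")
  n_ds <- dplyr::n_distinct(results$dataset_id)
  if (nrow(kept) == 0) {
    return(tibble::tibble(gene_id = character(), probe_id = character(),
                          distance = numeric()))
  }
  kept |>
    dplyr::filter(dplyr::n() == n_ds, .by = c("gene_id", "probe_id")) |>
    tidyr::pivot_wider(id_cols = c("gene_id", "probe_id", "distance"),
                       names_from = "dataset_id",
                       values_from = c("rho", "p", "n", "rank")) |>
    dplyr::arrange(dplyr::pick(dplyr::starts_with("rank_")))
}
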