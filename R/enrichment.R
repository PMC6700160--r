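#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   member genes, tab-separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("package 'fgsea' is required to read GMT files")
  }
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(genes, nm) {
    paste(c(nm, "na", genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by effective size within a universe
#'
#' Sets are intersected with the analyzed universe first; sets whose
#' effective size falls below `min_size` or above `max_size` are removed
#' (the bounds themselves are retained).
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of analyzed gene ids.
#' @param min_size,max_size Inclusive size bounds, defaults 20 and 200.
#' @return A list with `sets` (filtered, members restricted to the universe)
#'   and `universe`.
#' @export
filter_sets <- function(sets, universe, min_size = 20, max_size = 200) {
  trimmed <- purrr::map(sets, intersect, universe)
  sizes <- lengths(trimmed)
  list(sets = trimmed[sizes >= min_size & sizes <= max_size],
       universe = universe)
}

#' Rank-based gene-set enrichment test
#'
#' Genes are ranked by ascending score (smaller = more significant, e.g. a
#' p-value); each set is tested with a one-sided Wilcoxon rank-sum test of
#' whether its members rank lower (better) than the complement. Being purely
#' rank-based, the result is invariant under any strictly monotone transform
#' of the scores. Set-level BH q-values are appended.
#'
#' @param gene_scores Named numeric vector of per-gene scores covering the
#'   universe (names = gene ids).
#' @param collection A filtered collection from [filter_sets()].
#' @return A tibble `set`, `size`, `rank_sum`, `p`, `q`, sorted by p.
#' @export
rank_set_test <- function(gene_scores, collection) {
  universe <- collection$universe
  if (!all(universe %in% names(gene_scores))) {
    abort("gene_scores must cover the universe",
          class = "npcomb_invalid_data")
  }
  scores <- gene_scores[universe]
  ranks <- rank(scores)  # average ranks for ties
  res <- purrr::imap(collection$sets, function(members, nm) {
    inside <- universe %in% members
    tibble::tibble(
      set = nm,
      size = sum(inside),
      rank_sum = sum(ranks[inside]),
      p = wilcox.test(scores[inside], scores[!inside],
                      alternative = "less", exact = FALSE)$p.value
    )
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble::tibble(set = character(), size = integer(),
                          rank_sum = numeric(), p = numeric(),
                          q = numeric()))
  }
  res |>
    dplyr::mutate(q = bh_fdr(.data$p)) |>
    dplyr::arrange(.data$p, .data$set)
}
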