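#' Tidy an NPC result
#'
#' @param x An `npc_result`.
#' @param ... Unused.
#' @return The per-feature result tibble (per-dataset F statistics and
#'   partial p-values, combined statistic, global p, BH q).
#' @method tidy npc_result
#' @export
tidy.npc_result <- function(x, ...) {
  x$table
}

#' One-row summary of an NPC result
#'
#' @param x An `npc_result`.
#' @param p_max,q_max Selection thresholds used for the `n_selected` column.
#' @param ... Unused.
#' @return A one-row tibble: feature count, permutation count, minimum
#'   attainable p, and the number of selected features.
#' @method glance npc_result
#' @export
glance.npc_result <- function(x, p_max = 0.001, q_max = 0.1, ...) {
  tibble::tibble(
    n_features = nrow(x$table),
    n_datasets = length(x$dataset_ids),
    B = x$B,
    min_attainable_p = 1 / (x$B + 1),
    n_selected = length(select_features(x, p_max, q_max))
  )
}

#' Tidy per-feature model fits
#'
#' @param x A `feature_fits` object.
#' @param ... Unused.
#' @return A long tibble of coefficients: `feature_id`, `term`, `estimate`.
#' @method tidy feature_fits
#' @export
tidy.feature_fits <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "term",
                        values_to = "estimate")
}

#' @method glance feature_fits
#' @export
glance.feature_fits <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$coefficients),
                 n_terms = ncol(x$coefficients),
                 df_residual = x$df_residual,
                 df_prior = x$df_prior,
                 s2_prior = x$s2_prior)
}
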