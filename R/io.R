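#' Write a feature-by-sample matrix as TSV
#'
#' First column `feature_id`, one column per sample. An optional comment
#' header (e.g. a config hash) is written as `#`-prefixed lines.
#'
#' @param values Numeric matrix with dimnames.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(values, path, comment = NULL) {
  tab <- tibble::as_tibble(values, rownames = "feature_id")
  .write_tsv_commented(tab, path, comment)
}

#' Read a feature-by-sample matrix from TSV
#'
#' @param path Path written by [write_matrix_tsv()].
#' @return A numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}

.write_tsv_commented <- function(tab, path, comment = NULL) {
  if (length(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Write feature annotations as a BED-like TSV
#'
#' Internally coordinates are 0-based half-open; the written table is
#' 1-based inclusive (`start` is shifted by +1; a probe occupies a single
#' written position with `start == end`), as stated in the file's comment
#' header.
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- annotations |>
    dplyr::mutate(
      start = .data$start + 1,
      end = dplyr::if_else(.data$feature_type == "probe",
                           .data$start, .data$end)
    ) |>
    dplyr::select("chrom", "start", "end", "feature_id", "feature_type",
                  "strand")
  .write_tsv_commented(out, path,
                       comment = "coordinates are 1-based inclusive")
}

#' Read feature annotations written by [write_annotations_tsv()]
#'
#' @param path Input path.
#' @return An annotation tibble in internal (0-based half-open) coordinates.
#' @export
read_annotations_tsv <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  tab |>
    dplyr::mutate(
      start = .data$start - 1,
      end = dplyr::if_else(.data$feature_type == "probe",
                           .data$start, as.numeric(.data$end))
    ) |>
    dplyr::select("feature_id", "feature_type", "chrom", "start", "end",
                  "strand")
}

#' Write / read a study design table
#'
#' @param design Design tibble.
#' @param path File path.
#' @return `path` (write) or the design tibble (read).
#' @export
write_design_tsv <- function(design, path) {
  .write_tsv_commented(design, path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         sample_id = "c", individual_id = "c",
                         dataset_id = "c", group = "c", sex = "c",
                         age = "d"))
  validate_design(d)
  d
}
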