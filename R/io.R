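#' Read and write expression matrices and sample tables as TSV
#'
#' Expression TSVs have a `gene` column followed by one column per sample
#' (log10 intensities). Sample-table TSVs carry `sample_id`, `tf`,
#' `condition`, `replicate`, `batch` (atlas tables: `sample_id`, `tissue`,
#' `replicate`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene") names(x)[1] <- "gene"
  check_expression(x)
  x
}

#' @rdname read_expression
#' @param expr Expression tibble.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_sample_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_expression
#' @param samples Sample-table tibble.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Write an induction profile as TSV
#'
#' Columns: `gene`, `logratio`, `p`, `fdr`, `fold`, `direction`.
#'
#' @param profile An induction profile.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param tf TF label restored into the `tf` attribute.
#' @export
read_profile <- function(path, tf = NA_character_) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(x, tf = tf, class = c("induction_profile", class(x)))
}
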