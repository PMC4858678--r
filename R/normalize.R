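#' Control-channel normalization of one array
#'
#' Normalizes log-scale feature intensities of an induced (Dox-) channel by
#' the paired control (Dox+) channel of the same array:
#' `x' = x - c + Median(c)`, where the median is taken over all features of
#' the array. Subtracting the control channel removes feature-level effects
#' shared by the two channels; adding back the array median restores the
#' intensity scale.
#'
#' @param x Numeric vector of induced log intensities.
#' @param c Numeric vector of paired control log intensities, same length.
#' @return Numeric vector `x - c + median(c)`.
#' @export
#' @examples
#' normalize_to_control(c(3, 2, 4), c(1, 2, 3))  # 4 2 3
normalize_to_control <- function(x, c) {
  if (length(x) != length(c)) {
    abort("`x` and `c` must have the same length.")
  }
  if (!all(is.finite(x)) || !all(is.finite(c))) {
    abort("`x` and `c` must be finite.")
  }
  x - c + median(c)
}

#' Combine expression batches by per-gene median normalization
#'
#' Combines several expression tibbles measured in different batches into one
#' matrix on the shared gene universe. Within each batch, every gene's values
#' are shifted (additively, on the log scale) so that its batch median equals
#' its global median, defined as the median of the per-batch medians. After
#' the operation each gene's median agrees across batches exactly.
#'
#' @param matrices Named list of expression tibbles (`gene` column plus
#'   sample columns); names are batch labels.
#' @return A single expression tibble over the intersected gene universe with
#'   all samples, plus a `batch` attribute mapping sample to batch.
#' @export
batch_normalize <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0) {
    abort("`matrices` must be a non-empty list of expression tibbles.")
  }
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    names(matrices) <- paste0("b", seq_along(matrices))
  }
  purrr::walk(matrices, check_expression)
  shared <- purrr::reduce(purrr::map(matrices, expr_genes), intersect)
  if (length(shared) == 0) {
    abort("Empty gene intersection across batches.")
  }
  mats <- purrr::map(matrices, function(x) {
    m <- expr_matrix(x)
    m[shared, , drop = FALSE]
  })
  batch_med <- vapply(mats, function(m) apply(m, 1, median),
                      numeric(length(shared)))
  if (!is.matrix(batch_med)) {  # single shared gene
    batch_med <- matrix(batch_med, nrow = 1,
                        dimnames = list(NULL, names(mats)))
  }
  global_med <- apply(batch_med, 1, median)
  shifted <- purrr::imap(mats, function(m, b) {
    m + (global_med - batch_med[, b])
  })
  combined <- do.call(cbind, unname(shifted))
  out <- dplyr::bind_cols(tibble::tibble(gene = shared),
                          tibble::as_tibble(combined))
  attr(out, "batch") <- tibble::tibble(
    sample_id = unlist(purrr::map(mats, colnames), use.names = FALSE),
    batch = rep(names(mats), vapply(mats, ncol, integer(1)))
  )
  out
}
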