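# broom-style tidiers for the fitted result types.

#' Tidy an induction profile
#'
#' @param x An induction profile.
#' @param ... Ignored.
#' @return A plain tibble, one row per gene.
#' @method tidy induction_profile
#' @export
tidy.induction_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.induction_profile
#' @method glance induction_profile
#' @export
glance.induction_profile <- function(x, ...) {
  sig <- significant_genes(x)
  tibble::tibble(
    tf = attr(x, "tf"),
    n_genes = nrow(x),
    n_up = sum(sig$direction == "up"),
    n_down = sum(sig$direction == "down")
  )
}

#' Tidy a correlation matrix
#'
#' @param x A [correlation_matrix()] result.
#' @param ... Ignored.
#' @return Long tibble of all TF-tissue correlations.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) x$results

#' @rdname tidy.correlation_matrix
#' @method glance correlation_matrix
#' @export
glance.correlation_matrix <- function(x, ...) {
  tibble::tibble(
    n_tfs = length(x$tf_order),
    n_tissues = length(x$tissue_order),
    n_genes = length(x$genes),
    n_significant = sum(x$results$significant)
  )
}

#' Tidy a profile PCA
#'
#' @param x A [pca_profiles()] result.
#' @param ... Ignored.
#' @return TF scores on the principal components.
#' @method tidy profile_pca
#' @export
tidy.profile_pca <- function(x, ...) x$scores

#' @rdname tidy.profile_pca
#' @method glance profile_pca
#' @export
glance.profile_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$var_explained),
    n_genes = length(x$genes),
    pc1_var = x$var_explained[1] / sum(x$var_explained)
  )
}

#' Tidy target calls
#'
#' @param x A [call_targets()] result.
#' @param ... Ignored.
#' @return A plain tibble, one row per candidate gene.
#' @method tidy target_calls
#' @export
tidy.target_calls <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.target_calls
#' @method glance target_calls
#' @export
glance.target_calls <- function(x, ...) {
  tibble::tibble(
    tf = attr(x, "tf"),
    n_candidates = nrow(x),
    n_regulated = sum(x$regulated),
    min_epfp = if (nrow(x)) min(x$epfp) else NA_real_
  )
}
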