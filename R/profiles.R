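#' Per-TF induction profile: logratio, p, FDR
#'
#' Contrasts induced (Dox-) against control (Dox+) replicates of one TF line.
#' The response of each gene is the logratio `L = mean(induced) -
#' mean(control)` of log10 intensities. Significance comes, by default, from
#' the limma moderated t-statistic (empirical-Bayes variance shrinkage),
#' which is the standard for arrays with two or three replicates per
#' condition: per-gene variances at such depths are too unstable for a
#' classical test to retain power. `method = "welch"` gives the plain Welch
#' two-sample t-test (per-gene variances floored at `var_floor`) instead.
#' The false discovery rate is Benjamini-Hochberg across all genes. With a
#' single replicate per condition only the logratio is computed (p and FDR
#' are `NA`).
#'
#' @param expr Expression tibble (`gene` plus sample columns, log10 scale).
#' @param samples Sample table (`sample_id`, `tf`, `condition`, `replicate`).
#' @param tf Which TF line to contrast.
#' @param method `"moderated"` (limma eBayes, default) or `"welch"`.
#' @param var_floor Lower bound on per-group variance in the Welch test.
#' @return An `induction_profile` tibble: `gene`, `logratio`, `p`, `fdr`,
#'   `fold` (`10^|logratio|`), `direction` (`"up"`/`"down"`), with the TF
#'   name in attribute `tf`.
#' @export
compute_induction_profile <- function(expr, samples, tf,
                                      method = c("moderated", "welch"),
                                      var_floor = 1e-4) {
  method <- match.arg(method)
  check_expression(expr)
  check_sample_table(samples, expr)
  sel <- samples[samples$tf == tf, , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(sprintf("TF '%s' not present in the sample table.", tf))
  }
  ind <- sel$sample_id[sel$condition == "induced"]
  ctl <- sel$sample_id[sel$condition == "control"]
  if (length(ind) < 1 || length(ctl) < 1) {
    abort(sprintf("TF '%s' needs at least one induced and one control sample.", tf))
  }
  m <- expr_matrix(expr)
  if (method == "moderated" && length(ind) >= 2 && length(ctl) >= 2) {
    des <- cbind(Intercept = 1,
                 induced = c(rep(1, length(ind)), rep(0, length(ctl))))
    fit <- limma::eBayes(limma::lmFit(m[, c(ind, ctl), drop = FALSE], des))
    res <- list(estimate = fit$coefficients[, "induced"],
                p = fit$p.value[, "induced"])
  } else {
    res <- welch_rows(m[, ind, drop = FALSE], m[, ctl, drop = FALSE],
                      var_floor = var_floor)
  }
  out <- tibble::tibble(
    gene = expr_genes(expr),
    logratio = unname(res$estimate),
    p = unname(res$p),
    fdr = if (all(is.na(res$p))) NA_real_ else p.adjust(res$p, method = "BH"),
    fold = 10^abs(unname(res$estimate)),
    direction = ifelse(res$estimate >= 0, "up", "down")
  )
  structure(out, tf = tf, class = c("induction_profile", class(out)))
}

#' Responder genes of an induction profile
#'
#' A gene responds to the TF if its logratio is significantly different from
#' zero (FDR at most `fdr_max`) and the expression change is at least
#' `min_fold`-fold; both thresholds are inclusive. Direction follows the sign
#' of the logratio.
#'
#' @param profile An [compute_induction_profile()] result.
#' @param fdr_max FDR threshold (inclusive).
#' @param min_fold Fold-change threshold (inclusive).
#' @return Tibble of significant genes: `gene`, `direction`, `logratio`,
#'   `fold`, `fdr`.
#' @export
significant_genes <- function(profile, fdr_max = 0.05, min_fold = 1.5) {
  if (!all(c("fdr", "fold") %in% names(profile))) {
    abort("`profile` must have `fdr` and `fold` columns.")
  }
  profile |>
    dplyr::filter(!is.na(.data$fdr), .data$fdr <= fdr_max,
                  .data$fold >= min_fold) |>
    dplyr::select("gene", "direction", "logratio", "fold", "fdr") |>
    tibble::as_tibble()
}

#' Responder counts per TF
#'
#' @param profiles List of induction profiles (one per TF).
#' @inheritParams significant_genes
#' @return Tibble with one row per TF: `tf`, `n_up`, `n_down`, `n_total`.
#' @export
count_responders <- function(profiles, fdr_max = 0.05, min_fold = 1.5) {
  purrr::map_dfr(profiles, function(p) {
    sig <- significant_genes(p, fdr_max = fdr_max, min_fold = min_fold)
    tibble::tibble(
      tf = attr(p, "tf"),
      n_up = sum(sig$direction == "up"),
      n_down = sum(sig$direction == "down"),
      n_total = nrow(sig)
    )
  })
}

#' PCA of induction profiles
#'
#' Principal component analysis of the TF-by-gene logratio matrix, restricted
#' to genes that respond significantly to at least one TF. Components are
#' ordered by explained variance; signs follow the convention that each
#' component's largest-magnitude gene loading is positive, which makes the
#' output deterministic.
#'
#' @param profiles List of at least two induction profiles.
#' @inheritParams significant_genes
#' @return A `profile_pca` list: `scores` (tibble `tf`, `PC1`, ...),
#'   `loadings` (gene-by-component matrix), `var_explained`, `genes`.
#' @export
pca_profiles <- function(profiles, fdr_max = 0.05, min_fold = 1.5) {
  if (length(profiles) < 2) {
    abort("At least two profiles are required for PCA.")
  }
  sig <- unique(unlist(purrr::map(
    profiles, ~ significant_genes(.x, fdr_max, min_fold)$gene
  )))
  if (length(sig) == 0) {
    abort("No genes are significant in any profile; PCA undefined.")
  }
  tfs <- purrr::map_chr(profiles, ~ attr(.x, "tf"))
  lr <- vapply(profiles, function(p) {
    setNames(p$logratio, p$gene)[sig]
  }, numeric(length(sig)))
  # observations = TFs, variables = genes
  pc <- prcomp(t(lr), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(tf = tfs), scores)
  structure(
    list(scores = scores, loadings = pc$rotation,
         var_explained = pc$sdev^2, genes = sig),
    class = "profile_pca"
  )
}
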