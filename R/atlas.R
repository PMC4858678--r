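#' Tissue-expression atlas from replicate-level intensities
#'
#' Collapses a replicate-level atlas into per-gene, per-tissue logratios of
#' each tissue versus the gene's median across tissues:
#' `A = mean(log10 tissue) - median over tissues of the tissue means`.
#' Significance of each cell is assessed by a moderated one-sample t-test
#' (limma eBayes, as in the induction contrast) of the tissue's
#' median-centred replicates against zero, Benjamini-Hochberg corrected over
#' all gene-tissue cells, and combined with a fold threshold of
#' `min_fold` (default 2, stricter than the induction threshold because
#' expression differences between adult tissues are much larger than
#' induction responses).
#'
#' @param expr Atlas expression tibble (`gene` plus tissue-replicate
#'   columns, log10 scale).
#' @param samples Atlas sample table: `sample_id`, `tissue`, `replicate`.
#' @param fdr_max,min_fold Significance thresholds (inclusive).
#' @return An `atlas_matrix` tibble: `gene`, `tissue`, `logratio`, `fold`,
#'   `p`, `fdr`, `significant`. Per-gene medians of `logratio` across tissues
#'   are zero by construction.
#' @export
atlas_from_replicates <- function(expr, samples, fdr_max = 0.05,
                                  min_fold = 2) {
  check_expression(expr)
  if (!all(c("sample_id", "tissue") %in% names(samples))) {
    abort("Atlas sample table needs `sample_id` and `tissue` columns.")
  }
  tissues <- unique(samples$tissue)
  if (length(tissues) < 2) {
    abort("At least two tissues are required to form tissue-vs-median logratios.")
  }
  m <- expr_matrix(expr)
  means <- vapply(tissues, function(t) {
    rowMeans(m[, samples$sample_id[samples$tissue == t], drop = FALSE])
  }, numeric(nrow(m)))
  med <- apply(means, 1, median)
  A <- means - med

  reps <- table(samples$tissue)
  if (any(reps < 2)) {
    warn("Some tissues have < 2 replicates; flagging all cells significant.")
    p <- matrix(0, nrow = nrow(A), ncol = ncol(A))
  } else {
    p <- vapply(tissues, function(t) {
      cols <- samples$sample_id[samples$tissue == t]
      x <- m[, cols, drop = FALSE] - med
      fit <- limma::eBayes(limma::lmFit(x, matrix(1, ncol(x), 1)))
      fit$p.value[, 1]
    }, numeric(nrow(m)))
  }

  out <- tibble::tibble(
    gene = rep(expr_genes(expr), times = length(tissues)),
    tissue = rep(tissues, each = nrow(m)),
    logratio = as.vector(A),
    fold = 10^abs(as.vector(A)),
    p = as.vector(p)
  )
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr <= fdr_max & out$fold >= min_fold
  structure(out, class = c("atlas_matrix", class(out)))
}

# Fisher z for a correlation; capped so r -> +-1 stays finite.
fisher_z <- function(r, n, cap = 50) {
  if (is.na(r) || n <= 3) return(0)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)
  max(min(z, cap), -cap)
}

#' Correlate one induction profile with one tissue signature
#'
#' Pearson correlation between the TF's induction logratios and the tissue's
#' atlas logratios over a shared gene universe — by default the genes
#' significant in both datasets (significant in this profile and in at least
#' one tissue of the atlas); [correlation_matrix()] passes a universe shared
#' by all cells. Significance is the Fisher transformation
#' `z = atanh(r) * sqrt(n - 3)`, capped at |z| = 50; with fewer than four
#' genes z is 0.
#'
#' @param profile An induction profile.
#' @param atlas An [atlas_from_replicates()] result.
#' @param tissue Tissue to correlate against.
#' @param genes Optional gene universe; default described above.
#' @param fdr_max,min_fold Profile significance thresholds used when `genes`
#'   is not supplied.
#' @return One-row tibble: `tf`, `tissue`, `r`, `n`, `z`.
#' @export
correlate <- function(profile, atlas, tissue, genes = NULL,
                      fdr_max = 0.05, min_fold = 1.5) {
  at <- dplyr::filter(atlas, .data$tissue == .env$tissue)
  if (nrow(at) == 0) {
    abort(sprintf("Tissue '%s' not present in the atlas.", tissue))
  }
  if (is.null(genes)) {
    sig_prof <- significant_genes(profile, fdr_max, min_fold)$gene
    sig_atlas <- unique(atlas$gene[atlas$significant])
    genes <- intersect(sig_prof, sig_atlas)
  }
  genes <- intersect(genes, intersect(profile$gene, at$gene))
  n <- length(genes)
  L <- setNames(profile$logratio, profile$gene)[genes]
  A <- setNames(at$logratio, at$gene)[genes]
  r <- if (n >= 2 && sd(L) > 0 && sd(A) > 0) cor(L, A) else NA_real_
  if (n < 4) {
    warn(sprintf("Only %d shared genes for %s vs %s; z set to 0.",
                 n, attr(profile, "tf") %||% "profile", tissue))
  }
  tibble::tibble(
    tf = attr(profile, "tf") %||% NA_character_,
    tissue = tissue,
    r = r,
    n = n,
    z = fisher_z(r, n)
  )
}

#' TF-by-tissue correlation matrix with clustered ordering
#'
#' Computes all profile-tissue correlations over a single shared gene
#' universe: genes significant for at least one TF in the induction data and
#' for at least one tissue in the atlas. Rows (TFs) and columns (tissues)
#' are ordered by average-linkage hierarchical clustering on the correlation
#' distance (1 - Pearson correlation between the corresponding rows/columns
#' of the r matrix). Cells with `|z| < z_min` are flagged non-significant.
#'
#' @param profiles List of induction profiles.
#' @param atlas An [atlas_from_replicates()] result.
#' @param fdr_max,min_fold Induction-side significance thresholds.
#' @param z_min Significance threshold on |z| (default 2).
#' @return A `correlation_matrix` list: `results` (long tibble `tf`,
#'   `tissue`, `r`, `n`, `z`, `significant`), `tf_order`, `tissue_order`,
#'   `genes` (the shared universe).
#' @export
correlation_matrix <- function(profiles, atlas, fdr_max = 0.05,
                               min_fold = 1.5, z_min = 2) {
  if (length(profiles) < 2) abort("Need at least two profiles.")
  tissues <- unique(atlas$tissue)
  if (length(tissues) < 2) abort("Need at least two tissues.")
  sig_prof <- unique(unlist(purrr::map(
    profiles, ~ significant_genes(.x, fdr_max, min_fold)$gene
  )))
  sig_atlas <- unique(atlas$gene[atlas$significant])
  universe <- intersect(sig_prof, sig_atlas)

  res <- purrr::map_dfr(profiles, function(p) {
    purrr::map_dfr(tissues, function(t) {
      suppressWarnings(correlate(p, atlas, t, genes = universe))
    })
  })
  res$significant <- !is.na(res$z) & abs(res$z) >= z_min

  rmat <- res |>
    dplyr::select("tf", "tissue", "r") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "r") |>
    tibble::column_to_rownames("tf") |>
    as.matrix()
  rmat[is.na(rmat)] <- 0

  order_by_clust <- function(m) {
    if (nrow(m) < 3) return(rownames(m))
    d <- as.dist(1 - suppressWarnings(cor(t(m))))
    d[is.na(d)] <- 1
    rownames(m)[hclust(d, method = "average")$order]
  }
  structure(
    list(
      results = res,
      tf_order = order_by_clust(rmat),
      tissue_order = order_by_clust(t(rmat)),
      genes = universe
    ),
    class = "correlation_matrix"
  )
}
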