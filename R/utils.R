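# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Expression tibbles are wide: first column `gene`, remaining columns samples.
expr_genes <- function(expr) expr[["gene"]]

expr_samples <- function(expr) setdiff(names(expr), "gene")

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(m) <- expr[["gene"]]
  storage.mode(m) <- "double"
  m
}

check_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || !"gene" %in% names(expr)) {
    abort(sprintf("`%s` must be a data frame with a `gene` column.", arg))
  }
  if (anyDuplicated(expr[["gene"]])) {
    abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  m <- expr_matrix(expr)
  if (!all(is.finite(m))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(expr)
}

check_sample_table <- function(samples, expr = NULL) {
  need <- c("sample_id", "tf", "condition", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("Sample table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- setdiff(samples$condition, c("induced", "control"))
  if (length(bad)) {
    abort(paste0("`condition` must be 'induced' or 'control'; found: ",
                 paste(unique(bad), collapse = ", ")))
  }
  if (!is.null(expr)) {
    absent <- setdiff(samples$sample_id, expr_samples(expr))
    if (length(absent)) {
      abort(paste0("Sample(s) in table but not in matrix: ",
                   paste(absent, collapse = ", ")))
    }
  }
  invisible(samples)
}

# Welch two-sample t-test, vectorised over rows of two matrices.
# Variances are floored to avoid zero-variance degeneracy on replicated
# values; returns NA p-values when either group has < 2 columns.
welch_rows <- function(x, y, var_floor = 1e-4) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  if (n1 < 2 || n2 < 2) {
    return(list(estimate = m1 - m2, p = rep(NA_real_, nrow(x))))
  }
  v1 <- pmax(apply(x, 1, stats::var), var_floor)
  v2 <- pmax(apply(y, 1, stats::var), var_floor)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(estimate = m1 - m2, p = 2 * pt(-abs(tt), df))
}
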