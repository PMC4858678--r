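new_gene_set_collection <- function(tbl, source = "custom") {
  stopifnot(all(c("set", "description", "genes") %in% names(tbl)))
  tbl$genes <- purrr::map(tbl$genes, ~ toupper(as.character(.x)))
  structure(tibble::as_tibble(tbl), source = source,
            class = c("gene_set_collection", class(tibble::tibble())))
}

#' Read a gene-set collection from a GMT file
#'
#' GMT files carry one named gene set per line: set name, description, then
#' the member symbols, all tab-separated. Symbols are uppercased on read so
#' matching against expression data is case-insensitive.
#'
#' @param path Path to a GMT file.
#' @param source Label for the collection (e.g. "GO", "GAD", "targets").
#' @return A `gene_set_collection`: tibble with `set`, `description` and a
#'   `genes` list-column.
#' @export
read_gmt <- function(path, source = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort(sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields.",
                  short[1]))
  }
  tbl <- tibble::tibble(
    set = purrr::map_chr(parts, 1),
    description = purrr::map_chr(parts, 2),
    genes = purrr::map(parts, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
  )
  if (anyDuplicated(tbl$set)) {
    abort(paste0("Duplicate set name(s) in GMT: ",
                 paste(unique(tbl$set[duplicated(tbl$set)]), collapse = ", ")))
  }
  empty <- lengths(tbl$genes) == 0
  if (any(empty)) {
    warn(sprintf("Skipping %d empty gene set(s).", sum(empty)))
    tbl <- tbl[!empty, , drop = FALSE]
  }
  new_gene_set_collection(tbl, source = source)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$set, collection$description, collection$genes),
    function(s, d, g) paste(c(s, d, g), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' PAGE z-score of one gene set
#'
#' Parametric Analysis of Gene set Enrichment: the set's mean score among the
#' analyzed genes, `Sm`, is compared to the background score distribution
#' (mean `mu`, SD `delta`) through `z = (Sm - mu) * sqrt(m) / delta`, where
#' `m` is the number of set members among the analyzed genes. Under the null
#' that members are an exchangeable draw from the background, z is
#' approximately standard normal for moderate m.
#'
#' @param scores Named numeric vector: per-gene scores (logratios) of the
#'   analyzed genes; names are gene symbols.
#' @param members Character vector of set member symbols.
#' @param background Numeric vector defining the background distribution;
#'   defaults to `scores` itself.
#' @param m_min Minimum overlap for a testable set (default 5).
#' @return One-row tibble: `m`, `Sm`, `mu`, `delta`, `z`, `tested`.
#' @export
#' @examples
#' sc <- setNames(rnorm(100), paste0("G", 1:100))
#' page_z(sc, paste0("G", 1:20))
page_z <- function(scores, members, background = NULL, m_min = 5) {
  if (is.null(names(scores))) abort("`scores` must be a named vector.")
  background <- background %||% scores
  mu <- mean(background)
  delta <- sd(background)
  hit <- intersect(toupper(names(scores)), toupper(members))
  m <- length(hit)
  if (m < m_min || !is.finite(delta) || delta == 0) {
    return(tibble::tibble(m = m, Sm = NA_real_, mu = mu, delta = delta,
                          z = NA_real_, tested = FALSE))
  }
  Sm <- mean(scores[match(hit, toupper(names(scores)))])
  tibble::tibble(m = m, Sm = Sm, mu = mu, delta = delta,
                 z = (Sm - mu) * sqrt(m) / delta, tested = TRUE)
}

#' PAGE enrichment of a collection against an induction profile
#'
#' Applies PAGE separately to the upregulated genes (top `fraction` of genes
#' sorted by logratio) and the downregulated genes (bottom `fraction`).
#' Within each pass, every set is scored by [page_z()] against a common
#' background; one-sided p-values (upper tail for the up pass, lower tail
#' for the down pass) are Benjamini-Hochberg corrected across sets within
#' the pass. Ties at the quartile boundary are broken by gene id so the
#' analyzed fraction is deterministic.
#'
#' The background defaults to the analyzed fraction itself: when scores are
#' restricted to the top (or bottom) quartile, comparing overlap means to
#' the whole-distribution mean would flag every random set as enriched
#' simply because its in-quartile members were selected for extreme scores.
#' The whole-distribution background remains available via
#' `background = "all"` for uses where `scores` are not truncated.
#'
#' @param profile An induction profile.
#' @param collection A `gene_set_collection`.
#' @param fraction Fraction of genes analyzed per direction (default 0.25;
#'   quartile size `ceiling(fraction * N)`).
#' @param background `"analyzed"` (default) computes mu/delta over the
#'   analyzed fraction's logratios; `"all"` uses every gene's logratio.
#' @param m_min Minimum overlap for a testable set.
#' @return Tibble: `set`, `direction`, `m`, `Sm`, `mu`, `delta`, `z`, `p`,
#'   `fdr`, `tested`.
#' @export
enrich_collection <- function(profile, collection, fraction = 0.25,
                              background = c("analyzed", "all"), m_min = 5) {
  background <- match.arg(background)
  if (nrow(collection) == 0) {
    return(tibble::tibble(set = character(), direction = character(),
                          m = integer(), Sm = double(), mu = double(),
                          delta = double(), z = double(), p = double(),
                          fdr = double(), tested = logical()))
  }
  N <- nrow(profile)
  if (N < ceiling(4 / fraction)) {
    abort("Profile has too few genes for the requested fraction.")
  }
  ord <- order(-profile$logratio, profile$gene)
  k <- ceiling(fraction * N)
  all_scores <- setNames(profile$logratio, toupper(profile$gene))
  passes <- list(
    up = all_scores[ord[seq_len(k)]],
    down = all_scores[ord[seq(N - k + 1, N)]]
  )
  purrr::imap_dfr(passes, function(scores, dir) {
    bg <- if (background == "all") all_scores else scores
    res <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
      page_z(scores, collection$genes[[i]], background = bg, m_min = m_min)
    })
    res <- dplyr::bind_cols(
      tibble::tibble(set = collection$set, direction = dir), res
    )
    res$p <- ifelse(res$tested,
                    if (dir == "up") pnorm(-res$z) else pnorm(res$z),
                    NA_real_)
    res$fdr <- NA_real_
    res$fdr[res$tested] <- p.adjust(res$p[res$tested], method = "BH")
    res
  })
}
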