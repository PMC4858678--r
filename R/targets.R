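#' Expected proportion of false positives within a candidate set
#'
#' Candidates (typically the TF-bound genes) are ranked by ascending p-value;
#' the raw value at rank r is `p(r) * n_candidates / r`, made monotone
#' non-decreasing in rank by a cumulative minimum taken from the largest rank
#' downwards. This is a step-up q-value computed within the candidate subset:
#' calling every candidate with EPFP below a cutoff keeps the expected
#' proportion of false positives among the calls below that cutoff.
#'
#' @param profile An induction profile (supplies per-gene p-values).
#' @param candidate_genes Character vector of candidate genes; must be a
#'   subset of the profile's genes.
#' @return Tibble ordered by ascending p: `gene`, `p`, `rank`, `epfp`.
#' @export
epfp <- function(profile, candidate_genes) {
  if (length(candidate_genes) == 0) {
    return(tibble::tibble(gene = character(), p = double(),
                          rank = integer(), epfp = double()))
  }
  missing <- setdiff(candidate_genes, profile$gene)
  if (length(missing)) {
    abort(paste0("Candidate gene(s) absent from the profile: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  p <- setNames(profile$p, profile$gene)[candidate_genes]
  if (anyNA(p)) abort("Profile has no p-values for some candidates.")
  n <- length(p)
  ord <- order(p, candidate_genes)
  raw <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(pmin(raw, 1))))
  tibble::tibble(gene = candidate_genes[ord], p = unname(p[ord]),
                 rank = seq_len(n), epfp = unname(q))
}

#' Call directly regulated target genes
#'
#' A bound gene is called a regulated target when its EPFP (computed within
#' the bound-gene candidate set, or genome-wide with `genomewide = TRUE`) is
#' at most `epfp_max`, its expression change is at least `min_fold`-fold,
#' and its logratio sign matches `direction` (upregulation by default).
#'
#' @param profile An induction profile.
#' @param bound A [bound_gene_sets()] result.
#' @param epfp_max EPFP threshold (inclusive; default 0.5).
#' @param min_fold Fold-change threshold (inclusive; default 1.5).
#' @param direction `"up"` or `"down"`.
#' @param genomewide Compute EPFP over all profile genes instead of within
#'   the bound set.
#' @return A `target_calls` tibble: `gene`, `logratio`, `fold`, `p`, `epfp`,
#'   `bound_class`, `regulated`.
#' @export
call_targets <- function(profile, bound, epfp_max = 0.5, min_fold = 1.5,
                         direction = c("up", "down"), genomewide = FALSE) {
  direction <- match.arg(direction)
  cand <- intersect(bound$gene, profile$gene)
  if (length(cand) == 0) {
    warn("No bound genes overlap the profile; no targets called.")
    return(structure(
      tibble::tibble(gene = character(), logratio = double(),
                     fold = double(), p = double(), epfp = double(),
                     bound_class = character(), regulated = logical()),
      tf = attr(profile, "tf"),
      class = c("target_calls", class(tibble::tibble()))
    ))
  }
  universe <- if (genomewide) profile$gene else cand
  q <- epfp(profile, universe)
  out <- profile |>
    dplyr::filter(.data$gene %in% cand) |>
    dplyr::select("gene", "logratio", "fold", "p") |>
    dplyr::left_join(q[, c("gene", "epfp")], by = "gene") |>
    dplyr::left_join(
      dplyr::transmute(
        bound, gene = .data$gene,
        bound_class = dplyr::case_when(
          .data$promoter & .data$enhancer ~ "both",
          .data$promoter ~ "promoter",
          TRUE ~ "enhancer"
        )
      ),
      by = "gene"
    ) |>
    dplyr::mutate(
      regulated = .data$epfp <= epfp_max & .data$fold >= min_fold &
        (if (direction == "up") .data$logratio > 0 else .data$logratio < 0)
    ) |>
    dplyr::arrange(.data$epfp, .data$gene)
  structure(tibble::as_tibble(out), tf = attr(profile, "tf"),
            class = c("target_calls", class(tibble::tibble())))
}

#' Sliding-window rank plot of bound-gene density
#'
#' Genes are sorted by expression change (logratio, descending); the curve
#' gives, for every window of `window` consecutive ranks, the proportion of
#' window genes bound by the TF. Enrichment of binding among the most
#' upregulated genes appears as an elevated left end of the curve.
#'
#' @param profile An induction profile.
#' @param bound_genes Character vector of bound genes (e.g.
#'   `bound$gene`).
#' @param window Window size in genes (default 300, minimum 10).
#' @param step Step between reported window positions (default 1).
#' @return A `rank_plot_curve` tibble: `position` (rank of the window's
#'   first gene), `center`, `prop`.
#' @export
rank_plot <- function(profile, bound_genes, window = 300, step = 1) {
  N <- nrow(profile)
  if (window < 10) abort("`window` must be at least 10.")
  if (window > N) abort("`window` exceeds the number of genes.")
  ord <- order(-profile$logratio, profile$gene)
  bound_ind <- as.integer(profile$gene[ord] %in% bound_genes)
  cs <- c(0L, cumsum(bound_ind))
  starts <- seq(1L, N - window + 1L, by = step)
  prop <- (cs[starts + window] - cs[starts]) / window
  structure(
    tibble::tibble(position = starts,
                   center = starts + (window - 1) / 2,
                   prop = prop),
    window = window, n_genes = N, n_bound = sum(bound_ind),
    tf = attr(profile, "tf"),
    class = c("rank_plot_curve", class(tibble::tibble()))
  )
}

#' PAGE test of binding enrichment among induced genes
#'
#' Scores the promoter-bound and enhancer-bound gene sets of a TF as a
#' two-set collection with [enrich_collection()], giving a PAGE z and FDR
#' per class and direction. This is the statistical companion of
#' [rank_plot()].
#'
#' @param profile An induction profile.
#' @param bound A [bound_gene_sets()] result.
#' @param fraction Analyzed fraction per direction (default 0.25).
#' @param m_min Minimum overlap for a testable class.
#' @return Tibble as from [enrich_collection()], sets `"promoter"` and
#'   `"enhancer"`.
#' @export
binding_enrichment_test <- function(profile, bound, fraction = 0.25,
                                    m_min = 5) {
  sets <- list(promoter = bound$gene[bound$promoter],
               enhancer = bound$gene[bound$enhancer])
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) {
    warn("Both bound-gene classes are empty; nothing to test.")
    return(enrich_collection(profile,
                             new_gene_set_collection(tibble::tibble(
                               set = character(), description = character(),
                               genes = list()))))
  }
  coll <- new_gene_set_collection(tibble::tibble(
    set = names(sets),
    description = paste0(attr(bound, "tf") %||% "TF", " bound genes"),
    genes = unname(sets)
  ), source = "targets")
  enrich_collection(profile, coll, fraction = fraction, m_min = m_min)
}
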