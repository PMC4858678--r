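#' Simulate a TF-induction expression experiment with planted truth
#'
#' Generates a gene-by-sample matrix of log10 intensities for `n_tfs`
#' inducible lines, each profiled in `reps_per_condition` induced (Dox-) and
#' control (Dox+) replicate wells. Baseline log10 intensities are drawn from
#' N(2.5, 0.7); for each TF a random `frac_affected` of genes receive a true
#' effect whose magnitude is `effect_floor` plus an exponential tail (mean
#' absolute effect `effect_loc`) with random sign, added to the induced wells
#' only. Replicate noise is N(0, `noise_sd`) in every well.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (tibble: `gene` column plus one column per
#'   sample, log10 intensities), `samples` (tibble: `sample_id`, `tf`,
#'   `condition`, `replicate`, `batch`), and `truth` (a `synthetic_truth`
#'   list with `$effects` — tibble of the planted nonzero effects — and
#'   `$tissue_alignment` mapping each TF to its correlated tissue).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 300, n_tfs = 2, seed = 1))
#' dim(sim$expr)
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  tissues <- sprintf("TISSUE%02d", seq_len(config$n_tissues))

  baseline <- rnorm(config$n_genes, mean = 2.5, sd = 0.7)
  n_aff <- round(config$n_genes * config$frac_affected)
  rate <- 1 / (config$effect_loc - config$effect_floor)

  effects <- purrr::map_dfr(tfs, function(tf) {
    if (n_aff == 0) {
      return(tibble::tibble(tf = character(), gene = character(),
                            effect = double()))
    }
    hit <- sample(genes, n_aff)
    mag <- config$effect_floor + rexp(n_aff, rate = rate)
    sgn <- sample(c(-1, 1), n_aff, replace = TRUE)
    tibble::tibble(tf = tf, gene = hit, effect = sgn * mag)
  })

  reps <- config$reps_per_condition
  samples <- tidyr::expand_grid(
    tf = tfs,
    condition = c("induced", "control"),
    replicate = seq_len(reps)
  ) |>
    dplyr::mutate(
      sample_id = paste(.data$tf, substr(.data$condition, 1, 3),
                        .data$replicate, sep = "_"),
      batch = "b1"
    ) |>
    dplyr::select("sample_id", "tf", "condition", "replicate", "batch")

  eff_mat <- matrix(0, nrow = config$n_genes, ncol = config$n_tfs,
                    dimnames = list(genes, tfs))
  if (nrow(effects)) {
    eff_mat[cbind(effects$gene, effects$tf)] <- effects$effect
  }

  vals <- matrix(NA_real_, nrow = config$n_genes, ncol = nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline
    if (samples$condition[j] == "induced") {
      mu <- mu + eff_mat[, samples$tf[j]]
    }
    vals[, j] <- mu + rnorm(config$n_genes, sd = config$noise_sd)
  }

  truth <- structure(
    list(
      effects = effects,
      tissue_alignment = tibble::tibble(tf = tfs,
                                        tissue = tissues[seq_along(tfs)]),
      bound_genes = tibble::tibble(tf = character(), gene = character(),
                                   class = character())
    ),
    class = "synthetic_truth"
  )

  list(
    expr = dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::as_tibble(vals)),
    samples = samples,
    truth = truth
  )
}

#' Simulate transcript models for the synthetic genome
#'
#' Lays genes out on synthetic chromosomes (100 genes per chromosome, TSSs
#' 200 kb apart) so that peak-to-gene attribution is unambiguous unless
#' deliberately confounded. One transcript per gene; 20% of transcripts are
#' given `symbol_score = 1` (clone/predicted-like symbols), the rest
#' `symbol_score = 3` (valid symbols), exercising the symbol-score rule of
#' peak annotation.
#'
#' @param config A [sim_config()].
#' @return Tibble with `transcript_id`, `chrom`, `strand`, `tss` (0-based),
#'   `symbol`, `symbol_score`.
#' @export
simulate_transcript_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_genes
  i <- seq_len(n)
  models <- tibble::tibble(
    transcript_id = sprintf("TX%05d", i),
    chrom = paste0("chr", 1L + (i - 1L) %/% 100L),
    strand = rep_len(c("+", "-"), n),
    tss = 150000L + ((i - 1L) %% 100L) * 200000L,
    symbol = sprintf("GENE%05d", i),
    symbol_score = ifelse(runif(n) < 0.2, 1L, 3L)
  )
  models
}

#' Simulate a tissue-expression atlas aligned with planted TF effects
#'
#' Builds replicate-level log10 intensities for `n_tissues` tissues. Each TF
#' is aligned with one tissue: that tissue's expression is shifted by
#' `alignment_strength` times the TF's planted effects, so the tissue
#' signature correlates positively with the induction profile. Unaligned
#' tissues receive their own random marker genes (fraction `frac_marker`,
#' shifts at least 2-fold) so the atlas has tissue-specific structure of its
#' own.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element returned by [simulate_experiment()].
#' @return A list with `expr` (tibble: `gene` plus one column per
#'   tissue-replicate) and `samples` (tibble: `sample_id`, `tissue`,
#'   `replicate`).
#' @export
simulate_atlas <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  if (config$n_tissues < nrow(truth$tissue_alignment)) {
    abort("`n_tissues` is smaller than the number of requested TF-tissue alignments.")
  }
  set.seed(config$seed + 4L)
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  tissues <- sprintf("TISSUE%02d", seq_len(config$n_tissues))
  baseline <- rnorm(config$n_genes, mean = 2.5, sd = 0.7)

  aligned_tf <- setNames(truth$tissue_alignment$tf,
                         truth$tissue_alignment$tissue)
  shift <- matrix(0, nrow = config$n_genes, ncol = config$n_tissues,
                  dimnames = list(genes, tissues))
  n_marker <- round(config$n_genes * config$frac_marker)
  for (t in tissues) {
    if (!is.na(aligned_tf[t])) {
      eff <- dplyr::filter(truth$effects, .data$tf == aligned_tf[[t]])
      if (nrow(eff)) {
        shift[eff$gene, t] <- config$alignment_strength * eff$effect
      }
    } else if (n_marker > 0) {
      mk <- sample(genes, n_marker)
      mag <- log10(2) + rexp(n_marker, rate = 1 / 0.3)
      shift[mk, t] <- sample(c(-1, 1), n_marker, replace = TRUE) * mag
    }
  }

  samples <- tidyr::expand_grid(tissue = tissues,
                                replicate = seq_len(config$atlas_reps)) |>
    dplyr::mutate(sample_id = paste0(.data$tissue, "_r", .data$replicate)) |>
    dplyr::select("sample_id", "tissue", "replicate")

  vals <- matrix(NA_real_, nrow = config$n_genes, ncol = nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    vals[, j] <- baseline + shift[, samples$tissue[j]] +
      rnorm(config$n_genes, sd = config$noise_sd)
  }

  list(
    expr = dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::as_tibble(vals)),
    samples = samples
  )
}

#' Simulate per-sample ChIP-seq peak files with planted binding
#'
#' For each TF, a fraction `frac_bound` of its upregulated effect genes
#' receives a planted peak: with probability `promoter_frac` the peak
#' midpoint is placed < 500 bp from the gene's TSS (promoter class),
#' otherwise in the 500 bp - 50 kb band (enhancer class). Planted peaks are
#' replicated (with small coordinate jitter) in all `n_peak_samples` samples;
#' decoy peaks are placed > 50 kb from every TSS and appear in a single
#' sample each, so they drop out of cross-sample matching and of the 50 kb
#' annotation window.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [simulate_experiment()].
#' @param models Transcript models from [simulate_transcript_models()].
#' @return A list with `peaks` (tibble: `tf`, `sample_id`, `chrom`, `start`,
#'   `end`, `name`, `score`; 0-based half-open) and `truth` (updated with
#'   `$bound_genes`: tibble of `tf`, `gene`, `class`).
#' @export
simulate_peaks <- function(config, truth, models) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 3L)
  width <- config$peak_width_bp
  tfs <- unique(truth$tissue_alignment$tf)
  mod_by_symbol <- models |> dplyr::distinct(.data$symbol, .keep_all = TRUE)

  all_peaks <- list()
  bound <- list()
  for (tf in tfs) {
    up <- dplyr::filter(truth$effects, .data$tf == .env$tf, .data$effect > 0)
    n_bound <- round(config$frac_bound * nrow(up))
    planted <- if (n_bound > 0) sample(up$gene, n_bound) else character()
    cls <- character(0)
    mids <- integer(0)
    chroms <- character(0)
    if (n_bound > 0) {
      mm <- mod_by_symbol[match(planted, mod_by_symbol$symbol), ]
      if (anyNA(mm$tss)) {
        abort("Planted bound gene missing from transcript models.")
      }
      is_prom <- runif(n_bound) < config$promoter_frac
      d <- ifelse(is_prom,
                  floor(runif(n_bound, 0, 451)),
                  floor(runif(n_bound, 600, 45001)))
      sgn <- sample(c(-1L, 1L), n_bound, replace = TRUE)
      mids <- as.integer(mm$tss + sgn * d)
      chroms <- mm$chrom
      cls <- ifelse(is_prom, "promoter", "enhancer")
      bound[[tf]] <- tibble::tibble(tf = tf, gene = planted, class = cls)
    }

    # decoys: midway between adjacent TSSs, >50 kb from every TSS
    n_decoy <- max(20L, n_bound)
    per_sample <- list()
    for (s in seq_len(config$n_peak_samples)) {
      jit <- if (n_bound > 0) {
        as.integer(floor(runif(n_bound, -20, 21)))
      } else integer(0)
      pl <- if (n_bound > 0) {
        tibble::tibble(
          chrom = chroms,
          start = mids + jit - width %/% 2L,
          end = mids + jit + width %/% 2L,
          score = round(runif(n_bound, 50, 200), 1)
        )
      } else NULL
      di <- sample(seq_len(nrow(models)), n_decoy, replace = TRUE)
      dmid <- as.integer(models$tss[di] + 100000L)
      dc <- tibble::tibble(
        chrom = models$chrom[di],
        start = dmid - width %/% 2L,
        end = dmid + width %/% 2L,
        score = round(runif(n_decoy, 5, 100), 1)
      )
      # decoys are sample-specific: keep each in one sample only
      dc <- dc[((di + s) %% config$n_peak_samples) == 0L, , drop = FALSE]
      ps <- dplyr::bind_rows(pl, dc)
      if (any(ps$start < 0)) {
        abort("Chromosome too short to place a requested peak.")
      }
      ps$sample_id <- paste0(tf, "_s", s)
      ps$tf <- tf
      per_sample[[s]] <- ps
    }
    all_peaks[[tf]] <- dplyr::bind_rows(per_sample)
  }

  peaks <- dplyr::bind_rows(all_peaks) |>
    dplyr::group_by(.data$tf) |>
    dplyr::mutate(name = paste0(.data$tf, "_pk", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("tf", "sample_id", "chrom", "start", "end", "name", "score")

  truth$bound_genes <- if (length(bound)) {
    dplyr::bind_rows(bound)
  } else {
    tibble::tibble(tf = character(), gene = character(), class = character())
  }
  list(peaks = peaks, truth = truth)
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds one set per TF drawn from that TF's upregulated planted effect
#' genes (so the set is truly enriched among induced genes) plus `n_random`
#' sets drawn uniformly from the gene universe (true nulls).
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [simulate_experiment()].
#' @param set_size Target number of genes per set.
#' @param n_random Number of null sets.
#' @return A `gene_set_collection` (see [read_gmt()]).
#' @export
simulate_gene_sets <- function(config, truth, set_size = 30, n_random = 10) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 5L)
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  planted <- truth$effects |>
    dplyr::filter(.data$effect > 0) |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(genes = list(sample(.data$gene,
                                         min(set_size, dplyr::n()))),
                     .groups = "drop") |>
    dplyr::transmute(set = paste0(.data$tf, "_planted_up"),
                     description = "planted", genes = .data$genes)
  random <- tibble::tibble(
    set = sprintf("RANDOM%02d", seq_len(n_random)),
    description = "null",
    genes = purrr::map(seq_len(n_random), ~ sample(genes, set_size))
  )
  new_gene_set_collection(dplyr::bind_rows(planted, random),
                          source = "synthetic")
}
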