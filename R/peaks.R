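#' Read ChIP-seq peaks from BED or narrowPeak files
#'
#' Accepts BED3/BED5 (score in column 5) or ENCODE narrowPeak (signal value
#' in column 7). Coordinates are 0-based half-open as in BED.
#'
#' @param path Path to a peak file.
#' @param sample_id Sample label attached to every peak; defaults to the file
#'   name without extension.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param score_col Override the 1-based column holding the score.
#' @return Tibble: `chrom`, `start`, `end`, `name`, `score`, `sample_id`.
#' @export
read_peaks <- function(path, sample_id = NULL,
                       format = c("bed", "narrowPeak"), score_col = NULL) {
  format <- match.arg(format)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  tbl <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 3) abort("Peak file needs at least 3 columns (chrom, start, end).")
  score_col <- score_col %||% if (format == "narrowPeak") 7L else 5L
  score <- if (ncol(tbl) >= score_col) as.numeric(tbl[[score_col]]) else 0
  out <- tibble::tibble(
    chrom = as.character(tbl[[1]]),
    start = as.integer(tbl[[2]]),
    end = as.integer(tbl[[3]]),
    name = if (ncol(tbl) >= 4) as.character(tbl[[4]]) else
      paste0(sample_id, "_", seq_len(nrow(tbl))),
    score = score,
    sample_id = sample_id
  )
  if (any(out$start >= out$end)) {
    abort("Peak file has intervals with start >= end.")
  }
  out
}

#' Write peaks as BED5
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  readr::write_tsv(peaks[, c("chrom", "start", "end", "name", "score")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read transcript models from a refFlat-like TSV
#'
#' Expected columns: `transcript_id`, `chrom`, `strand`, `tss` (0-based),
#' `symbol`, `symbol_score` (3 for valid gene symbols, 1 for clones and
#' predicted genes).
#'
#' @param path Path to the TSV (with header).
#' @return Transcript-model tibble.
#' @export
read_transcript_models <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("transcript_id", "chrom", "strand", "tss", "symbol", "symbol_score")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("Transcript table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(tbl$symbol_score %in% c(1L, 3L))) {
    abort("`symbol_score` must be 1 or 3.")
  }
  if (any(tbl$tss < 0)) abort("`tss` must be >= 0.")
  tbl
}

#' Filter peaks by score
#'
#' Peaks with low scores are filtered out; a peak is retained when its score
#' is at least `min_score` (the threshold is the lowest retained score).
#'
#' @param peaks Peak tibble.
#' @param min_score Minimum retained score.
#' @return Filtered peak tibble.
#' @export
filter_by_score <- function(peaks, min_score = 0) {
  dplyr::filter(peaks, .data$score >= min_score)
}

#' Consensus peaks supported by multiple samples
#'
#' Groups peaks from replicate samples into connected components of the
#' at-least-1-bp overlap graph (a chain A-B, B-C lands in one component even
#' if A and C do not touch) and emits one consensus peak per component that
#' spans at least `min_samples` distinct samples. The consensus interval is
#' the union of the members; the consensus score is the maximum member score.
#'
#' @param peaks Peak tibble with `sample_id`.
#' @param min_samples Minimum number of distinct supporting samples.
#' @return Tibble: `peak_id`, `chrom`, `start`, `end`, `score`, `n_samples`,
#'   `n_peaks`.
#' @export
match_across_samples <- function(peaks, min_samples = 2) {
  n_avail <- dplyr::n_distinct(peaks$sample_id)
  if (min_samples > n_avail) {
    abort(sprintf("min_samples = %d exceeds the %d available sample(s).",
                  min_samples, n_avail))
  }
  per_chrom <- split(peaks, peaks$chrom)
  out <- purrr::map_dfr(per_chrom, function(pk) {
    ir <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    # overlapping-only merge: min.gapwidth = 0 keeps bookended intervals apart
    comp <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, comp)
    pk$component <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    pk |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(
        chrom = dplyr::first(.data$chrom),
        start = min(.data$start),
        end = max(.data$end),
        score = max(.data$score),
        n_samples = dplyr::n_distinct(.data$sample_id),
        n_peaks = dplyr::n(),
        .groups = "drop"
      )
  })
  out <- out |>
    dplyr::filter(.data$n_samples >= min_samples) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(peak_id = paste0("cons_", dplyr::row_number())) |>
    dplyr::select("peak_id", "chrom", "start", "end", "score",
                  "n_samples", "n_peaks")
  out
}

#' Score a transcript for a peak
#'
#' A transcript's score for a peak is its symbol score (3 for valid symbols,
#' 1 for clones/predicted genes) divided by the peak-midpoint-to-TSS
#' distance in kb, with distances below 1 kb counted as 1 kb. Transcripts on
#' a different chromosome are not candidates (score `NA`).
#'
#' @param peak One-row peak tibble (`chrom`, `start`, `end`).
#' @param transcript One-row transcript tibble (`chrom`, `tss`,
#'   `symbol_score`).
#' @return Numeric score `S = symbol_score / max(d_kb, 1)`.
#' @export
#' @examples
#' pk <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1400L)
#' tx <- tibble::tibble(chrom = "chr1", tss = 1500L, symbol_score = 3L)
#' score_transcript(pk, tx)  # d = 300 bp -> 3 / 1 = 3
score_transcript <- function(peak, transcript) {
  if (peak$chrom[1] != transcript$chrom[1]) return(NA_real_)
  mid <- peak_midpoint(peak$start[1], peak$end[1])
  d <- abs(mid - transcript$tss[1])
  transcript$symbol_score[1] / pmax(d, 1000) * 1000
}

# midpoint of a 0-based half-open interval
peak_midpoint <- function(start, end) (start + end) / 2

#' Assign consensus peaks to transcripts
#'
#' For each peak, transcripts on the same chromosome with midpoint-to-TSS
#' distance below 50 kb are candidates, scored as in [score_transcript()].
#' The highest-scoring transcript is assigned (ties broken by transcript
#' id); the runner-up is also assigned iff its score exceeds 25% of the top
#' score (strict). Assignments are classed as promoter (d < 500 bp) or
#' enhancer (500 bp <= d < 50 kb). Peaks with no candidate are unannotated
#' and absent from the output.
#'
#' @param peaks Consensus-peak tibble (`peak_id`, `chrom`, `start`, `end`).
#' @param models Transcript-model tibble.
#' @param max_dist Candidate window around the TSS in bp (default 50000).
#' @param second_frac Fraction of the top score the second transcript must
#'   exceed (default 0.25).
#' @return Tibble: `peak_id`, `chrom`, `start`, `end`, `rank`,
#'   `transcript_id`, `symbol`, `distance`, `S`, `class`.
#' @export
assign_peaks <- function(peaks, models, max_dist = 50000,
                         second_frac = 0.25) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(peak_id = character(), chrom = character(),
                          start = integer(), end = integer(), rank = integer(),
                          transcript_id = character(), symbol = character(),
                          distance = double(), S = double(),
                          class = character()))
  }
  peaks$mid <- peak_midpoint(peaks$start, peaks$end)
  cand <- dplyr::inner_join(
    peaks[, c("peak_id", "chrom", "start", "end", "mid")],
    models[, c("transcript_id", "chrom", "tss", "symbol", "symbol_score")],
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = abs(.data$mid - .data$tss)) |>
    dplyr::filter(.data$distance < max_dist) |>
    dplyr::mutate(S = .data$symbol_score / pmax(.data$distance, 1000) * 1000)

  cand |>
    dplyr::arrange(.data$peak_id, dplyr::desc(.data$S), .data$transcript_id) |>
    dplyr::group_by(.data$peak_id) |>
    dplyr::slice_head(n = 2) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank == 1 | .data$S > second_frac * dplyr::first(.data$S)) |>
    dplyr::ungroup() |>
    dplyr::mutate(class = ifelse(.data$distance < 500, "promoter", "enhancer")) |>
    dplyr::select("peak_id", "chrom", "start", "end", "rank",
                  "transcript_id", "symbol", "distance", "S", "class")
}

#' Bound-gene sets from peak assignments
#'
#' A gene is promoter-bound if any assignment to it is promoter-class, and
#' enhancer-bound likewise; a gene may be both.
#'
#' @param assignments An [assign_peaks()] result.
#' @param tf Optional TF label stored as an attribute.
#' @return A `bound_gene_set` tibble: `gene`, `promoter`, `enhancer`
#'   (logicals); `any_genes` is the full `gene` column.
#' @export
bound_gene_sets <- function(assignments, tf = NULL) {
  out <- assignments |>
    dplyr::group_by(gene = .data$symbol) |>
    dplyr::summarise(
      promoter = any(.data$class == "promoter"),
      enhancer = any(.data$class == "enhancer"),
      .groups = "drop"
    )
  structure(out, tf = tf, class = c("bound_gene_set", class(out)))
}
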