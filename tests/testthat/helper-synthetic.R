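# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (loops, enumeration, resampling) so they
# stay independent of the implementation they check.

small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 600, n_tfs = 2, seed = seed, ...)
}

# Build an induction_profile tibble directly from given columns.
make_profile <- function(gene, logratio, p = NULL, fdr = NULL, tf = "TFX") {
  structure(
    tibble::tibble(
      gene = gene,
      logratio = logratio,
      p = p %||% rep(NA_real_, length(gene)),
      fdr = fdr %||% rep(NA_real_, length(gene)),
      fold = 10^abs(logratio),
      direction = ifelse(logratio >= 0, "up", "down")
    ),
    tf = tf, class = c("induction_profile", class(tibble::tibble()))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# wide expression tibble -> numeric matrix with gene rownames
emat <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(m) <- expr$gene
  m
}

new_collection <- function(sets) {
  tfinduce:::new_gene_set_collection(tibble::tibble(
    set = names(sets) %||% character(),
    description = rep("", length(sets)),
    genes = unname(sets)
  ))
}

# Brute-force BH q-values: literal step-up definition.
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(ord == i)  # rank of p[i]
    q[i] <- min(1, min(p[ord][r:n] * n / (r:n)))
  }
  q
}

# Monte-Carlo PAGE null: mean/SD of resampled set means.
page_mc_z <- function(scores, members, background, n_draws = 10000) {
  hit <- intersect(names(scores), members)
  m <- length(hit)
  Sm <- mean(scores[hit])
  draws <- replicate(n_draws, mean(sample(background, m)))
  (Sm - mean(draws)) / sd(draws)
}

# Brute-force consensus grouping: BFS over the >=1 bp overlap graph.
brute_consensus <- function(peaks, min_samples) {
  n <- nrow(peaks)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- peaks$chrom[i] == peaks$chrom[j] &&
        peaks$start[i] < peaks$end[j] && peaks$start[j] < peaks$end[i]
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- lapply(split(seq_len(n), comp), function(idx) {
    data.frame(
      chrom = peaks$chrom[idx[1]],
      start = min(peaks$start[idx]),
      end = max(peaks$end[idx]),
      score = max(peaks$score[idx]),
      n_samples = length(unique(peaks$sample_id[idx]))
    )
  })
  out <- do.call(rbind, out)
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Brute-force peak->transcript assignment: score every transcript, sort.
brute_assign <- function(peaks, models, max_dist = 50000,
                         second_frac = 0.25) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    cand <- models[models$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(mid - cand$tss)
    keep <- d < max_dist
    cand <- cand[keep, , drop = FALSE]; d <- d[keep]
    if (nrow(cand) == 0) next
    S <- cand$symbol_score / pmax(d, 1000) * 1000
    o <- order(-S, cand$transcript_id)
    take <- o[1]
    if (length(o) > 1 && S[o[2]] > second_frac * S[o[1]]) {
      take <- o[1:2]
    }
    rows[[length(rows) + 1]] <- data.frame(
      peak_id = peaks$peak_id[i],
      rank = seq_along(take),
      transcript_id = cand$transcript_id[take],
      symbol = cand$symbol[take],
      distance = d[take],
      S = S[take],
      class = ifelse(d[take] < 500, "promoter", "enhancer")
    )
  }
  do.call(rbind, rows)
}

# Random peak/transcript sets for oracle comparisons.
random_annotation_case <- function(n_peaks, n_models, seed) {
  set.seed(seed)
  chroms <- paste0("chr", 1:4)
  models <- tibble::tibble(
    transcript_id = sprintf("T%04d", seq_len(n_models)),
    chrom = sample(chroms, n_models, replace = TRUE),
    strand = sample(c("+", "-"), n_models, replace = TRUE),
    tss = sample.int(2e6, n_models),
    symbol = sprintf("S%04d", sample.int(n_models, n_models)),
    symbol_score = sample(c(1L, 3L), n_models, replace = TRUE)
  )
  st <- sample.int(2e6, n_peaks)
  peaks <- tibble::tibble(
    peak_id = sprintf("p%04d", seq_len(n_peaks)),
    chrom = sample(chroms, n_peaks, replace = TRUE),
    start = st,
    end = st + sample(100:800, n_peaks, replace = TRUE)
  )
  list(peaks = peaks, models = models)
}
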