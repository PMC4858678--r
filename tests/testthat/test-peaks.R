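pk_tbl <- function(chrom, start, end, sample_id, score = 10) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = paste0("p", seq_along(start)),
                 score = score, sample_id = sample_id)
}

test_that("score filtering keeps the threshold value itself", {
  pk <- pk_tbl("chr1", c(0, 100, 200), c(50, 150, 250), "s1",
               score = c(7, 8, 9))
  expect_equal(filter_by_score(pk, 8)$score, c(8, 9))
  expect_equal(nrow(filter_by_score(pk, 0)), 3)
  expect_equal(nrow(filter_by_score(pk[0, ], 5)), 0)
})

test_that("consensus requires the configured number of distinct samples", {
  same <- pk_tbl(rep("chr1", 3), rep(100, 3), rep(200, 3),
                 c("s1", "s2", "s3"))
  cons <- match_across_samples(same, 3)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 200)

  lone <- dplyr::bind_rows(same,
                           pk_tbl("chr1", 5000, 5100, "s1"))
  cons2 <- match_across_samples(lone, 2)
  expect_equal(nrow(cons2), 1)  # the singleton is dropped

  expect_error(match_across_samples(same, 4), "exceeds")
})

test_that("overlap chains merge transitively; bookended peaks do not", {
  chain <- pk_tbl(rep("chr1", 3), c(100, 180, 260), c(200, 280, 360),
                  c("s1", "s2", "s3"))
  cons <- match_across_samples(chain, 3)
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(100, 360))

  # 0-based half-open: [100,200) and [200,300) share no base
  booked <- pk_tbl(rep("chr1", 2), c(100, 200), c(200, 300), c("s1", "s2"))
  expect_equal(nrow(match_across_samples(booked, 2)), 0)
})

test_that("consensus grouping equals the brute-force overlap-graph oracle", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 60
    st <- sample.int(5000, n)
    pk <- pk_tbl(sample(c("chr1", "chr2"), n, TRUE), st,
                 st + sample(50:400, n, TRUE),
                 sample(paste0("s", 1:3), n, TRUE),
                 score = runif(n, 1, 100))
    for (min_s in 1:3) {
      got <- match_across_samples(pk, min_s)
      want <- brute_consensus(pk, min_s)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$score, want$score)
      expect_equal(got$n_samples, want$n_samples)
    }
  }
})

test_that("transcript scoring applies the 1 kb distance floor", {
  tx <- function(score, tss) tibble::tibble(chrom = "chr1", tss = tss,
                                            symbol_score = score)
  pk <- function(mid) tibble::tibble(chrom = "chr1", start = mid - 200,
                                     end = mid + 200)
  expect_equal(score_transcript(pk(1000), tx(3, 1300)), 3)     # d=300 -> floor
  expect_equal(score_transcript(pk(1000), tx(1, 11000)), 0.1)  # d=10 kb
  expect_equal(score_transcript(pk(1000), tx(3, 2000)), 3)     # d=1 kb exactly
  expect_true(is.na(score_transcript(
    pk(1000), tibble::tibble(chrom = "chr2", tss = 1300, symbol_score = 3))))
})

test_that("second transcript joins only above 25% of the top score", {
  models <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    chrom = "chr1", strand = "+",
    tss = c(1300, NA), symbol = c("A", "B"),
    symbol_score = c(3L, 3L)
  )
  pk <- tibble::tibble(peak_id = "p1", chrom = "chr1",
                       start = 800L, end = 1200L)  # midpoint 1000
  # S1 = 3 (d=300); S2 = 3/d_kb: d = 3750 -> 0.8 -> 26.7% > 25%
  models$tss[2] <- 1000 + 3750
  both <- assign_peaks(pk, models)
  expect_equal(both$transcript_id, c("t1", "t2"))
  # S2 = 3/4 = 0.75 -> exactly 25% of S1, excluded (strict >)
  models$tss[2] <- 1000 + 4000
  one <- assign_peaks(pk, models)
  expect_equal(one$transcript_id, "t1")
  # only candidate beyond 50 kb -> unannotated
  far <- tibble::tibble(transcript_id = "t3", chrom = "chr1", strand = "+",
                        tss = 61000L, symbol = "C", symbol_score = 3L)
  expect_equal(nrow(assign_peaks(pk, far)), 0)
})

test_that("promoter/enhancer classes follow the distance bands", {
  models <- tibble::tibble(
    transcript_id = c("t1", "t2"), chrom = "chr1", strand = "+",
    tss = c(1499L, 90000L), symbol = c("A", "B"), symbol_score = 3L
  )
  pk <- tibble::tibble(peak_id = c("p1", "p2"), chrom = "chr1",
                       start = c(800L, 89300L), end = c(1200L, 89700L))
  res <- assign_peaks(pk, models)
  expect_equal(res$class[res$peak_id == "p1"][1], "promoter")   # d = 499
  expect_equal(res$class[res$peak_id == "p2"][1], "enhancer")   # d = 500
})

test_that("ties in score resolve to the lower transcript id", {
  models <- tibble::tibble(
    transcript_id = c("tB", "tA"), chrom = "chr1", strand = "+",
    tss = c(1200L, 800L), symbol = c("B", "A"), symbol_score = 3L
  )
  pk <- tibble::tibble(peak_id = "p", chrom = "chr1",
                       start = 900L, end = 1100L)  # midpoint 1000, d=200 both
  res <- assign_peaks(pk, models)
  expect_equal(res$transcript_id[1], "tA")
})

test_that("assignment equals the brute-force all-pairs oracle", {
  case <- random_annotation_case(n_peaks = 150, n_models = 120, seed = 9)
  got <- assign_peaks(case$peaks, case$models)
  want <- brute_assign(case$peaks, case$models)
  got <- got[order(got$peak_id, got$rank), ]
  want <- want[order(want$peak_id, want$rank), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$transcript_id, want$transcript_id)
  expect_equal(got$S, want$S, tolerance = 1e-12)
  expect_equal(got$class, want$class)
})

test_that("assignment is invariant under coordinate translation", {
  case <- random_annotation_case(n_peaks = 40, n_models = 40, seed = 10)
  base <- assign_peaks(case$peaks, case$models)
  shift <- 12345L
  pk2 <- dplyr::mutate(case$peaks, start = start + shift, end = end + shift)
  mod2 <- dplyr::mutate(case$models, tss = tss + shift)
  moved <- assign_peaks(pk2, mod2)
  expect_equal(base$transcript_id, moved$transcript_id)
  expect_equal(base$S, moved$S)
  expect_equal(base$class, moved$class)
})

test_that("moving a peak closer to a TSS never lowers that transcript's score", {
  tx <- tibble::tibble(chrom = "chr1", tss = 100000L, symbol_score = 3L)
  d <- seq(49000, 0, by = -700)
  S <- sapply(d, function(dd) {
    score_transcript(tibble::tibble(chrom = "chr1", start = 100000 - dd - 100,
                                    end = 100000 - dd + 100), tx)
  })
  expect_true(all(diff(S) >= 0))
})

test_that("bound-gene sets merge classes per gene", {
  asg <- tibble::tibble(
    peak_id = c("p1", "p2", "p3"), chrom = "chr1",
    start = 1L, end = 2L, rank = 1L,
    transcript_id = c("t1", "t2", "t3"),
    symbol = c("A", "A", "B"),
    distance = c(100, 3000, 200), S = 3,
    class = c("promoter", "enhancer", "promoter")
  )
  bs <- bound_gene_sets(asg, tf = "T1")
  expect_equal(bs$gene, c("A", "B"))
  expect_true(bs$promoter[bs$gene == "A"] && bs$enhancer[bs$gene == "A"])
  expect_false(bs$enhancer[bs$gene == "B"])
  empty <- bound_gene_sets(asg[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("peak files round-trip through BED and narrowPeak score columns", {
  pk <- pk_tbl("chr1", c(10L, 500L), c(200L, 900L), "s1", score = c(5.5, 7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, path)
  back <- read_peaks(path, sample_id = "s1")
  expect_equal(back$start, pk$start)
  expect_equal(back$score, pk$score)
  # narrowPeak: signal in column 7
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t300\tpk1\t0\t.\t42.5\t10\t9\t55", np)
  got <- read_peaks(np, format = "narrowPeak")
  expect_equal(got$score, 42.5)
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t300\t100\tx\t1", bad)
  expect_error(read_peaks(bad), "start >= end")
})
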