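# CLIP pipeline: sites, windows, shuffles, rank statistics.

test_that("IUPAC motif matching inside peaks follows the site rules", {
  tx <- c(t1 = "CCACUGCCACUUCC")
  pk <- data.frame(transcript = "t1", start = 2, end = 12)
  sites <- find_motif_sites(tx, "ACUK", pk)
  expect_identical(sites$start, c(2L, 8L)) # ACUG and ACUU; K = {G, U}
  expect_identical(sites$peak, c(1L, 1L))

  # W = {A, U}: CGGA does not match WGGA
  expect_identical(nrow(find_motif_sites(c(t1 = "CCCGGACC"), "WGGA",
                                         data.frame(transcript = "t1",
                                                    start = 0, end = 8))),
                   0L)
  expect_error(find_motif_sites(tx, "ACZK", pk), "invalid IUPAC")
})

test_that("length <= 2 peaks are widened by 10 nt, others are not", {
  # motif exactly 10 nt right of a single-base peak at position p = 20
  s <- paste0(strrep("C", 30), "ACUG", strrep("C", 30))
  tx <- c(t1 = s)
  hit10 <- data.frame(transcript = "t1", start = 20, end = 21)
  expect_identical(find_motif_sites(tx, "ACUK", hit10)$start, 30L)
  hit11 <- data.frame(transcript = "t1", start = 19, end = 20)
  expect_identical(nrow(find_motif_sites(tx, "ACUK", hit11)), 0L)
  # a wide peak gets no slack
  wide <- data.frame(transcript = "t1", start = 20, end = 25)
  expect_identical(nrow(find_motif_sites(tx, "ACUK", wide)), 0L)
})

test_that("positive windows are cut, offset and truncation-flagged correctly", {
  set.seed(60)
  s <- rand_seq(1000)
  substr(s, 301, 304) <- "ACUG"
  tx <- c(t1 = s)
  sites <- data.frame(transcript = "t1", start = 300L, length = 4L,
                      peak = 1L)
  w <- extract_positive_windows(tx, sites, flank = 200)[[1]]
  expect_identical(nchar(w$seq), 404L)
  expect_identical(w$motif_at, 200L)
  expect_identical(substr(w$seq, 201, 204), "ACUG")
  expect_false(w$truncated)

  sites2 <- data.frame(transcript = "t1", start = 50L, length = 4L,
                       peak = 1L)
  w2 <- extract_positive_windows(tx, sites2, flank = 200)[[1]]
  expect_true(w2$truncated)
  expect_identical(w2$motif_at, 50L)
})

test_that("unbound sites obey the distance rule and exclude bound sites", {
  base <- strrep("C", 3000)
  plant <- function(s, at) { substr(s, at + 1, at + 4) <- "ACUG"; s }
  s <- plant(base, 500)    # bound (inside the peak)
  s <- plant(s, 900)       # within 1000 -> unbound
  s <- plant(s, 2200)      # 1700 away -> excluded under default rule
  s <- plant(s, 520)       # inside the peak but != bound start: bound
  tx <- c(t1 = s)
  peaks <- data.frame(transcript = "t1", start = 495, end = 530)
  bound <- find_motif_sites(tx, "ACUK", peaks)
  expect_setequal(bound$start, c(500L, 520L))
  unb <- build_unbound_dataset(tx, "ACUK", bound, peaks)
  expect_identical(unb$start, 900L)
  unb2 <- build_unbound_dataset(tx, "ACUK", bound, peaks, rule = "beyond")
  expect_identical(unb2$start, 2200L)
})

test_that("dinucleotide shuffling preserves counts, endpoints and edge cases", {
  set.seed(61)
  for (r in 1:200) {
    n <- sample(4:80, 1)
    s <- rand_seq(n)
    sh <- dinuc_shuffle(s)
    expect_true(same_dinucs(s, sh), info = s)
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, n, n), substr(s, n, n))
  }
  expect_identical(dinuc_shuffle("ACG"), "ACG")
  expect_identical(dinuc_shuffle("AAAAAAA"), "AAAAAAA")
  # long sequences do get rearranged
  set.seed(62)
  s <- rand_seq(300)
  expect_false(dinuc_shuffle(s) == s)
})

test_that("shuffled datasets keep the motif (and the partial core) intact", {
  set.seed(63)
  win <- list(make_window(rand_seq(200), 98, 4, 1))
  core <- substr(win[[1]]$seq, 99, 102)
  for (keep in c(0, 5, 10)) {
    sh <- build_shuffled_dataset(win, keep = keep)[[1]]
    expect_identical(nchar(sh$seq), 200L)
    expect_identical(substr(sh$seq, 99, 102), core)
    expect_identical(substr(sh$seq, 99 - keep, 102 + keep),
                     substr(win[[1]]$seq, 99 - keep, 102 + keep))
    # each flank separately preserves its dinucleotides
    a <- 98 - keep
    b <- 102 + keep
    expect_true(same_dinucs(substr(win[[1]]$seq, 1, a),
                            substr(sh$seq, 1, a)))
    expect_true(same_dinucs(substr(win[[1]]$seq, b + 1, 200),
                            substr(sh$seq, b + 1, 200)))
  }
  expect_identical(build_partial_shuffled_dataset(win, keep = 5)[[1]]$motif_at,
                   win[[1]]$motif_at)
})

test_that("one-sided rank-sum p-values match exact enumeration", {
  expect_equal(wmw_one_sided(c(1, 2, 3), c(4, 5, 6), "less"), 0.05,
               tolerance = 1e-12) # 1 of choose(6,3) = 20 orderings
  expect_equal(wmw_one_sided(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05,
               tolerance = 1e-12) # swapping flips the small side
  a <- c(0.1, 0.2, 0.3, 0.4)
  expect_gte(wmw_one_sided(a, a, "greater"), 0.5)
  expect_gte(wmw_one_sided(a, a, "less"), 0.5)
  expect_warning(p <- wmw_one_sided(1, c(1, 2)), "fewer than 2")
  expect_identical(p, 1)
})

test_that("P scores carry the documented sign and magnitude", {
  rel <- -1:2
  mk <- function(v) { # constant across positions/contexts, varying obs
    arr <- array(rep(v, times = length(rel) * 7),
                 c(length(v), length(rel), 7))
    make_dataset(arr, rel)
  }
  lo <- mk(c(1, 2, 3))
  hi <- mk(c(4, 5, 6))
  expect_equal(pscore(hi, lo, 0, "H"), -log10(0.05), tolerance = 1e-9)
  expect_equal(pscore(lo, hi, 0, "H"), log10(0.05), tolerance = 1e-9)
  expect_lte(abs(pscore(lo, lo, 0, "H")), log10(2) + 1e-12)
  expect_error(pscore(lo, hi, 99, "H"), "outside")
  expect_error(pscore(lo, hi, 0, "Q"), "unknown context")
})

test_that("combining the two negatives is conservative", {
  expect_identical(combine_negatives(3.0, 1.2), 1.2)
  expect_identical(combine_negatives(2.0, -1.0), 0)
  expect_identical(combine_negatives(-4.0, -2.5), -2.5)
  expect_identical(combine_negatives(0, 5), 0)
  expect_identical(combine_negatives(c(3, 2, -4), c(1.2, -1, -2.5)),
                   c(1.2, 0, -2.5))
})

test_that("Bonferroni levels and the significance rule", {
  expect_identical(bonferroni_level(0.05, 1), 0.05)
  expect_identical(bonferroni_level(0.05, 250), 2e-4)
  expect_error(bonferroni_level(0.05, 0), "positive integer")
  # a score of 1.0 is not significant at level 2e-4
  expect_lt(1.0, -log10(2e-4))
})

test_that("span-sensitivity ratios", {
  rel <- 0:1
  tr <- function(scores) {
    structure(data.frame(rel_position = rel, context = "U",
                         score = scores, significant = FALSE),
              class = c("pscore_track", "data.frame"), threshold = 3)
  }
  expect_identical(w_sensitivity(tr(c(1, 2)), tr(c(1, 2)), "U"), 1)
  expect_identical(w_sensitivity(tr(c(4, 0)), tr(c(2, 1)), "U"), 2)
  expect_true(is.na(w_sensitivity(tr(c(4, 0)), tr(c(-1, -2)), "U")))
})

test_that("a planted hairpin motif is recovered end to end", {
  fx <- clip_fixture(n_transcripts = 8, transcript_length = 1000,
                     motif = "ACUGGC", context = "H", seed = 5)
  res <- run_clip_pipeline(fx$transcripts, fx$peaks, fx$motif,
                           flank = 200, max_span = 100, window = 8,
                           seed = 1, parameters = test_params())
  tr <- res$track
  motif_rows <- tr$context == "H" & tr$rel_position %in% 0:5
  expect_true(all(tr$score_unbound[motif_rows] > 0))
  expect_true(all(tr$score_shuffled[motif_rows] > 0))
  expect_true(all(tr$score[motif_rows] > 0))
  expect_true(any(tr$significant[motif_rows]))
})
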