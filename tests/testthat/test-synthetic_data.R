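# Synthetic-data generators.

test_that("random sequences respect GC content and are seed-deterministic", {
  s <- random_sequences(3, 50, gc = 1.0, seed = 1)
  expect_true(all(grepl("^[GC]+$", s)))
  s0 <- random_sequences(2, 40, gc = 0.0, seed = 1)
  expect_true(all(grepl("^[AU]+$", s0)))

  long <- random_sequences(1, 1e5, gc = 0.5, seed = 2)
  obs <- mean(strsplit(long[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 1e5))

  expect_identical(random_sequences(5, 100, seed = 9),
                   random_sequences(5, 100, seed = 9))
  expect_false(identical(random_sequences(1, 100, seed = 1),
                         random_sequences(1, 100, seed = 2)))
  expect_error(random_sequences(1, 10, gc = 1.5), "in \\[0, 1\\]")
})

test_that("span sweeps return proper probability rows", {
  par <- test_params()
  seqs <- random_sequences(3, 120, seed = 3)
  df <- w_sweep(seqs, c(4, 30), parameters = par)
  expect_identical(df$W, c(4L, 30L))
  m <- as.matrix(df[, c("B", "E", "H", "I", "M", "S")])
  expect_true(all(m >= 0 & m <= 1))
  expect_lt(max(abs(rowSums(m) - 1)), 1e-6)
  # below the minimum pairable span, everything is exterior
  expect_identical(df$E[1], 1)
  expect_equal(df$U, df$E + df$M, tolerance = 1e-12)
})

test_that("gc sweeps cover the requested grid reproducibly", {
  par <- test_params()
  df <- gc_sweep(c(0.2, 0.8), max_span = 50, n = 4, length = 150, seed = 4,
                 parameters = par)
  expect_identical(df$gc, c(0.2, 0.8))
  expect_lt(max(abs(rowSums(as.matrix(df[, c("B", "E", "H", "I", "M",
                                             "S")])) - 1)), 1e-6)
  # more GC, more stem (large separation, small n keeps this cheap)
  expect_gt(df$S[2], df$S[1])
  expect_identical(df, gc_sweep(c(0.2, 0.8), max_span = 50, n = 4,
                                length = 150, seed = 4, parameters = par))
})

test_that("truncation keeping everything correlates perfectly", {
  par <- test_params()
  df <- truncation_experiment(n_seqs = 2, total_length = 400, core = 100,
                              l_values = c(50, 150), max_span = 50,
                              seed = 5, parameters = par)
  expect_identical(nrow(df), 4L)
  r150 <- df$r[df$l == 150]
  expect_true(all(abs(r150 - 1) < 1e-12)) # l = 150 covers everything
  expect_true(all(df$r >= -1 & df$r <= 1))
  expect_true(mean(r150) >= mean(df$r[df$l == 50]))
  expect_error(truncation_experiment(n_seqs = 1, l_values = -5), "non-negative")
})

test_that("clip fixtures are reproducible with peaks matching the truth table", {
  fx <- clip_fixture(n_transcripts = 5, transcript_length = 900,
                     motif = "ACUK", context = "H", seed = 6)
  expect_identical(fx$peaks$start, fx$truth$motif_start)
  expect_identical(fx$peaks$end, fx$truth$motif_start + fx$truth$motif_len)
  expect_identical(unique(fx$truth$context), "H")
  expect_identical(nchar(fx$transcripts[[1]]), 900L)
  fx2 <- clip_fixture(n_transcripts = 5, transcript_length = 900,
                      motif = "ACUK", context = "H", seed = 6)
  expect_identical(fx, fx2)
  fx3 <- clip_fixture(n_transcripts = 5, transcript_length = 900,
                      motif = "ACUK", context = "H", seed = 7)
  expect_false(identical(fx$transcripts, fx3$transcripts))
  # the planted motif is where the truth table says, and matches the IUPAC
  for (k in 1:5) {
    site <- substr(fx$transcripts[[k]], fx$truth$motif_start[k] + 1,
                   fx$truth$motif_start[k] + fx$truth$motif_len[k])
    expect_match(site, "^ACU[GU]$")
  }
})

test_that("hairpin plants actually sit in hairpin loops on average", {
  par <- test_params()
  fx <- clip_fixture(n_transcripts = 8, transcript_length = 800,
                     motif = "ACUK", context = "H", seed = 8)
  ph <- ps <- numeric(8)
  for (k in 1:8) {
    sp <- structural_profile(fx$transcripts[[k]], max_span = 100,
                             parameters = par)
    idx <- (fx$truth$motif_start[k] + 1):(fx$truth$motif_start[k] +
                                            fx$truth$motif_len[k])
    ph[k] <- mean(sp$prob[idx, "H"])
    ps[k] <- mean(sp$prob[idx, "S"])
  }
  expect_gt(mean(ph), mean(ps))
  expect_gt(mean(ph), 0.5)
})

test_that("infeasible plants are rejected explicitly", {
  long_motif <- strrep("A", 29)
  expect_error(clip_fixture(n_transcripts = 1, transcript_length = 900,
                            motif = long_motif, context = "I", seed = 1),
               "cannot be planted")
  expect_error(clip_fixture(n_transcripts = 1, motif = "ACUK",
                            context = "X", seed = 1))
})
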