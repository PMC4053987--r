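# Banded inside-outside dynamic program.

test_that("a pair-free sequence has trivial inside and outside tables", {
  par <- test_params()
  it <- rfold_inside("AAAA", par, 4)
  expect_identical(it$alpha_outer, rep(1, 5))
  for (st in names(it$alpha)) {
    expect_true(all(it$alpha[[st]] == 0), info = st)
  }
  ot <- rfold_outside("AAAA", par, 4)
  expect_identical(ot$beta_outer, rep(1, 5))
  expect_identical(as.numeric(partition_function(it)), 1)
})

test_that("beta_outer ends at 1 and shapes are validated", {
  par <- test_params()
  it <- rfold_inside("GGGAAACCC", par, 9)
  ot <- rfold_outside("GGGAAACCC", par, 9, inside = it)
  expect_identical(ot$beta_outer[10], 1)
  expect_error(rfold_outside("GGGAAACCCA", par, 9, inside = it),
               "different")
})

test_that("a span of 1 leaves only the open chain", {
  par <- test_params()
  set.seed(30)
  s <- rand_seq(40)
  it <- rfold_inside(s, par, 1)
  expect_equal(as.numeric(partition_function(it)), 1, tolerance = 1e-12)
})

test_that("the partition function equals the oracle's structure sum", {
  par <- test_params()
  rt <- par$gas_constant * par$temperature_K
  for (s in c("GGGAAACCC", "GCGCAAAGCGC", "AUAUAUAUAUAU")) {
    for (W in c(6, nchar(s))) {
      z_oracle <- sum(vapply(enumerate_structures(s, W), function(db) {
        e <- structure_energy(s, db, par)
        if (is.finite(e)) exp(-e / rt) else 0
      }, 1))
      it <- rfold_inside(s, par, W)
      expect_equal(exp(it$logZ), z_oracle, tolerance = 1e-9,
                   info = paste(s, W))
    }
  }
  # flat energies: Z counts structures exactly
  flat <- flat_energy_parameters()
  it <- rfold_inside("GGGAAACCC", flat, 9)
  expect_equal(exp(it$logZ), count_structures("GGGAAACCC", 9),
               tolerance = 1e-9)
})

test_that("alpha * beta of the Stem state recovers oracle pair probabilities", {
  par <- test_params()
  rt <- par$gas_constant * par$temperature_K
  s <- "GGGAAACCC"
  W <- 9
  dbs <- enumerate_structures(s, W)
  ws <- vapply(dbs, function(db) exp(-structure_energy(s, db, par) / rt), 1)
  z <- sum(ws)
  it <- rfold_inside(s, par, W)
  ot <- rfold_outside(s, par, W)
  n <- nchar(s)
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      p_oracle <- sum(ws[vapply(dbs, function(db) {
        pr <- db_pairs(db)
        nrow(pr) > 0 && any(pr[, 1] == a & pr[, 2] == b)
      }, TRUE)]) / z
      w <- b - (a - 1)
      p_dp <- if (w <= it$W) {
        it$alpha$Stem[a, w + 1] * ot$beta$Stem[a, w + 1] / z
      } else 0
      expect_equal(p_dp, p_oracle, tolerance = 1e-9, info = paste(a, b))
    }
  }
})

test_that("alpha*beta never exceeds Z and pair sums match the stem profile", {
  par <- test_params()
  set.seed(31)
  s <- rand_seq(60, gc = 0.6)
  W <- 40
  it <- rfold_inside(s, par, W)
  ot <- rfold_outside(s, par, W)
  Z <- exp(it$logZ)
  for (st in names(it$alpha)) {
    prod <- it$alpha[[st]] * ot$beta[[st]]
    expect_true(all(prod <= Z * (1 + 1e-9), na.rm = TRUE), info = st)
  }
  sp <- structural_profile(s, max_span = W, parameters = par)
  n <- nchar(s)
  pS <- numeric(n)
  A <- it$alpha$Stem
  B <- ot$beta$Stem
  for (i in 0:n) {
    for (w in 5:it$W) {
      if (i + w > n) next
      pp <- A[i + 1, w + 1] * B[i + 1, w + 1] / Z
      if (pp > 0) {
        pS[i + 1] <- pS[i + 1] + pp
        pS[i + w] <- pS[i + w] + pp
      }
    }
  }
  expect_lt(max(abs(pS - sp$prob[, "S"])), 1e-9)
})

test_that("spans beyond the sequence length are clamped silently", {
  par <- test_params()
  s <- "GGGCGAAAGCCC"
  a <- structural_profile(s, max_span = 12, parameters = par)
  b <- structural_profile(s, max_span = 5000, parameters = par)
  expect_identical(b$span_used, nchar(s))
  expect_equal(a$prob, b$prob, tolerance = 1e-12)
})

test_that("invalid inputs are rejected", {
  par <- test_params()
  expect_error(rfold_inside("ACGU", par, 0), "must be an integer >= 1")
  expect_error(rfold_inside("", par, 5), "empty")
  expect_error(rfold_inside("ACGU", list(), 5), "energy_parameters")
  expect_error(structural_profile("ACGXU", max_span = 5), NA) # X -> N, fine
})

test_that("no overflow or underflow up to N = 10,000 at W = 800", {
  par <- test_params()
  set.seed(32)
  s <- rand_seq(10000)
  sp <- structural_profile(s, max_span = 800, parameters = par)
  expect_true(all(is.finite(sp$prob)))
  expect_true(is.finite(sp$logZ))
  expect_lt(max(abs(rowSums(sp$prob) - 1)), 1e-6)
  expect_true(all(sp$prob >= 0 & sp$prob <= 1 + 1e-12))
})
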