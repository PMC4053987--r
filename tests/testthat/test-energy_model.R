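# Energy model: parameter parsing, round-trips, and transition weights.

test_that("bundled parameters load with the study temperature and round-trip", {
  par <- test_params()
  expect_equal(par$temperature_K, 310.15)
  expect_true(all(dim(par$stack) == c(6, 6)))
  expect_false(is.null(par$int22))
  expect_length(par$hairpin_length, 31)
  expect_true(all(is.infinite(par$hairpin_length[1:3])))

  # stack (CG closing, CG inner) reads back bit-exactly from the raw file
  raw <- readLines(system.file("extdata", "turner2004.par",
                               package = "rnaprofile"))
  first_row <- strsplit(trimws(raw[which(raw == "# stack") + 1]), "\\s+")[[1]]
  expect_identical(par$stack["CG", "CG"], as.numeric(first_row[1]))

  # writer -> parser identity for every table entry
  tmp <- tempfile(fileext = ".par")
  write_parameters(par, tmp)
  par2 <- load_parameters(tmp)
  expect_equal(par2, par, tolerance = 0)
})

test_that("a temperature override in the file is honoured", {
  par <- test_params()
  par$temperature_K <- 300
  tmp <- tempfile(fileext = ".par")
  write_parameters(par, tmp)
  expect_equal(load_parameters(tmp)$temperature_K, 300)
})

test_that("malformed parameter files fail with the offending block named", {
  par <- test_params()
  tmp <- tempfile(fileext = ".par")
  write_parameters(par, tmp)
  lines <- readLines(tmp)
  i <- which(lines == "# stack") + 1
  lines[i] <- sub("^\\S+ ", "", lines[i]) # drop one stack entry
  writeLines(lines, tmp)
  expect_error(load_parameters(tmp), "stack")
  expect_error(load_parameters(tempfile()), "cannot read")
})

test_that("boltzmann_weight matches hand-computed values and is decreasing", {
  par <- test_params()
  expect_identical(boltzmann_weight(0, par), 1)
  expect_equal(boltzmann_weight(-par$gas_constant * par$temperature_K * log(2),
                                par), 2, tolerance = 1e-12)
  # exp(-1 / (0.00198717 * 310.15)), computed independently
  expect_equal(boltzmann_weight(1, par), 0.1973983112, tolerance = 1e-9)
  gs <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(vapply(gs, boltzmann_weight, 1, params = par)) < 0))
})

test_that("hairpin weights: minimum loop, canonical closing, table assembly", {
  par <- test_params()
  rt <- par$gas_constant * par$temperature_K
  expect_identical(hairpin_weight("GAAC", 1, 4, par), 0)   # loop of 2
  expect_identical(hairpin_weight("AAAAAA", 1, 6, par), 0) # A-A closing
  # tabulated special loop, looked up by hand
  expect_equal(hairpin_weight("CAACGG", 1, 6, par),
               exp(-par$special_hairpins[["CAACGG"]] / rt), tolerance = 1e-12)
  # GC-closed GAAA tetraloop is NOT tabulated: length term + mismatch
  e_manual <- par$hairpin_length[["4"]] + par$mismatch_hairpin["GC", "G", "A"]
  expect_equal(hairpin_weight("GGAAAC", 1, 6, par), exp(-e_manual / rt),
               tolerance = 1e-12)
  # loop of exactly 3 closed by A-U: length term + terminal AU penalty
  e3 <- par$hairpin_length[["3"]] + par$terminal_au
  expect_equal(hairpin_weight("AUUUU", 1, 5, par), exp(-e3 / rt),
               tolerance = 1e-12)
})

test_that("interior weights: bulges, size cap, and geometry guards", {
  par <- test_params()
  rt <- par$gas_constant * par$temperature_K
  # stacked helix is not an interior loop
  expect_identical(interior_weight("GGAAACCC", 1, 8, 2, 7, par), 0)
  # single bulge: bulge[1] + continued stack, assembled by hand
  s <- "GAGAAACCC" # outer pair (1,9) G-C, inner (3,8) G-C, one bulged A
  e_manual <- par$bulge_length[["1"]] + par$stack["GC", "CG"]
  expect_equal(interior_weight(s, 1, 9, 3, 8, par), exp(-e_manual / rt),
               tolerance = 1e-12)
  # m + n = 31 exceeds the default loop cap
  expect_identical(
    interior_weight(paste0("G", strrep("A", 31), "GAAAAC", "C"),
                    1, 39, 33, 38, par), 0)
  # violated geometry returns 0, not an error
  expect_identical(interior_weight("GGAAACCC", 1, 8, 6, 3, par), 0)
})

test_that("stack, multibranch and exterior weights follow the affine model", {
  par <- test_params()
  # stack of (GC over CG): manual lookup with reversed inner orientation
  expect_equal(stack_weight("GCGC", 1, 4, par),
               boltzmann_weight(par$stack["GC", "GC"], par),
               tolerance = 1e-12)
  expect_identical(stack_weight("GAGC", 1, 4, par), 0) # inner A-G impossible
  flat <- flat_energy_parameters()
  expect_identical(multiloop_unpaired_weight(flat), 1)
  expect_equal(multiloop_close_weight(par),
               boltzmann_weight(par$ml_close, par))
  expect_equal(multiloop_branch_weight(par),
               boltzmann_weight(par$ml_branch, par))
  # terminal penalty applies to AU/GU helix ends only
  expect_identical(external_branch_weight("GAAAC", 1, 5, par), 1)
  expect_equal(external_branch_weight("AAAAU", 1, 5, par),
               boltzmann_weight(par$terminal_au, par))
  expect_equal(external_branch_weight("GAAAU", 1, 5, par),
               boltzmann_weight(par$terminal_au, par))
  expect_identical(external_branch_weight("AAAAG", 1, 5, par), 0) # A-G
})

test_that("all weights are non-negative with zeros only for impossible emissions", {
  par <- test_params()
  set.seed(101)
  for (r in 1:50) {
    s <- rand_seq(12)
    w <- hairpin_weight(s, 1, 12, par)
    expect_gte(w, 0)
    w2 <- interior_weight(s, 1, 12, sample(2:5, 1), sample(7:11, 1), par)
    expect_gte(w2, 0)
  }
})
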