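# Enumeration oracle: structure sets, context classification, energies.

test_that("sequences without canonical pairs have exactly the open chain", {
  expect_identical(enumerate_structures("AAAA"), "....")
  expect_identical(count_structures("AAAA"), 1)
  ep <- exact_profile("AAAA", max_span = 4, parameters = test_params())
  expect_true(all(ep$prob[, "E"] == 1))
})

test_that("enumeration agrees with the independent counting recursion", {
  set.seed(20)
  for (r in 1:40) {
    n <- sample(5:12, 1)
    s <- rand_seq(n)
    W <- sample(c(4:12, Inf), 1)
    expect_identical(length(enumerate_structures(s, W)),
                     as.integer(count_structures(s, W)),
                     info = paste(s, W))
  }
  expect_identical(length(enumerate_structures("GCGAAACGC", 9)),
                   as.integer(count_structures("GCGAAACGC", 9)))
})

test_that("every enumerated structure respects hairpin and span constraints", {
  for (W in c(6, 9, 12)) {
    dbs <- enumerate_structures("GGGAAACCC", W)
    expect_true("........." %in% dbs)
    for (db in dbs) {
      pr <- db_pairs(db)
      if (nrow(pr)) {
        expect_true(all(pr[, 2] - pr[, 1] >= 4))  # min hairpin loop of 3
        expect_true(all(pr[, 2] - pr[, 1] <= min(W, 9) - 2)) # grammar span
      }
    }
  }
  # the span bound actually bites
  expect_gt(length(enumerate_structures("GGGAAACCC", 9)),
            length(enumerate_structures("GGGAAACCC", 7)))
})

test_that("context classification matches the polygon definitions", {
  expect_identical(classify_contexts("(((...)))"),
                   c("S", "S", "S", "H", "H", "H", "S", "S", "S"))
  expect_identical(classify_contexts("(.((...)))"),
                   c("S", "B", "S", "S", "H", "H", "H", "S", "S", "S"))
  lab <- classify_contexts(".((..((...))((...)).)).")
  expect_identical(lab[1], "E")
  expect_identical(lab[length(lab)], "E")
  expect_identical(lab[c(4, 5, 20)], c("M", "M", "M")) # 3-bond polygon
  expect_identical(lab[8:10], c("H", "H", "H"))
  # classification is total and idempotent
  expect_true(all(lab %in% c("B", "E", "H", "I", "M", "S")))
  expect_identical(classify_contexts(".((..((...))((...)).))."), lab)
  expect_error(classify_contexts("(()"), "unbalanced")
})

test_that("structure energies follow the shared attribution conventions", {
  par <- test_params()
  expect_identical(structure_energy("GGGAAACCC", ".........", par), 0)
  # fully stacked hairpin, assembled by hand from the tables
  s <- "GGGAAACCC"
  # stacks index (closing pair, reversed inner pair): G1-C9 over G2-C8 is
  # stack["GC","CG"], likewise G2-C8 over G3-C7
  e_hand <- 2 * par$stack["GC", "CG"] + par$hairpin_length[["3"]]
  expect_equal(structure_energy(s, "(((...)))", par), e_hand,
               tolerance = 1e-12)
  # exterior AU helix end pays the terminal penalty
  e_au <- par$hairpin_length[["3"]] + par$terminal_au + # loop-3 closing AU
    par$terminal_au                                     # exterior helix end
  expect_equal(structure_energy("AUUUU", "(...)", par), e_au,
               tolerance = 1e-12)
})

test_that("oracle profile rows sum to one and the flat ensemble counts structures", {
  par <- test_params()
  flat <- flat_energy_parameters()
  set.seed(21)
  for (r in 1:10) {
    s <- rand_seq(sample(8:12, 1))
    ep <- exact_profile(s, max_span = 12, parameters = par)
    expect_lt(max(abs(rowSums(ep$prob) - 1)), 1e-12)
    epf <- exact_profile(s, max_span = 12, parameters = flat)
    expect_equal(exp(epf$logZ), count_structures(s, 12), tolerance = 1e-9)
  }
})

test_that("the enumeration guard rejects long sequences", {
  expect_error(enumerate_structures(strrep("A", 17)), "at most 16")
  expect_error(exact_profile(strrep("A", 17), max_span = 10), "at most 16")
})
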