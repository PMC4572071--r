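test_that("PLINK-style .hom files round-trip losslessly with KB arithmetic", {
  roh <- data.frame(sample = "IND1", contig = "ctg01",
                    start = 1000000L, end = 3000000L)
  f <- withr::local_tempfile(fileext = ".hom")
  write_roh(roh, f)
  tab <- utils::read.table(f, header = TRUE)
  expect_equal(tab$KB, 2000.001)  # inclusive interval length / 1000
  expect_equal(read_roh(f), roh, ignore_attr = TRUE)
  # empty set: header-only file
  f2 <- withr::local_tempfile(fileext = ".hom")
  write_roh(roh[0, ], f2)
  expect_equal(length(readLines(f2)), 1)
  expect_equal(nrow(read_roh(f2)), 0)
  # many random intervals survive the round trip (disjoint per individual)
  set.seed(1)
  big <- data.frame(sample = sprintf("I%02d", 1:100), contig = "ctg01",
                    start = as.integer(seq(1e6, 300e6, length.out = 100)))
  big$end <- big$start + as.integer(runif(100, 1.5e6, 3e6))
  f3 <- withr::local_tempfile(fileext = ".hom")
  write_roh(big, f3)
  back <- read_roh(f3)
  expect_equal(back[order(back$sample), c("sample", "start", "end")],
               big[order(big$sample), c("sample", "start", "end")],
               ignore_attr = TRUE)
})

test_that("overlapping intervals of one individual are merged with a warning", {
  roh <- data.frame(sample = "I1", contig = "c",
                    start = c(1e6, 2e6), end = c(2.5e6, 4e6))
  expect_warning(m <- merge_roh(roh), "merged")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1e6); expect_equal(m$end, 4e6)
})

test_that("carrier ROH membership is inclusive and matches a linear scan", {
  roh <- data.frame(sample = "I1", contig = "c", start = 100L, end = 200L)
  expect_true(carrier_in_roh("c", 100L, "I1", roh))   # start bound
  expect_true(carrier_in_roh("c", 200L, "I1", roh))   # end bound
  expect_false(carrier_in_roh("c", 99L, "I1", roh))
  expect_false(carrier_in_roh("c", 150L, "I2", roh))  # absent individual
  set.seed(4)
  big <- data.frame(sample = sample(c("I1", "I2", "I3"), 60, replace = TRUE),
                    contig = sample(c("c1", "c2"), 60, replace = TRUE),
                    start = sample.int(1e6, 60))
  big$end <- big$start + sample.int(1e5, 60)
  for (rep in 1:100) {
    ind <- sample(c("I1", "I2", "I3", "I4"), 1)
    ctg <- sample(c("c1", "c2"), 1)
    p <- sample.int(1.2e6, 1)
    naive <- any(big$sample == ind & big$contig == ctg &
                 big$start <= p & big$end >= p)
    expect_identical(carrier_in_roh(ctg, p, ind, big), naive)
  }
})

test_that("binomial bias classification matches tail summation for all small cases", {
  for (n in 1:8) {
    for (k in 0:n) {
      for (f in c(0.02, 0.1, 0.3)) {
        cl <- classify_roh_bias(k, n, f)
        expect_equal(cl$p_inside, oracle_binom_upper(k, n, f),
                     tolerance = 1e-12)
        expect_equal(cl$p_outside, oracle_binom_lower(k, n, f),
                     tolerance = 1e-12)
        # both tails significant simultaneously is impossible at alpha <= 0.5
        expect_false(cl$p_inside < 0.1 && cl$p_outside < 0.1)
      }
    }
  }
  # all five carriers autozygous against a 5% expectation: inside-biased
  expect_equal(classify_roh_bias(5, 5, 0.05)$class, "inside_biased")
  # a single carrier outside ROHs is uninformative
  expect_equal(classify_roh_bias(0, 1, 0.05)$class, "unclassified")
  expect_error(classify_roh_bias(1, 0, 0.05), "carriers")
})

test_that("population ROH frequencies span the trivial extremes", {
  obs <- data.frame(key = c("a", "b"), contig = "c", pos = 1:2,
                    carrier = c("I1", "I2"), population = "P",
                    in_roh = c(FALSE, FALSE))
  expect_equal(population_roh_frequency(obs, "P"), 0)
  obs$in_roh <- TRUE
  expect_equal(population_roh_frequency(obs, "P"), 1)
  expect_error(population_roh_frequency(obs, "Q"), "Q")
})

test_that("allele-frequency contrast between bias classes is exact and guarded", {
  bt <- data.frame(key = letters[1:8],
                   class = rep(c("inside_biased", "outside_biased"), each = 4),
                   af = c(0.01, 0.02, 0.015, 0.03, 0.2, 0.35, 0.3, 0.4))
  cmp <- compare_af_by_bias(bt)
  expect_true(cmp$testable)
  expect_lt(cmp$median_inside, cmp$median_outside)
  expect_equal(cmp$p, oracle_ranksum_p(bt$af[1:4], bt$af[5:8]),
               tolerance = 1e-9)
  # identical AF lists: P = 1 by symmetry
  bt2 <- bt; bt2$af <- rep(c(0.11, 0.12, 0.13, 0.14), 2)
  expect_equal(compare_af_by_bias(bt2)$p, 1)
  # fewer than three in a class: flagged untestable
  bt3 <- bt[c(1, 2, 5, 6, 7, 8), ]
  expect_false(compare_af_by_bias(bt3)$testable)
})

test_that("the population ROH contrast equals hypergeometric enumeration and is symmetric", {
  expect_equal(compare_populations_roh(c(10, 90), c(10, 90)), 1)
  p <- compare_populations_roh(c(1, 99), c(10, 90))
  expect_equal(p, oracle_fisher_two_sided(1, 99, 10, 90), tolerance = 1e-9)
  expect_equal(p, compare_populations_roh(c(10, 90), c(1, 99)))
  # zero margin
  expect_equal(compare_populations_roh(c(0, 0), c(3, 7)), 1)
  # small random tables against the enumeration oracle
  set.seed(6)
  for (rep in 1:20) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(compare_populations_roh(tab[1, ], tab[2, ]),
                 oracle_fisher_two_sided(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("isolate populations show higher in-ROH HLOF frequencies than the cosmopolitan sample", {
  st <- small_study()
  sc <- small_scan()
  obs <- roh_observations(sc$survivor_candidates, st$roh, st$samples)
  f_cosmo <- population_roh_frequency(obs, "COSMO")
  f_iso <- vapply(c("ISL_A", "ISL_B"), function(p)
    population_roh_frequency(obs, p), numeric(1))
  expect_true(all(f_iso > f_cosmo))
})
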