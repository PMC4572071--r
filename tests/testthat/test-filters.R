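opts <- cascade_options()

test_that("relative-position filter excludes the last 10% of any transcript", {
  late <- make_candidate()
  late$csq <- rbind(late$csq, late$csq)
  late$csq$transcript_id <- c("TX1", "TX2")
  late$csq$rel_pos <- c(0.5, 0.95)
  expect_false(filter_relative_position(late, opts)$pass)
  # permissive mode keeps it: early in at least one transcript
  expect_true(filter_relative_position(
    late, cascade_options(rel_pos_mode = "any"))$pass)
  early <- make_candidate(); early$csq$rel_pos <- 0.0
  expect_true(filter_relative_position(early, opts)$pass)
  boundary <- make_candidate(); boundary$csq$rel_pos <- 0.90
  expect_false(filter_relative_position(boundary, opts)$pass)
})

test_that("minimum-sample filter sits exactly at the threshold", {
  expect_false(filter_min_samples(make_candidate(n_called = 199L), opts)$pass)
  expect_true(filter_min_samples(make_candidate(n_called = 200L), opts)$pass)
  expect_false(filter_min_samples(make_candidate(n_called = 0L), opts)$pass)
})

test_that("capture-kit intersection honours 50 bp padding on both kits", {
  kit_a <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2000, 2100))
  kit_b <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1900, 2100))
  # 30 bp upstream of kit A's target but inside kit B: padding rescues it
  cand <- make_candidate(pos = 1970L)
  expect_true(filter_capture_intersection(cand, kit_a, kit_b, opts)$pass)
  # 60 bp outside kit A exceeds the padding
  cand2 <- make_candidate(pos = 1940L)
  expect_false(filter_capture_intersection(cand2, kit_a, kit_b, opts)$pass)
  # empty track fails everything, with a reason
  d <- filter_capture_intersection(cand, GenomicRanges::GRanges(), kit_b, opts)
  expect_false(d$pass)
  expect_match(d$reason, "empty")
})

test_that("mapability filter uses the full reference span, inclusive", {
  low <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1010, 1020))
  tracks <- list(alignability = list(low, GenomicRanges::GRanges()),
                 blacklist = GenomicRanges::GRanges())
  ok <- make_candidate(pos = 1004L)       # SNV well before the region
  expect_true(filter_mapability(ok, tracks)$pass)
  # deletion straddling the boundary by a single base
  del <- make_candidate(pos = 1008L, ref = "AAA", alt = "A")
  expect_false(filter_mapability(del, tracks)$pass)
  # blacklist alone is also fatal
  tracks2 <- list(alignability = list(GenomicRanges::GRanges(),
                                      GenomicRanges::GRanges()),
                  blacklist = low)
  hit <- make_candidate(pos = 1015L)
  expect_false(filter_mapability(hit, tracks2)$pass)
})

test_that("ancestral filter applies the stop-gain and frameshift rules separately", {
  sg <- make_candidate()
  prim <- data.frame(contig = "chrT", pos = 1004L, species = "chimp",
                     aligned = TRUE, allele = "T", indel_type = "none",
                     indel_len = 0L)
  expect_false(filter_ancestral(sg, prim)$pass)       # chimp carries the alt
  prim$allele <- "C"
  expect_true(filter_ancestral(sg, prim)$pass)        # chimp matches reference
  expect_true(filter_ancestral(sg, prim[0, ])$pass)   # absent: no evidence
  fs <- make_candidate(key = "chrT:1010:AA:A", pos = 1010L, ref = "AA",
                       alt = "A", consequence = "frameshift")
  one <- data.frame(contig = "chrT", pos = 1010L, species = "chimp",
                    aligned = TRUE, allele = ".", indel_type = "deletion",
                    indel_len = 1L)
  expect_true(filter_ancestral(fs, one)$pass)         # only one aligned primate
  two <- rbind(one, transform(one, species = "gorilla"))
  expect_false(filter_ancestral(fs, two)$pass)        # two matching primates
  two$indel_len <- 2L
  expect_true(filter_ancestral(fs, two)$pass)         # length mismatch
})

test_that("same-codon SNPs disqualify stop-gains but not neighbours", {
  tx <- make_tx()  # codon 2 at 1004-1006
  mk_callset <- function(extra_pos) {
    v <- data.frame(contig = "chrT", pos = c(1004L, extra_pos),
                    ref = "C", alt = "T", stringsAsFactors = FALSE)
    hlof_callset(v, matrix(0L, 2, 2), matrix(30L, 2, 2),
                 data.frame(sample_id = c("S1", "S2"), population = "P1"))
  }
  cand <- make_candidate(codon_index = 2L)
  expect_false(filter_mnp_codon(cand, mk_callset(1006L), list(tx))$pass)
  expect_true(filter_mnp_codon(cand, mk_callset(1007L), list(tx))$pass)
  fs <- make_candidate(consequence = "frameshift")
  expect_true(filter_mnp_codon(fs, mk_callset(1006L), list(tx))$pass)
})

test_that("frameshift rescue fails restored frames, chains of three, and spares distant pairs", {
  mk_fs <- function(key, codon, len, carriers = "S1") {
    ref <- if (len < 0) paste(rep("A", 1 - len), collapse = "") else "A"
    alt <- if (len < 0) "A" else paste(c("A", rep("T", len)), collapse = "")
    make_candidate(key = key, pos = 1000L + codon, ref = ref, alt = alt,
                   consequence = "frameshift", codon_index = codon,
                   carriers = carriers)
  }
  dec <- function(cands, o = opts) {
    d <- filter_frameshift_rescue(cands, o)
    setNames(d$pass, d$key)
  }
  # +1 and -1 four codons apart: frame restored, both fail
  pair <- list(mk_fs("a", 10L, +1L), mk_fs("b", 14L, -1L))
  expect_equal(unname(dec(pair)), c(FALSE, FALSE))
  # +1 and +1 (sum 2): both pass
  pair2 <- list(mk_fs("a", 10L, +1L), mk_fs("b", 14L, +1L))
  expect_equal(unname(dec(pair2)), c(TRUE, TRUE))
  # ten or more amino acids apart: independent, both pass
  pair3 <- list(mk_fs("a", 10L, +1L), mk_fs("b", 20L, -1L))
  expect_equal(unname(dec(pair3)), c(TRUE, TRUE))
  # chain of three within the vicinity: all fail even though pair sums vary
  trio <- list(mk_fs("a", 10L, +1L), mk_fs("b", 14L, -2L), mk_fs("c", 18L, +1L))
  expect_equal(unname(dec(trio)), c(FALSE, FALSE, FALSE))
  # carrier mode: the restored pair is spared when carriers differ
  pairc <- list(mk_fs("a", 10L, +1L, carriers = "S1"),
                mk_fs("b", 14L, -1L, carriers = "S2"))
  expect_equal(unname(dec(pairc, cascade_options(rescue_mode = "carrier"))),
               c(TRUE, TRUE))
  expect_equal(unname(dec(pair, cascade_options(rescue_mode = "carrier"))),
               c(FALSE, FALSE))
  # a lone frameshift always passes
  expect_true(dec(list(mk_fs("a", 10L, +1L)))[["a"]])
})

test_that("the HWE filter rejects in any single population and matches the exact test", {
  pc <- matrix(c(200, 10, 1,   98, 0, 2), 3, 2,
               dimnames = list(c("hom_ref", "het", "hom_alt"), c("P1", "P2")))
  cand <- make_candidate(pop_counts = pc)
  d <- filter_hwe(cand, opts)
  expect_false(d$pass)
  expect_match(d$reason, "P2")
  # the decision flips exactly at the alpha threshold of the exact test
  p2 <- hwe_excess_test(98, 0, 2)
  expect_true(p2 < opts$hwe_alpha)
  pc2 <- pc; pc2[, "P2"] <- c(96, 4, 0)
  expect_true(filter_hwe(make_candidate(pop_counts = pc2), opts)$pass)
  # a singleton homozygote's decision matches the enumeration oracle
  pc3 <- matrix(c(199, 0, 1), 3, 1,
                dimnames = list(c("hom_ref", "het", "hom_alt"), "P1"))
  d3 <- filter_hwe(make_candidate(pop_counts = pc3), opts)
  expect_equal(d3$pass, oracle_hwe_excess_p(199, 0, 1) >= opts$hwe_alpha)
})

test_that("coverage filter spares known variants and enforces 20x for novel ones", {
  novel19 <- make_candidate(carrier_depth = c(S1 = 19L), known = FALSE)
  expect_false(filter_coverage(novel19, opts)$pass)
  novel20 <- make_candidate(carrier_depth = c(S1 = 20L), known = FALSE)
  expect_true(filter_coverage(novel20, opts)$pass)
  known8 <- make_candidate(carrier_depth = c(S1 = 8L), known = TRUE)
  expect_true(filter_coverage(known8, opts)$pass)
})

test_that("near-fixed variants are recognized from pooled genotype counts", {
  fixed <- make_candidate(counts_all = c(hom_ref = 0, het = 0, hom_alt = 260))
  expect_false(filter_near_fixed(fixed)$pass)
  one_het <- make_candidate(counts_all = c(hom_ref = 0, het = 1, hom_alt = 259))
  expect_false(filter_near_fixed(one_het)$pass)
  two_het <- make_candidate(counts_all = c(hom_ref = 0, het = 2, hom_alt = 258))
  expect_true(filter_near_fixed(two_het)$pass)
})

test_that("the cascade is an order-independent intersection with a faithful audit", {
  sc <- small_scan()
  keys <- vapply(sc$candidates, `[[`, character(1), "key")
  # survivors = candidates passing every filter
  pass_all <- vapply(keys, function(k) {
    all(sc$decisions$pass[sc$decisions$key == k])
  }, logical(1))
  expect_setequal(sc$survivors, keys[pass_all])
  # all-filters count cannot exceed any single-filter count
  single <- sc$audit$n_pass_alone[sc$audit$filter != "all_filters"]
  all_f <- sc$audit$n_pass_alone[sc$audit$filter == "all_filters"]
  expect_true(all(all_f <= single))
  # exactly one decision per (variant, filter)
  expect_false(any(duplicated(sc$decisions[, c("key", "filter")])))
  # a rerun gives the identical audit
  sc2 <- run_cascade(sc$candidates, study_resources(small_study()))
  expect_identical(sc2$audit, sc$audit)
  expect_identical(sc2$decisions, sc$decisions)
})

test_that("a missing resource is reported by name", {
  expect_error(run_cascade(list(), list(tracks = NULL)), "tracks")
})
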