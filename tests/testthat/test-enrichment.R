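test_that("enrichment ratios reproduce the published GO table to two decimals", {
  go <- published_go_counts()
  got <- with(go, mapply(enrichment_ratio, N, B, n, b))
  expect_equal(round(got, 2),
               c(7.65, 3.81, 2.80, 2.52, 2.58, 2.09, 2.09),
               ignore_attr = TRUE)
  # no enrichment when the target proportion equals the background
  expect_equal(enrichment_ratio(1000, 100, 50, 5), 1.00)
  expect_error(enrichment_ratio(100, 0, 10, 0), "B = 0")
})

test_that("hypergeometric tails equal combinatorial enumeration on small universes", {
  expect_equal(hypergeometric_enrichment_p(20, 5, 5, 5), 1 / choose(20, 5))
  expect_equal(hypergeometric_enrichment_p(100, 10, 10, 0), 1)
  set.seed(8)
  for (rep in 1:60) {
    N <- sample(5:25, 1); B <- sample(0:N, 1); n <- sample(1:N, 1)
    b <- sample(0:min(B, n), 1)
    expect_equal(hypergeometric_enrichment_p(N, B, n, b),
                 oracle_hyper_upper(N, B, n, b), tolerance = 1e-12,
                 label = sprintf("N=%d B=%d n=%d b=%d", N, B, n, b))
  }
  # the tail never grows as the overlap grows at fixed margins
  ps <- vapply(0:8, function(b) hypergeometric_enrichment_p(30, 10, 8, b),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("enrichment tables carry consistent counts and ordered q-values", {
  st <- small_study()
  et <- enrichment_table(st$tables$hlof_genes, st$tables$gene_universe,
                         st$tables$go_annotations)
  expect_true(all(et$b <= pmin(et$B, et$n)))
  expect_equal(et$enrichment, (et$b / et$n) / (et$B / et$N))
  expect_true(all(et$q >= et$p - 1e-12))
})

test_that("tissue summaries report argmax shares and expressed fractions", {
  em <- matrix(1, 143, 3, dimnames = list(sprintf("g%03d", 1:143),
                                          c("testis", "brain", "liver")))
  em[1:41, "testis"] <- 5                    # 41 genes peak in testis
  em[42:143, "brain"] <- 5
  em[1:119, "testis"] <- pmax(em[1:119, "testis"], 2)  # 119 expressed > 1
  ts <- tissue_summary(em, rownames(em), expressed_threshold = 1,
                       focus_tissue = "testis")
  pt <- ts$per_tissue
  expect_equal(round(100 * pt$max_prop[pt$tissue == "testis"], 1), 28.7)
  expect_equal(ts$n_expressed_focus, 119)
  expect_equal(round(100 * ts$prop_expressed_focus), 83)
  expect_equal(sum(pt$max_prop), 1)
  # ties credit each tissue equally
  em2 <- matrix(c(2, 2, 1), 1, 3,
                dimnames = list("g1", c("testis", "brain", "liver")))
  ts2 <- tissue_summary(em2, "g1")
  expect_equal(ts2$per_tissue$max_count[1:2], c(0.5, 0.5))
  # absent genes are excluded from the denominator with a message
  expect_message(ts3 <- tissue_summary(em, c(rownames(em), "missing_gene")),
                 "absent")
  expect_equal(ts3$n_genes, 143)
})

test_that("population yields agree with direct counts on the genotype matrix", {
  st <- small_study()
  sc <- small_scan()
  yt <- population_yield(sc$survivor_candidates, st$samples)
  keys <- vapply(sc$survivor_candidates, `[[`, character(1), "key")
  rows <- match(keys, st$callset$variants$key)
  for (p in yt$population) {
    cols <- st$samples$population == p
    d5 <- st$callset$depth[rows, cols, drop = FALSE] >= 5
    hom <- st$callset$geno[rows, cols, drop = FALSE] == 2L & d5
    n_direct <- sum(rowSums(hom, na.rm = TRUE) > 0)
    expect_equal(yt$n_hlofs[yt$population == p], n_direct)
    expect_equal(yt$yield[yt$population == p],
                 round(n_direct / sum(cols), 2))
  }
  # private classes are disjoint
  expect_true(all(yt$private_hlofs >= 0 & yt$private_lofs >= 0))
})

test_that("deleteriousness summaries handle degenerate and tied inputs", {
  mk <- function(score, ncar) {
    cand <- make_candidate(cscore = score)
    cand$carriers <- sprintf("S%d", seq_len(ncar))
    cand
  }
  flat <- lapply(1:5, function(i) mk(10, i))
  expect_false(cscore_summary(flat)$testable)
  anti <- lapply(1:6, function(i) mk(40 - i * 5, i))
  expect_equal(cscore_summary(anti)$spearman_rho, -1)
  set.seed(10)
  tied <- lapply(1:12, function(i) mk(sample(c(10, 20, 30), 1),
                                      sample(1:4, 1)))
  cs <- cscore_summary(tied)
  sc <- vapply(tied, `[[`, numeric(1), "cscore")
  nc <- vapply(tied, function(x) length(x$carriers), numeric(1))
  expect_equal(cs$spearman_rho, cor(rank(sc), rank(nc)), tolerance = 1e-12)
})

test_that("paralogue comparisons report direction and honour exclusions", {
  set.seed(11)
  bg <- rpois(400, 2.2)
  same <- list("70" = setNames(bg, sprintf("g%03d", seq_along(bg))))
  out <- compare_paralogues(same, list("70" = bg))
  expect_gt(out$p, 0.9)
  shifted <- list("70" = setNames(rpois(100, 0.8), sprintf("g%03d", 1:100)))
  out2 <- compare_paralogues(shifted, list("70" = bg))
  expect_lt(out2$p, 0.01)
  expect_equal(out2$direction, "fewer_paralogues")
  out3 <- compare_paralogues(shifted, list("70" = bg),
                             exclude_genes = sprintf("g%03d", 1:40))
  expect_equal(out3$n_hlof, 60)
  expect_error(compare_paralogues(list(), list()), "empty")
})
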