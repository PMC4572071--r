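test_that("transcript coordinate maps invert each other on both strands", {
  for (s in 1:6) {
    tx <- random_tx(s)
    for (idx in unique(c(1L, tx$cds_len, sample(tx$cds_len, 25)))) {
      p <- cds_to_genomic(tx, idx)
      expect_identical(genomic_to_cds(tx, p), as.integer(idx))
    }
    # positions just outside the CDS are unmapped
    expect_true(is.na(genomic_to_cds(tx, min(tx$exons$start) - 1L)))
    expect_true(is.na(genomic_to_cds(tx, max(tx$exons$end) + 1L)))
  }
})

test_that("transcript models enforce frame and segment sanity", {
  expect_error(transcript_model("g", "t", "c", "+",
                                data.frame(start = 1, end = 10), "ACGTACGTAC"),
               "divisible by 3")
  expect_error(transcript_model("g", "t", "c", "+",
                                data.frame(start = c(1, 5), end = c(6, 12)),
                                paste(rep("ACG", 4), collapse = "")),
               "overlap")
})

test_that("stop-gain, synonymous and missense SNVs are classified by the genetic code", {
  tx <- make_tx()  # codon 2 is CGA at positions 1004-1006
  expect_equal(classify_consequence(list(pos = 1004L, ref = "C", alt = "T"),
                                    tx)$consequence, "stop_gain")  # CGA -> TGA
  expect_equal(classify_consequence(list(pos = 1006L, ref = "A", alt = "G"),
                                    tx)$consequence, "synonymous") # CGA -> CGG
  expect_equal(classify_consequence(list(pos = 1005L, ref = "G", alt = "A"),
                                    tx)$consequence, "missense")   # CGA -> CAA
  out <- classify_consequence(list(pos = 10L, ref = "A", alt = "T"), tx)
  expect_equal(out$consequence, "non_coding")
})

test_that("in-frame deletions are never called frameshift", {
  tx <- make_tx()
  # remove codon 3 entirely (3 bp), anchored at the last base of codon 2
  v <- list(pos = 1006L, ref = "AAAA", alt = "A")
  expect_equal(classify_consequence(v, tx)$consequence, "inframe")
  # 2-bp deletion shifts the frame
  v2 <- list(pos = 1006L, ref = "AAA", alt = "A")
  expect_equal(classify_consequence(v2, tx)$consequence, "frameshift")
})

test_that("indel and SNV labels match the full-CDS retranslation oracle", {
  set.seed(42)
  n_checked <- 0
  for (s in 1:12) {
    tx <- random_tx(s)
    interior <- tx$exons[1, ]
    for (rep in 1:20) {
      type <- sample(c("SNV", "ins", "del"), 1)
      if (type == "SNV") {
        idx <- sample(tx$cds_len, 1)
        p <- cds_to_genomic(tx, idx)
        ref <- tx_ref_base(tx, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        v <- list(pos = p, ref = ref, alt = alt)
      } else if (type == "ins") {
        ex <- tx$exons[sample(nrow(tx$exons), 1), ]
        p <- sample(seq(ex$start, ex$end - 1L), 1)
        ref <- tx_ref_base(tx, p)
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                            replace = TRUE), collapse = "")
        v <- list(pos = p, ref = ref, alt = paste0(ref, ins))
      } else {
        ex <- tx$exons[sample(nrow(tx$exons), 1), ]
        len <- sample(1:4, 1)
        if (ex$end - ex$start < len + 2) next
        p <- sample(seq(ex$start, ex$end - len), 1)
        ref <- paste(vapply(p:(p + len), function(q) tx_ref_base(tx, q),
                            character(1)), collapse = "")
        v <- list(pos = p, ref = ref, alt = substr(ref, 1, 1))
      }
      got <- classify_consequence(v, tx)$consequence
      expect_equal(got, oracle_consequence(v, tx),
                   label = sprintf("seed %d %s at %d (%s>%s)", s, type,
                                   v$pos, v$ref, v$alt))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 200)
})

test_that("relative position indexes the linearized CDS and hits the 90% boundary exactly", {
  codons <- c("ATG", rep("GCT", 99), "TAA")  # protein length 100
  tx <- make_tx(codons)
  # start codon
  expect_equal(relative_position(list(pos = 1001L, ref = "A", alt = "C"), tx), 0)
  # codon 91 -> (91 - 1) / 100 = 0.90, exactly at the exclusion boundary
  p <- cds_to_genomic(tx, (91 - 1) * 3 + 1)
  expect_equal(relative_position(list(pos = p, ref = "G", alt = "A"), tx), 0.90)
})

test_that("relative position is invariant under a whole-fixture strand flip", {
  for (s in 1:6) {
    tx_f <- random_tx(s, strand = "+")
    tx_r <- transcript_model(tx_f$gene_id, tx_f$transcript_id, tx_f$contig,
                             "-", tx_f$exons, tx_f$cds_seq)
    for (idx in sample(tx_f$cds_len, 10)) {
      pf <- cds_to_genomic(tx_f, idx)
      pr <- cds_to_genomic(tx_r, idx)
      ref_f <- tx_ref_base(tx_f, pf); ref_r <- tx_ref_base(tx_r, pr)
      vf <- list(pos = pf, ref = ref_f,
                 alt = setdiff(c("A", "C", "G", "T"), ref_f)[1])
      vr <- list(pos = pr, ref = ref_r,
                 alt = chartr("ACGT", "TGCA", setdiff(c("A", "C", "G", "T"),
                                                      ref_f)[1]))
      expect_equal(relative_position(vf, tx_f), relative_position(vr, tx_r))
    }
  }
})

test_that("multi-allelic decomposition conserves per-sample allele dosage", {
  # forced example: genotype 1/2 becomes het in both split records
  rec <- list(contig = "c", pos = 10L, ref = "A", alt = c("C", "T"),
              gt = c("1/2", "0/1", "2/2", "./."))
  out <- decompose_multiallelic(list(rec))
  expect_equal(nrow(out$variants), 2)
  expect_equal(out$geno[, 1], c(1L, 1L))          # sample 1 het for both
  expect_equal(out$geno[, 3], c(0L, 2L))          # sample 3 hom for alt 2
  expect_true(all(is.na(out$geno[, 4])))
  # biallelic records pass through unchanged
  rec2 <- list(contig = "c", pos = 11L, ref = "A", alt = "G",
               gt = c("0/0", "0/1", "1/1"))
  out2 <- decompose_multiallelic(list(rec2))
  expect_equal(out2$geno[1, ], c(0L, 1L, 2L))
  # random 3-allelic fixtures: dosage accounting oracle
  set.seed(7)
  for (rep in 1:25) {
    gts <- replicate(12, paste(sample(0:3, 2, replace = TRUE), collapse = "/"))
    rec3 <- list(contig = "c", pos = 1L, ref = "A",
                 alt = c("C", "G", "TT"), gt = gts)
    out3 <- decompose_multiallelic(list(rec3))
    pairs <- do.call(rbind, strsplit(gts, "/"))
    for (ai in 1:3) {
      dosage <- rowSums(matrix(as.integer(pairs), ncol = 2) == ai)
      expect_equal(unname(out3$geno[ai, ]), as.integer(dosage))
    }
  }
})

test_that("symbolic alleles are skipped with a message", {
  rec <- list(contig = "c", pos = 5L, ref = "A", alt = c("<DEL>", "G"),
              gt = c("0/2", "0/0"))
  expect_message(out <- decompose_multiallelic(list(rec)), "symbolic")
  expect_equal(nrow(out$variants), 1)
  expect_equal(out$variants$alt, "G")
})

test_that("candidate identification requires a homozygote and an HLOF consequence", {
  st <- small_study()
  sc <- small_scan()
  keys <- vapply(sc$candidates, `[[`, character(1), "key")
  # every planted true HLOF is recovered as a candidate
  true_keys <- st$truth$key[st$truth$category == "TRUE_HLOF"]
  expect_true(all(true_keys %in% keys))
  # planted in-frame deletions never qualify
  inframe <- st$truth$key[st$truth$category == "INFRAME"]
  expect_false(any(inframe %in% keys))
  # every candidate has a homozygous carrier and an HLOF consequence
  for (cand in sc$candidates) {
    expect_gt(length(cand$carriers), 0)
    expect_true(any(cand$csq$consequence %in% c("stop_gain", "frameshift")))
  }
  # without a catalogue nothing is known
  cands <- identify_candidates(st$callset, st$transcripts)
  expect_false(any(vapply(cands, `[[`, logical(1), "known")))
})
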