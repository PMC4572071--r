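# Shared fixtures. The small study is generated once per test session.

small_config <- function(seed = 3) {
  sim_config(
    seed = seed,
    populations = data.frame(
      name = c("COSMO", "ISL_A", "ISL_B"), size = c(150L, 60L, 50L),
      roh_genome_fraction = c(0.03, 0.07, 0.10),
      mean_roh_length_bp = c(2.0e6, 2.4e6, 2.6e6),
      mean_depth = c(60, 45, 25), stringsAsFactors = FALSE),
    n_genes = 80, n_true_hlof = 20,
    artifact_counts = c(LAST10PCT = 2L, LOW_MAPABILITY = 3L, OFF_TARGET = 2L,
                        FEW_SAMPLES = 2L, ANCESTRAL = 2L, MNP_CODON = 2L,
                        FRAME_RESCUE = 2L, INFRAME = 2L, HWE_EXCESS = 2L,
                        LOW_COVERAGE = 2L, NEAR_FIXED = 2L),
    trait_count = 30, n_neutral = 120)
}

.fixtures <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- generate_study(small_config())
  .fixtures$study
}

small_scan <- function() {
  if (is.null(.fixtures$scan))
    .fixtures$scan <- scan_study(small_study())
  .fixtures$scan
}

# a simple unspliced plus-strand transcript: ATG, then fixed codons
make_tx <- function(codons = c("ATG", "CGA", "AAA", "TGG", "CCC", "GAA",
                               "TTT", "GGG", "AAC", "TAA"),
                    strand = "+", start = 1001L, contig = "chrT",
                    introns = NULL) {
  seq <- paste(codons, collapse = "")
  len <- nchar(seq)
  if (is.null(introns)) {
    exons <- data.frame(start = start, end = start + len - 1L)
  } else {
    # introns: list of (after_base, intron_len) splitting the CDS
    cuts <- vapply(introns, `[[`, numeric(1), 1)
    ilen <- vapply(introns, `[[`, numeric(1), 2)
    lens <- diff(c(0, cuts, len))
    starts <- start + cumsum(c(0, head(lens, -1) + ilen))
    exons <- data.frame(start = starts, end = starts + lens - 1L)
  }
  transcript_model("GENE1", "TX1", contig, strand, exons, seq)
}

# minimal candidate object for exercising individual filters directly
make_candidate <- function(key = "chrT:1004:C:T", contig = "chrT",
                           pos = 1004L, ref = "C", alt = "T",
                           consequence = "stop_gain", codon_index = 2L,
                           rel_pos = 0.1, gene_id = "GENE1",
                           transcript_id = "TX1",
                           carriers = "S1", carrier_depth = c(S1 = 30L),
                           n_called = 260L,
                           pop_counts = NULL, counts_all = NULL,
                           known = FALSE, cscore = NA_real_,
                           cds_index = NA_integer_) {
  if (is.null(pop_counts))
    pop_counts <- matrix(c(200, 10, 1), 3, 1,
                         dimnames = list(c("hom_ref", "het", "hom_alt"), "P1"))
  if (is.null(counts_all))
    counts_all <- c(hom_ref = sum(pop_counts["hom_ref", ]),
                    het = sum(pop_counts["het", ]),
                    hom_alt = sum(pop_counts["hom_alt", ]))
  structure(list(
    key = key, row = 1L, contig = contig, pos = pos, ref = ref, alt = alt,
    vtype = variant_type(ref, alt),
    csq = data.frame(gene_id = gene_id, transcript_id = transcript_id,
                     consequence = consequence, cds_index = cds_index,
                     codon_index = codon_index, rel_pos = rel_pos,
                     stringsAsFactors = FALSE),
    carriers = carriers, carrier_depth = carrier_depth,
    n_called = n_called, pop_counts = pop_counts, counts_all = counts_all,
    known = known, cscore = cscore), class = "hlof_candidate")
}

# random spliced transcript for property-style consequence tests
random_tx <- function(seed, n_codons = 60, strand = c("+", "-")) {
  set.seed(seed)
  strand <- if (length(strand) > 1) sample(strand, 1) else strand
  nonstop <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                           paste0), c("A","C","G","T"), paste0)),
                     c("TAA", "TAG", "TGA"))
  seq <- paste(c("ATG", sample(nonstop, n_codons - 2, replace = TRUE), "TAA"),
               collapse = "")
  len <- nchar(seq)
  n_ex <- sample(1:3, 1)
  repeat {
    cuts <- sort(sample(seq_len(len - 1), n_ex - 1))
    lens <- diff(c(0, cuts, len))
    if (all(lens >= 9)) break
  }
  ilen <- if (n_ex > 1) sample(50:200, n_ex - 1, replace = TRUE) else integer(0)
  starts <- 2000L + cumsum(c(0, head(lens, -1) + ilen))
  transcript_model("G", "T", "chrR", strand,
                   data.frame(start = starts, end = starts + lens - 1L), seq)
}
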