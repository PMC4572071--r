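# Synthetic gene models and variant planting.
#
# Genes are placed sequentially on ~5 Mb contigs with large intergenic
# gaps (so multi-megabase runs of homozygosity are meaningful), each with
# 1-3 CDS segments and a premature-stop-free coding sequence. Planting a
# stop-gain rewrites the target codon to one that is a single substitution
# away from a stop; indels never alter the reference sequence.

.NONSTOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# ref codon, substituted position, alternate sense base, resulting stop
.STOP_SUBS <- list(
  c("CAA", "1", "T"), c("CAG", "1", "T"), c("CGA", "1", "T"),
  c("TGG", "3", "A"), c("TAC", "3", "A"), c("TCA", "2", "G"))

.sim_genes <- function(config) {
  n <- config$n_genes
  clen <- config$contig_length
  genes <- vector("list", n)
  contig_i <- 1L
  cursor <- sample(10000:30000, 1)
  for (g in seq_len(n)) {
    prot <- sample(150:350, 1)
    cds_len <- 3L * (prot + 1L)
    n_ex <- sample(1:3, 1)
    repeat {
      cuts <- sort(sample(seq_len(cds_len - 1), n_ex - 1))
      lens <- diff(c(0, cuts, cds_len))
      if (all(lens >= 60)) break
    }
    introns <- if (n_ex > 1) sample(500:2000, n_ex - 1, replace = TRUE) else integer(0)
    extent <- cds_len + sum(introns)
    if (cursor + extent > clen - 20000) {
      contig_i <- contig_i + 1L
      cursor <- sample(10000:30000, 1)
    }
    starts <- cursor + cumsum(c(0, head(lens, -1) + introns))
    exons <- data.frame(start = as.integer(starts),
                        end = as.integer(starts + lens - 1))
    seq <- paste(c("ATG", sample(.NONSTOP_CODONS, prot - 1, replace = TRUE),
                   "TAA"), collapse = "")
    genes[[g]] <- list(
      gene_id = sprintf("G%04d", g), contig = sprintf("ctg%02d", contig_i),
      strand = sample(c("+", "-"), 1), exons = exons, seq = seq,
      protein_len = prot, cds_len = cds_len)
    cursor <- cursor + extent + sample(80000:160000, 1)
  }
  contigs <- data.frame(contig = sprintf("ctg%02d", seq_len(contig_i)),
                        length = clen, stringsAsFactors = FALSE)
  list(genes = genes, contigs = contigs)
}

.gene_tx <- function(gene, suffix = "_1") {
  transcript_model(gene$gene_id, paste0(gene$gene_id, suffix), gene$contig,
                   gene$strand, gene$exons, gene$seq)
}

# --- planting primitives ------------------------------------------------

# sample() treats a length-1 numeric as 1:x; this keeps singletons literal
.sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# Rewrite codon `c` so a single substitution creates a stop; return the
# variant record. Mutates and returns the gene.
.plant_stop_gain <- function(gene, rel_range) {
  prot <- gene$protein_len
  lo <- max(2L, ceiling(rel_range[1] * prot) + 1L)
  hi <- max(lo, floor(rel_range[2] * prot) + 1L)
  hi <- min(hi, prot)
  codon <- .sample1(lo:hi)
  sub <- .STOP_SUBS[[.sample1(seq_along(.STOP_SUBS))]]
  ref_codon <- sub[1]; sub_pos <- as.integer(sub[2]); alt_sense <- sub[3]
  ci <- .codon_indices(codon)
  substr(gene$seq, ci[1], ci[3]) <- ref_codon
  tx <- .gene_tx(gene)
  idx <- ci[1] + sub_pos - 1L
  pos <- cds_to_genomic(tx, idx)
  ref <- if (gene$strand == "+") substr(ref_codon, sub_pos, sub_pos)
         else .comp(substr(ref_codon, sub_pos, sub_pos))
  alt <- if (gene$strand == "+") alt_sense else .comp(alt_sense)
  list(gene = gene,
       variant = list(contig = gene$contig, pos = pos, ref = ref, alt = alt,
                      codon = codon))
}

# Pick a second position of the same codon and a non-stop-making alternate
# allele: the companion SNP of a multi-nucleotide (same-codon) change.
.plant_codon_companion <- function(gene, codon, avoid_pos) {
  tx <- .gene_tx(gene)
  ci <- .codon_indices(codon)
  ref_codon <- substr(gene$seq, ci[1], ci[3])
  for (sub_pos in sample(1:3)) {
    idx <- ci[1] + sub_pos - 1L
    pos <- cds_to_genomic(tx, idx)
    if (pos == avoid_pos) next
    ref_sense <- substr(ref_codon, sub_pos, sub_pos)
    for (alt_sense in setdiff(c("A", "C", "G", "T"), ref_sense)) {
      cand <- ref_codon
      substr(cand, sub_pos, sub_pos) <- alt_sense
      if (cand %in% .STOP_CODONS) next
      ref <- if (gene$strand == "+") ref_sense else .comp(ref_sense)
      alt <- if (gene$strand == "+") alt_sense else .comp(alt_sense)
      return(list(contig = gene$contig, pos = pos, ref = ref, alt = alt,
                  codon = codon))
    }
  }
  stop("could not place companion SNP for MNP_CODON")
}

# Genomic-first indel planting: search exon interiors for a placement whose
# classified consequence and codon meet the request.
.plant_indel <- function(gene, type, len, rel_range, codon_target = NULL,
                         category = "indel") {
  tx <- .gene_tx(gene)
  for (try in 1:300) {
    ex <- gene$exons[sample(nrow(gene$exons), 1, prob = gene$exons$end -
                              gene$exons$start + 1), ]
    if (type == "insertion") {
      if (ex$end - ex$start < 3) next
      p <- .sample1(seq(ex$start + 1L, ex$end - 1L))
      ref <- tx_ref_base(tx, p)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      alt <- paste0(ref, ins)
    } else {
      if (ex$end - ex$start < len + 3) next
      p <- .sample1(seq(ex$start + 1L, ex$end - len - 1L))
      ref <- paste(vapply(p:(p + len), function(q) tx_ref_base(tx, q),
                          character(1)), collapse = "")
      alt <- substr(ref, 1, 1)
    }
    v <- list(pos = p, ref = ref, alt = alt)
    cc <- classify_consequence(v, tx)
    want <- if (len %% 3 == 0) "inframe" else "frameshift"
    if (cc$consequence != want) next
    rel <- (cc$codon_index - 1) / tx$protein_len
    if (rel < rel_range[1] || rel >= rel_range[2]) next
    if (!is.null(codon_target) &&
        !(cc$codon_index > codon_target[1] &&
          cc$codon_index - codon_target[1] < codon_target[2])) next
    return(list(contig = gene$contig, pos = p, ref = ref, alt = alt,
                codon = cc$codon_index))
  }
  stop("could not place ", category, " variant in gene ", gene$gene_id,
       " (transcript too short or exon structure unsuitable)")
}
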