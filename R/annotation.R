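#' Variant call sets
#'
#' A call set bundles normalized biallelic variant records with per-sample
#' genotype and depth matrices. Genotypes are coded 0 (hom ref), 1 (het),
#' 2 (hom alt) and `NA` (missing).
#'
#' @param variants data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @param geno integer matrix, variants x samples.
#' @param depth integer matrix, variants x samples.
#' @param samples data.frame with columns `sample_id`, `population`.
#' @return A `hlof_callset` list.
#' @export
hlof_callset <- function(variants, geno, depth, samples) {
  stopifnot(nrow(variants) == nrow(geno), nrow(geno) == nrow(depth),
            ncol(geno) == nrow(samples), ncol(depth) == nrow(samples))
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  variants$vtype <- variant_type(variants$ref, variants$alt)
  variants$key <- variant_key(variants)
  rownames(geno) <- rownames(depth) <- variants$key
  colnames(geno) <- colnames(depth) <- samples$sample_id
  structure(list(variants = variants, geno = geno, depth = depth,
                 samples = samples), class = "hlof_callset")
}

#' @export
print.hlof_callset <- function(x, ...) {
  cat(sprintf("<hlof_callset: %d variants x %d samples (%d populations)>\n",
              nrow(x$variants), nrow(x$samples),
              length(unique(x$samples$population))))
  invisible(x)
}

#' Canonical variant key
#' @param v data.frame with `contig`, `pos`, `ref`, `alt`.
#' @return character vector "contig:pos:ref:alt".
#' @export
variant_key <- function(v) paste(v$contig, v$pos, v$ref, v$alt, sep = ":")

#' Variant type from allele strings
#' @param ref,alt Allele strings.
#' @return "SNV", "insertion" or "deletion".
#' @export
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

# signed indel length: inserted bases positive, deleted negative; 0 for SNV
indel_length <- function(ref, alt) nchar(alt) - nchar(ref)

#' Decompose multi-allelic records into biallelic variant records
#'
#' Each input record carries a reference allele, one or more alternate
#' alleles, and per-sample genotypes given as allele-index pairs (e.g.
#' "1/2"). Every alternate allele becomes its own biallelic record whose
#' per-sample genotype is the count of that allele, so the total
#' alternate-allele dosage of each sample is conserved across the split.
#' Symbolic and breakend alleles are skipped with a message.
#'
#' @param records list of records, each a list with `contig`, `pos`, `ref`,
#'   `alt` (character vector of alternate alleles) and `gt` (character
#'   vector of per-sample genotypes "a/b" with "." for missing alleles).
#' @return data.frame of biallelic records plus a genotype matrix, as a
#'   list `(variants, geno)` aligned row-wise.
#' @export
decompose_multiallelic <- function(records) {
  out_var <- list(); out_geno <- list()
  for (rec in records) {
    alts <- rec$alt
    keep <- !grepl("[][<>]", alts)
    if (any(!keep))
      message("skipping symbolic/breakend allele(s) at ", rec$contig, ":", rec$pos)
    gtm <- .parse_gt_pairs(rec$gt)  # samples x 2 allele indices (NA = missing)
    for (ai in which(keep)) {
      cnt <- rowSums(gtm == ai, na.rm = TRUE)
      cnt[rowSums(is.na(gtm)) == 2L] <- NA_integer_
      out_var[[length(out_var) + 1L]] <- data.frame(
        contig = rec$contig, pos = rec$pos, ref = rec$ref, alt = alts[ai],
        stringsAsFactors = FALSE)
      out_geno[[length(out_geno) + 1L]] <- as.integer(cnt)
    }
  }
  variants <- do.call(rbind, out_var)
  geno <- do.call(rbind, out_geno)
  list(variants = variants, geno = geno)
}

.parse_gt_pairs <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  t(vapply(parts, function(p) {
    p <- suppressWarnings(as.integer(p))
    c(p[1], if (length(p) > 1) p[2] else NA_integer_)
  }, integer(2)))
}

#' Classify the coding consequence of a variant in one transcript
#'
#' Single-nucleotide variants are classified by translating the affected
#' codon (strand-aware): an alternate codon that is a stop while the
#' reference codon is not yields `stop_gain`. Coding indels whose in-CDS
#' length is not a multiple of three are `frameshift`; multiples of three
#' are `inframe` -- never frameshift, however disruptive. Variants outside
#' the CDS are `non_coding`.
#'
#' @param variant list or one-row data.frame with `pos`, `ref`, `alt`.
#' @param tx A [transcript_model()].
#' @return list with `consequence`, `cds_index` (first affected CDS base),
#'   `codon_index`.
#' @export
classify_consequence <- function(variant, tx) {
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  vt <- variant_type(ref, alt)
  none <- list(consequence = "non_coding", cds_index = NA_integer_,
               codon_index = NA_integer_)
  if (vt == "SNV") {
    idx <- genomic_to_cds(tx, pos)
    if (is.na(idx)) return(none)
    codon <- .codon_of(idx)
    ci <- .codon_indices(codon)
    if (any(ci > tx$cds_len)) stop("incomplete codon context at CDS index ", idx)
    ref_codon <- substr(tx$cds_seq, ci[1], ci[3])
    alt_base <- if (tx$strand == "+") alt else .comp(alt)
    within <- idx - ci[1] + 1L
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_base
    ref_stop <- ref_codon %in% .STOP_CODONS
    alt_stop <- alt_codon %in% .STOP_CODONS
    csq <- if (alt_stop && !ref_stop) "stop_gain"
    else if (alt_codon == ref_codon ||
             (!ref_stop && !alt_stop &&
              .translate_codon(ref_codon) == .translate_codon(alt_codon)))
      "synonymous"
    else "missense"
    return(list(consequence = csq, cds_index = idx, codon_index = codon))
  }
  # indel; VCF left-anchored: first changed genomic base is pos + 1 for both
  # insertions (bases appear after the anchor) and deletions (ref[2..] removed)
  if (vt == "deletion") {
    span <- seq.int(pos + 1L, pos + nchar(ref) - 1L)
    idxs <- vapply(span, function(p) genomic_to_cds(tx, p), integer(1))
    in_cds <- sum(!is.na(idxs))
    if (in_cds == 0) return(none)
    first_idx <- min(idxs, na.rm = TRUE)
    csq <- if (in_cds %% 3 != 0) "frameshift" else "inframe"
    return(list(consequence = csq, cds_index = as.integer(first_idx),
                codon_index = .codon_of(first_idx)))
  }
  # insertion between pos and pos + 1
  ins_len <- nchar(alt) - nchar(ref)
  idx_a <- genomic_to_cds(tx, pos)
  idx_b <- genomic_to_cds(tx, pos + 1L)
  if (is.na(idx_a) || is.na(idx_b)) return(none)  # insertion point not strictly inside CDS
  first_idx <- min(idx_a, idx_b) + 1L  # first transcript base pushed downstream
  csq <- if (ins_len %% 3 != 0) "frameshift" else "inframe"
  list(consequence = csq, cds_index = as.integer(first_idx),
       codon_index = .codon_of(as.integer(first_idx)))
}

#' Relative position of a coding variant within a transcript's protein
#'
#' Defined as (first affected codon index - 1) / protein length, i.e. 0 for
#' the start codon. Variants beyond the last 10% of any transcript of a
#' gene are candidates for removal downstream.
#'
#' @param variant list with `pos`, `ref`, `alt`.
#' @param tx A [transcript_model()].
#' @return Fraction in `[0, 1]`.
#' @export
relative_position <- function(variant, tx) {
  if (tx$protein_len <= 0) stop("zero-length protein in ", tx$transcript_id)
  cc <- classify_consequence(variant, tx)
  if (cc$consequence == "non_coding")
    stop("variant is non-coding in transcript ", tx$transcript_id)
  (cc$codon_index - 1) / tx$protein_len
}

#' Identify candidate HLOF variants in a call set
#'
#' A candidate is any biallelic record that is homozygous for the alternate
#' allele in at least one individual and is a stop-gain or frameshift in at
#' least one transcript. Per-transcript consequences and relative
#' positions, carrier lists, per-population genotype counts (restricted to
#' individuals at the coverage floor used for frequency work), the
#' known-catalogue flag and any supplied deleteriousness score are
#' attached.
#'
#' @param callset A [hlof_callset()].
#' @param transcripts list of [transcript_model()]s.
#' @param known_catalogue optional data.frame `contig`, `pos`, `ref`, `alt`
#'   of previously observed variants.
#' @param cscores optional data.frame `contig`, `pos`, `ref`, `alt`, `cscore`.
#' @param min_depth coverage floor for the per-population genotype counts
#'   used in frequency-based filters (default 5).
#' @return list of `hlof_candidate` objects.
#' @export
identify_candidates <- function(callset, transcripts, known_catalogue = NULL,
                                cscores = NULL, min_depth = 5) {
  v <- callset$variants
  known_keys <- if (!is.null(known_catalogue) && nrow(known_catalogue))
    variant_key(known_catalogue) else character(0)
  cscore_map <- if (!is.null(cscores) && nrow(cscores))
    setNames(cscores$cscore, variant_key(cscores)) else NULL
  # restrict consequence work to records whose reference span touches a CDS
  cds_tbl <- do.call(rbind, lapply(seq_along(transcripts), function(t) {
    tx <- transcripts[[t]]
    data.frame(t = t, contig = tx$contig, start = tx$exons$start,
               end = tx$exons$end, stringsAsFactors = FALSE)
  }))
  cds_gr <- GenomicRanges::GRanges(cds_tbl$contig,
                                   IRanges::IRanges(cds_tbl$start, cds_tbl$end))
  site_gr <- GenomicRanges::GRanges(v$contig,
    IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, cds_gr))
  tx_hits <- lapply(split(cds_tbl$t[S4Vectors::subjectHits(ov)],
                          S4Vectors::queryHits(ov)), unique)
  pops <- sort(unique(callset$samples$population))
  out <- list()
  for (i in seq_len(nrow(v))) {
    hits <- tx_hits[[as.character(i)]]
    if (is.null(hits)) next
    g <- callset$geno[i, ]
    carriers <- callset$samples$sample_id[!is.na(g) & g == 2L]
    if (length(carriers) == 0) next
    txs <- transcripts[hits]
    csq <- .consequence_table(v[i, ], txs)
    if (is.null(csq) || !any(csq$consequence %in% c("stop_gain", "frameshift")))
      next
    d <- callset$depth[i, ]
    keep <- !is.na(g) & !is.na(d) & d >= min_depth
    pop_counts <- vapply(pops, function(p) {
      sel <- keep & callset$samples$population == p
      c(hom_ref = sum(g[sel] == 0L), het = sum(g[sel] == 1L),
        hom_alt = sum(g[sel] == 2L))
    }, numeric(3))
    key <- v$key[i]
    out[[length(out) + 1L]] <- structure(list(
      key = key, row = i, contig = v$contig[i], pos = v$pos[i],
      ref = v$ref[i], alt = v$alt[i], vtype = v$vtype[i],
      csq = csq, carriers = carriers,
      carrier_depth = setNames(d[!is.na(g) & g == 2L], carriers),
      n_called = sum(!is.na(g)),
      pop_counts = pop_counts,
      counts_all = c(hom_ref = sum(g == 0L, na.rm = TRUE),
                     het = sum(g == 1L, na.rm = TRUE),
                     hom_alt = sum(g == 2L, na.rm = TRUE)),
      known = key %in% known_keys,
      cscore = if (!is.null(cscore_map)) unname(cscore_map[key]) else NA_real_
    ), class = "hlof_candidate")
  }
  out
}

# per-transcript consequence table for one variant record
.consequence_table <- function(variant, txs) {
  rows <- lapply(txs, function(tx) {
    cc <- classify_consequence(variant, tx)
    if (cc$consequence == "non_coding") return(NULL)
    data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               consequence = cc$consequence, cds_index = cc$cds_index,
               codon_index = cc$codon_index,
               rel_pos = (cc$codon_index - 1) / tx$protein_len,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.hlof_candidate <- function(x, ...) {
  cat(sprintf("<hlof_candidate %s [%s] %d carrier(s), %s>\n", x$key, x$vtype,
              length(x$carriers),
              paste(unique(x$csq$consequence), collapse = "/")))
  invisible(x)
}
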