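#' Options controlling the artifact-filter cascade
#'
#' Defaults reproduce the survey's stated thresholds: relative transcript
#' position < 0.9, at least 200 genotyped individuals, 50 bp capture-target
#' padding, Hardy-Weinberg alpha 0.01 on individuals covered at >= 5x,
#' minimum 20x coverage in at least one homozygote for novel variants, and
#' frame-restoration checked within 10 amino acids.
#'
#' @param rel_pos_max Variants at or beyond this fraction of a transcript
#'   fail the relative-position filter.
#' @param rel_pos_mode `"all"` (conservative: must be early in every coding
#'   transcript of the gene) or `"any"` (early in at least one).
#' @param min_called Minimum number of genotyped (non-missing) individuals.
#' @param pad Capture-target padding in bp.
#' @param hwe_alpha One-sided significance level of the homozygote-excess test.
#' @param min_depth Coverage floor for inclusion in frequency/HWE counts.
#' @param min_hom_depth Coverage required in at least one homozygote for
#'   variants absent from the known catalogue.
#' @param rescue_max_gap_aa Frameshifts closer than this many amino acids
#'   are considered neighbours for frame-restoration.
#' @param rescue_mode `"transcript"` (all homozygous frameshifts of a
#'   transcript interact) or `"carrier"` (only frameshifts sharing a
#'   homozygous carrier interact).
#' @return list of options.
#' @export
cascade_options <- function(rel_pos_max = 0.9,
                            rel_pos_mode = c("all", "any"),
                            min_called = 200,
                            pad = 50,
                            hwe_alpha = 0.01,
                            min_depth = 5,
                            min_hom_depth = 20,
                            rescue_max_gap_aa = 10,
                            rescue_mode = c("transcript", "carrier")) {
  list(rel_pos_max = rel_pos_max, rel_pos_mode = match.arg(rel_pos_mode),
       min_called = min_called, pad = pad, hwe_alpha = hwe_alpha,
       min_depth = min_depth, min_hom_depth = min_hom_depth,
       rescue_max_gap_aa = rescue_max_gap_aa,
       rescue_mode = match.arg(rescue_mode))
}

.overlaps_any <- function(query, subject) {
  # seqlevels differ between tracks and variants routinely; that is not
  # worth a warning per lookup
  length(suppressWarnings(GenomicRanges::findOverlaps(query, subject))) > 0
}

.decision <- function(key, filter, pass, reason = "") {
  data.frame(key = key, filter = filter, pass = pass, reason = reason,
             stringsAsFactors = FALSE)
}

#' Relative-position filter
#'
#' Keeps variants lying in the first 90% (by default) of the protein in
#' every transcript of the gene in which the variant is coding; variants in
#' the last 10% of any transcript fail under the conservative mode.
#'
#' @param candidate An `hlof_candidate`.
#' @param opts [cascade_options()].
#' @return One-row decision data.frame.
#' @export
filter_relative_position <- function(candidate, opts = cascade_options()) {
  rp <- candidate$csq$rel_pos
  if (length(rp) == 0)
    return(.decision(candidate$key, "relative_position", FALSE,
                     "no coding transcript"))
  ok <- if (opts$rel_pos_mode == "all") all(rp < opts$rel_pos_max)
        else any(rp < opts$rel_pos_max)
  .decision(candidate$key, "relative_position", ok,
            sprintf("rel_pos=%s", paste(round(rp, 3), collapse = ",")))
}

#' Mapability / blacklist filter
#'
#' Fails a variant if any base of its reference span overlaps a region of
#' alignability score below 1 in either alignability track, or any
#' blacklisted interval.
#'
#' @param candidate An `hlof_candidate`.
#' @param tracks list with `alignability` (list of GRanges of low-score
#'   regions) and `blacklist` (GRanges).
#' @return One-row decision data.frame.
#' @export
filter_mapability <- function(candidate, tracks) {
  span <- GenomicRanges::GRanges(candidate$contig,
    IRanges::IRanges(candidate$pos, candidate$pos + nchar(candidate$ref) - 1L))
  bad <- vapply(c(tracks$alignability, list(tracks$blacklist)), function(gr) {
    .overlaps_any(span, gr)
  }, logical(1))
  .decision(candidate$key, "mapability", !any(bad),
            if (any(bad)) "overlaps low-alignability/blacklist region" else "")
}

#' Minimum-genotyped-individuals filter
#' @param candidate An `hlof_candidate`.
#' @param opts [cascade_options()].
#' @return One-row decision data.frame.
#' @export
filter_min_samples <- function(candidate, opts = cascade_options()) {
  .decision(candidate$key, "min_samples", candidate$n_called >= opts$min_called,
            sprintf("called=%d", candidate$n_called))
}

#' Capture-kit intersection filter
#'
#' Keeps variants whose position lies within the padded targets of *both*
#' capture kits, so cross-population comparisons are confined to regions
#' both designs enrich.
#'
#' @param candidate An `hlof_candidate`.
#' @param kit_a,kit_b GRanges of capture targets.
#' @param opts [cascade_options()].
#' @return One-row decision data.frame.
#' @export
filter_capture_intersection <- function(candidate, kit_a, kit_b,
                                        opts = cascade_options()) {
  if (length(kit_a) == 0 || length(kit_b) == 0)
    return(.decision(candidate$key, "capture_intersection", FALSE,
                     "empty capture track"))
  p <- GenomicRanges::GRanges(candidate$contig,
                              IRanges::IRanges(candidate$pos, candidate$pos))
  in_a <- .overlaps_any(p, kit_a + opts$pad)
  in_b <- .overlaps_any(p, kit_b + opts$pad)
  .decision(candidate$key, "capture_intersection", in_a && in_b,
            if (in_a && in_b) "" else "outside padded intersection of kits")
}

#' Primate ancestral-allele filter
#'
#' Stop-gains fail if one or more primate species carries the human
#' alternate allele at the aligned site. Frameshifts fail only if at least
#' two primates have aligning sequence, all aligned species carry the
#' non-reference variant, and the position, length and type of the primate
#' indel match the human one. Sites absent from the table pass.
#'
#' @param candidate An `hlof_candidate`.
#' @param primates data.frame with columns `contig`, `pos`, `species`,
#'   `aligned` (logical), `allele`, `indel_type`, `indel_len`.
#' @return One-row decision data.frame.
#' @export
filter_ancestral <- function(candidate, primates) {
  rows <- primates[primates$contig == candidate$contig &
                   primates$pos == candidate$pos, , drop = FALSE]
  if (nrow(rows) == 0)
    return(.decision(candidate$key, "ancestral", TRUE, "no primate alignment"))
  aligned <- rows[rows$aligned, , drop = FALSE]
  if (candidate$vtype == "SNV") {
    hit <- any(aligned$allele == candidate$alt)
    return(.decision(candidate$key, "ancestral", !hit,
                     if (hit) "primate carries human alt allele" else ""))
  }
  match_var <- nrow(aligned) >= 2 &&
    all(aligned$indel_type == candidate$vtype) &&
    all(aligned$indel_len == abs(indel_length(candidate$ref, candidate$alt)))
  .decision(candidate$key, "ancestral", !match_var,
            if (match_var) "matching indel in >=2 aligned primates" else "")
}

#' Same-codon SNP (MNP) filter
#'
#' A stop-gain is unreliable when another called SNP falls inside the same
#' codon in any transcript where the candidate is a stop-gain: the joint
#' multi-nucleotide change may not create a stop at all. Frameshifts pass
#' unconditionally here.
#'
#' @param candidate An `hlof_candidate`.
#' @param callset The full [hlof_callset()] (all called records).
#' @param transcripts list of [transcript_model()]s, named or not.
#' @return One-row decision data.frame.
#' @export
filter_mnp_codon <- function(candidate, callset, transcripts) {
  sg <- candidate$csq[candidate$csq$consequence == "stop_gain", , drop = FALSE]
  if (nrow(sg) == 0)
    return(.decision(candidate$key, "mnp_codon", TRUE, "not a stop-gain"))
  tx_map <- setNames(transcripts,
                     vapply(transcripts, `[[`, character(1), "transcript_id"))
  v <- callset$variants
  snv <- v$vtype == "SNV" & v$key != candidate$key
  for (j in seq_len(nrow(sg))) {
    tx <- tx_map[[sg$transcript_id[j]]]
    codon_pos <- vapply(.codon_indices(sg$codon_index[j]),
                        function(i) cds_to_genomic(tx, i), integer(1))
    hit <- snv & v$contig == candidate$contig & v$pos %in% codon_pos
    if (any(hit))
      return(.decision(candidate$key, "mnp_codon", FALSE,
                       paste("other SNP in codon:", v$key[which(hit)[1]])))
  }
  .decision(candidate$key, "mnp_codon", TRUE, "")
}

#' Frameshift frame-restoration (rescue) filter
#'
#' Within each transcript, homozygous frameshifts are chained when
#' consecutive affected codons are fewer than `rescue_max_gap_aa` amino
#' acids apart. A lone frameshift passes; a near pair fails when the signed
#' sum of inserted/deleted bases is a multiple of three (the reading frame
#' is restored downstream); three or more chained frameshifts all fail,
#' because some combination restoring the frame is possible. In
#' `"carrier"` mode two frameshifts interact only when at least one
#' individual is homozygous for both.
#'
#' @param candidates list of `hlof_candidate`s (the full candidate set).
#' @param opts [cascade_options()].
#' @return decision data.frame with one row per frameshift candidate.
#' @export
filter_frameshift_rescue <- function(candidates, opts = cascade_options()) {
  rows <- list()
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    fs <- cand$csq[cand$csq$consequence == "frameshift", , drop = FALSE]
    if (nrow(fs) == 0) next
    for (j in seq_len(nrow(fs)))
      rows[[length(rows) + 1L]] <- data.frame(
        idx = k, key = cand$key, transcript_id = fs$transcript_id[j],
        codon = fs$codon_index[j],
        len = indel_length(cand$ref, cand$alt), stringsAsFactors = FALSE)
  }
  fs_keys <- unique(vapply(rows, function(r) r$key, character(1)))
  failed <- character(0)
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    for (tx_id in unique(tab$transcript_id)) {
      sub <- tab[tab$transcript_id == tx_id, , drop = FALSE]
      sub <- sub[order(sub$codon), , drop = FALSE]
      if (nrow(sub) < 2) next
      linked <- diff(sub$codon) < opts$rescue_max_gap_aa
      if (opts$rescue_mode == "carrier") {
        share <- vapply(seq_len(nrow(sub) - 1), function(i) {
          length(intersect(candidates[[sub$idx[i]]]$carriers,
                           candidates[[sub$idx[i + 1]]]$carriers)) > 0
        }, logical(1))
        linked <- linked & share
      }
      comp <- cumsum(c(TRUE, !linked))
      for (g in split(seq_len(nrow(sub)), comp)) {
        if (length(g) == 1) next
        if (length(g) >= 3 || sum(sub$len[g]) %% 3 == 0)
          failed <- c(failed, sub$key[g])
      }
    }
  }
  if (length(fs_keys) == 0) return(.decision(character(0), character(0), logical(0)))
  do.call(rbind, lapply(fs_keys, function(k) {
    .decision(k, "frameshift_rescue", !(k %in% failed),
              if (k %in% failed) "reading frame restored by nearby frameshift(s)" else "")
  }))
}

#' Hardy-Weinberg homozygote-excess filter
#'
#' Applies [hwe_excess_test()] to each population separately (individuals
#' covered at the coverage floor only, via the candidate's per-population
#' counts); the variant fails when any population rejects at `hwe_alpha`.
#'
#' @param candidate An `hlof_candidate`.
#' @param opts [cascade_options()].
#' @return One-row decision data.frame.
#' @export
filter_hwe <- function(candidate, opts = cascade_options()) {
  pc <- candidate$pop_counts
  ps <- vapply(colnames(pc), function(p) {
    cnt <- pc[, p]
    if (sum(cnt) == 0) return(1)
    hwe_excess_test(cnt["hom_ref"], cnt["het"], cnt["hom_alt"])
  }, numeric(1))
  bad <- ps < opts$hwe_alpha
  .decision(candidate$key, "hwe", !any(bad),
            if (any(bad))
              sprintf("homozygote excess in %s (P=%.3g)",
                      names(ps)[which(bad)[1]], ps[which(bad)[1]])
            else sprintf("min P=%.3g", min(ps)))
}

#' Homozygote-coverage filter
#'
#' Novel variants (absent from the known catalogue) must be covered at
#' `min_hom_depth` in at least one homozygous carrier; previously validated
#' variants pass regardless of depth.
#'
#' @param candidate An `hlof_candidate`.
#' @param opts [cascade_options()].
#' @return One-row decision data.frame.
#' @export
filter_coverage <- function(candidate, opts = cascade_options()) {
  ok <- isTRUE(candidate$known) ||
    any(candidate$carrier_depth >= opts$min_hom_depth, na.rm = TRUE)
  .decision(candidate$key, "coverage", ok,
            sprintf("known=%s max_hom_depth=%d", candidate$known,
                    suppressWarnings(max(c(candidate$carrier_depth, 0L),
                                         na.rm = TRUE))))
}

#' Fixed / nearly fixed reference-error filter
#'
#' Variants homozygous-alternate in essentially the whole cohort (no
#' homozygous-reference individual and at most one heterozygote across all
#' populations) are treated as errors or rare alleles in the reference
#' sequence and removed.
#'
#' @param candidate An `hlof_candidate`.
#' @return One-row decision data.frame.
#' @export
filter_near_fixed <- function(candidate) {
  tot <- candidate$counts_all
  fixed <- tot["hom_ref"] == 0 && tot["het"] <= 1
  .decision(candidate$key, "near_fixed", !fixed,
            if (fixed) "no hom-ref and <=1 het cohort-wide" else "")
}

#' Run the full filter cascade with single-filter accounting
#'
#' Every filter is evaluated independently on every candidate, mirroring
#' published per-filter accounting: the audit reports how many candidates
#' survive each filter applied alone, and how many survive all filters
#' (the intersection of the single-filter pass sets, so the result is
#' order-independent).
#'
#' @param candidates list of `hlof_candidate`s.
#' @param resources list with `tracks` (list: `alignability` list of
#'   GRanges, `blacklist`, `kit_a`, `kit_b`), `primates` table,
#'   `transcripts`, and `callset`.
#' @param opts [cascade_options()].
#' @return list with `survivors` (keys), `survivor_candidates`,
#'   `decisions` (long data.frame) and `audit` (per-filter counts).
#' @export
run_cascade <- function(candidates, resources, opts = cascade_options()) {
  for (r in c("tracks", "primates", "transcripts", "callset"))
    if (is.null(resources[[r]]))
      stop("missing cascade resource: ", r)
  per_cand <- lapply(candidates, function(cand) rbind(
    filter_relative_position(cand, opts),
    filter_min_samples(cand, opts),
    filter_ancestral(cand, resources$primates),
    filter_mnp_codon(cand, resources$callset, resources$transcripts),
    filter_hwe(cand, opts),
    filter_coverage(cand, opts),
    filter_near_fixed(cand)))
  decisions <- rbind(do.call(rbind, per_cand),
                     .filter_mapability_all(candidates, resources$tracks),
                     .filter_capture_all(candidates, resources$tracks$kit_a,
                                         resources$tracks$kit_b, opts))
  fs <- filter_frameshift_rescue(candidates, opts)
  if (nrow(fs)) decisions <- rbind(decisions, fs)
  keys <- vapply(candidates, `[[`, character(1), "key")
  fail_keys <- unique(decisions$key[!decisions$pass])
  survivors <- setdiff(keys, fail_keys)
  filters <- unique(decisions$filter)
  audit <- data.frame(
    filter = filters,
    n_pass_alone = vapply(filters, function(f) {
      d <- decisions[decisions$filter == f, ]
      # filters that only apply to a subset (e.g. frameshift rescue) do not
      # remove candidates they never saw
      length(keys) - sum(!d$pass)
    }, numeric(1)),
    row.names = NULL)
  audit <- rbind(audit, data.frame(filter = "all_filters",
                                   n_pass_alone = length(survivors)))
  list(survivors = survivors,
       survivor_candidates = candidates[keys %in% survivors],
       decisions = decisions, audit = audit)
}

# vectorized equivalents of filter_mapability()/filter_capture_intersection()
# used by run_cascade(): one interval query for the whole candidate set
.cand_span_gr <- function(candidates) {
  GenomicRanges::GRanges(
    vapply(candidates, `[[`, character(1), "contig"),
    IRanges::IRanges(
      vapply(candidates, `[[`, numeric(1), "pos"),
      vapply(candidates, function(x) x$pos + nchar(x$ref) - 1L, numeric(1))))
}

.filter_mapability_all <- function(candidates, tracks) {
  if (length(candidates) == 0)
    return(.decision(character(0), character(0), logical(0)))
  span <- .cand_span_gr(candidates)
  low <- suppressWarnings(c(tracks$alignability[[1]], tracks$alignability[[2]],
                            tracks$blacklist))
  bad <- suppressWarnings(IRanges::overlapsAny(span, low))
  .decision(vapply(candidates, `[[`, character(1), "key"), "mapability", !bad,
            ifelse(bad, "overlaps low-alignability/blacklist region", ""))
}

.filter_capture_all <- function(candidates, kit_a, kit_b,
                                opts = cascade_options()) {
  if (length(candidates) == 0)
    return(.decision(character(0), character(0), logical(0)))
  keys <- vapply(candidates, `[[`, character(1), "key")
  if (length(kit_a) == 0 || length(kit_b) == 0)
    return(.decision(keys, "capture_intersection", rep(FALSE, length(keys)),
                     "empty capture track"))
  p <- GenomicRanges::GRanges(
    vapply(candidates, `[[`, character(1), "contig"),
    IRanges::IRanges(vapply(candidates, `[[`, numeric(1), "pos"),
                     vapply(candidates, `[[`, numeric(1), "pos")))
  ok <- suppressWarnings(IRanges::overlapsAny(p, kit_a + opts$pad)) &
    suppressWarnings(IRanges::overlapsAny(p, kit_b + opts$pad))
  .decision(keys, "capture_intersection", ok,
            ifelse(ok, "", "outside padded intersection of kits"))
}

#' Filters failed by each candidate
#' @param decisions decision data.frame from [run_cascade()].
#' @return named list: key -> character vector of failed filter names.
#' @export
failing_filters <- function(decisions) {
  bad <- decisions[!decisions$pass, , drop = FALSE]
  split(bad$filter, bad$key)
}
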