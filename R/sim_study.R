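#' Generate a complete synthetic HLOF study with planted ground truth
#'
#' Builds an internally consistent study bundle: synthetic transcript
#' models, a multi-population cohort with per-individual runs of
#' homozygosity (ROHs), genotype and depth matrices over planted true HLOF
#' variants, planted artifact variants of every filter-target category,
#' neutral Hardy-Weinberg sites, mapability/blacklist/capture tracks, a
#' primate allele table, deleteriousness scores, a known-variant
#' catalogue, gene annotations, and a quantitative phenotype matrix with
#' an optional planted burden effect. A truth table maps every planted
#' candidate variant to its category and the filter expected to remove it.
#'
#' Genotypes at non-forced sites are drawn under Hardy-Weinberg
#' equilibrium given the simulated allele frequency, except that
#' individuals whose ROH covers the site are drawn autozygous (homozygous
#' for one allele). Planted variants that must *pass* the cascade are
#' drawn conditionally: heterozygous support is added (or the column
#' redrawn) until the per-population exact homozygote-excess P-value
#' clears a margin, so chance rejections cannot contaminate the planted
#' truth. Planted genotyping-error variants are constructed to fail the
#' test at the nominal level.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, the bundle is also written
#'   to standard formats (VCF, GTF, FASTA, BED, PLINK .hom, TSV) via
#'   [write_study()].
#' @return A `hlof_study` list with elements `config`, `samples`,
#'   `contigs`, `transcripts`, `callset`, `tracks`, `primates`, `roh`,
#'   `phenotypes`, `truth`, `tables`, `burden`.
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  samples <- data.frame(
    sample_id = unlist(lapply(seq_len(nrow(pops)), function(i)
      sprintf("%s_%04d", pops$name[i], seq_len(pops$size[i])))),
    population = rep(pops$name, pops$size), stringsAsFactors = FALSE)
  n_ind <- nrow(samples)

  sg <- .sim_genes(config)
  genes <- sg$genes; contigs <- sg$contigs

  plan <- .sim_plan(config)
  if (length(plan) > length(genes))
    stop("n_genes too small for the requested planting plan")
  gene_order <- sample(length(genes))

  # plant variants gene by gene; stop-gain planting rewrites the codon
  planted <- list()
  for (u in seq_along(plan)) {
    unit <- plan[[u]]
    gi <- gene_order[u]
    res <- .plant_unit(genes[[gi]], unit)
    genes[[gi]] <- res$gene
    for (v in res$variants) {
      v$gene_idx <- gi
      planted[[length(planted) + 1L]] <- v
    }
  }
  planted_gene_idx <- unique(vapply(planted, `[[`, numeric(1), "gene_idx"))

  transcripts <- .build_transcripts(genes, planted_gene_idx, config)

  # neutral non-coding sites in intergenic space
  neutral <- .sim_neutral_sites(config, genes, contigs)

  # base ROHs, then forced autozygosity for designated rare carriers
  planted <- .assign_carriers(planted, samples, pops)
  roh <- .sim_roh(config, samples, contigs)
  roh <- .force_carrier_roh(roh, planted, config, contigs)
  roh <- suppressWarnings(merge_roh(roh))

  # assemble the variant table (planted + neutral), sorted
  vtab <- rbind(
    do.call(rbind, lapply(planted, function(v)
      data.frame(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
                 stringsAsFactors = FALSE))),
    neutral[, c("contig", "pos", "ref", "alt")])
  meta <- c(planted, lapply(seq_len(nrow(neutral)), function(i)
    list(category = "NEUTRAL", role = "neutral", af = neutral$af[i])))
  ord <- order(vtab$contig, vtab$pos)
  vtab <- vtab[ord, , drop = FALSE]; meta <- meta[ord]
  if (anyDuplicated(paste(vtab$contig, vtab$pos)))
    stop("position collision among simulated sites")

  depth <- .sim_depth(vtab, samples, pops)
  autoz <- .autozygous_index(vtab, roh, samples)
  gm <- .sim_genotypes(vtab, meta, samples, pops, depth, autoz, config)
  geno <- gm$geno; depth <- gm$depth

  callset <- hlof_callset(vtab, geno, depth, samples)
  truth <- .truth_table(callset$variants, meta)

  tracks <- .sim_tracks(genes, planted, contigs)
  primates <- .sim_primates(callset$variants, meta)
  tables <- .sim_tables(config, genes, callset, meta, truth)

  true_rows <- which(truth$category == "TRUE_HLOF")
  true_keys <- truth$key[true_rows]
  burden <- colSums(geno[callset$variants$key %in% true_keys, , drop = FALSE] == 2L,
                    na.rm = TRUE)
  phenotypes <- sim_phenotype_matrix(
    burden, n_traits = config$trait_count,
    beta = config$burden_effect_beta,
    missing_rate = config$trait_missing_rate)
  rownames(phenotypes) <- samples$sample_id

  study <- structure(list(
    config = config, samples = samples, contigs = contigs,
    transcripts = transcripts, callset = callset, tracks = tracks,
    primates = primates, roh = roh, phenotypes = phenotypes, truth = truth,
    tables = tables, burden = burden), class = "hlof_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.hlof_study <- function(x, ...) {
  cat(sprintf(paste0("<hlof_study: %d samples, %d sites (%d planted candidates),",
                     " %d transcripts, %d ROH intervals>\n"),
              nrow(x$samples), nrow(x$callset$variants), nrow(x$truth),
              length(x$transcripts), nrow(x$roh)))
  invisible(x)
}

# --- planting plan ------------------------------------------------------

.sim_plan <- function(config) {
  n_true <- config$n_true_hlof
  n_common <- round(0.145 * n_true)
  n_medium <- round(0.16 * n_true)
  n_rare <- n_true - n_common - n_medium
  n_rare_roh <- round(0.7 * n_rare)
  subclass <- c(rep("common_cosmo", floor(n_common / 2)),
                rep("common_pan", n_common - floor(n_common / 2)),
                rep("medium", n_medium),
                rep("rare_roh", n_rare_roh),
                rep("rare_plain", n_rare - n_rare_roh))
  stop_frac <- 94 / 173
  plan <- lapply(sample(subclass), function(sc) list(
    category = "TRUE_HLOF", subclass = sc,
    vtype = if (runif(1) < stop_frac) "stop_gain" else "frameshift"))
  ac <- config$artifact_counts
  add <- function(category, n, vtype_fun) {
    lapply(seq_len(n), function(i)
      list(category = category, subclass = "artifact", vtype = vtype_fun()))
  }
  mixed <- function() if (runif(1) < 0.5) "stop_gain" else "frameshift"
  plan <- c(plan,
    add("LAST10PCT", ac[["LAST10PCT"]], mixed),
    add("LOW_MAPABILITY", ac[["LOW_MAPABILITY"]], mixed),
    add("OFF_TARGET", ac[["OFF_TARGET"]], mixed),
    add("FEW_SAMPLES", ac[["FEW_SAMPLES"]], mixed),
    add("ANCESTRAL", ac[["ANCESTRAL"]], mixed),
    add("MNP_CODON", ac[["MNP_CODON"]], function() "stop_gain"),
    add("FRAME_RESCUE", ac[["FRAME_RESCUE"]], function() "frameshift"),
    add("INFRAME", ac[["INFRAME"]], function() "inframe"),
    add("HWE_EXCESS", ac[["HWE_EXCESS"]], function() "stop_gain"),
    add("LOW_COVERAGE", ac[["LOW_COVERAGE"]], mixed),
    add("NEAR_FIXED", ac[["NEAR_FIXED"]], function() "stop_gain"))
  plan
}

# Plant one unit in one gene; returns updated gene + variant spec list.
.plant_unit <- function(gene, unit) {
  cat_ <- unit$category
  rel_main <- c(0, 0.85)
  out <- list()
  mk <- function(v, role = "focal") {
    c(v, list(category = cat_, subclass = unit$subclass, role = role,
              vtype_plan = unit$vtype))
  }
  if (cat_ == "FRAME_RESCUE") {
    ins <- .plant_indel(gene, "insertion", 1L, c(0, 0.7), category = cat_)
    del <- .plant_indel(gene, "deletion", 1L, c(0, 0.85),
                        codon_target = c(ins$codon, 10L), category = cat_)
    return(list(gene = gene, variants = list(mk(ins), mk(del))))
  }
  if (cat_ == "INFRAME") {
    v <- .plant_indel(gene, "deletion", 3L, rel_main, category = cat_)
    return(list(gene = gene, variants = list(mk(v))))
  }
  rel <- if (cat_ == "LAST10PCT") c(0.92, 0.985) else rel_main
  if (unit$vtype == "stop_gain") {
    res <- .plant_stop_gain(gene, rel)
    gene <- res$gene
    out <- list(mk(res$variant))
    if (cat_ == "MNP_CODON") {
      comp <- .plant_codon_companion(gene, res$variant$codon, res$variant$pos)
      out[[2]] <- c(comp, list(category = cat_, subclass = "companion",
                               role = "companion", vtype_plan = "SNV"))
    }
  } else {
    len <- .sample1(1:2)
    type <- if (runif(1) < 0.5) "insertion" else "deletion"
    v <- .plant_indel(gene, type, len, rel, category = cat_)
    out <- list(mk(v))
  }
  list(gene = gene, variants = out)
}

.build_transcripts <- function(genes, planted_gene_idx, config) {
  two_tx_ok <- setdiff(seq_along(genes), planted_gene_idx)
  want_two <- if (max(config$transcripts_per_gene) >= 2)
    two_tx_ok[runif(length(two_tx_ok)) < 0.25] else integer(0)
  txs <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    txs[[length(txs) + 1L]] <- .gene_tx(g)
    if (i %in% want_two) {
      # truncated isoform: first 70% of the CDS, frame preserved
      keep <- 3L * floor(0.7 * (g$cds_len / 3))
      ex <- g$exons
      lens <- ex$end - ex$start + 1
      cum <- cumsum(lens)
      last <- which(cum >= keep)[1]
      drop_tail <- cum[last] - keep
      ex <- ex[seq_len(last), , drop = FALSE]
      if (g$strand == "+") {
        ex$end[last] <- ex$end[last] - drop_tail
        seq2 <- substr(g$seq, 1, keep)
      } else {
        # minus strand: transcript starts at the highest coordinate; keep
        # the top `keep` spliced bases by trimming from the genomic left
        total <- g$cds_len
        drop <- total - keep
        ex2 <- g$exons
        lens2 <- ex2$end - ex2$start + 1
        cum2 <- cumsum(lens2)
        first <- which(cum2 > drop)[1]
        ex2$start[first] <- ex2$start[first] + (drop - c(0, cum2)[first])
        ex <- ex2[first:nrow(ex2), , drop = FALSE]
        seq2 <- substr(g$seq, 1, keep)
      }
      txs[[length(txs) + 1L]] <- transcript_model(
        g$gene_id, paste0(g$gene_id, "_2"), g$contig, g$strand, ex, seq2)
    }
  }
  txs
}

.sim_neutral_sites <- function(config, genes, contigs) {
  n <- config$n_neutral
  if (n == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), af = numeric(0)))
  cds <- do.call(rbind, lapply(genes, function(g)
    data.frame(contig = g$contig, start = g$exons$start - 200,
               end = g$exons$end + 200)))
  cds_gr <- GenomicRanges::GRanges(cds$contig, IRanges::IRanges(cds$start, cds$end))
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- 2L * n
    contig <- sample(contigs$contig, m, replace = TRUE)
    pos <- sample.int(config$contig_length - 1000L, m, replace = TRUE) + 500L
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
    free <- !IRanges::overlapsAny(gr, cds_gr)
    cand <- unique(data.frame(contig = contig[free], pos = pos[free],
                              stringsAsFactors = FALSE))
    out <- rbind(out, cand)
    out <- out[!duplicated(paste(out$contig, out$pos)), , drop = FALSE]
  }
  out <- out[seq_len(n), , drop = FALSE]
  ra <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample(nrow(ra), n, replace = TRUE)
  data.frame(contig = out$contig, pos = out$pos,
             ref = ra[pick, 1], alt = ra[pick, 2],
             af = 10^runif(n, -2.7, -0.35), stringsAsFactors = FALSE)
}

# --- carriers, ROHs -----------------------------------------------------

.assign_carriers <- function(planted, samples, pops) {
  isolates <- pops$name[-which.max(pops$size)]
  by_pop <- split(samples$sample_id, samples$population)
  for (i in seq_along(planted)) {
    v <- planted[[i]]
    if (v$role != "focal") { planted[[i]] <- v; next }
    sc <- v$subclass
    if (v$category == "NEAR_FIXED") { planted[[i]] <- v; next }
    if (sc %in% c("medium", "common_pan", "common_cosmo")) {
      v$af <- switch(sc,
        medium = runif(1, 0.03, 0.12),
        common_pan = runif(1, 0.35, 0.65),
        common_cosmo = NA)  # per-population, set at draw time
      planted[[i]] <- v; next
    }
    if (v$category == "HWE_EXCESS") {
      v$target_pop <- .sample1(pops$name[pops$size >= min(90, max(pops$size))])
      planted[[i]] <- v; next
    }
    if (sc == "rare_roh") {
      pop <- .sample1(rep(isolates, times = pops$size[match(isolates, pops$name)]))
      k <- .sample1(2:3)
      v$force_roh <- TRUE
    } else {
      pop <- .sample1(rep(pops$name, times = pops$size))
      k <- .sample1(1:2)
      v$force_roh <- FALSE
    }
    v$carrier_pop <- pop
    v$carriers <- sample(by_pop[[pop]], k)
    planted[[i]] <- v
  }
  planted
}

.sim_roh <- function(config, samples, contigs) {
  pops <- config$populations
  genome <- sum(contigs$length)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    p <- pops[match(samples$population[i], pops$name), ]
    if (p$roh_genome_fraction <= 0) next
    mean_len <- p$mean_roh_length_bp
    n_roh <- rpois(1, p$roh_genome_fraction * genome / mean_len)
    if (n_roh == 0) next
    len <- pmin(round(1.5e6 + rexp(n_roh, 1 / (mean_len - 1.5e6))), 4.5e6)
    contig <- sample(contigs$contig, n_roh, replace = TRUE,
                     prob = contigs$length)
    clen <- contigs$length[match(contig, contigs$contig)]
    start <- floor(runif(n_roh, 1, clen - len))
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples$sample_id[i], contig = contig,
      start = as.integer(start), end = as.integer(start + len - 1),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(sample = character(0), contig = character(0),
                      start = integer(0), end = integer(0)))
  do.call(rbind, rows)
}

.force_carrier_roh <- function(roh, planted, config, contigs) {
  rows <- list()
  for (v in planted) {
    if (is.null(v$force_roh) || !v$force_roh) next
    clen <- contigs$length[match(v$contig, contigs$contig)]
    for (s in v$carriers) {
      len <- round(1.5e6 + rexp(1, 1 / 8e5))
      start <- max(1, v$pos - floor(runif(1, 0.1, 0.9) * len))
      end <- min(clen, start + len - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, contig = v$contig, start = as.integer(start),
        end = as.integer(end), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) rbind(roh, do.call(rbind, rows)) else roh
}

# indices of autozygous individuals per site
.autozygous_index <- function(vtab, roh, samples) {
  res <- vector("list", nrow(vtab))
  if (nrow(roh) == 0) return(res)
  site_gr <- GenomicRanges::GRanges(vtab$contig, IRanges::IRanges(vtab$pos, vtab$pos))
  roh_gr <- GenomicRanges::GRanges(roh$contig, IRanges::IRanges(roh$start, roh$end))
  ov <- GenomicRanges::findOverlaps(site_gr, roh_gr)
  sample_idx <- match(roh$sample, samples$sample_id)
  hits <- split(sample_idx[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
  for (nm in names(hits)) res[[as.integer(nm)]] <- unique(hits[[nm]])
  res
}
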