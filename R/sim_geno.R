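# Genotype, depth, phenotype and annotation-table simulation.

.sim_depth <- function(vtab, samples, pops) {
  n_sites <- nrow(vtab); n <- nrow(samples)
  md <- pops$mean_depth[match(samples$population, pops$name)]
  depth <- matrix(0L, n_sites, n)
  for (j in seq_len(n))
    depth[, j] <- as.integer(round(rgamma(n_sites, shape = 6, scale = md[j] / 6)))
  depth
}

# add heterozygotes (non-autozygous, adequately covered individuals of the
# given population) until the exact homozygote-excess P clears `target`
.ensure_hwe <- function(g, depth_row, members, autoz, target = 0.10) {
  repeat {
    sel <- members[!is.na(g[members]) & depth_row[members] >= 5]
    cnt <- c(sum(g[sel] == 0L), sum(g[sel] == 1L), sum(g[sel] == 2L))
    p <- if (sum(cnt) == 0) 1 else hwe_excess_test(cnt[1], cnt[2], cnt[3])
    if (p >= target) return(g)
    cand <- members[!is.na(g[members]) & g[members] == 0L &
                    depth_row[members] >= 5 & !(members %in% autoz)]
    if (length(cand) == 0)
      stop("cannot add heterozygous support to satisfy HWE")
    g[.sample1(cand)] <- 1L
  }
}

# plain HWE draw with autozygous individuals homozygous by allele frequency
.draw_hwe_site <- function(af, autoz, n) {
  u <- runif(n)
  p0 <- (1 - af)^2
  g <- (u > p0) + (u > p0 + 2 * af * (1 - af))
  if (length(autoz)) g[autoz] <- ifelse(runif(length(autoz)) < af, 2L, 0L)
  as.integer(g)
}

.sim_genotypes <- function(vtab, meta, samples, pops, depth, autoz, config) {
  n <- nrow(samples)
  n_sites <- nrow(vtab)
  geno <- matrix(0L, n_sites, n)
  pop_idx <- split(seq_len(n), samples$population)
  sample_idx <- setNames(seq_len(n), samples$sample_id)
  isl <- names(pop_idx)

  for (i in seq_len(n_sites)) {
    v <- meta[[i]]
    az <- autoz[[i]]
    if (is.null(az)) az <- integer(0)
    d <- depth[i, ]
    if (v$role == "neutral") {
      geno[i, ] <- .draw_hwe_site(v$af, az, n)
      next
    }
    if (v$role == "companion") {
      geno[i, ] <- .draw_hwe_site(runif(1, 0.05, 0.20), az, n)
      next
    }
    cat_ <- v$category
    if (cat_ == "NEAR_FIXED") {
      g <- rep(2L, n)
      if (runif(1) < 0.5) {
        het_cand <- setdiff(seq_len(n), az)
        g[.sample1(het_cand)] <- 1L
      }
      ci <- .sample1(which(g == 2L & d >= 5))
      depth[i, ci] <- max(depth[i, ci], 25L)
      geno[i, ] <- g
      next
    }
    if (cat_ == "HWE_EXCESS") {
      g <- rep(0L, n)
      tp <- pop_idx[[v$target_pop]]
      h0 <- .sample1(6:10)
      chosen <- sample(setdiff(tp, az), h0)
      depth[i, chosen] <- pmax(depth[i, chosen], 6L)
      n_hom <- max(2L, round(config$error_hom_rate * h0))
      g[chosen[seq_len(min(n_hom, h0))]] <- 2L
      if (h0 > n_hom) g[chosen[(n_hom + 1):h0]] <- 1L
      bump <- chosen[1]
      depth[i, bump] <- max(depth[i, bump], 25L)
      # drive the miscall rate up until the exact test rejects at 0.01
      repeat {
        sel <- tp[!is.na(g[tp]) & depth[i, tp] >= 5]
        p <- hwe_excess_test(sum(g[sel] == 0L), sum(g[sel] == 1L),
                             sum(g[sel] == 2L))
        if (p < 0.01) break
        hets <- tp[g[tp] == 1L]
        if (length(hets)) g[.sample1(hets)] <- 2L
        else {
          extra <- setdiff(tp[depth[i, tp] >= 5 & g[tp] == 0L], az)
          g[.sample1(extra)] <- 2L
        }
      }
      for (p_ in setdiff(isl, v$target_pop)) {
        m <- rpois(1, 1)
        if (m > 0) {
          cand <- setdiff(pop_idx[[p_]][g[pop_idx[[p_]]] == 0L], az)
          g[sample(cand, min(m, length(cand)))] <- 1L
        }
      }
      geno[i, ] <- g
      next
    }
    if (!is.null(v$subclass) &&
        v$subclass %in% c("medium", "common_pan", "common_cosmo")) {
      res <- .draw_conditioned_common(v, pop_idx, az, depth[i, ], n)
      geno[i, ] <- res$g
      depth[i, res$bump] <- max(depth[i, res$bump], 25L)
      next
    }
    # forced rare pattern (true rares and most artifact categories)
    g <- rep(0L, n)
    carriers <- sample_idx[v$carriers]
    g[carriers] <- 2L
    if (cat_ == "LOW_COVERAGE") {
      depth[i, carriers] <- sample(8:19, length(carriers), replace = TRUE)
    } else {
      depth[i, carriers] <- pmax(depth[i, carriers], 25L)
    }
    called <- seq_len(n)
    if (cat_ == "FEW_SAMPLES") {
      n_called <- min(150L, round(0.6 * n))
      extra <- sample(setdiff(seq_len(n), carriers),
                      max(0, n_called - length(carriers)))
      called <- sort(c(as.integer(carriers), extra))
      g[setdiff(seq_len(n), called)] <- NA_integer_
    }
    # heterozygous support in other populations (shared variants)
    if (runif(1) < 0.9) {
      for (p_ in setdiff(isl, v$carrier_pop)) {
        m <- rpois(1, 1.3)
        if (m == 0) next
        cand <- intersect(setdiff(pop_idx[[p_]], c(az, carriers)), called)
        cand <- cand[!is.na(g[cand]) & g[cand] == 0L & depth[i, cand] >= 5]
        if (length(cand)) g[sample(cand, min(m, length(cand)))] <- 1L
      }
    }
    g <- .ensure_hwe(g, depth[i, ], intersect(pop_idx[[v$carrier_pop]], called),
                     az, target = 0.10)
    geno[i, ] <- g
  }
  list(geno = geno, depth = depth)
}

# medium/common variants: Hardy-Weinberg (plus ROH autozygosity) draws,
# redrawn until every population's exact homozygote-excess P clears 0.05
# and at least one adequately covered homozygote exists
.draw_conditioned_common <- function(v, pop_idx, az, d, n) {
  cosmo <- names(pop_idx)[which.max(lengths(pop_idx))]
  af_pop <- if (v$subclass == "common_cosmo") {
    af <- setNames(runif(length(pop_idx), 0.03, 0.12), names(pop_idx))
    af[cosmo] <- runif(1, 0.5, 0.7)
    af
  } else setNames(rep(v$af, length(pop_idx)), names(pop_idx))
  for (try in 1:200) {
    g <- integer(n)
    for (p_ in names(pop_idx)) {
      idx <- pop_idx[[p_]]
      g[idx] <- .draw_hwe_site(af_pop[[p_]], integer(0), length(idx))
    }
    # autozygotes are homozygous by their own population's frequency
    if (length(az)) {
      pop_of <- character(n)
      pop_of[unlist(pop_idx)] <- rep(names(pop_idx), lengths(pop_idx))
      g[az] <- ifelse(runif(length(az)) < af_pop[pop_of[az]], 2L, 0L)
    }
    hom_ok <- which(g == 2L & d >= 5)
    if (length(hom_ok) == 0) next
    ok <- all(vapply(names(pop_idx), function(p_) {
      sel <- pop_idx[[p_]][d[pop_idx[[p_]]] >= 5]
      hwe_excess_test(sum(g[sel] == 0L), sum(g[sel] == 1L),
                      sum(g[sel] == 2L)) >= 0.05
    }, logical(1)))
    if (ok) return(list(g = g, bump = .sample1(hom_ok)))
  }
  stop("could not draw HWE-consistent genotypes for a ",
       v$subclass, " variant")
}

#' Simulate a quantitative phenotype matrix with an optional burden effect
#'
#' Traits are standard normal; a planted burden effect adds, per
#' individual, a Poisson(`beta` x burden) number of traits forced to an
#' extreme value (about five standard deviations, random sign), so the
#' expected number of extreme trait values increases linearly in the
#' burden with slope ~`beta`.
#'
#' @param burden Integer vector of per-individual HLOF burdens.
#' @param n_traits Number of traits.
#' @param beta Planted slope (extra extreme traits per HLOF carried).
#' @param missing_rate Fraction of missing measurements.
#' @param extreme_mean Magnitude of planted extreme values (SD units).
#' @return numeric matrix, individuals x traits.
#' @export
sim_phenotype_matrix <- function(burden, n_traits, beta = 0,
                                 missing_rate = 0.1, extreme_mean = 5) {
  n <- length(burden)
  m <- matrix(rnorm(n * n_traits), n, n_traits,
              dimnames = list(NULL, sprintf("trait_%04d", seq_len(n_traits))))
  if (missing_rate > 0) m[runif(n * n_traits) < missing_rate] <- NA
  if (beta != 0) {
    for (i in seq_len(n)) {
      k <- rpois(1, abs(beta) * burden[i])
      if (k == 0) next
      avail <- which(!is.na(m[i, ]))
      k <- min(k, length(avail))
      cols <- if (length(avail) == 1) avail else sample(avail, k)
      m[i, cols] <- sign(beta) * sample(c(-1, 1), k, replace = TRUE) *
        rnorm(k, extreme_mean, 0.3)
    }
  }
  m
}

# --- tracks, primate table, annotation tables, truth --------------------

.sim_tracks <- function(genes, planted, contigs) {
  exon_rows <- do.call(rbind, lapply(genes, function(g)
    data.frame(contig = g$contig, start = g$exons$start, end = g$exons$end,
               stringsAsFactors = FALSE)))
  all_ex <- GenomicRanges::GRanges(exon_rows$contig,
    IRanges::IRanges(exon_rows$start - 20L, exon_rows$end + 20L))
  kit_b <- GenomicRanges::reduce(all_ex)
  # kit A omits the exon containing each OFF_TARGET variant entirely
  off <- Filter(function(v) v$category == "OFF_TARGET" && v$role == "focal",
                planted)
  drop <- rep(FALSE, nrow(exon_rows))
  for (v in off) {
    g <- genes[[v$gene_idx]]
    hit <- which(exon_rows$contig == v$contig &
                 exon_rows$start <= v$pos & exon_rows$end >= v$pos)
    drop[hit] <- TRUE
  }
  kit_a <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exon_rows$contig[!drop],
    IRanges::IRanges(exon_rows$start[!drop] - 20L, exon_rows$end[!drop] + 20L)))
  lows <- Filter(function(v) v$category == "LOW_MAPABILITY" && v$role == "focal",
                 planted)
  mk_gr <- function(vs) {
    if (length(vs) == 0)
      return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
      vapply(vs, `[[`, character(1), "contig"),
      IRanges::IRanges(vapply(vs, function(v) v$pos - 25L, numeric(1)),
                       vapply(vs, function(v) v$pos + nchar(v$ref) + 24L,
                              numeric(1))),
      score = 0.5)
  }
  lane <- rep_len(1:3, length(lows))
  list(alignability = list(mk_gr(lows[lane == 1]), mk_gr(lows[lane == 2])),
       blacklist = mk_gr(lows[lane == 3]),
       kit_a = kit_a, kit_b = kit_b)
}

.sim_primates <- function(variants, meta) {
  species <- c("chimp", "gorilla", "orangutan")
  rows <- list()
  add <- function(contig, pos, sp, aligned, allele, itype, ilen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, pos = pos, species = sp, aligned = aligned,
      allele = allele, indel_type = itype, indel_len = ilen,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(meta)) {
    v <- meta[[i]]
    if (is.null(v$role) || v$role != "focal") next
    vt <- variant_type(variants$ref[i], variants$alt[i])
    if (v$category == "ANCESTRAL") {
      if (vt == "SNV") {
        add(variants$contig[i], variants$pos[i], "chimp", TRUE,
            variants$alt[i], "none", 0L)
        add(variants$contig[i], variants$pos[i], "gorilla", TRUE,
            variants$ref[i], "none", 0L)
      } else {
        len <- abs(nchar(variants$alt[i]) - nchar(variants$ref[i]))
        for (sp in species[seq_len(.sample1(2:3))])
          add(variants$contig[i], variants$pos[i], sp, TRUE, ".", vt, len)
      }
    } else if (runif(1) < 0.3) {
      # aligned but concordant with the human reference: must pass
      if (vt == "SNV") {
        add(variants$contig[i], variants$pos[i], "chimp", TRUE,
            variants$ref[i], "none", 0L)
      } else {
        add(variants$contig[i], variants$pos[i], "chimp", TRUE, ".",
            "none", 0L)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      species = character(0), aligned = logical(0),
                      allele = character(0), indel_type = character(0),
                      indel_len = integer(0)))
  do.call(rbind, rows)
}

.INTENDED_FILTER <- c(
  TRUE_HLOF = "", LAST10PCT = "relative_position",
  LOW_MAPABILITY = "mapability", OFF_TARGET = "capture_intersection",
  FEW_SAMPLES = "min_samples", ANCESTRAL = "ancestral",
  MNP_CODON = "mnp_codon", FRAME_RESCUE = "frameshift_rescue",
  INFRAME = "consequence", HWE_EXCESS = "hwe", LOW_COVERAGE = "coverage",
  NEAR_FIXED = "near_fixed")

.truth_table <- function(variants, meta) {
  focal <- which(vapply(meta, function(v)
    !is.null(v$role) && v$role == "focal", logical(1)))
  data.frame(
    key = variants$key[focal],
    category = vapply(meta[focal], `[[`, character(1), "category"),
    intended_filter = unname(.INTENDED_FILTER[
      vapply(meta[focal], `[[`, character(1), "category")]),
    stringsAsFactors = FALSE)
}

.sim_tables <- function(config, genes, callset, meta, truth) {
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  focal <- which(vapply(meta, function(v)
    !is.null(v$role) && v$role == "focal", logical(1)))
  meta_f <- meta[focal]
  is_true <- vapply(meta_f, function(v) v$category == "TRUE_HLOF", logical(1))
  hlof_genes <- unique(vapply(meta_f[is_true], function(v)
    gene_ids[v$gene_idx], character(1)))
  # known catalogue: commoner variants first, so novelty concentrates in
  # rare (often autozygous) variants
  sub_of <- vapply(meta_f, function(v)
    if (is.null(v$subclass)) "artifact" else v$subclass, character(1))
  pri <- match(sub_of, c("common_cosmo", "common_pan", "medium",
                         "rare_plain", "rare_roh"))
  ord <- order(pri)
  true_ord <- ord[is_true[ord]]
  n_known <- round(config$known_fraction * sum(is_true))
  known_rows <- focal[true_ord[seq_len(min(n_known, length(true_ord)))]]
  known_catalogue <- callset$variants[known_rows,
                                      c("contig", "pos", "ref", "alt")]
  # deleteriousness scores: higher for rarer variants
  n_car <- vapply(focal, function(i)
    sum(callset$geno[i, ] == 2L, na.rm = TRUE), numeric(1))
  cscores <- data.frame(
    callset$variants[focal, c("contig", "pos", "ref", "alt")],
    cscore = round(pmin(44, pmax(1.4, 30 - 4.5 * log1p(n_car) +
                                   rnorm(length(focal), 0, 6))), 1))
  # the annotation universe also holds captured genes that carry no
  # simulated variant, so term enrichments have a realistic denominator
  bg_genes <- sprintf("BG%04d", seq_len(2 * length(gene_ids)))
  gene_universe <- c(gene_ids, bg_genes)
  other_genes <- setdiff(gene_universe, hlof_genes)
  pick <- function(x, k) sample(x, min(k, length(x)))
  go <- rbind(
    data.frame(gene = c(pick(hlof_genes, 24), pick(other_genes, 16)),
               term = "OLFR"),
    data.frame(gene = c(pick(hlof_genes, 26), pick(other_genes, 54)),
               term = "GPCR"),
    data.frame(gene = pick(gene_universe, 180), term = "CTRL"))
  tissues <- c("testis", "brain", "liver", "kidney", "heart", "lung",
               "spleen", "muscle", "skin", "ovary", "colon", "stomach",
               "thyroid", "adrenal", "pancreas", "blood")
  expr <- matrix(round(abs(rnorm(length(gene_universe) * 16, 2, 2)), 2),
                 length(gene_universe), 16,
                 dimnames = list(gene_universe, tissues))
  boost <- pick(hlof_genes, round(0.25 * length(hlof_genes)))
  expr[boost, "testis"] <- apply(expr[boost, , drop = FALSE], 1, max) +
    runif(length(boost), 0.5, 2)
  paralogues <- rbind(
    data.frame(gene = gene_universe, cutoff = "70",
               n_paralogues = rpois(length(gene_universe),
                                    ifelse(gene_universe %in% hlof_genes,
                                           1.3, 2.2))),
    data.frame(gene = gene_universe, cutoff = "80",
               n_paralogues = rpois(length(gene_universe),
                                    ifelse(gene_universe %in% hlof_genes,
                                           0.9, 1.6))))
  list(known_catalogue = known_catalogue, cscores = cscores,
       go_annotations = go, expression = expr, paralogues = paralogues,
       olfactory_genes = unique(go$gene[go$term == "OLFR"]),
       hlof_genes = hlof_genes, gene_universe = gene_universe)
}
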