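#' Gene-set enrichment ratio
#'
#' `(b/n) / (B/N)` where `N` is the number of background genes, `B` the
#' genes annotated to the term, `n` the target-set genes and `b` the
#' target genes annotated to the term.
#'
#' @param N,B,n,b Gene counts (see description).
#' @return Enrichment ratio.
#' @export
enrichment_ratio <- function(N, B, n, b) {
  stopifnot(N > 0, n > 0, B >= 0, b >= 0, b <= min(B, n))
  if (B == 0) stop("term has no background genes (B = 0)")
  (b / n) / (B / N)
}

#' Hypergeometric upper-tail enrichment P-value
#'
#' `P(X >= b)` for the number of term genes drawn in a target set of size
#' `n` from a background of `N` genes of which `B` carry the term.
#'
#' @inheritParams enrichment_ratio
#' @return Upper-tail P-value.
#' @export
hypergeometric_enrichment_p <- function(N, B, n, b) {
  stopifnot(N > 0, B >= 0, B <= N, n >= 0, n <= N, b >= 0, b <= min(B, n))
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#' @param p Vector of P-values in `[0, 1]`.
#' @return q-values (step-up, monotone).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment table
#'
#' One row per term: counts, enrichment ratio, hypergeometric P and BH q.
#'
#' @param target_genes Character vector of target (e.g. HLOF) genes.
#' @param background_genes Character vector of background genes.
#' @param annotations data.frame `gene`, `term`.
#' @return data.frame sorted by P.
#' @export
enrichment_table <- function(target_genes, background_genes, annotations) {
  target_genes <- intersect(unique(target_genes), background_genes)
  N <- length(unique(background_genes))
  n <- length(target_genes)
  ann <- annotations[annotations$gene %in% background_genes, , drop = FALSE]
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    term_genes <- unique(ann$gene[ann$term == tm])
    B <- length(term_genes)
    b <- length(intersect(term_genes, target_genes))
    data.frame(term = tm, N = N, B = B, n = n, b = b,
               enrichment = enrichment_ratio(N, B, n, b),
               p = hypergeometric_enrichment_p(N, B, n, b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Tissue-expression summary of a gene set
#'
#' For each gene the tissue of maximal expression is identified (ties
#' credit each tied tissue 0.5, or 1/k for k-way ties); counts and
#' proportions per tissue are reported, along with the fraction of genes
#' expressed above a threshold in a named tissue.
#'
#' @param expression numeric matrix, genes x tissues (rownames = genes).
#' @param gene_set Character vector of genes to summarize.
#' @param expressed_threshold Expression level counting as "expressed".
#' @param focus_tissue Tissue for the expressed-fraction summary (default:
#'   the tissue with the largest max-expression share).
#' @return list with `per_tissue` (data.frame `tissue`, `max_count`,
#'   `max_prop`), `n_genes`, `focus_tissue`, `n_expressed_focus`,
#'   `prop_expressed_focus`.
#' @export
tissue_summary <- function(expression, gene_set, expressed_threshold = 1,
                           focus_tissue = NULL) {
  present <- intersect(gene_set, rownames(expression))
  missing <- setdiff(gene_set, rownames(expression))
  if (length(missing))
    message(length(missing), " gene(s) absent from the expression matrix")
  if (length(present) == 0) stop("no genes present in the expression matrix")
  em <- expression[present, , drop = FALSE]
  credit <- matrix(0, nrow(em), ncol(em), dimnames = dimnames(em))
  for (i in seq_len(nrow(em))) {
    mx <- which(em[i, ] == max(em[i, ]))
    credit[i, mx] <- 1 / length(mx)
  }
  counts <- colSums(credit)
  per_tissue <- data.frame(tissue = colnames(em), max_count = unname(counts),
                           max_prop = unname(counts) / nrow(em))
  if (is.null(focus_tissue))
    focus_tissue <- per_tissue$tissue[which.max(per_tissue$max_count)]
  n_exp <- sum(em[, focus_tissue] > expressed_threshold)
  list(per_tissue = per_tissue, n_genes = nrow(em),
       focus_tissue = focus_tissue, n_expressed_focus = n_exp,
       prop_expressed_focus = n_exp / nrow(em))
}

#' Per-population yield and sharing summary of HLOF variants
#'
#' Yield is the number of distinct HLOF variants observed homozygous in a
#' population divided by the number of individuals sampled. Private LOFs
#' are variants whose alternate allele (in any genotype state) is seen in
#' one population only; private HLOFs are homozygous in one population only
#' although the allele may segregate as heterozygous elsewhere.
#'
#' @param candidates list of surviving `hlof_candidate`s.
#' @param samples sample table (`sample_id`, `population`).
#' @return data.frame, one row per population: `n_individuals`, `n_hlofs`,
#'   `yield`, `private_lofs`, `private_hlofs`, `median_burden`.
#' @export
population_yield <- function(candidates, samples) {
  pops <- sort(unique(samples$population))
  n_ind <- table(factor(samples$population, levels = pops))
  if (any(n_ind == 0)) stop("population with zero individuals")
  # per variant: which populations see the allele / a homozygote
  hom_pops <- lapply(candidates, function(cand)
    colnames(cand$pop_counts)[cand$pop_counts["hom_alt", ] > 0])
  any_pops <- lapply(candidates, function(cand)
    colnames(cand$pop_counts)[colSums(cand$pop_counts[c("het", "hom_alt"), ,
                                                      drop = FALSE]) > 0])
  burden <- burden_by_individual(candidates, samples)
  rows <- lapply(pops, function(p) {
    hom_here <- vapply(hom_pops, function(x) p %in% x, logical(1))
    n_hlof <- sum(hom_here)
    private_lof <- sum(vapply(seq_along(candidates), function(i)
      identical(any_pops[[i]], p), logical(1)))
    private_hlof <- sum(vapply(seq_along(candidates), function(i) {
      identical(hom_pops[[i]], p) && length(any_pops[[i]]) > 1
    }, logical(1)))
    data.frame(population = p, n_individuals = as.integer(n_ind[[p]]),
               n_hlofs = n_hlof,
               yield = round(n_hlof / n_ind[[p]], 2),
               private_lofs = private_lof, private_hlofs = private_hlof,
               median_burden = stats::median(
                 burden[samples$population == p]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-individual HLOF burden
#' @param candidates list of `hlof_candidate`s.
#' @param samples sample table.
#' @return Named integer vector (one entry per individual): number of
#'   variants for which the individual is homozygous-alternate.
#' @export
burden_by_individual <- function(candidates, samples) {
  burden <- setNames(integer(nrow(samples)), samples$sample_id)
  for (cand in candidates)
    burden[cand$carriers] <- burden[cand$carriers] + 1L
  burden
}

#' Deleteriousness-score summary of surviving variants
#'
#' Median score and the Spearman correlation (average ranks for ties)
#' between score and homozygous-carrier count.
#'
#' @param candidates list of `hlof_candidate`s with `cscore` set.
#' @return list `(n_scored, median_cscore, spearman_rho, p, testable)`.
#' @export
cscore_summary <- function(candidates) {
  sc <- vapply(candidates, `[[`, numeric(1), "cscore")
  nc <- vapply(candidates, function(x) length(x$carriers), numeric(1))
  keep <- !is.na(sc)
  sc <- sc[keep]; nc <- nc[keep]
  res <- list(n_scored = length(sc),
              median_cscore = if (length(sc)) stats::median(sc) else NA_real_,
              spearman_rho = NA_real_, p = NA_real_, testable = FALSE)
  if (length(sc) >= 3 && stats::sd(sc) > 0 && stats::sd(nc) > 0) {
    ct <- suppressWarnings(stats::cor.test(sc, nc, method = "spearman"))
    res$spearman_rho <- unname(ct$estimate); res$p <- ct$p.value
    res$testable <- TRUE
  }
  res
}

#' Compare paralogue counts of HLOF genes against the genomic background
#'
#' One Wilcoxon rank-sum comparison per sequence-identity cutoff, with the
#' direction of the difference; genes in an exclusion set (e.g. olfactory
#' receptors) can be removed from the target set first.
#'
#' @param hlof_counts named list: cutoff -> paralogue counts of HLOF genes
#'   (named numeric vectors, names = genes).
#' @param background_counts named list: cutoff -> background counts.
#' @param exclude_genes genes removed from the target sets before testing.
#' @return data.frame per cutoff: medians, direction, P.
#' @export
compare_paralogues <- function(hlof_counts, background_counts,
                               exclude_genes = character(0)) {
  if (length(hlof_counts) == 0) stop("empty paralogue input")
  rows <- lapply(names(hlof_counts), function(cut) {
    a <- hlof_counts[[cut]]
    if (length(exclude_genes) && !is.null(names(a)))
      a <- a[!(names(a) %in% exclude_genes)]
    b <- background_counts[[cut]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(cutoff = cut, n_hlof = length(a), n_background = length(b),
               median_hlof = stats::median(a), median_background = stats::median(b),
               direction = ifelse(mean(a) < mean(b),
                                  "fewer_paralogues", "more_paralogues"),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
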