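#' Count an individual's HLOF burden
#'
#' Number of surviving variants for which the individual is
#' homozygous-alternate, optionally restricted to strongly deleterious
#' variants (`cscore_min`) and/or excluding a gene set (e.g. olfactory
#' receptors).
#'
#' @param individual Sample id.
#' @param candidates list of surviving `hlof_candidate`s.
#' @param samples sample table (used to validate the id).
#' @param cscore_min Keep only variants with `cscore` strictly above this
#'   (default `NULL`: no score filter).
#' @param exclude_genes Character vector of gene ids whose variants are
#'   dropped.
#' @return Integer count.
#' @export
count_burden <- function(individual, candidates, samples, cscore_min = NULL,
                         exclude_genes = character(0)) {
  if (!individual %in% samples$sample_id)
    stop("unknown individual: ", individual)
  sum(vapply(candidates, function(cand) {
    if (!is.null(cscore_min) &&
        (is.na(cand$cscore) || cand$cscore <= cscore_min)) return(FALSE)
    if (length(exclude_genes) &&
        all(unique(cand$csq$gene_id) %in% exclude_genes)) return(FALSE)
    individual %in% cand$carriers
  }, logical(1)))
}

#' Count an individual's extreme trait values
#'
#' Number of the individual's non-missing traits falling into the bottom
#' or top `q` tail of that trait's within-population distribution
#' (empirical order-statistic quantiles, ties included in the extreme
#' set; the focal individual is part of the distribution).
#'
#' @param traits numeric matrix, individuals x traits (rownames = ids),
#'   `NA` allowed.
#' @param populations Character vector of population labels, one per row.
#' @param individual Sample id (must be a rowname).
#' @param q Tail probability (default 0.01).
#' @return Integer count.
#' @export
count_extreme_traits <- function(traits, populations, individual, q = 0.01) {
  if (!individual %in% rownames(traits))
    stop("unknown individual: ", individual)
  flags <- extreme_trait_matrix(traits, populations, q)
  sum(flags[individual, ], na.rm = TRUE)
}

#' Flag extreme trait values within populations
#'
#' @inheritParams count_extreme_traits
#' @return logical matrix of the same shape as `traits` (`NA` where the
#'   trait is missing).
#' @export
extreme_trait_matrix <- function(traits, populations, q = 0.01) {
  stopifnot(nrow(traits) == length(populations))
  flags <- matrix(NA, nrow(traits), ncol(traits), dimnames = dimnames(traits))
  for (p in unique(populations)) {
    sel <- populations == p
    sub <- traits[sel, , drop = FALSE]
    lo <- apply(sub, 2, stats::quantile, probs = q, na.rm = TRUE, type = 1)
    hi <- apply(sub, 2, stats::quantile, probs = 1 - q, na.rm = TRUE, type = 1)
    flags[sel, ] <- sweep(sub, 2, lo, "<=") | sweep(sub, 2, hi, ">=")
  }
  flags
}

#' Build per-individual burden records
#'
#' @param candidates list of surviving `hlof_candidate`s.
#' @param samples sample table.
#' @param traits trait matrix (individuals x traits, rownames = ids).
#' @param q Extreme-tail probability.
#' @param cscore_min,exclude_genes Passed to the burden definition (see
#'   [count_burden()]).
#' @return data.frame `individual`, `population`, `burden`,
#'   `n_traits_measured`, `n_extreme`.
#' @export
burden_records <- function(candidates, samples, traits, q = 0.01,
                           cscore_min = NULL, exclude_genes = character(0)) {
  stopifnot(all(samples$sample_id %in% rownames(traits)))
  traits <- traits[samples$sample_id, , drop = FALSE]
  burden <- burden_by_individual(candidates, samples)
  if (!is.null(cscore_min) || length(exclude_genes)) {
    keep <- vapply(candidates, function(cand) {
      if (!is.null(cscore_min) &&
          (is.na(cand$cscore) || cand$cscore <= cscore_min)) return(FALSE)
      !(length(exclude_genes) &&
          all(unique(cand$csq$gene_id) %in% exclude_genes))
    }, logical(1))
    burden <- burden_by_individual(candidates[keep], samples)
  }
  flags <- extreme_trait_matrix(traits, samples$population, q)
  data.frame(individual = samples$sample_id,
             population = samples$population,
             burden = unname(burden[samples$sample_id]),
             n_traits_measured = rowSums(!is.na(traits)),
             n_extreme = rowSums(flags, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress extreme-trait counts on HLOF burden
#'
#' Ordinary least squares of the number of extreme trait values on the
#' HLOF burden and the number of traits measured, fitted per population.
#'
#' @param records data.frame from [burden_records()].
#' @param population Optional single population to fit; default fits each.
#' @return data.frame per population: burden slope, its SE and two-sided
#'   P, intercept, n; rank-deficient designs (e.g. constant burden) are
#'   flagged with `ok = FALSE`.
#' @export
fit_burden_model <- function(records, population = NULL) {
  pops <- if (is.null(population)) unique(records$population) else population
  rows <- lapply(pops, function(p) {
    sub <- records[records$population == p, , drop = FALSE]
    base <- data.frame(population = p, n = nrow(sub), slope = NA_real_,
                       se = NA_real_, p_value = NA_real_,
                       intercept = NA_real_, ok = FALSE,
                       stringsAsFactors = FALSE)
    if (nrow(sub) < 3 || stats::sd(sub$burden) == 0) return(base)
    preds <- "burden"
    if (stats::sd(sub$n_traits_measured) > 0)
      preds <- c(preds, "n_traits_measured")
    fit <- stats::lm(stats::reformulate(preds, "n_extreme"), data = sub)
    sm <- summary(fit)$coefficients
    base$slope <- sm["burden", "Estimate"]
    base$se <- sm["burden", "Std. Error"]
    base$p_value <- sm["burden", "Pr(>|t|)"]
    base$intercept <- sm["(Intercept)", "Estimate"]
    base$ok <- TRUE
    base
  })
  do.call(rbind, rows)
}
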