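#' Read a PLINK .hom-style file of runs of homozygosity
#'
#' Expects whitespace-separated columns including FID, IID, CHR, POS1,
#' POS2 (1-based inclusive). Overlapping intervals of one individual are
#' merged with a warning.
#'
#' @param path File path.
#' @return data.frame with columns `sample`, `contig`, `start`, `end`.
#' @export
read_roh <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0)
    return(data.frame(sample = character(0), contig = character(0),
                      start = integer(0), end = integer(0)))
  roh <- data.frame(sample = as.character(tab$IID), contig = as.character(tab$CHR),
                    start = as.integer(tab$POS1), end = as.integer(tab$POS2),
                    stringsAsFactors = FALSE)
  merge_roh(roh)
}

#' Write runs of homozygosity as a PLINK .hom-style file
#'
#' Columns FID, IID, CHR, POS1, POS2, KB; KB is the interval length in
#' kilobases. Overlapping intervals of one individual are merged first
#' (with a warning).
#'
#' @param roh data.frame with `sample`, `contig`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roh <- function(roh, path) {
  roh <- merge_roh(roh)
  out <- data.frame(FID = roh$sample, IID = roh$sample, CHR = roh$contig,
                    POS1 = roh$start, POS2 = roh$end,
                    KB = (roh$end - roh$start + 1) / 1000)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Merge overlapping ROH intervals per individual
#' @param roh data.frame with `sample`, `contig`, `start`, `end`.
#' @return data.frame of the same shape, intervals disjoint per individual.
#' @export
merge_roh <- function(roh) {
  if (nrow(roh) == 0) return(roh)
  gr <- GenomicRanges::GRanges(paste(roh$sample, roh$contig, sep = "\r"),
                               IRanges::IRanges(roh$start, roh$end))
  red <- GenomicRanges::reduce(gr)
  if (length(red) < length(gr))
    warning("merged ", length(gr) - length(red),
            " overlapping ROH interval(s)")
  parts <- do.call(rbind, strsplit(as.character(GenomicRanges::seqnames(red)), "\r"))
  out <- data.frame(sample = parts[, 1], contig = parts[, 2],
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red), stringsAsFactors = FALSE)
  out[order(out$sample, out$contig, out$start), , drop = FALSE]
}

#' Is a carrier autozygous at a variant position?
#'
#' TRUE when the position lies inside any ROH interval of that individual
#' (inclusive bounds). Individuals absent from the ROH set have no ROHs.
#'
#' @param contig,pos Variant location.
#' @param carrier Sample id.
#' @param roh ROH data.frame (`sample`, `contig`, `start`, `end`).
#' @return logical.
#' @export
carrier_in_roh <- function(contig, pos, carrier, roh) {
  sub <- roh[roh$sample == carrier & roh$contig == contig, , drop = FALSE]
  any(pos >= sub$start & pos <= sub$end)
}

#' Per-carrier ROH membership for a set of candidates
#'
#' One row per (variant, homozygous carrier) observation.
#'
#' @param candidates list of `hlof_candidate`s.
#' @param roh ROH data.frame.
#' @param samples sample table (`sample_id`, `population`).
#' @return data.frame `key`, `contig`, `pos`, `carrier`, `population`, `in_roh`.
#' @export
roh_observations <- function(candidates, roh, samples) {
  pop_of <- setNames(samples$population, samples$sample_id)
  rows <- lapply(candidates, function(cand) {
    if (length(cand$carriers) == 0) return(NULL)
    data.frame(key = cand$key, contig = cand$contig, pos = cand$pos,
               carrier = cand$carriers,
               population = unname(pop_of[cand$carriers]),
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(obs) || nrow(obs) == 0)
    return(data.frame(key = character(0), contig = character(0),
                      pos = integer(0), carrier = character(0),
                      population = character(0), in_roh = logical(0)))
  obs$in_roh <- mapply(carrier_in_roh, obs$contig, obs$pos, obs$carrier,
                       MoreArgs = list(roh = roh))
  obs
}

#' Fraction of carrier-variant observations inside ROHs for one population
#' @param obs Output of [roh_observations()].
#' @param population Population name.
#' @return Fraction in `[0, 1]`.
#' @export
population_roh_frequency <- function(obs, population) {
  sub <- obs[obs$population == population, , drop = FALSE]
  if (nrow(sub) == 0) stop("no carrier observations for population ", population)
  mean(sub$in_roh)
}

#' Classify a variant as inside- or outside-ROH biased
#'
#' One-sided binomial tails for `k` of `n` homozygous carriers being
#' autozygous at the variant, against an expected frequency equal to the
#' overall fraction of HLOF carrier observations inside ROHs.
#'
#' @param k Carriers inside ROHs.
#' @param n Total homozygous carriers.
#' @param expected_freq Expected in-ROH fraction.
#' @param alpha Significance level (default 0.1).
#' @return list `(k, n, p_inside, p_outside, class)` with class one of
#'   `inside_biased`, `outside_biased`, `unclassified`.
#' @export
classify_roh_bias <- function(k, n, expected_freq, alpha = 0.1) {
  if (n <= 0) stop("no carriers to classify")
  stopifnot(k >= 0, k <= n, expected_freq >= 0, expected_freq <= 1)
  p_in <- stats::pbinom(k - 1, n, expected_freq, lower.tail = FALSE)
  p_out <- stats::pbinom(k, n, expected_freq)
  cls <- if (p_in < alpha) "inside_biased"
         else if (p_out < alpha) "outside_biased"
         else "unclassified"
  list(k = k, n = n, p_inside = p_in, p_outside = p_out, class = cls)
}

#' Per-variant ROH-bias table
#'
#' Pools carriers across populations (the expected frequency is taken from
#' all carrier observations unless supplied) and attaches the allele
#' frequency computed over adequately covered individuals.
#'
#' @param candidates list of `hlof_candidate`s.
#' @param roh ROH data.frame.
#' @param samples sample table.
#' @param alpha Binomial significance level.
#' @param expected_freq Optional fixed expected in-ROH frequency; default
#'   is the overall observed fraction.
#' @return data.frame, one row per variant: counts, tail P-values, class,
#'   allele frequency.
#' @export
roh_bias_table <- function(candidates, roh, samples, alpha = 0.1,
                           expected_freq = NULL) {
  obs <- roh_observations(candidates, roh, samples)
  if (nrow(obs) == 0) stop("no carrier observations")
  if (is.null(expected_freq)) expected_freq <- mean(obs$in_roh)
  af <- vapply(candidates, allele_frequency, numeric(1))
  keys <- vapply(candidates, `[[`, character(1), "key")
  rows <- lapply(seq_along(candidates), function(i) {
    sub <- obs[obs$key == keys[i], , drop = FALSE]
    cl <- classify_roh_bias(sum(sub$in_roh), nrow(sub), expected_freq, alpha)
    data.frame(key = keys[i], carriers_in_roh = cl$k, carriers_total = cl$n,
               p_inside = cl$p_inside, p_outside = cl$p_outside,
               class = cl$class, af = af[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "expected_freq") <- expected_freq
  out
}

#' Alternate-allele frequency of a candidate over covered individuals
#'
#' Denominator: two chromosomes per individual covered at the coverage
#' floor (the candidate's per-population counts are already restricted to
#' those individuals).
#'
#' @param candidate An `hlof_candidate`.
#' @return Allele frequency.
#' @export
allele_frequency <- function(candidate) {
  cnt <- rowSums(candidate$pop_counts)
  n <- sum(cnt)
  if (n == 0) return(NA_real_)
  (2 * cnt[["hom_alt"]] + cnt[["het"]]) / (2 * n)
}

#' Compare allele frequencies of inside- vs outside-ROH-biased variants
#'
#' Two-sample Wilcoxon rank-sum test of the allele frequencies of the two
#' bias classes. With fewer than 3 variants in either class the comparison
#' is flagged untestable.
#'
#' @param bias_table Output of [roh_bias_table()].
#' @param min_n Minimum class size for testing (default 3).
#' @return list `(n_inside, n_outside, median_inside, median_outside,
#'   statistic, p, testable)`.
#' @export
compare_af_by_bias <- function(bias_table, min_n = 3) {
  a <- bias_table$af[bias_table$class == "inside_biased"]
  b <- bias_table$af[bias_table$class == "outside_biased"]
  res <- list(n_inside = length(a), n_outside = length(b),
              median_inside = stats::median(a), median_outside = stats::median(b),
              statistic = NA_real_, p = NA_real_,
              testable = length(a) >= min_n && length(b) >= min_n)
  if (res$testable) {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    res$statistic <- unname(wt$statistic); res$p <- wt$p.value
  }
  res
}

#' Fisher's exact test comparing in/out-of-ROH counts between populations
#' @param counts_a,counts_b length-2 vectors `(inside, outside)` for the
#'   two populations.
#' @return Two-sided exact P-value (1 when any margin is zero).
#' @export
compare_populations_roh <- function(counts_a, counts_b) {
  m <- rbind(counts_a, counts_b)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}
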