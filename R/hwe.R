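#' Exact one-sided test for homozygote excess under Hardy-Weinberg equilibrium
#'
#' Conditional on the sample size and the minor/alternate allele count, the
#' number of heterozygotes under Hardy-Weinberg equilibrium follows the
#' Levene-Haldane distribution. Genotyping artifacts that miscall
#' heterozygotes as homozygotes depress the heterozygote count, so the
#' one-sided P-value is the probability of observing the realized
#' heterozygote count *or fewer*, summing over all heterozygote counts of
#' matching parity. This exact formulation remains valid at the rare-allele
#' counts where the chi-square approximation fails.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts for one
#'   population sample.
#' @return One-sided P-value for an excess of homozygotes. Monomorphic
#'   sites return 1.
#' @examples
#' hwe_excess_test(98, 0, 2)   # two homozygotes, no heterozygotes: small P
#' hwe_excess_test(90, 10, 0)  # no homozygote excess: P = 1
#' @export
hwe_excess_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n <= 0) stop("empty genotype sample")
  n_alt <- 2L * n_hom_alt + n_het
  if (n_alt == 0L || n_alt == 2L * n) return(1)
  dist <- hwe_het_distribution(n, n_alt)
  sum(dist$p[dist$het <= n_het])
}

# Levene-Haldane pmf of the heterozygote count given n diploids and n_alt
# alternate alleles. Returned probabilities are normalized over the support
# (heterozygote counts sharing the parity of n_alt).
hwe_het_distribution <- function(n, n_alt) {
  stopifnot(n_alt >= 0, n_alt <= 2 * n)
  n_alt <- min(n_alt, 2L * n - n_alt)  # distribution depends on the minor count
  hets <- seq.int(n_alt %% 2L, n_alt, by = 2L)
  hom_alt <- (n_alt - hets) / 2L
  hom_ref <- n - hets - hom_alt
  logw <- lfactorial(n) - lfactorial(hom_ref) - lfactorial(hets) -
    lfactorial(hom_alt) + hets * log(2)
  w <- exp(logw - max(logw))
  data.frame(het = hets, p = w / sum(w))
}
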