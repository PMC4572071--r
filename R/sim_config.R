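#' Configuration of a synthetic HLOF study
#'
#' Defines the cohort (five European-style populations by default: one
#' large cosmopolitan sample and four isolates with longer and more
#' abundant runs of homozygosity and differing mean sequencing depth), the
#' synthetic gene complement, the number of true planted HLOF variants,
#' the per-category artifact counts, phenotype dimensions and the planted
#' burden effect. With a fixed seed the generated study is reproducible
#' bit for bit.
#'
#' @param seed Integer seed driving all randomness of the generator.
#' @param populations data.frame with columns `name`, `size`,
#'   `roh_genome_fraction` (fraction of the genome inside runs of
#'   homozygosity per individual), `mean_roh_length_bp` and `mean_depth`
#'   (mean sequencing depth, reads).
#' @param n_genes Number of synthetic genes.
#' @param transcripts_per_gene Length-2 integer range; a second, truncated
#'   isoform is generated for a fraction of genes.
#' @param n_true_hlof Number of planted true HLOF variants.
#' @param artifact_counts Named integer vector of planted artifact counts
#'   per category. `FRAME_RESCUE` counts *pairs* (each pair plants two
#'   variants).
#' @param error_hom_rate Fraction of heterozygotes miscalled as
#'   homozygous-alternate at planted genotyping-error sites.
#' @param trait_count Number of quantitative traits measured.
#' @param trait_missing_rate Fraction of missing trait measurements.
#' @param burden_effect_beta Planted linear effect of the HLOF burden on
#'   the expected number of extreme trait values (0 = null).
#' @param n_neutral Number of neutral (non-candidate) sites carrying
#'   Hardy-Weinberg genotypes, used for calibration work.
#' @param known_fraction Fraction of true HLOF variants present in the
#'   known-variant catalogue.
#' @param contig_length Length of each synthetic contig (bp).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       populations = default_populations(),
                       n_genes = 340,
                       transcripts_per_gene = c(1L, 2L),
                       n_true_hlof = 173,
                       artifact_counts = default_artifact_counts(),
                       error_hom_rate = 0.85,
                       trait_count = 400,
                       trait_missing_rate = 0.10,
                       burden_effect_beta = 0,
                       n_neutral = 2000,
                       known_fraction = 0.561,
                       contig_length = 5e6) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(all(c("name", "size", "roh_genome_fraction",
                  "mean_roh_length_bp", "mean_depth") %in% names(populations)))
  stopifnot(all(populations$size >= 1))
  stopifnot(all(populations$roh_genome_fraction >= 0 &
                populations$roh_genome_fraction <= 1))
  stopifnot(error_hom_rate >= 0, error_hom_rate <= 1,
            trait_missing_rate >= 0, trait_missing_rate < 1,
            known_fraction >= 0, known_fraction <= 1)
  known_cats <- c("LAST10PCT", "LOW_MAPABILITY", "OFF_TARGET", "FEW_SAMPLES",
                  "ANCESTRAL", "MNP_CODON", "FRAME_RESCUE", "INFRAME",
                  "HWE_EXCESS", "LOW_COVERAGE", "NEAR_FIXED")
  bad <- setdiff(names(artifact_counts), known_cats)
  if (length(bad)) stop("unknown artifact categories: ", paste(bad, collapse = ", "))
  structure(list(
    seed = as.integer(seed), populations = populations, n_genes = n_genes,
    transcripts_per_gene = transcripts_per_gene, n_true_hlof = n_true_hlof,
    artifact_counts = artifact_counts, error_hom_rate = error_hom_rate,
    trait_count = trait_count, trait_missing_rate = trait_missing_rate,
    burden_effect_beta = burden_effect_beta, n_neutral = n_neutral,
    known_fraction = known_fraction, contig_length = contig_length
  ), class = "sim_config")
}

#' Default synthetic cohort: one cosmopolitan sample and four isolates
#'
#' Sizes mirror a 1432-exome survey design; isolates carry a larger
#' fraction of their genome in longer runs of homozygosity, and one
#' isolate is sequenced at markedly lower depth.
#' @return data.frame of population parameters.
#' @export
default_populations <- function() {
  data.frame(
    name = c("COSMO", "ISL_A", "ISL_B", "ISL_C", "ISL_D"),
    size = c(844L, 193L, 197L, 98L, 100L),
    roh_genome_fraction = c(0.03, 0.07, 0.06, 0.08, 0.10),
    mean_roh_length_bp = c(2.0e6, 2.4e6, 2.4e6, 2.6e6, 2.6e6),
    mean_depth = c(60, 59, 45, 59, 19),
    stringsAsFactors = FALSE)
}

#' Default planted artifact counts per category
#' @return Named integer vector.
#' @export
default_artifact_counts <- function() {
  c(LAST10PCT = 12L, LOW_MAPABILITY = 12L, OFF_TARGET = 12L,
    FEW_SAMPLES = 12L, ANCESTRAL = 12L, MNP_CODON = 12L,
    FRAME_RESCUE = 6L, INFRAME = 8L, HWE_EXCESS = 12L,
    LOW_COVERAGE = 12L, NEAR_FIXED = 6L)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: seed %d, %d individuals in %d populations, ",
                     "%d genes, %d true HLOFs, %d artifact variants>\n"),
              x$seed, sum(x$populations$size), nrow(x$populations), x$n_genes,
              x$n_true_hlof, sum(x$artifact_counts) + x$artifact_counts[["FRAME_RESCUE"]]))
  invisible(x)
}
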