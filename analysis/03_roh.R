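#!/usr/bin/env Rscript

# Relate surviving HLOF variants to runs of homozygosity: per-population
# in-ROH frequencies, Fisher contrasts of each isolate against the
# cosmopolitan cohort, per-variant binomial bias classification, and the
# allele-frequency comparison between inside- and outside-biased
# variants.

library(hlofscan)

study <- read_study("results/study")
scan <- scan_study(study)
surv <- scan$survivor_candidates

obs <- roh_observations(surv, study$roh, study$samples)
pops <- unique(study$samples$population)
freqs <- vapply(pops, function(p) population_roh_frequency(obs, p), numeric(1))
message("fraction of HLOF carrier observations inside ROHs, by population:")
print(round(freqs, 3))

cosmo <- names(which.max(table(study$samples$population)))
for (p in setdiff(pops, cosmo)) {
  a <- c(sum(obs$in_roh[obs$population == cosmo]),
         sum(!obs$in_roh[obs$population == cosmo]))
  b <- c(sum(obs$in_roh[obs$population == p]),
         sum(!obs$in_roh[obs$population == p]))
  message(sprintf("Fisher %s vs %s: P = %.3g", cosmo, p,
                  compare_populations_roh(a, b)))
}

bt <- roh_bias_table(surv, study$roh, study$samples)
write.table(bt, "results/roh_bias.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("bias classes: %s",
                paste(names(table(bt$class)), table(bt$class),
                      collapse = ", ", sep = "=")))

cmp <- compare_af_by_bias(bt)
message(sprintf(paste0("allele frequency, inside- vs outside-ROH-biased: ",
                       "median %.4f vs %.4f (Wilcoxon P = %.3g)"),
                cmp$median_inside, cmp$median_outside, cmp$p))
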