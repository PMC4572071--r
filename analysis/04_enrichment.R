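#!/usr/bin/env Rscript

# Summaries of the surviving HLOF set: per-population yield and sharing,
# gene-set enrichment over the synthetic annotations, tissue-expression
# profile, deleteriousness-score summary and the paralogue-count
# contrast. Also recomputes the published survey's enrichment ratios and
# yields from their printed inputs.

library(hlofscan)

study <- read_study("results/study")
scan <- scan_study(study)
surv <- scan$survivor_candidates

yt <- population_yield(surv, study$samples)
write.table(yt, "results/population_yield.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(yt)

hlof_genes <- unique(unlist(lapply(surv, function(x) x$csq$gene_id)))
universe <- unique(study$tables$go_annotations$gene)
et <- enrichment_table(hlof_genes, universe, study$tables$go_annotations)
write.table(et, "results/go_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(et)

ts <- tissue_summary(study$tables$expression, hlof_genes,
                     expressed_threshold = 1, focus_tissue = "testis")
message(sprintf("testis is the top tissue for %.1f%% of HLOF genes; %.0f%% expressed in testis",
                100 * ts$per_tissue$max_prop[ts$per_tissue$tissue == "testis"],
                100 * ts$prop_expressed_focus))

cs <- cscore_summary(surv)
message(sprintf("median C-score %.1f; Spearman rho(score, carriers) = %.2f (P = %.3g)",
                cs$median_cscore, cs$spearman_rho, cs$p))

par <- study$tables$paralogues
counts <- setNames(par$n_paralogues, par$gene)
hl <- lapply(split(par, par$cutoff), function(x)
  setNames(x$n_paralogues, x$gene)[intersect(x$gene, hlof_genes)])
bg <- lapply(split(par, par$cutoff), function(x) x$n_paralogues)
cp <- compare_paralogues(hl, bg, exclude_genes = study$tables$olfactory_genes)
print(cp)

# published survey numbers recomputed from printed inputs
go <- published_go_counts()
go$enrichment <- round(mapply(enrichment_ratio, go$N, go$B, go$n, go$b), 2)
print(go[, c("term", "description", "enrichment")])
pc <- published_population_counts()
pc$yield <- round(pc$n_hlofs / pc$n_individuals, 2)
print(pc)
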