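#!/usr/bin/env Rscript
# Step 7: GWAS post-processing on the simulated trait.
#
# Variant filters, the 0.05/n threshold, the dosage score test (stand-in
# for a mixed-model scan), iterative 200-kb candidate-region definition,
# gene-haplotype phenotype testing at the top region, and a term-
# enrichment check of the candidate genes.

source("analysis/00_config.R")

dir <- res_dir("gwas")

pop <- simulate_population(cfg_population)

snps <- variant_filters(pop$snp, "SNP")
pavs <- variant_filters(pop$pav, "PAV")
message(nrow(snps$sites), " SNPs and ", nrow(pavs$sites),
        " PAVs pass the MAF/missing filters")

res <- assoc_scan(snps, pop$phenotype)
thr <- bonferroni_threshold(nrow(res))
message("threshold 0.05/", nrow(res), " = ", signif(thr$threshold, 3),
        " (-log10 = ", thr$neglog10, ")")
write_tsv(res, file.path(dir, "snp_assoc.tsv"))

regions <- define_candidate_regions(res, thr$threshold)
write_tsv(regions, file.path(dir, "candidate_regions.tsv"))
message(nrow(regions), " candidate region(s)")

if (nrow(regions) > 0) {
  top <- regions[which.min(regions$peak_p), ]
  gene <- list(chrom = top$chrom, start = top$peak_pos - 1000L,
               end = top$peak_pos + 1000L)
  haps <- gene_haplotypes(snps, gene, min_group = 5L)
  ht <- haplotype_phenotype_test(haps, pop$phenotype, min_group = 5L)
  if (ht$testable) {
    write_tsv(cbind(ht$group_stats, letter = ht$letters[ht$group_stats$hap]),
              file.path(dir, "top_region_haplotypes.tsv"))
    message("top-region haplotype test: ", ht$method, ", P = ",
            signif(ht$p, 3))
  } else message("top-region haplotype groups too small to test")
}

# enrichment of genes near candidate regions against a synthetic term map
genes <- sprintf("simgene%04d", seq_len(cfg_population$n_genes))
set.seed(SEED)
term_map <- data.frame(gene_id = genes,
                       term = sample(paste0("TERM", 1:5),
                                     length(genes), TRUE))
linked <- pop$truth$pav_gene_map$gene_id
enr <- hypergeometric_enrichment(unique(linked), term_map, genes)
write_tsv(enr, file.path(dir, "enrichment.tsv"))
message(sum(enr$enriched), " term(s) enriched among PAV-linked genes")
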