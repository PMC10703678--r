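#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Builds the ancestral reference with genes, TE copies, gaps and
# centromeres; derives five accession assemblies carrying a shared pool of
# implanted SVs; and simulates the structured wild + cultivated population
# (SNPs, PAV genotypes, phenotypes, FPKM). Everything is written as
# FASTA/GFF3/BED/VCF/TSV under results/sim/.

source("analysis/00_config.R")

dir <- res_dir("sim")

pg <- simulate_pangenome(cfg_pangenome, n_accessions = N_ACCESSIONS)
write_genome(pg$ancestral, file.path(dir, "ancestral"))
for (id in names(pg$accessions)) {
  Biostrings::writeXStringSet(pg$accessions[[id]]$genome$chromosomes,
                              file.path(dir, paste0(id, ".fa")), width = 60L)
}
write_tsv(pg$truth, file.path(dir, "sv_truth.tsv"))
message("pangenome: ", N_ACCESSIONS, " accessions, ",
        nrow(pg$truth), " implanted SV events (",
        paste(names(table(pg$truth$subtype)), table(pg$truth$subtype),
              collapse = ", "), ")")

pop <- simulate_population(cfg_population)
write_snp_vcf(pop$snp, file.path(dir, "population_snps.vcf"),
              contigs = pop_lengths(cfg_population))
write_snp_vcf(pop$pav, file.path(dir, "population_pavs.vcf"),
              contigs = pop_lengths(cfg_population))
write_tsv(data.frame(accession = names(pop$labels), label = pop$labels),
          file.path(dir, "population_labels.tsv"))
write_tsv(data.frame(accession = names(pop$phenotype),
                     trait1 = pop$phenotype),
          file.path(dir, "phenotype.tsv"))
write_tsv(data.frame(gene_id = rownames(pop$fpkm), pop$fpkm,
                     check.names = FALSE),
          file.path(dir, "fpkm.tsv"))
write_tsv(pop$truth$sweep_region, file.path(dir, "sweep_truth.tsv"))
message("population: ", nrow(pop$snp$sites), " SNPs and ",
        nrow(pop$pav$sites), " PAVs across ", length(pop$labels),
        " accessions (", sum(pop$labels == "W1"), " wild)")
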