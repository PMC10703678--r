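# Shared configuration for the analysis workflow.
#
# Every step regenerates its inputs deterministically from these seeded
# configurations (no binary intermediates); file outputs under results/ are
# plain text. Problem sizes are desk-scale stand-ins for the study design:
# a 5-Mb ancestral genome with 5 derived assemblies, and a 2-Mb genome for
# the 230-accession population analyses.

library(panpav)

SEED <- 1L

cfg_pangenome <- sim_config(seed = SEED, n_chrom = 2,
                            chrom_length = 2500000L)
N_ACCESSIONS <- 5L

cfg_population <- sim_config(seed = SEED, n_chrom = 2,
                             chrom_length = 1000000L,
                             n_wild = 30L, n_cultivated = 200L)

pop_lengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                  paste0("chr", seq_len(cfg$n_chrom)))
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
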