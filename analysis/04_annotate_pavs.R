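#!/usr/bin/env Rscript
# Step 4: annotate the nonredundant PAVs (TE content, genic context),
# classify gene loss/pseudogenization, and screen expression impact in the
# simulated FPKM matrix.

source("analysis/00_config.R")

dir <- res_dir("annotation")

pg <- simulate_pangenome(cfg_pangenome, n_accessions = N_ACCESSIONS)
anc <- pg$ancestral
calls <- lapply(names(pg$accessions), function(id) {
  d <- pg$accessions[[id]]
  net <- build_net(chain_blocks(truth_alignment_blocks(anc, d$truth)),
                   ref_lengths = chrom_lengths(anc))
  filter_svs(call_svs(net, anc, d$genome), anc$gaps, anc$centromeres)
})
clusters <- merge_pavs(do.call(rbind, calls))

ann <- annotate_pavs(clusters, anc, te_lib = attr(anc, "te_library"))
write_tsv(ann, file.path(dir, "pav_annotation.tsv"))
message(round(100 * mean(ann$te_status == "TE-derived"), 1),
        "% of PAVs are TE-derived; genic contexts: ",
        paste(names(table(ann$context)), table(ann$context),
              collapse = ", "))

cl <- clusters$clusters
dels <- cl[cl$subtype %in% c("DEL", "INS"),
           c("subtype", "chrom", "start", "end", "seq")]
impact <- gene_impact(dels, anc)
write_tsv(impact, file.path(dir, "gene_impact.tsv"))
message(sum(impact$status == "lost"), " genes lost, ",
        sum(impact$status == "pseudogenized"), " pseudogenized of ",
        nrow(impact))

# expression screen on the population FPKM matrix: carriers of a
# gene-linked PAV against non-carriers
pop <- simulate_population(cfg_population)
map <- pop$truth$pav_gene_map
carrier <- matrix(FALSE, nrow(pop$fpkm), ncol(pop$fpkm),
                  dimnames = dimnames(pop$fpkm))
for (i in seq_len(nrow(map))) {
  cr <- pop$pav$dosage[map$pav_index[i], ] > 0
  cr[is.na(cr)] <- FALSE
  carrier[map$gene_id[i], ] <- cr
}
expr <- expression_impact(pop$fpkm, carrier)
write_tsv(expr, file.path(dir, "expression_impact.tsv"))
message(sum(expr$significant), " genes pass the fold-change/FDR screen (",
        sum(expr$tested), " tested)")
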