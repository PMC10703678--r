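test_that("TE classification uses the union of overlapping TE intervals", {
  pav <- list(chrom = "chr1", start = 1000, end = 2000)
  te95 <- data.frame(chrom = "chr1", start = 1000L, end = 1950L,
                     te_class = "LTR")
  expect_equal(classify_te(pav, te95)$te_status, "TE-derived")
  te50 <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                     te_class = "LTR")
  expect_equal(classify_te(pav, te50)$te_status, "non-TE")
  # overlapping intervals cover 0.92 after union although 0.95 + 0.40 raw
  te_two <- data.frame(chrom = "chr1", start = c(1050L, 1400L),
                       end = c(2000L, 1800L), te_class = c("LTR", "DNA"))
  res <- classify_te(pav, te_two)
  expect_equal(res$te_fraction, 0.95)
  expect_equal(res$te_status, "TE-derived")
  expect_equal(res$te_class, "LTR")
  expect_error(classify_te(list(chrom = "chr1", start = 5, end = 5), te95),
               "zero-length")
})

test_that("TE classification is monotone in the threshold", {
  set.seed(5)
  pav <- list(chrom = "chr1", start = 0, end = 1000)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    te <- data.frame(chrom = "chr1",
                     start = as.integer(sort(sample.int(900L, k))),
                     end = 0L, te_class = "LTR")
    te$end <- te$start + sample(50:400, k, TRUE)
    for (thr_hi in c(0.9, 0.7, 0.5)) {
      hi <- classify_te(pav, te, threshold = thr_hi)$te_status
      lo <- classify_te(pav, te, threshold = thr_hi - 0.3)$te_status
      if (hi == "TE-derived") expect_equal(lo, "TE-derived")
    }
  }
})

test_that("genic context precedence and strand-aware flanks", {
  g <- toy_genome()
  # overlaps exon 1 of gA and runs into the intron: coding wins
  both <- genic_context(list(chrom = "chr1", start = 1200, end = 1350),
                        g$genes, g$exons)
  expect_equal(both$context, "coding")
  expect_equal(both$distance, 0)
  intron <- genic_context(list(chrom = "chr1", start = 1310, end = 1390),
                          g$genes, g$exons)
  expect_equal(intron$context, "intron")
  # gB is minus strand (body 2000..2900): upstream lies right of the end
  up_minus <- genic_context(list(chrom = "chr2", start = 4300, end = 4400),
                            g$genes, g$exons)
  expect_equal(up_minus$context, "upstream2kb")
  expect_equal(up_minus$nearest_gene_id, "gB")
  down_minus <- genic_context(list(chrom = "chr2", start = 500, end = 600),
                              g$genes, g$exons)
  expect_equal(down_minus$context, "downstream2kb")
  far <- genic_context(list(chrom = "chr1", start = 8000, end = 8100),
                       g$genes, g$exons)
  expect_equal(far$context, "intergenic")
  expect_equal(far$distance, 8000 - 1600)
})

test_that("every PAV gets exactly one context and counts partition", {
  g <- toy_genome()
  set.seed(8)
  ctxs <- character(50)
  for (i in 1:50) {
    s <- sample.int(9000L, 1)
    ctxs[i] <- genic_context(list(chrom = sample(c("chr1", "chr2"), 1),
                                  start = s, end = s + 100),
                             g$genes, g$exons)$context
  }
  expect_true(all(ctxs %in% c("coding", "intron", "upstream2kb",
                              "downstream2kb", "intergenic")))
  expect_equal(sum(table(ctxs)), 50)
})

test_that("gene impact classifies loss, pseudogenization and intact genes", {
  g <- toy_genome()
  whole <- data.frame(subtype = "DEL", chrom = "chr1", start = 900L,
                      end = 1700L, seq = "")
  imp <- gene_impact(whole, g)
  expect_equal(imp$status[imp$gene_id == "gA"], "lost")
  expect_equal(imp$status[imp$gene_id == "gB"], "intact")
  # deletion removing one complete exon truncates the gene
  one_exon <- data.frame(subtype = "DEL", chrom = "chr1", start = 1350L,
                         end = 1650L, seq = "")
  imp2 <- gene_impact(one_exon, g)
  expect_equal(imp2$status[imp2$gene_id == "gA"], "pseudogenized")
  # insertion wholly inside the intron leaves the gene intact
  intronic <- data.frame(subtype = "INS", chrom = "chr1", start = 1350L,
                         end = 1350L, seq = strrep("A", 100))
  imp3 <- gene_impact(intronic, g)
  expect_equal(imp3$status[imp3$gene_id == "gA"], "intact")
  # frame-shifting coding insertion pseudogenizes
  frameshift <- data.frame(subtype = "INS", chrom = "chr1", start = 1100L,
                           end = 1100L, seq = strrep("A", 70))
  imp4 <- gene_impact(frameshift, g)
  expect_equal(imp4$status[imp4$gene_id == "gA"], "pseudogenized")
  # statuses partition genes: lost genes are never also pseudogenized
  expect_false(any(duplicated(imp$gene_id)))
})

test_that("multi-exon truncation mirrors the six-of-nine-exons pattern", {
  len <- 20000L
  set.seed(21)
  seqs <- c(chrX = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                         collapse = ""))
  starts <- seq(1000L, by = 600L, length.out = 9)
  genes <- data.frame(gene_id = "g9", chrom = "chrX", strand = "+",
                      start = 1000L, end = starts[9] + 300L)
  exons <- data.frame(gene_id = "g9", start = starts, end = starts + 300L)
  g9 <- genome_assembly("toy9", seqs, genes = genes, exons = exons)
  del <- data.frame(subtype = "DEL", chrom = "chrX",
                    start = starts[4] - 50L, end = starts[9] + 350L,
                    seq = "")  # removes the last six exons
  imp <- gene_impact(del, g9)
  expect_equal(imp$status, "pseudogenized")
})

test_that("expression impact applies the fold-change and FDR screen", {
  set.seed(10)
  n_genes <- 60
  fpkm <- matrix(rlnorm(n_genes * 20, 1.5, 0.4), n_genes, 20,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 sprintf("s%02d", 1:20)))
  carrier <- matrix(FALSE, n_genes, 20, dimnames = dimnames(fpkm))
  carrier[, 1:10] <- TRUE
  # gene 1: carriers ~N(2, .1), non-carriers ~N(8, .1)
  fpkm[1, 1:10] <- rnorm(10, 2, 0.1)
  fpkm[1, 11:20] <- rnorm(10, 8, 0.1)
  res <- expression_impact(fpkm, carrier)
  expect_true(res$significant[1])
  expect_equal(res$fold_change[1], (2 + 0.1) / (8 + 0.1), tolerance = 0.05)
  # identical group means are never significant
  fpkm[2, ] <- 5
  res2 <- expression_impact(fpkm, carrier)
  expect_equal(res2$fold_change[2], 1)
  expect_false(res2$significant[2])
  # FPKM < 1 defines silencing
  fpkm[3, 1:10] <- 0.5
  res3 <- expression_impact(fpkm, carrier)
  expect_equal(res3$silenced_carriers[3], 1)
  # too-small groups are flagged untested
  small <- expression_impact(fpkm[, 1:4, drop = FALSE],
                             carrier[, 1:4, drop = FALSE])
  expect_false(any(small$tested))
})

test_that("down-shifted genes separate carriers at the configured effect", {
  cfg <- sim_config(seed = 37, n_wild = 8L, n_cultivated = 24L)
  pop <- simulate_population(cfg)
  map <- pop$truth$pav_gene_map
  carrier <- matrix(FALSE, nrow(pop$fpkm), ncol(pop$fpkm),
                    dimnames = dimnames(pop$fpkm))
  for (i in seq_len(nrow(map))) {
    cr <- pop$pav$dosage[map$pav_index[i], ] > 0
    cr[is.na(cr)] <- FALSE
    carrier[map$gene_id[i], ] <- cr
  }
  res <- expression_impact(pop$fpkm, carrier)
  linked <- res$tested & rownames(pop$fpkm) %in% map$gene_id
  lower <- res$mean_carrier[linked] < res$mean_noncarrier[linked]
  expect_gte(mean(lower), 0.9)
})

test_that("cluster annotation combines TE status and genic context", {
  g <- toy_genome()
  g$te <- data.frame(chrom = "chr1", start = 3000L, end = 4000L,
                     te_class = "LTR", template_id = "TE01")
  clusters <- list(clusters = data.frame(
    cluster_id = c("pav00001", "pav00002"), subtype = c("DEL", "DEL"),
    chrom = "chr1", start = c(3050L, 7000L), end = c(3950L, 7400L),
    seq = "", n_members = 1L, n_accessions = 1L, stringsAsFactors = FALSE))
  ann <- annotate_pavs(clusters, g)
  expect_equal(ann$te_status, c("TE-derived", "non-TE"))
  expect_equal(nrow(ann), 2)
  expect_true(all(ann$context %in% c("coding", "intron", "upstream2kb",
                                     "downstream2kb", "intergenic")))
})
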