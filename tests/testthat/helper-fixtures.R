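# Shared builders for small fixtures; everything is generated in code.

block_row <- function(rs, re, qs, qe, strand = "+",
                      ref_chrom = "chr1", query_chrom = "chr1",
                      n_matches = re - rs) {
  data.frame(ref_chrom = ref_chrom, ref_start = rs, ref_end = re,
             query_chrom = query_chrom, query_start = qs, query_end = qe,
             strand = strand, n_matches = n_matches,
             stringsAsFactors = FALSE)
}

sv_row <- function(subtype, start, end, seq = "", acc = "acc1",
                   chrom = "chr1") {
  data.frame(accession_id = acc, subtype = subtype, ref_chrom = chrom,
             ref_start = start, ref_end = end, query_chrom = chrom,
             query_start = start, query_end = end, inserted_seq = seq,
             stringsAsFactors = FALSE)
}

# two-chromosome toy genome with one gene on each strand
toy_genome <- function(len = 10000L) {
  set.seed(42)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                         collapse = ""),
            chr2 = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                         collapse = ""))
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
                      strand = c("+", "-"), start = c(1000L, 2000L),
                      end = c(1600L, 2900L))
  exons <- data.frame(gene_id = c("gA", "gA", "gB", "gB"),
                      start = c(1000L, 1402L, 2000L, 2600L),
                      end = c(1300L, 1600L, 2300L, 2900L))
  genome_assembly("toy", seqs, genes = genes, exons = exons)
}

# brute-force single-linkage clustering by transitive closure
brute_closure <- function(svs, params = merge_params()) {
  n <- nrow(svs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- i == j ||
        (svs$subtype[i] == svs$subtype[j] &&
           pav_link(svs[i, ], svs[j, ], params))
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# random SV set for merge oracles
random_svs <- function(n, seed) {
  set.seed(seed)
  st <- sample(c("DEL", "INS"), n, TRUE)
  start <- sample.int(20000L, n)
  len <- sample(60:500, n, TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    if (st[i] == "INS")
      paste(sample(c("A", "C", "G", "T"), len[i], TRUE), collapse = "")
    else ""
  }, character(1))
  data.frame(accession_id = paste0("a", sample(1:4, n, TRUE)),
             subtype = st, ref_chrom = "chr1", ref_start = start,
             ref_end = ifelse(st == "INS", start, start + len),
             query_chrom = "chr1", query_start = start,
             query_end = start, inserted_seq = seqs,
             stringsAsFactors = FALSE)
}

# genotype matrix from a dosage matrix with convenience defaults
gt_fixture <- function(dosage, pos = NULL, chrom = "chr1", labels = NULL) {
  n <- nrow(dosage)
  if (is.null(pos)) pos <- seq(0L, by = 100L, length.out = n)
  genotype_matrix(
    data.frame(chrom = rep(chrom, n), pos = as.integer(pos),
               id = paste0("v", seq_len(n)),
               ref = rep("A", n), alt = rep("G", n),
               stringsAsFactors = FALSE),
    dosage, labels)
}

# per-base boolean-coverage oracle for interval algebra on a small space
coverage_vec <- function(x, space = 5000L) {
  v <- rep(FALSE, space)
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i])
      v[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  v
}
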