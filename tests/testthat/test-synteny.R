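test_that("chaining basics: single block, colinear join, strand break", {
  one <- block_row(0, 1000, 0, 1000)
  ch <- chain_blocks(one)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$score, 1000)

  two <- rbind(block_row(0, 1000, 0, 1000),
               block_row(1100, 2100, 1000, 2000))  # 100-bp ref gap, 0 query
  ch2 <- chain_blocks(two)
  expect_length(ch2, 1)
  expect_equal(nrow(ch2[[1]]$blocks), 2)

  mixed <- rbind(block_row(0, 1000, 0, 1000),
                 block_row(1100, 2100, 1100, 2100, strand = "-"))
  expect_length(chain_blocks(mixed), 2)
})

test_that("gapless-anchor violations are rejected by name", {
  bad <- block_row(0, 1000, 0, 900)
  expect_error(chain_blocks(bad), "block 1")
})

test_that("chain DP equals exhaustive colinear-subset search", {
  score_subset <- function(b, idx, gap_open, gap_extend) {
    if (length(idx) == 0) return(-Inf)
    s <- b[idx, , drop = FALSE]
    s <- s[order(s$ref_start), , drop = FALSE]
    total <- s$n_matches[1]
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        gr <- s$ref_start[i] - s$ref_end[i - 1]
        gq <- s$query_start[i] - s$query_end[i - 1]
        if (gr < 0 || gq < 0 || gr > 10000 || gq > 10000) return(-Inf)
        total <- total + s$n_matches[i] - gap_open - gap_extend * (gr + gq)
      }
    }
    total
  }
  for (seed in c(3, 8, 15)) {
    set.seed(seed)
    n <- 10
    start <- sort(sample.int(20000L, n))
    len <- sample(50:400, n, TRUE)
    qstart <- start + sample(-300:300, n, TRUE)
    b <- do.call(rbind, lapply(seq_len(n), function(i) {
      block_row(start[i], start[i] + len[i], qstart[i], qstart[i] + len[i])
    }))
    best_brute <- -Inf
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      best_brute <- max(best_brute, score_subset(b, idx, 10, 0.01))
    }
    ch <- chain_blocks(b)
    best_dp <- max(vapply(ch, `[[`, numeric(1), "score"))
    expect_equal(best_dp, best_brute, tolerance = 1e-9)
  }
})

test_that("netting keeps the best chain per territory and trims on both axes", {
  disjoint <- list(
    list(blocks = block_row(0, 20000, 0, 20000), score = 20000,
         strand = "+", ref_chrom = "chr1", query_chrom = "chr1",
         ref_start = 0, ref_end = 20000, query_start = 0,
         query_end = 20000),
    list(blocks = block_row(30000, 50000, 30000, 50000), score = 20000,
         strand = "+", ref_chrom = "chr1", query_chrom = "chr1",
         ref_start = 30000, ref_end = 50000, query_start = 30000,
         query_end = 50000))
  net <- build_net(disjoint)
  expect_length(net$chains, 2)

  same_span <- disjoint
  same_span[[2]]$blocks <- block_row(0, 20000, 40000, 60000)
  same_span[[2]]$ref_start <- 0; same_span[[2]]$ref_end <- 20000
  same_span[[2]]$query_start <- 40000; same_span[[2]]$query_end <- 60000
  same_span[[1]]$score <- 900; same_span[[2]]$score <- 400
  net2 <- build_net(same_span)
  expect_length(net2$chains, 1)
  expect_equal(net2$chains[[1]]$score, 900)

  # query-only overlap: B disjoint on ref but on A's query territory
  qclash <- disjoint
  qclash[[2]]$blocks <- block_row(30000, 50000, 5000, 25000)
  qclash[[2]]$query_start <- 5000; qclash[[2]]$query_end <- 25000
  net3 <- build_net(qclash)
  expect_length(net3$chains, 1)

  # uncovered reference intervals are the complement of accepted spans
  net4 <- build_net(disjoint, ref_lengths = c(chr1 = 60000L))
  expect_equal(net4$uncovered,
               data.frame(chrom = "chr1", start = c(20000L, 50000L),
                          end = c(30000L, 60000L)))
})

test_that("SV calls from adjacency gaps follow the size rules", {
  g <- toy_genome()
  ref <- genome_assembly("ref", stats::setNames(
    as.character(g$chromosomes), names(g$chromosomes)))
  qry <- ref
  mknet <- function(b) build_net(chain_blocks(b), min_span = 100L)
  del <- mknet(rbind(block_row(0, 1000, 0, 1000),
                     block_row(1500, 2500, 1000, 2000)))
  calls <- call_svs(del, ref, qry)
  expect_equal(calls$subtype, "DEL")
  expect_equal(c(calls$ref_start, calls$ref_end), c(1000, 1500))

  ins <- mknet(rbind(block_row(0, 1000, 0, 1000),
                     block_row(1000, 2000, 1300, 2300)))
  ic <- call_svs(ins, ref, qry)
  expect_equal(ic$subtype, "INS")
  expect_equal(ic$ref_start, 1000)
  expect_equal(nchar(ic$inserted_seq), 300)
  expect_equal(ic$inserted_seq,
               substr(as.character(g$chromosomes[["chr1"]]), 1001, 1300))

  small <- mknet(rbind(block_row(0, 1000, 0, 1000),
                       block_row(1030, 2030, 1030, 2030)))
  expect_equal(nrow(call_svs(small, ref, qry)), 0)

  cpx <- mknet(rbind(block_row(0, 1000, 0, 1000),
                     block_row(1400, 2400, 1200, 2200)))
  expect_equal(call_svs(cpx, ref, qry)$subtype, "CPX")
})

test_that("backward query step is reported as tandem duplication", {
  g <- toy_genome()
  ref <- genome_assembly("ref", as.character(g$chromosomes))
  chain <- list(list(
    blocks = rbind(block_row(0, 1000, 0, 1000),
                   block_row(1000, 2000, 800, 1800)),
    score = 2000, strand = "+", ref_chrom = "chr1", query_chrom = "chr1",
    ref_start = 0, ref_end = 2000, query_start = 0, query_end = 1800))
  net <- structure(list(chains = chain, uncovered = NULL),
                   class = "synteny_net")
  calls <- call_svs(net, ref, ref)
  expect_equal(calls$subtype, "TDUP")
})

test_that("swapping reference and query converts DEL into INS of the same sequence", {
  cfg <- sim_config(seed = 41, n_chrom = 1, chrom_length = 200000L,
                    n_genes = 5, n_te = 10,
                    sv_counts = c(DEL = 3L, INS = 0L, INV = 0L, TDUP = 0L,
                                  CPX = 0L))
  anc <- simulate_ancestral_genome(cfg)
  d <- derive_accession_genome(anc, cfg, "accR", seed = 2)
  blocks <- truth_alignment_blocks(anc, d$truth)
  fwd <- call_svs(build_net(chain_blocks(blocks),
                            ref_lengths = chrom_lengths(anc)),
                  anc, d$genome)
  swapped <- blocks
  swapped[c("ref_start", "ref_end", "query_start", "query_end")] <-
    blocks[c("query_start", "query_end", "ref_start", "ref_end")]
  rev <- call_svs(build_net(chain_blocks(swapped),
                            ref_lengths = chrom_lengths(d$genome)),
                  d$genome, anc, accession_id = "accR")
  expect_equal(sort(table(fwd$subtype))[["DEL"]], 3)
  expect_equal(rev$subtype, rep("INS", 3))
  del_seqs <- vapply(seq_len(nrow(fwd)), function(i) {
    substr(as.character(anc$chromosomes[[fwd$ref_chrom[i]]]),
           fwd$ref_start[i] + 1, fwd$ref_end[i])
  }, character(1))
  expect_setequal(rev$inserted_seq, del_seqs)
})

test_that("gap/centromere filtering removes the rule-specified records", {
  gaps <- data.frame(chrom = "chr1", start = c(550L, 2005L),
                     end = c(700L, 2100L))
  cens <- data.frame(chrom = "chr1", start = 5000L, end = 6000L)
  svs <- rbind(sv_row("DEL", 100, 600),     # overlaps gap -> removed
               sv_row("DEL", 5500, 5600),   # inside centromere -> removed
               sv_row("INS", 5500, 5500),   # junction in centromere -> removed
               sv_row("INV", 1000, 2000),   # 2000+10 >= 2005 -> removed
               sv_row("INV", 1000, 1990),   # margin misses the gap -> kept
               sv_row("DEL", 8000, 8100))   # far away -> kept
  out <- filter_svs(svs, gaps, cens, inv_gap_margin = 10L)
  expect_equal(nrow(out), 2)
  expect_setequal(out$ref_start, c(1000, 8000))
  removed <- attr(out, "removed")
  expect_equal(nrow(removed), 4)
  expect_true(all(removed$reason %in%
                    c("gap_or_centromere", "inversion_near_gap")))
})

test_that("net single-coverage invariant holds after netting random chains", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 12
    start <- sample.int(100000L, n)
    len <- sample(5000:20000, n, TRUE)
    qstart <- sample.int(100000L, n)
    chains <- lapply(seq_len(n), function(i) {
      list(blocks = block_row(start[i], start[i] + len[i], qstart[i],
                              qstart[i] + len[i]),
           score = len[i], strand = "+", ref_chrom = "chr1",
           query_chrom = "chr1", ref_start = start[i],
           ref_end = start[i] + len[i], query_start = qstart[i],
           query_end = qstart[i] + len[i])
    })
    net <- build_net(chains, min_span = 1000L)
    spans_r <- do.call(rbind, lapply(net$chains, function(ch)
      data.frame(chrom = ch$ref_chrom, start = ch$ref_start,
                 end = ch$ref_end)))
    spans_q <- do.call(rbind, lapply(net$chains, function(ch)
      data.frame(chrom = ch$query_chrom, start = ch$query_start,
                 end = ch$query_end)))
    expect_equal(interval_bases(spans_r), sum(spans_r$end - spans_r$start))
    expect_equal(interval_bases(spans_q), sum(spans_q$end - spans_q$start))
  }
})

test_that("round trip recovers implanted events with exact coordinates", {
  cfg <- sim_config(seed = 53, n_chrom = 2, chrom_length = 600000L,
                    n_genes = 30, n_te = 60)
  anc <- simulate_ancestral_genome(cfg)
  d <- derive_accession_genome(anc, cfg, "accT", seed = 7)
  tr <- d$truth
  net <- build_net(chain_blocks(truth_alignment_blocks(anc, tr)),
                   ref_lengths = chrom_lengths(anc))
  svs <- call_svs(net, anc, d$genome)
  key <- function(x, chrom, start, end)
    paste(x[[chrom]], x[[start]], x[[end]])
  for (st in c("DEL", "INS", "INV", "TDUP", "CPX")) {
    t2 <- tr[tr$subtype == st, ]
    s2 <- svs[svs$subtype == st, ]
    expect_equal(nrow(s2), nrow(t2))
    expect_true(all(key(t2, "chrom", "start", "end") %in%
                      key(s2, "ref_chrom", "ref_start", "ref_end")))
  }
  ins_t <- tr[tr$subtype == "INS", ]
  ins_c <- svs[svs$subtype == "INS", ]
  expect_setequal(ins_c$inserted_seq, ins_t$seq)
})
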