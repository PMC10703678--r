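lens1 <- c(chr1 = 100000L)

test_that("windowed pi matches the per-site formula", {
  # single site with c = 5, n = 10 in a 20-kb window
  dos <- matrix(c(2L, 2L, 1L, 0L, 0L), 1, 5,
                dimnames = list(NULL, paste0("a", 1:5)))
  gt <- gt_fixture(dos, pos = 10000L)
  tr <- windowed_pi(gt, NULL, lens1)
  w1 <- tr$value[tr$start == 0]
  expect_equal(w1, (2 * 5 * 5 / (10 * 9)) / 20000)
  expect_equal(signif(w1, 3), 2.78e-5)
  # doubling the window length halves the value
  tr2 <- windowed_pi(gt, NULL, lens1, window = 40000L)
  expect_equal(tr2$value[tr2$start == 0], w1 / 2)
  # a monomorphic window is 0, a window with no sites is missing
  mono <- gt_fixture(matrix(0L, 1, 5, dimnames = list(NULL, paste0("a", 1:5))),
                     pos = 10000L)
  trm <- windowed_pi(mono, NULL, lens1)
  expect_equal(trm$value[trm$start == 0], 0)
  expect_true(is.na(tr$value[tr$start == 60000]))
})

test_that("windowed pi agrees with an independent site-loop evaluation", {
  set.seed(9)
  n <- 10
  dos <- matrix(sample(c(0L, 2L, NA), n * 8, TRUE, prob = c(5, 3, 1)), n, 8,
                dimnames = list(NULL, paste0("a", 1:8)))
  pos <- sort(sample.int(90000L, n))
  gt <- gt_fixture(dos, pos = pos)
  tr <- windowed_pi(gt, NULL, lens1)
  # independent oracle: explicit loop over sites per window
  for (w in sample(nrow(tr), 12)) {
    h <- 0; seen <- 0
    for (i in seq_len(n)) {
      if (pos[i] >= tr$start[w] && pos[i] < tr$end[w]) {
        called <- dos[i, !is.na(dos[i, ])]
        nn <- 2 * length(called)
        if (nn < 2) next
        cc <- sum(called)
        h <- h + 2 * cc * (nn - cc) / (nn * (nn - 1))
        seen <- seen + 1
      }
    }
    if (seen == 0) expect_true(is.na(tr$value[w]))
    else expect_equal(tr$value[w], h / 20000)
  }
})

test_that("Weir-Cockerham FST hits the fixed-difference and null cases", {
  labels <- stats::setNames(rep(c("A", "B"), each = 10), paste0("x", 1:20))
  fixed <- gt_fixture(matrix(c(rep(0L, 10), rep(2L, 10)), 1, 20,
                             dimnames = list(NULL, paste0("x", 1:20))),
                      pos = 5000L, labels = labels)
  tr <- windowed_fst(fixed, "A", "B", lens1)
  expect_equal(tr$value[tr$start == 0], 1)
  # identical allele frequencies, equal sizes: estimator <= ~0
  same <- gt_fixture(matrix(rep(c(2L, 2L, 0L, 0L, 2L, 0L, 0L, 2L, 0L, 2L),
                                2), 1, 20,
                            dimnames = list(NULL, paste0("x", 1:20))),
                     pos = 5000L, labels = labels)
  trs <- windowed_fst(same, "A", "B", lens1)
  expect_lte(trs$value[trs$start == 0], 1e-12)
  expect_error(windowed_fst(fixed, "A", "nope", lens1), "unknown population")
})

test_that("FST components match a hand evaluation at p1=0.2, p2=0.8", {
  labels <- stats::setNames(rep(c("A", "B"), each = 10), paste0("x", 1:20))
  dosage <- matrix(c(rep(2L, 2), rep(0L, 8), rep(2L, 8), rep(0L, 2)), 1, 20,
                   dimnames = list(NULL, paste0("x", 1:20)))
  gt <- gt_fixture(dosage, pos = 100L, labels = labels)
  comp <- fst_site_components(gt, "A", "B")
  # hand evaluation of the 1984 components: r=2, n1=n2=10, h=0
  n1 <- 10; n2 <- 10; p1 <- 0.2; p2 <- 0.8; r <- 2
  nbar <- 10; nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- 0.5
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  expect_equal(comp$a, a)
  expect_equal(comp$b, b)
  expect_equal(comp$c, 0)
  # relabeling within populations leaves the estimate unchanged
  perm <- c(sample(1:10), sample(11:20))
  gt2 <- gt_fixture(dosage[, perm, drop = FALSE], pos = 100L,
                    labels = labels[perm])
  comp2 <- fst_site_components(gt2, "A", "B")
  expect_equal(comp2$a, comp$a)
})

test_that("track smoothing averages midpoints into covering windows", {
  lens <- c(chr1 = 300000L)
  win <- panpav:::make_windows(lens, 20000L, 2000L)
  const <- panpav:::window_track(win, rep(2.5, nrow(win)), "pi", lens)
  sm <- smooth_track(const)
  expect_true(all(abs(sm$value - 2.5) < 1e-12, na.rm = TRUE))
  expect_equal(nrow(sm), floor((300000 - 100000) / 10000) + 1)
  # a single nonzero input window contributes to the covering outputs
  one <- panpav:::window_track(win, rep(0, nrow(win)), "pi", lens)
  one$value[71] <- 10  # start 140000, midpoint 150000 (interior)
  sm1 <- smooth_track(one)
  touched <- sm1$value > 0 & !is.na(sm1$value)
  expect_equal(sum(touched), 10)  # covering 100-kb windows at 10-kb step
  expect_true(all(sm1$start[touched] <= 150000 &
                    sm1$end[touched] > 150000))
})

test_that("top-quantile selection uses the order-statistic threshold", {
  lens <- c(chr1 = 1000000L)
  win <- data.frame(chrom = "chr1",
                    start = seq(0L, by = 10000L, length.out = 100))
  win$end <- win$start + 10000L
  tr <- panpav:::window_track(win, 1:100, "fst", lens)
  sel <- top_quantile_regions(tr, q = 0.05)
  expect_equal(attr(sel, "threshold"), 96)
  expect_equal(interval_bases(sel), 5 * 10000)
  const <- panpav:::window_track(win, rep(7, 100), "fst", lens)
  all_sel <- top_quantile_regions(const, q = 0.05)
  expect_equal(interval_bases(all_sel), 100 * 10000)
  # overlapping selected windows merge into one region
  win2 <- panpav:::make_windows(c(chr1 = 100000L), 20000L, 2000L)
  v <- rep(0, nrow(win2)); v[10:11] <- 100
  tr2 <- panpav:::window_track(win2, v, "fst", c(chr1 = 100000L))
  sel2 <- top_quantile_regions(tr2, q = 2 / nrow(win2))
  expect_equal(nrow(sel2), 1)
  expect_error(top_quantile_regions(
    panpav:::window_track(win[1:5, ], rep(NA_real_, 5), "x", lens)),
    "missing|20")
})

test_that("sweep intersection is the common territory of all tracks", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  b <- data.frame(chrom = "chr1", start = 5000L, end = 15000L)
  c <- data.frame(chrom = "chr1", start = 5000L, end = 8000L)
  out <- intersect_sweeps(list(x = a, y = b, z = c))
  expect_equal(out$start, 5000L)
  expect_equal(out$end, 8000L)
  expect_equal(attr(out, "provenance"), c("x", "y", "z"))
  ident <- intersect_sweeps(list(a = a, b = a))
  expect_equal(ident$end, 10000L)
  expect_equal(nrow(intersect_sweeps(list(a = a, b = data.frame(
    chrom = "chr1", start = 90000L, end = 95000L)))), 0)
})

test_that("LD decay: perfect proxy pairs, independence baseline, distance cap", {
  dup <- matrix(rep(c(0L, 2L, 2L, 0L, 2L, 0L, 0L, 2L), 2), 2, 8,
                byrow = TRUE, dimnames = list(NULL, paste0("a", 1:8)))
  gt <- gt_fixture(dup, pos = c(100L, 600L))
  ld <- ld_decay(gt, bin = 1000L)
  expect_equal(ld$mean_r2, 1)
  # pair beyond max_dist is excluded
  far <- gt_fixture(dup, pos = c(100L, 900000L))
  expect_equal(nrow(ld_decay(far, max_dist = 500000L)), 0)
  # independent sites at frequency 0.5: mean r2 near 1/n
  set.seed(12)
  n_acc <- 500
  dos <- matrix(sample(c(0L, 2L), 40 * n_acc, TRUE), 40, n_acc,
                dimnames = list(NULL, paste0("a", seq_len(n_acc))))
  gti <- gt_fixture(dos, pos = sort(sample.int(400000L, 40)))
  ldi <- ld_decay(gti, max_dist = 500000L, bin = 500000L)
  expect_lt(abs(sum(ldi$mean_r2 * ldi$n_pairs) / sum(ldi$n_pairs) -
                  1 / n_acc), 3 / n_acc)
  # MAF filter drops rare sites
  rare <- dos; rare[1, ] <- 0L; rare[1, 1] <- 2L
  gtr <- gt_fixture(rare, pos = sort(sample.int(400000L, 40)))
  expect_lt(max(ld_decay(gtr, maf_min = 0.01)$n_pairs), sum(39:1) + 1)
})

test_that("4DTv extraction keeps fourfold sites and only those", {
  len <- 6000L
  base <- strrep("A", len)
  # plus-strand gene with one exon at 999..1299 (0-based 998..1298?); build
  # an explicit codon structure: GGA repeated -> all third positions 4DTv
  cds_plus <- strrep("GGA", 40)   # 120 bp
  cds_tg <- strrep("TGA", 40)     # TGx family is not fourfold
  seqv <- strsplit(base, "")[[1]]
  seqv[1001:1120] <- strsplit(cds_plus, "")[[1]]
  seqv[3001:3120] <- strsplit(cds_tg, "")[[1]]
  g <- genome_assembly("t4", c(chrZ = paste(seqv, collapse = "")),
    genes = data.frame(gene_id = c("gp", "gt"), chrom = "chrZ",
                       strand = "+", start = c(1000L, 3000L),
                       end = c(1120L, 3120L)),
    exons = data.frame(gene_id = c("gp", "gt"),
                       start = c(1000L, 3000L), end = c(1120L, 3120L)))
  pos <- c(1002L, 1001L, 3002L, 5000L)  # GG_3rd, GG_2nd, TG_3rd, intergenic
  dos <- matrix(0L, 4, 4, dimnames = list(NULL, paste0("a", 1:4)))
  gt <- gt_fixture(dos, pos = pos, chrom = "chrZ")
  out <- extract_4dtv(gt, g)
  expect_equal(out$sites$pos, 1002L)
  # idempotence and strict subset of coding positions
  again <- extract_4dtv(out, g)
  expect_equal(again$sites, out$sites)
  # minus-strand gene: genomic third positions sit at the exon start side
  gm <- genome_assembly("t5", c(chrZ = paste(seqv, collapse = "")),
    genes = data.frame(gene_id = "gm", chrom = "chrZ", strand = "-",
                       start = 1000L, end = 1120L),
    exons = data.frame(gene_id = "gm", start = 1000L, end = 1120L))
  # reverse complement of GGA-repeats is TCC-repeats: TC_ is fourfold, and
  # its third codon position is the first base of each genomic triplet
  gtm <- gt_fixture(matrix(0L, 2, 4, dimnames = list(NULL, paste0("a", 1:4))),
                    pos = c(1000L, 1002L), chrom = "chrZ")
  outm <- extract_4dtv(gtm, gm)
  expect_equal(outm$sites$pos, 1000L)
  # CDS not divisible by 3 raises a warning and is skipped
  gbad <- genome_assembly("t6", c(chrZ = paste(seqv, collapse = "")),
    genes = data.frame(gene_id = "gb", chrom = "chrZ", strand = "+",
                       start = 1000L, end = 1100L),
    exons = data.frame(gene_id = "gb", start = 1000L, end = 1100L))
  expect_warning(extract_4dtv(gt, gbad), "not divisible")
})

test_that("PAV frequency shift: Fisher tail, proportional null, reporting", {
  labels <- stats::setNames(c(rep("W1", 20), rep("C1", 60)),
                            paste0("p", 1:80))
  # wild 2/20 carriers vs cultivated 40/60
  dos <- matrix(c(rep(2L, 2), rep(0L, 18), rep(2L, 40), rep(0L, 20)), 1, 80,
                dimnames = list(NULL, paste0("p", 1:80)))
  shift <- gt_fixture(dos, pos = 100L, labels = labels)
  res <- pav_frequency_shift(shift, "W1", "C1")
  expect_lt(res$p, 1e-3)
  expect_true(res$significant)
  expect_equal(res$freq_wild, 0.1)
  # proportional cells: P = 1
  dosn <- matrix(c(rep(2L, 10), rep(0L, 10), rep(2L, 30), rep(0L, 30)),
                 1, 80, dimnames = list(NULL, paste0("p", 1:80)))
  resn <- pav_frequency_shift(gt_fixture(dosn, pos = 100L,
                                         labels = labels), "W1", "C1")
  expect_equal(resn$p, 1)
  expect_false(resn$significant)
  # frequencies are carriers over called: 8 of 45
  dosm <- matrix(NA_integer_, 1, 80, dimnames = list(NULL, paste0("p", 1:80)))
  dosm[1, 21:65] <- c(rep(2L, 8), rep(0L, 37))
  resm <- pav_frequency_shift(gt_fixture(dosm, pos = 1L, labels = labels),
                              "W1", "C1")
  expect_equal(round(100 * resm$freq_cultivated, 1), 17.8)
  expect_false(resm$tested)  # wild side has no calls
})

test_that("pi-ratio flags zero or missing denominators", {
  win <- data.frame(chrom = "chr1", start = c(0L, 2000L, 4000L),
                    end = c(20000L, 22000L, 24000L))
  num <- panpav:::window_track(win, c(1, 2, 3), "pi", c(chr1 = 30000L))
  den <- panpav:::window_track(win, c(2, 0, NA), "pi", c(chr1 = 30000L))
  r <- pi_ratio_track(num, den)
  expect_equal(r$value, c(0.5, NA, NA))
})
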