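test_that("Bonferroni thresholds reproduce the division rule", {
  t1 <- bonferroni_threshold(1890542)
  expect_equal(signif(t1$threshold, 3), 2.64e-8)
  expect_equal(t1$neglog10, 7.58)
  expect_equal(bonferroni_threshold(1)$threshold, 0.05)
  t2 <- bonferroni_threshold(19492)
  expect_equal(signif(t2$threshold, 3), 2.57e-6)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("variant filters apply the MAF and missing-rate presets", {
  dos <- rbind(
    c(rep(2L, 1), rep(0L, 24), NA),         # maf 1/50 = 0.02 -> dropped
    c(rep(2L, 13), rep(0L, 13)),            # maf 0.5, fully called -> kept
    c(rep(2L, 7), rep(0L, 7), rep(NA, 12))) # missing 0.46
  colnames(dos) <- paste0("a", 1:26)
  gt <- gt_fixture(dos)
  expect_equal(nrow(variant_filters(gt, "SNP")$sites), 1)
  expect_equal(nrow(variant_filters(gt, "PAV")$sites), 2)
})

test_that("candidate regions equal the literal iterative extension", {
  res <- data.frame(chrom = "chr1", pos = c(1000000L, 1150000L, 1500000L),
                    p = c(1e-10, 1e-9, 1e-12))
  r <- define_candidate_regions(res, threshold = 1e-8)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(1000000L, 1500000L))
  expect_equal(r$end, c(1150000L, 1500000L))
  expect_equal(r$peak_pos, c(1000000L, 1500000L))
  single <- define_candidate_regions(
    data.frame(chrom = "chr2", pos = 5L, p = 1e-9), 1e-8)
  expect_equal(single$start, single$end)
  none <- define_candidate_regions(
    data.frame(chrom = "chr1", pos = 1L, p = 0.5), 1e-8)
  expect_equal(nrow(none), 0)

  # literal iterative-scan oracle on random layouts
  literal_scan <- function(pos, ext) {
    pos <- sort(pos)
    out <- list()
    used <- rep(FALSE, length(pos))
    while (any(!used)) {
      i <- which(!used)[1]
      last <- pos[i]
      used[i] <- TRUE
      repeat {
        nxt <- which(!used & pos > last & pos <= last + ext)
        if (length(nxt) == 0) break
        last <- max(pos[nxt])
        used[nxt] <- TRUE
      }
      out[[length(out) + 1L]] <- c(pos[i], last)
    }
    do.call(rbind, out)
  }
  set.seed(14)
  for (rep in 1:150) {
    pos <- sort(sample.int(3000000L, sample(2:25, 1)))
    df <- data.frame(chrom = "chr1", pos = pos, p = 1e-10)
    got <- define_candidate_regions(df, 1e-8, ext = 200000L)
    want <- literal_scan(pos, 200000L)
    expect_equal(cbind(got$start, got$end), unname(want))
  }
  # input order invariance
  shuf <- df[sample(nrow(df)), ]
  expect_equal(define_candidate_regions(shuf, 1e-8), got)
})

test_that("reliable regions need support from two environments", {
  r1 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  r2 <- data.frame(chrom = "chr1", start = 150L, end = 300L)
  r3 <- data.frame(chrom = "chr1", start = 5000L, end = 5100L)
  rel <- reliable_regions(list(r1, r2, r3))
  expect_equal(nrow(rel), 1)
  expect_equal(rel$support, 2)
})

test_that("haplotypes group accessions by joint allele strings", {
  dos <- rbind(c(0L, 0L, 2L, 2L, NA, 0L),
               c(0L, 2L, 0L, 2L, 0L, 1L))
  colnames(dos) <- paste0("s", 1:6)
  gt <- gt_fixture(dos, pos = c(1200L, 1800L))
  gene <- list(chrom = "chr1", start = 1000L, end = 2000L)
  h <- gene_haplotypes(gt, gene, min_group = 1L)
  # s5 (missing) and s6 (het) are excluded; 4 accessions remain
  expect_setequal(names(h$assignment), paste0("s", 1:4))
  expect_equal(sum(h$groups$n), 4)
  expect_lte(nrow(h$groups), 4)
  # brute-force string grouping oracle
  strings <- c(s1 = "AA", s2 = "AG", s3 = "GA", s4 = "GG")
  for (acc in names(strings)) {
    mates <- names(strings)[strings == strings[[acc]]]
    expect_setequal(names(h$assignment)[h$assignment == h$assignment[[acc]]],
                    mates)
  }
  expect_error(gene_haplotypes(gt, list(chrom = "chr9", start = 1L,
                                        end = 2L)), "zero selected")
})

test_that("haplotype phenotype test: Wilcoxon fallback, KW, letters", {
  set.seed(30)
  acc <- paste0("a", 1:60)
  haps <- structure(list(
    assignment = stats::setNames(rep(c("Hap1", "Hap2", "Hap3"), each = 20),
                                 acc),
    groups = data.frame(hap = c("Hap1", "Hap2", "Hap3"), n = 20,
                        small = FALSE),
    positions = 1:2), class = "haplotype_table")
  y <- stats::setNames(c(rnorm(20), rnorm(20) + 3, rnorm(20)), acc)
  r <- haplotype_phenotype_test(haps, y)
  expect_equal(r$method, "kruskal_nemenyi")
  expect_lt(r$p, 0.001)
  expect_false(r$letters[["Hap1"]] == r$letters[["Hap2"]])
  expect_equal(r$letters[["Hap1"]], r$letters[["Hap3"]])

  # two groups shifted by 3 SD: Wilcoxon fallback, distinct letters
  two <- haps
  two$assignment <- stats::setNames(rep(c("Hap1", "Hap2"), each = 20),
                                    acc[1:40])
  y2 <- stats::setNames(c(rnorm(20), rnorm(20) + 3), acc[1:40])
  r2 <- haplotype_phenotype_test(two, y2)
  expect_equal(r2$method, "wilcoxon")
  expect_lt(r2$p, 0.001)
  expect_setequal(unname(r2$letters), c("a", "b"))

  # constant phenotype: no signal
  r3 <- haplotype_phenotype_test(haps, stats::setNames(rep(1, 60), acc))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  expect_true(all(r3$letters == "a"))

  # groups below the minimum size make the test untestable
  r4 <- haplotype_phenotype_test(haps, y[1:12])
  expect_false(r4$testable)
})

test_that("KW reduces to the Wilcoxon view for two groups on toys", {
  set.seed(31)
  y <- c(rnorm(15), rnorm(15, 1))
  g <- factor(rep(c("A", "B"), each = 15))
  kw <- stats::kruskal.test(y, g)$p.value
  wx <- stats::wilcox.test(y ~ g, exact = FALSE, correct = FALSE)$p.value
  expect_equal(kw, wx, tolerance = 0.05)
})

test_that("hypergeometric enrichment equals the exact tail summation", {
  universe <- paste0("g", 1:100)
  term_map <- data.frame(gene_id = paste0("g", 1:10), term = "T1")
  gene_set <- paste0("g", c(1:8, 21:32))   # overlap 8 of 20 drawn
  res <- hypergeometric_enrichment(gene_set, term_map, universe)
  brute <- sum(vapply(8:10, function(k) {
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)
  }, numeric(1)))
  expect_equal(res$p, brute)
  expect_true(res$enriched)
  # zero overlap: P = 1; set = universe: P = 1
  none <- hypergeometric_enrichment(paste0("g", 50:60),
                                    data.frame(gene_id = "g1", term = "T"),
                                    universe)
  expect_equal(none$p, 1)
  all_in <- hypergeometric_enrichment(universe, term_map, universe)
  expect_equal(all_in$p, 1)
  expect_error(hypergeometric_enrichment("g1", term_map, character(0)),
               "empty universe")
  # P monotone decreasing in overlap at fixed margins
  ps <- vapply(4:9, function(k) {
    gs <- paste0("g", c(seq_len(k), 21:(40 - k)))
    hypergeometric_enrichment(gs, term_map, universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("dosage score test ranks causal variants first", {
  set.seed(33)
  n <- 80
  dos <- matrix(sample(c(0L, 2L), 30 * n, TRUE), 30, n,
                dimnames = list(NULL, paste0("a", 1:n)))
  gt <- gt_fixture(dos, pos = seq(0L, by = 1000L, length.out = 30))
  y <- stats::setNames(dos[7, ] * 1.5 + rnorm(n, 0, 0.8), paste0("a", 1:n))
  res <- assoc_scan(gt, y)
  expect_equal(which.min(res$p), 7)
  expect_lt(res$p[7], 1e-6)
})

test_that("phenotype replicates reduce to accession means", {
  df <- data.frame(accession = c("a", "a", "b"), value = c(1, 3, 5))
  m <- phenotype_means(df)
  expect_equal(unname(m[c("a", "b")]), c(2, 5))
})
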