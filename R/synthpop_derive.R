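#' Derive an accession genome from the ancestral genome
#'
#' Implants the configured numbers of deletions, insertions, inversions,
#' tandem duplications and complex replacements into a copy of the ancestral
#' genome and records every event in ancestral (reference) coordinates. A
#' fraction `te_derived_fraction` of deletions remove an existing TE copy and
#' the same fraction of insertions are fresh (1-5% diverged) copies from the
#' TE library, so TE-derived variants recur across accessions with high
#' identity.
#'
#' Events are placed outside assembly gaps, centromeres and the outermost
#' 15 kb of each chromosome, with at least 2 kb between events, so each
#' event sits between unambiguous alignment anchors. Deletion/insertion lengths are
#' log-uniform on 60-8,000 bp; inversions span 12-40 kb (the resolution at
#' which a single-coverage net retains an inverted chain); tandem
#' duplications copy 100-2,000 bp; complex events replace 200-2,000 bp with
#' unrelated sequence of 0.5-1.5x length.
#'
#' @param ancestral the [simulate_ancestral_genome] output.
#' @param config a [sim_config] (uses `sv_counts`, `te_derived_fraction`).
#' @param accession_id label for the derived accession.
#' @param seed integer seed for this accession.
#' @param events optional explicit event table (`subtype`, `chrom`, `start`,
#'   `end`, `seq`) overriding random generation; events must be >= 50 bp and
#'   non-overlapping on the ancestral coordinate system.
#' @return list with `genome` (the derived [genome_assembly]) and `truth`
#'   (data frame: `variant_id`, `accession_id`, `subtype`, `chrom`, `start`,
#'   `end`, `seq`, `svlen`).
#' @export
derive_accession_genome <- function(ancestral, config, accession_id,
                                    seed = config$seed, events = NULL) {
  if (is.null(events)) {
    events <- with_seed(seed, paste0("sv_events_", accession_id),
                        random_sv_events(ancestral, config))
  } else {
    validate_sv_events(events)
  }
  events <- events[order(events$chrom, events$start), , drop = FALSE]
  lib <- attr(ancestral, "te_library")
  chroms <- lapply(names(ancestral$chromosomes), function(cname) {
    ev <- events[events$chrom == cname, , drop = FALSE]
    apply_events(as.character(ancestral$chromosomes[[cname]]), ev)
  })
  chroms <- unlist(chroms)
  names(chroms) <- names(ancestral$chromosomes)
  truth <- events
  if (nrow(truth) > 0) {
    truth$accession_id <- accession_id
    truth$svlen <- ifelse(truth$subtype == "INS", nchar(truth$seq),
                          truth$end - truth$start)
    truth$variant_id <- sprintf("%s_sv%03d", accession_id,
                                seq_len(nrow(truth)))
  } else {
    truth <- cbind(truth, accession_id = character(), svlen = integer(),
                   variant_id = character())
  }
  g <- genome_assembly(accession_id, chroms)
  attr(g, "te_library") <- lib
  list(genome = g, truth = truth)
}

#' @keywords internal
validate_sv_events <- function(events) {
  len <- ifelse(events$subtype == "INS", nchar(events$seq),
                events$end - events$start)
  if (any(len < 50)) stop("implanted SVs must be >= 50 bp")
  ev <- events[order(events$chrom, events$start), , drop = FALSE]
  if (nrow(ev) > 1) {
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    ovl <- same & ev$start[-1] < ev$end[-nrow(ev)]
    if (any(ovl)) {
      i <- which(ovl)[1]
      stop(sprintf("overlapping SV requests: %s:[%d,%d) and %s:[%d,%d)",
                   ev$chrom[i], ev$start[i], ev$end[i],
                   ev$chrom[i + 1], ev$start[i + 1], ev$end[i + 1]))
    }
  }
  invisible(events)
}

#' @keywords internal
random_sv_events <- function(ancestral, config) {
  lib <- attr(ancestral, "te_library")
  counts <- config$sv_counts
  lens <- chrom_lengths(ancestral)
  out <- list()
  # forbidden zones: gaps, centromeres, chromosome ends
  edges <- do.call(rbind, lapply(names(lens), function(cn) {
    data.frame(chrom = cn, start = c(0L, lens[[cn]] - 15000L),
               end = c(15000L, lens[[cn]]))
  }))
  forbidden <- rbind(ancestral$gaps[c("chrom", "start", "end")],
                     ancestral$centromeres[c("chrom", "start", "end")],
                     edges)
  rlen <- function(n, lo, hi) round(exp(runif(n, log(lo), log(hi))))
  # TE-derived deletions take an existing TE copy wholesale
  n_del <- counts[["DEL"]]
  n_del_te <- rbinom(1, n_del, config$te_derived_fraction)
  te_ok <- ancestral$te[!interval_overlaps_any(
    ancestral$te[c("chrom", "start", "end")], forbidden), , drop = FALSE]
  te_ok <- te_ok[te_ok$end - te_ok$start >= 60, , drop = FALSE]
  n_del_te <- min(n_del_te, nrow(te_ok))
  specs <- list()
  if (n_del_te > 0) {
    pick <- te_ok[sample(nrow(te_ok), n_del_te), , drop = FALSE]
    specs$del_te <- data.frame(subtype = "DEL", fixed_chrom = pick$chrom,
                               fixed_start = pick$start,
                               len = pick$end - pick$start, seq = "",
                               stringsAsFactors = FALSE)
  }
  add_float <- function(subtype, n, len, seq = rep("", n)) {
    if (n <= 0) return(NULL)
    data.frame(subtype = subtype, fixed_chrom = NA_character_,
               fixed_start = NA_integer_, len = len, seq = seq,
               stringsAsFactors = FALSE)
  }
  n_ins <- counts[["INS"]]
  n_ins_te <- rbinom(1, n_ins, config$te_derived_fraction)
  ins_seq <- character(n_ins)
  if (n_ins_te > 0) {
    tmpl <- sample(nrow(lib), n_ins_te, replace = TRUE)
    ins_seq[seq_len(n_ins_te)] <- vapply(tmpl, function(i) {
      mutate_seq(lib$seq[i], runif(1, 0.01, 0.05))
    }, character(1))
  }
  if (n_ins > n_ins_te)
    ins_seq[(n_ins_te + 1):n_ins] <-
      vapply(rlen(n_ins - n_ins_te, 60, 8000), rand_dna, character(1))
  specs$del <- add_float("DEL", n_del - n_del_te,
                         rlen(max(n_del - n_del_te, 0), 60, 8000))
  specs$ins <- add_float("INS", n_ins, rep(0L, n_ins), ins_seq)
  specs$inv <- add_float("INV", counts[["INV"]],
                         sample(12000:40000, max(counts[["INV"]], 1))[
                           seq_len(counts[["INV"]])])
  specs$tdup <- add_float("TDUP", counts[["TDUP"]],
                          rlen(counts[["TDUP"]], 100, 2000))
  cpx_ref <- rlen(counts[["CPX"]], 200, 2000)
  specs$cpx <- add_float("CPX", counts[["CPX"]], cpx_ref)
  if (counts[["CPX"]] > 0)
    specs$cpx$seq <- vapply(round(cpx_ref * runif(counts[["CPX"]], 0.5, 1.5)),
                            rand_dna, character(1))
  spec <- do.call(rbind, specs)
  if (is.null(spec) || nrow(spec) == 0) {
    return(data.frame(subtype = character(), chrom = character(),
                      start = integer(), end = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  # fixed-position events join the forbidden set; floating events are packed
  # per chromosome proportionally to length
  fixed <- !is.na(spec$fixed_chrom)
  if (any(fixed))   # inflate so floating events keep their distance too
    forbidden <- rbind(forbidden, data.frame(
      chrom = spec$fixed_chrom[fixed],
      start = pmax(spec$fixed_start[fixed] - 2000L, 0L),
      end = spec$fixed_start[fixed] + spec$len[fixed] + 2000L))
  spec$chrom <- spec$fixed_chrom
  spec$start <- spec$fixed_start
  float_idx <- which(!fixed)
  if (length(float_idx) > 0) {
    assign_chrom <- sample(names(lens), length(float_idx), replace = TRUE,
                           prob = lens / sum(lens))
    for (cn in unique(assign_chrom)) {
      idx <- float_idx[assign_chrom == cn]
      forb <- forbidden[forbidden$chrom == cn, , drop = FALSE]
      forb$chrom <- "x"
      # footprint on the reference; insertions occupy a point
      fp <- ifelse(spec$subtype[idx] == "INS", 1L, spec$len[idx])
      pos <- place_intervals(lens[[cn]], fp, forb, margin = 2000L,
                             what = "SV event")
      spec$chrom[idx] <- cn
      spec$start[idx] <- pos
    }
  }
  spec$end <- spec$start + ifelse(spec$subtype == "INS", 0L, spec$len)
  rownames(spec) <- NULL
  spec[, c("subtype", "chrom", "start", "end", "seq")]
}

## build the derived chromosome sequence left to right
#' @keywords internal
apply_events <- function(refseq, ev) {
  if (nrow(ev) == 0) return(refseq)
  pieces <- character(0)
  r <- 0L
  for (i in seq_len(nrow(ev))) {
    a <- ev$start[i]; b <- ev$end[i]
    if (a > r) pieces <- c(pieces, substr(refseq, r + 1L, a))
    piece <- switch(ev$subtype[i],
      DEL = "",
      INS = ev$seq[i],
      INV = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(refseq, a + 1L, b)))),
      TDUP = paste0(substr(refseq, a + 1L, b), substr(refseq, a + 1L, b)),
      CPX = ev$seq[i],
      stop("unknown subtype ", ev$subtype[i]))
    pieces <- c(pieces, piece)
    r <- b
  }
  if (r < nchar(refseq)) pieces <- c(pieces, substr(refseq, r + 1L,
                                                   nchar(refseq)))
  paste(pieces, collapse = "")
}

#' Exact alignment anchors implied by a truth set
#'
#' Emits the gapless anchor blocks that a perfect whole-genome alignment of
#' the derived genome against the ancestral genome would produce: one block
#' per colinear segment between events, a minus-strand block across each
#' inversion, and ref/query gaps encoding the other event types. This is the
#' default input to [chain_blocks] for simulated data (an external aligner
#' is not required).
#'
#' @param ancestral the ancestral [genome_assembly].
#' @param truth a truth table from [derive_accession_genome].
#' @return a block data frame (see [read_paf] for columns).
#' @export
truth_alignment_blocks <- function(ancestral, truth) {
  lens <- chrom_lengths(ancestral)
  out <- list()
  for (cname in names(lens)) {
    ev <- truth[truth$chrom == cname, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    r <- 0L; q <- 0L
    emit <- function(rs, re, qs, qe, strand = "+") {
      out[[length(out) + 1L]] <<- data.frame(
        ref_chrom = cname, ref_start = rs, ref_end = re,
        query_chrom = cname, query_start = qs, query_end = qe,
        strand = strand, n_matches = re - rs, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(ev))) {
      a <- ev$start[i]; b <- ev$end[i]
      if (a > r) { emit(r, a, q, q + (a - r)); q <- q + (a - r) }
      L <- ev$svlen[i]
      switch(ev$subtype[i],
        DEL = { r <- b },
        INS = { q <- q + L; r <- b },
        INV = { emit(a, b, q, q + (b - a), "-"); q <- q + (b - a); r <- b },
        TDUP = { emit(a, b, q, q + (b - a)); q <- q + 2L * (b - a); r <- b },
        CPX = { q <- q + nchar(ev$seq[i]); r <- b })
    }
    if (r < lens[[cname]]) emit(r, lens[[cname]], q, q + (lens[[cname]] - r))
  }
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  blocks
}

#' Simulate a pangenome: ancestral genome plus derived accessions
#'
#' Draws one population pool of SV events (sized `pool_factor` times the
#' per-accession `sv_counts`) with Beta(0.8, 1.2)-distributed population
#' frequencies, then lets every accession carry each pool event
#' independently with its frequency. Carried events are implanted with
#' [derive_accession_genome], so accessions share identical alleles at
#' shared events (insertion sequences included), exercising the
#' cross-accession merge rules, while rare events stay private.
#'
#' @param config a [sim_config].
#' @param n_accessions number of derived genomes.
#' @param pool_factor pool size multiplier.
#' @return list: `ancestral`, `accessions` (named list of
#'   `derive_accession_genome` results), `truth` (row-bound truth tables),
#'   `pool` (event table with `freq`).
#' @export
simulate_pangenome <- function(config, n_accessions = 5L,
                               pool_factor = 2.5) {
  anc <- simulate_ancestral_genome(config)
  pool_cfg <- config
  pool_cfg$sv_counts <- round(config$sv_counts * pool_factor)
  pool <- with_seed(config$seed, "sv_pool",
                    random_sv_events(anc, pool_cfg))
  pool$freq <- with_seed(config$seed, "sv_pool_freq",
                         stats::rbeta(nrow(pool), 0.8, 1.2))
  ids <- sprintf("BC%03d", seq_len(n_accessions))
  accessions <- list()
  truths <- list()
  for (id in ids) {
    carried <- with_seed(config$seed, paste0("carry_", id),
                         stats::runif(nrow(pool)) < pool$freq)
    ev <- pool[carried, c("subtype", "chrom", "start", "end", "seq"),
               drop = FALSE]
    d <- derive_accession_genome(anc, config, id, events = ev)
    accessions[[id]] <- d
    truths[[id]] <- d$truth
  }
  list(ancestral = anc, accessions = accessions,
       truth = do.call(rbind, truths), pool = pool)
}
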