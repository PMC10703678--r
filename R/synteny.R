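#' Chain colinear alignment blocks
#'
#' Sparse dynamic programming over gapless anchor blocks, the chain step of
#' classic chain/net processing. A block may extend a chain when both blocks
#' share reference chromosome, query chromosome and strand, coordinates
#' advance on the reference and on the query (query descending for minus
#' strand), blocks do not overlap, and neither gap exceeds `max_gap`. The
#' chain score is the sum of member `n_matches` minus
#' `gap_open + gap_extend * (ref_gap + query_gap)` per join; each block
#' belongs to at most one chain and chains are returned sorted by
#' descending score.
#'
#' `max_gap` sets the net resolution: events larger than it split chains
#' instead of appearing as within-chain gaps (inversions are recovered from
#' between-chain structure by [call_svs]).
#'
#' @param blocks block data frame (see [read_paf]).
#' @param gap_open,gap_extend nonnegative gap penalties.
#' @param max_gap largest within-chain gap on either axis (bp).
#' @return list of chains; each chain is a list with `blocks` (data frame,
#'   ordered along the reference), `score`, `strand`, `ref_chrom`,
#'   `query_chrom` and span columns.
#' @export
chain_blocks <- function(blocks, gap_open = 10, gap_extend = 0.01,
                         max_gap = 10000L) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (nrow(blocks) == 0) return(list())
  bad <- which((blocks$ref_end - blocks$ref_start) !=
                 abs(blocks$query_end - blocks$query_start))
  if (length(bad) > 0)
    stop("block ", bad[1], " violates the gapless anchor invariant")
  chains <- list()
  key <- paste(blocks$ref_chrom, blocks$query_chrom, blocks$strand)
  for (k in unique(key)) {
    b <- blocks[key == k, , drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    n <- nrow(b)
    minus <- b$strand[1] == "-"
    score <- b$n_matches
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1)) {
        gr <- b$ref_start[j] - b$ref_end[i]
        gq <- if (minus) b$query_start[i] - b$query_end[j]
              else b$query_start[j] - b$query_end[i]
        if (gr < 0 || gq < 0 || gr > max_gap || gq > max_gap) next
        cand <- score[i] + b$n_matches[j] - gap_open -
          gap_extend * (gr + gq)
        if (cand > score[j]) { score[j] <- cand; prev[j] <- i }
      }
    }
    used <- rep(FALSE, n)
    # trace back from best unused ends until all blocks are consumed
    ord <- order(score, decreasing = TRUE)
    for (j0 in ord) {
      if (used[j0]) next
      path <- integer(0)
      j <- j0
      while (!is.na(j) && !used[j]) { path <- c(j, path); used[j] <- TRUE
                                      j <- prev[j] }
      cb <- b[path, , drop = FALSE]
      chains[[length(chains) + 1L]] <- list(
        blocks = cb,
        score = sum(cb$n_matches) -
          chain_gap_cost(cb, gap_open, gap_extend, minus),
        strand = b$strand[1],
        ref_chrom = cb$ref_chrom[1], query_chrom = cb$query_chrom[1],
        ref_start = min(cb$ref_start), ref_end = max(cb$ref_end),
        query_start = min(cb$query_start), query_end = max(cb$query_end))
    }
  }
  ord <- order(vapply(chains, `[[`, numeric(1), "score"),
               decreasing = TRUE)
  chains[ord]
}

#' @keywords internal
chain_gap_cost <- function(cb, gap_open, gap_extend, minus) {
  n <- nrow(cb)
  if (n < 2) return(0)
  gr <- cb$ref_start[-1] - cb$ref_end[-n]
  gq <- if (minus) cb$query_start[-n] - cb$query_end[-1]
        else cb$query_start[-1] - cb$query_end[-n]
  sum(gap_open + gap_extend * (gr + gq))
}

#' Build a single-coverage synteny net from scored chains
#'
#' Greedy, kent-style netting: chains are visited by descending score (ties
#' broken by reference chromosome then start, for determinism) and accepted
#' only where their reference span and query span do not overlap any
#' previously accepted span. A partially overlapping chain is trimmed at
#' block granularity (blocks landing in occupied territory are dropped); a
#' chain whose trimmed reference span falls below `min_span` is discarded.
#' Reference intervals not covered by any accepted chain span are recorded
#' as the genotype-missing zones.
#'
#' @param chains output of [chain_blocks].
#' @param min_span minimum reference span (bp) of an accepted chain.
#' @param ref_lengths optional named chromosome lengths; when given,
#'   uncovered reference intervals are reported.
#' @return an object of class `synteny_net`: list with `chains` (accepted,
#'   trimmed) and `uncovered` (interval data frame).
#' @export
build_net <- function(chains, min_span = 10000L, ref_lengths = NULL) {
  if (length(chains) > 0) {
    ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
                 vapply(chains, `[[`, character(1), "ref_chrom"),
                 vapply(chains, `[[`, numeric(1), "ref_start"))
    chains <- chains[ord]
  }
  acc_ref <- empty_intervals()
  acc_query <- empty_intervals()
  accepted <- list()
  for (ch in chains) {
    b <- ch$blocks
    refspan <- data.frame(chrom = ch$ref_chrom, start = ch$ref_start,
                          end = ch$ref_end)
    qryspan <- data.frame(chrom = ch$query_chrom, start = ch$query_start,
                          end = ch$query_end)
    clash <- any(interval_overlaps_any(refspan, acc_ref)) ||
      any(interval_overlaps_any(qryspan, acc_query))
    if (clash) {
      keep <- !interval_overlaps_any(
        data.frame(chrom = b$ref_chrom, start = b$ref_start,
                   end = b$ref_end), acc_ref) &
        !interval_overlaps_any(
          data.frame(chrom = b$query_chrom, start = b$query_start,
                     end = b$query_end), acc_query)
      b <- b[keep, , drop = FALSE]
      if (nrow(b) == 0) next
      ch$blocks <- b
      ch$ref_start <- min(b$ref_start); ch$ref_end <- max(b$ref_end)
      ch$query_start <- min(b$query_start); ch$query_end <- max(b$query_end)
      ch$score <- sum(b$n_matches)
      if (ch$ref_end - ch$ref_start < min_span) next
      refspan <- data.frame(chrom = ch$ref_chrom, start = ch$ref_start,
                            end = ch$ref_end)
      qryspan <- data.frame(chrom = ch$query_chrom, start = ch$query_start,
                            end = ch$query_end)
      # trimming must have resolved the clash on both axes
      if (any(interval_overlaps_any(refspan, acc_ref)) ||
          any(interval_overlaps_any(qryspan, acc_query))) next
    }
    accepted[[length(accepted) + 1L]] <- ch
    acc_ref <- rbind(acc_ref, refspan)
    acc_query <- rbind(acc_query, qryspan)
  }
  uncovered <- empty_intervals()
  if (!is.null(ref_lengths)) {
    whole <- data.frame(chrom = names(ref_lengths), start = 0L,
                        end = as.integer(ref_lengths))
    uncovered <- interval_subtract(whole, acc_ref)
  }
  structure(list(chains = accepted, uncovered = uncovered),
            class = "synteny_net")
}

#' @export
print.synteny_net <- function(x, ...) {
  cat("synteny_net:", length(x$chains), "accepted chains,",
      nrow(x$uncovered), "uncovered reference intervals\n")
  invisible(x)
}

#' Call structural variants from a synteny net
#'
#' Within each accepted chain, every adjacency between consecutive blocks is
#' classified from its reference gap `g_r` and query gap `g_q`:
#' `g_r >= min_size` and `g_q < min_size` is a deletion of the reference
#' gap; `g_q >= min_size` and `g_r < min_size` is an insertion at the
#' reference junction carrying the query-gap sequence; both at or above
#' `min_size` is a complex event. An insertion whose sequence matches the
#' immediately preceding aligned query segment of equal length at identity
#' `>= tdup_identity` is reclassified as a tandem duplication (its reference
#' interval is placed over the duplicated copy). An adjacency whose query
#' interval steps backward by at least `min_size` while the reference
#' advances (possible in externally produced block lists) is likewise
#' reported as a tandem duplication. Between accepted chains, a minus-strand
#' chain flanked by plus-strand chains over colinear query territory (within
#' `inv_colinear_tol`) is an inversion over its reference span.
#'
#' The default `min_size = 51` makes the size floor strict (events must
#' exceed 50 bp).
#'
#' @param net a [build_net] result.
#' @param ref_genome,query_genome `genome_assembly` objects for sequence
#'   lookup.
#' @param accession_id label recorded on each call (defaults to the query
#'   genome's accession).
#' @param min_size minimum event size (bp).
#' @param tdup_identity identity floor for tandem-duplication
#'   reclassification.
#' @param inv_colinear_tol query colinearity tolerance for inversions (bp).
#' @return data frame of calls: `accession_id`, `subtype`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `query_chrom`, `query_start`, `query_end`,
#'   `inserted_seq`.
#' @export
call_svs <- function(net, ref_genome, query_genome,
                     accession_id = query_genome$accession_id,
                     min_size = 51L, tdup_identity = 0.8,
                     inv_colinear_tol = 100000L) {
  qlens <- chrom_lengths(query_genome)
  rlens <- chrom_lengths(ref_genome)
  calls <- list()
  add <- function(subtype, rc, rs, re, qc, qs, qe, seq = "") {
    if (rs < 0 || re > rlens[[rc]] || qs < 0 || qe > qlens[[qc]])
      stop("integrity: call coordinates outside genome")
    calls[[length(calls) + 1L]] <<- data.frame(
      accession_id = accession_id, subtype = subtype,
      ref_chrom = rc, ref_start = rs, ref_end = re,
      query_chrom = qc, query_start = qs, query_end = qe,
      inserted_seq = seq, stringsAsFactors = FALSE)
  }
  qseq <- function(chrom, s, e) {
    as.character(Biostrings::subseq(query_genome$chromosomes[[chrom]],
                                    s + 1L, e))
  }
  for (ch in net$chains) {
    b <- ch$blocks
    minus <- ch$strand == "-"
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      gr <- b$ref_start[i + 1] - b$ref_end[i]
      gq <- if (minus) b$query_start[i] - b$query_end[i + 1]
            else b$query_start[i + 1] - b$query_end[i]
      rc <- b$ref_chrom[1]; qc <- b$query_chrom[1]
      if (gq <= -min_size && gr >= 0) {
        # query steps backward over already-aligned territory
        L <- -gq
        add("TDUP", rc, b$ref_end[i], b$ref_start[i + 1], qc,
            min(b$query_start[i + 1], b$query_end[i] - L),
            max(b$query_end[i], b$query_start[i + 1] + L))
        next
      }
      if (gr < min_size && gq < min_size) next
      if (gr >= min_size && gq < min_size) {
        add("DEL", rc, b$ref_end[i], b$ref_start[i + 1], qc,
            if (minus) b$query_start[i] else b$query_end[i],
            if (minus) b$query_start[i] else b$query_end[i])
      } else if (gq >= min_size && gr < min_size) {
        qs <- if (minus) b$query_end[i + 1] else b$query_end[i]
        qe <- if (minus) b$query_start[i] else b$query_start[i + 1]
        seq <- qseq(qc, qs, qe)
        if (minus)
          seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        subtype <- "INS"
        rs <- b$ref_end[i]; re <- b$ref_start[i + 1]
        # tandem copy of the immediately preceding aligned query segment?
        L <- nchar(seq)
        prev_lo <- if (minus) b$query_start[i + 1] - 0L else qs - L
        if (!minus && qs - L >= 0) {
          prev <- qseq(qc, qs - L, qs)
          if (tandem_identity_at_least(seq, prev, tdup_identity)) {
            subtype <- "TDUP"
            rs <- max(b$ref_end[i] - L, 0L); re <- b$ref_end[i]
          }
        } else if (minus && qe + L <= qlens[[qc]]) {
          prev <- qseq(qc, qe, qe + L)  # upstream in alignment orientation
          prev <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(prev)))
          if (tandem_identity_at_least(seq, prev, tdup_identity)) {
            subtype <- "TDUP"
            rs <- max(b$ref_end[i] - L, 0L); re <- b$ref_end[i]
          }
        }
        add(subtype, rc, rs, re, qc, qs, qe, seq)
      } else {
        qs <- if (minus) b$query_end[i + 1] else b$query_end[i]
        qe <- if (minus) b$query_start[i] else b$query_start[i + 1]
        add("CPX", rc, b$ref_end[i], b$ref_start[i + 1], qc, qs, qe,
            qseq(qc, qs, qe))
      }
    }
  }
  # inversions: minus chain flanked by plus chains over colinear query spans
  chs <- net$chains
  if (length(chs) >= 3) {
    info <- data.frame(
      ref_chrom = vapply(chs, `[[`, character(1), "ref_chrom"),
      ref_start = vapply(chs, `[[`, numeric(1), "ref_start"),
      ref_end = vapply(chs, `[[`, numeric(1), "ref_end"),
      query_chrom = vapply(chs, `[[`, character(1), "query_chrom"),
      query_start = vapply(chs, `[[`, numeric(1), "query_start"),
      query_end = vapply(chs, `[[`, numeric(1), "query_end"),
      strand = vapply(chs, `[[`, character(1), "strand"))
    ord <- order(info$ref_chrom, info$ref_start)
    info <- info[ord, , drop = FALSE]
    for (i in seq_len(nrow(info) - 2)) {
      a <- info[i, ]; m <- info[i + 1, ]; z <- info[i + 2, ]
      if (a$ref_chrom != m$ref_chrom || m$ref_chrom != z$ref_chrom) next
      if (!(a$strand == "+" && m$strand == "-" && z$strand == "+")) next
      if (a$query_chrom != m$query_chrom || m$query_chrom != z$query_chrom)
        next
      if (m$ref_end - m$ref_start < min_size) next
      colinear <- m$query_start >= a$query_end - inv_colinear_tol &&
        m$query_end <= z$query_start + inv_colinear_tol
      if (!colinear) next
      add("INV", m$ref_chrom, m$ref_start, m$ref_end, m$query_chrom,
          m$query_start, m$query_end)
    }
  }
  if (length(calls) == 0) return(empty_sv_frame())
  out <- do.call(rbind, calls)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_sv_frame <- function() {
  data.frame(accession_id = character(), subtype = character(),
             ref_chrom = character(), ref_start = integer(),
             ref_end = integer(), query_chrom = character(),
             query_start = integer(), query_end = integer(),
             inserted_seq = character(), stringsAsFactors = FALSE)
}

## two-stage identity for the equal-length tandem comparison: Hamming
## identity is a lower bound on edit identity, so a clear pass or a clear
## miss skips the quadratic edit distance
tandem_identity_at_least <- function(a, b, threshold) {
  v1 <- utf8ToInt(a); v2 <- utf8ToInt(b)
  ham <- 1 - sum(v1 != v2) / length(v1)
  if (ham >= threshold) return(TRUE)
  if (ham < threshold - 0.3) return(FALSE)
  seq_identity(a, b) >= threshold
}

#' Global sequence identity from edit distance
#'
#' identity = 1 - Levenshtein distance / length of the longer sequence.
#'
#' @param a,b character scalars.
#' @return numeric in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  L <- max(nchar(a), nchar(b))
  if (L == 0) return(1)
  if (a == b) return(1)
  1 - as.numeric(utils::adist(a, b)) / L
}

#' Filter structural variants against gap and centromere tracks
#'
#' Deletions and insertions are removed when their reference interval
#' (insertions: their junction point) intersects a sequencing gap or a
#' centromere interval; inversions are removed when their reference
#' interval, expanded by `inv_gap_margin` bp on each side, intersects a gap.
#' All other records pass unchanged.
#'
#' @param svs SV call data frame.
#' @param gaps,centromeres interval data frames on reference coordinates.
#' @param inv_gap_margin margin (bp) around inversions.
#' @return the retained calls, with the removed records and their reasons in
#'   `attr(, "removed")`.
#' @export
filter_svs <- function(svs, gaps, centromeres, inv_gap_margin = 10L) {
  if (nrow(svs) == 0) return(svs)
  bad_tracks <- interval_merge(rbind(gaps[c("chrom", "start", "end")],
                                     centromeres[c("chrom", "start", "end")]))
  fp <- data.frame(chrom = svs$ref_chrom,
                   start = ifelse(svs$subtype == "INS",
                                  svs$ref_start, svs$ref_start),
                   end = ifelse(svs$subtype == "INS",
                                svs$ref_start + 1L, svs$ref_end))
  drop <- rep(FALSE, nrow(svs))
  reason <- rep(NA_character_, nrow(svs))
  di <- svs$subtype %in% c("DEL", "INS")
  hit <- interval_overlaps_any(fp, bad_tracks)
  drop[di & hit] <- TRUE
  reason[di & hit] <- "gap_or_centromere"
  inv <- svs$subtype == "INV"
  if (any(inv) && nrow(gaps) > 0) {
    expanded <- data.frame(chrom = svs$ref_chrom[inv],
                           start = pmax(svs$ref_start[inv] - inv_gap_margin,
                                        0L),
                           end = svs$ref_end[inv] + inv_gap_margin)
    hit_inv <- interval_overlaps_any(expanded,
                                     gaps[c("chrom", "start", "end")])
    drop[which(inv)[hit_inv]] <- TRUE
    reason[which(inv)[hit_inv]] <- "inversion_near_gap"
  }
  out <- svs[!drop, , drop = FALSE]
  removed <- svs[drop, , drop = FALSE]
  removed$reason <- reason[drop]
  attr(out, "removed") <- removed
  rownames(out) <- NULL
  out
}
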