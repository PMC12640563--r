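# Multimapping trimming. Sticky-end proximity ligation reconstitutes a
# single restriction motif at the junction between two ligated loci; since
# that motif borders both loci in the reference, a local aligner maps it
# into BOTH flanking soft-clipped alignments of the read. Those read bases
# can only derive from one locus in vivo, so every read base shared by two
# adjacent alignments of one mate is removed from both.

#' Adjacent segment pairs of each mate chain
#'
#' For every (read, mate) chain, returns consecutive segment pairs in read
#' order with their read-coordinate overlap and gap. Overlapping pairs are
#' the multimapping artifact targeted by [trim_multimap()]; abutting pairs
#' (`gap_len == 0`) are the junctions eligible for 1 bp breakpoint calls.
#'
#' @param alignments Segments tibble.
#' @return Tibble with one row per adjacent pair: `read_id`, `mate`,
#'   `up_row`, `down_row` (row indices into `alignments`), `overlap_len`,
#'   `gap_len`. At most one of `overlap_len`/`gap_len` is positive.
#' @export
find_adjacent_pairs <- function(alignments) {
  n <- nrow(alignments)
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), mate = character(),
                          up_row = integer(), down_row = integer(),
                          overlap_len = integer(), gap_len = integer()))
  }
  same_chain <- alignments$read_id[-n] == alignments$read_id[-1L] &
    alignments$mate[-n] == alignments$mate[-1L]
  up <- which(same_chain)
  if (any(alignments$read_start[up + 1L] < alignments$read_start[up])) {
    stop("chains must be sorted by read_start", call. = FALSE)
  }
  overlap <- pmax(0L, alignments$read_end[up] - alignments$read_start[up + 1L])
  gap <- pmax(0L, alignments$read_start[up + 1L] - alignments$read_end[up])
  tibble::tibble(
    read_id = alignments$read_id[up],
    mate = alignments$mate[up],
    up_row = up,
    down_row = up + 1L,
    overlap_len = as.integer(overlap),
    gap_len = as.integer(gap)
  )
}

# Remove n aligned query bases from one end (in read orientation) of a
# segment given as scalar fields; returns updated scalar fields.
trim_segment_end <- function(cigar, strand, ref_start, ref_end,
                             read_start, read_end, n,
                             read_side = c("5", "3")) {
  read_side <- match.arg(read_side)
  ops <- cigar_ops_fast(cigar)
  # the CIGAR is in reference orientation; map the read side onto it
  ref_side <- if ((strand == "-") == (read_side == "3")) "left" else "right"
  tr <- trim_cigar(ops, n, ref_side)
  if (ref_side == "left") {
    ref_start <- ref_start + tr$ref_removed
  } else {
    ref_end <- ref_end - tr$ref_removed
  }
  if (read_side == "5") {
    read_start <- read_start + as.integer(n)
  } else {
    read_end <- read_end - as.integer(n)
  }
  list(cigar = cigar_string_fast(tr$op, tr$len), ref_start = ref_start,
       ref_end = ref_end, read_start = read_start, read_end = read_end,
       removed = tr$all_removed)
}

#' Trim multimapped read bases shared by adjacent soft-clipped alignments
#'
#' For each (read, mate) chain sorted by read position, every pair of
#' consecutive segments whose read spans overlap has the shared read bases
#' removed from BOTH segments: the upstream segment loses them from its
#' 3'-in-read end and the downstream segment from its 5'-in-read end. In
#' each CIGAR the removed query-consuming ops become soft clip (merged with
#' any existing clip), reference spans shrink by the reference-consuming
#' length removed on the strand-correct side, and deletions stranded at a
#' new alignment edge are dropped. A segment whose aligned span is removed
#' entirely is dropped from the chain. Pairs separated by a gap are never
#' modified. The result has pairwise-disjoint read spans per chain and the
#' operation is idempotent.
#'
#' Per-segment statistics (whether a soft-clipped segment had multimapping,
#' and the fraction of its original aligned read span trimmed) are attached
#' as a `trim_stats` attribute; retrieve with [trim_stats()].
#'
#' @param alignments Segments tibble (name-grouped, chains sorted by
#'   `read_start` as produced by [read_alignments()]).
#' @return Trimmed segments tibble.
#' @export
trim_multimap <- function(alignments) {
  n <- nrow(alignments)
  stats <- tibble::tibble(
    read_id = alignments$read_id,
    mate = alignments$mate,
    is_soft_clipped = alignments$is_soft_clipped,
    aligned_span = alignments$read_end - alignments$read_start,
    had_multimapping = FALSE,
    bases_trimmed = 0L,
    removed_entirely = FALSE
  )
  adj <- if (n) find_adjacent_pairs(alignments) else NULL
  if (n == 0L || !any(adj$overlap_len > 0L)) {
    out <- alignments
    attr(out, "trim_stats") <- finish_trim_stats(stats)
    return(carry_attrs(out, alignments))
  }
  # work on plain column vectors; data-frame row assignment is too slow
  cigar <- alignments$cigar
  strand <- alignments$strand
  ref_start <- alignments$ref_start
  ref_end <- alignments$ref_end
  read_start <- alignments$read_start
  read_end <- alignments$read_end
  had_mm <- stats$had_multimapping
  trimmed <- stats$bases_trimmed
  removed <- stats$removed_entirely

  chain_id <- cumsum(c(TRUE, alignments$read_id[-1L] != alignments$read_id[-n] |
                         alignments$mate[-1L] != alignments$mate[-n]))
  hot_chains <- unique(chain_id[adj$up_row[adj$overlap_len > 0L]])
  chain_rows <- split(seq_len(n), chain_id)
  for (ck in hot_chains) {
    alive <- chain_rows[[ck]]
    i <- 1L
    while (i < length(alive)) {
      r_up <- alive[i]; r_dn <- alive[i + 1L]
      L <- read_end[r_up] - read_start[r_dn]
      if (L <= 0L) {
        i <- i + 1L
        next
      }
      for (r in c(r_up, r_dn)) {
        side <- if (r == r_up) "3" else "5"
        take <- min(L, read_end[r] - read_start[r])
        tr <- trim_segment_end(cigar[r], strand[r], ref_start[r], ref_end[r],
                               read_start[r], read_end[r], take, side)
        cigar[r] <- tr$cigar
        ref_start[r] <- tr$ref_start; ref_end[r] <- tr$ref_end
        read_start[r] <- tr$read_start; read_end[r] <- tr$read_end
        had_mm[r] <- TRUE
        trimmed[r] <- trimmed[r] + as.integer(take)
        if (tr$removed || read_end[r] <= read_start[r]) removed[r] <- TRUE
      }
      if (removed[r_up] || removed[r_dn]) {
        alive <- alive[!removed[alive]]
        i <- max(i - 1L, 1L)
      } else {
        i <- i + 1L
      }
    }
  }
  out <- alignments
  out$cigar <- cigar
  out$ref_start <- ref_start; out$ref_end <- ref_end
  out$read_start <- read_start; out$read_end <- read_end
  out$is_soft_clipped <- out$is_soft_clipped | had_mm
  stats$had_multimapping <- had_mm
  stats$bases_trimmed <- trimmed
  stats$removed_entirely <- removed
  if (any(removed)) out <- out[!removed, ]
  out <- carry_attrs(out, alignments)
  attr(out, "trim_stats") <- finish_trim_stats(stats)
  out
}

finish_trim_stats <- function(stats) {
  stats$trimmed_fraction <- ifelse(
    stats$aligned_span > 0L, stats$bases_trimmed / stats$aligned_span, 0
  )
  stats
}

#' @rdname trim_multimap
#' @export
trim_stats <- function(alignments) attr(alignments, "trim_stats")
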