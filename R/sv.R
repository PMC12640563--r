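# Cut-site proximity annotation and 1 bp breakpoint calling. In a proper
# sticky-end ligation product the facing ends of a contact's two
# alignments coincide with restriction cut sites (up to the overhang
# length); a facing end distal from every cut site is more consistent with
# a structural-variant junction than with digestion and ligation.

#' Annotate contacts with restriction cut-site proximity
#'
#' Computes, for each contact, the distance from each facing end (the
#' junction-proximal reference coordinate of each alignment, carried in the
#' `end1`/`end2` columns) to the nearest cut site, and flags the contact as
#' a likely SV-induced junction when either distance exceeds `tolerance`.
#' Both distances are always recorded so users can impose a stricter
#' both-ends rule downstream.
#'
#' @param contacts Contacts tibble from [call_contacts()] (canonicalized or
#'   not; the `end1`/`end2` columns travel with their sides).
#' @param index A `pairwalk_cutsites` index over the same reference.
#' @param tolerance Maximum facing-end distance (bp) still considered
#'   proximal. Default: longest enzyme motif + 1, since sticky-end fill-in
#'   shifts the observed junction by up to the overhang length.
#' @return The contacts tibble with `dist1`, `dist2` and `sv_flag` columns.
#' @export
annotate_sv <- function(contacts, index, tolerance = NULL) {
  stopifnot(inherits(index, "pairwalk_cutsites"))
  tolerance <- tolerance %||% default_sv_tolerance(index)
  stopifnot(tolerance >= 0)
  out <- contacts
  if (nrow(contacts) == 0L) {
    out$dist1 <- numeric(); out$dist2 <- numeric(); out$sv_flag <- logical()
    return(carry_attrs(out, contacts))
  }
  out$dist1 <- nearest_cut_distance(index, contacts$chrom1, contacts$end1)
  out$dist2 <- nearest_cut_distance(index, contacts$chrom2, contacts$end2)
  out$sv_flag <- out$dist1 > tolerance | out$dist2 > tolerance
  carry_attrs(out, contacts)
}

default_sv_tolerance <- function(index) {
  motifs <- vapply(index$enzymes, function(e) e$motif, "")
  motifs <- motifs[!is.na(motifs)]
  if (length(motifs) == 0L) {
    stop("cut-site index has no motif provenance; supply `tolerance`",
         call. = FALSE)
  }
  max(nchar(motifs)) + 1L
}

#' Call 1 bp-resolution breakpoints from adjacent soft-clipped alignments
#'
#' When two alignments of one mate abut in read coordinates (gap at most
#' `max_junction_gap`) and their facing ends are distal from every cut
#' site, the junction read base pinpoints a candidate SV breakpoint at
#' single-base resolution: `posA`/`posB` are the 1-based coordinates of the
#' junction-adjacent aligned base on each side. Junctions with unread bases
#' between the segments, and mate-paired contacts (whose junction is never
#' sequenced), yield no breakpoint. Run on trimmed chains so the duplicated
#' ligation motif cannot shift the junction.
#'
#' Both intra- and inter-chromosomal junctions are reported.
#'
#' @param alignments Trimmed, MAPQ-filtered segments tibble.
#' @param index A `pairwalk_cutsites` index.
#' @param tolerance Proximity tolerance in bp (see [annotate_sv()]).
#' @param max_junction_gap Maximum unaligned read bases allowed between the
#'   two segments (default 0: strict adjacency, required for an exact 1 bp
#'   claim).
#' @return Tibble with one row per supporting junction observation:
#'   `chromA`, `posA`, `strandA`, `chromB`, `posB`, `strandB`, `read_id`,
#'   `mate`, `dA`, `dB`, `source`. Aggregate with
#'   [aggregate_breakpoints()].
#' @export
call_breakpoints <- function(alignments, index, tolerance = NULL,
                             max_junction_gap = 0L) {
  stopifnot(inherits(index, "pairwalk_cutsites"))
  tolerance <- tolerance %||% default_sv_tolerance(index)
  adj <- find_adjacent_pairs(alignments)
  adj <- adj[adj$gap_len <= max_junction_gap & adj$overlap_len == 0L, ,
             drop = FALSE]
  if (nrow(adj) == 0L) return(empty_breakpoints())
  up <- alignments[adj$up_row, ]
  dn <- alignments[adj$down_row, ]
  endA <- facing_3prime(up$strand, up$ref_start, up$ref_end)
  endB <- facing_5prime(dn$strand, dn$ref_start, dn$ref_end)
  dA <- nearest_cut_distance(index, up$chrom, endA)
  dB <- nearest_cut_distance(index, dn$chrom, endB)
  keep <- dA > tolerance | dB > tolerance
  if (!any(keep)) return(empty_breakpoints())
  up <- up[keep, ]; dn <- dn[keep, ]
  tibble::tibble(
    chromA = up$chrom,
    # junction-adjacent aligned base, 1-based
    posA = as.integer(ifelse(up$strand == "+", up$ref_end, up$ref_start + 1L)),
    strandA = up$strand,
    chromB = dn$chrom,
    posB = as.integer(ifelse(dn$strand == "+", dn$ref_start + 1L, dn$ref_end)),
    strandB = dn$strand,
    read_id = up$read_id,
    mate = up$mate,
    dA = dA[keep],
    dB = dB[keep],
    source = "adjacent_softclip"
  )
}

empty_breakpoints <- function() {
  tibble::tibble(
    chromA = character(), posA = integer(), strandA = character(),
    chromB = character(), posB = integer(), strandB = character(),
    read_id = character(), mate = character(),
    dA = numeric(), dB = numeric(), source = character()
  )
}

#' Tabulate unique breakpoints with supporting-read counts
#'
#' @param breakpoints Result of [call_breakpoints()].
#' @return Tibble with one row per unique junction
#'   (`chromA`, `posA`, `strandA`, `chromB`, `posB`, `strandB`), a
#'   `n_support` count and a representative `read_id`.
#' @export
aggregate_breakpoints <- function(breakpoints) {
  if (nrow(breakpoints) == 0L) {
    out <- empty_breakpoints()[, c("chromA", "posA", "strandA",
                                   "chromB", "posB", "strandB", "read_id")]
    out$n_support <- integer()
    return(out)
  }
  breakpoints |>
    dplyr::group_by(.data$chromA, .data$posA, .data$strandA,
                    .data$chromB, .data$posB, .data$strandB) |>
    dplyr::summarise(
      read_id = dplyr::first(.data$read_id),
      n_support = dplyr::n(),
      .groups = "drop"
    )
}
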