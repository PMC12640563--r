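# Contact calling. The "mask" policy reports at most one two-locus contact
# per read pair (rescuing the common chimeric 2+1 configuration); the
# "all" policy reconstructs the full ligation walk and reports every
# adjacent locus pair along it. Both are implemented as vectorized passes
# over the grouped segments tibble.

five_prime_pos <- function(strand, ref_start, ref_end) {
  ifelse(strand == "+", ref_start + 1L, ref_end)  # 1-based
}

# junction-proximal reference coordinates, 0-based between-base positions
facing_3prime <- function(strand, ref_start, ref_end) {
  ifelse(strand == "+", ref_end, ref_start)
}
facing_5prime <- function(strand, ref_start, ref_end) {
  ifelse(strand == "+", ref_start, ref_end)
}

empty_contacts <- function() {
  tibble::tibble(
    read_id = character(), chrom1 = character(), pos1 = integer(),
    strand1 = character(), chrom2 = character(), pos2 = integer(),
    strand2 = character(), pair_type = character(),
    junction_class = character(), contact_index = integer(),
    end1 = integer(), end2 = integer(), flipped = logical()
  )
}

#' Call chromatin contacts from trimmed, MAPQ-filtered alignments
#'
#' Under `policy = "mask"`, a read pair yields one contact when each mate
#' has exactly one segment (pair type `UU`), or when one mate has exactly
#' two segments whose 3'-in-read segment matches the other mate's single
#' segment (same chromosome, opposite strand, 5' positions within
#' `rescue_window`): the contact then joins the two 5'-in-read segments
#' (pair type `RU`/`UR`). A mate with no segments gives an `N` code and no
#' contact; anything more complex is masked (`MM`, or `MU`/`UM` for an
#' unrescued chimera). Under `policy = "all"`, the full walk is built —
#' R1's chain in read order followed by R2's chain in reverse read order,
#' merging the two mates' terminal segments when they cover the same locus
#' — and one contact is emitted per consecutive walk pair
#' (`contact_index` ascending); a walk of k merged segments yields k - 1
#' contacts, and a fully merged self-ligation walk of one segment yields
#' none. The reported position of each side is the 5'-in-read reference
#' coordinate of its segment (1-based: `ref_start + 1` on `+`, `ref_end`
#' on `-`), the pairs convention.
#'
#' Contacts are returned in read order, un-canonicalized; pass the result
#' through [canonicalize_contacts()] before writing. A `pair_types`
#' attribute records the per-read classification for QC.
#'
#' @param alignments Segments tibble (trim and MAPQ-filter first; the
#'   contract is that calling operates on cleaned chains).
#' @param policy `"mask"` or `"all"`.
#' @param rescue_window Maximum distance (bp) between the chimeric mate's
#'   3' segment and the other mate's segment for mask rescue, and between
#'   the two mates' terminal segments for walk merging. Default 500.
#' @return Contacts tibble with columns `read_id`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, `pair_type`,
#'   `junction_class` (`adjacent_softclip`, `gapped` or `mate_paired`),
#'   `contact_index`, and the facing-end coordinates `end1`/`end2`
#'   (0-based) used for cut-site annotation.
#' @export
call_contacts <- function(alignments, policy = c("mask", "all"),
                          rescue_window = 500L) {
  policy <- match.arg(policy)
  cs <- attr(alignments, "chromsizes")
  n <- nrow(alignments)
  if (n == 0L) {
    out <- empty_contacts()
    attr(out, "pair_types") <- tibble::tibble(read_id = character(),
                                              pair_type = character())
    attr(out, "chromsizes") <- cs
    return(out)
  }
  read_ids <- unique(alignments$read_id)
  g <- list(
    read = match(alignments$read_id, read_ids),
    mate = alignments$mate,
    chrom = alignments$chrom,
    strand = alignments$strand,
    ref_start = alignments$ref_start,
    ref_end = alignments$ref_end,
    read_start = alignments$read_start,
    read_end = alignments$read_end,
    pos5 = five_prime_pos(alignments$strand, alignments$ref_start,
                          alignments$ref_end),
    nr = length(read_ids)
  )
  res <- if (policy == "mask") call_mask_all_reads(g, rescue_window)
         else call_all_all_reads(g, rescue_window)
  contacts <- res$contacts
  contacts$read_id <- read_ids[contacts$read]
  contacts$read <- NULL
  contacts <- contacts[, c("read_id", "chrom1", "pos1", "strand1", "chrom2",
                           "pos2", "strand2", "pair_type", "junction_class",
                           "contact_index", "end1", "end2", "flipped")]
  attr(contacts, "pair_types") <- tibble::tibble(
    read_id = read_ids, pair_type = res$pair_type
  )
  attr(contacts, "chromsizes") <- cs
  contacts
}

# position of each row within its (read, mate) chain, in read order
chain_positions <- function(g) {
  n <- length(g$read)
  new_chain <- c(TRUE, g$read[-1L] != g$read[-n] | g$mate[-1L] != g$mate[-n])
  idx <- seq_len(n)
  idx - cummax(idx * new_chain) + 1L
}

contact_tbl <- function(read, a, b, g, pair_type, junction_class,
                        contact_index, end1, end2) {
  tibble::tibble(
    read = read,
    chrom1 = g$chrom[a], pos1 = as.integer(g$pos5[a]),
    strand1 = g$strand[a],
    chrom2 = g$chrom[b], pos2 = as.integer(g$pos5[b]),
    strand2 = g$strand[b],
    pair_type = pair_type, junction_class = junction_class,
    contact_index = as.integer(contact_index),
    end1 = as.integer(end1), end2 = as.integer(end2), flipped = FALSE
  )
}

call_mask_all_reads <- function(g, rescue_window) {
  pic <- chain_positions(g)
  nr <- g$nr
  n1 <- tabulate(g$read[g$mate == "R1"], nr)
  n2 <- tabulate(g$read[g$mate == "R2"], nr)
  row_at <- function(mate, pos) {
    out <- rep(NA_integer_, nr)
    r <- which(g$mate == mate & pic == pos)
    out[g$read[r]] <- r
    out
  }
  i11 <- row_at("R1", 1L); i12 <- row_at("R1", 2L)
  i21 <- row_at("R2", 1L); i22 <- row_at("R2", 2L)

  pt <- rep("MM", nr)
  pt[n1 == 0L & n2 == 0L] <- "NN"
  pt[n1 == 0L & n2 == 1L] <- "NU"
  pt[n1 == 0L & n2 > 1L] <- "NM"
  pt[n2 == 0L & n1 == 1L] <- "UN"
  pt[n2 == 0L & n1 > 1L] <- "MN"
  pt[n1 == 1L & n2 == 1L] <- "UU"

  match_ok <- function(a, b) {
    !is.na(a) & !is.na(b) &
      g$chrom[a] == g$chrom[b] & g$strand[a] != g$strand[b] &
      abs(g$pos5[a] - g$pos5[b]) <= rescue_window
  }
  r1_chim <- n1 == 2L & n2 == 1L
  r2_chim <- n1 == 1L & n2 == 2L
  resc1 <- r1_chim & match_ok(i12, i21)
  resc2 <- r2_chim & match_ok(i22, i11)
  pt[r1_chim] <- ifelse(resc1[r1_chim], "RU", "MU")
  pt[r2_chim] <- ifelse(resc2[r2_chim], "UR", "UM")

  uu <- which(pt == "UU")
  ct_uu <- contact_tbl(
    uu, i11[uu], i21[uu], g, "UU", "mate_paired", 1L,
    end1 = facing_3prime(g$strand[i11[uu]], g$ref_start[i11[uu]],
                         g$ref_end[i11[uu]]),
    end2 = facing_3prime(g$strand[i21[uu]], g$ref_start[i21[uu]],
                         g$ref_end[i21[uu]])
  )
  rescued_ct <- function(reads, chim5, chim3, other, type) {
    # contact joins the chimera's 5' segment and the other mate's segment;
    # the junction itself is read through between the chimera's segments
    gap <- g$read_start[chim3] - g$read_end[chim5]
    contact_tbl(
      reads, chim5, other, g, type,
      as.character(ifelse(gap <= 0L, "adjacent_softclip", "gapped")), 1L,
      end1 = facing_3prime(g$strand[chim5], g$ref_start[chim5],
                           g$ref_end[chim5]),
      end2 = facing_5prime(g$strand[chim3], g$ref_start[chim3],
                           g$ref_end[chim3])
    )
  }
  w1 <- which(resc1); w2 <- which(resc2)
  ct <- dplyr::bind_rows(
    ct_uu,
    rescued_ct(w1, i11[w1], i12[w1], i21[w1], "RU"),
    rescued_ct(w2, i21[w2], i22[w2], i11[w2], "UR")
  )
  ct <- ct[order(ct$read), ]
  list(contacts = ct, pair_type = pt)
}

call_all_all_reads <- function(g, rescue_window) {
  n <- length(g$read)
  pic <- chain_positions(g)
  nr <- g$nr
  n1 <- tabulate(g$read[g$mate == "R1"], nr)
  n2 <- tabulate(g$read[g$mate == "R2"], nr)
  last_at <- function(mate, count) {
    out <- rep(NA_integer_, nr)
    r <- which(g$mate == mate & pic == count[g$read])
    out[g$read[r]] <- r
    out
  }
  i1L <- last_at("R1", n1)   # R1's 3'-most segment
  i2L <- last_at("R2", n2)   # R2's 3'-most segment
  merged <- !is.na(i1L) & !is.na(i2L) &
    g$chrom[i1L] == g$chrom[i2L] & g$strand[i1L] != g$strand[i2L] &
    abs(g$pos5[i1L] - g$pos5[i2L]) <= rescue_window
  drop <- rep(FALSE, n)
  drop[i2L[which(merged)]] <- TRUE

  # walk order: R1 ascending read position, then R2 descending
  walk_ord <- order(g$read, g$mate,
                    ifelse(g$mate == "R2", -g$read_start, g$read_start))
  walk <- walk_ord[!drop[walk_ord]]
  wread <- g$read[walk]
  k <- tabulate(wread, nr)
  pt <- ifelse(k > 2L, "RR",
        ifelse(n1 > 0L & n2 > 0L, "UU",
        ifelse(n1 > 0L, "UN", "NU")))
  pt[k == 0L] <- "NN"

  m <- length(walk)
  if (m >= 2L) {
    a <- walk[-m]; b <- walk[-1L]
    keep <- wread[-m] == wread[-1L]
    a <- a[keep]; b <- b[keep]
  } else {
    a <- integer(); b <- integer()
  }
  if (length(a) == 0L) {
    return(list(contacts = contact_tbl(integer(), integer(), integer(), g,
                                       character(), character(), integer(),
                                       integer(), integer()),
                pair_type = pt))
  }
  same_mate <- g$mate[a] == g$mate[b]
  # within-mate junction: identify up/downstream in read order
  up <- ifelse(g$read_start[a] <= g$read_start[b], a, b)
  dn <- ifelse(g$read_start[a] <= g$read_start[b], b, a)
  fe_up <- facing_3prime(g$strand[up], g$ref_start[up], g$ref_end[up])
  fe_dn <- facing_5prime(g$strand[dn], g$ref_start[dn], g$ref_end[dn])
  fe3_a <- facing_3prime(g$strand[a], g$ref_start[a], g$ref_end[a])
  fe3_b <- facing_3prime(g$strand[b], g$ref_start[b], g$ref_end[b])
  gap <- g$read_start[dn] - g$read_end[up]
  jc <- ifelse(!same_mate, "mate_paired",
               ifelse(gap <= 0L, "adjacent_softclip", "gapped"))
  end_a <- ifelse(!same_mate, fe3_a, ifelse(up == a, fe_up, fe_dn))
  end_b <- ifelse(!same_mate, fe3_b, ifelse(up == a, fe_dn, fe_up))
  reads <- g$read[a]
  idx <- stats::ave(seq_along(reads), reads, FUN = seq_along)
  ct <- contact_tbl(reads, a, b, g, pt[reads], jc, idx, end_a, end_b)
  list(contacts = ct, pair_type = pt)
}

#' Per-read pair-type classification attached to a contacts tibble
#'
#' @param contacts Result of [call_contacts()].
#' @return Tibble with columns `read_id` and `pair_type` covering every
#'   read in the input, including reads that yielded no contact.
#' @export
pair_types <- function(contacts) attr(contacts, "pair_types")

#' Canonicalize contacts into upper-triangle order
#'
#' Swaps the two sides of each contact where needed so that
#' `chrom1 < chrom2` in the fixed chromosome order (reference header
#' order), or `chrom1 == chrom2` and `pos1 <= pos2`; strands and facing-end
#' annotations swap together and the `flipped` flag records the swap.
#' Idempotent.
#'
#' @param contacts Contacts tibble.
#' @param chrom_order Character vector giving the chromosome order; default
#'   taken from the `chromsizes` attribute.
#' @return Canonicalized contacts tibble.
#' @export
canonicalize_contacts <- function(contacts, chrom_order = NULL) {
  if (is.null(chrom_order)) {
    cs <- attr(contacts, "chromsizes")
    if (is.null(cs)) stop("chrom_order required (no chromsizes attribute)",
                          call. = FALSE)
    chrom_order <- cs$chrom
  }
  r1 <- match(contacts$chrom1, chrom_order)
  r2 <- match(contacts$chrom2, chrom_order)
  if (anyNA(r1) || anyNA(r2)) {
    bad <- unique(c(contacts$chrom1[is.na(r1)], contacts$chrom2[is.na(r2)]))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  swap <- r1 > r2 | (r1 == r2 & contacts$pos1 > contacts$pos2)
  out <- contacts
  cols <- list(c("chrom1", "chrom2"), c("pos1", "pos2"),
               c("strand1", "strand2"), c("end1", "end2"))
  if (all(c("dist1", "dist2") %in% names(contacts))) {
    cols <- c(cols, list(c("dist1", "dist2")))
  }
  for (cc in cols) {
    a <- out[[cc[1L]]]; b <- out[[cc[2L]]]
    out[[cc[1L]]] <- ifelse(swap, b, a)
    out[[cc[2L]]] <- ifelse(swap, a, b)
  }
  out$flipped <- xor(contacts$flipped, swap)
  carry_attrs(out, contacts)
}
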