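# Alignment segments are rows of a tibble; a (read_id, mate) group ordered
# by read_start is a mate chain, the unit of trimming and contact calling.

FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_MREVERSE <- 0x20L
FLAG_REVERSE <- 0x10L
FLAG_R1 <- 0x40L
FLAG_R2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Build alignment-segment rows from SAM-level fields
#'
#' Low-level vectorized constructor used by [read_alignments()] and by the
#' simulator. Read coordinates are derived from the CIGAR and reported in
#' original read orientation: for a minus-strand record the leading/trailing
#' clips are flipped. Hard-clipped bases count into `read_length` so read
#' coordinates agree across supplementary records of one chimeric read.
#'
#' @param read_id,chrom,pos,strand,mapq,cigar,flag Parallel vectors of SAM
#'   fields; `pos` is the 1-based POS column.
#' @param seq,qual,rnext,pnext,tlen Optional parallel vectors carried
#'   through to writers (`NA` allowed).
#' @return A segments tibble with 0-based half-open `ref_start`/`ref_end`
#'   and `read_start`/`read_end` columns.
#' @export
alignment_segments <- function(read_id, chrom, pos, strand, mapq, cigar, flag,
                               seq = NA_character_, qual = NA_character_,
                               rnext = NA_character_, pnext = NA_integer_,
                               tlen = NA_integer_) {
  n <- length(read_id)
  sp <- cigar_spans(cigar, strand)
  mate <- ifelse(bitwAnd(flag, FLAG_R2) > 0L, "R2", "R1")
  seq <- rep_len(seq, n)
  has_seq <- !is.na(seq) & seq != "*"
  if (any(has_seq)) {
    # SEQ excludes hard-clipped bases: its width must equal aligned query
    # ops plus soft clips
    bad <- has_seq & (nchar(seq) != sp$aligned_query + soft_len(cigar))
    if (any(bad)) {
      stop("CIGAR query length inconsistent with sequence for record(s): ",
           paste(utils::head(read_id[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  tibble::tibble(
    read_id = as.character(read_id),
    mate = mate,
    chrom = as.character(chrom),
    ref_start = as.integer(pos) - 1L,
    ref_end = as.integer(pos) - 1L + sp$ref_len,
    strand = as.character(strand),
    mapq = as.integer(mapq),
    cigar = as.character(cigar),
    read_start = sp$read_start,
    read_end = sp$read_end,
    read_length = sp$read_length,
    is_soft_clipped = sp$is_soft_clipped,
    flag = as.integer(flag),
    seq = seq,
    qual = rep_len(qual, n),
    rnext = rep_len(rnext, n),
    pnext = rep_len(pnext, n),
    tlen = rep_len(tlen, n)
  )
}

soft_len <- function(cigar) {
  vapply(parse_cigar(cigar), function(ops) sum(ops$len[ops$op == "S"]), 0L)
}

#' Read name-grouped alignments into a segments tibble
#'
#' Accepts SAM or BAM produced by a soft-clipping local aligner (BWA-MEM
#' family, including the bisulfite aligners Biscuit/BSBolt); chimeric reads
#' appear as a primary plus supplementary records. Secondary (0x100),
#' duplicate (0x400) and unmapped records are dropped; supplementary
#' (0x800) records are kept as chain segments. Input must be name-grouped
#' (all records of one read adjacent); coordinate-sorted input is rejected.
#'
#' @param path SAM or BAM file.
#' @return Segments tibble (see [alignment_segments()]) ordered by read,
#'   mate and `read_start`, with a `chromsizes` attribute taken from the
#'   header. Retrieve it with [chromsizes()].
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  targets <- hdr$targets
  hd <- unlist(hdr$text[names(hdr$text) == "@HD"])
  if (any(grepl("^SO:coordinate$", hd))) {
    stop("input is coordinate-sorted; name-collate it first ",
         "(e.g. samtools collate)", call. = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual", "mrnm", "mpos", "isize")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  qn <- rec$qname
  if (length(qn) && anyDuplicated(rle(qn)$values)) {
    stop("records with the same name are not adjacent; input must be ",
         "name-grouped (samtools collate/sort -n)", call. = FALSE)
  }
  keep <- bitwAnd(rec$flag, FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_DUP) == 0L &
    !is.na(rec$pos)
  qual <- as.character(rec$qual)
  qual[!nzchar(trimws(qual))] <- NA_character_  # '*' comes back as blanks
  seqs <- as.character(rec$seq)
  seqs[!nzchar(seqs)] <- NA_character_
  seg <- alignment_segments(
    read_id = rec$qname[keep],
    chrom = as.character(rec$rname)[keep],
    pos = rec$pos[keep],
    strand = as.character(rec$strand)[keep],
    mapq = rec$mapq[keep],
    cigar = rec$cigar[keep],
    flag = rec$flag[keep],
    seq = seqs[keep],
    qual = qual[keep],
    rnext = as.character(rec$mrnm)[keep],
    pnext = rec$mpos[keep],
    tlen = rec$isize[keep]
  )
  # order: file order of reads, then mate, then read_start within the chain
  ord <- order(match(seg$read_id, unique(seg$read_id)),
               seg$mate, seg$read_start)
  seg <- seg[ord, ]
  attr(seg, "chromsizes") <- tibble::tibble(
    chrom = names(targets), length = unname(as.integer(targets))
  )
  seg
}

#' Chromosome names and lengths attached to a segments or contacts tibble
#'
#' @param x A tibble produced by [read_alignments()], [simulate_hic()] or a
#'   downstream stage, or a `pairwalk_cutsites` index.
#' @return Tibble with columns `chrom` and `length`.
#' @export
chromsizes <- function(x) {
  if (inherits(x, "pairwalk_cutsites")) {
    return(tibble::tibble(chrom = names(x$chrom_lengths),
                          length = unname(as.integer(x$chrom_lengths))))
  }
  cs <- attr(x, "chromsizes")
  if (is.null(cs)) stop("no chromsizes attribute on this object", call. = FALSE)
  cs
}

carry_attrs <- function(to, from) {
  for (a in c("chromsizes", "mapq_stats", "trim_stats", "pair_types")) {
    if (!is.null(attr(from, a)) && is.null(attr(to, a))) {
      attr(to, a) <- attr(from, a)
    }
  }
  to
}

#' Filter alignment segments by mapping quality
#'
#' Removes segments with `mapq < min_mapq`; chains remain ordered. The
#' number of removed segments is recorded in a `mapq_stats` attribute
#' (retrieve with [mapq_stats()]) for QC reporting.
#'
#' @param alignments Segments tibble.
#' @param min_mapq Minimum MAPQ to keep (default 30).
#' @return Filtered segments tibble.
#' @export
filter_mapq <- function(alignments, min_mapq = 30L) {
  stopifnot(min_mapq >= 0L)
  out <- dplyr::filter(alignments, .data$mapq >= min_mapq)
  out <- carry_attrs(out, alignments)
  attr(out, "mapq_stats") <- tibble::tibble(
    segments_total = nrow(alignments),
    segments_filtered_by_mapq = nrow(alignments) - nrow(out),
    min_mapq = as.integer(min_mapq)
  )
  out
}

#' @rdname filter_mapq
#' @export
mapq_stats <- function(alignments) attr(alignments, "mapq_stats")
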