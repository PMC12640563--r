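# Output serialization. Internal computation is 0-based half-open
# throughout; conversion to the 1-based PAIRS convention and back happens
# only here, so there is a single off-by-one boundary.

#' Write contacts as a 4DN PAIRS file
#'
#' Produces a `## pairs format v1.0` file with `#chromsize` lines in
#' reference order, a `#columns` line declaring the annotation columns, and
#' rows sorted by (chrom1, chrom2, pos1, pos2) in the given chromosome
#' order. Contacts must be canonicalized (upper-triangle) first. Positions
#' are 1-based. No duplicate removal is performed; the sorted output is
#' ready for downstream dedup tools.
#'
#' @param contacts Canonicalized, optionally [annotate_sv()]-annotated
#'   contacts tibble.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @param chromsizes Tibble (`chrom`, `length`); default from the
#'   `chromsizes` attribute.
#' @param params Optional named list recorded as `#command:`-style header
#'   comments for provenance.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(contacts, path, chromsizes = NULL, params = NULL) {
  chromsizes <- chromsizes %||% attr(contacts, "chromsizes")
  if (is.null(chromsizes)) stop("chromsizes required", call. = FALSE)
  ord <- chromsizes$chrom
  r1 <- match(contacts$chrom1, ord)
  r2 <- match(contacts$chrom2, ord)
  if (nrow(contacts) > 0L) {
    bad <- r1 > r2 | (r1 == r2 & contacts$pos1 > contacts$pos2)
    if (anyNA(bad) || any(bad)) {
      stop("contacts must be canonicalized before writing", call. = FALSE)
    }
  }
  cols <- c("readID", "chrom1", "pos1", "chrom2", "pos2", "strand1",
            "strand2", "pair_type")
  extra <- intersect(c("dist1", "dist2", "sv_flag", "junction_class",
                       "contact_index"), names(contacts))
  header <- c(
    "## pairs format v1.0",
    "#sorted: chr1-chr2-pos1-pos2",
    "#shape: upper triangle",
    paste0("#chromsize: ", chromsizes$chrom, " ", chromsizes$length),
    if (!is.null(params)) {
      paste0("#command: pairwalk ",
             paste(names(params), unlist(params), sep = "=", collapse = " "))
    },
    paste("#columns:", paste(c(cols, extra), collapse = " "))
  )
  o <- order(r1, r2, contacts$pos1, contacts$pos2)
  body <- tibble::tibble(
    readID = contacts$read_id, chrom1 = contacts$chrom1,
    pos1 = contacts$pos1, chrom2 = contacts$chrom2, pos2 = contacts$pos2,
    strand1 = contacts$strand1, strand2 = contacts$strand2,
    pair_type = contacts$pair_type
  )
  for (e in extra) body[[e]] <- format_pairs_col(contacts[[e]])
  body <- body[o, ]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(body) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(body)), sep = "\t")), con)
  }
  invisible(path)
}

format_pairs_col <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    out <- ifelse(is.finite(x), format(x, scientific = FALSE, trim = TRUE),
                  ".")
    return(ifelse(is.na(x), ".", out))
  }
  ifelse(is.na(x), ".", as.character(x))
}

#' Read a PAIRS file written by [write_pairs()]
#'
#' @param path PAIRS file (optionally gzipped).
#' @return Contacts-shaped tibble with a `chromsizes` attribute parsed
#'   from the header.
#' @export
read_pairs <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  cs_lines <- hdr[startsWith(hdr, "#chromsize:")]
  cs <- tibble::tibble(
    chrom = sub("^#chromsize:\\s+(\\S+)\\s+(\\d+)$", "\\1", cs_lines),
    length = as.integer(sub("^#chromsize:\\s+(\\S+)\\s+(\\d+)$", "\\2",
                            cs_lines))
  )
  col_line <- hdr[startsWith(hdr, "#columns:")]
  cols <- strsplit(sub("^#columns:\\s*", "", col_line), "\\s+")[[1]]
  if (length(body) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      replicate(length(cols), character(), simplify = FALSE), cols))
  } else {
    out <- readr::read_tsv(I(body), col_names = cols, na = ".",
                           show_col_types = FALSE, progress = FALSE)
  }
  attr(out, "chromsizes") <- cs
  out
}

sam_header_lines <- function(chromsizes, sort_order = "unsorted",
                             pg_args = NULL) {
  c(
    paste0("@HD\tVN:1.6\tSO:", sort_order),
    paste0("@SQ\tSN:", chromsizes$chrom, "\tLN:", chromsizes$length),
    paste0("@PG\tID:pairwalk\tPN:pairwalk\tVN:",
           as.character(utils::packageVersion("pairwalk")),
           if (!is.null(pg_args)) {
             paste0("\tCL:pairwalk ",
                    paste(names(pg_args), unlist(pg_args), sep = "=",
                          collapse = " "))
           } else "")
  )
}

#' Write alignment segments as SAM or BAM
#'
#' Emits every surviving segment with its (possibly trim-rewritten) POS and
#' CIGAR, preserving flags, mate fields and sequence where available, plus
#' a `@PG` program line recording the tool and parameters. A `.bam` output
#' path writes through [Rsamtools::asBam()].
#'
#' @param alignments Segments tibble (e.g. after [filter_mapq()] and
#'   [trim_multimap()]).
#' @param path Output `.sam` or `.bam` path.
#' @param chromsizes Tibble (`chrom`, `length`); default from attribute.
#' @param params Optional named list recorded on the `@PG` line.
#' @return The output path, invisibly; the number of records written is
#'   attached as attribute `n_records`.
#' @export
write_trimmed_bam <- function(alignments, path, chromsizes = NULL,
                              params = NULL) {
  chromsizes <- chromsizes %||% attr(alignments, "chromsizes")
  if (is.null(chromsizes)) stop("chromsizes required", call. = FALSE)
  lens <- stats::setNames(chromsizes$length, chromsizes$chrom)
  if (nrow(alignments) > 0L) {
    over <- alignments$ref_end > lens[alignments$chrom]
    if (any(is.na(over) | over)) {
      stop("segment reference span exceeds chromosome length", call. = FALSE)
    }
  }
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (to_bam) tempfile(fileext = ".sam") else path
  a <- alignments
  for (col in c("rnext", "seq", "qual")) {
    if (is.null(a[[col]])) a[[col]] <- NA_character_
  }
  for (col in c("pnext", "tlen")) {
    if (is.null(a[[col]])) a[[col]] <- NA_integer_
  }
  na_dot <- function(x) ifelse(is.na(x) | x == "", "*", x)
  rec <- if (nrow(a) == 0L) character() else paste(
    a$read_id, a$flag, a$chrom, a$ref_start + 1L,
    a$mapq, a$cigar,
    na_dot(a$rnext),
    dplyr::coalesce(a$pnext, 0L),
    dplyr::coalesce(a$tlen, 0L),
    na_dot(a$seq), na_dot(a$qual),
    sep = "\t"
  )
  writeLines(c(sam_header_lines(chromsizes, pg_args = params), rec), sam_path)
  if (to_bam) {
    out <- Rsamtools::asBam(sam_path, sub("\\.bam$", "", path),
                            overwrite = TRUE, indexDestination = FALSE)
    unlink(sam_path)
    path <- out
  }
  structure(invisible(path), n_records = nrow(a))
}

#' Write breakpoints as BEDPE
#'
#' One aggregate row per unique junction: 0-based half-open single-base
#' intervals on each side, `name` a representative supporting read id,
#' `score` the supporting-read count, strands in columns 9-10. Optionally
#' also writes one row per supporting read.
#'
#' @param breakpoints Result of [call_breakpoints()].
#' @param path Output BEDPE path (aggregate).
#' @param per_read_path Optional path for a per-read BEDPE (score 1).
#' @return `path`, invisibly.
#' @export
write_breakpoints_bedpe <- function(breakpoints, path, per_read_path = NULL) {
  agg <- aggregate_breakpoints(breakpoints)
  bedpe <- function(b, score) tibble::tibble(
    chrom1 = b$chromA, start1 = b$posA - 1L, end1 = b$posA,
    chrom2 = b$chromB, start2 = b$posB - 1L, end2 = b$posB,
    name = b$read_id, score = score,
    strand1 = b$strandA, strand2 = b$strandB
  )
  readr::write_tsv(bedpe(agg, agg$n_support), path, col_names = FALSE)
  if (!is.null(per_read_path)) {
    readr::write_tsv(bedpe(breakpoints, 1L), per_read_path,
                     col_names = FALSE)
  }
  invisible(path)
}

#' Emit simulated alignments as a name-grouped SAM file
#'
#' Reconstructs each molecule's sequence from the simulated genome, derives
#' the paired reads (R1 the first `read_length` bases, R2 the reverse
#' complement of the last), and writes one soft-clipped record per visible
#' fragment (primary plus supplementary) with full SEQ/QUAL and mate
#' fields, ready to be parsed back by [read_alignments()].
#'
#' @param sim A `pairwalk_sim` from [simulate_hic()].
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
emit_sam <- function(sim, path) {
  stopifnot(inherits(sim, "pairwalk_sim"))
  rl <- sim$config$read_length
  fr <- sim$truth$fragments
  core <- character(nrow(fr))
  for (i in seq_len(nrow(fr))) {
    s <- Biostrings::subseq(sim$genome[[fr$chrom[i]]], fr$gs[i] + 1L,
                            fr$ge[i])
    if (fr$orient[i] == "-") s <- Biostrings::reverseComplement(s)
    core[i] <- as.character(s)
  }
  mols <- vapply(split(core, factor(fr$read_id, unique(fr$read_id))),
                 paste0, "", collapse = "")
  r1 <- substr(mols, 1L, rl)
  r2 <- stats::setNames(
    revcomp_vec(substr(mols, nchar(mols) - rl + 1L, nchar(mols))),
    names(mols)
  )
  aln <- sim$alignments
  read_seq <- ifelse(aln$mate == "R1", r1[aln$read_id], r2[aln$read_id])
  seq_out <- ifelse(aln$strand == "+", read_seq, revcomp_vec(read_seq))
  qual <- strrep("I", rl)
  # mate fields: point at the other mate's primary record
  prim <- aln[bitwAnd(aln$flag, FLAG_SUPPLEMENTARY) == 0L, ]
  key <- paste(prim$read_id, prim$mate)
  other <- paste(aln$read_id, ifelse(aln$mate == "R1", "R2", "R1"))
  mi <- match(other, key)
  rec <- paste(
    aln$read_id, aln$flag, aln$chrom, aln$ref_start + 1L, aln$mapq,
    aln$cigar, prim$chrom[mi], prim$ref_start[mi] + 1L, 0L,
    seq_out, qual,
    sep = "\t"
  )
  writeLines(c(sam_header_lines(chromsizes(aln)), rec), path)
  invisible(path)
}

revcomp_vec <- function(x) {
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  )
  unname(out)
}
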