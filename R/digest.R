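#' Define a restriction enzyme
#'
#' A recognition motif plus the 0-based offset of the cut within the motif.
#' A cut at offset `k` of an occurrence starting at 0-based position `p`
#' places a cut site between bases `p + k - 1` and `p + k`.
#'
#' @param motif Recognition sequence over A/C/G/T (case-insensitive);
#'   degenerate IUPAC codes are not supported.
#' @param cut_offset Integer, 0 to `nchar(motif)`; e.g. DpnII/MboI (`^GATC`)
#'   cut at offset 0.
#' @param name Optional enzyme name used in output provenance.
#' @return An object of class `pairwalk_enzyme`.
#' @examples
#' enzyme("GATC", 0, "DpnII")
#' @export
enzyme <- function(motif, cut_offset = 0L, name = NULL) {
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 3L) stop("motif length must be >= 3", call. = FALSE)
  if (grepl("[^ACGT]", motif)) {
    stop("motif must contain only A/C/G/T: ", motif, call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must lie within the motif", call. = FALSE)
  }
  structure(
    list(name = name %||% motif, motif = motif, cut_offset = cut_offset),
    class = "pairwalk_enzyme"
  )
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_palindromic <- function(motif) identical(motif, revcomp_chr(motif))

#' In-silico restriction digestion of a reference genome
#'
#' Scans the genome for each enzyme's recognition motif and records cut
#' positions as 0-based offsets between bases (a cut at position `k`
#' separates bases `k - 1` and `k`). Palindromic motifs are scanned once on
#' the forward strand; non-palindromic motifs are scanned on both strands
#' and the site sets merged. Occurrences overlapping `N` never match.
#' Multiple enzymes are merged into one index.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file
#'   (optionally bgzipped).
#' @param enzymes A [enzyme()] object or list of them.
#' @return A `pairwalk_cutsites` index: per-chromosome sorted unique cut
#'   positions, chromosome lengths and enzyme provenance. Use
#'   [generics::tidy()] to get a tibble of sites.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrA = "AAGATCAA"))
#' cut_sites(digest_genome(g, enzyme("GATC", 0)))
#' @export
digest_genome <- function(genome, enzymes) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or FASTA path", call. = FALSE)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  if (inherits(enzymes, "pairwalk_enzyme")) enzymes <- list(enzymes)
  if (length(enzymes) == 0L) stop("at least one enzyme required", call. = FALSE)
  sites <- lapply(seq_along(genome), function(i) {
    chr <- genome[[i]]
    pos <- integer()
    for (ez in enzymes) {
      m <- nchar(ez$motif)
      fwd <- Biostrings::start(Biostrings::matchPattern(ez$motif, chr)) - 1L
      pos <- c(pos, fwd + ez$cut_offset)
      if (!is_palindromic(ez$motif)) {
        rc <- Biostrings::start(
          Biostrings::matchPattern(revcomp_chr(ez$motif), chr)
        ) - 1L
        pos <- c(pos, rc + (m - ez$cut_offset))
      }
    }
    sort(unique(as.integer(pos)))
  })
  names(sites) <- names(genome)
  new_cutsites(sites, stats::setNames(Biostrings::width(genome), names(genome)),
               enzymes)
}

new_cutsites <- function(sites, chrom_lengths, enzymes) {
  stopifnot(identical(names(sites), names(chrom_lengths)))
  for (nm in names(sites)) {
    p <- sites[[nm]]
    if (length(p) && (is.unsorted(p, strictly = TRUE) ||
                      p[1L] < 0L || p[length(p)] > chrom_lengths[[nm]])) {
      stop("cut sites for ", nm, " must be sorted, unique and within bounds",
           call. = FALSE)
    }
  }
  structure(
    list(sites = sites, chrom_lengths = chrom_lengths, enzymes = enzymes),
    class = "pairwalk_cutsites"
  )
}

#' @export
print.pairwalk_cutsites <- function(x, ...) {
  cat("<pairwalk_cutsites> ", length(x$sites), " chromosome(s), ",
      sum(lengths(x$sites)), " cut sites [",
      paste(vapply(x$enzymes, function(e) e$name, ""), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Extract cut sites as a tibble
#'
#' @param index A `pairwalk_cutsites` object.
#' @return Tibble with columns `chrom` and `pos` (0-based cut positions).
#' @export
cut_sites <- function(index) {
  stopifnot(inherits(index, "pairwalk_cutsites"))
  tibble::tibble(
    chrom = rep(names(index$sites), lengths(index$sites)),
    pos = as.integer(unlist(index$sites, use.names = FALSE))
  )
}

#' @method tidy pairwalk_cutsites
#' @export
tidy.pairwalk_cutsites <- function(x, ...) cut_sites(x)

#' Distance to the nearest restriction cut site
#'
#' @param index A `pairwalk_cutsites` index.
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 0-based coordinate(s).
#' @return Integer-valued distances (`>= 0`); `Inf` for a chromosome with
#'   no cut sites.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrA = "AAGATCAA"))
#' idx <- digest_genome(g, enzyme("GATC", 0))
#' nearest_cut_distance(idx, "chrA", c(2, 7))
#' @export
nearest_cut_distance <- function(index, chrom, pos) {
  stopifnot(inherits(index, "pairwalk_cutsites"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  unknown <- setdiff(unique(chrom), names(index$sites))
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- numeric(n)
  for (nm in unique(chrom)) {
    sel <- chrom == nm
    s <- index$sites[[nm]]
    if (length(s) == 0L) {
      out[sel] <- Inf
      next
    }
    p <- pos[sel]
    i <- findInterval(p, s)
    d_lo <- ifelse(i >= 1L, p - s[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(s), s[pmin(i + 1L, length(s))] - p, Inf)
    out[sel] <- pmin(d_lo, d_hi)
  }
  out
}

#' Read a precomputed cut-site BED file
#'
#' For enzymes whose recognition sequence cannot be expressed as a single
#' exact motif, an explicit site list may be supplied instead of digesting.
#' The BED must contain 0-based half-open single-position intervals
#' (`end == start + 1`); the `start` column is taken as the cut position.
#'
#' @param path BED file (chrom, start, end, ...).
#' @param chrom_lengths Named integer vector of chromosome lengths covering
#'   every chromosome in the BED.
#' @return A `pairwalk_cutsites` index.
#' @export
read_cutsites_bed <- function(path, chrom_lengths) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  if (any(bed$end - bed$start != 1L)) {
    stop("cut-site BED must contain single-position intervals", call. = FALSE)
  }
  unknown <- setdiff(unique(bed$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("BED chromosomes missing from chrom_lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sites <- lapply(names(chrom_lengths), function(nm) {
    sort(unique(as.integer(bed$start[bed$chrom == nm])))
  })
  names(sites) <- names(chrom_lengths)
  provenance <- structure(
    list(name = basename(path), motif = NA_character_,
         cut_offset = NA_integer_),
    class = "pairwalk_enzyme"
  )
  new_cutsites(sites, chrom_lengths, list(provenance))
}

#' Write cut sites as BED
#'
#' 0-based half-open single-position intervals, one per cut site.
#'
#' @param index A `pairwalk_cutsites` index.
#' @param path Output path.
#' @return Invisibly, the number of sites written.
#' @export
write_cutsites_bed <- function(index, path) {
  tab <- cut_sites(index)
  readr::write_tsv(
    tibble::tibble(chrom = tab$chrom, start = tab$pos, end = tab$pos + 1L),
    path, col_names = FALSE
  )
  invisible(nrow(tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
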