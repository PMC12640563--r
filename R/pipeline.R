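#' Run the full contact-calling pipeline on one cell
#'
#' The end-to-end flow: read name-grouped alignments, filter by MAPQ, trim
#' multimapping between adjacent soft-clipped alignments, call contacts
#' under the chosen policy, canonicalize, annotate cut-site proximity and
#' SV likelihood, call 1 bp breakpoints, and compute QC. Optionally writes
#' the standard outputs (`<prefix>.trimmed.sam`/`.bam`, `<prefix>.pairs`,
#' `<prefix>.breakpoints.bedpe`, `<prefix>.qc.json`, `<prefix>.qc.tsv`).
#'
#' Trimming runs before contact and breakpoint calling so junction
#' coordinates come from trimmed alignments; an untrimmed junction would be
#' shifted by up to the duplicated motif length.
#'
#' @param alignments Path to a name-grouped SAM/BAM file, or a segments
#'   tibble (e.g. from [simulate_hic()]).
#' @param genome Reference FASTA path or [Biostrings::DNAStringSet]
#'   (required unless `cutsites` is given).
#' @param enzymes An [enzyme()] or list of enzymes (ignored if `cutsites`
#'   given).
#' @param cutsites Optional precomputed `pairwalk_cutsites` index or path
#'   to a cut-site BED.
#' @param min_mapq Minimum MAPQ (default 30).
#' @param policy Contact-calling policy, `"mask"` or `"all"`.
#' @param sv_tolerance Facing-end cut-site distance still considered
#'   proximal; default motif length + 1 (see [annotate_sv()]).
#' @param max_junction_gap Maximum read gap for breakpoint junctions
#'   (default 0).
#' @param rescue_window Mask-rescue / walk-merge window in bp (default
#'   500).
#' @param out_prefix If non-`NULL`, write all outputs under this prefix.
#' @param bam_out Write the trimmed alignments as `.bam` (default) or
#'   `.sam`.
#' @return A `pairwalk_result` list: `alignments` (trimmed tibble),
#'   `contacts` (canonicalized, annotated), `breakpoints`, `qc` and
#'   `params`.
#' @export
pairwalk_call <- function(alignments, genome = NULL, enzymes = NULL,
                          cutsites = NULL, min_mapq = 30L,
                          policy = c("mask", "all"), sv_tolerance = NULL,
                          max_junction_gap = 0L, rescue_window = 500L,
                          out_prefix = NULL, bam_out = TRUE) {
  policy <- match.arg(policy)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  index <- resolve_cutsites(cutsites, genome, enzymes, alignments)
  aln <- alignments |>
    filter_mapq(min_mapq) |>
    trim_multimap()
  contacts <- aln |>
    call_contacts(policy = policy, rescue_window = rescue_window) |>
    canonicalize_contacts() |>
    annotate_sv(index, tolerance = sv_tolerance)
  breakpoints <- call_breakpoints(aln, index, tolerance = sv_tolerance,
                                  max_junction_gap = max_junction_gap)
  qc <- compute_qc(contacts, breakpoints, trim_stats(aln), mapq_stats(aln))
  params <- list(
    min_mapq = min_mapq, policy = policy,
    sv_tolerance = sv_tolerance %||% default_sv_tolerance(index),
    max_junction_gap = max_junction_gap, rescue_window = rescue_window
  )
  res <- structure(
    list(alignments = aln, contacts = contacts, breakpoints = breakpoints,
         qc = qc, params = params),
    class = "pairwalk_result"
  )
  if (!is.null(out_prefix)) write_outputs(res, out_prefix, bam_out)
  res
}

resolve_cutsites <- function(cutsites, genome, enzymes, alignments) {
  if (inherits(cutsites, "pairwalk_cutsites")) return(cutsites)
  if (is.character(cutsites)) {
    cs <- chromsizes(alignments)
    return(read_cutsites_bed(cutsites,
                             stats::setNames(cs$length, cs$chrom)))
  }
  if (is.null(genome) || is.null(enzymes)) {
    stop("supply either `cutsites` or `genome` + `enzymes`", call. = FALSE)
  }
  digest_genome(genome, enzymes)
}

write_outputs <- function(res, out_prefix, bam_out = TRUE) {
  aln_path <- paste0(out_prefix, ".trimmed.", if (bam_out) "bam" else "sam")
  write_trimmed_bam(res$alignments, aln_path, params = res$params)
  write_pairs(res$contacts, paste0(out_prefix, ".pairs"),
              params = res$params)
  write_breakpoints_bedpe(res$breakpoints,
                          paste0(out_prefix, ".breakpoints.bedpe"))
  write_qc(res$qc, paste0(out_prefix, ".qc.json"),
           paste0(out_prefix, ".qc.tsv"), params = res$params)
  invisible(out_prefix)
}

#' @export
print.pairwalk_result <- function(x, ...) {
  cat("<pairwalk_result>\n",
      "  segments (trimmed): ", nrow(x$alignments), "\n",
      "  contacts:           ", nrow(x$contacts), "\n",
      "  breakpoints:        ", nrow(x$breakpoints), "\n",
      "  cis/trans ratio:    ",
      format(x$qc$cis_trans_ratio, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method glance pairwalk_result
#' @export
glance.pairwalk_result <- function(x, ...) glance.pairwalk_qc(x$qc)
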