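#' Per-cell quality-control report
#'
#' Aggregates the metrics used to judge a single-cell Hi-C run: alignment
#' and filtering counts, soft-clipping and multimapping-trimming
#' statistics, contact-class counts, the intrachromosomal-to-
#' interchromosomal (cis/trans) contact ratio, SV-flag counts and
#' breakpoint tallies. `cis` means `chrom1 == chrom2` with no distance
#' cutoff. The trimmed-span statistics (mean and SD of the fraction of a
#' segment's original aligned read span removed) are computed over
#' soft-clipped segments that had multimapping.
#'
#' @param contacts Annotated contacts tibble ([call_contacts()] +
#'   [annotate_sv()]); its `pair_types` attribute, if present, provides the
#'   per-read pair-type histogram.
#' @param breakpoints Result of [call_breakpoints()] (optional).
#' @param trim_stats Per-segment trimming statistics ([trim_stats()]).
#' @param mapq_stats Filtering counts ([mapq_stats()]).
#' @param n_read_pairs Total read pairs processed; default: number of
#'   distinct reads in the `pair_types` attribute.
#' @return A `pairwalk_qc` object (a named list); see
#'   [tidy.pairwalk_qc()], [glance.pairwalk_qc()] and
#'   [autoplot.pairwalk_qc()].
#' @export
compute_qc <- function(contacts, breakpoints = NULL, trim_stats = NULL,
                       mapq_stats = NULL, n_read_pairs = NULL) {
  pt <- attr(contacts, "pair_types")
  n_read_pairs <- n_read_pairs %||%
    (if (!is.null(pt)) nrow(pt) else length(unique(contacts$read_id)))
  cis <- sum(contacts$chrom1 == contacts$chrom2)
  trans <- nrow(contacts) - cis
  qc <- list(
    total_read_pairs = n_read_pairs,
    segments_total = if (!is.null(mapq_stats)) mapq_stats$segments_total
                     else NA_integer_,
    segments_filtered_by_mapq = if (!is.null(mapq_stats))
      mapq_stats$segments_filtered_by_mapq else NA_integer_,
    min_mapq = if (!is.null(mapq_stats)) mapq_stats$min_mapq else NA_integer_,
    softclipped_segments = if (!is.null(trim_stats))
      sum(trim_stats$is_soft_clipped) else NA_integer_,
    softclipped_with_multimapping = if (!is.null(trim_stats))
      sum(trim_stats$is_soft_clipped & trim_stats$had_multimapping)
      else NA_integer_,
    multimapping_fraction = NA_real_,
    trimmed_fraction_mean = NA_real_,
    trimmed_fraction_sd = NA_real_,
    contacts_total = nrow(contacts),
    contacts_cis = cis,
    contacts_trans = trans,
    cis_trans_ratio = if (trans > 0L) cis / trans else NA_real_,
    pair_type_histogram = if (!is.null(pt)) {
      tab <- table(pt$pair_type)
      stats::setNames(as.integer(tab), names(tab))
    } else {
      tab <- table(contacts$pair_type)
      stats::setNames(as.integer(tab), names(tab))
    },
    sv_flagged_contacts = if ("sv_flag" %in% names(contacts))
      sum(contacts$sv_flag) else NA_integer_,
    breakpoints_total = if (!is.null(breakpoints)) nrow(breakpoints)
                        else NA_integer_,
    unique_breakpoints = if (!is.null(breakpoints))
      nrow(aggregate_breakpoints(breakpoints)) else NA_integer_
  )
  if (!is.null(trim_stats)) {
    mm <- trim_stats[trim_stats$is_soft_clipped & trim_stats$had_multimapping, ]
    if (qc$softclipped_segments > 0L) {
      qc$multimapping_fraction <-
        qc$softclipped_with_multimapping / qc$softclipped_segments
    }
    if (nrow(mm) > 0L) {
      qc$trimmed_fraction_mean <- mean(mm$trimmed_fraction)
      qc$trimmed_fraction_sd <- stats::sd(mm$trimmed_fraction)
    }
  }
  structure(qc, class = "pairwalk_qc")
}

#' @export
print.pairwalk_qc <- function(x, ...) {
  cat("<pairwalk_qc>\n")
  print(tidy.pairwalk_qc(x), n = Inf)
  invisible(x)
}

#' Tidy a QC report into a metric/value tibble
#'
#' @param x A `pairwalk_qc` object.
#' @param ... Unused.
#' @return Tibble with columns `metric` and `value`; the pair-type
#'   histogram appears as one `pair_type_<code>` row per code.
#' @method tidy pairwalk_qc
#' @export
tidy.pairwalk_qc <- function(x, ...) {
  scalars <- x[setdiff(names(x), "pair_type_histogram")]
  tab <- tibble::tibble(
    metric = names(scalars),
    value = as.numeric(unlist(scalars, use.names = FALSE))
  )
  h <- x$pair_type_histogram
  if (length(h)) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      metric = paste0("pair_type_", names(h)), value = as.numeric(h)
    ))
  }
  tab
}

#' One-row summary of a QC report
#'
#' @inheritParams tidy.pairwalk_qc
#' @return A one-row tibble of the headline metrics.
#' @method glance pairwalk_qc
#' @export
glance.pairwalk_qc <- function(x, ...) {
  tibble::tibble(
    total_read_pairs = x$total_read_pairs,
    contacts_total = x$contacts_total,
    cis_trans_ratio = x$cis_trans_ratio,
    multimapping_fraction = x$multimapping_fraction,
    trimmed_fraction_mean = x$trimmed_fraction_mean,
    sv_flagged_contacts = x$sv_flagged_contacts,
    breakpoints_total = x$breakpoints_total
  )
}

#' Write a QC report as JSON and TSV
#'
#' @param qc A `pairwalk_qc` object.
#' @param json_path,tsv_path Output paths; either may be `NULL` to skip.
#' @param params Optional named list of run parameters embedded in the
#'   JSON for provenance.
#' @return `qc`, invisibly.
#' @export
write_qc <- function(qc, json_path = NULL, tsv_path = NULL, params = NULL) {
  stopifnot(inherits(qc, "pairwalk_qc"))
  if (!is.null(json_path)) {
    payload <- unclass(qc)
    payload$pair_type_histogram <- as.list(payload$pair_type_histogram)
    if (!is.null(params)) payload$parameters <- params
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(tidy.pairwalk_qc(qc), tsv_path)
  }
  invisible(qc)
}

#' Read a QC report written by [write_qc()]
#'
#' @param json_path Path to the JSON report.
#' @return A `pairwalk_qc` object.
#' @export
read_qc <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  x$parameters <- NULL
  x$pair_type_histogram <- unlist(x$pair_type_histogram)
  structure(x, class = "pairwalk_qc")
}

#' Cross-cell QC summary
#'
#' Tabulates mean and standard deviation of every numeric QC metric over a
#' set of per-cell reports, the usual way per-cell Hi-C QC is summarised
#' over a plate or dataset.
#'
#' @param reports A list of `pairwalk_qc` objects or a character vector of
#'   JSON paths.
#' @return Tibble with columns `metric`, `mean`, `sd`, `n_cells`.
#' @export
merge_qc <- function(reports) {
  if (is.character(reports)) reports <- lapply(reports, read_qc)
  tabs <- purrr::imap(reports, function(r, i) {
    t <- tidy.pairwalk_qc(r)
    t$cell <- i
    t
  })
  dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}
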