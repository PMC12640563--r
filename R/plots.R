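#' Plot a QC report
#'
#' Bar chart of the per-read pair-type histogram with the headline metrics
#' (contacts, cis/trans ratio, SV flags) in the subtitle.
#'
#' @param object A `pairwalk_qc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairwalk_qc
#' @export
autoplot.pairwalk_qc <- function(object, ...) {
  h <- object$pair_type_histogram
  df <- tibble::tibble(pair_type = names(h), n = as.numeric(h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "pair type", y = "read pairs",
      title = "Read-pair classification",
      subtitle = sprintf(
        "%d contacts | cis/trans = %s | %s SV-flagged",
        object$contacts_total,
        format(object$cis_trans_ratio, digits = 3),
        format(object$sv_flagged_contacts)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Contact-distance distribution
#'
#' Histogram of log10 genomic separation of cis contacts, the standard
#' first look at Hi-C contact decay.
#'
#' @param contacts Contacts tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_contact_distance <- function(contacts, bins = 40) {
  cis <- dplyr::filter(contacts, .data$chrom1 == .data$chrom2,
                       .data$pos2 > .data$pos1)
  cis$log10_dist <- log10(cis$pos2 - cis$pos1)
  ggplot2::ggplot(cis, ggplot2::aes(x = .data$log10_dist)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = "log10 contact distance (bp)", y = "contacts",
                  title = "Cis contact distance distribution") +
    ggplot2::theme_minimal()
}
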