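#' Plot per-class detection outcomes
#'
#' Stacked bars of detected vs undetected antigen ORFs per class
#' (any-sample scope).
#'
#' @param object A `detection_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_matrix
#' @export
autoplot.detection_matrix <- function(object, ...) {
  per_orf <- object$detections |>
    dplyr::group_by(.data$orf_id, .data$class_label) |>
    dplyr::summarise(detected = any(.data$detected), .groups = "drop")
  ggplot2::ggplot(per_orf,
                  ggplot2::aes(x = .data$class_label, fill = .data$detected)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey70"),
                               name = "detected") +
    ggplot2::labs(x = "antigen ORF class", y = "ORFs") +
    ggplot2::theme_minimal()
}

#' Plot the detection-count histogram
#'
#' Number of ORFs by the number of samples in which they were detected.
#'
#' @param dm A `detection_matrix`.
#' @return A ggplot object.
#' @export
plot_detection_histogram <- function(dm) {
  h <- detection_histogram(dm)
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$n_samples_detected),
                                  y = .data$n_orfs)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "samples in which detected", y = "ORFs") +
    ggplot2::theme_minimal()
}

#' Plot expression-stratified detection counts
#'
#' Detection count across samples against the expression bin of the
#' encoding gene, faceted by antigen class.
#'
#' @param dm A `detection_matrix` carrying `gene_id`.
#' @param expression Tibble (`gene_id`, `rpkm`).
#' @param thresholds RPKM bin edges (default `c(1, 10)`).
#' @return A ggplot object.
#' @export
plot_expression_strata <- function(dm, expression, thresholds = c(1, 10)) {
  st <- expression_strata(dm, expression, thresholds)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$expression_bin,
                                   y = factor(.data$n_samples_detected),
                                   size = .data$n_orfs)) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::facet_wrap(~class_label) +
    ggplot2::labs(x = "gene expression (RPKM)",
                  y = "samples in which detected", size = "ORFs") +
    ggplot2::theme_minimal()
}

#' Plot a P-site track with called initiation sites
#'
#' Per-nucleotide P-site counts along one transcript, with the annotated CDS
#' shaded and called TISs marked (significant calls dark, others light).
#'
#' @param tracks A `psite_tracks` tibble.
#' @param transcripts Transcript tibble.
#' @param transcript_id Which transcript to draw.
#' @param calls Optional `tis_calls` to mark.
#' @return A ggplot object.
#' @export
plot_psite_track <- function(tracks, transcripts, transcript_id,
                             calls = NULL) {
  i <- match(transcript_id, tracks$transcript_id)
  if (is.na(i)) abort(sprintf("no track for transcript %s", transcript_id))
  df <- tibble(position = seq_len(tracks$length[i]) - 1L,
               count = tracks$track[[i]])
  j <- match(transcript_id, transcripts$transcript_id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::labs(x = "transcript position (nt)", y = "P-sites") +
    ggplot2::theme_minimal()
  if (!is.na(transcripts$cds_start[j])) {
    p <- p + ggplot2::annotate("rect",
                               xmin = transcripts$cds_start[j],
                               xmax = transcripts$cds_end[j],
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.08, fill = "#2166ac")
  }
  if (!is.null(calls)) {
    cc <- dplyr::filter(as_tibble(calls),
                        .data$transcript_id == !!transcript_id)
    if (nrow(cc)) {
      p <- p + ggplot2::geom_point(
        data = cc,
        ggplot2::aes(x = .data$position, y = .data$psite_count,
                     colour = .data$significant)) +
        ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837",
                                                `FALSE` = "#a6dba0"),
                                     name = "significant")
    }
  }
  p
}
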