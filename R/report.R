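#' Per-sample and union class summaries of ORF calls
#'
#' Tabulates detected initiation sites by positional class: per sample and
#' for the unique union across samples (a TIS counted once per unique
#' (transcript, position) pair). Mean ORF lengths are taken over complete
#' ORFs only; incomplete ORFs still count toward TIS and gene totals.
#'
#' @param calls Classified ORF calls; a `sample_id` column separates samples
#'   (a single sample is assumed when absent).
#' @return Tibble (`scope`, `class`, `n_tis`, `n_genes`, `mean_orf_length`),
#'   `scope` being each sample id plus `"union"`, including a `"total"`
#'   class row per scope.
#' @export
class_summary <- function(calls) {
  assert_columns(calls, c("transcript_id", "gene_id", "tis_position",
                          "length_aa", "complete", "class"), "calls")
  calls <- as_tibble(calls)
  if (!"sample_id" %in% names(calls)) calls$sample_id <- "sample1"
  union_calls <- calls |>
    dplyr::distinct(.data$transcript_id, .data$tis_position,
                    .keep_all = TRUE) |>
    dplyr::mutate(sample_id = "union")
  summarise_one <- function(df) {
    by_class <- df |>
      dplyr::group_by(scope = .data$sample_id, class = .data$class) |>
      dplyr::summarise(
        n_tis = dplyr::n_distinct(paste(.data$transcript_id,
                                        .data$tis_position)),
        n_genes = dplyr::n_distinct(.data$gene_id),
        mean_orf_length = mean(.data$length_aa[.data$complete]),
        .groups = "drop")
    total <- df |>
      dplyr::group_by(scope = .data$sample_id) |>
      dplyr::summarise(
        class = "total",
        n_tis = dplyr::n_distinct(paste(.data$transcript_id,
                                        .data$tis_position)),
        n_genes = dplyr::n_distinct(.data$gene_id),
        mean_orf_length = mean(.data$length_aa[.data$complete]),
        .groups = "drop")
    dplyr::bind_rows(by_class, total)
  }
  out <- dplyr::bind_rows(summarise_one(calls), summarise_one(union_calls))
  cls_order <- c(ORF_CLASSES, "total")
  dplyr::arrange(out, .data$scope != "union", .data$scope,
                 match(.data$class, cls_order))
}

#' Class shares of TIS counts
#'
#' Percentage of each class among the total, rounded half-away-from-zero to
#' one decimal.
#'
#' @param counts Tibble with `class` and `n_tis` columns (rows with
#'   `class == "total"` are ignored), e.g. the union rows of
#'   [class_summary()].
#' @return `counts` plus a `percent` column.
#' @examples
#' class_proportions(tibble::tibble(
#'   class = c("annotated", "upstream"), n_tis = c(60, 40)))
#' @export
class_proportions <- function(counts) {
  assert_columns(counts, c("class", "n_tis"), "counts")
  counts <- dplyr::filter(as_tibble(counts), .data$class != "total")
  counts$percent <- round_half_up(100 * counts$n_tis / sum(counts$n_tis), 1)
  counts
}

#' Detection sensitivity per antigen class
#'
#' Sensitivity is the percentage of antigen-encoding ORFs detected out of
#' all catalogued ORFs, per class and pooled, rounded half-away-from-zero to
#' one decimal.
#'
#' * `scope = "any_sample"`: an ORF counts as detected when found in at
#'   least one sample; the denominator is all ORFs.
#' * `scope = "all_samples"`: the denominator is restricted to ORFs present
#'   in every sample, and detection requires every sample.
#'
#' @param dm A `detection_matrix`.
#' @param scope `"any_sample"` (default) or `"all_samples"`.
#' @param classes Optional class filter (e.g.
#'   `c("annotated", "upstream", "alternative")`); per-class rows and the
#'   pooled row are computed over this subset.
#' @return Tibble (`class_label`, `n_detected`, `n_total`,
#'   `sensitivity_pct`, `scope`) with a final pooled row
#'   (`class_label = "pooled"`).
#' @export
detection_sensitivity <- function(dm,
                                  scope = c("any_sample", "all_samples"),
                                  classes = NULL) {
  stopifnot(inherits(dm, "detection_matrix"))
  scope <- match.arg(scope)
  per_orf <- dm$detections |>
    dplyr::group_by(.data$orf_id, .data$class_label) |>
    dplyr::summarise(all_present = all(.data$present),
                     det_any = any(.data$detected),
                     det_all = all(.data$detected),
                     .groups = "drop")
  if (!is.null(classes)) {
    per_orf <- dplyr::filter(per_orf, .data$class_label %in% classes)
  }
  if (scope == "all_samples") {
    per_orf <- dplyr::filter(per_orf, .data$all_present)
    per_orf$hit <- per_orf$det_all
  } else {
    per_orf$hit <- per_orf$det_any
  }
  by_class <- per_orf |>
    dplyr::group_by(class_label = .data$class_label) |>
    dplyr::summarise(n_detected = sum(.data$hit), n_total = dplyr::n(),
                     .groups = "drop")
  pooled <- tibble(class_label = "pooled",
                   n_detected = sum(per_orf$hit),
                   n_total = nrow(per_orf))
  out <- dplyr::bind_rows(by_class, pooled)
  out$sensitivity_pct <- round_half_up(100 * out$n_detected / out$n_total, 1)
  out$scope <- scope
  out
}

#' Histogram of detection counts across samples
#'
#' @param dm A `detection_matrix`.
#' @return Tibble (`n_samples_detected`, `n_orfs`) over bins `0..n_samples`;
#'   `n_orfs` sums to the number of catalogued ORFs.
#' @export
detection_histogram <- function(dm) {
  stopifnot(inherits(dm, "detection_matrix"))
  n_samples <- length(dm$samples)
  per_orf <- dm$detections |>
    dplyr::group_by(.data$orf_id) |>
    dplyr::summarise(k = sum(.data$detected), .groups = "drop")
  tibble(n_samples_detected = 0:n_samples) |>
    dplyr::left_join(dplyr::count(per_orf, n_samples_detected = .data$k,
                                  name = "n_orfs"),
                     by = "n_samples_detected") |>
    dplyr::mutate(n_orfs = dplyr::coalesce(.data$n_orfs, 0L))
}

#' Expression-stratified detection cross-tab
#'
#' Cross-tabulates ORFs by class, expression bin of the encoding gene, and
#' the number of samples in which the ORF was detected. ORFs whose gene
#' lacks an expression value are reported in a separate
#' `"no expression data"` stratum rather than dropped.
#'
#' @param dm A `detection_matrix` whose detections carry `gene_id`.
#' @param expression Tibble (`gene_id`, `rpkm`).
#' @param thresholds Ascending RPKM cut points (default `c(1, 10)`, i.e.
#'   bins `<1`, `1-10`, `>10`).
#' @return Tibble (`class_label`, `expression_bin`, `n_samples_detected`,
#'   `n_orfs`).
#' @export
expression_strata <- function(dm, expression, thresholds = c(1, 10)) {
  stopifnot(inherits(dm, "detection_matrix"))
  assert_columns(dm$detections, "gene_id", "detections")
  assert_columns(expression, c("gene_id", "rpkm"), "expression")
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  labels <- c(sprintf("<%g", thresholds[1]),
              if (length(thresholds) > 1) {
                sprintf("%g-%g", head(thresholds, -1), tail(thresholds, -1))
              },
              sprintf(">%g", tail(thresholds, 1)))
  per_orf <- dm$detections |>
    dplyr::group_by(.data$orf_id, .data$gene_id, .data$class_label) |>
    dplyr::summarise(n_samples_detected = sum(.data$detected),
                     .groups = "drop") |>
    dplyr::left_join(expression, by = "gene_id")
  per_orf$expression_bin <- ifelse(
    is.na(per_orf$rpkm), "no expression data",
    as.character(cut(per_orf$rpkm, breaks = c(-Inf, thresholds, Inf),
                     labels = labels, right = TRUE)))
  per_orf |>
    dplyr::count(.data$class_label, .data$expression_bin,
                 .data$n_samples_detected, name = "n_orfs") |>
    dplyr::mutate(expression_bin = factor(.data$expression_bin,
                                          levels = c(labels,
                                                     "no expression data")))
}
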