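#' Match antigens against one sample's ORF calls
#'
#' Two detection criteria are exposed because the operational definition used
#' for published detection counts is not fixed by class labels:
#' * `peptide_containment` (default): an antigen is detected when some
#'   significant ORF call on the antigen's gene contains the epitope as an
#'   in-frame substring of its peptide. This never compares class labels, so
#'   a catalog's `out_of_frame` antigen can be matched by an ORF the
#'   classifier calls `upstream`.
#' * `exact_tis`: detected when a significant call sits at `expected_tis`
#'   (within `tis_tolerance` nt) on the stated transcript; requires
#'   `expected_tis`.
#'
#' @param catalog Antigen tibble (`antigen_id`, `epitope`, `gene_id`;
#'   `transcript_id` and `expected_tis` for `exact_tis`).
#' @param calls One sample's ORF calls (rows with `significant == FALSE` are
#'   ignored when the column is present).
#' @param mode `"peptide_containment"` or `"exact_tis"`.
#' @param tis_tolerance nt tolerance for `exact_tis` (default 0).
#' @return `catalog` with a logical `detected` column.
#' @export
match_antigens <- function(catalog, calls,
                           mode = c("peptide_containment", "exact_tis"),
                           tis_tolerance = 0) {
  mode <- match.arg(mode)
  assert_columns(catalog, c("antigen_id", "epitope", "gene_id"), "catalog")
  if ("significant" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$significant)
  }
  if (mode == "peptide_containment") {
    assert_columns(calls, c("gene_id", "peptide"), "calls")
    detected <- vapply(seq_len(nrow(catalog)), function(i) {
      pep <- calls$peptide[calls$gene_id == catalog$gene_id[i]]
      any(stringr::str_detect(pep,
                              stringr::fixed(catalog$epitope[i])))
    }, logical(1))
  } else {
    assert_columns(catalog, c("transcript_id", "expected_tis"), "catalog")
    if (anyNA(catalog$expected_tis)) {
      abort("mode 'exact_tis' requires expected_tis for every antigen")
    }
    assert_columns(calls, c("transcript_id", "tis_position"), "calls")
    detected <- vapply(seq_len(nrow(catalog)), function(i) {
      any(calls$transcript_id == catalog$transcript_id[i] &
            abs(calls$tis_position - catalog$expected_tis[i]) <= tis_tolerance)
    }, logical(1))
  }
  catalog$detected <- detected
  catalog
}

#' Build an antigen-ORF detection matrix across samples
#'
#' Collapses antigens to their encoding ORF (several epitopes from one ORF
#' count once: the ORF is detected when any of its epitopes matches), applies
#' the presence mask (an ORF absent from a sample's genotype cannot be
#' detected there), and records one detection flag per ORF and sample.
#'
#' @param catalog Antigen tibble; an `orf_id` column groups antigens by
#'   encoding ORF (defaults to `antigen_id`, i.e. no collapsing).
#' @param calls_by_sample Named list of per-sample classified ORF calls, or a
#'   single tibble with a `sample_id` column.
#' @param mode,tis_tolerance Passed to [match_antigens()].
#' @param presence Optional tibble (`orf_id`, `sample_id`, `present`);
#'   missing pairs default to present.
#' @return A `detection_matrix` object; see [as_detection_matrix()].
#' @export
detection_matrix <- function(catalog, calls_by_sample,
                             mode = c("peptide_containment", "exact_tis"),
                             tis_tolerance = 0, presence = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(calls_by_sample)) {
    assert_columns(calls_by_sample, "sample_id", "calls_by_sample")
    calls_by_sample <- split(calls_by_sample, calls_by_sample$sample_id)
  }
  if (is.null(names(calls_by_sample)) || any(names(calls_by_sample) == "")) {
    abort("calls_by_sample must be a named list (one element per sample)")
  }
  if (!"orf_id" %in% names(catalog)) catalog$orf_id <- catalog$antigen_id
  if (!"class_label" %in% names(catalog)) {
    abort("catalog needs a class_label column")
  }
  long <- purrr::list_rbind(purrr::imap(calls_by_sample, function(calls, sid) {
    m <- match_antigens(catalog, calls, mode = mode,
                        tis_tolerance = tis_tolerance)
    m |>
      dplyr::group_by(.data$orf_id, .data$gene_id, .data$class_label) |>
      dplyr::summarise(detected = any(.data$detected), .groups = "drop") |>
      dplyr::mutate(sample_id = sid)
  }))
  if (!is.null(presence)) {
    assert_columns(presence, c("orf_id", "sample_id", "present"), "presence")
    long <- dplyr::left_join(long, presence, by = c("orf_id", "sample_id"))
    long$present <- dplyr::coalesce(long$present, TRUE)
  } else {
    long$present <- TRUE
  }
  long$detected <- long$detected & long$present
  as_detection_matrix(dplyr::select(long, "orf_id", "gene_id", "class_label",
                                    "sample_id", "present", "detected"))
}

#' Construct a detection matrix from a long detection table
#'
#' @param detections Tibble with one row per (ORF, sample):
#'   `orf_id`, `class_label`, `sample_id`, `present`, `detected`
#'   (an optional `gene_id` column enables expression stratification).
#'   Every ORF must appear once per sample, and `detected` must imply
#'   `present`.
#' @return Object of class `detection_matrix`.
#' @export
as_detection_matrix <- function(detections) {
  assert_columns(detections, c("orf_id", "class_label", "sample_id",
                               "present", "detected"), "detections")
  bad_label <- setdiff(unique(detections$class_label), CATALOG_CLASSES)
  if (length(bad_label)) {
    abort(sprintf("unknown class_label(s): %s",
                  paste(bad_label, collapse = ", ")))
  }
  if (any(detections$detected & !detections$present)) {
    abort("detection implies presence: some detected ORFs are marked absent")
  }
  counts <- dplyr::count(detections, .data$orf_id, .data$sample_id)
  if (any(counts$n > 1L)) {
    abort("duplicate (orf_id, sample_id) rows in detections")
  }
  n_per_orf <- dplyr::count(detections, .data$orf_id)
  if (dplyr::n_distinct(n_per_orf$n) > 1L) {
    abort("every ORF must appear in every sample")
  }
  structure(
    list(detections = as_tibble(detections),
         samples = sort(unique(detections$sample_id))),
    class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<detection_matrix> %d ORFs x %d samples; %d detected in >= 1 sample\n",
    g$n_orfs, g$n_samples, g$n_detected_any))
  invisible(x)
}

#' @method tidy detection_matrix
#' @export
tidy.detection_matrix <- function(x, ...) {
  x$detections
}

#' @method glance detection_matrix
#' @export
glance.detection_matrix <- function(x, ...) {
  per_orf <- x$detections |>
    dplyr::group_by(.data$orf_id) |>
    dplyr::summarise(any_det = any(.data$detected), .groups = "drop")
  tibble(
    n_orfs = nrow(per_orf),
    n_samples = length(x$samples),
    n_detected_any = sum(per_orf$any_det),
    n_classes = dplyr::n_distinct(x$detections$class_label)
  )
}
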