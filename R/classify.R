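#' Classify ORFs relative to the annotated CDS
#'
#' Positional classification of each ORF call on its transcript:
#' * no CDS annotation -> `lncRNA`
#' * `tis == cds_start` -> `annotated`
#' * `tis < cds_start` -> `upstream`
#' * `tis >= cds_end` -> `downstream`
#' * inside the CDS -> `internal_in_frame` when `(tis - cds_start) %% 3 == 0`,
#'   else `internal_out_of_frame`.
#'
#' Upstream ORFs additionally get `cds_overlap` (does the ORF span reach into
#' the CDS?) and `cds_overlap_frame` (`(tis - cds_start) %% 3`, recorded when
#' overlapping). An upstream-initiating ORF that overlaps the CDS
#' out-of-frame is still classed `upstream` by its TIS position; antigen
#' catalogs may label the same ORF `out_of_frame`, which is why antigen
#' matching never compares class labels.
#'
#' @param orfs ORF-call tibble from [build_orfs()].
#' @param transcripts Transcript tibble.
#' @return `orfs` with `class`, `cds_overlap`, `cds_overlap_frame` columns.
#' @export
classify_orfs <- function(orfs, transcripts) {
  assert_columns(orfs, c("transcript_id", "tis_position", "length_aa",
                         "complete"), "orfs")
  idx <- match(orfs$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) abort("orfs reference unknown transcripts")
  cds_start <- transcripts$cds_start[idx]
  cds_end <- transcripts$cds_end[idx]
  tis <- orfs$tis_position
  span_end <- dplyr::if_else(orfs$complete,
                             orfs$stop_position + 3L,
                             tis + 3L * orfs$length_aa)
  cls <- dplyr::case_when(
    is.na(cds_start) ~ "lncRNA",
    tis == cds_start ~ "annotated",
    tis < cds_start ~ "upstream",
    tis >= cds_end ~ "downstream",
    (tis - cds_start) %% 3L == 0L ~ "internal_in_frame",
    TRUE ~ "internal_out_of_frame"
  )
  overlap <- cls == "upstream" & span_end > cds_start
  orfs$class <- cls
  orfs$cds_overlap <- dplyr::if_else(cls == "upstream", overlap, NA)
  orfs$cds_overlap_frame <- dplyr::if_else(
    overlap, as.integer((tis - cds_start) %% 3L), NA_integer_)
  orfs
}
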