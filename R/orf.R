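#' Extend TIS calls to open reading frames
#'
#' Scans codons from each initiation site to the first in-frame stop
#' (TAA/TAG/TGA). ORFs with no stop before the transcript end are kept with
#' `complete = FALSE` and their length counted to the last full codon.
#' Peptides use the standard genetic code with the initiator rendered as M
#' regardless of a near-cognate start.
#'
#' @param tis A `tis_calls` tibble (or any tibble with `transcript_id` and
#'   `position`). By default only significant calls are extended when a
#'   `significant` column is present.
#' @param transcripts Transcript tibble.
#' @param significant_only Drop non-significant calls first (default TRUE).
#' @return Tibble of ORF calls: `transcript_id`, `gene_id`, `tis_position`,
#'   `stop_position` (first nt of the stop codon, NA if incomplete),
#'   `length_aa` (excluding the stop), `peptide`, `complete`, plus any
#'   `codon`, `q_value`, `significant`, `sample_id` columns carried through.
#' @export
build_orfs <- function(tis, transcripts, significant_only = TRUE) {
  assert_columns(tis, c("transcript_id", "position"), "tis")
  calls <- as_tibble(tis)
  if (significant_only && "significant" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$significant)
  }
  idx <- match(calls$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) abort("tis calls reference unknown transcripts")
  tr <- translate_from(transcripts$sequence[idx], calls$position)
  keep <- intersect(c("codon", "psite_count", "p_value", "q_value",
                      "significant", "sample_id"), names(calls))
  dplyr::bind_cols(
    tibble(transcript_id = calls$transcript_id,
           gene_id = transcripts$gene_id[idx],
           tis_position = calls$position),
    tr[c("stop_position", "length_aa", "peptide", "complete")],
    calls[keep]
  )
}

#' Resolve a TIS assigned to multiple transcripts
#'
#' When one initiation site is carried by several transcripts of a gene, a
#' single representative ORF is kept per group: in-frame ORFs (class
#' `annotated` or `internal_in_frame`) are preferred; among the remainder the
#' longest peptide wins; a final tie resolves to the lexicographically
#' smallest `transcript_id`.
#'
#' @param orfs Classified ORF calls (a `class` column enables the in-frame
#'   preference; without it selection is by length then id).
#' @param group_vars Columns identifying one shared TIS (default
#'   `c("gene_id", "tis_group")` when a `tis_group` column exists, else
#'   `c("gene_id", "tis_position")`).
#' @return One ORF call per group.
#' @export
resolve_orf_calls <- function(orfs, group_vars = NULL) {
  if (is.null(group_vars)) {
    group_vars <- if ("tis_group" %in% names(orfs)) {
      c("gene_id", "tis_group")
    } else {
      c("gene_id", "tis_position")
    }
  }
  assert_columns(orfs, c(group_vars, "length_aa", "transcript_id"), "orfs")
  pick_one <- function(g) {
    if (nrow(g) == 1L) return(g)
    if ("class" %in% names(g)) {
      in_frame <- g$class %in% c("annotated", "internal_in_frame")
      if (any(in_frame)) g <- g[in_frame, , drop = FALSE]
    }
    g <- g[g$length_aa == max(g$length_aa), , drop = FALSE]
    g[order(g$transcript_id)[1L], , drop = FALSE]
  }
  orfs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::group_modify(~ pick_one(.x)) |>
    dplyr::ungroup()
}
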