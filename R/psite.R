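#' Estimate P-site offsets by start-codon enrichment
#'
#' For each read length with sufficient support, slides candidate offsets
#' over a search window and scores how many shifted 5' ends land on one of
#' the three nucleotides of an annotated CDS start codon, aggregated over all
#' coding transcripts (the metagene enrichment created by
#' harringtonine-arrested initiating ribosomes). The argmax is the offset;
#' exact ties resolve to the smaller offset. Scoring targets the whole start
#' codon rather than a single nucleotide to tolerate +/-1 jitter.
#'
#' @param footprints Footprint tibble (`transcript_id`, `five_prime_pos`,
#'   `read_length`).
#' @param transcripts Transcript tibble; at least one coding record needed.
#' @param search_window Inclusive offset window in nt (default `c(10, 15)`).
#' @param length_range Inclusive read-length range considered
#'   (default `c(25, 35)`).
#' @param min_reads_per_length Minimum reads for a length to be calibrated
#'   (default 100).
#' @return Tibble (`read_length`, `offset`, `score`, `n_reads`), one row per
#'   retained read length, with the full per-offset score profile in the
#'   `profile` attribute. Errors if no read length meets the support
#'   threshold.
#' @export
estimate_psite_offsets <- function(footprints, transcripts,
                                   search_window = c(10, 15),
                                   length_range = c(25, 35),
                                   min_reads_per_length = 100) {
  assert_columns(footprints, c("transcript_id", "five_prime_pos",
                               "read_length"), "footprints")
  coding <- dplyr::filter(transcripts, .data$biotype == "coding")
  if (!nrow(coding)) abort("offset estimation needs >= 1 coding transcript")
  fp <- dplyr::filter(footprints,
                      .data$read_length >= length_range[1],
                      .data$read_length <= length_range[2])
  fp$cds_start <- coding$cds_start[match(fp$transcript_id,
                                         coding$transcript_id)]
  fp <- dplyr::filter(fp, !is.na(.data$cds_start))
  support <- dplyr::count(footprints, .data$read_length, name = "n_reads")
  offsets <- seq(search_window[1], search_window[2])
  lengths <- sort(unique(fp$read_length))
  profile <- purrr::list_rbind(purrr::map(lengths, function(L) {
    n_total <- support$n_reads[support$read_length == L]
    if (n_total < min_reads_per_length) return(NULL)
    rel <- fp$cds_start[fp$read_length == L] - fp$five_prime_pos[fp$read_length == L]
    tibble(read_length = L, offset = offsets,
           score = vapply(offsets,
                          function(d) sum(d >= rel & d <= rel + 2L),
                          numeric(1)),
           n_reads = n_total)
  }))
  if (is.null(profile) || !nrow(profile)) {
    abort(sprintf(
      "no read length has >= %d supporting reads; deeper input is needed",
      min_reads_per_length))
  }
  out <- profile |>
    dplyr::group_by(.data$read_length) |>
    dplyr::slice(which.max(.data$score)) |>   # ties -> smallest offset
    dplyr::ungroup() |>
    dplyr::select("read_length", "offset", "score", "n_reads")
  attr(out, "profile") <- profile
  out
}

#' Convert footprints to per-nucleotide P-site tracks
#'
#' Each read's P-site is `five_prime_pos + offset(read_length)`. Reads whose
#' length has no calibrated offset, and P-sites falling past the transcript
#' end, are dropped and counted. Every transcript gets a track (all-zero when
#' it has no reads), so retained + dropped always equals the input read
#' count.
#'
#' @param footprints Footprint tibble.
#' @param transcripts Transcript tibble.
#' @param offsets Offset tibble from [estimate_psite_offsets()], or any
#'   tibble with `read_length` and `offset` columns (e.g. known simulation
#'   offsets).
#' @return Tibble (`transcript_id`, `length`, `track`) of class
#'   `psite_tracks`, `track` a list column of per-nt integer counts, with
#'   attributes `n_input`, `n_retained`, `n_dropped_no_offset`,
#'   `n_dropped_out_of_range`.
#' @export
psite_tracks <- function(footprints, transcripts, offsets) {
  assert_columns(footprints, c("transcript_id", "five_prime_pos",
                               "read_length"), "footprints")
  assert_columns(offsets, c("read_length", "offset"), "offsets")
  off <- offsets$offset[match(footprints$read_length, offsets$read_length)]
  no_off <- is.na(off)
  psite <- footprints$five_prime_pos + off
  tlen <- nchar(transcripts$sequence)[match(footprints$transcript_id,
                                            transcripts$transcript_id)]
  if (anyNA(tlen)) {
    abort("footprints reference transcripts absent from `transcripts`")
  }
  oob <- !no_off & (psite >= tlen | psite < 0L)
  keep <- !no_off & !oob
  kept <- tibble(transcript_id = footprints$transcript_id[keep],
                 psite = psite[keep])
  lens <- setNames(nchar(transcripts$sequence), transcripts$transcript_id)
  by_tx <- split(kept$psite, factor(kept$transcript_id,
                                    levels = transcripts$transcript_id))
  tracks <- purrr::imap(by_tx, function(pos, id) {
    as.integer(tabulate(pos + 1L, nbins = lens[[id]]))
  })
  out <- tibble(transcript_id = transcripts$transcript_id,
                length = unname(lens),
                track = unname(tracks[transcripts$transcript_id]))
  class(out) <- c("psite_tracks", class(out))
  attr(out, "n_input") <- nrow(footprints)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped_no_offset") <- sum(no_off)
  attr(out, "n_dropped_out_of_range") <- sum(oob)
  out
}
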