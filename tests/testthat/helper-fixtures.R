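# Small fixtures built in code.

tiny_sim_config <- function(seed = 1L, ...) {
  sim_config(n_coding_transcripts = 6, n_lncrna_transcripts = 2,
             utr5_length_range = c(60, 120), cds_length_range = c(150, 300),
             utr3_length_range = c(45, 90), total_reads = 3e4,
             seed = seed, ...)
}

# one hand-built coding transcript: 12 nt 5'UTR, 18 nt CDS, 9 nt 3'UTR
toy_transcript <- function() {
  tibble::tibble(
    transcript_id = "T1", gene_id = "G1", biotype = "coding",
    sequence = paste0("GGGACCACCAAA",              # 5' UTR [0, 12)
                      "ATGGCTGAATTCAAATAA",        # CDS   [12, 30)
                      "CCCGGGTTT"),                # 3' UTR [30, 39)
    cds_start = 12L, cds_end = 30L)
}

# a track of zeros with counts set at given 0-based positions
toy_track <- function(transcripts, counts = list()) {
  out <- tibble::tibble(
    transcript_id = transcripts$transcript_id,
    length = nchar(transcripts$sequence),
    track = lapply(nchar(transcripts$sequence), function(n) integer(n)))
  for (id in names(counts)) {
    i <- match(id, out$transcript_id)
    for (pos in names(counts[[id]])) {
      out$track[[i]][as.integer(pos) + 1L] <- counts[[id]][[pos]]
    }
  }
  class(out) <- c("psite_tracks", class(out))
  out
}

# long-format detection table realising given per-class any-sample outcomes
build_detection_table <- function(spec, n_samples = 6) {
  # spec: data.frame(class_label, n_total, n_detected, n_partial = 0,
  #                  n_detected_all = 0); detected ORFs are present in all
  # samples; partial ORFs (absent from sample 1) are never detected.
  rows <- list()
  orf <- 0
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    stopifnot(s$n_detected + s$n_partial <= s$n_total)
    for (j in seq_len(s$n_total)) {
      orf <- orf + 1
      detected_any <- j <= s$n_detected
      detected_all <- j <= (s$n_detected_all %||% 0)
      partial <- j > s$n_total - s$n_partial
      for (k in seq_len(n_samples)) {
        present <- !(partial && k == 1)
        detected <- present && detected_any && (detected_all || k == 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          orf_id = sprintf("ORF%04d", orf), gene_id = sprintf("G%04d", orf),
          class_label = s$class_label, sample_id = sprintf("s%d", k),
          present = present, detected = detected)
      }
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
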