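# All coordinates everywhere are 0-based, half-open, transcript-space,
# sense strand. Readers validate; writers emit a header line. Reading is
# gzip-transparent (readr and Biostrings both detect compression).

#' Read a transcriptome (FASTA + annotation table)
#'
#' @param fasta_path Transcript sequences, one record per transcript.
#' @param annotation_path Tab-separated annotation with header
#'   `transcript_id`, `gene_id`, `biotype` (`coding`/`lncRNA`), `cds_start`,
#'   `cds_end` (0-based half-open; empty/NA for lncRNA).
#' @return Validated tibble of transcript records (`transcript_id`,
#'   `gene_id`, `biotype`, `sequence`, `cds_start`, `cds_end`). Invariant
#'   violations (CDS out of bounds, length not a multiple of 3, CDS not
#'   starting ATG, annotation id absent from the FASTA) abort with
#'   per-record messages.
#' @export
read_transcriptome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = "c", gene_id = "c", biotype = "c",
                           cds_start = "i", cds_end = "i"))
  assert_columns(ann, c("transcript_id", "gene_id", "biotype",
                        "cds_start", "cds_end"), "annotation")
  problems <- character()
  missing <- setdiff(ann$transcript_id, names(seqs))
  if (length(missing)) {
    problems <- c(problems, sprintf(
      "transcript %s: present in annotation but absent from FASTA", missing))
  }
  tx <- dplyr::filter(ann, .data$transcript_id %in% names(seqs))
  tx$sequence <- toupper(as.character(seqs[tx$transcript_id]))
  tx$length <- nchar(tx$sequence)
  for (i in seq_len(nrow(tx))) {
    r <- tx[i, ]
    if (r$biotype == "lncRNA") {
      if (!is.na(r$cds_start) || !is.na(r$cds_end)) {
        problems <- c(problems, sprintf(
          "transcript %s: lncRNA must not carry a CDS annotation",
          r$transcript_id))
      }
      next
    }
    if (r$biotype != "coding") {
      problems <- c(problems, sprintf("transcript %s: unknown biotype '%s'",
                                      r$transcript_id, r$biotype))
      next
    }
    if (is.na(r$cds_start) || is.na(r$cds_end)) {
      problems <- c(problems, sprintf(
        "transcript %s: coding record lacks CDS coordinates", r$transcript_id))
      next
    }
    if (r$cds_start < 0 || r$cds_start >= r$cds_end || r$cds_end > r$length) {
      problems <- c(problems, sprintf(
        "transcript %s: CDS [%d, %d) outside sequence of length %d",
        r$transcript_id, r$cds_start, r$cds_end, r$length))
      next
    }
    if ((r$cds_end - r$cds_start) %% 3L != 0L) {
      problems <- c(problems, sprintf(
        "transcript %s: CDS length %d is not a multiple of 3",
        r$transcript_id, r$cds_end - r$cds_start))
    }
    if (codon_at(r$sequence, r$cds_start) != "ATG") {
      problems <- c(problems, sprintf(
        "transcript %s: CDS does not begin with ATG", r$transcript_id))
    }
  }
  if (length(problems)) {
    abort(c("invalid transcriptome annotation", problems))
  }
  dplyr::select(tx, "transcript_id", "gene_id", "biotype", "sequence",
                "cds_start", "cds_end")
}

#' Write a transcriptome as FASTA + annotation TSV
#'
#' @param transcripts Transcript tibble (see [read_transcriptome()]).
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path) {
  assert_columns(transcripts, c("transcript_id", "gene_id", "biotype",
                                "sequence", "cds_start", "cds_end"),
                 "transcripts")
  seqs <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                            transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    dplyr::select(transcripts, "transcript_id", "gene_id", "biotype",
                  "cds_start", "cds_end"),
    annotation_path)
  invisible(c(fasta_path, annotation_path))
}

#' Read footprint alignments (TSV or transcript-space SAM)
#'
#' SAM input must be single-end against transcript-space references;
#' unmapped, secondary and supplementary records are skipped and counted, as
#' are reverse-strand records (antisense footprints are invalid on a
#' sense-strand transcriptome) and records whose 5' end falls outside the
#' transcript. A reference name absent from the transcriptome is an error.
#'
#' @param path Input file. `format = "auto"` keys on the extension
#'   (`.sam` vs `.tsv`/`.txt`, optionally `.gz`).
#' @param transcripts Transcript tibble used for reference validation.
#' @param format `"auto"`, `"tsv"` or `"sam"`.
#' @return Tibble (`transcript_id`, `five_prime_pos`, `read_length`) with a
#'   `skipped` attribute: named counts of skipped records by reason.
#' @export
read_footprints <- function(path, transcripts,
                            format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.sam$", base, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "sam") {
    read_footprints_sam(path, transcripts)
  } else {
    read_footprints_tsv(path, transcripts)
  }
}

footprint_skip_counts <- function(unmapped = 0L, secondary = 0L,
                                  supplementary = 0L, reverse_strand = 0L,
                                  out_of_range = 0L) {
  c(unmapped = unmapped, secondary = secondary,
    supplementary = supplementary, reverse_strand = reverse_strand,
    out_of_range = out_of_range)
}

finish_footprints <- function(fp, transcripts, skipped) {
  bad_ref <- setdiff(fp$transcript_id, transcripts$transcript_id)
  if (length(bad_ref)) {
    abort(sprintf("footprint reference(s) absent from transcriptome: %s",
                  paste(unique(bad_ref), collapse = ", ")))
  }
  tlen <- nchar(transcripts$sequence)[match(fp$transcript_id,
                                            transcripts$transcript_id)]
  in_range <- fp$five_prime_pos >= 0L & fp$five_prime_pos < tlen
  skipped[["out_of_range"]] <- skipped[["out_of_range"]] + sum(!in_range)
  fp <- fp[in_range, ]
  attr(fp, "skipped") <- skipped
  fp
}

read_footprints_tsv <- function(path, transcripts) {
  fp <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          transcript_id = "c", five_prime_pos = "i",
                          read_length = "i"))
  assert_columns(fp, c("transcript_id", "five_prime_pos", "read_length"),
                 "footprint TSV")
  finish_footprints(fp, transcripts, footprint_skip_counts())
}

read_footprints_sam <- function(path, transcripts) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "flag")))[[1]]
  flag <- rec$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  reverse <- !unmapped & !secondary & !supplementary &
    as.character(rec$strand) == "-"
  keep <- !(unmapped | secondary | supplementary | reverse)
  skipped <- footprint_skip_counts(
    unmapped = sum(unmapped),
    secondary = sum(secondary & !unmapped),
    supplementary = sum(supplementary & !unmapped & !secondary),
    reverse_strand = sum(reverse))
  fp <- tibble(
    transcript_id = as.character(rec$rname)[keep],
    five_prime_pos = rec$pos[keep] - 1L,
    read_length = rec$qwidth[keep]
  )
  finish_footprints(fp, transcripts, skipped)
}

#' Write footprints (TSV or transcript-space SAM)
#'
#' @param footprints Tibble (`transcript_id`, `five_prime_pos`,
#'   `read_length`).
#' @param path Output path; extension selects the format under
#'   `format = "auto"`.
#' @param transcripts Required for SAM output (`@SQ` header and read
#'   sequences).
#' @param format `"auto"`, `"tsv"` or `"sam"`.
#' @return Invisibly, `path`.
#' @export
write_footprints <- function(footprints, path, transcripts = NULL,
                             format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  assert_columns(footprints, c("transcript_id", "five_prime_pos",
                               "read_length"), "footprints")
  if (format == "tsv") {
    readr::write_tsv(
      dplyr::select(footprints, "transcript_id", "five_prime_pos",
                    "read_length"), path)
    return(invisible(path))
  }
  if (is.null(transcripts)) {
    abort("SAM output needs `transcripts` for the header and read sequences")
  }
  idx <- match(footprints$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) {
    abort("footprints reference transcripts absent from `transcripts`")
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", transcripts$transcript_id,
            nchar(transcripts$sequence))
  )
  n <- nrow(footprints)
  body <- if (n) {
    seqs <- substr(transcripts$sequence[idx],
                   footprints$five_prime_pos + 1L,
                   footprints$five_prime_pos + footprints$read_length)
    sprintf("read%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
            seq_len(n), footprints$transcript_id,
            footprints$five_prime_pos + 1L, footprints$read_length, seqs)
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene expression table
#'
#' @param path Two-column TSV with header `gene_id`, `rpkm`.
#' @return Tibble (`gene_id`, `rpkm`); duplicate gene ids or negative values
#'   abort.
#' @export
read_expression <- function(path) {
  ex <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(gene_id = "c", rpkm = "d"))
  assert_columns(ex, c("gene_id", "rpkm"), "expression table")
  dup <- unique(ex$gene_id[duplicated(ex$gene_id)])
  if (length(dup)) {
    abort(sprintf("duplicate gene id(s) in expression table: %s",
                  paste(dup, collapse = ", ")))
  }
  if (any(ex$rpkm < 0, na.rm = TRUE)) {
    abort("expression table contains negative RPKM values")
  }
  ex
}

#' Write a gene expression table
#' @param expression Tibble (`gene_id`, `rpkm`).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expression, path) {
  assert_columns(expression, c("gene_id", "rpkm"), "expression")
  readr::write_tsv(dplyr::select(expression, "gene_id", "rpkm"), path)
  invisible(path)
}
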