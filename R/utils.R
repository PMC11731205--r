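BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- {
  g <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

ORF_CLASSES <- c("annotated", "upstream", "internal_in_frame",
                 "internal_out_of_frame", "downstream", "lncRNA")

CATALOG_CLASSES <- c("annotated", "out_of_frame", "upstream",
                     "alternative", "lncRNA")

# catalog nomenclature for antigen ORFs differs from positional classes:
# internal out-of-frame ORFs are catalogued "out_of_frame"; internal in-frame
# and downstream ORFs fall under "alternative"
truth_to_catalog_class <- function(class) {
  map <- c(annotated = "annotated",
           upstream = "upstream",
           internal_out_of_frame = "out_of_frame",
           internal_in_frame = "alternative",
           downstream = "alternative",
           lncRNA = "lncRNA")
  unname(map[class])
}

#' Round half away from zero
#'
#' Standard commercial rounding: ties go away from zero, so `63.55` rounds to
#' `63.6` at one decimal (base [round()] uses round-half-even). All percentage
#' summaries in this package use this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(63.55)   # 63.6
#' round_half_up(-0.25, 1) # -0.3
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + .5 + sqrt(.Machine$double.eps)) / m
}

random_bases <- function(n) {
  sample(BASES, n, replace = TRUE)
}

sample_len <- function(range, multiple_of = 1L) {
  lo <- as.integer(ceiling(range[[1]] / multiple_of))
  hi <- as.integer(floor(range[[2]] / multiple_of))
  if (hi < lo) {
    abort(sprintf("length range [%s, %s] admits no multiple of %d",
                  range[[1]], range[[2]], multiple_of))
  }
  multiple_of * (if (lo == hi) lo else sample(lo:hi, 1L))
}

# Translate in-frame from 0-based `pos` to the first stop codon (or the last
# full codon). Vectorised over records; returns peptide with the initiator
# rendered as M, the 0-based first nt of the stop (NA if none), completeness
# and length in aa.
translate_from <- function(sequence, pos) {
  stopifnot(length(sequence) == length(pos))
  n <- nchar(sequence)
  n_codons <- pmax((n - pos) %/% 3L, 0L)
  sub <- substr(sequence, pos + 1L, pos + 3L * n_codons)
  aa <- character(length(sub))
  ok <- n_codons > 0L
  if (any(ok)) {
    aa[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(sub[ok]), no.init.codon = TRUE))
  }
  star <- regexpr("*", aa, fixed = TRUE)
  complete <- star > 0L
  length_aa <- ifelse(complete, star - 1L, n_codons)
  peptide <- substr(aa, 1L, length_aa)
  # near-cognate initiators decode as Met in vivo
  has_pep <- length_aa > 0L
  substr(peptide[has_pep], 1L, 1L) <- "M"
  tibble(
    peptide = peptide,
    stop_position = ifelse(complete, pos + 3L * (star - 1L), NA_integer_),
    complete = complete,
    length_aa = as.integer(length_aa)
  )
}

codon_at <- function(sequence, pos) {
  substr(sequence, pos + 1L, pos + 3L)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
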