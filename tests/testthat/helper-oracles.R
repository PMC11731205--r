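# Independent oracles used throughout the suite. These deliberately avoid the
# package's code paths (and Biostrings): a hand-written codon table, a looped
# translator, a 3-frame start-to-stop enumerator, a manual BH procedure and
# brute-force NB/Poisson tail summation.

ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# translate in-frame from 0-based pos; initiator rendered M; stops at the
# first stop codon or the last full codon
oracle_translate_from <- function(sequence, pos) {
  aa <- character()
  stop_position <- NA_integer_
  complete <- FALSE
  p <- pos
  n <- nchar(sequence)
  first <- TRUE
  while (p + 3L <= n) {
    codon <- substr(sequence, p + 1L, p + 3L)
    res <- ORACLE_CODON_TABLE[[codon]]
    if (res == "*") {
      stop_position <- p
      complete <- TRUE
      break
    }
    aa <- c(aa, if (first) "M" else res)
    first <- FALSE
    p <- p + 3L
  }
  list(peptide = paste(aa, collapse = ""), stop_position = stop_position,
       complete = complete, length_aa = length(aa))
}

# every start-to-stop span in all 3 frames
oracle_enumerate_orfs <- function(sequence, start_codons = "ATG") {
  n <- nchar(sequence)
  out <- list()
  for (p in 0:(n - 3L)) {
    codon <- substr(sequence, p + 1L, p + 3L)
    if (!codon %in% start_codons) next
    tr <- oracle_translate_from(sequence, p)
    out[[length(out) + 1L]] <- data.frame(
      tis = p, stop_position = tr$stop_position, complete = tr$complete,
      length_aa = tr$length_aa, peptide = tr$peptide,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Benjamini-Hochberg with explicit multiplicity m (>= length(p))
oracle_bh <- function(p, m = length(p)) {
  k <- length(p)
  o <- order(p)
  q_sorted <- numeric(k)
  running <- 1
  for (j in k:1) {
    running <- min(running, p[o[j]] * m / j)
    q_sorted[j] <- running
  }
  q <- numeric(k)
  q[o] <- q_sorted
  q
}

# P(X >= k) by pmf summation far into the tail
oracle_nb_tail <- function(k, mu, size) {
  if (k <= 0) return(1)
  sd_x <- sqrt(mu + if (is.finite(size)) mu^2 / size else 0)
  upper <- ceiling(k + mu + 200 * sd_x) + 5000L
  xs <- upper:k   # ascending magnitude of terms: sum smallest first
  if (is.finite(size)) {
    sum(dnbinom(xs, mu = mu, size = size))
  } else {
    sum(dpois(xs, lambda = mu))
  }
}
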