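#' Start-codon sets for candidate scanning
#'
#' `"near_cognate"` is ATG plus its nine single-substitution neighbours
#' (CTG, GTG, TTG, AAG, ACG, AGG, ATA, ATC, ATT) — near-cognate initiation is
#' common at upstream ORFs. `"atg"` restricts scanning to ATG.
#'
#' @param set `"near_cognate"` (default) or `"atg"`.
#' @return Character vector of codons.
#' @export
tis_codon_set <- function(set = c("near_cognate", "atg")) {
  set <- match.arg(set)
  if (set == "atg") return("ATG")
  neighbours <- unlist(lapply(1:3, function(i) {
    vapply(setdiff(BASES, substr("ATG", i, i)), function(b) {
      x <- "ATG"
      substr(x, i, i) <- b
      x
    }, character(1))
  }))
  unique(c("ATG", neighbours))
}

#' Scan P-site tracks for candidate initiation codons
#'
#' Scans every position of every transcript (all three frames) for codons in
#' `codon_set` whose P-site count summed over the codon's three nucleotides
#' reaches `min_count`. The 3-nt sum (not the first nucleotide alone)
#' tolerates +/-1 P-site jitter. The total number of codon-set positions
#' scanned is kept in the `n_scanned` attribute; it is the multiplicity used
#' by default for FDR control in [call_tis()].
#'
#' @param tracks `psite_tracks` from [psite_tracks()].
#' @param transcripts Transcript tibble (lengths must agree with the tracks).
#' @param codon_set Codons to scan (default [tis_codon_set()]).
#' @param min_count Minimum 3-nt P-site sum (default 5).
#' @return Tibble (`transcript_id`, `position`, `codon`, `psite_count`) with
#'   attribute `n_scanned`.
#' @export
find_tis_candidates <- function(tracks, transcripts,
                                codon_set = tis_codon_set(),
                                min_count = 5) {
  assert_columns(tracks, c("transcript_id", "track"), "tracks")
  seqs <- setNames(transcripts$sequence, transcripts$transcript_id)
  n_scanned <- 0L
  rows <- purrr::map(seq_len(nrow(tracks)), function(i) {
    id <- tracks$transcript_id[i]
    if (!id %in% names(seqs)) {
      abort(sprintf("track for unknown transcript %s", id))
    }
    s <- seqs[[id]]
    n <- nchar(s)
    tr <- tracks$track[[i]]
    if (length(tr) != n) {
      abort(sprintf("track length %d != sequence length %d for %s",
                    length(tr), n, id))
    }
    if (n < 3L) return(NULL)
    idx <- seq_len(n - 2L)
    codons <- substring(s, idx, idx + 2L)
    is_cand <- codons %in% codon_set
    n_scanned <<- n_scanned + sum(is_cand)
    csum <- tr[idx] + tr[idx + 1L] + tr[idx + 2L]
    sel <- is_cand & csum >= min_count
    if (!any(sel)) return(NULL)
    tibble(transcript_id = id, position = idx[sel] - 1L,
           codon = codons[sel], psite_count = as.integer(csum[sel]))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (!nrow(out)) {
    out <- tibble(transcript_id = character(), position = integer(),
                  codon = character(), psite_count = integer())
  }
  attr(out, "n_scanned") <- n_scanned
  out
}

#' Fit a per-transcript negative-binomial background
#'
#' Bins each track into consecutive codons (3-nt windows in frame 0),
#' excludes bins within `exclusion_radius` codons of any candidate codon, and
#' estimates the background mean per codon and the NB size parameter by the
#' method of moments (`size = mu^2 / (var - mu)`, floored at `min_dispersion`;
#' `var <= mu` falls back to Poisson, reported as `dispersion = Inf`).
#' Transcripts with fewer than `min_codons` background bins are skipped and
#' listed in the `skipped` attribute.
#'
#' @param tracks `psite_tracks`.
#' @param candidates Candidate tibble from [find_tis_candidates()] (may be
#'   empty).
#' @param exclusion_radius Codons excluded on each side of a candidate
#'   (default 1).
#' @param min_codons Minimum background bins per transcript (default 20).
#' @param min_dispersion Floor on the NB size parameter (default 0.1).
#' @return Tibble (`transcript_id`, `mu`, `dispersion`,
#'   `n_background_codons`) with attribute `skipped` (transcript ids).
#' @export
fit_nb_background <- function(tracks, candidates, exclusion_radius = 1,
                              min_codons = 20, min_dispersion = 0.1) {
  assert_columns(tracks, c("transcript_id", "track"), "tracks")
  cand_by_tx <- if (nrow(candidates)) {
    split(candidates$position, candidates$transcript_id)
  } else {
    list()
  }
  skipped <- character()
  rows <- purrr::map(seq_len(nrow(tracks)), function(i) {
    id <- tracks$transcript_id[i]
    tr <- tracks$track[[i]]
    n_bins <- length(tr) %/% 3L
    if (n_bins == 0L) {
      skipped <<- c(skipped, id)
      return(NULL)
    }
    starts <- 3L * (seq_len(n_bins) - 1L)
    bins <- tr[starts + 1L] + tr[starts + 2L] + tr[starts + 3L]
    cand <- cand_by_tx[[id]]
    if (!is.null(cand) && length(cand)) {
      r <- 3L * exclusion_radius
      lo <- rep(cand - r, each = 1L)
      hi <- cand + 2L + r
      excl <- vapply(seq_len(n_bins), function(b) {
        s <- starts[b]
        any(s + 2L >= lo & s <= hi)
      }, logical(1))
      bins <- bins[!excl]
    }
    if (length(bins) < min_codons) {
      skipped <<- c(skipped, id)
      return(NULL)
    }
    mu <- mean(bins)
    v <- var(bins)
    disp <- if (v <= mu) Inf else max(mu^2 / (v - mu), min_dispersion)
    tibble(transcript_id = id, mu = mu, dispersion = disp,
           n_background_codons = length(bins))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (!nrow(out)) {
    out <- tibble(transcript_id = character(), mu = numeric(),
                  dispersion = numeric(), n_background_codons = integer())
  }
  attr(out, "skipped") <- skipped
  out
}

#' Negative-binomial upper-tail p-value
#'
#' `P(X >= count)` for `X ~ NB(mu, size)` (variance `mu + mu^2/size`), the
#' survival function evaluated at `count - 1`; `size = Inf` gives the Poisson
#' limit. `count = 0` returns 1.
#'
#' @param count Observed count (vectorised).
#' @param mu Background mean.
#' @param size NB size (dispersion) parameter; `Inf` for Poisson.
#' @return p-values in `[0, 1]`.
#' @export
nb_tail_pvalue <- function(count, mu, size) {
  n <- max(length(count), length(mu), length(size))
  count <- rep_len(count, n); mu <- rep_len(mu, n); size <- rep_len(size, n)
  p <- numeric(n)
  pois <- !is.finite(size)
  if (any(pois)) {
    p[pois] <- ppois(count[pois] - 1, lambda = mu[pois], lower.tail = FALSE)
  }
  if (any(!pois)) {
    p[!pois] <- pnbinom(count[!pois] - 1, mu = mu[!pois], size = size[!pois],
                        lower.tail = FALSE)
  }
  p
}

#' Attach p-values to TIS candidates
#'
#' Joins each candidate to its transcript's fitted background and computes
#' the NB upper-tail p-value of the candidate's 3-nt P-site sum. Candidates
#' on transcripts without a fitted background are dropped and counted in the
#' `n_dropped_no_background` attribute.
#'
#' @param candidates Tibble from [find_tis_candidates()].
#' @param background Tibble from [fit_nb_background()].
#' @return Candidates with `mu`, `dispersion`, `p_value` columns.
#' @export
test_tis_candidates <- function(candidates, background) {
  assert_columns(candidates, c("transcript_id", "position", "psite_count"),
                 "candidates")
  assert_columns(background, c("transcript_id", "mu", "dispersion"),
                 "background")
  n_scanned <- attr(candidates, "n_scanned")
  out <- dplyr::inner_join(
    candidates,
    dplyr::select(background, "transcript_id", "mu", "dispersion"),
    by = "transcript_id")
  out$p_value <- nb_tail_pvalue(out$psite_count, out$mu, out$dispersion)
  attr(out, "n_scanned") <- n_scanned
  attr(out, "n_dropped_no_background") <- nrow(candidates) - nrow(out)
  out
}

#' Call significant translation initiation sites
#'
#' Runs the full caller on P-site tracks: candidate scan
#' ([find_tis_candidates()]), per-transcript NB background
#' ([fit_nb_background()]), upper-tail test ([test_tis_candidates()]), and
#' Benjamini-Hochberg correction across the whole sample; a site is
#' significant when `q_value < alpha`.
#'
#' By default the BH multiplicity is the number of codon-set positions
#' scanned (`mt_scope = "scanned"`): positions below `min_count` are treated
#' as tests with p = 1, so the count prefilter only prunes hopeless tests and
#' cannot inflate the false discovery rate. `mt_scope = "candidates"`
#' restricts the multiplicity to the prefiltered candidates.
#'
#' @param tracks `psite_tracks`.
#' @param transcripts Transcript tibble.
#' @param codon_set Codons scanned (default [tis_codon_set()]).
#' @param min_count Candidate prefilter on the 3-nt P-site sum (default 5).
#' @param alpha FDR level (default 0.05).
#' @param exclusion_radius,min_codons,min_dispersion Background-fit
#'   parameters, see [fit_nb_background()].
#' @param mt_scope `"scanned"` (default) or `"candidates"`; see Details.
#' @return Tibble of class `tis_calls` (`transcript_id`, `position`,
#'   `codon`, `psite_count`, `mu`, `dispersion`, `p_value`, `q_value`,
#'   `significant`) with attributes `alpha`, `n_scanned`, `n_candidates`,
#'   `skipped_transcripts`.
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_coding_transcripts = 5, seed = 1))
#' fp <- simulate_footprints(sim)
#' tr <- psite_tracks(fp, sim$transcripts,
#'                    tibble::tibble(read_length = c(28, 29, 30),
#'                                   offset = c(12, 12, 13)))
#' calls <- call_tis(tr, sim$transcripts)
#' glance(calls)
#' @export
call_tis <- function(tracks, transcripts, codon_set = tis_codon_set(),
                     min_count = 5, alpha = 0.05, exclusion_radius = 1,
                     min_codons = 20, min_dispersion = 0.1,
                     mt_scope = c("scanned", "candidates")) {
  mt_scope <- match.arg(mt_scope)
  candidates <- find_tis_candidates(tracks, transcripts,
                                    codon_set = codon_set,
                                    min_count = min_count)
  background <- fit_nb_background(tracks, candidates,
                                  exclusion_radius = exclusion_radius,
                                  min_codons = min_codons,
                                  min_dispersion = min_dispersion)
  tested <- test_tis_candidates(candidates, background)
  m <- if (mt_scope == "scanned") {
    max(attr(candidates, "n_scanned"), nrow(tested))
  } else {
    nrow(tested)
  }
  tested$q_value <- if (nrow(tested)) {
    p.adjust(tested$p_value, method = "BH", n = m)
  } else {
    numeric()
  }
  tested$significant <- tested$q_value < alpha
  out <- as_tibble(tested)
  class(out) <- c("tis_calls", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_scanned") <- attr(candidates, "n_scanned")
  attr(out, "n_candidates") <- nrow(candidates)
  attr(out, "skipped_transcripts") <- attr(background, "skipped")
  out
}

#' @method tidy tis_calls
#' @export
tidy.tis_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tis_calls")
  out
}

#' @method glance tis_calls
#' @export
glance.tis_calls <- function(x, ...) {
  tibble(
    n_scanned = attr(x, "n_scanned") %||% NA_integer_,
    n_candidates = attr(x, "n_candidates") %||% nrow(x),
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% NA_real_,
    n_skipped_transcripts = length(attr(x, "skipped_transcripts"))
  )
}
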