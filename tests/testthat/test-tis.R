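test_that("near-cognate codon set is ATG plus all single substitutions", {
  set <- tis_codon_set("near_cognate")
  expect_length(set, 10)
  hamming1 <- vapply(set, function(x) {
    sum(strsplit(x, "")[[1]] != c("A", "T", "G"))
  }, numeric(1))
  expect_true(all(hamming1 <= 1))
  expect_identical(tis_codon_set("atg"), "ATG")
})

test_that("candidate scan equals an exhaustive 3-mer scan", {
  sim <- simulate_transcriptome(tiny_sim_config(seed = 8))
  fp <- simulate_footprints(sim)
  offs <- tibble::tibble(read_length = c(28L, 29L, 30L),
                         offset = c(12L, 12L, 13L))
  tr <- psite_tracks(fp, sim$transcripts, offs)
  set <- tis_codon_set()
  cand <- find_tis_candidates(tr, sim$transcripts, codon_set = set,
                              min_count = 5)
  for (i in seq_len(nrow(sim$transcripts))) {
    s <- sim$transcripts$sequence[i]
    trk <- tr$track[[i]]
    expected <- integer()
    for (p in 0:(nchar(s) - 3)) {
      if (substr(s, p + 1, p + 3) %in% set &&
          sum(trk[(p + 1):(p + 3)]) >= 5) {
        expected <- c(expected, p)
      }
    }
    got <- sort(cand$position[cand$transcript_id ==
                                sim$transcripts$transcript_id[i]])
    expect_equal(got, expected)
  }
})

test_that("degenerate candidate scans return empty sets", {
  tx <- toy_transcript()
  tr <- toy_track(tx)
  expect_equal(nrow(find_tis_candidates(tr, tx)), 0)
  # transcript without any ATG, scanned for ATG only
  tx2 <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                        biotype = "lncRNA",
                        sequence = strrep("C", 60),
                        cds_start = NA_integer_, cds_end = NA_integer_)
  tr2 <- toy_track(tx2, list(T1 = list(`10` = 50L)))
  expect_equal(nrow(find_tis_candidates(tr2, tx2, codon_set = "ATG")), 0)
})

test_that("background fit matches direct moment recomputation", {
  tx <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                       biotype = "lncRNA", sequence = strrep("C", 300),
                       cds_start = NA_integer_, cds_end = NA_integer_)
  withr::with_seed(42, {
    counts <- rnbinom(300, mu = 2, size = 1)
    tr <- toy_track(tx)
    tr$track[[1]] <- as.integer(counts)
    none <- tibble::tibble(transcript_id = character(), position = integer(),
                           codon = character(), psite_count = integer())
    bg <- fit_nb_background(tr, none)
    bins <- sapply(seq_len(100), function(b) {
      sum(counts[(3 * (b - 1) + 1):(3 * b)])
    })
    expect_equal(bg$mu, mean(bins))
    expect_equal(bg$dispersion, mean(bins)^2 / (var(bins) - mean(bins)))
    expect_equal(bg$n_background_codons, 100L)
  })
  # constant track -> Poisson limit with mu = 3c
  trc <- toy_track(tx)
  trc$track[[1]] <- rep(2L, 300)
  bgc <- fit_nb_background(trc, tibble::tibble(transcript_id = character(),
                                               position = integer(),
                                               codon = character(),
                                               psite_count = integer()))
  expect_equal(bgc$mu, 6)
  expect_equal(bgc$dispersion, Inf)
  # candidate exclusion removes the candidate codon and its neighbours
  cand <- tibble::tibble(transcript_id = "T1", position = 30L,
                         codon = "ATG", psite_count = 50L)
  bg2 <- fit_nb_background(trc, cand, exclusion_radius = 1)
  expect_equal(bg2$n_background_codons, 97L)
  # short transcripts are skipped, not fitted
  short <- toy_track(tibble::tibble(
    transcript_id = "S", gene_id = "S", biotype = "lncRNA",
    sequence = strrep("C", 30), cds_start = NA_integer_,
    cds_end = NA_integer_))
  bg3 <- fit_nb_background(short, cand[0, ], min_codons = 20)
  expect_equal(nrow(bg3), 0)
  expect_equal(attr(bg3, "skipped"), "S")
})

test_that("NB tail p-values match brute-force pmf summation", {
  for (mu in c(0.2, 2, 15)) {
    for (size in c(0.1, 1, 10, Inf)) {
      for (k in c(0L, 1L, 4L, 30L)) {
        expect_lt(abs(nb_tail_pvalue(k, mu, size) -
                        oracle_nb_tail(k, mu, size)), 1e-9)
      }
    }
  }
  expect_equal(nb_tail_pvalue(0, 5, 1), 1)
  # monotone non-increasing in the observed count
  p <- nb_tail_pvalue(0:50, mu = 3, size = 0.7)
  expect_true(all(diff(p) <= 0))
})

test_that("q-values match an independent BH oracle at the scanned multiplicity", {
  sim <- simulate_transcriptome(tiny_sim_config(seed = 14))
  fp <- simulate_footprints(sim)
  offs <- tibble::tibble(read_length = c(28L, 29L, 30L),
                         offset = c(12L, 12L, 13L))
  tr <- psite_tracks(fp, sim$transcripts, offs)
  calls <- call_tis(tr, sim$transcripts)
  m <- attr(calls, "n_scanned")
  expect_gte(m, nrow(calls))
  expect_equal(calls$q_value, oracle_bh(calls$p_value, m))
  expect_identical(calls$significant, calls$q_value < 0.05)
})

test_that("with candidate-scoped multiplicity a lone candidate keeps q = p", {
  tx <- toy_transcript()
  tr <- toy_track(tx, list(T1 = list(`12` = 30L)))
  calls <- call_tis(tr, tx, min_codons = 5, mt_scope = "candidates")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$q_value, calls$p_value)
})
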