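make_call <- function(gene, peptide, transcript = "T1", tis = 0L,
                      significant = TRUE) {
  tibble::tibble(transcript_id = transcript, gene_id = gene,
                 tis_position = tis, stop_position = 3L * nchar(peptide),
                 length_aa = nchar(peptide), peptide = peptide,
                 complete = TRUE, significant = significant)
}

test_that("peptide containment detects epitopes within called ORFs only", {
  catalog <- tibble::tibble(antigen_id = "A1", epitope = "MLKTEAPQW",
                            gene_id = "G1", transcript_id = "T1",
                            expected_tis = 30L, class_label = "upstream")
  hit <- make_call("G1", "MLKTEAPQWVVRRR")
  expect_true(match_antigens(catalog, hit)$detected)
  # empty call set
  expect_false(match_antigens(catalog, hit[0, ])$detected)
  # same peptide but not significant
  expect_false(match_antigens(catalog,
                              make_call("G1", "MLKTEAPQWVVRRR",
                                        significant = FALSE))$detected)
  # epitope on a different gene does not count
  expect_false(match_antigens(catalog,
                              make_call("G2", "MLKTEAPQWVVRRR"))$detected)
})

test_that("an epitope encoded in an uncalled frame is not detected", {
  # plant epitope-coding codons in frame 1 of a transcript; the only call is
  # the frame-0 ORF, whose peptide does not contain the epitope
  epi <- "KLYQSVTML"
  codons <- c(K = "AAA", L = "CTG", Y = "TAT", Q = "CAA", S = "TCT",
              V = "GTT", T = "ACT", M = "ATG")
  epi_nt <- paste(vapply(strsplit(epi, "")[[1]],
                         function(a) codons[[a]], character(1)),
                  collapse = "")
  seq <- paste0("C", "ATG", epi_nt, "TGACC",
                "G", "ATGGGGCCCGGG", "TAA")
  # frame-1 ORF at position 1 encodes M + the epitope tail
  o1 <- oracle_translate_from(seq, 1L)
  expect_true(grepl(substr(epi, 2, 9), o1$peptide, fixed = TRUE))
  tx <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                       biotype = "lncRNA", sequence = seq,
                       cds_start = NA_integer_, cds_end = NA_integer_)
  catalog <- tibble::tibble(antigen_id = "A1",
                            epitope = substr(o1$peptide, 1, 9),
                            gene_id = "G1", transcript_id = "T1",
                            expected_tis = 1L, class_label = "out_of_frame")
  # the only significant TIS is the second ORF's (peptide MGPG)
  other <- build_orfs(tibble::tibble(transcript_id = "T1", position = 37L),
                      tx, significant_only = FALSE)
  other$gene_id <- "G1"
  other$significant <- TRUE
  expect_false(match_antigens(catalog, other)$detected)
  # whereas a call at the expected frame-1 TIS detects it
  right <- build_orfs(tibble::tibble(transcript_id = "T1", position = 1L),
                      tx, significant_only = FALSE)
  right$significant <- TRUE
  expect_true(match_antigens(catalog, right)$detected)
})

test_that("exact-TIS mode demands the annotated position", {
  catalog <- tibble::tibble(antigen_id = "A1", epitope = "MAAAAAAAA",
                            gene_id = "G1", transcript_id = "T1",
                            expected_tis = 30L, class_label = "annotated")
  calls <- make_call("G1", strrep("A", 12), tis = 30L)
  expect_true(match_antigens(catalog, calls, mode = "exact_tis")$detected)
  expect_false(match_antigens(catalog,
                              make_call("G1", strrep("A", 12), tis = 33L),
                              mode = "exact_tis")$detected)
  expect_true(match_antigens(catalog,
                             make_call("G1", strrep("A", 12), tis = 33L),
                             mode = "exact_tis",
                             tis_tolerance = 3)$detected)
  catalog$expected_tis <- NA_integer_
  expect_error(match_antigens(catalog, calls, mode = "exact_tis"),
               "expected_tis")
})

test_that("exact-TIS detections are a subset of peptide containment on simulated data", {
  sim <- simulate_transcriptome(tiny_sim_config(seed = 23))
  catalog <- plant_antigens(sim, class_mix = c(annotated = 4, upstream = 2),
                            epitope_offset = 0, seed = 2)
  calls <- build_orfs(
    tibble::tibble(transcript_id = sim$planted$transcript_id,
                   position = sim$planted$tis),
    sim$transcripts, significant_only = FALSE) |>
    dplyr::mutate(significant = TRUE)
  by_tis <- match_antigens(catalog, calls, mode = "exact_tis")$detected
  by_pep <- match_antigens(catalog, calls)$detected
  expect_true(all(!by_tis | by_pep))
  expect_true(all(by_pep))
})

test_that("detection matrices collapse to ORF level, gate on presence and recount", {
  catalog <- tibble::tibble(
    antigen_id = c("A1", "A2", "A3"),
    orf_id = c("O1", "O1", "O2"),       # two epitopes from one ORF
    epitope = c("MKKKKKKKK", "KKKKKKKKW", "MRERERERE"),
    gene_id = c("G1", "G1", "G2"),
    transcript_id = "T1", expected_tis = 0L,
    class_label = c("annotated", "annotated", "upstream"))
  s1 <- make_call("G1", "MKKKKKKKKW")      # matches A1 and A2 -> O1
  s2 <- make_call("G1", "MKKKKKKKKC")      # matches A1 only -> O1
  s3 <- make_call("G3", "MMMMMMMMMM")      # matches nothing
  dm <- detection_matrix(catalog, list(s1 = s1, s2 = s2, s3 = s3))
  d <- tidy(dm)
  expect_equal(nrow(d), 6)  # 2 ORFs x 3 samples
  o1 <- dplyr::filter(d, orf_id == "O1")
  expect_equal(sum(o1$detected), 2)
  expect_equal(sum(dplyr::filter(d, orf_id == "O2")$detected), 0)
  # independent per-sample recount
  for (sid in c("s1", "s2", "s3")) {
    calls <- list(s1 = s1, s2 = s2, s3 = s3)[[sid]]
    for (orf in c("O1", "O2")) {
      eps <- catalog$epitope[catalog$orf_id == orf]
      genes <- catalog$gene_id[catalog$orf_id == orf]
      manual <- any(mapply(function(e, g) {
        any(grepl(e, calls$peptide[calls$gene_id == g], fixed = TRUE))
      }, eps, genes))
      expect_equal(d$detected[d$orf_id == orf & d$sample_id == sid], manual)
    }
  }
  # presence gating
  presence <- tibble::tibble(orf_id = "O1", sample_id = "s1",
                             present = FALSE)
  dm2 <- detection_matrix(catalog, list(s1 = s1, s2 = s2, s3 = s3),
                          presence = presence)
  d2 <- tidy(dm2)
  expect_false(d2$detected[d2$orf_id == "O1" & d2$sample_id == "s1"])
  expect_true(d2$detected[d2$orf_id == "O1" & d2$sample_id == "s2"])
  expect_true(all(!d2$detected | d2$present))
  # constructing a matrix that violates presence gating fails
  bad <- d2
  bad$present[bad$orf_id == "O1" & bad$sample_id == "s2"] <- FALSE
  expect_error(as_detection_matrix(bad), "implies presence")
  expect_equal(glance(dm)$n_orfs, 2)
})
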