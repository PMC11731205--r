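test_that("generation is a pure function of the seed and honors architecture", {
  cfg <- tiny_sim_config(seed = 7)
  sim1 <- simulate_transcriptome(cfg)
  sim2 <- simulate_transcriptome(cfg)
  expect_identical(sim1, sim2)
  fp1 <- simulate_footprints(sim1)
  fp2 <- simulate_footprints(sim2)
  expect_identical(fp1, fp2)

  # CDS starts with ATG and ends at a stop, lengths divisible by 3
  coding <- dplyr::filter(sim1$transcripts, biotype == "coding")
  expect_true(all((coding$cds_end - coding$cds_start) %% 3 == 0))
  expect_true(all(substr(coding$sequence, coding$cds_start + 1,
                         coding$cds_start + 3) == "ATG"))
  expect_true(all(substr(coding$sequence, coding$cds_end - 2,
                         coding$cds_end) %in% c("TAA", "TAG", "TGA")))

  # zero-length 5' UTR forces cds_start 0
  cfg0 <- sim_config(n_coding_transcripts = 3, n_lncrna_transcripts = 0,
                     utr5_length_range = c(0, 0),
                     planted_orf_mix = c(internal_in_frame = 1), seed = 1)
  sim0 <- simulate_transcriptome(cfg0)
  expect_true(all(sim0$transcripts$cds_start == 0))

  # no coding transcripts -> pure lncRNA set without CDS
  cfgl <- sim_config(n_coding_transcripts = 0, n_lncrna_transcripts = 4,
                     planted_orf_mix = c(lncRNA = 1), seed = 2)
  siml <- simulate_transcriptome(cfgl)
  expect_true(all(siml$transcripts$biotype == "lncRNA"))
  expect_true(all(is.na(siml$transcripts$cds_start)))
  expect_true(all(siml$planted$class == "lncRNA"))
})

test_that("planted TISs re-translate to the recorded peptide and stop", {
  sim <- simulate_transcriptome(tiny_sim_config(seed = 11))
  for (i in seq_len(nrow(sim$planted))) {
    pl <- sim$planted[i, ]
    seq <- sim$transcripts$sequence[
      sim$transcripts$transcript_id == pl$transcript_id]
    o <- oracle_translate_from(seq, pl$tis)
    expect_identical(o$peptide, pl$peptide)
    expect_identical(o$length_aa, pl$length_aa)
    expect_identical(o$complete, pl$complete)
    if (pl$complete) expect_identical(o$stop_position, pl$stop_position)
  }
  # frame law for internal plants
  cds <- sim$transcripts$cds_start[match(sim$planted$transcript_id,
                                         sim$transcripts$transcript_id)]
  frame <- (sim$planted$tis - cds) %% 3
  expect_true(all(frame[sim$planted$class == "internal_in_frame"] == 0))
  expect_true(all(frame[sim$planted$class == "internal_out_of_frame"] != 0))
})

test_that("infeasible configurations fail with the violated constraint named", {
  expect_error(sim_config(utr5_length_range = c(6, 9),
                          planted_orf_mix = c(upstream = 1)),
               "utr5_length_range")
  expect_error(sim_config(planted_orf_mix = c(nonsense = 1)), "unknown class")
  expect_error(sim_config(initiation_enrichment = 0.5), "initiation_enrichment")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(read_length_weights = c(`33` = 1)),
               "offset_map is missing")
})

test_that("antigen epitopes are in-frame substrings of oracle peptides", {
  sim <- simulate_transcriptome(tiny_sim_config(seed = 3))
  cat <- plant_antigens(sim, class_mix = c(annotated = 3, upstream = 2,
                                           internal_out_of_frame = 2,
                                           lncRNA = 1),
                        seed = 5)
  expect_equal(nrow(cat), 8)
  expect_true(all(nchar(cat$epitope) == 9))
  for (i in seq_len(nrow(cat))) {
    seq <- sim$transcripts$sequence[
      sim$transcripts$transcript_id == cat$transcript_id[i]]
    o <- oracle_translate_from(seq, cat$expected_tis[i])
    expect_true(grepl(cat$epitope[i], o$peptide, fixed = TRUE))
  }
  # offset 0 pins the epitope to the first residues of the peptide
  cat0 <- plant_antigens(sim, class_mix = c(upstream = 2), epitope_offset = 0,
                         seed = 5)
  pl <- sim$planted[match(paste0(cat0$transcript_id, ":", cat0$expected_tis),
                          paste0(sim$planted$transcript_id, ":",
                                 sim$planted$tis)), ]
  expect_identical(cat0$epitope, substr(pl$peptide, 1, 9))
  # catalog labels follow antigen nomenclature
  expect_true(all(cat$class_label %in%
                    c("annotated", "out_of_frame", "upstream",
                      "alternative", "lncRNA")))
  expect_identical(cat$class_label[cat$truth_class == "internal_out_of_frame"],
                   rep("out_of_frame",
                       sum(cat$truth_class == "internal_out_of_frame")))
  # over-requesting a class fails
  expect_error(plant_antigens(sim, class_mix = c(annotated = 100)),
               "more ORFs than planted")
  lnc <- simulate_transcriptome(
    sim_config(n_coding_transcripts = 0, n_lncrna_transcripts = 2,
               planted_orf_mix = c(lncRNA = 1), seed = 1))
  expect_error(plant_antigens(lnc, class_mix = c(annotated = 1)),
               "annotated")
})

test_that("footprint counts follow the configured background mean", {
  # equal expression across transcripts so every position shares one mean
  cfg <- sim_config(n_coding_transcripts = 12, n_lncrna_transcripts = 0,
                    initiation_enrichment = 1, expression_log10_sd = 0,
                    total_reads = 6e4, seed = 9)
  sim <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(sim)
  offs <- tibble::tibble(read_length = as.integer(names(cfg$offset_map)),
                         offset = as.integer(cfg$offset_map))
  tr <- psite_tracks(fp, sim$transcripts, offs)
  # under enrichment 1 every position shares one mean; edge losses trim a few
  # reads so compare interior positions only
  counts <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    n <- tr$length[i]
    tr$track[[i]][20:(n - 35)]
  }))
  mu <- cfg$total_reads / sum(nchar(sim$transcripts$sequence))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # overdispersion consistent with NB(mu, size): var/mu ~ 1 + mu/size
  expect_gt(var(counts) / mean(counts), 1 + 0.5 * mu / cfg$nb_dispersion)
  expect_lt(var(counts) / mean(counts), 1 + 2.0 * mu / cfg$nb_dispersion)
})

test_that("zero background concentrates all P-sites on active TIS codons", {
  cfg <- sim_config(n_coding_transcripts = 4, n_lncrna_transcripts = 0,
                    background_scale = 0, total_reads = 5e3, seed = 13)
  sim <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(sim)
  expect_gt(nrow(fp), 0)
  offs <- cfg$offset_map[as.character(fp$read_length)]
  psite <- fp$five_prime_pos + as.integer(offs)
  tis_nt <- unlist(lapply(seq_len(nrow(sim$planted)), function(i) {
    paste0(sim$planted$transcript_id[i], ":", sim$planted$tis[i] + 0:2)
  }))
  expect_true(all(paste0(fp$transcript_id, ":", psite) %in% tis_nt))
})
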