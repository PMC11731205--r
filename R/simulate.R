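#' Simulation configuration
#'
#' Bundles every knob of the synthetic ribosome-profiling study: transcript
#' architecture, the mix of planted ORF classes, expression spread, the
#' strength of initiation-site enrichment produced by harringtonine arrest,
#' the negative-binomial noise model, and the footprint geometry
#' (read-length distribution and per-length P-site offsets).
#'
#' The count model at a transcript position with mean `mu` is
#' NB with variance `mu + mu^2 / nb_dispersion`; positions covered by an
#' active initiation codon have their mean multiplied by
#' `initiation_enrichment`. Expression is log10-normal, spanning roughly
#' 0.1--1000 RPKM at the defaults. Footprint 5' ends sit `offset_map[length]`
#' nucleotides upstream of the P-site.
#'
#' @param n_coding_transcripts,n_lncrna_transcripts Transcript counts.
#' @param utr5_length_range,cds_length_range,utr3_length_range Integer
#'   `c(min, max)` nucleotide ranges; CDS lengths are drawn as multiples of 3.
#' @param planted_orf_mix Named counts of non-annotated ORFs planted per
#'   transcript; names among `upstream`, `internal_in_frame`,
#'   `internal_out_of_frame`, `downstream` (coding transcripts) and `lncRNA`
#'   (per lncRNA transcript). The annotated CDS start is always recorded.
#' @param expression_log10_mean,expression_log10_sd Per-gene log10 RPKM
#'   distribution.
#' @param initiation_enrichment Fold increase of the P-site mean on the three
#'   nucleotides of an active initiation codon relative to background
#'   (`>= 1`; `1` means no initiation signal).
#' @param background_scale Multiplier on the elongation background, modelling
#'   harringtonine run-off as a uniform down-scaling (0 removes background).
#' @param nb_dispersion NB size parameter (`variance = mu + mu^2/dispersion`);
#'   `Inf` gives Poisson counts.
#' @param offset_map Named integer vector, read length -> P-site offset (nt).
#' @param read_length_weights Named sampling weights over read lengths; every
#'   name must appear in `offset_map`.
#' @param total_reads Expected total footprints per sample.
#' @param start_codons Codons used for planted non-annotated ORFs; default
#'   `"ATG"`. Include near-cognates (single substitutions of ATG) to stress
#'   the caller's codon filter.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `sim_config`.
#' @seealso [simulate_transcriptome()], [simulate_footprints()]
#' @export
sim_config <- function(n_coding_transcripts = 30,
                       n_lncrna_transcripts = 5,
                       utr5_length_range = c(90, 240),
                       cds_length_range = c(300, 900),
                       utr3_length_range = c(60, 200),
                       planted_orf_mix = c(upstream = 1,
                                           internal_in_frame = 1,
                                           internal_out_of_frame = 1,
                                           downstream = 1,
                                           lncRNA = 1),
                       expression_log10_mean = 1,
                       expression_log10_sd = 1,
                       initiation_enrichment = 50,
                       background_scale = 1,
                       nb_dispersion = 2,
                       offset_map = c(`28` = 12L, `29` = 12L, `30` = 13L),
                       read_length_weights = c(`28` = 0.35, `29` = 0.40,
                                               `30` = 0.25),
                       total_reads = 2e5,
                       start_codons = "ATG",
                       seed = 1L) {
  cfg <- list(
    n_coding_transcripts = as.integer(n_coding_transcripts),
    n_lncrna_transcripts = as.integer(n_lncrna_transcripts),
    utr5_length_range = as.integer(utr5_length_range),
    cds_length_range = as.integer(cds_length_range),
    utr3_length_range = as.integer(utr3_length_range),
    planted_orf_mix = planted_orf_mix,
    expression_log10_mean = expression_log10_mean,
    expression_log10_sd = expression_log10_sd,
    initiation_enrichment = initiation_enrichment,
    background_scale = background_scale,
    nb_dispersion = nb_dispersion,
    offset_map = setNames(as.integer(offset_map), names(offset_map)),
    read_length_weights = read_length_weights,
    total_reads = total_reads,
    start_codons = toupper(start_codons),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

mix_get <- function(mix, key) {
  if (key %in% names(mix)) mix[[key]] else 0
}

validate_sim_config <- function(cfg) {
  for (fld in c("utr5_length_range", "cds_length_range", "utr3_length_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || any(r < 0) || r[2] < r[1]) {
      abort(sprintf("%s must be a non-negative c(min, max) interval", fld))
    }
  }
  if (cfg$cds_length_range[2] < 9L) {
    abort("cds_length_range must allow a CDS of at least 9 nt (start + codon + stop)")
  }
  if (!any(seq(cfg$cds_length_range[1], cfg$cds_length_range[2]) %% 3L == 0)) {
    abort("cds_length_range contains no multiple of 3")
  }
  if (cfg$initiation_enrichment < 1) {
    abort("initiation_enrichment must be >= 1")
  }
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (cfg$background_scale < 0) abort("background_scale must be >= 0")
  mix <- cfg$planted_orf_mix
  bad <- setdiff(names(mix), setdiff(ORF_CLASSES, "annotated"))
  if (length(bad)) {
    abort(sprintf("planted_orf_mix has unknown class(es): %s",
                  paste(bad, collapse = ", ")))
  }
  n_up <- mix_get(mix, "upstream")
  if (n_up > 0 && cfg$utr5_length_range[2] < 15L * n_up) {
    abort(sprintf(
      "utr5_length_range too short for %d upstream ORF(s): needs >= %d nt (constraint: 3*(min_len_aa+1) per uORF, min_len_aa = 4)",
      n_up, 15L * n_up))
  }
  n_int <- (mix_get(mix, "internal_in_frame")) +
    (mix_get(mix, "internal_out_of_frame"))
  if (n_int > 0 && cfg$cds_length_range[1] < 3L * (n_int + 4L)) {
    abort("cds_length_range too short for the requested internal ORFs")
  }
  if ((mix_get(mix, "downstream")) > 0 && cfg$utr3_length_range[2] < 3L) {
    abort("utr3_length_range too short for a downstream ORF start codon")
  }
  bad_codon <- setdiff(cfg$start_codons, SENSE_CODONS)
  if (length(bad_codon)) {
    abort(sprintf("start_codons must be sense codons; got: %s",
                  paste(bad_codon, collapse = ", ")))
  }
  missing_off <- setdiff(names(cfg$read_length_weights), names(cfg$offset_map))
  if (length(missing_off)) {
    abort(sprintf("offset_map is missing read length(s): %s",
                  paste(missing_off, collapse = ", ")))
  }
  invisible(cfg)
}

# draw a sense codon string of n codons (no in-frame stops)
sense_codon_string <- function(n) {
  if (n <= 0L) return("")
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

pick_free <- function(candidates, occupied, span) {
  # candidates: vector of 0-based start positions; occupied: 2-col matrix of
  # [start, end) intervals; returns one position whose [p, p+span) is free
  if (!length(candidates)) return(NA_integer_)
  free <- vapply(candidates, function(p) {
    !nrow(occupied) || all(p + span <= occupied[, 1] | p >= occupied[, 2])
  }, logical(1))
  if (!any(free)) return(NA_integer_)
  cand <- candidates[free]
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

#' Generate a synthetic transcriptome with planted ORFs
#'
#' Builds coding transcripts (random 5'UTR, ATG-initiated CDS with a terminal
#' stop, random 3'UTR) and lncRNA transcripts, planting ORFs of every
#' requested class at recorded positions: upstream ORFs wholly within the
#' 5'UTR, internal in/out-of-frame starts inside the CDS, downstream ORFs in
#' the 3'UTR, and free-standing ORFs on lncRNAs. Ground truth records each
#' planted initiation site with the peptide and stop actually encoded by the
#' final sequence, plus log10-normal per-gene expression.
#'
#' @param config A [sim_config()].
#' @return A list of class `ribotis_sim` with elements
#'   * `transcripts`: tibble (`transcript_id`, `gene_id`, `biotype`,
#'     `sequence`, `cds_start`, `cds_end`), 0-based half-open coordinates;
#'   * `planted`: tibble of planted initiation sites (`transcript_id`,
#'     `gene_id`, `class`, `tis`, `stop_position`, `complete`, `length_aa`,
#'     `peptide`);
#'   * `expression`: tibble (`gene_id`, `rpkm`).
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_coding_transcripts = 2, seed = 7))
#' sim$planted
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_transcriptome_impl(config))
}

generate_transcriptome_impl <- function(config) {
  mix <- config$planted_orf_mix
  n_coding <- config$n_coding_transcripts
  n_lnc <- config$n_lncrna_transcripts
  recs <- vector("list", n_coding + n_lnc)
  plants <- vector("list", n_coding + n_lnc)

  for (i in seq_len(n_coding)) {
    id <- sprintf("TX%04d", i)
    gene <- sprintf("GENE%04d", i)
    u5 <- sample_len(config$utr5_length_range)
    cds_len <- sample_len(config$cds_length_range, 3L)
    u3 <- sample_len(config$utr3_length_range)
    m <- cds_len %/% 3L   # codons incl. start and stop
    seq_chr <- paste0(
      paste(random_bases(u5), collapse = ""),
      "ATG", sense_codon_string(m - 2L), sample(STOP_CODONS, 1L),
      paste(random_bases(u3), collapse = "")
    )
    bases <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
    len <- length(bases)
    cds_start <- u5
    cds_end <- u5 + cds_len
    # protect annotated start and stop codons from being overwritten
    occupied <- rbind(c(cds_start, cds_start + 3L),
                      c(cds_end - 3L, cds_end))
    tis_rows <- list(tibble(transcript_id = id, gene_id = gene,
                            class = "annotated", tis = cds_start))

    plant_mini_orf <- function(lo, hi, class) {
      # full mini-ORF (start + sense body + stop) within [lo, hi)
      max_aa <- (hi - lo) %/% 3L - 1L
      if (max_aa < 4L) {
        abort(sprintf("%s region too short to plant a %s ORF on %s",
                      if (class == "upstream") "5' UTR" else "region",
                      class, id))
      }
      len_aa <- sample(4:min(25L, max_aa), 1L)
      span <- 3L * (len_aa + 1L)
      p <- pick_free(lo:(hi - span), occupied, span)
      if (is.na(p)) {
        abort(sprintf("no room to plant a %s ORF on %s (constraint: region %d-%d occupied)",
                      class, id, lo, hi))
      }
      body <- strsplit(paste0(sample(config$start_codons, 1L),
                              sense_codon_string(len_aa - 1L),
                              sample(STOP_CODONS, 1L)), "", fixed = TRUE)[[1]]
      bases[(p + 1L):(p + span)] <<- body
      occupied <<- rbind(occupied, c(p, p + span))
      tis_rows[[length(tis_rows) + 1L]] <<-
        tibble(transcript_id = id, gene_id = gene, class = class, tis = p)
    }

    for (j in seq_len(mix_get(mix, "upstream"))) {
      plant_mini_orf(0L, cds_start, "upstream")
    }
    for (j in seq_len(mix_get(mix, "internal_in_frame"))) {
      ks <- setdiff(seq_len(m - 2L), 0L)  # sense codon indices 1..m-2
      pos <- cds_start + 3L * ks
      p <- pick_free(pos, occupied, 3L)
      if (is.na(p)) abort(sprintf("no room for internal_in_frame ORF on %s", id))
      bases[(p + 1L):(p + 3L)] <-
        strsplit(sample(config$start_codons, 1L), "", fixed = TRUE)[[1]]
      occupied <- rbind(occupied, c(p, p + 3L))
      tis_rows[[length(tis_rows) + 1L]] <-
        tibble(transcript_id = id, gene_id = gene,
               class = "internal_in_frame", tis = p)
    }
    for (j in seq_len(mix_get(mix, "internal_out_of_frame"))) {
      planted <- FALSE
      for (attempt in 1:100) {
        f <- sample(1:2, 1L)
        k <- sample(seq_len(m - 3L), 1L)
        p <- cds_start + 3L * k + f
        if (p + 3L > cds_end - 3L) next
        if (nrow(occupied) &&
            any(p + 3L > occupied[, 1] & p < occupied[, 2])) next
        old <- bases[(p + 1L):(p + 3L)]
        bases[(p + 1L):(p + 3L)] <-
          strsplit(sample(config$start_codons, 1L), "", fixed = TRUE)[[1]]
        # the write straddles two CDS codons; reject if it creates an
        # in-frame stop that would truncate the annotated protein
        touched <- cds_start + 3L * (k + 0:1)
        cods <- substr(paste(bases, collapse = ""), touched + 1L, touched + 3L)
        if (any(cods %in% STOP_CODONS)) {
          bases[(p + 1L):(p + 3L)] <- old
          next
        }
        occupied <- rbind(occupied, c(p, p + 3L))
        tis_rows[[length(tis_rows) + 1L]] <-
          tibble(transcript_id = id, gene_id = gene,
                 class = "internal_out_of_frame", tis = p)
        planted <- TRUE
        break
      }
      if (!planted) {
        abort(sprintf("could not plant internal_out_of_frame ORF on %s after 100 placements", id))
      }
    }
    for (j in seq_len(mix_get(mix, "downstream"))) {
      if (u3 >= 15L) {
        plant_mini_orf(cds_end, len, "downstream")
      } else {
        p <- pick_free(cds_end:(len - 3L), occupied, 3L)
        if (is.na(p)) abort(sprintf("no room for downstream ORF on %s", id))
        bases[(p + 1L):(p + 3L)] <-
          strsplit(sample(config$start_codons, 1L), "", fixed = TRUE)[[1]]
        occupied <- rbind(occupied, c(p, p + 3L))
        tis_rows[[length(tis_rows) + 1L]] <-
          tibble(transcript_id = id, gene_id = gene,
                 class = "downstream", tis = p)
      }
    }

    recs[[i]] <- tibble(
      transcript_id = id, gene_id = gene, biotype = "coding",
      sequence = paste(bases, collapse = ""),
      cds_start = cds_start, cds_end = cds_end
    )
    plants[[i]] <- dplyr::bind_rows(tis_rows)
  }

  for (i in seq_len(n_lnc)) {
    idx <- n_coding + i
    id <- sprintf("TX%04d", idx)
    gene <- sprintf("GENE%04d", idx)
    len <- sample_len(config$utr5_length_range) +
      sample_len(config$cds_length_range, 3L) +
      sample_len(config$utr3_length_range)
    bases <- random_bases(len)
    occupied <- matrix(integer(), ncol = 2)
    tis_rows <- list()
    n_orfs <- max(1L, max(1L, mix_get(mix, "lncRNA")))
    for (j in seq_len(n_orfs)) {
      len_aa <- sample(4:25, 1L)
      span <- 3L * (len_aa + 1L)
      p <- pick_free(0:(len - span), occupied, span)
      if (is.na(p)) abort(sprintf("no room for lncRNA ORF on %s", id))
      body <- strsplit(paste0(sample(config$start_codons, 1L),
                              sense_codon_string(len_aa - 1L),
                              sample(STOP_CODONS, 1L)), "", fixed = TRUE)[[1]]
      bases[(p + 1L):(p + span)] <- body
      occupied <- rbind(occupied, c(p, p + span))
      tis_rows[[length(tis_rows) + 1L]] <-
        tibble(transcript_id = id, gene_id = gene, class = "lncRNA", tis = p)
    }
    recs[[idx]] <- tibble(
      transcript_id = id, gene_id = gene, biotype = "lncRNA",
      sequence = paste(bases, collapse = ""),
      cds_start = NA_integer_, cds_end = NA_integer_
    )
    plants[[idx]] <- dplyr::bind_rows(tis_rows)
  }

  transcripts <- dplyr::bind_rows(recs)
  planted <- dplyr::bind_rows(plants)
  if (nrow(planted)) {
    seqs <- transcripts$sequence[match(planted$transcript_id,
                                       transcripts$transcript_id)]
    planted <- dplyr::bind_cols(planted, translate_from(seqs, planted$tis))
  } else {
    planted <- tibble(transcript_id = character(), gene_id = character(),
                      class = character(), tis = integer(),
                      peptide = character(), stop_position = integer(),
                      complete = logical(), length_aa = integer())
  }
  expression <- tibble(
    gene_id = unique(transcripts$gene_id),
    rpkm = 10^rnorm(dplyr::n_distinct(transcripts$gene_id),
                    config$expression_log10_mean, config$expression_log10_sd)
  )
  structure(list(transcripts = transcripts, planted = planted,
                 expression = expression, config = config),
            class = "ribotis_sim")
}

#' Draw an antigen catalog from planted ORFs
#'
#' Samples planted ORFs and cuts a contiguous in-frame epitope out of each
#' peptide, mirroring a catalog of T-cell antigens with known encoding ORFs.
#' Catalog class labels follow antigen nomenclature (`annotated`,
#' `out_of_frame`, `upstream`, `alternative`, `lncRNA`); the planted
#' positional class is kept alongside.
#'
#' @param sim A `ribotis_sim` from [simulate_transcriptome()].
#' @param n Number of antigens (ignored when `class_mix` is given).
#' @param class_mix Named counts over planted classes, e.g.
#'   `c(annotated = 5, upstream = 2)`.
#' @param epitope_length Epitope length in aa (default 9).
#' @param epitope_offset `NULL` for a random in-frame offset, or a fixed
#'   0-based aa offset (0 = epitope is the first `epitope_length` residues).
#' @param seed Integer seed.
#' @return Tibble: `antigen_id`, `orf_id`, `epitope`, `gene_id`,
#'   `transcript_id`, `expected_tis`, `class_label` (catalog nomenclature),
#'   `truth_class`.
#' @export
plant_antigens <- function(sim, n = 10, class_mix = NULL, epitope_length = 9,
                           epitope_offset = NULL, seed = 1L) {
  stopifnot(inherits(sim, "ribotis_sim"))
  eligible <- dplyr::filter(sim$planted, .data$complete,
                            .data$length_aa >= epitope_length)
  if (is.null(class_mix)) {
    if (n > nrow(eligible)) {
      abort(sprintf("requested %d antigens but only %d eligible planted ORFs",
                    n, nrow(eligible)))
    }
  } else {
    bad <- setdiff(names(class_mix), ORF_CLASSES)
    if (length(bad)) {
      abort(sprintf("class_mix has unknown class(es): %s",
                    paste(bad, collapse = ", ")))
    }
    avail <- table(factor(eligible$class, levels = ORF_CLASSES))
    short <- names(class_mix)[class_mix > avail[names(class_mix)]]
    if (length(short)) {
      abort(sprintf(
        "class_mix requests more ORFs than planted for class(es): %s",
        paste(short, collapse = ", ")))
    }
  }
  withr::with_seed(seed, {
    chosen <- if (is.null(class_mix)) {
      dplyr::slice_sample(eligible, n = n)
    } else {
      purrr::list_rbind(purrr::imap(as.list(class_mix), function(k, cls) {
        dplyr::slice_sample(dplyr::filter(eligible, .data$class == cls),
                            n = k)
      }))
    }
    off <- if (is.null(epitope_offset)) {
      vapply(chosen$length_aa - epitope_length,
             function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    } else {
      if (any(epitope_offset + epitope_length > chosen$length_aa)) {
        abort("epitope_offset places the epitope beyond some peptides")
      }
      rep_len(as.integer(epitope_offset), nrow(chosen))
    }
    tibble(
      antigen_id = sprintf("AG%03d", seq_len(nrow(chosen))),
      orf_id = paste0(chosen$transcript_id, ":", chosen$tis),
      epitope = substr(chosen$peptide, off + 1L, off + epitope_length),
      gene_id = chosen$gene_id,
      transcript_id = chosen$transcript_id,
      expected_tis = chosen$tis,
      class_label = truth_to_catalog_class(chosen$class),
      truth_class = chosen$class
    )
  })
}

#' Simulate harringtonine-arrested ribosome footprints
#'
#' Draws per-nucleotide P-site counts from a negative binomial whose mean is
#' proportional to the transcript's expression, multiplied by
#' `initiation_enrichment` on the three nucleotides of each active initiation
#' codon (harringtonine concentrates initiating ribosomes at start codons).
#' Each count is then emitted as individual reads: a read length is drawn
#' from `read_length_weights` and the 5' end placed `offset_map[length]`
#' nucleotides upstream of the P-site. Reads that would start before the
#' transcript or run past its end are dropped and counted.
#'
#' @param sim A `ribotis_sim`.
#' @param active_tis Subset of `sim$planted` rows whose initiation sites are
#'   active (default: all planted sites). Must be a subset of the planted
#'   sites.
#' @param config Simulation config (default `sim$config`).
#' @param seed Integer seed (default `config$seed`); same seed, same output.
#' @return Tibble (`transcript_id`, `five_prime_pos`, `read_length`) with
#'   attributes `n_psites` (counts drawn) and `n_dropped_edge`.
#' @export
simulate_footprints <- function(sim, active_tis = NULL, config = sim$config,
                                seed = config$seed) {
  stopifnot(inherits(sim, "ribotis_sim"))
  active <- active_tis %||% sim$planted
  if (nrow(active)) {
    key <- paste0(active$transcript_id, ":", active$tis)
    pkey <- paste0(sim$planted$transcript_id, ":", sim$planted$tis)
    if (!all(key %in% pkey)) {
      abort("active_tis contains sites that were never planted")
    }
  }
  lens <- as.integer(names(config$read_length_weights))
  missing_off <- setdiff(as.character(lens), names(config$offset_map))
  if (length(missing_off)) {
    abort(sprintf("offset_map is missing read length(s): %s",
                  paste(missing_off, collapse = ", ")))
  }
  offsets <- config$offset_map[as.character(lens)]

  tx <- sim$transcripts
  rpkm <- sim$expression$rpkm[match(tx$gene_id, sim$expression$gene_id)]
  tlen <- nchar(tx$sequence)

  withr::with_seed(seed, {
    mus <- purrr::map(seq_len(nrow(tx)), function(i) {
      mu <- rep(rpkm[i] * config$background_scale, tlen[i])
      act <- active[active$transcript_id == tx$transcript_id[i], ]
      if (nrow(act)) {
        pos <- as.vector(outer(act$tis, 0:2, `+`)) + 1L
        mu[pos] <- rpkm[i] * config$initiation_enrichment
      }
      mu
    })
    total_mu <- sum(vapply(mus, sum, numeric(1)))
    if (total_mu <= 0) abort("simulated intensity is identically zero")
    scale <- config$total_reads / total_mu
    out <- purrr::map(seq_len(nrow(tx)), function(i) {
      mu <- mus[[i]] * scale
      counts <- if (is.finite(config$nb_dispersion)) {
        rnbinom(length(mu), size = config$nb_dispersion, mu = mu)
      } else {
        rpois(length(mu), mu)
      }
      hit <- which(counts > 0L)
      if (!length(hit)) {
        return(list(fps = NULL, n_drop = 0L, n_psites = 0L))
      }
      psite <- rep(hit - 1L, counts[hit])
      rl <- lens[sample.int(length(lens), length(psite), replace = TRUE,
                            prob = config$read_length_weights)]
      fp <- psite - offsets[match(rl, lens)]
      keep <- fp >= 0L & fp + rl <= tlen[i]
      list(fps = tibble(transcript_id = tx$transcript_id[i],
                        five_prime_pos = fp[keep], read_length = rl[keep]),
           n_drop = sum(!keep), n_psites = length(psite))
    })
    fps <- purrr::list_rbind(purrr::compact(purrr::map(out, "fps")))
    if (!nrow(fps)) {
      fps <- tibble(transcript_id = character(), five_prime_pos = integer(),
                    read_length = integer())
    }
    attr(fps, "n_psites") <- sum(purrr::map_int(out, "n_psites"))
    attr(fps, "n_dropped_edge") <- sum(purrr::map_int(out, "n_drop"))
    fps
  })
}
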