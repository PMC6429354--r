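# Synthetic-data layer: circadian time-course expression with planted
# isoform switches, and gene models with planted consequence truth, so the
# full pipeline is testable without external data.

#' Simulation configuration for time-course profiles
#'
#' Defaults emulate the study design being modelled: 11 time points 3 h
#' apart spanning 30 h of experimental time (one sample per time point),
#' roughly 24-h periodic isoform profiles with baseline 10 TPM and
#' amplitude 5 TPM, and uniform measurement noise of half-range 2 TPM.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Length-2 integer range of isoforms per gene.
#' @param fraction_switching Fraction of genes with a planted switching
#'   pair.
#' @param times Sampling times (hours), strictly increasing.
#' @param period Oscillation period (hours).
#' @param baseline,amplitude Mean and half-range of the planted profiles
#'   (TPM); `amplitude <= baseline` keeps clean profiles non-negative.
#' @param noise_amount Uniform noise half-range (TPM).
#' @param archetype Shape of the planted switching pair: `"sinusoid"`
#'   (antiphase sines, crossings at the sine zeros), `"step"` (sharp
#'   exchange of levels at one crossing) or `"ramp"` (linear exchange over
#'   a 6-h window).
#' @param switch_window Length-2 range from which step/ramp crossing times
#'   are drawn; defaults to the sampling range minus a 3-h margin.
#' @param phase Optional fixed phase (radians) for every planted sinusoid
#'   pair; `NULL` draws one phase per gene.
#' @param seed Integer seed fixing every draw.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 20, isoforms_per_gene = c(2, 3),
                              fraction_switching = 0.5,
                              times = seq(0, 30, by = 3), period = 24,
                              baseline = 10, amplitude = 5,
                              noise_amount = 2,
                              archetype = c("sinusoid", "step", "ramp"),
                              switch_window = NULL, phase = NULL,
                              seed = 1) {
  archetype <- match.arg(archetype)
  problems <- character(0)
  if (fraction_switching < 0 || fraction_switching > 1) {
    problems <- c(problems, "fraction_switching must lie in [0, 1]")
  }
  if (amplitude > baseline) {
    problems <- c(problems, "amplitude must not exceed baseline")
  }
  if (length(times) < 4 || any(diff(times) <= 0)) {
    problems <- c(problems, "times must be >= 4 strictly increasing values")
  }
  if (noise_amount < 0) problems <- c(problems, "noise_amount must be >= 0")
  if (period <= 0) problems <- c(problems, "period must be > 0")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  if (is.null(switch_window)) {
    switch_window <- c(min(times) + 3, max(times) - 3)
  }
  structure(
    list(n_genes = n_genes, isoforms_per_gene = isoforms_per_gene,
         fraction_switching = fraction_switching, times = times,
         period = period, baseline = baseline, amplitude = amplitude,
         noise_amount = noise_amount, archetype = archetype,
         switch_window = switch_window, phase = phase, seed = seed),
    class = "sim_config"
  )
}

# analytic crossing times of the planted pair within [t_min, t_max]
planted_crossings <- function(archetype, period, phi, centre, times) {
  if (archetype == "sinusoid") {
    # zeros of sin(2*pi*t/period + phi)
    k <- seq(ceiling((2 * pi * min(times) / period + phi) / pi),
             floor((2 * pi * max(times) / period + phi) / pi))
    (k * pi - phi) * period / (2 * pi)
  } else {
    centre
  }
}

# a crossing is identifiable under the sampling grid iff at least two
# samples fall strictly inside each flanking partition (bounded by the
# neighbouring crossings); the minimum-points filter removes anything less
# by definition
crossing_identifiable <- function(crossings, times) {
  bounds <- c(-Inf, crossings, Inf)
  vapply(seq_along(crossings), function(m) {
    n1 <- sum(times > bounds[m] & times < crossings[m])
    n2 <- sum(times > crossings[m] & times < bounds[m + 2L])
    n1 >= 2 && n2 >= 2
  }, logical(1))
}

#' Simulate a time course with planted isoform switches
#'
#' The first `round(fraction_switching * n_genes)` genes carry a planted
#' switching pair; its two isoforms exchange abundance around the baseline
#' (antiphase sinusoids by default) and the analytic crossing times are
#' recorded in the truth table together with an identifiability flag (see
#' the vignette). Remaining isoforms of switching genes are low constant
#' profiles; isoforms of non-switching genes are proportional copies of a
#' common rhythmic profile and never cross in the clean signal. Uniform
#' noise of half-range `noise_amount` is then added and clamped at zero.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (noisy [time_course_matrix()]), `clean`
#'   (noise-free matrix) and `truth` (`data.frame`: `gene_id`, `iso_i`,
#'   `iso_j`, `crossing_time`, `identifiable`).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng_seed(config$seed, {
    t <- config$times
    B <- config$baseline; A <- config$amplitude; P <- config$period
    n_sw <- round(config$fraction_switching * config$n_genes)
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    rows <- list(); tx2gene <- character(0); truth <- list()
    for (g in seq_len(config$n_genes)) {
      gid <- gene_ids[g]
      iso_range <- seq(config$isoforms_per_gene[1L],
                       config$isoforms_per_gene[2L])
      n_iso <- iso_range[sample.int(length(iso_range), 1L)]
      txs <- paste0(gid, ".i", seq_len(n_iso))
      profiles <- matrix(0, nrow = n_iso, ncol = length(t),
                         dimnames = list(txs, NULL))
      if (g <= n_sw) {
        phi <- if (is.null(config$phase)) stats::runif(1, 0, 2 * pi)
               else config$phase
        centre <- stats::runif(1, config$switch_window[1L],
                               config$switch_window[2L])
        s <- switch(config$archetype,
          sinusoid = sin(2 * pi * t / P + phi),
          step = ifelse(t < centre, 1, ifelse(t > centre, -1, 0)),
          ramp = pmax(-1, pmin(1, (centre - t) / 3)))
        profiles[1L, ] <- B + A * s
        profiles[2L, ] <- B - A * s
        cr <- planted_crossings(config$archetype, P, phi, centre, t)
        if (length(cr)) {
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = gid, iso_i = txs[1L], iso_j = txs[2L],
            crossing_time = cr,
            identifiable = crossing_identifiable(cr, t))
        }
        if (n_iso > 2) {
          for (k in seq(3L, n_iso)) {
            profiles[k, ] <- stats::runif(1, 0.2, 1)
          }
        }
      } else {
        phi <- stats::runif(1, 0, 2 * pi)
        base <- B + A * sin(2 * pi * t / P + phi)
        ratios <- sort(stats::runif(n_iso, 0.3, 0.9), decreasing = TRUE)
        for (k in seq_len(n_iso)) profiles[k, ] <- ratios[k] * base
      }
      rows[[g]] <- profiles
      tx2gene <- c(tx2gene, stats::setNames(rep(gid, n_iso), txs))
    }
    values <- do.call(rbind, rows)
    clean <- time_course_matrix(values, t, tx2gene)
    noisy <- add_noise(clean, config$noise_amount)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), iso_i = character(0),
                 iso_j = character(0), crossing_time = numeric(0),
                 identifiable = logical(0))
    list(matrix = noisy, clean = clean, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# gene-model simulation with planted consequence truth

NONSTOP_CODONS <- local({
  all <- names(Biostrings::GENETIC_CODE)
  all[!all %in% c("TAA", "TAG", "TGA")]
})

AA_TO_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# remove every ATG occurrence so no ORF can start in this segment
atg_free <- function(s) {
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ATT", s, fixed = TRUE)
  s
}

encode_protein <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) AA_TO_CODON[[a]][1L], character(1)),
        collapse = "")
}

# coding codon run: ATG + body (no in-frame stops) with a protein motif
# encoded at codon offset motif_at (0-based, counted after the start codon)
make_cds <- function(n_codons, motif = NULL, motif_at = NULL) {
  body <- sample(NONSTOP_CODONS, n_codons - 1L, replace = TRUE)
  if (!is.null(motif)) {
    codons <- strsplit(encode_protein(motif), "(?<=...)", perl = TRUE)[[1L]]
    body[motif_at + seq_along(codons)] <- codons
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# map transcript-order exon widths (with given intron widths between them)
# onto genomic 0-based half-open intervals; minus-strand layouts are the
# mirror image so both isoforms of a gene stay in one coordinate frame
layout_exons <- function(widths, introns, strand, origin = 1000,
                         mirror_span = NULL) {
  n <- length(widths)
  starts <- numeric(n)
  pos <- origin
  for (k in seq_len(n)) {
    starts[k] <- pos
    pos <- pos + widths[k] + if (k < n) introns[k] else 0
  }
  ex <- cbind(start = starts, end = starts + widths)
  if (strand == "-") {
    Z <- if (is.null(mirror_span)) 2 * origin + sum(widths) + sum(introns)
         else mirror_span
    ex <- cbind(start = Z - ex[, "end"], end = Z - ex[, "start"])
  }
  ex
}

SIM_DOMAIN_LIB <- data.frame(
  name = c("zf_like", "helix_rich", "wd_like"),
  motif = c("CWHCWHC", "HHLLHHLLHH", "WDWDWDW"),
  stringsAsFactors = FALSE
)

#' Built-in domain library of the gene-model simulator
#'
#' Three literal protein motifs planted into simulated coding isoforms;
#' used as the scanning library when recovering planted domain truth.
#'
#' @return `data.frame` with columns `name` and `motif`.
#' @export
sim_domain_library <- function() SIM_DOMAIN_LIB

# one gene: isoform pair with a single planted contrast; returns models,
# the planted pair orientation and the expected per-axis consequence truth
build_gene <- function(gid, contrast, strand) {
  u5 <- 90; u3 <- 150
  motif_idx <- sample(nrow(SIM_DOMAIN_LIB), 1L)
  motif <- SIM_DOMAIN_LIB$motif[motif_idx]
  motif_name <- SIM_DOMAIN_LIB$name[motif_idx]

  if (contrast == "exon_skip") {
    k2 <- 30L; k3 <- 40L; k4 <- 40L
    cds <- make_cds(k2 + k3 + k4, motif = motif, motif_at = k2 + 5L)
    tx_a <- paste0(atg_free(rand_dna(u5 - 6)), cds, atg_free(rand_dna(u3)))
    w1 <- u5 - 6; w2 <- 3 * k2; w3 <- 3 * k3
    w4 <- nchar(tx_a) - w1 - w2 - w3
    widths_a <- c(w1, w2, w3, w4)
    ex_a <- layout_exons(widths_a, c(200, 180, 160), strand)
    tx_b <- paste0(substr(tx_a, 1, w1 + w2),
                   substr(tx_a, w1 + w2 + w3 + 1, nchar(tx_a)))
    ex_b <- ex_a[-3L, , drop = FALSE]
    a <- transcript_model(paste0(gid, ".t1"), gid, strand, ex_a, tx_a)
    b <- transcript_model(paste0(gid, ".t2"), gid, strand, ex_b, tx_b)
    orf_a <- c(w1, w1 + 3 * (k2 + k3 + k4) + 3)
    orf_b <- c(w1, w1 + 3 * (k2 + k4) + 3)
    return(list(
      before = a, after = b, orf_before = orf_a, orf_after = orf_b,
      truth = data.frame(
        gene_id = gid, iso_before = a$transcript_id,
        iso_after = b$transcript_id, contrast = contrast,
        cp_class = "coding->coding", orf_class = "shorter",
        nmd_class = "unchanged", ir_class = "unchanged",
        domain_change = "loss", splice_events = "exon_skipping",
        orf_similar = FALSE),
      domains_before = motif_name, domains_after = ""))
  }

  n_cod <- sample(100:140, 1L)
  cds <- make_cds(n_cod, motif = motif, motif_at = 10L)
  tx <- paste0(atg_free(rand_dna(u5)), cds, atg_free(rand_dna(u3)))
  orf_end <- u5 + 3 * n_cod + 3
  total <- nchar(tx)

  if (contrast %in% c("nmd", "ir")) {
    # canonical isoform has four exons; the partner retains the last intron
    j1 <- 60; j2 <- orf_end - 30
    j3 <- orf_end + if (contrast == "nmd") 60 else 30
    iw <- 150
    widths4 <- c(j1, j2 - j1, j3 - j2, total - j3)
    introns4 <- c(200, 180, iw)
    ex4 <- layout_exons(widths4, introns4, strand)
    intron_seq <- atg_free(rand_dna(iw))
    tx_ret <- paste0(substr(tx, 1, j3), intron_seq,
                     substr(tx, j3 + 1, total))
    # retained-intron exon spans canonical exons 3+intron+4
    if (strand == "+") {
      ex_ret <- rbind(ex4[1:2, ],
                      c(ex4[3L, 1L], ex4[4L, 2L]))
    } else {
      ex_ret <- rbind(c(ex4[4L, 1L], ex4[3L, 2L]), ex4[2:1, ])
    }
    canon <- transcript_model(paste0(gid, ".t1"), gid, strand, ex4, tx)
    retained <- transcript_model(paste0(gid, ".t2"), gid, strand, ex_ret,
                                 tx_ret)
    orf <- c(u5, orf_end)
    if (contrast == "nmd") {
      # gained canonical isoform: stop 60 nt upstream of its last junction
      return(list(
        before = retained, after = canon, orf_before = orf, orf_after = orf,
        truth = data.frame(
          gene_id = gid, iso_before = retained$transcript_id,
          iso_after = canon$transcript_id, contrast = contrast,
          cp_class = "coding->coding", orf_class = "similar",
          nmd_class = "gain sensitivity", ir_class = "loss",
          domain_change = "unchanged", splice_events = "intron_retention",
          orf_similar = TRUE),
        domains_before = motif_name, domains_after = motif_name))
    }
    return(list(
      before = canon, after = retained, orf_before = orf, orf_after = orf,
      truth = data.frame(
        gene_id = gid, iso_before = canon$transcript_id,
        iso_after = retained$transcript_id, contrast = contrast,
        cp_class = "coding->coding", orf_class = "similar",
        nmd_class = "unchanged", ir_class = "gain",
        domain_change = "unchanged", splice_events = "intron_retention",
        orf_similar = TRUE),
      domains_before = motif_name, domains_after = motif_name))
  }

  j1 <- 60; j2 <- orf_end - 30
  widths3 <- c(j1, j2 - j1, total - j2)
  ex3 <- layout_exons(widths3, c(200, 180), strand)
  a <- transcript_model(paste0(gid, ".t1"), gid, strand, ex3, tx)
  orf <- c(u5, orf_end)

  if (contrast == "noncoding") {
    # partner transcribed from inside the 3' UTR: ATG-free by construction
    keep <- 120
    tx_b <- substr(tx, total - keep + 1, total)
    if (strand == "+") {
      ex_b <- cbind(ex3[3L, 2L] - keep, ex3[3L, 2L])
    } else {
      ex_b <- cbind(ex3[3L, 1L], ex3[3L, 1L] + keep)
    }
    b <- transcript_model(paste0(gid, ".t2"), gid, strand, ex_b, tx_b)
    return(list(
      before = a, after = b, orf_before = orf, orf_after = NULL,
      truth = data.frame(
        gene_id = gid, iso_before = a$transcript_id,
        iso_after = b$transcript_id, contrast = contrast,
        cp_class = "coding->noncoding", orf_class = "complete loss",
        nmd_class = "unchanged", ir_class = "unchanged",
        domain_change = "loss", splice_events = "alt_tss",
        orf_similar = FALSE),
      domains_before = motif_name, domains_after = ""))
  }

  if (contrast == "alt_tss") {
    shift <- 45
    tx_b <- substr(tx, shift + 1, total)
    ex_b <- ex3
    if (strand == "+") ex_b[1L, 1L] <- ex_b[1L, 1L] + shift
    else ex_b[1L, 2L] <- ex_b[1L, 2L] - shift
    b <- transcript_model(paste0(gid, ".t2"), gid, strand, ex_b, tx_b)
    return(list(
      before = a, after = b, orf_before = orf,
      orf_after = c(u5 - shift, orf_end - shift),
      truth = data.frame(
        gene_id = gid, iso_before = a$transcript_id,
        iso_after = b$transcript_id, contrast = contrast,
        cp_class = "coding->coding", orf_class = "similar",
        nmd_class = "unchanged", ir_class = "unchanged",
        domain_change = "unchanged", splice_events = "alt_tss",
        orf_similar = TRUE),
      domains_before = motif_name, domains_after = motif_name))
  }

  # alt_tts: 3' UTR trimmed by 60 nt
  trim <- 60
  tx_b <- substr(tx, 1, total - trim)
  ex_b <- ex3
  if (strand == "+") ex_b[3L, 2L] <- ex_b[3L, 2L] - trim
  else ex_b[3L, 1L] <- ex_b[3L, 1L] + trim
  b <- transcript_model(paste0(gid, ".t2"), gid, strand, ex_b, tx_b)
  list(
    before = a, after = b, orf_before = orf, orf_after = orf,
    truth = data.frame(
      gene_id = gid, iso_before = a$transcript_id,
      iso_after = b$transcript_id, contrast = "alt_tts",
      cp_class = "coding->coding", orf_class = "similar",
      nmd_class = "unchanged", ir_class = "unchanged",
      domain_change = "unchanged", splice_events = "alt_tts",
      orf_similar = TRUE),
    domains_before = motif_name, domains_after = motif_name)
}

# structural self-check: the planted ORF must be exactly what find_orf
# recovers and planted domains must match exactly; guarantees that the
# emitted truth labels hold for the emitted sequences
gene_truth_holds <- function(gene) {
  check_orf <- function(model, expected) {
    orf <- find_orf(model$sequence)
    if (is.null(expected)) return(is.null(orf))
    !is.null(orf) && orf$start == expected[1L] && orf$end == expected[2L]
  }
  check_domains <- function(model, expected_orf, expected_names) {
    orf <- find_orf(model$sequence)
    found <- if (is.null(orf)) character(0) else
      unique(identify_domains(orf$protein, SIM_DOMAIN_LIB)$domain)
    setequal(found, expected_names[nzchar(expected_names)])
  }
  check_orf(gene$before, gene$orf_before) &&
    check_orf(gene$after, gene$orf_after) &&
    check_domains(gene$before, gene$orf_before, gene$domains_before) &&
    check_domains(gene$after, gene$orf_after, gene$domains_after)
}

#' Simulate gene models with planted consequence truth
#'
#' Each gene contributes one switching isoform pair carrying exactly one
#' planted contrast: loss of coding potential (`noncoding`), gain of NMD
#' sensitivity (`nmd`), intron retention (`ir`), an alternative
#' transcription start or stop site (`alt_tss`, `alt_tts`) or an exon skip
#' removing a domain-coding exon (`exon_skip`). Contrasts cycle across
#' genes; strands are drawn at random. The generator re-samples a gene
#' until its structural truth is self-consistent (the planted ORF is the
#' longest ORF and planted domain motifs occur exactly where intended), so
#' the emitted truth table is guaranteed to hold for the emitted
#' sequences.
#'
#' @param n_genes Number of genes (= switching pairs).
#' @param seed Integer seed.
#' @return List with `models` (named list of [transcript_model()]),
#'   `truth` (per-pair expected classification), `transcripts` (per-
#'   transcript coding/NMD/domain truth) and `lib` (the
#'   [sim_domain_library()]).
#' @export
simulate_gene_models <- function(n_genes = 200, seed = 1) {
  contrasts <- c("noncoding", "nmd", "ir", "alt_tss", "alt_tts",
                 "exon_skip")
  with_rng_seed(seed, {
    models <- list(); truth <- list(); tx_truth <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("SG%04d", g)
      contrast <- contrasts[(g - 1L) %% length(contrasts) + 1L]
      strand <- sample(c("+", "-"), 1L)
      for (attempt in seq_len(50L)) {
        gene <- build_gene(gid, contrast, strand)
        if (gene_truth_holds(gene)) break
        if (attempt == 50L) stop("gene simulation failed to converge: ", gid)
      }
      models[[gene$before$transcript_id]] <- gene$before
      models[[gene$after$transcript_id]] <- gene$after
      truth[[g]] <- gene$truth
      nmd_flag <- function(model, orf) {
        !is.null(orf) &&
          detect_nmd(model, list(start = orf[1L], end = orf[2L]))
      }
      tx_truth[[g]] <- data.frame(
        transcript_id = c(gene$before$transcript_id,
                          gene$after$transcript_id),
        gene_id = gid,
        coding = c(!is.null(gene$orf_before), !is.null(gene$orf_after)),
        nmd = c(nmd_flag(gene$before, gene$orf_before),
                nmd_flag(gene$after, gene$orf_after)),
        domains = c(gene$domains_before, gene$domains_after))
    }
    list(models = models, truth = do.call(rbind, truth),
         transcripts = do.call(rbind, tx_truth), lib = SIM_DOMAIN_LIB)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits one `quant_t<hours>.sf` file per time point (Salmon dialect, TPM
#' at full precision so re-ingestion is bit-exact), `tx2gene.tsv`,
#' `truth_switches.tsv` and, when models are given, `models.gtf`,
#' `transcripts.fa` and `domains.tsv`.
#'
#' @param sim Output of [simulate_profiles()].
#' @param dir Output directory (created if needed).
#' @param models Optional named list of [transcript_model()] objects.
#' @param lib Optional domain library to write.
#' @param clean Write the noise-free profiles instead of the noisy matrix
#'   (use this when the downstream pipeline injects its own noise, as the
#'   emulated workflow does).
#' @return Character vector of written paths (the manifest), invisibly.
#' @export
write_dataset <- function(sim, dir, models = NULL, lib = NULL,
                          clean = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  x <- if (clean) sim$clean else sim$matrix
  manifest <- character(0)
  tx_len <- vapply(rownames(x$values), function(tx) {
    if (!is.null(models) && !is.null(models[[tx]])) {
      transcript_length(models[[tx]])
    } else 1000
  }, numeric(1))
  for (k in seq_along(x$times)) {
    path <- file.path(dir, sprintf("quant_t%g.sf", x$times[k]))
    tab <- data.frame(
      Name = rownames(x$values),
      Length = as.integer(tx_len),
      EffectiveLength = pmax(tx_len - 200, 1),
      TPM = sprintf("%.17g", x$values[, k]),
      NumReads = sprintf("%.17g", x$values[, k]))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, path)
  }
  path <- file.path(dir, "tx2gene.tsv")
  utils::write.table(
    data.frame(transcript_id = names(x$tx2gene), gene_id = x$tx2gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- c(manifest, path)
  path <- file.path(dir, "truth_switches.tsv")
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- c(manifest, path)
  if (!is.null(models)) {
    path <- file.path(dir, "models.gtf")
    write_gene_models_gtf(models, path)
    manifest <- c(manifest, path)
    path <- file.path(dir, "transcripts.fa")
    write_transcript_fasta(models, path)
    manifest <- c(manifest, path)
  }
  if (!is.null(lib)) {
    path <- file.path(dir, "domains.tsv")
    utils::write.table(lib, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, path)
  }
  invisible(manifest)
}
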