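# Consequence layer: structural comparison of switching isoform pairs and
# per-axis classification (coding potential, ORF, NMD, intron retention,
# domains, splice events), plus per-STP gain/loss summaries.

spans_an_intron <- function(exon, introns) {
  if (is.null(introns) || !nrow(introns)) return(FALSE)
  any(exon[1L] < introns[, 1L] & exon[2L] > introns[, 2L])
}

intron_table <- function(exons) {
  n <- nrow(exons)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(exons[-n, 2L], exons[-1L, 1L])
}

#' Classify splice events between two isoforms
#'
#' Pairwise structural comparison on genomic coordinates, strand-aware
#' (the transcription start site is the 5' end on the coding strand):
#' * `alt_tss` / `alt_tts` — differing outermost 5' / 3' transcript
#'   boundary;
#' * `exon_skipping` — an exon of one isoform lying fully inside an intron
#'   of the other (attributed to the isoform containing the exon);
#' * `intron_retention` — an exon of one isoform spanning an entire intron
#'   of the other together with both flanking exon ends (attributed to the
#'   retaining isoform);
#' * `alt_5prime` / `alt_3prime` — overlapping exons differing at an
#'   internal donor / acceptor boundary (exon pairs already explained by an
#'   intron retention are not re-classified).
#'
#' @param model_a,model_b [transcript_model()] objects of the same gene
#'   and strand.
#' @return `data.frame` with columns `event` and `isoform` (`"a"`, `"b"`
#'   or `NA` for boundary events); zero rows for identical structures.
#' @export
classify_splice_events <- function(model_a, model_b) {
  if (model_a$gene_id != model_b$gene_id) stop("different genes")
  if (model_a$strand != model_b$strand) stop("different strands")
  strand <- model_a$strand
  ea <- model_a$exons; eb <- model_b$exons
  ia <- intron_table(ea); ib <- intron_table(eb)
  ev <- list()
  add <- function(event, isoform) {
    ev[[length(ev) + 1L]] <<- data.frame(event = event, isoform = isoform,
                                         stringsAsFactors = FALSE)
  }
  five_a <- if (strand == "+") ea[1L, 1L] else ea[nrow(ea), 2L]
  five_b <- if (strand == "+") eb[1L, 1L] else eb[nrow(eb), 2L]
  three_a <- if (strand == "+") ea[nrow(ea), 2L] else ea[1L, 1L]
  three_b <- if (strand == "+") eb[nrow(eb), 2L] else eb[1L, 1L]
  if (five_a != five_b) add("alt_tss", NA_character_)
  if (three_a != three_b) add("alt_tts", NA_character_)

  for (k in seq_len(nrow(ea))) {
    if (nrow(ib) && any(ea[k, 1L] >= ib[, 1L] & ea[k, 2L] <= ib[, 2L])) {
      add("exon_skipping", "a")
    }
    if (spans_an_intron(ea[k, ], ib)) add("intron_retention", "a")
  }
  for (k in seq_len(nrow(eb))) {
    if (nrow(ia) && any(eb[k, 1L] >= ia[, 1L] & eb[k, 2L] <= ia[, 2L])) {
      add("exon_skipping", "b")
    }
    if (spans_an_intron(eb[k, ], ia)) add("intron_retention", "b")
  }

  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      overlap <- ea[i, 1L] < eb[j, 2L] && eb[j, 1L] < ea[i, 2L]
      if (!overlap) next
      if (spans_an_intron(ea[i, ], ib) || spans_an_intron(eb[j, ], ia)) next
      start_internal <- (i > 1L) && (j > 1L)
      end_internal <- (i < nrow(ea)) && (j < nrow(eb))
      if (ea[i, 1L] != eb[j, 1L] && start_internal) {
        add(if (strand == "+") "alt_3prime" else "alt_5prime",
            NA_character_)
      }
      if (ea[i, 2L] != eb[j, 2L] && end_internal) {
        add(if (strand == "+") "alt_5prime" else "alt_3prime",
            NA_character_)
      }
    }
  }
  if (!length(ev)) {
    return(data.frame(event = character(0), isoform = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, ev))
}

pair_skip_reason <- function(event, models) {
  for (id in c(event$iso_after, event$iso_before)) {
    if (is.null(models[[id]])) return(paste0(id, ": no model"))
    if (!models[[id]]$has_sequence) return(paste0(id, ": no sequence"))
  }
  NULL
}

axis_from_flags <- function(gained_flag, lost_flag, gain_label, loss_label) {
  if (gained_flag && !lost_flag) gain_label
  else if (lost_flag && !gained_flag) loss_label
  else "unchanged"
}

#' Classify the functional consequence of one switching pair
#'
#' The gained isoform is the one dominant after the switch time
#' (`iso_after`); all gain/loss polarity follows from that orientation.
#' Axes: coding potential (at `cp_cutoff`), ORF length (relative
#' difference `<= len_frac` is "similar"), NMD sensitivity (50-nt rule),
#' intron retention, domain content and the splice-event set; ORF
#' similarity is the genomic Jaccard of the two CDS footprints.
#'
#' @param event One-row switch event (or a list with `iso_before`,
#'   `iso_after`, `gene_id`).
#' @param models Named list of [transcript_model()] objects.
#' @param lib Optional domain library (see [read_domain_library()]).
#' @param cp_scores Optional named vector of external coding probabilities
#'   (used verbatim when a transcript is present).
#' @param cp_cutoff Coding-potential calling threshold.
#' @param len_frac Relative ORF-length difference below which the ORFs
#'   count as similar.
#' @param sim_threshold ORF-similarity threshold for the `orf_similar`
#'   flag.
#' @return One-row `data.frame` (list-columns `domains_gained`,
#'   `domains_lost`, `splice_events`), or `NULL` when either isoform lacks
#'   a usable model ([classify_switches()] logs the reason).
#' @export
classify_pair <- function(event, models, lib = NULL, cp_scores = NULL,
                          cp_cutoff = 0.725, len_frac = 0.1,
                          sim_threshold = 0.9) {
  gained_id <- event$iso_after
  lost_id <- event$iso_before
  if (!is.null(pair_skip_reason(event, models))) return(NULL)
  mg <- models[[gained_id]]; ml <- models[[lost_id]]

  cp_of <- function(m) {
    ext <- if (!is.null(cp_scores) && m$transcript_id %in% names(cp_scores)) {
      cp_scores[[m$transcript_id]]
    } else NULL
    coding_potential(m, external_score = ext, cutoff = cp_cutoff)
  }
  cp_g <- cp_of(mg); cp_l <- cp_of(ml)
  cp_class <- paste0(if (cp_l$is_coding) "coding" else "noncoding", "->",
                     if (cp_g$is_coding) "coding" else "noncoding")

  orf_g <- find_orf(mg$sequence); orf_l <- find_orf(ml$sequence)
  orf_class <- if (is.null(orf_g) && is.null(orf_l)) {
    "both absent"
  } else if (is.null(orf_l)) {
    "complete gain"
  } else if (is.null(orf_g)) {
    "complete loss"
  } else {
    lg <- orf_g$end - orf_g$start; ll <- orf_l$end - orf_l$start
    if (abs(lg - ll) / max(lg, ll) <= len_frac) "similar"
    else if (lg > ll) "longer" else "shorter"
  }

  nmd_g <- !is.null(orf_g) && detect_nmd(mg, orf_g)
  nmd_l <- !is.null(orf_l) && detect_nmd(ml, orf_l)
  nmd_class <- axis_from_flags(nmd_g, nmd_l,
                               "gain sensitivity", "loss sensitivity")

  splice <- classify_splice_events(mg, ml)
  ir_rows <- splice$isoform[splice$event == "intron_retention"]
  ir_class <- axis_from_flags(any(ir_rows == "a", na.rm = TRUE),
                              any(ir_rows == "b", na.rm = TRUE),
                              "gain", "loss")

  doms <- function(orf) {
    if (is.null(lib) || is.null(orf)) return(character(0))
    unique(identify_domains(orf$protein, lib)$domain)
  }
  dg <- doms(orf_g); dl <- doms(orf_l)

  sim <- orf_similarity(mg, ml, orf_g, orf_l)

  data.frame(
    gene_id = mg$gene_id, gained_iso = gained_id, lost_iso = lost_id,
    cp_class = cp_class, orf_class = orf_class, nmd_class = nmd_class,
    ir_class = ir_class,
    cp_score_gained = cp_g$score, cp_score_lost = cp_l$score,
    orf_similarity = sim, orf_similar = sim >= sim_threshold,
    domains_gained = I(list(setdiff(dg, dl))),
    domains_lost = I(list(setdiff(dl, dg))),
    splice_events = I(list(unique(splice$event))),
    stringsAsFactors = FALSE
  )
}

#' Classify all switching pairs of an event table
#'
#' Pairs whose isoform models are missing or sequence-less are skipped
#' with a recorded reason rather than aborting the run.
#'
#' @inheritParams classify_pair
#' @param events Switch-event `data.frame`.
#' @return Consequence `data.frame` (one row per classified pair) with the
#'   skip log attached as attribute `skipped`.
#' @export
classify_switches <- function(events, models, lib = NULL, cp_scores = NULL,
                              cp_cutoff = 0.725, len_frac = 0.1,
                              sim_threshold = 0.9) {
  records <- list(); skipped <- character(0)
  for (i in seq_len(nrow(events))) {
    reason <- pair_skip_reason(events[i, ], models)
    if (!is.null(reason)) {
      skipped <- c(skipped, reason)
      next
    }
    records[[length(records) + 1L]] <-
      classify_pair(events[i, ], models, lib, cp_scores,
                    cp_cutoff, len_frac, sim_threshold)
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(gene_id = character(0))
  attr(out, "skipped") <- skipped
  out
}

# two-sided exact binomial p under p0 = 1/2 by integer summation of
# binomial coefficients (exact in double precision for the n seen here)
exact_binom_p <- function(g, n) {
  coefs <- choose(n, 0:n)
  min(1, sum(coefs[coefs <= coefs[g + 1L]]) / 2^n)
}

axis_polarity <- function(records, axis) {
  switch(axis,
    cp = list(gain = records$cp_class == "noncoding->coding",
              loss = records$cp_class == "coding->noncoding"),
    orf = list(gain = records$orf_class %in% c("longer", "complete gain"),
               loss = records$orf_class %in% c("shorter", "complete loss")),
    nmd = list(gain = records$nmd_class == "gain sensitivity",
               loss = records$nmd_class == "loss sensitivity"),
    ir = list(gain = records$ir_class == "gain",
              loss = records$ir_class == "loss"),
    domains = {
      ng <- lengths(records$domains_gained)
      nl <- lengths(records$domains_lost)
      list(gain = ng > nl, loss = nl > ng)
    },
    stop("unknown axis: ", axis))
}

#' Summarise consequence gains vs losses for one STP
#'
#' For each axis (coding potential, ORF, NMD, intron retention, domains)
#' the classified pairs are counted as gains, losses or unchanged, and the
#' gain/loss imbalance is tested with a two-sided exact binomial test
#' against p = 0.5 (unchanged pairs excluded), with a 95% Clopper-Pearson
#' interval for the gain fraction. Axes with no gains or losses report
#' `NA` (test not applicable).
#'
#' @param records Consequence `data.frame` from [classify_switches()],
#'   typically restricted to one STP's member events.
#' @param conf_level Confidence level of the interval.
#' @return `data.frame` with columns `axis`, `gains`, `losses`,
#'   `unchanged`, `p`, `ci_low`, `ci_high`.
#' @export
summarize_consequences <- function(records, conf_level = 0.95) {
  if (!nrow(records)) stop("no consequence records")
  axes <- c("cp", "orf", "nmd", "ir", "domains")
  rows <- lapply(axes, function(ax) {
    pol <- axis_polarity(records, ax)
    g <- sum(pol$gain); l <- sum(pol$loss)
    u <- nrow(records) - g - l
    if (g + l == 0) {
      return(data.frame(axis = ax, gains = g, losses = l, unchanged = u,
                        p = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    bt <- stats::binom.test(g, g + l, p = 0.5, conf.level = conf_level)
    data.frame(axis = ax, gains = g, losses = l, unchanged = u,
               p = exact_binom_p(g, g + l), ci_low = bt$conf.int[1L],
               ci_high = bt$conf.int[2L])
  })
  do.call(rbind, rows)
}
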