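# ORF finding, coding-potential scoring and NMD sensitivity.

STOP_CODONS <- c("TAA", "TAG", "TGA")

split_codons <- function(chars, frame) {
  n <- length(chars)
  if (n - frame < 3) return(character(0))
  k <- (n - frame) %/% 3
  idx <- frame + seq_len(k * 3)
  m <- matrix(chars[idx], nrow = 3)
  paste0(m[1, ], m[2, ], m[3, ])
}

#' Find the longest open reading frame
#'
#' Scans all three forward frames for ATG-initiated ORFs terminated by a
#' stop codon (TAA/TAG/TGA) and returns the longest; ties resolve to the
#' 5'-most start. Codons containing `N` match neither start nor stop and
#' translate to `X`. Incomplete ORFs (no in-frame stop) are not reported.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return `NULL` if no complete ORF exists, else a list with `start`,
#'   `end` (transcript coordinates, 0-based half-open, stop codon
#'   included), `protein` (amino acids, stop excluded) and `complete =
#'   TRUE`.
#' @export
find_orf <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) && any(!chars %in% c("A", "C", "G", "T", "N"))) {
    stop("invalid nucleotide character: ",
         chars[!chars %in% c("A", "C", "G", "T", "N")][1L])
  }
  best <- NULL
  for (frame in 0:2) {
    codons <- split_codons(chars, frame)
    if (!length(codons)) next
    starts <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    for (s in starts) {
      e <- stops[stops >= s]
      if (!length(e)) next
      e <- e[1L]
      len <- (e - s + 1L) * 3L
      start_nt <- frame + (s - 1L) * 3L
      if (is.null(best) || len > best$len ||
          (len == best$len && start_nt < best$start)) {
        best <- list(start = start_nt, end = start_nt + len, len = len,
                     codons = codons[s:(e - 1L)])
      }
    }
  }
  if (is.null(best)) return(NULL)
  aa <- GENETIC_CODE_TABLE[best$codons]
  aa[is.na(aa)] <- "X"
  list(start = best$start, end = best$end,
       protein = paste(aa, collapse = ""), complete = TRUE)
}

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# Fickett TESTCODE-style statistic: weighted sum of probabilities looked up
# from position-asymmetry and base-composition parameters. Used as one term
# of the built-in coding-potential heuristic.
FICKETT_POS_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_CONT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                       0.17, 0.0)
FICKETT_POS_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_POS_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
FICKETT_CONT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

#' Fickett TESTCODE-style coding statistic
#'
#' Position-asymmetry and composition statistic over the four bases,
#' following the classic TESTCODE scheme: for each base the maximum over
#' the three codon positions divided by the minimum plus one is looked up
#' in a probability table, as is the overall base content, and the eight
#' probabilities are combined with fixed weights. Higher values indicate
#' protein-coding-like periodicity.
#'
#' @param sequence Nucleotide string.
#' @return Scalar score, roughly in `[0.2, 1.6]`.
#' @export
fickett_score <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) < 6) return(0)
  pos <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- vapply(0:2, function(p) sum(chars == b & pos == p), numeric(1))
    asym <- max(counts) / (min(counts) + 1)
    idx <- which(asym >= FICKETT_POS_PARA)[1L]
    score <- score + FICKETT_POS_PROB[[b]][idx] * FICKETT_POS_WEIGHT[[b]]
    cont <- sum(counts) / length(chars)
    idx <- which(cont >= FICKETT_CONT_PARA)[1L]
    score <- score + FICKETT_CONT_PROB[[b]][idx] * FICKETT_CONT_WEIGHT[[b]]
  }
  score
}

#' Coding-potential score of a transcript
#'
#' When an externally computed coding probability is supplied (for example
#' ingested from a CPAT-format table) it is used verbatim. Otherwise a
#' built-in logistic heuristic is applied:
#' `score = logistic(2 * log(orf_length + 1) + 2 * orf_coverage +
#' fickett - 10)`, where `orf_length` is the nucleotide length of the
#' longest complete ORF, `orf_coverage` its fraction of the transcript and
#' `fickett` the [fickett_score()] of the transcript. A transcript without
#' a complete ORF scores 0. A transcript is called coding when the score
#' reaches `cutoff` (default 0.725).
#'
#' @param model A [transcript_model()] with sequence, or a plain
#'   nucleotide string.
#' @param external_score Optional coding probability in `[0, 1]`.
#' @param cutoff Calling threshold.
#' @return List with `score` and `is_coding`.
#' @export
coding_potential <- function(model, external_score = NULL, cutoff = 0.725) {
  if (!is.null(external_score)) {
    return(list(score = external_score, is_coding = external_score >= cutoff))
  }
  seq <- if (inherits(model, "transcript_model")) {
    if (!model$has_sequence) stop("model has no sequence and no external score")
    model$sequence
  } else {
    model
  }
  orf <- find_orf(seq)
  if (is.null(orf)) return(list(score = 0, is_coding = FALSE))
  coverage <- (orf$end - orf$start) / nchar(seq)
  z <- 2 * log(orf$end - orf$start + 1) + 2 * coverage +
    fickett_score(seq) - 10
  score <- stats::plogis(z)
  list(score = score, is_coding = score >= cutoff)
}

#' Read a CPAT-format coding-probability table
#'
#' Tab-separated table with a transcript-id column (first column or a
#' column named like `seq/ID/transcript`) and a coding-probability column
#' (named like `coding_prob`).
#'
#' @param path Path to the table.
#' @return Named numeric vector of coding probabilities.
#' @export
read_cp_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  pcol <- grep("coding_?prob", names(tab), ignore.case = TRUE, value = TRUE)
  if (!length(pcol)) stop("no coding-probability column in ", path)
  idcol <- grep("^(seq|id|transcript)", names(tab), ignore.case = TRUE,
                value = TRUE)
  ids <- if (length(idcol)) tab[[idcol[1L]]] else tab[[1L]]
  stats::setNames(as.numeric(tab[[pcol[1L]]]), ids)
}

#' Nonsense-mediated decay sensitivity (50-nt rule)
#'
#' A transcript is NMD-sensitive when its stop codon ends more than 50 nt
#' upstream of the last exon-exon junction; junction positions are derived
#' from cumulative exon lengths in transcript coordinates. Single-exon
#' transcripts are never sensitive.
#'
#' @param model A [transcript_model()].
#' @param orf An ORF as returned by [find_orf()] (stop codon included in
#'   `end`).
#' @return Logical flag.
#' @export
detect_nmd <- function(model, orf) {
  stopifnot(inherits(model, "transcript_model"))
  tx_len <- transcript_length(model)
  if (orf$start < 0 || orf$end > tx_len) stop("ORF outside transcript")
  junctions <- junction_positions(model)
  if (!length(junctions)) return(FALSE)
  (max(junctions) - orf$end) > 50
}

#' Scan a protein for domain motifs
#'
#' Every motif of the library is matched as a regular expression against
#' the protein; overlapping matches (within and across motifs) are all
#' reported with 0-based positions. This is a literal pattern scanner for
#' motif-table libraries, not a profile-HMM search.
#'
#' @param protein Amino-acid string (20-letter alphabet, `*` and `X`
#'   tolerated).
#' @param lib Domain library `data.frame` (`name`, `motif`), see
#'   [read_domain_library()].
#' @return `data.frame` with columns `domain` and `position`.
#' @export
identify_domains <- function(protein, lib) {
  ok <- strsplit(protein, "", fixed = TRUE)[[1L]]
  valid <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X", "*")
  if (length(ok) && any(!ok %in% valid)) {
    stop("invalid amino-acid character: ", ok[!ok %in% valid][1L])
  }
  hits <- list()
  for (i in seq_len(nrow(lib))) {
    m <- gregexpr(paste0("(?=", lib$motif[i], ")"), protein,
                  perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      hits[[length(hits) + 1L]] <- data.frame(
        domain = lib$name[i], position = as.integer(m) - 1L)
    }
  }
  if (!length(hits)) {
    return(data.frame(domain = character(0), position = integer(0)))
  }
  do.call(rbind, hits)
}

# project a transcript-coordinate interval [start, end) through the exon
# structure to genomic 0-based half-open intervals
project_to_genome <- function(model, start, end) {
  exons <- model$exons
  widths <- exons[, 2L] - exons[, 1L]
  if (model$strand == "-") {
    ord <- rev(seq_len(nrow(exons)))
  } else {
    ord <- seq_len(nrow(exons))
  }
  out <- NULL
  offset <- 0
  for (k in ord) {
    w <- widths[k]
    lo <- max(start - offset, 0)
    hi <- min(end - offset, w)
    if (hi > lo) {
      if (model$strand == "+") {
        g <- c(exons[k, 1L] + lo, exons[k, 1L] + hi)
      } else {
        g <- c(exons[k, 2L] - hi, exons[k, 2L] - lo)
      }
      out <- rbind(out, g)
    }
    offset <- offset + w
  }
  if (is.null(out)) {
    return(IRanges::IRanges())
  }
  IRanges::IRanges(start = out[, 1L] + 1L, end = out[, 2L])
}

#' ORF similarity of two isoforms
#'
#' Jaccard index of the genomic base sets covered by the two ORFs (each
#' ORF mapped through its isoform's exon structure to genomic intervals).
#' Returns 0 when either isoform lacks a complete ORF.
#'
#' @param model_a,model_b [transcript_model()] objects of the same gene.
#' @param orf_a,orf_b ORFs from [find_orf()] (or `NULL`).
#' @return Scalar in `[0, 1]`.
#' @export
orf_similarity <- function(model_a, model_b, orf_a, orf_b) {
  if (is.null(orf_a) || is.null(orf_b)) return(0)
  ra <- project_to_genome(model_a, orf_a$start, orf_a$end)
  rb <- project_to_genome(model_b, orf_b$start, orf_b$end)
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  if (uni == 0) return(0)
  inter / uni
}
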