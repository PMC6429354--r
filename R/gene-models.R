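#' Construct a transcript model
#'
#' Exons are stored internally as 0-based half-open genomic intervals,
#' sorted ascending; conversion from the 1-based inclusive GTF convention
#' happens only at I/O boundaries. The sequence is the sense-strand
#' transcript sequence (already reverse-complemented for minus-strand
#' transcripts, as in a reference transcriptome FASTA).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`) of 0-based half-open
#'   genomic intervals.
#' @param sequence Sense-strand nucleotide string, or `NA` if unavailable
#'   (the model is then flagged via `has_sequence`).
#' @param cds Optional length-2 vector, transcript-coordinate 0-based
#'   half-open CDS interval (length divisible by 3).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, strand, exons,
                             sequence = NA_character_, cds = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon in ", transcript_id)
  if (nrow(exons) > 1 &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  tx_len <- sum(exons[, 2L] - exons[, 1L])
  has_seq <- !is.na(sequence) && nzchar(sequence)
  if (has_seq && nchar(sequence) != tx_len) {
    stop("sequence length (", nchar(sequence),
         ") does not match summed exon length (", tx_len, ") for ",
         transcript_id)
  }
  if (!is.null(cds)) {
    if (cds[1L] < 0 || cds[2L] > tx_len || (cds[2L] - cds[1L]) %% 3 != 0) {
      stop("invalid cds for ", transcript_id)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, strand = strand,
         exons = exons, sequence = if (has_seq) sequence else NA_character_,
         has_sequence = has_seq, cds = cds),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "(", x$gene_id, ",", x$strand,
      ")\n  exons:", nrow(x$exons),
      " length:", sum(x$exons[, 2] - x$exons[, 1]),
      " sequence:", if (x$has_sequence) "yes" else "absent", "\n")
  invisible(x)
}

transcript_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

# transcript coordinates of exon-exon junctions (0-based positions in the
# spliced sequence where one exon ends and the next begins), 5'->3'
junction_positions <- function(model) {
  widths <- model$exons[, 2L] - model$exons[, 1L]
  if (model$strand == "-") widths <- rev(widths)
  cs <- cumsum(widths)
  cs[-length(cs)]
}

#' Load transcript models from GTF and transcript FASTA
#'
#' Exon records are grouped per transcript, converted from GTF 1-based
#' inclusive to internal 0-based half-open coordinates and sorted. FASTA
#' headers are tokenized at the first whitespace; sequences are taken as
#' given (sense orientation, as in a reference transcriptome). Models whose
#' transcript id has no FASTA entry, or whose sequence length disagrees
#' with the summed exon length, are kept but flagged (`has_sequence =
#' FALSE`) with a warning.
#'
#' @param gtf_path GTF file with `exon` features carrying `transcript_id`
#'   and `gene_id` attributes.
#' @param fasta_path Transcriptome FASTA.
#' @param strip_versions Strip `.N` suffixes from ids before matching.
#' @return Named list of [transcript_model()] objects.
#' @export
load_gene_models <- function(gtf_path, fasta_path, strip_versions = FALSE) {
  gr <- rtracklayer::import(gtf_path)
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon records in ", gtf_path)
  tx_ids <- as.character(gr$transcript_id)
  gene_ids <- as.character(gr$gene_id)
  if (strip_versions) tx_ids <- strip_tx_version(tx_ids)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (strip_versions) names(seqs) <- strip_tx_version(names(seqs))

  models <- list()
  for (tx in unique(tx_ids)) {
    sel <- tx_ids == tx
    # GTF 1-based inclusive -> 0-based half-open
    exons <- cbind(start = GenomicRanges::start(gr[sel]) - 1L,
                   end   = GenomicRanges::end(gr[sel]))
    strand <- as.character(GenomicRanges::strand(gr[sel]))[1L]
    if (strand == "*") strand <- "+"
    seq <- NA_character_
    if (tx %in% names(seqs)) seq <- as.character(seqs[[tx]])
    model <- tryCatch(
      transcript_model(tx, gene_ids[sel][1L], strand, exons, sequence = seq),
      error = function(e) {
        if (grepl("overlapping exons", conditionMessage(e))) stop(e)
        warning("dropping sequence for ", tx, ": ", conditionMessage(e),
                call. = FALSE)
        transcript_model(tx, gene_ids[sel][1L], strand, exons)
      })
    if (!model$has_sequence && !tx %in% names(seqs)) {
      warning("no FASTA sequence for transcript ", tx, call. = FALSE)
    }
    models[[tx]] <- model
  }
  models
}

#' Export transcript models as GTF
#'
#' Writes `transcript` and `exon` features with 1-based inclusive
#' coordinates (the inverse of the import conversion).
#'
#' @param models Named list of [transcript_model()] objects.
#' @param path Output GTF path.
#' @param seqname Chromosome/contig name to write (synthetic models live on
#'   one artificial contig per gene by default).
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path, seqname = NULL) {
  grl <- lapply(models, function(m) {
    sn <- if (is.null(seqname)) m$gene_id else seqname
    n <- nrow(m$exons)
    GenomicRanges::GRanges(
      seqnames = sn,
      ranges = IRanges::IRanges(start = c(min(m$exons[, 1L]) + 1L,
                                          m$exons[, 1L] + 1L),
                                end = c(max(m$exons[, 2L]),
                                        m$exons[, 2L])),
      strand = m$strand,
      type = c("transcript", rep("exon", n)),
      source = "chronoswitch",
      transcript_id = m$transcript_id,
      gene_id = m$gene_id
    )
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write transcript sequences as FASTA
#'
#' @param models Named list of [transcript_model()] objects; models without
#'   sequence are skipped.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(models, path) {
  keep <- Filter(function(m) m$has_sequence, models)
  seqs <- Biostrings::DNAStringSet(vapply(keep, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(keep, `[[`, character(1), "transcript_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
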