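# fixtures built in code: tiny quant tables, hand-made transcript models
# and codon-level sequence constructors used across test files

write_quant_fixture <- function(rows, path = tempfile(fileext = ".sf"),
                                columns = c("Name", "Length",
                                            "EffectiveLength", "TPM",
                                            "NumReads")) {
  full <- data.frame(Name = rows$Name,
                     Length = rows$Length,
                     EffectiveLength = rows$EffectiveLength,
                     TPM = rows$TPM,
                     NumReads = rows$NumReads,
                     stringsAsFactors = FALSE)
  utils::write.table(full[, columns, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

quant_rows <- function(ids, tpm, length = 1000) {
  data.frame(Name = ids, Length = length, EffectiveLength = length - 200,
             TPM = tpm, NumReads = tpm * 10, stringsAsFactors = FALSE)
}

# codon-level CDS builder independent of the package generator
test_cds <- function(n_codons, body_codon = "GCT") {
  paste0("ATG", paste(rep(body_codon, n_codons - 1L), collapse = ""), "TAA")
}

# single-exon plus-strand model from a raw sequence
single_exon_model <- function(id, seq, gene = "G1", origin = 0,
                              strand = "+") {
  transcript_model(id, gene, strand,
                   cbind(origin, origin + nchar(seq)), seq)
}

toy_matrix <- function(values, times, gene_of_row = NULL) {
  if (is.null(gene_of_row)) gene_of_row <- rep("G1", nrow(values))
  ids <- rownames(values)
  time_course_matrix(values, times, stats::setNames(gene_of_row, ids))
}
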