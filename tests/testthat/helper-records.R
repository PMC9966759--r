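# Shared fixture builders. All fixtures are constructed in code.

make_records <- function(ids, seqs, fpkm = NULL) {
  df <- data.frame(gene_id = ids, sequence = seqs,
                   fpkm = if (is.null(fpkm)) NA_real_ else fpkm,
                   subset_label = NA_character_, stringsAsFactors = FALSE)
  df
}

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# random clean CDS: k sense codons plus a terminal stop
random_cds <- function(k, with_stop = TRUE) {
  body <- paste0(sample(sense_codons(), k, replace = TRUE), collapse = "")
  if (with_stop) paste0(body, "TAA") else body
}
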