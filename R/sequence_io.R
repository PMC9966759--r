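# Reading, validating and quality-filtering in-frame CDS sets.
#
# A gene set is held as a plain data.frame with one row per CDS:
#   gene_id (unique), sequence (uppercase DNA over A,C,G,T,N),
#   fpkm (numeric or NA), subset_label (character or NA).

new_gene_records <- function(gene_id, sequence,
                             fpkm = rep(NA_real_, length(gene_id)),
                             subset_label = rep(NA_character_, length(gene_id))) {
  data.frame(
    gene_id = as.character(gene_id),
    sequence = as.character(sequence),
    fpkm = as.numeric(fpkm),
    subset_label = as.character(subset_label),
    stringsAsFactors = FALSE
  )
}

#' Read a CDS FASTA file
#'
#' Reads a multi-record (possibly multi-line) FASTA of in-frame coding
#' sequences, one CDS per record, frame starting at the first base. Sequences
#' are uppercased and RNA spelling is converted to DNA (U -> T). The record id
#' is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A gene-record data.frame with columns `gene_id`, `sequence`,
#'   `fpkm` (NA), `subset_label` (NA).
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: file does not exist: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate gene ids in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- chartr("Uu", "Tt", as.character(x))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(
      "records with characters outside {A,C,G,T,N,U}: ",
      paste(ids[bad], collapse = ", ")
    )
  }
  short <- nchar(seqs) < 3L
  if (any(short)) {
    stop("records shorter than one codon: ", paste(ids[short], collapse = ", "))
  }
  new_gene_records(ids, unname(seqs))
}

#' Write gene records as FASTA
#'
#' @param records Gene-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_two_col_tsv <- function(path, value_col) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected a 2-column TSV with a header row: ", path)
  names(tab)[1:2] <- c("gene_id", value_col)
  tab[, 1:2]
}

#' Attach FPKM expression values to gene records
#'
#' @param records Gene-record data.frame.
#' @param table Path to a 2-column TSV (header row; gene_id, fpkm), or an
#'   equivalent data.frame.
#' @return `records` with `fpkm` filled where ids match. Table rows whose id
#'   matches no record are reported as a warning; records absent from the
#'   table keep `fpkm = NA`.
#' @export
attach_expression <- function(records, table) {
  tab <- if (is.character(table)) read_two_col_tsv(table, "fpkm") else table
  tab$fpkm <- as.numeric(tab$fpkm)
  if (any(!is.na(tab$fpkm) & tab$fpkm < 0)) {
    stop("negative FPKM values in expression table")
  }
  unmatched <- setdiff(tab$gene_id, records$gene_id)
  if (length(unmatched) > 0L) {
    warning("expression table rows with no matching record: ",
            paste(unmatched, collapse = ", "))
  }
  idx <- match(records$gene_id, tab$gene_id)
  hit <- !is.na(idx)
  records$fpkm[hit] <- tab$fpkm[idx[hit]]
  records
}

#' Attach gene-subset (family) labels to gene records
#'
#' @param records Gene-record data.frame.
#' @param table Path to a 2-column TSV (header row; gene_id, family), or an
#'   equivalent data.frame.
#' @return `records` with `subset_label` filled where ids match.
#' @export
attach_subsets <- function(records, table) {
  tab <- if (is.character(table)) read_two_col_tsv(table, "subset_label") else table
  unmatched <- setdiff(tab$gene_id, records$gene_id)
  if (length(unmatched) > 0L) {
    warning("subset table rows with no matching record: ",
            paste(unmatched, collapse = ", "))
  }
  idx <- match(records$gene_id, tab$gene_id)
  hit <- !is.na(idx)
  records$subset_label[hit] <- as.character(tab$subset_label)[idx[hit]]
  records
}

# split a sequence into complete codons (trailing 1-2 bases dropped)
split_codons <- function(sequence) {
  n <- floor(nchar(sequence) / 3L)
  if (n == 0L) return(character(0))
  starts <- 3L * seq_len(n) - 2L
  substring(sequence, starts, starts + 2L)
}

# number of in-frame stop codons strictly before the last complete codon
count_internal_stops <- function(sequence) {
  cods <- split_codons(sequence)
  k <- length(cods)
  if (k <= 1L) return(0L)
  sum(cods[-k] %in% STOP_CODONS)
}

#' Quality-filter a CDS set
#'
#' Removes sequences shorter than `min_len` bases, sequences whose fraction
#' of N exceeds `max_n_frac`, and sequences with more than
#' `max_internal_stops` in-frame stop codons before the final codon (the
#' terminal codon is never counted: a terminal stop is expected in a complete
#' CDS). Each failing record is tallied once, under its first failing rule in
#' the fixed order short -> N -> stops, so the report is deterministic.
#'
#' @param records Gene-record data.frame.
#' @param min_len Minimum sequence length in bases (default 200).
#' @param max_n_frac Maximum tolerated fraction of N over the whole sequence
#'   (default 0.10).
#' @param max_internal_stops Maximum tolerated internal stop codons
#'   (default 1; i.e. one internal stop is allowed).
#' @return A list with `records` (the retained rows, byte-identical to their
#'   inputs) and `report`, a one-row data.frame with `n_input`,
#'   `n_too_short`, `n_too_many_n`, `n_internal_stops`, `n_pass`.
#' @export
filter_cds <- function(records, min_len = 200L, max_n_frac = 0.10,
                       max_internal_stops = 1L) {
  stopifnot(min_len >= 3L)
  len <- nchar(records$sequence)
  n_count <- nchar(gsub("[^N]", "", records$sequence))
  too_short <- len < min_len
  too_many_n <- !too_short & (n_count / len > max_n_frac)
  stops <- vapply(records$sequence, count_internal_stops, integer(1),
                  USE.NAMES = FALSE)
  too_many_stops <- !too_short & !too_many_n & (stops > max_internal_stops)
  keep <- !(too_short | too_many_n | too_many_stops)
  if (any(keep & (len %% 3L != 0L))) {
    warning(sum(keep & (len %% 3L != 0L)),
            " retained record(s) have length not a multiple of 3; ",
            "trailing bases are ignored by codon counting")
  }
  report <- data.frame(
    n_input = length(len),
    n_too_short = sum(too_short),
    n_too_many_n = sum(too_many_n),
    n_internal_stops = sum(too_many_stops),
    n_pass = sum(keep)
  )
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, report = report)
}
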