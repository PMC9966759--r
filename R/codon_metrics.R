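# Per-gene codon usage metrics: codon counts, RSCU, Wright's ENC, the
# mutation-pressure expected-ENC curve, deviation ratios, and protein
# property indices (GRAVY, aromaticity).

#' Count sense codons in one CDS
#'
#' Counts complete, N-free codons; stop codons are tallied separately and
#' excluded from the sense-codon vector. Trailing bases beyond the last
#' complete codon are ignored with a warning.
#'
#' @param record One gene record or a bare sequence string.
#' @return Named integer vector over the 61 sense codons, with attribute
#'   `stops` (stop-codon tally).
#' @export
count_codons <- function(record) {
  sequence <- if (is.character(record)) record else record$sequence
  stopifnot(length(sequence) == 1L)
  if (nchar(sequence) %% 3L != 0L) {
    warning("sequence length not a multiple of 3; trailing bases ignored")
  }
  cods <- split_codons(sequence)
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  if (length(cods) == 0L) stop("no countable codons in sequence")
  tab <- table(factor(cods, levels = c(sense_codons(), STOP_CODONS)))
  counts <- as.integer(tab[sense_codons()])
  names(counts) <- sense_codons()
  attr(counts, "stops") <- sum(tab[STOP_CODONS])
  counts
}

#' Codon count matrix for a CDS set
#'
#' Fast pooled counting over many genes. Rows are genes (named by gene id),
#' columns the 61 sense codons in [sense_codons()] order; the `stops`
#' attribute holds the per-gene stop-codon tally. Codons containing N and
#' trailing bases are skipped.
#'
#' @param records Gene-record data.frame.
#' @return Integer matrix genes x 61 with attribute `stops`.
#' @export
codon_count_matrix <- function(records) {
  x <- Biostrings::DNAStringSet(records$sequence)
  freq <- Biostrings::trinucleotideFrequency(x, step = 3)
  counts <- freq[, sense_codons(), drop = FALSE]
  rownames(counts) <- records$gene_id
  attr(counts, "stops") <- unname(rowSums(freq[, STOP_CODONS, drop = FALSE]))
  counts
}

#' Relative synonymous codon usage
#'
#' RSCU of codon j of amino acid i is its observed count divided by the count
#' expected if all n_i synonymous codons of that amino acid were used
#' equally: RSCU_ij = x_ij / (sum_j x_ij / n_i). Within each observed family
#' the values sum to the family's degeneracy; 1 means no bias. Families with
#' zero occurrences yield NA (never 0); the 1-fold codons ATG and TGG are 1
#' when present.
#'
#' @param counts Named count vector over the 61 sense codons (as from
#'   [count_codons()] or one row of [codon_count_matrix()]).
#' @return Named numeric vector of 61 RSCU values.
#' @export
rscu <- function(counts) {
  fams <- synonymous_families()
  out <- stats::setNames(rep(NA_real_, length(sense_codons())), sense_codons())
  for (f in fams) {
    tot <- sum(counts[f])
    if (tot > 0) out[f] <- counts[f] / (tot / length(f))
  }
  out
}

#' Per-gene RSCU matrix
#'
#' @param counts Codon count matrix from [codon_count_matrix()].
#' @return Numeric matrix genes x 61 of RSCU values (NA for absent families).
#' @export
rscu_matrix <- function(counts) {
  fams <- synonymous_families()
  out <- matrix(NA_real_, nrow = nrow(counts), ncol = ncol(counts),
                dimnames = dimnames(counts))
  for (f in fams) {
    tot <- rowSums(counts[, f, drop = FALSE])
    scale <- ifelse(tot > 0, length(f) / tot, NA_real_)
    out[, f] <- counts[, f, drop = FALSE] * scale
  }
  out
}

#' Pooled (genome-level) RSCU
#'
#' Computed on the summed codon counts of the whole set — not the mean of
#' per-gene RSCU values.
#'
#' @param counts Codon count matrix.
#' @return data.frame with `amino_acid`, `codon`, `codon_rna`, `count`,
#'   `rscu`, sorted by amino acid.
#' @export
pooled_rscu <- function(counts) {
  total <- colSums(counts)
  r <- rscu(total)
  aa <- codon_to_aa()
  out <- data.frame(
    amino_acid = unname(aa), codon = names(r),
    codon_rna = chartr("T", "U", names(r)),
    count = as.integer(total), rscu = unname(r),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  out
}

# Wright's per-amino-acid homozygosity F = (n * sum(p_j^2) - 1) / (n - 1),
# defined only for n >= 2 total codons of that amino acid.
wright_f <- function(fam_counts) {
  n <- sum(fam_counts)
  if (n < 2) return(NA_real_)
  p <- fam_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons (ENC)
#'
#' ENC summarises how far a gene's codon usage departs from uniform use of
#' synonymous codons: 20 (one codon per amino acid, maximal bias) to 61
#' (uniform use). Per amino acid with at least two counted codons, the
#' homozygosity F is estimated; class means over the 2-, 3-, 4- and 6-fold
#' degenerate families (only defined, positive F values enter a mean) give
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61. A missing 3-fold mean
#' (Ile absent) is replaced by (F2 + F4)/2, Wright's own fallback; if any
#' other class mean is missing the gene's ENC is NA.
#'
#' @param counts Named count vector over the 61 sense codons.
#' @return ENC in [20, 61], or NA when too few families are observed.
#' @export
enc <- function(counts) {
  fams <- synonymous_families()
  deg <- family_degeneracy()
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in names(fams)) {
    k <- deg[[a]]
    if (k == 1L) next
    f <- wright_f(counts[fams[[a]]])
    if (!is.na(f) && f > 0) {
      f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
    }
  }
  fbar <- vapply(f_by_class, function(v) {
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  if (anyNA(fbar)) return(NA_real_)
  val <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(val, 61))
}

#' Expected ENC under mutation pressure alone
#'
#' When third-position base composition (GC3) is the only force shaping codon
#' usage, the expected ENC is 2 + s + 29 / (s^2 + (1 - s)^2) with s = GC3.
#' The curve is symmetric about s = 0.5 up to the linear term, peaks at
#' balanced composition (60.5 at s = 0.5) and falls towards the
#' composition extremes (31 at s = 0, 32 at s = 1).
#'
#' @param gc3 GC3 value(s) in [0, 1].
#' @return Expected ENC.
#' @export
expected_enc <- function(gc3) {
  if (any(gc3 < 0 | gc3 > 1)) stop("gc3 must be in [0, 1]")
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' The standard 1000-point expected-ENC curve
#'
#' Expected ENC evaluated at 1000 GC3 values equally spaced between 0.001
#' and 1.000.
#'
#' @return data.frame with `gc3` and `expected_enc`.
#' @export
expected_enc_curve <- function() {
  s <- seq(0.001, 1, by = 0.001)
  data.frame(gc3 = s, expected_enc = expected_enc(s))
}

#' Deviation ratio of observed from expected ENC
#'
#' (ENC_exp - ENC_obs) / ENC_exp, with ENC_exp = [expected_enc()] at the
#' gene's GC3. Near 0 under mutation pressure alone; positive when usage is
#' more biased than composition predicts.
#'
#' @param enc_obs Observed ENC value(s); NA propagates.
#' @param gc3 GC3 value(s) in [0, 1].
#' @return Deviation ratio(s).
#' @export
deviation_ratio <- function(enc_obs, gc3) {
  e <- expected_enc(gc3)
  (e - enc_obs) / e
}

#' Protein property indices from a CDS
#'
#' Translates the CDS (standard code) and returns the Kyte-Doolittle grand
#' average of hydropathy (GRAVY), the fraction of aromatic residues
#' (Phe, Tyr, Trp; AROMO), and the 20-amino-acid composition profile.
#' Codons containing N and stop codons are skipped (internal stops with a
#' warning).
#'
#' @param record One gene record or a bare sequence string.
#' @return List with `gravy`, `aromo`, `aa_profile` (named 20-vector summing
#'   to 1), `n_residues`.
#' @export
protein_indices <- function(record) {
  sequence <- if (is.character(record)) record else record$sequence
  cods <- split_codons(sequence)
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  is_stop <- cods %in% STOP_CODONS
  if (any(is_stop[-length(is_stop)])) {
    warning("internal stop codon(s) skipped during translation")
  }
  cods <- cods[!is_stop]
  if (length(cods) == 0L) stop("no translatable residues")
  aa <- codon_to_aa()[cods]
  prof_counts <- table(factor(aa, levels = names(KYTE_DOOLITTLE)))
  profile <- as.numeric(prof_counts) / length(aa)
  names(profile) <- names(KYTE_DOOLITTLE)
  list(
    gravy = mean(KYTE_DOOLITTLE[aa]),
    aromo = mean(aa %in% AROMATIC_AA),
    aa_profile = profile,
    n_residues = length(aa)
  )
}

# vectorised ENC over the rows of a codon count matrix
enc_by_gene <- function(counts) {
  apply(counts, 1L, enc)
}

# GC3 over sense codons only (stops excluded), from a count matrix
gc3_sense <- function(counts) {
  gc_cols <- third_base(colnames(counts)) %in% c("G", "C")
  tot <- rowSums(counts)
  ifelse(tot > 0, rowSums(counts[, gc_cols, drop = FALSE]) / tot, NA_real_)
}

# amino-acid profile matrix (genes x 20) from a codon count matrix
aa_profile_matrix <- function(counts) {
  aa <- codon_to_aa()
  ind <- outer(aa, names(KYTE_DOOLITTLE), `==`) * 1
  prof <- counts %*% ind
  colnames(prof) <- names(KYTE_DOOLITTLE)
  prof / pmax(rowSums(prof), 1)
}

#' Per-gene codon usage bias metrics
#'
#' One row per gene: length, codon-position GC fractions, sense-codon GC3,
#' ENC, deviation ratio, GRAVY, AROMO and FPKM. The `gc3` column used for
#' ENC-plot purposes counts G/C at the third position of sense codons only
#' (stops excluded), consistent with the codon table behind ENC.
#'
#' @param records Gene-record data.frame (quality-filtered).
#' @return data.frame of per-gene metrics, with the codon count matrix in
#'   attribute `counts` and the amino-acid profile matrix in attribute
#'   `aa_profile`.
#' @export
bias_metrics <- function(records) {
  counts <- codon_count_matrix(records)
  gcpos <- gc_by_position(records)
  prof <- aa_profile_matrix(counts)
  gravy <- as.numeric(prof %*% KYTE_DOOLITTLE)
  aromo <- rowSums(prof[, AROMATIC_AA, drop = FALSE])
  enc_v <- enc_by_gene(counts)
  gc3 <- gc3_sense(counts)
  out <- data.frame(
    gene_id = records$gene_id,
    length = nchar(records$sequence),
    n_codons = as.integer(rowSums(counts)),
    gc1 = gcpos$gc1, gc2 = gcpos$gc2, gc12 = gcpos$gc12,
    gc3 = gc3,
    enc = enc_v,
    deviation_ratio = deviation_ratio(enc_v, gc3),
    gravy = gravy, aromo = aromo,
    fpkm = records$fpkm,
    subset_label = records$subset_label,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- counts
  attr(out, "aa_profile") <- prof
  out
}
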