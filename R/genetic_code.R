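# Genetic-code tables shared across the package. All codons are DNA-alphabet
# (T, not U); conversion to RNA spelling happens only at report time.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#'
#' Codons are in DNA spelling and sorted alphabetically; this fixed order is
#' the column order of every codon-count and RSCU matrix in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

# codon -> one-letter amino acid, sense codons only
codon_to_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[sense_codons()]
}

# list: one-letter AA -> its synonymous codons (Ser, Leu, Arg as single
# 6-fold families, CodonW's standard-table convention)
synonymous_families <- function() {
  aa <- codon_to_aa()
  split(names(aa), aa)
}

# degeneracy (family size) per one-letter AA
family_degeneracy <- function() {
  vapply(synonymous_families(), length, integer(1))
}

# Kyte-Doolittle hydropathy, one-letter AA names
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AROMATIC_AA <- c("F", "Y", "W")

# third base of each codon
third_base <- function(codons) substr(codons, 3L, 3L)

#' Enumerate GC-conservative synonymous codon pairs
#'
#' A GC-conservative pair is two synonymous codons that differ only at the
#' third position by an A<->T or C<->G swap, so their relative usage is
#' unaffected by AT/GC mutation bias and GC-biased gene conversion. The
#' standard genetic code contains exactly 17 such pairs. `codon_a` carries
#' the A (or C) third base, `codon_b` the T (or G) third base.
#'
#' @return data.frame with columns `amino_acid`, `codon_a`, `codon_b`,
#'   `pair_class` (`"AT"` or `"CG"`).
#' @export
enumerate_conservative_pairs <- function() {
  aa <- codon_to_aa()
  codons <- names(aa)
  out <- list()
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i >= j) next
      ci <- codons[i]; cj <- codons[j]
      if (aa[ci] != aa[cj]) next
      if (substr(ci, 1, 2) != substr(cj, 1, 2)) next
      tb <- sort(c(third_base(ci), third_base(cj)))
      if (identical(tb, c("A", "T"))) {
        cls <- "AT"
      } else if (identical(tb, c("C", "G"))) {
        cls <- "CG"
      } else {
        next
      }
      a <- if (third_base(ci) %in% c("A", "C")) ci else cj
      b <- setdiff(c(ci, cj), a)
      out[[length(out) + 1L]] <- data.frame(
        amino_acid = unname(aa[ci]), codon_a = a, codon_b = b,
        pair_class = cls, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$amino_acid, res$codon_a), ]
  rownames(res) <- NULL
  res
}
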