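# Independent, from-definition oracles for RSCU and ENC, written before the
# package implementations and kept deliberately naive: an explicit genetic
# code table typed in by hand, plain loops, no shared helpers.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_sense <- sort(names(ORACLE_CODE)[ORACLE_CODE != "*"])

# codon counts of a sequence: plain loop over codon windows
oracle_count_codons <- function(sequence) {
  counts <- setNames(rep(0L, length(oracle_sense)), oracle_sense)
  i <- 1L
  while (i + 2L <= nchar(sequence)) {
    cod <- substr(sequence, i, i + 2L)
    if (cod %in% oracle_sense) counts[cod] <- counts[cod] + 1L
    i <- i + 3L
  }
  counts
}

# RSCU straight from the definition: observed count over the equal-use
# expectation within the codon's own synonymous family
oracle_rscu <- function(counts) {
  out <- setNames(rep(NA_real_, length(counts)), names(counts))
  for (cod in names(counts)) {
    syn <- names(ORACLE_CODE)[ORACLE_CODE == ORACLE_CODE[cod]]
    syn <- syn[syn %in% names(counts)]
    total <- 0
    for (sc in syn) total <- total + counts[[sc]]
    if (total > 0) out[cod] <- counts[[cod]] / (total / length(syn))
  }
  out
}

# Wright's ENC, codon by codon
oracle_enc <- function(counts) {
  aas <- unique(ORACLE_CODE[ORACLE_CODE != "*"])
  f_vals <- list()
  for (aa in aas) {
    syn <- names(ORACLE_CODE)[ORACLE_CODE == aa]
    k <- length(syn)
    if (k == 1L) next
    n <- 0
    for (sc in syn) n <- n + counts[[sc]]
    if (n < 2) next
    sum_p2 <- 0
    for (sc in syn) sum_p2 <- sum_p2 + (counts[[sc]] / n)^2
    f <- (n * sum_p2 - 1) / (n - 1)
    if (f > 0) f_vals[[length(f_vals) + 1L]] <- c(k = k, f = f)
  }
  if (length(f_vals) == 0L) return(NA_real_)
  fm <- do.call(rbind, f_vals)
  fbar <- function(k) {
    v <- fm[fm[, "k"] == k, "f"]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (any(is.na(c(f2, f3, f4, f6)))) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# brute-force scan of the code for synonymous third-position A<->T / C<->G
# codon pairs (the GC-conservative pairs)
oracle_conservative_pairs <- function() {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  found <- character(0)
  for (a in sense) {
    for (b in sense) {
      if (a >= b) next
      if (ORACLE_CODE[a] != ORACLE_CODE[b]) next
      if (substr(a, 1, 2) != substr(b, 1, 2)) next
      tb <- paste(sort(c(substr(a, 3, 3), substr(b, 3, 3))), collapse = "")
      if (tb %in% c("AT", "CG")) {
        found <- c(found, paste(a, b))
      }
    }
  }
  sort(found)
}
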