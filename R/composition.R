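# Nucleotide and dinucleotide composition by codon position.

BASES <- c("A", "C", "G", "T")

# bases at codon position p (1,2,3) over complete codons, N dropped
position_bases <- function(sequence, p) {
  n <- floor(nchar(sequence) / 3L)
  if (n == 0L) return(character(0))
  idx <- 3L * seq_len(n) - 3L + p
  b <- substring(sequence, idx, idx)
  b[b != "N"]
}

base_fractions <- function(bases) {
  if (length(bases) == 0L) return(stats::setNames(rep(NA_real_, 4), BASES))
  tab <- table(factor(bases, levels = BASES))
  as.numeric(tab) / length(bases) -> fr
  stats::setNames(fr, BASES)
}

#' Nucleotide composition by codon position for one CDS
#'
#' Fractions of A, C, G, T at codon positions 1, 2, 3 and overall, computed
#' over complete codons only, with N excluded from both numerator and
#' denominator. `gc12` is the mean of the first- and second-position GC
#' fractions.
#'
#' @param record One gene record (one-row data.frame or a list with a
#'   `sequence` element), or a bare sequence string.
#' @return A list with `by_position` (4 x 4 matrix: positions 1,2,3,all by
#'   base), and scalars `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`.
#' @export
position_composition <- function(record) {
  sequence <- if (is.character(record)) record else record$sequence
  stopifnot(length(sequence) == 1L)
  if (floor(nchar(sequence) / 3L) == 0L) {
    stop("sequence has no complete codon")
  }
  b1 <- position_bases(sequence, 1L)
  b2 <- position_bases(sequence, 2L)
  b3 <- position_bases(sequence, 3L)
  f1 <- base_fractions(b1)
  f2 <- base_fractions(b2)
  f3 <- base_fractions(b3)
  fa <- base_fractions(c(b1, b2, b3))
  gc <- function(f) unname(f["G"] + f["C"])
  list(
    by_position = rbind(pos1 = f1, pos2 = f2, pos3 = f3, all = fa),
    gc1 = gc(f1), gc2 = gc(f2), gc3 = gc(f3),
    gc12 = (gc(f1) + gc(f2)) / 2, gc_all = gc(fa)
  )
}

#' Per-gene GC content by codon position
#'
#' @param records Gene-record data.frame.
#' @return data.frame with `gene_id`, `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`.
#' @export
gc_by_position <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    pc <- position_composition(records$sequence[i])
    data.frame(gene_id = records$gene_id[i], gc1 = pc$gc1, gc2 = pc$gc2,
               gc3 = pc$gc3, gc12 = pc$gc12, gc_all = pc$gc_all)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled nucleotide composition over a CDS set
#'
#' Base counts are pooled over all genes before normalising (not averaged
#' per gene), so long genes weigh more — the convention used for
#' whole-transcriptome composition summaries.
#'
#' @param records Gene-record data.frame.
#' @return Same structure as [position_composition()].
#' @export
pooled_composition <- function(records) {
  counts <- matrix(0, nrow = 4, ncol = 4,
                   dimnames = list(c("pos1", "pos2", "pos3", "all"), BASES))
  for (s in records$sequence) {
    for (p in 1:3) {
      b <- position_bases(s, p)
      tab <- table(factor(b, levels = BASES))
      counts[p, ] <- counts[p, ] + as.numeric(tab)
      counts[4, ] <- counts[4, ] + as.numeric(tab)
    }
  }
  frac <- counts / rowSums(counts)
  gc <- function(p) unname(frac[p, "G"] + frac[p, "C"])
  list(by_position = frac, gc1 = gc("pos1"), gc2 = gc("pos2"),
       gc3 = gc("pos3"), gc12 = (gc("pos1") + gc("pos2")) / 2,
       gc_all = gc("all"))
}

# dinucleotide pairs (first base, second base) for one sequence at a junction
junction_pairs <- function(sequence, junction) {
  n <- floor(nchar(sequence) / 3L)
  if (n == 0L) return(NULL)
  if (junction == 12L) {
    i <- 3L * seq_len(n) - 2L
    j <- i + 1L
  } else if (junction == 23L) {
    i <- 3L * seq_len(n) - 1L
    j <- i + 1L
  } else if (junction == 31L) {
    # third base of codon k with first base of codon k+1; no pair crosses a
    # gene boundary (handled by the caller passing one gene at a time)
    if (n < 2L) return(NULL)
    i <- 3L * seq_len(n - 1L)
    j <- i + 1L
  } else {
    stop("junction must be one of 12, 23, 31")
  }
  cbind(substring(sequence, i, i), substring(sequence, j, j))
}

#' Observed/expected dinucleotide frequencies at a codon-position junction
#'
#' For each of the 16 dinucleotides at a junction (codon positions 1-2, 2-3,
#' or 3-1), computes the observed frequency over the pooled gene set, the
#' expected frequency as the product of the two marginal base frequencies at
#' the junction's own positions, and their ratio. Pairs containing N are
#' skipped entirely; junction 3-1 never pairs across gene boundaries. Under
#' equal base usage every dinucleotide has the reference frequency 1/16.
#'
#' @param records Gene-record data.frame.
#' @param junction One of 12, 23, 31.
#' @return data.frame with `junction`, `dinucleotide`, `observed`,
#'   `expected`, `ratio`, `reference` (the equal-frequency value 1/16).
#'   `ratio` is NA (with a warning) where `expected` is 0.
#' @export
dinucleotide_ratios <- function(records, junction) {
  junction <- as.integer(junction)
  pairs <- do.call(rbind, lapply(records$sequence, junction_pairs, junction))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no dinucleotide pairs at junction ", junction)
  }
  ok <- pairs[, 1] != "N" & pairs[, 2] != "N"
  pairs <- pairs[ok, , drop = FALSE]
  m1 <- base_fractions(pairs[, 1])
  m2 <- base_fractions(pairs[, 2])
  dinucs <- as.vector(t(outer(BASES, BASES, paste0)))
  obs_tab <- table(factor(paste0(pairs[, 1], pairs[, 2]), levels = dinucs))
  observed <- as.numeric(obs_tab) / nrow(pairs)
  expected <- as.numeric(m1[substr(dinucs, 1, 1)] * m2[substr(dinucs, 2, 2)])
  ratio <- ifelse(expected > 0, observed / expected, NA_real_)
  if (any(expected == 0)) {
    warning("expected frequency 0 for some dinucleotides at junction ",
            junction, "; their ratio is reported as NA")
  }
  data.frame(
    junction = junction, dinucleotide = dinucs,
    observed = observed, expected = expected, ratio = ratio,
    reference = 1 / 16
  )
}

#' Dinucleotide ratios at all three junctions
#'
#' @param records Gene-record data.frame.
#' @return Row-bound [dinucleotide_ratios()] tables for junctions 12, 23, 31.
#' @export
dinucleotide_table <- function(records) {
  do.call(rbind, lapply(c(12L, 23L, 31L), function(j) {
    dinucleotide_ratios(records, j)
  }))
}
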