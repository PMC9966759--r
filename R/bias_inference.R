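# Genome-level inference: PCA of the RSCU matrix, correlation screens,
# GC-conservative preferred-codon detection, subset-vs-background comparison.

# the 59 informative codons: 61 sense minus the 1-fold ATG and TGG
informative_codons <- function() {
  setdiff(sense_codons(), c("ATG", "TGG"))
}

#' Build the genes x 59 RSCU matrix for multivariate analysis
#'
#' Drops the invariant 1-fold codons (ATG, TGG) and imputes RSCU of absent
#' synonymous families at the neutral value 1 (the no-bias value, which adds
#' no spurious variance direction). Row order is input order.
#'
#' @param metrics [bias_metrics()] output (carries the count matrix), or a
#'   codon count matrix directly.
#' @param impute Value for undefined entries (default 1); set `NA` to keep
#'   them undefined and drop incomplete genes instead.
#' @return Numeric matrix genes x 59.
#' @export
build_rscu_matrix <- function(metrics, impute = 1) {
  counts <- if (is.matrix(metrics)) metrics else attr(metrics, "counts")
  if (nrow(counts) < 3L) stop("need at least 3 genes for an RSCU matrix")
  r <- rscu_matrix(counts)[, informative_codons(), drop = FALSE]
  if (is.na(impute)) {
    r <- r[stats::complete.cases(r), , drop = FALSE]
  } else {
    r[is.na(r)] <- impute
  }
  r
}

#' PCA of the RSCU matrix
#'
#' Principal components of the column-centred (not variance-scaled) RSCU
#' matrix: RSCU values share a common scale by construction, so no
#' per-codon rescaling is applied. The sign of PC1 is fixed so that it
#' correlates non-negatively with GC3 when `gc3` is supplied, making score
#' plots deterministic.
#'
#' @param mat Matrix from [build_rscu_matrix()].
#' @param gc3 Optional per-gene GC3 vector (row-aligned) for the sign
#'   convention.
#' @return List with `scores` (genes x k), `variance_fraction` (descending,
#'   summing to <= 1), and the `prcomp` fit.
#' @export
pca_rscu <- function(mat, gc3 = NULL) {
  fit <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  scores <- fit$x
  varfrac <- fit$sdev^2 / max(sum(fit$sdev^2), .Machine$double.eps)
  if (!is.null(gc3) && ncol(scores) >= 1L) {
    r <- suppressWarnings(stats::cor(scores[, 1L], gc3,
                                     use = "pairwise.complete.obs"))
    if (!is.na(r) && r < 0) {
      scores[, 1L] <- -scores[, 1L]
      fit$rotation[, 1L] <- -fit$rotation[, 1L]
    }
  }
  list(scores = scores, variance_fraction = varfrac, fit = fit)
}

# safe correlation test returning r, r^2, p, n
cor_row <- function(x, y, method = "pearson") {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(data.frame(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                         exact = FALSE))
  r <- unname(ct$estimate)
  data.frame(r = r, r_squared = r^2, p = ct$p.value, n = n)
}

#' Correlation screen of bias summaries against gene properties
#'
#' Correlates ENC and the first two RSCU principal components against GC3,
#' log2(FPKM + 1), GRAVY, AROMO and the first three principal components of
#' the 20-column amino-acid composition matrix. Missing values are deleted
#' pairwise and n is reported per pair; Benjamini-Hochberg adjusted p-values
#' accompany the raw ones.
#'
#' @param metrics [bias_metrics()] output.
#' @param scores PCA scores from [pca_rscu()] (row-aligned with `metrics`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with `response`, `predictor`, `r`, `r_squared`, `p`,
#'   `p_adj`, `n`.
#' @export
correlation_screen <- function(metrics, scores, method = "pearson") {
  prof <- attr(metrics, "aa_profile")
  aa_pcs <- NULL
  if (!is.null(prof) && nrow(prof) >= 3L) {
    aa_fit <- stats::prcomp(prof, center = TRUE, scale. = FALSE)
    k <- min(3L, ncol(aa_fit$x))
    aa_pcs <- aa_fit$x[, seq_len(k), drop = FALSE]
    colnames(aa_pcs) <- paste0("aa_pc", seq_len(k))
  }
  responses <- list(enc = metrics$enc)
  if (!is.null(scores)) {
    responses$pc1 <- scores[, 1L]
    if (ncol(scores) >= 2L) responses$pc2 <- scores[, 2L]
  }
  predictors <- list(
    gc3 = metrics$gc3,
    log2_fpkm = log2(metrics$fpkm + 1),
    gravy = metrics$gravy,
    aromo = metrics$aromo
  )
  if (!is.null(aa_pcs)) {
    for (j in colnames(aa_pcs)) predictors[[j]] <- aa_pcs[, j]
  }
  rows <- list()
  for (rn in names(responses)) {
    for (pn in names(predictors)) {
      row <- cor_row(responses[[rn]], predictors[[pn]], method = method)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(response = rn, predictor = pn), row
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Detect preferred codons from GC-conservative pair usage vs expression
#'
#' For each of the 17 GC-conservative synonymous codon pairs, the relative
#' usage count(codon_a) / (count(codon_a) + count(codon_b)) is computed per
#' gene (defined only where the pair occurs) and correlated across genes with
#' log2(FPKM + 1). A pair yields a preferred-codon call iff |r| exceeds
#' `r_threshold` and p is below `p_threshold`; the preferred codon is
#' `codon_a` when r > 0, else `codon_b`. Because both members of a pair share
#' the same GC category at the third base, these calls are immune to AT/GC
#' mutation bias and GC-biased gene conversion, isolating translational
#' selection.
#'
#' @param counts Codon count matrix ([codon_count_matrix()]), or a
#'   [bias_metrics()] data.frame carrying it.
#' @param fpkm Per-gene expression vector, row-aligned.
#' @param r_threshold Absolute-correlation call threshold (default 0.05).
#' @param p_threshold p-value call threshold (default 0.001).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: one row per pair with `amino_acid`, `codon_a`,
#'   `codon_b`, `pair_class`, `r`, `p`, `n_genes_used`, `preferred`
#'   (called codon or NA).
#' @export
detect_preferred_codons <- function(counts, fpkm, r_threshold = 0.05,
                                    p_threshold = 0.001, method = "pearson") {
  if (!is.matrix(counts)) {
    fpkm <- if (missing(fpkm)) counts$fpkm else fpkm
    counts <- attr(counts, "counts")
  }
  fpkm <- as.numeric(fpkm)
  if (sum(!is.na(fpkm)) < 10L) {
    stop("need at least 10 genes with expression values")
  }
  logx <- log2(fpkm + 1)
  if (stats::sd(logx, na.rm = TRUE) == 0) {
    warning("constant expression vector; all correlations undefined")
  }
  pairs <- enumerate_conservative_pairs()
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- counts[, pairs$codon_a[i]]
    b <- counts[, pairs$codon_b[i]]
    denom <- a + b
    rel <- ifelse(denom > 0, a / denom, NA_real_)
    cr <- cor_row(rel, logx, method = method)
    called <- !is.na(cr$r) && !is.na(cr$p) &&
      abs(cr$r) > r_threshold && cr$p < p_threshold
    data.frame(
      pairs[i, , drop = FALSE],
      r = cr$r, p = cr$p, n_genes_used = cr$n,
      preferred = if (called) {
        if (cr$r > 0) pairs$codon_a[i] else pairs$codon_b[i]
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare the codon bias of labelled gene subsets with the background
#'
#' Per family label, a two-sided Mann-Whitney (Wilcoxon rank-sum) test of the
#' family's ENC and GC3 against all unlabelled background genes. Families
#' with fewer than 3 genes with defined ENC are reported with their n and no
#' test.
#'
#' @param metrics [bias_metrics()] output with `subset_label` filled for
#'   family members (NA = background).
#' @return data.frame: `family`, `n`, `median_enc`, `median_gc3`,
#'   `enc_statistic`, `enc_p`, `gc3_statistic`, `gc3_p`.
#' @export
subset_bias_comparison <- function(metrics) {
  bg <- metrics[is.na(metrics$subset_label) & !is.na(metrics$enc), ]
  fams <- sort(unique(metrics$subset_label[!is.na(metrics$subset_label)]))
  if (length(fams) == 0L) stop("no subset labels present")
  rows <- lapply(fams, function(f) {
    fam <- metrics[!is.na(metrics$subset_label) & metrics$subset_label == f &
                     !is.na(metrics$enc), ]
    base <- data.frame(
      family = f, n = nrow(fam),
      median_enc = stats::median(fam$enc),
      median_gc3 = stats::median(fam$gc3),
      enc_statistic = NA_real_, enc_p = NA_real_,
      gc3_statistic = NA_real_, gc3_p = NA_real_
    )
    if (nrow(fam) >= 3L && nrow(bg) >= 3L) {
      we <- suppressWarnings(stats::wilcox.test(fam$enc, bg$enc,
                                                alternative = "two.sided"))
      wg <- suppressWarnings(stats::wilcox.test(fam$gc3, bg$gc3,
                                                alternative = "two.sided"))
      base$enc_statistic <- unname(we$statistic)
      base$enc_p <- we$p.value
      base$gc3_statistic <- unname(wg$statistic)
      base$gc3_p <- wg$p.value
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
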