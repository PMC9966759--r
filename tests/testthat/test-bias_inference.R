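test_that("RSCU matrix building imputes absent families at the neutral value", {
  counts <- matrix(0L, nrow = 3, ncol = 61,
                   dimnames = list(paste0("g", 1:3), sense_codons()))
  counts[, "GCT"] <- c(4L, 2L, 1L)
  counts[, "GCC"] <- c(0L, 2L, 3L)
  counts[, "TTT"] <- c(2L, 2L, 2L)  # Phe present, His absent everywhere
  mat <- build_rscu_matrix(counts)
  expect_equal(ncol(mat), 59L)
  expect_false(any(c("ATG", "TGG") %in% colnames(mat)))
  expect_true(all(mat[, "CAT"] == 1))  # His imputed at 1
  # defined entries pass through from the per-gene RSCU computation
  expect_equal(mat[2, "GCT"], unname(rscu(counts[2, ])["GCT"]))
  expect_error(build_rscu_matrix(counts[1:2, ]), "at least 3")
})

test_that("PCA handles degenerate inputs and fixes the PC1 sign to GC3", {
  all_one <- matrix(1, nrow = 4, ncol = 59,
                    dimnames = list(NULL, setdiff(sense_codons(),
                                                  c("ATG", "TGG"))))
  p <- pca_rscu(all_one)
  expect_equal(p$variance_fraction, rep(0, length(p$variance_fraction)),
               tolerance = 1e-12)

  # variation along a single codon axis -> PC1 carries all variance
  one_axis <- all_one
  one_axis[, "GCT"] <- c(0, 1, 2, 3)
  p1 <- pca_rscu(one_axis)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-12)
  expect_lt(sum(p1$variance_fraction), 1 + 1e-12)

  # sign convention: PC1 correlates non-negatively with gc3
  gc3 <- c(0.9, 0.6, 0.4, 0.1)
  p2 <- pca_rscu(one_axis, gc3 = gc3)
  expect_gte(cor(p2$scores[, 1], gc3), 0)
  p3 <- pca_rscu(one_axis, gc3 = rev(gc3))
  expect_gte(cor(p3$scores[, 1], rev(gc3)), 0)
})

test_that("PCA scores are invariant to row permutation up to the sign convention", {
  set.seed(301)
  ds <- generate_dataset(synthetic_config(n_genes = 60, seed = 301))
  met <- bias_metrics(ds$records)
  mat <- build_rscu_matrix(met)
  perm <- sample(nrow(mat))
  p_orig <- pca_rscu(mat, gc3 = met$gc3)
  p_perm <- pca_rscu(mat[perm, ], gc3 = met$gc3[perm])
  expect_equal(abs(p_perm$scores[, 1]), abs(p_orig$scores[perm, 1]),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(p_perm$variance_fraction, p_orig$variance_fraction,
               tolerance = 1e-8)
})

test_that("correlation screen recovers exact dependence and reports n", {
  set.seed(302)
  ds <- generate_dataset(synthetic_config(n_genes = 80, seed = 302))
  met <- bias_metrics(ds$records)
  scores <- cbind(PC1 = met$gc3, PC2 = rnorm(nrow(met)))  # PC1 == gc3
  tab <- correlation_screen(met, scores)
  row <- tab[tab$response == "pc1" & tab$predictor == "gc3", ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_equal(row$r_squared, 1, tolerance = 1e-9)
  expect_equal(row$n, nrow(met))
  expect_true(all(c("p", "p_adj") %in% names(tab)))
  expect_true(all(tab$n <= nrow(met)))
})

test_that("independent variables show no systematic significance", {
  set.seed(303)
  n_sig <- 0L
  n_tests <- 0L
  for (rep in 1:25) {
    x <- rnorm(400)
    y <- rnorm(400)
    ct <- cor.test(x, y)
    n_tests <- n_tests + 1L
    if (ct$p.value < 0.001) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)  # expectation 0.025 across 25 null tests
})

test_that("the 17 GC-conservative pairs match a brute-force scan of the code", {
  pairs <- enumerate_conservative_pairs()
  expect_equal(nrow(pairs), 17L)
  got <- sort(paste(pmin(pairs$codon_a, pairs$codon_b),
                    pmax(pairs$codon_a, pairs$codon_b)))
  expect_equal(got, oracle_conservative_pairs())
  # both members synonymous, never 1-fold or stop codons
  aa <- Biostrings::GENETIC_CODE
  expect_equal(unname(aa[pairs$codon_a]), unname(aa[pairs$codon_b]))
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in%
                     c(pairs$codon_a, pairs$codon_b)))
  # codon_a carries the A or C third base; classes partition 17 as 9 + 8
  expect_true(all(substr(pairs$codon_a, 3, 3) %in% c("A", "C")))
  expect_equal(as.vector(table(pairs$pair_class)[c("AT", "CG")]), c(9L, 8L))
})

test_that("relative pair usage is invariant to equal scaling of both codons", {
  set.seed(304)
  ds <- generate_dataset(synthetic_config(n_genes = 30, seed = 304))
  counts <- codon_count_matrix(ds$records)
  pairs <- enumerate_conservative_pairs()
  rel <- function(cts) {
    a <- cts[, pairs$codon_a[1]]; b <- cts[, pairs$codon_b[1]]
    ifelse(a + b > 0, a / (a + b), NA_real_)
  }
  scaled <- counts
  scaled[, pairs$codon_a[1]] <- scaled[, pairs$codon_a[1]] * 7L
  scaled[, pairs$codon_b[1]] <- scaled[, pairs$codon_b[1]] * 7L
  expect_equal(rel(scaled), rel(counts))
})

test_that("planted preferred codons are recovered and nulls stay silent", {
  set.seed(305)
  cfg <- synthetic_config(n_genes = 2000, selection_strength = 2.5,
                          seed = 305)
  ds <- generate_dataset(cfg)
  pref <- detect_preferred_codons(codon_count_matrix(ds$records),
                                  ds$records$fpkm)
  called <- pref$preferred[!is.na(pref$preferred)]
  expect_setequal(called, cfg$preferred_set)
})

test_that("degenerate expression inputs are handled explicitly", {
  set.seed(306)
  ds <- generate_dataset(synthetic_config(n_genes = 30, seed = 306))
  counts <- codon_count_matrix(ds$records)
  expect_error(detect_preferred_codons(counts, rep(NA_real_, 30)),
               "at least 10")
  expect_warning(
    out <- detect_preferred_codons(counts, rep(2, 30)),
    "constant expression"
  )
  expect_true(all(is.na(out$preferred)))
  expect_true(all(is.na(out$r)))
})

test_that("a subset shifted down in ENC is detected; a null subset is not", {
  set.seed(307)
  ds <- generate_dataset(synthetic_config(n_genes = 300, seed = 307,
                                          subset_families = c(NULLFAM = 30)))
  met <- bias_metrics(ds$records)
  # planted null family: drawn from the background distribution; n counts
  # the members with defined ENC
  cmp_null <- subset_bias_comparison(met)
  expect_equal(cmp_null$family, "NULLFAM")
  n_def <- sum(!is.na(met$subset_label) & !is.na(met$enc))
  expect_equal(cmp_null$n, n_def)

  # shifted family: subtract 10 from ENC of the family members
  met_shift <- met
  fam <- !is.na(met_shift$subset_label)
  met_shift$enc[fam] <- pmax(met_shift$enc[fam] - 10, 20)
  cmp_shift <- subset_bias_comparison(met_shift)
  expect_lt(cmp_shift$enc_p, 0.01)

  # family identical to the background: rank statistic at its null centre
  bg <- met[is.na(met$subset_label), ]
  dup <- rbind(bg, transform(bg,
                             gene_id = paste0(gene_id, "_dup"),
                             subset_label = "DUP"))
  cmp_dup <- subset_bias_comparison(dup)
  n_fam <- sum(!is.na(dup$subset_label) & !is.na(dup$enc))
  n_bg <- sum(is.na(dup$subset_label) & !is.na(dup$enc))
  expect_equal(cmp_dup$enc_statistic, n_fam * n_bg / 2, tolerance = 0.01)
})

test_that("a null family drawn from the background rarely rejects", {
  ps <- vapply(1:20, function(k) {
    ds <- generate_dataset(synthetic_config(n_genes = 200, seed = 1200 + k,
                                            subset_families = c(F1 = 30)))
    met <- bias_metrics(ds$records)
    subset_bias_comparison(met)$enc_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.85)
})

test_that("families with too few genes are reported without a test", {
  set.seed(308)
  ds <- generate_dataset(synthetic_config(n_genes = 50, seed = 308,
                                          subset_families = c(TINY = 2)))
  met <- bias_metrics(ds$records)
  cmp <- subset_bias_comparison(met)
  expect_equal(cmp$n[cmp$family == "TINY"], 2)
  expect_true(is.na(cmp$enc_p[cmp$family == "TINY"]))
})
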