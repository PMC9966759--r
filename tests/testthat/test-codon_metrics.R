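test_that("codon counting matches hand counts, skips N, warns on trailing bases", {
  counts <- count_codons("ATGGCTGCTGCCTAA")
  expect_equal(unname(counts["ATG"]), 1L)
  expect_equal(unname(counts["GCT"]), 2L)
  expect_equal(unname(counts["GCC"]), 1L)
  expect_equal(sum(counts), 4L)
  expect_equal(attr(counts, "stops"), 1L)

  counts2 <- count_codons("ATGNNNGCT")
  expect_equal(sum(counts2), 2L)
  expect_equal(unname(counts2[c("ATG", "GCT")]), c(1L, 1L))

  expect_warning(counts3 <- count_codons("ATGGC"), "trailing")
  expect_equal(sum(counts3), 1L)
})

test_that("the count matrix agrees with per-record counting", {
  set.seed(201)
  recs <- make_records(paste0("g", 1:30),
                       replicate(30, random_cds(sample(30:90, 1))))
  mat <- codon_count_matrix(recs)
  for (i in c(1, 7, 30)) {
    expect_equal(mat[i, ], count_codons(recs$sequence[i]),
                 ignore_attr = TRUE)
  }
  expect_equal(rownames(mat), recs$gene_id)
})

test_that("RSCU matches the definitional hand computation", {
  counts <- count_codons(paste0("GCT", "GCT", "GCC", "TAA"))
  r <- rscu(counts)
  expect_equal(unname(r["GCT"]), 2 / (3 / 4), tolerance = 1e-12)
  expect_equal(unname(r["GCC"]), 1 / (3 / 4), tolerance = 1e-12)
  expect_equal(unname(r[c("GCA", "GCG")]), c(0, 0))
  # absent families are NA, never 0
  expect_true(is.na(r["GGT"]))
})

test_that("equal use of all codons of every family gives RSCU 1 everywhere", {
  counts <- setNames(rep(3L, 61), sense_codons())
  expect_equal(unname(rscu(counts)), rep(1, 61), tolerance = 1e-12)
})

test_that("RSCU family sums equal the degeneracy for random genes", {
  set.seed(202)
  recs <- make_records(paste0("g", 1:50),
                       replicate(50, random_cds(sample(50:150, 1))))
  rmat <- rscu_matrix(codon_count_matrix(recs))
  fams <- split(sense_codons(), Biostrings::GENETIC_CODE[sense_codons()])
  for (f in fams) {
    sums <- rowSums(rmat[, f, drop = FALSE])
    present <- !is.na(sums)
    expect_equal(unname(sums[present]),
                 rep(length(f), sum(present)), tolerance = 1e-9)
  }
})

test_that("pooled RSCU is computed on summed counts, not averaged per gene", {
  set.seed(203)
  recs <- make_records(paste0("g", 1:10),
                       replicate(10, random_cds(sample(30:60, 1))))
  counts <- codon_count_matrix(recs)
  pooled <- pooled_rscu(counts)
  direct <- rscu(colSums(counts))
  expect_equal(pooled$rscu[match(names(direct), pooled$codon)],
               unname(direct), tolerance = 1e-12)
  # and the family-sum shape holds on the pooled table too
  gly <- pooled$rscu[pooled$amino_acid == "G"]
  expect_equal(sum(gly), 4, tolerance = 1e-9)
})

test_that("ENC hits its analytic extremes", {
  # all 61 sense codons used equally (large n) -> 61
  uniform <- setNames(rep(100L, 61), sense_codons())
  expect_equal(enc(uniform), 61, tolerance = 1e-9)
  # exactly one codon per amino acid -> 20
  one_per_aa <- setNames(rep(0L, 61), sense_codons())
  aa <- Biostrings::GENETIC_CODE[sense_codons()]
  for (a in unique(aa)) {
    one_per_aa[names(aa)[aa == a][1]] <- 50L
  }
  expect_equal(enc(one_per_aa), 20, tolerance = 1e-9)
})

test_that("ENC decreases as usage within families concentrates", {
  # one-parameter family: mix uniform usage with single-codon usage
  aa <- Biostrings::GENETIC_CODE[sense_codons()]
  concentrated <- setNames(rep(0, 61), sense_codons())
  for (a in unique(aa)) concentrated[names(aa)[aa == a][1]] <- 1
  uniform <- setNames(rep(1 / 61, 61), sense_codons()) * 61 / 61
  enc_at <- function(w) {
    mix <- round(600 * ((1 - w) * uniform / sum(uniform) +
                          w * concentrated / sum(concentrated)))
    enc(mix)
  }
  vals <- vapply(c(0, 0.3, 0.6, 0.9), enc_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("RSCU and ENC agree with the from-definition oracles on random genes", {
  set.seed(204)
  recs <- make_records(paste0("g", 1:200),
                       replicate(200, random_cds(sample(40:200, 1))))
  counts <- codon_count_matrix(recs)
  for (i in seq_len(nrow(counts))) {
    cts <- counts[i, ]
    expect_equal(rscu(cts), oracle_rscu(cts), tolerance = 1e-9)
    expect_equal(enc(cts), oracle_enc(cts), tolerance = 1e-9)
  }
})

test_that("expected ENC has its closed-form values and symmetry", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1), 32)
  expect_equal(expected_enc(0), 31)
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
  s <- seq(0.05, 0.95, by = 0.05)
  expect_equal(expected_enc(s) - s, expected_enc(1 - s) - (1 - s),
               tolerance = 1e-12)
  curve <- expected_enc_curve()
  expect_equal(nrow(curve), 1000L)
  expect_equal(range(curve$gc3), c(0.001, 1))
  # the curve peaks at (very nearly) balanced third-position composition;
  # the linear term shifts the grid argmax a touch above 0.5
  expect_lt(abs(curve$gc3[which.max(curve$expected_enc)] - 0.5), 0.005)
})

test_that("deviation ratio is zero on the curve and matches hand values", {
  expect_equal(deviation_ratio(expected_enc(0.3), 0.3), 0)
  expect_equal(deviation_ratio(40, 0.5), (60.5 - 40) / 60.5,
               tolerance = 1e-12)
  expect_true(is.na(deviation_ratio(NA_real_, 0.5)))
})

test_that("protein indices follow the Kyte-Doolittle table", {
  # poly-Ile
  ile <- paste0(strrep("ATT", 10), "TAA")
  pi_ile <- protein_indices(ile)
  expect_equal(pi_ile$gravy, 4.5)
  expect_equal(pi_ile$aromo, 0)
  # FFFF
  phe <- paste0(strrep("TTT", 4), "TAA")
  expect_equal(protein_indices(phe)$aromo, 1)
  # FG
  fg <- protein_indices("TTTGGA")
  expect_equal(fg$aromo, 0.5)
  expect_equal(fg$gravy, (2.8 + (-0.4)) / 2, tolerance = 1e-12)
  expect_equal(sum(fg$aa_profile), 1)
  # internal stops are skipped with a warning
  expect_warning(protein_indices("TTTTAAGGATGA"), "internal stop")
})

test_that("bias_metrics assembles consistent per-gene rows", {
  set.seed(205)
  recs <- make_records(paste0("g", 1:40),
                       replicate(40, random_cds(sample(67:150, 1))),
                       fpkm = rlnorm(40))
  met <- bias_metrics(recs)
  expect_equal(nrow(met), 40L)
  expect_true(all(met$enc >= 20 & met$enc <= 61, na.rm = TRUE))
  expect_equal(met$deviation_ratio,
               (expected_enc(met$gc3) - met$enc) / expected_enc(met$gc3))
  i <- 11
  pi_i <- protein_indices(recs$sequence[i])
  expect_equal(met$gravy[i], pi_i$gravy, tolerance = 1e-12)
  expect_equal(met$aromo[i], pi_i$aromo, tolerance = 1e-12)
  # sense-codon GC3 matches a direct recount
  cods <- substring(recs$sequence[i],
                    seq(1, nchar(recs$sequence[i]) - 2, 3),
                    seq(3, nchar(recs$sequence[i]), 3))
  cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
  expect_equal(met$gc3[i], mean(substr(cods, 3, 3) %in% c("G", "C")),
               tolerance = 1e-12)
})
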