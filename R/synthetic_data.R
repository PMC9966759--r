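# Synthetic CDS generator with known ground truth. Emulates the two regimes
# the downstream statistics are designed to separate: mutation pressure only
# (per-gene third-position GC preference drives codon choice) and
# translational selection (an expression-correlated boost for a designated
# preferred-codon set), plus corrupted records for filter testing.

#' Configuration for the synthetic CDS generator
#'
#' Defaults describe a de novo insect transcriptome CDS set: about a
#' thousand genes, lognormal CDS lengths with mean near 489 bp, per-gene
#' third-position GC preference spread widely over (0, 1) by a Beta law, and
#' lognormal FPKM expression. With `selection_strength = 0` codon choice
#' within each synonymous family depends only on the gene's GC3 parameter
#' (mutation-only regime); with positive strength, codons in
#' `preferred_set` receive a multiplicative boost `exp(strength * z)` where
#' z in [0, 1] is the gene's min-max-normalised log expression.
#'
#' @param n_genes Number of clean genes.
#' @param length_meanlog,length_sdlog Lognormal law for protein length in
#'   residues (defaults give mean CDS length about 489 bp incl. stop).
#' @param min_aa Minimum protein length in residues (default 66, so every
#'   clean CDS is at least 201 bp and passes the length filter).
#' @param gc3_shape1,gc3_shape2 Beta law for the per-gene GC3 preference
#'   (default Beta(2, 2): wide spread centred at 0.5).
#' @param selection_strength Non-negative selection coefficient (0 =
#'   mutation-only).
#' @param preferred_set Codons favoured in highly expressed genes (DNA
#'   spelling). Default: one member from each of five GC-conservative pairs.
#' @param expression_meanlog,expression_sdlog Lognormal FPKM law.
#' @param aa_profile Amino-acid sampling weights (named 20-vector; default
#'   uniform).
#' @param n_short,n_n_rich,n_multi_stop Planted corrupted records (default 0).
#' @param subset_families Named integer vector: how many clean genes to label
#'   per family (labels are assigned to random genes, i.e. null subsets).
#' @param seed Integer seed; fully determines the output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 1000L,
                             length_meanlog = log(162) - 0.45^2 / 2,
                             length_sdlog = 0.45,
                             min_aa = 66L,
                             gc3_shape1 = 2, gc3_shape2 = 2,
                             selection_strength = 0,
                             preferred_set = c("GCC", "GGC", "ACC",
                                               "GTG", "CTG"),
                             expression_meanlog = 1,
                             expression_sdlog = 1.5,
                             aa_profile = NULL,
                             n_short = 0L, n_n_rich = 0L, n_multi_stop = 0L,
                             subset_families = NULL,
                             seed = 1L) {
  if (selection_strength < 0) stop("selection_strength must be >= 0")
  if (gc3_shape1 <= 0 || gc3_shape2 <= 0 || length_sdlog < 0 ||
      expression_sdlog < 0) {
    stop("invalid distribution parameters")
  }
  if (is.null(aa_profile)) {
    aa_profile <- stats::setNames(rep(1 / 20, 20), names(KYTE_DOOLITTLE))
  }
  stopifnot(length(aa_profile) == 20L, all(aa_profile >= 0))
  bad <- setdiff(preferred_set, sense_codons())
  if (length(bad) > 0L) stop("preferred_set contains non-sense codons: ",
                             paste(bad, collapse = ", "))
  structure(list(
    n_genes = as.integer(n_genes),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_aa = as.integer(min_aa),
    gc3_shape1 = gc3_shape1, gc3_shape2 = gc3_shape2,
    selection_strength = selection_strength,
    preferred_set = preferred_set,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    aa_profile = aa_profile,
    n_short = as.integer(n_short), n_n_rich = as.integer(n_n_rich),
    n_multi_stop = as.integer(n_multi_stop),
    subset_families = subset_families,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# family structure cached for the sampler: per family, codons and which
# third bases are G/C
family_sampler_tables <- function() {
  fams <- synonymous_families()
  lapply(fams, function(cods) {
    list(codons = cods, is_gc = third_base(cods) %in% c("G", "C"))
  })
}

# codon sampling weights for one gene in one family
family_weights <- function(tab, s, boost) {
  w <- numeric(length(tab$codons))
  n_gc <- sum(tab$is_gc)
  n_at <- sum(!tab$is_gc)
  if (n_gc > 0L && n_at > 0L) {
    w[tab$is_gc] <- s / n_gc
    w[!tab$is_gc] <- (1 - s) / n_at
  } else {
    w[] <- 1 / length(w)
  }
  w * boost
}

#' Generate a synthetic CDS dataset with ground truth
#'
#' Each gene draws a protein length and a GC3 preference s; every residue's
#' amino acid is drawn from the profile and its codon from the gene's
#' synonymous-family weights (third-position G/C codons share probability s,
#' A/T codons 1 - s, optionally boosted for preferred codons in proportion
#' to expression). A terminal stop codon is appended. Corrupted records are
#' appended per the config. The seed fully determines the output.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (gene-record data.frame; `fpkm` and
#'   `subset_label` filled) and `truth` (per-record `gene_id`, `true_gc3`,
#'   `fpkm`, `n_residues`, `selected`, `corrupt_class`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  tabs <- family_sampler_tables()
  aa_names <- names(config$aa_profile)

  len_aa <- pmax(config$min_aa,
                 round(stats::rlnorm(n, config$length_meanlog,
                                     config$length_sdlog)))
  s <- stats::rbeta(n, config$gc3_shape1, config$gc3_shape2)
  fpkm <- stats::rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  # normalised log expression: empirical quantile of log FPKM in [0, 1]
  # (rank-based, so the selection gradient is not dominated by the
  # lognormal tails)
  lx <- log(fpkm)
  z <- if (n > 1L && diff(range(lx)) > 0) {
    (rank(lx) - 1) / (n - 1)
  } else {
    rep(0.5, n)
  }
  # one flat residue vector over all genes, codons chosen by vectorised
  # inverse-CDF sampling with per-gene synonymous-family weights
  gidx <- rep(seq_len(n), len_aa)
  aa_all <- sample(aa_names, length(gidx), replace = TRUE,
                   prob = config$aa_profile)
  codon_all <- character(length(gidx))
  mult_gene <- exp(config$selection_strength * z)
  for (a in names(tabs)) {
    rows <- which(aa_all == a)
    if (length(rows) == 0L) next
    tab <- tabs[[a]]
    k <- length(tab$codons)
    if (k == 1L) {
      codon_all[rows] <- tab$codons
      next
    }
    g <- gidx[rows]
    n_gc <- sum(tab$is_gc)
    n_at <- k - n_gc
    w <- matrix(0, nrow = length(rows), ncol = k)
    for (j in seq_len(k)) {
      base <- if (n_gc > 0L && n_at > 0L) {
        if (tab$is_gc[j]) s[g] / n_gc else (1 - s[g]) / n_at
      } else {
        rep(1 / k, length(rows))
      }
      boost <- if (tab$codons[j] %in% config$preferred_set) {
        mult_gene[g]
      } else {
        1
      }
      w[, j] <- base * boost
    }
    cw <- w / rowSums(w)
    for (j in 2:k) cw[, j] <- cw[, j] + cw[, j - 1L]
    u <- stats::runif(length(rows))
    pick <- rep(1L, length(rows))
    for (j in seq_len(k - 1L)) pick <- pick + (u > cw[, j])
    codon_all[rows] <- tab$codons[pick]
  }
  stop_cod <- sample(STOP_CODONS, n, replace = TRUE)
  seqs <- vapply(split(codon_all, gidx), paste0, character(1), collapse = "")
  seqs <- paste0(unname(seqs), stop_cod)

  ids <- sprintf("gene_%05d", seq_len(n))
  records <- new_gene_records(ids, seqs, fpkm = fpkm)
  truth <- data.frame(
    gene_id = ids, true_gc3 = s, fpkm = fpkm, n_residues = len_aa,
    selected = config$selection_strength > 0,
    corrupt_class = NA_character_, stringsAsFactors = FALSE
  )

  if (!is.null(config$subset_families)) {
    fams <- config$subset_families
    pool <- sample(ids, sum(fams))
    offset <- 0L
    for (f in names(fams)) {
      members <- pool[offset + seq_len(fams[[f]])]
      records$subset_label[match(members, records$gene_id)] <- f
      offset <- offset + fams[[f]]
    }
  }

  planted <- plant_corruptions(records, config)
  truth <- rbind(truth, attr(planted, "corrupt_truth"))
  list(records = planted, truth = truth, config = config)
}

random_sense_codons <- function(k) {
  sample(sense_codons(), k, replace = TRUE)
}

#' Append corrupted records that exercise the CDS quality filter
#'
#' Adds `n_short` records under 200 bp, `n_n_rich` records with > 10% N, and
#' `n_multi_stop` records with three internal stop codons (each corrupt
#' record fails exactly one rule). Uses the current RNG stream.
#'
#' @param records Gene-record data.frame to append to.
#' @param config A [synthetic_config()] (only the corruption counts are
#'   used).
#' @return The extended records, with the corrupt rows' ground truth in
#'   attribute `corrupt_truth`.
#' @export
plant_corruptions <- function(records, config) {
  mk <- function(class, i, seq) {
    id <- sprintf("corrupt_%s_%03d", class, i)
    list(rec = new_gene_records(id, seq),
         truth = data.frame(gene_id = id, true_gc3 = NA_real_,
                            fpkm = NA_real_, n_residues = NA_integer_,
                            selected = FALSE, corrupt_class = class,
                            stringsAsFactors = FALSE))
  }
  out <- list()
  for (i in seq_len(config$n_short)) {
    out[[length(out) + 1L]] <- mk("short", i,
      paste0(random_sense_codons(50L), collapse = ""))  # 150 bp
  }
  for (i in seq_len(config$n_n_rich)) {
    s <- paste0(random_sense_codons(100L), collapse = "")  # 300 bp
    pos <- sample(nchar(s), 45L)  # 15% N
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- "N"
    out[[length(out) + 1L]] <- mk("n_rich", i, paste0(chars, collapse = ""))
  }
  for (i in seq_len(config$n_multi_stop)) {
    cods <- random_sense_codons(100L)
    cods[sample(99L, 3L)] <- sample(STOP_CODONS, 3L, replace = TRUE)
    cods[100L] <- sample(STOP_CODONS, 1L)
    out[[length(out) + 1L]] <- mk("multi_stop", i,
                                  paste0(cods, collapse = ""))
  }
  if (length(out) == 0L) {
    attr(records, "corrupt_truth") <- NULL
    return(records)
  }
  recs <- do.call(rbind, c(list(records), lapply(out, `[[`, "rec")))
  rownames(recs) <- NULL
  attr(recs, "corrupt_truth") <- do.call(rbind, lapply(out, `[[`, "truth"))
  recs
}

#' Write a synthetic dataset to disk
#'
#' Emits `cds.fasta`, `expression.tsv`, `subsets.tsv` (if any labels) and
#' `truth.tsv` under `dir`.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cds_fasta(dataset$records, file.path(dir, "cds.fasta"))
  expr <- dataset$records[!is.na(dataset$records$fpkm),
                          c("gene_id", "fpkm")]
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sub <- dataset$records[!is.na(dataset$records$subset_label),
                         c("gene_id", "subset_label")]
  if (nrow(sub) > 0L) {
    utils::write.table(sub, file.path(dir, "subsets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
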