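# End-to-end orchestration: filter -> composition -> codon metrics ->
# bias inference (+ subset comparison), with TSV outputs and a run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default: the CDS quality
#' filter thresholds (200 bp / 10% N / 1 internal stop), the RSCU display
#' thresholds for preferred/avoided codons (1.5/0.5, with 1.25/0.75 as the
#' milder convention), the preferred-codon call thresholds (|r| > 0.05,
#' p < 0.001), and the correlation method. The config is serialised alongside
#' the outputs for provenance.
#'
#' @param fasta Path to the CDS FASTA (or NULL when records are passed to
#'   [run_pipeline()] directly).
#' @param expression Optional expression TSV path.
#' @param subsets Optional subset-label TSV path.
#' @param out_dir Output directory.
#' @param min_len,max_n_frac,max_internal_stops Filter thresholds.
#' @param rscu_preferred,rscu_avoided Display thresholds for the pooled RSCU
#'   table.
#' @param r_threshold,p_threshold Preferred-codon call thresholds.
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param seed Integer seed (only used by stochastic consumers; the pipeline
#'   itself is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, expression = NULL, subsets = NULL,
                            out_dir = "results",
                            min_len = 200L, max_n_frac = 0.10,
                            max_internal_stops = 1L,
                            rscu_preferred = 1.5, rscu_avoided = 0.5,
                            r_threshold = 0.05, p_threshold = 0.001,
                            cor_method = "pearson", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full codon-usage-bias analysis
#'
#' Executes filter -> composition -> per-gene metrics -> RSCU PCA ->
#' correlation screen -> preferred-codon detection (when expression is
#' available) -> subset comparison (when labels are available), writing all
#' tables under `config$out_dir` and returning a manifest. Identical inputs
#' and config give identical outputs. Genes entering PCA and correlations are
#' the filtered genes with defined ENC; the number excluded is recorded in
#' the manifest.
#'
#' @param config A [pipeline_config()].
#' @param records Optional gene-record data.frame, bypassing `config$fasta`.
#' @return The run manifest (list), invisibly containing all in-memory
#'   results in `$results`.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(records)) {
    records <- stage("read", read_cds_fasta(config$fasta))
  }
  if (!is.null(config$expression)) {
    records <- stage("expression", attach_expression(records,
                                                     config$expression))
  }
  if (!is.null(config$subsets)) {
    records <- stage("subsets", attach_subsets(records, config$subsets))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  filt <- stage("filter", filter_cds(records, config$min_len,
                                     config$max_n_frac,
                                     config$max_internal_stops))
  write_tsv(filt$report, file.path(config$out_dir, "filter_report.tsv"))
  kept <- filt$records
  if (nrow(kept) == 0L) stop("pipeline stage 'filter': no records pass")

  dinuc <- stage("composition", dinucleotide_table(kept))
  write_tsv(dinuc, file.path(config$out_dir, "dinucleotide_ratios.tsv"))
  pooled <- stage("composition", pooled_composition(kept))
  comp_tab <- data.frame(position = rownames(pooled$by_position),
                         pooled$by_position,
                         gc = rowSums(pooled$by_position[, c("G", "C")]))
  write_tsv(comp_tab, file.path(config$out_dir, "base_composition.tsv"))

  metrics <- stage("metrics", bias_metrics(kept))
  write_tsv(metrics, file.path(config$out_dir, "gene_metrics.tsv"))
  counts <- attr(metrics, "counts")
  prscu <- pooled_rscu(counts)
  prscu$preferred <- !is.na(prscu$rscu) & prscu$rscu > config$rscu_preferred
  prscu$avoided <- !is.na(prscu$rscu) & prscu$rscu < config$rscu_avoided
  write_tsv(prscu, file.path(config$out_dir, "pooled_rscu.tsv"))

  usable <- !is.na(metrics$enc)
  met_u <- metrics[usable, , drop = FALSE]
  attr(met_u, "counts") <- counts[usable, , drop = FALSE]
  attr(met_u, "aa_profile") <- attr(metrics, "aa_profile")[usable, ,
                                                           drop = FALSE]
  pca <- NULL
  screen <- NULL
  preferred <- NULL
  subset_cmp <- NULL
  if (nrow(met_u) >= 3L) {
    mat <- stage("pca", build_rscu_matrix(attr(met_u, "counts")))
    pca <- stage("pca", pca_rscu(mat, gc3 = met_u$gc3))
    scores <- data.frame(gene_id = met_u$gene_id,
                         pca$scores[, seq_len(min(5L, ncol(pca$scores))),
                                    drop = FALSE])
    write_tsv(scores, file.path(config$out_dir, "pca_scores.tsv"))
    write_tsv(data.frame(component = seq_along(pca$variance_fraction),
                         variance_fraction = pca$variance_fraction),
              file.path(config$out_dir, "pca_variance.tsv"))
    screen <- stage("correlations",
                    correlation_screen(met_u, pca$scores,
                                       method = config$cor_method))
    write_tsv(screen, file.path(config$out_dir, "correlation_screen.tsv"))
  }
  if (sum(!is.na(met_u$fpkm)) >= 10L) {
    preferred <- stage("preferred_codons",
                       detect_preferred_codons(attr(met_u, "counts"),
                                               met_u$fpkm,
                                               config$r_threshold,
                                               config$p_threshold,
                                               config$cor_method))
    write_tsv(preferred, file.path(config$out_dir, "preferred_codons.tsv"))
  }
  if (any(!is.na(met_u$subset_label))) {
    subset_cmp <- stage("subset_comparison", subset_bias_comparison(met_u))
    write_tsv(subset_cmp, file.path(config$out_dir, "subset_comparison.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cricketcub")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    n_input = filt$report$n_input,
    n_pass = filt$report$n_pass,
    n_enc_defined = sum(usable),
    n_enc_undefined = sum(!usable),
    n_with_expression = sum(!is.na(met_u$fpkm)),
    n_preferred_calls = if (is.null(preferred)) {
      NA_integer_
    } else {
      sum(!is.na(preferred$preferred))
    },
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$results <- list(
    filter_report = filt$report, metrics = metrics, pooled_rscu = prscu,
    dinucleotides = dinuc, composition = pooled, pca = pca, screen = screen,
    preferred = preferred, subset_comparison = subset_cmp
  )
  invisible(manifest)
}

#' ENC-GC3 plot with the mutation-pressure expected curve
#'
#' Scatter of per-gene (GC3, ENC) with the expected-ENC curve; genes with a
#' subset label are coloured by family over the grey background, mirroring
#' the standard ENC-plot presentation.
#'
#' @param metrics [bias_metrics()] output.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_enc_gc3 <- function(metrics) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_enc_gc3 requires ggplot2")
  }
  curve <- expected_enc_curve()
  df <- metrics[!is.na(metrics$enc), ]
  df$family <- ifelse(is.na(df$subset_label), "background", df$subset_label)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = df[df$family == "background", ],
      ggplot2::aes(x = gc3, y = enc),
      colour = "grey70", size = 0.6, alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = df[df$family != "background", ],
      ggplot2::aes(x = gc3, y = enc, colour = family),
      size = 1.2
    ) +
    ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = gc3, y = expected_enc)
    ) +
    ggplot2::labs(x = "GC3", y = "ENC", colour = "family") +
    ggplot2::theme_classic()
}
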