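#' Simulate a gene expression matrix coupled to gene-body methylation
#'
#' Expression is log-normal per gene; for GBM genes the log-expression is
#' linearly coupled to the gene-by-accession GBM liability planted by
#' [simulate_methylomes()], so a positive coupling makes GBM genes more
#' highly expressed in accessions with more gene-body methylation (and
#' hence, under the default latitudinal architecture, in the north).
#' Non-GBM genes are uncoupled. An optional per-sample library-size factor
#' can be planted to exercise normalization downstream.
#'
#' @param genotypes A `geno_table`.
#' @param annot An `annot_set`.
#' @param truth The `truth_record` from [simulate_methylomes()].
#' @param cfg The shared [sim_config()].
#' @param coupling Linear coefficient from GBM liability to log2
#'   expression; 0 decouples expression from methylation, negative values
#'   reverse the direction.
#' @param noise_sd Residual sd of log2 expression.
#' @param library_factor Optional named numeric vector (accession ->
#'   multiplicative factor) applied to every gene of that accession,
#'   simulating a library-size confounder.
#' @param environments Environment labels, matching the methylomes.
#' @return Tibble with `gene_id`, `accession`, `env`, `expression`.
#' @export
simulate_expression <- function(genotypes, annot, truth, cfg,
                                coupling = 0.5, noise_sd = 0.5,
                                library_factor = NULL,
                                environments = c("10C", "16C")) {
  stopf(inherits(truth, "truth_record"), "truth must be a truth_record")
  genes <- annot$features$feature_id[annot$features$type == "gene"]
  acc <- rownames(genotypes$calls)
  n <- length(acc)
  seeds <- derive_seeds(cfg$seed + 3L, 1)
  with_seed(seeds[1], {
    base <- rnorm(length(genes), 6, 1.5)          # log2 baseline per gene
    out <- vector("list", length(environments))
    for (e in seq_along(environments)) {
      mu <- matrix(base, length(genes), n)
      gbm_rows <- which(genes %in% rownames(truth$gbm_liability))
      if (length(gbm_rows) && coupling != 0)
        mu[gbm_rows, ] <- mu[gbm_rows, ] +
          coupling * truth$gbm_liability[genes[gbm_rows], , drop = FALSE]
      x <- 2^(mu + matrix(rnorm(length(genes) * n, 0, noise_sd), length(genes), n))
      if (!is.null(library_factor))
        x <- x * matrix(library_factor[acc], length(genes), n, byrow = TRUE)
      out[[e]] <- tibble::tibble(
        gene_id = rep(genes, n),
        accession = rep(acc, each = length(genes)),
        env = environments[e],
        expression = as.numeric(x))
    }
    dplyr::bind_rows(out)
  })
}
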