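#' Simulate a summarized expression matrix with planted DE genes
#'
#' Generates per-gene un-logged signals for a two-group (control vs
#' treated) design with a paired batch structure: batch b contributes one
#' control and one treated sample, and a shared batch offset on the log2
#' scale. Planted DE genes have their treated group shifted by
#' log2(multiplier) in the planted direction, so the ratio of group means
#' on the un-logged scale equals the multiplier in expectation.
#'
#' @param annotation A \code{genome_annotation} (genes are its promoters).
#' @param truth A \code{synthetic_truth} (\code{de_genes} are planted), or
#'   NULL for a null run.
#' @param n_per_group Samples per treatment group (>= 2); batches are
#'   paired across groups, one per replicate.
#' @param batch_effect_sd SD of the per-batch log2 offset.
#' @param noise_sd SD of the per-sample log2 noise.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 expression.
#' @param seed Integer seed.
#'
#' @return List of class \code{expression_set}: \code{signals} (genes x
#'   samples, un-logged, positive), \code{samples} (sample, treatment in
#'   \{control, treated\}, batch), \code{genes}.
#' @export
simulate_expression <- function(annotation,
                                truth = NULL,
                                n_per_group = 3,
                                batch_effect_sd = 0.3,
                                noise_sd = 0.2,
                                baseline_log2_mean = 7,
                                baseline_log2_sd = 1,
                                seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (n_per_group < 2)
    stop("n_per_group must be >= 2 to test a treatment effect")
  set.seed(as.integer(seed))
  genes <- annotation$promoters$gene
  ng <- length(genes)
  samples <- data.frame(
    sample = c(paste0("C", seq_len(n_per_group)),
               paste0("T", seq_len(n_per_group))),
    treatment = rep(c("control", "treated"), each = n_per_group),
    batch = paste0("b", rep(seq_len(n_per_group), 2)),
    stringsAsFactors = FALSE)

  base <- stats::rnorm(ng, baseline_log2_mean, baseline_log2_sd)
  eff <- numeric(ng)
  if (!is.null(truth) && nrow(truth$de_genes) > 0) {
    i <- match(truth$de_genes$gene, genes)
    if (anyNA(i)) stop("planted DE gene not present in annotation")
    eff[i] <- truth$de_genes$direction * log2(truth$de_genes$multiplier)
  }
  batch_off <- stats::rnorm(n_per_group, 0, batch_effect_sd)

  lg <- matrix(base, ng, 2 * n_per_group)
  treated <- samples$treatment == "treated"
  lg[, treated] <- lg[, treated] + eff
  lg <- sweep(lg, 2, batch_off[rep(seq_len(n_per_group), 2)], `+`)
  lg <- lg + matrix(stats::rnorm(length(lg), 0, noise_sd), ng)
  signals <- 2^lg
  dimnames(signals) <- list(genes, samples$sample)
  structure(list(signals = signals, samples = samples, genes = genes),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (%d batches)\n",
              nrow(x$signals), ncol(x$signals),
              length(unique(x$samples$batch))))
  invisible(x)
}
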