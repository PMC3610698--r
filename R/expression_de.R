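#' Test one gene for differential expression (treatment + batch)
#'
#' Fits an additive two-factor linear model on log2 signals
#' (\code{log2(signal) ~ treatment + batch}; the batch term is dropped
#' automatically when only one batch is present) and takes the marginal
#' F-test p-value for the treatment effect. Fold change and mean
#' difference are computed on the un-logged group means: fold is the
#' larger of the ratio and its reciprocal, with a direction flag; the
#' mean difference is the absolute difference of un-logged means. A gene
#' is selected when p < p_max AND fold > fold_min AND mean difference >
#' diff_min (defaults 0.05, 1.2, 10).
#'
#' @param signals Un-logged positive signals, one per sample.
#' @param treatment Factor/character with levels control, treated.
#' @param batch Factor/character batch labels (one level allowed).
#' @param gene Gene id used in messages.
#' @param p_max,fold_min,diff_min Selection thresholds.
#' @return One-row data frame: gene, p_value, fold_change, direction
#'   (+1 up in treated, -1 down), mean_difference, selected.
#' @export
de_test <- function(signals, treatment, batch = NULL, gene = "gene",
                    p_max = 0.05, fold_min = 1.2, diff_min = 10) {
  stopifnot(all(signals > 0), length(treatment) == length(signals))
  treatment <- factor(treatment, levels = c("control", "treated"))
  if (any(table(treatment) < 2))
    stop("need >= 2 samples per treatment group for gene ", gene)
  y <- log2(signals)
  use_batch <- !is.null(batch) && length(unique(batch)) > 1
  if (use_batch) {
    fit <- stats::lm(y ~ treatment + factor(batch))
  } else {
    fit <- stats::lm(y ~ treatment)
  }
  if (stats::df.residual(fit) == 0)
    stop("model for gene ", gene, " has zero residual degrees of freedom")
  dr <- withCallingHandlers(
    stats::drop1(fit, scope = ~treatment, test = "F"),
    warning = function(w) {
      # R^2 ~ 1 on low-noise synthetic genes; the F test is still exact
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- dr[["Pr(>F)"]][2]

  mc <- mean(signals[treatment == "control"])
  mt <- mean(signals[treatment == "treated"])
  ratio <- mt / mc
  data.frame(gene = gene, p_value = p,
             fold_change = max(ratio, 1 / ratio),
             direction = ifelse(ratio >= 1, 1L, -1L),
             mean_difference = abs(mt - mc),
             selected = p < p_max & max(ratio, 1 / ratio) > fold_min &
               abs(mt - mc) > diff_min,
             stringsAsFactors = FALSE)
}

#' Select differentially expressed genes by the three-criterion rule
#'
#' Applies \code{\link{de_test}} to every gene of an expression set and
#' partitions the selected genes by direction. Summary counts (selected,
#' up, down) are attached as attribute \code{"counts"} and logged.
#'
#' @param expr An \code{expression_set} (see
#'   \code{\link{simulate_expression}}), or a list with \code{signals}
#'   (genes x samples un-logged matrix) and \code{samples} (data frame
#'   with treatment and batch).
#' @param p_max,fold_min,diff_min Selection thresholds (defaults 0.05,
#'   1.2, 10).
#' @return Data frame with one row per gene (columns as in
#'   \code{de_test}); attribute \code{"counts"} holds n_selected, n_up,
#'   n_down.
#' @export
select_de_genes <- function(expr, p_max = 0.05, fold_min = 1.2,
                            diff_min = 10) {
  stopifnot(!is.null(expr$signals), !is.null(expr$samples))
  sm <- expr$samples
  out <- do.call(rbind, lapply(rownames(expr$signals), function(g)
    de_test(expr$signals[g, ], sm$treatment, sm$batch, gene = g,
            p_max = p_max, fold_min = fold_min, diff_min = diff_min)))
  rownames(out) <- NULL
  counts <- c(n_selected = sum(out$selected),
              n_up = sum(out$selected & out$direction == 1),
              n_down = sum(out$selected & out$direction == -1))
  message(sprintf("DE selection: %d genes (%d up, %d down) of %d",
                  counts[1], counts[2], counts[3], nrow(out)))
  attr(out, "counts") <- counts
  out
}
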