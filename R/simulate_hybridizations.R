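#' Simulate comparative two-channel hybridizations
#'
#' Generates log2 Cy3/Cy5 signals for every probe in the annotation across
#' \code{n_pairs} comparative (treatment vs control) hybridizations. The two
#' channels share a per-probe abundance term (the A dimension); the log
#' ratio M carries: the planted DMR shift (\code{effect}, consistent in sign
#' across hybridizations), an optional smooth intensity- and GC-dependent
#' dye bias, and independent Gaussian noise per probe per hybridization.
#'
#' Treatment samples are on the Cy3 channel and controls on Cy5, so
#' M = Cy5 - Cy3 is control minus treatment; the planted \code{effect} is
#' applied directly on the M scale.
#'
#' @param annotation A \code{genome_annotation}.
#' @param truth A \code{synthetic_truth} (planted DMRs shift M), or NULL
#'   for a null run.
#' @param noise_sd SD of the Gaussian M noise per probe per hybridization.
#' @param dye_bias_amplitude Amplitude of the smooth dye bias added to M:
#'   \code{amp * (0.8*(gc - mean(gc)) + 0.4*((A-10)^2 - var0))}. Zero
#'   disables it.
#' @param n_pairs Number of comparative hybridizations.
#' @param abundance_mean,abundance_sd Per-probe log2 abundance (the A
#'   baseline); the default mean of 10 keeps typical region intensities
#'   above the 9.5 filter.
#' @param planted_min_mean_A Floor on the mean abundance of the probes of
#'   each planted DMR (default 9.6, just above the 9.5 region filter):
#'   planted regions are defined as recoverable, so their intensity is
#'   guaranteed not to fall under the filter by chance. NULL disables.
#' @param seed Integer seed.
#'
#' @return An object of class \code{hyb_set}: list with \code{probes}
#'   (copied from the annotation), \code{cy3} and \code{cy5} (probes x
#'   hybridizations, log2), \code{n_pairs} and \code{treatment_channel}.
#' @export
simulate_hybridizations <- function(annotation,
                                    truth = NULL,
                                    noise_sd = 0.3,
                                    dye_bias_amplitude = 0,
                                    n_pairs = 3,
                                    abundance_mean = 10,
                                    abundance_sd = 0.5,
                                    planted_min_mean_A = 9.6,
                                    seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"),
            n_pairs >= 1, noise_sd > 0)
  set.seed(as.integer(seed))
  pb <- annotation$probes
  n <- nrow(pb)
  mids <- (pb$start + pb$end) / 2

  # planted M shift per probe
  delta <- numeric(n)
  if (!is.null(truth) && nrow(truth$dmrs) > 0) {
    for (j in seq_len(nrow(truth$dmrs))) {
      hit <- pb$chrom == truth$dmrs$chrom[j] &
        mids >= truth$dmrs$start[j] & mids < truth$dmrs$end[j]
      if (!any(hit))
        warning(sprintf("planted DMR %s:%d-%d covers no probes and cannot be recovered",
                        truth$dmrs$chrom[j], truth$dmrs$start[j],
                        truth$dmrs$end[j]))
      delta[hit] <- truth$dmrs$effect[j]
    }
  }

  a0 <- stats::rnorm(n, abundance_mean, abundance_sd)
  if (!is.null(planted_min_mean_A) && !is.null(truth) &&
      nrow(truth$dmrs) > 0) {
    for (j in seq_len(nrow(truth$dmrs))) {
      hit <- pb$chrom == truth$dmrs$chrom[j] &
        mids >= truth$dmrs$start[j] & mids < truth$dmrs$end[j]
      if (any(hit) && mean(a0[hit]) < planted_min_mean_A)
        a0[hit] <- a0[hit] + (planted_min_mean_A - mean(a0[hit]))
    }
  }
  gc0 <- pb$gc - mean(pb$gc)
  cy3 <- cy5 <- matrix(NA_real_, n, n_pairs,
                       dimnames = list(pb$probe_id,
                                       paste0("h", seq_len(n_pairs))))
  for (h in seq_len(n_pairs)) {
    A <- a0 + stats::rnorm(n, 0, 0.1)
    bias <- if (dye_bias_amplitude != 0) {
      dev2 <- (A - abundance_mean)^2
      dye_bias_amplitude * (0.8 * gc0 + 0.4 * (dev2 - mean(dev2)))
    } else 0
    M <- delta + bias + stats::rnorm(n, 0, noise_sd)
    cy5[, h] <- A + M / 2
    cy3[, h] <- A - M / 2
  }
  structure(list(probes = pb, cy3 = cy3, cy5 = cy5, n_pairs = n_pairs,
                 treatment_channel = "Cy3"),
            class = "hyb_set")
}

#' @export
print.hyb_set <- function(x, ...) {
  cat(sprintf("hyb_set: %d probes x %d comparative hybridizations (treatment on %s)\n",
              nrow(x$probes), x$n_pairs, x$treatment_channel))
  invisible(x)
}
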