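#' Simulate promoter sequences with planted motif occurrences
#'
#' Builds one random sequence per promoter, matching the promoter's length
#' and approximate CpG content (the planted CpG positions of the annotation
#' are written in as literal CG dinucleotides). A concrete instance of the
#' IUPAC consensus is then planted at the truth's recorded offsets, and in
#' a Bernoulli(\code{background_rate}) fraction of the remaining sequences
#' at a random offset.
#'
#' @param annotation A \code{genome_annotation}.
#' @param truth A \code{synthetic_truth} (its \code{motif_sites} are
#'   planted), or NULL for no planted sites.
#' @param motif_consensus IUPAC consensus string (e.g. \code{"TGYCCTGC..."});
#'   ambiguity codes are instantiated uniformly at random per planted site.
#' @param background_rate Probability that a sequence without a planted
#'   site receives one anyway.
#' @param seed Integer seed.
#'
#' @return A \code{Biostrings::DNAStringSet} named by gene id; zero-length
#'   set if the annotation has no promoters.
#' @export
simulate_promoter_sequences <- function(annotation,
                                        truth = NULL,
                                        motif_consensus = default_motif(),
                                        background_rate = 0,
                                        seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"),
            background_rate >= 0, background_rate <= 1)
  check_iupac(motif_consensus)
  set.seed(as.integer(seed))
  pr <- annotation$promoters
  if (nrow(pr) == 0) return(Biostrings::DNAStringSet())
  span <- annotation$params$upstream_bp + annotation$params$downstream_bp
  ml <- nchar(motif_consensus)
  if (ml > span)
    stop("motif is longer than the shortest promoter sequence")

  planted <- if (!is.null(truth)) truth$motif_sites else list()
  seqs <- character(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    g <- pr$gene[k]
    # base composition from the promoter's mean probe GC
    gc <- mean(annotation$probes$gc[annotation$probes$gene == g])
    if (!is.finite(gc)) gc <- 0.4
    s <- sample(c("A", "T", "C", "G"), span, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    # write planted CpGs in as literal CG dinucleotides
    rel <- annotation$cpg$pos[annotation$cpg$chrom == pr$chrom[k]] - pr$start[k]
    rel <- rel[rel >= 0 & rel < span - 1] + 1L  # 1-based
    if (length(rel)) { s[rel] <- "C"; s[rel + 1L] <- "G" }
    off <- NULL
    if (g %in% names(planted)) {
      off <- planted[[g]] + 1L  # stored 0-based
    } else if (background_rate > 0 && stats::runif(1) < background_rate) {
      off <- sample.int(span - ml + 1L, 1)
    }
    for (o in off)
      s[o:(o + ml - 1L)] <- instantiate_iupac(motif_consensus)
    seqs[k] <- paste(s, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- pr$gene
  out
}

#' Placeholder demo motif (synthetic stand-in)
#'
#' A 21-bp consensus used in demos and tests. It is a synthetic
#' placeholder: the analysis takes any consensus or PWM as input, and no
#' claim is made that this sequence matches any motif observed in real
#' data.
#' @return A character scalar.
#' @export
default_motif <- function() "GCTGCAWAGTTAGCGTTGCAG"

# IUPAC helpers ------------------------------------------------------------

check_iupac <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1 || nchar(consensus) < 4)
    stop("motif consensus must be a single string of length >= 4")
  ok <- strsplit(consensus, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("motif consensus contains non-IUPAC characters: ",
         paste(unique(strsplit(consensus, "")[[1]][!ok]), collapse = ", "))
  invisible(TRUE)
}

# draw one concrete DNA instance of an IUPAC consensus
instantiate_iupac <- function(consensus) {
  vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1), USE.NAMES = FALSE)
}
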