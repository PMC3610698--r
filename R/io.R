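#' Write a data frame as TSV with a provenance header
#'
#' Output files carry a single comment header line naming the producing
#' stage, its parameters and the package version, so every artifact is
#' self-describing. \code{read_stage_tsv} skips such headers.
#'
#' @param df Data frame.
#' @param path File path.
#' @param stage Stage name recorded in the header.
#' @param params Named list of parameters echoed into the header.
#' @return The path, invisibly.
#' @export
write_stage_tsv <- function(df, path, stage, params = list()) {
  ver <- as.character(utils::packageVersion("medipdmr"))
  ptxt <- if (length(params))
    paste(names(params), unlist(params), sep = "=", collapse = " ") else ""
  header <- sprintf("# stage=%s version=%s %s", stage, ver, ptxt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(trimws(header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_tsv
#' @export
read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write regions as BED
#'
#' BED6 when direction and p-value columns are present (name = gene,
#' score = -log10 region p, strand = +/- for hyper/hypo), BED3 otherwise.
#' Coordinates are already 0-based half-open.
#'
#' @param regions Region data frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (all(c("direction", "p_value") %in% names(regions))) {
    name <- if ("gene" %in% names(regions)) regions$gene else "."
    name[is.na(name)] <- "."
    score <- round(-log10(pmax(regions$p_value, 1e-300)), 3)
    bed <- data.frame(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
                      format(regions$end, scientific = FALSE, trim = TRUE),
                      name, score,
                      ifelse(regions$direction >= 0, "+", "-"))
  } else {
    bed <- data.frame(regions$chrom,
                      format(regions$start, scientific = FALSE, trim = TRUE),
                      format(regions$end, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read hybridizations as a pair table
#'
#' The pair-table dialect is one row per probe: probe_id, chrom, start,
#' end, gc, gene, then cy3_h/cy5_h log2 column pairs per hybridization.
#'
#' @param hyb A \code{hyb_set}.
#' @param path File path.
#' @return \code{read_pair_table} returns a \code{hyb_set} (probe table
#'   without gc/gene columns round-trips as NA).
#' @export
write_pair_table <- function(hyb, path) {
  df <- hyb$probes
  for (h in seq_len(hyb$n_pairs)) {
    df[[paste0("cy3_", h)]] <- hyb$cy3[, h]
    df[[paste0("cy5_", h)]] <- hyb$cy5[, h]
  }
  write_stage_tsv(df, path, stage = "simulate_hybridizations",
                  params = list(n_pairs = hyb$n_pairs,
                                treatment_channel = hyb$treatment_channel))
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  df <- read_stage_tsv(path)
  c3 <- grep("^cy3_", names(df)); c5 <- grep("^cy5_", names(df))
  stopifnot(length(c3) == length(c5), length(c3) >= 1)
  probes <- df[, setdiff(names(df), names(df)[c(c3, c5)]), drop = FALSE]
  cy3 <- as.matrix(df[, c3, drop = FALSE])
  cy5 <- as.matrix(df[, c5, drop = FALSE])
  rownames(cy3) <- rownames(cy5) <- probes$probe_id
  colnames(cy3) <- colnames(cy5) <- paste0("h", seq_along(c3))
  structure(list(probes = probes, cy3 = cy3, cy5 = cy5,
                 n_pairs = length(c3), treatment_channel = "Cy3"),
            class = "hyb_set")
}

#' Write a genome annotation to a directory of plain-text files
#'
#' Promoters and gene bodies as BED-like TSV, probes and CpG positions as
#' TSV, chromosome lengths as TSV.
#'
#' @param annotation A \code{genome_annotation}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stage_tsv(data.frame(chrom = names(annotation$chromosomes),
                             length = unname(annotation$chromosomes)),
                  file.path(dir, "chromosomes.tsv"), "generate_genome")
  write_stage_tsv(annotation$promoters, file.path(dir, "promoters.tsv"),
                  "generate_genome")
  write_stage_tsv(annotation$gene_bodies, file.path(dir, "gene_bodies.tsv"),
                  "generate_genome")
  write_stage_tsv(annotation$cpg, file.path(dir, "cpg_positions.tsv"),
                  "generate_genome")
  write_stage_tsv(annotation$probes, file.path(dir, "probes.tsv"),
                  "generate_genome")
  invisible(dir)
}
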