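# Genome feature statistics (size, GC, ORF counts and lengths, coding
# density, stable-RNA counts) and a side-by-side comparison table.

#' Genome feature statistics
#'
#' Computes the headline descriptive statistics of one annotated replicon:
#' size, GC percent over unambiguous bases, ORF count and mean length,
#' coding density, pseudogene/tRNA/rRNA counts and the rRNA operon count
#' (delegated to [groupRrnaOperons()]). Two coding-density variants are
#' reported: `coding_density_union` (percent of bases covered by at least
#' one CDS, circular-aware interval union) and `coding_density_summed`
#' (summed CDS lengths over size, which can exceed the union when genes
#' overlap).
#'
#' @param seq a [CircularSequence-class].
#' @param annotations an [AnnotationSet-class] for the same sequence.
#' @param include_pseudogenes count pseudogenes as ORFs (default `FALSE`).
#' @param operon_gap gap threshold forwarded to [groupRrnaOperons()].
#' @return one-row data.frame of class `genome_stats`.
#' @export
genomeStats <- function(seq, annotations, include_pseudogenes = FALSE,
                        operon_gap = 3000L) {
  if (seqID(seq) != annotations@sequence_id)
    stop("annotation sequence id ('", annotations@sequence_id,
         "') does not match sequence ('", seqID(seq), "')")
  L <- length(seq)
  freq <- Biostrings::letterFrequency(seq@seq, c("A", "C", "G", "T"))
  unamb <- sum(freq)
  gc_percent <- if (unamb > 0) 100 * sum(freq[c("C", "G")]) / unamb else NA_real_
  orf_types <- if (include_pseudogenes) c("CDS", "pseudogene") else "CDS"
  orfs <- featuresOfType(annotations, orf_types)
  orf_widths <- BiocGenerics::width(orfs)
  segs <- featureSegments(orfs, L)
  union_cov <- sum(BiocGenerics::width(IRanges::reduce(segs)))
  operons <- groupRrnaOperons(annotations, max_gap = operon_gap)
  out <- data.frame(
    genome_id = seqID(seq),
    size_bp = L,
    gc_percent = gc_percent,
    orf_count = length(orfs),
    pseudogene_count = length(featuresOfType(annotations, "pseudogene")),
    coding_density_union = 100 * union_cov / L,
    coding_density_summed = 100 * sum(orf_widths) / L,
    mean_orf_length = if (length(orfs)) mean(orf_widths) else NA_real_,
    trna_count = length(featuresOfType(annotations, "tRNA")),
    rrna_gene_count = length(featuresOfType(annotations, "rRNA")),
    rrna_operon_count = length(operons),
    stringsAsFactors = FALSE)
  class(out) <- c("genome_stats", class(out))
  out
}

#' Side-by-side genome statistics table
#'
#' Stacks [genomeStats()] rows into a fields-by-genomes table (one column
#' per genome), optionally written as TSV.
#'
#' @param stats a `genome_stats` data.frame or a list of them.
#' @param path optional output TSV path.
#' @param digits decimals for numeric fields in the written file (default 2).
#' @return data.frame with one row per statistic and one column per genome.
#' @export
compareStatsTable <- function(stats, path = NULL, digits = 2L) {
  if (is.data.frame(stats)) stats <- list(stats)
  if (!length(stats)) stop("no statistics to tabulate")
  df <- do.call(rbind, lapply(stats, as.data.frame))
  fields <- setdiff(names(df), "genome_id")
  out <- data.frame(feature = fields, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df)))
    out[[df$genome_id[i]]] <- unlist(df[i, fields], use.names = FALSE)
  if (!is.null(path)) {
    wr <- out
    for (j in seq_along(wr)[-1]) wr[[j]] <- round(wr[[j]], digits)
    utils::write.table(wr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
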