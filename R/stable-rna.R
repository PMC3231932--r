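# rRNA operon grouping, stable-RNA density and the cross-genome density
# survey (dedup / Candidatus exclusion / strict threshold / ranking).

#' Group rRNA genes into operons
#'
#' Single-linkage chaining of rRNA features along the (circular) genome:
#' consecutive rRNA features whose intervening gap is at most `max_gap`
#' bases belong to one operon. Intervening tRNA genes do not break a chain
#' (only rRNA-to-rRNA gaps are examined), and a chain split across the
#' circular junction is merged into one wrapped operon.
#'
#' @param annotations an [AnnotationSet-class].
#' @param max_gap largest allowed gap between consecutive rRNA genes of one
#'   operon, bases (default 3000; rRNA operons carry internal tRNAs and
#'   spacers, so the gap must comfortably exceed spacer lengths).
#' @return a [GenomicRanges::GRanges] of operon spans with metadata columns
#'   `n_members`, `subunits` (comma-joined, 16S/23S/5S order) and `wraps`;
#'   empty when there are no rRNA features.
#' @export
groupRrnaOperons <- function(annotations, max_gap = 3000L) {
  rr <- featuresOfType(annotations, "rRNA")
  seqid <- annotations@sequence_id
  if (!length(rr))
    return(GenomicRanges::GRanges(n_members = integer(0),
                                  subunits = character(0), wraps = logical(0)))
  L <- annotations@seq_length
  o <- order(BiocGenerics::start(rr), BiocGenerics::end(rr))
  rr <- rr[o]
  s <- BiocGenerics::start(rr)
  e <- BiocGenerics::end(rr)
  n <- length(rr)
  gap <- if (n > 1L) s[-1L] - cummax(e)[-n] - 1L else integer(0)
  cl <- cumsum(c(1L, as.integer(gap > max_gap)))
  ncl <- cl[n]
  # wrap-around: join last cluster to first when the junction gap is small
  wrap_merge <- FALSE
  if (!is.na(L) && ncl > 1L && annotationTopologyIsCircular(annotations)) {
    junction_gap <- (L - max(e)) + min(s) - 1L
    if (junction_gap <= max_gap) wrap_merge <- TRUE
  }
  spans <- lapply(seq_len(ncl), function(k) {
    i <- which(cl == k)
    sub <- S4Vectors::mcols(rr)$rrna_subunit[i]
    list(start = min(s[i]), end = max(e[i]), n = length(i),
         subunits = paste(intersect(c("16S", "23S", "5S"), sub), collapse = ","))
  })
  if (wrap_merge) {
    a <- spans[[ncl]]; b <- spans[[1L]]
    merged <- list(start = a$start, end = b$end + L, n = a$n + b$n,
                   subunits = paste(intersect(c("16S", "23S", "5S"),
                     unlist(strsplit(c(a$subunits, b$subunits), ","))),
                     collapse = ","))
    spans <- c(list(merged), spans[-c(1L, ncl)])
  }
  st <- vapply(spans, `[[`, numeric(1), "start")
  en <- vapply(spans, `[[`, numeric(1), "end")
  out <- GenomicRanges::GRanges(seqnames = seqid,
    ranges = IRanges::IRanges(start = st, end = en))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    n_members = vapply(spans, `[[`, numeric(1), "n"),
    subunits = vapply(spans, `[[`, character(1), "subunits"),
    wraps = if (!is.na(L)) en > L else rep(FALSE, length(en)))
  out[order(BiocGenerics::start(out))]
}

# the AnnotationSet does not carry topology; treat a known-length genome as
# circular for operon chaining (the package's target replicons are circular)
annotationTopologyIsCircular <- function(annotations) TRUE

#' rRNA operon density
#'
#' Operons per megabase: `operon_count / (genome_size / 1e6)`. The
#' full-precision value is returned; round for reporting.
#'
#' @param operon_count number of rRNA operons.
#' @param genome_size genome size in bases.
#' @return density in operons per Mbp.
#' @examples
#' round(rrnDensity(7, 1298316), 2)  # 5.39
#' @export
rrnDensity <- function(operon_count, genome_size) {
  if (genome_size <= 0) stop("genome size must be positive")
  operon_count / (genome_size / 1e6)
}

#' Read a genome-metadata table for the density survey
#'
#' Tab-separated columns: `genome_id`, `species`, `size_bp`, `rrna_operons`,
#' `trna_genes`, `candidatus` (0/1), `free_living` (0/1). Density and size
#' in Mbp are computed on ingest.
#'
#' @param path TSV file.
#' @return data.frame of survey records.
#' @export
readSurveyTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species", "size_bp", "rrna_operons", "trna_genes",
            "candidatus", "free_living")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("survey table misses column(s): ", paste(miss, collapse = ", "))
  if (any(df$size_bp <= 0)) stop("non-positive genome size in survey table")
  df$size_mbp <- df$size_bp / 1e6
  df$density <- df$rrna_operons / df$size_mbp
  df
}

#' Rank genomes by rRNA operon density under survey rules
#'
#' Applies, in order: (1) drop genomes flagged Candidatus or not free-living;
#' (2) deduplicate by species, keeping the highest-density representative;
#' (3) keep densities strictly above `threshold`; (4) rank by descending
#' density, ties broken by `genome_id`.
#'
#' @param records data.frame as returned by [readSurveyTable()] (a `density`
#'   column is computed from `rrna_operons` and `size_bp`/`size_mbp` if
#'   absent).
#' @param threshold strict lower density bound (default 2.9 operons/Mbp).
#' @param top_k size of the reported head slice (default 20).
#' @return list with `ranked` (full surviving table), `top` (first `top_k`
#'   rows) and filtering tallies.
#' @export
surveyRrnaDensity <- function(records, threshold = 2.9, top_k = 20L) {
  if (!nrow(records)) stop("empty survey input")
  df <- records
  if (!"density" %in% names(df)) {
    size_mbp <- if ("size_mbp" %in% names(df)) df$size_mbp else df$size_bp / 1e6
    df$density <- df$rrna_operons / size_mbp
  }
  as_flag <- function(x) as.logical(as.integer(x))
  keep <- !as_flag(df$candidatus) & as_flag(df$free_living)
  n_lifestyle <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  # best representative per species
  if (nrow(df)) {
    df <- df[order(df$species, -df$density, df$genome_id), , drop = FALSE]
    dedup <- !duplicated(df$species)
    n_dedup <- sum(!dedup)
    df <- df[dedup, , drop = FALSE]
  } else n_dedup <- 0L
  n_below <- sum(df$density <= threshold)
  df <- df[df$density > threshold, , drop = FALSE]
  df <- df[order(-df$density, df$genome_id), , drop = FALSE]
  rownames(df) <- NULL
  list(ranked = df, top = utils::head(df, top_k),
       threshold = threshold,
       dropped = c(lifestyle = n_lifestyle, duplicate_species = n_dedup,
                   below_threshold = n_below))
}

#' Write a ranked survey table
#'
#' @param survey result of [surveyRrnaDensity()].
#' @param path output TSV.
#' @param digits decimals for the reported density column (default 2).
#' @return `path`, invisibly.
#' @export
writeSurveyTable <- function(survey, path, digits = 2L) {
  df <- survey$ranked
  df$density <- round(df$density, digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
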