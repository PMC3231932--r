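# Codon usage bias: per-gene codon counts, reference-set relative
# adaptiveness (w), the geometric-mean adaptation index, RSCU, and ranking
# of translationally optimized genes.

# bacterial/plastid genetic code
geneticCode <- function(code = "11") Biostrings::getGeneticCode(code)

stopCodons <- function(code = "11") {
  gc <- geneticCode(code)
  names(gc)[gc == "*"]
}

# single-codon amino acids are uninformative for bias and are excluded from
# the adaptation index (code 11: ATG/Met, TGG/Trp)
singleCodonCodons <- function(code = "11") {
  gc <- geneticCode(code)
  aa <- gc[gc != "*"]
  fam <- split(names(aa), aa)
  unlist(fam[lengths(fam) == 1L], use.names = FALSE)
}

#' Count in-frame codons of a coding sequence
#'
#' Counts all in-frame codons (stop included). A gene is flagged invalid —
#' and excluded from downstream ranking — when its length is not a multiple
#' of three or it contains an in-frame internal stop codon; counting still
#' proceeds. Codons containing ambiguity codes are ignored.
#'
#' @param cds coding sequence (character or `DNAString`), 5'->3' on the
#'   coding strand.
#' @param gene_id identifier carried through to the ranking.
#' @param code NCBI genetic code id (default `"11"`, bacterial).
#' @return object of class `codon_counts`: list with `gene_id`, `counts`
#'   (named 64-vector), `valid`, `n_codons`.
#' @examples
#' codonCounts("ATGAAATAA", "toy")
#' @export
codonCounts <- function(cds, gene_id = "gene", code = "11") {
  s <- toupper(as.character(cds))
  len <- nchar(s)
  all_codons <- names(geneticCode(code))
  n3 <- len %/% 3L
  cod <- if (n3 > 0L)
    substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3)) else character(0)
  clean <- cod[grepl("^[ACGT]{3}$", cod)]
  counts <- table(factor(clean, levels = all_codons))
  counts <- stats::setNames(as.integer(counts), all_codons)
  stops <- stopCodons(code)
  internal_stop <- n3 > 1L && any(cod[-n3] %in% stops)
  valid <- (len %% 3L == 0L) && len > 0L && !internal_stop
  structure(list(gene_id = gene_id, counts = counts, valid = valid,
                 n_codons = length(clean), code = code),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("codon_counts '%s': %d codons, %s\n", x$gene_id, x$n_codons,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

pooledCounts <- function(reference) {
  mats <- vapply(reference, function(g) g$counts, numeric(64L))
  rowSums(mats)
}

#' Relative adaptiveness of codons from a reference gene set
#'
#' Pools codon counts over the reference genes (canonically, ribosomal
#' protein genes as proxies for the highly expressed set) and sets
#' `w(codon) = count / max(count over synonymous codons)`. Stop codons are
#' excluded; codons absent from the pooled reference get the floor value so
#' downstream geometric means stay positive.
#'
#' @param reference list of `codon_counts` objects.
#' @param floor value assigned to reference-absent codons (default 0.01).
#' @param code NCBI genetic code id.
#' @return object of class `adaptiveness`: list with `w` (named vector over
#'   the sense codons), `reference_ids`, `floor`.
#' @export
relativeAdaptiveness <- function(reference, floor = 0.01, code = "11") {
  if (!length(reference)) stop("empty reference set")
  pooled <- pooledCounts(reference)
  gc <- geneticCode(code)
  sense <- names(gc)[gc != "*"]
  aa <- gc[sense]
  w <- stats::setNames(numeric(length(sense)), sense)
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    m <- max(pooled[fam])
    if (m == 0)
      stop("reference set has no codon for amino acid ", a)
    w[fam] <- pooled[fam] / m
  }
  w[w == 0] <- floor
  structure(list(w = w, reference_ids = vapply(reference, `[[`, character(1),
                                               "gene_id"),
                 floor = floor, code = code),
            class = "adaptiveness")
}

#' Codon adaptation index of one gene
#'
#' Geometric mean of the relative adaptiveness `w` over the gene's codons,
#' excluding stop codons and the single-codon amino acids (ATG, TGG under
#' code 11). Equals 1 exactly when every counted codon is a major codon.
#'
#' @param gene a `codon_counts` object (must be valid).
#' @param w an `adaptiveness` object from [relativeAdaptiveness()].
#' @return score in (0, 1].
#' @export
adaptationIndex <- function(gene, w) {
  if (!gene$valid) stop("gene '", gene$gene_id, "' is not a valid CDS")
  use <- setdiff(names(w$w), singleCodonCodons(w$code))
  cnt <- gene$counts[use]
  total <- sum(cnt)
  if (total == 0)
    stop("gene '", gene$gene_id, "' has no countable codons")
  exp(sum(cnt * log(w$w[use])) / total)
}

#' Relative synonymous codon usage of one gene
#'
#' Observed codon count divided by its expectation under uniform synonymous
#' usage (family mean). Families with zero observations get `NA`.
#'
#' @param gene a `codon_counts` object.
#' @param code NCBI genetic code id.
#' @return named numeric vector over the sense codons.
#' @export
rscu <- function(gene, code = "11") {
  gc <- geneticCode(code)
  sense <- names(gc)[gc != "*"]
  aa <- gc[sense]
  out <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    tot <- sum(gene$counts[fam])
    if (tot > 0) out[fam] <- gene$counts[fam] / (tot / length(fam))
  }
  out
}

#' Rank genes by codon-bias adaptation index
#'
#' Scores every valid gene with [adaptationIndex()], sorts descending
#' (ties broken by `gene_id`) and reports the top slice together with
#' per-category counts inside it.
#'
#' @param genes list of `codon_counts` objects.
#' @param w an `adaptiveness` object.
#' @param top_k size of the reported head slice (default 80).
#' @param categories optional named character vector mapping `gene_id` to a
#'   category label (e.g. `"ribosomal"`).
#' @return list with `ranking` (data.frame `gene_id`, `score`), `top`,
#'   `category_counts` (table over labels within the top slice) and
#'   `short_of_top_k` flag (set, with a warning, when fewer valid genes than
#'   `top_k` exist).
#' @export
rankOptimized <- function(genes, w, top_k = 80L, categories = NULL) {
  valid <- Filter(function(g) g$valid, genes)
  short <- length(valid) < top_k
  if (short)
    warning("only ", length(valid), " valid genes for a top-", top_k, " ranking")
  if (!length(valid)) stop("no valid genes to rank")
  df <- data.frame(
    gene_id = vapply(valid, `[[`, character(1), "gene_id"),
    score = vapply(valid, adaptationIndex, numeric(1), w = w),
    stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  top <- utils::head(df, top_k)
  category_counts <- if (!is.null(categories)) {
    lab <- categories[top$gene_id]
    table(lab[!is.na(lab)])
  } else table(character(0))
  list(ranking = df, top = top, category_counts = category_counts,
       short_of_top_k = short)
}

#' Build codon count tables from annotated coding sequences
#'
#' Extracts every CDS of the annotation from the genome sequence (reverse
#' complemented for minus-strand genes, junction-wrapping aware) and counts
#' its codons.
#'
#' @param seq a [CircularSequence-class].
#' @param annotations an [AnnotationSet-class].
#' @param code NCBI genetic code id.
#' @return named list of `codon_counts`, one per CDS (named by locus tag).
#' @export
codonCountsFromAnnotation <- function(seq, annotations, code = "11") {
  cds <- featuresOfType(annotations, "CDS")
  if (!length(cds)) return(list())
  L <- length(seq)
  s2 <- paste0(residues(seq), residues(seq))  # wrap-safe extraction
  mc <- S4Vectors::mcols(cds)
  ids <- ifelse(is.na(mc$locus_tag), paste0("cds_", seq_along(cds)), mc$locus_tag)
  out <- lapply(seq_along(cds), function(i) {
    st <- BiocGenerics::start(cds)[i]
    en <- BiocGenerics::end(cds)[i]
    sub <- substr(s2, st, en)
    if (as.character(BiocGenerics::strand(cds))[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    codonCounts(sub, gene_id = ids[i], code = code)
  })
  names(out) <- ids
  out
}

#' Reference-set selection by product text
#'
#' Returns the locus tags of CDS features whose product matches `pattern`
#' (default the canonical highly-expressed proxy, ribosomal proteins).
#'
#' @param annotations an [AnnotationSet-class].
#' @param pattern regular expression matched against the product text.
#' @return character vector of locus tags.
#' @export
referenceGeneIds <- function(annotations, pattern = "ribosomal protein") {
  cds <- featuresOfType(annotations, "CDS")
  mc <- S4Vectors::mcols(cds)
  mc$locus_tag[!is.na(mc$product) &
                 grepl(pattern, mc$product, ignore.case = TRUE)]
}
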