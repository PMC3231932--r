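#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet
NULL

FEATURE_TYPES <- c("CDS", "rRNA", "tRNA", "pseudogene", "other")
RRNA_SUBUNITS <- c("16S", "23S", "5S", "none")
SKEW_CONVENTIONS <- c("G_minus_C", "C_minus_G")

#' CircularSequence: a nucleotide sequence with topology
#'
#' Holds one replicon: an identifier, the residues (as a
#' [Biostrings::DNAString], upper-cased on construction) and a topology flag.
#' Circular topology makes windows, motif scans and feature coordinates wrap
#' across the junction between the last and first base.
#'
#' @slot id single non-empty character, the sequence identifier.
#' @slot seq a [Biostrings::DNAString] over the IUPAC alphabet.
#' @slot topology `"circular"` or `"linear"`.
#' @exportClass CircularSequence
setClass("CircularSequence",
  representation(id = "character", seq = "DNAString", topology = "character"))

setValidity("CircularSequence", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@topology) != 1L || !object@topology %in% c("circular", "linear"))
    msg <- c(msg, "'topology' must be \"circular\" or \"linear\"")
  if (length(object@seq) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a CircularSequence
#'
#' @param id sequence identifier.
#' @param residues character string or `DNAString`; lower case is mapped to
#'   upper case, non-IUPAC characters are rejected.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return a [CircularSequence-class] object.
#' @examples
#' CircularSequence("chr", "acgtACGT")
#' @export
CircularSequence <- function(id, residues, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (is.character(residues)) residues <- toupper(residues)
  seq <- tryCatch(Biostrings::DNAString(residues), error = function(e)
    stop("non-IUPAC characters in sequence '", id, "': ", conditionMessage(e),
         call. = FALSE))
  new("CircularSequence", id = id, seq = seq, topology = topology)
}

#' @describeIn CircularSequence-class number of bases.
#' @param x a `CircularSequence`.
#' @export
setMethod("length", "CircularSequence", function(x) length(x@seq))

#' Accessors for CircularSequence
#'
#' `seqID()` returns the identifier, `residues()` the sequence as a plain
#' character string, `topology()` the topology flag.
#'
#' @param x a [CircularSequence-class].
#' @return character scalar.
#' @name circular-sequence-accessors
NULL

#' @rdname circular-sequence-accessors
#' @export
seqID <- function(x) x@id

#' @rdname circular-sequence-accessors
#' @export
residues <- function(x) as.character(x@seq)

#' @rdname circular-sequence-accessors
#' @export
topology <- function(x) x@topology

setMethod("show", "CircularSequence", function(object) {
  cat(sprintf("CircularSequence '%s': %d bp, %s\n",
              object@id, length(object@seq), object@topology))
})

#' AnnotationSet: typed genomic features on one sequence
#'
#' Wraps a [GenomicRanges::GRanges] whose metadata columns carry
#' `feature_type` (CDS, rRNA, tRNA, pseudogene, other), `locus_tag`, `gene`,
#' `product`, `rrna_subunit` (16S/23S/5S/none) and `wraps`. Coordinates are
#' 1-based inclusive. A feature spanning the circular junction is stored with
#' `end > seq_length` (never `end < start`) and `wraps = TRUE`; use
#' [featureSegments()] to split such features for interval arithmetic.
#'
#' @slot sequence_id id of the sequence the features annotate.
#' @slot seq_length length of that sequence in bases (`NA` if unknown).
#' @slot features a `GRanges`, sorted by start.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(sequence_id = "character", seq_length = "integer",
                 features = "GRanges"))

setValidity("AnnotationSet", function(object) {
  msg <- character(0)
  gr <- object@features
  mc <- S4Vectors::mcols(gr)
  need <- c("feature_type", "locus_tag", "gene", "product", "rrna_subunit", "wraps")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (length(object@sequence_id) != 1L || !nzchar(object@sequence_id))
    msg <- c(msg, "'sequence_id' must be a single non-empty string")
  if (length(gr)) {
    if (!all(mc$feature_type %in% FEATURE_TYPES))
      msg <- c(msg, "unknown feature_type")
    if (!all(mc$rrna_subunit %in% RRNA_SUBUNITS))
      msg <- c(msg, "unknown rrna_subunit")
    if (any(BiocGenerics::start(gr) < 1L))
      msg <- c(msg, "feature start < 1")
    L <- object@seq_length
    if (!is.na(L)) {
      ok_plain <- !mc$wraps & BiocGenerics::end(gr) <= L
      ok_wrap <- mc$wraps & BiocGenerics::end(gr) > L &
        (BiocGenerics::end(gr) - L) < BiocGenerics::start(gr)
      if (!all(ok_plain | ok_wrap))
        msg <- c(msg, "feature coordinates outside sequence (non-wrapping) or malformed wrap")
    }
    stranded <- mc$feature_type %in% c("CDS", "rRNA", "tRNA")
    if (any(stranded & !as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "CDS/rRNA/tRNA features must have strand + or -")
    if (is.unsorted(BiocGenerics::start(gr)))
      msg <- c(msg, "features must be sorted by start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationSet
#'
#' @param sequence_id id of the annotated sequence.
#' @param features a `GRanges` (metadata columns are completed with defaults)
#'   or a data.frame with columns `feature_type`, `start`, `end`, `strand` and
#'   optionally `locus_tag`, `gene`, `product`, `rrna_subunit`, `wraps`.
#' @param seq_length sequence length in bases, or `NA`.
#' @return an [AnnotationSet-class].
#' @examples
#' annotationSet("chr", data.frame(feature_type = "CDS", start = 1, end = 300,
#'                                 strand = "+"), seq_length = 1000)
#' @export
annotationSet <- function(sequence_id, features, seq_length = NA_integer_) {
  if (is.data.frame(features)) {
    df <- features
    n <- nrow(df)
    fill <- function(col, default) if (col %in% names(df)) df[[col]] else rep(default, n)
    gr <- GenomicRanges::GRanges(
      seqnames = rep(sequence_id, n),
      ranges = IRanges::IRanges(start = as.integer(df$start), end = as.integer(df$end)),
      strand = fill("strand", "*"))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      feature_type = as.character(df$feature_type),
      locus_tag = as.character(fill("locus_tag", NA_character_)),
      gene = as.character(fill("gene", NA_character_)),
      product = as.character(fill("product", NA_character_)),
      rrna_subunit = as.character(fill("rrna_subunit", "none")),
      wraps = as.logical(fill("wraps", FALSE)))
    features <- gr
  } else {
    mc <- S4Vectors::mcols(features)
    n <- length(features)
    defaults <- list(feature_type = "other", locus_tag = NA_character_,
                     gene = NA_character_, product = NA_character_,
                     rrna_subunit = "none", wraps = FALSE)
    for (col in names(defaults))
      if (!col %in% colnames(mc)) mc[[col]] <- rep(defaults[[col]], n)
    S4Vectors::mcols(features) <- mc[, names(defaults)]
  }
  if (length(features))
    features <- features[order(BiocGenerics::start(features),
                               BiocGenerics::end(features))]
  new("AnnotationSet", sequence_id = sequence_id,
      seq_length = as.integer(seq_length), features = features)
}

#' @describeIn AnnotationSet-class number of features.
#' @param x an `AnnotationSet`.
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@features))

#' Accessors for AnnotationSet
#'
#' `features()` returns the underlying `GRanges`; `featureType()` its
#' `feature_type` column; `featuresOfType()` the subset of a given type.
#'
#' @param x an [AnnotationSet-class].
#' @param type one of `"CDS"`, `"rRNA"`, `"tRNA"`, `"pseudogene"`, `"other"`.
#' @name annotation-set-accessors
NULL

#' @rdname annotation-set-accessors
#' @export
features <- function(x) x@features

#' @rdname annotation-set-accessors
#' @export
featureType <- function(x) S4Vectors::mcols(x@features)$feature_type

#' @rdname annotation-set-accessors
#' @export
featuresOfType <- function(x, type) {
  x@features[S4Vectors::mcols(x@features)$feature_type %in% type]
}

setMethod("show", "AnnotationSet", function(object) {
  tab <- table(factor(featureType(object), levels = FEATURE_TYPES))
  cat(sprintf("AnnotationSet on '%s' (%s bp): %d features\n",
              object@sequence_id,
              ifelse(is.na(object@seq_length), "?", object@seq_length),
              length(object@features)))
  cat(" ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
})

#' SkewProfile: windowed GC\% and GC skew
#'
#' Windowed nucleotide-composition profile of one sequence: for windows of
#' `window` bases anchored every `step` bases (wrapping on circular
#' sequences), the GC fraction and the GC skew under the recorded sign
#' convention.
#'
#' @slot sequence_id id of the profiled sequence.
#' @slot window,step window length and anchor spacing, bases.
#' @slot starts,centers 1-based window anchor and center positions.
#' @slot gc_percent GC fraction per window, in `[0, 1]`.
#' @slot skew GC skew per window, in `[-1, 1]`.
#' @slot convention `"G_minus_C"` for (G-C)/(G+C), `"C_minus_G"` for the negation.
#' @exportClass SkewProfile
setClass("SkewProfile",
  representation(sequence_id = "character", window = "integer", step = "integer",
                 starts = "integer", centers = "integer",
                 gc_percent = "numeric", skew = "numeric", convention = "character"))

setValidity("SkewProfile", function(object) {
  msg <- character(0)
  n <- length(object@starts)
  if (length(object@centers) != n || length(object@gc_percent) != n ||
      length(object@skew) != n)
    msg <- c(msg, "starts, centers, gc_percent and skew must have equal length")
  if (any(object@gc_percent < 0 | object@gc_percent > 1, na.rm = TRUE))
    msg <- c(msg, "gc_percent outside [0, 1]")
  if (any(abs(object@skew) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "|skew| > 1")
  if (!object@convention %in% SKEW_CONVENTIONS)
    msg <- c(msg, "unknown sign convention")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SkewProfile", function(object) {
  cat(sprintf(
    "SkewProfile of '%s': %d windows (window %d, step %d, %s)\n  GC%% %.1f-%.1f, skew %+.3f..%+.3f\n",
    object@sequence_id, length(object@starts), object@window, object@step,
    object@convention, 100 * min(object@gc_percent), 100 * max(object@gc_percent),
    min(object@skew), max(object@skew)))
})

#' CumulativeSkew: per-base running skew sum
#'
#' Running sum over bases of +1 for G and -1 for C (under `G_minus_C`;
#' negated under `C_minus_G`), starting at `start_phase` and wrapping on
#' circular sequences. Its global minimum marks the replication origin and
#' its global maximum the terminus (under `G_minus_C`).
#'
#' @slot sequence_id id of the sequence walked.
#' @slot values numeric vector, one running-sum value per base.
#' @slot start_phase 1-based position where the walk begins.
#' @slot convention sign convention of the contributions.
#' @exportClass CumulativeSkew
setClass("CumulativeSkew",
  representation(sequence_id = "character", values = "numeric",
                 start_phase = "integer", convention = "character"))

setMethod("show", "CumulativeSkew", function(object) {
  cat(sprintf(
    "CumulativeSkew of '%s': %d bases from phase %d (%s), final %g, range [%g, %g]\n",
    object@sequence_id, length(object@values), object@start_phase,
    object@convention, object@values[length(object@values)],
    min(object@values), max(object@values)))
})

#' ReplicationPrediction: predicted oriC/terminus and replichore layout
#'
#' @slot sequence_id id of the predicted sequence.
#' @slot ori,ter 1-based predicted origin and terminus positions.
#' @slot method free-text description of the predictor.
#' @slot genome_length sequence length, bases.
#' @slot replichore_lengths named integer vector (replichore1 = ori to ter in
#'   increasing coordinates, replichore2 the complement); sums to the length.
#' @slot lead_strand_cds_fraction per-replichore fraction of CDSs coded on the
#'   leading strand (`NA` when no annotation was supplied).
#' @slot dnaA_distance circular distance from predicted ori to the annotated
#'   dnaA start (`NA` without annotation).
#' @slot dnaA_supported `TRUE` when that distance is within the support
#'   threshold.
#' @slot convention sign convention the prediction was made under.
#' @exportClass ReplicationPrediction
setClass("ReplicationPrediction",
  representation(sequence_id = "character", ori = "integer", ter = "integer",
                 method = "character", genome_length = "integer",
                 replichore_lengths = "integer",
                 lead_strand_cds_fraction = "numeric",
                 dnaA_distance = "numeric", dnaA_supported = "logical",
                 convention = "character"))

setValidity("ReplicationPrediction", function(object) {
  msg <- character(0)
  if (object@ori == object@ter) msg <- c(msg, "ori must differ from ter")
  if (sum(object@replichore_lengths) != object@genome_length)
    msg <- c(msg, "replichore lengths must sum to the genome length")
  f <- object@lead_strand_cds_fraction
  if (any(!is.na(f) & (f < 0 | f > 1)))
    msg <- c(msg, "leading-strand fractions outside [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReplicationPrediction", function(object) {
  cat(sprintf("ReplicationPrediction for '%s' (%s):\n", object@sequence_id,
              object@method))
  cat(sprintf("  ori %d, ter %d (of %d bp); replichores %d / %d bp\n",
              object@ori, object@ter, object@genome_length,
              object@replichore_lengths[1], object@replichore_lengths[2]))
  if (!all(is.na(object@lead_strand_cds_fraction)))
    cat(sprintf("  leading-strand CDS fraction: %.3f / %.3f\n",
                object@lead_strand_cds_fraction[1],
                object@lead_strand_cds_fraction[2]))
  if (!is.na(object@dnaA_distance))
    cat(sprintf("  dnaA start at circular distance %d (%s)\n",
                as.integer(object@dnaA_distance),
                if (isTRUE(object@dnaA_supported)) "dnaA-supported" else "not supported"))
})

#' @describeIn ReplicationPrediction-class predicted origin position.
#' @param x a `ReplicationPrediction`.
#' @export
oriPosition <- function(x) x@ori

#' @describeIn ReplicationPrediction-class predicted terminus position.
#' @export
terPosition <- function(x) x@ter
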