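# GC%/GC-skew profiles, cumulative skew, ori/ter prediction, genome rotation
# and replication-strand bias statistics.

# per-base indicator vectors; bases other than A,C,G,T count in none of them
baseIndicators <- function(seq) {
  chars <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
  list(G = as.integer(chars == "G"), C = as.integer(chars == "C"),
       A = as.integer(chars == "A"), T = as.integer(chars == "T"))
}

#' Windowed GC content and GC skew
#'
#' Slides a window of `window` bases anchored at positions 1, 1+step,
#' 1+2*step, ... over the sequence. On circular sequences windows wrap across
#' the junction and there are `ceiling(L/step)` of them; on linear sequences
#' only fully contained windows are emitted. Per window,
#' `gc_percent = (G+C)/(A+C+G+T)` and `skew = (G-C)/(G+C)` under the
#' `G_minus_C` convention (negated under `C_minus_G`); ambiguity codes are
#' excluded from both denominators and windows with no G or C get skew 0.
#'
#' @param seq a [CircularSequence-class].
#' @param window window length, bases (default 10000).
#' @param step anchor spacing, bases (default 200).
#' @param convention skew sign convention.
#' @return a [SkewProfile-class]; window centers are
#'   `start + floor(window/2)` (wrapped).
#' @examples
#' s <- CircularSequence("x", strrep("GGGGCCCCAT", 200))
#' windowedProfile(s, window = 100, step = 50)
#' @export
windowedProfile <- function(seq, window = 10000L, step = 200L,
                            convention = c("G_minus_C", "C_minus_G")) {
  convention <- match.arg(convention)
  window <- as.integer(window)
  step <- as.integer(step)
  L <- length(seq)
  if (L == 0L) stop("empty sequence")
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > L) stop("window (", window, ") exceeds sequence length (", L, ")")
  ind <- baseIndicators(seq@seq)
  circular <- topology(seq) == "circular"
  starts <- if (circular) seq.int(1L, L, by = step)
            else seq.int(1L, L - window + 1L, by = step)
  ext <- function(v) if (circular) c(v, v[seq_len(window - 1L)]) else v
  csum <- lapply(ind, function(v) c(0, cumsum(ext(v))))
  wcount <- function(cs) cs[starts + window] - cs[starts]
  G <- wcount(csum$G); C <- wcount(csum$C)
  A <- wcount(csum$A); T <- wcount(csum$T)
  denom_gc <- G + C
  denom_all <- A + C + G + T
  skew <- ifelse(denom_gc == 0, 0, (G - C) / pmax(denom_gc, 1))
  if (convention == "C_minus_G") skew <- -skew
  gc <- ifelse(denom_all == 0, NA_real_, denom_gc / pmax(denom_all, 1))
  centers <- if (circular) mod1(starts + window %/% 2L, L)
             else starts + window %/% 2L
  new("SkewProfile", sequence_id = seqID(seq), window = window, step = step,
      starts = as.integer(starts), centers = as.integer(centers),
      gc_percent = gc, skew = skew, convention = convention)
}

#' Per-base cumulative GC skew
#'
#' Running sum over bases of +1 for G and -1 for C (0 for everything else)
#' under `G_minus_C`, negated under `C_minus_G`, starting at `start_phase`
#' and wrapping on circular sequences. The final value equals
#' `count(G) - count(C)` (resp. its negation); the global minimum marks the
#' replication origin and the maximum the terminus under `G_minus_C`.
#'
#' @param seq a [CircularSequence-class].
#' @param start_phase 1-based position where the walk begins.
#' @param convention sign convention of the per-base contributions.
#' @return a [CumulativeSkew-class].
#' @examples
#' cumulativeSkew(CircularSequence("x", "GCAT"))@values
#' @export
cumulativeSkew <- function(seq, start_phase = 1L,
                           convention = c("G_minus_C", "C_minus_G")) {
  convention <- match.arg(convention)
  L <- length(seq)
  if (L == 0L) stop("empty sequence")
  start_phase <- as.integer(start_phase)
  if (start_phase < 1L || start_phase > L) stop("start_phase outside sequence")
  ind <- baseIndicators(seq@seq)
  contrib <- ind$G - ind$C
  if (convention == "C_minus_G") contrib <- -contrib
  if (start_phase != 1L)
    contrib <- c(contrib[start_phase:L], contrib[seq_len(start_phase - 1L)])
  new("CumulativeSkew", sequence_id = seqID(seq),
      values = cumsum(contrib), start_phase = start_phase,
      convention = convention)
}

# locate the dnaA feature: gene name "dnaA" or a product naming the
# chromosomal replication initiator
findDnaA <- function(annotations) {
  gr <- annotations@features
  mc <- S4Vectors::mcols(gr)
  hit <- (!is.na(mc$gene) & tolower(mc$gene) == "dnaa") |
    (!is.na(mc$product) &
       (grepl("chromosomal replication initiat", mc$product, ignore.case = TRUE) |
        grepl("\\bDnaA\\b", mc$product)))
  if (!any(hit)) return(NULL)
  gr[which(hit)[1]]
}

findDnaN <- function(annotations) {
  gr <- annotations@features
  mc <- S4Vectors::mcols(gr)
  hit <- (!is.na(mc$gene) & tolower(mc$gene) == "dnan") |
    (!is.na(mc$product) &
       grepl("DNA polymerase III.*beta", mc$product, ignore.case = TRUE))
  if (!any(hit)) return(NULL)
  gr[which(hit)[1]]
}

# fraction of CDSs per replichore whose coding strand is the leading strand;
# a CDS belongs to the replichore containing its start
leadStrandFractions <- function(ori, ter, L, cds_start, cds_strand) {
  on1 <- inArc(cds_start, ori, ter, L)
  lead <- ifelse(on1, "+", "-")
  n1 <- sum(on1); n2 <- sum(!on1)
  c(replichore1 = if (n1) mean(cds_strand[on1] == "+") else NA_real_,
    replichore2 = if (n2) mean(cds_strand[!on1] == "-") else NA_real_)
}

#' Predict replication origin and terminus from cumulative skew
#'
#' The origin is placed at the global minimum of the cumulative skew walk and
#' the terminus at the global maximum (the stored sign convention makes this
#' self-consistent: negating the convention swaps the two). Ties are broken
#' toward the smallest genomic position. When annotations containing a dnaA
#' gene are supplied, the circular distance from the predicted origin to the
#' dnaA start is reported and the prediction is flagged dnaA-supported when
#' that distance is at most `dnaA_threshold`; leading-strand CDS fractions
#' per replichore are computed from CDS features.
#'
#' @param cumskew a [CumulativeSkew-class] from a circular sequence.
#' @param annotations optional [AnnotationSet-class] on the same sequence.
#' @param dnaA_threshold distance (bases) within which a dnaA gene counts as
#'   supporting the prediction (default 20000).
#' @return a [ReplicationPrediction-class].
#' @export
predictOriTer <- function(cumskew, annotations = NULL, dnaA_threshold = 20000) {
  v <- cumskew@values
  L <- length(v)
  if (diff(range(v)) == 0)
    stop("no skew signal: cumulative skew is flat")
  pos <- mod1(cumskew@start_phase + seq_len(L) - 1L, L)
  at_min <- which(v == min(v))
  at_max <- which(v == max(v))
  ori <- min(pos[at_min])
  ter <- min(pos[at_max])
  r1 <- as.integer(forwardDistance(ori, ter, L))
  repl <- c(replichore1 = r1, replichore2 = as.integer(L - r1))
  dnaA_distance <- NA_real_
  dnaA_supported <- NA
  frac <- c(replichore1 = NA_real_, replichore2 = NA_real_)
  if (!is.null(annotations)) {
    dnaA <- findDnaA(annotations)
    if (!is.null(dnaA)) {
      dnaA_distance <- circularDistance(ori, BiocGenerics::start(dnaA), L)
      dnaA_supported <- dnaA_distance <= dnaA_threshold
    }
    cds <- featuresOfType(annotations, "CDS")
    if (length(cds))
      frac <- leadStrandFractions(ori, ter, L, BiocGenerics::start(cds),
                                  as.character(BiocGenerics::strand(cds)))
  }
  new("ReplicationPrediction", sequence_id = cumskew@sequence_id,
      ori = as.integer(ori), ter = as.integer(ter),
      method = paste0("cumulative-skew extremum (", cumskew@convention,
                      if (isTRUE(dnaA_supported)) ", dnaA-supported" else "", ")"),
      genome_length = as.integer(L), replichore_lengths = repl,
      lead_strand_cds_fraction = frac, dnaA_distance = dnaA_distance,
      dnaA_supported = dnaA_supported, convention = cumskew@convention)
}

#' Rotate a circular genome so a chosen origin becomes base one
#'
#' Returns the sequence rotated so position `ori` becomes base 1 and (when
#' supplied) the annotations with every feature remapped modulo the length.
#' Features that span the new junction get the wrap flag (`end > L`).
#' Rotation by `ori = 1` is the identity.
#'
#' @param seq a circular [CircularSequence-class].
#' @param annotations optional [AnnotationSet-class] to remap.
#' @param ori 1-based position that becomes base one.
#' @return the rotated [CircularSequence-class], or
#'   `list(sequence=, annotations=)` when annotations were supplied.
#' @examples
#' residues(rotateToOrigin(CircularSequence("x", "ACGT"), ori = 3))
#' @export
rotateToOrigin <- function(seq, annotations = NULL, ori) {
  if (topology(seq) != "circular") stop("cannot rotate a linear sequence")
  L <- length(seq)
  ori <- as.integer(ori)
  if (ori < 1L || ori > L) stop("ori outside sequence")
  s <- as.character(seq@seq)
  rotated <- if (ori == 1L) s else
    paste0(substr(s, ori, L), substr(s, 1L, ori - 1L))
  newseq <- new("CircularSequence", id = seqID(seq),
                seq = Biostrings::DNAString(rotated), topology = "circular")
  if (is.null(annotations)) return(newseq)
  gr <- annotations@features
  if (length(gr)) {
    width <- BiocGenerics::width(gr)
    ns <- mod1(BiocGenerics::start(gr) - ori + 1L, L)
    ne <- ns + width - 1L
    wraps <- ne > L
    newgr <- GenomicRanges::GRanges(seqnames = seqID(seq),
      ranges = IRanges::IRanges(start = ns, end = ne),
      strand = BiocGenerics::strand(gr))
    mc <- S4Vectors::mcols(gr)
    mc$wraps <- wraps
    S4Vectors::mcols(newgr) <- mc
  } else newgr <- gr
  newann <- annotationSet(annotations@sequence_id, newgr, seq_length = L)
  list(sequence = newseq, annotations = newann)
}

#' Replication-strand bias of coding sequences
#'
#' Assigns every CDS to the replichore containing its start (replichore 1
#' runs ori to ter in increasing coordinates; its leading strand is `+`,
#' replichore 2's is `-`), reports the per-replichore fraction of CDSs coded
#' on the leading strand, the 2x2 count table, and a two-sided exact binomial
#' test of the pooled leading-strand fraction against 0.5.
#'
#' @param prediction a [ReplicationPrediction-class].
#' @param annotations an [AnnotationSet-class] with CDS features.
#' @return list with `fractions`, `counts` (replichore x leading/lagging),
#'   `pooled_fraction` and `binomial` (an `htest`).
#' @export
strandBias <- function(prediction, annotations) {
  if (prediction@sequence_id != annotations@sequence_id)
    stop("prediction and annotations refer to different sequences")
  cds <- featuresOfType(annotations, "CDS")
  if (!length(cds)) stop("no CDS features in annotations")
  L <- prediction@genome_length
  st <- BiocGenerics::start(cds)
  strand <- as.character(BiocGenerics::strand(cds))
  on1 <- inArc(st, prediction@ori, prediction@ter, L)
  lead <- ifelse(on1, "+", "-")
  is_lead <- strand == lead
  counts <- table(replichore = ifelse(on1, "replichore1", "replichore2"),
                  strand_class = ifelse(is_lead, "leading", "lagging"))
  frac <- leadStrandFractions(prediction@ori, prediction@ter, L, st, strand)
  test <- stats::binom.test(sum(is_lead), length(is_lead), p = 0.5)
  list(fractions = frac, counts = counts,
       pooled_fraction = mean(is_lead), binomial = test)
}
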