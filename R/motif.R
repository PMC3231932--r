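# IUPAC consensus scanning, specialized to DnaA-box reporting around oriC.

IUPAC_LETTERS <- names(Biostrings::IUPAC_CODE_MAP)

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every exact match of the consensus (IUPAC codes in the consensus
#' are expanded; sequence letters are matched literally) on the requested
#' strands. Minus-strand matches are found by matching the reverse complement
#' of the consensus against the forward sequence and are reported with their
#' forward start coordinate; `matched` is the site read 5'->3' on the hit
#' strand. On circular sequences matches may span the junction. Overlapping
#' matches are all reported.
#'
#' @param seq a [CircularSequence-class].
#' @param consensus IUPAC consensus string, e.g. the DnaA box `"TTATNCACA"`.
#' @param region optional `c(from, to)` 1-based inclusive interval to scan
#'   (may wrap on circular sequences, i.e. `from > to`).
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return data.frame with columns `position`, `strand`, `matched`,
#'   `consensus`, ordered by position.
#' @examples
#' scanIUPAC(CircularSequence("x", "TTATCCACAGG"), "TTATNCACA")
#' @export
scanIUPAC <- function(seq, consensus, region = NULL,
                      strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("empty consensus")
  letters_used <- strsplit(consensus, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters_used, IUPAC_LETTERS)
  if (length(bad))
    stop("invalid IUPAC character(s) in consensus: ", paste(bad, collapse = ", "))
  k <- nchar(consensus)
  L <- length(seq)
  s <- as.character(seq@seq)
  circular <- topology(seq) == "circular"

  offset <- 0L
  subject_len <- L
  if (!is.null(region)) {
    from <- as.integer(region[1]); to <- as.integer(region[2])
    if (from < 1L || from > L || to < 1L || to > L) stop("region outside sequence")
    if (from <= to) {
      s <- substr(s, from, to)
    } else {
      if (!circular) stop("wrapped region on a linear sequence")
      s <- paste0(substr(s, from, L), substr(s, 1L, to))
    }
    offset <- from - 1L
    subject_len <- nchar(s)
    circular <- FALSE  # a region is scanned as a linear subsequence
  }
  if (k > subject_len) return(emptyHits(consensus))
  subject <- if (circular) paste0(s, substr(s, 1L, k - 1L)) else s
  subject <- Biostrings::DNAString(subject)

  hitsFor <- function(pattern, strand_label) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = "subject")
    st <- BiocGenerics::start(m)
    if (!length(st)) return(emptyHits(consensus))
    site <- as.character(m)
    if (strand_label == "-")
      site <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(site)))
    data.frame(position = st, strand = strand_label, matched = site,
               consensus = consensus, stringsAsFactors = FALSE)
  }
  out <- list()
  if (strands %in% c("both", "+")) out$fwd <- hitsFor(consensus, "+")
  if (strands %in% c("both", "-")) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
    out$rev <- hitsFor(rc, "-")
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || !nrow(hits)) return(emptyHits(consensus))
  hits$position <- hits$position + offset
  hits$position <- mod1(hits$position, L)
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

emptyHits <- function(consensus) {
  data.frame(position = integer(0), strand = character(0),
             matched = character(0), consensus = character(0),
             stringsAsFactors = FALSE)
}

#' Count DnaA boxes around the origin
#'
#' Counts consensus hits (both strands, overlaps counted individually) in
#' (a) the intergenic region upstream of the annotated dnaA gene — from the
#' end of the previous annotated feature to the base before dnaA, capped at
#' `upstream_cap` bases immediately upstream — and (b) the region strictly
#' between dnaA and dnaN. Regions respect dnaA's strand ("upstream" is 5' of
#' the gene) and the circular topology.
#'
#' @param seq a [CircularSequence-class].
#' @param annotations an [AnnotationSet-class] containing dnaA and dnaN.
#' @param consensus DnaA-box consensus (default `"TTATNCACA"`).
#' @param upstream_cap maximum upstream extent, bases (default 1000).
#' @return list with `upstream`, `intergenic` (counts), the two `regions`,
#'   and the per-region hit tables.
#' @export
dnaABoxReport <- function(seq, annotations, consensus = "TTATNCACA",
                          upstream_cap = 1000L) {
  dnaA <- findDnaA(annotations)
  if (is.null(dnaA)) stop("annotation does not contain a dnaA gene")
  dnaN <- findDnaN(annotations)
  if (is.null(dnaN)) stop("annotation does not contain a dnaN gene")
  L <- length(seq)
  gr <- annotations@features
  aS <- BiocGenerics::start(dnaA); aE <- BiocGenerics::end(dnaA)
  nS <- BiocGenerics::start(dnaN); nE <- BiocGenerics::end(dnaN)
  strand <- as.character(BiocGenerics::strand(dnaA))

  # nearest feature boundary upstream of dnaA (circularly), excluding dnaA
  others <- gr[!(BiocGenerics::start(gr) == aS & BiocGenerics::end(gr) == aE)]
  if (strand == "+") {
    ends <- BiocGenerics::end(others)
    gap_back <- forwardDistance(mod1(ends, L), aS, L)  # distance end -> dnaA start
    prev_end <- if (length(ends)) mod1(ends[which.min(gap_back)], L) else mod1(aS - upstream_cap - 1L, L)
    up_len <- min(forwardDistance(prev_end, aS, L) - 1L, upstream_cap)
    up_region <- if (up_len >= 1L)
      c(mod1(aS - up_len, L), mod1(aS - 1L, L)) else NULL
  } else {
    starts <- BiocGenerics::start(others)
    gap_fwd <- forwardDistance(aE, starts, L)
    next_start <- if (length(starts)) starts[which.min(gap_fwd)] else mod1(aE + upstream_cap + 1L, L)
    up_len <- min(forwardDistance(aE, next_start, L) - 1L, upstream_cap)
    up_region <- if (up_len >= 1L)
      c(mod1(aE + 1L, L), mod1(aE + up_len, L)) else NULL
  }

  # strictly between dnaA and dnaN, whichever order they sit in
  if (forwardDistance(aE, nS, L) <= forwardDistance(nE, aS, L)) {
    ig_len <- forwardDistance(aE, nS, L) - 1L
    ig_region <- if (ig_len >= 1L) c(mod1(aE + 1L, L), mod1(nS - 1L, L)) else NULL
  } else {
    ig_len <- forwardDistance(nE, aS, L) - 1L
    ig_region <- if (ig_len >= 1L) c(mod1(nE + 1L, L), mod1(aS - 1L, L)) else NULL
  }

  scan_region <- function(region) {
    if (is.null(region)) return(emptyHits(consensus))
    scanIUPAC(seq, consensus, region = region, strands = "both")
  }
  up_hits <- scan_region(up_region)
  ig_hits <- scan_region(ig_region)
  list(upstream = nrow(up_hits), intergenic = nrow(ig_hits),
       regions = list(upstream = up_region, intergenic = ig_region),
       hits = list(upstream = up_hits, intergenic = ig_hits),
       consensus = consensus)
}

#' Expected IUPAC hit rate on uniform random sequence
#'
#' For a consensus of length `k` with degeneracy `d` (product over positions
#' of the number of bases each IUPAC code admits), the per-position match
#' probability on i.i.d. uniform sequence is `d / 4^k`; scanning both strands
#' of `L` positions gives expectation `2 * L * d / 4^k` (minus-strand matches
#' of a non-palindromic consensus are independent positions).
#'
#' @param consensus IUPAC consensus string.
#' @param L number of scanned positions.
#' @param strands `"both"` (default) or a single strand.
#' @return list with `p` (per position per strand) and `expected` hits.
#' @export
expectedIUPACHits <- function(consensus, L, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  letters_used <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  deg <- nchar(Biostrings::IUPAC_CODE_MAP[letters_used])
  if (any(is.na(deg))) stop("invalid IUPAC character in consensus")
  p <- prod(deg / 4)
  nstrand <- if (strands == "both") 2 else 1
  list(p = p, expected = nstrand * L * p)
}
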