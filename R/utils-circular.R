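# Circular coordinate helpers. Positions are 1-based inclusive everywhere;
# a wrapped feature is stored with end > L (never end < start).

# map any integer onto 1..L
mod1 <- function(x, L) ((x - 1L) %% L) + 1L

# forward (clockwise, increasing-coordinate) distance from a to b on a circle
forwardDistance <- function(a, b, L) (b - a) %% L

# minimal circular distance between two positions
circularDistance <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# is position p in the circular half-open arc [from, to)?
inArc <- function(p, from, to, L) {
  forwardDistance(from, p, L) < forwardDistance(from, to, L)
}

# split features (possibly with end > L) into in-bounds segments for
# interval arithmetic; returns an IRanges
featureSegments <- function(gr, L) {
  s <- BiocGenerics::start(gr)
  e <- BiocGenerics::end(gr)
  wraps <- e > L
  segs <- IRanges::IRanges(
    start = c(s, rep(1L, sum(wraps))),
    end = c(ifelse(wraps, L, e), e[wraps] - L))
  segs
}

#' Split wrapped features into linear segments
#'
#' Features spanning the circular junction are stored with `end` greater than
#' the sequence length. This helper returns, for every feature, its one or two
#' in-bounds segments as an [IRanges::IRanges], ready for union/coverage
#' arithmetic.
#'
#' @param annotations an [AnnotationSet-class] with known sequence length.
#' @param type optional feature type filter.
#' @return an `IRanges` of linear segments.
#' @export
annotationSegments <- function(annotations, type = NULL) {
  L <- annotations@seq_length
  if (is.na(L)) stop("sequence length unknown; cannot split wrapped features")
  gr <- if (is.null(type)) annotations@features else featuresOfType(annotations, type)
  featureSegments(gr, L)
}

# tiny polynomial rolling hash of a character vector, for config fingerprints
# (stays below 2^31 so plain double arithmetic is exact)
configHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
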