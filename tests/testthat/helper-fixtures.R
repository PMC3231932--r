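# Shared test fixtures and independent oracles, all built in code.

# minimal circular distance, independent of the package's helper
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  min(d, L - d)
}

# naive IUPAC matcher (regex lookahead, counts overlaps), the oracle for the
# Biostrings-backed scanner; counts both strands, circular-aware
naive_iupac_count <- function(s, consensus, circular = TRUE) {
  iupac_regex <- function(cons) {
    map <- Biostrings::IUPAC_CODE_MAP
    paste(vapply(strsplit(cons, "")[[1]], function(l)
      if (nchar(map[[l]]) == 1L) map[[l]]
      else paste0("[", map[[l]], "]"), character(1)), collapse = "")
  }
  k <- nchar(consensus)
  subj <- if (circular) paste0(s, substr(s, 1, k - 1)) else s
  count1 <- function(cons) {
    m <- gregexpr(paste0("(?=", iupac_regex(cons), ")"), subj, perl = TRUE)[[1]]
    sum(m > 0)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  count1(consensus) + count1(rc)
}

# naive count within a (possibly wrapping) region of a circular sequence
naive_iupac_count_region <- function(s, consensus, from, to) {
  L <- nchar(s)
  sub <- if (from <= to) substr(s, from, to)
         else paste0(substr(s, from, L), substr(s, 1, to))
  naive_iupac_count(sub, consensus, circular = FALSE)
}

# toy annotation data.frame -> AnnotationSet
toy_annotation <- function(id = "toy", L = 1000, ...) {
  df <- data.frame(...)
  annotationSet(id, df, seq_length = L)
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# uniform random DNA string
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

survey_fixture_path <- function() {
  system.file("extdata", "survey_demo_synthetic.tsv", package = "BacArch",
              mustWork = TRUE)
}
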