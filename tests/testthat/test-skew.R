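test_that("windowed profile matches trivial compositions", {
  g <- CircularSequence("g", strrep("G", 400))
  p <- windowedProfile(g, window = 100, step = 50)
  expect_true(all(p@skew == 1))
  expect_true(all(p@gc_percent == 1))

  gc <- CircularSequence("gc", strrep("GGGGCCCC", 1))
  p <- windowedProfile(gc, window = 8, step = 8)
  expect_equal(p@skew, 0)
  expect_equal(p@gc_percent, 1)

  # no G/C in a window: skew 0 by convention; ambiguity excluded from GC%
  a <- CircularSequence("a", paste0(strrep("A", 50), "GN"))
  p <- windowedProfile(a, window = 52, step = 52)
  expect_equal(p@skew, 1)           # one G, zero C
  expect_equal(p@gc_percent, 1 / 51)  # N excluded from the denominator
})

test_that("windowed profile equals a brute-force recount on random sequence", {
  s <- random_dna(50000, seed = 42)
  g <- CircularSequence("g", s)
  p <- windowedProfile(g, window = 1000, step = 100)
  expect_length(p@starts, ceiling(50000 / 100))
  s2 <- paste0(s, substr(s, 1, 999))
  for (i in sample(seq_along(p@starts), 40)) {  # spot-check windows incl. wrap
    win <- substr(s2, p@starts[i], p@starts[i] + 999)
    nG <- lengths(regmatches(win, gregexpr("G", win)))
    nC <- lengths(regmatches(win, gregexpr("C", win)))
    expect_equal(p@skew[i], (nG - nC) / (nG + nC))
    expect_equal(p@gc_percent[i], (nG + nC) / 1000)
  }
  expect_equal(p@centers, ((p@starts + 500 - 1) %% 50000) + 1)
})

test_that("tiling windows aggregate to the total G-C difference", {
  s <- random_dna(1200, seed = 9)
  g <- CircularSequence("g", s)
  p <- windowedProfile(g, window = 100, step = 100)
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  gcn <- p@gc_percent * 100          # per-window G+C count
  expect_equal(sum(p@skew * gcn), counts[["G"]] - counts[["C"]])
})

test_that("window/step preconditions are enforced", {
  lin <- CircularSequence("l", "ACGTACGT", topology = "linear")
  expect_error(windowedProfile(lin, window = 20, step = 5), "exceeds")
  expect_error(windowedProfile(CircularSequence("c", "ACGT"), window = 0, step = 1))
})

test_that("cumulative skew walks +1/-1 and ends at count(G)-count(C)", {
  expect_equal(cumulativeSkew(CircularSequence("x", "GC"))@values, c(1, 0))
  expect_equal(cumulativeSkew(CircularSequence("x", "AAAA"))@values, rep(0, 4))
  s <- random_dna(5000, seed = 13)
  cs <- cumulativeSkew(CircularSequence("x", s))
  ch <- strsplit(s, "")[[1]]
  expect_equal(cs@values[5000], sum(ch == "G") - sum(ch == "C"))
  expect_length(cs@values, 5000)
  # start phase rotates the walk
  cs2 <- cumulativeSkew(CircularSequence("x", s), start_phase = 100)
  expect_equal(cs2@values[1], as.numeric((ch[100] == "G") - (ch[100] == "C")))
})

test_that("ori/ter prediction recovers a planted two-replichore signal", {
  sim <- simulateGenome(length = 50000, skew_delta = 0.08, n_genes = 30,
                        n_rrna_operons = 1, n_trna = 4, seed = 21)
  pred <- predictOriTer(cumulativeSkew(sim$sequence), sim$annotations)
  L <- length(sim$sequence)
  expect_lt(circ_dist(pred@ori, sim$truth$ori, L), 5000)
  expect_lt(circ_dist(pred@ter, sim$truth$ter, L), 5000)
  expect_equal(sum(pred@replichore_lengths), L)
  expect_true(pred@dnaA_supported)
  expect_lt(pred@dnaA_distance, 20000)
})

test_that("prediction is rotation-invariant and convention-negation swaps ori/ter", {
  sim <- simulateGenome(length = 40000, skew_delta = 0.1, n_genes = 20,
                        n_rrna_operons = 1, n_trna = 2, seed = 33)
  g <- sim$sequence
  L <- length(g)
  p0 <- predictOriTer(cumulativeSkew(g))
  off <- 12345L
  rot <- rotateToOrigin(g, ori = off)
  p1 <- predictOriTer(cumulativeSkew(rot))
  shift_back <- function(x) ((x + off - 1L - 1L) %% L) + 1L
  # the circular walk is only shift-equivariant up to the (small, random)
  # total G-C imbalance, so both frames must localize the planted truth
  expect_lt(circ_dist(p0@ori, sim$truth$ori, L), 3000)
  expect_lt(circ_dist(p0@ter, sim$truth$ter, L), 3000)
  expect_lt(circ_dist(shift_back(p1@ori), sim$truth$ori, L), 3000)
  expect_lt(circ_dist(shift_back(p1@ter), sim$truth$ter, L), 3000)
  # negated convention swaps the extrema
  pneg <- predictOriTer(cumulativeSkew(g, convention = "C_minus_G"))
  expect_equal(pneg@ori, p0@ter)
  expect_equal(pneg@ter, p0@ori)
})

test_that("flat skew is rejected as no-signal", {
  expect_error(predictOriTer(cumulativeSkew(CircularSequence("a", strrep("AT", 50)))),
               "no skew signal")
})

test_that("rotation remaps sequence and features, and round-trips", {
  g <- CircularSequence("g", "ACGT")
  expect_equal(residues(rotateToOrigin(g, ori = 3)), "GTAC")
  expect_equal(residues(rotateToOrigin(g, ori = 1)), "ACGT")
  expect_error(rotateToOrigin(CircularSequence("l", "ACGT", topology = "linear"),
                              ori = 2), "linear")

  sim <- simulateGenome(length = 30000, n_genes = 15, n_rrna_operons = 1,
                        n_trna = 2, seed = 8)
  g <- sim$sequence; ann <- sim$annotations
  L <- length(g)
  ori <- 7777L
  fwd <- rotateToOrigin(g, ann, ori = ori)
  # rotating by 1 is the identity
  id <- rotateToOrigin(g, ann, ori = 1L)
  expect_equal(residues(id$sequence), residues(g))
  expect_equal(BiocGenerics::start(features(id$annotations)),
               BiocGenerics::start(features(ann)))
  # composing with the inverse rotation restores all coordinates
  back <- rotateToOrigin(fwd$sequence, fwd$annotations,
                         ori = ((L - ori + 2L - 1L) %% L) + 1L)
  expect_equal(residues(back$sequence), residues(g))
  expect_equal(sort(BiocGenerics::start(features(back$annotations))),
               sort(BiocGenerics::start(features(ann))))
  # widths survive wrapping
  expect_equal(sort(BiocGenerics::width(features(fwd$annotations))),
               sort(BiocGenerics::width(features(ann))))
})

test_that("strand bias recovers planted leading-strand preference", {
  # all CDSs leading on replichore 1
  ann <- toy_annotation(L = 1000,
    feature_type = rep("CDS", 10), start = seq(10, 460, 50),
    end = seq(30, 480, 50), strand = rep("+", 10))
  pred <- new("ReplicationPrediction", sequence_id = "toy", ori = 1L,
              ter = 501L, method = "planted", genome_length = 1000L,
              replichore_lengths = c(replichore1 = 500L, replichore2 = 500L),
              lead_strand_cds_fraction = c(NA_real_, NA_real_),
              dnaA_distance = NA_real_, dnaA_supported = NA,
              convention = "G_minus_C")
  sb <- strandBias(pred, ann)
  expect_equal(unname(sb$fractions["replichore1"]), 1.0)
  expect_equal(sb$pooled_fraction, 1.0)

  # symmetric placement, no bias: fraction 0.5
  ann2 <- toy_annotation(L = 1000,
    feature_type = rep("CDS", 8), start = c(10, 110, 210, 310, 510, 610, 710, 810),
    end = c(40, 140, 240, 340, 540, 640, 740, 840),
    strand = c("+", "-", "+", "-", "+", "-", "+", "-"))
  sb2 <- strandBias(pred, ann2)
  expect_equal(sb2$pooled_fraction, 0.5)
  expect_gt(sb2$binomial$p.value, 0.5)

  expect_error(strandBias(pred, toy_annotation(L = 1000, feature_type = "tRNA",
                                               start = 1, end = 70, strand = "+")),
               "no CDS")

  # planted bias on a simulated genome is recovered within sampling error
  sim <- simulateGenome(length = 60000, n_genes = 60, strand_bias = 0.8,
                        n_rrna_operons = 1, n_trna = 4, seed = 14)
  predS <- predictOriTer(cumulativeSkew(sim$sequence), sim$annotations)
  sbS <- strandBias(predS, sim$annotations)
  n <- sum(sbS$counts)
  expect_lt(abs(sbS$pooled_fraction - 0.8), 3 * sqrt(0.8 * 0.2 / n) + 0.02)
})
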