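# small helper: a CDS that uses every amino acid, for reference sets
all_aa_cds <- function(seed, n_rep = 5) {
  set.seed(seed)
  gc11 <- Biostrings::getGeneticCode("11")
  aas <- setdiff(unique(gc11), "*")
  body <- vapply(rep(aas, n_rep), function(a) {
    syn <- names(gc11)[gc11 == a]
    sample(syn, 1)
  }, character(1))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

test_that("codon counting and validity flags follow the CDS rules", {
  cc <- codonCounts("ATGAAATAA", "toy")
  expect_true(cc$valid)
  expect_equal(cc$counts[c("ATG", "AAA", "TAA")], c(ATG = 1L, AAA = 1L, TAA = 1L))
  expect_equal(sum(cc$counts), 3L)

  expect_false(codonCounts("ATGAAAT", "short")$valid)     # not a codon multiple
  expect_false(codonCounts("ATGTAAAAATAA", "stopin")$valid)  # internal stop
  set.seed(2)
  orf <- paste0("ATG", paste(sample(c("AAA", "GAA", "GCT", "TTG"), 331,
                                    replace = TRUE), collapse = ""), "TAA")
  expect_equal(sum(codonCounts(orf, "r999")$counts), 333L)  # 999/3
  # ambiguous codons are ignored, not fatal
  ccn <- codonCounts("ATGANATAA", "amb")
  expect_equal(sum(ccn$counts), 2L)
})

test_that("relative adaptiveness equals hand-computed synonymous ratios", {
  # Lys: AAA only; Phe: 3x TTT, 1x TTC; Glu: 2x GAA, 2x GAG
  ref <- codonCounts(paste0("ATG", "AAAAAA", "TTTTTTTTTTTC", "GAAGAAGAGGAG",
                            all_aa_cds(7)), "ref")
  # neutralize the helper's random tail for the codons under test by
  # computing expected ratios directly from pooled counts
  w <- relativeAdaptiveness(list(ref))
  pooled <- ref$counts
  expect_equal(unname(w$w["AAA"]),
               unname(pooled["AAA"] / max(pooled[c("AAA", "AAG")])))
  expect_equal(unname(w$w["TTT"]),
               unname(pooled["TTT"] / max(pooled[c("TTT", "TTC")])))
  expect_equal(unname(w$w["GAG"]),
               unname(pooled["GAG"] / max(pooled[c("GAA", "GAG")])))
  expect_true(all(w$w > 0 & w$w <= 1))
  # per family, the major codon has w = 1
  gc11 <- Biostrings::getGeneticCode("11")
  sense <- names(gc11)[gc11 != "*"]
  for (a in unique(gc11[sense])) {
    fam <- sense[gc11[sense] == a]
    expect_equal(max(w$w[fam]), 1, label = a)
  }
  # absent codons get the floor
  expect_error(relativeAdaptiveness(list()), "empty")
  ref2 <- codonCounts(all_aa_cds(9, n_rep = 1), "r2")
  w2 <- relativeAdaptiveness(list(ref2), floor = 0.01)
  expect_true(any(w2$w == 0.01))
})

test_that("adaptation index is the geometric mean over informative codons", {
  ref <- codonCounts(all_aa_cds(11, n_rep = 20), "ref")
  w <- relativeAdaptiveness(list(ref))
  gene <- codonCounts("ATGAAAGAATTTGGTTAA", "g")  # ATG,AAA,GAA,TTT,GGT,TAA
  # oracle: exp(mean(log w)) over the informative codons only
  use <- c("AAA", "GAA", "TTT", "GGT")            # no ATG/TGG, no stop
  expect_equal(adaptationIndex(gene, w), exp(mean(log(w$w[use]))))
  # all-major gene scores exactly 1
  majors <- names(w$w)[w$w == 1]
  g1 <- codonCounts(paste0("ATG", paste(rep(setdiff(majors, c("ATG", "TGG"))[1:5],
                                            4), collapse = ""), "TAA"), "m")
  expect_equal(adaptationIndex(g1, w), 1)
  # ATG/TGG-only gene has no countable codons
  expect_error(adaptationIndex(codonCounts("ATGTGGTGGTAA", "mw"), w),
               "no countable")
  # invariance to codon order
  g2 <- codonCounts("ATGTTTGAAAAAGGTTAA", "g2")
  expect_equal(adaptationIndex(g2, w), adaptationIndex(gene, w))
  # replacing a major codon by a lower-w synonym strictly lowers the score
  fam_tt <- w$w[c("TTT", "TTC")]
  hi <- names(which.max(fam_tt)); lo <- names(which.min(fam_tt))
  if (w$w[hi] > w$w[lo]) {
    ghi <- codonCounts(paste0("ATG", strrep(hi, 10), "TAA"), "hi")
    glo <- codonCounts(paste0("ATG", strrep(hi, 9), lo, "TAA"), "lo")
    expect_gt(adaptationIndex(ghi, w), adaptationIndex(glo, w))
  }
})

test_that("adaptation index matches the seqinr implementation", {
  skip_if_not_installed("seqinr")
  ref <- codonCounts(all_aa_cds(23, n_rep = 30), "ref")
  w <- relativeAdaptiveness(list(ref))
  set.seed(5)
  gc11 <- Biostrings::getGeneticCode("11")
  body <- paste(sample(names(gc11)[gc11 != "*"], 60, replace = TRUE),
                collapse = "")
  gene_s <- paste0("ATG", body, "TAA")
  gene <- codonCounts(gene_s, "g")
  ws <- stats::setNames(rep(0.01, 64), seqinr::words())
  ws[tolower(names(w$w))] <- w$w
  expect_equal(adaptationIndex(gene, w),
               as.numeric(seqinr::cai(seqinr::s2c(tolower(gene_s)), w = ws)),
               tolerance = 1e-6)
})

test_that("RSCU is observed over expected-uniform synonymous usage", {
  gene <- codonCounts(paste0("ATG", "GAAGAAGAAGAG", "AAAAAA", "TAA"), "g")
  r <- rscu(gene)
  expect_equal(unname(r["GAA"]), 3 / 2)   # 3 of 4 in a 2-codon family
  expect_equal(unname(r["GAG"]), 1 / 2)
  expect_equal(unname(r["AAA"]), 2)       # 2 of 2 in a 2-codon family
  expect_true(is.na(r["TTT"]))            # unobserved family
})

test_that("ranking orders by score with gene-id tie-break and category counts", {
  ref <- codonCounts(all_aa_cds(31, n_rep = 20), "ref")
  w <- relativeAdaptiveness(list(ref))
  g <- function(id, s) codonCounts(s, id)
  genes <- list(g("b", "ATGAAAGAATAA"), g("a", "ATGAAAGAATAA"),
                g("c", "ATGTTTTTCTAA"))
  expect_warning(rk <- rankOptimized(genes, w, top_k = 80), "valid genes")
  expect_true(rk$short_of_top_k)
  # identical genes rank by id
  same <- rk$ranking$gene_id[rk$ranking$score == rk$ranking$score[
    rk$ranking$gene_id == "a"]]
  expect_equal(sort(same[1:2]), c("a", "b"))
  cats <- c(a = "ribosomal", b = "ribosomal")
  rk2 <- suppressWarnings(rankOptimized(genes, w, top_k = 2, categories = cats))
  expect_equal(unname(rk2$category_counts["ribosomal"]),
               sum(rk2$top$gene_id %in% c("a", "b")))
  # invalid genes are excluded from the ranking
  genes2 <- c(genes, list(g("z", "ATGAA")))
  expect_false("z" %in% suppressWarnings(rankOptimized(genes2, w))$ranking$gene_id)
})

test_that("planted expression level drives the adaptation-index ranking", {
  sim <- simulateGenome(length = 90000, n_genes = 80, pseudogene_fraction = 0,
                        n_rrna_operons = 1, n_trna = 4, seed = 27)
  counts <- codonCountsFromAnnotation(sim$sequence, sim$annotations)
  ref_ids <- referenceGeneIds(sim$annotations)
  expect_gt(length(ref_ids), 10)
  w <- relativeAdaptiveness(counts[intersect(ref_ids, names(counts))])
  gene_ids <- sim$truth$genes$gene_id
  sc <- vapply(counts[gene_ids], adaptationIndex, numeric(1), w = w)
  rho <- cor(sim$truth$genes$expression, sc, method = "spearman")
  expect_gt(rho, 0.8)
})
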