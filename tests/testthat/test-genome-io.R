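test_that("FASTA reading maps headers, case and wrapped lines correctly", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s", "ACGT"), fa)
  recs <- readGenomeFasta(fa)
  expect_length(recs, 1)
  expect_equal(length(recs$s), 4L)
  expect_equal(topology(recs$s), "circular")

  # multi-record, wrapped lines, lower case: lengths match character counts
  set.seed(11)
  s1 <- random_dna(230)
  s2 <- tolower(random_dna(77))
  writeLines(c(">a desc text", substring(s1, seq(1, 230, 60), pmin(seq(60, 290, 60), 230)),
               ">b", substring(s2, c(1, 41), c(40, 77))), fa)
  recs <- readGenomeFasta(fa, topology = "linear")
  expect_equal(vapply(recs, length, integer(1)), c(a = 230L, b = 77L))
  expect_equal(residues(recs$b), toupper(s2))
})

test_that("FASTA reading rejects empty files, duplicate ids and bad residues", {
  fa <- tempfile(fileext = ".fa")
  file.create(fa)
  expect_error(readGenomeFasta(fa), "empty")
  writeLines(c(">x", "ACGT", ">x", "GGCC"), fa)
  expect_error(readGenomeFasta(fa), "duplicate.*x")
  writeLines(c(">x", "AC!T"), fa)
  expect_error(readGenomeFasta(fa))
})

test_that("FASTA round-trip preserves sequence content byte-for-byte", {
  set.seed(3)
  seqs <- list(CircularSequence("g1", random_dna(501)),
               CircularSequence("g2", random_dna(89)))
  fa <- tempfile(fileext = ".fa")
  writeGenomeFasta(seqs, fa, width = 60)
  back <- readGenomeFasta(fa)
  expect_equal(residues(back$g1), residues(seqs[[1]]))
  expect_equal(residues(back$g2), residues(seqs[[2]]))
})

test_that("GFF3 parsing extracts typed features with 1-based coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 5000",
    "chr\tsrc\tCDS\t1\t300\t.\t+\t0\tID=c1;locus_tag=c1",
    "chr\tsrc\trRNA\t400\t1900\t.\t+\t.\tID=r1;product=16S ribosomal RNA",
    "chr\tsrc\tCDS\t2000\t2500\t.\t-\t0\tID=c2;pseudo=true",
    "chr\tsrc\tpseudogene\t2600\t2900\t.\t+\t.\tID=p1"), gff)
  ann <- readAnnotations(gff, format = "gff3")
  expect_equal(length(ann), 4L)
  cds <- featuresOfType(ann, "CDS")
  expect_equal(BiocGenerics::start(cds), 1L)
  expect_equal(BiocGenerics::width(cds), 300L)
  expect_equal(S4Vectors::mcols(featuresOfType(ann, "rRNA"))$rrna_subunit, "16S")
  expect_equal(sum(featureType(ann) == "pseudogene"), 2L)
  expect_equal(ann@seq_length, 5000L)
})

test_that("GenBank parsing handles pseudo, complement, products and wrap joins", {
  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       toychr                  5000 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             10..309",
    '                     /locus_tag="t0001"',
    '                     /gene="dnaA"',
    '                     /product="chromosomal replication initiator protein',
    '                     DnaA"',
    "     rRNA            complement(400..1900)",
    '                     /product="16S ribosomal RNA"',
    "     CDS             2000..2302",
    '                     /locus_tag="t0002"',
    "                     /pseudo",
    "     tRNA            join(4960..5000,1..34)",
    '                     /product="tRNA-Ala"',
    "ORIGIN",
    "//"), gbk)
  ann <- readAnnotations(gbk)  # auto-sniffed
  expect_equal(ann@sequence_id, "toychr")
  expect_equal(ann@seq_length, 5000L)
  expect_equal(length(ann), 4L)
  mc <- S4Vectors::mcols(ann@features)
  expect_true("pseudogene" %in% mc$feature_type)
  rr <- featuresOfType(ann, "rRNA")
  expect_equal(as.character(BiocGenerics::strand(rr)), "-")
  expect_equal(S4Vectors::mcols(rr)$rrna_subunit, "16S")
  tr <- featuresOfType(ann, "tRNA")
  expect_true(S4Vectors::mcols(tr)$wraps)
  expect_equal(BiocGenerics::start(tr), 4960L)
  expect_equal(BiocGenerics::end(tr), 5034L)  # 5000 + 34
  # the CDS with a multi-line product keeps dnaA identifiable
  expect_match(mc$product[mc$feature_type == "CDS" & !is.na(mc$gene)],
               "replication initiator")
})

test_that("out-of-bounds non-wrapping coordinates are rejected", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 100",
    "chr\tsrc\tCDS\t50\t290\t.\t+\t0\tID=c1"), gff)
  expect_error(readAnnotations(gff, format = "gff3"), "outside")
})

test_that("bedGraph export converts to 0-based half-open and round-trips", {
  s <- CircularSequence("chr", random_dna(1000, seed = 5))
  p <- windowedProfile(s, window = 400, step = 200)
  bg <- tempfile(fileext = ".bedgraph")
  writeTrack(p, bg, format = "bedgraph", stat = "skew")
  tab <- read.table(bg, sep = "\t")
  expect_equal(nrow(tab), length(p@starts))
  expect_equal(tab$V2[1], 0)          # first interval starts at 0
  expect_equal(tab$V3[1], 200)
  expect_equal(tab$V4, round(p@skew, 6), tolerance = 1e-9)
  # wig export holds the same values
  wg <- tempfile(fileext = ".wig")
  writeTrack(p, wg, format = "wig", stat = "gc")
  vals <- as.numeric(readLines(wg)[-1])
  expect_equal(vals, round(p@gc_percent, 6), tolerance = 1e-9)
})

test_that("AnnotationSet validity enforces the feature invariants", {
  expect_error(toy_annotation(L = 100, feature_type = "CDS", start = 10,
                              end = 150, strand = "+"),
               "outside|wrap")
  expect_error(toy_annotation(L = 100, feature_type = "CDS", start = 10,
                              end = 50, strand = "*"), "strand")
  ann <- toy_annotation(L = 100, feature_type = c("CDS", "tRNA"),
                        start = c(60, 5), end = c(90, 40),
                        strand = c("+", "-"))
  expect_equal(BiocGenerics::start(features(ann)), c(5L, 60L))  # sorted
})
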