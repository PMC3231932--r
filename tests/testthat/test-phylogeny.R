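test_that("p-distance uses pairwise deletion of gaps/ambiguities", {
  aln <- Biostrings::DNAStringSet(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(max(pDistanceMatrix(aln)), 0)

  # 1 mismatch over 100 retained sites
  s <- random_dna(100, seed = 1)
  s2 <- s
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 50, 50))[1]
  d <- pDistanceMatrix(Biostrings::DNAStringSet(c(a = s, b = s2)))
  expect_equal(d["a", "b"], 0.01)

  # masking the mismatch with N discards that column: hand count on 10 sites
  a <- "ACGTACGTAC"
  b <- "ACGTNCGTTC"   # site 5 masked, site 9 mismatch -> 1/9
  d2 <- pDistanceMatrix(Biostrings::DNAStringSet(c(a = a, b = b)))
  expect_equal(d2["a", "b"], 1 / 9)
  # gaps are discarded the same way
  b3 <- "AC-TACGTAC"
  d3 <- pDistanceMatrix(Biostrings::DNAStringSet(c(a = a, b = b3)))
  expect_equal(d3["a", "b"], 0)

  expect_error(pDistanceMatrix(Biostrings::DNAStringSet(
    c(a = "NNNN", b = "ACGT"))), "no comparable sites.*a.*b")
  # symmetry and zero diagonal by construction
  set.seed(6)
  rows <- vapply(1:4, function(i) random_dna(60), character(1))
  names(rows) <- paste0("t", 1:4)
  d4 <- pDistanceMatrix(Biostrings::DNAStringSet(rows))
  expect_equal(d4, t(d4))
  expect_true(all(diag(d4) == 0))
})

test_that("Jukes-Cantor correction applies the closed form", {
  s <- random_dna(400, seed = 2)
  s2 <- s
  idx <- sample(400, 40)
  for (i in idx)
    substr(s2, i, i) <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
  aln <- Biostrings::DNAStringSet(c(a = s, b = s2))
  p <- pDistanceMatrix(aln)["a", "b"]
  jc <- pDistanceMatrix(aln, model = "jc")["a", "b"]
  expect_equal(jc, -0.75 * log(1 - 4 * p / 3))
})

test_that("3-taxon NJ solves the three-point closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["A"]), (3 + 4 - 5) / 2)   # 1
  expect_equal(unname(len["B"]), (3 + 5 - 4) / 2)   # 2
  expect_equal(unname(len["C"]), (4 + 5 - 3) / 2)   # 3
})

test_that("4-taxon additive matrix is inverted exactly", {
  # quartet AB|CD with pendant lengths 1,2,3,4 and internal 5
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, dimnames = list(taxa, taxa))
  tr <- neighborJoining(D)
  expect_equal(pathDistances(tr)[taxa, taxa], D, tolerance = 1e-12)
  expect_equal(sort(tr$edge.length), c(1, 2, 3, 4, 5))
  keys <- BacArch:::bipartitionKeys(tr)$keys
  expect_true("C|D" %in% keys || "A|B" %in% keys)
})

test_that("NJ is consistent on random additive matrices and agrees with ape", {
  for (seed in 1:10) {
    n <- sample(5:8, 1)
    ra <- random_additive(n, seed = seed + 100)
    tr <- neighborJoining(ra$D)
    expect_true(same_topology(tr, ra$tree), label = paste("seed", seed))
    expect_lt(max(abs(pathDistances(tr)[rownames(ra$D), colnames(ra$D)] -
                        ra$D)), 1e-9)
    # independent implementation agrees on the topology
    expect_true(same_topology(tr, ape::nj(as.dist(ra$D))))
  }
})

test_that("NJ validates its input and breaks ties deterministically", {
  D <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighborJoining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 5, 0, 3, 2, 3, 0), 3)
  expect_error(neighborJoining(D3), "symmetric")
  # fully tied distances: result is deterministic across repeated calls
  De <- matrix(1, 5, 5) - diag(5)
  dimnames(De) <- list(letters[1:5], letters[1:5])
  t1 <- neighborJoining(De)
  t2 <- neighborJoining(De)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # permuting the input taxa leaves the tied join choices label-driven
  perm <- c(3, 1, 5, 2, 4)
  t3 <- neighborJoining(De[perm, perm])
  expect_true(same_topology(t1, t3))
})

test_that("negative branch lengths are clamped with the deficit on the sister", {
  # a matrix engineered to produce a negative NJ branch
  taxa <- paste0("t", 1:4)
  D <- matrix(c(0, 0.1, 0.6, 0.6,
                0.1, 0, 0.7, 0.5,
                0.6, 0.7, 0, 0.3,
                0.6, 0.5, 0.3, 0), 4, dimnames = list(taxa, taxa))
  tr <- neighborJoining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap gives full support to a strongly resolved quartet", {
  tree <- ape::read.tree(text = "((A:0.05,B:0.05):0.3,C:0.05,D:0.05);")
  sim <- simulateAlignment(tree, site_count = 500, seed = 99)
  boot <- bootstrapSupport(sim$alignment, replicates = 100, seed = 7)
  sup <- supportValues(boot)
  expect_length(sup, 1L)
  expect_equal(unname(sup), 100)
  expect_equal(attr(boot, "replicates_used"), 100L)
  expect_true(same_topology(boot, tree))
})

test_that("identical rows give a tree without support structure", {
  aln <- Biostrings::DNAStringSet(setNames(rep("ACGTACGTAA", 4),
                                           paste0("t", 1:4)))
  boot <- suppressWarnings(bootstrapSupport(aln, replicates = 10, seed = 1))
  expect_true(all(!nzchar(boot$node.label)))
})

test_that("bootstrap supports are seed-reproducible and stable across seeds", {
  set.seed(42)
  tree <- ape::read.tree(text = "((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06,E:0.1);")
  sim <- simulateAlignment(tree, site_count = 300, seed = 5)
  b1 <- bootstrapSupport(sim$alignment, replicates = 100, seed = 11)
  b2 <- bootstrapSupport(sim$alignment, replicates = 100, seed = 11)
  expect_identical(b1$node.label, b2$node.label)
  b3 <- bootstrapSupport(sim$alignment, replicates = 100, seed = 12)
  s1 <- supportValues(b1); s3 <- supportValues(b3)
  common <- intersect(names(s1), names(s3))
  expect_gt(length(common), 0)
  # binomial sampling error around a common expectation (<= ~15 points)
  expect_true(all(abs(s1[common] - s3[common]) <= 15))
})

test_that("Newick output round-trips and quotes awkward labels", {
  ra <- random_additive(6, seed = 7)
  tr <- neighborJoining(ra$D)
  tr$node.label <- c("", "87", "99", "55")
  p <- tempfile(fileext = ".nwk")
  writeNewick(tr, p, digits = 12)
  back <- readNewick(p)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-10)
  expect_equal(sort(back$node.label), sort(tr$node.label))
  # labels with spaces are single-quoted
  tq <- tr
  tq$tip.label[1] <- "Lactobacillus sp. X"
  pq <- tempfile(fileext = ".nwk")
  writeNewick(tq, pq)
  expect_match(readLines(pq), "'Lactobacillus sp. X'", fixed = TRUE)
  # 3-taxon shape
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p3 <- tempfile()
  writeNewick(neighborJoining(D), p3)
  expect_match(readLines(p3), "^\\(.*:.*,.*:.*,.*:.*\\);$")
})
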