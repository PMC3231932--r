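# Distance-based 16S phylogeny: p-distance with pairwise deletion,
# neighbor-joining (with deterministic tie-breaking), column-resampling
# bootstrap supports, Newick serialization. Trees are ape "phylo" objects.

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (rows of equal length; gaps `-`, unknowns `N`
#'   and other IUPAC codes allowed).
#' @return a named [Biostrings::DNAStringSet].
#' @export
readAlignedFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  validateAlignment(set)
  set
}

validateAlignment <- function(aln) {
  if (length(aln) < 2L) stop("alignment needs at least two taxa")
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("alignment rows differ in length")
  if (anyDuplicated(names(aln)) || is.null(names(aln)) || any(!nzchar(names(aln))))
    stop("alignment taxa must have unique non-empty names")
  invisible(aln)
}

alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  m <- t(vapply(as.character(aln),
                function(s) strsplit(s, "", fixed = TRUE)[[1]],
                character(Biostrings::width(aln)[1])))
  rownames(m) <- names(aln)
  m
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' For every pair of rows, alignment columns where either row carries a gap,
#' `N` or any other ambiguity code are discarded ("unknown bases were
#' discarded"); the distance is the mismatch fraction over the retained
#' columns. `model = "jc"` applies the Jukes-Cantor correction
#' `-3/4 log(1 - 4p/3)` on top.
#'
#' @param aln a `DNAStringSet` (or character matrix) alignment.
#' @param model `"p"` (default, uncorrected) or `"jc"`.
#' @return symmetric numeric matrix, units substitutions per site.
#' @export
pDistanceMatrix <- function(aln, model = c("p", "jc")) {
  model <- match.arg(model)
  if (!is.matrix(aln)) validateAlignment(aln)
  m <- alignmentMatrix(aln)
  taxa <- rownames(m)
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- ok[i, ] & ok[j, ]
      nk <- sum(keep)
      if (nk == 0L)
        stop("no comparable sites between '", taxa[i], "' and '", taxa[j], "'")
      p <- sum(m[i, keep] != m[j, keep]) / nk
      if (model == "jc") {
        if (p >= 0.75)
          stop("Jukes-Cantor undefined for p >= 0.75 ('", taxa[i], "' vs '",
               taxa[j], "')")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

formatBranch <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomerative neighbor joining: at each step the pair
#' minimizing `Q(i,j) = (m-2) d(i,j) - r(i) - r(j)` is joined, branch
#' lengths follow the standard formulas, and remaining distances are updated
#' as `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken toward
#' the lexicographically smallest joined taxon-pair label, so the result is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sister edge. On an additive matrix the output tree's
#' path lengths reproduce the input exactly.
#'
#' @param D symmetric distance matrix (or `dist`) with taxon names.
#' @return an unrooted `phylo` object (basal trifurcation).
#' @export
neighborJoining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix or dist")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < -1e-12)) stop("negative distances")
  if (any(abs(diag(D)) > 1e-12)) stop("non-zero diagonal")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  taxa <- rownames(D)
  # work on safe placeholder labels; restore the real names after parsing
  frag <- sprintf("txp%d", seq_len(n))
  lab <- taxa            # tie-break label: smallest leaf name in the cluster
  d <- D
  dimnames(d) <- NULL
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(lab[cand[, 1]], lab[cand[, 2]])
    key2 <- pmax(lab[cand[, 1]], lab[cand[, 2]])
    sel <- order(key1, key2)[1]
    i <- cand[sel, 1]; j <- cand[sel, 2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], formatBranch(vi),
                       frag[j], formatBranch(vj))
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    frag <- c(frag[keep], newfrag)
    lab <- c(lab[keep], min(lab[c(i, j)]))
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], formatBranch(v1), frag[2], formatBranch(v2),
                 frag[3], formatBranch(v3))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- taxa[as.integer(sub("^txp", "", tree$tip.label))]
  tree
}

#' Path-length (patristic) distance matrix of a tree
#'
#' Used to check additivity: on trees returned by [neighborJoining()] from
#' an additive matrix it reproduces the input.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix over the tip labels.
#' @export
pathDistances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

# tip-label sets below every node (indexed 1..Ntip+Nnode)
tipSets <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  eo <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# canonical keys of the non-trivial bipartitions (one per internal non-root
# node); sides are canonicalized to exclude the alphabetically first taxon
bipartitionKeys <- function(tree) {
  n <- length(tree$tip.label)
  if (tree$Nnode < 2L)
    return(list(keys = character(0), nodes = integer(0)))
  all_taxa <- sort(tree$tip.label)
  anchor <- all_taxa[1]
  desc <- tipSets(tree)
  root <- n + 1L
  nodes <- setdiff((n + 1L):(n + tree$Nnode), root)
  keys <- character(0); knodes <- integer(0)
  for (v in nodes) {
    s <- sort(desc[[v]])
    if (anchor %in% s) s <- setdiff(all_taxa, s)
    if (length(s) >= 2L && length(s) <= n - 2L) {
      keys <- c(keys, paste(s, collapse = "|"))
      knodes <- c(knodes, v)
    }
  }
  list(keys = keys, nodes = knodes)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the tree from the full alignment, then resamples alignment columns
#' with replacement `replicates` times, rebuilds a tree per replicate, and
#' scores every internal bipartition of the main tree by the percentage of
#' replicate trees containing it. The supports are stored as internal node
#' labels (`tree$node.label`; the basal node gets an empty label). A
#' replicate whose resampled columns leave some pair with no comparable
#' sites is skipped and tallied. All randomness flows from `seed`. A
#' reporting threshold (conventionally 50\%) is a display choice and is not
#' applied here.
#'
#' @param aln a `DNAStringSet` alignment.
#' @param replicates bootstrap resamplings (default 100).
#' @param seed RNG seed; set for reproducibility.
#' @param model distance model, see [pDistanceMatrix()].
#' @return a `phylo` with `node.label` supports (percent) and attributes
#'   `replicates_used` and `replicates_skipped`.
#' @export
bootstrapSupport <- function(aln, replicates = 100L, seed = NULL,
                             model = "p") {
  validateAlignment(aln)
  if (!is.null(seed)) set.seed(seed)
  m <- alignmentMatrix(aln)
  m <- m[order(rownames(m)), , drop = FALSE]  # canonical taxon order
  D <- pDistanceMatrix(m, model = model)
  main <- neighborJoining(D)
  bp <- bipartitionKeys(main)
  counts <- stats::setNames(rep(0L, length(bp$keys)), bp$keys)
  skipped <- 0L
  used <- 0L
  nsite <- ncol(m)
  for (r in seq_len(replicates)) {
    idx <- sample.int(nsite, nsite, replace = TRUE)
    rep_tree <- tryCatch(
      neighborJoining(pDistanceMatrix(m[, idx, drop = FALSE], model = model)),
      error = function(e) NULL)
    if (is.null(rep_tree)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    hit <- bp$keys %in% bipartitionKeys(rep_tree)$keys
    counts[hit] <- counts[hit] + 1L
  }
  if (skipped > 0L)
    warning(skipped, " bootstrap replicate(s) skipped (no comparable sites ",
            "for some pair)")
  n <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  if (length(bp$nodes) && used > 0L) {
    support <- 100 * counts / used
    if (max(D) == 0) support[] <- NA_real_  # identical rows: no structure
    labels[bp$nodes - n] <- ifelse(is.na(support), "",
                                   sprintf("%g", round(support, 1)))
  }
  main$node.label <- labels
  attr(main, "replicates_used") <- used
  attr(main, "replicates_skipped") <- skipped
  main
}

#' Bootstrap support values of a tree
#'
#' @param tree a `phylo` from [bootstrapSupport()].
#' @return named numeric vector: support percentage per internal
#'   bipartition key.
#' @export
supportValues <- function(tree) {
  bp <- bipartitionKeys(tree)
  n <- length(tree$tip.label)
  vals <- suppressWarnings(as.numeric(tree$node.label[bp$nodes - n]))
  stats::setNames(vals, bp$keys)
}

quoteNewickLabel <- function(x) {
  needs <- grepl("[][ \t():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree as Newick
#'
#' Serializes a `phylo` with branch lengths and (when present) internal node
#' labels such as bootstrap supports. Taxon names containing spaces or
#' Newick metacharacters are single-quoted.
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @param digits significant digits for branch lengths (default 10).
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path, digits = 10L) {
  n <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  fmt <- paste0("%.", digits, "g")
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  serialize <- function(v) {
    if (v <= n) return(quoteNewickLabel(tree$tip.label[v]))
    inner <- vapply(kids[[as.character(v)]], function(ch) {
      row <- which(tree$edge[, 2] == ch)
      paste0(serialize(ch),
             if (has_len) paste0(":", sprintf(fmt, tree$edge.length[row])) else "")
    }, character(1))
    lab <- if (!is.null(tree$node.label)) {
      l <- tree$node.label[v - n]
      if (is.na(l) || !nzchar(l)) "" else quoteNewickLabel(l)
    } else ""
    paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  writeLines(paste0(serialize(n + 1L), ";"), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()], the standard Newick parser.
#'
#' @param path Newick file.
#' @return a `phylo`.
#' @export
readNewick <- function(path) ape::read.tree(path)
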