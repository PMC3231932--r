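# Seeded synthetic data with full ground truth: circular genomes with two
# oppositely G/C-biased replichores, a DnaA-box cluster at the origin,
# 16S-23S-5S rRNA operons, tRNAs, CDSs with expression-correlated codon
# bias, frameshift pseudogenes; and alignments evolved along a known tree.

AA20 <- setdiff(unique(Biostrings::getGeneticCode("11")), "*")

# deterministic "major codon" table: per amino acid, the synonym most
# probable under the genome-average (skew-free) composition, ties broken
# alphabetically. Low-GC genomes thus prefer A/T-ending codons.
majorCodonTable <- function(gc, code = "11") {
  gcmap <- geneticCode(code)
  sense <- names(gcmap)[gcmap != "*"]
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  wt <- vapply(sense, function(cod) {
    prod(pb[strsplit(cod, "")[[1]]])
  }, numeric(1))
  vapply(split(seq_along(sense), gcmap[sense]), function(i) {
    s <- sense[i]
    s[order(-wt[i], s)][1]
  }, character(1))
}

# codon weights proportional to per-base probabilities of a composition
codonWeights <- function(pb, code = "11") {
  gcmap <- geneticCode(code)
  sense <- names(gcmap)[gcmap != "*"]
  vapply(sense, function(cod) prod(pb[strsplit(cod, "")[[1]]]), numeric(1))
}

# draw one CDS: ATG + aa codons + TAA; synonymous codons are the major codon
# with probability m, otherwise sampled with composition weights (the coding
# strand's replichore composition), so genes carry realistic wobble-position
# replication strand bias.
sampleGene <- function(n_aa, m, major, weights, gcmap_sense, code = "11") {
  aa <- sample(AA20, n_aa, replace = TRUE)
  codons <- character(n_aa)
  take_major <- stats::runif(n_aa) < m
  fam <- split(seq_len(n_aa), aa)
  for (a in names(fam)) {
    idx <- fam[[a]]
    syn <- names(gcmap_sense)[gcmap_sense == a]
    maj_idx <- idx[take_major[idx]]
    codons[maj_idx] <- major[[a]]
    rest <- idx[!take_major[idx]]
    if (length(rest))
      codons[rest] <- sample(syn, length(rest), replace = TRUE,
                             prob = weights[syn])
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# instantiate an IUPAC consensus: each degenerate position gets one of its
# admissible bases uniformly
instantiateConsensus <- function(consensus) {
  letters_used <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(letters_used, function(l) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    sample(opts, 1L)
  }, character(1)), collapse = "")
}

revcompChar <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# non-overlapping start positions for n motifs of length k in 1..region_len
plantPositions <- function(n, k, region_len) {
  if (n == 0L) return(integer(0))
  if (n * k > region_len) stop("region too small to plant ", n, " motifs")
  for (try in 1:200) {
    pos <- sort(sample.int(region_len - k + 1L, n))
    if (n == 1L || all(diff(pos) >= k)) return(pos)
  }
  # deterministic fallback: evenly spaced
  as.integer(round(seq(1, region_len - k + 1L, length.out = n)))
}

#' Simulate a circular bacterial genome with known architecture
#'
#' Generates a circular chromosome whose two replichores have opposite G/C
#' bias switching exactly at the planted origin (base 1 before rotation) and
#' terminus (`ori + floor(length/2)`), with: a dnaA-dnaN cassette at the
#' origin carrying planted DnaA boxes upstream of dnaA and in the dnaA-dnaN
#' intergap; 16S-23S-5S rRNA operons with sub-threshold internal spacers;
#' tRNA genes; CDSs placed non-overlapping, coded on the leading strand with
#' probability `strand_bias`, their synonymous codons drawn from a mixture of
#' a fixed major-codon table (weight `codon_bias_strength` scaled by the
#' gene's expression level) and a composition-weighted background — so highly
#' expressed genes show strong codon usage bias and all genes carry
#' wobble-position strand bias; and a fraction of CDSs turned into
#' pseudogenes by a single-base deletion. On the leading strand the
#' background satisfies `freq(G) - freq(C) = skew_delta`
#' (`P(G) = (gc + skew_delta)/2`, `P(C) = (gc - skew_delta)/2`).
#'
#' Identical arguments (including `seed`) give byte-identical output.
#'
#' @param length genome length, bases.
#' @param ori position at which the planted origin is placed (default 1).
#' @param skew_delta leading-strand G-C frequency excess, in `[0, gc)`.
#' @param gc target GC fraction.
#' @param n_genes number of intact CDSs beside dnaA/dnaN.
#' @param strand_bias probability a gene is coded on the leading strand.
#' @param n_rrna_operons,n_trna stable-RNA feature counts.
#' @param n_dnaA_boxes_upstream,n_dnaA_boxes_intergenic planted DnaA-box
#'   counts (consensus `TTATNCACA`).
#' @param pseudogene_fraction fraction of the `n_genes` CDSs converted to
#'   frameshift pseudogenes (default 0.106, a realistic reductive-evolution
#'   load).
#' @param expression_levels optional positive per-gene weights (length
#'   `n_genes`); by default 30\% of genes are highly expressed (level 1,
#'   labelled as ribosomal proteins) and the rest draw levels from
#'   `U(0, 0.3)`.
#' @param codon_bias_strength mixture weight of the major-codon component
#'   for a gene at the maximum expression level (default 0.7).
#' @param seed mandatory RNG seed.
#' @param id sequence identifier.
#' @param out_dir optional directory: writes `genome.fasta`, `genome.gff3`
#'   and `truth.json`.
#' @return list with `sequence` ([CircularSequence-class]), `annotations`
#'   ([AnnotationSet-class]) and `truth` (planted ground-truth record).
#' @export
simulateGenome <- function(length = 100000L, ori = 1L, skew_delta = 0.05,
                           gc = 0.35, n_genes = 100L, strand_bias = 0.8,
                           n_rrna_operons = 2L, n_trna = 8L,
                           n_dnaA_boxes_upstream = 5L,
                           n_dnaA_boxes_intergenic = 3L,
                           pseudogene_fraction = 0.106,
                           expression_levels = NULL,
                           codon_bias_strength = 0.7,
                           seed, id = "synth_genome", out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(skew_delta >= 0, skew_delta < gc, gc > 0, gc < 1,
            strand_bias >= 0, strand_bias <= 1,
            codon_bias_strength >= 0, codon_bias_strength <= 1,
            pseudogene_fraction >= 0, pseudogene_fraction <= 1)
  set.seed(seed)
  L <- as.integer(length)
  ter <- L %/% 2L + 1L  # in the ori=1 frame

  code <- "11"
  gcmap <- geneticCode(code)
  gcmap_sense <- gcmap[gcmap != "*"]
  major <- majorCodonTable(gc, code)
  # forward-strand base probabilities per replichore (leading = forward on
  # replichore 1)
  p_lead <- c(A = (1 - gc) / 2, C = (gc - skew_delta) / 2,
              G = (gc + skew_delta) / 2, T = (1 - gc) / 2)
  p_lag <- p_lead[c("A", "G", "C", "T")]
  names(p_lag) <- c("A", "C", "G", "T")
  w_lead <- codonWeights(p_lead, code)   # coding strand == leading strand
  w_lag <- codonWeights(p_lag, code)

  # ---- origin cassette geometry (positions in the ori=1 frame) ----
  up_len <- 500L
  dnaA_len <- 3L * (445L + 2L)
  inter_len <- 300L
  dnaN_len <- 3L * (366L + 2L)
  cassette <- up_len + dnaA_len + inter_len + dnaN_len

  # ---- movable feature blocks ----
  n_genes <- as.integer(n_genes)
  n_pseudo <- as.integer(round(pseudogene_fraction * n_genes))
  pseudo_idx <- if (n_pseudo > 0L) sort(sample.int(n_genes, n_pseudo)) else integer(0)
  if (is.null(expression_levels)) {
    n_high <- as.integer(round(0.3 * n_genes))
    expr <- c(rep(1, n_high), stats::runif(n_genes - n_high, 0, 0.3))
  } else {
    if (base::length(expression_levels) != n_genes || any(expression_levels <= 0))
      stop("expression_levels must be ", n_genes, " positive weights")
    expr <- as.numeric(expression_levels)
  }
  emax <- max(expr)
  high <- expr >= 0.5 * emax
  aa_len <- pmax(60L, as.integer(round(stats::rgamma(n_genes, shape = 6, scale = 40))))
  gene_len <- 3L * (aa_len + 2L) - ifelse(seq_len(n_genes) %in% pseudo_idx, 1L, 0L)

  op_parts <- c(`16S` = 1550L, spacer1 = 150L, `23S` = 2900L,
                spacer2 = 80L, `5S` = 115L)
  op_len <- sum(op_parts)
  trna_len <- 75L

  block_len <- c(gene_len,
                 rep(op_len, n_rrna_operons),
                 rep(trna_len, n_trna))
  block_kind <- c(rep("gene", n_genes),
                  rep("operon", n_rrna_operons),
                  rep("trna", n_trna))
  block_idx <- c(seq_len(n_genes), seq_len(n_rrna_operons), seq_len(n_trna))
  total <- cassette + sum(block_len)
  if (total > 0.97 * L)
    stop("infeasible packing: features need ", total, " of ", L, " bases")

  nb <- base::length(block_len)
  B <- L - total
  len0 <- block_len; kind0 <- block_kind; idx0 <- block_idx
  # resample the layout until planted operons sit further apart than the
  # operon-calling gap (intervening genes do not break an rRNA chain, so
  # two nearby operon blocks would merge and falsify the planted count)
  for (attempt in 1:200) {
    ord <- sample.int(nb)
    block_len <- len0[ord]; block_kind <- kind0[ord]; block_idx <- idx0[ord]
    gaps <- as.integer(stats::rmultinom(1, B, rep(1, nb + 1L)))
    starts <- cassette + cumsum(c(gaps[1L], utils::head(block_len, -1L) +
                                    gaps[-1L][seq_len(nb - 1L)])) + 1L
    if (n_rrna_operons < 2L) break
    op_i <- which(block_kind == "operon")
    op_start <- sort(starts[op_i])
    op_end <- op_start + op_len - 1L
    gap_fwd <- c(op_start[-1L] - op_end[-base::length(op_end)] - 1L,
                 (L - op_end[base::length(op_end)]) + op_start[1L] - 1L)
    if (all(gap_fwd > 3100L)) break
    if (attempt == 200L)
      stop("infeasible packing: cannot separate ", n_rrna_operons,
           " rRNA operons in ", L, " bases")
  }

  # ---- background with the two-replichore composition ----
  bases <- c("A", "C", "G", "T")
  chars <- c(sample(bases, ter - 1L, replace = TRUE, prob = p_lead),
             sample(bases, L - ter + 1L, replace = TRUE, prob = p_lag))

  put <- function(chars, at, s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[at:(at + base::length(v) - 1L)] <- v
    chars
  }
  geneSeqAt <- function(start, strand, n_aa, m) {
    leading <- start < ter
    w <- if ((leading && strand == "+") || (!leading && strand == "-"))
      w_lead else w_lag
    s <- sampleGene(n_aa, m, major, w, gcmap_sense, code)
    if (strand == "-") s <- revcompChar(s)
    s
  }

  feats <- list()
  addFeat <- function(type, start, end, strand, locus_tag, gene = NA_character_,
                      product = NA_character_, rrna_subunit = "none") {
    feats[[base::length(feats) + 1L]] <<- data.frame(
      feature_type = type, start = start, end = end, strand = strand,
      locus_tag = locus_tag, gene = gene, product = product,
      rrna_subunit = rrna_subunit, stringsAsFactors = FALSE)
  }

  # origin cassette: boxes upstream of dnaA and in the dnaA-dnaN intergap
  consensus <- "TTATNCACA"
  k <- nchar(consensus)
  boxes <- data.frame(position = integer(0), strand = character(0),
                      region = character(0), stringsAsFactors = FALSE)
  up_pos <- plantPositions(n_dnaA_boxes_upstream, k, up_len)
  for (p in up_pos) {
    site <- instantiateConsensus(consensus)
    strand <- sample(c("+", "-"), 1L)
    chars <- put(chars, p, if (strand == "+") site else revcompChar(site))
    boxes <- rbind(boxes, data.frame(position = p, strand = strand,
                                     region = "upstream"))
  }
  dnaA_start <- up_len + 1L
  chars <- put(chars, dnaA_start, geneSeqAt(dnaA_start, "+", 445L,
                                            0.5 * codon_bias_strength))
  addFeat("CDS", dnaA_start, dnaA_start + dnaA_len - 1L, "+", "SYN_dnaA",
          gene = "dnaA",
          product = "chromosomal replication initiator protein DnaA")
  ig_start <- dnaA_start + dnaA_len
  ig_pos <- plantPositions(n_dnaA_boxes_intergenic, k, inter_len)
  for (p in ig_pos) {
    site <- instantiateConsensus(consensus)
    strand <- sample(c("+", "-"), 1L)
    chars <- put(chars, ig_start + p - 1L,
                 if (strand == "+") site else revcompChar(site))
    boxes <- rbind(boxes, data.frame(position = ig_start + p - 1L,
                                     strand = strand, region = "intergenic"))
  }
  dnaN_start <- ig_start + inter_len
  chars <- put(chars, dnaN_start, geneSeqAt(dnaN_start, "+", 366L,
                                            0.5 * codon_bias_strength))
  addFeat("CDS", dnaN_start, dnaN_start + dnaN_len - 1L, "+", "SYN_dnaN",
          gene = "dnaN", product = "DNA polymerase III, beta subunit")

  # movable blocks
  genes <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      expression = numeric(0), pseudo = logical(0),
                      high = logical(0), stringsAsFactors = FALSE)
  operons <- data.frame(start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  ribo_i <- 0L
  for (b in seq_len(nb)) {
    st <- starts[b]
    if (block_kind[b] == "gene") {
      g <- block_idx[b]
      leading <- st < ter
      lead_strand <- if (leading) "+" else "-"
      strand <- if (stats::runif(1) < strand_bias) lead_strand
                else setdiff(c("+", "-"), lead_strand)
      m <- codon_bias_strength * expr[g] / emax
      s <- geneSeqAt(st, strand, aa_len[g], m)
      is_pseudo <- g %in% pseudo_idx
      if (is_pseudo) {
        del <- sample.int(nchar(s) - 2L, 1L) + 1L  # internal single-base deletion
        s <- paste0(substr(s, 1L, del - 1L), substr(s, del + 1L, nchar(s)))
      }
      en <- st + nchar(s) - 1L
      chars <- put(chars, st, s)
      tag <- sprintf("SYN_%04d", g)
      if (is_pseudo) {
        addFeat("pseudogene", st, en, strand, tag, product = "pseudogene")
      } else if (high[g]) {
        ribo_i <- ribo_i + 1L
        sub <- if (ribo_i %% 2L) "50S" else "30S"
        addFeat("CDS", st, en, strand, tag,
                product = sprintf("%s ribosomal protein %s%d", sub,
                                  if (sub == "50S") "L" else "S", ribo_i))
      } else {
        addFeat("CDS", st, en, strand, tag, product = "hypothetical protein")
      }
      genes <- rbind(genes, data.frame(
        gene_id = tag, start = st, end = en, strand = strand,
        expression = expr[g], pseudo = is_pseudo, high = high[g],
        stringsAsFactors = FALSE))
    } else if (block_kind[b] == "operon") {
      o <- block_idx[b]
      p16 <- st
      p23 <- p16 + op_parts[["16S"]] + op_parts[["spacer1"]]
      p5 <- p23 + op_parts[["23S"]] + op_parts[["spacer2"]]
      addFeat("rRNA", p16, p16 + op_parts[["16S"]] - 1L, "+",
              sprintf("SYN_rrs%d", o), product = "16S ribosomal RNA",
              rrna_subunit = "16S")
      addFeat("rRNA", p23, p23 + op_parts[["23S"]] - 1L, "+",
              sprintf("SYN_rrl%d", o), product = "23S ribosomal RNA",
              rrna_subunit = "23S")
      addFeat("rRNA", p5, p5 + op_parts[["5S"]] - 1L, "+",
              sprintf("SYN_rrf%d", o), product = "5S ribosomal RNA",
              rrna_subunit = "5S")
      operons <- rbind(operons, data.frame(start = st, end = st + op_len - 1L))
    } else {
      t <- block_idx[b]
      addFeat("tRNA", st, st + trna_len - 1L,
              sample(c("+", "-"), 1L), sprintf("SYN_t%02d", t),
              product = "tRNA")
    }
  }

  seq1 <- new("CircularSequence", id = id,
              seq = Biostrings::DNAString(paste(chars, collapse = "")),
              topology = "circular")
  ann1 <- annotationSet(id, do.call(rbind, feats), seq_length = L)

  truth <- list(ori = 1L, ter = ter, genes = genes, operons = operons,
                boxes = boxes,
                regions = list(upstream = c(1L, up_len),
                               intergenic = c(ig_start, ig_start + inter_len - 1L)),
                dnaA = c(start = dnaA_start, end = dnaA_start + dnaA_len - 1L),
                dnaN = c(start = dnaN_start, end = dnaN_start + dnaN_len - 1L),
                consensus = consensus, seed = seed,
                params = list(length = L, skew_delta = skew_delta, gc = gc,
                              n_genes = n_genes, strand_bias = strand_bias,
                              codon_bias_strength = codon_bias_strength))

  ori <- as.integer(ori)
  if (ori != 1L) {
    rot <- rotateToOrigin(seq1, ann1, ori = mod1(L - ori + 2L, L))
    seq1 <- rot$sequence; ann1 <- rot$annotations
    shift <- function(p) mod1(p + ori - 1L, L)
    truth$ori <- shift(truth$ori); truth$ter <- shift(truth$ter)
    truth$genes$start <- shift(truth$genes$start)
    truth$genes$end <- shift(truth$genes$end)
    truth$operons$start <- shift(truth$operons$start)
    truth$operons$end <- shift(truth$operons$end)
    truth$boxes$position <- shift(truth$boxes$position)
    truth$regions <- lapply(truth$regions, shift)
    truth$dnaA <- shift(truth$dnaA); truth$dnaN <- shift(truth$dnaN)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeGenomeFasta(seq1, file.path(out_dir, "genome.fasta"))
    writeAnnotationsGff3(ann1, file.path(out_dir, "genome.gff3"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sequence = seq1, annotations = ann1, truth = truth)
}

#' Write an AnnotationSet as GFF3
#'
#' @param annotations an [AnnotationSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationsGff3 <- function(annotations, path) {
  gr <- annotations@features
  mc <- S4Vectors::mcols(gr)
  L <- annotations@seq_length
  id <- annotations@sequence_id
  enc <- function(x) {  # GFF3 reserves ; = , & in attribute values
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    gsub("&", "%26", x, fixed = TRUE)
  }
  attr_of <- function(i) {
    parts <- c(sprintf("ID=%s", enc(mc$locus_tag[i])),
               sprintf("locus_tag=%s", enc(mc$locus_tag[i])),
               if (!is.na(mc$gene[i])) sprintf("gene=%s", enc(mc$gene[i])),
               if (!is.na(mc$product[i])) sprintf("product=%s", enc(mc$product[i])))
    paste(parts, collapse = ";")
  }
  lines <- c("##gff-version 3",
             if (!is.na(L)) sprintf("##sequence-region %s 1 %d", id, L))
  for (i in seq_along(gr)) {
    lines <- c(lines, sprintf("%s\tBacArch\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      id, mc$feature_type[i], BiocGenerics::start(gr)[i],
      BiocGenerics::end(gr)[i],
      as.character(BiocGenerics::strand(gr))[i],
      if (mc$feature_type[i] == "CDS") "0" else ".",
      attr_of(i)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an alignment along a known tree (Jukes-Cantor)
#'
#' The root sequence is i.i.d. uniform over A/C/G/T; each site evolves
#' independently down the tree, substituting with probability
#' `3/4 (1 - exp(-4 b / 3))` per branch of length `b` (substitutions per
#' site) to one of the three other bases uniformly. No indels: the sequence
#' matrix is the alignment.
#'
#' @param tree a `phylo` with non-negative branch lengths.
#' @param site_count number of alignment columns.
#' @param seed mandatory RNG seed.
#' @param model only `"jukes_cantor"`.
#' @return list with `alignment` (a named `DNAStringSet` over the tips) and
#'   `truth` (the generating tree and the pairwise expected p-distances).
#' @export
simulateAlignment <- function(tree, site_count, seed,
                              model = "jukes_cantor") {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory")
  site_count <- as.integer(site_count)
  if (site_count < 1L) stop("site_count must be >= 1")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  set.seed(seed)
  n <- base::length(tree$tip.label)
  bases <- c("A", "C", "G", "T")
  nodes <- n + tree$Nnode
  seqs <- matrix(NA_integer_, nodes, site_count)
  root <- n + 1L
  seqs[root, ] <- sample.int(4L, site_count, replace = TRUE)
  eo <- stats::reorder(tree, "cladewise")  # parents before children
  for (kk in seq_len(nrow(eo$edge))) {
    p <- eo$edge[kk, 1]; ch <- eo$edge[kk, 2]
    b <- eo$edge.length[kk]
    psub <- 0.75 * (1 - exp(-4 * b / 3))
    s <- seqs[p, ]
    mut <- stats::runif(site_count) < psub
    nm <- sum(mut)
    if (nm)
      s[mut] <- ((s[mut] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    seqs[ch, ] <- s
  }
  rows <- vapply(seq_len(n), function(i)
    paste(bases[seqs[i, ]], collapse = ""), character(1))
  aln <- Biostrings::DNAStringSet(rows)
  names(aln) <- tree$tip.label
  t_pair <- ape::cophenetic.phylo(tree)
  expected_p <- 0.75 * (1 - exp(-4 * t_pair / 3))
  list(alignment = aln,
       truth = list(tree = tree, expected_p = expected_p, seed = seed))
}
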