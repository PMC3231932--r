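#' Read genome sequences from FASTA
#'
#' One [CircularSequence-class] per record. The record id is the first
#' whitespace-delimited token of the header; lower case is mapped to upper
#' case by construction of the underlying `DNAString`.
#'
#' @param path FASTA file.
#' @param topology topology assigned to every record, `"circular"` (default,
#'   the bacterial-chromosome convention) or `"linear"`.
#' @return named list of [CircularSequence-class] objects.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr demo", "ACGTACGT"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop("FASTA format error in '", path, "': ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("FASTA format error in '", path, "': non-IUPAC characters (",
             conditionMessage(w), ")", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "))
  out <- lapply(seq_along(set), function(i)
    new("CircularSequence", id = ids[i], seq = set[[i]], topology = topology))
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#'
#' @param seqs a [CircularSequence-class] or a list of them.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(seqs, path, width = 70L) {
  if (is(seqs, "CircularSequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(lapply(seqs, slot, "seq"))
  names(set) <- vapply(seqs, seqID, character(1))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

# product text -> rRNA subunit label
rrnaSubunitFromProduct <- function(product) {
  out <- rep("none", length(product))
  hit <- regmatches(product, regexpr("\\b(16S|23S|5S)\\b", product, ignore.case = TRUE))
  has <- grepl("\\b(16S|23S|5S)\\b", product, ignore.case = TRUE)
  out[has] <- toupper(unlist(hit))
  out
}

#' Read genome annotations (GFF3 or GenBank flat file)
#'
#' Extracts CDS, rRNA, tRNA and pseudogene features into an
#' [AnnotationSet-class]. A GenBank `/pseudo` qualifier and the GFF3
#' `pseudogene` type (or a `pseudo=true` attribute) both map to feature type
#' `pseudogene`; rRNA `product` text is parsed into 16S/23S/5S subunit
#' labels. Coordinates are kept 1-based inclusive; a GenBank
#' `join(a..L,1..b)` location on a circular record becomes a wrapped feature
#' (`end = L + b`, `wraps = TRUE`).
#'
#' @param path annotation file.
#' @param format `"auto"` (sniffs the first line), `"gff3"` or `"genbank"`.
#' @param seq_length sequence length if the file does not state it
#'   (`##sequence-region` directive or LOCUS line).
#' @return an [AnnotationSet-class].
#' @export
readAnnotations <- function(path, format = c("auto", "gff3", "genbank"),
                            seq_length = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank"
      else if (grepl("^##gff-version|^#|\t", first)) "gff3"
      else stop("cannot determine annotation format of '", path, "'")
  }
  if (format == "gff3") readAnnotationsGff3(path, seq_length)
  else readAnnotationsGenbank(path, seq_length)
}

readAnnotationsGff3 <- function(path, seq_length = NA_integer_) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.na(seq_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) && !is.na(sl[1])) seq_length <- unname(sl[1])
  }
  if (is.na(seq_length)) {  # fall back to the ##sequence-region directive
    hdr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
    if (length(hdr)) {
      tok <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
      seq_length <- suppressWarnings(as.integer(tok[length(tok)]))
    }
  }
  seqid <- as.character(GenomeInfoDb::seqnames(gr))
  if (length(gr) == 0L) stop("no features in '", path, "'")
  sequence_id <- seqid[1]
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (!nm %in% colnames(mc)) return(rep(NA_character_, length(gr)))
    col <- mc[[nm]]
    if (is(col, "List"))  # multi-valued attributes come back as CharacterList
      col <- vapply(col, function(x)
        if (length(x)) paste(x, collapse = ",") else NA_character_, character(1))
    vapply(as.character(col), function(x)
      if (is.na(x)) x else utils::URLdecode(x), character(1), USE.NAMES = FALSE)
  }
  type <- as.character(mc$type)
  pseudo <- getcol("pseudo")
  ftype <- rep(NA_character_, length(gr))
  ftype[type == "CDS"] <- "CDS"
  ftype[type == "rRNA"] <- "rRNA"
  ftype[type == "tRNA"] <- "tRNA"
  ftype[type == "pseudogene"] <- "pseudogene"
  ftype[!is.na(pseudo) & tolower(pseudo) %in% c("true", "1")] <- "pseudogene"
  keep <- !is.na(ftype)
  gr <- gr[keep]
  product <- getcol("product")[keep]
  df <- data.frame(
    feature_type = ftype[keep],
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    locus_tag = ifelse(is.na(getcol("locus_tag")[keep]),
                       getcol("ID")[keep], getcol("locus_tag")[keep]),
    gene = getcol("gene")[keep],
    product = product,
    rrna_subunit = ifelse(ftype[keep] == "rRNA",
                          rrnaSubunitFromProduct(product), "none"),
    stringsAsFactors = FALSE)
  if (!is.na(seq_length)) {
    bad <- df$end > seq_length
    df$wraps <- bad
    if (any(bad & (df$end - seq_length) >= df$start))
      stop("feature coordinates outside sequence in '", path, "'")
  }
  out <- annotationSet(sequence_id, df, seq_length = seq_length)
  validObject(out)
  out
}

# Minimal GenBank flat-file feature-table parser: LOCUS line, FEATURES block
# with CDS/rRNA/tRNA keys, qualifiers /locus_tag /gene /product /pseudo,
# locations n..m, complement(...), join(a..L,1..b) (circular wrap). Enough
# for single-record bacterial flat files; not a general GenBank reader.
readAnnotationsGenbank <- function(path, seq_length = NA_integer_) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  sequence_id <- "unknown"
  if (length(locus)) {
    tok <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]]
    sequence_id <- tok[1]
    bp <- suppressWarnings(as.integer(tok[which(tok == "bp") - 1L]))
    if (is.na(seq_length) && length(bp) && !is.na(bp[1])) seq_length <- bp[1]
  }
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("no FEATURES block in '", path, "'")
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  block <- lines[(fstart[1] + 1L):fend]

  # a new feature starts with a key in column 6; qualifiers are indented deeper
  is_key <- grepl("^\\s{2,8}\\S", block) & !grepl("^\\s{9,}", block)
  idx <- which(is_key)
  if (!length(idx)) stop("empty FEATURES block in '", path, "'")
  ends <- c(idx[-1] - 1L, length(block))
  feats <- list()
  for (k in seq_along(idx)) {
    chunk <- block[idx[k]:ends[k]]
    key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1])
    if (!key %in% c("CDS", "rRNA", "tRNA", "gene")) next
    # location may continue over lines until the first /qualifier
    qual_at <- grep("^\\s+/", chunk)
    loc_lines <- if (length(qual_at)) chunk[1:(qual_at[1] - 1L)] else chunk
    loc <- gsub("\\s", "", paste(c(sub("^\\s*\\S+\\s*", "", loc_lines[1]),
                                   trimws(loc_lines[-1])), collapse = ""))
    quals <- paste(trimws(chunk[seq_along(chunk) >= ifelse(length(qual_at),
                                                           qual_at[1], Inf)]),
                   collapse = " ")
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    wraps <- FALSE
    if (grepl("^join\\(", loc)) {
      parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
      rng <- lapply(parts, function(p)
        as.integer(sub("[<>]", "", strsplit(p, "\\.\\.")[[1]])))
      st <- rng[[1]][1]
      en <- rng[[length(rng)]][2]
      if (!is.na(seq_length) && en < st) {  # wrap across the junction
        wraps <- TRUE
        en <- en + seq_length
      }
    } else {
      bits <- as.integer(gsub("[<>]", "", strsplit(loc, "\\.\\.")[[1]]))
      st <- bits[1]
      en <- if (length(bits) > 1L) bits[2] else bits[1]
    }
    qval <- function(name) {
      m <- regmatches(quals, regexpr(paste0("/", name, '="[^"]*"'), quals))
      if (length(m)) sub('^.*?"(.*)"$', "\\1", m) else NA_character_
    }
    pseudo <- grepl("/pseudo\\b", quals)
    ftype <- if (key == "gene") next else key
    if (pseudo) ftype <- "pseudogene"
    feats[[length(feats) + 1L]] <- data.frame(
      feature_type = ftype, start = st, end = en, strand = strand,
      locus_tag = qval("locus_tag"), gene = qval("gene"),
      product = qval("product"), wraps = wraps, stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("no CDS/rRNA/tRNA features found in '", path, "'")
  df <- do.call(rbind, feats)
  df$rrna_subunit <- ifelse(df$feature_type == "rRNA",
                            rrnaSubunitFromProduct(df$product), "none")
  if (!is.na(seq_length) &&
      any(!df$wraps & df$end > seq_length))
    stop("feature coordinates outside sequence (non-wrapping) in '", path, "'")
  out <- annotationSet(sequence_id, df, seq_length = seq_length)
  validObject(out)
  out
}

#' Export a skew profile as a genome-browser track
#'
#' Writes one interval per window anchor with the chosen statistic. Internal
#' coordinates are 1-based inclusive; bedGraph output converts to 0-based
#' half-open intervals, one `step`-sized tile per window anchor. WIG output
#' uses a `fixedStep` block.
#'
#' @param profile a [SkewProfile-class].
#' @param path output file.
#' @param format `"bedgraph"` or `"wig"`.
#' @param stat `"skew"` or `"gc"` (GC fraction).
#' @return `path`, invisibly.
#' @export
writeTrack <- function(profile, path, format = c("bedgraph", "wig"),
                       stat = c("skew", "gc")) {
  format <- match.arg(format)
  stat <- match.arg(stat)
  if (length(profile@starts) == 0L) stop("empty profile")
  vals <- if (stat == "skew") profile@skew else profile@gc_percent
  id <- profile@sequence_id
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bedgraph") {
    start0 <- profile@starts - 1L
    end0 <- start0 + profile@step
    writeLines(sprintf("%s\t%d\t%d\t%.6f", id, start0, end0, vals), con)
  } else {
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       id, profile@starts[1], profile@step, profile@step), con)
    writeLines(sprintf("%.6f", vals), con)
  }
  invisible(path)
}
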