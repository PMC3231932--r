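# End-to-end orchestration: skew profile -> ori/ter -> rotation -> DnaA
# boxes -> genome stats -> rRNA density (+ optional survey, codon-usage
# ranking, 16S tree), with a JSON + TSV report bundle.

pipelineDefaults <- function() {
  list(
    fasta = NULL, annotations = NULL, annotation_format = "auto",
    survey_tsv = NULL, alignment_fasta = NULL,
    window = 10000L, step = 200L, convention = "G_minus_C",
    operon_gap = 3000L, survey_threshold = 2.9, survey_top_k = 20L,
    cub_reference_pattern = "ribosomal protein", cub_top_k = 80L,
    bootstrap_replicates = 100L, dnaA_box_consensus = "TTATNCACA",
    upstream_cap = 1000L, rotate = FALSE, seed = 1L, out_dir = "pipeline_out")
}

#' Read / write a flat key=value pipeline configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Unknown keys are rejected; missing keys take the defaults (window 10000,
#' step 200, operon gap 3000, survey threshold 2.9, 100 bootstrap
#' replicates).
#'
#' @param path config file.
#' @return named list (the full config with defaults applied).
#' @export
readPipelineConfig <- function(path) {
  defaults <- pipelineDefaults()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    key <- kv[1]; val <- kv[2]
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    old <- defaults[[key]]
    cfg[[key]] <- if (is.numeric(old) || is.null(old) &&
                        grepl("^-?[0-9.]+$", val)) {
      if (grepl("^-?[0-9]+$", val) && is.integer(old)) as.integer(val)
      else if (grepl("^-?[0-9.eE+-]+$", val) && is.numeric(old)) as.numeric(val)
      else val
    } else if (is.logical(old)) as.logical(val) else val
  }
  cfg
}

#' @rdname readPipelineConfig
#' @param config named list of settings (missing entries take defaults).
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- utils::modifyList(pipelineDefaults(), config)
  keep <- !vapply(cfg, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(cfg)[keep],
                     vapply(cfg[keep], as.character, character(1))), path)
  invisible(path)
}

stageError <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

runStage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) stageError(stage, e))
  message(sprintf("[%s] done in %.2fs", stage,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full genome-architecture pipeline
#'
#' Executes, in dependency order: input reading and validation, windowed
#' GC/skew profile (exported as bedGraph), cumulative skew and ori/terminus
#' prediction (optionally rotating the genome to put the origin at base 1),
#' DnaA-box counting around dnaA, genome feature statistics, rRNA operon
#' grouping and density, and — when the corresponding inputs are configured —
#' the rRNA-density survey, the codon-usage ranking and the bootstrapped
#' neighbor-joining 16S tree. A machine-readable `summary.json` (carrying the
#' config hash, package version and seed) plus TSV/track/Newick files are
#' written to `out_dir`. Stage failures abort with the stage name; identical
#' config and seed give identical output.
#'
#' @param config named list (see [readPipelineConfig()] for keys) or path to
#'   a config file. `fasta` is required.
#' @return the summary as a list, invisibly; files under `config$out_dir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && base::length(config) == 1L)
    config <- readPipelineConfig(config)
  cfg <- utils::modifyList(pipelineDefaults(), config)
  if (is.null(cfg$fasta)) stop("config must name a 'fasta' input")
  for (f in c("fasta", "annotations", "survey_tsv", "alignment_fasta")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("pipeline stage 'inputs' failed: missing ", f, " file: ", cfg[[f]])
  }
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(sprintf("%s=%s", names(cfg),
                             vapply(cfg, function(x)
                               paste(as.character(x), collapse = ","),
                               character(1))))

  seqs <- runStage("read_fasta", readGenomeFasta(cfg$fasta))
  genome <- seqs[[1]]
  ann <- if (!is.null(cfg$annotations))
    runStage("read_annotations",
             readAnnotations(cfg$annotations, format = cfg$annotation_format,
                             seq_length = base::length(genome))) else NULL

  profile <- runStage("skew_profile",
    windowedProfile(genome, window = cfg$window, step = cfg$step,
                    convention = cfg$convention))
  writeTrack(profile, file.path(cfg$out_dir, "skew.bedgraph"), "bedgraph")
  cum <- runStage("cumulative_skew",
                  cumulativeSkew(genome, convention = cfg$convention))
  pred <- runStage("predict_ori_ter", predictOriTer(cum, ann))

  if (isTRUE(cfg$rotate)) {
    rot <- runStage("rotate_to_origin",
                    rotateToOrigin(genome, ann, ori = pred@ori))
    if (is.list(rot)) { genome <- rot$sequence; ann <- rot$annotations }
    else genome <- rot
    writeGenomeFasta(genome, file.path(cfg$out_dir, "genome_rotated.fasta"))
  }

  summary <- list(
    config_hash = hash, package_version = as.character(
      utils::packageVersion("BacArch")),
    seed = cfg$seed, genome_id = seqID(genome),
    convention = cfg$convention,
    prediction = list(ori = pred@ori, ter = pred@ter, method = pred@method,
                      replichore_lengths = unname(pred@replichore_lengths),
                      dnaA_distance = pred@dnaA_distance,
                      dnaA_supported = pred@dnaA_supported))

  if (!is.null(ann)) {
    boxes <- tryCatch(
      runStage("dnaA_boxes",
               dnaABoxReport(genome, ann, consensus = cfg$dnaA_box_consensus,
                             upstream_cap = cfg$upstream_cap)),
      error = function(e) NULL)
    if (!is.null(boxes))
      summary$dnaA_boxes <- list(upstream = boxes$upstream,
                                 intergenic = boxes$intergenic)
    stats <- runStage("genome_stats",
                      genomeStats(genome, ann, operon_gap = cfg$operon_gap))
    compareStatsTable(stats, file.path(cfg$out_dir, "genome_stats.tsv"))
    operons <- groupRrnaOperons(ann, max_gap = cfg$operon_gap)
    summary$genome_stats <- as.list(stats)
    summary$rrna_density_per_mbp <-
      rrnDensity(base::length(operons), base::length(genome))
    sb <- tryCatch(strandBias(pred, ann), error = function(e) NULL)
    if (!is.null(sb))
      summary$strand_bias <- list(fractions = as.list(sb$fractions),
                                  pooled = sb$pooled_fraction,
                                  p_value = sb$binomial$p.value)

    cub_ref <- referenceGeneIds(ann, cfg$cub_reference_pattern)
    if (base::length(cub_ref) > 0) {
      cub <- runStage("codon_usage", {
        counts <- codonCountsFromAnnotation(genome, ann)
        w <- relativeAdaptiveness(counts[intersect(cub_ref, names(counts))])
        rankOptimized(counts, w, top_k = cfg$cub_top_k)
      })
      utils::write.table(cub$ranking,
                         file.path(cfg$out_dir, "cub_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$cub <- list(n_ranked = nrow(cub$ranking),
                          top_k = min(cfg$cub_top_k, nrow(cub$ranking)),
                          top_score = cub$ranking$score[1])
    }
  }

  if (!is.null(cfg$survey_tsv)) {
    sv <- runStage("rrna_survey",
      surveyRrnaDensity(readSurveyTable(cfg$survey_tsv),
                        threshold = cfg$survey_threshold,
                        top_k = cfg$survey_top_k))
    writeSurveyTable(sv, file.path(cfg$out_dir, "survey_ranked.tsv"))
    summary$survey <- list(n_ranked = nrow(sv$ranked),
                           top_density = if (nrow(sv$ranked))
                             sv$ranked$density[1] else NA)
  }

  if (!is.null(cfg$alignment_fasta)) {
    tree <- runStage("phylogeny", {
      aln <- readAlignedFasta(cfg$alignment_fasta)
      bootstrapSupport(aln, replicates = cfg$bootstrap_replicates,
                       seed = cfg$seed)
    })
    tree_path <- file.path(cfg$out_dir, "tree.nwk")
    writeNewick(tree, tree_path)
    summary$tree <- list(path = tree_path, n_taxa = base::length(tree$tip.label),
                         replicates_used = attr(tree, "replicates_used"))
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(summary)
}
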