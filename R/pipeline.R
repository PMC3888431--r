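#' Default thresholds of the consolidation workflow
#'
#' One place for every tunable the pipeline stages use; values are the
#' package defaults (mapping coverage 0.90, GT-AG canonical introns, locus
#' ORF fraction 0.75, CDS minimum 200 nt, containment dedup 0.90/95,
#' cluster k-mer 14 at shared fraction 0.30, assembly overlap 40 nt at 98,
#' merge coverage 0.95, classification coverages 0.90/0.90 with 1 percent
#' gaps at identity 90, u80 coverage 0.80, presence identity drop 5
#' points).
#'
#' @param ... Named overrides.
#' @return A named list of thresholds.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    minMappingCov = 0.90, canonicalPairs = "GT-AG", minOrfFraction = 0.75,
    minOrfNt = 200L, dedupeCov = 0.90, dedupeIdentityPct = 95,
    clusterK = 14L, clusterMinShared = 0.30,
    minOverlapNt = 40L, assembleIdentityPct = 98,
    mergeCov = 0.95, mergeIdentityPct = 90,
    refCov = 0.90, queryCov = 0.90, maxGapFraction = 0.01,
    classifyIdentityPct = 90, classifyMinMatches = 33L,
    u80Cov = 0.80, maxIdentityDropPoints = 5, presenceMinMatches = 16L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

.configString <- function(cfg) {
  paste(vapply(names(cfg), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1)),
    collapse = "; ")
}

.provenanceHeader <- function(seed, cfg) {
  c(sprintf("# TxConsolidate %s; seed=%s",
            as.character(utils::packageVersion("TxConsolidate")),
            if (is.null(seed)) "NA" else seed),
    paste0("# config: ", .configString(cfg)))
}

.writeTsv <- function(df, path, seed, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed, cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-tiered consolidation workflow
#'
#' End-to-end orchestration: reference-branch filtering
#' ([runRefPipeline()]), de novo consolidation ([runDenovoPipeline()]),
#' cross-branch merging ([mergeSets()]), clustering of the final set
#' ([clusterKmer()]), the cluster-vs-locus paralog table and, optionally,
#' evaluation against a reference proteome ([classifySet()], [u80Metric()]).
#'
#' @param refModels A [TranscriptModels-class] object (reference branch).
#' @param genome Named `DNAStringSet` or character vector of contigs.
#' @param denovo Named character vector / `DNAStringSet` (de novo branch).
#' @param proteins Optional named reference proteome for evaluation.
#' @param config A [pipelineConfig()] list.
#' @param outDir Optional directory; when given, the final FASTA, cluster
#'   TSV, per-stage report and evaluation tables are written there, each
#'   carrying a provenance header (package version, seed, config).
#' @param seed Seed recorded in reports (the workflow itself is
#'   deterministic).
#' @return A list: `final` (named character), `clusters`, `loci`,
#'   `paralogTable`, `report` (stage count table), `ref`, `denovo`,
#'   `merge`, and (with `proteins`) `classification` and `u80`.
#' @export
runPipeline <- function(refModels, genome, denovo, proteins = NULL,
                        config = pipelineConfig(), outDir = NULL,
                        seed = NULL) {
  ref <- runRefPipeline(refModels, genome, minCov = config$minMappingCov,
                        canonicalPairs = config$canonicalPairs,
                        minOrfFraction = config$minOrfFraction)
  refSeqs <- splicedSequence(ref$models, genome)
  dnv <- runDenovoPipeline(denovo, minOrfNt = config$minOrfNt,
                           dedupeCov = config$dedupeCov,
                           dedupeIdentityPct = config$dedupeIdentityPct,
                           clusterK = config$clusterK,
                           clusterMinShared = config$clusterMinShared,
                           minOverlapNt = config$minOverlapNt,
                           assembleIdentityPct = config$assembleIdentityPct)
  mrg <- mergeSets(refSeqs, dnv$transcripts,
                   denovoRemovalCov = config$mergeCov,
                   minIdentityPct = config$mergeIdentityPct)
  clusters <- clusterKmer(mrg$final, k = config$clusterK,
                          minSharedFraction = config$clusterMinShared)
  loci <- stats::setNames(rep(NA_character_, length(mrg$final)),
                          names(mrg$final))
  refLoci <- ref$loci[intersect(names(mrg$final), names(ref$loci))]
  loci[names(refLoci)] <- refLoci
  ptab <- paralogTable(clusters, loci)
  stageReport <- rbind(
    cbind(branch = "reference", ref$report),
    cbind(branch = "denovo", dnv$report),
    data.frame(branch = "merge", stage = "merge_sets",
               input = length(refSeqs) + length(dnv$transcripts),
               kept = length(mrg$final),
               removed = nrow(mrg$log), stringsAsFactors = FALSE))
  out <- list(final = mrg$final, clusters = clusters, loci = loci,
              paralogTable = ptab, report = stageReport, ref = ref,
              denovo = dnv, merge = mrg, config = config, seed = seed)
  if (!is.null(proteins)) {
    out$classification <- classifySet(
      mrg$final, proteins, minOrfNt = config$minOrfNt,
      refCov = config$refCov, queryCov = config$queryCov,
      maxGapFraction = config$maxGapFraction,
      minIdentityPct = config$classifyIdentityPct,
      minMatches = config$classifyMinMatches)
    out$u80 <- u80Metric(proteins, mrg$final, minCov = config$u80Cov)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(Biostrings::DNAStringSet(mrg$final),
               file.path(outDir, "final_transcripts.fasta"))
    asn <- attr(clusters, "assignment")
    .writeTsv(data.frame(clusterId = unname(asn), transcriptId = names(asn)),
              file.path(outDir, "clusters.tsv"), seed, config)
    .writeTsv(stageReport, file.path(outDir, "report.tsv"), seed, config)
    .writeTsv(as.data.frame.matrix(ptab),
              file.path(outDir, "paralog_table.tsv"), seed, config)
    if (!is.null(proteins)) {
      .writeTsv(out$classification$classes,
                file.path(outDir, "transcript_classes.tsv"), seed, config)
      .writeTsv(data.frame(proteinId = names(out$u80$gapClass),
                           gapClass = unname(out$u80$gapClass)),
                file.path(outDir, "u80_classes.tsv"), seed, config)
    }
  }
  out
}
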