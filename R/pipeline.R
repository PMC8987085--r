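#' Pipeline configuration
#'
#' All tunable parameters of the single-axis pipeline with their defaults:
#' correlation distance, 5% expression-fraction cutoff (1% suits deeply
#' sequenced class-enriched data), DE p-value cutoff 0.001 with a top-1000
#' set, Welch t-test contrast, median aggregation of expression fractions,
#' conservation window of 50 leaves, smoothing window of 21 leaves, 100
#' bootstrap resamples, and peak height/prominence thresholds of 0.05 on
#' the rescaled profile with 50-leaf separation and a 50-receptor
#' membership cap.
#'
#' @param metric distance metric for co-expression
#' @param fractionCutoff per-sample expressed-gene cutoff
#' @param minCells minimal target-class cells per usable sample
#' @param deAlpha,deTop,deScheme differential-expression parameters
#' @param fractionAggregator `"median"` or `"mean"` across samples
#' @param conservationWindow window (leaves) for cross-species conservation
#' @param smoothWindow moving-average window for the combination
#' @param nResamples bootstrap resamples N
#' @param peakMinHeight,peakMinProminence,peakMinSeparation,peakMaxMembers
#'   peak detection parameters
#' @param pseudoParts pseudo-samples created when fewer than five samples
#' @param maxFailFraction tolerated fraction of failing resamples
#' @return a named list with class `comberonConfig`
#' @export
comberonConfig <- function(metric = "correlation", fractionCutoff = 0.05,
                           minCells = 10L, deAlpha = 0.001, deTop = 1000L,
                           deScheme = "t_test",
                           fractionAggregator = "median",
                           conservationWindow = 50L, smoothWindow = 21L,
                           nResamples = 100L, peakMinHeight = 0.05,
                           peakMinProminence = 0.05,
                           peakMinSeparation = 50L, peakMaxMembers = 50L,
                           pseudoParts = 10L, maxFailFraction = 0.1) {
  cfg <- list(metric = metric, fractionCutoff = fractionCutoff,
              minCells = as.integer(minCells), deAlpha = deAlpha,
              deTop = as.integer(deTop), deScheme = deScheme,
              fractionAggregator = fractionAggregator,
              conservationWindow = as.integer(conservationWindow),
              smoothWindow = as.integer(smoothWindow),
              nResamples = as.integer(nResamples),
              peakMinHeight = peakMinHeight,
              peakMinProminence = peakMinProminence,
              peakMinSeparation = as.integer(peakMinSeparation),
              peakMaxMembers = as.integer(peakMaxMembers),
              pseudoParts = as.integer(pseudoParts),
              maxFailFraction = maxFailFraction)
  class(cfg) <- "comberonConfig"
  cfg
}

# heavy per-sample quantities, computed once and reused by every resample
.prepareAxis <- function(dataset, receptors, config, seed) {
  receptors <- toupper(receptors)
  k <- length(unique(unname(cellSamples(dataset))))
  if (k < 5L)
    dataset <- pseudoSplit(dataset, nParts = config$pseudoParts, seed = seed,
                           minCells = config$minCells)
  ids <- unique(unname(cellSamples(dataset)))
  dists <- list()
  for (s in ids) {
    sd <- sampleDistance(dataset, receptors, s, metric = config$metric,
                         fractionCutoff = config$fractionCutoff,
                         minCells = config$minCells)
    if (!is.null(sd)) dists[[s]] <- sd
  }
  if (length(dists) == 0L) stop("no usable samples")
  fracs <- .perSampleFractions(dataset, receptors, config$minCells)
  de <- .perSampleDE(dataset, alpha = config$deAlpha,
                     scheme = config$deScheme, minCells = config$minCells)
  list(dataset = dataset, receptors = receptors, dists = dists,
       fracs = fracs, de = de, samples = names(dists))
}

# one pipeline pass (original data or one bootstrap draw)
.runOne <- function(state, network, sampleIds, partnerDend, config) {
  agg <- aggregateMedian(state$dists[sampleIds], metric = config$metric)
  suppressWarnings(A <- receptorMatrix(agg))
  dend <- buildDendrogram(A)
  labels <- dend@order

  fracFull <- .aggregateFractions(state$fracs, state$receptors,
                                  config$fractionAggregator, sampleIds)
  frac <- new("MeasureTrack", name = "fraction",
              values = fracFull@values[labels], missing = character())
  names(frac@values) <- labels

  S <- .aggregateDE(state$de, top = config$deTop, sampleIds = sampleIds)
  enr <- networkEnrichment(network, S, labels)

  cons <- if (is.null(partnerDend)) {
    new("MeasureTrack", name = "conservation",
        values = stats::setNames(numeric(length(labels)), labels),
        missing = character())
  } else {
    evolutionaryConservation(dend, partnerDend,
                             window = config$conservationWindow)
  }

  profile <- combineMeasures(list(frac, enr, cons), labels,
                             window = config$smoothWindow)
  list(dend = dend, tracks = list(fraction = frac, enrichment = enr,
                                  conservation = cons),
       profile = profile,
       mainMembers = mainPeak(profile)@members,
       peakSet = allPeaks(profile, minHeight = config$peakMinHeight,
                          minProminence = config$peakMinProminence,
                          minSeparation = config$peakMinSeparation,
                          maxMembers = config$peakMaxMembers))
}

#' Run the full comberon-detection pipeline for one gene axis
#'
#' Computes per-sample co-expression distances over the target-class cells,
#' aggregates them with the median, orders the genes of interest along a
#' Ward dendrogram with optimal leaf ordering, scores expression fraction,
#' network enrichment and (when a partner species is given) evolutionary
#' conservation, combines and smooths the measures, detects peaks, and
#' quantifies main-peak membership over `nResamples` bootstrap resamples of
#' the samples. Within a resample, conservation is always computed against
#' the partner species' original (non-resampled) ordering.
#'
#' @param dataset a [ComberonDataset-class]
#' @param receptors genes of interest (e.g. all receptors)
#' @param network an [InteractionNetwork-class]
#' @param partner optional partner species: a [ComberonDataset-class]
#'   (already homolog-mapped, or supply `homologs`), or a pre-built
#'   [OrderedDendrogram-class]
#' @param homologs optional [HomologMap-class] applied to `partner`
#' @param config a [comberonConfig()] list
#' @param seed integer seed driving the resample plan
#' @return a [ComberonResult-class]
#' @export
runComberon <- function(dataset, receptors, network, partner = NULL,
                        homologs = NULL, config = comberonConfig(), seed = 1L) {
  receptors <- toupper(receptors)
  partnerDend <- NULL
  if (!is.null(partner)) {
    if (is(partner, "OrderedDendrogram")) {
      partnerDend <- partner
    } else {
      if (!is.null(homologs))
        partner <- applyHomologs(partner, homologs, dataset@species)
      pState <- .prepareAxis(partner, receptors, config, seed)
      pAgg <- aggregateMedian(pState$dists, metric = config$metric)
      suppressWarnings(pA <- receptorMatrix(pAgg))
      partnerDend <- buildDendrogram(pA)
    }
  } else {
    warning("no partner species: conservation track is zero", call. = FALSE)
  }

  state <- .prepareAxis(dataset, receptors, config, seed)
  original <- .runOne(state, network, state$samples, partnerDend, config)

  plan <- makeResamples(state$samples, N = config$nResamples, seed = seed)
  counts <- stats::setNames(integer(length(state$receptors)),
                            state$receptors)
  resampleOrders <- vector("list", length(plan@draws))
  resamplePeaks <- vector("list", length(plan@draws))
  failures <- character()
  for (c_i in seq_along(plan@draws)) {
    draw <- plan@draws[[c_i]]
    res <- tryCatch(.runOne(state, network, draw, partnerDend, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    mem <- intersect(res$mainMembers, names(counts))
    counts[mem] <- counts[mem] + 1L
    resampleOrders[[c_i]] <- res$dend@order
    resamplePeaks[[c_i]] <- res$peakSet
  }
  if (length(failures) > config$maxFailFraction * length(plan@draws))
    stop(length(failures), " of ", length(plan@draws),
         " resamples failed; first error: ", failures[1])
  if (length(failures))
    warning(length(failures), " resample(s) failed and were skipped",
            call. = FALSE)
  freq <- new("BootstrapFrequencies",
              freq = counts / length(plan@draws),
              N = as.integer(length(plan@draws)))
  new("ComberonResult", dendrogram = original$dend,
      tracks = original$tracks, profile = original$profile,
      peaks = original$peakSet, frequencies = freq,
      resampleOrders = Filter(Negate(is.null), resampleOrders),
      resamplePeaks = Filter(Negate(is.null), resamplePeaks),
      plan = plan, config = unclass(config))
}

#' Bootstrap frequencies of main-peak inclusion
#'
#' Convenience wrapper returning only the [BootstrapFrequencies-class] of a
#' full [runComberon()] run.
#'
#' @inheritParams runComberon
#' @return a [BootstrapFrequencies-class]
#' @export
bootstrapFrequencies <- function(dataset, receptors, network, partner = NULL,
                                 homologs = NULL, config = comberonConfig(),
                                 seed = 1L) {
  runComberon(dataset, receptors, network, partner = partner,
              homologs = homologs, config = config, seed = seed)@frequencies
}

#' Write the analysis bundle of a pipeline run
#'
#' Writes, under `dir`: `frequencies.tsv`, `peaks.json`,
#' `measure_<name>.tsv` for the three tracks, `combination.tsv`,
#' `config.json`, a `report.json` with the statistical tests against a
#' known-gene list (hypergeometric enrichment of the main peak and of the
#' frequency-0.5 set, and the likelihood-ratio distance test anchored at
#' each of up to two top known genes), and a `comberon.png` overview figure.
#'
#' @param result a [ComberonResult-class]
#' @param dir output directory (created if needed)
#' @param known known genes for the validation tests (default: the packaged
#'   angiogenesis receptors); set `NULL` to skip the report
#' @return invisibly, the directory
#' @export
writeComberonBundle <- function(result, dir,
                                known = knownAngiogenesisReceptors()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freq <- sort(result@frequencies@freq, decreasing = TRUE)
  utils::write.table(data.frame(receptor = names(freq),
                                frequency = unname(freq)),
                     file.path(dir, "frequencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .peakJSON <- function(p) list(apex = p@apex, height = p@height,
                                prominence = p@prominence,
                                members = p@members)
  jsonlite::write_json(
    list(main = .peakJSON(result@peaks@main),
         secondary = lapply(result@peaks@secondary, .peakJSON)),
    file.path(dir, "peaks.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result@tracks))
    writeMeasureTrack(result@tracks[[nm]],
                      file.path(dir, paste0("measure_", nm, ".tsv")),
                      order = result@dendrogram@order)
  utils::write.table(data.frame(receptor = result@profile@order,
                                combination = result@profile@combo),
                     file.path(dir, "combination.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(known)) {
    rep <- comberonReport(result, known)
    jsonlite::write_json(rep, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  grDevices::png(file.path(dir, "comberon.png"), width = 1200, height = 900)
  plotComberon(result, known = if (is.null(known)) character() else known)
  grDevices::dev.off()
  invisible(dir)
}

#' Statistical report for a pipeline run
#'
#' Computes, against a known-gene list: the hypergeometric upper tail of the
#' known-gene overlap with (a) the main-peak members and (b) the receptors
#' with bootstrap frequency above 0.5, over the universe of receptors in
#' the dendrogram, plus likelihood-ratio dendrogram-distance tests anchored
#' at the two known genes with the highest bootstrap frequency.
#'
#' @param result a [ComberonResult-class]
#' @param known character vector of known genes
#' @return a nested list of inputs, statistics and p values
#' @export
comberonReport <- function(result, known = knownAngiogenesisReceptors()) {
  known <- toupper(known)
  universe <- result@dendrogram@order
  knownIn <- intersect(known, universe)
  main <- result@peaks@main@members
  freq <- result@frequencies@freq
  hi <- names(freq)[freq > 0.5]
  mk <- function(set) {
    k <- length(intersect(set, knownIn))
    list(setSize = length(set), knownInUniverse = length(knownIn),
         overlap = k,
         p = hypergeomTail(length(universe), length(knownIn),
                           length(intersect(set, universe)), k))
  }
  anchors <- intersect(names(sort(freq[knownIn], decreasing = TRUE)),
                       universe)
  lr <- list()
  for (a in utils::head(anchors, 2L)) {
    t <- tryCatch(lrDistanceTest(result@dendrogram, a, known),
                  error = function(e) NULL)
    if (!is.null(t)) lr[[a]] <- t
  }
  list(universe = length(universe),
       mainPeak = mk(main),
       frequencyAbove0.5 = mk(hi),
       lrDistance = lr)
}
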