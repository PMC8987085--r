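#' Combine the three measures along the dendrogram
#'
#' Each track is aligned to the leaf order (missing receptors contribute 0),
#' scaled so that its values sum to one (an all-zero track stays zero),
#' smoothed with a centered uniform moving average of `window` receptors
#' (truncated and renormalized at the edges), summed, and the sum smoothed
#' once more with the same kernel, giving the combination score per leaf.
#'
#' @param tracks list of three [MeasureTrack-class] objects (fraction,
#'   enrichment, conservation, in any order)
#' @param order leaf order (character) to align to
#' @param window smoothing window (default 21)
#' @return a [CombinationProfile-class]
#' @export
combineMeasures <- function(tracks, order, window = 21L) {
  stopifnot(length(tracks) == 3L)
  names(tracks) <- vapply(tracks, function(t) t@name, character(1))
  comp <- lapply(tracks, function(t) {
    v <- t@values[order]
    v[is.na(v)] <- 0
    movingAverage(.normalizeSum(unname(v)), window)
  })
  combo <- movingAverage(comp[[1]] + comp[[2]] + comp[[3]], window)
  new("CombinationProfile", order = order, combo = combo,
      components = comp, window = as.integer(window))
}

#' Main peak of a combination profile
#'
#' The apex is the (leftmost, on ties) argmax of the combination score; the
#' members are the receptors of the maximal contiguous run around the apex
#' whose score is at least half the apex score ("immediate proximity" of
#' the main peak).
#'
#' @param profile a [CombinationProfile-class]
#' @return a [Peak-class]
#' @export
mainPeak <- function(profile) {
  s <- profile@combo
  if (all(s == 0)) stop("combination profile is identically zero")
  apex <- which.max(s)
  run <- .halfHeightRun(s, apex)
  rescaled <- minMaxScale(s)
  new("Peak", apex = as.integer(apex), height = s[apex],
      prominence = .prominence(rescaled, apex),
      members = profile@order[run])
}

# maximal contiguous run around apex with s >= 0.5 * s[apex]
.halfHeightRun <- function(s, apex) {
  thr <- 0.5 * s[apex]
  lo <- apex; hi <- apex
  while (lo > 1L && s[lo - 1L] >= thr) lo <- lo - 1L
  while (hi < length(s) && s[hi + 1L] >= thr) hi <- hi + 1L
  seq.int(lo, hi)
}

# prominence of the peak at `apex`: vertical distance to the lowest contour
# line encircling it without enclosing a higher peak; computed as
# s[apex] - max(left base, right base), each base being the minimum between
# the apex and the nearest strictly higher point (or the signal end)
.prominence <- function(s, apex) {
  n <- length(s)
  leftBase <- if (apex == 1L) s[1L] else {
    higher <- which(s[seq_len(apex - 1L)] > s[apex])
    from <- if (length(higher)) max(higher) + 1L else 1L
    min(s[from:apex])
  }
  rightBase <- if (apex == n) s[n] else {
    upper <- seq.int(apex + 1L, n)
    higher <- upper[s[upper] > s[apex]]
    to <- if (length(higher)) min(higher) - 1L else n
    min(s[apex:to])
  }
  s[apex] - max(leftBase, rightBase)
}

# local maxima positions (left edge of plateaus; signal ends included when
# they dominate their inner neighbor)
.localMaxima <- function(s) {
  n <- length(s)
  if (n == 1L) return(1L)
  out <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    leftOK <- i == 1L || s[i - 1L] < s[i]
    rightOK <- j == n || s[j + 1L] < s[i]
    if (leftOK && rightOK) out <- c(out, i)
    i <- j + 1L
  }
  out
}

#' All peaks of a combination profile
#'
#' Finds every local maximum of the min-max rescaled combination score whose
#' rescaled height and prominence both exceed `minHeight` and
#' `minProminence`, keeps peaks at least `minSeparation` leaves apart
#' (preferring the higher peak), and assigns to each peak the receptors of
#' its half-height run truncated to the `maxMembers` positions nearest the
#' apex. The global maximum is always retained as the main peak. Height and
#' prominence thresholds act on the rescaled profile because the raw scores
#' scale as 1/m.
#'
#' @param profile a [CombinationProfile-class]
#' @param minHeight,minProminence thresholds on the rescaled profile
#'   (default 0.05, strict)
#' @param minSeparation minimal apex distance in leaves (default 50)
#' @param maxMembers membership cap per peak (default 50)
#' @return a [PeakSet-class]
#' @export
allPeaks <- function(profile, minHeight = 0.05, minProminence = 0.05,
                     minSeparation = 50L, maxMembers = 50L) {
  s <- profile@combo
  if (all(s == 0)) stop("combination profile is identically zero")
  r <- minMaxScale(s)
  cand <- .localMaxima(r)
  apex0 <- which.max(s)
  keepHP <- vapply(cand, function(p) {
    p == apex0 || (r[p] > minHeight && .prominence(r, p) > minProminence)
  }, logical(1))
  cand <- cand[keepHP]
  cand <- cand[order(-s[cand], cand)]
  accepted <- integer()
  for (p in cand) {
    if (all(abs(accepted - p) >= minSeparation)) accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  mk <- function(p) {
    run <- .halfHeightRun(s, p)
    if (length(run) > maxMembers)
      run <- run[order(abs(run - p), run)][seq_len(maxMembers)] |> sort()
    new("Peak", apex = as.integer(p), height = s[p],
        prominence = .prominence(r, p), members = profile@order[run])
  }
  peaks <- lapply(accepted, mk)
  mainIdx <- which(accepted == apex0)
  new("PeakSet", main = peaks[[mainIdx]], secondary = peaks[-mainIdx])
}

#' Group peaks across bootstrap resamples
#'
#' Builds the binary receptor-by-peak membership matrix over all peaks
#' (main and secondary) from a list of per-resample [PeakSet-class]s,
#' clusters both axes with Ward linkage on Euclidean distances of the
#' binary profiles, cuts each side into `nGroups` groups (fewer if fewer
#' items), and reports every receptor-group x peak-group block whose
#' membership density is at least `minDensity`, with the number of peaks,
#' the block density, the mean peak height, and the mean per-receptor
#' frequency of inclusion in the block's peaks (relative to the number of
#' resamples).
#'
#' @param peakSets list of [PeakSet-class], one per resample
#' @param nGroups groups per axis (default 15)
#' @param minDensity block density cutoff (default 0.5)
#' @return a data frame, one row per retained block, with a `receptors`
#'   list-column
#' @export
groupPeaks <- function(peakSets, nGroups = 15L, minDensity = 0.5) {
  if (length(peakSets) < 2L) stop("need at least two resamples")
  peaks <- list(); heights <- numeric(); resample <- integer()
  for (i in seq_along(peakSets)) {
    ps <- peakSets[[i]]
    for (pk in c(list(ps@main), ps@secondary)) {
      peaks[[length(peaks) + 1L]] <- pk@members
      heights <- c(heights, pk@height)
      resample <- c(resample, i)
    }
  }
  receptors <- sort(unique(unlist(peaks)))
  B <- matrix(0L, length(receptors), length(peaks),
              dimnames = list(receptors, NULL))
  for (q in seq_along(peaks)) B[peaks[[q]], q] <- 1L
  gR <- .wardGroups(B, nGroups)
  gP <- .wardGroups(t(B), nGroups)
  out <- list()
  for (a in sort(unique(gR))) for (b in sort(unique(gP))) {
    rows <- which(gR == a); cols <- which(gP == b)
    dens <- mean(B[rows, cols, drop = FALSE])
    if (dens >= minDensity) {
      out[[length(out) + 1L]] <- data.frame(
        receptorGroup = a, peakGroup = b,
        nReceptors = length(rows), nPeaks = length(cols),
        density = dens,
        meanHeight = mean(heights[cols]),
        meanFrequency = mean(rowSums(B[rows, cols, drop = FALSE])) /
          length(peakSets))
      out[[length(out)]]$receptors <- I(list(receptors[rows]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(receptorGroup = integer(), peakGroup = integer(),
                      nReceptors = integer(), nPeaks = integer(),
                      density = numeric(), meanHeight = numeric(),
                      meanFrequency = numeric()))
  do.call(rbind, out)
}

.wardGroups <- function(X, nGroups) {
  n <- nrow(X)
  if (n == 1L) return(stats::setNames(1L, rownames(X)))
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  # never split beyond the number of distinct profiles (identical peaks
  # across resamples belong to one group)
  nDistinct <- nrow(unique(X))
  stats::cutree(hc, k = min(nGroups, nDistinct))
}
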