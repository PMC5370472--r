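# Segmentation accuracy metrics and the statistics used to compare
# registration variants: Dice overlap, one-directional surface distances
# in mm, the paired two-sided Wilcoxon signed-rank test, and Cohen's d.

#' Dice similarity coefficient for one label
#'
#' \code{DSC = 2 |Vseg intersect Vgd| / (|Vseg| + |Vgd|)}; 1 is perfect
#' agreement, 0 is no overlap. If the label is empty in both maps the
#' coefficient is defined as 1 with a warning (degenerate agreement).
#'
#' @param seg,gold LabelMaps on the same grid.
#' @param label integer label value.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(seg, gold, label) {
  if (!identical(dim(seg@voxels), dim(gold@voxels)))
    stop("segmentation and gold standard must share a grid")
  a <- seg@voxels == label
  b <- gold@voxels == label
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("label ", label, " empty in both maps; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' One-directional surface distances for one label
#'
#' Surface voxels are labelled voxels with at least one unlabelled
#' face-neighbour (6-connectivity). For every surface voxel of \code{seg},
#' the shortest Euclidean distance (mm, honouring anisotropic spacing) to
#' the gold-standard surface point set is computed; the mean and maximum of
#' these one-directional distances are returned. Set \code{symmetric =
#' TRUE} to average with the gold-to-seg direction.
#'
#' @param seg,gold LabelMaps on the same grid.
#' @param label integer label, non-empty in both maps.
#' @param symmetric average both directions (off by default; the
#'   one-directional seg-to-gold form is the reported convention).
#' @return list with \code{mean}, \code{max} (mm) and \code{distances}
#'   (per-surface-point, seg to gold).
#' @export
surfaceDistances <- function(seg, gold, label, symmetric = FALSE) {
  if (!identical(dim(seg@voxels), dim(gold@voxels)))
    stop("segmentation and gold standard must share a grid")
  ptsS <- .surfacePoints(seg, label)
  ptsG <- .surfacePoints(gold, label)
  if (nrow(ptsS) == 0 || nrow(ptsG) == 0)
    stop("label ", label, " is empty in one of the maps")
  d <- .minDistances(ptsS, ptsG)
  if (symmetric) {
    d2 <- .minDistances(ptsG, ptsS)
    return(list(mean = (mean(d) + mean(d2)) / 2, max = max(d, d2),
                distances = d))
  }
  list(mean = mean(d), max = max(d), distances = d)
}

# world coordinates (mm) of the 6-connectivity surface voxels of a label
.surfacePoints <- function(lm, label) {
  m <- .surfaceMask(lm@voxels, value = label)
  ix <- which(m, arr.ind = TRUE)
  if (nrow(ix) == 0) return(matrix(numeric(0), 0, 3))
  indexToWorld(lm, ix - 1)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' For n <= 25 non-zero differences the exact sign-flip null distribution
#' of the positive-rank sum is enumerated (with midranks under tied
#' magnitudes, via a dynamic program over the 2^n sign assignments);
#' larger samples use the normal approximation with tie correction and
#' continuity correction. Zero differences are dropped, as in the
#' standard signed-rank procedure; p < 0.05 is conventionally flagged
#' significant.
#'
#' @param a,b equal-length numeric vectors (n >= 5), paired.
#' @param alternative "two.sided" (default), "greater" (b > a) or "less".
#' @return the p-value.
#' @export
wilcoxonPaired <- function(a, b, alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- b - a
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero; the test is degenerate")
  n <- length(d)
  r <- rank(abs(d))                       # midranks under ties
  wObs <- sum(r[d > 0])
  if (n <= 25) {
    # counts of each achievable doubled rank sum over all sign flips
    ints <- as.integer(round(2 * r))
    total <- sum(ints)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in ints) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * wObs))
    pGe <- sum(f[(w2 + 1):(total + 1)])
    pLe <- sum(f[1:(w2 + 1)])
    switch(alternative,
           two.sided = min(1, 2 * min(pGe, pLe)),
           greater = pGe,
           less = pLe)
  } else {
    suppressWarnings(
      stats::wilcox.test(b, a, paired = TRUE, alternative = alternative,
                         exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' \code{d = (mean(b) - mean(a)) / s_pooled} with the pooled SD using
#' n - 1 denominators; the sign is positive when \code{b} exceeds
#' \code{a} (current method minus previous method in method-comparison
#' tables).
#'
#' @param a,b numeric vectors of length >= 2.
#' @return the effect size.
#' @export
cohensD <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
         (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation; effect undefined")
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Per-structure evaluation report
#'
#' Dice and surface-distance summaries for every non-background label of
#' the gold standard, in the layout of a method-comparison table: one row
#' per label with the voxel counts, DSC and the mean/max one-directional
#' surface distance in mm. The whole-heart mean surface distance is
#' reported both as the mean of per-structure means and pooled over all
#' surface points (the two common conventions).
#'
#' @param seg,gold LabelMaps on one grid.
#' @return list with \code{perLabel} (data.frame: label, name, dsc,
#'   meanSurfDist, maxSurfDist, nSeg, nGold) and \code{wholeHeart} (list:
#'   meanOfMeans, pooledMean, mm).
#' @export
evaluateSegmentation <- function(seg, gold) {
  labs <- sort(setdiff(unique(as.integer(gold@voxels)), 0L))
  rows <- lapply(labs, function(l) {
    dsc <- diceCoefficient(seg, gold, l)
    sd <- tryCatch(surfaceDistances(seg, gold, l),
                   error = function(e) list(mean = NA_real_,
                                            max = NA_real_,
                                            distances = numeric(0)))
    data.frame(label = l,
               name = ifelse(as.character(l) %in% names(gold@legend),
                             gold@legend[[as.character(l)]], ""),
               dsc = dsc, meanSurfDist = sd$mean, maxSurfDist = sd$max,
               nSeg = sum(seg@voxels == l), nGold = sum(gold@voxels == l))
  })
  per <- do.call(rbind, rows)
  allD <- unlist(lapply(labs, function(l)
    tryCatch(surfaceDistances(seg, gold, l)$distances,
             error = function(e) numeric(0))))
  list(perLabel = per,
       wholeHeart = list(meanOfMeans = mean(per$meanSurfDist, na.rm = TRUE),
                         pooledMean = if (length(allD)) mean(allD)
                                      else NA_real_))
}
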