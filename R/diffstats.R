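# Effect sizes and hypothesis testing between groups of statistical units
# (pixels-in-region for the 2D workflow, 3D voxel objects for the 3D
# workflow): Cohen's d marker concordance, Welch/Student t-tests with
# Benjamini-Hochberg correction, and volcano tables.

#' Cohen's d effect size per feature
#'
#' d = (meanA - meanB) / pooled sd, with the pooled sd computed from n-1
#' sample variances. When the pooled sd is zero, d is 0 for equal means
#' and +/-Inf otherwise (flagged with a warning).
#'
#' @param groupA,groupB matrices (units x features) or numeric vectors.
#' @return numeric vector of d values (one per feature).
#' @export
cohensD <- function(groupA, groupB) {
  if (!is.matrix(groupA)) groupA <- matrix(groupA, ncol = 1)
  if (!is.matrix(groupB)) groupB <- matrix(groupB, ncol = 1)
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 units")
  mA <- colMeans(groupA); mB <- colMeans(groupB)
  vA <- apply(groupA, 2, var); vB <- apply(groupB, 2, var)
  pooled <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2))
  d <- (mA - mB) / pooled
  degenerate <- pooled == 0
  if (any(degenerate)) {
    d[degenerate] <- ifelse(mA[degenerate] == mB[degenerate], 0,
                            sign(mA[degenerate] - mB[degenerate]) * Inf)
    if (any(is.infinite(d)))
      warning(sum(is.infinite(d)),
              " feature(s) have zero pooled sd with unequal means (d = +/-Inf)")
  }
  d
}

#' Marker concordance between two Cohen's-d comparisons
#'
#' A feature is a concordant marker when both comparisons (e.g. cancer vs
#' fibroblast within a biculture, and between monocultures) show a strong
#' effect of the same sign. Concordant features split by sign into the
#' per-cell-type candidate sets.
#'
#' @param effectsA,effectsB Cohen's d vectors on the same feature axis.
#' @param mz the feature m/z values.
#' @param dThreshold minimum |d| in both comparisons (default 0.8, a
#'   conventional "large" effect).
#' @return data.frame with d values, concordance flag, and the sign-based
#'   candidate set ("positive" = higher in group A of both comparisons).
#' @export
markerConcordance <- function(effectsA, effectsB, mz,
                              dThreshold = 0.8) {
  stopifnot(length(effectsA) == length(effectsB),
            length(mz) == length(effectsA))
  conc <- abs(effectsA) >= dThreshold & abs(effectsB) >= dThreshold &
    sign(effectsA) == sign(effectsB)
  set <- ifelse(!conc, NA_character_,
                ifelse(effectsA > 0, "positive", "negative"))
  data.frame(mz = mz, d_comparison1 = effectsA, d_comparison2 = effectsB,
             concordant = conc, candidate_set = set)
}

# vectorized two-sided t-tests over the columns of two matrices
.tTestCols <- function(A, B, welch = TRUE) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, var); vB <- apply(B, 2, var)
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- nA + nB - 2
  }
  tstat <- (mA - mB) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  flat <- se2 == 0
  p[flat] <- 1          # zero variance in both groups: untestable, flagged
  tstat[flat] <- 0
  list(t = tstat, df = df, p = p, flat = flat)
}

#' Differential test between two groups of object profiles
#'
#' Per feature: a two-sided t-test (Welch by default) on per-object mean
#' intensities, Benjamini-Hochberg adjustment across all tested features,
#' and the log2 fold change of group means guarded by a small additive
#' offset. A feature is significant when \code{p_adj < alpha} and
#' \code{|log2_fc| > lfcThreshold}.
#'
#' @param profilesA,profilesB matrices (objects x features) of per-object
#'   mean intensities, columns aligned; group A is the fold-change
#'   numerator.
#' @param mz feature m/z values (defaults to profile column names).
#' @param alpha significance level on the adjusted p-value (0.01 for the
#'   spheroid workflow, 0.05 for organoids).
#' @param lfcThreshold minimum |log2 fold change| (1 for spheroids, 1.75
#'   for organoids).
#' @param test "welch" (unequal variances, default) or "student".
#' @param epsilon additive offset guarding zero means; defaults to the
#'   smallest positive group mean times 1e-3.
#' @return data.frame (class \code{"DifferentialResult"}): mz, log2_fc,
#'   t, df, p_value, p_adj, significant, flat.
#' @export
differentialTest <- function(profilesA, profilesB, mz = NULL, alpha = 0.01,
                             lfcThreshold = 1, test = c("welch", "student"),
                             epsilon = NULL) {
  test <- match.arg(test)
  if (is.null(dim(profilesA))) profilesA <- matrix(profilesA, nrow = 1)
  if (is.null(dim(profilesB))) profilesB <- matrix(profilesB, nrow = 1)
  stopifnot(ncol(profilesA) == ncol(profilesB))
  if (nrow(profilesA) < 2 || nrow(profilesB) < 2)
    stop("each group needs at least 2 objects")
  if (is.null(mz)) {
    mz <- suppressWarnings(as.numeric(colnames(profilesA)))
    if (!length(mz) || any(is.na(mz))) mz <- seq_len(ncol(profilesA))
  }
  mA <- colMeans(profilesA); mB <- colMeans(profilesB)
  if (is.null(epsilon)) {
    pos <- c(mA[mA > 0], mB[mB > 0])
    epsilon <- if (length(pos)) min(pos) * 1e-3 else 1e-9
  }
  lfc <- log2((mA + epsilon) / (mB + epsilon))
  tt <- .tTestCols(profilesA, profilesB, welch = test == "welch")
  padj <- p.adjust(tt$p, method = "BH")
  res <- data.frame(mz = mz, log2_fc = lfc, t = tt$t, df = tt$df,
                    p_value = tt$p, p_adj = padj,
                    significant = padj < alpha & abs(lfc) > lfcThreshold,
                    flat = tt$flat, row.names = NULL)
  attr(res, "alpha") <- alpha
  attr(res, "lfcThreshold") <- lfcThreshold
  attr(res, "test") <- test
  attr(res, "epsilon") <- epsilon
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

#' Volcano table: sorted differential results and the selected features
#'
#' @param result a \code{DifferentialResult} from
#'   \code{\link{differentialTest}}.
#' @return the table (mz, log2_fc, p_value, p_adj, significant) sorted by
#'   adjusted p-value; the significant m/z values are in attribute
#'   \code{"selected"} and via \code{\link{selectedFeatures}}.
#' @export
volcanoTable <- function(result) {
  tab <- result[order(result$p_adj, result$p_value),
                c("mz", "log2_fc", "p_value", "p_adj", "significant")]
  rownames(tab) <- NULL
  attr(tab, "selected") <- tab$mz[tab$significant]
  tab
}

#' Significant features of a differential result
#'
#' @param result a \code{DifferentialResult} or volcano table.
#' @return m/z values passing both significance thresholds.
#' @export
selectedFeatures <- function(result) {
  result$mz[result$significant]
}
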