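# Shared fixtures: a reduced phantom keeps unit tests fast; the full-scale
# study conditions are exercised in the acceptance tests.

smallPhantomSpec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, spheroidRadiusUm = 160, nClusters = 4L,
         clusterRadiusRangeUm = c(25, 60), marginPx = 8L),
    list(...))
  do.call(phantomSpec, args)
}

# cache one default small phantom per session
.phantomCache <- new.env(parent = emptyenv())
cachedPhantom <- function(key = "default", spec = smallPhantomSpec()) {
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- generatePhantom(spec)
  .phantomCache[[key]]
}

# adjusted Rand index, used to compare clusterings against truth
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sumI * sumJ / n
  (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}

# brute-force step-up BH construction, independent of stats::p.adjust
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force AUC by pair counting (concordant + half ties)
aucOracle <- function(a, b) {
  s <- 0
  for (x in a) for (y in b)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# brute-force exposed-face count for one labeled object
surfaceOracle <- function(mask, voxelUm) {
  d <- dim(mask)
  area <- 0
  face <- c(voxelUm[2] * voxelUm[3], voxelUm[1] * voxelUm[3],
            voxelUm[1] * voxelUm[2])
  for (i in which(mask)) {
    co <- arrayInd(i, d)
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      nb <- co
      nb[ax] <- nb[ax] + dir
      outside <- nb[ax] < 1 || nb[ax] > d[ax]
      if (outside || !mask[nb[1], nb[2], nb[3]])
        area <- area + face[ax]
    }
  }
  area
}
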