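# internal helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# V1/V2/V3 size classes; boundary convention: V1 < lower, lower <= V2 <= upper,
# V3 > upper (the inclusive reading of the prose thresholds)
.sizeClassOf <- function(counts, lower = 10, upper = 100) {
  if (lower >= upper) stop("size-class bounds must satisfy lower < upper")
  ifelse(counts < lower, "V1", ifelse(counts <= upper, "V2", "V3"))
}

# neighbor offsets (dz, dy, dx) for a given 3D connectivity
.neighborOffsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  l1 <- rowSums(abs(g))
  keep <- l1 > 0 & switch(as.character(connectivity),
                          "6" = l1 <= 1, "18" = l1 <= 2, "26" = TRUE)
  g[keep, , drop = FALSE]
}
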