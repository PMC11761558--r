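# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round-half-up to `digits` decimals; used only at the I/O layer so internal
# arithmetic keeps full precision.
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Squared distances from points (n x 2) to a segment a-b.
pointSegmentDist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  t <- (sweep(pts, 2, a) %*% ab) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2])
  sqrt(rowSums((pts - proj)^2))
}

# Minimum distance from each point to the closed polyline through `verts`
# (m x 2, closed: last edge joins row m back to row 1).
pointPolygonDist <- function(pts, verts) {
  m <- nrow(verts)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    d <- pmin(d, pointSegmentDist(pts, verts[i, ], verts[j, ]))
  }
  d
}
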