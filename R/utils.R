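# All unordered atom pairs (i < j) with Euclidean distance <= cutoff.
# dist() keeps this exact and vectorised; fixture-scale structures are
# well within its memory envelope.
.pairs_within <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  dv <- stats::dist(xyz)
  hit <- which(dv <= cutoff)
  if (!length(hit)) {
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  }
  ij <- .dist_index_to_pair(hit, n)
  data.frame(i = ij$i, j = ij$j, d = as.numeric(dv[hit]))
}

# Convert linear indices of a dist object (lower triangle, column major)
# into (row, col) pairs with col < row, returned as i < j.
.dist_index_to_pair <- function(k, n) {
  # column c occupies indices (c-1)*n - c*(c-1)/2 + (1 .. n-c)
  ends <- cumsum((n - 1):1)
  col <- findInterval(k - 1, c(0, ends), rightmost.closed = FALSE)
  start <- c(0, ends)[col]
  row <- col + (k - start)
  list(i = pmin(col, row), j = pmax(col, row))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Angle in degrees between two 3-vectors.
.angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("degenerate zero-length vector in angle")
  acos(.clamp(sum(v1 * v2) / (n1 * n2), -1, 1)) * 180 / pi
}

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D
# angle (degrees) and the A-B-C-D torsion (degrees). Standard internal-
# coordinate (NeRF) construction.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- cbind(bc, c(nrm[2] * bc[3] - nrm[3] * bc[2],
                   nrm[3] * bc[1] - nrm[1] * bc[3],
                   nrm[1] * bc[2] - nrm[2] * bc[1]), nrm)
  as.numeric(c + m %*% d2)
}
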