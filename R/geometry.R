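# Small 3D geometry kernel shared by perception and detection.
# All coordinates are in Angstrom, all angles in degrees.

# Inclusive-threshold epsilon: distances constructed analytically at a cutoff
# (e.g. exactly 3.20 A) must pass a "<=" test despite floating-point round-off.
# Far below PDB coordinate precision (1e-3 A).
.EPS <- 1e-9

vnorm <- function(v) sqrt(sum(v * v))

#' Angle between two vectors
#'
#' @param u,v numeric 3-vectors (need not be unit length).
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
vec_angle <- function(u, v) {
  cu <- u / vnorm(u)
  cv <- v / vnorm(v)
  d <- sum(cu * cv)
  d <- max(-1, min(1, d))
  acos(d) * 180 / pi
}

# Angle A-B-C at vertex B, degrees.
angle3 <- function(a, b, c) vec_angle(a - b, c - b)

# Pairwise Euclidean distances between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Neighbor pairs within a cutoff via a uniform cell grid
#'
#' Cell-list neighbor search: atoms are binned into cubic cells of edge
#' `cutoff` and only the 27 surrounding cells are scanned per query atom.
#' Used by all detectors; the test suite checks it against a plain
#' all-pairs scan.
#'
#' @param a,b coordinate matrices (n x 3, m x 3).
#' @param cutoff maximum distance in Angstrom (inclusive).
#' @return data.frame with columns `i` (row of `a`), `j` (row of `b`),
#'   `d` (distance, A), possibly empty.
#' @keywords internal
neighbor_pairs <- function(a, b, cutoff) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  empty <- data.frame(i = integer(), j = integer(), d = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  h <- max(cutoff, 1e-6)
  org <- pmin(apply(a, 2, min), apply(b, 2, min))
  cell_of <- function(x) floor(sweep(x, 2, org) / h)
  key_of <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3], sep = ",")
  cb <- cell_of(b)
  bmap <- split(seq_len(nrow(b)), key_of(cb))
  ca <- cell_of(a)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (ii in seq_len(nrow(a))) {
    cand <- integer(0)
    for (k in seq_len(27L)) {
      key <- paste(ca[ii, 1] + off[k, 1], ca[ii, 2] + off[k, 2],
                   ca[ii, 3] + off[k, 3], sep = ",")
      hit <- bmap[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    dv <- sweep(b[cand, , drop = FALSE], 2, a[ii, ])
    dd <- sqrt(rowSums(dv^2))
    keep <- dd <= cutoff + .EPS
    if (any(keep)) {
      out_i <- c(out_i, rep.int(ii, sum(keep)))
      out_j <- c(out_j, cand[keep])
      out_d <- c(out_d, dd[keep])
    }
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}

#' Centroid, unit normal and planarity of a ring of atoms
#'
#' The normal is the least-squares plane normal (smallest principal axis of
#' the centered coordinates); its sign is arbitrary and downstream angle
#' conventions are unsigned. Planarity is the RMS out-of-plane deviation.
#'
#' @param xyz (k x 3) matrix of ring member coordinates, k >= 3.
#' @return list with `centroid`, `normal` (unit), `rms_dev` (A).
#' @keywords internal
ring_plane <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  cen <- colMeans(xyz)
  m <- sweep(xyz, 2, cen)
  sv <- svd(m)
  n <- sv$v[, 3]
  n <- n / vnorm(n)
  dev <- as.numeric(m %*% n)
  list(centroid = cen, normal = n, rms_dev = sqrt(mean(dev^2)))
}

# Unsigned angle between two plane normals, folded to [0, 90] degrees.
interplanar_angle <- function(n1, n2) {
  th <- vec_angle(n1, n2)
  if (th > 90) th <- 180 - th
  th
}

# Least-squares rigid-body fit guard: centered coordinates of the fit atoms
# must span at least a plane, otherwise the optimal rotation is degenerate.
assert_fittable <- function(xyz, what = "alignment") {
  xyz <- matrix(xyz, ncol = 3)
  if (nrow(xyz) < 3)
    stop(what, " requires at least 3 atoms, got ", nrow(xyz))
  m <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(m)$d
  if (s[2] < 1e-8 * max(s[1], 1))
    stop(what, " atoms are (near-)collinear; rigid fit is degenerate")
  invisible(TRUE)
}
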