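# Rigid-body geometry: Kabsch superposition, RMSD, internal-coordinate atom
# placement used by the fixture builders.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the (optionally
#' weighted) squared deviation between `mobile` and `reference`, and applies
#' it to `mobile`. Reflections are excluded: the returned rotation always has
#' determinant +1, so a mirror image cannot be superposed exactly.
#'
#' @param mobile numeric n x 3 matrix of coordinates to move.
#' @param reference numeric n x 3 matrix, same row order as `mobile`.
#' @param weights optional non-negative per-point weights.
#' @return list with `coords` (aligned mobile), `rotation` (3 x 3),
#'   `translation` (length-3; aligned = mobile %*% R + t), and `rmsd`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- rigid_align(p %*% R + 5, p)
#' fit$rmsd  # ~ 0
#' @export
rigid_align <- function(mobile, reference, weights = NULL) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  n <- nrow(mobile)
  if (n < 1L) stop("rigid_align: need at least one point")
  if (nrow(reference) != n) stop("rigid_align: coordinate sets differ in size")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("rigid_align: invalid weights")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # aligned = P %*% R
  aligned <- P %*% R
  aligned <- sweep(aligned, 2, cr, "+")
  list(
    coords = aligned,
    rotation = R,
    translation = cr - as.numeric(cm %*% R),
    rmsd = sqrt(sum(w * rowSums((aligned - reference)^2)))
  )
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b numeric n x 3 matrices in the same atom order.
#' @param align superpose `b` onto `a` first (default TRUE).
#' @return RMSD in the units of the input (Angstrom for structures).
#' @export
coord_rmsd <- function(a, b, align = TRUE) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  if (nrow(a) != nrow(b)) stop("coord_rmsd: coordinate sets differ in size")
  if (align && nrow(a) >= 3L) b <- rigid_align(b, a)$coords
  sqrt(mean(rowSums((a - b)^2)))
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected an n x 3 coordinate matrix")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("coordinates must be finite")
  x
}

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Natural-extension-reference-frame placement: position atom D given
# positions A-B-C, the bond length C-D, angle B-C-D (deg) and dihedral
# A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  ab <- b - a
  n <- unit(pracma_cross(ab, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), -bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
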