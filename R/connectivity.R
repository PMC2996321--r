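#' Overlap area of two circular fields
#'
#' Intersection area of a disk of radius `R` and a disk of radius `r` whose
#' centres are `dist` apart. Vectorised over all arguments.
#'
#' @param R,r disk radii (non-negative).
#' @param dist centre distance (non-negative).
#' @return Numeric vector of intersection areas.
#' @examples
#' disk_overlap(1, 1, 0)  # pi
#' disk_overlap(1, 1, 1)  # 2*pi/3 - sqrt(3)/2
#' @export
disk_overlap <- function(R, r, dist) {
  k <- pmax(length(R), length(r), length(dist))
  R <- rep_len(R, k); r <- rep_len(r, k); dist <- rep_len(dist, k)
  out <- numeric(k)
  pos <- R > 0 & r > 0 & dist < R + r
  # full containment
  cont <- pos & dist <= abs(R - r)
  out[cont] <- pi * pmin(R[cont], r[cont])^2
  # lens
  len <- pos & !cont
  if (any(len)) {
    Rl <- R[len]; rl <- r[len]; dl <- dist[len]
    d2 <- dl^2; R2 <- Rl^2; r2 <- rl^2
    t1 <- R2 * acos(pmin(1, pmax(-1, (d2 + R2 - r2) / (2 * dl * Rl))))
    t2 <- r2 * acos(pmin(1, pmax(-1, (d2 + r2 - R2) / (2 * dl * rl))))
    s <- pmax(0, (-dl + Rl + rl) * (dl + Rl - rl) * (dl - Rl + rl) * (dl + Rl + rl))
    out[len] <- t1 + t2 - 0.5 * sqrt(s)
  }
  out
}

#' Overlap integral of two Gaussian fields
#'
#' Alternative smooth connectivity kernel: the integral over the plane of the
#' product of two unnormalised Gaussian zones `exp(-x^2 / (2 R^2))`, which
#' equals `2*pi*R^2*r^2/(R^2 + r^2) * exp(-dist^2 / (2 (R^2 + r^2)))`.
#' Monotone increasing in both radii, like the disk overlap, but with smooth
#' tails.
#'
#' @inheritParams disk_overlap
#' @return Numeric vector of overlap values.
#' @export
gaussian_overlap <- function(R, r, dist) {
  k <- pmax(length(R), length(r), length(dist))
  R <- rep_len(R, k); r <- rep_len(r, k); dist <- rep_len(dist, k)
  out <- numeric(k)
  pos <- R > 0 & r > 0
  s2 <- R[pos]^2 + r[pos]^2
  out[pos] <- 2 * pi * R[pos]^2 * r[pos]^2 / s2 * exp(-dist[pos]^2 / (2 * s2))
  out
}

#' Connectivity matrix from axonal and dendritic fields
#'
#' `Omega[i, j]` is the overlap of the dendritic zone of neuron `i` (radius
#' `d[i]`, centred at `positions[i, ]`) with the axonal zone of neuron `j`
#' (radius `a[j]`): the synaptic density from presynaptic `j` to
#' postsynaptic `i`. The diagonal is zero (no autapses). The matrix is
#' symmetric only when `a == d` elementwise.
#'
#' @param a,d per-neuron axonal and dendritic field radii.
#' @param positions numeric matrix of 2-D coordinates (one row per neuron).
#' @param kernel `"disk"` or `"gaussian"`.
#' @return `n x n` matrix of non-negative synaptic densities.
#' @examples
#' pos <- cbind(c(0, 1), c(0, 0))
#' compute_connectivity(a = c(1, 1), d = c(1, 1), positions = pos)
#' @export
compute_connectivity <- function(a, d, positions,
                                 kernel = c("disk", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(length(a) == length(d), nrow(positions) == length(a),
            all(a >= 0), all(d >= 0))
  dist <- as.matrix(stats::dist(positions))
  omega <- .connectivity_cpp(as.numeric(a), as.numeric(d), dist,
                             if (kernel == "disk") 0L else 1L)
  dimnames(omega) <- NULL
  omega
}

# pure-R reference used in tests to cross-check the compiled kernel
connectivity_r <- function(a, d, positions, kernel = c("disk", "gaussian")) {
  kernel <- match.arg(kernel)
  n <- length(a)
  dist <- as.matrix(stats::dist(positions))
  f <- if (kernel == "disk") disk_overlap else gaussian_overlap
  omega <- matrix(f(rep(d, times = n), rep(a, each = n), as.vector(dist)),
                  n, n)
  diag(omega) <- 0
  omega
}

grid_positions <- function(params) {
  n <- params$n_neurons
  rows <- params$grid_rows; cols <- params$grid_cols
  idx <- seq_len(n) - 1L
  cbind(x = (idx %% cols) * params$grid_spacing,
        y = (idx %/% cols) * params$grid_spacing)
}
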