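#' Magnetic field of a current dipole in a conducting sphere
#'
#' Closed-form external magnetic field of a current dipole inside a
#' homogeneous spherical volume conductor (Sarvas formula), projected onto a
#' sensor orientation. Radial dipoles — and any dipole at the sphere centre —
#' are magnetically silent.
#'
#' @param dipolePos Dipole position (m), 3-vector.
#' @param moment Dipole moment (A m), 3-vector.
#' @param sensorPos Sensor position(s): 3-vector or n x 3 matrix (m).
#' @param orientation Sensor orientation unit vector(s), same shape.
#' @param headModel [HeadModel-class]; the dipole must lie strictly inside.
#' @return Field component(s) along the orientation(s), in tesla.
#' @export
sphereDipoleField <- function(dipolePos, moment, sensorPos, orientation,
                              headModel = makeHeadModel()) {
  if (is.null(dim(sensorPos))) sensorPos <- matrix(sensorPos, 1)
  if (is.null(dim(orientation))) orientation <- matrix(orientation, 1)
  r0 <- dipolePos - headModel@origin
  if (sqrt(sum(r0^2)) >= headModel@radius) {
    stop("dipole lies outside the head-model sphere")
  }
  B <- sarvasField(r0, moment, sweep(sensorPos, 2, headModel@origin))
  rowSums(B * orientation)
}

# Sarvas (1987): B(r) for dipole Q at r0 inside a conducting sphere centred
# at the origin. r: n x 3 matrix of field points. Returns n x 3.
sarvasField <- function(r0, Q, r) {
  mu0_4pi <- 1e-7
  a <- sweep(r, 2, r0)                       # r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(a * r)
  F <- an * (rn * an + rn^2 - drop(r %*% r0))
  gF <- (an^2 / rn + ar / an + 2 * an + 2 * rn) * r -
    outer(an + 2 * rn + ar / an, r0)
  Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
  if (all(Qxr0 == 0)) return(matrix(0, nrow(r), 3))
  s <- drop(r %*% Qxr0)
  mu0_4pi / F^2 * (F * matrix(Qxr0, nrow(r), 3, byrow = TRUE) - s * gF)
}

#' Regular source grid inside a head model
#'
#' Isotropic voxel grid clipped to a sphere of radius `fill * radius`
#' (sources must lie strictly inside the conductor).
#'
#' @param spacing Grid spacing (m); 0.004 is the whole-brain default, 0.001
#'   the refined default.
#' @param headModel [HeadModel-class].
#' @param fill Fraction of the head radius to fill (default 0.9).
#' @param centre Optional centre (m) of a restricted cubic region.
#' @param halfWidth Half-width (m) of the restricted region (with `centre`).
#' @return A [SourceGrid-class].
#' @export
makeSourceGrid <- function(spacing = 0.004, headModel = makeHeadModel(),
                           fill = 0.9, centre = NULL, halfWidth = NULL) {
  stopifnot(spacing > 0)
  rmax <- fill * headModel@radius
  if (is.null(centre)) {
    ax <- seq(-rmax, rmax, by = spacing)
    g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  } else {
    ax <- seq(-halfWidth, halfWidth, by = spacing)
    g <- as.matrix(expand.grid(x = centre[1] + ax, y = centre[2] + ax,
                               z = centre[3] + ax))
  }
  g <- sweep(g, 2, -headModel@origin)
  keep <- rowSums(sweep(g, 2, headModel@origin)^2) <= rmax^2
  new("SourceGrid", voxels = g[keep, , drop = FALSE], spacing = spacing)
}

# Row-wise Sarvas field: dipole r0[i, ] with moment Q[i, ] observed at
# r[i, ] (all relative to the sphere centre). Returns an m x 3 matrix.
sarvasFieldRows <- function(r0, Q, r) {
  mu0_4pi <- 1e-7
  a <- r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(a * r)
  F <- an * (rn * an + rn^2 - rowSums(r * r0))
  c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + ar / an
  gF <- c1 * r - c2 * r0
  Qxr0 <- cbind(Q[, 2] * r0[, 3] - Q[, 3] * r0[, 2],
                Q[, 3] * r0[, 1] - Q[, 1] * r0[, 3],
                Q[, 1] * r0[, 2] - Q[, 2] * r0[, 1])
  s <- rowSums(r * Qxr0)
  B <- mu0_4pi / F^2 * (F * Qxr0 - s * gF)
  B[rowSums(Qxr0^2) == 0, ] <- 0
  B
}

#' Compute the lead field of a source grid
#'
#' For every voxel, the forward fields of unit dipoles along the two
#' tangential directions (radial dipoles are silent in a sphere, so the lead
#' field is restricted to the 2-dim tangential subspace). Voxels at (or
#' numerically indistinguishable from) the sphere origin are flagged
#' non-localizable and given zero columns.
#'
#' @param grid [SourceGrid-class].
#' @param sensors [SensorArray-class].
#' @param headModel [HeadModel-class].
#' @param chunk Voxels processed per vectorized block.
#' @return A [LeadField-class] with `L` of size channels x 2V.
#' @export
computeLeadField <- function(grid, sensors, headModel = makeHeadModel(),
                             chunk = 2048L) {
  V <- nrow(grid@voxels)
  nc <- nChannels(sensors)
  L <- matrix(0, nc, 2L * V)
  basis <- matrix(0, 2L * V, 3)
  vox <- sweep(grid@voxels, 2, headModel@origin)
  vr <- sqrt(rowSums(vox^2))
  localizable <- vr >= 1e-6
  pos <- sweep(sensors@positions[sensors@sensorIndex, , drop = FALSE],
               2, headModel@origin)
  for (v in which(localizable)) {
    tb <- tangentialBasis(vox[v, ] / vr[v])
    basis[2 * v - 1, ] <- tb[1, ]
    basis[2 * v, ] <- tb[2, ]
  }
  todo <- which(localizable)
  for (s in seq(1L, length(todo), by = chunk)) {
    vs <- todo[s:min(s + chunk - 1L, length(todo))]
    m <- length(vs)
    rows <- rep(vs, each = nc)
    r0 <- vox[rows, , drop = FALSE]
    r <- pos[rep(seq_len(nc), m), , drop = FALSE]
    orient <- sensors@orientations[rep(seq_len(nc), m), , drop = FALSE]
    for (dir in 1:2) {
      Q <- basis[2 * rows - 2L + dir, , drop = FALSE]
      B <- sarvasFieldRows(r0, Q, r)
      L[cbind(rep(seq_len(nc), m), 2L * rows - 2L + dir)] <- rowSums(B * orient)
    }
  }
  new("LeadField", L = L, grid = grid, sensors = sensors,
      headModel = headModel, tangentBasis = basis, localizable = localizable)
}

#' Sensor gain of a set of fixed-orientation dipoles
#'
#' Forward fields (one column per source) of unit dipoles with given
#' positions and moment orientations — the mixing matrix used to project
#' simulated source time courses to the sensor array.
#'
#' @param positions nSrc x 3 matrix of dipole positions (m).
#' @param moments nSrc x 3 matrix of dipole moment orientations.
#' @param sensors [SensorArray-class].
#' @param headModel [HeadModel-class].
#' @return channels x nSrc gain matrix (T per unit moment).
#' @export
sourceGain <- function(positions, moments, sensors,
                       headModel = makeHeadModel()) {
  positions <- matrix(positions, ncol = 3)
  moments <- matrix(moments, ncol = 3)
  pos <- sensors@positions[sensors@sensorIndex, , drop = FALSE]
  G <- matrix(0, nChannels(sensors), nrow(positions))
  for (s in seq_len(nrow(positions))) {
    r0 <- positions[s, ] - headModel@origin
    if (sqrt(sum(r0^2)) >= headModel@radius) {
      stop("source ", s, " lies outside the head-model sphere")
    }
    B <- sarvasField(r0, moments[s, ], sweep(pos, 2, headModel@origin))
    G[, s] <- rowSums(B * sensors@orientations)
  }
  G
}

#' Tangential dipole moment direction at a source position
#'
#' First tangential unit vector at a position inside the sphere — the
#' canonical moment direction used for planted dipoles (radial moments are
#' magnetically silent).
#'
#' @param position Source position (m).
#' @param headModel [HeadModel-class].
#' @return Unit 3-vector orthogonal to the radial direction.
#' @export
tangentialMoment <- function(position, headModel = makeHeadModel()) {
  r0 <- position - headModel@origin
  tangentialBasis(r0 / sqrt(sum(r0^2)))[1, ]
}
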