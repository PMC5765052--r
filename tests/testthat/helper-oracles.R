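# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# Brute-force maximal-inscribed-sphere local thickness on small grids:
# sphere radius at p = min distance to a background voxel centre; the
# thickness at x is the largest diameter over all spheres containing x.
oracle_local_thickness <- function(mask) {
  dm <- dim(mask$data)
  sp <- mask$spacing
  fg <- which(mask$data)
  bg <- which(!mask$data)
  coords <- function(lin) {
    i <- (lin - 1L) %% dm[1]
    j <- ((lin - 1L) %/% dm[1]) %% dm[2]
    k <- (lin - 1L) %/% (dm[1] * dm[2])
    cbind(i * sp[1], j * sp[2], k * sp[3])
  }
  P <- coords(fg)
  B <- coords(bg)
  r <- vapply(seq_len(nrow(P)), function(t)
    sqrt(min(colSums((t(B) - P[t, ])^2))), 0)
  th <- numeric(length(fg))
  for (t in seq_along(fg)) {
    d <- sqrt(colSums((t(P) - P[t, ])^2))
    th[t] <- 2 * max(r[d <= r + 1e-12])
  }
  out <- array(0, dm)
  out[fg] <- th
  out
}

# Welch t-test from the textbook formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Holm-Sidak step-down by direct definition
oracle_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (k in seq_len(m)) {
    run <- max(run, 1 - (1 - p[o[k]])^(m - k + 1))
    adj[o[k]] <- min(1, run)
  }
  adj
}

# a random rigid motion (proper rotation + translation)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 5))
}
apply_rigid <- function(points, rig) {
  sweep(points %*% t(rig$R), 2, rig$t, `+`)
}

# minimal closed unit-cube mesh (8 vertices, 12 faces, outward normals)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, f)
}

# solid-sphere mask of the given radius (mm), isotropic spacing
sphere_mask <- function(radius, spacing, margin = 2) {
  n <- 2 * ceiling(radius / spacing) + 2 * margin + 1
  cs <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(outer(cs^2, cs^2, `+`), cs^2, `+`)
  binary_mask(array(r2 <= radius^2, c(n, n, n)), rep(spacing, 3))
}

# axis-1-normal slab mask: nvox foreground slices padded with background
slab_mask <- function(nvox, spacing, lateral = 20, pad = 3) {
  d <- array(FALSE, c(nvox + 2 * pad, lateral, lateral))
  d[pad + seq_len(nvox), , ] <- TRUE
  binary_mask(d, rep(spacing, 3))
}
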