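#' Three-shell spherical head model
#'
#' Concentric-sphere volume conductor with scalp, skull and brain
#' compartments. Defaults are the conventional 88/85/81 mm radii with
#' conductivities 0.33/0.0042/0.33 S/m (skull ~80x less conductive than
#' soft tissue).
#'
#' @param radii Numeric length-3, shell outer radii in mm, ordered
#'   scalp, skull, brain (strictly decreasing).
#' @param conductivities Numeric length-3, conductivities in S/m for the
#'   scalp, skull and brain compartments.
#' @param center Numeric length-3, sphere center in head-frame mm.
#' @return An object of class `head_model`.
#' @export
#' @examples
#' hm <- head_model()
#' hm$radii
head_model <- function(radii = c(88, 85, 81),
                       conductivities = c(0.33, 0.0042, 0.33),
                       center = c(0, 0, 0)) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) != 3L || any(diff(radii) >= 0))
    stop("`radii` must be 3 strictly decreasing values (scalp, skull, brain)")
  if (length(conductivities) != 3L || any(conductivities <= 0))
    stop("`conductivities` must be 3 positive values")
  structure(list(radii = radii, conductivities = conductivities,
                 center = as.numeric(center)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("3-shell spherical head model\n")
  cat(sprintf("  radii (scalp/skull/brain): %s mm\n",
              paste(x$radii, collapse = "/")))
  cat(sprintf("  conductivities: %s S/m\n",
              paste(x$conductivities, collapse = "/")))
  invisible(x)
}

#' Regular source grid clipped to the brain shell
#'
#' Builds a regular cubic lattice of voxel centers covering the brain
#' compartment of a spherical head model. Voxels are kept when their
#' center lies strictly inside the brain shell. Ordering is
#' deterministic: x varies fastest, then y, then z.
#'
#' @param head_model A [head_model()].
#' @param spacing Voxel edge length in mm (> 0).
#' @return An object of class `source_grid` with fields `pos` (N x 3
#'   voxel centers, mm), `spacing`, `radius` (brain shell radius) and
#'   `n` (voxel count).
#' @export
#' @examples
#' g <- build_source_grid(head_model(), spacing = 20)
#' g$n
build_source_grid <- function(head_model, spacing) {
  stopifnot(inherits(head_model, "head_model"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (mm)")
  r_brain <- min(head_model$radii)
  if (spacing >= 2 * r_brain) {
    pos <- matrix(head_model$center, nrow = 1)
  } else {
    ax <- seq(-r_brain, r_brain, by = spacing)
    ax <- ax - mean(range(ax))            # center the lattice on the origin
    gp <- as.matrix(expand.grid(x = ax, y = ax, z = ax))  # x fastest
    keep <- sqrt(rowSums(gp^2)) < r_brain
    pos <- sweep(gp[keep, , drop = FALSE], 2, head_model$center, `+`)
  }
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(list(pos = pos, spacing = spacing, radius = r_brain,
                 center = head_model$center, n = nrow(pos)),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("source grid: %d voxels, %g mm spacing, brain radius %g mm\n",
              x$n, x$spacing, x$radius))
  invisible(x)
}

#' Quasi-uniform scalp montage
#'
#' Generates an electrode montage of approximately uniformly spaced
#' positions on the upper portion of the scalp sphere (Fibonacci
#' lattice restricted to z above a coverage cutoff, mimicking the
#' coverage of a dense geodesic sensor net).
#'
#' @param n_channels Number of electrodes.
#' @param head_model A [head_model()].
#' @param coverage Fraction of the sphere (by z-extent, from the vertex
#'   downward) covered by electrodes; 0.65 reaches below the ears.
#' @return A tibble of class `lep_montage` with columns
#'   `label`, `x`, `y`, `z` (mm).
#' @export
default_montage <- function(n_channels = 64, head_model = head_model(),
                            coverage = 0.65) {
  stopifnot(n_channels >= 2)
  R <- max(head_model$radii)
  i <- seq_len(n_channels) - 0.5
  # Fibonacci lattice on the spherical cap z/R in (1 - 2*coverage, 1)
  z <- 1 - 2 * coverage * i / n_channels
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- R * cbind(x = s * cos(phi), y = s * sin(phi), z = z)
  pos <- sweep(pos, 2, head_model$center, `+`)
  out <- tibble::tibble(label = sprintf("E%03d", seq_len(n_channels)),
                        x = pos[, 1], y = pos[, 2], z = pos[, 3])
  class(out) <- c("lep_montage", class(out))
  out
}

#' Read / write a montage as whitespace-delimited text
#'
#' Format: one electrode per line, `label x y z` in mm, with a header line.
#'
#' @param path File path.
#' @return `read_montage()` returns a `lep_montage` tibble.
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, header = TRUE,
                          col.names = c("label", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("lep_montage", class(out))
  out
}

#' @param montage A `lep_montage`.
#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Per-degree transfer coefficients for the concentric 3-shell conductor.
# For each harmonic degree n, solves the interface conditions (continuity
# of potential and of radial current, zero radial current at the scalp
# surface) for a unit r^-(n+1) source term in the brain compartment and
# returns the surface potential relative to the infinite-medium value
# R^-(n+1). Degree-wise the problem is a small linear system; orientation
# (m = 0 vs m = 1) shares the same radial equation, so one factor per n.
shell_transfer <- function(head_model, n_max) {
  R <- max(head_model$radii)
  # interfaces in normalized radius, inner -> outer: brain/skull, skull/scalp
  u <- c(min(head_model$radii), head_model$radii[2]) / R
  sig <- rev(head_model$conductivities)  # brain, skull, scalp (inner -> outer)
  f <- numeric(n_max)
  for (n in seq_len(n_max)) {
    # V_j(u) = A_j u^n + B_j u^-(n+1); source term B_1 = 1 in the brain shell.
    # Propagate (A, B) across each interface: continuity of V and of
    # sigma dV/du gives (A_{j+1}, B_{j+1}) = Mo^-1 Mi (A_j, B_j).
    Tm <- diag(2)
    for (j in 1:2) {
      uj <- u[j]; si <- sig[j]; so <- sig[j + 1]
      p <- uj^n; q <- uj^(-(n + 1))
      dp <- n * uj^(n - 1); dq <- -(n + 1) * uj^(-(n + 2))
      Mi <- rbind(c(p, q), c(si * dp, si * dq))
      det_o <- so * (p * dq - q * dp)
      Mo_inv <- rbind(c(so * dq, -q), c(-so * dp, p)) / det_o
      Tm <- Mo_inv %*% Mi %*% Tm
    }
    # outer shell: (A3, B3) = Tm %*% c(A1, 1); scalp BC V3'(1) = 0:
    # n A3 - (n+1) B3 = 0
    num <- -(n * Tm[1, 2] - (n + 1) * Tm[2, 2])
    den <- n * Tm[1, 1] - (n + 1) * Tm[2, 1]
    A1 <- num / den
    AB3 <- Tm %*% c(A1, 1)
    f[n] <- AB3[1] + AB3[2]              # V(1) relative to infinite-medium u^-(n+1)=1
  }
  f
}

#' Lead field of a 3-shell spherical head model
#'
#' Computes the channels x (voxels x 3 orientations) gain matrix mapping
#' dipole moments (nA.m) at the grid voxels to average-referenced scalp
#' potentials (uV). Uses the Legendre-series solution for concentric
#' spherical shells; each harmonic degree is attenuated by the
#' shell-transfer factor obtained from the interface conditions.
#' Electrodes are radially projected onto the scalp shell.
#'
#' @param head_model A [head_model()].
#' @param montage A `lep_montage` (or data frame with columns x, y, z in mm).
#' @param grid A [build_source_grid()] grid.
#' @param n_terms Number of Legendre terms in the series.
#' @return An object of class `lead_field` with fields `gain`
#'   (C x 3N matrix, uV per nA.m; orientation triplets x,y,z per voxel,
#'   voxel-major), `grid`, `montage`, `head_model`, `n_terms`.
#' @export
lead_field <- function(head_model, montage, grid, n_terms = 200) {
  stopifnot(inherits(head_model, "head_model"), inherits(grid, "source_grid"))
  elec <- as.matrix(montage[, c("x", "y", "z")])
  C <- nrow(elec); N <- grid$n
  ctr <- head_model$center
  R <- max(head_model$radii) / 1000                       # scalp radius, m
  e <- sweep(elec, 2, ctr) / 1000                         # m, centered
  e <- e / sqrt(rowSums(e^2)) * R                         # project to scalp
  src <- sweep(grid$pos, 2, ctr) / 1000                   # m
  b <- sqrt(rowSums(src^2))
  if (any(b >= min(head_model$radii) / 1000))
    stop("source at or outside the brain shell boundary")
  f <- shell_transfer(head_model, n_terms)
  sigma1 <- head_model$conductivities[3]                  # brain

  # pairwise geometry, voxel-major vectors of length N*C
  idx_v <- rep(seq_len(N), each = C)
  idx_c <- rep(seq_len(C), times = N)
  bv <- b[idx_v]
  r0h <- src[idx_v, , drop = FALSE] / ifelse(bv > 0, bv, 1)  # unit r0 (0-safe)
  reh <- e[idx_c, , drop = FALSE] / R
  cg <- rowSums(r0h * reh)                                # cos(gamma)
  cg[bv == 0] <- 0

  # series: K1 = sum f_n b^(n-1)/R^(n+1) (n P_n - c P_n')
  #         K2 = sum f_n b^(n-1)/R^(n+1) P_n'
  # potential = 1/(4 pi sigma1) * (K1 (q . r0h) + K2 (q . reh))
  m <- length(cg)
  P_nm1 <- rep(1, m)        # P_0
  P_n <- cg                 # P_1
  dP_nm1 <- rep(0, m)       # P_0'
  dP_n <- rep(1, m)         # P_1'
  K1 <- numeric(m); K2 <- numeric(m)
  tv <- bv / R              # eccentricity ratio < 1; powers cannot overflow
  radial <- rep(1 / R^2, m) # n = 1 term b^(n-1)/R^(n+1) = t^(n-1)/R^2
  K1 <- K1 + f[1] * radial * (1 * P_n - cg * dP_n)
  K2 <- K2 + f[1] * radial * dP_n
  for (n in 2:n_terms) {
    P_np1 <- ((2 * n - 1) * cg * P_n - (n - 1) * P_nm1) / n
    dP_np1 <- dP_nm1 + (2 * n - 1) * P_n
    P_nm1 <- P_n; P_n <- P_np1
    dP_nm1 <- dP_n; dP_n <- dP_np1
    radial <- tv^(n - 1) / R^2
    K1 <- K1 + f[n] * radial * (n * P_n - cg * dP_n)
    K2 <- K2 + f[n] * radial * dP_n
  }
  scale <- 1 / (4 * pi * sigma1)
  # gain for unit moment along axis a: scale * (K1 * r0h[,a] + K2 * reh[,a])
  gain <- matrix(0, C, 3 * N)
  for (a in 1:3) {
    va <- scale * (K1 * r0h[, a] + K2 * reh[, a])         # length N*C
    gain[, seq.int(a, 3 * N, by = 3)] <- matrix(va, nrow = C)
  }
  # units: moments arrive in nA.m (1e-9 A.m), potentials reported in uV (1e6 V)
  gain <- gain * 1e-9 * 1e6
  gain <- sweep(gain, 2, colMeans(gain))                  # average reference
  structure(list(gain = gain, grid = grid,
                 montage = tibble::as_tibble(montage),
                 head_model = head_model, n_terms = n_terms),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead field: %d channels x %d voxels x 3 orientations\n",
              nrow(x$gain), x$grid$n))
  invisible(x)
}

#' Project dipole moments through a lead field
#'
#' @param lf A [lead_field()].
#' @param moments Either a 3N-vector or a 3N x T matrix of dipole
#'   moments (nA.m), voxel-major orientation triplets.
#' @return Channels x T matrix of average-referenced potentials (uV).
#' @export
project_sources <- function(lf, moments) {
  stopifnot(inherits(lf, "lead_field"))
  lf$gain %*% as.matrix(moments)
}

#' Export a per-voxel volume to NIfTI
#'
#' Rasterizes per-voxel values onto the grid's bounding lattice and
#' writes a NIfTI file with the grid spacing as voxel dimensions and an
#' affine placing the head-frame origin at the sphere center.
#'
#' @param values Numeric vector, one value per grid voxel.
#' @param grid A [build_source_grid()] grid.
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @export
export_volume_nifti <- function(values, grid, path) {
  stopifnot(length(values) == grid$n)
  sp <- grid$spacing
  pos <- sweep(grid$pos, 2, grid$center)
  ijk <- round(sweep(pos, 2, apply(pos, 2, min)) / sp) + 1
  dims <- apply(ijk, 2, max)
  arr <- array(0, dim = dims)
  arr[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- values
  img <- RNifti::asNifti(arr, pixdim = rep(sp, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
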