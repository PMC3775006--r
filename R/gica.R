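#' Stack source-volume series and reduce by PCA
#'
#' Temporally concatenates the time x voxel magnitude matrices of all
#' subjects and conditions, then reduces the time dimension by principal
#' component analysis, keeping `n_pc` whitened spatial eigenimages. The
#' reduction operator is stored for back-reconstruction.
#'
#' @param series_list List of `source_series` objects (or plain
#'   time x voxel matrices) sharing the voxel grid and sample count.
#' @param n_pc Number of principal components to retain.
#' @return An object of class `gica_reduction`: `Y` (n_pc x voxels,
#'   whitened rows), `U` (total time x n_pc temporal eigenvectors), `d`
#'   (singular values), `row_mean` (per-time-point spatial mean),
#'   `blocks` (tibble mapping concatenated rows to subject/condition),
#'   `explained` (variance fraction per component), `grid`.
#' @export
stack_and_reduce <- function(series_list, n_pc = 30) {
  mats <- lapply(series_list, function(s)
    if (inherits(s, "source_series")) s$magnitudes else as.matrix(s))
  nv <- unique(vapply(mats, ncol, integer(1)))
  if (length(nv) != 1L) stop("series differ in voxel count")
  nt <- unique(vapply(mats, nrow, integer(1)))
  if (length(nt) != 1L) stop("series differ in sample count")
  X <- do.call(rbind, mats)
  blocks <- tibble::tibble(
    block = seq_along(mats),
    subject = vapply(series_list, function(s)
      if (inherits(s, "source_series")) s$subject else NA_character_,
      character(1)),
    condition = vapply(series_list, function(s)
      if (inherits(s, "source_series")) s$condition else NA_character_,
      character(1)),
    first_row = (seq_along(mats) - 1L) * nt + 1L,
    last_row = seq_along(mats) * nt)
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  if (n_pc > min(dim(Xc))) stop("`n_pc` exceeds the data rank bound")
  # eigendecompose the smaller-dimension crossproduct
  if (ncol(Xc) <= nrow(Xc)) {
    ed <- eigen(crossprod(Xc), symmetric = TRUE)
    d <- sqrt(pmax(ed$values, 0))
    Vv <- ed$vectors[, seq_len(n_pc), drop = FALSE]
    U <- Xc %*% Vv
    U <- sweep(U, 2, pmax(d[seq_len(n_pc)], 1e-300), `/`)
  } else {
    ed <- eigen(tcrossprod(Xc), symmetric = TRUE)
    d <- sqrt(pmax(ed$values, 0))
    U <- ed$vectors[, seq_len(n_pc), drop = FALSE]
  }
  dr <- d[seq_len(n_pc)]
  nvx <- ncol(Xc)
  Y <- sweep(t(U) %*% Xc, 1, dr / sqrt(nvx - 1), `/`)   # unit-variance rows
  grid <- if (inherits(series_list[[1]], "source_series"))
    series_list[[1]]$grid else NULL
  structure(list(Y = Y, U = U, d = dr, row_mean = rm_, blocks = blocks,
                 explained = d^2 / sum(d^2), grid = grid,
                 n_time = nt, n_pc = n_pc),
            class = "gica_reduction")
}

#' Reconstruct the stacked data from a reduction
#'
#' @param red A `gica_reduction`.
#' @param k Number of components to use (default all retained).
#' @return The rank-`k` reconstruction of the stacked (centered) matrix.
#' @export
reduction_reconstruct <- function(red, k = red$n_pc) {
  nvx <- ncol(red$Y)
  (red$U[, seq_len(k), drop = FALSE] *
     rep(red$d[seq_len(k)] / sqrt(nvx - 1), each = nrow(red$U))) %*%
    red$Y[seq_len(k), , drop = FALSE]
}

#' Infomax ICA
#'
#' Natural-gradient Infomax with the logistic nonlinearity and an
#' annealed learning rate, run on whitened data. Deterministic for a
#' given seed. Converges when the relative weight change falls below
#' `tol`; non-convergence raises an error carrying the final delta.
#'
#' @param Y Whitened data, components-space rows x samples (e.g. the
#'   first `K` rows of a [stack_and_reduce()] reduction).
#' @param K Number of components (must not exceed `nrow(Y)`).
#' @param seed Integer seed for the sample permutations.
#' @param max_iter Maximum passes over the data.
#' @param lrate Initial learning rate.
#' @param tol Convergence tolerance on the summed squared weight change.
#' @return List with `W` (K x K unmixing of the whitened rows), `maps`
#'   (K x samples source estimates), `iterations`, `wchange`.
#' @export
run_infomax <- function(Y, K = nrow(Y), seed = 1, max_iter = 512,
                        lrate = NULL, tol = 1e-6) {
  if (K > nrow(Y)) stop("K must not exceed the reduced dimension")
  Y <- Y[seq_len(K), , drop = FALSE]
  nsmp <- ncol(Y)
  old <- .Random.seed_exists(); set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  # random orthogonal start: repeated runs from different seeds explore
  # genuinely different basins, which is what the stability analysis needs
  W <- qr.Q(qr(matrix(stats::rnorm(K * K), K)))
  bias <- numeric(K)                 # handles skewed / non-zero-mean sources
  if (is.null(lrate)) lrate <- 0.015 / log(K + 2)
  block <- max(8L, floor(sqrt(nsmp / 3)))
  wchange_old <- Inf; wchange <- Inf
  for (it in seq_len(max_iter)) {
    W_old <- W
    perm <- sample.int(nsmp)
    for (b0 in seq(1L, nsmp - block + 1L, by = block)) {
      idx <- perm[b0:(b0 + block - 1L)]
      u <- W %*% Y[, idx, drop = FALSE] + bias
      y1m2 <- 1 - 2 / (1 + exp(-u))
      dW <- lrate * (diag(block, K) + y1m2 %*% t(u)) %*% W
      if (max(abs(dW)) > 1e8) stop("Infomax diverged; lower the learning rate")
      W <- W + dW
      bias <- bias + lrate * rowSums(y1m2)
    }
    wchange <- sum((W - W_old)^2) / sum(W_old^2)
    if (wchange > wchange_old) lrate <- lrate * 0.9
    wchange_old <- wchange
    if (wchange < tol) break
  }
  if (wchange >= tol)
    stop(sprintf("Infomax did not converge: final weight delta %.3g", wchange))
  maps <- W %*% Y
  list(W = W, bias = bias, maps = maps, iterations = it, wchange = wchange)
}

# |spatial correlation| similarity between two map matrices (rows = maps)
map_similarity <- function(M1, M2) {
  abs(stats::cor(t(M1), t(M2)))
}

#' ICASSO stability analysis and model-order selection
#'
#' Runs Infomax repeatedly for each candidate model order — each run
#' from a fresh random rotation and (by default) on a bootstrap
#' resample of the voxels — pools the resulting spatial maps, clusters
#' them by average-linkage on `1 - |spatial correlation|`, and scores
#' each cluster by its stability index (mean within-cluster minus mean
#' between-cluster similarity; a cluster seen in only one run scores 0).
#' The selected order is the largest candidate whose clusters all reach
#' `stability_floor` — the most components that can be estimated
#' reliably; if no candidate clears the floor, the order with maximal
#' mean stability is returned with a warning. Final maps are the
#' cluster centrotypes.
#'
#' @param red A `gica_reduction` (or whitened matrix).
#' @param K_candidates Integer vector of candidate component counts.
#' @param n_runs ICA repetitions per candidate.
#' @param seed Base seed; run r uses `seed + r`.
#' @param stability_floor Minimum acceptable stability index.
#' @param bootstrap Resample voxels (with replacement) for the unmixing
#'   estimation of each run; maps are always computed on the full data.
#' @return An object of class `icasso_result`: `K`, `maps`
#'   (K x samples centrotype maps), `stability` (per selected cluster),
#'   `table` (tibble over all candidates: K, mean/min stability).
#' @export
run_icasso <- function(red, K_candidates, n_runs = 15, seed = 1,
                       stability_floor = 0.8, bootstrap = TRUE) {
  Y <- if (inherits(red, "gica_reduction")) red$Y else red
  K_candidates <- sort(unique(as.integer(K_candidates)))
  if (any(K_candidates > nrow(Y)))
    stop("candidate K exceeds the reduced dimension")
  if (n_runs == 1L)
    warning("n_runs = 1: stability indices are degenerate (1 by convention)")
  per_k <- vector("list", length(K_candidates))
  tab <- vector("list", length(K_candidates))
  for (ki in seq_along(K_candidates)) {
    K <- K_candidates[ki]
    runs <- lapply(seq_len(n_runs), function(r) {
      Yr <- if (bootstrap && n_runs > 1L) {
        old <- .Random.seed_exists(); set.seed(seed + 7919L * r)
        idx <- sample.int(ncol(Y), replace = TRUE)
        .restore_seed(old)
        Y[, idx, drop = FALSE]
      } else Y
      W <- run_infomax(Yr, K, seed = seed + r)$W
      W %*% Y[seq_len(K), , drop = FALSE]
    })
    pool <- do.call(rbind, runs)
    if (n_runs == 1L) {
      cl <- seq_len(K)
      stab <- rep(1, K)
      cent <- pool
    } else {
      sim <- map_similarity(pool, pool)
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
      cl <- stats::cutree(hc, k = K)
      stab <- numeric(K); cent <- matrix(0, K, ncol(pool))
      for (c_ in seq_len(K)) {
        inC <- which(cl == c_); outC <- which(cl != c_)
        sin_ <- sim[inC, inC, drop = FALSE]
        # a cluster represented in only one run has not replicated:
        # its within-cluster similarity is scored 0, not 1
        win <- if (length(inC) > 1)
          mean(sin_[upper.tri(sin_)]) else 0
        btw <- if (length(outC)) mean(sim[inC, outC, drop = FALSE]) else 0
        stab[c_] <- win - btw
        # centrotype: member most similar to its own cluster
        score <- rowMeans(sim[inC, inC, drop = FALSE])
        cent[c_, ] <- pool[inC[which.max(score)], ]
      }
    }
    ord <- order(stab, decreasing = TRUE)
    per_k[[ki]] <- list(stability = stab[ord],
                        maps = cent[ord, , drop = FALSE])
    tab[[ki]] <- tibble::tibble(K = K, mean_stability = mean(stab),
                                min_stability = min(stab))
  }
  tab <- do.call(rbind, tab)
  ok <- tab$min_stability >= stability_floor
  # reliable model order: the largest candidate before stability first
  # breaks down (occasional re-passes at higher K are clustering
  # artifacts, not evidence of more reliable components)
  sel <- if (ok[1]) {
    if (all(ok)) length(ok) else which(!ok)[1] - 1L
  } else {
    warning("no candidate K reaches the stability floor; using max mean stability")
    which.max(tab$mean_stability)
  }
  structure(list(K = K_candidates[sel],
                 maps = per_k[[sel]]$maps,
                 stability = per_k[[sel]]$stability,
                 table = tab, n_runs = n_runs, seed = seed),
            class = "icasso_result")
}

#' @export
print.icasso_result <- function(x, ...) {
  cat(sprintf("ICASSO: selected K = %d (stability %s)\n", x$K,
              paste(sprintf("%.2f", x$stability), collapse = ", ")))
  invisible(x)
}

# normalize maps to unit variance over voxels with map peak positive;
# returns list(maps, scale, sign)
normalize_maps <- function(maps) {
  sds <- apply(maps, 1, stats::sd)
  sds[sds == 0] <- 1
  maps <- maps / sds
  sgn <- vapply(seq_len(nrow(maps)), function(k) {
    v <- maps[k, ]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  list(maps = maps * sgn, scale = sds, sign = sgn)
}

#' Group ICA decomposition of stacked source-volume series
#'
#' Convenience wrapper: PCA reduction, ICASSO (or a single Infomax run
#' at fixed `K`), map normalization (unit variance, peak-positive sign
#' convention), and back-reconstruction of per subject x condition
#' component time courses.
#'
#' @param series_list List of `source_series` (subject x condition).
#' @param n_pc Principal components kept before ICA.
#' @param K Fixed component count, or `NULL` to select via ICASSO.
#' @param K_candidates Candidate orders for ICASSO selection.
#' @param n_runs ICASSO repetitions.
#' @param seed Seed.
#' @param stability_floor Minimum acceptable ICASSO stability index.
#' @return An object of class `gica_fit`: `maps` (K x voxels), `tc`
#'   (long tibble subject, condition, component, time, value),
#'   `stability`, `explained` (variance fraction of the K-component
#'   reconstruction of the stacked data), `reduction`, `grid`.
#' @export
group_ica <- function(series_list, n_pc = 30, K = NULL,
                      K_candidates = NULL, n_runs = 15, seed = 1,
                      stability_floor = 0.8) {
  red <- stack_and_reduce(series_list, n_pc)
  if (is.null(K)) {
    if (is.null(K_candidates)) K_candidates <- seq(2L, min(10L, n_pc))
    ica <- run_icasso(red, K_candidates, n_runs, seed, stability_floor)
    maps <- ica$maps; stab <- ica$stability; Ksel <- ica$K
    icasso_table <- ica$table
  } else {
    fit <- run_infomax(red$Y, K, seed = seed)
    maps <- fit$maps; stab <- rep(NA_real_, K); Ksel <- K
    icasso_table <- NULL
  }
  nm <- normalize_maps(maps)
  maps <- nm$maps
  # explained variance of the K-component reconstruction: PCA-retained
  # fraction times the fraction of that subspace captured by the maps
  Xc_hat <- back_project_fit(red, maps)
  Xc <- reduction_reconstruct(red, red$n_pc)
  evf <- sum(red$explained[seq_len(red$n_pc)]) *
    (1 - sum((Xc - Xc_hat)^2) / sum(Xc^2))
  tc <- back_reconstruct(list(maps = maps, reduction = red), series_list)
  structure(list(maps = maps, tc = tc, stability = stab, K = Ksel,
                 explained = evf, reduction = red, grid = red$grid,
                 icasso = icasso_table, seed = seed),
            class = "gica_fit")
}

# least-squares reconstruction of the stacked centered data from maps
back_project_fit <- function(red, maps) {
  Xc <- reduction_reconstruct(red, red$n_pc)
  Sp <- t(maps) %*% solve(tcrossprod(maps))      # voxels x K pseudoinverse
  (Xc %*% Sp) %*% maps
}

#' Back-reconstruct per subject/condition component time courses
#'
#' Least-squares projection of each subject x condition volume series
#' onto the group spatial maps: `tc = X S' (S S')^-1` per block.
#'
#' @param fit A `gica_fit` (or list with `maps` and `reduction`).
#' @param series_list The per subject x condition `source_series` list
#'   used for the decomposition (or compatible new data).
#' @return Long tibble: subject, condition, component, time, value.
#' @export
back_reconstruct <- function(fit, series_list) {
  maps <- fit$maps
  Sp <- t(maps) %*% solve(tcrossprod(maps))
  rows <- lapply(series_list, function(s) {
    X <- if (inherits(s, "source_series")) s$magnitudes else as.matrix(s)
    tc <- (X - rowMeans(X)) %*% Sp                 # T x K
    t_ax <- if (inherits(s, "source_series")) s$time else seq_len(nrow(X))
    subj <- if (inherits(s, "source_series")) s$subject else NA_character_
    cond <- if (inherits(s, "source_series")) s$condition else NA_character_
    tibble::tibble(
      subject = rep(subj, nrow(tc) * ncol(tc)),
      condition = rep(cond, nrow(tc) * ncol(tc)),
      component = rep(seq_len(ncol(tc)), each = nrow(tc)),
      time = rep(t_ax, ncol(tc)),
      value = as.vector(tc))
  })
  do.call(rbind, rows)
}

#' Per-subject component maps
#'
#' Subject-specific spatial maps obtained by regressing each subject's
#' (condition-averaged) volume series onto that subject's component time
#' courses: `S_i = (M_i' M_i)^-1 M_i' X_i`, averaged over conditions.
#'
#' @param fit A `gica_fit`.
#' @param series_list The `source_series` list used in the fit.
#' @return 3-d array subjects x components x voxels.
#' @export
subject_component_maps <- function(fit, series_list) {
  tc <- fit$tc
  subjects <- unique(tc$subject)
  K <- nrow(fit$maps); nvx <- ncol(fit$maps)
  out <- array(0, dim = c(length(subjects), K, nvx),
               dimnames = list(subjects, NULL, NULL))
  for (si in seq_along(subjects)) {
    blocks <- which(vapply(series_list, function(s)
      s$subject == subjects[si], logical(1)))
    acc <- matrix(0, K, nvx)
    for (b in blocks) {
      s <- series_list[[b]]
      X <- s$magnitudes - rowMeans(s$magnitudes)
      M <- matrix(0, nrow(X), K)
      sub_tc <- tc[tc$subject == subjects[si] &
                     tc$condition == s$condition, ]
      for (k in seq_len(K))
        M[, k] <- sub_tc$value[sub_tc$component == k]
      acc <- acc + solve(crossprod(M), t(M) %*% X)
    }
    out[si, , ] <- acc / length(blocks)
  }
  out
}

# Gaussian smoothing kernel over the grid lattice
grid_smooth <- function(values, grid, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  sg <- fwhm_mm / (2 * sqrt(2 * log(2)))
  D2 <- as.matrix(stats::dist(grid$pos))^2
  Km <- exp(-D2 / (2 * sg^2))
  as.vector(Km %*% values / rowSums(Km))
}

#' Z-score and threshold a component map
#'
#' Mildly smooths the spatial map on the voxel lattice (Gaussian kernel),
#' standardizes it to zero mean and unit SD over brain voxels, and
#' thresholds at `z_threshold`.
#'
#' @param map Numeric vector of per-voxel component weights.
#' @param grid The `source_grid` the map lives on.
#' @param smooth_fwhm Smoothing kernel FWHM in mm (default one voxel).
#' @param z_threshold Z threshold (default 3.1).
#' @return An object of class `component_map`: `z` (per-voxel Z),
#'   `threshold`, `surviving` (voxel indices with `z >= threshold`),
#'   `peak` (tibble with the peak voxel coordinate and Z).
#' @export
component_zmap <- function(map, grid, smooth_fwhm = grid$spacing,
                           z_threshold = 3.1) {
  sm <- grid_smooth(as.numeric(map), grid, smooth_fwhm)
  sdv <- stats::sd(sm)
  z <- if (sdv == 0) rep(0, length(sm)) else (sm - mean(sm)) / sdv
  surv <- which(z >= z_threshold)
  pk <- if (length(surv)) surv[which.max(z[surv])] else integer(0)
  peak <- if (length(pk))
    tibble::tibble(x = grid$pos[pk, 1], y = grid$pos[pk, 2],
                   z = grid$pos[pk, 3], Z = z[pk])
  else tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                      Z = numeric(0))
  structure(list(z = z, threshold = z_threshold, surviving = surv,
                 peak = peak, smooth_fwhm = smooth_fwhm, grid = grid),
            class = "component_map")
}

# 26-connectivity components of a voxel index set on the grid lattice
lattice_clusters <- function(idx, grid) {
  if (!length(idx)) return(integer(0))
  pos <- grid$pos[idx, , drop = FALSE]
  sp <- grid$spacing
  n <- length(idx)
  lab <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i; lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      d <- sqrt(colSums((t(pos) - pos[j, ])^2))
      nb <- which(lab == 0L & d > 0 & d <= sp * sqrt(3) * 1.0001)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Group one-sample T map with cluster peaks
#'
#' Per-voxel one-sample t statistic of subject component maps against
#' zero (variance floored at `var_floor` to handle degenerate voxels),
#' thresholded at `t_threshold`; suprathreshold voxels are grouped by
#' 26-connectivity and reported as a peak table sorted by T.
#'
#' @param subject_maps Subjects x voxels matrix for one component.
#' @param grid The `source_grid`.
#' @param t_threshold T threshold (e.g. 70 for the LEP window maps, 50
#'   for the peri-stimulus window).
#' @param var_floor Variance floor.
#' @return An object of class `group_map`: `t` (per-voxel T), `peaks`
#'   (tibble x, y, z, k, T per cluster, sorted by T), `threshold`.
#' @export
group_tmap <- function(subject_maps, grid, t_threshold = 70,
                       var_floor = 1e-12) {
  n <- nrow(subject_maps)
  mu <- colMeans(subject_maps)
  v <- apply(subject_maps, 2, stats::var)
  degenerate <- v < var_floor
  tstat <- mu / sqrt(pmax(v, var_floor) / n)
  surv <- which(tstat >= t_threshold)
  lab <- lattice_clusters(surv, grid)
  peaks <- if (length(surv)) {
    do.call(rbind, lapply(seq_len(max(lab)), function(c_) {
      vox <- surv[lab == c_]
      pk <- vox[which.max(tstat[vox])]
      tibble::tibble(x = grid$pos[pk, 1], y = grid$pos[pk, 2],
                     z = grid$pos[pk, 3], k = length(vox),
                     T = tstat[pk])
    }))
  } else tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                        k = integer(0), T = numeric(0))
  peaks <- peaks[order(-peaks$T), ]
  structure(list(t = tstat, peaks = peaks, threshold = t_threshold,
                 degenerate = which(degenerate), grid = grid),
            class = "group_map")
}

#' @export
glance.gica_fit <- function(x, ...) {
  tibble::tibble(K = x$K, explained = x$explained,
                 min_stability = if (all(is.na(x$stability))) NA_real_
                 else min(x$stability),
                 n_pc = x$reduction$n_pc)
}

#' @export
tidy.gica_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K),
                 stability = x$stability,
                 map_max = apply(x$maps, 1, max),
                 map_min = apply(x$maps, 1, min))
}

#' Plot group-ICA component time courses by condition
#'
#' @param fit A `gica_fit`.
#' @param components Components to show (default all).
#' @return A ggplot object: mean time course per condition, one facet
#'   per component.
#' @export
plot_component_timecourses <- function(fit, components = seq_len(fit$K)) {
  tc <- fit$tc[fit$tc$component %in% components, ]
  agg <- stats::aggregate(value ~ condition + component + time, tc, mean)
  ggplot2::ggplot(agg, ggplot2::aes(.data$time * 1000, .data$value,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "component amplitude (a.u.)")
}
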