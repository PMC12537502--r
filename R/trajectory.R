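# Motif deviation scores, pseudotime interpolation to a fixed grid,
# dynamic time warping, and the conserved/shift-early classification of
# motif trajectories between species.

#' Per-cell motif deviation z-scores
#'
#' For motif m and cell j: observed X = insertions in m-containing peaks,
#' expected E = depth_j * (global fraction of insertions in m-peaks), raw
#' deviation (X - E) / E. The z-score compares the raw deviation against
#' `n_bg` background peak sets matched on accessibility decile.
#'
#' @param counts peak x cell count matrix (sparse ok).
#' @param motif_mat logical peak x motif matrix (shared peak index).
#' @param n_bg background sets (default 50).
#' @param seed integer seed.
#' @return motif x cell matrix of deviation z-scores; motifs with zero
#'   peaks are dropped.
#' @export
motif_deviation <- function(counts, motif_mat, n_bg = 50L, seed = 1L) {
  set.seed(seed)
  counts <- methods::as(counts, "CsparseMatrix")
  motif_mat <- as.matrix(motif_mat) > 0
  keep <- colSums(motif_mat) > 0
  motif_mat <- motif_mat[, keep, drop = FALSE]
  depth <- Matrix::colSums(counts)
  total <- sum(depth)
  peak_tot <- Matrix::rowSums(counts)
  frac <- peak_tot / total
  # accessibility deciles for background matching
  decile <- cut(rank(peak_tot, ties.method = "first"),
                breaks = 10, labels = FALSE)
  raw_dev <- function(sel) {
    X <- Matrix::colSums(counts[sel, , drop = FALSE])
    E <- depth * sum(frac[sel])
    E[E == 0] <- 1
    (X - E) / E
  }
  out <- matrix(NA_real_, ncol(motif_mat), ncol(counts),
                dimnames = list(colnames(motif_mat), colnames(counts)))
  for (m in seq_len(ncol(motif_mat))) {
    sel <- which(motif_mat[, m])
    obs <- raw_dev(sel)
    bg <- matrix(0, n_bg, ncol(counts))
    tab <- table(decile[sel])
    for (b in seq_len(n_bg)) {
      bg_sel <- unlist(lapply(names(tab), function(d) {
        pool <- which(decile == as.integer(d))
        sample(pool, tab[[d]], replace = length(pool) < tab[[d]])
      }))
      bg[b, ] <- raw_dev(bg_sel)
    }
    mu <- colMeans(bg)
    sdv <- apply(bg, 2, sd)
    sdv[sdv == 0] <- 1
    out[m, ] <- (obs - mu) / sdv
  }
  out
}

#' Interpolate deviation curves to a fixed pseudotime grid and z-scale
#'
#' Gaussian-kernel weighted mean of each motif's per-cell deviations at
#' `n_points` evenly spaced grid points over the pseudotime range, then
#' per-motif z-scaling (mean 0, SD 1) across the grid. Grid points with an
#' empty kernel window fall back to the nearest cell.
#'
#' @param dev motif x cell deviation matrix.
#' @param pseudotime per-cell pseudotime.
#' @param n_points grid size (default 200).
#' @param bandwidth kernel SD as a fraction of the pseudotime range
#'   (default 0.1).
#' @return motif x n_points matrix of z-scaled curves.
#' @export
interpolate_scale <- function(dev, pseudotime, n_points = 200L,
                              bandwidth = 0.1) {
  stopifnot(ncol(dev) == length(pseudotime), length(pseudotime) >= 10)
  rng <- range(pseudotime)
  if (diff(rng) == 0) stop("pseudotime spread is zero")
  grid <- seq(rng[1], rng[2], length.out = n_points)
  h <- bandwidth * diff(rng)
  W <- outer(grid, pseudotime, function(g, t) exp(-((g - t)^2) / (2 * h^2)))
  wsum <- rowSums(W)
  empty <- wsum < 1e-12
  if (any(empty)) {
    for (i in which(empty)) {
      j <- which.min(abs(pseudotime - grid[i]))
      W[i, ] <- 0
      W[i, j] <- 1
    }
    wsum <- rowSums(W)
  }
  W <- W / wsum
  curves <- dev %*% t(W)
  mu <- rowMeans(curves)
  sdv <- apply(curves, 1, sd)
  # constant curves (numerically flat) z-scale to zero, not amplified noise
  flat <- sdv <= 1e-9 * pmax(1, abs(mu))
  sdv[flat] <- Inf
  out <- sweep(sweep(curves, 1, mu, "-"), 1, sdv, "/")
  out[flat, ] <- 0
  out
}

#' Dynamic time warping distance between two curves
#'
#' Classic DTW with Euclidean (absolute-difference) local cost and a
#' boundary-anchored monotone path. The distance is the summed path cost
#' divided by sqrt(G) (G = number of features aligned jointly; 1 for a
#' single motif pair). Also returns the path lag: the mean of
#' indexA - indexB along the path, weighted by the local signal change
#' |dA| + |dB| so that flat plateau stretches (where the warping path is
#' uninformative) do not dilute it. Negative lag means curve A's features
#' occur at lower grid indices, i.e. A leads.
#'
#' @param a,b numeric curves of equal length.
#' @param G feature count for the sqrt normalization (default 1).
#' @return list: distance, lag, path (two-column matrix of indices).
#' @export
dtw_distance <- function(a, b, G = 1L) {
  stopifnot(length(a) == length(b))
  if (anyNA(a) || anyNA(b)) stop("NaN/NA in curves")
  n <- length(a)
  cost <- abs(outer(a, b, "-"))
  D <- matrix(Inf, n + 1L, n + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i + 1, j + 1] <- cost[i, j] +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # traceback
  path <- list()
  i <- n; j <- n
  while (i >= 1 && j >= 1) {
    path[[length(path) + 1L]] <- c(i, j)
    steps <- c(D[i, j], D[i, j + 1], D[i + 1, j])
    k <- which.min(steps)
    if (i == 1 && j == 1) break
    if (k == 1) { i <- i - 1; j <- j - 1 }
    else if (k == 2) i <- i - 1
    else j <- j - 1
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("a", "b")
  da <- c(0, abs(diff(a)))
  db <- c(0, abs(diff(b)))
  w <- da[path[, 1]] + db[path[, 2]]
  lag <- if (sum(w) > 0) {
    sum(w * (path[, 1] - path[, 2])) / sum(w)
  } else {
    mean(path[, 1] - path[, 2])
  }
  list(distance = D[n + 1, n + 1] / sqrt(G), lag = lag, path = path)
}

#' Classify motif trajectory pairs as conserved / shift-early / unknown
#'
#' DTW distances between the two species' interpolated curves are
#' clustered with k-means (k = 2); the higher-mean cluster is the "high"
#' distance group. Per motif, the difference curve
#' delta(t) = devA(t) - devB(t) is regressed on grid pseudotime with a
#' quadratic term (the difference of two time-shifted sigmoids is a bump,
#' so a pure linear slope has no power against it); the regression F-test
#' p-values are BH-adjusted over motifs and gate the shift labels:
#' high-group motifs with q > `alpha` are `unknown`, otherwise labelled
#' `shiftEarlyA` when species A leads and `shiftEarlyB` otherwise. The
#' lead direction is the sign of the grid shift that maximizes the
#' cross-correlation between the two curves (the DTW path lag, reported
#' alongside, is dominated by plateau stretches of the warping path and
#' is too noisy to fix the direction reliably). Low-group motifs are `conserved` when the two
#' species' own linear slopes share a sign (the conserved call does not
#' require a significant difference curve), else labelled by lag when
#' significant and `unknown` when not.
#'
#' @param curves_a,curves_b motif x grid matrices (same motifs and grid).
#' @param k clusters for the distance split (default 2).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return data.frame: motif, distance, group, lag (DTW path lag), shift
#'   (cross-correlation grid shift; positive = A leads), slope_a,
#'   slope_b, slope_delta, p, q, label.
#' @export
classify_shift <- function(curves_a, curves_b, k = 2L, alpha = 0.05) {
  stopifnot(nrow(curves_a) == nrow(curves_b),
            ncol(curves_a) == ncol(curves_b), nrow(curves_a) >= 2)
  motifs <- rownames(curves_a)
  n <- nrow(curves_a)
  grid <- seq(0, 1, length.out = ncol(curves_a))
  dist <- numeric(n)
  lag <- numeric(n)
  cshift <- numeric(n)
  for (m in seq_len(n)) {
    d <- dtw_distance(curves_a[m, ], curves_b[m, ])
    dist[m] <- d$distance
    lag[m] <- d$lag
    cshift[m] <- .best_shift(curves_a[m, ], curves_b[m, ])
  }
  if (length(unique(round(dist, 12))) < 2) {
    group <- rep("low", n)
  } else {
    km <- kmeans(dist, centers = 2L, nstart = 5L)
    hi <- which.max(km$centers)
    group <- ifelse(km$cluster == hi, "high", "low")
  }
  slope_a <- numeric(n)
  slope_b <- numeric(n)
  slope_d <- numeric(n)
  p <- numeric(n)
  for (m in seq_len(n)) {
    slope_a[m] <- coef(lm(curves_a[m, ] ~ grid))[2]
    slope_b[m] <- coef(lm(curves_b[m, ] ~ grid))[2]
    delta <- curves_a[m, ] - curves_b[m, ]
    fit <- lm(delta ~ grid + I(grid^2))
    sm <- summary(fit)
    slope_d[m] <- sm$coefficients[2, 1]
    fstat <- sm$fstatistic
    p[m] <- if (is.null(fstat)) 1 else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  q <- p.adjust(p, method = "BH")
  label <- character(n)
  for (m in seq_len(n)) {
    if (group[m] == "low" && sign(slope_a[m]) == sign(slope_b[m])) {
      label[m] <- "conserved"
    } else if (q[m] > alpha) {
      label[m] <- "unknown"
    } else {
      label[m] <- if (cshift[m] > 0) "shiftEarlyA" else "shiftEarlyB"
    }
  }
  data.frame(motif = motifs, distance = dist, group = group, lag = lag,
             shift = cshift, slope_a = slope_a, slope_b = slope_b,
             slope_delta = slope_d, p = p, q = q, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

# grid shift s maximizing cor(a[i], b[i + s]); positive s means curve A's
# features occur earlier (A leads). Ties go to the smallest |s|.
.best_shift <- function(a, b, max_shift = floor(length(a) / 3)) {
  n <- length(a)
  best_s <- 0L
  best_r <- -Inf
  for (s in seq(-max_shift, max_shift)) {
    ia <- if (s >= 0) 1:(n - s) else (1 - s):n
    ib <- if (s >= 0) (1 + s):n else 1:(n + s)
    if (sd(a[ia]) == 0 || sd(b[ib]) == 0) next
    r <- cor(a[ia], b[ib])
    if (r > best_r + 1e-12 ||
          (abs(r - best_r) <= 1e-12 && abs(s) < abs(best_s))) {
      best_r <- r
      best_s <- s
    }
  }
  best_s
}

#' Correlation between TF gene accessibility and cognate motif deviation
#'
#' Pearson r across cells (or cell types) between each TF's accessibility
#' vector and its motif's deviation vector; zero-variance vectors are
#' skipped.
#'
#' @param tf_acc TF x cell accessibility (or expression) matrix.
#' @param dev motif x cell deviation matrix (same columns).
#' @param tf_map data.frame (tf, motif) mapping TFs to motifs.
#' @return list: `table` (tf, motif, r) and `frac_positive`.
#' @export
tf_motif_correlation <- function(tf_acc, dev, tf_map) {
  rows <- list()
  for (i in seq_len(nrow(tf_map))) {
    tf <- tf_map$tf[i]
    mo <- tf_map$motif[i]
    if (!tf %in% rownames(tf_acc) || !mo %in% rownames(dev)) next
    x <- tf_acc[tf, ]
    y <- dev[mo, ]
    if (sd(x) == 0 || sd(y) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(tf = tf, motif = mo,
                                            r = cor(x, y),
                                            stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), motif = character(0), r = numeric(0))
  list(table = tab, frac_positive = if (nrow(tab)) mean(tab$r > 0) else
    NA_real_)
}
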