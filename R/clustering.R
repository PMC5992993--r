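# Polarity-invariant (modified) K-means microstate segmentation.
# Clustering operates on the normalized topographies at GFP peaks only;
# each cluster is represented by the dominant eigenvector of the sum of
# outer products of its member topographies, so map polarity is ignored.

normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero topography")
  maps / nrm
}

#' Electrode-corrected cross-validation criterion
#'
#' The residual-variance criterion minimized across K-means runs,
#' `CV = sigma2 * ((n_ch - 1) / (n_ch - 1 - n_maps))^2`, where `sigma2` is
#' the mean residual variance of the polarity-invariant fit. The second
#' factor penalizes model size relative to the number of electrodes.
#'
#' @param residual_variance Mean residual variance `sigma2 >= 0`.
#' @param n_ch Number of electrodes; must exceed `n_maps + 1`.
#' @param n_maps Number of microstate maps.
#' @return The CV value (same units as `residual_variance`).
#' @export
cv_criterion <- function(residual_variance, n_ch, n_maps) {
  if (n_ch <= n_maps + 1) stop("cv_criterion requires n_ch > n_maps + 1")
  if (residual_variance < 0) stop("residual variance must be non-negative")
  residual_variance * ((n_ch - 1) / (n_ch - 1 - n_maps))^2
}

#' Competitive back-fitting of microstate maps
#'
#' Assigns every time sample the label of the map with the largest squared
#' spatial correlation to the (average-referenced) topography. Polarity is
#' ignored: a sample equal to `-maps[k, ]` also receives label `k`. Ties
#' are broken in favor of the lowest map index.
#'
#' @param maps Numeric matrix `(n_maps, n_ch)` of topographies.
#' @param data Numeric matrix `(n_t, n_ch)` or an [eeg_record()].
#' @return Integer label vector of length `n_t`, values in
#'   `0 .. n_maps - 1`.
#' @export
backfit_labels <- function(maps, data) {
  if (inherits(data, "eeg_record")) data <- data$data
  maps <- as.matrix(maps)
  if (ncol(maps) != ncol(data)) {
    stop("maps and data must have the same number of channels")
  }
  xc <- average_reference(data)
  m <- normalize_maps(maps)
  scores <- (xc %*% t(m))^2
  as.integer(max.col(scores, ties.method = "first") - 1L)
}

#' Global explained variance per microstate map
#'
#' `gev[k]` is the GFP-squared-weighted mean squared spatial correlation
#' between each sample assigned to map `k` and that map, normalized by the
#' total GFP-squared mass, so that `sum(gev)` is the total fraction of
#' (GFP-weighted) variance explained by the segmentation.
#'
#' @param maps Numeric matrix `(n_maps, n_ch)`.
#' @param data Numeric matrix `(n_t, n_ch)` or an [eeg_record()].
#' @param labels Integer labels in `0 .. n_maps - 1`, length `n_t`.
#' @return Numeric vector of length `n_maps`; entries in `[0, 1]`.
#' @export
global_explained_variance <- function(maps, data, labels) {
  if (inherits(data, "eeg_record")) data <- data$data
  maps <- as.matrix(maps)
  xc <- average_reference(data)
  if (length(labels) != nrow(xc)) stop("labels must have one entry per sample")
  denom <- sum(xc^2)
  if (denom == 0) stop("zero total GFP: cannot compute explained variance")
  m <- normalize_maps(maps)
  proj <- (xc %*% t(m))[cbind(seq_len(nrow(xc)), labels + 1L)]
  num <- vapply(seq_len(nrow(maps)), function(k) {
    sum(proj[labels == (k - 1L)]^2)
  }, numeric(1))
  num / denom
}

#' Modified K-means microstate segmentation
#'
#' Clusters the average-referenced EEG topographies at GFP-peak samples
#' with the polarity-invariant K-means algorithm: samples are assigned by
#' maximum squared spatial correlation, and each cluster's map is updated
#' to the dominant eigenvector of the sum of outer products of its member
#' topographies. Each run iterates until the relative change in explained
#' variance falls below `maxerr` (or `maxiter` is reached); `n_runs`
#' restarts from random GFP-peak initializations are performed and the run
#' minimizing the cross-validation criterion is returned. The full-length
#' label sequence is obtained by back-fitting every sample.
#'
#' @param record An [eeg_record()] (band-pass filter beforehand if wanted).
#' @param n_maps Number of microstate maps (any integer `>= 2`); default 4.
#' @param n_runs Number of random restarts; default 10.
#' @param maxerr Relative explained-variance convergence tolerance;
#'   default `1e-6`.
#' @param maxiter Maximum iterations per run; default 500.
#' @param seed Optional integer seed for reproducible restarts.
#' @return A `microstate_segmentation` object: list with `maps`
#'   (`(n_maps, n_ch)`, zero-mean unit-norm rows), `labels` (0-based,
#'   length `n_t`), `gfp_peaks`, `gev` (per map), `cv` (minimum across
#'   runs), `fs`, plus the configuration.
#' @examples
#' \donttest{
#' maps <- matrix(rnorm(4 * 10), 4, 10)
#' maps <- (maps - rowMeans(maps)) / sqrt(rowSums(maps^2))
#' lab <- rep(0:3, each = 50)
#' x <- maps[lab + 1, ] * abs(sin(seq_len(200) / 3))
#' seg <- modified_kmeans(eeg_record(x, fs = 100), n_maps = 4, seed = 1)
#' sum(seg$gev)
#' }
#' @export
modified_kmeans <- function(record, n_maps = 4L, n_runs = 10L,
                            maxerr = 1e-6, maxiter = 500L, seed = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  n_maps <- as.integer(n_maps)
  if (n_maps < 2L) stop("`n_maps` must be an integer >= 2")
  if (n_runs < 1L || maxiter < 1L || maxerr <= 0) {
    stop("invalid K-means configuration")
  }
  data <- average_reference(record$data)
  n_ch <- ncol(data)
  if (n_ch <= n_maps + 1L) stop("need n_ch > n_maps + 1 for the CV criterion")
  g <- gfp(data)
  peaks <- find_gfp_peaks(g)
  if (length(peaks) < n_maps) {
    stop("fewer GFP peaks (", length(peaks), ") than requested maps")
  }
  X <- data[peaks, , drop = FALSE]
  V <- normalize_maps(X)
  n_peaks <- nrow(V)
  sumX2 <- sum(X^2)

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (run in seq_len(n_runs)) {
    maps <- V[sample.int(n_peaks, n_maps), , drop = FALSE]
    ev_old <- -Inf
    for (it in seq_len(maxiter)) {
      sc <- (V %*% t(maps))^2
      lab <- max.col(sc, ties.method = "first")
      for (k in seq_len(n_maps)) {
        members <- which(lab == k)
        if (length(members) == 0L) {           # dead cluster: reseed
          maps[k, ] <- V[sample.int(n_peaks, 1L), ]
          next
        }
        S <- crossprod(V[members, , drop = FALSE])
        maps[k, ] <- eigen(S, symmetric = TRUE)$vectors[, 1L]
      }
      maps <- maps / sqrt(rowSums(maps^2))
      ev <- mean(apply((V %*% t(maps))^2, 1L, max))
      if (is.finite(ev_old) &&
          abs(ev - ev_old) / max(ev, .Machine$double.eps) < maxerr) break
      ev_old <- ev
    }
    lab <- max.col((V %*% t(maps))^2, ties.method = "first")
    proj <- (X %*% t(maps))[cbind(seq_len(n_peaks), lab)]
    sigma2 <- max((sumX2 - sum(proj^2)) / (n_peaks * (n_ch - 1)), 0)
    cv <- cv_criterion(sigma2, n_ch, n_maps)
    if (is.null(best) || cv < best$cv) {
      best <- list(maps = maps, cv = cv)
    }
  }

  labels <- backfit_labels(best$maps, data)
  gev <- global_explained_variance(best$maps, data, labels)
  maps <- best$maps
  colnames(maps) <- record$channel_names
  structure(
    list(maps = maps, labels = labels, gfp_peaks = peaks, gev = gev,
         cv = best$cv, fs = record$fs, n_maps = n_maps, n_runs = n_runs,
         maxerr = maxerr, maxiter = maxiter, seed = seed),
    class = "microstate_segmentation"
  )
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf(
    "<microstate_segmentation> %d maps, %d samples, %d GFP peaks\n",
    x$n_maps, length(x$labels), length(x$gfp_peaks)
  ))
  cat(sprintf("  total GEV = %.3f, CV = %.4g\n", sum(x$gev), x$cv))
  cat("  per-map GEV:", paste(sprintf("%.3f", x$gev), collapse = " "), "\n")
  invisible(x)
}

#' Reorder microstate maps
#'
#' Applies a permutation to a segmentation: map rows, per-map GEV, and all
#' labels are permuted consistently, so back-fitting the reordered maps
#' reproduces the permuted labels.
#'
#' @param result A `microstate_segmentation`.
#' @param permutation Integer vector of length `n_maps`: a bijection on
#'   `0 .. n_maps - 1`, giving the new index of each current map.
#' @return The reordered `microstate_segmentation`.
#' @export
reorder_maps <- function(result, permutation) {
  stopifnot(inherits(result, "microstate_segmentation"))
  p <- as.integer(permutation)
  n <- result$n_maps
  if (length(p) != n || !identical(sort(p), 0:(n - 1L))) {
    stop("`permutation` must be a bijection on 0..n_maps-1")
  }
  inv <- order(p)                         # inv[new + 1] = old + 1
  result$maps <- result$maps[inv, , drop = FALSE]
  result$gev <- result$gev[inv]
  result$labels <- p[result$labels + 1L]
  result
}

#' Match maps against reference topographies
#'
#' Greedy assignment of clustered maps to reference maps (for example
#' [template_maps()]) by maximal absolute spatial correlation, for
#' non-interactive canonical A-D ordering.
#'
#' @param maps Numeric matrix `(n_maps, n_ch)`.
#' @param reference Numeric matrix with the same number of columns and at
#'   least `n_maps` rows.
#' @return 0-based permutation suitable for [reorder_maps()]: entry `i + 1`
#'   is the reference index assigned to map `i`.
#' @export
match_maps <- function(maps, reference) {
  m <- normalize_maps(as.matrix(maps))
  r <- normalize_maps(as.matrix(reference))
  if (ncol(m) != ncol(r)) stop("maps and reference differ in channel count")
  if (nrow(r) < nrow(m)) stop("reference has fewer maps than `maps`")
  cc <- abs(m %*% t(r))
  perm <- integer(nrow(m))
  for (step in seq_len(nrow(m))) {
    ij <- arrayInd(which.max(cc), dim(cc))
    perm[ij[1L]] <- ij[2L] - 1L
    cc[ij[1L], ] <- -Inf
    cc[, ij[2L]] <- -Inf
  }
  perm
}
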