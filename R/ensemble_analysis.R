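# Ensemble-level summaries: superposition to the average structure, RMSd
# series, cluster representatives, equipartition stiffness constants and
# series correlations.

# Boltzmann constant in kcal/mol/K, normalised so kB * 298 K = 0.593 kcal/mol
# (the conventional room-temperature thermal energy used for the stiffness
# constants; 0.13% from the CODATA value, far inside sampling error).
.kB <- 0.593 / 298

# xyz row (3N) <-> n x 3 matrix helpers
.row2mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
.mat2row <- function(m) as.vector(t(m))

# superpose matrix y (n x 3) onto ref (n x 3); returns fitted coords + rmsd
.superpose <- function(y, ref) {
  fit <- kabsch(y, ref)
  list(coords = sweep(tcrossprod(y, fit$R), 2L, fit$t, "+"), rmsd = fit$rmsd)
}

#' Average structure and RMSd series
#'
#' Iteratively superposes every frame onto the running mean structure until
#' the mean moves by less than \code{tol} (max atom displacement), then
#' reports the per-frame RMSd after optimal rigid superposition onto the
#' converged average.
#'
#' @param traj a \code{dna_trajectory}.
#' @param selection optional logical/integer index over atoms (rows of the
#'   topology) restricting the superposition; default all atoms.
#' @param tol convergence tolerance on the mean structure (A, default 1e-6).
#' @param max_iter iteration cap (default 50).
#' @return object of class \code{ensemble_summary}: \code{average} (n x 3
#'   coordinates), \code{rmsd} series (A), \code{iterations}.
#' @export
rmsd_and_average <- function(traj, selection = NULL, tol = 1e-6,
                             max_iter = 50L) {
  stopifnot(inherits(traj, "dna_trajectory"))
  n_frames <- nrow(traj$xyz)
  if (n_frames < 2L) stop("need at least 2 frames to average")
  mats <- lapply(seq_len(n_frames), function(f) .row2mat(traj$xyz[f, ]))
  if (!is.null(selection)) mats <- lapply(mats, function(m) m[selection, , drop = FALSE])
  mean_m <- mats[[1L]]
  iters <- 0L
  repeat {
    iters <- iters + 1L
    fitted <- lapply(mats, function(m) .superpose(m, mean_m)$coords)
    new_mean <- Reduce(`+`, fitted) / n_frames
    shift <- max(sqrt(rowSums((new_mean - mean_m)^2)))
    mean_m <- new_mean
    if (shift < tol || iters >= max_iter) break
  }
  rmsd <- vapply(mats, function(m) .superpose(m, mean_m)$rmsd, 0)
  structure(list(average = mean_m, rmsd = rmsd, iterations = iters),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble average over %d frames: RMSd %.2f +/- %.2f A (%d iterations)\n",
              length(x$rmsd), mean(x$rmsd), stats::sd(x$rmsd), x$iterations))
  invisible(x)
}

#' Pairwise RMSd matrix
#'
#' RMSd after optimal rigid superposition for every frame pair.
#'
#' @param traj a \code{dna_trajectory}.
#' @param selection optional atom selection.
#' @return symmetric matrix of RMSd values (A).
#' @export
pairwise_rmsd <- function(traj, selection = NULL) {
  n_frames <- nrow(traj$xyz)
  mats <- lapply(seq_len(n_frames), function(f) .row2mat(traj$xyz[f, ]))
  if (!is.null(selection)) mats <- lapply(mats, function(m) m[selection, , drop = FALSE])
  d <- matrix(0, n_frames, n_frames)
  for (i in seq_len(n_frames - 1L)) for (j in (i + 1L):n_frames)
    d[i, j] <- d[j, i] <- kabsch(mats[[i]], mats[[j]])$rmsd
  d
}

#' Main-cluster representative snapshot
#'
#' Average-linkage agglomerative clustering of the pairwise-RMSd matrix cut
#' at \code{cutoff}; the representative is the medoid (minimum summed RMSd)
#' of the largest cluster. Ties on cluster size go to the cluster holding
#' the lowest frame index; ties on the medoid go to the lowest frame index.
#'
#' @param traj a \code{dna_trajectory}.
#' @param cutoff RMSd height at which the dendrogram is cut (A).
#' @param selection optional atom selection.
#' @return list with \code{representative} (frame index), \code{labels}
#'   (cluster id per frame) and \code{cluster_sizes}.
#' @export
cluster_representative <- function(traj, cutoff, selection = NULL) {
  n_frames <- nrow(traj$xyz)
  if (n_frames == 0L) stop("empty trajectory")
  if (n_frames == 1L)
    return(list(representative = 1L, labels = 1L, cluster_sizes = 1L))
  d <- pairwise_rmsd(traj, selection)
  if (max(d) < 1e-9)                      # all frames identical
    return(list(representative = 1L, labels = rep(1L, n_frames),
                cluster_sizes = n_frames))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hc$height <- cummax(hc$height)          # guard against fp non-monotonicity
  labels <- stats::cutree(hc, h = cutoff)
  sizes <- table(labels)
  big <- max(sizes)
  cand <- as.integer(names(sizes)[sizes == big])
  first_member <- vapply(cand, function(k) min(which(labels == k)), 0L)
  main <- cand[which.min(first_member)]
  members <- which(labels == main)
  ss <- rowSums(d[members, members, drop = FALSE])
  rep_frame <- members[which.min(ss)]       # which.min takes the first tie
  list(representative = rep_frame, labels = labels,
       cluster_sizes = as.integer(sizes))
}

#' Equipartition stiffness constants
#'
#' Harmonic force constants from thermal fluctuations: k = kB T / Var(x),
#' with kB T = 0.593 kcal/mol at 298 K. Applied to the global helical bend
#' (deg), the lesion-pair opening (deg) and the central minor groove width
#' (A), giving constants in kcal/mol/deg^2 and kcal/mol/A^2. A constant
#' series is flagged as infinitely stiff.
#'
#' @param bend,opening,minw numeric fluctuation series (any may be NULL).
#' @param temperature Kelvin (default 298).
#' @return object of class \code{stiffness_set}: per-series k, variance,
#'   and an \code{infinite} flag.
#' @export
stiffness_constants <- function(bend = NULL, opening = NULL, minw = NULL,
                                temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive")
  kBT <- .kB * temperature
  one <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) < 2L) stop("series too short")
    v <- stats::var(x)
    list(k = if (v == 0) Inf else kBT / v, variance = v, n = length(x),
         infinite = v == 0)
  }
  structure(list(k_bend = one(bend), k_opening = one(opening),
                 k_minW = one(minw), temperature = temperature, kBT = kBT),
            class = "stiffness_set")
}

#' @export
print.stiffness_set <- function(x, ...) {
  fmt <- function(nm, s, unit) if (!is.null(s))
    cat(sprintf("  %-10s k = %8.4f kcal/mol/%s^2  (var %.3f)\n", nm, s$k, unit,
                s$variance))
  cat("stiffness constants at", x$temperature, "K:\n")
  fmt("bend", x$k_bend, "deg"); fmt("opening", x$k_opening, "deg")
  fmt("minW", x$k_minW, "A")
  invisible(x)
}

# Fisher-Lee circular correlation (computational O(n) form)
.circ_cor <- function(a, b) {
  a <- .rad(a); b <- .rad(b)
  n <- length(a)
  A <- sum(cos(a) * cos(b)); B <- sum(sin(a) * sin(b))
  C <- sum(cos(a) * sin(b)); D <- sum(sin(a) * cos(b))
  E <- sum(cos(2 * a)); FF <- sum(sin(2 * a))
  G <- sum(cos(2 * b)); H <- sum(sin(2 * b))
  den <- sqrt((n^2 - E^2 - FF^2) * (n^2 - G^2 - H^2))
  if (den == 0) return(NA_real_)
  4 * (A * B - C * D) / den
}

# Mardia circular-linear association in [0, 1]
.circ_lin_cor <- function(theta, x) {
  theta <- .rad(theta)
  rxc <- stats::cor(x, cos(theta)); rxs <- stats::cor(x, sin(theta))
  rcs <- stats::cor(cos(theta), sin(theta))
  if (anyNA(c(rxc, rxs, rcs)) || abs(rcs) >= 1) return(NA_real_)
  sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
}

#' Correlation matrix over named series
#'
#' Pearson correlation for linear series; Fisher-Lee circular correlation
#' when both series are angle-flagged; Mardia circular-linear association
#' (non-negative) for mixed pairs. Zero-variance series give NA entries.
#'
#' @param series named list of equal-length numeric vectors (n >= 3).
#' @param circular logical vector (recycled) flagging angular series
#'   (degrees).
#' @return correlation matrix with a \code{circular} attribute.
#' @export
series_correlations <- function(series, circular = FALSE) {
  stopifnot(is.list(series), length(series) >= 1L)
  n <- unique(vapply(series, length, 0L))
  if (length(n) != 1L) stop("series must have equal lengths")
  if (n < 3L) stop("need n >= 3")
  circular <- rep_len(circular, length(series))
  k <- length(series)
  out <- matrix(NA_real_, k, k, dimnames = list(names(series), names(series)))
  for (i in seq_len(k)) for (j in i:k) {
    x <- series[[i]]; y <- series[[j]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out[i, j] <- out[j, i] <- if (i == j) 1 else NA_real_
      next
    }
    r <- if (circular[i] && circular[j]) .circ_cor(x, y)
    else if (!circular[i] && !circular[j]) stats::cor(x, y)
    else if (circular[i]) .circ_lin_cor(x, y)
    else .circ_lin_cor(y, x)
    out[i, j] <- out[j, i] <- r
  }
  attr(out, "circular") <- circular
  out
}
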