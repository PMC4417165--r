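# Independent oracles and fixture builders used across the suite.

# Horn's closed-form quaternion superposition: an algorithmically independent
# check on the SVD-based Kabsch fit (largest eigenvalue of the 4x4 profile
# matrix gives the optimal rotation).
horn_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  M <- crossprod(xc, yc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

# Brute-force per-frame scan of a breathing series: walk the frames, collect
# open runs, drop runs shorter than min_frames, then count everything
# directly (no run-length encoding).
brute_breathing <- function(opening, threshold, min_frames, reference) {
  open_raw <- abs(opening - reference) > threshold
  n <- length(open_raw)
  runs <- list(); start <- NA
  for (f in seq_len(n)) {
    if (open_raw[f] && is.na(start)) start <- f
    if ((!open_raw[f] || f == n) && !is.na(start)) {
      end <- if (open_raw[f]) f else f - 1L
      if (end - start + 1L >= min_frames) runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  lens <- vapply(runs, function(r) r[2] - r[1] + 1L, 0L)
  list(occupancy_pct = 100 * sum(lens) / n,
       n_transitions = length(runs),
       mean_residence = if (length(lens)) mean(lens) else 0,
       max_residence = if (length(lens)) max(lens) else 0)
}

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rand_table <- function(n_pairs = 13, t_max = 3, r_max = 60, rise_min = 0.5) {
  intra <- cbind(matrix(runif(n_pairs * 3, -t_max, t_max), n_pairs),
                 matrix(runif(n_pairs * 3, -r_max, r_max), n_pairs))
  inter <- cbind(matrix(runif((n_pairs - 1) * 2, -t_max, t_max), n_pairs - 1),
                 runif(n_pairs - 1, rise_min, max(t_max, rise_min + 0.8)),
                 matrix(runif((n_pairs - 1) * 3, -r_max, r_max), n_pairs - 1))
  chi <- matrix(runif(2 * n_pairs, -170, 170), n_pairs)
  parameter_table(n_pairs, intra, inter, chi)
}

# wrap a list of dna_structure snapshots (same topology) into a trajectory
structures_as_traj <- function(structs, seq) {
  xyz <- do.call(rbind, lapply(structs, function(s) as.vector(t(s$coords))))
  structure(list(topology = structs[[1]]$topology, xyz = xyz,
                 ions = replicate(length(structs), matrix(numeric(0), 0, 3),
                                  simplify = FALSE),
                 seq = seq),
            class = "dna_trajectory")
}

# duplex with a given intra-parameter vector planted at the lesion pair
build_with_mm_intra <- function(seq, intra_mm, n_pairs = seq$n_pairs) {
  intra <- matrix(0, n_pairs, 6)
  intra[seq$mm_position, ] <- intra_mm
  build_duplex(seq, parameter_table(n_pairs, intra = intra))
}
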