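# Groove geometry and cation atmosphere mapping.

.P_RADIUS_CORR <- 5.8   # two phosphate van der Waals radii, Angstrom

#' Minor and major groove width profile
#'
#' Cross-strand P-P minimum-distance convention: at pair i the minor groove
#' width is the minimum distance between the Watson P of pair i and the
#' Crick P of pairs i-2 and i-3, minus 5.8 A of phosphate radius (floored at
#' 0); the major groove uses the window i+2..i+3. Positions whose window
#' does not fit inside the duplex are reported as NA, never zero-filled.
#'
#' @param struct a \code{dna_structure} with P (pseudo-)atoms on both
#'   strands.
#' @param offsets integer offsets of the cross-strand window (default 2:3).
#' @return data frame (class \code{groove_profile}) with columns
#'   \code{position} (relative, lesion = 0), \code{minor}, \code{major}
#'   (Angstrom; NA where undefined); the method tag is carried in the
#'   \code{method} attribute.
#' @export
groove_width_profile <- function(struct, offsets = 2:3) {
  stopifnot(inherits(struct, "dna_structure"))
  topo <- struct$topology
  n <- struct$seq$n_pairs
  pw_i <- which(topo$chain == "A" & topo$atom == "P")
  pc_i <- which(topo$chain == "B" & topo$atom == "P")
  if (length(pw_i) != n || length(pc_i) != n) stop("missing P atoms")
  Pw <- struct$coords[pw_i[order(topo$resno[pw_i])], , drop = FALSE]
  Pc_res <- struct$coords[pc_i[order(topo$resno[pc_i])], , drop = FALSE]
  Pc <- Pc_res[n:1, , drop = FALSE]        # row i = Crick P of pair i
  width_at <- function(i, js) {
    js <- js[js >= 1L & js <= n]
    if (length(js) < length(offsets)) return(NA_real_)
    d <- min(sqrt(rowSums(sweep(Pc[js, , drop = FALSE], 2L, Pw[i, ])^2)))
    max(d - .P_RADIUS_CORR, 0)
  }
  minor <- vapply(seq_len(n), function(i) width_at(i, i - offsets), 0)
  major <- vapply(seq_len(n), function(i) width_at(i, i + offsets), 0)
  out <- data.frame(position = seq_len(n) - struct$seq$mm_position,
                    minor = minor, major = major)
  attr(out, "method") <- sprintf("cross-strand P-P minimum, offsets %s, -%.1f A",
                                 paste(offsets, collapse = "/"), .P_RADIUS_CORR)
  class(out) <- c("groove_profile", "data.frame")
  out
}

#' Cylindrical cation density map
#'
#' Accumulates per-frame cation positions in radial x angular bins of a slab
#' centred on the plane of a chosen base pair. The cylindrical system is the
#' pair's own frame: z along the local helix axis, theta = 0 at the pair's x
#' axis (the major-groove centre direction). Counts convert to molarity via
#' the factor 6.022e-4 ions per cubic Angstrom per molar, so the sum of
#' molarity x bin volume x 6.022e-4 over bins equals the mean in-slab ion
#' count per frame exactly.
#'
#' @param traj a \code{dna_trajectory} whose \code{ions} field holds one
#'   coordinate matrix per frame (lab coordinates).
#' @param center_position absolute pair index defining the slab (default:
#'   lesion position).
#' @param r_max,dr radial extent and bin width (A; defaults 16 and 0.5).
#' @param dtheta angular bin width (deg; default 10).
#' @param z_half slab half-thickness (A; default 1.7, about half a rise).
#' @return object of class \code{ion_density_map}: \code{molarity} matrix
#'   (radial x angular), bin edges, slab half-thickness, \code{counts} and
#'   \code{n_frames}.
#' @export
ion_density_map <- function(traj, center_position = NULL, r_max = 16,
                            dr = 0.5, dtheta = 10, z_half = 1.7) {
  stopifnot(inherits(traj, "dna_trajectory"))
  n_frames <- nrow(traj$xyz)
  if (n_frames == 0L) stop("no frames")
  if (dr <= 0 || dtheta <= 0 || z_half <= 0) stop("zero-volume bins")
  if (is.null(center_position)) center_position <- traj$seq$mm_position
  r_edges <- seq(0, r_max, by = dr)
  t_edges <- seq(0, 360, by = dtheta)
  nr <- length(r_edges) - 1L; nt <- length(t_edges) - 1L
  counts <- matrix(0, nr, nt)
  topo <- traj$topology
  n <- traj$seq$n_pairs
  idx <- .residue_index(topo, n)
  for (f in seq_len(n_frames)) {
    ions <- traj$ions[[f]]
    if (is.null(ions) || nrow(ions) == 0L) next
    coords <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    i <- center_position
    aw <- coords[idx$w[[i]], , drop = FALSE]; rownames(aw) <- idx$w_names[[i]]
    ac <- coords[idx$c[[i]], , drop = FALSE]; rownames(ac) <- idx$c_names[[i]]
    pf <- intra_bp_params(fit_base_frame(aw, idx$w_base[i]),
                          fit_base_frame(ac, idx$c_base[i]))$pair_frame
    loc <- sweep(ions, 2L, pf$origin) %*% pf$rotation
    keep <- abs(loc[, 3L]) <= z_half
    if (!any(keep)) next
    r <- sqrt(loc[keep, 1L]^2 + loc[keep, 2L]^2)
    th <- (.deg(atan2(loc[keep, 2L], loc[keep, 1L]))) %% 360
    ri <- findInterval(r, r_edges, rightmost.closed = TRUE)
    ti <- findInterval(th, t_edges, rightmost.closed = TRUE)
    ok <- ri >= 1L & ri <= nr
    for (k in which(ok)) counts[ri[k], ti[k]] <- counts[ri[k], ti[k]] + 1
  }
  vol <- outer(diff(r_edges^2), diff(.rad(t_edges)) / 2) * (2 * z_half)
  molarity <- counts / (n_frames * vol * .MOLAR_CONV)
  structure(list(molarity = molarity, counts = counts,
                 r_edges = r_edges, theta_edges = t_edges,
                 z_half = z_half, bin_volumes = vol, n_frames = n_frames,
                 center_position = center_position),
            class = "ion_density_map")
}

#' @export
print.ion_density_map <- function(x, ...) {
  cat(sprintf("ion density map: %d x %d bins, %d frames, mean %.3f M, max %.3f M\n",
              nrow(x$molarity), ncol(x$molarity), x$n_frames,
              mean(x$molarity), max(x$molarity)))
  invisible(x)
}

#' Mean in-slab ion count per frame implied by a density map
#'
#' Exact inverse of the molarity conversion; equals the accumulated count
#' divided by the frame count.
#'
#' @param map an \code{ion_density_map}.
#' @return mean ion count per frame.
#' @export
map_mean_count <- function(map) {
  sum(map$molarity * map$bin_volumes * .MOLAR_CONV)
}
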