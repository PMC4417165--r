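# Base reference frames and mid-frame (CEHS-style) helical parameter
# decomposition. The builder in synthetic_duplex.R uses the exact inverse of
# the decomposition implemented here, which gives the round-trip contract:
# analysing a built structure reproduces every planted parameter to numerical
# tolerance. No claim is made of matching any particular published tool's
# numbers; the scheme (symmetric split about the mean frame) is the standard
# mid-frame construction.

new_base_frame <- function(origin, rotation, rms_fit = 0) {
  stopifnot(length(origin) == 3L, all(dim(rotation) == c(3L, 3L)))
  structure(list(origin = as.numeric(origin), rotation = rotation,
                 rms_fit = rms_fit),
            class = "base_frame")
}

#' @export
print.base_frame <- function(x, ...) {
  cat("base frame: origin", sprintf("%.3f", x$origin),
      " rms_fit", sprintf("%.4f", x$rms_fit), "\n")
  invisible(x)
}

.check_frame <- function(f) {
  R <- f$rotation
  if (max(abs(crossprod(R) - diag(3L))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("frame rotation is not a proper orthonormal matrix")
  invisible(f)
}

#' Fit a base reference frame
#'
#' Least-squares rigid superposition of the idealized planar base geometry
#' onto observed atom coordinates. Only the planar base atoms are matched
#' (sugar/backbone pseudo-atoms are ignored), so the frame is insensitive to
#' the glycosidic torsion.
#'
#' @param atoms matrix of observed coordinates with atom names as rownames,
#'   or a data frame with columns \code{atom, x, y, z}.
#' @param base_type one of "A", "C", "G", "T".
#' @return a \code{base_frame}: origin, 3x3 rotation (columns are the base
#'   x/y/z axes in lab coordinates), and the fit RMS in Angstrom.
#' @export
fit_base_frame <- function(atoms, base_type) {
  ref <- standard_base(base_type)
  if (is.data.frame(atoms)) {
    m <- as.matrix(atoms[, c("x", "y", "z")])
    rownames(m) <- atoms$atom
    atoms <- m
  }
  want <- intersect(.frame_atoms(base_type), rownames(atoms))
  if (length(want) < 3L)
    stop("need at least 3 matched base atoms to fit a frame for ", base_type)
  fit <- kabsch(ref[want, , drop = FALSE], atoms[want, , drop = FALSE])
  new_base_frame(origin = fit$t, rotation = fit$R, rms_fit = fit$rmsd)
}

# ---- symmetric mid-frame decomposition ------------------------------------
# Shared by the intra-pair and the inter-pair (step) parameter sets. Given
# two frames it returns three translations (displacement of frame2 relative
# to frame1 expressed in the mid-frame) and three rotations (deg): the
# RollTilt magnitude split by the hinge phase plus the twist-like angle about
# the mean z axis.

frame_decompose <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3L]; z2 <- R2[, 3L]
  cr <- .cross(z1, z2)
  s <- sqrt(sum(cr * cr))
  gamma <- atan2(s, sum(z1 * z2))
  hinge <- if (s < 1e-12) R1[, 2L] else cr / s
  R1p <- rot_axis(hinge, gamma / 2) %*% R1
  R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  zm <- R1p[, 3L]
  y1 <- R1p[, 2L]; y2 <- R2p[, 2L]
  omega <- atan2(sum(.cross(y1, y2) * zm), sum(y1 * y2))
  ym <- drop(rot_axis(zm, omega / 2) %*% y1)
  xm <- .cross(ym, zm)
  Rm <- cbind(xm, ym, zm, deparse.level = 0)
  phi <- atan2(sum(.cross(hinge, ym) * zm), sum(hinge * ym))
  om <- (o1 + o2) / 2
  trans <- drop(crossprod(Rm, o2 - o1))
  list(trans = trans,
       rot = c(.deg(gamma * sin(phi)),   # tilt-like (about mid x)
               .deg(gamma * cos(phi)),   # roll-like (about mid y)
               .deg(omega)),             # twist-like (about mid z)
       Rm = Rm, om = om)
}

# Exact inverse of frame_decompose: place frame2 relative to frame1 from the
# six parameters (translations in Angstrom, rotations in degrees).
frame_compose <- function(R1, o1, par) {
  tl <- .rad(par[4L]); rl <- .rad(par[5L]); tw <- .rad(par[6L])
  gamma <- sqrt(tl^2 + rl^2)
  phi <- atan2(tl, rl)
  h <- c(sin(phi), cos(phi), 0)          # hinge axis in mid-frame coords
  A <- rot_axis(h, -gamma / 2) %*% rot_z(-tw / 2)
  B <- rot_axis(h, gamma / 2) %*% rot_z(tw / 2)
  Rm <- R1 %*% t(A)
  R2 <- Rm %*% B
  o2 <- o1 + drop(Rm %*% par[1:3])
  list(R2 = R2, o2 = o2, Rm = Rm, om = (o1 + o2) / 2)
}

#' Intra-base-pair helical parameters
#'
#' Six-parameter rigid decomposition of a base pair relative to its
#' mid-frame: shear, stretch, stagger (Angstrom) and buckle, propeller,
#' opening (degrees). The Crick frame is flipped 180 degrees about its x
#' axis before pairing, per convention, and the decomposition runs from the
#' flipped Crick frame to the Watson frame.
#'
#' @param frame_w,frame_c \code{base_frame}s of the Watson and Crick bases.
#' @return list with \code{params} (named numeric length 6) and
#'   \code{pair_frame} (\code{base_frame} of the pair mid-frame).
#' @export
intra_bp_params <- function(frame_w, frame_c) {
  .check_frame(frame_w); .check_frame(frame_c)
  Rc <- frame_c$rotation %*% .flip_x
  d <- frame_decompose(Rc, frame_c$origin, frame_w$rotation, frame_w$origin)
  params <- c(shear = d$trans[1L], stretch = d$trans[2L], stagger = d$trans[3L],
              buckle = d$rot[1L], propeller = d$rot[2L], opening = d$rot[3L])
  list(params = params,
       pair_frame = new_base_frame(d$om, d$Rm,
                                   rms_fit = max(frame_w$rms_fit, frame_c$rms_fit)))
}

#' Inter-base-pair (step) helical parameters
#'
#' Six-parameter mid-frame decomposition between consecutive pair frames:
#' shift, slide, rise (Angstrom) and tilt, roll, twist (degrees).
#'
#' @param pair_frame_i,pair_frame_j \code{base_frame}s of pairs i and i+1.
#' @return list with \code{params} (named numeric length 6) and
#'   \code{step_frame} (mid-step frame; its z column is the local helix axis).
#' @export
inter_bp_params <- function(pair_frame_i, pair_frame_j) {
  .check_frame(pair_frame_i); .check_frame(pair_frame_j)
  d <- frame_decompose(pair_frame_i$rotation, pair_frame_i$origin,
                       pair_frame_j$rotation, pair_frame_j$origin)
  params <- c(shift = d$trans[1L], slide = d$trans[2L], rise = d$trans[3L],
              tilt = d$rot[1L], roll = d$rot[2L], twist = d$rot[3L])
  list(params = params, step_frame = new_base_frame(d$om, d$Rm))
}

# ---- glycosidic torsion ----------------------------------------------------

.chi_bins <- function(chi) {
  ifelse(chi > 120 | chi <= -90, "anti",
         ifelse(chi <= -30, "high-anti",
                ifelse(chi <= 90, "syn", "other")))
}

#' Glycosidic torsion state
#'
#' Computes the signed chi dihedral O4'-C1'-N9-C4 (purines) or
#' O4'-C1'-N1-C2 (pyrimidines) and classifies the conformer with the
#' declared bins: anti (120, 180] and (-180, -90]; high-anti (-90, -30];
#' syn (-30, 90]; other (90, 120].
#'
#' @param atoms named coordinate matrix (or data frame with
#'   \code{atom,x,y,z}) for one nucleotide.
#' @param base_type one of "A", "C", "G", "T".
#' @return list \code{chi} (degrees) and \code{conformer}.
#' @export
chi_state <- function(atoms, base_type) {
  if (is.data.frame(atoms)) {
    m <- as.matrix(atoms[, c("x", "y", "z")])
    rownames(m) <- atoms$atom
    atoms <- m
  }
  need <- c("O4'", "C1'", .glyco_n(base_type), .chi_ref(base_type))
  if (!all(need %in% rownames(atoms)))
    stop("missing chi atoms: ", paste(setdiff(need, rownames(atoms)), collapse = ", "))
  chi <- dihedral(atoms[need[1L], ], atoms[need[2L], ],
                  atoms[need[3L], ], atoms[need[4L], ])
  list(chi = chi, conformer = .chi_bins(chi))
}

#' Classify a chi angle into its conformer bin
#' @param chi glycosidic torsion(s) in degrees, in (-180, 180].
#' @return character vector of conformers.
#' @export
chi_conformer <- function(chi) .chi_bins(wrap_angle(chi))

# ---- global descriptors ----------------------------------------------------

# bend angle between terminal three-step windows of local helix axes
# (columns of `axes`); NA when the duplex is too short for the two windows
.bend_from_axes <- function(axes, step_range, window = 3L) {
  usable <- setdiff(step_range, range(step_range))
  if (length(usable) < 2L * window) return(NA_real_)
  keep <- match(usable, step_range)
  sub <- axes[, step_range, drop = FALSE]
  z_head <- .normalize(rowMeans(sub[, keep[seq_len(window)], drop = FALSE]))
  z_tail <- .normalize(rowMeans(sub[, keep[seq(length(keep) - window + 1L,
                                               length(keep))], drop = FALSE]))
  .deg(acos(.clamp1(sum(z_head * z_tail))))
}

#' Global helical descriptors of one snapshot
#'
#' Helical bend is the angle between the mean local helix axes (mid-step z
#' vectors) of two terminal three-step windows; the outermost step at each
#' end is excluded to avoid end fraying. Total twist is the sum of the step
#' twists over \code{step_range}.
#'
#' @param pair_frames list of pair \code{base_frame}s for one snapshot, 5' to
#'   3' on the Watson strand.
#' @param step_range integer vector of step indices to include (step i joins
#'   pairs i and i+1); default all steps.
#' @param window number of steps in each terminal window (default 3).
#' @return list with \code{helical_bend} (deg, in [0, 180]),
#'   \code{total_twist} (deg) and \code{step_range}.
#' @export
global_descriptors <- function(pair_frames, step_range = NULL, window = 3L) {
  n_pairs <- length(pair_frames)
  if (n_pairs < 4L) stop("need at least 4 pairs")
  n_steps <- n_pairs - 1L
  if (is.null(step_range)) step_range <- seq_len(n_steps)
  stopifnot(all(step_range >= 1L), all(step_range <= n_steps))
  axes <- matrix(NA_real_, 3L, n_steps)
  total_twist <- 0
  for (i in step_range) {
    st <- inter_bp_params(pair_frames[[i]], pair_frames[[i + 1L]])
    axes[, i] <- st$step_frame$rotation[, 3L]
    total_twist <- total_twist + st$params[["twist"]]
  }
  bend <- .bend_from_axes(axes, step_range, window = window)
  if (is.na(bend)) stop("too few steps for the two terminal windows")
  list(helical_bend = bend, total_twist = total_twist, step_range = step_range)
}

# ---- trajectory driver -----------------------------------------------------

# Fit base frames for every residue of one frame of a trajectory.
# Returns list(w = list of frames for Watson residues 1..N (5'->3'),
#              c = list of frames for Crick residues indexed by PAIR,
#              chi_w, chi_c numeric vectors, rms matrix)
.fit_frame_set <- function(coords, topo, idx) {
  n <- length(idx$w)
  fw <- vector("list", n); fc <- vector("list", n)
  chi_w <- numeric(n); chi_c <- numeric(n)
  for (i in seq_len(n)) {
    aw <- coords[idx$w[[i]], , drop = FALSE]
    rownames(aw) <- idx$w_names[[i]]
    ac <- coords[idx$c[[i]], , drop = FALSE]
    rownames(ac) <- idx$c_names[[i]]
    fw[[i]] <- fit_base_frame(aw, idx$w_base[i])
    fc[[i]] <- fit_base_frame(ac, idx$c_base[i])
    chi_w[i] <- chi_state(aw, idx$w_base[i])$chi
    chi_c[i] <- chi_state(ac, idx$c_base[i])$chi
  }
  list(w = fw, c = fc, chi_w = chi_w, chi_c = chi_c)
}

# Precompute residue -> atom-row indices for a trajectory topology.
# Crick entries are stored in PAIR order (pair i <-> Crick residue N+1-i).
.residue_index <- function(topo, n_pairs) {
  idx <- list(w = vector("list", n_pairs), c = vector("list", n_pairs),
              w_names = vector("list", n_pairs), c_names = vector("list", n_pairs),
              w_base = character(n_pairs), c_base = character(n_pairs))
  for (i in seq_len(n_pairs)) {
    wi <- which(topo$chain == "A" & topo$resno == i)
    ci <- which(topo$chain == "B" & topo$resno == (n_pairs + 1L - i))
    idx$w[[i]] <- wi; idx$c[[i]] <- ci
    idx$w_names[[i]] <- topo$atom[wi]; idx$c_names[[i]] <- topo$atom[ci]
    idx$w_base[i] <- topo$base[wi[1L]]; idx$c_base[i] <- topo$base[ci[1L]]
  }
  idx
}

#' Analyse a duplex trajectory
#'
#' Batch driver: fits base frames for every residue of every frame and
#' assembles tidy per-frame series of intra-pair parameters, step parameters,
#' chi states and global descriptors, plus per-position means and SDs.
#' Positions are reported in relative coordinates with the duplex centre
#' (lesion position) at 0; a step keeps the relative coordinate of its 5'
#' pair.
#'
#' @param traj a \code{dna_trajectory} (see \code{\link{sample_trajectory}}
#'   or \code{\link{read_trajectory_pdb}}).
#' @param step_range step range forwarded to \code{\link{global_descriptors}}.
#' @return object of class \code{duplex_analysis}: list with tidy data frames
#'   \code{intra}, \code{inter}, \code{chi}, \code{globals}, a \code{summary}
#'   list of per-position statistics, and \code{pair_frames} for the last
#'   frame analysed.
#' @export
analyze_trajectory <- function(traj, step_range = NULL) {
  stopifnot(inherits(traj, "dna_trajectory"))
  topo <- traj$topology
  n_pairs <- max(topo$resno[topo$chain == "A"])
  idx <- .residue_index(topo, n_pairs)
  n_frames <- nrow(traj$xyz)
  rel <- seq_len(n_pairs) - (n_pairs + 1L) %/% 2L
  intra_names <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
  inter_names <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  intra_arr <- array(NA_real_, c(n_frames, n_pairs, 6L),
                     dimnames = list(NULL, NULL, intra_names))
  inter_arr <- array(NA_real_, c(n_frames, n_pairs - 1L, 6L),
                     dimnames = list(NULL, NULL, inter_names))
  chi_arr <- array(NA_real_, c(n_frames, n_pairs, 2L),
                   dimnames = list(NULL, NULL, c("W", "C")))
  bend <- rep(NA_real_, n_frames); twist_tot <- numeric(n_frames)
  pf_last <- NULL
  sr <- if (is.null(step_range)) seq_len(n_pairs - 1L) else step_range
  for (f in seq_len(n_frames)) {
    coords <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    fs <- .fit_frame_set(coords, topo, idx)
    pf <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      dec <- intra_bp_params(fs$w[[i]], fs$c[[i]])
      intra_arr[f, i, ] <- dec$params
      pf[[i]] <- dec$pair_frame
    }
    axes <- matrix(NA_real_, 3L, n_pairs - 1L)
    for (i in seq_len(n_pairs - 1L)) {
      st <- inter_bp_params(pf[[i]], pf[[i + 1L]])
      inter_arr[f, i, ] <- st$params
      axes[, i] <- st$step_frame$rotation[, 3L]
    }
    chi_arr[f, , 1L] <- fs$chi_w
    chi_arr[f, , 2L] <- fs$chi_c
    twist_tot[f] <- sum(inter_arr[f, sr, "twist"])
    bend[f] <- .bend_from_axes(axes, sr)
    pf_last <- pf
  }
  tidy <- function(arr, positions, kind) {
    d <- dim(arr)
    data.frame(
      frame = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
      position = rep(rep(positions, each = d[1L]), times = d[3L]),
      parameter = rep(dimnames(arr)[[3L]], each = d[1L] * d[2L]),
      value = as.vector(arr),
      kind = kind,
      stringsAsFactors = FALSE)
  }
  intra_df <- tidy(intra_arr, rel, "intra")
  inter_df <- tidy(inter_arr, rel[-n_pairs], "inter")
  chi_df <- data.frame(
    frame = rep(seq_len(n_frames), times = 2L * n_pairs),
    position = rep(rep(rel, each = n_frames), times = 2L),
    strand = rep(c("W", "C"), each = n_frames * n_pairs),
    chi = as.vector(chi_arr),
    stringsAsFactors = FALSE)
  chi_df$conformer <- chi_conformer(chi_df$chi)
  summarise <- function(df) {
    agg_m <- stats::aggregate(value ~ position + parameter, df, mean)
    agg_s <- stats::aggregate(value ~ position + parameter, df, stats::sd)
    names(agg_m)[3L] <- "mean"; agg_m$sd <- agg_s$value
    agg_m[order(agg_m$parameter, agg_m$position), ]
  }
  structure(list(
    intra = intra_df, inter = inter_df, chi = chi_df,
    globals = data.frame(frame = seq_len(n_frames), helical_bend = bend,
                         total_twist = twist_tot),
    summary = list(intra = summarise(intra_df), inter = summarise(inter_df)),
    n_pairs = n_pairs, positions = rel,
    pair_frames = pf_last
  ), class = "duplex_analysis")
}

#' @export
print.duplex_analysis <- function(x, ...) {
  cat("duplex ensemble analysis:", max(x$intra$frame), "frames,",
      x$n_pairs, "pairs\n")
  cat(sprintf("  helical bend  %.2f +/- %.2f deg\n",
              mean(x$globals$helical_bend), stats::sd(x$globals$helical_bend)))
  cat(sprintf("  total twist   %.2f +/- %.2f deg\n",
              mean(x$globals$total_twist), stats::sd(x$globals$total_twist)))
  invisible(x)
}
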