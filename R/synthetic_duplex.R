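# Synthetic duplex builder and ensemble generator. Stands in for fiber-model
# construction plus MD sampling: every structure is built from an explicit
# table of helical parameters, so the ground truth of any ensemble is known
# exactly and every downstream analysis can be validated against it.

# ions / A^3 per molar: 6.022e23 / 1e27
.MOLAR_CONV <- 6.022e-4

.environments <- c(f1 = "CCATACXATACGG",
                   f2 = "CCAATTXAATTGG",
                   r  = "CCCAGTXCTTTGG")

#' Duplex sequence with an optional central lesion
#'
#' @param watson Watson strand, 5' to 3', over A/C/G/T.
#' @param crick Crick strand, 5' to 3' of the complementary strand; defaults
#'   to the reverse complement of \code{watson}.
#' @param mm_position absolute (1-based) Watson index of the lesion pair;
#'   defaults to the central position.
#' @return object of class \code{duplex_sequence} with fields \code{watson},
#'   \code{crick}, \code{mm_position} (absolute) and \code{n_pairs}. The
#'   relative coordinate of pair i is \code{i - mm_position} (lesion = 0).
#' @export
duplex_sequence <- function(watson, crick = NULL, mm_position = NULL) {
  wb <- strsplit(toupper(watson), "")[[1L]]
  if (!all(wb %in% names(.complement)))
    stop("watson strand must be over A/C/G/T")
  n <- length(wb)
  if (n < 2L) stop("need at least 2 pairs")
  if (is.null(crick)) {
    cb <- unname(rev(.complement[wb]))
  } else {
    cb <- strsplit(toupper(crick), "")[[1L]]
    if (length(cb) != n) stop("strand lengths differ")
    if (!all(cb %in% names(.complement)))
      stop("crick strand must be over A/C/G/T")
  }
  if (is.null(mm_position)) mm_position <- (n + 1L) %/% 2L
  # every pair except mm_position must be Watson-Crick
  partner <- rev(cb)                      # partner[i] pairs watson[i]
  wc_ok <- partner == .complement[wb]
  bad <- which(!wc_ok)
  if (length(setdiff(bad, mm_position)) > 0L)
    stop("non-complementary pair outside mm_position at Watson index ",
         paste(setdiff(bad, mm_position), collapse = ", "))
  structure(list(watson = paste(wb, collapse = ""),
                 crick = paste(cb, collapse = ""),
                 watson_bases = wb, crick_bases = cb,
                 mm_position = as.integer(mm_position), n_pairs = n),
            class = "duplex_sequence")
}

#' @export
print.duplex_sequence <- function(x, ...) {
  cat("5'-", x$watson, "-3'\n", sep = "")
  cat("3'-", paste(rev(x$crick_bases), collapse = ""), "-5'",
      "   lesion pair ", x$mm_position, " (",
      x$watson_bases[x$mm_position], "·",
      rev(x$crick_bases)[x$mm_position], ")\n", sep = "")
  invisible(x)
}

#' Bases of the pair at a given position
#' @param seq a \code{duplex_sequence}.
#' @param i absolute pair index (default: lesion position).
#' @return character vector \code{c(watson, crick)} bases of the pair.
#' @export
pair_bases <- function(seq, i = seq$mm_position) {
  c(seq$watson_bases[i], rev(seq$crick_bases)[i])
}

#' 13-mer duplex for one of the three study environments
#'
#' The three 13-mer containers: two flexible, d(CCATACXATACGG) ("f1") and
#' d(CCAATTXAATTGG) ("f2"), and one rigid, d(CCCAGTXCTTTGG) ("r"). X marks
#' the central (lesion) position; the Watson X and its Crick partner are set
#' independently so any of the 12 mismatches or the 4 canonical controls can
#' be planted.
#'
#' @param environment one of "f1", "f2", "r".
#' @param watson_base base replacing X on the Watson strand.
#' @param crick_base base placed opposite X on the Crick strand.
#' @return a \code{duplex_sequence}.
#' @export
sequence_for <- function(environment, watson_base, crick_base) {
  if (!environment %in% names(.environments))
    stop("unknown environment '", environment, "' (use f1, f2 or r)")
  watson_base <- match.arg(watson_base, c("A", "C", "G", "T"))
  crick_base <- match.arg(crick_base, c("A", "C", "G", "T"))
  wb <- strsplit(.environments[[environment]], "")[[1L]]
  center <- which(wb == "X")
  wb[center] <- watson_base
  cb <- unname(rev(.complement[wb]))
  cb[length(cb) + 1L - center] <- crick_base
  duplex_sequence(paste(wb, collapse = ""), paste(cb, collapse = ""),
                  mm_position = center)
}

# ---- parameter tables ------------------------------------------------------

.intra_names <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
.inter_names <- c("shift", "slide", "rise", "tilt", "roll", "twist")

#' Helical parameter table
#'
#' Per-pair intra parameters, per-step inter parameters and per-nucleotide
#' chi targets that fully determine a built duplex.
#'
#' @param n_pairs number of base pairs (>= 2).
#' @param intra N x 6 matrix (shear, stretch, stagger, buckle, propeller,
#'   opening); a length-6 vector is recycled across pairs.
#' @param inter (N-1) x 6 matrix (shift, slide, rise, tilt, roll, twist);
#'   a length-6 vector is recycled across steps.
#' @param chi N x 2 matrix of glycosidic torsions (columns W, C; degrees);
#'   a scalar is recycled.
#' @return object of class \code{parameter_table}.
#' @export
parameter_table <- function(n_pairs,
                            intra = rep(0, 6),
                            inter = c(0, 0, 3.38, 0, 0, 36),
                            chi = -117) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  expand <- function(x, nr, nm) {
    if (is.null(dim(x))) x <- matrix(x, nr, length(nm), byrow = TRUE)
    if (!all(dim(x) == c(nr, length(nm)))) stop("malformed table dimensions")
    colnames(x) <- nm
    x
  }
  intra <- expand(intra, n_pairs, .intra_names)
  inter <- expand(inter, n_pairs - 1L, .inter_names)
  if (length(chi) == 1L) chi <- matrix(chi, n_pairs, 2L)
  if (!all(dim(chi) == c(n_pairs, 2L))) stop("malformed chi dimensions")
  colnames(chi) <- c("W", "C")
  ang <- c(intra[, 4:6], inter[, 4:6], chi)
  if (any(ang <= -180 | ang > 180)) stop("angles must lie in (-180, 180]")
  if (any(inter[, "rise"] <= 0)) stop("rise must be positive for a B-like build")
  structure(list(n_pairs = n_pairs, intra = intra, inter = inter, chi = chi),
            class = "parameter_table")
}

# ---- structure builder -----------------------------------------------------

# topology of a built duplex (atom bookkeeping only); memoised per sequence
.topo_cache <- new.env(parent = emptyenv())

.duplex_topology <- function(seq) {
  key <- paste(seq$watson, seq$crick)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  res_atoms <- function(base) c(rownames(.base_coords[[base]]), "O4'", "P")
  rows <- list(); k <- 0L
  for (i in seq_len(seq$n_pairs)) {
    b <- seq$watson_bases[i]; a <- res_atoms(b); k <- k + 1L
    rows[[k]] <- data.frame(chain = "A", resno = i, base = b, atom = a,
                            stringsAsFactors = FALSE)
  }
  for (r in seq_len(seq$n_pairs)) {
    b <- seq$crick_bases[r]; a <- res_atoms(b); k <- k + 1L
    rows[[k]] <- data.frame(chain = "B", resno = r, base = b, atom = a,
                            stringsAsFactors = FALSE)
  }
  topo <- do.call(rbind, rows)
  rownames(topo) <- NULL
  .topo_cache[[key]] <- topo
  topo
}

# place Watson/Crick base frames of one pair from its mid-frame + intra params
.pair_place <- function(Rm, om, par) {
  bk <- .rad(par[4L]); pr <- .rad(par[5L]); op <- .rad(par[6L])
  gamma <- sqrt(bk^2 + pr^2)
  phi <- atan2(bk, pr)
  h <- c(sin(phi), cos(phi), 0)
  A <- rot_axis(h, -gamma / 2) %*% rot_z(-op / 2)   # flipped Crick side
  B <- rot_axis(h, gamma / 2) %*% rot_z(op / 2)     # Watson side
  half <- drop(Rm %*% par[1:3]) / 2
  list(Rw = Rm %*% B, ow = om + half,
       Rc = Rm %*% A %*% .flip_x, oc = om - half)
}

# atoms of one nucleotide given its base frame; O4' realises the chi target
.nucleotide_atoms <- function(base, R, o, chi) {
  local <- .base_coords[[base]]
  lab <- sweep(tcrossprod(local, R), 2L, o, "+")    # local %*% t(R) + o
  rownames(lab) <- rownames(local)
  p <- o + drop(R %*% .p_offset)
  nglc <- lab[.glyco_n(base), ]
  cref <- lab[.chi_ref(base), ]
  c1p <- lab["C1'", ]
  o4p <- place_atom_zmat(cref, nglc, c1p, r = 1.45, theta = 108, chi = chi)
  rbind(lab, "O4'" = o4p, "P" = p)
}

#' Build a reduced-atom duplex from a parameter table
#'
#' Places pair mid-frames by chaining the step parameters from the first
#' pair, splits each pair into Watson and Crick base frames with the intra
#' parameters (exact inverse of the analyser's mid-frame decomposition), and
#' instantiates the idealized base atoms, C1', a pseudo-O4' realising the
#' requested chi, and a fiber-B phosphate pseudo-atom per nucleotide.
#' Re-analysing the built structure reproduces the table exactly.
#'
#' @param seq a \code{duplex_sequence}.
#' @param table a \code{parameter_table} dimensioned for \code{seq}.
#' @return object of class \code{dna_structure}: \code{topology} data frame
#'   (chain, resno, base, atom) and \code{coords} (n_atoms x 3, Angstrom).
#'   Chain A is Watson (residues 1..N, 5' to 3'), chain B is Crick
#'   (residues 1..N, 5' to 3'); pair i joins A:i with B:(N+1-i).
#' @export
build_duplex <- function(seq, table) {
  stopifnot(inherits(seq, "duplex_sequence"), inherits(table, "parameter_table"))
  n <- seq$n_pairs
  if (table$n_pairs != n) stop("table dimensioned for ", table$n_pairs,
                               " pairs but sequence has ", n)
  if (any(table$inter[, "rise"] <= 0)) stop("rise must be positive")
  # chain pair frames
  Rm <- diag(3L); om <- c(0, 0, 0)
  pf <- vector("list", n)
  pf[[1L]] <- list(Rm = Rm, om = om)
  for (i in seq_len(n - 1L)) {
    nxt <- frame_compose(pf[[i]]$Rm, pf[[i]]$om, table$inter[i, ])
    pf[[i + 1L]] <- list(Rm = nxt$R2, om = nxt$o2)
  }
  w_atoms <- vector("list", n); c_atoms <- vector("list", n)
  for (i in seq_len(n)) {
    pl <- .pair_place(pf[[i]]$Rm, pf[[i]]$om, table$intra[i, ])
    wb <- seq$watson_bases[i]
    cb <- rev(seq$crick_bases)[i]
    w_atoms[[i]] <- .nucleotide_atoms(wb, pl$Rw, pl$ow, table$chi[i, "W"])
    c_atoms[[i]] <- .nucleotide_atoms(cb, pl$Rc, pl$oc, table$chi[i, "C"])
  }
  xyz <- do.call(rbind, c(w_atoms, c_atoms[n:1]))  # chain A 5'->3', then B 5'->3'
  rownames(xyz) <- NULL
  structure(list(topology = .duplex_topology(seq), coords = xyz, seq = seq),
            class = "dna_structure")
}

#' @export
print.dna_structure <- function(x, ...) {
  cat("reduced-atom duplex:", x$seq$n_pairs, "pairs,",
      nrow(x$coords), "atoms\n")
  invisible(x)
}

#' Analyse a single structure
#'
#' Convenience wrapper: fits all base frames of one \code{dna_structure} and
#' returns intra/inter parameter matrices, chi values and pair frames.
#'
#' @param struct a \code{dna_structure}.
#' @return list with matrices \code{intra} (N x 6), \code{inter} ((N-1) x 6),
#'   \code{chi} (N x 2) and the list of pair \code{base_frame}s.
#' @export
analyze_structure <- function(struct) {
  stopifnot(inherits(struct, "dna_structure"))
  traj <- .structure_as_traj(struct)
  topo <- traj$topology
  n <- max(topo$resno[topo$chain == "A"])
  idx <- .residue_index(topo, n)
  fs <- .fit_frame_set(struct$coords, topo, idx)
  intra <- matrix(NA_real_, n, 6L, dimnames = list(NULL, .intra_names))
  pfs <- vector("list", n)
  for (i in seq_len(n)) {
    dec <- intra_bp_params(fs$w[[i]], fs$c[[i]])
    intra[i, ] <- dec$params
    pfs[[i]] <- dec$pair_frame
  }
  inter <- matrix(NA_real_, n - 1L, 6L, dimnames = list(NULL, .inter_names))
  for (i in seq_len(n - 1L))
    inter[i, ] <- inter_bp_params(pfs[[i]], pfs[[i + 1L]])$params
  list(intra = intra, inter = inter,
       chi = cbind(W = fs$chi_w, C = fs$chi_c), pair_frames = pfs)
}

.structure_as_traj <- function(struct) {
  structure(list(topology = struct$topology,
                 xyz = matrix(t(struct$coords), nrow = 1L),
                 ions = list(matrix(numeric(0), 0L, 3L)),
                 seq = struct$seq),
            class = "dna_trajectory")
}

# ---- ensemble specification and sampling -----------------------------------

#' Ensemble specification
#'
#' Defines a synthetic conformational ensemble: a mean parameter table, a
#' fluctuation model (independent per-coordinate SDs or a full covariance of
#' the stacked parameter vector), planted breathing excursions, and an
#' optional ion atmosphere of known molarity.
#'
#' @param seq a \code{duplex_sequence}.
#' @param table mean \code{parameter_table} (default: straight fiber-like
#'   B helix, rise 3.38 A, twist 36 deg, chi -117 deg).
#' @param sds list with optional entries \code{intra} (length 6, per intra
#'   parameter), \code{inter} (length 6), \code{chi} (scalar); SDs of
#'   independent Gaussian fluctuations, recycled across positions. Zero =
#'   frozen coordinate.
#' @param covariance optional full covariance matrix of the stacked parameter
#'   vector (order: intra pair-major, then inter step-major, then chi W 1..N
#'   followed by chi C 1..N); overrides \code{sds}. Must be symmetric
#'   positive semidefinite.
#' @param n_frames number of snapshots.
#' @param seed master RNG seed; identical specs with identical seeds give
#'   bit-identical ensembles.
#' @param planted_breathing data frame with columns \code{pair} (relative
#'   coordinate, lesion = 0), \code{start}, \code{end} (frame window,
#'   1-based inclusive), \code{amplitude} (deg) and \code{direction}
#'   ("major" or "minor"). Within the window the opening of the target pair
#'   is overridden by mean + signed amplitude (major positive).
#' @param ion_spec either \code{list(type = "uniform", molarity, r_min,
#'   r_max, z_half)} (cylindrical shell around the central pair) or
#'   \code{list(type = "field", molarity, r_edges, theta_edges, z_half)}
#'   with a radial x angular molarity matrix.
#' @return object of class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(seq, table = NULL, sds = list(), covariance = NULL,
                          n_frames = 100L, seed = 1L,
                          planted_breathing = NULL, ion_spec = NULL) {
  stopifnot(inherits(seq, "duplex_sequence"))
  if (is.null(table)) table <- parameter_table(seq$n_pairs)
  if (table$n_pairs != seq$n_pairs) stop("table does not match sequence length")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (!is.null(planted_breathing)) {
    pb <- as.data.frame(planted_breathing)
    need <- c("pair", "start", "end", "amplitude", "direction")
    if (!all(need %in% names(pb))) stop("planted_breathing needs columns ",
                                        paste(need, collapse = ", "))
    if (any(pb$start < 1L | pb$end > n_frames | pb$start > pb$end))
      stop("planted breathing windows must lie within [1, n_frames]")
    if (!all(pb$direction %in% c("major", "minor")))
      stop("breathing direction must be 'major' or 'minor'")
    planted_breathing <- pb
  }
  if (!is.null(covariance)) {
    d <- .stack_dim(seq$n_pairs)
    if (!all(dim(covariance) == c(d, d))) stop("covariance must be ", d, " x ", d)
    if (max(abs(covariance - t(covariance))) > 1e-8)
      stop("covariance must be symmetric")
  }
  if (!is.null(ion_spec)) .validate_ion_spec(ion_spec)
  structure(list(seq = seq, table = table, sds = sds, covariance = covariance,
                 n_frames = n_frames, seed = as.integer(seed),
                 planted_breathing = planted_breathing, ion_spec = ion_spec),
            class = "ensemble_spec")
}

.stack_dim <- function(n) 6L * n + 6L * (n - 1L) + 2L * n

.validate_ion_spec <- function(spec) {
  if (identical(spec$type, "uniform")) {
    if (is.null(spec$r_max) || !is.finite(spec$r_max) ||
        is.null(spec$z_half) || !is.finite(spec$z_half))
      stop("uniform ion field needs finite r_max and z_half")
    if (spec$molarity < 0) stop("molarity must be >= 0")
  } else if (identical(spec$type, "field")) {
    m <- spec$molarity
    if (any(m < 0)) stop("molarity must be >= 0")
    if (length(spec$r_edges) != nrow(m) + 1L ||
        length(spec$theta_edges) != ncol(m) + 1L)
      stop("field bin edges do not match the molarity matrix")
    if (!is.finite(spec$z_half)) stop("field needs finite z_half")
  } else stop("ion_spec$type must be 'uniform' or 'field'")
  invisible(spec)
}

# stacked mean vector and its unstacking
.stack_table <- function(table) {
  c(as.vector(t(table$intra)), as.vector(t(table$inter)), table$chi[, "W"],
    table$chi[, "C"])
}

.unstack_table <- function(v, n) {
  i6 <- 6L * n
  intra <- matrix(v[seq_len(i6)], n, 6L, byrow = TRUE,
                  dimnames = list(NULL, .intra_names))
  inter <- matrix(v[i6 + seq_len(6L * (n - 1L))], n - 1L, 6L, byrow = TRUE,
                  dimnames = list(NULL, .inter_names))
  chi <- cbind(W = v[i6 + 6L * (n - 1L) + seq_len(n)],
               C = v[i6 + 6L * (n - 1L) + n + seq_len(n)])
  list(intra = intra, inter = inter, chi = chi)
}

.sds_vector <- function(sds, n) {
  intra <- rep(0, 6); inter <- rep(0, 6); chi <- 0
  if (!is.null(sds$intra)) intra <- rep(sds$intra, length.out = 6L)
  if (!is.null(sds$inter)) inter <- rep(sds$inter, length.out = 6L)
  if (!is.null(sds$chi)) chi <- sds$chi[1L]
  if (any(c(intra, inter, chi) < 0)) stop("SDs must be >= 0")
  c(rep(intra, times = n), rep(inter, times = n - 1L), rep(chi, 2L * n))
}

# matrix square root for sampling; tolerant of semidefinite covariances
.cov_root <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance is not positive semidefinite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

#' Sample a synthetic trajectory
#'
#' Draws per-frame parameter vectors from the multivariate normal defined by
#' the spec, applies planted breathing overrides, rebuilds atomic structures
#' frame by frame, and (optionally) scatters cations as a Poisson point
#' process of the specified molarity in the cylindrical frame of the central
#' pair of the mean structure. Frames whose sampled rise becomes degenerate
#' (<= 0.05 A anywhere) are redrawn; the count of redraws is recorded in the
#' \code{resampled} attribute and reported with a warning.
#'
#' @param spec an \code{ensemble_spec}.
#' @return object of class \code{dna_trajectory}: \code{topology},
#'   \code{xyz} (frames x 3 n_atoms), \code{ions} (per-frame coordinate
#'   matrices), \code{seq}, and \code{truth} (per-frame parameter arrays:
#'   the planted ground truth).
#' @export
sample_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$seq$n_pairs
  d <- .stack_dim(n)
  mu <- .stack_table(spec$table)
  set.seed(spec$seed)
  draw <- function(k) {
    if (!is.null(spec$covariance)) {
      z <- matrix(stats::rnorm(k * d), k, d)
      sweep(z %*% t(.cov_root(spec$covariance)), 2L, mu, "+")
    } else {
      sdv <- .sds_vector(spec$sds, n)
      z <- matrix(stats::rnorm(k * d), k, d)
      sweep(sweep(z, 2L, sdv, "*"), 2L, mu, "+")
    }
  }
  X <- draw(spec$n_frames)
  rise_cols <- 6L * n + seq(3L, by = 6L, length.out = n - 1L)
  resampled <- 0L
  for (attempt in seq_len(100L)) {
    bad <- which(apply(X[, rise_cols, drop = FALSE] <= 0.05, 1L, any))
    if (length(bad) == 0L) break
    resampled <- resampled + length(bad)
    X[bad, ] <- draw(length(bad))
  }
  if (length(bad <- which(apply(X[, rise_cols, drop = FALSE] <= 0.05, 1L, any))))
    stop("degenerate rise persists after 100 resampling rounds")
  if (resampled > 0L)
    warning(sprintf("resampled %d frame(s) with degenerate rise", resampled))
  # planted breathing overrides (opening = column 6 of pair block)
  if (!is.null(spec$planted_breathing)) {
    for (j in seq_len(nrow(spec$planted_breathing))) {
      pb <- spec$planted_breathing[j, ]
      abs_pair <- pb$pair + spec$seq$mm_position
      if (abs_pair < 1L || abs_pair > n) stop("planted pair outside duplex")
      col <- (abs_pair - 1L) * 6L + 6L
      amp <- if (pb$direction == "major") abs(pb$amplitude) else -abs(pb$amplitude)
      X[pb$start:pb$end, col] <- mu[col] + amp
    }
  }
  # rebuild structures; duplicated parameter rows (frozen coordinates,
  # planted plateaus, degenerate Gaussians) are built once and reused
  frames <- spec$n_frames
  dup <- duplicated(X)
  proto <- which(!dup)
  match_row <- integer(frames)
  match_row[proto] <- proto
  if (any(dup)) {
    key <- apply(X, 1L, function(r) paste(r, collapse = "\r"))
    match_row <- proto[match(key, key[proto])]
  }
  built <- vector("list", frames)
  first <- NULL
  truth_intra <- array(NA_real_, c(frames, n, 6L),
                       dimnames = list(NULL, NULL, .intra_names))
  truth_inter <- array(NA_real_, c(frames, n - 1L, 6L),
                       dimnames = list(NULL, NULL, .inter_names))
  truth_chi <- array(NA_real_, c(frames, n, 2L), dimnames = list(NULL, NULL, c("W", "C")))
  xyz <- NULL
  for (f in seq_len(frames)) {
    tb <- .unstack_table(X[f, ], n)
    truth_intra[f, , ] <- tb$intra; truth_inter[f, , ] <- tb$inter
    truth_chi[f, , ] <- tb$chi
    if (match_row[f] == f) {
      st <- build_duplex(spec$seq, do.call(parameter_table,
        c(list(n_pairs = n), tb)))
      if (is.null(first)) {
        first <- st
        xyz <- matrix(NA_real_, frames, 3L * nrow(st$coords))
      }
      built[[f]] <- as.vector(t(st$coords))
    }
    xyz[f, ] <- built[[match_row[f]]]
  }
  # ion atmosphere, sampled in the frame of the central pair of the mean build
  ions <- replicate(frames, matrix(numeric(0), 0L, 3L), simplify = FALSE)
  if (!is.null(spec$ion_spec)) {
    cf <- .center_pair_frame(spec)
    ions <- lapply(seq_len(frames), function(f)
      .sample_ions_once(spec$ion_spec, cf$Rm, cf$om))
  }
  structure(list(topology = first$topology, xyz = xyz, ions = ions,
                 seq = spec$seq,
                 truth = list(intra = truth_intra, inter = truth_inter,
                              chi = truth_chi),
                 spec = spec, resampled = resampled),
            class = "dna_trajectory")
}

#' @export
print.dna_trajectory <- function(x, ...) {
  cat("dna trajectory:", nrow(x$xyz), "frames,",
      nrow(x$topology), "atoms/frame\n")
  invisible(x)
}

.center_pair_frame <- function(spec) {
  mean_struct <- build_duplex(spec$seq, spec$table)
  an <- analyze_structure(mean_struct)
  pf <- an$pair_frames[[spec$seq$mm_position]]
  list(Rm = pf$rotation, om = pf$origin)
}

# one frame of Poisson cation positions, returned in lab coordinates
.sample_ions_once <- function(ion_spec, Rm, om) {
  to_lab <- function(loc) {
    if (nrow(loc) == 0L) return(matrix(numeric(0), 0L, 3L))
    sweep(tcrossprod(loc, Rm), 2L, om, "+")
  }
  if (ion_spec$type == "uniform") {
    r0 <- if (is.null(ion_spec$r_min)) 0 else ion_spec$r_min
    vol <- pi * (ion_spec$r_max^2 - r0^2) * 2 * ion_spec$z_half
    lam <- ion_spec$molarity * vol * .MOLAR_CONV
    k <- stats::rpois(1L, lam)
    r <- sqrt(stats::runif(k, r0^2, ion_spec$r_max^2))
    th <- stats::runif(k, 0, 2 * pi)
    z <- stats::runif(k, -ion_spec$z_half, ion_spec$z_half)
    return(to_lab(cbind(r * cos(th), r * sin(th), z)))
  }
  re <- ion_spec$r_edges; te <- .rad(ion_spec$theta_edges)
  h2 <- 2 * ion_spec$z_half
  out <- list(); k <- 0L
  for (i in seq_len(nrow(ion_spec$molarity))) {
    for (j in seq_len(ncol(ion_spec$molarity))) {
      vol <- (te[j + 1L] - te[j]) / 2 * (re[i + 1L]^2 - re[i]^2) * h2
      lam <- ion_spec$molarity[i, j] * vol * .MOLAR_CONV
      nij <- stats::rpois(1L, lam)
      if (nij == 0L) next
      r <- sqrt(stats::runif(nij, re[i]^2, re[i + 1L]^2))
      th <- stats::runif(nij, te[j], te[j + 1L])
      z <- stats::runif(nij, -ion_spec$z_half, ion_spec$z_half)
      k <- k + 1L
      out[[k]] <- cbind(r * cos(th), r * sin(th), z)
    }
  }
  loc <- if (k == 0L) matrix(numeric(0), 0L, 3L) else do.call(rbind, out)
  to_lab(loc)
}

#' Sample cation positions for a fixed duplex
#'
#' Stand-alone Poisson point-process sampler: draws \code{frame_count}
#' independent cation coordinate sets with intensity molarity x bin volume x
#' 6.022e-4 ions/A^3/M, in the cylindrical frame of the central pair of the
#' spec's mean structure.
#'
#' @param spec an \code{ensemble_spec} with a non-null \code{ion_spec}.
#' @param frame_count number of frames to draw.
#' @return object of class \code{ion_ensemble}: list with \code{ions}
#'   (per-frame lab-coordinate matrices) and \code{frame} (the cylindrical
#'   reference frame used).
#' @export
sample_ion_positions <- function(spec, frame_count) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(spec$ion_spec)) stop("spec has no ion_spec")
  set.seed(spec$seed)
  cf <- .center_pair_frame(spec)
  ions <- lapply(seq_len(frame_count), function(f)
    .sample_ions_once(spec$ion_spec, cf$Rm, cf$om))
  structure(list(ions = ions, frame = cf), class = "ion_ensemble")
}
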