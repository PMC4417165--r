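# Hydrogen-bond detection, pairing-scheme classification and base-pair
# breathing statistics. The reduced-atom model carries no explicit
# hydrogens, so bonds are scored on heavy-atom geometry with a
# pseudo-hydrogen reconstructed from the donor's covalent neighbours.

#' Hydrogen-bond donor/acceptor catalog of a structure
#'
#' Expands the per-base chemistry tables into atom-level donor and acceptor
#' lists for every residue of a structure. The sugar O4' is an acceptor on
#' every nucleotide.
#'
#' @param struct a \code{dna_structure}.
#' @return list of data frames \code{donors} (chain, resno, base, atom,
#'   antecedents) and \code{acceptors} (chain, resno, base, atom).
#' @export
hbond_catalog <- function(struct) {
  topo <- struct$topology
  res <- unique(topo[, c("chain", "resno", "base")])
  don <- list(); acc <- list(); k <- 0L; m <- 0L
  for (r in seq_len(nrow(res))) {
    b <- res$base[r]
    for (a in names(.hb_donors[[b]])) {
      k <- k + 1L
      don[[k]] <- data.frame(chain = res$chain[r], resno = res$resno[r],
                             base = b, atom = a,
                             antecedents = paste(.hb_donors[[b]][[a]], collapse = ","),
                             stringsAsFactors = FALSE)
    }
    for (a in c(.hb_acceptors[[b]], .sugar_acceptors)) {
      m <- m + 1L
      acc[[m]] <- data.frame(chain = res$chain[r], resno = res$resno[r],
                             base = b, atom = a, stringsAsFactors = FALSE)
    }
  }
  list(donors = do.call(rbind, don), acceptors = do.call(rbind, acc))
}

.atom_xyz <- function(struct, chain, resno, atom) {
  i <- which(struct$topology$chain == chain & struct$topology$resno == resno &
               struct$topology$atom == atom)
  if (length(i) != 1L) stop("atom not found: ", chain, ":", resno, ":", atom)
  struct$coords[i, ]
}

# Reconstruct the pseudo-hydrogen of a donor and return the D-H...A angle
# (deg) for a candidate acceptor position. Ring donors (two antecedents)
# carry one in-plane H on the external bisector; amine donors (one
# antecedent) carry two in-plane Hs at 120 deg from the C-N bond, and the
# one pointing closer to the acceptor is scored.
.dha_angle <- function(d_pos, ante_pos, normal, a_pos) {
  hs <- list()
  if (nrow(ante_pos) == 2L) {
    u <- .normalize(.normalize(ante_pos[1L, ] - d_pos) +
                      .normalize(ante_pos[2L, ] - d_pos))
    hs[[1L]] <- d_pos - 1.01 * u
  } else {
    u <- .normalize(d_pos - ante_pos[1L, ])
    hs[[1L]] <- d_pos + 1.01 * drop(rot_axis(normal, .rad(60)) %*% u)
    hs[[2L]] <- d_pos + 1.01 * drop(rot_axis(normal, -.rad(60)) %*% u)
  }
  best <- -Inf
  for (h in hs) {
    v1 <- d_pos - h; v2 <- a_pos - h
    ang <- .deg(acos(.clamp1(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    best <- max(best, ang)
  }
  best
}

# base-plane normal of one residue (lab frame), from the fitted base frame
.residue_normal <- function(struct, chain, resno) {
  topo <- struct$topology
  sel <- topo$chain == chain & topo$resno == resno
  m <- struct$coords[sel, , drop = FALSE]
  rownames(m) <- topo$atom[sel]
  fit_base_frame(m, topo$base[sel][1L])$rotation[, 3L]
}

#' Detect hydrogen bonds
#'
#' All donor-acceptor pairs (across different residues) satisfying the
#' heavy-atom criterion: donor-acceptor distance <= \code{d_max} and
#' pseudo-hydrogen D-H...A angle >= \code{theta_min}. Results are in
#' deterministic order (donor row, then acceptor row).
#'
#' @param struct a \code{dna_structure}.
#' @param catalog optional catalog from \code{\link{hbond_catalog}};
#'   computed from the structure when NULL. Restricting the catalog
#'   restricts the search.
#' @param d_max heavy-atom distance cutoff (Angstrom, default 3.5).
#' @param theta_min D-H...A angle cutoff (degrees, default 135).
#' @return data frame of observations: donor chain/resno/atom, acceptor
#'   chain/resno/atom, \code{distance} (A) and \code{angle} (deg).
#' @export
detect_hbonds <- function(struct, catalog = NULL, d_max = 3.5, theta_min = 135) {
  if (is.null(catalog)) catalog <- hbond_catalog(struct)
  don <- catalog$donors; acc <- catalog$acceptors
  topo <- struct$topology
  key <- paste(topo$chain, topo$resno, topo$atom)
  di <- match(paste(don$chain, don$resno, don$atom), key)
  ai <- match(paste(acc$chain, acc$resno, acc$atom), key)
  if (anyNA(di) || anyNA(ai)) stop("catalog names an atom absent from the structure")
  dp <- struct$coords[di, , drop = FALSE]
  ap <- struct$coords[ai, , drop = FALSE]
  normals <- new.env()
  out <- list(); k <- 0L
  for (i in seq_len(nrow(don))) {
    dv <- sweep(ap, 2L, dp[i, ])
    dist <- sqrt(rowSums(dv^2))
    cand <- which(dist <= d_max &
                    !(acc$chain == don$chain[i] & acc$resno == don$resno[i]))
    if (length(cand) == 0L) next
    antes <- strsplit(don$antecedents[i], ",")[[1L]]
    ante_pos <- do.call(rbind, lapply(antes, function(a)
      .atom_xyz(struct, don$chain[i], don$resno[i], a)))
    nkey <- paste0(don$chain[i], don$resno[i])
    if (is.null(normals[[nkey]]))
      normals[[nkey]] <- .residue_normal(struct, don$chain[i], don$resno[i])
    for (j in cand) {
      ang <- .dha_angle(dp[i, ], ante_pos, normals[[nkey]], ap[j, ])
      if (ang >= theta_min) {
        k <- k + 1L
        out[[k]] <- data.frame(
          donor_chain = don$chain[i], donor_resno = don$resno[i],
          donor_atom = don$atom[i],
          acceptor_chain = acc$chain[j], acceptor_resno = acc$resno[j],
          acceptor_atom = acc$atom[j],
          distance = dist[j], angle = ang, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# ---- pairing schemes -------------------------------------------------------

#' Read a pairing-scheme catalog
#'
#' Catalogs are YAML: one entry per scheme, each with an \code{annotation}
#' (WC-side / major-groove / minor-groove) and a list of \code{bonds} written
#' as \code{"W:atom > C:atom"} donor-to-acceptor strings, W/C naming the
#' strand carrying the atom at the lesion pair. Sugar O4' acceptors are
#' allowed.
#'
#' @param path path to a YAML file; or one of the shipped catalog names
#'   (e.g. "GT", "GG", "AT") resolved against the package's
#'   \code{extdata/schemes}.
#' @return named list of schemes (\code{pairing_catalog}).
#' @export
read_scheme_catalog <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", "schemes", paste0(path, ".yaml"),
                           package = "mmduplex")
    if (!nzchar(shipped)) stop("no such catalog: ", path)
    path <- shipped
  }
  cat <- yaml::read_yaml(path)
  for (nm in names(cat)) {
    if (length(cat[[nm]]$bonds) == 0L) stop("scheme ", nm, " has no bonds")
  }
  structure(cat, class = "pairing_catalog")
}

.parse_bond <- function(s) {
  m <- regmatches(s, regexec("^\\s*([WC])\\s*:\\s*(\\S+)\\s*>\\s*([WC])\\s*:\\s*(\\S+)\\s*$", s))[[1L]]
  if (length(m) != 5L) stop("malformed bond spec: '", s, "'")
  list(donor_strand = m[2L], donor_atom = m[3L],
       acceptor_strand = m[4L], acceptor_atom = m[5L])
}

# Does one frame's lesion pair satisfy a bond? hb is the detected bond table
# for the frame, already restricted or not; wres/cres are (chain, resno).
.bond_formed <- function(hb, bond, wres, cres) {
  dres <- if (bond$donor_strand == "W") wres else cres
  ares <- if (bond$acceptor_strand == "W") wres else cres
  any(hb$donor_chain == dres[1L] & hb$donor_resno == as.integer(dres[2L]) &
        hb$donor_atom == bond$donor_atom &
        hb$acceptor_chain == ares[1L] & hb$acceptor_resno == as.integer(ares[2L]) &
        hb$acceptor_atom == bond$acceptor_atom)
}

#' Pairing-scheme occupancies along a trajectory
#'
#' Labels every frame by the catalog scheme whose hydrogen-bond set is fully
#' formed at the lesion pair. Ties go to the scheme with the most bonds,
#' then to catalog order; frames matching no scheme fall into the
#' "unassigned" sink. Occupancy fractions sum to one.
#'
#' @param traj a \code{dna_trajectory}.
#' @param mm_position absolute pair index of the lesion (default: the
#'   trajectory sequence's \code{mm_position}).
#' @param catalog a \code{pairing_catalog} (see
#'   \code{\link{read_scheme_catalog}}).
#' @param d_max,theta_min hydrogen-bond criteria.
#' @param threshold reportable-occupancy threshold for the promiscuity count
#'   (default 0.05).
#' @return list with \code{fractions} (named, sums to 1), \code{labels}
#'   (per frame), \code{promiscuity} (number of schemes above threshold,
#'   excluding "unassigned"), and \code{annotation} per scheme.
#' @export
scheme_occupancies <- function(traj, mm_position = NULL, catalog,
                               d_max = 3.5, theta_min = 135,
                               threshold = 0.05) {
  stopifnot(inherits(traj, "dna_trajectory"))
  n_frames <- nrow(traj$xyz)
  if (n_frames == 0L) stop("empty trajectory")
  if (is.null(mm_position)) mm_position <- traj$seq$mm_position
  n <- traj$seq$n_pairs
  wres <- c("A", mm_position)
  cres <- c("B", n + 1L - mm_position)
  bonds <- lapply(catalog, function(s) lapply(s$bonds, .parse_bond))
  # restrict the donor/acceptor search to the lesion pair's residues
  st0 <- .traj_frame(traj, 1L)
  cat0 <- hbond_catalog(st0)
  keep <- function(df) df[(df$chain == wres[1L] & df$resno == as.integer(wres[2L])) |
                            (df$chain == cres[1L] & df$resno == as.integer(cres[2L])), ]
  cat0$donors <- keep(cat0$donors); cat0$acceptors <- keep(cat0$acceptors)
  labels <- character(n_frames)
  scheme_names <- names(catalog)
  nbonds <- vapply(bonds, length, 0L)
  for (f in seq_len(n_frames)) {
    st <- .traj_frame(traj, f)
    hb <- detect_hbonds(st, cat0, d_max = d_max, theta_min = theta_min)
    formed <- vapply(seq_along(bonds), function(s)
      all(vapply(bonds[[s]], function(b) .bond_formed(hb, b, wres, cres), TRUE)),
      TRUE)
    if (!any(formed)) {
      labels[f] <- "unassigned"
    } else {
      cand <- which(formed)
      labels[f] <- scheme_names[cand[order(-nbonds[cand], cand)][1L]]
    }
  }
  lev <- c(scheme_names, "unassigned")
  fr <- table(factor(labels, levels = lev)) / n_frames
  fractions <- as.numeric(fr); names(fractions) <- lev
  list(fractions = fractions, labels = labels,
       promiscuity = sum(fractions[scheme_names] >= threshold),
       annotation = vapply(catalog, function(s)
         if (is.null(s$annotation)) NA_character_ else s$annotation, ""))
}

# materialise frame f of a trajectory as a dna_structure
.traj_frame <- function(traj, f) {
  structure(list(topology = traj$topology,
                 coords = matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE),
                 seq = traj$seq),
            class = "dna_structure")
}

# ---- breathing -------------------------------------------------------------

#' Base-pair breathing statistics
#'
#' Classifies each frame of an opening-angle series as closed, open toward
#' the major groove, or open toward the minor groove, and summarises the
#' events by run-length encoding. A frame is raw-open when the opening
#' deviates from \code{reference} by more than \code{threshold}; raw-open
#' runs shorter than \code{min_frames} are suppressed (hysteresis against
#' single-frame flickers). Positive excursions point toward the major
#' groove by the opening sign convention.
#'
#' @param opening numeric series of opening angles (deg).
#' @param frame_dt time per frame (any unit; residence times are reported in
#'   frames and in time units).
#' @param threshold opening deviation defining an open frame (deg, default
#'   45).
#' @param min_frames minimum sustained length of an open run (default 2).
#' @param reference baseline opening; by convention the ensemble median of
#'   the canonical control at the same position (defaults to the series
#'   median).
#' @return object of class \code{breathing_trace}: per-frame \code{state}
#'   and a \code{summary} list (occupancy \%, transitions, mean/max
#'   residence per direction).
#' @export
breathing_analysis <- function(opening, frame_dt = 1, threshold = 45,
                               min_frames = 2L, reference = NULL) {
  if (!all(is.finite(opening))) stop("opening series must be finite")
  if (frame_dt <= 0) stop("frame_dt must be positive")
  if (length(opening) < min_frames) stop("series shorter than min_frames")
  if (is.null(reference)) reference <- stats::median(opening)
  delta <- opening - reference
  raw_open <- abs(delta) > threshold
  r <- rle(raw_open)
  r$values[r$values & r$lengths < min_frames] <- FALSE
  open <- inverse.rle(r)
  state <- rep("closed", length(opening))
  # direction of each surviving open run from the mean excursion sign
  r2 <- rle(open)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  runs <- data.frame(start = starts, end = ends, open = r2$values)
  runs <- runs[runs$open, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    dir <- if (mean(delta[runs$start[i]:runs$end[i]]) >= 0) "open_major" else "open_minor"
    state[runs$start[i]:runs$end[i]] <- dir
  }
  n <- length(opening)
  res_len <- runs$end - runs$start + 1L
  res_dir <- state[runs$start]
  per_dir <- function(d) {
    len <- res_len[res_dir == d]
    list(occupancy_pct = 100 * sum(len) / n,
         n_events = length(len),
         mean_residence_frames = if (length(len)) mean(len) else 0,
         max_residence_frames = if (length(len)) max(len) else 0,
         mean_residence_time = if (length(len)) mean(len) * frame_dt else 0,
         max_residence_time = if (length(len)) max(len) * frame_dt else 0)
  }
  summary <- list(
    occupancy_pct = 100 * sum(res_len) / n,
    n_transitions = nrow(runs),            # closed -> open boundaries
    mean_residence_frames = if (nrow(runs)) mean(res_len) else 0,
    max_residence_frames = if (nrow(runs)) max(res_len) else 0,
    mean_residence_time = if (nrow(runs)) mean(res_len) * frame_dt else 0,
    max_residence_time = if (nrow(runs)) max(res_len) * frame_dt else 0,
    major = per_dir("open_major"),
    minor = per_dir("open_minor"),
    threshold = threshold, min_frames = min_frames, reference = reference,
    frame_dt = frame_dt)
  structure(list(state = state, summary = summary), class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  s <- x$summary
  cat(sprintf("breathing: occupancy %.2f%% (%d events; major %.2f%%, minor %.2f%%)\n",
              s$occupancy_pct, s$n_transitions,
              s$major$occupancy_pct, s$minor$occupancy_pct))
  invisible(x)
}
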