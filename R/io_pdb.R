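# Multi-model PDB I/O for reduced-atom duplex trajectories. A dedicated
# fixed-column reader/writer is used because trajectories carry a varying
# number of cation HETATM records per MODEL, which general-purpose
# multi-model readers (constant atom count per model) cannot represent.

.pdb_resname <- c(A = "DA", C = "DC", G = "DG", T = "DT")

.pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                           xyz, element) {
  nm <- if (nchar(name) <= 3L) sprintf(" %-3s", name) else substr(name, 1L, 4L)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, nm, resname, chain, resno,
          xyz[1L], xyz[2L], xyz[3L], 1, 0, element)
}

.element_of <- function(atom) substr(gsub("[^A-Z]", "", atom), 1L, 1L)

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; duplex atoms as ATOM records (chain A =
#' Watson, chain B = Crick, residues DA/DC/DG/DT numbered 1..N per strand),
#' cations as HETATM records (residue NA, chain I) appended after the duplex
#' atoms of each model. Coordinates are written at 3 decimals.
#'
#' @param traj a \code{dna_trajectory}.
#' @param path output file.
#' @param ion_name residue/element name for cation records (default "NA").
#' @return \code{path}, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, ion_name = "NA") {
  stopifnot(inherits(traj, "dna_trajectory"))
  topo <- traj$topology
  n_frames <- nrow(traj$xyz)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    coords <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    lines <- character(nrow(topo))
    for (i in seq_len(nrow(topo)))
      lines[i] <- .pdb_atom_line("ATOM", i, topo$atom[i],
                                 .pdb_resname[[topo$base[i]]], topo$chain[i],
                                 topo$resno[i], coords[i, ],
                                 .element_of(topo$atom[i]))
    ions <- traj$ions[[f]]
    ion_lines <- character(0L)
    if (!is.null(ions) && nrow(ions) > 0L)
      ion_lines <- vapply(seq_len(nrow(ions)), function(k)
        .pdb_atom_line("HETATM", nrow(topo) + k, ion_name, ion_name, "I", k,
                       ions[k, ], ion_name), "")
    writeLines(c(sprintf("MODEL     %4d", f), lines, ion_lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

.parse_pdb_records <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  data.frame(
    record = trimws(substr(lines, 1L, 6L)),
    atom = trimws(substr(lines, 13L, 16L)),
    resname = trimws(substr(lines, 18L, 20L)),
    chain = substr(lines, 22L, 22L),
    resno = as.integer(substr(lines, 23L, 26L)),
    x = as.numeric(substr(lines, 31L, 38L)),
    y = as.numeric(substr(lines, 39L, 46L)),
    z = as.numeric(substr(lines, 47L, 54L)),
    stringsAsFactors = FALSE)
}

#' Read a multi-model PDB trajectory
#'
#' Inverse of \code{\link{write_trajectory_pdb}}. Duplex topology is taken
#' from the first model and must be identical in every model; HETATM records
#' become per-frame ion coordinate sets and may vary in number across
#' frames. A file without MODEL records is read as a single frame.
#'
#' @param path PDB file.
#' @param mm_position lesion pair index recorded on the returned sequence
#'   (default: centre).
#' @return a \code{dna_trajectory}.
#' @export
read_trajectory_pdb <- function(path, mm_position = NULL) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    blocks <- list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
    blocks <- Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
  }
  frames <- lapply(blocks, .parse_pdb_records)
  first <- frames[[1L]]
  dna <- first[first$record == "ATOM", ]
  base <- names(.pdb_resname)[match(dna$resname, .pdb_resname)]
  if (anyNA(base)) stop("unknown residue name(s): ",
                        paste(unique(dna$resname[is.na(base)]), collapse = ", "))
  topo <- data.frame(chain = dna$chain, resno = dna$resno, base = base,
                     atom = dna$atom, stringsAsFactors = FALSE)
  n <- max(topo$resno[topo$chain == "A"])
  watson <- vapply(seq_len(n), function(i)
    topo$base[topo$chain == "A" & topo$resno == i][1L], "")
  crick <- vapply(seq_len(n), function(i)
    topo$base[topo$chain == "B" & topo$resno == i][1L], "")
  seq <- duplex_sequence(paste(watson, collapse = ""),
                         paste(crick, collapse = ""),
                         mm_position = mm_position)
  sig <- paste(topo$chain, topo$resno, topo$atom)
  xyz <- matrix(NA_real_, length(frames), 3L * nrow(topo))
  ions <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    d <- fr[fr$record == "ATOM", ]
    if (!identical(paste(d$chain, d$resno, d$atom), sig))
      stop("topology mismatch across frames (model ", f, ")")
    xyz[f, ] <- as.vector(t(as.matrix(d[, c("x", "y", "z")])))
    h <- fr[fr$record == "HETATM", ]
    ions[[f]] <- if (nrow(h)) as.matrix(h[, c("x", "y", "z")])
    else matrix(numeric(0), 0L, 3L)
  }
  structure(list(topology = topo, xyz = xyz, ions = ions, seq = seq),
            class = "dna_trajectory")
}

#' Write one frame as a single-model PDB
#'
#' @param traj a \code{dna_trajectory}.
#' @param frame frame index.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_snapshot_pdb <- function(traj, frame, path) {
  sub <- traj
  sub$xyz <- traj$xyz[frame, , drop = FALSE]
  sub$ions <- traj$ions[frame]
  write_trajectory_pdb(sub, path)
}
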