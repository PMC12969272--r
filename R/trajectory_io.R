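#' Default role specification for trajectory loading
#'
#' Maps particle roles to PDB atom-name / residue-name patterns.  Each
#' element is a list with regular expressions `atom` and (optionally)
#' `resname`.  The defaults match the naming used by [write_trajectory()]:
#' lipid phosphorus `P` in residue `LIP`, acyl carbons/hydrogens `C*`/`H*`,
#' solute centre-of-mass markers `S` in residue `SLT`, and hopanoid
#' polar-end markers `O1` in residue `HOP`.
#'
#' @return Named list of role selection rules.
#' @export
default_role_spec <- function() {
  list(phosphorus     = list(atom = "^P$"),
       chain_carbon   = list(atom = "^C[0-9]*$"),
       chain_hydrogen = list(atom = "^H[0-9]*$"),
       solute_com     = list(atom = "^S$", resname = "^SLT$"),
       polar_marker   = list(atom = "^O1$", resname = "^HOP$"))
}

role_atom_name <- function(role, k) {
  switch(role,
         phosphorus = "P",
         chain_carbon = paste0("C", k),
         chain_hydrogen = paste0("H", k),
         solute_com = "S",
         polar_marker = "O1",
         "X")
}

role_res_name <- function(role) {
  switch(role,
         phosphorus = "LIP", chain_carbon = "LIP", chain_hydrogen = "LIP",
         solute_com = "SLT", polar_marker = "HOP", "OTH")
}

# ---- PDB ------------------------------------------------------------------

format_pdb_atom <- function(serial, name, resname, resid, xyz) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, name4, resname, resid %% 10000L,
          xyz[1], xyz[2], xyz[3])
}

format_cryst1 <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1], box[2], box[3], 90, 90, 90)
}

write_pdb_frames <- function(traj, path, frames = seq_len(n_frames(traj))) {
  np <- dim(traj$coords)[1]
  atom_counter <- integer(max(traj$molecule_ids))
  names_vec <- character(np)
  res_vec <- character(np)
  per_mol_k <- new.env(parent = emptyenv())
  k_of <- integer(np)
  for (i in seq_len(np)) {
    key <- as.character(traj$molecule_ids[i])
    k <- if (is.null(per_mol_k[[key]])) 1L else per_mol_k[[key]] + 1L
    per_mol_k[[key]] <- k
    k_of[i] <- k
    names_vec[i] <- role_atom_name(traj$roles[i], k)
    res_vec[i] <- role_res_name(traj$roles[i])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("REMARK 250 TIME=%.6f NS", traj$times[f]), con)
    writeLines(format_cryst1(traj$box[f, ]), con)
    lines <- vapply(seq_len(np), function(i)
      format_pdb_atom(i, names_vec[i], res_vec[i], traj$molecule_ids[i],
                      traj$coords[i, , f]), "")
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

parse_pdb_atoms <- function(lines) {
  atom <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  data.frame(
    name = trimws(substr(atom, 13, 16)),
    resname = trimws(substr(atom, 18, 20)),
    resid = as.integer(substr(atom, 23, 26)),
    x = as.numeric(substr(atom, 31, 38)),
    y = as.numeric(substr(atom, 39, 46)),
    z = as.numeric(substr(atom, 47, 54)),
    stringsAsFactors = FALSE)
}

read_pdb_frames <- function(path) {
  lines <- readLines(path)
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- vector("list", length(starts))
  boxes <- matrix(NA_real_, length(starts), 3L)
  times <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    cr <- chunk[startsWith(chunk, "CRYST1")]
    if (length(cr) == 0L)
      stop(sprintf("frame %d has no CRYST1 unit cell: box-derived quantities undefined", k))
    boxes[k, ] <- c(as.numeric(substr(cr[1], 7, 15)),
                    as.numeric(substr(cr[1], 16, 24)),
                    as.numeric(substr(cr[1], 25, 33)))
    tm <- chunk[startsWith(chunk, "REMARK 250 TIME=")]
    if (length(tm))
      times[k] <- as.numeric(sub("REMARK 250 TIME=([-0-9.eE+]+) NS", "\\1", tm[1]))
    frames[[k]] <- parse_pdb_atoms(chunk)
  }
  np <- nrow(frames[[1]])
  coords <- array(NA_real_, c(np, 3L, length(frames)))
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != np) stop("frames differ in particle count")
    coords[, , k] <- as.matrix(frames[[k]][, c("x", "y", "z")])
  }
  list(coords = coords, box = boxes, times = times, atoms = frames[[1]])
}

# ---- DCD (CHARMM/NAMD binary trajectory) ----------------------------------

AKMA_PS <- 0.0488882129  # 1 AKMA time unit in ps

write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  np <- dim(traj$coords)[1]
  nf <- n_frames(traj)
  dt_ns <- if (is.na(traj$frame_interval)) 1 else traj$frame_interval
  delta <- dt_ns * 1e3 / AKMA_PS
  rec <- function(writer) {
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    bytes <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(bytes), con, size = 4L)
    writeBin(bytes, con)
    writeBin(length(bytes), con, size = 4L)
  }
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4L, eos = NULL)
    writeBin(as.integer(c(nf, 0L, 1L, nf, 0L, 0L, 0L, 0L, 0L)), c2, size = 4L)
    writeBin(as.numeric(delta), c2, size = 4L)            # float32 DELTA
    writeBin(as.integer(c(1L, rep(0L, 8L), 24L)), c2, size = 4L)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4L)
    writeChar(formatC("Created by bilayertools", width = -80), c2,
              nchars = 80L, eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(np), c2, size = 4L))
  for (f in seq_len(nf)) {
    b <- traj$box[f, ]
    rec(function(c2) writeBin(as.numeric(c(b[1], 90, b[2], 90, 90, b[3])),
                              c2, size = 8L))
    for (ax in 1:3)
      rec(function(c2) writeBin(as.numeric(traj$coords[, ax, f]),
                                c2, size = 4L))
  }
  invisible(path)
}

read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_rec_len <- function() {
    n <- readBin(con, "integer", n = 1L, size = 4L)
    if (length(n) == 0L) NA_integer_ else n
  }
  len <- read_rec_len()
  if (is.na(len) || len != 84L) stop("not a DCD file (bad header record)")
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD file")
  icntrl_a <- readBin(con, "integer", n = 9L, size = 4L)
  delta <- readBin(con, "numeric", n = 1L, size = 4L)
  icntrl_b <- readBin(con, "integer", n = 10L, size = 4L)
  invisible(read_rec_len())
  has_cell <- icntrl_b[1] == 1L
  if (!has_cell)
    stop("DCD has no unit-cell records: box-derived quantities undefined")
  nsavc <- max(icntrl_a[3], 1L)
  dt_ns <- delta * nsavc * AKMA_PS / 1e3
  len <- read_rec_len()
  ntitle <- readBin(con, "integer", n = 1L, size = 4L)
  if (ntitle > 0L) readChar(con, 80L * ntitle, useBytes = TRUE)
  invisible(read_rec_len())
  invisible(read_rec_len())
  np <- readBin(con, "integer", n = 1L, size = 4L)
  invisible(read_rec_len())
  frames <- list(); boxes <- list()
  repeat {
    len <- read_rec_len()
    if (is.na(len)) break
    cell <- readBin(con, "numeric", n = 6L, size = 8L)
    invisible(read_rec_len())
    xyz <- matrix(NA_real_, np, 3L)
    for (ax in 1:3) {
      invisible(read_rec_len())
      xyz[, ax] <- readBin(con, "numeric", n = np, size = 4L)
      invisible(read_rec_len())
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- cell[c(1L, 3L, 6L)]
  }
  nf <- length(frames)
  coords <- array(NA_real_, c(np, 3L, nf))
  for (k in seq_len(nf)) coords[, , k] <- frames[[k]]
  list(coords = coords, box = do.call(rbind, boxes),
       times = (seq_len(nf) - 1L) * dt_ns, dt = dt_ns)
}

# ---- public interface -----------------------------------------------------

#' Write a trajectory to standard MD files
#'
#' Writes a single-frame PDB topology (atom names encode particle roles,
#' residue numbers encode molecule ids) and a coordinate file that is either
#' a CHARMM-style binary DCD (extension `.dcd`; float32 coordinates, per
#' frame unit-cell records, time step in the header) or a multi-model PDB
#' (any other extension; per-model CRYST1 and a TIME remark).
#'
#' @param traj A `bt_trajectory`.
#' @param topology Path for the topology PDB.
#' @param coords Path for the coordinate file (`.dcd` or `.pdb`).
#' @return Invisibly, `c(topology, coords)`.
#' @export
write_trajectory <- function(traj, topology, coords) {
  stopifnot(inherits(traj, "bt_trajectory"))
  write_pdb_frames(traj, topology, frames = 1L)
  if (grepl("\\.dcd$", coords, ignore.case = TRUE)) write_dcd(traj, coords)
  else write_pdb_frames(traj, coords)
  invisible(c(topology, coords))
}

match_roles <- function(atoms, role_spec, optional = "polar_marker") {
  roles <- rep("other", nrow(atoms))
  for (role in names(role_spec)) {
    rule <- role_spec[[role]]
    if (is.character(rule)) rule <- list(atom = rule)
    sel <- grepl(rule$atom, atoms$name)
    if (!is.null(rule$resname)) sel <- sel & grepl(rule$resname, atoms$resname)
    sel <- sel & roles == "other"
    if (!any(sel) && !(role %in% optional))
      stop(sprintf("role selection '%s' matched no particles", role))
    roles[sel] <- role
  }
  roles
}

#' Load a trajectory from topology + coordinate files
#'
#' @param topology PDB topology path (first MODEL is used for atom metadata).
#' @param coords Coordinate path: `.dcd` (binary, frame interval taken from
#'   the header time step) or multi-model `.pdb` (frame interval from the
#'   per-model TIME remarks, else `dt`).
#' @param role_spec Role selection rules, see [default_role_spec()].
#' @param optional Roles allowed to match zero particles without error
#'   (by default every role a bilayer-only trajectory may legitimately
#'   lack; pass `character(0)` to make all selections mandatory).
#' @param dt Fallback frame interval (ns) when the file carries no timing.
#' @param replica_id Replica label stored on the trajectory.
#' @return A `bt_trajectory`.
#' @export
load_trajectory <- function(topology, coords,
                            role_spec = default_role_spec(),
                            optional = c("polar_marker", "solute_com",
                                         "chain_carbon", "chain_hydrogen"),
                            dt = NULL, replica_id = 1L) {
  top <- read_pdb_frames(topology)
  atoms <- top$atoms
  roles <- match_roles(atoms, role_spec, optional)
  if (grepl("\\.dcd$", coords, ignore.case = TRUE)) {
    tr <- read_dcd(coords)
    times <- tr$times
  } else {
    tr <- read_pdb_frames(coords)
    times <- tr$times
    if (anyNA(times)) {
      if (is.null(dt)) dt <- 1
      times <- (seq_len(dim(tr$coords)[3]) - 1L) * dt
    }
  }
  if (dim(tr$coords)[1] != nrow(atoms))
    stop("topology and coordinate files disagree on particle count")
  bt_trajectory(tr$coords, tr$box, times, roles, atoms$resid,
                replica_id = replica_id)
}
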