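#' @importFrom stats rnorm runif sd quantile median setNames cor dist optim
#' @importFrom utils head tail write.table read.table
NULL

# Bondi van der Waals radii (angstrom); 1.70 fallback for anything unlisted.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
.VDW_DEFAULT <- 1.70

#' Van der Waals radius for an element symbol
#'
#' Bondi radii with a 1.70 angstrom fallback for unlisted elements.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .BONDI[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Infer element symbols from atom names when the element column is blank.
# Leading digits are stripped (e.g. "1HB"); a two-letter match against the
# radius table wins over one letter so CL/BR parse correctly.
.infer_element <- function(atom_name) {
  nm <- toupper(gsub("^[0-9 ]+", "", atom_name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% names(.BONDI) & !(one %in% c("C", "N", "O", "H")), two, one)
}

#' Construct a structure object
#'
#' A structure is one frame of named atoms: identity columns, coordinates in
#' angstrom, element and van der Waals radius. The (chain_id, residue_number,
#' atom_name) triples must be unique.
#'
#' @param atoms data.frame with columns atom_name, residue_name,
#'   residue_number, chain_id, element, x, y, z and optionally vdw_radius.
#' @param label free-text label carried through reports.
#' @return object of class \code{md_structure}.
#' @export
md_structure <- function(atoms, label = "") {
  req <- c("atom_name", "residue_name", "residue_number", "chain_id",
           "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- vdw_radius(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure")
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name) triple: ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("<md_structure> %s: %d atoms, %d residues, chains: %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s an \code{md_structure}.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinates of a structure as a matrix
#' @param s an \code{md_structure}.
#' @return n x 3 numeric matrix (angstrom).
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Replace the coordinates of a structure
#' @param s an \code{md_structure}.
#' @param xyz n x 3 matrix.
#' @return updated structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == n_atoms(s), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Construct a trajectory object
#'
#' Ordered frames sharing one topology. Every frame carries exactly one
#' coordinate triple per topology atom; frame times (ns) increase strictly.
#'
#' @param topology an \code{md_structure}.
#' @param frames list of n x 3 coordinate matrices.
#' @param times_ns numeric vector of frame times in nanoseconds.
#' @return object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(topology, frames, times_ns) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(frames) != length(times_ns))
    stop("frames and times_ns differ in length")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3)
      stop(sprintf("frame %d has %s atoms; topology has %d (topology mismatch)",
                   i, if (is.matrix(f)) nrow(f) else "?", na))
  }
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames,
                 times_ns = as.numeric(times_ns)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %.3g..%.3g ns\n",
              n_frames(x), n_atoms(x$topology),
              x$times_ns[1], x$times_ns[length(x$times_ns)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{md_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a structure
#' @param traj an \code{md_trajectory}.
#' @param i frame index (1-based).
#' @return \code{md_structure} with that frame's coordinates.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  set_coords(traj$topology, traj$frames[[i]])
}

# ---- PDB I/O ---------------------------------------------------------------

.parse_pdb_atom_line <- function(line, lineno) {
  field <- function(a, b) substr(line, a, b)
  num <- function(a, b, what) {
    txt <- trimws(field(a, b))
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v))
      stop(sprintf("line %d: malformed %s field '%s'", lineno, what, txt),
           call. = FALSE)
    v
  }
  altloc <- field(17, 17)
  if (!(altloc %in% c(" ", "", "A"))) return(NULL)  # keep '' or 'A' only
  el <- trimws(field(77, 78))
  nm <- trimws(field(13, 16))
  if (!nzchar(el)) el <- .infer_element(nm)
  list(atom_name = nm,
       residue_name = trimws(field(18, 20)),
       residue_number = as.integer(num(23, 26, "residue number")),
       chain_id = trimws(field(22, 22)),
       element = toupper(el),
       x = num(31, 38, "x coordinate"),
       y = num(39, 46, "y coordinate"),
       z = num(47, 54, "z coordinate"))
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records with fixed columns. MODEL/ENDMDL blocks are
#' optional; with \code{model_policy = "all"} a multi-model file becomes a
#' trajectory whose topology is model 1 (frame times default to the model
#' index in ns unless given). Alternate locations other than '' or 'A' are
#' dropped. Elements are taken from the element column when present, else
#' inferred from the atom name; Bondi radii are attached.
#'
#' @param path PDB file path.
#' @param model_policy "first" returns an \code{md_structure} from model 1;
#'   "all" returns an \code{md_trajectory} over all models (a single-model
#'   file still yields a structure).
#' @param times_ns optional frame times when reading all models.
#' @return \code{md_structure} or \code{md_trajectory}.
#' @export
read_pdb <- function(path, model_policy = c("first", "all"), times_ns = NULL) {
  model_policy <- match.arg(model_policy)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list(); cur <- list(); in_any <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      if (length(cur)) { models[[length(models) + 1L]] <- cur; cur <- list() }
      in_any <- TRUE
    } else if (r == "ENDMDL") {
      models[[length(models) + 1L]] <- cur; cur <- list()
    } else if (r %in% c("ATOM  ", "HETATM")) {
      a <- .parse_pdb_atom_line(lines[i], i)
      if (!is.null(a)) cur[[length(cur) + 1L]] <- a
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- cur
  models <- Filter(length, models)
  if (!length(models)) stop("no ATOM/HETATM records in ", path)

  as_struct <- function(recs, label) {
    df <- do.call(rbind, lapply(recs, function(a)
      as.data.frame(a, stringsAsFactors = FALSE)))
    md_structure(df, label = label)
  }
  topo <- as_struct(models[[1]], label = basename(path))
  if (model_policy == "first" || length(models) == 1L) return(topo)

  na <- n_atoms(topo)
  frames <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    if (length(m) != na)
      stop(sprintf("model %d has %d atoms but model 1 has %d (topology mismatch)",
                   k, length(m), na))
    matrix(unlist(lapply(m, function(a) c(a$x, a$y, a$z))),
           ncol = 3, byrow = TRUE)
  })
  if (is.null(times_ns)) times_ns <- seq_along(frames)
  md_trajectory(topo, frames, times_ns)
}

.format_pdb_atom <- function(i, a) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          i %% 100000,
          if (nchar(a$atom_name) < 4) paste0(" ", a$atom_name) else a$atom_name,
          substr(a$residue_name, 1, 3),
          if (nzchar(a$chain_id)) substr(a$chain_id, 1, 1) else "A",
          a$residue_number %% 10000, a$x, a$y, a$z, substr(a$element, 1, 2))
}

#' Write a structure or trajectory as PDB
#'
#' Fixed-column ATOM records; trajectories become MODEL/ENDMDL blocks.
#' Coordinates are serialized at 3 decimals (PDB fixed width), so a
#' read-back reproduces names, numbering and coordinates to 3 decimals.
#'
#' @param s \code{md_structure} or \code{md_trajectory}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(s, path) {
  con <- file(path, "w"); on.exit(close(con))
  emit_struct <- function(st) {
    at <- st$atoms
    for (i in seq_len(nrow(at)))
      writeLines(.format_pdb_atom(i, as.list(at[i, ])), con)
  }
  if (inherits(s, "md_structure")) {
    emit_struct(s)
  } else if (inherits(s, "md_trajectory")) {
    for (k in seq_len(n_frames(s))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      emit_struct(get_frame(s, k))
      writeLines("ENDMDL", con)
    }
  } else stop("not an md_structure or md_trajectory")
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a plain per-frame coordinate table
#'
#' Lightweight trajectory dialect: a delimited table with columns
#' frame, time_ns, atom_index, x, y, z.
#'
#' @param traj an \code{md_trajectory}.
#' @param path output path (tab-separated).
#' @return invisibly, the path.
#' @export
write_coord_table <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj); na <- n_atoms(traj$topology)
  xyz <- do.call(rbind, traj$frames)
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   time_ns = rep(traj$times_ns, each = na),
                   atom_index = rep(seq_len(na), nf),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-frame coordinate table as a trajectory
#'
#' @param path table written by \code{\link{write_coord_table}}.
#' @param topology the \code{md_structure} the coordinates belong to.
#' @return an \code{md_trajectory}.
#' @export
read_coord_table <- function(path, topology) {
  df <- read.table(path, header = TRUE, sep = "\t")
  req <- c("frame", "time_ns", "atom_index", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("coordinate table must have columns ", paste(req, collapse = ", "))
  na <- n_atoms(topology)
  ids <- sort(unique(df$frame))
  frames <- lapply(ids, function(k) {
    sub <- df[df$frame == k, ]
    sub <- sub[order(sub$atom_index), ]
    if (nrow(sub) != na)
      stop(sprintf("frame %d has %d atoms; topology has %d (topology mismatch)",
                   k, nrow(sub), na))
    as.matrix(sub[, c("x", "y", "z")])
  })
  times <- vapply(ids, function(k) df$time_ns[df$frame == k][1], numeric(1))
  md_trajectory(topology, frames, times)
}

# ---- selection -------------------------------------------------------------

#' Select atom indices by identity criteria
#'
#' Returns indices (topology order) of atoms matching every criterion that is
#' provided; omitted criteria match everything. An empty result is valid.
#'
#' @param s an \code{md_structure}.
#' @param chain,residue_number,residue_name,atom_names,element optional
#'   filters; vectors select any of their values.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(s, chain = NULL, residue_number = NULL,
                         residue_name = NULL, atom_names = NULL,
                         element = NULL) {
  at <- s$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain))          keep <- keep & at$chain_id %in% chain
  if (!is.null(residue_number)) keep <- keep & at$residue_number %in% residue_number
  if (!is.null(residue_name))   keep <- keep & toupper(at$residue_name) %in% toupper(residue_name)
  if (!is.null(atom_names))     keep <- keep & toupper(at$atom_name) %in% toupper(atom_names)
  if (!is.null(element))        keep <- keep & toupper(at$element) %in% toupper(element)
  which(keep)
}

# Parse residue labels like "Tyr221" / "ARG 127" into name + number.
.parse_residue_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]{3})\\s*([0-9]+)$", trimws(label)))[[1]]
  if (length(m) != 3) stop("cannot parse residue label '", label,
                           "' (expected e.g. 'Tyr221')")
  list(residue_name = toupper(m[2]), residue_number = as.integer(m[3]))
}

#' Subset a structure by atom indices
#' @param s an \code{md_structure}.
#' @param idx atom indices to keep (order preserved as given).
#' @return \code{md_structure} with those atoms.
#' @export
subset_structure <- function(s, idx) {
  md_structure(s$atoms[idx, , drop = FALSE], label = s$label)
}
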