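# Core geometric observables: superposition/RMSD, pair distances, hydrogen
# bonds, SASA/volume, contact residues, steric clash.

#' Hydrogen-bond geometric criterion
#'
#' Distance/angle convention of the common MD H-bond tools: donor-acceptor
#' distance at most \code{donor_acceptor_cutoff} and hydrogen-donor-acceptor
#' angle (vertex at the donor) at most \code{angle_cutoff_deg}. The
#' \code{optimal_window} is the donor-acceptor distance band treated as
#' optimal for bond formation in occupancy reports.
#'
#' @param donor_acceptor_cutoff angstrom, default 3.5.
#' @param angle_cutoff_deg degrees, default 30.
#' @param optimal_window closed interval in angstrom, default c(2.7, 3.3).
#' @return object of class \code{hbond_criterion}.
#' @export
hbond_criterion <- function(donor_acceptor_cutoff = 3.5, angle_cutoff_deg = 30,
                            optimal_window = c(2.7, 3.3)) {
  stopifnot(donor_acceptor_cutoff > 0, angle_cutoff_deg > 0,
            length(optimal_window) == 2, optimal_window[1] < optimal_window[2])
  structure(list(donor_acceptor_cutoff = donor_acceptor_cutoff,
                 angle_cutoff_deg = angle_cutoff_deg,
                 optimal_window = optimal_window),
            class = "hbond_criterion")
}

#' Per-frame scalar series (distances, RMSD)
#'
#' @param label series label, e.g. "Tyr309O-HTyr221".
#' @param times_ns frame times (ns).
#' @param values_A per-frame values (angstrom).
#' @return object of class \code{distance_series}.
#' @export
distance_series <- function(label, times_ns, values_A) {
  if (length(times_ns) != length(values_A))
    stop("times and values differ in length")
  if (any(values_A < 0)) stop("distances must be non-negative")
  structure(list(label = label, times_ns = as.numeric(times_ns),
                 values_A = as.numeric(values_A)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s: %d frames, mean %.3f A\n",
              x$label, length(x$values_A), mean(x$values_A)))
  invisible(x)
}

#' Write a series as a tidy delimited table
#' @param series a \code{distance_series} or \code{hbond_series}.
#' @param path output path (tab-separated, columns time_ns and value).
#' @return invisibly, the path.
#' @export
write_series <- function(series, path) {
  val <- if (inherits(series, "hbond_series")) series$counts else series$values_A
  write.table(data.frame(time_ns = series$times_ns, value = val),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Kabsch superposition --------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' deviation between paired atoms of two structures, and reports the
#' minimized RMSD.
#'
#' @param mobile,reference \code{md_structure}s (or n x 3 coordinate
#'   matrices).
#' @param mobile_idx,reference_idx paired atom indices (equal length, >= 3
#'   non-collinear atoms).
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3), \code{rmsd} (angstrom). The transform maps mobile
#'   coordinates as \code{x \%*\% t(R) + t}.
#' @export
kabsch_superpose <- function(mobile, reference,
                             mobile_idx = NULL, reference_idx = NULL) {
  X <- if (is.matrix(mobile)) mobile else coords(mobile)
  Y <- if (is.matrix(reference)) reference else coords(reference)
  if (!is.null(mobile_idx)) X <- X[mobile_idx, , drop = FALSE]
  if (!is.null(reference_idx)) Y <- Y[reference_idx, , drop = FALSE]
  if (nrow(X) != nrow(Y)) stop("paired selections differ in length")
  if (nrow(X) < 3) stop("degenerate geometry: need >= 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity check: rank of the centered reference < 2
  if (sum(svd(Yc)$d > 1e-8) < 2 || sum(svd(Xc)$d > 1e-8) < 2)
    stop("degenerate geometry: collinear atom set")
  H <- crossprod(Xc, Yc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)       # maps mobile -> reference
  tr <- cy - as.vector(R %*% cx)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 rotation.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, -translation)
}

#' Per-frame RMSD trace of a trajectory
#'
#' Each frame is superposed onto frame 1 using \code{fit_selection}; the RMSD
#' is then measured over \code{measure_selection} (default: same atoms).
#' The frame-1 value is 0 by construction.
#'
#' @param traj an \code{md_trajectory}.
#' @param fit_selection atom indices used for superposition.
#' @param measure_selection atom indices the RMSD is computed over.
#' @return a \code{distance_series} (values in angstrom).
#' @export
rmsd_trace <- function(traj, fit_selection, measure_selection = fit_selection) {
  if (!length(fit_selection) || !length(measure_selection))
    stop("empty selection")
  ref <- traj$frames[[1]]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- traj$frames[[k]]
    fit <- kabsch_superpose(fr, ref, fit_selection, fit_selection)
    moved <- apply_transform(fr[measure_selection, , drop = FALSE],
                             fit$rotation, fit$translation)
    sqrt(mean(rowSums((moved - ref[measure_selection, , drop = FALSE])^2)))
  }, numeric(1))
  vals[1] <- 0
  distance_series("RMSD", traj$times_ns, vals)
}

# ---- distances -------------------------------------------------------------

#' Distance between two atoms across all frames
#'
#' @param traj an \code{md_trajectory}.
#' @param atom_a,atom_b atom indices into the topology.
#' @param label optional series label.
#' @return a \code{distance_series}.
#' @export
pair_distance_series <- function(traj, atom_a, atom_b, label = NULL) {
  na <- n_atoms(traj$topology)
  if (any(c(atom_a, atom_b) < 1) || any(c(atom_a, atom_b) > na))
    stop("atom index out of range")
  if (is.null(label)) {
    at <- traj$topology$atoms
    label <- sprintf("%s%d:%s-%s%d:%s",
                     at$residue_name[atom_a], at$residue_number[atom_a],
                     at$atom_name[atom_a],
                     at$residue_name[atom_b], at$residue_number[atom_b],
                     at$atom_name[atom_b])
  }
  d <- vapply(traj$frames, function(f)
    sqrt(sum((f[atom_a, ] - f[atom_b, ])^2)), numeric(1))
  distance_series(label, traj$times_ns, d)
}

#' Mean of a distance series, optionally at subsampled times
#'
#' @param series a \code{distance_series}.
#' @param subsample_times optional times (ns) to restrict the mean to; each
#'   must exist in the series.
#' @return arithmetic mean in angstrom (exact; see
#'   \code{\link{format_distance}} for the 2-decimal report convention).
#' @export
mean_distance <- function(series, subsample_times = NULL) {
  v <- series$values_A
  if (!length(v)) stop("empty series")
  if (!is.null(subsample_times)) {
    idx <- vapply(subsample_times, function(t) {
      j <- which(abs(series$times_ns - t) < 1e-9)
      if (!length(j)) stop("subsample time ", t, " ns not in series")
      j[1]
    }, integer(1))
    v <- v[idx]
  }
  mean(v)
}

#' Format a distance for reports (two decimals, truncated)
#'
#' Report tables carry distances truncated (not rounded) to two decimals,
#' matching the convention of the upstream visualization tools whose printed
#' tables this package reproduces.
#'
#' @param x numeric distances (angstrom).
#' @return character vector, e.g. "6.11".
#' @export
format_distance <- function(x) sprintf("%.2f", trunc(x * 100 + 1e-7) / 100)

#' Fraction of frames inside a closed distance window
#'
#' @param series a \code{distance_series}.
#' @param window closed interval c(lo, hi) in angstrom.
#' @return fraction in [0, 1].
#' @export
window_occupancy <- function(series, window = c(2.7, 3.3)) {
  v <- series$values_A
  if (!length(v)) stop("empty series")
  stopifnot(length(window) == 2, window[1] <= window[2])
  mean(v >= window[1] & v <= window[2])
}

# ---- hydrogen bonds --------------------------------------------------------

# Hydrogens covalently attached to a donor, located by the bonded-name
# convention (donor "OH" -> hydrogen "HH", "NE2" -> "HE2", "N" -> "H") or,
# failing that, by proximity (<= 1.25 A).
.donor_hydrogens <- function(s, donor) {
  at <- s$atoms
  same_res <- which(at$chain_id == at$chain_id[donor] &
                    at$residue_number == at$residue_number[donor] &
                    toupper(at$element) == "H")
  if (!length(same_res)) return(integer(0))
  want <- paste0("H", sub("^[A-Za-z]", "", toupper(at$atom_name[donor])))
  named <- same_res[toupper(at$atom_name[same_res]) == want |
                    grepl(paste0("^", want, "[0-9]$"),
                          toupper(at$atom_name[same_res]))]
  if (length(named)) return(named)
  xyz <- coords(s)
  d <- sqrt(rowSums(sweep(xyz[same_res, , drop = FALSE], 2,
                          xyz[donor, ])^2))
  same_res[d <= 1.25]
}

.angle_deg <- function(v1, v2) {
  ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-acceptor pair forms a bond iff their distance is at most the
#' criterion cutoff AND, when a bonded hydrogen is present on the donor, the
#' hydrogen-donor-acceptor angle (vertex at the donor) is at most the angle
#' cutoff. Donors without locatable hydrogens are assessed on distance alone
#' and flagged \code{distance_only}. Pairs within the same residue are
#' skipped.
#'
#' @param frame an \code{md_structure}.
#' @param criterion an \code{\link{hbond_criterion}}.
#' @param donors indices of donor heavy atoms.
#' @param acceptors indices of acceptor heavy atoms.
#' @return data.frame with columns donor, hydrogen (NA when distance-only),
#'   acceptor, distance_A, angle_deg, distance_only.
#' @export
detect_hbonds <- function(frame, criterion = hbond_criterion(),
                          donors, acceptors) {
  at <- frame$atoms
  xyz <- coords(frame)
  out <- list()
  for (d in donors) {
    hyd <- .donor_hydrogens(frame, d)
    for (a in acceptors) {
      if (a == d) next
      if (at$chain_id[a] == at$chain_id[d] &&
          at$residue_number[a] == at$residue_number[d]) next
      dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dist > criterion$donor_acceptor_cutoff) next
      if (length(hyd)) {
        angs <- vapply(hyd, function(h)
          .angle_deg(xyz[h, ] - xyz[d, ], xyz[a, ] - xyz[d, ]), numeric(1))
        j <- which.min(angs)
        if (angs[j] > criterion$angle_cutoff_deg) next
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = hyd[j], acceptor = a, distance_A = dist,
          angle_deg = angs[j], distance_only = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = NA_integer_, acceptor = a, distance_A = dist,
          angle_deg = NA_real_, distance_only = TRUE)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance_A = numeric(0),
                      angle_deg = numeric(0), distance_only = logical(0)))
  do.call(rbind, out)
}

#' Per-frame hydrogen-bond counts
#'
#' @param traj an \code{md_trajectory}.
#' @param criterion an \code{\link{hbond_criterion}}.
#' @param donors,acceptors heavy-atom index vectors.
#' @return object of class \code{hbond_series} with \code{times_ns} and
#'   integer \code{counts}.
#' @export
hbond_series <- function(traj, criterion = hbond_criterion(),
                         donors, acceptors) {
  counts <- vapply(seq_len(n_frames(traj)), function(k)
    nrow(detect_hbonds(get_frame(traj, k), criterion, donors, acceptors)),
    integer(1))
  structure(list(times_ns = traj$times_ns, counts = counts),
            class = "hbond_series")
}

# ---- SASA ------------------------------------------------------------------

# Deterministic quasi-uniform sphere points (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley) and molecular volume
#'
#' Area: each atom's solvent-accessible sphere (vdW radius + probe) is
#' sampled with a deterministic quasi-uniform point set; the accessible
#' fraction times the sphere area gives the per-atom area. Volume: Monte
#' Carlo integration of the union of (vdW + probe) spheres inside their
#' bounding box, with a fixed seed so results are reproducible; the standard
#' error of the volume estimate is reported.
#'
#' @param s an \code{md_structure} (radii attached at construction).
#' @param probe_radius probe sphere radius in angstrom (water: 1.4).
#' @param n_points surface sample points per atom (default 960).
#' @param volume_samples Monte-Carlo samples for the volume (default 1e6).
#' @param seed RNG seed for the volume integration.
#' @return object of class \code{sasa_result}: \code{area_A2},
#'   \code{volume_A3}, \code{volume_se_A3}, \code{per_atom_area}.
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 960,
                 volume_samples = 1e6, seed = 1L) {
  n <- n_atoms(s)
  if (!n) stop("empty structure")
  xyz <- coords(s)
  rad <- s$atoms$vdw_radius + probe_radius
  pts <- .sphere_points(n_points)
  d2 <- as.matrix(dist(xyz))^2
  per_atom <- vapply(seq_len(n), function(i) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    surf <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(surf[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj2 >= rad[j]^2
    }
    4 * pi * rad[i]^2 * mean(acc)
  }, numeric(1))

  vol <- NA_real_; vse <- NA_real_
  if (volume_samples > 0) {
    lo <- apply(xyz - rad, 2, min); hi <- apply(xyz + rad, 2, max)
    box <- prod(hi - lo)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    m <- as.integer(volume_samples)
    p <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
               runif(m, lo[3], hi[3]))
    inside <- rep(FALSE, m)
    for (i in seq_len(n)) {
      todo <- which(!inside)
      if (!length(todo)) break
      inside[todo] <- rowSums(sweep(p[todo, , drop = FALSE], 2,
                                    xyz[i, ])^2) < rad[i]^2
    }
    frac <- mean(inside)
    vol <- box * frac
    vse <- box * sqrt(frac * (1 - frac) / m)
  }
  structure(list(area_A2 = sum(per_atom), volume_A3 = vol,
                 volume_se_A3 = vse, per_atom_area = per_atom,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> area %.2f A^2; volume %.2f A^3 (se %.2f)\n",
              x$area_A2, x$volume_A3, x$volume_se_A3))
  invisible(x)
}

# ---- contacts and clash ----------------------------------------------------

.residue_label <- function(name, number) {
  nm <- paste0(toupper(substr(name, 1, 1)), tolower(substr(name, 2, 3)))
  paste0(nm, number)
}

#' Residues contacting a ligand
#'
#' Residues (outside the ligand selection) with at least one heavy atom
#' within \code{cutoff} of any ligand heavy atom, sorted by residue number.
#'
#' @param complex an \code{md_structure} holding receptor and ligand.
#' @param ligand_selection atom indices of the ligand.
#' @param cutoff heavy-atom distance cutoff in angstrom (default 4.0).
#' @return character vector of residue labels, e.g. "Trp85".
#' @export
residue_contacts <- function(complex, ligand_selection, cutoff = 4.0) {
  if (!length(ligand_selection)) stop("empty ligand selection")
  at <- complex$atoms
  xyz <- coords(complex)
  heavy <- toupper(at$element) != "H"
  lig <- intersect(ligand_selection, which(heavy))
  rec <- setdiff(which(heavy), ligand_selection)
  if (!length(lig) || !length(rec)) return(character(0))
  hits <- logical(length(rec))
  for (i in seq_along(rec)) {
    d2 <- rowSums(sweep(xyz[lig, , drop = FALSE], 2, xyz[rec[i], ])^2)
    hits[i] <- any(d2 <= cutoff^2)
  }
  sub <- at[rec[hits], , drop = FALSE]
  if (!nrow(sub)) return(character(0))
  u <- unique(sub[, c("residue_name", "residue_number")])
  u <- u[order(u$residue_number), , drop = FALSE]
  .residue_label(u$residue_name, u$residue_number)
}

#' Steric-clash check between two residues
#'
#' Two residues clash when any heavy-atom pair between them is closer than
#' the sum of their van der Waals radii minus \code{tolerance}.
#'
#' @param receptor,partner \code{md_structure}s carrying the residues.
#' @param receptor_residue,partner_residue labels like "Arg127", "Tyr356".
#' @param tolerance allowed overlap in angstrom (default 0.4).
#' @return object of class \code{clash_report}: \code{min_distance_A},
#'   \code{overlapping_pairs} (data.frame with overlap in angstrom),
#'   \code{clash}.
#' @export
clash_check <- function(receptor, partner, receptor_residue = "Arg127",
                        partner_residue = "Tyr356", tolerance = 0.4) {
  pick <- function(s, label) {
    r <- .parse_residue_label(label)
    idx <- select_atoms(s, residue_number = r$residue_number,
                        residue_name = r$residue_name)
    idx <- idx[toupper(s$atoms$element[idx]) != "H"]
    if (!length(idx)) stop("residue ", label, " not found (or has no heavy atoms)")
    idx
  }
  ri <- pick(receptor, receptor_residue)
  pi_ <- pick(partner, partner_residue)
  rx <- coords(receptor); px <- coords(partner)
  rows <- list(); mind <- Inf
  for (i in ri) for (j in pi_) {
    d <- sqrt(sum((rx[i, ] - px[j, ])^2))
    mind <- min(mind, d)
    thr <- receptor$atoms$vdw_radius[i] + partner$atoms$vdw_radius[j] - tolerance
    if (d < thr)
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_atom = receptor$atoms$atom_name[i],
        partner_atom = partner$atoms$atom_name[j],
        distance_A = d, overlap_A = thr - d)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(receptor_atom = character(0), partner_atom = character(0),
               distance_A = numeric(0), overlap_A = numeric(0))
  structure(list(receptor_residue = receptor_residue,
                 partner_residue = partner_residue,
                 tolerance_A = tolerance,
                 min_distance_A = mind,
                 overlapping_pairs = pairs,
                 clash = nrow(pairs) > 0),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> %s vs %s: min distance %.2f A, clash = %s\n",
              x$receptor_residue, x$partner_residue, x$min_distance_A,
              x$clash))
  invisible(x)
}
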