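# Biased-agonism structural diagnostic: Tyr-pair hydrogen-bond persistence
# combined with a G-protein steric-clash assessment.

#' Tyrosine-pair distance report (TM5/TM7 hydrogen-bond diagnostic)
#'
#' For a tyrosine pair (phenolic oxygen OH, hydroxyl hydrogen HH) the report
#' carries both donor-direction series in the style of an MD distance table:
#' acceptor-oxygen to donor-hydrogen distances for a->b and b->a. Hydrogen
#' bond occupancy is assessed on the donor-acceptor heavy-atom (O...O)
#' distance against the optimal window, since the geometric criterion for
#' bond formation is stated between donor and acceptor heavy atoms.
#'
#' @param traj an \code{md_trajectory}.
#' @param res_a,res_b residue labels (default "Tyr221", "Tyr309"); both must
#'   carry OH and HH atoms.
#' @param window optimal donor-acceptor window in angstrom (default
#'   c(2.7, 3.3)).
#' @param subsample_ns optional times (ns) at which subsampled means are
#'   reported, e.g. \code{seq(10, 100, 10)}; used only when every time
#'   exists in the trajectory.
#' @return object of class \code{tyr_pair_report}: \code{series_ab} (O of
#'   res_b to H of res_a), \code{series_ba}, \code{oo_series} (heavy-atom
#'   distance), \code{pair_means_A}, \code{subsample_means_A} (or NULL),
#'   \code{occupancy}, \code{window}.
#' @export
tyr_pair_report <- function(traj, res_a = "Tyr221", res_b = "Tyr309",
                            window = c(2.7, 3.3), subsample_ns = NULL) {
  topo <- traj$topology
  find_atom <- function(label, atom) {
    r <- .parse_residue_label(label)
    idx <- select_atoms(topo, residue_number = r$residue_number,
                        residue_name = r$residue_name, atom_names = atom)
    if (!length(idx))
      stop("atom ", atom, " of residue ", label, " not found in topology")
    idx[1]
  }
  oa <- find_atom(res_a, "OH"); ha <- find_atom(res_a, "HH")
  ob <- find_atom(res_b, "OH"); hb <- find_atom(res_b, "HH")
  lab <- function(x) { r <- .parse_residue_label(x)
    .residue_label(r$residue_name, r$residue_number) }
  series_ab <- pair_distance_series(traj, ob, ha,
    label = sprintf("%sO-H%s", lab(res_b), lab(res_a)))
  series_ba <- pair_distance_series(traj, oa, hb,
    label = sprintf("%sO-H%s", lab(res_a), lab(res_b)))
  oo <- pair_distance_series(traj, oa, ob,
    label = sprintf("%sO-%sO", lab(res_a), lab(res_b)))
  means <- c(mean_distance(series_ab), mean_distance(series_ba))
  names(means) <- c(series_ab$label, series_ba$label)
  sub <- NULL
  if (!is.null(subsample_ns) &&
      all(vapply(subsample_ns, function(t)
        any(abs(traj$times_ns - t) < 1e-9), logical(1)))) {
    sub <- c(mean_distance(series_ab, subsample_ns),
             mean_distance(series_ba, subsample_ns))
    names(sub) <- names(means)
  }
  structure(list(series_ab = series_ab, series_ba = series_ba,
                 oo_series = oo, pair_means_A = means,
                 subsample_means_A = sub,
                 occupancy = window_occupancy(oo, window),
                 window = window),
            class = "tyr_pair_report")
}

#' @export
print.tyr_pair_report <- function(x, ...) {
  cat(sprintf("<tyr_pair_report> %s = %s A; %s = %s A; occupancy[%.1f,%.1f] = %.2f\n",
              x$series_ab$label, format_distance(x$pair_means_A[1]),
              x$series_ba$label, format_distance(x$pair_means_A[2]),
              x$window[1], x$window[2], x$occupancy))
  invisible(x)
}

#' Format a tyrosine-pair report as a distance table
#'
#' One row per frame (or per subsample time), both donor directions as
#' columns, distances truncated to two decimals.
#'
#' @param report a \code{tyr_pair_report}.
#' @param times_ns optional subset of times to print.
#' @return data.frame with columns time_ns and one per direction.
#' @export
tyr_pair_table <- function(report, times_ns = NULL) {
  t <- report$series_ab$times_ns
  keep <- if (is.null(times_ns)) seq_along(t) else
    which(vapply(t, function(x) any(abs(times_ns - x) < 1e-9), logical(1)))
  out <- data.frame(time_ns = t[keep],
                    a = format_distance(report$series_ab$values_A[keep]),
                    b = format_distance(report$series_ba$values_A[keep]))
  names(out)[2:3] <- c(report$series_ab$label, report$series_ba$label)
  out
}

#' Superpose a receptor conformer into a G-protein template and test the
#' activation-cavity clash
#'
#' The receptor conformer (typically the top cluster centroid) is superposed
#' onto the template's receptor chain by Kabsch on CA atoms paired by shared
#' residue numbers; the template receptor is then discarded and a van der
#' Waals clash check is run between the conformer's Arg residue (TM3,
#' intracellular cavity) and the G-protein partner chain's Tyr residue.
#'
#' @param receptor_centroid \code{md_structure} conformer carrying
#'   \code{receptor_residue}.
#' @param template_complex two-chain \code{md_structure}: a receptor-like
#'   chain to superpose on (then discard) and a partner (G-protein) chain.
#' @param receptor_chain,partner_chain chain ids in the template.
#' @param receptor_residue,partner_residue labels (defaults "Arg127",
#'   "Tyr356").
#' @param tolerance clash tolerance in angstrom (default 0.4).
#' @return a \code{clash_report} (see \code{\link{clash_check}}).
#' @export
gprotein_dock_assess <- function(receptor_centroid, template_complex,
                                 receptor_chain = "A", partner_chain = "B",
                                 receptor_residue = "Arg127",
                                 partner_residue = "Tyr356",
                                 tolerance = 0.4) {
  tat <- template_complex$atoms
  if (!any(tat$chain_id == receptor_chain))
    stop("template has no chain '", receptor_chain, "'")
  if (!any(tat$chain_id == partner_chain))
    stop("template has no chain '", partner_chain, "'")
  tmpl_ca <- select_atoms(template_complex, chain = receptor_chain,
                          atom_names = "CA")
  cent_ca <- select_atoms(receptor_centroid, atom_names = "CA")
  shared <- intersect(receptor_centroid$atoms$residue_number[cent_ca],
                      tat$residue_number[tmpl_ca])
  if (length(shared) < 3)
    stop("fewer than 3 shared CA residues between centroid and template")
  m_idx <- cent_ca[match(shared, receptor_centroid$atoms$residue_number[cent_ca])]
  r_idx <- tmpl_ca[match(shared, tat$residue_number[tmpl_ca])]
  fit <- kabsch_superpose(receptor_centroid, template_complex, m_idx, r_idx)
  moved <- set_coords(receptor_centroid,
                      apply_transform(coords(receptor_centroid),
                                      fit$rotation, fit$translation))
  partner <- subset_structure(template_complex,
                              select_atoms(template_complex,
                                           chain = partner_chain))
  clash_check(moved, partner, receptor_residue, partner_residue, tolerance)
}

#' Classify transducer bias from H-bond persistence and G-protein clash
#'
#' Pure rule over the two structural observables: the ligand is called
#' beta-arrestin-biased when the tyrosine-pair hydrogen bond is persistent
#' (occupancy at or above the threshold) AND the G-protein partner residue
#' clashes with the receptor cavity; G-protein-competent when neither holds;
#' indeterminate otherwise.
#'
#' @param tyr_report a \code{\link{tyr_pair_report}} (or a bare occupancy in
#'   [0, 1]).
#' @param clash_report a \code{\link{clash_check}} report.
#' @param occupancy_threshold persistence threshold (default 0.5).
#' @return object of class \code{bias_report}: \code{pair_means_A},
#'   \code{occupancy}, \code{hbond_persistent}, \code{clash},
#'   \code{call} (one of "beta-arrestin-biased", "G-protein-competent",
#'   "indeterminate"), \code{evidence}.
#' @export
classify_bias <- function(tyr_report, clash_report,
                          occupancy_threshold = 0.5) {
  occ <- if (inherits(tyr_report, "tyr_pair_report")) tyr_report$occupancy
         else as.numeric(tyr_report)
  stopifnot(occ >= 0, occ <= 1, inherits(clash_report, "clash_report"))
  persistent <- occ >= occupancy_threshold
  call <- if (persistent && clash_report$clash) "beta-arrestin-biased"
          else if (!persistent && !clash_report$clash) "G-protein-competent"
          else "indeterminate"
  evidence <- c(
    sprintf("Tyr-pair donor-acceptor window occupancy %.3f %s threshold %.2f -> hydrogen bond %s",
            occ, if (persistent) ">=" else "<", occupancy_threshold,
            if (persistent) "persistent" else "not persistent"),
    sprintf("%s vs %s min heavy-atom distance %.2f A (vdW overlap tolerance %.2f A) -> clash %s",
            clash_report$receptor_residue, clash_report$partner_residue,
            clash_report$min_distance_A, clash_report$tolerance_A,
            clash_report$clash),
    "Clash is computed from van der Waals overlap, a deterministic stand-in for visual inspection of the docked G protein.")
  structure(list(
    pair_means_A = if (inherits(tyr_report, "tyr_pair_report"))
      tyr_report$pair_means_A else NULL,
    occupancy = occ,
    hbond_persistent = persistent,
    clash = clash_report,
    call = call,
    evidence = evidence), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> call = %s\n", x$call))
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Serialize a bias report as JSON
#' @param report a \code{bias_report}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bias_report <- function(report, path) {
  obj <- list(call = report$call,
              occupancy = report$occupancy,
              hbond_persistent = report$hbond_persistent,
              pair_means_A = as.list(report$pair_means_A),
              clash = list(receptor_residue = report$clash$receptor_residue,
                           partner_residue = report$clash$partner_residue,
                           min_distance_A = report$clash$min_distance_A,
                           clash = report$clash$clash),
              evidence = report$evidence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
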