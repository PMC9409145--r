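test_that("Kabsch superposition: identity, rigid-motion invariance, symmetry", {
  s <- make_toy_receptor(12)
  X <- coords(s)
  fit <- kabsch_superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  # 90 degrees about z plus a translation: RMSD must return to zero
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- sweep(X %*% t(Rz), 2, c(5, -3, 11), "+")
  fit2 <- kabsch_superpose(Y, X)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)

  # symmetry and invariance under rigid motion of either argument
  set.seed(9)
  Z <- X + matrix(rnorm(length(X), sd = 0.5), ncol = 3)
  r_ab <- kabsch_superpose(X, Z)$rmsd
  expect_equal(kabsch_superpose(Z, X)$rmsd, r_ab, tolerance = 1e-9)
  for (sd in c(1, 2)) {
    mv <- random_rigid(sd)
    Zm <- sweep(Z %*% t(mv$R), 2, mv$t, "+")
    expect_equal(kabsch_superpose(X, Zm)$rmsd, r_ab, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD matches a brute-force rotation search on toy sets", {
  toys <- list(
    list(X = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE),
         Y = matrix(c(0, 0, 0, 0, 1.2, 0, -1, 0, 0.3, 0, 0.1, 1.1),
                    4, 3, byrow = TRUE)),
    list(X = matrix(c(1, 2, 0, -1, 0, 2, 0, -2, 1, 2, 1, -1),
                    4, 3, byrow = TRUE),
         Y = matrix(c(0.5, 2.5, 0, -1, 0.2, 1.8, 0.1, -2, 1.4, 1.9, 0.8, -1),
                    4, 3, byrow = TRUE)))
  for (toy in toys) {
    expect_equal(kabsch_superpose(toy$X, toy$Y)$rmsd,
                 oracle_min_rmsd(toy$X, toy$Y), tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD agrees with bio3d's fitted RMSD", {
  skip_if_not_installed("bio3d")
  set.seed(21)
  X <- matrix(rnorm(30, sd = 3), ncol = 3)
  Y <- X + matrix(rnorm(30, sd = 0.4), ncol = 3)
  ours <- kabsch_superpose(Y, X)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})

test_that("degenerate superposition inputs error", {
  X <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_error(kabsch_superpose(X, X), "3 paired atoms")
  L <- cbind(1:4, 0, 0)  # exactly collinear
  expect_error(kabsch_superpose(L, L), "collinear")
})

test_that("RMSD trace is zero for static or rigidly moved frames and matches
          the direct formula on a crafted perturbation", {
  base <- make_toy_receptor(10)
  X <- coords(base)
  static <- md_trajectory(base, list(X, X, X), 1:3)
  sel <- select_atoms(base, atom_names = "CA")
  expect_equal(rmsd_trace(static, sel)$values_A, c(0, 0, 0))

  shifted <- md_trajectory(base, list(X, X + 5, sweep(X %*%
    t(quat_to_rot(c(1, 2, 3, 4))), 2, c(1, 2, 3), "+")), 1:3)
  expect_equal(rmsd_trace(shifted, sel)$values_A, c(0, 0, 0),
               tolerance = 1e-9)

  # perturb one CA by delta: fitted RMSD must match its own definition
  X2 <- X; X2[sel[2], ] <- X2[sel[2], ] + c(0.9, 0, 0)
  tr <- md_trajectory(base, list(X, X2), 1:2)
  got <- rmsd_trace(tr, sel)$values_A[2]
  fit <- kabsch_superpose(X2[sel, ], X[sel, ])
  expect_equal(got, fit$rmsd, tolerance = 1e-12)
  expect_lt(got, 0.9 / sqrt(length(sel)) + 1e-6)  # fit can only shrink it
  expect_error(rmsd_trace(tr, integer(0)), "empty selection")
})

test_that("pair distances: Pythagorean check, coincident atoms, bad index", {
  at <- data.frame(atom_name = c("A1", "A2"), residue_name = "LIG",
                   residue_number = 1:2, chain_id = "A", element = "C",
                   x = c(0, 3), y = c(0, 4), z = 0)
  s <- md_structure(at)
  tr <- md_trajectory(s, list(coords(s), coords(s)), 1:2)
  expect_equal(pair_distance_series(tr, 1, 2)$values_A, c(5, 5))
  expect_equal(pair_distance_series(tr, 1, 1)$values_A, c(0, 0))
  expect_error(pair_distance_series(tr, 1, 7), "out of range")
})

test_that("printed distance-table columns reproduce the reported means and
          window occupancies", {
  t5 <- TYR_DIST_TABLE
  mk <- function(v) distance_series("x", t5$times, v)
  expect_equal(format_distance(mean_distance(mk(t5$ec_309O_H221))), "2.97")
  expect_equal(format_distance(mean_distance(mk(t5$ec_221O_H309))), "2.94")
  expect_equal(format_distance(mean_distance(mk(t5$cmf_309O_H221))), "6.11")
  expect_equal(format_distance(mean_distance(mk(t5$cmf_221O_H309))), "6.02")
  # hand-counted occupancy of the optimal window
  expect_equal(window_occupancy(mk(t5$ec_221O_H309), c(2.7, 3.3)), 5 / 10)
  expect_equal(window_occupancy(mk(t5$cmf_221O_H309), c(2.7, 3.3)), 0)
  # subsampling picks exactly the requested times
  s <- mk(t5$ec_309O_H221)
  expect_equal(mean_distance(s, c(10, 20)), mean(c(3.04, 3.41)))
  expect_error(mean_distance(s, 15), "not in series")
  expect_equal(mean_distance(mk(rep(4.2, 10))), 4.2)
})

test_that("window occupancy is monotone non-decreasing as the window widens", {
  set.seed(5)
  s <- distance_series("x", 1:200, runif(200, 1, 8))
  widths <- seq(0.1, 4, by = 0.1)
  occ <- sapply(widths, function(w)
    window_occupancy(s, c(3 - w, 3 + w)))
  expect_true(all(diff(occ) >= 0))
  expect_equal(window_occupancy(s, c(0, 10)), 1)
})

test_that("hydrogen-bond detection follows the distance + angle criterion", {
  mk <- function(hpos, apos, dpos = c(0, 0, 0)) {
    at <- data.frame(
      atom_name = c("OG", "HG", "O"),
      residue_name = c("SER", "SER", "GLY"),
      residue_number = c(1L, 1L, 2L),
      chain_id = "A", element = c("O", "H", "O"),
      x = c(dpos[1], hpos[1], apos[1]),
      y = c(dpos[2], hpos[2], apos[2]),
      z = c(dpos[3], hpos[3], apos[3]))
    md_structure(at)
  }
  crit <- hbond_criterion()
  # collinear D-H...A at 2.9 A: both criteria met
  expect_equal(nrow(detect_hbonds(mk(c(1, 0, 0), c(2.9, 0, 0)), crit,
                                  donors = 1, acceptors = 3)), 1)
  # too far
  expect_equal(nrow(detect_hbonds(mk(c(1, 0, 0), c(4.0, 0, 0)), crit,
                                  donors = 1, acceptors = 3)), 0)
  # close enough but hydrogen 60 degrees off the D->A direction
  h60 <- c(cos(pi / 3), sin(pi / 3), 0)
  expect_equal(nrow(detect_hbonds(mk(h60, c(3.0, 0, 0)), crit,
                                  donors = 1, acceptors = 3)), 0)
  # donor without hydrogen: distance-only, flagged
  s <- mk(c(1, 0, 0), c(2.9, 0, 0))
  s2 <- subset_structure(s, c(1, 3))
  hb <- detect_hbonds(s2, crit, donors = 1, acceptors = 2)
  expect_equal(nrow(hb), 1)
  expect_true(hb$distance_only)
})

test_that("hydrogen-bond counts equal brute-force enumeration on random
          small systems", {
  crit <- hbond_criterion()
  for (seed in 1:20) {
    sys <- random_hbond_system(seed)
    got <- nrow(detect_hbonds(sys$frame, crit, sys$donors, sys$acceptors))
    expect_equal(got, oracle_hbonds(sys$frame, crit, sys$donors,
                                    sys$acceptors),
                 info = paste("seed", seed))
  }
})

test_that("per-frame H-bond series tracks alternating geometries", {
  sys <- random_hbond_system(1, n_donors = 1, n_acceptors = 1)
  s <- sys$frame
  xyz <- coords(s)
  bonded <- xyz; bonded[3, ] <- bonded[1, ] + c(2.9, 0, 0)
  bonded[2, ] <- bonded[1, ] + c(1, 0, 0)
  unbonded <- bonded; unbonded[3, ] <- bonded[1, ] + c(6, 0, 0)
  tr <- md_trajectory(s, list(bonded, unbonded, bonded, unbonded), 1:4)
  hs <- hbond_series(tr, hbond_criterion(), sys$donors, sys$acceptors)
  expect_equal(hs$counts, c(1L, 0L, 1L, 0L))
})

test_that("SASA: analytic sphere, disjoint additivity, overlap cap formula", {
  one <- md_structure(data.frame(
    atom_name = "S1", residue_name = "LIG", residue_number = 1,
    chain_id = "A", element = "C", x = 0, y = 0, z = 0, vdw_radius = 1.5))
  res <- sasa(one, probe_radius = 1.4, n_points = 960, volume_samples = 2e5)
  expect_equal(res$area_A2, 4 * pi * 2.9^2, tolerance = 0.005)
  # Monte-Carlo volume of the solvent-inflated sphere within 4 SE
  expect_lt(abs(res$volume_A3 - 4 / 3 * pi * 2.9^3), 4 * res$volume_se_A3)

  two_far <- md_structure(data.frame(
    atom_name = c("S1", "S2"), residue_name = "LIG", residue_number = 1:2,
    chain_id = "A", element = "C", x = c(0, 10), y = 0, z = 0,
    vdw_radius = 1.5))
  far <- sasa(two_far, volume_samples = 0)
  expect_equal(far$area_A2, 2 * 4 * pi * 2.9^2, tolerance = 1e-6)
  expect_equal(sum(far$per_atom_area), far$area_A2, tolerance = 1e-9)

  for (d in c(2.0, 3.5, 5.0)) {
    two <- md_structure(data.frame(
      atom_name = c("S1", "S2"), residue_name = "LIG", residue_number = 1:2,
      chain_id = "A", element = "C", x = c(0, d), y = 0, z = 0,
      vdw_radius = 1.5))
    got <- sasa(two, volume_samples = 0)$area_A2
    expect_equal(got, two_sphere_area(2.9, d), tolerance = 0.01 *
                   two_sphere_area(2.9, d))
    expect_true(all(sasa(two, volume_samples = 0)$per_atom_area >= 0))
  }
  expect_error(sasa(md_structure(one$atoms[0, ])), "empty")
})

test_that("contact residues match an exhaustive distance matrix", {
  place <- function(resno, resn, d) data.frame(
    atom_name = "CB", residue_name = resn, residue_number = resno,
    chain_id = "A", element = "C", x = d, y = 0, z = 0)
  lig <- data.frame(atom_name = "C1", residue_name = "LIG",
                    residue_number = 900, chain_id = "L", element = "C",
                    x = 0, y = 0, z = 0)
  cplx <- md_structure(rbind(lig, place(85, "TRP", 3), place(109, "ILE", 4.5),
                             place(182, "TYR", 6)))
  lsel <- select_atoms(cplx, chain = "L")
  expect_equal(residue_contacts(cplx, lsel, cutoff = 4.0), "Trp85")
  expect_equal(residue_contacts(cplx, lsel, cutoff = 5.0),
               c("Trp85", "Ile109"))
  expect_equal(residue_contacts(cplx, lsel, cutoff = 0), character(0))
  expect_error(residue_contacts(cplx, integer(0)), "empty")
  # brute force: each residue in iff its min heavy distance <= cutoff
  xyz <- coords(cplx)
  for (cut in c(2, 4, 5, 7)) {
    want <- c("Trp85", "Ile109", "Tyr182")[c(3, 4.5, 6) <= cut]
    expect_equal(residue_contacts(cplx, lsel, cut), want)
  }
})

test_that("steric clash flips exactly at the vdW threshold", {
  carbons <- function(d) md_structure(data.frame(
    atom_name = c("C1", "C2"), residue_name = c("ALA", "GLY"),
    residue_number = c(1, 2), chain_id = c("A", "B"), element = "C",
    x = c(0, d), y = 0, z = 0))
  s <- carbons(1.0)
  rep <- clash_check(subset_structure(s, 1), subset_structure(s, 2),
                     "Ala1", "Gly2")
  expect_true(rep$clash)
  expect_equal(rep$overlapping_pairs$overlap_A, 2.0)  # 1.7+1.7-0.4-1.0
  far <- carbons(10)
  rep2 <- clash_check(subset_structure(far, 1), subset_structure(far, 2),
                      "Ala1", "Gly2")
  expect_false(rep2$clash)
  expect_equal(rep2$min_distance_A, 10)
  # threshold: sum of radii minus tolerance = 3.0 exactly
  thr <- 1.7 + 1.7 - 0.4
  for (d in c(thr - 0.01, thr + 0.01)) {
    s <- carbons(d)
    expect_equal(clash_check(subset_structure(s, 1), subset_structure(s, 2),
                             "Ala1", "Gly2")$clash, d < thr)
  }
  expect_error(clash_check(subset_structure(far, 1), subset_structure(far, 2),
                           "Arg127", "Gly2"), "not found")
})
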