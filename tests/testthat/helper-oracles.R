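# Independent oracles and fixture builders used across the suite.

# Printed tyrosine-pair distance table (ns 10..100): both donor directions
# for the epicatechin-like and CMF-019-like runs.
TYR_DIST_TABLE <- list(
  times = seq(10, 100, 10),
  ec_309O_H221 = c(3.04, 3.41, 3.08, 4.25, 2.7, 2.18, 2.15, 3.49, 3.3, 2.12),
  ec_221O_H309 = c(2.22, 2.31, 2.11, 3.41, 2.94, 2.8, 3.07, 4.34, 3.29, 2.92),
  cmf_309O_H221 = c(4.15, 3.85, 3.42, 4.66, 4.85, 5.52, 10.31, 6.42, 9.31, 8.67),
  cmf_221O_H309 = c(3.96, 3.57, 3.38, 3.99, 4.06, 4.68, 11.13, 5.72, 9.95, 9.82))

# Printed maximal-binding values: apelin-13 reference, EC, EC + ML221.
BMAX_TABLE <- c("apelin-13" = 801286, "EC" = 810100, "EC+ML221" = 733981)

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force rotation-search minimum RMSD: quasi-random quaternion grid
# followed by a direct-search polish. Independent of the SVD route.
oracle_min_rmsd <- function(X, Y, n_grid = 4000) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  set.seed(424242)
  qs <- rbind(c(1, 0, 0, 0),
              matrix(rnorm(4 * n_grid), ncol = 4))
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  opt$value
}

# Brute-force H-bond enumeration over every donor-acceptor pair, applied
# directly from the criterion definition.
oracle_hbonds <- function(frame, criterion, donors, acceptors) {
  at <- frame$atoms
  xyz <- coords(frame)
  n <- 0L
  for (d in donors) for (a in acceptors) {
    if (a == d) next
    if (at$chain_id[a] == at$chain_id[d] &&
        at$residue_number[a] == at$residue_number[d]) next
    dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
    if (dda > criterion$donor_acceptor_cutoff) next
    hs <- which(at$chain_id == at$chain_id[d] &
                at$residue_number == at$residue_number[d] &
                toupper(at$element) == "H")
    hs <- hs[vapply(hs, function(h)
      sqrt(sum((xyz[h, ] - xyz[d, ])^2)) <= 1.25, logical(1))]
    if (!length(hs)) { n <- n + 1L; next }  # distance-only
    ang <- sapply(hs, function(h) {
      v1 <- xyz[h, ] - xyz[d, ]; v2 <- xyz[a, ] - xyz[d, ]
      acos(min(1, max(-1, sum(v1 * v2) /
                        sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    })
    if (min(ang) <= criterion$angle_cutoff_deg) n <- n + 1L
  }
  n
}

# Exhaustive evaluation of the GROMOS greedy rule: every round scores every
# remaining frame, takes the maximal neighbor count (ties: lowest index).
oracle_gromos <- function(M, cutoff) {
  remaining <- seq_len(nrow(M))
  assign <- integer(nrow(M)); cl <- 0L
  cent <- integer(0); sizes <- integer(0)
  while (length(remaining)) {
    counts <- sapply(remaining, function(i) sum(M[i, remaining] <= cutoff))
    best <- remaining[counts == max(counts)][1]
    members <- remaining[M[best, remaining] <= cutoff]
    cl <- cl + 1L
    assign[members] <- cl; cent <- c(cent, best)
    sizes <- c(sizes, length(members))
    remaining <- setdiff(remaining, members)
  }
  ord <- order(-sizes, cent)
  remap <- integer(cl); remap[ord] <- seq_len(cl)
  list(assignments = remap[assign], centroids = cent[ord], sizes = sizes[ord])
}

# Exposed area of two equal spheres (radius R, center distance d < 2R):
# each loses a spherical cap of height R - d/2.
two_sphere_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Minimal 4-atom topology for replaying a printed distance table: frame k
# places H221 1 A from O221 and positions O309 / H309 so that
# d(O309, H221) = ab[k] and d(O221, H309) = ba[k].
replay_trajectory <- function(ab, ba, times) {
  atoms <- data.frame(
    atom_name = c("OH", "HH", "OH", "HH"),
    residue_name = "TYR",
    residue_number = c(221L, 221L, 309L, 309L),
    chain_id = "A",
    element = c("O", "H", "O", "H"),
    x = 0, y = 0, z = 0)
  topo <- md_structure(atoms, label = "replay")
  frames <- lapply(seq_along(ab), function(k)
    matrix(c(0, 0, 0,
             1, 0, 0,
             1 + ab[k], 0, 0,
             0, ba[k], 0), ncol = 3, byrow = TRUE))
  md_trajectory(topo, frames, times)
}

# Random small structure with labelled donors/acceptors for H-bond
# property tests: O donors (each with one hydrogen), O acceptors.
random_hbond_system <- function(seed, n_donors = 3, n_acceptors = 4) {
  set.seed(seed)
  rows <- list(); donors <- integer(0); acceptors <- integer(0)
  idx <- 0L
  for (i in seq_len(n_donors)) {
    p <- runif(3, 0, 6)
    hdir <- rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = "OG", residue_name = "SER", residue_number = i,
      chain_id = "A", element = "O", x = p[1], y = p[2], z = p[3])
    donors <- c(donors, idx + 1L)
    h <- p + hdir
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = "HG", residue_name = "SER", residue_number = i,
      chain_id = "A", element = "H", x = h[1], y = h[2], z = h[3])
    idx <- idx + 2L
  }
  for (j in seq_len(n_acceptors)) {
    p <- runif(3, 0, 6)
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = "O", residue_name = "GLY", residue_number = 100L + j,
      chain_id = "A", element = "O", x = p[1], y = p[2], z = p[3])
    idx <- idx + 1L
    acceptors <- c(acceptors, idx)
  }
  list(frame = md_structure(do.call(rbind, rows)),
       donors = donors, acceptors = acceptors)
}

# Random rigid motion (seeded).
random_rigid <- function(seed) {
  set.seed(seed)
  R <- quat_to_rot(rnorm(4))
  list(R = R, t = runif(3, -20, 20))
}
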