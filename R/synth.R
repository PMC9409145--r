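# Synthetic structures, trajectories, template complexes and assay tables
# with known ground truth. These generators define the study conditions the
# pipeline is exercised under; they emulate the observables the analyses
# consume, not force-field physics.

# Evaluate fn with a private RNG stream; the caller's RNG state is restored.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  fn()
}

# Idealized alpha-helical CA scaffold: 1.5 A rise and 100 degrees per
# residue on a 2.3 A radius, axis along z.
.helix_ca <- function(n) {
  k <- seq_len(n) - 1
  ang <- k * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * k)
}

.RESIDUE_BASE <- 100L  # first scaffold residue number

#' Idealized toy receptor structure
#'
#' A helical CA scaffold with residues numbered from 100 upward. When
#' requested, two scaffold positions are converted into the diagnostic
#' tyrosine pair: TYR 221 and TYR 309 (author-style numbering), each
#' carrying a phenolic oxygen OH and hydroxyl hydrogen HH placed so the
#' O...O distance equals \code{pair_distance_A} exactly, with each HH on the
#' O-O axis (ideal donor geometry). If the scaffold numbering covers 127,
#' that residue becomes ARG with an NH1 guanidinium nitrogen extended
#' radially, so the same structure can enter the G-protein clash assessment.
#'
#' @param n_residues number of scaffold residues (>= 4, < 100).
#' @param include_tyr_pair add the TYR 221 / TYR 309 pair (default TRUE).
#' @param pair_distance_A O...O distance for the pair (default 3.0).
#' @return an \code{md_structure} (chain "A").
#' @export
make_toy_receptor <- function(n_residues, include_tyr_pair = TRUE,
                              pair_distance_A = 3.0) {
  if (n_residues < 4) stop("n_residues must be >= 4")
  if (n_residues >= 100) stop("n_residues must be < 100 (scaffold numbering)")
  if (include_tyr_pair && pair_distance_A < 0)
    stop("infeasible geometry: negative pair distance")
  ca <- .helix_ca(n_residues)
  num <- .RESIDUE_BASE + seq_len(n_residues) - 1L
  resname <- rep("ALA", n_residues)
  rows <- list()
  add <- function(an, rn, rnum, el, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = an, residue_name = rn, residue_number = rnum,
      chain_id = "A", element = el, x = xyz[1], y = xyz[2], z = xyz[3])
  p1 <- max(2L, floor(n_residues / 3)); p2 <- min(n_residues - 1L,
                                                  floor(2 * n_residues / 3))
  if (include_tyr_pair && p2 <= p1) stop("n_residues too small for tyr pair")
  for (i in seq_len(n_residues)) {
    rnum <- num[i]; rn <- resname[i]
    if (include_tyr_pair && i %in% c(p1, p2)) {
      rn <- "TYR"; rnum <- if (i == p1) 221L else 309L
    } else if (rnum == 127L) rn <- "ARG"
    add("CA", rn, rnum, "C", ca[i, ])
    if (rn == "ARG") {
      u <- c(cos((num[i] - .RESIDUE_BASE) * 100 * pi / 180),
             sin((num[i] - .RESIDUE_BASE) * 100 * pi / 180), 0)
      add("NH1", rn, rnum, "N", ca[i, ] + 6 * u)
    }
  }
  if (include_tyr_pair) {
    m <- (ca[p1, ] + ca[p2, ]) / 2
    w <- ca[p2, ] - ca[p1, ]; w <- w / sqrt(sum(w^2))
    o1 <- m - w * pair_distance_A / 2
    o2 <- m + w * pair_distance_A / 2
    add("OH", "TYR", 221L, "O", o1)
    add("HH", "TYR", 221L, "H", o1 + 0.97 * w)
    add("OH", "TYR", 309L, "O", o2)
    add("HH", "TYR", 309L, "H", o2 - 0.97 * w)
  }
  md_structure(do.call(rbind, rows), label = "toy receptor")
}

#' Trajectory generator specification
#'
#' The controlled observable is the TYR221-TYR309 O...O distance, which
#' follows a discrete mean-reverting (Ornstein-Uhlenbeck) process:
#' d[t+1] = d[t] + (mean - d[t])/relaxation_frames +
#' sd * sqrt(2/relaxation_frames) * eps[t], giving stationary mean
#' \code{pair_mean_A} and stationary sd approximately \code{pair_sd_A}. An
#' optional regime switch at \code{transition_frame} changes the mean/sd,
#' emulating a hydrogen bond that holds for part of the run and then breaks.
#'
#' @param n_frames number of frames (>= 2).
#' @param dt_ns frame spacing in ns (default 0.01, i.e. 100 ns per 10,000
#'   frames).
#' @param pair_mean_A target mean O...O distance (angstrom).
#' @param pair_sd_A stationary sd (default 0.1).
#' @param relaxation_frames mean-reversion time in frames (default 50).
#' @param seed RNG seed.
#' @param transition_frame optional frame index at which the regime
#'   switches.
#' @param post_mean_A,post_sd_A post-switch mean/sd.
#' @param jitter_A isotropic positional noise on non-controlled atoms
#'   (default 0.05).
#' @return object of class \code{trajectory_spec}.
#' @export
trajectory_spec <- function(n_frames, dt_ns = 0.01, pair_mean_A = 3.0,
                            pair_sd_A = 0.1, relaxation_frames = 50,
                            seed = 1L, transition_frame = NULL,
                            post_mean_A = NULL, post_sd_A = NULL,
                            jitter_A = 0.05) {
  stopifnot(n_frames >= 2, pair_sd_A >= 0, relaxation_frames >= 1,
            dt_ns > 0, jitter_A >= 0)
  if (!is.null(transition_frame)) {
    stopifnot(transition_frame >= 1, transition_frame < n_frames)
    if (is.null(post_mean_A)) stop("post_mean_A required with a transition")
    if (is.null(post_sd_A)) post_sd_A <- pair_sd_A
  }
  structure(list(n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 pair_mean_A = pair_mean_A, pair_sd_A = pair_sd_A,
                 relaxation_frames = relaxation_frames, seed = as.integer(seed),
                 transition_frame = transition_frame,
                 post_mean_A = post_mean_A, post_sd_A = post_sd_A,
                 jitter_A = jitter_A),
            class = "trajectory_spec")
}

#' Generate a synthetic trajectory with a controlled tyrosine-pair distance
#'
#' The TYR 309 OH/HH atoms are moved along the fixed O-O axis of the base
#' structure so the O...O distance follows the spec's mean-reverting
#' process; all other atoms receive small isotropic jitter. Deterministic
#' under the spec seed.
#'
#' @param spec a \code{\link{trajectory_spec}}.
#' @param base an \code{md_structure} containing the TYR 221 / TYR 309 pair
#'   (see \code{\link{make_toy_receptor}}).
#' @return an \code{md_trajectory}.
#' @export
make_trajectory <- function(spec, base) {
  stopifnot(inherits(spec, "trajectory_spec"), inherits(base, "md_structure"))
  o1 <- select_atoms(base, residue_number = 221, residue_name = "TYR",
                     atom_names = "OH")
  h1 <- select_atoms(base, residue_number = 221, residue_name = "TYR",
                     atom_names = "HH")
  o2 <- select_atoms(base, residue_number = 309, residue_name = "TYR",
                     atom_names = "OH")
  h2 <- select_atoms(base, residue_number = 309, residue_name = "TYR",
                     atom_names = "HH")
  if (!all(lengths(list(o1, h1, o2, h2)) == 1))
    stop("base must contain the TYR221/TYR309 OH/HH pair")
  xyz0 <- coords(base)
  w <- xyz0[o2, ] - xyz0[o1, ]
  d0 <- sqrt(sum(w^2))
  if (d0 < 1e-9) stop("base pair atoms are coincident; axis undefined")
  w <- w / d0
  nf <- spec$n_frames
  .with_seed(spec$seed, function() {
    mu <- rep(spec$pair_mean_A, nf); sdv <- rep(spec$pair_sd_A, nf)
    if (!is.null(spec$transition_frame)) {
      post <- (spec$transition_frame + 1):nf
      mu[post] <- spec$post_mean_A; sdv[post] <- spec$post_sd_A
    }
    d <- numeric(nf); d[1] <- mu[1]
    k <- 1 / spec$relaxation_frames
    amp <- sqrt(2 / spec$relaxation_frames)
    eps <- rnorm(nf)
    for (t in seq_len(nf - 1))
      d[t + 1] <- d[t] + (mu[t + 1] - d[t]) * k + sdv[t + 1] * amp * eps[t]
    d <- pmax(d, 0.1)
    ctrl <- c(o1, h1, o2, h2)
    na <- nrow(xyz0)
    frames <- vector("list", nf)
    for (t in seq_len(nf)) {
      f <- xyz0
      if (spec$jitter_A > 0) {
        free <- setdiff(seq_len(na), ctrl)
        f[free, ] <- f[free, ] +
          matrix(rnorm(3 * length(free), sd = spec$jitter_A), ncol = 3)
      }
      f[o2, ] <- xyz0[o1, ] + w * d[t]
      f[h2, ] <- f[o2, ] - 0.97 * w
      frames[[t]] <- f
    }
    md_trajectory(base, frames, spec$dt_ns * seq_len(nf))
  })
}

#' Synthetic receptor/G-protein template complex
#'
#' Two chains: a receptor-like helical chain "A" (same scaffold and
#' numbering as \code{\link{make_toy_receptor}}) whose residue ARG 127
#' carries an NH1 nitrogen, and a G-protein-like chain "B" whose residue
#' TYR 356 carries an OH oxygen placed so the closest heavy-atom separation
#' between the chains equals \code{separation_A} (realized by the
#' NH1...OH pair).
#'
#' @param separation_A closest cross-chain heavy-atom distance (>= 0).
#' @param n_receptor_residues receptor scaffold length (default 30; must
#'   cover residue 127).
#' @return an \code{md_structure} with chains "A" and "B".
#' @export
make_template_complex <- function(separation_A, n_receptor_residues = 30) {
  if (separation_A < 0) stop("separation must be >= 0")
  if (.RESIDUE_BASE + n_receptor_residues - 1L < 127L)
    stop("receptor scaffold must cover residue 127")
  rec <- make_toy_receptor(n_receptor_residues, include_tyr_pair = FALSE)
  arg_nh1 <- select_atoms(rec, residue_number = 127, atom_names = "NH1")
  stopifnot(length(arg_nh1) == 1)
  nh1 <- coords(rec)[arg_nh1, ]
  u <- nh1 - c(0, 0, nh1[3])          # radial direction from the helix axis
  u <- u / sqrt(sum(u^2))
  ca_b <- .helix_ca(16)
  ca_b[, 3] <- ca_b[, 3] + max(coords(rec)[, 3]) + 25
  rows <- list()
  for (i in seq_len(16)) {
    rnum <- 348L + i            # residues 349..364; 356 is the TYR
    rn <- if (rnum == 356L) "TYR" else "GLY"
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = "CA", residue_name = rn, residue_number = rnum,
      chain_id = "B", element = "C",
      x = ca_b[i, 1], y = ca_b[i, 2], z = ca_b[i, 3])
  }
  oh <- nh1 + separation_A * u
  rows[[length(rows) + 1L]] <- data.frame(
    atom_name = "OH", residue_name = "TYR", residue_number = 356L,
    chain_id = "B", element = "O", x = oh[1], y = oh[2], z = oh[3])
  partner <- do.call(rbind, rows)
  md_structure(rbind(rec$atoms[, names(partner)], partner),
               label = sprintf("synthetic template (separation %.2f A)",
                               separation_A))
}

#' Assay generator specification
#'
#' @param model one of "hill_binding", "operational", "inhibition".
#' @param true_params named list of generating parameters
#'   (hill_binding: Bmax, Kd, h; operational: Em, tau, KA, n;
#'   inhibition: top, bottom, IC50, s).
#' @param doses_M positive dose vector (M).
#' @param noise_sd_fraction Gaussian noise sd as a fraction of the model
#'   maximum (Bmax / Em / top).
#' @param replicates replicates per dose (default 1).
#' @param seed RNG seed.
#' @return object of class \code{assay_spec}.
#' @export
assay_spec <- function(model = c("hill_binding", "operational", "inhibition"),
                       true_params, doses_M, noise_sd_fraction = 0,
                       replicates = 1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(all(doses_M > 0), noise_sd_fraction >= 0, replicates >= 1)
  need <- switch(model,
                 hill_binding = c("Bmax", "Kd", "h"),
                 operational = c("Em", "tau", "KA", "n"),
                 inhibition = c("top", "bottom", "IC50", "s"))
  miss <- setdiff(need, names(true_params))
  if (length(miss)) stop("true_params missing: ", paste(miss, collapse = ", "))
  structure(list(model = model, true_params = true_params,
                 doses_M = as.numeric(doses_M),
                 noise_sd_fraction = noise_sd_fraction,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "assay_spec")
}

#' Generate a synthetic dose-response table
#'
#' Responses are the named model's curve at the spec doses plus Gaussian
#' noise with sd = noise_sd_fraction x the model maximum; deterministic
#' under the spec seed.
#'
#' @param spec an \code{\link{assay_spec}}.
#' @return data.frame with columns concentration_M, response, replicate.
#' @export
make_assay <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  p <- spec$true_params
  curve <- switch(spec$model,
    hill_binding = function(x) hill_binding_curve(x, p$Bmax, p$Kd, p$h),
    operational = function(x) operational_curve(x, p$Em, p$tau, p$KA, p$n),
    inhibition = function(x) inhibition_curve(x, p$top, p$bottom, p$IC50, p$s))
  scale <- switch(spec$model, hill_binding = p$Bmax, operational = p$Em,
                  inhibition = p$top)
  x <- rep(spec$doses_M, times = spec$replicates)
  rep_id <- rep(seq_len(spec$replicates), each = length(spec$doses_M))
  .with_seed(spec$seed, function() {
    y <- curve(x) + rnorm(length(x), sd = spec$noise_sd_fraction * scale)
    data.frame(concentration_M = x, response = y, replicate = rep_id)
  })
}
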