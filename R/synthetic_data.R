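## synthetic_data: deterministic fixture generators. Everything here stands in
## for microsecond MD output: small peptides with ideal geometry, solvated
## systems with controlled water shells, multi-monomer trajectories with
## scripted approach events and known ground-truth contact counts, and
## excipient populations with the formulation-table charge logic.

# ideal backbone internal coordinates (A / degrees)
BB_N_CA <- 1.458; BB_CA_C <- 1.525; BB_C_N <- 1.329; BB_C_O <- 1.231
ANG_N_CA_C <- 111.0; ANG_CA_C_N <- 116.2; ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.5

# place D from A-B-C with bond |C-D|, angle B-C-D, torsion A-B-C-D (degrees)
place_atom <- function(A, B, C, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma::cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# backbone (N, CA, C, O per residue) from phi/psi vectors; omega fixed trans
build_backbone <- function(phi, psi, sequence, chain_id = "A",
                           start_resno = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n, length(sequence) == n)
  N <- CA <- C <- O <- matrix(0, n, 3)
  # seed the first three atoms
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_N_CA, 0, 0)
  C[1, ] <- place_atom(c(-1, 1, 0), N[1, ], CA[1, ], BB_CA_C, ANG_N_CA_C,
                       psi[1] + 60)  # arbitrary initial orientation
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], BB_C_N,
                           ANG_CA_C_N, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], BB_N_CA,
                            ANG_C_N_CA, 180)       # omega trans
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], BB_CA_C,
                           ANG_N_CA_C, phi[i])
    }
    nxt_psi <- if (i < n) psi[i] else psi[i]
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB_C_O, ANG_CA_C_O,
                         nxt_psi + 180)
  }
  rows <- lapply(seq_len(n), function(i) {
    pos <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    data.frame(element = c("N", "C", "C", "O"),
               name = c("N", "CA", "C", "O"),
               residue_index = start_resno + i - 1L,
               residue_name = sequence[i], chain_id = chain_id,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               role = "protein", stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure_model(atoms)
}

# antiparallel pairing of two ideal strands: flip 180 deg about z, then
# offset; calibrated once on the ideal strand geometry so Kabsch-Sander
# bonds form between opposing residues (inter-strand spacing 3.6 A in y,
# register shift -1.9 A along the strand axis)
HAIRPIN_FLIP <- diag(c(-1, -1, 1))
HAIRPIN_OFFSET <- c(-1.9, 3.6, 0)

# rotate a fragment so its CA principal axis runs along +x (in residue
# order), centred at the CA centroid; proper rotation by construction
orient_along_x <- function(model) {
  ca <- coords(model, atom_mask(model, name = "CA"))
  ctr <- colMeans(ca)
  xc <- sweep(coords(model), 2, ctr)
  cac <- sweep(ca, 2, ctr)
  p <- stats::prcomp(cac)$rotation
  if (sum((cac %*% p)[, 1] * seq_len(nrow(ca))) < 0) p[, 1] <- -p[, 1]
  p[, 3] <- pracma::cross(p[, 1], p[, 2])
  set_coords(model, xc %*% p)
}

#' Build an ideal secondary-structure fragment
#'
#' Backbones are generated from ideal torsions: alpha-helix
#' (phi = -57, psi = -47), extended strand (phi = -139, psi = 135), or a
#' hairpin of two hydrogen-bond-registered antiparallel strands joined by a
#' two-residue connector (the connector residues have non-ideal local
#' geometry; only the strand residues carry beta structure).
#'
#' @param kind `"helix"`, `"extended"` or `"hairpin"`.
#' @param n_residues total residue count (>= 4).
#' @param sequence 3-letter codes recycled to length; default poly-alanine.
#' @param chain_id chain id of the fragment.
#' @return A [structure_model()] with N/CA/C/O backbone atoms.
#' @export
make_ideal_fragment <- function(kind = c("helix", "hairpin", "extended"),
                                n_residues, sequence = "ALA",
                                chain_id = "A") {
  kind <- match.arg(kind)
  if (n_residues < 4) stop("n_residues must be >= 4")
  sequence <- rep(toupper(sequence), length.out = n_residues)
  if (kind == "helix")
    return(build_backbone(rep(-57, n_residues), rep(-47, n_residues),
                          sequence, chain_id))
  if (kind == "extended")
    return(build_backbone(rep(-139, n_residues), rep(135, n_residues),
                          sequence, chain_id))
  # hairpin: strand / 2-residue connector / strand
  if (n_residues < 10)
    stop("a registered hairpin needs n_residues >= 10 ",
         "(two strands of >= 4 plus a 2-residue connector)")
  n1 <- ceiling((n_residues - 2) / 2)
  n2 <- n_residues - 2 - n1
  s1 <- orient_along_x(
    build_backbone(rep(-139, n1), rep(135, n1), sequence[1:n1], chain_id))
  s2 <- orient_along_x(
    build_backbone(rep(-139, n2), rep(135, n2),
                   sequence[(n1 + 3):n_residues], chain_id,
                   start_resno = n1 + 3L))
  s2 <- set_coords(s2, sweep(coords(s2) %*% HAIRPIN_FLIP, 2,
                             HAIRPIN_OFFSET, "+"))
  conn <- hairpin_connector(s1, s2, sequence[(n1 + 1):(n1 + 2)],
                            chain_id, start_resno = n1 + 1L)
  combine_models(list(s1, conn, s2))
}

# two connector residues interpolated between the strand ends
hairpin_connector <- function(s1, s2, seqs, chain_id, start_resno) {
  p1 <- coords(s1)[nrow(s1$atoms) - 1, ]  # C of last strand-1 residue
  p2 <- coords(s2)[1, ]                   # N of first strand-2 residue
  out <- list()
  for (k in 1:2) {
    f0 <- k / 3; f1 <- f0 + 0.08
    base <- p1 + f0 * (p2 - p1) + c(0, 0, 2.5)
    pos <- rbind(base, base + c(0.8, 0.9, -0.6), base + c(1.9, 1.2, -0.9),
                 base + c(2.3, 0.4, -1.9))
    out[[k]] <- data.frame(element = c("N", "C", "C", "O"),
                           name = c("N", "CA", "C", "O"),
                           residue_index = start_resno + k - 1L,
                           residue_name = seqs[k], chain_id = chain_id,
                           x = pos[, 1], y = pos[, 2], z = pos[, 3],
                           role = "protein", stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, out)
  rownames(atoms) <- NULL
  structure_model(atoms)
}

#' Solvated fixture with controlled water shells
#'
#' Places water oxygens so that each one's minimum distance to the protein
#' equals a requested shell distance to within 0.05 A — ground truth for the
#' bulk-water strip rule. Deterministic given the seed.
#'
#' @param protein a [structure_model()].
#' @param shell_spec list of `c(distance, n_waters)` pairs (A, count).
#' @param seed integer seed.
#' @param max_tries placement retries per water before giving up.
#' @return the protein with waters appended (chain `"W"`, oxygen-only
#'   molecules).
#' @export
make_solvated_fixture <- function(protein, shell_spec, seed = 1,
                                  max_tries = 2000) {
  set.seed(seed)
  prot_xyz <- coords(protein, atom_mask(protein, role = "protein"))
  placed <- matrix(numeric(), 0, 3)
  for (spec in shell_spec) {
    d_target <- spec[1]; n_want <- spec[2]
    if (d_target <= 0) stop("shell distances must be > 0")
    got <- 0
    tries <- 0
    while (got < n_want) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place shell waters at ", d_target, " A")
      anchor <- prot_xyz[sample(nrow(prot_xyz), 1), ]
      cand <- anchor + d_target * random_unit_vector()
      dmin <- sqrt(min(cross_dist2(rbind(cand), prot_xyz)))
      if (abs(dmin - d_target) > 0.05) next
      if (nrow(placed) > 0 &&
          min(cross_dist2(rbind(cand), placed)) < 2.4^2) next
      placed <- rbind(placed, cand)
      got <- got + 1
    }
  }
  wat <- structure_model(water_atoms(placed, chain_id = "W",
                                     with_h = FALSE))
  combine_models(list(protein, wat), box = protein$box,
                 net_charge = protein$net_charge)
}

#' Scripted aggregation schedule
#'
#' Describes which monomer pairs approach to which distances in which frames
#' of a synthetic coarse-grained trajectory. Scheduled distances must clear
#' the contact cutoff by at least 0.5 A on either side so the ground-truth
#' contact count is unambiguous.
#'
#' @param n_monomers monomer count (placed on the replication grid).
#' @param n_frames total frames.
#' @param schedule list of entries `list(frames =, pair =, distance =)`:
#'   integer frame vector, monomer index pair, target minimum inter-monomer
#'   distance (A).
#' @param cutoff the contact cutoff the fixture is scripted against (A).
#' @param spacing,grid monomer lattice (defaults 85 A, 2 x 2 x 2).
#' @param seed integer seed.
#' @return list of class `aggregation_script`.
#' @export
aggregation_script <- function(n_monomers = 8L, n_frames = 10L,
                               schedule = list(), cutoff = 4,
                               spacing = 85, grid = c(2L, 2L, 2L),
                               seed = 1L) {
  if (prod(grid) != n_monomers)
    stop("grid must hold exactly n_monomers monomers")
  seen <- list()
  for (e in schedule) {
    if (!all(c("frames", "pair", "distance") %in% names(e)))
      stop("schedule entries need frames, pair, distance")
    if (abs(e$distance - cutoff) < 0.5)
      stop("scheduled distance within 0.5 A of the cutoff: ground truth ",
           "would be ambiguous")
    if (any(e$frames < 1 | e$frames > n_frames))
      stop("schedule frames outside 1..n_frames")
    key <- paste(sort(e$pair), collapse = "-")
    if (!is.null(seen[[key]]) && length(intersect(seen[[key]], e$frames)))
      stop("overlapping schedule entries for pair ", key)
    seen[[key]] <- c(seen[[key]], e$frames)
  }
  structure(list(n_monomers = as.integer(n_monomers),
                 n_frames = as.integer(n_frames), schedule = schedule,
                 cutoff = cutoff, spacing = spacing,
                 grid = as.integer(grid), seed = as.integer(seed)),
            class = "aggregation_script")
}

#' Synthetic multi-monomer aggregation trajectory
#'
#' Monomers start on the replication lattice; scheduled pairs are rigidly
#' translated along their centre-of-mass line so the pair's minimum
#' inter-monomer distance equals the scripted value in the scripted frames
#' (solved exactly by root finding). The per-frame ground-truth contact
#' count, recomputed by an independent brute-force distance loop, is attached
#' as the `"ground_truth"` attribute.
#'
#' @param monomer single-chain [structure_model()].
#' @param script an [aggregation_script()].
#' @return A [trajectory_segment()] (stage RT) with attribute
#'   `ground_truth`: data.frame `frame`, `contacts`.
#' @export
make_aggregation_trajectory <- function(monomer, script) {
  set.seed(script$seed)
  base <- replicate_monomers(monomer, grid = script$grid,
                             spacing = script$spacing)
  chains <- CHAIN_ALPHABET[seq_len(script$n_monomers)]
  base_xyz <- coords(base)
  idx_of <- lapply(chains, function(ch) which(base$atoms$chain_id == ch))
  frames <- vector("list", script$n_frames)
  for (f in seq_len(script$n_frames)) {
    xyz <- base_xyz
    for (e in script$schedule) {
      if (!(f %in% e$frames)) next
      ia <- idx_of[[e$pair[1]]]; ib <- idx_of[[e$pair[2]]]
      A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
      u <- center_of_mass(A) - center_of_mass(B)
      u <- u / sqrt(sum(u^2))
      d0 <- min_dist(A, B)
      if (d0 <= e$distance) next
      shift_for <- function(t) min_dist(A, sweep(B, 2, t * u, "+")) -
        e$distance
      t_hi <- sqrt(sum((center_of_mass(A) - center_of_mass(B))^2))
      while (shift_for(t_hi) > 0) t_hi <- t_hi * 1.5
      t_star <- stats::uniroot(shift_for, c(0, t_hi), tol = 1e-8)$root
      xyz[ib, ] <- sweep(B, 2, t_star * u, "+")
    }
    frames[[f]] <- xyz
  }
  gt <- data.frame(frame = seq_len(script$n_frames),
                   contacts = vapply(frames, function(fr)
                     brute_force_contact_count(base, fr, script$cutoff),
                     numeric(1)))
  traj <- trajectory_segment(base, frames, stage = "RT")
  attr(traj, "ground_truth") <- gt
  traj
}

# independent O(N^2) oracle: plain loops over residue pairs across chains
brute_force_contact_count <- function(model, xyz, cutoff,
                                      box_lengths = NULL) {
  a <- model$atoms
  chains <- sort(unique(a$chain_id[a$role == "protein"]))
  count <- 0L
  for (ia in seq_len(max(length(chains) - 1, 0))) {
    for (ib in (ia + 1):length(chains)) {
      ra <- which(a$chain_id == chains[ia])
      rb <- which(a$chain_id == chains[ib])
      for (r1 in unique(a$residue_index[ra])) {
        for (r2 in unique(a$residue_index[rb])) {
          i1 <- ra[a$residue_index[ra] == r1]
          i2 <- rb[a$residue_index[rb] == r2]
          best <- Inf
          for (p in i1) for (q in i2) {
            dv <- xyz[p, ] - xyz[q, ]
            if (!is.null(box_lengths))
              dv <- dv - box_lengths * round(dv / box_lengths)
            best <- min(best, sum(dv^2))
          }
          if (best < cutoff^2) count <- count + 1L
        }
      }
    }
  }
  count
}

# excipient molecule templates: minimal rigid fragments, one residue each
EXCIPIENT_TEMPLATES <- list(
  ARG = list(element = c("N", "C", "C", "O", "N"),
             name = c("N", "CA", "C", "O", "NH1"),
             xyz = rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.4, 0),
                         c(3.2, 1.5, 0), c(1.2, 2.4, 0))),
  TXA = list(element = c("C", "N", "C", "O"),
             name = c("C1", "N1", "C7", "O1"),
             xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
                         c(3.4, 1.2, 0))),
  SUC = list(element = c("C", "O", "C"),
             name = c("C1", "O1", "C2"),
             xyz = rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 1.2, 0))))

#' Synthetic excipient population
#'
#' `n` single-residue excipient molecules (residue name = spec name, role
#' `excipient`) on a non-clashing grid; the population's total formal charge
#' (`n * net_charge`) is recorded on the returned model, ready for
#' [neutralize()].
#'
#' @param spec an [excipient_spec()].
#' @param n molecule count (>= 0).
#' @param box optional [simulation_box()] to place within; default a grid
#'   around the origin.
#' @param avoid optional m x 3 coordinates to keep `clash_cutoff` away from.
#' @param clash_cutoff minimum distance to `avoid` atoms (A).
#' @param chain_id chain id of the population.
#' @return A [structure_model()] with `net_charge = n * spec$net_charge`.
#' @export
make_excipient_population <- function(spec, n, box = NULL, avoid = NULL,
                                      clash_cutoff = 2.4, chain_id = "E") {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  tpl <- EXCIPIENT_TEMPLATES[[spec$name]]
  if (is.null(tpl))
    tpl <- list(element = c("C", "O"), name = c("C1", "O1"),
                xyz = rbind(c(0, 0, 0), c(1.4, 0, 0)))
  if (n == 0)
    return(structure_model(water_atoms(matrix(numeric(), 0, 3))[0, ],
                           net_charge = 0L))
  spacing <- 6
  free_sites <- function(k) {
    sites <- if (!is.null(box)) solvent_grid(box, spacing) else {
      g <- expand.grid(i = 0:(k - 1), j = 0:(k - 1), l = 0:(k - 1))
      as.matrix(g) * spacing
    }
    if (!is.null(avoid) && nrow(sites) > 0 && NROW(avoid) > 0) {
      d2 <- cross_dist2(sites, as.matrix(avoid))
      sites <- sites[apply(d2, 1, min) >= (clash_cutoff + 2)^2, ,
                     drop = FALSE]
    }
    sites
  }
  k <- ceiling(n^(1 / 3))
  sites <- free_sites(k)
  while (is.null(box) && nrow(sites) < n && k < 60) {
    k <- k + 1
    sites <- free_sites(k)
  }
  if (nrow(sites) < n)
    stop("not enough non-clashing sites for ", n, " excipient molecules")
  sites <- sites[seq_len(n), , drop = FALSE]
  rows <- lapply(seq_len(n), function(i) {
    pos <- sweep(tpl$xyz, 2, sites[i, ], "+")
    data.frame(element = tpl$element, name = tpl$name, residue_index = i,
               residue_name = spec$name, chain_id = chain_id,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               role = "excipient", stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure_model(atoms, net_charge = n * spec$net_charge)
}

#' Jittered single-structure trajectory
#'
#' Thermal-noise stand-in: frames are the model coordinates plus seeded
#' Gaussian displacements — enough structure for the time-course observables
#' without any dynamics.
#'
#' @param model a [structure_model()].
#' @param stage stage label for the segment.
#' @param n_frames frame count.
#' @param amplitude per-coordinate standard deviation (A).
#' @param seed integer seed.
#' @param time_per_frame ns per frame.
#' @return A [trajectory_segment()].
#' @export
make_jitter_trajectory <- function(model, stage = "RT", n_frames = 5,
                                   amplitude = 0.1, seed = 1,
                                   time_per_frame = 1) {
  set.seed(seed)
  base <- coords(model)
  frames <- lapply(seq_len(n_frames), function(i)
    base + matrix(stats::rnorm(length(base), sd = amplitude),
                  ncol = 3))
  trajectory_segment(model, frames, stage = stage,
                     time_per_frame = time_per_frame)
}
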