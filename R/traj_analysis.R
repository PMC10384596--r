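## traj_analysis: scalar structural observables along the pipeline.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference coordinate set over a common atom selection, via the
#' SVD of the covariance matrix with the usual sign correction so that
#' `det(rotation) = +1`.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix.
#' @param selection optional index vector; superpose and score on this subset.
#' @return list with `rotation` (3 x 3), `translation` (length 3; apply as
#'   `coords %*% rotation + translation`), and `rmsd` (A, the minimum over
#'   rigid motions).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.null(selection)) {
    mobile_s <- mobile[selection, , drop = FALSE]
    reference_s <- reference[selection, , drop = FALSE]
  } else {
    mobile_s <- mobile; reference_s <- reference
  }
  if (nrow(mobile_s) != nrow(reference_s))
    stop("selections are not congruent")
  if (nrow(mobile_s) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile_s); cr <- colMeans(reference_s)
  P <- sweep(mobile_s, 2, cm); Q <- sweep(reference_s, 2, cr)
  H <- crossprod(P, Q)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)    # right-multiplication rotation
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = cr - as.vector(cm %*% R), rmsd = rmsd)
}

#' Apply a superposition to coordinates
#' @param coords n x 3 matrix.
#' @param fit result of [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_fit <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

#' Resolve an atom selection on a model
#'
#' @param model a [structure_model()].
#' @param selection `"calpha"` (default), `"heavy"`, `"protein"`, or an
#'   integer/logical index vector used as-is.
#' @return integer atom row indices.
#' @export
resolve_selection <- function(model, selection = "calpha") {
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.logical(selection)) return(which(selection))
  a <- model$atoms
  switch(match.arg(selection, c("calpha", "heavy", "protein")),
         calpha = which(a$role == "protein" & a$name == "CA"),
         heavy = which(a$role == "protein" & a$element != "H"),
         protein = which(a$role == "protein"))
}

#' RMSD time course against the starting structure
#'
#' Per-frame superposed RMSD of every frame against a fixed reference — the
#' first frame of the first stage — concatenated across stages.
#'
#' @param traj a [trajectory_segment()] or list of them in pipeline order.
#' @param selection see [resolve_selection()]; default C-alpha.
#' @param reference optional n x 3 reference coordinates; default the first
#'   frame.
#' @return A [stage_series()] of RMSD values (A).
#' @export
rmsd_timecourse <- function(traj, selection = "calpha", reference = NULL) {
  segs <- as_segment_list(traj)
  if (length(segs) == 0 || n_frames(segs) == 0) stop("empty trajectory")
  sel <- resolve_selection(segs[[1]]$model, selection)
  if (length(sel) < 3) stop("selection has fewer than 3 atoms")
  if (is.null(reference)) reference <- segs[[1]]$frames[[1]]
  times <- c(); values <- c(); stages <- c()
  t0 <- 0
  for (s in segs) {
    v <- vapply(s$frames, function(f)
      superpose(f, reference, selection = sel)$rmsd, numeric(1))
    tt <- t0 + s$time_per_frame * seq_along(s$frames)
    times <- c(times, tt); values <- c(values, v)
    stages <- c(stages, rep(s$stage, length(v)))
    t0 <- tt[length(tt)]
  }
  stage_series("rmsd", times, values, stages, units = "A")
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of atoms from their centre of mass.
#'
#' @param coords n x 3 coordinate matrix (A).
#' @param masses atomic masses; default unit masses.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("no atoms")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (any(masses <= 0)) stop("masses must be > 0")
  com <- center_of_mass(coords, masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / sum(masses))
}

#' Radius-of-gyration time course
#' @param traj segment or list of segments.
#' @param selection see [resolve_selection()]; default all protein atoms.
#' @return A [stage_series()] (A).
#' @export
rg_timecourse <- function(traj, selection = "protein") {
  segs <- as_segment_list(traj)
  sel <- resolve_selection(segs[[1]]$model, selection)
  masses <- atom_masses(segs[[1]]$model)[sel]
  times <- c(); values <- c(); stages <- c(); t0 <- 0
  for (s in segs) {
    v <- vapply(s$frames, function(f)
      radius_of_gyration(f[sel, , drop = FALSE], masses), numeric(1))
    tt <- t0 + s$time_per_frame * seq_along(s$frames)
    times <- c(times, tt); values <- c(values, v)
    stages <- c(stages, rep(s$stage, length(v)))
    t0 <- tt[length(tt)]
  }
  stage_series("radius_of_gyration", times, values, stages, units = "A")
}

## ---- SASA (Shrake-Rupley) -------------------------------------------------

# Bondi-type van der Waals radii (A)
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, NA. = 2.27, CL = 1.75, K = 2.75, MG = 1.73,
               CA. = 2.31)

vdw_radius <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  r <- VDW_RADII[key]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-spiral / Fibonacci)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe_radius` over each atom's van der Waals
#' sphere, sampled with a deterministic golden-spiral point set; a point is
#' accessible if it lies outside every neighbouring solvent-expanded sphere.
#'
#' @param model a [structure_model()] (or n x 3 matrix with `elements`).
#' @param probe_radius probe radius (A), default 1.4 (water).
#' @param n_sphere_points test points per atom; accuracy improves with more.
#' @param elements element vector when `model` is a bare matrix.
#' @return numeric vector of per-atom areas (A^2); total SASA is its sum.
#' @export
sasa <- function(model, probe_radius = 1.4, n_sphere_points = 240,
                 elements = NULL) {
  if (inherits(model, "structure_model")) {
    xyz <- coords(model); elements <- model$atoms$element
  } else {
    xyz <- as.matrix(model)
    if (is.null(elements)) stop("elements required for bare coordinates")
  }
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  n <- nrow(xyz)
  radii <- vdw_radius(elements) + probe_radius
  pts <- sphere_points(n_sphere_points)
  areas <- numeric(n)
  # neighbour lists via one squared-distance pass
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    cut <- (radii[i] + radii)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj2 > radii[j]^2
    }
    areas[i] <- 4 * pi * radii[i]^2 * sum(acc) / n_sphere_points
  }
  areas
}

#' Non-polar fraction of the SASA
#'
#' Non-polar atoms are carbons and sulfurs; hydrogens inherit the class of
#' their closest heavy atom within the same residue.
#'
#' @param model the [structure_model()] the areas were computed on.
#' @param areas per-atom areas from [sasa()]; computed if missing.
#' @param ... passed to [sasa()] when `areas` is missing.
#' @return fraction in `[0, 1]`.
#' @export
nonpolar_sasa_ratio <- function(model, areas = NULL, ...) {
  if (is.null(areas)) areas <- sasa(model, ...)
  a <- model$atoms
  if (length(areas) != nrow(a)) stop("areas do not match the model")
  nonpolar <- a$element %in% c("C", "S")
  h <- which(a$element == "H")
  if (length(h) > 0) {
    heavy <- which(a$element != "H")
    d2 <- cross_dist2(coords(model, h), coords(model, heavy))
    same_res <- outer(paste(a$chain_id[h], a$residue_index[h]),
                      paste(a$chain_id[heavy], a$residue_index[heavy]), "==")
    d2[!same_res] <- Inf
    owner <- heavy[apply(d2, 1, which.min)]
    nonpolar[h] <- nonpolar[owner]
  }
  total <- sum(areas)
  if (total <= 0) stop("total SASA is zero")
  sum(areas[nonpolar]) / total
}

## ---- secondary structure (Kabsch-Sander) ----------------------------------

# backbone table: one row per protein residue with N/CA/C/O (and H) indices
backbone_table <- function(model) {
  a <- model$atoms
  prot <- a$role == "protein"
  key <- paste(a$chain_id, a$residue_index)
  res_keys <- unique(key[prot])
  get_idx <- function(k, nm) {
    idx <- which(key == k & a$name == nm & prot)
    if (length(idx) == 0) NA_integer_ else idx[1]
  }
  data.frame(key = res_keys,
             chain = a$chain_id[match(res_keys, key)],
             resno = a$residue_index[match(res_keys, key)],
             resname = a$residue_name[match(res_keys, key)],
             N = vapply(res_keys, get_idx, 1L, nm = "N"),
             CA = vapply(res_keys, get_idx, 1L, nm = "CA"),
             C = vapply(res_keys, get_idx, 1L, nm = "C"),
             O = vapply(res_keys, get_idx, 1L, nm = "O"),
             H = vapply(res_keys, get_idx, 1L, nm = "H"),
             stringsAsFactors = FALSE)
}

# Kabsch-Sander electrostatic H-bond energy matrix (kcal/mol).
# E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN); bond if E < -0.5.
# The amide H, when absent, is reconstructed 1 A from N opposite the previous
# residue's carbonyl (DSSP convention); chain-starts and prolines donate
# nothing.
ks_energy_matrix <- function(model, bb = backbone_table(model)) {
  xyz <- coords(model)
  nres <- nrow(bb)
  Hpos <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    if (bb$resname[i] == "PRO") next
    if (!is.na(bb$H[i])) { Hpos[i, ] <- xyz[bb$H[i], ]; next }
    if (i == 1 || bb$chain[i] != bb$chain[i - 1]) next
    if (is.na(bb$C[i - 1]) || is.na(bb$O[i - 1]) || is.na(bb$N[i])) next
    co <- xyz[bb$C[i - 1], ] - xyz[bb$O[i - 1], ]
    co <- co / sqrt(sum(co^2))
    Hpos[i, ] <- xyz[bb$N[i], ] + co
  }
  E <- matrix(Inf, nres, nres)     # E[i, j]: donor i (N-H), acceptor j (C=O)
  q <- 0.084 * 332
  for (i in seq_len(nres)) {
    if (any(is.na(Hpos[i, ])) || is.na(bb$N[i])) next
    for (j in seq_len(nres)) {
      if (abs(i - j) < 2 && bb$chain[i] == bb$chain[j]) next
      if (is.na(bb$C[j]) || is.na(bb$O[j])) next
      rON <- sqrt(sum((xyz[bb$N[i], ] - xyz[bb$O[j], ])^2))
      if (rON > 5.2) next        # beyond H-bond range; skip the arithmetic
      rCH <- sqrt(sum((Hpos[i, ] - xyz[bb$C[j], ])^2))
      rOH <- sqrt(sum((Hpos[i, ] - xyz[bb$O[j], ])^2))
      rCN <- sqrt(sum((xyz[bb$N[i], ] - xyz[bb$C[j], ])^2))
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Beta-sheet content
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
#' criterion (bond if E < -0.5 kcal/mol); residues are assigned to beta
#' structure if they take part in a parallel or antiparallel bridge. The
#' returned fraction is (bridge residues) / (protein residues).
#'
#' @param model a [structure_model()] with backbone N, CA, C, O per residue
#'   (amide H reconstructed when absent).
#' @param energy_cutoff H-bond energy threshold (kcal/mol).
#' @return fraction in `[0, 1]`; chains shorter than 3 residues give 0.
#' @export
beta_sheet_content <- function(model, energy_cutoff = -0.5) {
  bb <- backbone_table(model)
  nres <- nrow(bb)
  if (nres < 3) return(0)
  E <- ks_energy_matrix(model, bb)
  hb <- E < energy_cutoff
  is_beta <- rep(FALSE, nres)
  for (i in 2:(nres - 1)) {
    for (j in 2:(nres - 1)) {
      if (abs(i - j) < 3) next
      para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (para || anti) is_beta[c(i, j)] <- TRUE
    }
  }
  sum(is_beta) / nres
}

## ---- hydrogen bonds -------------------------------------------------------

#' Geometric hydrogen-bond count
#'
#' Counts donor-acceptor pairs with heavy-atom (donor N/O to acceptor N/O)
#' distance at most `d_cutoff` and donor-H...acceptor deviation from
#' linearity at most `angle_cutoff`. Intra-protein pairs only; pairs within
#' one residue are excluded.
#'
#' @param model a [structure_model()] with hydrogens present (donors without
#'   an attached H within 1.25 A are skipped).
#' @param d_cutoff heavy-atom distance cutoff (A), default 3.5.
#' @param angle_cutoff deviation from linear D-H...A (degrees), default 30.
#' @return integer bond count.
#' @export
hbond_count <- function(model, d_cutoff = 3.5, angle_cutoff = 30) {
  a <- model$atoms
  prot <- which(a$role == "protein")
  heavy <- prot[a$element[prot] %in% c("N", "O")]
  hyd <- prot[a$element[prot] == "H"]
  if (length(heavy) == 0) return(0L)
  xyz <- coords(model)
  # attach each H to its nearest N/O within 1.25 A (same residue)
  donors <- list()
  if (length(hyd) > 0) {
    d2 <- cross_dist2(xyz[hyd, , drop = FALSE], xyz[heavy, , drop = FALSE])
    for (k in seq_along(hyd)) {
      j <- which.min(d2[k, ])
      if (d2[k, j] <= 1.25^2)
        donors[[length(donors) + 1]] <- c(h = hyd[k], d = heavy[j])
    }
  }
  if (length(donors) == 0) return(0L)
  count <- 0L
  reskey <- paste(a$chain_id, a$residue_index)
  for (don in donors) {
    dvec <- xyz[don["d"], ]; hvec <- xyz[don["h"], ]
    for (acc in heavy) {
      if (acc == don["d"]) next
      if (reskey[acc] == reskey[don["d"]]) next
      dist <- sqrt(sum((dvec - xyz[acc, ])^2))
      if (dist > d_cutoff || dist < 1.5) next
      v1 <- dvec - hvec; v2 <- xyz[acc, ] - hvec
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (180 - ang <= angle_cutoff) count <- count + 1L
    }
  }
  count
}

#' H-bond count time course
#' @param traj segment or list of segments.
#' @param ... passed to [hbond_count()].
#' @return A [stage_series()].
#' @export
hbond_timecourse <- function(traj, ...) {
  segs <- as_segment_list(traj)
  times <- c(); values <- c(); stages <- c(); t0 <- 0
  for (s in segs) {
    v <- vapply(s$frames, function(f)
      hbond_count(set_coords(s$model, f), ...), numeric(1))
    tt <- t0 + s$time_per_frame * seq_along(s$frames)
    times <- c(times, tt); values <- c(values, v)
    stages <- c(stages, rep(s$stage, length(v)))
    t0 <- tt[length(tt)]
  }
  stage_series("hbonds", times, values, stages, units = "count")
}

## ---- domains --------------------------------------------------------------

#' Domain definition
#'
#' Residue index ranges of the kringle-2 domain, the catalytic domain and the
#' connecting linker, whose collapse and re-separation the pipeline tracks.
#'
#' @param kringle2,catalytic integer residue-index ranges (vectors).
#' @param linker optional linker range.
#' @return list of class `domain_definition`; ranges must be disjoint.
#' @export
domain_definition <- function(kringle2, catalytic, linker = integer()) {
  ranges <- list(kringle2 = as.integer(kringle2),
                 catalytic = as.integer(catalytic),
                 linker = as.integer(linker))
  all_idx <- unlist(ranges)
  if (anyDuplicated(all_idx) > 0) stop("domain ranges overlap")
  structure(ranges, class = "domain_definition")
}

#' Separation between two domains
#'
#' Mass-weighted centre-of-mass distance between the kringle-2 and catalytic
#' residue ranges, with the minimum inter-domain atom distance reported
#' alongside (a small value flags domain collapse into contact).
#'
#' @param model a [structure_model()].
#' @param domains a [domain_definition()].
#' @return list with `com_distance` and `min_distance` (A).
#' @export
domain_separation <- function(model, domains) {
  a <- model$atoms
  prot <- a$role == "protein"
  sel1 <- which(prot & a$residue_index %in% domains$kringle2)
  sel2 <- which(prot & a$residue_index %in% domains$catalytic)
  if (length(sel1) == 0 || length(sel2) == 0)
    stop("empty domain selection")
  m <- atom_masses(model)
  c1 <- center_of_mass(coords(model, sel1), m[sel1])
  c2 <- center_of_mass(coords(model, sel2), m[sel2])
  list(com_distance = sqrt(sum((c1 - c2)^2)),
       min_distance = min_dist(coords(model, sel1), coords(model, sel2)))
}

#' Per-atom root mean square fluctuation (utility)
#'
#' RMSF about the mean structure after superposing every frame onto the first.
#'
#' @param traj segment or list of segments.
#' @param selection see [resolve_selection()].
#' @return numeric vector, one value per selected atom (A).
#' @export
rmsf <- function(traj, selection = "calpha") {
  segs <- as_segment_list(traj)
  sel <- resolve_selection(segs[[1]]$model, selection)
  ref <- segs[[1]]$frames[[1]]
  fitted <- lapply(segs, function(s) lapply(s$frames, function(f) {
    fit <- superpose(f, ref, selection = sel)
    apply_fit(f[sel, , drop = FALSE], fit)
  }))
  fitted <- do.call(c, fitted)
  arr <- simplify2array(fitted)              # natoms x 3 x nframes
  mean_xyz <- apply(arr, c(1, 2), mean)
  sqrt(colMeans(t(apply(arr, 3, function(f)
    rowSums((f - mean_xyz)^2)))))
}
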