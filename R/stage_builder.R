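## stage_builder: the five-stage system-construction operators.
## RT  - cubic box (15 A margin), excipients, solvent, counterions
## F   - hexagonal-ice slabs covering the box faces
## 1D  - bulk-water stripping (3 A) and a 50 A vacuum box
## 2D  - residual waters matching crystal-water sites (1.5 A)
## REC - re-solvation in a fresh 15 A cubic box

AVOGADRO <- 6.02214076e23
WATER_MOLAR_MASS <- 18.015

#' Per-stage geometric configuration
#'
#' Collects every numeric rule the stage operators use. Defaults follow the
#' protocol: box margins of 15 A at room temperature and reconstitution, 7.5 A
#' for the coarse-grained aggregation systems, 50 A for the drying vacuum
#' boxes; 3 A bulk-water strip cutoff; 1.5 A crystal-water match cutoff; 2.4 A
#' steric clash cutoff; a 2x2x2 monomer grid at 85 A centre-of-mass spacing;
#' a 4 A inter-monomer contact cutoff and a 25% heatmap filter.
#'
#' @param stage one of `RT`, `F`, `1D`, `2D`, `REC`, `CG`.
#' @param box_margin protein-to-box-face distance in Angstrom; default depends
#'   on `stage` (RT/REC 15, CG 7.5, 1D/2D 50).
#' @param strip_cutoff bulk-water strip cutoff (A).
#' @param residual_match_cutoff crystal-water match cutoff (A).
#' @param clash_cutoff steric clash cutoff (A).
#' @param cg_grid integer triple, monomer replication grid.
#' @param cg_spacing centre-of-mass spacing of replicated monomers (A).
#' @param heatmap_filter fraction of the reference maximum below which heatmap
#'   cells are zeroed; in (0, 1).
#' @param contact_cutoff inter-monomer contact cutoff (A; strict `<`).
#' @param water_grid_spacing solvent grid spacing for re-solvation (A).
#' @return list of class `stage_config`.
#' @export
stage_config <- function(stage = c("RT", "F", "1D", "2D", "REC", "CG"),
                         box_margin = NULL, strip_cutoff = 3,
                         residual_match_cutoff = 1.5, clash_cutoff = 2.4,
                         cg_grid = c(2L, 2L, 2L), cg_spacing = 85,
                         heatmap_filter = 0.25, contact_cutoff = 4,
                         water_grid_spacing = 3.1) {
  stage <- match.arg(stage)
  if (is.null(box_margin))
    box_margin <- switch(stage, RT = 15, REC = 15, CG = 7.5,
                         `1D` = 50, `2D` = 50, F = 15)
  cfg <- list(stage = stage, box_margin = box_margin,
              strip_cutoff = strip_cutoff,
              residual_match_cutoff = residual_match_cutoff,
              clash_cutoff = clash_cutoff, cg_grid = as.integer(cg_grid),
              cg_spacing = cg_spacing, heatmap_filter = heatmap_filter,
              contact_cutoff = contact_cutoff,
              water_grid_spacing = water_grid_spacing)
  dists <- c(cfg$box_margin, cfg$strip_cutoff, cfg$residual_match_cutoff,
             cfg$clash_cutoff, cfg$cg_spacing, cfg$contact_cutoff,
             cfg$water_grid_spacing)
  if (any(!is.finite(dists)) || any(dists <= 0))
    stop("all distances in a stage_config must be > 0")
  if (cfg$heatmap_filter <= 0 || cfg$heatmap_filter >= 1)
    stop("heatmap_filter must lie in (0, 1)")
  if (any(cfg$cg_grid < 1)) stop("cg_grid dimensions must be >= 1")
  class(cfg) <- "stage_config"
  cfg
}

#' Load stage configurations from a YAML file
#'
#' Top-level keys name stages (`RT`, `F`, `1D`, `2D`, `REC`, `CG`); their
#' entries override [stage_config()] defaults.
#'
#' @param path YAML file path.
#' @return named list of `stage_config` objects.
#' @export
read_stage_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(st)
    do.call(stage_config, c(list(stage = st), raw[[st]])))
  setNames(out, names(raw))
}

#' Excipient descriptor
#'
#' Name, molar mass and net formal charge of a formulation excipient, plus
#' exactly one concentration mode. The built-in trio: free arginine
#' (`ARG`, 174.2 g/mol, +1 at formulation pH), tranexamic acid (`TXA`,
#' 157.2 g/mol, zwitterionic, net 0) and sucrose (`SUC`, 342.3 g/mol, 0).
#'
#' @param name `"ARG"`, `"TXA"`, `"SUC"` or a custom label.
#' @param molar_mass g/mol; defaults provided for the built-in trio.
#' @param net_charge elementary charges per molecule; defaults ARG +1,
#'   TXA/SUC 0.
#' @param conc_mM molar concentration (mM), or `NULL`.
#' @param mass_fraction w/w mass fraction in (0, 1), or `NULL`.
#' @return list of class `excipient_spec`.
#' @export
excipient_spec <- function(name, molar_mass = NULL, net_charge = NULL,
                           conc_mM = NULL, mass_fraction = NULL) {
  defaults <- list(ARG = list(mm = 174.20, q = 1L),
                   TXA = list(mm = 157.21, q = 0L),
                   SUC = list(mm = 342.30, q = 0L))
  d <- defaults[[toupper(name)]]
  if (is.null(molar_mass)) molar_mass <- if (!is.null(d)) d$mm else
    stop("molar_mass required for custom excipient ", name)
  if (is.null(net_charge)) net_charge <- if (!is.null(d)) d$q else 0L
  if (molar_mass <= 0) stop("molar_mass must be > 0")
  if (is.null(conc_mM) == is.null(mass_fraction))
    stop("exactly one of conc_mM and mass_fraction must be set")
  structure(list(name = toupper(name), molar_mass = molar_mass,
                 net_charge = as.integer(net_charge), conc_mM = conc_mM,
                 mass_fraction = mass_fraction),
            class = "excipient_spec")
}

#' Counterion inventory
#'
#' @param n_na number of Na+ ions.
#' @param n_cl number of Cl- ions.
#' @return list of class `ion_inventory`; at most one species is nonzero.
#' @export
ion_inventory <- function(n_na = 0L, n_cl = 0L) {
  n_na <- as.integer(n_na); n_cl <- as.integer(n_cl)
  if (n_na < 0 || n_cl < 0) stop("ion counts must be >= 0")
  if (n_na > 0 && n_cl > 0)
    stop("an inventory never mixes Na+ and Cl-")
  structure(list(n_na = n_na, n_cl = n_cl), class = "ion_inventory")
}

#' @export
print.ion_inventory <- function(x, ...) {
  if (x$n_na == 0 && x$n_cl == 0) cat("ion_inventory: no ions\n")
  else if (x$n_na > 0) cat("ion_inventory:", x$n_na, "Na+\n")
  else cat("ion_inventory:", x$n_cl, "Cl-\n")
  invisible(x)
}

## ---- box definition -------------------------------------------------------

#' Define a simulation box around the protein
#'
#' The box is sized so the minimum distance from any protein atom to the
#' nearest box face equals `margin`. With `cubic = TRUE` the side is the
#' largest protein axis extent plus twice the margin and the protein is
#' centred, so faces along shorter axes are at least `margin` away.
#'
#' @param model a [structure_model()] with at least one protein atom.
#' @param margin protein-to-face distance (A).
#' @param cubic force equal side lengths.
#' @return A [simulation_box()].
#' @export
define_box <- function(model, margin, cubic = TRUE) {
  sel <- atom_mask(model, role = "protein")
  if (!any(sel)) stop("no protein atoms to box")
  xyz <- coords(model, sel)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  extent <- hi - lo
  if (cubic) {
    side <- max(extent) + 2 * margin
    centre <- (lo + hi) / 2
    simulation_box(rep(side, 3), origin = centre - side / 2)
  } else {
    simulation_box(extent + 2 * margin, origin = lo - margin)
  }
}

#' Minimum protein-to-box-face distance
#' @param model a [structure_model()] whose box is set (or pass `box`).
#' @param box override box.
#' @return minimum over protein atoms and the six faces, in Angstrom.
#' @export
box_margin <- function(model, box = model$box) {
  if (is.null(box)) stop("model has no box")
  xyz <- coords(model, atom_mask(model, role = "protein"))
  lo <- box$origin; hi <- box$origin + box$lengths
  min(apply(xyz, 1, function(p) min(p - lo, hi - p)))
}

## ---- monomer replication --------------------------------------------------

#' Replicate a monomer on a lattice
#'
#' Places `prod(grid)` rigid copies of a single-chain monomer with
#' centre-of-mass spacing `spacing` along each occupied axis, assigning each
#' copy a fresh chain id. Internal geometry is untouched (pure translation).
#'
#' @param monomer single-chain [structure_model()].
#' @param grid integer triple, e.g. `c(2, 2, 2)` for eight monomers.
#' @param spacing centre-of-mass spacing (A); default 85.
#' @return multi-chain [structure_model()].
#' @export
replicate_monomers <- function(monomer, grid = c(2L, 2L, 2L), spacing = 85) {
  grid <- as.integer(grid)
  if (length(grid) != 3 || any(grid < 1))
    stop("grid must be three integers >= 1")
  if (length(unique(monomer$atoms$chain_id)) != 1)
    stop("monomer must be single-chain")
  n_copies <- prod(grid)
  if (n_copies > length(CHAIN_ALPHABET))
    stop("grid asks for more copies than available chain ids")
  cells <- expand.grid(ix = 0:(grid[1] - 1), iy = 0:(grid[2] - 1),
                       iz = 0:(grid[3] - 1))
  copies <- lapply(seq_len(n_copies), function(k) {
    shift <- spacing * as.numeric(cells[k, ])
    m <- set_coords(monomer, sweep(coords(monomer), 2, shift, "+"))
    m$atoms$chain_id <- CHAIN_ALPHABET[k]
    m
  })
  q <- monomer$net_charge
  combine_models(copies,
                 net_charge = if (is.null(q)) NULL else n_copies * q)
}

## ---- excipient arithmetic -------------------------------------------------

#' Number of excipient molecules at a molar concentration
#'
#' `N = round(C * V * N_A)` with the box volume in litres
#' (1 cubic Angstrom = 1e-27 L).
#'
#' @param box a [simulation_box()].
#' @param conc_mM concentration in millimolar (>= 0).
#' @return integer molecule count.
#' @export
count_excipients_molar <- function(box, conc_mM) {
  if (conc_mM < 0) stop("concentration must be >= 0")
  volume_L <- prod(box$lengths) * 1e-27
  as.integer(round(conc_mM * 1e-3 * volume_L * AVOGADRO))
}

#' Number of excipient molecules at a mass fraction
#'
#' The w/w basis is excipient mass over (excipient + water) mass, so
#' `N = round(f/(1-f) * n_waters * M_water / M_excipient)`.
#'
#' @param n_waters number of water molecules in the system.
#' @param spec an [excipient_spec()].
#' @param fraction mass fraction in `[0, 1)`; defaults to
#'   `spec$mass_fraction`.
#' @param water_molar_mass g/mol.
#' @return integer molecule count.
#' @export
count_excipients_ww <- function(n_waters, spec, fraction = spec$mass_fraction,
                                water_molar_mass = WATER_MOLAR_MASS) {
  if (is.null(fraction)) stop("no mass fraction given")
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  as.integer(round(fraction / (1 - fraction) * n_waters *
                     water_molar_mass / spec$molar_mass))
}

#' Counterions needed to neutralize a solute charge
#'
#' A positive total charge (protein plus excipients) is balanced with that
#' many Cl-, a negative one with Na+, zero with none. Example from the
#' formulation table: protein charge -1 plus 284 arginine (+1 each) gives a
#' +283 total and 283 Cl-.
#'
#' @param solute_net_charge integer total charge in elementary charges.
#' @return An [ion_inventory()] whose charge cancels the input exactly.
#' @export
neutralize <- function(solute_net_charge) {
  q <- solute_net_charge
  if (length(q) != 1 || !is.finite(q) || abs(q - round(q)) > 1e-9)
    stop("solute net charge must be a single integer")
  q <- as.integer(round(q))
  if (q > 0) ion_inventory(n_cl = q)
  else if (q < 0) ion_inventory(n_na = -q)
  else ion_inventory()
}

## ---- ice ------------------------------------------------------------------

ICE_A <- 4.497   # hexagonal a (A)
ICE_C <- 7.322   # hexagonal c (A)
OH_BOND <- 0.9572
HOH_ANGLE <- 104.52 * pi / 180

# oxygen sites of the ice-Ih (lonsdaleite) lattice, fractional hexagonal coords
ICE_FRAC <- matrix(c(1/3, 2/3, 1/16,
                     1/3, 2/3, 7/16,
                     2/3, 1/3, 9/16,
                     2/3, 1/3, 15/16), ncol = 3, byrow = TRUE)

#' Build a hexagonal ice block
#'
#' Oxygens sit on an ice-Ih lattice (hexagonal cell a = 4.497 A, c = 7.322 A,
#' four molecules per unit cell; nearest O-O distance ~2.75 A). Hydrogens are
#' placed with ideal intramolecular geometry (O-H 0.9572 A, 104.52 deg) in
#' randomized orientations — proton disorder without Bernal-Fowler ring
#' bookkeeping, which is irrelevant downstream since the block only enters
#' geometric operations. Atoms carry role `ice`, residue name `ICE`.
#'
#' @param nx,ny,nz unit-cell counts along the hexagonal axes (>= 1).
#' @param chain_id chain id for the block.
#' @return A [structure_model()] with `4 * nx * ny * nz` water molecules.
#' @export
build_ice_block <- function(nx, ny, nz, chain_id = "X") {
  if (any(c(nx, ny, nz) < 1)) stop("unit-cell counts must be >= 1")
  # hexagonal cell vectors
  a1 <- c(ICE_A, 0, 0)
  a2 <- c(-ICE_A / 2, ICE_A * sqrt(3) / 2, 0)
  a3 <- c(0, 0, ICE_C)
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  n_mol <- nrow(cells) * nrow(ICE_FRAC)
  oxy <- matrix(0, n_mol, 3)
  m <- 0
  for (r in seq_len(nrow(cells))) {
    base <- cells$i[r] * a1 + cells$j[r] * a2 + cells$k[r] * a3
    for (s in seq_len(nrow(ICE_FRAC))) {
      m <- m + 1
      oxy[m, ] <- base + ICE_FRAC[s, 1] * a1 + ICE_FRAC[s, 2] * a2 +
        ICE_FRAC[s, 3] * a3
    }
  }
  atoms <- water_atoms(oxy, residue_name = "ICE", role = "ice",
                       chain_id = chain_id)
  structure_model(atoms)
}

# O + 2 H atom rows for a set of oxygen positions; random orientations
water_atoms <- function(oxy, residue_name = "HOH", role = "water",
                        chain_id = "W", with_h = TRUE) {
  n <- nrow(oxy)
  if (n == 0)
    return(data.frame(element = character(), name = character(),
                      residue_index = integer(), residue_name = character(),
                      chain_id = character(), x = numeric(), y = numeric(),
                      z = numeric(), role = character(),
                      stringsAsFactors = FALSE))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    o <- oxy[i, ]
    if (with_h) {
      u <- random_unit_vector()
      # second O-H in the plane spanned by u and a perpendicular vector
      p <- perpendicular_unit(u)
      v <- cos(HOH_ANGLE) * u + sin(HOH_ANGLE) * p
      pos <- rbind(o, o + OH_BOND * u, o + OH_BOND * v)
      el <- c("O", "H", "H"); nm <- c("O", "H1", "H2")
    } else {
      pos <- rbind(o); el <- "O"; nm <- "O"
    }
    rows[[i]] <- data.frame(element = el, name = nm, residue_index = i,
                            residue_name = residue_name, chain_id = chain_id,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            role = role, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

perpendicular_unit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * u) * u
  p / sqrt(sum(p^2))
}

#' Cover the box faces with ice slabs
#'
#' Appends three hexagonal-ice slabs, one spanning each of the +x, +y and +z
#' box faces, placed just outside the face. Ice molecules with any atom closer
#' than `clash_cutoff` to a pre-existing atom (or to an earlier slab) are
#' deleted — the geometric counterpart of relaxing bad contacts by
#' minimization.
#'
#' @param system a [structure_model()] with a box.
#' @param thickness slab thickness (A).
#' @param clash_cutoff deletion distance (A).
#' @param gap clearance between the box face and the slab (A).
#' @return the system with ice appended (role `ice`).
#' @export
place_ice_blocks <- function(system, thickness = ICE_C, clash_cutoff = 2.4,
                             gap = 0.5) {
  if (is.null(system$box)) stop("system has no box")
  box <- system$box
  slabs <- vector("list", 3)
  existing <- coords(system)
  free_chains <- setdiff(CHAIN_ALPHABET, unique(system$atoms$chain_id))
  for (axis in 1:3) {
    face_dims <- box$lengths[-axis]
    # cell footprints in the block frame: x spans ~a, y spans ~a*sqrt(3)/2
    nx <- max(1L, ceiling(face_dims[1] / ICE_A) + 1L)
    ny <- max(1L, ceiling(face_dims[2] / (ICE_A * sqrt(3) / 2)) + 1L)
    nz <- max(1L, ceiling(thickness / ICE_C))
    block <- build_ice_block(nx, ny, nz, chain_id = free_chains[axis])
    xyz <- coords(block)
    # rotate block frame (u,v,w) so w lies along `axis` (cyclic permutation,
    # det +1)
    perm <- switch(axis, c(3, 1, 2), c(2, 3, 1), c(1, 2, 3))
    xyz <- xyz[, order(perm), drop = FALSE]
    # anchor: slab starts just outside the + face, spans the face laterally
    lo <- apply(xyz, 2, min)
    target <- box$origin
    target[axis] <- box$origin[axis] + box$lengths[axis] + gap
    xyz <- sweep(xyz, 2, target - lo, "+")
    block <- set_coords(block, xyz)
    # prune molecules clashing with existing atoms (incl. earlier slabs)
    block <- prune_clashing_molecules(block, existing, clash_cutoff)
    existing <- rbind(existing, coords(block))
    slabs[[axis]] <- block
  }
  out <- combine_models(c(list(system), slabs), box = box,
                        net_charge = system$net_charge)
  out
}

# delete whole molecules (residues) of `block` with any atom within cutoff of
# `ref_coords`
prune_clashing_molecules <- function(block, ref_coords, cutoff) {
  if (nrow(block$atoms) == 0 || nrow(ref_coords) == 0) return(block)
  d2 <- cross_dist2(coords(block), ref_coords)
  atom_clash <- apply(d2, 1, min) < cutoff^2
  res <- paste(block$atoms$chain_id, block$atoms$residue_index)
  bad_res <- unique(res[atom_clash])
  subset_model(block, !(res %in% bad_res))
}

## ---- water operations -----------------------------------------------------

#' Strip bulk water (primary drying)
#'
#' Retains a water molecule iff its oxygen lies within `cutoff` (inclusive) of
#' any protein atom; all other waters are removed. Non-water atoms are never
#' touched.
#'
#' @param system a [structure_model()] containing protein.
#' @param cutoff strip distance (A), default 3.
#' @return the stripped system.
#' @export
strip_bulk_water <- function(system, cutoff = 3) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  prot <- coords(system, atom_mask(system, role = "protein"))
  if (nrow(prot) == 0) stop("system contains no protein")
  a <- system$atoms
  wat_res <- unique(a[a$role == "water", c("chain_id", "residue_index")])
  if (nrow(wat_res) == 0) return(system)
  ox <- water_oxygens(system)
  d2 <- cross_dist2(coords(system, ox), prot)
  near <- apply(d2, 1, min) <= cutoff^2
  keep_key <- paste(a$chain_id[ox], a$residue_index[ox])[near]
  is_wat <- a$role == "water"
  key <- paste(a$chain_id, a$residue_index)
  subset_model(system, !is_wat | key %in% keep_key)
}

#' Select residual waters (secondary drying)
#'
#' Retains a water iff its oxygen lies within `match_cutoff` of any
#' crystal-water position (expressed in the protein frame; superpose the
#' system onto the reference protein first if needed). All other waters are
#' removed.
#'
#' @param system a [structure_model()].
#' @param crystal_waters n x 3 matrix of crystal-water oxygen positions (A).
#' @param match_cutoff matching distance (A), default 1.5.
#' @return the system with only residual waters left.
#' @export
select_residual_waters <- function(system, crystal_waters,
                                   match_cutoff = 1.5) {
  a <- system$atoms
  is_wat <- a$role == "water"
  if (is.null(crystal_waters) || NROW(crystal_waters) == 0) {
    warning("empty crystal-water list: removing all waters", call. = FALSE)
    return(subset_model(system, !is_wat))
  }
  crystal_waters <- matrix(as.numeric(as.matrix(crystal_waters)), ncol = 3)
  ox <- water_oxygens(system)
  if (length(ox) == 0) return(system)
  d2 <- cross_dist2(coords(system, ox), crystal_waters)
  near <- apply(d2, 1, min) <= match_cutoff^2
  keep_key <- paste(a$chain_id[ox], a$residue_index[ox])[near]
  key <- paste(a$chain_id, a$residue_index)
  subset_model(system, !is_wat | key %in% keep_key)
}

#' Convert ice to liquid water
#'
#' Used at the start of primary drying: the ice front becomes bulk water (role
#' and residue name change only) so the strip rule applies to it.
#'
#' @param system a [structure_model()].
#' @return the system with `ice` atoms relabelled `water`.
#' @export
melt_ice <- function(system) {
  is_ice <- system$atoms$role == "ice"
  system$atoms$role[is_ice] <- "water"
  system$atoms$residue_name[is_ice] <- "HOH"
  system
}

#' Re-solvate a dried system (reconstitution)
#'
#' Defines a fresh cubic box with the given protein-to-face margin and fills
#' it with waters on a cubic grid, excluding sites within `clash_cutoff` of
#' any existing atom. For a box of side L the grid carries `floor(L/spacing)`
#' sites per axis.
#'
#' @param system a non-empty [structure_model()].
#' @param margin protein-to-face distance (A), default 15.
#' @param grid_spacing water grid spacing (A), default 3.1 (roughly liquid
#'   density).
#' @param clash_cutoff exclusion distance around solute atoms (A).
#' @param with_h place hydrogens on the grid waters.
#' @return the solvated system with the new box.
#' @export
resolvate <- function(system, margin = 15, grid_spacing = 3.1,
                      clash_cutoff = 2.4, with_h = FALSE) {
  if (grid_spacing <= 0) stop("grid_spacing must be > 0")
  box <- if (any(atom_mask(system, role = "protein")))
    define_box(system, margin, cubic = TRUE)
  else system$box
  if (is.null(box)) stop("no protein and no box: cannot size the system")
  sites <- solvent_grid(box, grid_spacing)
  solute <- coords(system)
  if (nrow(solute) > 0 && nrow(sites) > 0) {
    d2 <- cross_dist2(sites, solute)
    sites <- sites[apply(d2, 1, min) >= clash_cutoff^2, , drop = FALSE]
  }
  free_chain <- setdiff(CHAIN_ALPHABET, unique(system$atoms$chain_id))[1]
  wat <- structure_model(water_atoms(sites, chain_id = free_chain,
                                     with_h = with_h))
  combine_models(list(system, wat), box = box,
                 net_charge = system$net_charge)
}

solvent_grid <- function(box, spacing) {
  counts <- floor(box$lengths / spacing)
  pts <- expand.grid(i = seq_len(max(counts[1], 0)),
                     j = seq_len(max(counts[2], 0)),
                     k = seq_len(max(counts[3], 0)))
  if (nrow(pts) == 0) return(matrix(numeric(), 0, 3))
  cbind(box$origin[1] + spacing * (pts$i - 0.5),
        box$origin[2] + spacing * (pts$j - 0.5),
        box$origin[3] + spacing * (pts$k - 0.5))
}

## ---- counterion placement and full stage preparation ----------------------

#' Materialize counterions as atoms
#'
#' Places Na+ or Cl- atoms on free solvent-grid sites of the box.
#'
#' @param system a [structure_model()] with a box.
#' @param ions an [ion_inventory()].
#' @param clash_cutoff minimum distance to existing atoms (A).
#' @return the system with ion atoms appended.
#' @export
add_ions <- function(system, ions, clash_cutoff = 2.4) {
  n <- ions$n_na + ions$n_cl
  if (n == 0) return(system)
  if (is.null(system$box)) stop("system has no box")
  sites <- solvent_grid(system$box, 4.0)
  d2 <- cross_dist2(sites, coords(system))
  sites <- sites[apply(d2, 1, min) >= clash_cutoff^2, , drop = FALSE]
  if (nrow(sites) < n) stop("not enough free sites to place ions")
  pick <- sites[seq_len(n), , drop = FALSE]
  el <- c(rep("NA", ions$n_na), rep("CL", ions$n_cl))
  free_chain <- setdiff(CHAIN_ALPHABET, unique(system$atoms$chain_id))[1]
  atoms <- data.frame(element = el, name = el, residue_index = seq_len(n),
                      residue_name = el, chain_id = free_chain,
                      x = pick[, 1], y = pick[, 2], z = pick[, 3],
                      role = "ion", stringsAsFactors = FALSE)
  combine_models(list(system, structure_model(atoms)), box = system$box,
                 net_charge = system$net_charge)
}

#' Prepare one pipeline stage
#'
#' Applies the system-construction rule of a stage to the previous stage's
#' output:
#' \describe{
#'   \item{RT}{cubic box (margin 15 A), excipients, grid solvent, counterions}
#'   \item{F}{ice slabs covering the +x, +y, +z box faces}
#'   \item{1D}{melt ice, strip waters beyond 3 A of protein, 50 A vacuum box}
#'   \item{2D}{keep only waters matching crystal-water sites (1.5 A)}
#'   \item{REC}{re-solvation in a fresh cubic box (margin 15 A)}
#' }
#'
#' @param system output of the previous stage (for RT: the dry protein).
#' @param stage one of `RT`, `F`, `1D`, `2D`, `REC`.
#' @param config a [stage_config()] for the stage; defaults per stage.
#' @param excipients optional [excipient_spec()]; RT only.
#' @param protein_net_charge protein net formal charge (elementary charges).
#' @param crystal_waters n x 3 crystal-water oxygen positions; 2D only.
#' @param seed integer seed controlling the randomized ice/water orientations.
#' @return the staged [structure_model()].
#' @export
prepare_stage <- function(system, stage, config = stage_config(stage),
                          excipients = NULL, protein_net_charge = -1,
                          crystal_waters = NULL, seed = 1) {
  stage <- match.arg(stage, STAGE_LEVELS)
  set.seed(seed)
  switch(stage,
    RT = {
      box <- define_box(system, config$box_margin, cubic = TRUE)
      system$box <- box
      q <- protein_net_charge
      if (!is.null(excipients)) {
        n_exc <- if (!is.null(excipients$conc_mM))
          count_excipients_molar(box, excipients$conc_mM)
        else {
          n_wat_est <- nrow(solvent_grid(box, config$water_grid_spacing))
          count_excipients_ww(n_wat_est, excipients)
        }
        pop <- make_excipient_population(excipients, n_exc, box = box,
                                         avoid = coords(system),
                                         clash_cutoff = config$clash_cutoff)
        system <- combine_models(list(system, pop), box = box)
        q <- q + n_exc * excipients$net_charge
      }
      system <- resolvate(system, margin = config$box_margin,
                          grid_spacing = config$water_grid_spacing,
                          clash_cutoff = config$clash_cutoff)
      system$net_charge <- as.integer(round(q))
      add_ions(system, neutralize(q), clash_cutoff = config$clash_cutoff)
    },
    F = place_ice_blocks(system, clash_cutoff = config$clash_cutoff),
    `1D` = {
      out <- strip_bulk_water(melt_ice(system), cutoff = config$strip_cutoff)
      out$box <- define_box(out, config$box_margin, cubic = TRUE)
      out
    },
    `2D` = select_residual_waters(system, crystal_waters,
                                  match_cutoff = config$residual_match_cutoff),
    REC = resolvate(system, margin = config$box_margin,
                    grid_spacing = config$water_grid_spacing,
                    clash_cutoff = config$clash_cutoff))
}

#' Run the full five-stage preparation pipeline
#'
#' Chains [prepare_stage()] through RT, F, 1D, 2D and REC, each stage
#' consuming the previous stage's output.
#'
#' @param protein the dry protein [structure_model()].
#' @param excipients optional [excipient_spec()].
#' @param protein_net_charge protein net charge.
#' @param crystal_waters crystal-water oxygen matrix for the 2D stage; when
#'   `NULL`, a subset of waters near the protein at the end of 1D stands in.
#' @param configs optional named list of per-stage [stage_config()]s.
#' @param seed integer seed.
#' @return named list of staged [structure_model()]s (`RT`, `F`, `1D`, `2D`,
#'   `REC`).
#' @export
run_fd_pipeline <- function(protein, excipients = NULL,
                            protein_net_charge = -1, crystal_waters = NULL,
                            configs = list(), seed = 1) {
  cfg <- function(st) if (!is.null(configs[[st]])) configs[[st]] else
    stage_config(st)
  out <- list()
  out$RT <- prepare_stage(protein, "RT", cfg("RT"), excipients = excipients,
                          protein_net_charge = protein_net_charge,
                          seed = seed)
  out$F <- prepare_stage(out$RT, "F", cfg("F"), seed = seed + 1)
  out$`1D` <- prepare_stage(out$F, "1D", cfg("1D"), seed = seed + 2)
  if (is.null(crystal_waters)) {
    # stand-in crystal-water list: the closest few hydration waters after 1D
    ox <- water_oxygens(out$`1D`)
    if (length(ox) > 0) {
      prot <- coords(out$`1D`, atom_mask(out$`1D`, role = "protein"))
      d <- apply(cross_dist2(coords(out$`1D`, ox), prot), 1, min)
      keep <- ox[order(d)][seq_len(min(5, length(ox)))]
      crystal_waters <- coords(out$`1D`, keep)
    } else crystal_waters <- matrix(numeric(), 0, 3)
  }
  out$`2D` <- prepare_stage(out$`1D`, "2D", cfg("2D"),
                            crystal_waters = crystal_waters, seed = seed + 3)
  out$REC <- prepare_stage(out$`2D`, "REC", cfg("REC"), seed = seed + 4)
  out
}
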