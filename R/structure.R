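ATOM_ROLES <- c("protein", "water", "excipient", "ion", "ice")
STAGE_LEVELS <- c("RT", "F", "1D", "2D", "REC")

# 62-symbol PDB chain alphabet, consumed in this order
CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Construct a structure model
#'
#' The shared container for every stage of the freeze-drying pipeline: an
#' ordered atom table plus an optional orthorhombic simulation box. Atoms carry
#' a role label (`protein`, `water`, `excipient`, `ion` or `ice`) that the
#' stage operators use to decide what to solvate, strip or count.
#'
#' @param atoms data.frame with columns `element`, `name`, `residue_index`
#'   (1-based, per chain), `residue_name` (3-letter code), `chain_id` (single
#'   character), `x`, `y`, `z` (Angstrom) and `role`.
#' @param box optional [simulation_box()].
#' @param net_charge optional integer net formal charge of the non-water,
#'   non-ion solute content (protein + excipients), in elementary charges.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, box = NULL, net_charge = NULL) {
  required <- c("element", "name", "residue_index", "residue_name",
                "chain_id", "x", "y", "z", "role")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$chain_id <- as.character(atoms$chain_id)
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("non-finite coordinates in atom table")
    if (!all(atoms$role %in% ATOM_ROLES))
      stop("unknown atom role(s): ",
           paste(unique(setdiff(atoms$role, ATOM_ROLES)), collapse = ", "))
    if (any(nchar(atoms$chain_id) != 1))
      stop("chain_id must be a single character")
    # residues must be contiguous runs of (chain_id, residue_index)
    key <- paste(atoms$chain_id, atoms$residue_index)
    if (anyDuplicated(rle(key)$values) > 0)
      stop("residue (chain_id, residue_index) groups are not contiguous")
  }
  if (!is.null(box)) box <- as_simulation_box(box)
  obj <- list(atoms = atoms, box = box, net_charge = net_charge)
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(a$chain_id)), "chain(s)\n")
  if (nrow(a) > 0) {
    tab <- table(a$role)
    cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$box))
    cat("  box: ", paste(sprintf("%.2f", x$box$lengths), collapse = " x "),
        " A\n", sep = "")
  invisible(x)
}

#' Orthorhombic simulation box
#'
#' @param lengths numeric 3-vector of edge lengths in Angstrom (all > 0).
#' @param origin numeric 3-vector, position of the box corner (Angstrom).
#' @return An object of class `simulation_box`.
#' @export
simulation_box <- function(lengths, origin = c(0, 0, 0)) {
  lengths <- as.numeric(lengths); origin <- as.numeric(origin)
  if (length(lengths) != 3 || length(origin) != 3)
    stop("lengths and origin must be 3-vectors")
  if (!all(is.finite(lengths)) || any(lengths <= 0))
    stop("box lengths must be finite and > 0")
  structure(list(lengths = lengths, origin = origin),
            class = "simulation_box")
}

as_simulation_box <- function(x) {
  if (inherits(x, "simulation_box")) return(x)
  simulation_box(x)
}

#' Is a box cubic?
#' @param box a [simulation_box()].
#' @param tol relative tolerance on edge-length equality.
#' @return logical.
#' @export
is_cubic <- function(box, tol = 1e-8) {
  diff(range(box$lengths)) <= tol * max(box$lengths)
}

#' Atom coordinates as a matrix
#' @param model a [structure_model()].
#' @param which optional row selector (logical or integer indices).
#' @return n x 3 numeric matrix in Angstrom.
#' @export
coords <- function(model, which = NULL) {
  m <- as.matrix(model$atoms[c("x", "y", "z")])
  colnames(m) <- c("x", "y", "z")
  if (!is.null(which)) m <- m[which, , drop = FALSE]
  m
}

#' Replace atom coordinates
#' @param model a [structure_model()].
#' @param value n x 3 matrix.
#' @return the updated model.
#' @export
set_coords <- function(model, value) {
  value <- as.matrix(value)
  if (nrow(value) != nrow(model$atoms) || ncol(value) != 3)
    stop("coordinate matrix must be n_atoms x 3")
  model$atoms$x <- value[, 1]; model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

#' Number of residues in a model
#' @param model a [structure_model()].
#' @param chain optional chain id; default counts over all chains.
#' @param role optional role filter (e.g. `"protein"`).
#' @return integer count of distinct (chain, residue_index) groups.
#' @export
n_residues <- function(model, chain = NULL, role = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain_id %in% chain, , drop = FALSE]
  if (!is.null(role)) a <- a[a$role %in% role, , drop = FALSE]
  nrow(unique(a[c("chain_id", "residue_index")]))
}

#' Select atoms by predicate columns
#' @param model a [structure_model()].
#' @param role,chain,element,name optional filters; `NULL` means no filter.
#' @return logical vector over atom rows.
#' @export
atom_mask <- function(model, role = NULL, chain = NULL, element = NULL,
                      name = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(name)) keep <- keep & a$name %in% name
  keep
}

#' Water oxygen rows of a model
#'
#' Every water (and ice) molecule exposes one oxygen; distances to water are
#' measured from it.
#'
#' @param model a [structure_model()].
#' @param include_ice also return ice oxygens.
#' @return integer atom row indices of the water oxygens.
#' @export
water_oxygens <- function(model, include_ice = FALSE) {
  roles <- if (include_ice) c("water", "ice") else "water"
  which(model$atoms$role %in% roles & model$atoms$element == "O")
}

# Concatenate atom tables of several models; box/net_charge from `box_from`
combine_models <- function(models, box = NULL, net_charge = NULL) {
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  rownames(atoms) <- NULL
  structure_model(atoms, box = box, net_charge = net_charge)
}

# Drop atom rows by logical keep-mask, preserving order
subset_model <- function(model, keep) {
  structure_model(model$atoms[keep, , drop = FALSE], box = model$box,
                  net_charge = model$net_charge)
}

## ---- geometry helpers -----------------------------------------------------

# squared cross-distance matrix between row-point sets A (n x 3) and B (m x 3)
cross_dist2 <- function(A, B, box_lengths = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  # per-axis differences: exact at cutoff boundaries, unlike the
  # expanded-square formulation
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    if (!is.null(box_lengths))                   # minimum image, orthorhombic
      dk <- dk - box_lengths[k] * round(dk / box_lengths[k])
    d2 <- d2 + dk^2
  }
  d2
}

min_dist <- function(A, B, box_lengths = NULL) {
  sqrt(min(cross_dist2(A, B, box_lengths)))
}

center_of_mass <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  colSums(coords * masses) / sum(masses)
}

## ---- element tables -------------------------------------------------------

# monoisotopic-ish standard atomic masses (g/mol)
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, NA. = 22.990, CL = 35.45,
                    K = 39.098, MG = 24.305, CA. = 40.078, F = 18.998)

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  m <- ELEMENT_MASSES[key]
  if (any(is.na(m)))
    stop("no mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Atomic masses of a model's atoms
#' @param model a [structure_model()].
#' @return numeric vector of masses (g/mol), one per atom.
#' @export
atom_masses <- function(model) element_mass(model$atoms$element)
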