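# Independent oracles used across the suite. These deliberately share no code
# with the package internals they check.

# Horn's quaternion method: minimum RMSD over rigid motions via the largest
# eigenvalue of the 4x4 quaternion matrix.
quaternion_rmsd <- function(mobile, reference) {
  P <- scale(as.matrix(mobile), scale = FALSE)
  Q <- scale(as.matrix(reference), scale = FALSE)
  S <- crossprod(P, Q)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

# Exact SASA of two overlapping spheres (solvent-expanded radii R1, R2 at
# centre distance d): each sphere loses one spherical cap.
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Plain-loop contact oracle: residue pairs on different chains whose minimum
# atom-atom (minimum-image) distance is strictly below the cutoff.
oracle_contacts <- function(model, xyz = coords(model), cutoff = 4,
                            box_lengths = NULL) {
  a <- model$atoms
  chains <- sort(unique(a$chain_id[a$role == "protein"]))
  out <- list()
  for (ia in seq_len(max(length(chains) - 1, 0))) for (ib in (ia + 1):length(chains)) {
    ra <- which(a$chain_id == chains[ia]); rb <- which(a$chain_id == chains[ib])
    for (r1 in unique(a$residue_index[ra])) for (r2 in unique(a$residue_index[rb])) {
      i1 <- ra[a$residue_index[ra] == r1]; i2 <- rb[a$residue_index[rb] == r2]
      best <- Inf
      for (p in i1) for (q in i2) {
        dv <- xyz[p, ] - xyz[q, ]
        if (!is.null(box_lengths)) dv <- dv - box_lengths * round(dv / box_lengths)
        best <- min(best, sum(dv^2))
      }
      if (best < cutoff^2)
        out[[length(out) + 1]] <- data.frame(chain_a = chains[ia],
                                             chain_b = chains[ib],
                                             residue_a = r1, residue_b = r2)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain_a = character(), chain_b = character(),
                      residue_a = integer(), residue_b = integer()))
  do.call(rbind, out)
}

# canonical string form of a contact set, for exact set comparison
contact_key <- function(rec) {
  if (nrow(rec) == 0) return(character(0))
  sort(paste(rec$chain_a, rec$chain_b, rec$residue_a, rec$residue_b))
}

# minimal single-chain monomer: one residue of `k` atoms in a compact blob
tiny_monomer <- function(k = 3, chain_id = "A") {
  pos <- cbind(seq_len(k) * 0.9, 0, 0)
  structure_model(data.frame(
    element = "C", name = paste0("C", seq_len(k)), residue_index = 1L,
    residue_name = "GLY", chain_id = chain_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3], role = "protein",
    stringsAsFactors = FALSE))
}

# random multi-chain system inside a box, for contact property tests
random_multichain <- function(n_chains = 3, res_per_chain = 4,
                              atoms_per_res = 3, box_side = 20) {
  rows <- list()
  for (c_i in seq_len(n_chains)) {
    for (r_i in seq_len(res_per_chain)) {
      centre <- runif(3, 0, box_side)
      for (a_i in seq_len(atoms_per_res)) {
        p <- centre + runif(3, -0.8, 0.8)
        rows[[length(rows) + 1]] <- data.frame(
          element = "C", name = paste0("C", a_i), residue_index = r_i,
          residue_name = "GLY", chain_id = LETTERS[c_i],
          x = p[1], y = p[2], z = p[3], role = "protein",
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  ord <- order(atoms$chain_id, atoms$residue_index)
  structure_model(atoms[ord, ], box = simulation_box(rep(box_side, 3)))
}
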