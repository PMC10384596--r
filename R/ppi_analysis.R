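## ppi_analysis: inter-monomer contact statistics of the coarse-grained
## aggregation systems.

#' Inter-monomer residue contacts in one frame
#'
#' A residue pair on two different chains is in contact iff the minimum
#' distance between any atom of one residue and any atom of the other is
#' strictly below `cutoff` (default 4 A). With a box present, distances use
#' the minimum-image convention; a pair is recorded once per frame however
#' many images or atom pairs satisfy the cutoff.
#'
#' @param model a multi-chain [structure_model()] (its box, if any, enables
#'   periodic wrapping).
#' @param frame optional n x 3 coordinate matrix overriding the model
#'   coordinates.
#' @param cutoff contact cutoff (A), strict `<`.
#' @param chains optional chain subset to consider.
#' @param frame_index frame number recorded in the output.
#' @return data.frame of class `contact_records` with columns `chain_a`,
#'   `chain_b` (a < b), `residue_a`, `residue_b`, `frame`.
#' @export
inter_monomer_contacts <- function(model, frame = NULL, cutoff = 4,
                                   chains = NULL, frame_index = 1L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- model$atoms
  xyz <- if (is.null(frame)) coords(model) else as.matrix(frame)
  if (is.null(chains))
    chains <- sort(unique(a$chain_id[a$role == "protein"]))
  box_len <- if (!is.null(model$box)) model$box$lengths else NULL
  empty <- data.frame(chain_a = character(), chain_b = character(),
                      residue_a = integer(), residue_b = integer(),
                      frame = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("contact_records", "data.frame")
  if (length(chains) < 2) {
    warning("fewer than 2 chains: no inter-monomer contacts", call. = FALSE)
    return(empty)
  }
  out <- list()
  for (ia in seq_len(length(chains) - 1)) {
    for (ib in (ia + 1):length(chains)) {
      ca <- chains[ia]; cb <- chains[ib]
      ra <- which(a$chain_id == ca); rb <- which(a$chain_id == cb)
      d2 <- cross_dist2(xyz[ra, , drop = FALSE], xyz[rb, , drop = FALSE],
                        box_len)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      pairs <- unique(data.frame(
        residue_a = a$residue_index[ra][hit[, 1]],
        residue_b = a$residue_index[rb][hit[, 2]]))
      out[[length(out) + 1]] <- data.frame(
        chain_a = ca, chain_b = cb,
        residue_a = pairs$residue_a, residue_b = pairs$residue_b,
        frame = as.integer(frame_index), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contact_records", "data.frame")
  res
}

#' Contacts over all frames of a trajectory
#'
#' @param traj a [trajectory_segment()] or list of them.
#' @param cutoff contact cutoff (A).
#' @param chains optional chain subset.
#' @return `contact_records` over all frames (frame numbering continues
#'   across segments).
#' @export
trajectory_contacts <- function(traj, cutoff = 4, chains = NULL) {
  segs <- as_segment_list(traj)
  if (n_frames(segs) == 0) stop("empty trajectory")
  out <- list(); fidx <- 0L
  for (s in segs) {
    for (f in s$frames) {
      fidx <- fidx + 1L
      out[[fidx]] <- suppressWarnings(
        inter_monomer_contacts(s$model, frame = f, cutoff = cutoff,
                               chains = chains, frame_index = fidx))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contact_records", "data.frame")
  res
}

#' Total PPI count of a trajectory
#'
#' The aggregation-propensity readout: contact records summed over frames
#' (one count per unique residue pair per frame). Set
#' `unique_pairs = TRUE` to instead count distinct residue pairs over the
#' whole trajectory.
#'
#' @param traj a [trajectory_segment()], list of segments, or a
#'   `contact_records` table.
#' @param cutoff contact cutoff (A).
#' @param unique_pairs count each residue pair at most once.
#' @return integer count.
#' @export
ppi_count <- function(traj, cutoff = 4, unique_pairs = FALSE) {
  rec <- if (inherits(traj, "contact_records")) traj
  else trajectory_contacts(traj, cutoff = cutoff)
  if (!unique_pairs) return(nrow(rec))
  nrow(unique(rec[c("chain_a", "chain_b", "residue_a", "residue_b")]))
}

#' Normalize PPI counts across conditions
#'
#' Divides every condition's count by the smallest positive count, so the
#' weakest-interacting condition maps to exactly 1. Ties all map to 1; the
#' result is invariant under a common scale factor.
#'
#' @param counts named numeric vector (or list) of per-condition PPI counts,
#'   all >= 0, at least one positive.
#' @return named numeric vector of relative counts.
#' @export
normalize_ppi <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) == 0 || any(counts < 0))
    stop("counts must be non-negative")
  pos <- counts[counts > 0]
  if (length(pos) == 0) stop("all PPI counts are zero: nothing to normalize")
  counts / min(pos)
}

#' Thresholded residue-pair interaction heatmap
#'
#' Accumulates per-residue-pair contact counts and zeroes every cell whose
#' count falls below `filter_fraction` of the strongest pair in the reference
#' (non-aggregating) condition; cells exactly at the threshold are retained.
#'
#' @param records `contact_records` of the condition to map.
#' @param reference_records `contact_records` of the reference condition
#'   (defaults to `records` itself).
#' @param filter_fraction threshold fraction of the reference maximum,
#'   default 0.25.
#' @param n_residues matrix dimension; default the largest residue index
#'   seen.
#' @return object of class `ppi_heatmap`: list with `matrix` (residue x
#'   residue counts, rows = first chain's residue), `reference_max`,
#'   `filter_fraction`.
#' @export
contact_heatmap <- function(records, reference_records = records,
                            filter_fraction = 0.25, n_residues = NULL) {
  if (nrow(reference_records) == 0) stop("empty reference record set")
  pair_counts <- function(rec) {
    if (nrow(rec) == 0) return(integer(0))
    tab <- table(paste(rec$residue_a, rec$residue_b))
    tab
  }
  ref_max <- max(pair_counts(reference_records))
  if (is.null(n_residues))
    n_residues <- max(records$residue_a, records$residue_b,
                      reference_records$residue_a,
                      reference_records$residue_b)
  m <- matrix(0L, n_residues, n_residues,
              dimnames = list(seq_len(n_residues), seq_len(n_residues)))
  if (nrow(records) > 0) {
    tab <- pair_counts(records)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    m[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- as.integer(tab)
  }
  m[m < filter_fraction * ref_max] <- 0L
  structure(list(matrix = m, reference_max = as.integer(ref_max),
                 filter_fraction = filter_fraction),
            class = "ppi_heatmap")
}

#' @export
print.ppi_heatmap <- function(x, ...) {
  nz <- sum(x$matrix > 0)
  cat("ppi_heatmap:", nrow(x$matrix), "x", ncol(x$matrix), "residues,",
      nz, "retained cell(s); reference max", x$reference_max,
      "; filter", x$filter_fraction, "\n")
  invisible(x)
}

#' @export
plot.ppi_heatmap <- function(x, ...) {
  graphics::image(seq_len(nrow(x$matrix)), seq_len(ncol(x$matrix)),
                  x$matrix, xlab = "residue (monomer A)",
                  ylab = "residue (monomer B)", ...)
  invisible(x)
}

#' Write a heatmap as a TSV matrix
#' @param heatmap a `ppi_heatmap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(heatmap, path) {
  utils::write.table(heatmap$matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Oligomer size distribution
#'
#' Builds the monomer contact graph (nodes = chains, edges = any
#' inter-monomer contact) and returns the connected-component sizes, which
#' always sum to the number of monomers.
#'
#' @param records `contact_records` (typically of one frame).
#' @param chains character vector of all monomer chain ids in the system.
#' @return integer vector of cluster sizes, decreasing.
#' @export
oligomer_size_distribution <- function(records, chains) {
  chains <- as.character(chains)
  bad <- setdiff(unique(c(records$chain_a, records$chain_b)), chains)
  if (length(bad) > 0)
    stop("contact records reference unknown chain(s): ",
         paste(bad, collapse = ", "))
  g <- igraph::make_empty_graph(n = length(chains), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = chains)
  if (nrow(records) > 0) {
    edges <- unique(records[c("chain_a", "chain_b")])
    g <- igraph::add_edges(g, rbind(match(edges$chain_a, chains),
                                    match(edges$chain_b, chains)))
  }
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}

#' Excipient contact occupancy of one residue
#'
#' Fraction of frames in which any atom of the given role (default
#' `excipient`) lies within `cutoff` of any atom of the residue — the
#' binding-site occupancy readout (e.g. Lys40 vs free arginine).
#'
#' @param traj a [trajectory_segment()] or list of them.
#' @param residue length-2 spec `list(chain, index)` or `c(chain, index)`.
#' @param partner_role role of the contacting partner.
#' @param cutoff contact distance (A), inclusive.
#' @return fraction in `[0, 1]`.
#' @export
excipient_contact_occupancy <- function(traj, residue,
                                        partner_role = "excipient",
                                        cutoff = 4) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  segs <- as_segment_list(traj)
  model <- segs[[1]]$model
  a <- model$atoms
  chain <- as.character(residue[[1]]); idx <- as.integer(residue[[2]])
  sel <- which(a$chain_id == chain & a$residue_index == idx)
  if (length(sel) == 0)
    stop("residue ", idx, " of chain ", chain, " not found")
  partner <- which(a$role == partner_role)
  if (length(partner) == 0) return(0)
  box_len <- if (!is.null(model$box)) model$box$lengths else NULL
  hits <- 0L; total <- 0L
  for (s in segs) {
    for (f in s$frames) {
      total <- total + 1L
      d2 <- cross_dist2(f[sel, , drop = FALSE], f[partner, , drop = FALSE],
                        box_len)
      if (min(d2) <= cutoff^2) hits <- hits + 1L
    }
  }
  hits / total
}
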