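## apr_analysis: aggregation-prone-residue scoring and difference maps.
## The score is a transparent structure-based stand-in: exposure-weighted
## hydrophobicity with linear spatial smoothing over a C-alpha neighbourhood.
## It follows the usual convention (higher = more aggregation-prone) and makes
## no claim of numeric equivalence with external aggregation predictors.

# Kyte-Doolittle hydropathy, the default per-residue aggregation propensity
KD_SCALE <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
              GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
              LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
              SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

# Theoretical maximum accessible surface areas (A^2), Tien et al. style
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Aggregation-prone-residue (APR) score profile
#'
#' For every protein residue i,
#' `score_i = sum over residues j with d(CA_i, CA_j) <= R of
#' w(d_ij) * h_j * rsa_j`, where `h_j` is the residue-type aggregation
#' propensity (default Kyte-Doolittle hydropathy), `rsa_j` the residue's
#' relative SASA (residue SASA over its fully exposed reference area) and
#' `w(d) = 1 - d/R` a linear distance decay over the neighbourhood radius
#' `R`. Higher scores mean more aggregation-prone; a residue whose whole
#' neighbourhood is buried (rsa 0) scores 0.
#'
#' @param model a [structure_model()] with CA atoms per protein residue.
#' @param scale named propensity vector covering all residue types present.
#' @param neighborhood_radius smoothing radius R (A), default 10.
#' @param condition label stored with the profile (e.g. `"RT"`).
#' @param ... passed to [sasa()].
#' @return object of class `apr_profile`: numeric scores named by residue
#'   index, with `condition` attribute.
#' @export
apr_score <- function(model, scale = KD_SCALE, neighborhood_radius = 10,
                      condition = "", ...) {
  a <- model$atoms
  prot <- a$role == "protein"
  bb <- backbone_table(model)
  if (any(is.na(bb$CA))) stop("every protein residue needs a CA atom")
  missing <- setdiff(unique(bb$resname), names(scale))
  if (length(missing) > 0)
    stop("propensity scale lacks residue type(s): ",
         paste(missing, collapse = ", "))
  areas <- sasa(model, ...)
  reskey <- paste(a$chain_id, a$residue_index)
  res_area <- vapply(bb$key, function(k)
    sum(areas[prot & reskey == k]), numeric(1))
  max_area <- MAX_ASA[bb$resname]
  max_area[is.na(max_area)] <- mean(MAX_ASA)
  rsa <- pmin(1, res_area / max_area)
  h <- unname(scale[bb$resname])
  ca_xyz <- coords(model)[bb$CA, , drop = FALSE]
  d <- sqrt(cross_dist2(ca_xyz, ca_xyz))
  w <- pmax(1 - d / neighborhood_radius, 0)   # keeps matrix shape
  w[d > neighborhood_radius] <- 0
  scores <- as.vector(w %*% (h * rsa))
  names(scores) <- bb$resno
  structure(scores, condition = condition, class = "apr_profile")
}

#' @export
print.apr_profile <- function(x, ...) {
  cat("apr_profile (", length(x), " residues",
      if (nzchar(attr(x, "condition")))
        paste0(", condition ", attr(x, "condition")), "):\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-residue APR difference map
#'
#' Element-wise `a - b` over congruent residue sets. Under the
#' higher-is-more-prone convention a positive difference means condition `a`
#' is more aggregation-prone at that residue; the operand order is recorded
#' in the result's `minuend`/`subtrahend` attributes so either reading of a
#' published difference map can be reproduced explicitly.
#'
#' @param profile_a,profile_b [apr_score()] profiles over the same residues.
#' @param threshold magnitude above which residues are flagged in
#'   `summary()` as destabilized (positive) or stabilized (negative).
#' @return object of class `apr_difference` (named numeric vector).
#' @export
apr_difference <- function(profile_a, profile_b, threshold = 0.5) {
  if (length(profile_a) != length(profile_b) ||
      !identical(names(profile_a), names(profile_b)))
    stop("profiles cover different residue sets")
  d <- unclass(profile_a) - unclass(profile_b)
  structure(d,
            minuend = attr(profile_a, "condition"),
            subtrahend = attr(profile_b, "condition"),
            threshold = threshold, class = "apr_difference")
}

#' @export
summary.apr_difference <- function(object, threshold = attr(object,
                                                            "threshold"),
                                   ...) {
  d <- unclass(object)
  list(minuend = attr(object, "minuend"),
       subtrahend = attr(object, "subtrahend"),
       destabilized = as.integer(names(d)[d > threshold]),
       stabilized = as.integer(names(d)[d < -threshold]))
}

#' @export
print.apr_difference <- function(x, ...) {
  cat("apr_difference (", attr(x, "minuend"), " - ", attr(x, "subtrahend"),
      "), ", length(x), " residues\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' APR region
#'
#' A labelled residue-index window (the published maps mark four, A-D; the
#' kringle-2 hotspot spans Met35-Val41).
#'
#' @param label region label, e.g. `"B"`.
#' @param residue_range integer residue indices.
#' @return list of class `apr_region`.
#' @export
apr_region <- function(label, residue_range) {
  if (length(residue_range) == 0) stop("empty region")
  structure(list(label = label, residue_range = as.integer(residue_range)),
            class = "apr_region")
}

#' Mean APR difference per region
#'
#' @param differences an [apr_difference()] (or named numeric vector keyed by
#'   residue index).
#' @param regions list of [apr_region()]s.
#' @return named numeric vector of per-region means.
#' @export
region_summary <- function(differences, regions) {
  d <- unclass(differences)
  idx <- as.integer(names(d))
  out <- vapply(regions, function(r) {
    sel <- idx %in% r$residue_range
    if (!any(sel)) stop("region ", r$label, " matches no residues")
    mean(d[sel])
  }, numeric(1))
  names(out) <- vapply(regions, `[[`, "", "label")
  out
}
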