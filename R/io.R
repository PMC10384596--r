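## core_io: PDB/XYZ reading and writing, role assignment, result export.
## PDB records handled: ATOM/HETATM/MODEL/ENDMDL/CRYST1/TER (orthorhombic
## CRYST1 only). bio3d does the fixed-width parsing/formatting; the CRYST1
## record, which bio3d's writer does not emit, is handled directly.

WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "WT4", "SPC")
ION_RESNAMES <- c("NA", "NA+", "SOD", "CL", "CL-", "CLA", "K", "K+", "MG")
ICE_RESNAMES <- c("ICE")

#' Assign atom roles from residue names
#'
#' Waters (`HOH`, `WAT`, `SOL`, ...) and ions (`NA`, `CL`, ...) are recognised
#' by residue name; ice molecules are tagged `ICE` by the ice builder. Free
#' excipients are declared explicitly, because arginine used as an excipient
#' shares its 3-letter code with the amino acid: a residue is an excipient if
#' its residue name is in `excipient_resnames` or its chain is in
#' `excipient_chains`. Everything else is protein; non-standard residue names
#' falling through to protein are reported once via a warning.
#'
#' @param atoms atom data.frame (as in [structure_model()], role column
#'   optional).
#' @param excipient_resnames residue names to label `excipient`.
#' @param excipient_chains chain ids whose residues are all excipient.
#' @param quiet suppress the unknown-residue warning.
#' @return the atom table with a filled `role` column.
#' @export
assign_roles <- function(atoms, excipient_resnames = c("TXA", "SUC"),
                         excipient_chains = NULL, quiet = FALSE) {
  rn <- toupper(atoms$residue_name)
  role <- rep("protein", nrow(atoms))
  role[rn %in% WATER_RESNAMES] <- "water"
  role[rn %in% ION_RESNAMES] <- "ion"
  role[rn %in% ICE_RESNAMES] <- "ice"
  role[rn %in% toupper(excipient_resnames)] <- "excipient"
  if (!is.null(excipient_chains))
    role[atoms$chain_id %in% excipient_chains] <- "excipient"
  unknown <- role == "protein" & !(rn %in% AMINO3)
  if (any(unknown) && !quiet)
    warning("unknown residue name(s) treated as protein: ",
            paste(unique(rn[unknown]), collapse = ", "), call. = FALSE)
  atoms$role <- role
  atoms
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("NA", "CL", "MG", "FE", "ZN", "BR"), two,
                substr(gsub("^[0-9]*", "", nm), 1, 1))
  out
}

parse_cryst1 <- function(lines) {
  hit <- grep("^CRYST1", lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  len <- suppressWarnings(as.numeric(c(substr(hit[1], 7, 15),
                                       substr(hit[1], 16, 24),
                                       substr(hit[1], 25, 33))))
  if (any(is.na(len)) || any(len <= 0)) return(NULL)
  simulation_box(len)
}

format_cryst1 <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box$lengths[1], box$lengths[2], box$lengths[3], 90, 90, 90)
}

#' Read a structure file
#'
#' Reads a PDB (subset: ATOM/HETATM/MODEL/ENDMDL/CRYST1/TER) or chemical XYZ
#' file into a [structure_model()]. For multi-model PDB the first model's
#' coordinates are used; see [read_trajectory()] for all frames. Roles are
#' assigned per [assign_roles()].
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension.
#' @param ... passed to [assign_roles()] (`excipient_resnames`,
#'   `excipient_chains`, `quiet`).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"), ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") return(read_xyz(path, ...))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(grepl("^(ATOM  |HETATM)", lines)))
    stop("empty or atom-free PDB file: ", path)
  validate_pdb_records(lines, path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb_to_atoms(pdb)
  atoms <- assign_roles(atoms, ...)
  structure_model(atoms, box = parse_cryst1(lines))
}

# coordinate fields of every ATOM/HETATM record must parse as numbers
validate_pdb_records <- function(lines, path) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate record at line ", i, " of ", path)
  }
  invisible(TRUE)
}

pdb_to_atoms <- function(pdb) {
  at <- pdb$atom
  elesy <- trimws(at$elesy)
  bad <- is.na(elesy) | elesy == ""
  elesy[bad] <- guess_element(at$elety[bad])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  data.frame(element = elesy, name = trimws(at$elety),
             residue_index = as.integer(at$resno),
             residue_name = trimws(at$resid), chain_id = chain,
             x = at$x, y = at$y, z = at$z,
             role = "protein", stringsAsFactors = FALSE)
}

read_xyz <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed atom count at line 1 of ", path)
  if (length(lines) < n + 2) stop("truncated XYZ file: ", path)
  rows <- strsplit(trimws(lines[3:(n + 2)]), "[[:space:]]+")
  bad <- which(vapply(rows, length, 1L) < 4)
  if (length(bad) > 0)
    stop("malformed coordinate record at line ", bad[1] + 2, " of ", path)
  el <- vapply(rows, `[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(is.na(xyz)))
    stop("malformed coordinate record at line ",
         which(rowSums(is.na(xyz)) > 0)[1] + 2, " of ", path)
  atoms <- data.frame(element = el, name = el,
                      residue_index = seq_len(n),
                      residue_name = ifelse(toupper(el) == "O", "HOH", "UNK"),
                      chain_id = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      role = "protein", stringsAsFactors = FALSE)
  atoms <- assign_roles(atoms, quiet = TRUE, ...)
  structure_model(atoms)
}

#' Write a structure or trajectory
#'
#' Writes PDB (with `CRYST1` when the model has a box; `MODEL`/`ENDMDL` pairs
#' for trajectories) or XYZ. Chain ids and residue numbering are preserved.
#'
#' @param model a [structure_model()] or [trajectory_segment()].
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"` (trajectories: pdb only).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (inherits(model, "trajectory_segment")) {
    if (format != "pdb") stop("trajectories are written as multi-model PDB")
    return(write_pdb_frames(model$model, model$frames, path))
  }
  if (nrow(model$atoms) == 0) stop("refusing to write an empty model")
  if (format == "xyz") return(write_xyz(model, path))
  write_pdb_frames(model, list(coords(model)), path, box = model$box)
}

write_pdb_frames <- function(model, frames, path, box = model$box) {
  a <- model$atoms
  if (length(unique(a$chain_id)) > length(CHAIN_ALPHABET))
    stop("more than ", length(CHAIN_ALPHABET),
         " chains: PDB chain-id alphabet exhausted")
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  if (!is.null(box)) writeLines(format_cryst1(box), path)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$role == "protein", "ATOM", "HETATM"),
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = seq_len(nrow(a)) %% 100000,
                   elety = a$name, chain = a$chain_id, elesy = a$element,
                   append = !is.null(box))
  invisible(path)
}

write_xyz <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(a)), "generated by lyotraj"), con)
  writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z),
             con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory segment
#'
#' @param path multi-model PDB path.
#' @param stage stage label, one of `RT`, `F`, `1D`, `2D`, `REC`.
#' @param time_per_frame ns between consecutive frames.
#' @param ... passed to [assign_roles()].
#' @return A [trajectory_segment()].
#' @export
read_trajectory <- function(path, stage = "RT", time_per_frame = 1, ...) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_records(lines, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- assign_roles(pdb_to_atoms(pdb), ...)
  model <- structure_model(atoms, box = parse_cryst1(lines))
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(i)
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory_segment(model, frames, stage = stage,
                     time_per_frame = time_per_frame)
}

## ---- trajectory segments --------------------------------------------------

#' Construct a trajectory segment
#'
#' A list of coordinate frames congruent with one [structure_model()], tagged
#' with the freeze-drying stage it belongs to.
#'
#' @param model the topology [structure_model()].
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param stage one of `RT`, `F`, `1D`, `2D`, `REC`.
#' @param time_per_frame ns between consecutive frames.
#' @return An object of class `trajectory_segment`.
#' @export
trajectory_segment <- function(model, frames, stage = "RT",
                               time_per_frame = 1) {
  stage <- match.arg(stage, STAGE_LEVELS)
  if (length(frames) == 0) stop("a trajectory segment needs >= 1 frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != nrow(model$atoms) || ncol(f) != 3)
      stop("frame dimensions do not match the structure model")
    unname(f)
  })
  structure(list(model = model, frames = frames, stage = stage,
                 time_per_frame = time_per_frame),
            class = "trajectory_segment")
}

#' @export
print.trajectory_segment <- function(x, ...) {
  cat("trajectory_segment: stage", x$stage, "-", length(x$frames),
      "frame(s) x", nrow(x$model$atoms), "atoms,",
      x$time_per_frame, "ns/frame\n")
  invisible(x)
}

#' Number of frames in a segment or segment list
#' @param traj a `trajectory_segment` or list of them.
#' @return integer.
#' @export
n_frames <- function(traj) {
  if (inherits(traj, "trajectory_segment")) return(length(traj$frames))
  sum(vapply(traj, function(s) length(s$frames), 1L))
}

as_segment_list <- function(traj) {
  if (inherits(traj, "trajectory_segment")) list(traj) else traj
}

#' Concatenate pipeline stage segments
#'
#' Segments must share a topology and appear in pipeline order
#' RT, F, 1D, 2D, REC (each stage at most once, later stages never before
#' earlier ones).
#'
#' @param ... `trajectory_segment` objects, or a single list of them.
#' @return ordered list of segments (class `stage_trajectory`).
#' @export
concat_segments <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && !inherits(segs[[1]], "trajectory_segment"))
    segs <- segs[[1]]
  ranks <- vapply(segs, function(s) match(s$stage, STAGE_LEVELS), 1L)
  if (any(diff(ranks) <= 0))
    stop("stage labels must follow the pipeline order RT, F, 1D, 2D, REC")
  n <- vapply(segs, function(s) nrow(s$model$atoms), 1L)
  if (length(unique(n)) != 1)
    stop("segments have differing atom counts")
  structure(segs, class = "stage_trajectory")
}

## ---- stage series ---------------------------------------------------------

#' Construct a stage-labelled time series
#'
#' One scalar observable along the pipeline, each point tagged with its stage
#' so that stage boundaries are recoverable.
#'
#' @param observable observable name (e.g. `"rmsd"`).
#' @param times times in ns.
#' @param values observable values.
#' @param stages stage label per point, in pipeline order.
#' @param units unit string for printing.
#' @return A data.frame of class `stage_series` with columns `time_ns`,
#'   `stage`, `value`.
#' @export
stage_series <- function(observable, times, values, stages, units = "") {
  if (length(times) == 0) stop("empty series")
  if (length(times) != length(values) || length(times) != length(stages))
    stop("times, values and stages must have equal length")
  stages <- as.character(stages)
  ranks <- match(stages, STAGE_LEVELS)
  if (any(is.na(ranks))) stop("unknown stage label(s)")
  if (any(diff(ranks) < 0))
    stop("stages must appear in pipeline order RT, F, 1D, 2D, REC")
  out <- data.frame(time_ns = as.numeric(times), stage = stages,
                    value = as.numeric(values))
  attr(out, "observable") <- observable
  attr(out, "units") <- units
  class(out) <- c("stage_series", "data.frame")
  out
}

#' @export
print.stage_series <- function(x, ...) {
  cat("stage_series '", attr(x, "observable"), "': ", nrow(x), " points, ",
      "stages ", paste(unique(x$stage), collapse = ","), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.stage_series <- function(x, ...) {
  graphics::plot(x$time_ns, x$value, type = "l",
                 xlab = "time (ns)",
                 ylab = paste(attr(x, "observable"), attr(x, "units")), ...)
  bounds <- x$time_ns[which(diff(match(x$stage, STAGE_LEVELS)) > 0) + 1]
  graphics::abline(v = bounds, lty = 2, col = "grey50")
  invisible(x)
}

#' Export a stage series as delimited text
#'
#' Writes columns `time_ns`, `stage`, `value` (tab-separated by default), from
#' which stage boundaries are recoverable.
#'
#' @param series a [stage_series()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
export_timeseries <- function(series, path, sep = "\t") {
  if (!inherits(series, "stage_series")) stop("not a stage_series")
  if (nrow(series) == 0) stop("empty series")
  utils::write.table(as.data.frame(series)[c("time_ns", "stage", "value")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
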