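## Readers/writers.  Standard MD formats (PDB topology, DCD coordinates) are
## handled by bio3d; the package additionally defines a small self-describing
## columnar text format for fixtures so tests and examples need no binary
## files.

#' Load a particle trajectory
#'
#' Reads a PDB topology plus one or more DCD coordinate files (via
#' \pkg{bio3d}), or a single file in the package's columnar fixture format
#' (see [writeTrajectoryFixture()]).  Only cubic boxes are accepted: every
#' correction formula in the package assumes a single box edge length L.
#'
#' @param topologyPath path to a PDB file, or to a `.traj` fixture file (in
#'   which case `coordinatePaths` is ignored).
#' @param coordinatePaths character vector of DCD paths, concatenated in
#'   order.
#' @param labelRules controls particle labeling.  Either `NULL` (molecules
#'   from PDB chain, heavy = non-hydrogen, C-alpha from atom name "CA",
#'   solvent from residue names HOH/TIP3/WAT/SOL), a function mapping the
#'   bio3d atom table to a `particles` data.frame, or a list with an element
#'   `molecule` giving an explicit molecule id per particle (used e.g. to
#'   treat a homo-dimer as one diffusing unit).
#' @param dt frame spacing in ns for DCD files (which do not store times).
#' @param cubicTol relative tolerance for accepting a box as cubic.
#' @return A [Trajectory-class] (flagged as wrapped).
#' @export
loadTrajectory <- function(topologyPath, coordinatePaths = NULL,
                           labelRules = NULL, dt = 1, cubicTol = 1e-4) {
  if (!file.exists(topologyPath))
    stop(sprintf("topology file '%s' does not exist", topologyPath))
  if (grepl("\\.traj$", topologyPath, ignore.case = TRUE))
    return(readTrajectoryFixture(topologyPath))
  if (any(grepl("\\.xtc$", coordinatePaths, ignore.case = TRUE)))
    stop("XTC coordinate files are not supported; convert to DCD or use the ",
         "columnar fixture format")
  pdb <- bio3d::read.pdb(topologyPath)
  atoms <- pdb$atom
  np <- nrow(atoms)

  coordsList <- list()
  cellList <- list()
  for (p in coordinatePaths) {
    if (!file.exists(p)) stop(sprintf("coordinate file '%s' does not exist", p))
    trj <- bio3d::read.dcd(p, cell = FALSE, verbose = FALSE)
    if (ncol(trj) != 3L * np)
      stop(sprintf(paste0("particle-count mismatch: topology has %d atoms ",
                          "but '%s' has %d"), np, p, ncol(trj) / 3))
    cell <- tryCatch(bio3d::read.dcd(p, cell = TRUE, verbose = FALSE),
                     error = function(e) NULL)
    coordsList[[length(coordsList) + 1L]] <- trj
    cellList[[length(cellList) + 1L]] <- cell
  }
  flat <- do.call(rbind, coordsList)
  nf <- nrow(flat)
  coords <- array(0, dim = c(nf, np, 3L))
  coords[, , 1] <- flat[, seq(1L, 3L * np, by = 3L)]
  coords[, , 2] <- flat[, seq(2L, 3L * np, by = 3L)]
  coords[, , 3] <- flat[, seq(3L, 3L * np, by = 3L)]

  cell <- do.call(rbind, cellList)
  if (is.null(cell)) stop("coordinate files carry no box information")
  edges <- cell[, 1:3, drop = FALSE]
  if (any(abs(edges - edges[, 1]) > cubicTol * edges[, 1]))
    stop("non-cubic box: all analysis formulas assume one edge length L")
  Trajectory(times = (seq_len(nf) - 1L) * dt, coords = coords,
             box = edges[, 1], particles = .resolveLabels(atoms, labelRules),
             wrapped = TRUE,
             metadata = list(topology = topologyPath))
}

.resolveLabels <- function(atoms, labelRules) {
  if (is.function(labelRules)) return(labelRules(atoms))
  solventResidues <- c("HOH", "TIP3", "WAT", "SOL", "TIP", "SPC")
  isSolvent <- atoms$resid %in% solventResidues
  if (is.list(labelRules) && !is.null(labelRules$molecule)) {
    molecule <- as.integer(labelRules$molecule)
    if (length(molecule) != nrow(atoms))
      stop("labelRules$molecule must supply one molecule id per atom")
  } else {
    key <- paste(atoms$chain, ifelse(isSolvent, atoms$resno, 0L))
    molecule <- as.integer(factor(key, levels = unique(key)))
  }
  isHeavy <- !grepl("^H", trimws(atoms$elety)) & !isSolvent
  particleTable(molecule, residue = atoms$resno, isHeavy = isHeavy,
                isCalpha = trimws(atoms$elety) == "CA" & isHeavy,
                isSolvent = isSolvent)
}

#' Read and write the columnar trajectory fixture format
#'
#' A self-describing plain-text format used for small test fixtures.  The
#' file holds a header, one `particle` line per particle (molecule id,
#' residue, heavy/C-alpha/solvent flags) and, per frame, a `frame` line
#' (time in ns, box edge L in Angstrom) followed by one x/y/z line per
#' particle.  Coordinates are written with 17 significant digits so a
#' write/read round trip is lossless.
#'
#' @param traj a [Trajectory-class].
#' @param path file path (conventionally `*.traj`).
#' @return `readTrajectoryFixture` returns a [Trajectory-class];
#'   `writeTrajectoryFixture` returns `path` invisibly.
#' @export
writeTrajectoryFixture <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(traj@coords)
  writeLines(c("#trajectory v1",
               sprintf("#wrapped %s", traj@wrapped),
               sprintf("#frames %d", d[1]),
               sprintf("#particles %d", d[2])), con)
  p <- traj@particles
  writeLines(sprintf("#particle %d %d %d %d %d", p$molecule, p$residue,
                     as.integer(p$isHeavy), as.integer(p$isCalpha),
                     as.integer(p$isSolvent)), con)
  for (f in seq_len(d[1])) {
    writeLines(sprintf("#frame %.17g %.17g", traj@times[f], traj@box[f]), con)
    writeLines(sprintf("%.17g %.17g %.17g", traj@coords[f, , 1],
                       traj@coords[f, , 2], traj@coords[f, , 3]), con)
  }
  invisible(path)
}

#' @rdname writeTrajectoryFixture
#' @export
readTrajectoryFixture <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#trajectory v1")
    stop(sprintf("'%s' is not a trajectory fixture", path))
  wrapped <- as.logical(sub("^#wrapped ", "", lines[2]))
  nf <- as.integer(sub("^#frames ", "", lines[3]))
  np <- as.integer(sub("^#particles ", "", lines[4]))
  plines <- lines[5:(4 + np)]
  pm <- matrix(as.numeric(unlist(strsplit(sub("^#particle ", "", plines),
                                          " ", fixed = TRUE))),
               ncol = 5, byrow = TRUE)
  particles <- particleTable(pm[, 1], residue = pm[, 2],
                             isHeavy = pm[, 3] > 0, isCalpha = pm[, 4] > 0,
                             isSolvent = pm[, 5] > 0)
  body <- lines[-(1:(4 + np))]
  perFrame <- np + 1L
  times <- numeric(nf)
  box <- numeric(nf)
  coords <- array(NA_real_, dim = c(nf, np, 3L))
  for (f in seq_len(nf)) {
    block <- body[((f - 1L) * perFrame + 1L):min(f * perFrame, length(body))]
    if (length(block) < perFrame || !startsWith(block[1], "#frame "))
      stop(sprintf("truncated or malformed coordinate block at frame %d", f))
    hdr <- as.numeric(strsplit(sub("^#frame ", "", block[1]), " ")[[1]])
    times[f] <- hdr[1]
    box[f] <- hdr[2]
    xyz <- matrix(as.numeric(unlist(strsplit(block[-1], " ", fixed = TRUE))),
                  ncol = 3, byrow = TRUE)
    if (nrow(xyz) != np || anyNA(xyz))
      stop(sprintf("truncated or malformed coordinate block at frame %d", f))
    coords[f, , ] <- xyz
  }
  Trajectory(times = times, coords = coords, box = box, particles = particles,
             wrapped = wrapped)
}

#' Load a pressure-tensor time series
#'
#' Reads a whitespace-delimited table with one row per sample: the time
#' stamp (ns) followed by the nine pressure-tensor components (bar).
#'
#' @param path table file path.
#' @param volume system volume in cubic Angstrom.
#' @param temperature temperature in K.
#' @return A [PressureSeries-class].
#' @export
loadPressureSeries <- function(path, volume, temperature) {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) != 10L)
    stop(sprintf("expected 10 columns (time + 9 tensor components), found %d",
                 ncol(tab)))
  PressureSeries(times = tab[[1]], tensors = as.matrix(tab[, -1]),
                 volume = volume, temperature = temperature,
                 metadata = list(source = path))
}

#' @rdname loadPressureSeries
#' @param series a [PressureSeries-class] to write.
#' @export
writePressureSeries <- function(series, path) {
  m <- cbind(series@times, series@tensors)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = "\t")), path)
  invisible(path)
}

#' Unwrap / wrap periodic coordinates
#'
#' `unwrapTrajectory` reconstructs continuous coordinates from wrapped ones
#' by minimum-image continuation: each frame-to-frame displacement is mapped
#' into `(-L/2, L/2)` and accumulated.  This is exact whenever true
#' displacements between stored frames are below L/2 (dense enough
#' sampling).  `wrapTrajectory` is the inverse, folding coordinates into
#' `[0, L)`.
#'
#' @param traj a [Trajectory-class].
#' @return A [Trajectory-class] with the `wrapped` flag toggled.
#' @export
unwrapTrajectory <- function(traj) {
  if (!traj@wrapped) stop("trajectory is already unwrapped")
  nf <- nFrames(traj)
  out <- traj@coords
  if (nf > 1L) {
    steps <- traj@coords[-1L, , , drop = FALSE] -
      traj@coords[-nf, , , drop = FALSE]
    L <- traj@box[-nf]
    steps <- steps - L * round(steps / L)
    bad <- abs(steps) >= L / 2 * (1 - 1e-12)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("apparent jump >= L/2 for particle %d between ",
                          "frames %d and %d; sampling too sparse to unwrap"),
                   idx[2], idx[1], idx[1] + 1L))
    }
    cs <- apply(steps, c(2L, 3L), cumsum)
    if (nf == 2L) dim(cs) <- c(1L, dim(cs))
    out[-1L, , ] <- cs + rep(out[1L, , ], each = nf - 1L)
  }
  initialize(traj, coords = out, wrapped = FALSE)
}

#' @rdname unwrapTrajectory
#' @export
wrapTrajectory <- function(traj) {
  if (traj@wrapped) return(traj)
  out <- traj@coords
  for (f in seq_len(nFrames(traj)))
    out[f, , ] <- out[f, , ] %% traj@box[f]
  initialize(traj, coords = out, wrapped = TRUE)
}
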