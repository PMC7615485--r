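# Trajectory container and readers for small slab trajectories in
# multi-frame XYZ and GRO-style text formats.
#
# No installed package parses these two text dialects as multi-frame
# trajectories, so the readers are implemented here; they are deliberately
# strict (truncated frames and unmapped atom names are errors, not
# warnings).

#' Construct a labelled trajectory
#'
#' @param coords list of `n_atoms x 3` coordinate matrices, nm, one per
#'   frame; the atom count must be constant.
#' @param labels per-atom component tags, each one of `"PDMS"`, `"PMOXA"`,
#'   `"WATER"`.
#' @param masses per-atom masses, amu.
#' @param box orthorhombic box dimensions: length-3 vector (constant) or
#'   `n_frames x 3` matrix, nm.
#' @param normal_axis axis index of the membrane normal (default 3 = z).
#' @return object of class `trajectory`. Coordinates are wrapped into
#'   `[0, box)`.
#' @export
trajectory <- function(coords, labels, masses, box, normal_axis = 3L) {
  if (!is.list(coords) || length(coords) == 0L) stop("coords must be a non-empty list")
  n <- nrow(coords[[1L]])
  if (!all(vapply(coords, nrow, integer(1)) == n))
    stop("atom count varies across frames")
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per atom required")
  bad <- setdiff(unique(labels), c("PDMS", "PMOXA", "WATER"))
  if (length(bad) > 0L)
    stop(sprintf("unknown component labels: %s", paste(bad, collapse = ", ")))
  masses <- as.numeric(masses)
  if (length(masses) == 1L) masses <- rep(masses, n)
  if (length(masses) != n || any(masses <= 0)) stop("invalid masses")
  if (is.null(dim(box))) box <- matrix(box, nrow = length(coords), ncol = 3, byrow = TRUE)
  if (nrow(box) != length(coords) || ncol(box) != 3) stop("box must be n_frames x 3")
  if (any(box <= 0)) stop("box dimensions must be > 0")
  coords <- lapply(seq_along(coords), function(f) {
    xyz <- coords[[f]]
    sweep(xyz, 2, box[f, ], function(x, L) x - L * floor(x / L))
  })
  structure(list(coords = coords, labels = labels, masses = masses,
                 box = box, normal_axis = as.integer(normal_axis)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms (%s), box %s nm\n",
              length(x$coords), length(x$labels),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              paste(signif(x$box[1L, ], 4), collapse = " x ")))
  invisible(x)
}

# default masses (amu) for pseudo-atom labels produced by the generator
.default_mass_map <- c(PDMS = 30, PMOXA = 30, WATER = 18.015)

.map_components <- function(names_seen, component_map) {
  mapped <- component_map[names_seen]
  missing <- unique(names_seen[is.na(mapped)])
  if (length(missing) > 0L)
    stop(sprintf("unmapped atom/residue names: %s", paste(missing, collapse = ", ")))
  unname(mapped)
}

#' Read a slab trajectory from an XYZ or GRO file
#'
#' XYZ: repeated frames of `n_atoms` / comment / `name x y z` lines; the
#' box is not part of the format and must be supplied via `box`. GRO:
#' repeated frames of title / `n_atoms` / fixed-width atom lines / box
#' line; the box is taken from the file (converted from the residue-name
#' column). Coordinates are interpreted in nm in both cases.
#'
#' @param path input file.
#' @param format `"xyz"` or `"gro"`.
#' @param component_map named character vector mapping atom names (xyz) or
#'   residue names (gro) to components, e.g. `c(SOL = "WATER")`. Unmapped
#'   names are an error listing the offenders.
#' @param box length-3 box dimensions, nm; required for xyz, ignored for
#'   gro.
#' @param mass_map named numeric vector of per-component atom masses, amu.
#' @param normal_axis membrane normal axis (default 3).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("xyz", "gro"), component_map,
                            box = NULL, mass_map = .default_mass_map,
                            normal_axis = 3L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (format == "xyz") {
    if (is.null(box)) stop("xyz trajectories need an explicit 'box'")
    coords <- list(); labels <- NULL
    i <- 1L; frame <- 0L
    while (i <= length(lines)) {
      frame <- frame + 1L
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n) || n < 1L)
        stop(sprintf("frame %d: invalid atom-count line", frame))
      if (i + 1L + n > length(lines))
        stop(sprintf("frame %d truncated: expected %d atoms", frame, n))
      block <- lines[(i + 2L):(i + 1L + n)]
      toks <- strsplit(trimws(block), "\\s+")
      if (any(lengths(toks) < 4L))
        stop(sprintf("frame %d: malformed atom line", frame))
      nm <- vapply(toks, `[[`, character(1), 1L)
      xyz <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))),
                    ncol = 3, byrow = TRUE)
      if (anyNA(xyz)) stop(sprintf("frame %d: non-numeric coordinates", frame))
      if (is.null(labels)) labels <- .map_components(nm, component_map)
      else if (n != length(labels))
        stop(sprintf("frame %d: atom count %d differs from first frame (%d)",
                     frame, n, length(labels)))
      coords[[frame]] <- xyz
      i <- i + 2L + n
    }
    boxm <- matrix(box, nrow = length(coords), ncol = 3, byrow = TRUE)
  } else {
    coords <- list(); labels <- NULL; boxes <- list()
    i <- 1L; frame <- 0L
    while (i <= length(lines)) {
      frame <- frame + 1L
      if (i + 1L > length(lines)) stop(sprintf("frame %d truncated", frame))
      n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
      if (is.na(n) || n < 1L)
        stop(sprintf("frame %d: invalid atom-count line", frame))
      if (i + 2L + n > length(lines))
        stop(sprintf("frame %d truncated: expected %d atoms plus box line", frame, n))
      block <- lines[(i + 2L):(i + 1L + n)]
      resname <- trimws(substr(block, 6L, 10L))
      x <- as.numeric(substr(block, 21L, 28L))
      y <- as.numeric(substr(block, 29L, 36L))
      z <- as.numeric(substr(block, 37L, 44L))
      if (anyNA(x) || anyNA(y) || anyNA(z))
        stop(sprintf("frame %d: malformed coordinate fields", frame))
      boxline <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]])
      if (length(boxline) < 3L || anyNA(boxline[1:3]))
        stop(sprintf("frame %d: missing box line", frame))
      if (is.null(labels)) labels <- .map_components(resname, component_map)
      else if (n != length(labels))
        stop(sprintf("frame %d: atom count %d differs from first frame (%d)",
                     frame, n, length(labels)))
      coords[[frame]] <- cbind(x, y, z)
      boxes[[frame]] <- boxline[1:3]
      i <- i + 3L + n
    }
    boxm <- do.call(rbind, boxes)
  }
  masses <- unname(mass_map[labels])
  if (anyNA(masses))
    stop(sprintf("no mass for components: %s",
                 paste(setdiff(unique(labels), names(mass_map)), collapse = ", ")))
  trajectory(coords, labels, masses, boxm, normal_axis = normal_axis)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Atom names are the component labels; the box is not stored by the
#' format (keep it alongside, e.g. in a run config).
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w"); on.exit(close(con))
  n <- length(traj$labels)
  for (f in seq_along(traj$coords)) {
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    xyz <- traj$coords[[f]]
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$labels,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
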