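#' Molecular geometry container
#'
#' A geometry holds atom labels, Cartesian coordinates in bohr (flat vector,
#' x1 y1 z1 x2 ...), and per-atom masses in electron masses. Masses default
#' to the isotope table lookup on the labels.
#'
#' @param labels character vector of element symbols.
#' @param coords numeric vector of length 3 * length(labels), bohr.
#' @param masses optional numeric vector of per-atom masses (m_e).
#' @return an object of class `vq_geometry`.
#' @export
geometry <- function(labels, coords, masses = NULL) {
  coords <- as.numeric(coords)
  if (length(coords) != 3L * length(labels)) {
    stop("coordinate length ", length(coords), " != 3 x ", length(labels), " atoms")
  }
  if (is.null(masses)) masses <- element_mass(labels)
  if (length(masses) != length(labels) || any(masses <= 0)) {
    stop("masses must be positive, one per atom")
  }
  structure(list(labels = labels, coords = coords, masses = masses),
            class = "vq_geometry")
}

#' @export
print.vq_geometry <- function(x, ...) {
  cat("<vq_geometry> ", length(x$labels), " atoms: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom a `vq_geometry`.
#' @export
n_atoms <- function(geom) length(geom$labels)

# coordinates as a 3 x N matrix
coord_matrix <- function(geom) matrix(geom$coords, nrow = 3L)

#' All internuclear distances of a geometry
#'
#' Pairs are ordered lexicographically by (i, j) with i < j; this canonical
#' ordering is shared with [morse_variables()] and the PIP basis.
#'
#' @param geom a `vq_geometry`.
#' @return numeric vector of length n(n-1)/2, bohr.
#' @export
pair_distances <- function(geom) {
  xyz <- coord_matrix(geom)
  d <- stats::dist(t(xyz))
  # stats::dist is ordered (1,2),(1,3),...: column-major lower triangle,
  # i.e. (i,j) pairs sorted by i then j -- our canonical order
  as.numeric(d)
}

#' Canonical atom-pair index table
#' @param n atom count.
#' @return 2-column matrix of (i, j), i < j, in canonical order.
#' @export
pair_index <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  # dist() order: (2,1),(3,1),...,(n,1),(3,2),... -> as (i<j): sort by j then i
  m <- cbind(i = idx[, 2L], j = idx[, 1L])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Read geometries from an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `element x y z` in
#' Angstrom. Coordinates are converted to bohr in memory. Multi-frame files
#' return one geometry per frame.
#'
#' @param path file path.
#' @return list of `vq_geometry`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  geoms <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0L) {
      stop("XYZ parse error at line ", pos, ": expected atom count, got '",
           lines[pos], "'")
    }
    if (pos + 1L + nat > length(lines)) {
      stop("XYZ parse error at line ", pos, ": count says ", nat,
           " atoms but file ends early")
    }
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad)) {
      stop("XYZ parse error at line ", pos + 1L + bad[1L],
           ": expected 'element x y z'")
    }
    labels <- vapply(toks, `[[`, "", 1L)
    xyz <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
    if (anyNA(xyz)) stop("XYZ parse error near line ", pos, ": non-numeric coordinate")
    geoms[[length(geoms) + 1L]] <- geometry(labels, angstrom_to_bohr(as.numeric(xyz)))
    pos <- pos + 2L + nat
  }
  geoms
}

#' Write geometries to an XYZ file
#' @param geoms a `vq_geometry` or list of them.
#' @param path file path.
#' @param comments optional per-frame comment lines.
#' @export
write_xyz <- function(geoms, path, comments = NULL) {
  if (inherits(geoms, "vq_geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]
    writeLines(as.character(n_atoms(g)), con)
    writeLines(if (is.null(comments)) "" else comments[[k]], con)
    xyz <- bohr_to_angstrom(coord_matrix(g))
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       g$labels, xyz[1, ], xyz[2, ], xyz[3, ]), con)
  }
  invisible(path)
}

#' Energy/gradient record
#'
#' One training-corpus entry: a geometry, its energy (hartree), an optional
#' Cartesian gradient (hartree/bohr, length 3N), and a provenance tag.
#'
#' @param geom a `vq_geometry`.
#' @param energy scalar energy, hartree.
#' @param gradient optional numeric vector of length `3 * n_atoms(geom)`.
#' @param tag provenance: `"low-level"`, `"high-level"` or `"correction"`.
#' @export
energy_record <- function(geom, energy, gradient = NULL,
                          tag = c("low-level", "high-level", "correction")) {
  tag <- match.arg(tag)
  if (!is.null(gradient) && length(gradient) != length(geom$coords)) {
    stop("gradient length ", length(gradient), " != 3N = ", length(geom$coords))
  }
  structure(list(geom = geom, energy = as.numeric(energy),
                 gradient = if (is.null(gradient)) NULL else as.numeric(gradient),
                 tag = tag),
            class = "vq_record")
}

#' Write energy/gradient records to the plain-text dataset format
#'
#' Block format, one record per block:
#' ```
#' N_atoms  tag
#' energy_hartree
#' element x y z [gx gy gz]   (N_atoms lines, bohr / hartree-per-bohr)
#' ```
#' Records without gradients write 4 columns; the reader keeps the gradient
#' absent rather than zero-filling it.
#'
#' @param records list of `vq_record`.
#' @param path file path.
#' @export
write_dataset <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    g <- r$geom
    writeLines(paste(n_atoms(g), r$tag), con)
    writeLines(sprintf("%.15e", r$energy), con)
    xyz <- coord_matrix(g)
    if (is.null(r$gradient)) {
      writeLines(sprintf("%-3s %.12e %.12e %.12e",
                         g$labels, xyz[1, ], xyz[2, ], xyz[3, ]), con)
    } else {
      gm <- matrix(r$gradient, nrow = 3L)
      writeLines(sprintf("%-3s %.12e %.12e %.12e %.12e %.12e %.12e",
                         g$labels, xyz[1, ], xyz[2, ], xyz[3, ],
                         gm[1, ], gm[2, ], gm[3, ]), con)
    }
  }
  invisible(path)
}

#' Read a plain-text dataset written by [write_dataset()]
#' @param path file path.
#' @return list of `vq_record`, in file order.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  records <- list()
  pos <- 1L
  block <- 0L
  while (pos <= length(lines)) {
    block <- block + 1L
    head <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
    nat <- suppressWarnings(as.integer(head[1L]))
    if (is.na(nat) || nat <= 0L) {
      stop("dataset parse error in block ", block, ": bad atom count line")
    }
    tag <- if (length(head) >= 2L) head[2L] else "low-level"
    if (pos + 1L + nat > length(lines)) {
      stop("dataset parse error in block ", block, ": truncated block (",
           nat, " atoms expected)")
    }
    energy <- as.numeric(lines[pos + 1L])
    toks <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + nat)]), "\\s+")
    ncol1 <- length(toks[[1L]])
    if (!all(vapply(toks, length, 0L) == ncol1) || !(ncol1 %in% c(4L, 7L))) {
      stop("dataset parse error in block ", block,
           ": atom lines must have 4 or 7 uniform columns")
    }
    labels <- vapply(toks, `[[`, "", 1L)
    vals <- vapply(toks, function(t) as.numeric(t[-1L]), numeric(ncol1 - 1L))
    geom <- geometry(labels, as.numeric(vals[1:3, ]))
    gradient <- if (ncol1 == 7L) as.numeric(vals[4:6, ]) else NULL
    records[[block]] <- energy_record(geom, energy, gradient, tag)
    pos <- pos + 2L + nat
  }
  records
}
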