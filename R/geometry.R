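#' Construct a conformation table
#'
#' A rigid-body receptor-ligand conformation is parameterized by the 6-vector
#' \eqn{\psi = (r, a, b, y_1, y_2, y_3)}: `r` is the center-to-center distance
#' in Angstrom (positive), `(a, b)` are exponential coordinates of the
#' direction of the translation vector on the unit sphere, and
#' `(y1, y2, y3)` is the axis-angle (tangent-space) rotation vector of the
#' ligand orientation, in radians. An optional `energy` column carries the
#' value of an energy model at each conformation.
#'
#' @param r,a,b,y1,y2,y3 Numeric vectors of equal length (or length 1,
#'   recycled) with the six rigid-body coordinates.
#' @param energy Optional numeric vector of energies (`NA` allowed).
#' @param wrap If `TRUE`, rotation vectors are re-wrapped into the open ball
#'   \eqn{\lVert y \rVert < \pi} (see [wrap_tangent()]).
#' @return A tibble with columns r, a, b, y1, y2, y3, energy.
#' @examples
#' conformations(r = 10, a = 0.1, b = -0.2, y1 = 0, y2 = 0.3, y3 = 0)
#' @export
conformations <- function(r, a = 0, b = 0, y1 = 0, y2 = 0, y3 = 0,
                          energy = NA_real_, wrap = FALSE) {
  out <- tibble::tibble(r = as.double(r), a = as.double(a), b = as.double(b),
                        y1 = as.double(y1), y2 = as.double(y2),
                        y3 = as.double(y3), energy = as.double(energy))
  validate_ensemble(out)
  if (wrap) {
    y <- wrap_tangent(as.matrix(out[c("y1", "y2", "y3")]))
    out$y1 <- y[, 1]; out$y2 <- y[, 2]; out$y3 <- y[, 3]
  }
  out
}

validate_ensemble <- function(df, require_energy = FALSE) {
  miss <- setdiff(psi_cols, names(df))
  if (length(miss) > 0)
    stop_ssdu("ensemble is missing column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(df[psi_cols])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop_ssdu("all six conformation coordinates must be finite")
  if (any(df$r <= 0)) stop_ssdu("`r` must be positive")
  if (require_energy && (!"energy" %in% names(df) || anyNA(df$energy)))
    stop_ssdu("ensemble must carry finite energies")
  invisible(df)
}

#' Drop the center-to-center distance from conformations
#'
#' Within a well-packed low-energy cluster the distance `r` varies little, so
#' refinement works in the remaining five coordinates
#' \eqn{x = (a, b, y_1, y_2, y_3)}. This simply drops the `r` (and `energy`)
#' columns.
#'
#' @param ensemble A conformation tibble (see [conformations()]).
#' @return A tibble with columns `a b y1 y2 y3`.
#' @export
reduce_coords <- function(ensemble) {
  validate_ensemble(ensemble)
  tibble::as_tibble(ensemble[red_cols])
}

#' Re-attach a distance to reduced coordinates
#'
#' Inverse of [reduce_coords()]: prepends `r` (recycled) to the five reduced
#' coordinates, restoring full conformations.
#'
#' @param reduced A tibble/data frame with columns `a b y1 y2 y3`.
#' @param r Positive distance(s), length 1 or `nrow(reduced)`.
#' @param energy Optional energies.
#' @return A conformation tibble.
#' @export
attach_distance <- function(reduced, r, energy = NA_real_) {
  if (any(r <= 0)) stop_ssdu("`r` must be positive")
  conformations(r = r, a = reduced$a, b = reduced$b,
                y1 = reduced$y1, y2 = reduced$y2, y3 = reduced$y3,
                energy = energy)
}

#' Direction vector from exponential coordinates
#'
#' Maps the exponential coordinates `(a, b)` of the azimuth/zenith direction
#' to a unit vector on the sphere: the anchor `(0, 0, 1)` is rotated by angle
#' \eqn{\lVert(a,b)\rVert} about the axis \eqn{(-b, a, 0)/\lVert(a,b)\rVert}
#' (the sphere exponential map at the north pole). `(0, 0)` maps to
#' `(0, 0, 1)` exactly.
#'
#' @param a,b Finite scalars.
#' @return A unit 3-vector.
#' @examples
#' exp_coords_to_direction(0, 0)
#' @export
exp_coords_to_direction <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop_ssdu("`a`, `b` must be finite")
  th <- sqrt(a^2 + b^2)
  if (th == 0) return(c(0, 0, 1))
  axis <- c(-b, a, 0) / th
  rot <- rotation_from_tangent(axis * th)
  drop(rot %*% c(0, 0, 1))
}

#' Rotation matrix from an axis-angle (tangent-space) vector
#'
#' The exponential map of SO(3): `y` encodes a rotation by angle
#' \eqn{\lVert y \rVert} about axis \eqn{y/\lVert y \rVert} (Rodrigues'
#' formula). `y = 0` yields the identity.
#'
#' @param y A finite numeric 3-vector.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_tangent <- function(y) {
  if (length(y) != 3 || any(!is.finite(y))) stop_ssdu("`y` must be a finite 3-vector")
  th <- sqrt(sum(y^2))
  if (th < 1e-300) return(diag(3))
  k <- y / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Wrap rotation vectors into the ball of radius pi
#'
#' Axis-angle vectors `y` and `y (1 - 2*pi/||y||)` encode the same rotation;
#' PCA over rotation coordinates is only meaningful on a single
#' representative, so vectors are re-wrapped into \eqn{\lVert y\rVert < \pi}.
#'
#' @param y A 3-vector or an n x 3 matrix of rotation vectors.
#' @return Same shape as `y`, with every row inside the open ball.
#' @export
wrap_tangent <- function(y) {
  one <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < pi) return(v)
    th2 <- th %% (2 * pi)
    if (th2 > pi) th2 <- th2 - 2 * pi   # signed residual in (-pi, pi]
    if (abs(th2) >= pi) th2 <- 0        # boundary: map to identity side
    v / th * th2
  }
  if (is.matrix(y)) t(apply(y, 1, one)) else one(y)
}

#' Rigid bodies (point sets)
#'
#' A rigid body is a set of atom coordinates (Angstrom), with optional partial
#' charges (elementary-charge units) and an optional logical interface mask.
#' Ligand coordinates are expected relative to the ligand centroid.
#'
#' @param coords An n x 3 numeric matrix of atom positions.
#' @param charges Optional numeric vector of length n.
#' @param mask Optional logical vector of length n marking interface atoms.
#' @return An object of class `rigid_body`.
#' @export
rigid_body <- function(coords, charges = NULL, mask = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1 || ncol(coords) != 3 || any(!is.finite(coords)))
    stop_ssdu("`coords` must be a non-empty n x 3 finite matrix")
  if (!is.null(charges) && length(charges) != nrow(coords))
    stop_ssdu("`charges` length must match atom count")
  if (!is.null(mask) && length(mask) != nrow(coords))
    stop_ssdu("`mask` length must match atom count")
  structure(list(coords = unname(coords), charges = charges, mask = mask),
            class = "rigid_body")
}

#' @export
print.rigid_body <- function(x, ...) {
  cat("<rigid_body> ", nrow(x$coords), " atoms",
      if (!is.null(x$charges)) ", charged", "\n", sep = "")
  invisible(x)
}

#' Read a rigid body from a PDB file
#'
#' Reads ATOM/HETATM records via \pkg{bio3d}, keeping the first alternate
#' location and optionally selecting chains. Coordinates are re-centered to
#' the centroid when `center = TRUE` (the convention expected by
#' [place_ligand()] for ligands).
#'
#' @param path Path to a PDB file.
#' @param chain Optional character vector of chain identifiers to keep.
#' @param center Recenter coordinates to the centroid (default `TRUE`).
#' @return A [rigid_body()].
#' @export
read_rigid_body <- function(path, chain = NULL, center = TRUE) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop_ssdu("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$alt %in% c("", " ", "A") | is.na(at$alt)
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop_ssdu("no atoms retained from ", path)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (center) xyz <- sweep(xyz, 2, colMeans(xyz))
  rigid_body(xyz)
}

#' Place a ligand according to a conformation
#'
#' Realizes \eqn{\psi} as atomic coordinates: the ligand (given relative to
#' its centroid) is rotated by [rotation_from_tangent()] about its centroid,
#' then its centroid is translated to
#' \eqn{r \cdot \mathrm{direction}(a, b)} with the receptor centroid at the
#' origin.
#'
#' @param ligand A [rigid_body()] with centroid-relative coordinates.
#' @param psi A one-row conformation tibble or a named/plain numeric 6-vector
#'   `(r, a, b, y1, y2, y3)`.
#' @return A [rigid_body()] with placed coordinates.
#' @export
place_ligand <- function(ligand, psi) {
  v <- as_psi_vector(psi)
  if (v[1] <= 0) stop_ssdu("`r` must be positive")
  rot <- rotation_from_tangent(v[4:6])
  dir <- exp_coords_to_direction(v[2], v[3])
  xyz <- ligand$coords %*% t(rot)
  xyz <- sweep(xyz, 2, v[1] * dir, `+`)
  rigid_body(xyz, charges = ligand$charges, mask = ligand$mask)
}

as_psi_vector <- function(psi) {
  if (is.data.frame(psi)) {
    if (nrow(psi) != 1) stop_ssdu("`psi` must be a single conformation")
    v <- as.double(psi[1, psi_cols])
  } else {
    if (length(psi) < 6) stop_ssdu("`psi` must have six coordinates")
    v <- as.double(psi[1:6])
  }
  if (any(!is.finite(v))) stop_ssdu("conformation coordinates must be finite")
  v
}

#' Root-mean-square deviation between two placements
#'
#' Plain coordinate RMSD with atoms in correspondence and **no**
#' superposition: this is the distance between two placements of the same
#' ligand, the quantity used for cluster distances and quality surrogates.
#'
#' @param A,B n x 3 coordinate matrices or [rigid_body()] objects of equal
#'   atom count.
#' @return RMSD in Angstrom.
#' @examples
#' rmsd(diag(3), diag(3))
#' @export
rmsd <- function(A, B) {
  if (inherits(A, "rigid_body")) A <- A$coords
  if (inherits(B, "rigid_body")) B <- B$coords
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || nrow(A) < 1)
    stop_ssdu("coordinate sets must be non-empty and of equal dimensions")
  sqrt(mean(rowSums((A - B)^2)))
}

# Flattened placed-ligand coordinates for every row of an ensemble, scaled so
# Euclidean distance between rows equals placement RMSD.
placement_matrix <- function(ensemble, ligand) {
  validate_ensemble(ensemble)
  n <- nrow(ensemble)
  na <- nrow(ligand$coords)
  out <- matrix(0, n, 3 * na)
  for (i in seq_len(n))
    out[i, ] <- as.vector(place_ligand(ligand, ensemble[i, ])$coords)
  out / sqrt(na)
}

#' Pairwise placement-RMSD matrix for an ensemble
#'
#' Places `ligand` at every conformation and returns the full symmetric
#' matrix of pairwise placement RMSDs (no superposition), as used by
#' [greedy_cluster()].
#'
#' @param ensemble A conformation tibble.
#' @param ligand A centroid-relative [rigid_body()].
#' @return An n x n numeric matrix.
#' @export
ensemble_rmsd_matrix <- function(ensemble, ligand) {
  as.matrix(stats::dist(placement_matrix(ensemble, ligand)))
}
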