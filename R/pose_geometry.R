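#' Euclidean distance between two points
#'
#' Distance in Angstrom between two 3D coordinates, used for the attack
#' distance between the adduct phosphorus and the catalytic-serine O-gamma
#' (or the oxime oxygen, depending on the configured distance definition).
#'
#' @param p,q Numeric 3-vectors (Angstrom).
#' @return Non-negative distance in Angstrom.
#' @export
#' @examples
#' atom_distance(c(0, 0, 0), c(3, 4, 0)) # 5
atom_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("atom_distance: coordinates must be finite")
  sqrt(sum((p - q)^2))
}

#' Angle at a vertex
#'
#' Angle in degrees subtended at `vertex` by points `a` and `b`, computed
#' from the normalized dot product with the arc-cosine argument clamped to
#' \[-1, 1\] so collinear arms never produce NaN. Used for the in-line attack
#' angle oxime-O -- P -- serine-O measured at the phosphorus.
#'
#' @param a,vertex,b Numeric 3-vectors (Angstrom).
#' @return Angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' atom_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
atom_angle <- function(a, vertex, b) {
  a <- as.numeric(a); vertex <- as.numeric(vertex); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(vertex) == 3L, length(b) == 3L)
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("atom_angle: zero-length arm (point coincides with vertex)")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' NAC classification criteria
#'
#' Bundles the thresholds that define a near attack conformation (NAC) and
#' how the pose population is filtered and counted: attack distance under
#' `d_max`, attack angle within `theta_center +/- theta_tol` (the distance
#' bound is strict, the angle window closed), restricted to "low-energy"
#' poses, i.e. poses within `energy_window` kcal/mol of the ensemble's
#' minimum docking energy.
#'
#' @param d_max Maximum attack distance in Angstrom (strict `<`). Default 10.
#' @param theta_center Center of the attack-angle window in degrees
#'   (default 180, the in-line attack geometry).
#' @param theta_tol Half-width of the angle window in degrees (default 60,
#'   i.e. angles in \[120, 180\] qualify; the window is closed).
#' @param energy_window Width in kcal/mol of the low-energy band above the
#'   ensemble minimum (default 5). The sentinel `"all"` disables energy
#'   filtering (every pose counts as low-energy).
#' @param distance_definition Which pair defines the attack distance:
#'   `"p_to_serO"` (phosphorus to serine O-gamma, the literal definition) or
#'   `"oximeO_to_p"` (attacking oxime oxygen to phosphorus, which varies
#'   pose by pose). Default `"p_to_serO"`.
#' @param denominator Denominator of the percent-NAC statistic:
#'   `"low_energy"` (NAC count over low-energy count, the default) or
#'   `"all"` (NAC-and-low-energy count over all poses).
#' @return An object of class `nac_criteria`.
#' @export
nac_criteria <- function(d_max = 10, theta_center = 180, theta_tol = 60,
                         energy_window = 5,
                         distance_definition = c("p_to_serO", "oximeO_to_p"),
                         denominator = c("low_energy", "all")) {
  distance_definition <- match.arg(distance_definition)
  denominator <- match.arg(denominator)
  stopifnot(is.numeric(d_max), length(d_max) == 1L, d_max > 0)
  stopifnot(is.numeric(theta_tol), length(theta_tol) == 1L,
            theta_tol > 0, theta_tol <= 180)
  if (!identical(energy_window, "all")) {
    stopifnot(is.numeric(energy_window), length(energy_window) == 1L,
              energy_window >= 0)
  }
  structure(list(d_max = d_max, theta_center = theta_center,
                 theta_tol = theta_tol, energy_window = energy_window,
                 distance_definition = distance_definition,
                 denominator = denominator),
            class = "nac_criteria")
}

#' @export
print.nac_criteria <- function(x, ...) {
  cat("NAC criteria: d <", format(x$d_max), "A (strict), theta in [",
      x$theta_center - x$theta_tol, ",",
      min(180, x$theta_center + x$theta_tol), "] deg,\n")
  ew <- if (identical(x$energy_window, "all")) "all poses" else
    paste0("min + ", format(x$energy_window), " kcal/mol")
  cat("  low-energy window:", ew,
      "| distance:", x$distance_definition,
      "| denominator:", x$denominator, "\n")
  invisible(x)
}

# Resolve the coordinates of the declared oxime oxygens inside one pose.
# Accepts atom names (matched against the ensemble's atom_names) or
# 1-based indices.
resolve_oxime_oxygens <- function(coords, atom_names, oxime) {
  sel <- oxime$oxime_oxygen_atoms
  idx <- if (is.numeric(sel)) {
    as.integer(sel)
  } else {
    m <- match(sel, atom_names)
    if (anyNA(m))
      stop("oxime oxygen atom(s) not found in pose: ",
           paste(sel[is.na(m)], collapse = ", "))
    m
  }
  if (any(idx < 1L) || any(idx > nrow(coords)))
    stop("oxime oxygen index out of range")
  coords[idx, , drop = FALSE]
}

# Geometry for a single pose against fixed receptor anchors.  Returns a
# one-row data.frame; is_low_energy is filled by the caller (it depends on
# the whole ensemble's energy minimum).
pose_geometry_one <- function(coords, atom_names, oxime, serine_O, op_P,
                              criteria) {
  oxy <- resolve_oxime_oxygens(coords, atom_names, oxime)
  labs <- if (is.numeric(oxime$oxime_oxygen_atoms))
    paste0("atom", oxime$oxime_oxygen_atoms) else oxime$oxime_oxygen_atoms
  n_oxy <- nrow(oxy)
  d_cand <- numeric(n_oxy)
  theta_cand <- numeric(n_oxy)
  for (i in seq_len(n_oxy)) {
    d_cand[i] <- switch(criteria$distance_definition,
      p_to_serO = atom_distance(op_P, serine_O),
      oximeO_to_p = atom_distance(oxy[i, ], op_P))
    theta_cand[i] <- atom_angle(oxy[i, ], op_P, serine_O)
  }
  # For bis-oximes: among oxygens meeting the distance test keep the one
  # maximizing theta; if none meets it, keep the one at minimal distance.
  # Boundary semantics (strict distance, closed angle window) are enforced
  # up to a 1e-9 guard so values sitting exactly on a threshold classify
  # the same way regardless of trigonometric round-off.
  eps <- 1e-9
  meets_d <- d_cand < criteria$d_max - eps
  keep <- if (any(meets_d)) {
    which(meets_d)[which.max(theta_cand[meets_d])]
  } else {
    which.min(d_cand)
  }
  theta_lo <- criteria$theta_center - criteria$theta_tol
  theta_hi <- criteria$theta_center + criteria$theta_tol
  is_nac <- meets_d[keep] &&
    theta_cand[keep] >= theta_lo - eps && theta_cand[keep] <= theta_hi + eps
  data.frame(d_op = d_cand[keep], theta_opo = theta_cand[keep],
             oxime_O_used = labs[keep], is_nac = is_nac,
             stringsAsFactors = FALSE)
}

#' Attack geometry of a single pose
#'
#' Computes the attack distance and attack angle of one ligand pose against
#' the receptor anchors (adduct phosphorus and catalytic-serine O-gamma)
#' and classifies the pose as a near attack conformation or not. For
#' bis-oximes (two declared oxime oxygens) the geometry is evaluated for
#' each oxygen; the record keeps the oxygen maximizing the attack angle
#' among those meeting the distance test, else the one at minimal distance.
#'
#' @param pose A single pose: a list with `coords` (n x 3 matrix) and
#'   energies, as stored in a [pose ensemble][read_pose_ensemble], or a bare
#'   n x 3 coordinate matrix.
#' @param complex A `receptor_complex` from [read_receptor_complex()].
#' @param oxime An [oxime_spec()] naming the oxime oxygen atom(s).
#' @param criteria [nac_criteria()].
#' @param atom_names Atom names matching the rows of the pose coordinates;
#'   defaults to `attr(pose, "atom_names")` when present.
#' @return A one-row data.frame: `d_op`, `theta_opo`, `oxime_O_used`,
#'   `is_nac`. The low-energy flag is ensemble-level and is added by
#'   [nac_summary()].
#' @export
pose_geometry <- function(pose, complex, oxime, criteria = nac_criteria(),
                          atom_names = NULL) {
  coords <- if (is.list(pose) && !is.null(pose$coords)) pose$coords else pose
  coords <- as.matrix(coords)
  if (is.null(atom_names)) atom_names <- attr(pose, "atom_names")
  if (is.null(atom_names) && is.list(pose)) atom_names <- pose$atom_names
  pose_geometry_one(coords, atom_names, oxime,
                    complex$serine_O, complex$op_P, criteria)
}

# Low-energy flags for a vector of total energies under the criteria window.
low_energy_flags <- function(energy_total, criteria) {
  if (identical(criteria$energy_window, "all"))
    return(rep(TRUE, length(energy_total)))
  energy_total <= min(energy_total) + criteria$energy_window
}

#' Per-pose geometry table for an ensemble
#'
#' Evaluates [pose_geometry()] for every pose of an ensemble and adds the
#' per-ensemble low-energy flag (pose energy within the criteria's window
#' of the ensemble minimum).
#'
#' @inheritParams nac_summary
#' @return A data.frame with one row per pose: `pose_index`, `d_op`,
#'   `theta_opo`, `oxime_O_used`, `energy_total`, `energy_hbond`,
#'   `is_low_energy`, `is_nac`.
#' @export
geometry_table <- function(ensemble, complex, criteria = nac_criteria()) {
  stopifnot(inherits(ensemble, "pose_ensemble"), length(ensemble$poses) >= 1L)
  rows <- lapply(ensemble$poses, function(p)
    pose_geometry_one(p$coords, ensemble$atom_names, ensemble$oxime,
                      complex$serine_O, complex$op_P, criteria))
  tab <- do.call(rbind, rows)
  tab$pose_index <- vapply(ensemble$poses, function(p) p$pose_index, 0)
  tab$energy_total <- vapply(ensemble$poses, function(p) p$energy_total, 0)
  tab$energy_hbond <- vapply(ensemble$poses, function(p)
    if (is.null(p$energy_hbond)) NA_real_ else p$energy_hbond, 0)
  tab$is_low_energy <- low_energy_flags(tab$energy_total, criteria)
  tab[, c("pose_index", "d_op", "theta_opo", "oxime_O_used",
          "energy_total", "energy_hbond", "is_low_energy", "is_nac")]
}

#' Percent-NAC summary for one pose ensemble
#'
#' Counts low-energy poses and near attack conformations, and reports the
#' percentage of poses at the NAC, the per-reactivator statistic that is
#' correlated with experimental percent reactivation.
#'
#' @param ensemble A `pose_ensemble`.
#' @param complex A `receptor_complex` providing the anchor coordinates.
#' @param criteria [nac_criteria()].
#' @return An object of class `nac_summary`: a list with `oxime`,
#'   `complex_label`, `n_poses`, `n_low_energy`, `n_nac`, `pct_nac`, and the
#'   per-pose `geometry` table.
#' @export
nac_summary <- function(ensemble, complex, criteria = nac_criteria()) {
  tab <- geometry_table(ensemble, complex, criteria)
  n_poses <- nrow(tab)
  n_low <- sum(tab$is_low_energy)
  n_nac <- sum(tab$is_nac & tab$is_low_energy)
  denom <- switch(criteria$denominator, low_energy = n_low, all = n_poses)
  if (denom == 0L) {
    warning("empty denominator for pct_nac; reporting 0")
    pct <- 0
  } else {
    pct <- 100 * n_nac / denom
  }
  structure(list(oxime = ensemble$oxime$name,
                 complex_label = ensemble$complex_label,
                 n_poses = n_poses, n_low_energy = n_low, n_nac = n_nac,
                 pct_nac = pct, geometry = tab, criteria = criteria),
            class = "nac_summary")
}

#' @export
print.nac_summary <- function(x, ...) {
  cat(sprintf("NAC summary: %s in %s\n", x$oxime, x$complex_label))
  cat(sprintf("  poses: %d | low-energy: %d | NAC: %d | %%NAC = %.1f\n",
              x$n_poses, x$n_low_energy, x$n_nac, x$pct_nac))
  invisible(x)
}

#' Select the best pose of an ensemble
#'
#' Within the low-energy set, applies a lexicographic rule: minimal attack
#' distance first, then maximal attack angle, then minimal total docking
#' energy. This mirrors reporting conventions in which the best pose is
#' annotated with the smallest distance and the largest in-line angle.
#'
#' @inheritParams nac_summary
#' @return A one-row data.frame (`best_pose_report`): `oxime`, `pose_index`,
#'   `d_op`, `theta_opo`, `energy_total`, `energy_hbond`.
#' @export
select_best_pose <- function(ensemble, complex, criteria = nac_criteria()) {
  tab <- geometry_table(ensemble, complex, criteria)
  pool <- tab[tab$is_low_energy, , drop = FALSE]
  if (nrow(pool) == 0L) pool <- tab   # defensive; window always holds the min
  ord <- order(pool$d_op, -pool$theta_opo, pool$energy_total)
  best <- pool[ord[1L], , drop = FALSE]
  out <- data.frame(oxime = ensemble$oxime$name,
                    pose_index = best$pose_index,
                    d_op = best$d_op, theta_opo = best$theta_opo,
                    energy_total = best$energy_total,
                    energy_hbond = best$energy_hbond,
                    stringsAsFactors = FALSE)
  class(out) <- c("best_pose_report", class(out))
  out
}

#' Ligand RMSD without superposition
#'
#' Root-mean-square deviation over positionally paired atoms of two
#' conformations sharing one coordinate frame (as docking output does). No
#' fitting or symmetry correction is applied; atom correspondence is by row
#' order.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices with identical atom
#'   order.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)))
    stop("pose_rmsd: coordinate sets differ in size")
  stopifnot(ncol(coords_a) == 3L, nrow(coords_a) >= 1L)
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Validate a redocked pose against its crystallographic reference
#'
#' Computes the unfitted RMSD between a reference ligand conformation and
#' its redocked copy and applies the conventional acceptance threshold:
#' RMSD strictly under 2.0 Angstrom validates the docking protocol.
#'
#' @param reference,redocked n x 3 coordinate matrices, same atom order.
#' @param threshold Acceptance threshold in Angstrom (default 2.0; strict
#'   `<`).
#' @return A list with `rmsd` and logical `pass`.
#' @export
validate_redock <- function(reference, redocked, threshold = 2.0) {
  r <- pose_rmsd(reference, redocked)
  list(rmsd = r, pass = r < threshold)
}
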