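# Distribution specs for scenario fields: list(family, a, b) with families
# "unif" (min, max), "norm" (mean, sd), "const" (value).
sample_dist <- function(spec, n) {
  fam <- spec[[1L]]
  switch(fam,
    unif = stats::runif(n, spec[[2L]], spec[[3L]]),
    norm = stats::rnorm(n, spec[[2L]], spec[[3L]]),
    const = rep(spec[[2L]], n),
    stop("unknown distribution family: ", fam))
}

#' Pose-ensemble scenario
#'
#' Describes a synthetic docking pose ensemble with known ground truth. The
#' defaults emulate a single docking run's worth of output: 100 poses, the
#' attack distance of the oxime oxygen spread over the gorge (uniform 3-14
#' Angstrom), attack angles uniform over 90-180 degrees, and a flat energy
#' landscape (all poses low-energy) so the NAC fraction is controlled by
#' geometry alone.
#'
#' @param n_poses Number of poses (default 100).
#' @param distance_distribution,angle_distribution,energy_distribution
#'   Lists `list(family, a, b)` with family `"unif"`, `"norm"`, or
#'   `"const"`. Angles are truncated to \[0, 180\].
#' @param nac_fraction_target Optional fraction in \[0, 1\]; when set, poses
#'   are stratified so the realized NAC fraction equals
#'   `round(n_poses * target) / n_poses` exactly.
#' @param n_oxime_oxygens 1 (mono-oxime) or 2 (bis-oxime).
#' @param seed Scenario seed; all draws derive from it.
#' @return An object of class `pose_scenario`.
#' @export
pose_scenario <- function(n_poses = 100,
                          distance_distribution = list("unif", 3, 14),
                          angle_distribution = list("unif", 90, 180),
                          energy_distribution = list("const", -100),
                          nac_fraction_target = NULL,
                          n_oxime_oxygens = 1, seed = 1) {
  stopifnot(n_poses >= 1, n_oxime_oxygens %in% c(1L, 2L))
  if (!is.null(nac_fraction_target))
    stopifnot(nac_fraction_target >= 0, nac_fraction_target <= 1)
  structure(list(n_poses = as.integer(n_poses),
                 distance_distribution = distance_distribution,
                 angle_distribution = angle_distribution,
                 energy_distribution = energy_distribution,
                 nac_fraction_target = nac_fraction_target,
                 n_oxime_oxygens = as.integer(n_oxime_oxygens),
                 seed = seed),
            class = "pose_scenario")
}

# Rigid 5-atom dummy ligand template (rows: O1, C1, N1, C2, O2), Angstrom.
# O1 (and O2 for bis-oximes) act as the oxime oxygens; the rest exist to
# exercise file I/O with a multi-atom rigid body.
ligand_template <- function() {
  rbind(O1 = c(0.0, 0.0, 0.0),
        C1 = c(1.3, 0.0, 0.0),
        N1 = c(2.4, 0.7, 0.0),
        C2 = c(3.7, 0.4, 0.0),
        O2 = c(4.6, 1.3, 0.0))
}

ligand_elements <- function() c("O", "C", "N", "C", "O")

# Random rotation matrix (uniform over SO(3) via QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Position of a point at distance d from the origin making angle theta
# (degrees) with the direction `axis`, at azimuth phi around it.
place_at_geometry <- function(d, theta, phi, axis) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  th <- theta * pi / 180
  d * (cos(th) * axis + sin(th) * (cos(phi) * e1 + sin(phi) * e2))
}

# Minimal synthetic receptor carrying just the two anchor atoms, in the
# geometry frame used by the generator: adduct P at the origin, catalytic
# serine O-gamma 1.6 Angstrom away along +x (a covalent P-O bond length).
synthetic_receptor <- function(enzyme_label = "AChE",
                               serine_O = c(1.6, 0, 0),
                               op_P = c(0, 0, 0)) {
  atoms <- data.frame(name = c("OG", "P"), element = c("O", "P"),
                      x = c(serine_O[1], op_P[1]),
                      y = c(serine_O[2], op_P[2]),
                      z = c(serine_O[3], op_P[3]),
                      residue_name = c("SER", "POX"),
                      residue_id = c(203L, 901L),
                      chain = c("A", "A"), stringsAsFactors = FALSE)
  structure(list(enzyme_label = enzyme_label, atoms = atoms,
                 serine_O = serine_O, op_P = op_P),
            class = "receptor_complex")
}

#' Criteria matching the generator's geometry frame
#'
#' The generator samples the attack distance as oxime-oxygen-to-phosphorus,
#' the quantity that varies pose by pose (the phosphorus-to-serine distance
#' is a fixed property of the covalent adduct). Ground-truth NAC fractions
#' are therefore defined under these criteria: default thresholds with
#' `distance_definition = "oximeO_to_p"`.
#'
#' @param ... Overrides passed to [nac_criteria()].
#' @return An `nac_criteria` object.
#' @export
generator_criteria <- function(...) {
  args <- list(...)
  if (is.null(args$distance_definition))
    args$distance_definition <- "oximeO_to_p"
  do.call(nac_criteria, args)
}

#' Generate a synthetic pose ensemble with known ground truth
#'
#' Places the adduct phosphorus at the origin and the serine O-gamma at a
#' covalent-bond offset, then builds each pose by putting an oxime oxygen
#' at a sampled attack distance and attack angle (random azimuth) and
#' attaching a rigid 5-atom dummy ligand in a random orientation. When
#' `nac_fraction_target` is set, poses are stratified: the NAC subset
#' samples geometry inside the default window, the rest are placed with
#' every ligand atom beyond the distance cutoff, so the realized fraction
#' is exact by construction.
#'
#' Ground truth is measured on the emitted coordinates with the threshold
#' arithmetic of `criteria`, counting a pose as NAC if any declared oxime
#' oxygen satisfies the window (so bis-oximes get two chances per pose).
#'
#' @param scenario A [pose_scenario()].
#' @param oxime_name Name stamped on the ensemble.
#' @param complex_label Complex label stamped on the ensemble.
#' @param criteria Criteria defining the ground truth; default
#'   [generator_criteria()].
#' @return A list: `ensemble` (a `pose_ensemble`), `complex` (a synthetic
#'   `receptor_complex` holding the anchors), `criteria`, and `truth`
#'   (list: `n_poses`, `n_nac`, `pct_nac`, per-pose `d`, `theta`, `is_nac`
#'   of the generating draw).
#' @export
generate_pose_ensemble <- function(scenario, oxime_name = "oxime",
                                   complex_label = "AChE/POX",
                                   criteria = generator_criteria()) {
  stopifnot(inherits(scenario, "pose_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_poses
  cpx <- synthetic_receptor(enzyme_label = complex_label)
  axis <- cpx$serine_O - cpx$op_P
  theta_lo <- criteria$theta_center - criteria$theta_tol
  theta_hi <- min(180, criteria$theta_center + criteria$theta_tol)
  span <- max(sqrt(rowSums(ligand_template()^2)))  # template radius ~4.8 A

  if (is.null(scenario$nac_fraction_target)) {
    d <- sample_dist(scenario$distance_distribution, n)
    theta <- pmin(180, pmax(0, sample_dist(scenario$angle_distribution, n)))
    if (any(d <= 0)) stop("sampled non-positive attack distance")
  } else {
    n_nac <- round(n * scenario$nac_fraction_target)
    is_target <- rep(FALSE, n)
    if (n_nac > 0) is_target[sample.int(n, n_nac)] <- TRUE
    d <- theta <- numeric(n)
    # NAC poses: comfortably inside the window; the rest: every ligand atom
    # pushed beyond d_max so no oxygen can classify as NAC.
    d[is_target] <- stats::runif(n_nac, 2.5,
                                 min(6, criteria$d_max - 0.5))
    theta[is_target] <- stats::runif(n_nac, theta_lo + 5, theta_hi - 5)
    d[!is_target] <- stats::runif(n - n_nac,
                                  criteria$d_max + span + 1,
                                  criteria$d_max + span + 6)
    theta[!is_target] <- stats::runif(n - n_nac, 0, 180)
  }
  energy <- sample_dist(scenario$energy_distribution, n)

  oxy_names <- if (scenario$n_oxime_oxygens == 2L) c("O1", "O2") else "O1"
  ox <- oxime_spec(oxime_name, oxy_names, ionization_label = "synthetic")
  tmpl <- ligand_template()

  coords_list <- vector("list", n)
  nac_flags <- logical(n)
  for (i in seq_len(n)) {
    phi <- stats::runif(1, 0, 2 * pi)
    o1 <- cpx$op_P + place_at_geometry(d[i], theta[i], phi, axis)
    rot <- random_rotation()
    coords <- sweep(tmpl %*% rot, 2, o1, "+")  # template O1 is the origin
    if (!is.null(scenario$nac_fraction_target)) {
      # keep the whole rigid body outside the cutoff for non-NAC poses
      k <- 0L
      while (k < 50L && any(sqrt(rowSums(
               sweep(coords, 2, cpx$op_P)^2)) < criteria$d_max) &&
             d[i] > criteria$d_max) {
        rot <- random_rotation()
        coords <- sweep(tmpl %*% rot, 2, o1, "+")
        k <- k + 1L
      }
    }
    coords_list[[i]] <- coords
    # ground truth measured on emitted coordinates, any declared oxygen
    oxy_idx <- match(oxy_names, rownames(tmpl))
    dd <- sqrt(rowSums(sweep(coords[oxy_idx, , drop = FALSE], 2,
                             cpx$op_P)^2))
    vv <- sweep(coords[oxy_idx, , drop = FALSE], 2, cpx$op_P)
    u <- (cpx$serine_O - cpx$op_P)
    ct <- (vv %*% u) / (dd * sqrt(sum(u^2)))
    tt <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
    nac_flags[i] <- any(dd < criteria$d_max & tt >= theta_lo & tt <= theta_hi)
  }
  if (!is.null(scenario$nac_fraction_target)) {
    want <- round(n * scenario$nac_fraction_target)
    if (sum(nac_flags) != want)
      stop("stratified generation failed to realize the target fraction")
  }
  ens <- make_pose_ensemble(complex_label, ox, rownames(tmpl),
                            ligand_elements(), coords_list, energy,
                            numeric(0))
  truth <- list(n_poses = n, n_nac = sum(nac_flags),
                pct_nac = 100 * sum(nac_flags) / n,
                d = d, theta = theta, is_nac = nac_flags)
  list(ensemble = ens, complex = cpx, criteria = criteria, truth = truth)
}

#' Assay scenario with known true percent reactivation
#'
#' Describes one reactivator x enzyme x concentration measurement whose
#' underlying activities are constructed so the reactivation formula
#' evaluates exactly to `true_pct_R` before noise: intact activity `a0`,
#' inhibited activity `a0 * inhibited_fraction` (enzymes are inhibited to
#' 5% of the original activity by default), reactivated activity solved
#' from the formula, and an additive oximolysis-control rate included in
#' the raw reactivated reading. Replicate activities carry multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param oxime,enzyme,concentration Labels (concentration in mol/L).
#' @param true_pct_R Ground-truth percent reactivation.
#' @param a0 Intact activity (default 1).
#' @param inhibited_fraction Residual activity fraction after inhibition
#'   (default 0.05).
#' @param oximolysis_rate Oximolysis-control activity (default 0.02).
#' @param noise_cv Coefficient of variation of replicate noise (default
#'   0.02, matching the small replicate SDs typical of the assay).
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Scenario seed.
#' @return An object of class `assay_scenario`.
#' @export
assay_scenario <- function(oxime = "oxime", enzyme = "AChE",
                           concentration = 1e-4, true_pct_R,
                           a0 = 1.0, inhibited_fraction = 0.05,
                           oximolysis_rate = 0.02, noise_cv = 0.02,
                           n_replicates = 3, seed = 1) {
  stopifnot(inhibited_fraction > 0, inhibited_fraction < 1,
            noise_cv >= 0, n_replicates >= 1, a0 > 0)
  structure(list(oxime = oxime, enzyme = enzyme,
                 concentration = concentration, true_pct_R = true_pct_R,
                 a0 = a0, inhibited_fraction = inhibited_fraction,
                 oximolysis_rate = oximolysis_rate, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "assay_scenario")
}

#' Generate synthetic assay activities (or traces) for a scenario
#'
#' Emits per-replicate activities for the four assay conditions (intact,
#' inhibited, reactivated, oximolysis control). In trace mode each activity
#' is rendered as a noiseless straight absorbance-versus-time line whose
#' slope is that (already noisy) activity, so trace and activity modes
#' encode identical ground truth.
#'
#' @param scenario An [assay_scenario()].
#' @param as_traces If `TRUE`, return time-absorbance traces instead of
#'   activities.
#' @param trace_points,trace_minutes Trace sampling (default 10 points over
#'   5 minutes).
#' @return A list: `activities` (data.frame `condition`, `replicate`,
#'   `activity`) or `traces` (data.frame `condition`, `replicate`,
#'   `time_min`, `absorbance`), plus `truth` (the scenario's noise-free
#'   activities and `true_pct_R`).
#' @export
generate_assay_scenario <- function(scenario, as_traces = FALSE,
                                    trace_points = 10, trace_minutes = 5) {
  stopifnot(inherits(scenario, "assay_scenario"))
  set.seed(scenario$seed)
  a0 <- scenario$a0
  ai <- a0 * scenario$inhibited_fraction
  if (a0 <= ai) stop("scenario has no inhibition window")
  ar <- a0 - (1 - scenario$true_pct_R / 100) * (a0 - ai)
  ar_raw <- ar + scenario$oximolysis_rate
  clean <- c(intact = a0, inhibited = ai, reactivated = ar_raw,
             oximolysis_control = scenario$oximolysis_rate)
  n <- scenario$n_replicates
  cond <- rep(names(clean), each = n)
  repl <- rep(seq_len(n), times = length(clean))
  base <- rep(unname(clean), each = n)
  noisy <- base * (1 + stats::rnorm(length(base), 0, scenario$noise_cv))
  activities <- data.frame(condition = cond, replicate = repl,
                           activity = noisy, stringsAsFactors = FALSE)
  truth <- list(a0 = a0, ai = ai, ar = ar, ar_raw = ar_raw,
                oximolysis = scenario$oximolysis_rate,
                true_pct_R = scenario$true_pct_R)
  if (!as_traces)
    return(list(activities = activities, truth = truth))
  t <- seq(0, trace_minutes, length.out = trace_points)
  traces <- do.call(rbind, lapply(seq_len(nrow(activities)), function(i) {
    data.frame(condition = activities$condition[i],
               replicate = activities$replicate[i],
               time_min = t,
               absorbance = 0.05 + activities$activity[i] * t,
               stringsAsFactors = FALSE)
  }))
  list(traces = traces, truth = truth)
}

#' Generate a pseudo-first-order inhibition time-course
#'
#' Exponential decay of residual enzyme activity with a known half-life,
#' with optional multiplicative Gaussian noise.
#'
#' @param T_half True half-life in minutes.
#' @param n_points Number of samples (default 8).
#' @param t_max Last time point (default 4 half-lives).
#' @param a0 Initial activity (default 1).
#' @param noise_cv Multiplicative noise CV (default 0).
#' @param seed Seed.
#' @return A list: `times`, `activities`, `truth` (list with `T_half`,
#'   `k_obs`).
#' @export
generate_inhibition_course <- function(T_half, n_points = 8,
                                       t_max = 4 * T_half, a0 = 1,
                                       noise_cv = 0, seed = 1) {
  stopifnot(T_half > 0, n_points >= 3)
  set.seed(seed)
  times <- seq(0, t_max, length.out = n_points)
  act <- a0 * 2^(-times / T_half)
  if (noise_cv > 0)
    act <- act * (1 + stats::rnorm(n_points, 0, noise_cv))
  list(times = times, activities = act,
       truth = list(T_half = T_half, k_obs = log(2) / T_half))
}

#' Rigidly or randomly perturb a ligand conformation
#'
#' Redocking-validation fixture: `translate` shifts every atom by one
#' random-direction vector of the requested length, so the true RMSD is the
#' translation magnitude exactly; `jitter` adds independent Gaussian
#' displacement of SD `magnitude` per coordinate and records the realized
#' RMSD.
#'
#' @param coords Reference n x 3 coordinate matrix.
#' @param mode `"translate"` or `"jitter"`.
#' @param magnitude Translation length, or per-coordinate jitter SD
#'   (Angstrom).
#' @param seed Seed.
#' @return A list: `coords` (perturbed), `true_rmsd`.
#' @export
perturb_ligand <- function(coords, mode = c("translate", "jitter"),
                           magnitude = 1, seed = 1) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1L, magnitude >= 0)
  set.seed(seed)
  if (mode == "translate") {
    dir <- stats::rnorm(3)
    dir <- if (magnitude == 0) c(0, 0, 0) else
      dir / sqrt(sum(dir^2)) * magnitude
    out <- sweep(coords, 2, dir, "+")
    list(coords = out, true_rmsd = magnitude)
  } else {
    delta <- matrix(stats::rnorm(length(coords), 0, magnitude),
                    nrow(coords), 3)
    out <- coords + delta
    list(coords = out, true_rmsd = sqrt(mean(rowSums(delta^2))))
  }
}

#' Reference reactivation table for the six-oxime benchmark
#'
#' Returns the checked-in transcription of the published benchmark:
#' mean and SD of percent reactivation for six reactivators (pralidoxime,
#' obidoxime, HI-6, K131, K142, K153) against paraoxon-inhibited human
#' AChE and BChE at 100 and 10 micromolar (three replicates each). These
#' values parameterize synthetic assay scenarios as ground truth.
#'
#' @return A 24-row data.frame: `oxime`, `enzyme`, `concentration_uM`,
#'   `pct_R_mean`, `pct_R_sd`.
#' @export
reactivation_fixture_table <- function() {
  path <- system.file("extdata", "reactivation_benchmark.csv",
                      package = "nacscan", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 24L,
            all(c("oxime", "enzyme", "concentration_uM",
                  "pct_R_mean", "pct_R_sd") %in% names(tab)))
  tab
}

#' Assay scenario for one row of the benchmark table
#'
#' Looks up a reactivator x enzyme x concentration row of
#' [reactivation_fixture_table()] and returns the matching
#' [assay_scenario()] with that row's mean percent reactivation as ground
#' truth.
#'
#' @param oxime,enzyme Row selectors.
#' @param concentration_uM Concentration in micromolar (100 or 10).
#' @param seed Scenario seed.
#' @param ... Further overrides passed to [assay_scenario()].
#' @return An `assay_scenario`.
#' @export
fixture_assay_scenario <- function(oxime, enzyme, concentration_uM = 100,
                                   seed = 1, ...) {
  tab <- reactivation_fixture_table()
  row <- tab[tab$oxime == oxime & tab$enzyme == enzyme &
               tab$concentration_uM == concentration_uM, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no benchmark row for ", oxime, "/", enzyme, "/",
         concentration_uM, " uM")
  assay_scenario(oxime = oxime, enzyme = enzyme,
                 concentration = concentration_uM * 1e-6,
                 true_pct_R = row$pct_R_mean, seed = seed, ...)
}

#' Write a synthetic receptor PDB with known anchor placement
#'
#' Emits a small (about 20-residue) poly-alanine-like chain plus a SER
#' residue carrying the O-gamma anchor and a HETATM organophosphate
#' phosphorus, at randomized but recorded coordinates. Used to exercise
#' the receptor reader end to end.
#'
#' @param path Output PDB path.
#' @param seed Seed for the decoy coordinates.
#' @param serine_residue_id Residue number given to the anchor serine
#'   (default 203).
#' @param serine_O,op_P Optional fixed anchor coordinates; by default the
#'   serine O-gamma is placed at random and the phosphorus 1.6 Angstrom
#'   away (a covalent P-O bond length).
#' @return Invisibly, a list with the ground-truth `serine_O` and `op_P`
#'   coordinates and the matching [anchor_spec()].
#' @export
write_synthetic_receptor_pdb <- function(path, seed = 1,
                                         serine_residue_id = 203L,
                                         serine_O = NULL, op_P = NULL) {
  set.seed(seed)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  emit <- function(record, name, resid, resno, x, y, z, element) {
    serial <<- serial + 1L
    writeLines(sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, serial, name, " ", resid, "A", resno, " ",
      x, y, z, 1, 20, element), con)
  }
  resnos <- setdiff(190:210, serine_residue_id)[1:19]
  for (rn in resnos) {
    base <- c(rn * 1.5, stats::runif(1, -5, 5), stats::runif(1, -5, 5))
    emit("ATOM", "N",  "ALA", rn, base[1], base[2], base[3], "N")
    emit("ATOM", "CA", "ALA", rn, base[1] + 0.7, base[2] + 0.9, base[3], "C")
    emit("ATOM", "C",  "ALA", rn, base[1] + 1.9, base[2] + 0.4, base[3], "C")
  }
  if (is.null(serine_O)) serine_O <- round(stats::runif(3, -8, 8), 3)
  if (is.null(op_P)) op_P <- round(serine_O + c(1.6, 0, 0), 3)
  sb <- serine_O + c(-1.2, -0.8, 0.3)
  emit("ATOM", "N",  "SER", serine_residue_id, sb[1], sb[2], sb[3], "N")
  emit("ATOM", "CA", "SER", serine_residue_id, sb[1] + 0.9, sb[2], sb[3], "C")
  emit("ATOM", "OG", "SER", serine_residue_id,
       serine_O[1], serine_O[2], serine_O[3], "O")
  emit("HETATM", "P", "POX", 901L, op_P[1], op_P[2], op_P[3], "P")
  emit("HETATM", "O1", "POX", 901L, op_P[1] + 1.4, op_P[2] + 0.3, op_P[3], "O")
  writeLines("END", con)
  invisible(list(serine_O = serine_O, op_P = op_P,
                 anchors = anchor_spec(serine_residue_id,
                                       op_residue = "POX")))
}
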