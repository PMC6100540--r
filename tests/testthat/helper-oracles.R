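# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

oracle_distance <- function(p, q) {
  s <- 0
  for (i in 1:3) s <- s + (p[i] - q[i])^2
  sqrt(s)
}

oracle_angle <- function(a, v, b) {
  u <- a - v; w <- b - v
  dot <- u[1] * w[1] + u[2] * w[2] + u[3] * w[3]
  nu <- oracle_distance(a, v); nw <- oracle_distance(b, v)
  x <- dot / (nu * nw)
  if (x > 1) x <- 1
  if (x < -1) x <- -1
  acos(x) * 180 / pi
}

oracle_rmsd <- function(A, B) {
  acc <- 0
  for (i in seq_len(nrow(A)))
    for (j in 1:3)
      acc <- acc + (A[i, j] - B[i, j])^2
  sqrt(acc / nrow(A))
}

# Independent re-count of NAC / low-energy poses by explicit loops over
# poses and declared oxime oxygens, using only the criteria thresholds.
oracle_nac_count <- function(ensemble, complex, criteria) {
  energies <- vapply(ensemble$poses, function(p) p$energy_total, 0)
  low <- if (identical(criteria$energy_window, "all"))
    rep(TRUE, length(energies))
  else energies <= min(energies) + criteria$energy_window
  oxy_idx <- match(ensemble$oxime$oxime_oxygen_atoms, ensemble$atom_names)
  lo <- criteria$theta_center - criteria$theta_tol
  hi <- criteria$theta_center + criteria$theta_tol
  n_nac <- 0L
  for (k in seq_along(ensemble$poses)) {
    if (!low[k]) next
    coords <- ensemble$poses[[k]]$coords
    hit <- FALSE
    for (i in oxy_idx) {
      d <- switch(criteria$distance_definition,
                  p_to_serO = oracle_distance(complex$op_P, complex$serine_O),
                  oximeO_to_p = oracle_distance(coords[i, ], complex$op_P))
      th <- oracle_angle(coords[i, ], complex$op_P, complex$serine_O)
      if (d < criteria$d_max && th >= lo && th <= hi) hit <- TRUE
    }
    if (hit) n_nac <- n_nac + 1L
  }
  list(n_low_energy = sum(low), n_nac = n_nac)
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = runif(3, -20, 20))
}

apply_rigid <- function(coords, tr) {
  sweep(as.matrix(coords) %*% tr$R, 2, tr$t, "+")
}

# Small hand-built ensemble from explicit per-pose oxime-O placements in the
# synthetic receptor frame (P at origin, serine O at (1.6, 0, 0)).
build_test_ensemble <- function(o1_positions, energies,
                                complex_label = "AChE") {
  n <- nrow(o1_positions)
  tmpl <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.4, 0.7, 0),
                c(3.7, 0.4, 0), c(4.6, 1.3, 0))
  coords <- lapply(seq_len(n), function(i)
    sweep(tmpl, 2, o1_positions[i, ], "+"))
  poses <- lapply(seq_len(n), function(i)
    list(pose_index = i, coords = coords[[i]],
         energy_total = energies[i], energy_hbond = NULL))
  structure(list(complex_label = complex_label,
                 oxime = oxime_spec("test", "O1"),
                 atom_names = c("O1", "C1", "N1", "C2", "O2"),
                 elements = c("O", "C", "N", "C", "O"),
                 poses = poses),
            class = "pose_ensemble")
}

test_receptor <- function() {
  atoms <- data.frame(name = c("OG", "P"), element = c("O", "P"),
                      x = c(1.6, 0), y = c(0, 0), z = c(0, 0),
                      residue_name = c("SER", "POX"),
                      residue_id = c(203L, 901L), chain = "A",
                      stringsAsFactors = FALSE)
  structure(list(enzyme_label = "AChE", atoms = atoms,
                 serine_O = c(1.6, 0, 0), op_P = c(0, 0, 0)),
            class = "receptor_complex")
}

# Place an oxime O at exact attack geometry (d, theta) in the test frame.
place_oxime_O <- function(d, theta, phi = 0) {
  th <- theta * pi / 180
  c(d * cos(th), d * sin(th) * cos(phi), d * sin(th) * sin(phi))
}
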