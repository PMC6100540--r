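test_that("distance and angle match hand values and brute-force oracles", {
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(atom_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(atom_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(3, -10, 10); q <- runif(3, -10, 10); v <- runif(3, -10, 10)
    expect_equal(atom_distance(p, q), oracle_distance(p, q),
                 tolerance = 1e-12)
    expect_equal(atom_angle(p, v, q), oracle_angle(p, v, q),
                 tolerance = 1e-9)
  }
  expect_error(atom_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
})

test_that("NAC classification honors the boundary conventions", {
  cpx <- test_receptor()
  cr <- nac_criteria(distance_definition = "oximeO_to_p")
  geom_at <- function(d, theta) {
    ens <- build_test_ensemble(rbind(place_oxime_O(d, theta)), -100)
    geometry_table(ens, cpx, cr)
  }
  # distance strict "<": d exactly at the cutoff fails
  expect_false(geom_at(10.0, 150)$is_nac)
  expect_true(geom_at(9.99, 150)$is_nac)
  # angle window closed: theta = 120.0 passes, 119.9 fails
  expect_true(geom_at(5, 120.0)$is_nac)
  expect_false(geom_at(5, 119.9)$is_nac)
  # benchmark-style best-pose geometry satisfies the window
  g <- geom_at(4.260, 155.00)
  expect_true(g$is_nac)
  expect_equal(g$d_op, 4.260, tolerance = 1e-9)
  expect_equal(g$theta_opo, 155.00, tolerance = 1e-9)
})

test_that("attack geometry is invariant under common rigid transforms", {
  set.seed(21)
  cr <- nac_criteria(distance_definition = "oximeO_to_p")
  for (i in 1:20) {
    d <- runif(1, 2, 12); th <- runif(1, 10, 175)
    ens <- build_test_ensemble(rbind(place_oxime_O(d, th)), -100)
    cpx <- test_receptor()
    g0 <- geometry_table(ens, cpx, cr)
    tr <- random_rigid_transform()
    ens$poses[[1]]$coords <- apply_rigid(ens$poses[[1]]$coords, tr)
    cpx$serine_O <- as.numeric(apply_rigid(rbind(cpx$serine_O), tr))
    cpx$op_P <- as.numeric(apply_rigid(rbind(cpx$op_P), tr))
    g1 <- geometry_table(ens, cpx, cr)
    expect_equal(g1$d_op, g0$d_op, tolerance = 1e-9)
    expect_equal(g1$theta_opo, g0$theta_opo, tolerance = 1e-9)
  }
})

test_that("nac_summary counts and percentage follow the criteria", {
  cpx <- test_receptor()
  cr <- nac_criteria(distance_definition = "oximeO_to_p")
  # all poses well inside the window
  o1 <- t(vapply(1:10, function(i) place_oxime_O(4, 170, i), numeric(3)))
  s <- nac_summary(build_test_ensemble(o1, rep(-100, 10)), cpx, cr)
  expect_equal(s$pct_nac, 100)
  # nothing in the angle window
  o2 <- t(vapply(1:10, function(i) place_oxime_O(4, 50, i), numeric(3)))
  s2 <- nac_summary(build_test_ensemble(o2, rep(-100, 10)), cpx, cr)
  expect_equal(s2$pct_nac, 0)
  # energy window restricts the denominator
  o3 <- rbind(place_oxime_O(4, 170), place_oxime_O(4, 170),
              place_oxime_O(4, 50))
  s3 <- nac_summary(build_test_ensemble(o3, c(-100, -90, -100)), cpx, cr)
  expect_equal(s3$n_low_energy, 2L)   # -90 is outside min + 5
  expect_equal(s3$n_nac, 1L)
  expect_equal(s3$pct_nac, 50)
  # denominator = all
  cr_all <- nac_criteria(distance_definition = "oximeO_to_p",
                         denominator = "all")
  s4 <- nac_summary(build_test_ensemble(o3, c(-100, -90, -100)), cpx, cr_all)
  expect_equal(s4$pct_nac, 100 * 1 / 3)
})

test_that("pct_nac is monotone in d_max and theta_tol; energy window in n_low", {
  set.seed(31)
  n <- 40
  o1 <- t(vapply(seq_len(n), function(i)
    place_oxime_O(runif(1, 2, 14), runif(1, 60, 180), runif(1, 0, 2 * pi)),
    numeric(3)))
  en <- rnorm(n, -100, 3)
  ens <- build_test_ensemble(o1, en)
  cpx <- test_receptor()
  pct <- function(d_max, tol, win = "all")
    nac_summary(ens, cpx,
                nac_criteria(d_max = d_max, theta_tol = tol,
                             energy_window = win,
                             distance_definition = "oximeO_to_p"))$pct_nac
  for (dm in c(12, 10, 8, 6, 4))
    for (dm2 in c(12, 10, 8, 6, 4))
      if (dm2 <= dm) expect_lte(pct(dm2, 60), pct(dm, 60))
  for (tol in c(80, 60, 40, 20))
    for (tol2 in c(80, 60, 40, 20))
      if (tol2 <= tol) expect_lte(pct(10, tol2), pct(10, tol))
  nlow <- function(win)
    nac_summary(ens, cpx,
                nac_criteria(energy_window = win,
                             distance_definition = "oximeO_to_p"))$n_low_energy
  expect_lte(nlow(2), nlow(5))
  expect_lte(nlow(5), nlow(20))
})

test_that("bis-oxime NAC fraction is at least either single-oxygen fraction", {
  set.seed(41)
  for (rep in 1:5) {
    g <- generate_pose_ensemble(
      pose_scenario(n_poses = 40, n_oxime_oxygens = 2, seed = rep),
      criteria = generator_criteria())
    ens <- g$ensemble
    pct_with <- function(oxys) {
      e <- ens
      e$oxime <- oxime_spec(e$oxime$name, oxys)
      nac_summary(e, g$complex, g$criteria)$pct_nac
    }
    both <- pct_with(c("O1", "O2"))
    expect_gte(both, pct_with("O1"))
    expect_gte(both, pct_with("O2"))
  }
})

test_that("best-pose selection is lexicographic: down-d, up-theta, down-E", {
  cpx <- test_receptor()
  cr <- nac_criteria(distance_definition = "oximeO_to_p",
                     energy_window = "all")
  # smaller d wins over larger theta
  ens <- build_test_ensemble(rbind(place_oxime_O(4, 150),
                                   place_oxime_O(6, 179)), c(-100, -120))
  expect_equal(select_best_pose(ens, cpx, cr)$pose_index, 1)
  # identical d: larger theta wins
  ens2 <- build_test_ensemble(rbind(place_oxime_O(5, 140),
                                    place_oxime_O(5, 160)), c(-120, -100))
  expect_equal(select_best_pose(ens2, cpx, cr)$pose_index, 2)
  # single pose
  ens3 <- build_test_ensemble(rbind(place_oxime_O(5, 140)), -100)
  b <- select_best_pose(ens3, cpx, cr)
  expect_equal(b$pose_index, 1)
  expect_equal(b$energy_total, -100)
})

test_that("rmsd matches oracle and redock validation uses a strict threshold", {
  set.seed(51)
  A <- matrix(runif(30, -5, 5), 10, 3)
  expect_equal(pose_rmsd(A, A), 0)
  expect_equal(pose_rmsd(A, sweep(A, 2, c(1, 0, 0), "+")), 1)
  for (i in 1:20) {
    B <- A + matrix(rnorm(30, 0, 0.5), 10, 3)
    expect_equal(pose_rmsd(A, B), oracle_rmsd(A, B), tolerance = 1e-12)
    # cross-check against the field's reference implementation (unfitted);
    # bio3d reports RMSD rounded to 3 decimals
    expect_lt(abs(pose_rmsd(A, B) -
                    bio3d::rmsd(as.vector(t(A)), as.vector(t(B)),
                                fit = FALSE)), 5.1e-4)
  }
  expect_error(pose_rmsd(A, A[1:5, ]), "differ in size")
  expect_true(validate_redock(A, A + 0.1)$pass)
  shifted <- sweep(A, 2, c(2, 0, 0), "+")
  expect_equal(validate_redock(A, shifted)$rmsd, 2)
  expect_false(validate_redock(A, shifted)$pass)  # 2.0 exactly fails
  expect_true(validate_redock(A, sweep(A, 2, c(1.18, 0, 0), "+"))$pass)
})
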