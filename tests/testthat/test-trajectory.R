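# random rotation matrix from a quaternion (oracle-side construction)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

test_that("kabsch_superpose removes rigid motion exactly", {
  set.seed(10)
  ref <- matrix(rnorm(30), ncol = 3)
  # identity
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # pure translation
  fit <- kabsch_superpose(ref, sweep(ref, 2, c(5, 0, 0), `+`))
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  # rotation 90 deg about z: fitted 0, unfitted > 0
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  rot <- ref %*% t(Rz)
  expect_gt(rmsd(rot, ref), 0.1)
  fit <- kabsch_superpose(ref, rot)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  # arbitrary quaternion rotations + translation, several draws
  for (s in 1:5) {
    R <- random_rotation(s)
    expect_equal(det(R), 1, tolerance = 1e-12)
    mob <- sweep(ref %*% t(R), 2, c(1, -2, 3), `+`)
    fit <- kabsch_superpose(ref, mob)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)  # proper rotation
  }
  # degenerate (collinear) selection errors
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("fitted RMSD never exceeds unfitted RMSD", {
  tr <- generate_trajectory(trajectory_sim_spec(
    n_frames = 15, fluctuation_sd = 0.5, drift_per_frame = 0.8, seed = 6))
  sel <- tr$atoms$serial
  unfit <- rmsd_series(tr, sel)
  fit <- rmsd_series(tr, sel, fit_selection = sel)
  expect_true(all(fit <= unfit + 1e-9))
  # rigid drift with fitting removed entirely
  rigid <- generate_trajectory(trajectory_sim_spec(
    n_frames = 6, fluctuation_sd = 0, drift_per_frame = 2, seed = 6))
  expect_equal(rmsd_series(rigid, fit_selection = rigid$atoms$serial),
               rep(0, 6), tolerance = 1e-9)
  expect_error(rmsd_series(tr, integer()), "empty")
})

test_that("single-sphere SASA is the closed form at 960 points", {
  atoms <- data.frame(serial = 1, element = "S", vdw_radius = 1.5,
                      role = "protein", hbond_class = "none",
                      bonded_heavy = NA)
  res <- shrake_rupley_sasa(matrix(0, 1, 3), atoms)
  analytic <- 4 * pi * 2.9^2
  expect_equal(res$total, analytic, tolerance = 5e-3)
  expect_equal(round(analytic, 2), 105.68)
  # two far-apart spheres: additive
  atoms2 <- rbind(atoms, transform(atoms, serial = 2))
  res2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(10, 0, 0)), atoms2)
  expect_equal(res2$total, 2 * analytic, tolerance = 5e-3)
  # fully buried atom: zero accessible area
  big <- data.frame(serial = 1:2, element = c("C", "X"),
                    vdw_radius = c(1.7, 20), role = "protein",
                    hbond_class = "none", bonded_heavy = NA)
  bur <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(0, 0, 1)), big)
  expect_equal(unname(bur$area[["1"]]), 0)
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3),
                                  transform(atoms, vdw_radius = NA)),
               "vdw_radius")
})

test_that("SASA matches a 10,000-point brute-force oracle within 2%", {
  set.seed(17)
  for (rep in 1:3) {
    coords <- matrix(rnorm(30, sd = 2.5), ncol = 3)
    radii <- runif(10, 1.2, 1.9)
    atoms <- data.frame(serial = 1:10, element = "C", vdw_radius = radii,
                        role = "protein", hbond_class = "none",
                        bonded_heavy = NA)
    mine <- shrake_rupley_sasa(coords, atoms)$total
    oracle <- oracle_sasa_total(coords, radii, probe = 1.4, seed = 100 + rep)
    expect_lt(abs(mine - oracle) / oracle, 0.02)
  }
})

test_that("SASA is rotation/translation invariant and converges in n", {
  set.seed(23)
  coords <- matrix(rnorm(18, sd = 2), ncol = 3)
  atoms <- data.frame(serial = 1:6, element = "O", vdw_radius = 1.52,
                      role = "protein", hbond_class = "none",
                      bonded_heavy = NA)
  base <- shrake_rupley_sasa(coords, atoms)$total
  R <- random_rotation(4)
  moved <- sweep(coords %*% t(R), 2, c(3, -1, 7), `+`)
  expect_equal(shrake_rupley_sasa(moved, atoms)$total, base,
               tolerance = 1e-9)
  # per-atom area bounded by the isolated-sphere area, non-negative
  res <- shrake_rupley_sasa(coords, atoms)
  expect_true(all(res$area >= 0))
  expect_true(all(res$area <= 4 * pi * (1.52 + 1.4)^2 + 1e-9))
  # two overlapping equal spheres have a closed-form accessible area
  # (sphere minus the buried cap of height R - d/2); the lattice estimate
  # converges to it as the point count grows
  two <- atoms[1:2, ]
  pair <- rbind(c(0, 0, 0), c(3, 0, 0))
  Rexp <- 1.52 + 1.4
  analytic <- 2 * (4 * pi * Rexp^2 - 2 * pi * Rexp * (Rexp - 1.5))
  err <- vapply(c(96, 960, 9600), function(n)
    abs(shrake_rupley_sasa(pair, two, n_sphere_points = n)$total - analytic),
    numeric(1))
  expect_lt(err[2] / analytic, 0.01)
  expect_lt(err[3] / analytic, 0.003)
  expect_lte(err[3], err[1])
})

test_that("detect_hbonds applies the distance and angle cutoffs", {
  atoms <- data.frame(
    serial = 1:3, element = c("N", "H", "O"),
    vdw_radius = bondi_radius(c("N", "H", "O")),
    role = c("ligand", "ligand", "protein"),
    hbond_class = c("donor-heavy", "hydrogen", "acceptor"),
    bonded_heavy = c(NA, 1, NA))
  place <- function(a_xyz) rbind(c(0, 0, 0), c(1, 0, 0), a_xyz)
  bonds <- function(a_xyz)
    nrow(detect_hbonds(place(a_xyz), atoms, group_a = 1:2, group_b = 3))
  expect_equal(bonds(c(3, 0, 0)), 1)          # 3.0 A, 180 deg
  expect_equal(bonds(c(4, 0, 0)), 0)          # distance fails
  expect_equal(bonds(c(1, 2, 0)), 0)          # angle at H = 90 deg
  expect_equal(bonds(c(3.5, 0, 0)), 1)        # boundary distance passes
  # angle exactly 120 deg passes: A at H + 2(cos60, sin60, 0)
  a120 <- c(1, 0, 0) + 2 * c(cos(pi / 3), sin(pi / 3), 0)
  expect_equal(bonds(a120), 1)
  # hydrogen missing its heavy-atom bond errors
  bad <- transform(atoms, bonded_heavy = NA)
  expect_error(detect_hbonds(place(c(3, 0, 0)), bad, group_a = 1:2,
                             group_b = 3), "bonded_heavy")
  expect_error(detect_hbonds(place(c(3, 0, 0)), atoms, group_a = 1:3,
                             group_b = 3), "disjoint")
})

test_that("hbond detection matches brute force on 100 random frames", {
  tr <- generate_trajectory(trajectory_sim_spec(
    n_frames = 100, n_protein_atoms = 25, n_ligand_atoms = 12,
    fluctuation_sd = 1.2, seed = 31))
  prot <- tr$atoms$serial[tr$atoms$role == "protein"]
  lig <- tr$atoms$serial[tr$atoms$role == "ligand"]
  counts <- hbond_count_series(tr, group_a = prot, group_b = lig)
  oracle <- vapply(seq_len(n_frames(tr)), function(f)
    oracle_hbonds(matrix(tr$coords[f, , ], ncol = 3), tr$atoms,
                  group_a = prot, group_b = lig), integer(1))
  expect_identical(counts, oracle)
  # nontrivial case: planted contacts under jitter, same equality, and the
  # detector actually fires
  st <- make_stable_binding_traj(n_frames = 50)
  set.seed(77)
  st$coords[-1, , ] <- st$coords[-1, , ] +
    rnorm(length(st$coords[-1, , ]), sd = 0.3)
  gp <- st$atoms$serial[st$atoms$role == "protein"]
  gl <- st$atoms$serial[st$atoms$role == "ligand"]
  jcounts <- hbond_count_series(st, group_a = gp, group_b = gl)
  jorac <- vapply(seq_len(n_frames(st)), function(f)
    oracle_hbonds(matrix(st$coords[f, , ], ncol = 3), st$atoms,
                  group_a = gp, group_b = gl), integer(1))
  expect_identical(jcounts, jorac)
  expect_gt(sum(jcounts), 0)
})

test_that("stable-binding fixture holds 3 bonds; counts are rigid-invariant", {
  tr <- make_stable_binding_traj(n_frames = 10)
  expect_equal(hbond_count_series(tr), rep(3L, 10))
  moved <- make_stable_binding_traj(n_frames = 10,
                                    rigid_shift = c(1.5, -2, 0.5),
                                    rotate_deg = 73)
  expect_equal(hbond_count_series(moved), rep(3L, 10))
  # monotone: tighter cutoffs never find more bonds
  c1 <- hbond_count_series(tr, hbond_criterion(3.5, 120))
  c2 <- hbond_count_series(tr, hbond_criterion(2.5, 120))
  c3 <- hbond_count_series(tr, hbond_criterion(3.5, 170))
  expect_true(all(c2 <= c1) && all(c3 <= c1))
  # empty ligand group: all zero
  expect_equal(hbond_count_series(tr, group_a = 1:5, group_b = integer()),
               rep(0L, 10))
})

test_that("wernet-nilsson mode applies the coupled distance-angle cone", {
  atoms <- data.frame(
    serial = 1:3, element = c("N", "H", "O"),
    vdw_radius = bondi_radius(c("N", "H", "O")),
    role = c("ligand", "ligand", "protein"),
    hbond_class = c("donor-heavy", "hydrogen", "acceptor"),
    bonded_heavy = c(NA, 1, NA))
  wn <- hbond_criterion(mode = "wernet-nilsson")
  # collinear at 3.2 A: theta_HDA = 0, cutoff 3.3 -> bond
  fr <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.2, 0, 0))
  expect_equal(nrow(detect_hbonds(fr, atoms, wn, 1:2, 3)), 1)
  # collinear at 3.4 A: beyond the 3.3 cone apex -> none
  fr2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.4, 0, 0))
  expect_equal(nrow(detect_hbonds(fr2, atoms, wn, 1:2, 3)), 0)
  # 45-deg off-axis acceptor at 3.2 A: cutoff 3.3 - 0.00044*45^2 = 2.41 -> none
  fr3 <- rbind(c(0, 0, 0), c(1, 0, 0), 3.2 * c(cos(pi / 4), sin(pi / 4), 0))
  expect_equal(nrow(detect_hbonds(fr3, atoms, wn, 1:2, 3)), 0)
})

test_that("summarize_stability computes mean and population SD", {
  s <- summarize_stability(list(rmsd = c(1, 2, 3)), complex = "X")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(s$sd, 4), 0.8165)
  const <- summarize_stability(list(a = rep(4.2, 8)))
  expect_equal(const$mean, 4.2)
  expect_equal(const$sd, 0)
  # frame-range slicing uses only the tail
  two <- c(rep(10, 50), rep(2, 50))
  tail_only <- summarize_stability(list(m = two), frames = 51:100)
  expect_equal(tail_only$mean, 2)
  expect_equal(tail_only$sd, 0)
  expect_error(summarize_stability(list()), "non-empty")
  expect_error(summarize_stability(list(a = numeric())), "empty series")
})
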