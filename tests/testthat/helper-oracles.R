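# Independent brute-force oracles. These deliberately avoid the package's
# own code paths so each check is a genuine cross-implementation.

# BH step-up by direct definition: find the largest k with p_(k) <= k*q/m
# is the rejection rule; the adjusted value of p_(i) is min over j >= i of
# m*p_(j)/j, computed with explicit loops.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Welch two-sample t by direct formula.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Spearman rho by rank-then-Pearson, from first principles.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Dense-grid Shrake-Rupley with a random (seeded) point cloud at high n,
# written independently of the package's Fibonacci-lattice path.
oracle_sasa_total <- function(coords, radii, probe, n_points = 10000L,
                              seed = 99L) {
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(coords))) {
    g <- matrix(rnorm(n_points * 3L), ncol = 3L)
    g <- g / sqrt(rowSums(g^2))
    ri <- radii[i] + probe
    pts <- sweep(g * ri, 2L, coords[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(coords))[-i]) {
      dj <- sqrt(rowSums(sweep(pts, 2L, coords[j, ])^2))
      acc <- acc & dj > radii[j] + probe
    }
    total <- total + 4 * pi * ri^2 * mean(acc)
  }
  total
}

# Exhaustive hydrogen-bond enumeration over all (donor, hydrogen,
# acceptor) triples with explicit vector arithmetic.
oracle_hbonds <- function(frame, atoms, max_da = 3.5, min_angle = 120,
                          group_a, group_b) {
  ang_at_h <- function(d, h, a) {
    u <- d - h; v <- a - h
    acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  found <- 0L
  for (dir in 1:2) {
    gd <- if (dir == 1) group_a else group_b
    ga <- if (dir == 1) group_b else group_a
    for (di in which(atoms$hbond_class == "donor-heavy" &
                     atoms$serial %in% gd)) {
      for (hi in which(atoms$hbond_class == "hydrogen" &
                       !is.na(atoms$bonded_heavy) &
                       atoms$bonded_heavy == atoms$serial[di])) {
        for (ai in which(atoms$hbond_class == "acceptor" &
                         atoms$serial %in% ga)) {
          dda <- sqrt(sum((frame[di, ] - frame[ai, ])^2))
          if (dda <= max_da &&
              ang_at_h(frame[di, ], frame[hi, ], frame[ai, ]) >= min_angle)
            found <- found + 1L
        }
      }
    }
  }
  found
}

# A hand-built "stable binding" trajectory: three persistent collinear
# D-H...A contacts between ligand donors and protein acceptors, plus
# spectator carbons, replicated over n_frames with optional rigid motion.
make_stable_binding_traj <- function(n_frames = 10L, rigid_shift = c(0, 0, 0),
                                     rotate_deg = 0) {
  # protein: 3 acceptors + 2 carbons; ligand: 3 donor+hydrogen pairs + 1 C
  prot_xyz <- rbind(c(0, 0, 0), c(0, 4, 0), c(0, 8, 0),
                    c(-3, 2, 1), c(-3, 6, -1))
  lig_xyz <- rbind(c(3, 0, 0), c(2, 0, 0),    # donor D1, its H (points at A1)
                   c(3, 4, 0), c(2, 4, 0),
                   c(3, 8, 0), c(2, 8, 0),
                   c(5, 4, 2))
  atoms <- data.frame(
    serial = 1:12,
    element = c("O", "O", "O", "C", "C", "N", "H", "N", "H", "N", "H", "C"),
    vdw_radius = cnstriage::bondi_radius(
      c("O", "O", "O", "C", "C", "N", "H", "N", "H", "N", "H", "C")),
    role = c(rep("protein", 5), rep("ligand", 7)),
    hbond_class = c(rep("acceptor", 3), "none", "none",
                    "donor-heavy", "hydrogen", "donor-heavy", "hydrogen",
                    "donor-heavy", "hydrogen", "none"),
    bonded_heavy = c(rep(NA, 5), NA, 6, NA, 8, NA, 10, NA),
    stringsAsFactors = FALSE)
  ref <- rbind(prot_xyz, lig_xyz)
  th <- rotate_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coords <- array(NA_real_, dim = c(n_frames, 12L, 3L))
  for (f in seq_len(n_frames)) {
    fr <- ref %*% t(R)
    fr <- sweep(fr, 2L, (f - 1) * rigid_shift, `+`)
    coords[f, , ] <- fr
  }
  cnstriage::trajectory(coords, atoms)
}
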