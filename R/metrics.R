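## From-scratch trajectory stability metrics: Kabsch superposition, RMSD
## series, Shrake-Rupley SASA, and geometric hydrogen-bond detection.

#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of `mobile` onto `reference`
#' over `fit_selection`, via SVD of the covariance of the centered
#' selections. The returned rotation is proper (determinant +1);
#' reflections are corrected by negating the smallest singular direction.
#'
#' @param reference,mobile numeric `atoms x 3` coordinate matrices with
#'   identical atom ordering.
#' @param fit_selection row indices used for the fit (default all). Needs
#'   >= 3 non-collinear atoms for a unique rotation.
#' @return list: `coords` (all mobile atoms transformed), `rotation`
#'   (3x3), `translation`, `rmsd` (fitted RMSD over the fit selection).
#' @export
kabsch_superpose <- function(reference, mobile, fit_selection = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  stopifnot(ncol(reference) == 3L, ncol(mobile) == 3L,
            nrow(reference) == nrow(mobile))
  sel <- fit_selection %||% seq_len(nrow(reference))
  if (length(sel) < 3L) abort("fit selection needs >= 3 atoms")
  P <- mobile[sel, , drop = FALSE]; Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  # collinear or coincident selections have a rank-deficient spread
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L)
    abort("degenerate (collinear or coincident) fit selection")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- sweep(sweep(mobile, 2L, cp) %*% t(R), 2L, cq, `+`)
  list(coords = moved, rotation = R, translation = cq - as.numeric(R %*% cp),
       rmsd = rmsd(moved[sel, , drop = FALSE], Q))
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b `atoms x 3` matrices with identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD series against frame 1
#'
#' For every frame, optionally superposes onto the reference (frame 1)
#' over `fit_selection` with [kabsch_superpose()], then measures RMSD over
#' `measure_selection`. With no fitting the raw deviation is reported, so
#' rigid drift shows up in the series.
#'
#' @param traj a [trajectory()].
#' @param measure_selection atom serials measured; default: all atoms.
#' @param fit_selection atom serials for the superposition, or `NULL`
#'   (default) for no fitting.
#' @return numeric vector of length `n_frames(traj)`; element 1 is 0.
#' @export
rmsd_series <- function(traj, measure_selection = NULL, fit_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  msel <- selection_index(traj, measure_selection)
  if (!length(msel)) abort("empty measure selection")
  fsel <- if (!is.null(fit_selection)) selection_index(traj, fit_selection)
  ref <- frame_coords(traj, 1L)
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)
    if (!is.null(fsel)) fr <- kabsch_superpose(ref, fr, fsel)$coords
    rmsd(fr[msel, , drop = FALSE], ref[msel, , drop = FALSE])
  }, numeric(1L))
}

# Map atom serials (or NULL = all) to row indices.
#' @keywords internal
selection_index <- function(traj, serials) {
  if (is.null(serials)) return(seq_len(nrow(traj$atoms)))
  idx <- match(serials, traj$atoms$serial)
  if (anyNA(idx)) abort("selection names unknown atom serial(s)")
  idx
}

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic golden-angle spiral; used as the test-point set of the
#' Shrake-Rupley algorithm.
#'
#' @param n number of points (>= 12).
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  n <- assert_count(n, "n", min = 12L)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom in `group`, `n_sphere_points` quasi-uniform test points
#' are placed on its probe-expanded sphere (radius `vdw + probe`); a point
#' is accessible iff it lies strictly outside every other atom's expanded
#' sphere. Group atoms are tested against ALL atoms as occluders. Per-atom
#' area is `4 pi (r + probe)^2` times the accessible fraction.
#'
#' @param frame `atoms x 3` coordinate matrix (one trajectory frame).
#' @param atoms atom metadata (needs `serial`, `vdw_radius`).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points test points per atom (default 960).
#' @param group atom serials to report areas for; default all.
#' @return list: `area` (named per-atom areas, Angstrom^2), `total`.
#' @export
shrake_rupley_sasa <- function(frame, atoms, probe_radius = 1.4,
                               n_sphere_points = 960L, group = NULL) {
  frame <- as.matrix(frame)
  probe_radius <- assert_number(probe_radius, "probe_radius", min = 0)
  if (is.null(atoms$vdw_radius) || any(is.na(atoms$vdw_radius)))
    abort("every atom needs a vdw_radius")
  stopifnot(nrow(frame) == nrow(atoms))
  gidx <- if (is.null(group)) seq_len(nrow(atoms)) else
    match(group, atoms$serial)
  if (anyNA(gidx)) abort("group names unknown atom serial(s)")
  # Orient the lattice in the molecule's principal-axes frame so the
  # estimate is exactly invariant under rigid motion of the input: the
  # frame co-rotates with the atoms, so every test point sees the same
  # relative geometry.
  pts <- fibonacci_sphere(n_sphere_points) %*% t(principal_frame(frame))
  rexp <- atoms$vdw_radius + probe_radius
  area <- numeric(length(gidx))
  for (k in seq_along(gidx)) {
    i <- gidx[[k]]
    ri <- rexp[[i]]
    # occluder pruning: only atoms whose expanded sphere can reach ours
    d2 <- rowSums(sweep(frame, 2L, frame[i, ])^2)
    occ <- which(d2 < (ri + rexp)^2 & seq_len(nrow(frame)) != i)
    if (!length(occ)) { area[[k]] <- 4 * pi * ri^2; next }
    sp <- sweep(pts * ri, 2L, frame[i, ], `+`)
    accessible <- rep(TRUE, n_sphere_points)
    for (j in occ) {
      dj2 <- rowSums(sweep(sp, 2L, frame[j, ])^2)
      accessible <- accessible & dj2 > rexp[[j]]^2   # strictly outside
      if (!any(accessible)) break
    }
    area[[k]] <- 4 * pi * ri^2 * mean(accessible)
  }
  names(area) <- atoms$serial[gidx]
  list(area = area, total = sum(area))
}

# Rotation-covariant orthonormal frame from the atom cloud: principal
# axes of the coordinate covariance, each axis' sign fixed by the third
# moment (skewness) of the projections, which is itself invariant under
# rigid motion; determinant forced to +1. Degenerate clouds (perfectly
# symmetric or < 3 atoms) fall back deterministically to the identity
# contributions of LAPACK's ordering.
#' @keywords internal
principal_frame <- function(coords) {
  if (nrow(coords) < 3L) return(diag(3))
  cc <- sweep(coords, 2L, colMeans(coords))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:3) {
    sk <- sum((cc %*% V[, j])^3)
    if (abs(sk) > 1e-8 && sk < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  V
}

#' Hydrogen-bond geometric criterion
#'
#' Default mode `"fixed"`: a donor--hydrogen--acceptor triple is a bond
#' iff the donor-acceptor distance is at most `max_da_distance` (3.5 A,
#' i.e. 0.35 nm) and the angle at the hydrogen (D-H...A) is at least
#' `min_dha_angle` (120 degrees). Mode `"wernet-nilsson"` uses the
#' coupled distance-angle cone `r_DA < 3.3 - 0.00044 * theta^2` (theta =
#' H-D-A angle at the donor, degrees), the criterion of the method the
#' fixed cutoffs approximate.
#'
#' @param max_da_distance donor-acceptor cutoff, Angstrom.
#' @param min_dha_angle D-H...A angle cutoff, degrees, in (0, 180].
#' @param mode `"fixed"` or `"wernet-nilsson"`.
#' @return a list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 3.5, min_dha_angle = 120,
                            mode = c("fixed", "wernet-nilsson")) {
  structure(list(
    max_da_distance = assert_number(max_da_distance, "max_da_distance",
                                    min = 1e-9),
    min_dha_angle = assert_number(min_dha_angle, "min_dha_angle", 1e-9, 180),
    mode = match.arg(mode)), class = "hbond_criterion")
}

#' Detect hydrogen bonds between two atom groups in one frame
#'
#' Enumerates (donor, hydrogen, acceptor) triples with the donor in one
#' group and the acceptor in the other (both directions), reporting each
#' triple at most once. Donors are atoms with `hbond_class ==
#' "donor-heavy"`; their hydrogens are atoms with `bonded_heavy` equal to
#' the donor serial; acceptors have `hbond_class == "acceptor"`.
#'
#' @param frame `atoms x 3` coordinate matrix.
#' @param atoms atom metadata table.
#' @param criterion an [hbond_criterion()].
#' @param group_a,group_b disjoint atom-serial vectors.
#' @return data.frame: donor, hydrogen, acceptor serials, `distance` (D-A,
#'   Angstrom), `angle` (D-H...A, degrees).
#' @export
detect_hbonds <- function(frame, atoms, criterion = hbond_criterion(),
                          group_a = NULL, group_b = NULL) {
  frame <- as.matrix(frame)
  stopifnot(nrow(frame) == nrow(atoms))
  if (is.null(group_a) || is.null(group_b))
    abort("detect_hbonds needs two atom groups")
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint")
  hyd <- which(atoms$hbond_class == "hydrogen")
  if (any(is.na(atoms$bonded_heavy[hyd])))
    abort("hydrogen without a bonded_heavy serial")
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  rows <- list(empty)
  for (dir in 1:2) {
    gd <- if (dir == 1L) group_a else group_b
    ga <- if (dir == 1L) group_b else group_a
    donors <- atoms$serial[atoms$hbond_class == "donor-heavy" &
                             atoms$serial %in% gd]
    acceptors <- atoms$serial[atoms$hbond_class == "acceptor" &
                                atoms$serial %in% ga]
    if (!length(donors) || !length(acceptors)) next
    di <- match(donors, atoms$serial); ai <- match(acceptors, atoms$serial)
    dmat <- sqrt(pmax(outer(rowSums(frame[di, , drop = FALSE]^2),
                            rowSums(frame[ai, , drop = FALSE]^2), `+`) -
                        2 * frame[di, , drop = FALSE] %*%
                        t(frame[ai, , drop = FALSE]), 0))
    for (k in seq_along(donors)) {
      hsel <- hyd[atoms$bonded_heavy[hyd] == donors[[k]]]
      if (!length(hsel)) next
      near <- which(dmat[k, ] <= max(criterion$max_da_distance, 3.3))
      for (m in near) {
        for (h in hsel) {
          geom <- hbond_geometry(frame[di[[k]], ], frame[h, ], frame[ai[[m]], ])
          pass <- if (criterion$mode == "fixed") {
            dmat[k, m] <= criterion$max_da_distance &&
              geom$dha >= criterion$min_dha_angle
          } else {
            dmat[k, m] < 3.3 - 0.00044 * geom$hda^2
          }
          if (pass)
            rows[[length(rows) + 1L]] <- data.frame(
              donor = atoms$serial[di[[k]]], hydrogen = atoms$serial[h],
              acceptor = atoms$serial[ai[[m]]], distance = dmat[k, m],
              angle = geom$dha)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  unique(out)
}

# D-H...A angle at the hydrogen and H-D-A angle at the donor, degrees.
#' @keywords internal
hbond_geometry <- function(d, h, a) {
  ang <- function(u, v) {
    cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(1, pmax(-1, cs))) * 180 / pi
  }
  list(dha = ang(d - h, a - h), hda = ang(h - d, a - d))
}

#' Per-frame hydrogen-bond counts
#'
#' @inheritParams detect_hbonds
#' @param traj a [trajectory()].
#' @return integer vector, one count per frame. Invariant under rigid
#'   motion of each frame.
#' @export
hbond_count_series <- function(traj, criterion = hbond_criterion(),
                               group_a = NULL, group_b = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  group_a <- group_a %||% traj$atoms$serial[traj$atoms$role == "protein"]
  group_b <- group_b %||% traj$atoms$serial[traj$atoms$role == "ligand"]
  vapply(seq_len(n_frames(traj)), function(f)
    nrow(detect_hbonds(frame_coords(traj, f), traj$atoms, criterion,
                       group_a, group_b)), integer(1L))
}

#' Mean +/- SD stability summary of metric series
#'
#' Arithmetic mean and population SD per metric, optionally over a frame
#' window (equilibration discard). The default window is the whole run.
#'
#' @param series named list of numeric per-frame series (e.g.
#'   `protein_rmsd`, `ligand_rmsd`, `protein_sasa`, `ligand_sasa`,
#'   `hbond_count`).
#' @param complex id of the complex being summarized.
#' @param frames optional integer vector of frame indices to keep.
#' @return data.frame of class `stability_summary`: complex, metric, mean,
#'   sd, n_frames.
#' @export
summarize_stability <- function(series, complex = "complex", frames = NULL) {
  if (!is.list(series) || !length(series) || is.null(names(series)))
    abort("series must be a non-empty named list")
  rows <- lapply(names(series), function(nm) {
    x <- series[[nm]]
    if (!is.null(frames)) x <- x[frames]
    if (!length(x)) abort(sprintf("empty series '%s'", nm))
    data.frame(complex = complex, metric = nm, mean = mean(x),
               sd = sd_pop(x), n_frames = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_summary", "data.frame")
  out
}
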