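## Synthetic-data module: every generator states its world explicitly in a
## spec object, and identical spec + seed reproduces identical output.

#' Simulation spec for regulator activity matrices
#'
#' Describes a synthetic regulator-activity matrix on the z-score scale, the
#' interface the differential-regulator statistics consume: a null of
#' i.i.d. Gaussian activity plus a constant case-vs-control shift for the
#' planted regulators.
#'
#' @param n_regulators number of regulators (rows).
#' @param n_metacells_per_group number of metacells in each of the two
#'   groups (AD and control).
#' @param n_clusters number of cell clusters; labels are assigned
#'   round-robin within each group so every cluster contains both groups.
#' @param planted_up,planted_down regulator ids (subset of
#'   `R0001...`-style ids, or integer indices) shifted up/down in AD.
#' @param effect_size case-minus-control mean shift, in SD units of the
#'   null activity distribution. Must be >= 0.
#' @param noise_sd SD of the Gaussian null activity.
#' @param seed integer RNG seed.
#' @return an object of class `activity_sim_spec`.
#' @export
activity_sim_spec <- function(n_regulators = 200L, n_metacells_per_group = 40L,
                              n_clusters = 3L, planted_up = integer(),
                              planted_down = integer(), effect_size = 1,
                              noise_sd = 1, seed = 1L) {
  spec <- list(
    n_regulators = assert_count(n_regulators, "n_regulators"),
    n_metacells_per_group = assert_count(n_metacells_per_group,
                                         "n_metacells_per_group", min = 2L),
    n_clusters = assert_count(n_clusters, "n_clusters"),
    planted_up = planted_up, planted_down = planted_down,
    effect_size = assert_number(effect_size, "effect_size", min = 0),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0),
    seed = assert_count(seed, "seed", min = 0L))
  if (length(intersect(spec$planted_up, spec$planted_down)))
    abort("planted_up and planted_down must be disjoint",
          "cnstriage_invalid_spec")
  structure(spec, class = "activity_sim_spec")
}

#' Generate a regulator activity matrix with planted signal
#'
#' @param spec an [activity_sim_spec()].
#' @return an [activity_matrix()] whose planted-up regulators have expected
#'   case-minus-control mean difference `+effect_size` (planted-down,
#'   `-effect_size`).
#' @export
generate_activity_matrix <- function(spec) {
  stopifnot(inherits(spec, "activity_sim_spec"))
  n <- spec$n_metacells_per_group
  p <- spec$n_regulators
  reg_ids <- sprintf("R%04d", seq_len(p))
  up <- resolve_ids(spec$planted_up, reg_ids, "planted_up")
  down <- resolve_ids(spec$planted_down, reg_ids, "planted_down")
  set.seed(spec$seed)
  vals <- matrix(stats::rnorm(p * 2L * n, sd = spec$noise_sd), nrow = p,
                 dimnames = list(reg_ids,
                                 c(sprintf("AD_mc%03d", seq_len(n)),
                                   sprintf("ctrl_mc%03d", seq_len(n)))))
  case_cols <- seq_len(n)
  vals[up, case_cols] <- vals[up, case_cols] + spec$effect_size
  vals[down, case_cols] <- vals[down, case_cols] - spec$effect_size
  group <- rep(c("AD", "control"), each = n)
  cluster <- c(rep_len(seq_len(spec$n_clusters), n),
               rep_len(seq_len(spec$n_clusters), n))
  am <- activity_matrix(vals, group, cluster, case_level = "AD")
  attr(am, "planted_up") <- up
  attr(am, "planted_down") <- down
  am
}

#' @keywords internal
resolve_ids <- function(x, ids, name) {
  if (!length(x)) return(character())
  if (is.numeric(x)) {
    if (any(x < 1 | x > length(ids)))
      abort(sprintf("`%s` index out of range", name), "cnstriage_invalid_spec")
    return(ids[x])
  }
  if (!all(x %in% ids))
    abort(sprintf("`%s` names unknown regulator '%s'", name,
                  setdiff(x, ids)[[1L]]), "cnstriage_invalid_spec")
  as.character(x)
}

#' Simulation spec for QC count matrices
#'
#' A cell-by-gene count table in which stated fractions of cells are
#' constructed to fail the UMI and detected-genes quality gates.
#'
#' @param n_cells number of cells.
#' @param umi_low_fraction fraction of cells built with < 800 total UMIs
#'   (each still detects >= 500 genes, so it fails only the UMI gate).
#' @param gene_low_fraction fraction of cells built with < 500 detected
#'   genes (but >= 800 UMIs). The two low sets are disjoint.
#' @param seed integer RNG seed.
#' @return an object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_cells = 100L, umi_low_fraction = 0,
                           gene_low_fraction = 0, seed = 1L) {
  spec <- list(
    n_cells = assert_count(n_cells, "n_cells"),
    umi_low_fraction = assert_number(umi_low_fraction, "umi_low_fraction", 0, 1),
    gene_low_fraction = assert_number(gene_low_fraction, "gene_low_fraction", 0, 1),
    seed = assert_count(seed, "seed", min = 0L))
  n_low <- round(spec$umi_low_fraction * spec$n_cells) +
    round(spec$gene_low_fraction * spec$n_cells)
  if (n_low > spec$n_cells)
    abort("low-quality fractions exceed 1 in combination", "cnstriage_invalid_spec")
  structure(spec, class = "count_sim_spec")
}

#' Generate a cell-by-gene count matrix with planted QC failures
#'
#' @param spec a [count_sim_spec()].
#' @return a list with `counts` (integer matrix, cells as rows over 1200
#'   genes) and `truth` (data.frame: cell, low_umi, low_gene flags).
#' @export
generate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  n_genes <- 1200L
  n <- spec$n_cells
  n_lu <- as.integer(round(spec$umi_low_fraction * n))
  n_lg <- as.integer(round(spec$gene_low_fraction * n))
  set.seed(spec$seed)
  counts <- matrix(0L, nrow = n, ncol = n_genes,
                   dimnames = list(sprintf("cell%04d", seq_len(n)),
                                   sprintf("g%04d", seq_len(n_genes))))
  low_umi <- seq_len(n) <= n_lu
  low_gene <- seq_len(n) > n_lu & seq_len(n) <= n_lu + n_lg
  for (i in seq_len(n)) {
    if (low_umi[i]) {
      # 520 detected genes at 1 UMI each: 520 total, genes pass, UMIs fail
      g <- sample.int(n_genes, 520L)
      counts[i, g] <- 1L
    } else if (low_gene[i]) {
      # 400 detected genes at 3 UMIs each: 1200 total, genes fail
      g <- sample.int(n_genes, 400L)
      counts[i, g] <- 3L
    } else {
      g <- sample.int(n_genes, 600L)
      counts[i, g] <- 1L + stats::rpois(600L, 2)
    }
  }
  list(counts = counts,
       truth = data.frame(cell = rownames(counts), low_umi = low_umi,
                          low_gene = low_gene, stringsAsFactors = FALSE))
}

#' Simulation spec for docking-affinity matrices
#'
#' Null affinities are Gaussian in kcal/mol; planted binder pairs are
#' shifted by a non-positive amount (more negative = stronger binding).
#'
#' @param n_drugs,n_targets matrix dimensions.
#' @param null_mean,null_sd null affinity distribution, kcal/mol.
#' @param planted_binders two-column matrix or data.frame of
#'   (drug index, target index) pairs to shift.
#' @param binder_shift shift in kcal/mol applied to planted pairs; <= 0.
#' @param seed integer RNG seed.
#' @return an object of class `docking_sim_spec`.
#' @export
docking_sim_spec <- function(n_drugs = 20L, n_targets = 5L, null_mean = -5,
                             null_sd = 1, planted_binders = NULL,
                             binder_shift = -3, seed = 1L) {
  spec <- list(
    n_drugs = assert_count(n_drugs, "n_drugs"),
    n_targets = assert_count(n_targets, "n_targets"),
    null_mean = assert_number(null_mean, "null_mean"),
    null_sd = assert_number(null_sd, "null_sd", min = 0),
    planted_binders = planted_binders,
    binder_shift = assert_number(binder_shift, "binder_shift", max = 0),
    seed = assert_count(seed, "seed", min = 0L))
  structure(spec, class = "docking_sim_spec")
}

#' Generate a docking-affinity matrix with planted binders
#'
#' @param spec a [docking_sim_spec()].
#' @return a [docking_matrix()] with engine label `"synthetic"`.
#' @export
generate_docking_matrix <- function(spec) {
  stopifnot(inherits(spec, "docking_sim_spec"))
  set.seed(spec$seed)
  m <- matrix(stats::rnorm(spec$n_drugs * spec$n_targets, spec$null_mean,
                           spec$null_sd),
              nrow = spec$n_drugs,
              dimnames = list(sprintf("drug%03d", seq_len(spec$n_drugs)),
                              sprintf("T%02d", seq_len(spec$n_targets))))
  pb <- spec$planted_binders
  if (!is.null(pb)) {
    pb <- as.matrix(as.data.frame(pb))
    for (k in seq_len(nrow(pb)))
      m[pb[k, 1L], pb[k, 2L]] <- m[pb[k, 1L], pb[k, 2L]] + spec$binder_shift
  }
  docking_matrix(m, engine = "synthetic")
}

#' Simulation spec for protein--ligand trajectories
#'
#' A geometric stand-in for a solvated MD production run: frame 0 is the
#' reference structure; later frames add i.i.d. Gaussian jitter per atom
#' and an optional rigid drift, and the ligand can be made to escape the
#' binding site at a set frame.
#'
#' @param n_frames number of frames (>= 2).
#' @param n_protein_atoms,n_ligand_atoms atom counts for the two roles.
#' @param fluctuation_sd per-atom isotropic jitter SD, Angstrom.
#' @param drift_per_frame rigid x-translation per frame, Angstrom.
#' @param ligand_escape_frame 1-based frame index after which the ligand
#'   centroid translates away by >= 10 Angstrom per frame, or `NULL`.
#' @param seed integer RNG seed.
#' @return an object of class `trajectory_sim_spec`.
#' @export
trajectory_sim_spec <- function(n_frames = 20L, n_protein_atoms = 60L,
                                n_ligand_atoms = 12L, fluctuation_sd = 0.2,
                                drift_per_frame = 0,
                                ligand_escape_frame = NULL, seed = 1L) {
  spec <- list(
    n_frames = assert_count(n_frames, "n_frames", min = 2L),
    n_protein_atoms = assert_count(n_protein_atoms, "n_protein_atoms", min = 4L),
    n_ligand_atoms = assert_count(n_ligand_atoms, "n_ligand_atoms", min = 1L),
    fluctuation_sd = assert_number(fluctuation_sd, "fluctuation_sd", min = 0),
    drift_per_frame = assert_number(drift_per_frame, "drift_per_frame"),
    ligand_escape_frame = if (!is.null(ligand_escape_frame))
      assert_count(ligand_escape_frame, "ligand_escape_frame"),
    seed = assert_count(seed, "seed", min = 0L))
  structure(spec, class = "trajectory_sim_spec")
}

#' Generate a synthetic protein--ligand trajectory
#'
#' Protein atoms are scattered in a ball around the origin; ligand atoms
#' sit at the interface. Elements are drawn from {C, N, O, H}: N/O heavy
#' atoms act as hydrogen-bond donors (each given one attached hydrogen) or
#' acceptors, and van der Waals radii follow the Bondi set.
#'
#' @param spec a [trajectory_sim_spec()].
#' @return a [trajectory()] object.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  set.seed(spec$seed)
  np <- spec$n_protein_atoms; nl <- spec$n_ligand_atoms
  build_group <- function(n, center, role) {
    # heavy-atom scaffold, ~40% polar; each donor gets one hydrogen 1 A away
    n_heavy <- max(1L, ceiling(n * 0.7))
    n_h <- n - n_heavy
    elem <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    coords <- sweep(matrix(stats::rnorm(n_heavy * 3L, sd = 3), ncol = 3L),
                    2L, center, `+`)
    hclass <- ifelse(elem == "C", "none",
                     sample(c("donor-heavy", "acceptor"), n_heavy, replace = TRUE))
    atoms <- data.frame(element = elem, role = role, hbond_class = hclass,
                        bonded_heavy = NA_integer_, stringsAsFactors = FALSE)
    # attach hydrogens preferentially to donor heavies, else carbons;
    # donor hydrogens point at the binding interface (the opposite
    # group's center) so interfacial D-H...A geometries actually occur
    if (n_h > 0L) {
      donors <- which(hclass == "donor-heavy")
      hosts <- rep_len(c(donors, which(elem == "C")), n_h)
      hdir <- matrix(stats::rnorm(n_h * 3L), ncol = 3L)
      target <- if (center[1L] > 0) c(0, 0, 0) else c(6, 0, 0)
      toward <- sweep(-coords[hosts, , drop = FALSE], 2L, target, `+`)
      is_donor_host <- hclass[hosts] == "donor-heavy"
      hdir[is_donor_host, 1L] <- toward[is_donor_host, 1L]
      hdir[is_donor_host, 2L] <- toward[is_donor_host, 2L]
      hdir[is_donor_host, 3L] <- toward[is_donor_host, 3L]
      hdir <- hdir / sqrt(rowSums(hdir^2))
      hxyz <- coords[hosts, , drop = FALSE] + hdir
      coords <- rbind(coords, hxyz)
      atoms <- rbind(atoms,
                     data.frame(element = "H", role = role,
                                hbond_class = "hydrogen", bonded_heavy = hosts,
                                stringsAsFactors = FALSE))
    }
    list(coords = coords, atoms = atoms)
  }
  prot <- build_group(np, c(0, 0, 0), "protein")
  lig <- build_group(nl, c(6, 0, 0), "ligand")
  # ligand hydrogens index into the full table after the protein block
  lig$atoms$bonded_heavy <- lig$atoms$bonded_heavy + np
  ref <- rbind(prot$coords, lig$coords)
  atoms <- rbind(prot$atoms, lig$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$vdw_radius <- bondi_radius(atoms$element)
  atoms <- atoms[, c("serial", "element", "vdw_radius", "role",
                     "hbond_class", "bonded_heavy")]

  nf <- spec$n_frames
  coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3L))
  coords[1L, , ] <- ref
  lig_idx <- which(atoms$role == "ligand")
  for (k in 2L:nf) {
    fr <- ref
    fr[, 1L] <- fr[, 1L] + (k - 1L) * spec$drift_per_frame
    if (spec$fluctuation_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = spec$fluctuation_sd),
                        ncol = 3L)
    if (!is.null(spec$ligand_escape_frame) && k > spec$ligand_escape_frame)
      fr[lig_idx, 1L] <- fr[lig_idx, 1L] +
        12 * (k - spec$ligand_escape_frame)
    coords[k, , ] <- fr
  }
  trajectory(coords, atoms)
}

#' Bondi van der Waals radii
#'
#' @param element character vector of element symbols.
#' @return radii in Angstrom; unknown elements fall back to 1.5 A.
#' @export
bondi_radius <- function(element) {
  tbl <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
  r <- unname(tbl[element])
  r[is.na(r)] <- 1.5
  r
}
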