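## Differentially active regulator (DER) calling: cluster-wise Welch
## statistics mapped to z, combined across clusters by Stouffer's method,
## BH-FDR across regulators, and a |Z| association gate.

# Welch z-scores are clamped at this magnitude where a zero-variance
# cluster would otherwise give +/-Inf.
Z_CLAMP <- 38

#' Construct a regulator activity matrix
#'
#' Container for inferred regulator activity on the z-score scale, with the
#' per-sample group (case/control) and cluster labels the DER statistics
#' need. Upstream network inference is not reimplemented here; this matrix
#' is the interface contract.
#'
#' @param values numeric matrix, regulators as rows, samples (cells or
#'   metacells) as columns.
#' @param group_labels character/factor of length `ncol(values)` with
#'   exactly two levels.
#' @param cluster_labels vector of length `ncol(values)` of cluster ids.
#' @param case_level which group label is the case (disease) group;
#'   defaults to `"AD"` when present.
#' @return an object of class `activity_matrix`.
#' @export
activity_matrix <- function(values, group_labels, cluster_labels,
                            case_level = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("activity values must be numeric")
  ns <- ncol(values)
  if (length(group_labels) != ns || length(cluster_labels) != ns)
    abort("label lengths must equal the sample count")
  group_labels <- as.character(group_labels)
  lv <- unique(group_labels)
  if (length(lv) != 2L) abort("group_labels must have exactly two levels")
  if (is.null(case_level))
    case_level <- if ("AD" %in% lv) "AD" else lv[[1L]]
  if (!case_level %in% lv)
    abort(sprintf("case_level '%s' not among group labels", case_level))
  if (min(table(group_labels)) < 2L)
    abort("need >= 2 samples per group")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("R%04d", seq_len(nrow(values)))
  structure(list(values = values, group = group_labels,
                 cluster = as.character(cluster_labels),
                 case_level = case_level),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d regulators x %d samples (%s vs %s), %d clusters\n",
              nrow(x$values), ncol(x$values), x$case_level,
              setdiff(unique(x$group), x$case_level),
              length(unique(x$cluster))))
  invisible(x)
}

#' Quality-control filter on a cell-by-gene count table
#'
#' A cell is retained iff its total UMI count is at least `min_umis` AND it
#' detects (count > 0) at least `min_genes` genes. The defaults encode the
#' usual snRNA-seq gate: cells with fewer than 800 UMIs or 500 detected
#' genes are excluded.
#'
#' @param counts non-negative integer matrix, cells as rows.
#' @param min_umis,min_genes retention thresholds (inclusive).
#' @return character vector of retained cell ids (rownames).
#' @export
qc_filter_cells <- function(counts, min_umis = 800L, min_genes = 500L) {
  min_umis <- assert_count(min_umis, "min_umis")
  min_genes <- assert_count(min_genes, "min_genes")
  counts <- as.matrix(counts)
  if (!nrow(counts)) {
    warning("empty count table; no cells retained")
    return(character())
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%04d", seq_len(nrow(counts)))
  keep <- rowSums(counts) >= min_umis & rowSums(counts > 0) >= min_genes
  rownames(counts)[keep]
}

#' Per-cluster Welch z statistics
#'
#' For each regulator and each cluster, computes the Welch two-sample t
#' statistic (case minus control) and maps it through the normal quantile
#' of its t-distribution tail probability, giving a z-score whose sign is
#' positive when the case mean exceeds the control mean. Clusters with
#' fewer than 2 samples in either group are dropped with a warning.
#' Zero variance in both groups gives z = 0 when the means are equal and
#' z clamped at +/-38 otherwise.
#'
#' @param am an [activity_matrix()].
#' @return numeric matrix, regulators x retained clusters, with an
#'   attribute `cluster_sizes` (total samples per retained cluster).
#' @export
cluster_zscores <- function(am) {
  stopifnot(inherits(am, "activity_matrix"))
  clusters <- unique(am$cluster)
  is_case <- am$group == am$case_level
  ok <- vapply(clusters, function(k) {
    sel <- am$cluster == k
    sum(sel & is_case) >= 2L && sum(sel & !is_case) >= 2L
  }, logical(1L))
  if (any(!ok))
    warning(sprintf("dropping %d cluster(s) with < 2 samples per group: %s",
                    sum(!ok), paste(clusters[!ok], collapse = ", ")))
  clusters <- clusters[ok]
  if (!length(clusters)) abort("no cluster has >= 2 samples per group")
  z <- matrix(NA_real_, nrow = nrow(am$values), ncol = length(clusters),
              dimnames = list(rownames(am$values), clusters))
  sizes <- integer(length(clusters))
  for (j in seq_along(clusters)) {
    sel <- am$cluster == clusters[[j]]
    X <- am$values[, sel & is_case, drop = FALSE]
    Y <- am$values[, sel & !is_case, drop = FALSE]
    n1 <- ncol(X); n2 <- ncol(Y)
    sizes[[j]] <- n1 + n2
    m1 <- rowMeans(X); m2 <- rowMeans(Y)
    v1 <- rowSums((X - m1)^2) / (n1 - 1L)
    v2 <- rowSums((Y - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
    # upper-tail mapping preserves sign: z = qnorm(P(T > t)) upper tail
    zj <- stats::qnorm(stats::pt(tstat, df, lower.tail = FALSE),
                       lower.tail = FALSE)
    zero_se <- se2 == 0
    zj[zero_se & m1 == m2] <- 0
    zj[zero_se & m1 != m2] <- sign(m1 - m2)[zero_se & m1 != m2] * Z_CLAMP
    zj[zj > Z_CLAMP] <- Z_CLAMP
    zj[zj < -Z_CLAMP] <- -Z_CLAMP
    z[, j] <- zj
  }
  attr(z, "cluster_sizes") <- stats::setNames(sizes, clusters)
  z
}

#' Stouffer combination of z-scores
#'
#' Weighted Stouffer meta-combination:
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`. With equal weights this reduces
#' to `sum(z_i) / sqrt(k)`. Invariant to rescaling all weights by a
#' positive constant.
#'
#' @param z numeric vector of per-cluster z-scores.
#' @param weights positive weights, recycled length must match `z`;
#'   default equal.
#' @return the combined z (association score).
#' @export
stouffer_combine <- function(z, weights = NULL) {
  if (!length(z)) abort("stouffer_combine needs >= 1 z-score")
  if (is.null(weights)) weights <- rep(1, length(z))
  if (length(weights) != length(z)) abort("weights length must match z")
  if (any(weights <= 0)) abort("weights must be > 0")
  sum(weights * z) / sqrt(sum(weights^2))
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Standard step-up procedure with monotonicity enforcement:
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, clamped to [0, 1], returned in
#' the input order. Ties in rank are broken by input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)                        # ties: input order (stable)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Call differentially active regulators
#'
#' Full DER pipeline on one activity matrix: per-cluster Welch z
#' ([cluster_zscores()]), Stouffer combination across clusters
#' ([stouffer_combine()]) with equal or sqrt-of-cluster-size weights,
#' two-sided normal p-values, BH adjustment across regulators
#' ([bh_adjust()]), and the significance gate
#' `q < fdr_threshold & |Z| > min_abs_association`.
#'
#' @param am an [activity_matrix()].
#' @param fdr_threshold BH-FDR significance threshold (default 0.05).
#' @param min_abs_association minimum |combined Z| (default 1.5).
#' @param cluster_weighting `"sqrt-size"` (default: weight each cluster by
#'   the square root of its sample count) or `"equal"`.
#' @return data.frame with one row per regulator: `regulator`,
#'   `association_score`, `p_value`, `q_value`, `direction` (up/down),
#'   `significant`.
#' @export
call_ders <- function(am, fdr_threshold = 0.05, min_abs_association = 1.5,
                      cluster_weighting = c("sqrt-size", "equal")) {
  cluster_weighting <- match.arg(cluster_weighting)
  fdr_threshold <- assert_number(fdr_threshold, "fdr_threshold", 0, 1)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    abort("fdr_threshold must be in (0, 1)", "cnstriage_invalid_spec")
  min_abs_association <- assert_number(min_abs_association,
                                       "min_abs_association", min = 0)
  z <- cluster_zscores(am)
  sizes <- attr(z, "cluster_sizes")
  w <- if (cluster_weighting == "sqrt-size") sqrt(sizes) else rep(1, ncol(z))
  Z <- as.numeric(z %*% w) / sqrt(sum(w^2))
  p <- 2 * stats::pnorm(-abs(Z))
  q <- bh_adjust(p)
  data.frame(
    regulator = rownames(z),
    association_score = Z,
    p_value = p,
    q_value = q,
    direction = ifelse(Z >= 0, "up", "down"),
    significant = q < fdr_threshold & abs(Z) > min_abs_association,
    stringsAsFactors = FALSE)
}

#' Intersect DER sets across cohorts
#'
#' Maps every regulator to the exact combination of named sets containing
#' it (the regions of a Venn diagram) and tabulates region sizes.
#'
#' @param sets named list (>= 2 entries) of character vectors of DER ids.
#' @return list with `membership` (data.frame: id, one logical column per
#'   set, `region` label like `"A&B"`) and `counts` (named integer vector
#'   of region sizes, including the full intersection under the region
#'   naming).
#' @export
intersect_ders <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)) ||
      any(!nzchar(names(sets))))
    abort("sets must be a named list of >= 2 id vectors")
  ids <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) memb <- matrix(memb, nrow = 1L,
                                        dimnames = list(NULL, names(sets)))
  region <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  membership <- data.frame(id = ids, memb, region = region,
                           stringsAsFactors = FALSE, check.names = FALSE)
  counts <- table(factor(region, levels = unique(region)))
  list(membership = membership,
       counts = stats::setNames(as.integer(counts), names(counts)))
}
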