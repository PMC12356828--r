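## Docking-score triage: threshold filtering of drug x target affinity
## matrices, aggregate ranking, and cross-engine concordance.

#' Construct a docking-affinity matrix
#'
#' Drugs as rows, targets as columns, binding affinities in kcal/mol (more
#' negative = stronger predicted binding). Missing cells are explicit `NA`,
#' never silently zero.
#'
#' @param values numeric matrix with drug rownames and target colnames.
#' @param engine label of the docking engine that produced the scores.
#' @return an object of class `docking_matrix`.
#' @export
docking_matrix <- function(values, engine = "unknown") {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("affinities must be numeric")
  if (any(is.infinite(values))) abort("affinities must be finite or NA")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("docking_matrix needs drug rownames and target colnames")
  structure(list(values = values, drugs = rownames(values),
                 targets = colnames(values), engine = engine),
            class = "docking_matrix")
}

#' @export
print.docking_matrix <- function(x, ...) {
  cat(sprintf("docking_matrix [%s]: %d drugs x %d targets (kcal/mol)\n",
              x$engine, length(x$drugs), length(x$targets)))
  invisible(x)
}

#' Read a docking matrix from TSV
#'
#' First column is the drug id; remaining columns are targets. The Unicode
#' minus dialect of typeset tables is normalized on read.
#'
#' @param path TSV/CSV path.
#' @param engine engine label to attach.
#' @return a [docking_matrix()].
#' @export
read_docking_matrix <- function(path, engine = "unknown") {
  df <- load_table(path)
  for (cn in names(df)[-1L]) df[[cn]] <- as.numeric(df[[cn]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  docking_matrix(m, engine = engine)
}

#' Count targets passing the affinity threshold for one drug
#'
#' @param drug_row named numeric vector of affinities (kcal/mol) for one
#'   drug, restricted to the targets of interest.
#' @param threshold pass iff affinity <= threshold (inclusive; default
#'   -7.0 kcal/mol, i.e. binding at least as strong as the threshold).
#' @return integer count of passing targets. `NA` cells are ignored with a
#'   warning.
#' @export
count_passing_targets <- function(drug_row, threshold = -7.0) {
  threshold <- assert_number(threshold, "threshold")
  if (anyNA(drug_row)) {
    warning(sprintf("%d absent affinity cell(s) ignored", sum(is.na(drug_row))))
    drug_row <- drug_row[!is.na(drug_row)]
  }
  sum(drug_row <= threshold)
}

#' Filter drugs by how many selected targets they bind strongly
#'
#' A drug passes iff its affinity is at or below `threshold` for at least
#' `min_targets_passing` of the `select_targets`. The permissive default
#' (`min_targets_passing = 1`) retains any drug with one strong
#' interaction among the selected targets.
#'
#' @param dm a [docking_matrix()].
#' @param select_targets target ids to count against; default all targets.
#' @param threshold affinity cutoff in kcal/mol (inclusive, see
#'   [count_passing_targets()]).
#' @param min_targets_passing minimum number of passing targets.
#' @return character vector of passing drug ids, in input row order.
#' @export
filter_candidates <- function(dm, select_targets = NULL, threshold = -7.0,
                              min_targets_passing = 1L) {
  stopifnot(inherits(dm, "docking_matrix"))
  select_targets <- select_targets %||% dm$targets
  unknown <- setdiff(select_targets, dm$targets)
  if (length(unknown))
    abort(sprintf("unknown target id '%s'", unknown[[1L]]))
  min_targets_passing <- assert_count(min_targets_passing,
                                      "min_targets_passing", min = 0L)
  if (min_targets_passing > length(select_targets))
    abort("min_targets_passing exceeds the number of selected targets")
  sub <- dm$values[, select_targets, drop = FALSE]
  npass <- apply(sub, 1L, count_passing_targets, threshold = threshold)
  dm$drugs[npass >= min_targets_passing]
}

#' Rank drugs or targets by aggregate binding strength
#'
#' Orders one axis of the matrix by the sum of its affinities: descending
#' binding strength means ascending algebraic sum (most negative total
#' first). Ties are broken lexicographically by id.
#'
#' @param dm a [docking_matrix()].
#' @param axis `"drugs"` (sum each drug's row over all targets) or
#'   `"targets"` (sum each target's column over all drugs).
#' @return character vector of ids, strongest aggregate binder first.
#' @export
rank_by_aggregate <- function(dm, axis = c("drugs", "targets")) {
  stopifnot(inherits(dm, "docking_matrix"))
  axis <- match.arg(axis)
  if (anyNA(dm$values)) abort("aggregate ranking needs a complete grid")
  if (axis == "drugs") {
    s <- rowSums(dm$values); ids <- dm$drugs
  } else {
    s <- colSums(dm$values); ids <- dm$targets
  }
  ids[order(s, ids)]
}

#' Compare docking scores between two engines
#'
#' Restricted to the drugs and targets shared by both matrices: per-pair
#' affinity deltas (`b - a`), per-target Spearman rank correlation over
#' shared drugs, and a top-k concordance flag per target (true iff the
#' top-k strongest-binding drug sets intersect in at least ceiling(k/2)
#' members).
#'
#' @param a,b [docking_matrix()] objects.
#' @param top_k size of the per-target top list for the concordance flag.
#' @return list of class `engine_comparison`: `targets`, `spearman_rho`
#'   (NA and flagged when < 3 shared drugs have values), `deltas`
#'   (matrix `b - a`), `concordant_top_k` (logical per target), `top_k`.
#' @export
compare_engines <- function(a, b, top_k = 3L) {
  stopifnot(inherits(a, "docking_matrix"), inherits(b, "docking_matrix"))
  top_k <- assert_count(top_k, "top_k")
  drugs <- intersect(a$drugs, b$drugs)
  targets <- intersect(a$targets, b$targets)
  if (!length(drugs) || !length(targets))
    abort("engines share no drugs/targets")
  av <- a$values[drugs, targets, drop = FALSE]
  bv <- b$values[drugs, targets, drop = FALSE]
  rho <- conc <- stats::setNames(rep(NA_real_, length(targets)), targets)
  for (tg in targets) {
    ok <- !is.na(av[, tg]) & !is.na(bv[, tg])
    if (sum(ok) >= 3L)
      rho[[tg]] <- stats::cor(av[ok, tg], bv[ok, tg], method = "spearman")
    k <- min(top_k, sum(ok))
    ta <- drugs[ok][order(av[ok, tg])][seq_len(k)]
    tb <- drugs[ok][order(bv[ok, tg])][seq_len(k)]
    conc[[tg]] <- length(intersect(ta, tb)) >= ceiling(k / 2)
  }
  structure(list(targets = targets, spearman_rho = rho,
                 deltas = bv - av, concordant_top_k = conc == 1,
                 undefined_rho = targets[is.na(rho)], top_k = top_k),
            class = "engine_comparison")
}
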