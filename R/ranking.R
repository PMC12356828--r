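## Integrative candidate ranking: pharmacokinetic gates on the CNS
## profiles, then a stable multi-key sort of the MD stability table.

#' Ranking policy
#'
#' The gates and sort order used to turn per-complex metrics into a ranked
#' report. The default policy is the minimal explicit rule set that
#' mirrors a CNS-first triage: drop drugs that are not predicted
#' BBB-permeable, drop likely P-gp substrates, then sort the survivors by
#' protein RMSD (ascending: most stable complex first), breaking ties by
#' hydrogen-bond count (descending) then logBB (descending), and finally
#' lexicographically by complex id.
#'
#' @param require_permeable drop drugs whose computed permeability bin is
#'   below Moderate (default `TRUE`).
#' @param exclude_pgp drop predicted P-gp substrates (default `TRUE`).
#' @param require_safety_window additionally require the LogP/TPSA safety
#'   window (default `FALSE`).
#' @param sort_keys ordered subset of `"protein_rmsd"` (ascending),
#'   `"hbond_count"` (descending), `"logbb"` (descending).
#' @return a list of class `ranking_policy`.
#' @export
ranking_policy <- function(require_permeable = TRUE, exclude_pgp = TRUE,
                           require_safety_window = FALSE,
                           sort_keys = c("protein_rmsd", "hbond_count",
                                         "logbb")) {
  allowed <- c("protein_rmsd", "hbond_count", "logbb")
  if (!length(sort_keys) || !all(sort_keys %in% allowed))
    abort(sprintf("sort_keys must be a non-empty subset of {%s}",
                  paste(allowed, collapse = ", ")))
  structure(list(require_permeable = isTRUE(require_permeable),
                 exclude_pgp = isTRUE(exclude_pgp),
                 require_safety_window = isTRUE(require_safety_window),
                 sort_keys = sort_keys), class = "ranking_policy")
}

#' Apply pharmacokinetic gates to drug profiles
#'
#' @param profiles a `cns_profile` data.frame ([profile_drugs()]).
#' @param policy a [ranking_policy()].
#' @param drugs drugs under consideration; default all profiled drugs. A
#'   drug without a profile is an error naming it.
#' @return list: `admitted` (drug ids), `exclusions` (data.frame drug,
#'   reason; one row per excluded drug, reasons joined by "; ").
#' @export
apply_gates <- function(profiles, policy = ranking_policy(), drugs = NULL) {
  stopifnot(is.data.frame(profiles))
  drugs <- drugs %||% profiles$drug
  missing <- setdiff(drugs, profiles$drug)
  if (length(missing))
    abort(sprintf("no CNS profile for drug '%s'", missing[[1L]]))
  pr <- profiles[match(drugs, profiles$drug), , drop = FALSE]
  reasons <- lapply(seq_along(drugs), function(i) {
    r <- character()
    if (policy$require_permeable && !pr$bbb_permeable[[i]])
      r <- c(r, sprintf("not BBB-permeable (logBB %.2f below Moderate)",
                        pr$logbb_2dp[[i]]))
    if (policy$exclude_pgp && pr$pgp_substrate[[i]])
      r <- c(r, "likely P-gp substrate (efflux from brain)")
    if (policy$require_safety_window && !isTRUE(pr$in_safety_window[[i]]))
      r <- c(r, "outside LogP/TPSA safety window")
    r
  })
  excluded <- lengths(reasons) > 0L
  list(admitted = drugs[!excluded],
       exclusions = data.frame(
         drug = drugs[excluded],
         reason = vapply(reasons[excluded], paste, character(1L),
                         collapse = "; "),
         stringsAsFactors = FALSE))
}

#' Rank drug-target complexes by stability and pharmacokinetics
#'
#' Joins the MD stability table with the drug CNS profiles, applies the
#' policy's gates, and produces a deterministic ranked report. Every input
#' complex appears exactly once, either ranked or excluded with a reason.
#'
#' @param md data.frame with one row per complex: `complex`, `drug`,
#'   `target`, `protein_rmsd_mean` and optionally `hbond_mean` and other
#'   metrics. Metrics named by the policy's sort keys must be present.
#' @param profiles a `cns_profile` data.frame covering every drug in `md`.
#' @param policy a [ranking_policy()].
#' @return a list of class `candidate_report`: `ranked` (data.frame with
#'   `rank` first), `excluded` (complex, drug, reason), `policy`.
#' @export
rank_candidates <- function(md, profiles, policy = ranking_policy()) {
  stopifnot(is.data.frame(md))
  for (f in c("complex", "drug"))
    if (is.null(md[[f]])) abort(sprintf("MD table is missing column '%s'", f))
  key_col <- c(protein_rmsd = "protein_rmsd_mean", hbond_count = "hbond_mean",
               logbb = "logbb")
  gates <- apply_gates(profiles, policy, drugs = unique(md$drug))
  pr <- profiles[match(md$drug, profiles$drug), , drop = FALSE]
  tab <- cbind(md, logbb = pr$logbb, logbb_2dp = pr$logbb_2dp, bin = pr$bin,
               pgp_substrate = pr$pgp_substrate,
               bbb_permeable = pr$bbb_permeable)
  for (k in policy$sort_keys)
    if (is.null(tab[[key_col[[k]]]]))
      abort(sprintf("sort key metric '%s' missing from table", key_col[[k]]))
  admitted <- tab[tab$drug %in% gates$admitted, , drop = FALSE]
  excl <- tab[!tab$drug %in% gates$admitted, c("complex", "drug"),
              drop = FALSE]
  excl$reason <- gates$exclusions$reason[match(excl$drug,
                                               gates$exclusions$drug)]
  if (nrow(admitted)) {
    keys <- lapply(policy$sort_keys, function(k) {
      v <- admitted[[key_col[[k]]]]
      if (k == "protein_rmsd") v else -v      # others sort descending
    })
    ord <- do.call(order, c(keys, list(admitted$complex)))
    admitted <- admitted[ord, , drop = FALSE]
    admitted <- cbind(rank = seq_len(nrow(admitted)), admitted)
  } else {
    admitted <- cbind(rank = integer(), admitted)
  }
  rownames(admitted) <- NULL; rownames(excl) <- NULL
  structure(list(ranked = admitted, excluded = excl, policy = policy),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report: %d ranked, %d excluded\n",
              nrow(x$ranked), nrow(x$excluded)))
  if (nrow(x$ranked))
    print(utils::head(x$ranked[, intersect(
      c("rank", "complex", "protein_rmsd_mean", "hbond_mean", "logbb_2dp"),
      names(x$ranked))], 5L))
  invisible(x)
}

#' Serialize / parse a candidate report
#'
#' `build_report` writes the report as TSV (two sections, `#ranked` and
#' `#excluded`) or JSON (matching the schema shipped in
#' `inst/schema/candidate_report.schema.json`); `parse_report` inverts it,
#' so that `parse_report(build_report(r, f), f)` reproduces the tables.
#'
#' @param report a `candidate_report`.
#' @param format `"tsv"` or `"json"`.
#' @param path optional output file; when `NULL` the serialized text is
#'   returned.
#' @return serialized character scalar (invisibly when written to `path`).
#' @export
build_report <- function(report, format = c("tsv", "json"), path = NULL) {
  stopifnot(inherits(report, "candidate_report"))
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(
      list(policy = unclass(report$policy), ranked = report$ranked,
           excluded = report$excluded, n_ranked = nrow(report$ranked),
           provenance = attr(report, "provenance") %||% "computed"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- as.character(txt)
  } else {
    ser <- function(df) paste(c(paste(names(df), collapse = "\t"),
                                do.call(paste, c(lapply(df, as.character),
                                                 sep = "\t"))),
                              collapse = "\n")
    txt <- paste0("#ranked\n", ser(report$ranked),
                  "\n#excluded\n", ser(report$excluded), "\n")
  }
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Validate a JSON report against the shipped schema
#'
#' Lightweight structural validator mirroring
#' `inst/schema/candidate_report.schema.json` (required keys, types, rank
#' positivity); no external JSON-Schema engine is needed.
#'
#' @param text JSON text (or a path to a JSON file).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_report_json <- function(text) {
  if (length(text) == 1L && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE)
  for (k in c("policy", "ranked", "excluded", "n_ranked"))
    if (is.null(obj[[k]])) abort(sprintf("report JSON missing key '%s'", k))
  for (k in c("require_permeable", "exclude_pgp", "sort_keys"))
    if (is.null(obj$policy[[k]]))
      abort(sprintf("report policy missing key '%s'", k))
  if (!is.numeric(obj$n_ranked) || obj$n_ranked < 0)
    abort("n_ranked must be a non-negative integer")
  ranked <- as.data.frame(obj$ranked)
  if (nrow(ranked)) {
    for (k in c("rank", "complex", "drug"))
      if (is.null(ranked[[k]]))
        abort(sprintf("ranked entries missing key '%s'", k))
    if (any(ranked$rank < 1)) abort("ranks must be >= 1")
  }
  if (nrow(ranked) != obj$n_ranked) abort("n_ranked disagrees with ranked")
  invisible(TRUE)
}

#' @rdname build_report
#' @param text serialized report (or a path to one).
#' @export
parse_report <- function(text, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (length(text) == 1L && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  if (format == "json") {
    obj <- jsonlite::fromJSON(text)
    ranked <- as.data.frame(obj$ranked)
    excluded <- as.data.frame(obj$excluded)
    pol <- do.call(ranking_policy, obj$policy)
  } else {
    lines <- strsplit(text, "\n")[[1L]]
    sec <- cumsum(grepl("^#", lines))
    read_sec <- function(i) {
      body <- lines[sec == i & !grepl("^#", lines)]
      utils::read.table(text = body, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    }
    ranked <- read_sec(1L); excluded <- read_sec(2L)
    pol <- ranking_policy()
  }
  structure(list(ranked = ranked, excluded = excluded, policy = pol),
            class = "candidate_report")
}
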