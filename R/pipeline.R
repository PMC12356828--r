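## End-to-end orchestration: packaged as-printed fixtures, a validated
## config object, and the run-all driver binding every stage.

#' Packaged as-printed fixtures
#'
#' Loads the three small tables shipped with the package: the
#' drug x target docking-affinity matrix for the 12 candidate drugs
#' against the five selected regulator targets (APP, PAX6, ZEB2, ETV6,
#' ST18), the per-drug physicochemical descriptor table with its printed
#' pharmacokinetic flags, and the per-complex MD stability summary
#' (means, SDs where printed, `NA` where the source prints none). All
#' values carry "as-printed" provenance: they are inputs, never
#' recomputed in place. Note the descriptor table's printed BBB flag for
#' Olaparib (1, with logBB -0.78) contradicts any logBB-threshold rule
#' and is retained verbatim; computed flags come from [profile_drugs()].
#' The printed protein SASA values near 87 are implausibly small for a
#' protein in Angstrom^2 and are stored units-as-printed.
#'
#' @return list: `table1` (a [docking_matrix()], engine "vina"),
#'   `table2` (descriptor data.frame), `md_summary` (data.frame).
#' @export
paper_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "cnstriage",
                                 mustWork = TRUE)
  table2 <- load_table(ext("table2_descriptors.tsv"),
                       required_cols = c("drug", "logp", "tpsa"),
                       numeric_cols = c("logp", "tpsa", "mw", "pka", "logd",
                                        "pgp_printed", "bbb_printed",
                                        "logbb_printed", "der_targets_gt7"))
  md <- load_table(ext("md_summary.tsv"),
                   required_cols = c("complex", "drug", "target",
                                     "protein_rmsd_mean"),
                   numeric_cols = c("protein_rmsd_mean", "protein_rmsd_sd",
                                    "hbond_mean", "hbond_sd", "protein_sasa",
                                    "ligand_sasa", "logbb_printed"))
  list(table1 = read_docking_matrix(ext("table1_docking.tsv"),
                                    engine = "vina"),
       table2 = table2, md_summary = md)
}

#' The five selected regulator targets for docking triage
#'
#' @format character vector of five target ids.
#' @export
SELECT_TARGETS <- c("APP", "ZEB2", "PAX6", "ETV6", "ST18")

#' Pipeline configuration
#'
#' Validated bag of stage settings; unknown keys are rejected before any
#' stage runs, and every threshold is echoed into the run log.
#'
#' @param seed global RNG seed; stage seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @param simulate run the synthetic regulator-calling arm (default
#'   `TRUE`); with `FALSE` the pipeline is fixture-only.
#' @param activity_spec an [activity_sim_spec()] for the synthetic arm;
#'   `NULL` uses defaults with 10 planted regulators.
#' @param fdr_threshold,min_abs_association DER-calling gates.
#' @param dock_threshold,min_targets_passing docking-triage gates.
#' @param policy a [ranking_policy()].
#' @param ... unknown keys: rejected.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("cnstriage_run_"),
                            simulate = TRUE, activity_spec = NULL,
                            fdr_threshold = 0.05, min_abs_association = 1.5,
                            dock_threshold = -7.0, min_targets_passing = 1L,
                            policy = ranking_policy(), ...) {
  extra <- list(...)
  if (length(extra))
    abort(sprintf("unknown config key '%s'", names(extra)[[1L]]),
          "cnstriage_invalid_spec")
  structure(list(seed = assert_count(seed, "seed", min = 0L),
                 out_dir = out_dir, simulate = isTRUE(simulate),
                 activity_spec = activity_spec,
                 fdr_threshold = fdr_threshold,
                 min_abs_association = min_abs_association,
                 dock_threshold = assert_number(dock_threshold, "dock_threshold"),
                 min_targets_passing = min_targets_passing,
                 policy = policy),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order, each consuming the previous stage's
#' declared outputs: (1) optional synthetic regulator-calling arm
#' (simulate activity, call DERs); (2) docking triage of the packaged
#' affinity matrix against the five selected targets; (3) CNS profiling of
#' the packaged descriptor table; (4) gated integrative ranking against
#' the packaged MD stability summary; (5) serialization of every output
#' with checksums. A failure halts with the stage name in the error.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `report`
#'   (a `candidate_report`), `ders` (or `NULL`), `dock_pass`, `profiles`,
#'   `files` (named paths), `checksums` (md5 per file), `log`
#'   (character, one structured line per stage).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste(sprintf(...), collapse = ""))
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "cnstriage_stage_error"))
  }
  fx <- stage("fixtures", paper_fixtures())
  files <- character()

  ders <- NULL
  if (config$simulate) {
    ders <- stage("call-ders", {
      spec <- config$activity_spec %||%
        activity_sim_spec(n_regulators = 200L, n_metacells_per_group = 40L,
                          planted_up = 1:5, planted_down = 6:10,
                          effect_size = 1.5, seed = config$seed)
      spec$seed <- config$seed
      am <- generate_activity_matrix(spec)
      call_ders(am, fdr_threshold = config$fdr_threshold,
                min_abs_association = config$min_abs_association)
    })
    files[["ders"]] <- file.path(config$out_dir, "ders.tsv")
    write_table(ders, files[["ders"]])
    note("call-ders", "fdr=%g min_score=%g significant=%d/%d",
         config$fdr_threshold, config$min_abs_association,
         sum(ders$significant), nrow(ders))
  }

  dock_pass <- stage("dock-filter",
    filter_candidates(fx$table1, select_targets = SELECT_TARGETS,
                      threshold = config$dock_threshold,
                      min_targets_passing = config$min_targets_passing))
  files[["dock_pass"]] <- file.path(config$out_dir, "dock_pass.tsv")
  write_table(data.frame(drug = dock_pass), files[["dock_pass"]])
  note("dock-filter", "threshold=%g min_pass=%d passed=%d/%d",
       config$dock_threshold, config$min_targets_passing,
       length(dock_pass), length(fx$table1$drugs))

  profiles <- stage("cns-profile", profile_drugs(fx$table2))
  files[["profiles"]] <- file.path(config$out_dir, "cns_profiles.tsv")
  write_table(profiles, files[["profiles"]])
  note("cns-profile", "profiled=%d permeable=%d pgp=%d", nrow(profiles),
       sum(profiles$bbb_permeable), sum(profiles$pgp_substrate))

  report <- stage("rank", {
    md <- fx$md_summary[fx$md_summary$drug %in% dock_pass, , drop = FALSE]
    rank_candidates(md, profiles, config$policy)
  })
  files[["report_tsv"]] <- file.path(config$out_dir, "report.tsv")
  files[["report_json"]] <- file.path(config$out_dir, "report.json")
  build_report(report, "tsv", files[["report_tsv"]])
  build_report(report, "json", files[["report_json"]])
  note("rank", "ranked=%d excluded=%d top=%s", nrow(report$ranked),
       nrow(report$excluded),
       if (nrow(report$ranked)) report$ranked$complex[[1L]] else "none")

  files[["log"]] <- file.path(config$out_dir, "run.log")
  writeLines(log, files[["log"]])
  checksums <- tools::md5sum(unname(files[names(files) != "log"]))
  structure(list(report = report, ders = ders, dock_pass = dock_pass,
                 profiles = profiles, files = files, checksums = checksums,
                 log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(x$log)
  invisible(x)
}
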