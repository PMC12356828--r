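## CNS / blood-brain-barrier profiling from physicochemical descriptors:
## Clark logBB model, permeability bins, P-gp efflux rule, and the safety
## and lipophilicity windows used to judge CNS suitability.

#' The Clark empirical logBB model
#'
#' Linear model of the blood-brain partition coefficient from lipophilicity
#' and polar surface area: `logBB = 0.152 LogP - 0.0148 TPSA + 0.139`.
#' The constants are fixed; override them only deliberately.
#'
#' @param logp_coeff,tpsa_coeff,intercept model coefficients.
#' @return a list of class `clark_model`.
#' @export
clark_model <- function(logp_coeff = 0.152, tpsa_coeff = -0.0148,
                        intercept = 0.139) {
  structure(list(logp_coeff = logp_coeff, tpsa_coeff = tpsa_coeff,
                 intercept = intercept), class = "clark_model")
}

#' Compute logBB from LogP and TPSA
#'
#' @param logp octanol-water partition coefficient(s).
#' @param tpsa topological polar surface area(s), Angstrom^2.
#' @param model a [clark_model()].
#' @return raw (unrounded) logBB values. The reporting layer rounds to two
#'   decimals with [round_half_away()].
#' @examples
#' compute_logbb(4.95, 12.47)  # 0.7068 -> printed as 0.71
#' @export
compute_logbb <- function(logp, tpsa, model = clark_model()) {
  if (any(!is.finite(logp)) || any(!is.finite(tpsa)))
    abort("logp and tpsa must be finite")
  model$logp_coeff * logp + model$tpsa_coeff * tpsa + model$intercept
}

# Bin edges, upper-category inclusive at every boundary.
.logbb_breaks <- c(0.7, 0.3, -0.3, -0.7)
.logbb_levels <- c("Very high", "High", "Moderate", "Low", "Very low")

#' Classify logBB into permeability bins
#'
#' Bins partition the real line; boundary values map to the higher
#' category: `>= 0.7` Very high, `[0.3, 0.7)` High, `[-0.3, 0.3)`
#' Moderate, `[-0.7, -0.3)` Low, `< -0.7` Very low.
#'
#' @param logbb numeric vector.
#' @return character vector of categories.
#' @export
classify_logbb <- function(logbb) {
  if (any(!is.finite(logbb))) abort("logbb must be finite")
  idx <- 1L + rowSums(outer(logbb, .logbb_breaks, `<`))
  .logbb_levels[idx]
}

#' P-glycoprotein efflux-liability rule
#'
#' A drug is flagged as a likely P-gp substrate iff `LogP > 4` AND
#' `TPSA < 75` (both inequalities strict).
#'
#' @param logp,tpsa descriptor vectors.
#' @param logp_min,tpsa_max rule thresholds.
#' @return logical vector.
#' @export
predict_pgp <- function(logp, tpsa, logp_min = 4, tpsa_max = 75) {
  if (any(!is.finite(logp)) || any(!is.finite(tpsa)))
    abort("logp and tpsa must be finite")
  logp > logp_min & tpsa < tpsa_max
}

#' CNS safety and toxicity property windows
#'
#' Default windows (all bounds inclusive): the favourable safety-risk space
#' `LogP in [3, 4]` and `TPSA in [60, 75]` A^2, and the low-toxicity
#' lipophilicity window `LogD(7.4) in [1, 3]` and `LogP in [2, 4]`.
#'
#' @param safety_logp,safety_tpsa,tox_logd,tox_logp length-2 numeric
#'   intervals `c(lo, hi)`.
#' @return a list of class `cns_windows`.
#' @export
cns_windows <- function(safety_logp = c(3, 4), safety_tpsa = c(60, 75),
                        tox_logd = c(1, 3), tox_logp = c(2, 4)) {
  chk <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x)) || x[1L] > x[2L])
      abort(sprintf("`%s` must be an ordered interval c(lo, hi)", nm))
    x
  }
  structure(list(safety_logp = chk(safety_logp, "safety_logp"),
                 safety_tpsa = chk(safety_tpsa, "safety_tpsa"),
                 tox_logd = chk(tox_logd, "tox_logd"),
                 tox_logp = chk(tox_logp, "tox_logp")),
            class = "cns_windows")
}

#' Membership in the CNS safety and toxicity windows
#'
#' @param logp,tpsa,logd descriptor vectors; `logd` may be `NA`, in which
#'   case the toxicity flag is `NA`.
#' @param windows a [cns_windows()].
#' @return data.frame with logical columns `in_safety_window`,
#'   `in_tox_window`.
#' @export
window_membership <- function(logp, tpsa, logd = NA_real_,
                              windows = cns_windows()) {
  inw <- function(x, w) x >= w[1L] & x <= w[2L]
  data.frame(
    in_safety_window = inw(logp, windows$safety_logp) &
      inw(tpsa, windows$safety_tpsa),
    in_tox_window = inw(logd, windows$tox_logd) & inw(logp, windows$tox_logp))
}

#' Full CNS profile for a descriptor table
#'
#' Composes [compute_logbb()], [classify_logbb()], [predict_pgp()] and
#' [window_membership()] over a table of per-drug descriptors. BBB
#' permeability is defined from the computed bin: permeable iff the bin is
#' Moderate or better (logBB >= -0.3). Where a source table prints its own
#' flag it is kept separately as provenance, never overwritten.
#'
#' @param descriptors data.frame with columns `drug`, `logp`, `tpsa`, and
#'   optionally `logd`, `mw`, `pka` (case-insensitive names accepted).
#' @param model a [clark_model()].
#' @param windows a [cns_windows()].
#' @return data.frame of class `cns_profile`: drug, logbb (raw),
#'   logbb_2dp, bin, pgp_substrate, in_safety_window, in_tox_window,
#'   bbb_permeable.
#' @export
profile_drugs <- function(descriptors, model = clark_model(),
                          windows = cns_windows()) {
  names(descriptors) <- tolower(names(descriptors))
  for (f in c("drug", "logp", "tpsa"))
    if (is.null(descriptors[[f]]))
      abort(sprintf("descriptor table is missing field '%s'", f))
  logd <- descriptors$logd %||% rep(NA_real_, nrow(descriptors))
  logbb <- compute_logbb(descriptors$logp, descriptors$tpsa, model)
  bin <- classify_logbb(logbb)
  wm <- window_membership(descriptors$logp, descriptors$tpsa, logd, windows)
  out <- data.frame(
    drug = descriptors$drug,
    logbb = logbb,
    logbb_2dp = round_half_away(logbb, 2L),
    bin = bin,
    pgp_substrate = predict_pgp(descriptors$logp, descriptors$tpsa),
    in_safety_window = wm$in_safety_window,
    in_tox_window = wm$in_tox_window,
    bbb_permeable = bin %in% c("Very high", "High", "Moderate"),
    stringsAsFactors = FALSE)
  class(out) <- c("cns_profile", "data.frame")
  out
}

#' Profile a single drug record
#'
#' Single-record convenience wrapper around [profile_drugs()].
#'
#' @param drug id; @param logp,tpsa required descriptors;
#' @param logd,mw,pka optional descriptors.
#' @inheritParams profile_drugs
#' @return one-row `cns_profile` data.frame.
#' @export
profile_drug <- function(drug, logp, tpsa, logd = NA_real_, mw = NA_real_,
                         pka = NA_real_, model = clark_model(),
                         windows = cns_windows()) {
  if (missing(drug)) abort("descriptor record is missing field 'drug'")
  if (missing(logp)) abort("descriptor record is missing field 'logp'")
  if (missing(tpsa)) abort("descriptor record is missing field 'tpsa'")
  profile_drugs(data.frame(drug = drug, logp = logp, tpsa = tpsa,
                           logd = logd, mw = mw, pka = pka,
                           stringsAsFactors = FALSE),
                model = model, windows = windows)
}
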