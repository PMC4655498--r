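# Evidence model: baseline event rates and relative risks per outcome,
# loaded from structured YAML/JSON and validated before any computation.

#' The six modelled outcomes
#'
#' Outcome identifiers used throughout the model, in reporting order:
#' postpartum haemorrhage (blood loss >= 500 mL), severe PPH (>= 1000 mL),
#' use of additional uterotonics, blood transfusion, shivering and fever.
#' Maternal death, hysterectomy, manual removal of placenta and
#' nausea/vomiting/diarrhoea are outside the model's scope.
#'
#' @return Character vector of the six outcome identifiers.
#' @export
outcome_ids <- function() {
  c("pph", "severe_pph", "additional_uterotonics",
    "blood_transfusion", "shivering", "fever")
}

#' Human-readable outcome labels
#' @return Named character vector mapping outcome ids to display labels.
#' @export
outcome_labels <- function() {
  c(pph = "PPH",
    severe_pph = "Severe PPH",
    additional_uterotonics = "Additional uterotonics",
    blood_transfusion = "Blood transfusion",
    shivering = "Shivering",
    fever = "Fever")
}

evidence_contexts <- function() c("placebo", "oxytocin")
evidence_comparisons <- function() c("misoprostol_vs_oxytocin", "misoprostol_vs_placebo")

as_estimate <- function(x, what, where) {
  if (!is.list(x) || is.null(x$point)) {
    stopf("evidence incomplete: %s at %s lacks a point estimate", what, where)
  }
  point <- as.numeric(x$point)
  low <- if (is.null(x$low)) NA_real_ else as.numeric(x$low)
  high <- if (is.null(x$high)) NA_real_ else as.numeric(x$high)
  c(point = point, low = low, high = high)
}

check_estimate <- function(est, where, type = c("rate", "rr")) {
  type <- match.arg(type)
  point <- est[["point"]]; low <- est[["low"]]; high <- est[["high"]]
  if (type == "rate") {
    ok <- point >= 0 && point <= 1 &&
      (is.na(low) || (low >= 0 && low <= point)) &&
      (is.na(high) || (high >= point && high <= 1))
    if (!ok) stopf("invalid rate estimate at %s: need 0 <= low <= point <= high <= 1", where)
  } else {
    ok <- point > 0 &&
      (is.na(low) || (low > 0 && low <= point)) &&
      (is.na(high) || high >= point)
    if (!ok) stopf("invalid relative-risk estimate at %s: need 0 < low <= point <= high", where)
  }
  invisible(est)
}

#' Construct an evidence set
#'
#' An evidence set couples baseline event rates per treatment context
#' (`placebo`, `oxytocin`) with pooled relative risks per comparison
#' (`misoprostol_vs_placebo`, `misoprostol_vs_oxytocin`), each outcome
#' carrying a point estimate and optional low/high bounds. Every context
#' and comparison that is present must cover all six outcomes; a source
#' may omit a whole context or comparison (e.g. a community-only review
#' has no oxytocin arm).
#'
#' @param source_label Short label identifying the evidence source.
#' @param baseline_rates Named list: context -> (outcome -> list(point, low, high)),
#'   rates as proportions in \[0, 1\].
#' @param relative_risks Named list: comparison -> (outcome -> list(point, low, high)),
#'   positive risk ratios; low/high are 95% confidence limits.
#' @return An object of class `evidence_set`.
#' @seealso [read_evidence()], [tuncalp_evidence()], [hundley_evidence()]
#' @export
evidence_set <- function(source_label, baseline_rates, relative_risks) {
  if (!is.character(source_label) || length(source_label) != 1L) {
    stopf("source_label must be a single string")
  }
  bad_ctx <- setdiff(names(baseline_rates), evidence_contexts())
  if (length(bad_ctx)) stopf("unknown baseline context: %s", paste(bad_ctx, collapse = ", "))
  bad_cmp <- setdiff(names(relative_risks), evidence_comparisons())
  if (length(bad_cmp)) stopf("unknown comparison: %s", paste(bad_cmp, collapse = ", "))

  norm_block <- function(block, kind, type) {
    out <- list()
    for (nm in names(block)) {
      entries <- block[[nm]]
      missing <- setdiff(outcome_ids(), names(entries))
      if (length(missing)) {
        stopf("evidence incomplete: %s '%s' lacks outcome(s) %s",
              kind, nm, paste(missing, collapse = ", "))
      }
      out[[nm]] <- lapply(setNames(outcome_ids(), outcome_ids()), function(oc) {
        where <- sprintf("%s/%s/%s", source_label, nm, oc)
        check_estimate(as_estimate(entries[[oc]], kind, where), where, type)
      })
    }
    out
  }

  structure(
    list(source_label = source_label,
         baseline_rates = norm_block(baseline_rates, "context", "rate"),
         relative_risks = norm_block(relative_risks, "comparison", "rr")),
    class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat("<evidence_set>", x$source_label, "\n")
  cat("  baseline contexts:", paste(names(x$baseline_rates), collapse = ", "), "\n")
  cat("  comparisons:      ", paste(names(x$relative_risks), collapse = ", "), "\n")
  invisible(x)
}

#' Read an evidence set from a YAML or JSON file
#'
#' The file must contain `source_label`, `baseline_rates.{placebo,oxytocin}`
#' and `relative_risks.{misoprostol_vs_placebo,misoprostol_vs_oxytocin}`
#' sections (contexts/comparisons may be omitted wholesale), each outcome
#' giving `point`/`low`/`high`. Validation failures name the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [evidence_set()].
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stopf("evidence file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("source_label", "baseline_rates", "relative_risks")) {
    if (is.null(raw[[key]])) stopf("evidence file %s lacks required key '%s'", path, key)
  }
  evidence_set(raw$source_label, raw$baseline_rates, raw$relative_risks)
}

evidence_file <- function(name) {
  system.file("extdata", name, package = "pphcca", mustWork = TRUE)
}

#' Packaged evidence sets
#'
#' `tuncalp_evidence()` returns the primary evidence set (mixed
#' hospital/community trials): placebo and oxytocin baseline rates plus
#' relative risks for misoprostol vs placebo and vs oxytocin.
#' `hundley_evidence()` returns the alternative home-birth evidence set:
#' placebo rates and misoprostol-vs-placebo relative risks only.
#'
#' @return An [evidence_set()].
#' @export
tuncalp_evidence <- function() read_evidence(evidence_file("evidence_tuncalp.yaml"))

#' @rdname tuncalp_evidence
#' @export
hundley_evidence <- function() read_evidence(evidence_file("evidence_hundley.yaml"))

#' Look up an evidence set by source label
#' @param label One of `"tuncalp2012"` or `"hundley2013"`.
#' @return An [evidence_set()].
#' @export
evidence_by_label <- function(label) {
  switch(label,
         tuncalp2012 = tuncalp_evidence(),
         hundley2013 = hundley_evidence(),
         stopf("unknown evidence source label: %s", label))
}

lookup_estimate <- function(block, group, item, bound, kind) {
  entry <- block[[group]]
  if (is.null(entry)) stopf("evidence incomplete: no %s '%s'", kind, group)
  est <- entry[[item]]
  if (is.null(est)) stopf("evidence incomplete: %s '%s' lacks outcome '%s'", kind, group, item)
  val <- est[[match_bound(bound)]]
  if (is.na(val)) stopf("evidence incomplete: %s '%s'/'%s' has no '%s' bound", kind, group, item, bound)
  val
}

#' Retrieve a baseline event rate
#'
#' @param evidence An [evidence_set()].
#' @param context Treatment context: `"placebo"` or `"oxytocin"`.
#' @param outcome One of [outcome_ids()].
#' @param bound `"point"`, `"low"` or `"high"`.
#' @return The stored proportion, unchanged.
#' @export
get_rate <- function(evidence, context, outcome, bound = "point") {
  stopifnot(inherits(evidence, "evidence_set"))
  lookup_estimate(evidence$baseline_rates, context, outcome, bound, "context")
}

#' Retrieve a relative risk
#'
#' @inheritParams get_rate
#' @param comparison `"misoprostol_vs_placebo"` or `"misoprostol_vs_oxytocin"`.
#' @return The stored risk ratio, unchanged.
#' @export
get_rr <- function(evidence, comparison, outcome, bound = "point") {
  stopifnot(inherits(evidence, "evidence_set"))
  lookup_estimate(evidence$relative_risks, comparison, outcome, bound, "comparison")
}

#' Overlay one evidence source on another
#'
#' Returns an evidence set in which every context and comparison present in
#' `overlay` replaces the corresponding block of `base`, while blocks absent
#' from `overlay` fall through to `base`. Used by the evidence-source
#' sensitivity substitution: a community-only source that prints no oxytocin
#' rates still needs the base source's oxytocin cells to evaluate the
#' hospital arm (those cells cancel in the base-case increments).
#'
#' @param overlay,base [evidence_set()] objects; `overlay` wins.
#' @return An [evidence_set()] labelled `"<overlay>+<base>"`.
#' @export
merge_evidence <- function(overlay, base) {
  stopifnot(inherits(overlay, "evidence_set"), inherits(base, "evidence_set"))
  unpack <- function(block) lapply(block, function(grp) lapply(grp, as.list))
  br <- modifyList(unpack(base$baseline_rates), unpack(overlay$baseline_rates))
  rr <- modifyList(unpack(base$relative_risks), unpack(overlay$relative_risks))
  evidence_set(paste0(overlay$source_label, "+", base$source_label), br, rr)
}
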