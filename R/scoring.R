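#' Risk rules and composite risk definitions
#'
#' A risk definition is a named list of binary rules; a patient's composite
#' prognostic score is the number of rules satisfied (0 up to the number of
#' rules, 4 in the standard definitions). Rule types:
#' \describe{
#'   \item{`le`}{risk when `value <= cutoff` (boundary equality counts as
#'     risk, matching the printed "<=" inequalities).}
#'   \item{`gt`}{risk when `value > cutoff` (boundary excluded).}
#'   \item{`eq`}{risk when the (categorical/logical) value equals `level`.}
#' }
#'
#' @param variable Column name on the patient record.
#' @param type One of `"le"`, `"gt"`, `"eq"`.
#' @param cutoff Numeric cutoff for `le` / `gt` rules.
#' @param level Value that counts as risk for `eq` rules.
#' @return A `risk_rule`; `risk_definition` bundles rules with an endpoint
#'   label.
#' @export
risk_rule <- function(variable, type = c("le", "gt", "eq"), cutoff = NULL,
                      level = NULL) {
  type <- match.arg(type)
  if (type %in% c("le", "gt") && (is.null(cutoff) || !is.finite(cutoff)))
    stop("numeric 'cutoff' required for rule type '", type, "'")
  if (type == "eq" && is.null(level))
    stop("'level' required for rule type 'eq'")
  structure(list(variable = variable, type = type, cutoff = cutoff,
                 level = level),
            class = "risk_rule")
}

#' @rdname risk_rule
#' @param endpoint Endpoint label, `"OS"` or `"RFS"`.
#' @param ... `risk_rule` objects.
#' @export
risk_definition <- function(endpoint = c("OS", "RFS"), ...) {
  endpoint <- match.arg(endpoint)
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1]]) &&
      !inherits(rules[[1]], "risk_rule")) rules <- rules[[1]]
  stopifnot(all(vapply(rules, inherits, logical(1), "risk_rule")))
  structure(list(endpoint = endpoint, rules = rules),
            class = "risk_definition")
}

#' Standard composite risk definitions
#'
#' The multivariate risk factors of the overall-survival system (smoking;
#' K^trans <= 0.5512 min^-1; K_ep <= 0.8872 min^-1; NGLCM uniformity
#' <= 0.00381 at 32 bins), the recurrence-free-survival system
#' (hypopharyngeal subsite; alcohol drinking; the same K^trans and K_ep
#' cutoffs), and the earlier two-factor system used for comparison
#' (K_ep <= 0.887; SUV > 14.22 g/mL).
#'
#' @return A `risk_definition`.
#' @export
os_risk_definition <- function() {
  risk_definition("OS",
    risk_rule("smoking", "eq", level = TRUE),
    risk_rule("ktrans", "le", cutoff = 0.5512),
    risk_rule("kep", "le", cutoff = 0.8872),
    risk_rule("uniformity", "le", cutoff = 0.00381))
}

#' @rdname os_risk_definition
#' @export
rfs_risk_definition <- function() {
  risk_definition("RFS",
    risk_rule("subsite", "eq", level = "hypopharynx"),
    risk_rule("alcohol", "eq", level = TRUE),
    risk_rule("ktrans", "le", cutoff = 0.5512),
    risk_rule("kep", "le", cutoff = 0.8872))
}

#' @rdname os_risk_definition
#' @export
prior_risk_definition <- function() {
  risk_definition("OS",
    risk_rule("kep", "le", cutoff = 0.887),
    risk_rule("suv", "gt", cutoff = 14.22))
}

rule_satisfied <- function(rule, record) {
  if (!rule$variable %in% names(record))
    stop("record lacks variable '", rule$variable, "'")
  v <- record[[rule$variable]]
  if (length(v) != 1L || is.na(v))
    stop("variable '", rule$variable, "' is missing on the record")
  switch(rule$type,
         le = v <= rule$cutoff,
         gt = v > rule$cutoff,
         eq = identical(as.vector(v), rule$level) || isTRUE(v == rule$level))
}

#' Composite prognostic score for one patient
#'
#' Counts the satisfied risk rules: each factor contributes 1 when present
#' and 0 when absent.
#'
#' @param patient A one-row data frame or named list with the variables the
#'   risk definition references.
#' @param riskdef A `risk_definition`.
#' @return Integer score in `0..length(riskdef$rules)`.
#' @examples
#' pt <- list(smoking = TRUE, ktrans = 1.056, kep = 1.1356,
#'            uniformity = 0.0047)
#' assign_score(pt, os_risk_definition())  # 1
#' @export
assign_score <- function(patient, riskdef) {
  stopifnot(inherits(riskdef, "risk_definition"))
  if (is.data.frame(patient) && nrow(patient) != 1L)
    stop("'patient' must be a single record")
  sum(vapply(riskdef$rules, rule_satisfied, logical(1), record = patient))
}

#' Score a whole cohort
#'
#' @param cohort Data frame of patient records.
#' @param riskdef A `risk_definition`.
#' @return Integer vector of per-patient scores.
#' @export
assign_scores <- function(cohort, riskdef) {
  vapply(seq_len(nrow(cohort)), function(i)
    assign_score(cohort[i, , drop = FALSE], riskdef), integer(1))
}

#' Stratified survival comparison by composite score
#'
#' Scores every patient, estimates a Kaplan-Meier curve per occupied score
#' stratum, tests the overall stratum difference by log-rank, and fits a
#' Cox model of the score strata with the worst (highest occupied) stratum
#' as the reference category, reporting per-stratum hazard ratios.
#'
#' @param cohort Data frame with the risk-definition variables plus the
#'   endpoint columns (`os_months`/`os_event` or `rfs_months`/`rfs_event`
#'   according to `riskdef$endpoint`, unless overridden).
#' @param riskdef A `risk_definition`.
#' @param time_col,event_col Optional endpoint column overrides.
#' @return Object of class `score_result`: `score` (per patient), `strata`
#'   (data frame: score, n, events, 3-year survival), `km` (list of
#'   `km_curve` per stratum), `logrank` (overall test), `cox` (per-stratum
#'   HR vs. the reference), `reference` (the reference score).
#' @export
stratify_and_compare <- function(cohort, riskdef, time_col = NULL,
                                 event_col = NULL) {
  stopifnot(inherits(riskdef, "risk_definition"))
  if (is.null(time_col))
    time_col <- if (riskdef$endpoint == "OS") "os_months" else "rfs_months"
  if (is.null(event_col))
    event_col <- if (riskdef$endpoint == "OS") "os_event" else "rfs_event"
  times <- cohort[[time_col]]; events <- cohort[[event_col]]
  score <- assign_scores(cohort, riskdef)
  occ <- sort(unique(score))
  if (length(occ) < 2) stop("only one occupied score stratum")
  km <- lapply(occ, function(s) km_estimate(times[score == s],
                                            events[score == s]))
  names(km) <- as.character(occ)
  surv3 <- vapply(km, function(k) as.numeric(survival_at(k, 36)), numeric(1))
  strata <- data.frame(score = occ,
                       n = as.integer(table(factor(score, levels = occ))),
                       events = vapply(occ, function(s)
                         sum(events[score == s]), numeric(1)),
                       surv_3yr = surv3, row.names = NULL)
  lr <- logrank_test(times, events, score)
  ref <- max(occ)
  fs <- stats::relevel(factor(score, levels = occ), ref = as.character(ref))
  cox <- NULL
  if (sum(events) >= length(occ) - 1)
    cox <- tryCatch(fit_cox(data.frame(stratum = fs), times, events),
                    error = function(e) NULL)
  structure(list(score = score, strata = strata, km = km, logrank = lr,
                 cox = if (is.null(cox)) NULL else cox$coef,
                 reference = ref, endpoint = riskdef$endpoint),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("Composite-score stratification (%s), reference stratum %d\n",
              x$endpoint, x$reference))
  s <- x$strata
  for (i in seq_len(nrow(s)))
    cat(sprintf("  score %d: n = %3d, events = %3d, 3-yr survival = %.1f%%\n",
                s$score[i], s$n[i], s$events[i], 100 * s$surv_3yr[i]))
  cat(sprintf("  overall log-rank chisq = %.3f (df %d), p = %.4g\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  if (!is.null(x$cox)) {
    for (i in seq_len(nrow(x$cox)))
      cat(sprintf("  %s: HR = %.3f (%.3f-%.3f), p = %.4g\n",
                  x$cox$term[i], x$cox$hr[i], x$cox$lower[i],
                  x$cox$upper[i], x$cox$p[i]))
  }
  invisible(x)
}

#' Side-by-side comparison of two scoring systems
#'
#' Applies two risk definitions to the same cohort and reports, for each,
#' the stratum counts, per-stratum hazard ratios against the worst stratum,
#' and the overall log-rank statistic, so the discriminations of the two
#' systems can be compared directly.
#'
#' @param cohort Patient table.
#' @param riskdef_a,riskdef_b The two `risk_definition`s.
#' @param time_col,event_col Endpoint columns (both systems are evaluated
#'   on the same endpoint).
#' @return List of class `system_comparison` with elements `a` and `b`
#'   (each a `score_result`).
#' @export
compare_systems <- function(cohort, riskdef_a, riskdef_b,
                            time_col = "os_months", event_col = "os_event") {
  a <- stratify_and_compare(cohort, riskdef_a, time_col, event_col)
  b <- stratify_and_compare(cohort, riskdef_b, time_col, event_col)
  structure(list(a = a, b = b), class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, ...) {
  cat("=== System A ===\n"); print(x$a)
  cat("=== System B ===\n"); print(x$b)
  invisible(x)
}
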