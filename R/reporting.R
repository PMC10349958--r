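# Cohort aggregation: top-N success rates by CAPRI accuracy level and
# score-vs-accuracy discrimination (ROC AUC).

capri_at_least <- function(cls, min_level) {
  lev <- factor(as.character(cls), levels = CAPRI_LEVELS, ordered = TRUE)
  min_level <- factor(min_level, levels = CAPRI_LEVELS, ordered = TRUE)
  lev >= min_level
}

#' Top-N success rate at a CAPRI accuracy level
#'
#' Percentage of complexes with at least one model of rank <= `top_n`
#' reaching at least `min_level` accuracy.
#'
#' @param records evaluation manifest: data.frame with `complex_id`, `rank`,
#'   `capri_class`.
#' @param top_n number of top-ranked models considered per complex.
#' @param min_level `"Acceptable"`, `"Medium"` or `"High"`.
#' @return percentage in \[0, 100\].
#' @export
success_rate <- function(records, top_n, min_level) {
  if (is.null(records) || nrow(records) == 0) stop("empty record set")
  ok <- records$rank <= top_n & capri_at_least(records$capri_class, min_level)
  hit <- tapply(ok, records$complex_id, any)
  100 * mean(hit)
}

#' Success-rate table over top-N and accuracy levels
#'
#' @param records evaluation manifest (see [success_rate()]).
#' @param top_ns integer vector of N values.
#' @param levels accuracy levels to report.
#' @return data.frame with `top_n`, `min_level`, `success_pct` (one decimal).
#' @export
success_table <- function(records, top_ns = c(1, 5, 25),
                          levels = c("Acceptable", "Medium", "High")) {
  grid <- expand.grid(top_n = top_ns, min_level = levels,
                      stringsAsFactors = FALSE)
  grid$success_pct <- round(mapply(function(n, l) success_rate(records, n, l),
                                   grid$top_n, grid$min_level), 1)
  grid
}

#' ROC AUC (rank-sum formulation)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`, computed with midranks.
#'
#' @param scores numeric scores (higher = more confident positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("both classes must be represented")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Score-discrimination report
#'
#' For each score field: binary AUCs for Incorrect vs High and Incorrect vs
#' Medium-and-High, plus an unweighted macro-average one-vs-rest AUC over
#' the four CAPRI classes. Fields absent from the records are skipped.
#'
#' @param records evaluation manifest with `capri_class` and score columns.
#' @param score_fields columns to evaluate (e.g. `"iplddt"`,
#'   `"model_confidence"`, `"dockq"`).
#' @return data.frame with one row per available score field.
#' @export
discrimination_report <- function(records,
                                  score_fields = c("iplddt", "model_confidence")) {
  rows <- list()
  cls <- as.character(records$capri_class)
  for (f in score_fields) {
    if (is.null(records[[f]])) next
    s <- records[[f]]
    sub_ih <- cls %in% c("Incorrect", "High")
    sub_imh <- cls %in% c("Incorrect", "Medium", "High")
    auc_ih <- tryCatch(roc_auc(s[sub_ih], cls[sub_ih] == "High"),
                       error = function(e) NA_real_)
    auc_imh <- tryCatch(roc_auc(s[sub_imh], cls[sub_imh] != "Incorrect"),
                        error = function(e) NA_real_)
    per_class <- vapply(CAPRI_LEVELS, function(k) {
      tryCatch(roc_auc(s, cls == k), error = function(e) NA_real_)
    }, numeric(1))
    rows[[f]] <- data.frame(
      score = f,
      auc_incorrect_vs_high = auc_ih,
      auc_incorrect_vs_medium_high = auc_imh,
      auc_multiclass_macro = mean(per_class, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report table as CSV
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a report table as JSON
#' @param x data.frame or list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
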