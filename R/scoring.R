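#' Total artifact severity score
#'
#' The product of the classifier's detection probability and the regressor's
#' severity for one artifact.  The raw severity is clamped to `[0, 3]`
#' first (the regression head is unconstrained), so the score always lands
#' in the `[0, 3]` domain of the grading table.
#'
#' @param prob Detection probability in `[0, 1]` (vectorised).
#' @param severity Raw regressed severity (vectorised).
#' @return `prob * clamp(severity, 0, 3)`, in `[0, 3]`.
#' @export
total_severity <- function(prob, severity) {
  if (any(prob < 0 | prob > 1)) value_error("`prob` must be in [0, 1]")
  prob * pmin(pmax(severity, 0), 3)
}

.grade_levels <- c("None", "Mild", "Medium", "Severe")

#' Grade a severity score
#'
#' Fixed thresholds: score `<= 0.5` is None; in `(0.5, 1]` Mild; in
#' `(1, 2)` Medium; `>= 2` Severe.  As printed, the Medium and Severe
#' intervals both contain exactly 2; this implementation resolves the
#' boundary to Severe (the stricter clinical reading), so every score in
#' `[0, 3]` maps to exactly one grade.
#'
#' @param score Numeric score(s) in `[0, 3]`; values outside are an error
#'   (clamp first via [total_severity()]).
#' @return Factor with levels None < Mild < Medium < Severe.
#' @examples
#' grade(c(0.3, 0.75, 1.5, 2.5))
#' @export
grade <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 3))
    value_error("`score` must lie in [0, 3]")
  lab <- ifelse(score <= 0.5, "None",
         ifelse(score <= 1, "Mild",
         ifelse(score < 2, "Medium", "Severe")))
  factor(lab, levels = .grade_levels, ordered = TRUE)
}

#' Combine both networks' outputs into a graded severity report
#'
#' For each artifact (motion, chemical shift, radio-frequency) the
#' classifier probability is multiplied by the clamped regressed severity
#' and the product graded.  The classifier's fourth ("normal") probability
#' does not enter any product; the overall normal flag is derived from the
#' three grades (normal iff all are None).
#'
#' @param probs 4 probabilities (motion, chemical_shift, radiofrequency,
#'   normal) from the classifier.
#' @param severities 3 raw severities from the regressor.
#' @return Object of class `severity_report`: a data frame (artifact,
#'   probability, severity, score, grade) with attribute `normal`.
#' @examples
#' make_report(c(0.95, 0.1, 0.2, 0.05), c(2.8, 0.2, 0.4))
#' @export
make_report <- function(probs, severities) {
  if (length(probs) != 4L) value_error("`probs` must have length 4")
  if (length(severities) != 3L) value_error("`severities` must have length 3")
  score <- total_severity(probs[1:3], severities)
  g <- grade(score)
  rep <- data.frame(artifact = c("Motion", "CS", "RF"),
                    probability = as.numeric(probs[1:3]),
                    severity = pmin(pmax(as.numeric(severities), 0), 3),
                    score = as.numeric(score),
                    grade = as.character(g))
  structure(rep, class = c("severity_report", "data.frame"),
            normal = all(g == "None"))
}

#' @export
format.severity_report <- function(x, ...) {
  line <- paste(sprintf("%s: %s", x$artifact, x$grade), collapse = ", ")
  if (attr(x, "normal")) paste0(line, " [Normal]") else line
}

#' @export
print.severity_report <- function(x, ...) {
  cat(format(x), "\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Parse a rendered severity report line
#'
#' Inverse of `format.severity_report()`: recovers the three grades from
#' text such as `"Motion: Medium, CS: Severe, RF: Severe"`.
#'
#' @param text One report line.
#' @return Named character vector of grades (Motion, CS, RF).
#' @export
parse_severity_report <- function(text) {
  text <- sub(" \\[Normal\\]$", "", trimws(text))
  parts <- strsplit(text, ",\\s*")[[1]]
  kv <- strsplit(parts, ":\\s*")
  out <- vapply(kv, `[`, character(1), 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  if (!all(out %in% .grade_levels))
    value_error("unrecognised grade label in report text")
  out
}

#' Run both networks on one slice and grade it
#'
#' @param classifier,regressor Fitted `rise_net` objects of the matching
#'   tasks.
#' @param image Preprocessed slice matrix (masked, normalized, resized to
#'   the networks' input size).
#' @return A `severity_report`.
#' @export
grade_slice <- function(classifier, regressor, image) {
  if (classifier$task != "classification" || regressor$task != "regression")
    config_error("`classifier`/`regressor` tasks do not match their roles")
  p <- predict(classifier, image)[1, ]
  s <- predict(regressor, image)[1, ]
  make_report(p, s)
}
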