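## Abnormality scoring for graded features (labs and vitals) and keyword-based
## symptom matching for clinical note text.

#' Fit a lab standardizer from a cohort value distribution
#'
#' A lab value is scored by its absolute deviation from the cohort population
#' mean in SD units, scaled linearly so that the mean scores 0 and deviations
#' of \code{cap} SDs or more saturate at 1:
#' \code{score = min(|value - mean| / (cap * sd), 1)}.
#'
#' @param values Numeric vector of lab results across the cohort (at least two
#'   distinct values).
#' @param cap Saturation point in SD units (default 3).
#' @return An object of class \code{"LabStandardizer"}: a list with
#'   \code{mean}, \code{sd} (sample SD) and \code{cap}.
#' @examples
#' s <- fitLabStandardizer(c(1, 2, 3))   # mean 2, sd 1
#' labScore(2, s)                        # 0
#' labScore(2 + 4.5, s)                  # 1.5 SD with cap 3 -> 0.5
#' @export
fitLabStandardizer <- function(values, cap = 3) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("need at least 2 values to fit a standardizer")
  s <- stats::sd(values)
  if (s == 0)
    stop("degenerate value distribution: SD is zero")
  structure(list(mean = mean(values), sd = s, cap = cap),
            class = "LabStandardizer")
}

#' @rdname fitLabStandardizer
#' @param value Numeric lab value(s) to score.
#' @param s A \code{LabStandardizer} (or a list with \code{mean}, \code{sd},
#'   optional \code{cap}).
#' @export
labScore <- function(value, s) {
  cap <- if (is.null(s$cap)) 3 else s$cap
  if (is.null(s$sd) || s$sd <= 0) stop("standardizer must have sd > 0")
  pmin(abs(value - s$mean) / (cap * s$sd), 1)
}

#' Score a vital sign against its normal range and extreme bounds
#'
#' Values inside the normal range \code{[lo_n, hi_n]} score 0; values at or
#' beyond the extreme bounds \code{lo_e} / \code{hi_e} score 1; values in
#' between are interpolated linearly between the nearest normal-range edge and
#' the extreme bound on that side.
#'
#' @param value Numeric vital value(s).
#' @param v A list with \code{lo_n}, \code{hi_n}, \code{lo_e}, \code{hi_e}
#'   (\code{lo_e < lo_n <= hi_n < hi_e}), e.g. the \code{meta} of a vital row
#'   in the registry.
#' @return Scores in [0, 1].
#' @examples
#' v <- list(lo_n = 60, hi_n = 100, lo_e = 25, hi_e = 190)  # pulse rate
#' vitalScore(c(80, 190, 145), v)   # 0, 1, 0.5
#' @export
vitalScore <- function(value, v) {
  stopifnot(v$lo_e < v$lo_n, v$lo_n <= v$hi_n, v$hi_n < v$hi_e)
  hi <- pmin(pmax((value - v$hi_n) / (v$hi_e - v$hi_n), 0), 1)
  lo <- pmin(pmax((v$lo_n - value) / (v$lo_n - v$lo_e), 0), 1)
  pmax(hi, lo)
}

#' Default symptom lexicon from a registry
#'
#' Collects the per-symptom-group keyword lists stored in the registry's
#' symptom rows into a named list (group name -> lowercase keywords).
#'
#' @param registry A \code{\linkS4class{FeatureRegistry}}.
#' @return Named list of character keyword vectors.
#' @export
defaultLexicon <- function(registry) {
  ft <- registry@features
  idx <- which(ft$group == "symptom")
  lex <- lapply(idx, function(i) tolower(ft$meta[[i]]$keywords))
  names(lex) <- ft$name[idx]
  lex[lengths(lex) > 0]
}

#' Match symptom groups in note text
#'
#' A symptom group is flagged when at least one of its keywords occurs in the
#' text, matched case-insensitively on word boundaries.  No negation handling
#' is attempted: "denies insomnia" flags insomnia.
#'
#' @param note_text A single character string (may be empty or \code{NA}).
#' @param lexicon Named list of keyword vectors, see
#'   \code{\link{defaultLexicon}}.
#' @return Character vector of matched group names (possibly empty).
#' @export
matchSymptoms <- function(note_text, lexicon) {
  if (is.na(note_text) || !nzchar(note_text)) return(character())
  txt <- tolower(note_text)
  hit <- vapply(lexicon, function(kws) {
    any(vapply(kws, function(k) {
      grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", k), "\\b"),
            txt, perl = TRUE)
    }, logical(1)))
  }, logical(1))
  names(lexicon)[hit]
}
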