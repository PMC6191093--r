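#' The ordinal severity scale
#'
#' Positive-valence symptom severity is judged on four ordered classes,
#' ABSENT < MILD < MODERATE < SEVERE, carrying integer scores 1..4. The
#' normalised macro-MAE divides each class's deviations by the largest
#' deviation possible for that class, `max(score - 1, |C| - score)`, i.e.
#' (3, 2, 2, 3) for the four classes.
#'
#' @return A list with elements `classes` (ordered character vector),
#'   `score_of(label)` and `normaliser_of(label)` (vectorised functions).
#' @examples
#' sc <- severity_scale()
#' sc$score_of("SEVERE")       # 4
#' sc$normaliser_of("MILD")    # 2
#' @export
severity_scale <- function() {
  list(
    classes = severity_classes(),
    score_of = severity_score,
    normaliser_of = severity_normaliser
  )
}

#' @rdname severity_scale
#' @export
severity_classes <- function() c("ABSENT", "MILD", "MODERATE", "SEVERE")

#' Integer score of severity labels
#'
#' @param label Character vector of severity labels.
#' @return Integer scores on the 1..4 scale.
#' @export
severity_score <- function(label) {
  s <- match(as.character(label), severity_classes())
  if (anyNA(s) && !anyNA(label)) {
    bad <- unique(setdiff(as.character(label), severity_classes()))
    stop("unknown severity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s
}

#' Per-class deviation normaliser
#'
#' `max(score - 1, |C| - score)`: the farthest a prediction can land from a
#' gold label of this class, used by the normalised macro-MAE.
#'
#' @param label Character vector of severity labels.
#' @return Integer normalisers, (3, 2, 2, 3) across the four classes.
#' @export
severity_normaliser <- function(label) {
  s <- severity_score(label)
  pmax(s - 1L, length(severity_classes()) - s)
}
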