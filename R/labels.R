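#' Expression and intensity label vocabulary
#'
#' The seven prototypical expressions of the Facial Action Coding System
#' (FACS) recognised by the pipeline, in the fixed class-encoding order used
#' everywhere in the package, and the mapping between FACS intensity letters
#' A-E and integer levels 1-5 (A = 1, minimal; E = 5, maximal).
#'
#' @format `feree_expressions` is a character vector of length 7.
#' @export
feree_expressions <- c(
  "contempt", "surprise", "sadness", "happiness", "anger", "disgust", "fear"
)

#' @rdname feree_expressions
#' @format `feree_channel_aus` is a character vector of length 10: the facial
#'   action unit recorded on each sEMG channel CH1..CH10. CH6, CH8 and CH10
#'   sit at the corners of the mouth.
#' @export
feree_channel_aus <- c(
  "AU1", "AU2", "AU4", "AU9", "AU10", "AU26", "AU12", "AU23", "AU17", "AU15"
)

#' Convert FACS intensity letters to integer levels and back
#'
#' @param letter Character vector of letters in `A`..`E`.
#' @param level Integer vector of levels in 1..5.
#' @return `intensity_level()` returns integers 1-5; `intensity_letter()`
#'   returns letters A-E. The two maps are inverse bijections.
#' @examples
#' intensity_level("C")   # 3
#' intensity_letter(5)    # "E"
#' @export
intensity_level <- function(letter) {
  idx <- match(toupper(letter), LETTERS[1:5])
  if (anyNA(idx)) {
    stop_feree("intensity letter must be one of A-E", "feree_label_error")
  }
  idx
}

#' @rdname intensity_level
#' @export
intensity_letter <- function(level) {
  LETTERS[vapply(level, check_intensity, 0L)]
}

#' Construct an expression label
#'
#' A label pairs one of the seven expression types with an intensity level
#' 1-5 (FACS letters A-E).
#'
#' @param expression One of [feree_expressions].
#' @param intensity Integer level 1-5, or a letter `"A"`..`"E"`.
#' @return An object of class `expression_label` with fields `expression`
#'   and `intensity`.
#' @export
expression_label <- function(expression, intensity) {
  expression <- check_expression(expression)
  if (is.character(intensity)) intensity <- intensity_level(intensity)
  intensity <- check_intensity(intensity)
  structure(list(expression = expression, intensity = intensity),
            class = "expression_label")
}

#' @export
print.expression_label <- function(x, ...) {
  cat(sprintf("<expression_label> %s, intensity %d (%s)\n",
              x$expression, x$intensity, intensity_letter(x$intensity)))
  invisible(x)
}

check_expression <- function(expression) {
  if (length(expression) != 1L || !expression %in% feree_expressions) {
    stop_feree(
      sprintf("expression must be one of: %s",
              paste(feree_expressions, collapse = ", ")),
      "feree_label_error"
    )
  }
  expression
}

check_intensity <- function(intensity) {
  if (length(intensity) != 1L || is.na(intensity) ||
      intensity != as.integer(intensity) || intensity < 1L || intensity > 5L) {
    stop_feree("intensity must be an integer in 1..5", "feree_label_error")
  }
  as.integer(intensity)
}
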