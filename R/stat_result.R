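#' Container for a single statistical test result
#'
#' Uniform record for every test the pipeline reports: the statistic name
#' and value, degrees of freedom (or sample size for Z-based tests), the
#' p-value, and an effect size with an explicit formula tag (effect-size
#' conventions differ between sources, so the formula used is always
#' recorded alongside the number).
#'
#' @param statistic One of `"F"`, `"t"`, `"z"`, `"U"`, `"r_pearson"`.
#' @param value Statistic value.
#' @param df Degrees of freedom (length 1 or 2), or `NULL`.
#' @param n Sample size underlying the statistic, or `NULL`.
#' @param p Two-sided p-value unless `alternative` says otherwise.
#' @param effect_size,effect_size_type,effect_size_formula Effect size,
#'   its kind (`"partial_eta_sq"`, `"r"`, `"cohen_d"`), and the formula.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return A list of class `stat_result`.
#' @export
stat_result <- function(statistic, value, df = NULL, n = NULL, p,
                        effect_size = NA_real_,
                        effect_size_type = NA_character_,
                        effect_size_formula = NA_character_,
                        alternative = "two.sided") {
  stopifnot(statistic %in% c("F", "t", "z", "U", "r_pearson"),
            p >= 0, p <= 1)
  if (identical(effect_size_type, "partial_eta_sq")) {
    stopifnot(effect_size >= 0, effect_size <= 1)
  }
  structure(
    list(statistic = statistic, value = value, df = df, n = n, p = p,
         effect_size = effect_size, effect_size_type = effect_size_type,
         effect_size_formula = effect_size_formula,
         alternative = alternative),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  dftxt <- if (!is.null(x$df)) paste0("(", paste(round(x$df, 2),
                                                 collapse = ","), ")")
           else if (!is.null(x$n)) paste0("[n=", x$n, "]") else ""
  cat(sprintf("%s%s = %.3f, p = %.4g", x$statistic, dftxt, x$value, x$p))
  if (!is.na(x$effect_size)) {
    cat(sprintf(", %s = %.3f", x$effect_size_type, x$effect_size))
  }
  if (!identical(x$alternative, "two.sided")) {
    cat(sprintf(" (%s)", x$alternative))
  }
  cat("\n")
  invisible(x)
}
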