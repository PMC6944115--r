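#' Digital IHC scores from pixel intensity bin counts
#'
#' Digital pathology scanners classify every pixel of a stained section as
#' negative (0), weakly positive (1), positive (2) or strongly positive (3).
#' These functions turn the per-sample bin counts into the standard
#' quantitative readouts:
#'
#' * **H-score**: \eqn{\sum_{i=0}^{3} i \times P_i}, where \eqn{P_i} is the
#'   percentage of pixels in intensity class \eqn{i}; range 0--300.
#' * **Percent strong**: the percentage of pixels in the strongest class,
#'   used for markers scored by labelled area (e.g. CD68); range 0--100.
#' * **Stain presence call**: a binary mutant/wild-type call for
#'   mutation-specific antibodies (e.g. IDH1 R132H), where any staining of
#'   any intensity counts as mutant and a completely negative section as
#'   wild-type.
#'
#' All three are vectorised over samples. Counts must be non-negative and
#' each sample must have a positive pixel total.
#'
#' @param n0,n1,n2,n3 Non-negative pixel counts for intensity classes 0-3.
#' @return `hscore()` and `percent_strong()` return numeric vectors;
#'   `stain_presence_call()` returns a character vector of `"mutant"` /
#'   `"wild_type"`.
#' @examples
#' hscore(25, 25, 25, 25)      # 150
#' percent_strong(90, 0, 0, 10) # 10
#' stain_presence_call(99, 1, 0, 0) # "mutant"
#' @export
hscore <- function(n0, n1, n2, n3) {
  check_pixel_counts(n0, n1, n2, n3)
  total <- n0 + n1 + n2 + n3
  100 * (0 * n0 + 1 * n1 + 2 * n2 + 3 * n3) / total
}

#' @rdname hscore
#' @export
percent_strong <- function(n0, n1, n2, n3) {
  check_pixel_counts(n0, n1, n2, n3)
  100 * n3 / (n0 + n1 + n2 + n3)
}

#' @rdname hscore
#' @export
stain_presence_call <- function(n0, n1, n2, n3) {
  check_pixel_counts(n0, n1, n2, n3)
  ifelse(n1 + n2 + n3 > 0, "mutant", "wild_type")
}

check_pixel_counts <- function(n0, n1, n2, n3) {
  counts <- cbind(n0, n1, n2, n3)
  if (!is.numeric(counts) || anyNA(counts)) abort("Pixel counts must be numeric and non-missing.")
  if (any(counts < 0)) abort("Pixel counts must be non-negative.")
  if (any(rowSums(counts) <= 0)) abort("Empty measurement: every sample needs a positive pixel total.")
  invisible(NULL)
}

#' Score a table of pixel bin counts
#'
#' Tidy front end for the IHC quantifications: takes one row per
#' sample/marker with the four intensity-bin counts and returns the requested
#' scores in long format, ready to join onto a clinical table.
#'
#' @param data Data frame with columns `sample_id`, `marker`, `n0`, `n1`,
#'   `n2`, `n3`.
#' @param kinds Character vector of scores to compute, any of `"hscore"`,
#'   `"percent_strong"`, `"presence_call"`.
#' @return A tibble with columns `sample_id`, `marker`, `kind`, `value`
#'   (`value` is `NA` for presence calls, which go in `call`).
#' @export
ihc_scores <- function(data, kinds = c("hscore", "percent_strong")) {
  needed <- c("sample_id", "marker", "n0", "n1", "n2", "n3")
  if (!all(needed %in% names(data))) {
    abort(sprintf("`data` needs columns: %s.", paste(needed, collapse = ", ")))
  }
  kinds <- match.arg(kinds, c("hscore", "percent_strong", "presence_call"), several.ok = TRUE)
  out <- purrr::map_dfr(kinds, function(k) {
    val <- switch(k,
      hscore = hscore(data$n0, data$n1, data$n2, data$n3),
      percent_strong = percent_strong(data$n0, data$n1, data$n2, data$n3),
      presence_call = NA_real_
    )
    tibble(
      sample_id = as.character(data$sample_id),
      marker = as.character(data$marker),
      kind = k,
      value = val,
      call = if (k == "presence_call") {
        stain_presence_call(data$n0, data$n1, data$n2, data$n3)
      } else {
        NA_character_
      }
    )
  })
  out
}
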