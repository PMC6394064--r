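#' uromark: discovery and verification of urinary kidney-specific mRNA markers
#'
#' Pipeline stages: synthetic compendium/cohort/dilution generators with
#' planted truth, multi-platform harmonization and matrix-level QC,
#' empirical-Bayes moderated-t differential expression, two-rule cross-tissue
#' candidate screening, and clinical verification statistics (delta-Ct
#' relative expression, fold of medians, rank tests, Spearman correlation,
#' ROC with Youden cutoff, replicate CV).
#'
#' @keywords internal
"_PACKAGE"

# Condition constructors: every user-facing error carries a subclass so
# callers (and tests) can distinguish configuration errors from data errors.
uromark_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "uromark_error"), call = call))
}

config_error       <- function(msg) uromark_error(msg, "uromark_config_error")
validation_error   <- function(msg) uromark_error(msg, "uromark_validation_error")
precondition_error <- function(msg) uromark_error(msg, "uromark_precondition_error")
parse_error        <- function(msg) uromark_error(msg, "uromark_parse_error")
harmonization_error <- function(msg) uromark_error(msg, "uromark_harmonization_error")
contrast_error     <- function(msg) uromark_error(msg, "uromark_contrast_error")
estimation_error   <- function(msg) uromark_error(msg, "uromark_estimation_error")
screening_error    <- function(msg) uromark_error(msg, "uromark_screening_error")
lookup_error       <- function(msg) uromark_error(msg, "uromark_lookup_error")

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (the convention of
#' printed clinical tables), as opposed to [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.1375, 2) # 0.14
#' round_half_up(2.25, 1)   # 2.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly .5 after
  # decimal-to-binary conversion do not fall on the floor side
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Deterministic per-component substream seeds derived from one global seed,
# so regenerating a single component does not disturb the others.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, component) {
  offsets <- c(compendium = 11L, cohort = 23L, dilution = 37L,
               variance = 41L, batch = 43L, noise = 47L,
               platform = 53L, planted = 59L)
  if (!component %in% names(offsets)) {
    offsets <- c(offsets, structure(sum(utf8ToInt(component)), names = component))
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[component]]) %% 2147483647)
}

assert_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    config_error(sprintf("field '%s' must be a positive integer (got %s)",
                         field, paste(format(x), collapse = ",")))
  }
  as.integer(x)
}

assert_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    config_error(sprintf("field '%s' must be a finite number in [%s, %s]",
                         field, format(lower), format(upper)))
  }
  as.numeric(x)
}
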