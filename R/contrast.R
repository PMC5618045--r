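#' Center-to-ring contrast model for synthetic blood stains
#'
#' The synthetic stain generator needs a documented mapping from the sickle
#' hemoglobin fraction of a sample to the S-index its stain would produce
#' with fresh reagents. The package uses a logistic-saturating curve
#' \deqn{g(x) = 1 + A \frac{x^h}{x^h + k^h}}
#' where \eqn{x} is \%HbS. \eqn{g(0) = 1} (no HbS, no center spot, equal
#' center and ring intensity), \eqn{g} is non-decreasing in \eqn{x}, and it
#' saturates at \eqn{1 + A} as nearly all hemoglobin becomes insoluble
#' deoxy-HbS. Parameters differ by reducing-agent formulation: sodium
#' metabisulfite (MS) buffers produce darker, better-defined center spots at
#' low \%HbS than sodium hydrosulfite (HS) buffers, so the MS curves rise
#' more steeply near the origin.
#'
#' @param hbs_percent \%HbS of total hemoglobin, in \[0, 100\].
#' @param formulation one of `"MS"`, `"HS"`, `"MS10"`, `"MS15"`, `"MS20"`
#'   (`"MS"` is the 15\% w/v metabisulfite formulation).
#' @return Expected noise-free S-index (dimensionless, `>= 1`).
#' @examples
#' stain_contrast(0, "MS")    # 1: uniform pink ring
#' stain_contrast(80, "MS")   # saturated dark center
#' @export
stain_contrast <- function(hbs_percent, formulation = c("MS", "HS", "MS10", "MS15", "MS20")) {
  formulation <- match.arg(formulation)
  if (any(!is.finite(hbs_percent)) || any(hbs_percent < 0) || any(hbs_percent > 100))
    abort_validation("hbs_percent must lie in [0, 100]")
  p <- contrast_params(formulation)
  xh <- hbs_percent^p$h
  1 + p$A * xh / (xh + p$k^p$h)
}

# Per-formulation curve parameters. MS15 is the canonical "MS" formulation.
contrast_params <- function(formulation) {
  switch(formulation,
    MS   = ,
    MS15 = list(A = 1.25, k = 22, h = 2),
    MS10 = list(A = 0.85, k = 30, h = 2),
    MS20 = list(A = 0.90, k = 16, h = 2),
    HS   = list(A = 1.00, k = 45, h = 2),
    abort_config(sprintf("unknown formulation '%s'", formulation))
  )
}

#' Reagent activity under the step-decay shelf-life model
#'
#' Reducing agents in the hemoglobin solubility buffer either work fully or
#' not at all: stored reagents behave like fresh ones up to a
#' formulation/storage-specific limit of stability (LOS), after which they
#' lose all activity. This step model reflects the observed all-or-nothing
#' loss of the HS formulation and the sustained stability of the MS
#' formulation. Limits of stability (days, room temperature):
#' MS wet 168, MS dry 168, HS wet 6, HS dry 36. When stored wet at elevated
#' temperature (> 40 degrees C, e.g. 62 degrees C desert storage), the MS
#' limit drops to 7 days; no other condition is temperature sensitive.
#'
#' @param formulation `"MS"` or `"HS"` (MS concentration variants `"MS10"`,
#'   `"MS15"`, `"MS20"` share the MS stability behavior).
#' @param storage `"wet"` (premixed aqueous buffer) or `"dry"` (powder mixed
#'   on the day of use).
#' @param age_days non-negative storage time in days.
#' @param temperature_c storage temperature, degrees Celsius.
#' @return An object of class `reagent_activity`: list with `activity`
#'   (1 = fresh behavior, 0 = total loss) and `limit_of_stability_days`.
#' @examples
#' reagent_activity("HS", "wet", 7)$activity    # 0: past the 6-day limit
#' reagent_activity("MS", "wet", 168)$activity  # 1: stable through 24 weeks
#' @export
reagent_activity <- function(formulation, storage, age_days, temperature_c = 22) {
  if (!is_scalar_number(age_days) || age_days < 0)
    abort_validation("age_days must be a non-negative number")
  if (!is.character(formulation) || !formulation %in% c("MS", "HS", "MS10", "MS15", "MS20"))
    abort_config(sprintf("unknown formulation '%s'", as.character(formulation)[1]))
  if (!is.character(storage) || !storage %in% c("wet", "dry"))
    abort_config(sprintf("unknown storage condition '%s'", as.character(storage)[1]))
  is_ms <- formulation != "HS"
  los <- if (is_ms) {
    if (storage == "wet" && temperature_c > 40) 7 else 168
  } else {
    if (storage == "wet") 6 else 36
  }
  structure(
    list(activity = as.numeric(age_days <= los), limit_of_stability_days = los),
    class = "reagent_activity"
  )
}

#' @export
print.reagent_activity <- function(x, ...) {
  cat(sprintf("Reagent activity: %g (limit of stability %g days)\n",
              x$activity, x$limit_of_stability_days))
  invisible(x)
}
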