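#' Blood component for reconstitution arithmetic
#'
#' @param hb_concentration total hemoglobin concentration (g/dL, > 0).
#' @param volume component volume (uL, >= 0).
#' @param hbs_percent \%HbS of this component's hemoglobin, in \[0, 100\].
#' @return An object of class `blood_component`.
#' @export
blood_component <- function(hb_concentration, volume, hbs_percent) {
  if (!is_scalar_number(hb_concentration) || hb_concentration <= 0)
    abort_validation("hb_concentration must be > 0")
  if (!is_scalar_number(volume) || volume < 0)
    abort_validation("volume must be >= 0")
  if (!is_scalar_number(hbs_percent) || hbs_percent < 0 || hbs_percent > 100)
    abort_validation("hbs_percent must lie in [0, 100]")
  structure(list(hb_concentration = hb_concentration, volume = volume,
                 hbs_percent = hbs_percent),
            class = "blood_component")
}

#' \%HbS of a type- and Hct-matched blood mixture
#'
#' When an SCA-donor component and a normal-donor component are combined,
#' the mixture's \%HbS is the HbS mass divided by the total hemoglobin mass:
#' \deqn{\%HbS = \frac{[Hb]_{SS} V_{SS} \, \%HbS_{SS}}
#'                    {[Hb]_{SS} V_{SS} + [Hb]_{AA} V_{AA}}}
#' Hematocrit matching is assumed already done (adjusted physically before
#' mixing) and is carried as metadata only. Units: any consistent pair for
#' concentration and volume — only the products enter.
#'
#' @param hbss a [blood_component()] from an SCA donor (\%HbS > 0).
#' @param hbaa a [blood_component()] from a normal donor (\%HbS = 0).
#' @param hematocrit_percent target hematocrit (\%), default 22, a
#'   physiological value for SCA; metadata only.
#' @return Mixture \%HbS (scalar in \[0, \%HbS of the SS component\]).
#' @examples
#' percent_hbs(blood_component(8, 100, 85), blood_component(14, 300, 0))
#' @export
percent_hbs <- function(hbss, hbaa, hematocrit_percent = 22) {
  stopifnot(inherits(hbss, "blood_component"), inherits(hbaa, "blood_component"))
  denom <- hbss$hb_concentration * hbss$volume + hbaa$hb_concentration * hbaa$volume
  if (denom <= 0)
    stop_sicklestain("degenerate_mixture", "both component volumes are zero")
  hbss$hb_concentration * hbss$volume * hbss$hbs_percent / denom
}

#' Volume ratio achieving a target mixture \%HbS
#'
#' Inverts the mixture equation: returns `r = V_SS / V_AA` such that
#' combining the components at volumes `(r, 1)` reproduces the target.
#' Closed form: `r = ([Hb]_AA * target) / ([Hb]_SS * (%HbS_SS - target))`.
#'
#' @param target_hbs_percent desired mixture \%HbS; must be strictly below
#'   the \%HbS of the SCA component.
#' @param hbss,hbaa [blood_component()]s (volumes ignored).
#' @return The volume ratio `V_SS / V_AA` (>= 0).
#' @export
solve_volume_ratio <- function(target_hbs_percent, hbss, hbaa) {
  stopifnot(inherits(hbss, "blood_component"), inherits(hbaa, "blood_component"))
  if (!is_scalar_number(target_hbs_percent) || target_hbs_percent < 0)
    abort_validation("target_hbs_percent must be >= 0")
  if (target_hbs_percent >= hbss$hbs_percent)
    stop_sicklestain("infeasible_target",
      sprintf("target %.3g%% >= %%HbS of the SCA component (%.3g%%)",
              target_hbs_percent, hbss$hbs_percent))
  hbaa$hb_concentration * target_hbs_percent /
    (hbss$hb_concentration * (hbss$hbs_percent - target_hbs_percent))
}
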