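#' Default test-kit cost ledger
#'
#' Per-test component costs (USD) of the self-contained, distributable
#' screening kit: off-the-shelf disposables plus food-grade reagents.
#'
#' @return data.frame with columns `component` and `unit_cost_usd`.
#' @export
kit_cost_ledger <- function() {
  data.frame(
    component = c("Foil pouch", "Reagent dropper", "Blood dropper",
                  "Chromatography paper", "Reagent tube", "Food grade reagents"),
    unit_cost_usd = c(0.02, 0.05, 0.08, 0.01, 0.03, 0.02)
  )
}

#' Total per-test kit cost
#'
#' Sums component costs exactly at cent precision (integer cents
#' internally, so no floating-point drift).
#'
#' @param ledger data.frame with a `unit_cost_usd` column (non-empty,
#'   costs >= 0), e.g. [kit_cost_ledger()].
#' @return Total cost in USD.
#' @examples
#' total_cost(kit_cost_ledger())  # 0.21
#' @export
total_cost <- function(ledger = kit_cost_ledger()) {
  if (!is.data.frame(ledger) || !"unit_cost_usd" %in% names(ledger) ||
      nrow(ledger) == 0L)
    abort_validation("ledger must be a non-empty data.frame with column 'unit_cost_usd'")
  costs <- ledger$unit_cost_usd
  if (anyNA(costs) || any(costs < 0))
    abort_validation("component costs must be non-negative")
  sum(round(costs * 100)) / 100
}

#' Hemoglobin solubility buffer recipe
#'
#' The buffer has three components: a concentrated potassium phosphate
#' buffer (monobasic + dibasic), saponin to lyse red cells and release
#' hemoglobin, and a reducing agent that converts hemoglobin to its deoxy
#' form — soluble for deoxy-HbA, insoluble for deoxy-HbS. Valid reducing
#' agent concentrations: MS at 10, 15 or 20\% w/v (15\% is the final
#' formulation), HS at 3\% w/v.
#'
#' @param reducing_agent `"MS"` or `"HS"`.
#' @param reducing_agent_percent_wv w/v percent of the reducing agent.
#' @param monobasic_molarity,dibasic_molarity phosphate molarities (mol/L).
#' @param saponin_g_per_l saponin concentration (g/L).
#' @return An object of class `buffer_recipe`.
#' @export
buffer_recipe <- function(reducing_agent = c("MS", "HS"),
                          reducing_agent_percent_wv = NULL,
                          monobasic_molarity = 1.24, dibasic_molarity = 1.25,
                          saponin_g_per_l = 4) {
  reducing_agent <- match.arg(reducing_agent)
  if (is.null(reducing_agent_percent_wv))
    reducing_agent_percent_wv <- if (reducing_agent == "MS") 15 else 3
  if (reducing_agent == "MS" && !reducing_agent_percent_wv %in% c(10, 15, 20))
    abort_validation("MS concentration must be 10, 15 or 20% w/v")
  if (reducing_agent == "HS" && reducing_agent_percent_wv != 3)
    abort_validation("HS concentration must be 3% w/v")
  if (any(c(monobasic_molarity, dibasic_molarity, saponin_g_per_l) <= 0))
    abort_validation("all buffer quantities must be > 0")
  structure(list(
    reducing_agent = reducing_agent,
    reducing_agent_percent_wv = reducing_agent_percent_wv,
    monobasic_molarity = monobasic_molarity,
    dibasic_molarity = dibasic_molarity,
    saponin_g_per_l = saponin_g_per_l
  ), class = "buffer_recipe")
}

#' Total phosphate molarity of a buffer recipe
#'
#' @param recipe a [buffer_recipe()].
#' @return Monobasic + dibasic molarity (mol/L).
#' @examples
#' buffer_molarity(buffer_recipe("MS"))  # 2.49
#' @export
buffer_molarity <- function(recipe) {
  stopifnot(inherits(recipe, "buffer_recipe"))
  recipe$monobasic_molarity + recipe$dibasic_molarity
}

#' Default package configuration
#'
#' Nested list holding the buffer recipes, the kit cost ledger, synthetic
#' generator defaults, the genotype class scheme and the significance level
#' used by the stability analysis. Written/read as YAML by
#' [write_kit_config()] / [read_kit_config()].
#'
#' @return Named list of configuration defaults.
#' @export
default_kit_config <- function() {
  list(
    buffer = list(
      ms = unclass(buffer_recipe("MS")),
      hs = unclass(buffer_recipe("HS"))
    ),
    cost_ledger = kit_cost_ledger(),
    generator = list(
      hbs_levels = c(0, 10, 20, 40, 80),
      hematocrit_percent = 22,
      image_size_px = 128, stain_radius_px = 44,
      center_radius_fraction = 0.35,
      noise_sd = 2, observer_slope = 40,
      observer_cutpoints = c(1.10, 2.06)
    ),
    scheme = list(as_min = 10, as_max = 40, ss_binary_min = 80),
    alpha = 0.05
  )
}

#' @rdname default_kit_config
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_kit_config <- function(config, path) {
  cfg <- config
  cfg$cost_ledger <- as.list(cfg$cost_ledger)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname default_kit_config
#' @export
read_kit_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$cost_ledger)) cfg$cost_ledger <- as.data.frame(cfg$cost_ledger)
  cfg
}
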