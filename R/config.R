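#' Default run configuration
#'
#' Builds the nested configuration list consumed by the triage, instrument,
#' engagement, exercise, and statistics functions. Every value can be
#' overridden either by argument here or by a YAML file via [load_config()].
#' Defaults encode the program's published operating points: weight-gain
#' thresholds of 3 lb/day and 5 lb/week (orange requires strictly more than
#' 5 lb), a 30-day protocol window, a 6 breaths/min breathing target, and
#' alpha 0.05 / power 0.80 for sample-size projection.
#'
#' @param ... Named overrides merged (recursively) over the defaults, e.g.
#'   `triage = list(gain_1d_lb = 4)`. Unknown keys raise an error.
#' @return A named list of class `hf_config` with components `triage`,
#'   `engagement`, `exercise`, `stats`, and `instruments`.
#' @examples
#' cfg <- hf_config(triage = list(gain_1d_lb = 4))
#' cfg$triage$gain_1d_lb
#' @export
hf_config <- function(...) {
  defaults <- list(
    triage = list(
      gain_1d_lb = 3,          # yellow: >= 3 lb gained in one day
      gain_7d_lb = 5,          # yellow: >= 5 lb gained in a week
      orange_gain_lb = 5,      # orange: moderate symptoms AND gain > 5 lb
      staleness_days = 3       # carry-forward limit for missing weights
    ),
    engagement = list(
      window_days = 30,
      low_engagement_pct = 50
    ),
    exercise = list(
      breath_target = 6,       # breaths per minute
      breath_tolerance = 1,    # +/- band around the target
      walk_equation = "enright_sherrill"
    ),
    stats = list(
      alpha = 0.05,
      power = 0.80
    ),
    instruments = list(
      schfi_items = list(maintenance = 10, management = 6, confidence = 6),
      schfi_item_range = c(1, 4),
      kccq_domains = list(
        physical_limitation = 1:6,
        symptoms = 7:13,
        quality_of_life = 14:16,
        social_interference = 17:20,
        self_efficacy = 21:23
      ),
      kccq_item_range = c(1, 5),
      mmas8_item8_map = c(0, 0.25, 0.5, 0.75, 1)
    )
  )
  overrides <- list(...)
  structure(merge_config(defaults, overrides, path = character()),
            class = "hf_config")
}

# Recursive merge with strict key checking; unknown keys are reported with
# their full dotted path so YAML typos are easy to locate.
merge_config <- function(base, override, path) {
  if (length(override) == 0) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) {
    abort(sprintf("config overrides at '%s' must all be named",
                  paste(path, collapse = ".")))
  }
  for (nm in nms) {
    full <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      abort(sprintf("unknown config key: '%s'", full))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) {
        abort(sprintf("config key '%s' must be a named list", full))
      }
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over the defaults from
#' [hf_config()]. An empty file yields the pure defaults; unknown keys raise
#' an error naming the offending dotted path. Positive-threshold sanity checks
#' are applied after the merge.
#'
#' @param path Path to a YAML file.
#' @return An `hf_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- do.call(hf_config, raw)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  tri <- cfg$triage
  for (key in c("gain_1d_lb", "gain_7d_lb", "orange_gain_lb", "staleness_days")) {
    v <- tri[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("config key 'triage.%s' must be a positive number", key))
    }
  }
  if (cfg$engagement$window_days < 1) {
    abort("config key 'engagement.window_days' must be >= 1")
  }
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1) {
    abort("config key 'stats.alpha' must lie in (0, 1)")
  }
  if (cfg$stats$power <= 0 || cfg$stats$power >= 1) {
    abort("config key 'stats.power' must lie in (0, 1)")
  }
  invisible(cfg)
}

#' @export
print.hf_config <- function(x, ...) {
  cat("<hf_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

# Pounds per kilogram, used wherever weights are ingested in kg.
LB_PER_KG <- 2.20462
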