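# Multiplicative unit conversions into each canonical unit. Temperature only
# accepts Celsius spellings: Fahrenheit needs an offset and has not been
# needed; the registry is data, so extra rows can be supplied per call.
ts_unit_registry <- function() {
  tibble::tribble(
    ~canonical, ~unit,            ~factor,
    "µm",  "µm",        1,
    "µm",  "um",             1,
    "µm",  "micrometer",     1,
    "µm",  "micrometers",    1,
    "µm",  "micrometre",     1,
    "µm",  "micron",         1,
    "µm",  "microns",        1,
    "µm",  "mm",             1000,
    "µm",  "nm",             0.001,
    "µm",  "cm",             10000,
    "h",        "h",              1,
    "h",        "hr",             1,
    "h",        "hrs",            1,
    "h",        "hour",           1,
    "h",        "hours",          1,
    "h",        "min",            1 / 60,
    "h",        "mins",           1 / 60,
    "h",        "minute",         1 / 60,
    "h",        "minutes",        1 / 60,
    "h",        "d",              24,
    "h",        "day",            24,
    "h",        "days",           24,
    "h",        "s",              1 / 3600,
    "h",        "sec",            1 / 3600,
    "bp",       "bp",             1,
    "bp",       "kb",             1e3,
    "bp",       "kbp",            1e3,
    "bp",       "mb",             1e6,
    "bp",       "mbp",            1e6,
    "bp",       "gb",             1e9,
    "bp",       "gbp",            1e9,
    "percent",  "percent",        1,
    "percent",  "%",              1,
    "percent",  "fraction",       100,
    "percent",  "proportion",     100,
    "°C",  "°c",        1,
    "°C",  "c",              1,
    "°C",  "celsius",        1,
    "°C",  "degc",           1,
    "°C",  "deg c",          1,
    "pH",       "ph",             1,
    "count",    "count",          1,
    "count",    "copies",         1,
    "count",    "genes",          1
  )
}

#' Convert numeric trait values into their canonical unit
#'
#' Conversions are exact multiplicative factors against the trait's canonical
#' unit as declared in the schema (`mm` to µm is ×1000, `Mbp` to bp is ×10^6,
#' minutes to hours is ÷60, ...).  An empty unit string is taken to mean the
#' value is already canonical.
#'
#' @param value Numeric vector.
#' @param unit Character vector of unit strings (recycled against `value`).
#' @param trait Numeric trait name whose canonical unit applies.
#' @param schema A [trait_schema].
#' @param extra_conversions Optional data frame `(canonical, unit, factor)`
#'   extending the built-in registry.
#' @return `value` expressed in the trait's canonical unit.
#' @export
#' @examples
#' convert_unit(0.002, "mm", "d1_lo", default_schema())
#' convert_unit(4.6, "Mbp", "genome_size", default_schema())
convert_unit <- function(value, unit, trait, schema, extra_conversions = NULL) {
  def <- trait_def(schema, trait)
  if (def$dtype != "numeric") {
    ts_abort(sprintf("trait '%s' is not numeric", trait),
             class = "traitsynth_usage_error")
  }
  registry <- ts_unit_registry()
  if (!is.null(extra_conversions)) {
    registry <- bind_rows(registry, as_tibble(extra_conversions))
  }
  registry <- registry[registry$canonical == def$unit, ]
  key <- fold_key(unit)
  key <- rep_len(key, length(value))
  key[is.na(key)] <- ""
  factor <- registry$factor[match(key, registry$unit)]
  factor[key == ""] <- 1  # already canonical
  unknown <- is.na(factor) & !is.na(value)
  if (any(unknown)) {
    ts_abort(
      sprintf("unknown unit '%s' for trait '%s' (canonical unit: %s)",
              unique(unit[unknown])[1], trait, def$unit),
      class = "traitsynth_conversion_error"
    )
  }
  value * factor
}
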