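# Balanced panel container, loaders and the region partition.

PANEL_OUTCOME <- "GDP"
PANEL_REGRESSORS <- c("Heal", "Cap", "Con", "Exp", "Hum", "Urb")

#' Default variable specification
#'
#' Maps raw input columns to model variables: log transforms for the monetary
#' and count variables (GDP, healthcare expenditure, fixed investment, retail
#' consumption, exports, college students) and a proportion for the urban
#' population share.
#'
#' @return A data frame with columns `name`, `raw`, `transform`, `units`.
#' @export
default_variable_spec <- function() {
  data.frame(
    name      = c("GDP", "Heal", "Cap", "Con", "Exp", "Hum", "Urb"),
    raw       = c("gdp", "heal", "cap", "con", "exp", "hum", "urb"),
    transform = c(rep("log", 6L), "proportion"),
    units     = c("log 100 million RMB", "log 100 million RMB",
                  "log 100 billion RMB", "log 100 billion RMB",
                  "log 100 billion RMB", "log 10,000 students",
                  "urban population share in [0, 1]"),
    stringsAsFactors = FALSE
  )
}

#' Construct a balanced panel dataset
#'
#' Validates balance (every unit observed in every period exactly once),
#' completeness and the `[0, 1]` domain of `Urb`, freezes the unit ordering
#' lexicographically, and sorts records by (period, unit). All spatial weight
#' matrices used with the panel must share this unit ordering.
#'
#' @param data Data frame with columns `unit`, `year`, the outcome and the
#'   regressors (already on the transformed scale).
#' @param outcome Name of the outcome column (default `"GDP"`).
#' @param regressors Character vector of regressor columns.
#' @param meta Optional list of provenance notes.
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(data, outcome = PANEL_OUTCOME,
                          regressors = PANEL_REGRESSORS, meta = list()) {
  stopifnot(is.data.frame(data))
  needed <- c("unit", "year", outcome, regressors)
  absent <- setdiff(needed, names(data))
  if (length(absent) > 0L) {
    stop("panel is missing columns: ", paste(absent, collapse = ", "))
  }
  data <- data[, needed, drop = FALSE]
  data$unit <- as.character(data$unit)
  data$year <- as.integer(data$year)

  units <- sort(unique(data$unit))
  periods <- sort(unique(data$year))
  key <- paste(data$unit, data$year, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    stop("duplicate (unit, year) records: ",
         paste(gsub("\r", "/", dup), collapse = ", "))
  }
  expected <- as.vector(outer(units, periods, paste, sep = "\r"))
  gaps <- setdiff(expected, key)
  if (length(gaps) > 0L) {
    stop("panel is not balanced; missing (unit, year) pairs: ",
         paste(gsub("\r", "/", gaps), collapse = ", "))
  }
  vals <- as.matrix(data[, c(outcome, regressors), drop = FALSE])
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("panel contains missing or non-finite values; the package rejects ",
         "incomplete panels rather than imputing")
  }
  if ("Urb" %in% regressors &&
      (any(data$Urb < 0) || any(data$Urb > 1))) {
    stop("Urb must be a proportion in [0, 1]")
  }

  data <- data[order(data$year, match(data$unit, units)), , drop = FALSE]
  rownames(data) <- NULL
  structure(
    list(units = units, periods = periods, outcome = outcome,
         regressors = regressors, data = data, meta = meta),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Balanced panel: %d units x %d periods (%d-%d), %d records\n",
              length(x$units), length(x$periods), min(x$periods),
              max(x$periods), nrow(x$data)))
  cat("Outcome:   ", x$outcome, "\n")
  cat("Regressors:", paste(x$regressors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.panel_dataset <- function(x, ...) x$data

n_units <- function(panel) length(panel$units)
n_periods <- function(panel) length(panel$periods)

# Urb scale policy: proportions taken as-is; percent-scaled columns (all
# values > 1.5) divided by 100; values in (1, 1.5] are ambiguous and rejected.
as_proportion <- function(x, name = "Urb") {
  mx <- max(x)
  mn <- min(x)
  if (mn < 0) stop(name, " contains negative values")
  if (mx <= 1) return(x)
  if (mx <= 1.5) {
    stop(name, " has values in (1, 1.5], ambiguous between percent and ",
         "proportion scales; rescale the input explicitly")
  }
  if (mn <= 1.5) {
    stop(name, " mixes proportion-scale and percent-scale values")
  }
  if (mx > 100) stop(name, " exceeds 100 on the percent scale")
  x / 100
}

#' Load a balanced panel from delimited text
#'
#' Reads a header-ed delimited file with one record per (unit, year), applies
#' the transforms in `spec` (log for strictly positive monetary/count
#' variables, proportion for the urbanization share), and returns a validated
#' [panel_dataset()].
#'
#' @param path Path to the delimited text file with columns
#'   `unit,year,<raw columns>`.
#' @param spec Variable specification; see [default_variable_spec()].
#' @param sep Field separator (default comma).
#' @return A `panel_dataset`.
#' @export
load_panel <- function(path, spec = default_variable_spec(), sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  needed <- c("unit", "year", spec$raw)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0L) {
    stop("input file is missing columns: ", paste(absent, collapse = ", "))
  }
  out <- data.frame(unit = as.character(raw$unit),
                    year = as.integer(raw$year),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(spec))) {
    x <- raw[[spec$raw[i]]]
    if (!is.numeric(x)) stop("column ", spec$raw[i], " is not numeric")
    out[[spec$name[i]]] <- switch(
      spec$transform[i],
      log = {
        if (any(x <= 0, na.rm = TRUE)) {
          stop("column ", spec$raw[i],
               " has nonpositive values; log transform requires > 0")
        }
        log(x)
      },
      proportion = as_proportion(x, spec$name[i]),
      identity = x,
      stop("unknown transform: ", spec$transform[i])
    )
  }
  outcome <- spec$name[1L]
  panel_dataset(out, outcome = outcome, regressors = spec$name[-1L],
                meta = list(source = path, spec = spec))
}

#' Write a panel back to delimited text
#'
#' Inverts the variable transforms (exponentiates log columns) and writes the
#' raw-scale table so that `load_panel(write_panel(p))` round-trips. A JSON
#' metadata sidecar (`<path>.meta.json`) records the package version and the
#' variable specification.
#'
#' @param panel A `panel_dataset`.
#' @param path Output file path.
#' @param spec Variable specification used to back-transform; defaults to the
#'   spec stored at load time, else [default_variable_spec()].
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, spec = NULL, sidecar = TRUE) {
  if (is.null(spec)) spec <- panel$meta$spec
  if (is.null(spec)) spec <- default_variable_spec()
  spec <- spec[match(c(panel$outcome, panel$regressors), spec$name), ]
  out <- data.frame(unit = panel$data$unit, year = panel$data$year,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(spec))) {
    x <- panel$data[[spec$name[i]]]
    out[[spec$raw[i]]] <- switch(spec$transform[i],
                                 log = exp(x),
                                 proportion = x,
                                 identity = x)
  }
  write_table(out, path)
  if (sidecar) {
    meta <- list(package = "sdmspill",
                 version = as.character(packageVersion("sdmspill")),
                 n_units = length(panel$units),
                 n_periods = length(panel$periods),
                 variables = spec[, c("name", "raw", "transform")])
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Full-precision deterministic delimited writer shared by all exporters.
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a panel by region
#'
#' @param panel A `panel_dataset`.
#' @param partition Data frame with columns `unit` and `region` covering every
#'   unit of the panel.
#' @return Named list of `panel_dataset` objects, one per region, each
#'   balanced over the same periods.
#' @export
partition_panel <- function(panel, partition) {
  stopifnot(is.data.frame(partition),
            all(c("unit", "region") %in% names(partition)))
  partition$unit <- as.character(partition$unit)
  if (anyDuplicated(partition$unit) > 0L) {
    stop("partition maps some units more than once")
  }
  absent <- setdiff(panel$units, partition$unit)
  if (length(absent) > 0L) {
    stop("units missing from partition: ", paste(absent, collapse = ", "))
  }
  regions <- unique(partition$region)
  out <- lapply(regions, function(r) {
    keep <- partition$unit[partition$region == r]
    sub <- panel$data[panel$data$unit %in% keep, , drop = FALSE]
    panel_dataset(sub, outcome = panel$outcome,
                  regressors = panel$regressors,
                  meta = c(panel$meta, list(region = r)))
  })
  names(out) <- regions
  out
}

#' Three-belt region partition of China's 31 provinces
#'
#' The standard National Bureau of Statistics east/central/west grouping with
#' 11, 8 and 12 provinces respectively. The split sizes are fixed by the
#' classification; membership is returned as data so it can be edited.
#'
#' @return Data frame with columns `unit`, `region`.
#' @export
china_regions <- function() {
  east <- c("Beijing", "Tianjin", "Hebei", "Liaoning", "Shanghai", "Jiangsu",
            "Zhejiang", "Fujian", "Shandong", "Guangdong", "Hainan")
  central <- c("Shanxi", "Jilin", "Heilongjiang", "Anhui", "Jiangxi",
               "Henan", "Hubei", "Hunan")
  west <- c("InnerMongolia", "Guangxi", "Chongqing", "Sichuan", "Guizhou",
            "Yunnan", "Tibet", "Shaanxi", "Gansu", "Qinghai", "Ningxia",
            "Xinjiang")
  data.frame(unit = c(east, central, west),
             region = rep(c("East", "Central", "West"),
                          times = c(11L, 8L, 12L)),
             stringsAsFactors = FALSE)
}

#' Assign units to regions by count
#'
#' Utility for synthetic panels: assigns the (sorted) units to regions in
#' order, with the given sizes (default the 11/8/12 three-belt split).
#'
#' @param units Character vector of unit labels.
#' @param sizes Named integer vector of region sizes summing to
#'   `length(units)`.
#' @return Data frame with columns `unit`, `region`.
#' @export
make_region_partition <- function(units,
                                  sizes = c(East = 11L, Central = 8L,
                                            West = 12L)) {
  if (sum(sizes) != length(units)) {
    stop("region sizes must sum to the number of units")
  }
  data.frame(unit = sort(units),
             region = rep(names(sizes), times = sizes),
             stringsAsFactors = FALSE)
}

#' Read a unit-to-region partition file
#'
#' @param path Delimited text with header `unit,region`.
#' @param sep Field separator.
#' @return Data frame with columns `unit`, `region`.
#' @export
read_partition <- function(path, sep = ",") {
  p <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("unit", "region") %in% names(p)))
  p
}
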