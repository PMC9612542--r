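#' Factor catalog
#'
#' A catalog maps every boolean crash item to a descriptive category (the
#' groups of Table-1-style descriptive statistics, e.g. "Violation" or
#' "Terrain") and to a system-level construct (driver, vehicle, roadway,
#' environment, crash, or context), and records which item sets are mutually
#' exclusive within a single crash record (a crash has one severity level, one
#' terrain, one posted speed limit band, ...).
#'
#' @param items character vector of item identifiers, normalised as
#'   `"Category: level"` strings.
#' @param category character vector, same length as `items`: descriptive
#'   category of each item.
#' @param construct character vector, same length as `items`: one of
#'   `"driver"`, `"vehicle"`, `"roadway"`, `"environment"`, `"crash"`,
#'   `"context"`.
#' @param exclusive_groups named list of character vectors; each vector is a
#'   set of items of which at most one may be true in any record. Groups must
#'   be pairwise disjoint.
#' @param marginal optional numeric vector of reference marginal frequencies
#'   (fractions in `[0, 1]`) per item, used as synthetic-generator defaults.
#' @return An object of class `factor_catalog`: a data frame with columns
#'   `item`, `category`, `construct` (and `marginal` if supplied), carrying the
#'   exclusive groups as an attribute.
#' @seealso [default_catalog()], [read_catalog()], [validate_transactions()]
#' @export
factor_catalog <- function(items, category, construct,
                           exclusive_groups = list(), marginal = NULL) {
  stopifnot(is.character(items), length(items) > 0)
  if (anyDuplicated(items)) {
    stop("duplicate item identifiers in catalog: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  }
  if (length(category) != length(items) || length(construct) != length(items)) {
    stop("`category` and `construct` must have one entry per item")
  }
  bad <- setdiff(unique(construct), CONSTRUCT_LEVELS)
  if (length(bad)) {
    stop("unknown construct(s): ", paste(bad, collapse = ", "))
  }
  if (!is.list(exclusive_groups)) stop("`exclusive_groups` must be a list")
  all_grp <- unlist(exclusive_groups, use.names = FALSE)
  if (length(all_grp)) {
    unknown <- setdiff(all_grp, items)
    if (length(unknown)) {
      stop("exclusive group refers to unknown item(s): ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(all_grp)) {
      stop("exclusive groups must be pairwise disjoint")
    }
  }
  cat_df <- data.frame(item = items, category = category,
                       construct = construct, stringsAsFactors = FALSE)
  if (!is.null(marginal)) {
    stopifnot(length(marginal) == length(items),
              all(is.na(marginal) | (marginal >= 0 & marginal <= 1)))
    cat_df$marginal <- marginal
  }
  attr(cat_df, "exclusive_groups") <- exclusive_groups
  class(cat_df) <- c("factor_catalog", "data.frame")
  cat_df
}

CONSTRUCT_LEVELS <- c("driver", "vehicle", "roadway", "environment",
                      "crash", "context")

#' Mutually exclusive item groups of a catalog
#' @param catalog a [factor_catalog()].
#' @return Named list of character vectors.
#' @export
exclusive_groups <- function(catalog) {
  stopifnot(inherits(catalog, "factor_catalog"))
  attr(catalog, "exclusive_groups")
}

#' @export
print.factor_catalog <- function(x, ...) {
  cat(sprintf("<factor_catalog> %d items, %d categories, %d exclusive groups\n",
              nrow(x), length(unique(x$category)),
              length(attr(x, "exclusive_groups"))))
  tab <- table(x$category)
  cat(paste(sprintf("  %-18s %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

# Default catalog rows: 84 items in 18 descriptive categories, each mapped to a
# system-level construct. Marginals are reference frequencies of the
# multi-fatality crash data the package is designed around (percent column of
# the descriptive statistics; the "Curve" aggregate alignment row is not an
# item -- curve geometry enters via up/down-curve and the radius classes).
default_catalog_rows <- function() {
  r <- function(item, category, construct, pct)
    data.frame(item = item, category = category, construct = construct,
               pct = pct, stringsAsFactors = FALSE)
  do.call(rbind, list(
    r("Severity: A",                 "Severity",          "context",     64.7),
    r("Severity: B",                 "Severity",          "context",     35.3),
    r("Time: workday",               "Time",              "context",     57.4),
    r("Time: weekend",               "Time",              "context",     42.6),
    r("Time: 0:00-6:00",             "Time",              "context",     20.6),
    r("Time: 7:00-12:00",            "Time",              "context",     25.1),
    r("Time: 13:00-17:00",           "Time",              "context",     29.6),
    r("Time: 18:00-23:00",           "Time",              "context",     24.1),
    r("Terrain: plain",              "Terrain",           "environment", 53.8),
    r("Terrain: mountainous",        "Terrain",           "environment", 46.2),
    r("Veh num = 1",                 "Veh num",           "crash",       22.1),
    r("Veh num = 2",                 "Veh num",           "crash",       54.6),
    r("Veh num >= 3",                "Veh num",           "crash",       23.3),
    r("Veh type: light-duty",        "Veh type",          "vehicle",     28.5),
    r("Veh type: truck",             "Veh type",          "vehicle",     42.3),
    r("Veh type: bus",               "Veh type",          "vehicle",     34.2),
    r("Light: daylight",             "Light",             "environment", 54.3),
    r("Light: dark",                 "Light",             "environment", 21.3),
    r("Light: dark without light",   "Light",             "environment", 24.3),
    r("Segment: uphill",             "Segment",           "roadway",      4.1),
    r("Segment: downhill",           "Segment",           "roadway",     11.05),
    r("Segment: up-curve",           "Segment",           "roadway",      2.8),
    r("Segment: down-curve",         "Segment",           "roadway",     19.2),
    r("Segment: radius < 500 m",     "Segment",           "roadway",     16.4),
    r("Segment: radius 500-1000 m",  "Segment",           "roadway",     14.8),
    r("Segment: radius > 1000 m",    "Segment",           "roadway",      6.0),
    r("Segment: grade >= 4%",        "Segment",           "roadway",     18.6),
    r("Segment: grade 2-4%",         "Segment",           "roadway",     21.2),
    r("Segment: straight",           "Segment",           "roadway",     51.1),
    r("Segment: intersection",       "Segment",           "roadway",     11.3),
    r("Segment: bridge/tunnel",      "Segment",           "roadway",      7.9),
    r("Segment: ramp/interchange",   "Segment",           "roadway",      5.6),
    r("Crash: head-on",              "Crash type",        "crash",       33.1),
    r("Crash: rear-end",             "Crash type",        "crash",       26.9),
    r("Crash: angle",                "Crash type",        "crash",       12.54),
    r("Crash: sideswipe",            "Crash type",        "crash",        2.0),
    r("Crash: hit object",           "Crash type",        "crash",       11.8),
    r("Crash: skidding",             "Crash type",        "crash",       18.4),
    r("Crash: rollover/overturn",    "Crash type",        "crash",       28.7),
    r("Crash: falling/immersion",    "Crash type",        "crash",       13.8),
    r("Lanes num <= 2",              "Lanes",             "roadway",     49.8),
    r("Lanes num > 2",               "Lanes",             "roadway",     50.2),
    r("Location: roadside",          "Location",          "crash",       31.36),
    r("Location: roadway",           "Location",          "crash",       62.9),
    r("Location: barrier/shoulder",  "Location",          "crash",        5.9),
    r("Env: rain",                   "Environment",       "environment", 21.8),
    r("Env: snow",                   "Environment",       "environment",  5.1),
    r("Env: wet/slippery",           "Environment",       "environment", 28.4),
    r("Deform: disabled",            "Deform",            "vehicle",     77.43),
    r("Deform: functional",          "Deform",            "vehicle",     19.0),
    r("Deform: minor",               "Deform",            "vehicle",      3.5),
    r("Violation: unlicensed",       "Violation",         "driver",      10.7),
    r("Violation: alcohol",          "Violation",         "driver",      12.9),
    r("Violation: speeding",         "Violation",         "driver",      31.0),
    r("Violation: improper lane usage", "Violation",      "driver",      33.0),
    r("Violation: insufficient distance", "Violation",    "driver",      23.5),
    r("Violation: improper operations", "Violation",      "driver",      23.4),
    r("Violation: illegal overtaking", "Violation",       "driver",      28.4),
    r("Violation: dangerous driving", "Violation",        "driver",      18.2),
    r("Violation: passenger overload", "Violation",       "vehicle",     28.1),
    r("Violation: overspeed > 20%",  "Violation",         "vehicle",     30.5),
    r("Violation: overspeed < 20%",  "Violation",         "vehicle",     18.1),
    r("Violation: low speed",        "Violation",         "vehicle",      1.8),
    r("Limit speed > 80 km/h",       "Limit speed",       "roadway",     39.6),
    r("Limit speed 60-80 km/h",      "Limit speed",       "roadway",     35.1),
    r("Limit speed < 60 km/h",       "Limit speed",       "roadway",     25.3),
    r("Dr: fatigue/impaired",        "Driver condition",  "driver",      25.5),
    r("Dr: unfamiliar",              "Driver condition",  "driver",      18.0),
    r("Dr: normal",                  "Driver condition",  "context",     56.5),
    r("Road: freeway",               "Road category",     "roadway",     28.7),
    r("Road: 1st-class highway",     "Road category",     "roadway",     17.5),
    r("Road: 2nd-class highway",     "Road category",     "roadway",     39.2),
    r("Road: lower-level road",      "Road category",     "roadway",     11.7),
    r("Road: urban road",            "Road category",     "roadway",      2.9),
    r("Veh cond: loss of control",   "Vehicle condition", "vehicle",     19.5),
    r("Veh cond: tire/brake failure", "Vehicle condition", "vehicle",    27.2),
    r("Veh cond: fire",              "Vehicle condition", "vehicle",      7.0),
    r("Veh cond: overweight",        "Vehicle condition", "vehicle",     25.7),
    r("Veh cond: unknown",           "Vehicle condition", "vehicle",     21.1),
    r("Traffic: free flow",          "Traffic",           "environment", 28.9),
    r("Traffic: stable flow",        "Traffic",           "environment", 20.31),
    r("Traffic: congestion",         "Traffic",           "environment", 11.9),
    r("Traffic: oversaturation",     "Traffic",           "environment", 10.0),
    r("Traffic: unknown",            "Traffic",           "environment", 28.8)
  ))
}

#' Default multi-fatality crash factor catalog
#'
#' The catalog the package ships for severe (3+ fatality) road-crash records:
#' 84 boolean items in 18 descriptive categories, each mapped to a
#' system-level construct. Items whose descriptive category is a driving
#' violation but whose substance is the vehicle state (passenger overload,
#' travelling over/under speed) are assigned to the vehicle construct; the
#' "normal" driver condition and the severity/time items are context, so that
#' construct-combination profiles count genuine contributing factors only.
#'
#' @return A [factor_catalog()] with a `marginal` column of reference
#'   frequencies (fractions) usable as synthetic-generator defaults.
#' @examples
#' cat84 <- default_catalog()
#' nrow(cat84)                      # 84
#' length(unique(cat84$category))   # 18
#' @export
default_catalog <- function() {
  rows <- default_catalog_rows()
  items <- rows$item
  grp <- function(category) items[rows$category == category]
  groups <- list(
    severity      = grp("Severity"),
    day_type      = c("Time: workday", "Time: weekend"),
    time_of_day   = c("Time: 0:00-6:00", "Time: 7:00-12:00",
                      "Time: 13:00-17:00", "Time: 18:00-23:00"),
    terrain       = grp("Terrain"),
    veh_num       = grp("Veh num"),
    light         = grp("Light"),
    lanes         = grp("Lanes"),
    location      = grp("Location"),
    deform        = grp("Deform"),
    limit_speed   = grp("Limit speed"),
    driver_cond   = grp("Driver condition"),
    road_category = grp("Road category"),
    traffic       = grp("Traffic")
  )
  factor_catalog(items, rows$category, rows$construct,
                 exclusive_groups = groups, marginal = rows$pct / 100)
}

#' Read a factor catalog from a YAML or JSON document
#'
#' The document must contain a list `items` of records with fields `item`,
#' `category`, `construct` and optionally `marginal`, plus an optional named
#' mapping `exclusive_groups` of group name to item list.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` vs
#'   `.json`).
#' @return A [factor_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$items)) stop("catalog document has no `items` list")
  items <- vapply(doc$items, function(x) as.character(x$item), "")
  category <- vapply(doc$items, function(x) as.character(x$category), "")
  construct <- vapply(doc$items, function(x) as.character(x$construct), "")
  marginal <- vapply(doc$items, function(x) {
    if (is.null(x$marginal)) NA_real_ else as.numeric(x$marginal)
  }, 0)
  if (all(is.na(marginal))) marginal <- NULL
  groups <- lapply(doc$exclusive_groups, function(g) as.character(unlist(g)))
  factor_catalog(items, category, construct,
                 exclusive_groups = groups, marginal = marginal)
}

#' Write a factor catalog as YAML
#' @param catalog a [factor_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "factor_catalog"))
  items <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- list(item = catalog$item[i], category = catalog$category[i],
                construct = catalog$construct[i])
    if (!is.null(catalog$marginal) && !is.na(catalog$marginal[i])) {
      rec$marginal <- catalog$marginal[i]
    }
    rec
  })
  yaml::write_yaml(list(items = items,
                        exclusive_groups = attr(catalog, "exclusive_groups")),
                   path)
  invisible(path)
}

#' Items belonging to a construct
#' @param catalog a [factor_catalog()].
#' @param construct construct name, e.g. `"driver"`.
#' @return Character vector of item identifiers.
#' @export
construct_items <- function(catalog, construct) {
  stopifnot(inherits(catalog, "factor_catalog"))
  catalog$item[catalog$construct == construct]
}
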