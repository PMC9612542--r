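#' Boolean transaction table
#'
#' The universe over which all rule metrics are computed: N crash records by M
#' boolean items. Support of an itemset is the fraction of records in which
#' every item of the set is true.
#'
#' @param x logical (or 0/1) matrix or data frame, records in rows, items in
#'   columns; column names are the item identifiers.
#' @param catalog optional [factor_catalog()] to attach.
#' @param provenance free-text description of where the table came from.
#' @return An object of class `transaction_table` with elements `matrix`
#'   (logical, with column names), `catalog`, `provenance`.
#' @export
transaction_table <- function(x, catalog = NULL, provenance = "") {
  m <- as.matrix(x)
  if (is.numeric(m)) {
    if (any(!m %in% c(0, 1) & !is.na(m))) {
      stop("transaction matrix must be boolean (0/1/TRUE/FALSE)")
    }
    storage.mode(m) <- "logical"
  }
  if (!is.logical(m)) stop("transaction matrix must be boolean")
  if (is.null(colnames(m))) stop("transaction matrix needs item column names")
  if (anyDuplicated(colnames(m))) {
    stop("duplicate item identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (nrow(m) == 0) stop("empty table: no records")
  if (!is.null(catalog)) stopifnot(inherits(catalog, "factor_catalog"))
  structure(list(matrix = m, catalog = catalog, provenance = provenance),
            class = "transaction_table")
}

#' @export
print.transaction_table <- function(x, ...) {
  cat(sprintf("<transaction_table> %d records x %d items%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (nzchar(x$provenance)) paste0(" (", x$provenance, ")") else ""))
  invisible(x)
}

#' Number of records in a transaction table
#' @param table a [transaction_table()].
#' @return Integer record count (the N of the support denominator).
#' @export
n_records <- function(table) {
  stopifnot(inherits(table, "transaction_table"))
  nrow(table$matrix)
}

#' Item identifiers of a transaction table
#' @param table a [transaction_table()].
#' @return Character vector of item names.
#' @export
items <- function(table) {
  stopifnot(inherits(table, "transaction_table"))
  colnames(table$matrix)
}

is_boolish <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(TRUE)
  if (is.logical(v)) return(TRUE)
  if (is.numeric(v)) return(all(v %in% c(0, 1)))
  if (is.character(v)) {
    return(all(trimws(v) %in% c("0", "1", "TRUE", "FALSE", "true", "false")))
  }
  FALSE
}

to_logical <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v == 1)
  trimws(as.character(v)) %in% c("1", "TRUE", "true")
}

#' Load a crash-record CSV as a boolean transaction table
#'
#' Accepts either an already-boolean table (0/1 or TRUE/FALSE columns named by
#' item) or raw categorical columns, which are one-hot expanded against the
#' catalog: a categorical column `Cat` with value `lvl` sets the item
#' `"Cat: lvl"`. Blank or missing categorical values expand to all-false
#' across that category's items (the record is kept; no value is invented).
#' Columns (or expanded items) unknown to the catalog are retained and
#' reported with a warning, never silently dropped.
#'
#' @param path CSV file (UTF-8, comma-separated, header row).
#' @param catalog optional [factor_catalog()]; required to one-hot raw
#'   categorical columns against normalised item labels.
#' @param strict if `TRUE`, exclusivity violations against the catalog raise
#'   an error; by default they only warn (published crash data may contain
#'   coding noise).
#' @return A [transaction_table()].
#' @export
load_crash_table <- function(path, catalog = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  hdr <- utils::read.csv(path, check.names = FALSE, nrows = 1)
  if (anyDuplicated(names(hdr))) {
    stop("duplicate header names: ",
         paste(unique(names(hdr)[duplicated(names(hdr))]), collapse = ", "))
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)

  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is_boolish(v)) {
      out <- matrix(to_logical(v) & !is.na(v), ncol = 1,
                    dimnames = list(NULL, nm))
      return(out)
    }
    # raw categorical column: one-hot against "Column: level" item labels
    v <- trimws(as.character(v))
    v[is.na(v)] <- ""
    lev <- sort(unique(v[nzchar(v)]))
    out <- vapply(lev, function(l) v == l, logical(length(v)))
    if (!length(lev)) out <- matrix(logical(length(v)), ncol = 0)
    colnames(out) <- paste0(nm, ": ", lev)
    out
  })
  m <- do.call(cbind, cols)
  if (is.null(m) || ncol(m) == 0) stop("empty table: no items in ", path)

  tab <- transaction_table(m, catalog = catalog, provenance = path)
  if (!is.null(catalog)) {
    rep <- validate_transactions(tab, catalog)
    if (length(rep$unknown_items)) {
      warning("items not in catalog (retained): ",
              paste(rep$unknown_items, collapse = ", "))
    }
    if (nrow(rep$violations)) {
      msg <- sprintf("%d record(s) violate exclusive groups (e.g. record %d, group %s)",
                     length(unique(rep$violations$record)),
                     rep$violations$record[1], rep$violations$group[1])
      if (strict) stop(msg) else warning(msg)
    }
  }
  tab
}

#' Write a transaction table as a 0/1 CSV
#'
#' Inverse of [load_crash_table()] for boolean tables: a load-write-load
#' round trip reproduces the matrix exactly.
#'
#' @param table a [transaction_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(table, path) {
  stopifnot(inherits(table, "transaction_table"))
  m <- table$matrix
  storage.mode(m) <- "integer"
  utils::write.csv(as.data.frame(m, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Marginal support of an itemset
#'
#' The fraction of records in which every item of the set is true:
#' `Supp(X) = #(X) / N`. The empty itemset has support 1 (a vacuous
#' conjunction holds in every record).
#'
#' @param table a [transaction_table()].
#' @param itemset character vector of item identifiers (possibly empty).
#' @return Fraction in `[0, 1]`.
#' @examples
#' m <- cbind(A = c(1, 1, 0), B = c(0, 1, 1))
#' tab <- transaction_table(m)
#' marginal_support(tab, c("A", "B"))  # 1/3
#' @export
marginal_support <- function(table, itemset) {
  stopifnot(inherits(table, "transaction_table"))
  itemset <- unique(as.character(itemset))
  if (!length(itemset)) return(1)
  unknown <- setdiff(itemset, items(table))
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  sub <- table$matrix[, itemset, drop = FALSE]
  mean(rowSums(sub) == length(itemset))
}

#' Validate a transaction table against a catalog
#'
#' Reports (without failing) every record in which more than one item of an
#' exclusive group is true, the items absent from the catalog, and per-item
#' missing-value rates.
#'
#' @param table a [transaction_table()].
#' @param catalog a [factor_catalog()].
#' @return An object of class `validation_report`: list with `violations`
#'   (data frame `record`, `group`, `items`, ordered by record index),
#'   `unknown_items` (character), `missing_rates` (named numeric).
#' @export
validate_transactions <- function(table, catalog) {
  stopifnot(inherits(table, "transaction_table"),
            inherits(catalog, "factor_catalog"))
  m <- table$matrix
  unknown <- setdiff(colnames(m), catalog$item)

  viol <- list()
  for (gname in names(exclusive_groups(catalog))) {
    g <- intersect(exclusive_groups(catalog)[[gname]], colnames(m))
    if (length(g) < 2) next
    hits <- rowSums(m[, g, drop = FALSE], na.rm = TRUE)
    for (i in which(hits > 1)) {
      on <- g[which(m[i, g])]
      viol[[length(viol) + 1L]] <- data.frame(
        record = i, group = gname,
        items = paste(on, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  violations <- if (length(viol)) {
    v <- do.call(rbind, viol)
    v[order(v$record, v$group), , drop = FALSE]
  } else {
    data.frame(record = integer(), group = character(),
               items = character(), stringsAsFactors = FALSE)
  }
  structure(list(violations = violations,
                 unknown_items = unknown,
                 missing_rates = colMeans(is.na(m))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d violation(s), %d unknown item(s)\n",
              nrow(x$violations), length(x$unknown_items)))
  invisible(x)
}

#' Per-record construct profile
#'
#' For each record, the set of system-level constructs (driver, vehicle,
#' roadway, environment) with at least one true item. Context items (time,
#' severity, the "normal" driver condition) and the crash-outcome construct do
#' not count as contributing-factor constructs.
#'
#' @param table a [transaction_table()].
#' @param catalog a [factor_catalog()]; defaults to the one attached to the
#'   table.
#' @return List of length `n_records(table)`; each element a character vector,
#'   a subset of `c("driver", "vehicle", "roadway", "environment")`.
#' @seealso [combination_profile()] for the aggregated Venn-cell fractions.
#' @export
construct_profile <- function(table, catalog = table$catalog) {
  stopifnot(inherits(table, "transaction_table"))
  if (is.null(catalog)) stop("a catalog is required for construct profiles")
  constructs <- c("driver", "vehicle", "roadway", "environment")
  m <- table$matrix
  present <- vapply(constructs, function(con) {
    its <- intersect(construct_items(catalog, con), colnames(m))
    if (!length(its)) return(logical(nrow(m)))
    rowSums(m[, its, drop = FALSE], na.rm = TRUE) > 0
  }, logical(nrow(m)))
  lapply(seq_len(nrow(m)), function(i) constructs[present[i, ]])
}
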