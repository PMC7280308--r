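# Parameter tables: the carrier for kinetic constants, HIF-1 induction
# constants, initial conditions, boundary values and oxygen-map parameters.
# The on-disk form is a plain CSV with columns
#   scope, id, parameter, value, unit, provenance
# mirroring a transcription of a published parameter/initial-condition table.

.unit_vocabulary <- c("mM", "mM/min", "1/min", "level/(uM*min)", "uM",
                      "percent", "dimensionless", "level")

.ps_required_columns <- c("scope", "id", "parameter", "value", "unit",
                          "provenance")

#' Construct a parameter set
#'
#' A `parameter_set` is a validated table of model constants keyed by
#' `(scope, id, parameter)`. Scopes used by the reference model are
#' `species` (initial conditions), `boundary` (fixed boundary values),
#' `reaction` (kinetic constants), `coupling` (`K_Eh` induction constants),
#' `pdh_cycle` (the PDK/PDP interconversion constants) and `oxygen_map`
#' (the oxygen to HIF-1 mapping). Each entry carries a unit from a fixed
#' vocabulary and a provenance string (`literature`, `database` or
#' `calibrated`).
#'
#' @param table data.frame with columns scope, id, parameter, value, unit,
#'   provenance.
#' @return an object of class `parameter_set`.
#' @seealso [load_parameters()], [save_parameters()]
#' @export
parameter_set <- function(table) {
  if (!is.data.frame(table)) {
    stop("format error: parameter table must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(.ps_required_columns, names(table))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table <- table[, .ps_required_columns]
  table$scope <- as.character(table$scope)
  table$id <- as.character(table$id)
  table$parameter <- as.character(table$parameter)
  table$unit <- as.character(table$unit)
  table$provenance <- as.character(table$provenance)
  table$value <- as.numeric(table$value)

  bad_unit <- which(!table$unit %in% .unit_vocabulary)
  if (length(bad_unit) > 0L) {
    stop("validation error: unknown unit '", table$unit[bad_unit[1L]],
         "' in row ", bad_unit[1L], call. = FALSE)
  }
  bad_value <- which(!is.finite(table$value) | table$value < 0)
  if (length(bad_value) > 0L) {
    stop("validation error: non-finite or negative value in row ",
         bad_value[1L], " (", table$scope[bad_value[1L]], "/",
         table$id[bad_value[1L]], "/", table$parameter[bad_value[1L]], ")",
         call. = FALSE)
  }
  key <- paste(table$scope, table$id, table$parameter, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("validation error: duplicated entry ",
         gsub("\r", "/", dup, fixed = TRUE), call. = FALSE)
  }
  structure(list(table = table), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  tab <- x$table
  cat("<parameter_set> ", nrow(tab), " entries\n", sep = "")
  counts <- table(tab$scope)
  cat("  scopes: ",
      paste(sprintf("%s (%d)", names(counts), as.integer(counts)),
            collapse = ", "), "\n", sep = "")
  prov <- table(tab$provenance)
  cat("  provenance: ",
      paste(sprintf("%s (%d)", names(prov), as.integer(prov)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) x$table

# Scalar lookup with a named-parameter error on absence.
ps_value <- function(ps, scope, id, parameter, required = TRUE) {
  tab <- ps$table
  hit <- tab$scope == scope & tab$id == id & tab$parameter == parameter
  if (!any(hit)) {
    if (required) {
      stop("named-parameter error: missing parameter '", parameter,
           "' for ", scope, " '", id, "'", call. = FALSE)
    }
    return(NA_real_)
  }
  tab$value[which(hit)[1L]]
}

ps_has <- function(ps, scope, id, parameter) {
  tab <- ps$table
  any(tab$scope == scope & tab$id == id & tab$parameter == parameter)
}

# Replace (or add) one entry, returning a new parameter_set.
ps_set <- function(ps, scope, id, parameter, value, unit = NULL,
                   provenance = "calibrated") {
  tab <- ps$table
  hit <- which(tab$scope == scope & tab$id == id & tab$parameter == parameter)
  if (length(hit) == 1L) {
    tab$value[hit] <- value
    tab$provenance[hit] <- provenance
  } else {
    if (is.null(unit)) {
      stop("validation error: unit required when adding a new entry",
           call. = FALSE)
    }
    tab <- rbind(tab, data.frame(scope = scope, id = id,
                                 parameter = parameter, value = value,
                                 unit = unit, provenance = provenance,
                                 stringsAsFactors = FALSE))
  }
  parameter_set(tab)
}

#' Load a parameter set from CSV
#'
#' Reads a comma-separated parameter table (UTF-8, dot decimal, header row)
#' with columns `scope, id, parameter, value, unit, provenance` and returns a
#' validated [parameter_set()]. Unknown units and negative or non-finite
#' values are rejected with the offending row identified.
#'
#' @param path path to a CSV file.
#' @return a `parameter_set`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: parameter file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.ps_required_columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  suppressWarnings(tab$value <- as.numeric(tab$value))
  parameter_set(tab)
}

#' Save a parameter set to CSV
#'
#' Writes the table in a deterministic order (sorted by scope, id,
#' parameter) with 17-significant-digit round-trip number formatting, so that
#' repeated saves of the same set are byte-identical and a save/load
#' round trip reproduces the set exactly.
#'
#' @param ps a [parameter_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  tab <- ps$table
  if (any(!is.finite(tab$value))) {
    stop("validation error: parameter set contains non-finite values",
         call. = FALSE)
  }
  ord <- order(tab$scope, tab$id, tab$parameter, method = "radix")
  tab <- tab[ord, ]
  out <- data.frame(scope = tab$scope, id = tab$id,
                    parameter = tab$parameter,
                    value = sprintf("%.17g", tab$value),
                    unit = tab$unit, provenance = tab$provenance,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(unname(out), list(sep = ","))), con)
  invisible(path)
}

#' Reference parameter set of the glycolysis model
#'
#' Loads the calibrated parameter/initial-condition table shipped with the
#' package. This fixture was produced by [calibrate_reference_fixture()] and
#' puts the normoxic pathway at steady state with a baseline intracellular
#' lactate of 5.66 mM; entries tuned during calibration carry provenance
#' `calibrated`.
#'
#' @return a [parameter_set()].
#' @export
reference_parameters <- function() {
  path <- system.file("extdata", "reference_parameters.csv",
                      package = "glycohif", mustWork = TRUE)
  load_parameters(path)
}
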