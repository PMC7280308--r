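# Oxygen to HIF-1 mapping. Hypoxia enters the pathway model only through
# the HIF-1 concentration; this module translates an ambient oxygen
# percentage into that forcing input with a monotone nonincreasing inverse
# Hill curve, a minimal parametric stand-in for the published O2/HIF-1
# input-output relationship.

#' Oxygen to HIF-1 map
#'
#' Defines the monotone nonincreasing mapping
#' `HIF(o2) = H_basal + (H_max - H_basal) * o2_half^n / (o2_half^n + o2^n)`
#' from ambient oxygen percentage to HIF-1 concentration. At 0% oxygen the
#' map returns `H_max`; at the half point `o2_half` it returns the midpoint
#' between `H_basal` and `H_max`; at normoxia (21%) it is close to
#' `H_basal`.
#'
#' @param H_max maximal HIF-1 level at 0% oxygen (uM).
#' @param H_basal normoxic HIF-1 level (uM), `0 <= H_basal < H_max`.
#' @param o2_half oxygen percentage at half-maximal HIF-1, > 0.
#' @param hill_n steepness exponent, >= 1.
#' @return an object of class `oxygen_hif_map`.
#' @export
oxygen_hif_map <- function(H_max = 1, H_basal = 0, o2_half = 1.2,
                           hill_n = 2.8) {
  if (!(H_max > H_basal) || H_basal < 0) {
    stop("parameter-domain error: need H_max > H_basal >= 0", call. = FALSE)
  }
  if (o2_half <= 0) {
    stop("parameter-domain error: o2_half must be > 0", call. = FALSE)
  }
  if (hill_n < 1) {
    stop("parameter-domain error: hill_n must be >= 1", call. = FALSE)
  }
  structure(list(H_max = H_max, H_basal = H_basal, o2_half = o2_half,
                 hill_n = hill_n), class = "oxygen_hif_map")
}

#' @export
print.oxygen_hif_map <- function(x, ...) {
  cat(sprintf(paste0("<oxygen_hif_map> H_max = %g uM, H_basal = %g uM, ",
                     "o2_half = %g%%, hill_n = %g\n"),
              x$H_max, x$H_basal, x$o2_half, x$hill_n))
  invisible(x)
}

#' Convert an oxygen percentage to a HIF-1 concentration
#'
#' @param map an [oxygen_hif_map()].
#' @param o2_percent ambient oxygen in percent, within `[0, 21]`.
#' @return HIF-1 concentration in uM, within `[H_basal, H_max]`.
#' @examples
#' m <- oxygen_hif_map(H_max = 1)
#' o2_to_hif(m, 0)    # H_max
#' o2_to_hif(m, 21)   # near H_basal
#' @export
o2_to_hif <- function(map, o2_percent) {
  stopifnot(inherits(map, "oxygen_hif_map"))
  if (!is.numeric(o2_percent) || any(is.na(o2_percent)) ||
      any(o2_percent < 0) || any(o2_percent > 21)) {
    stop("input-domain error: o2_percent must lie in [0, 21]", call. = FALSE)
  }
  h <- map$o2_half^map$hill_n
  map$H_basal + (map$H_max - map$H_basal) * h / (h + o2_percent^map$hill_n)
}
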