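#' Convert a tagged quantity to SI base units
#'
#' Internal unit handling: all lengths are metres and all attenuation
#' coefficients are 1/m inside the package. Configuration files may tag
#' values with the units common in tissue optics (\code{"cm-1"}, \code{"mm"},
#' \code{"um"}, \code{"nm"}, ...) and they are converted on load.
#'
#' @param value numeric vector.
#' @param unit unit tag; one of \code{"m"}, \code{"cm"}, \code{"mm"},
#'   \code{"um"}, \code{"nm"} for lengths and \code{"1/m"} (alias
#'   \code{"m-1"}), \code{"1/cm"} (\code{"cm-1"}), \code{"1/mm"}
#'   (\code{"mm-1"}) for coefficients.
#' @return numeric vector in SI units (m or 1/m).
#' @examples
#' toSI(45.9, "1/cm")   # 4590 1/m
#' toSI(100, "um")      # 1e-4 m
#' @export
toSI <- function(value, unit) {
  stopifnot(is.numeric(value), is.character(unit), length(unit) == 1L)
  factor <- switch(unit,
    "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9,
    "1/m" = 1, "m-1" = 1,
    "1/cm" = 1e2, "cm-1" = 1e2,
    "1/mm" = 1e3, "mm-1" = 1e3,
    stop("unknown unit tag: ", unit)
  )
  value * factor
}
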