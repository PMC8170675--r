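# CSV exchange for the small tabular inputs (isotherms, spacer series,
# denaturation curves, occupancy counts)

#' Read and write binding isotherms and spacer series as CSV
#'
#' Isotherm files carry columns `x` (ligand concentration, nM), `f` (bound
#' fraction) and optionally `f_err`; spacer-series files carry `ds` (bp),
#' `y` and optionally `y_err` plus a `kind` recorded in the header comment
#' argument.
#'
#' @param path file path.
#' @param data the object to write.
#' @param kind series kind for [read_spacer_series()].
#' @return the read object.
#' @export
read_isotherm <- function(path) {
  x <- utils::read.csv(path)
  stop_if_not(all(c("x", "f") %in% names(x)),
              "isotherm file needs columns x and f")
  structure(x, class = c("binding_isotherm", "data.frame"))
}

#' @rdname read_isotherm
#' @export
write_isotherm <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_isotherm
#' @export
read_spacer_series <- function(path, kind = c("energy", "hill", "gel_fraction")) {
  kind <- match.arg(kind)
  x <- utils::read.csv(path)
  stop_if_not(all(c("ds", "y") %in% names(x)),
              "spacer-series file needs columns ds and y")
  spacer_series(x$ds, x$y, y_err = x$y_err %||% NA_real_, kind = kind)
}

#' @rdname read_isotherm
#' @export
write_spacer_series <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_isotherm
#' @export
read_denaturation_curve <- function(path) {
  x <- utils::read.csv(path)
  stop_if_not(all(c("x", "R") %in% names(x)),
              "denaturation file needs columns x and R")
  structure(x, class = c("denaturation_curve", "data.frame"))
}
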