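CULTIVAR_KEYS <- c("Gv", "A", "Th", "DVI_star", "Lc", "Bp",
                   "Gr", "Kr", "Tcr",
                   "C0", "Rm", "Kc", "Cf", "Bf", "tf",
                   "hm", "Kh", "gamma0", "Kq", "aq",
                   "LAI_max", "k_beer", "LAI_rise", "LAI_end_frac")

#' Cultivar parameter set
#'
#' Loads the constants of the crop model for one cultivar from a flat
#' `key: value` text config (comment lines start with `#`). With no
#' arguments, the packaged Koshihikari-like synthetic calibration is
#' used; individual values can be overridden through `...`.
#'
#' The parameter groups are: vegetative phenology (`Gv`, `A`, `Th`,
#' `DVI_star`, `Lc`, `Bp`), grain-filling phenology (`Gr`, `Kr`, `Tcr`),
#' radiation conversion and CO2 response (`C0`, `Rm`, `Kc`, `Cf`, `Bf`,
#' `tf`), harvest index and sterility (`hm`, `Kh`, `gamma0`, `Kq`, `aq`),
#' and the canopy surrogate (`LAI_max`, `k_beer`, `LAI_rise`,
#' `LAI_end_frac`). See the config file for units.
#'
#' @param file Path to a parameter config; `NULL` for the packaged set.
#' @param ... Named numeric overrides of individual parameters.
#' @return A named list of class `cultivar_params`.
#' @examples
#' p <- cultivar_params()
#' p$Gv
#' cooler <- cultivar_params(Th = 16)
#' @export
cultivar_params <- function(file = NULL, ...) {
  if (is.null(file)) {
    file <- system.file("extdata", "cultivar_koshihikari_synthetic.txt",
                        package = "cropdistill", mustWork = TRUE)
  }
  lines <- readLines(file, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- vapply(kv, function(x) as.numeric(trimws(paste(x[-1], collapse = ":"))),
                 numeric(1))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  p <- as.list(vals)

  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), CULTIVAR_KEYS)
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  missing <- setdiff(CULTIVAR_KEYS, names(p))
  if (length(missing)) stop("config missing parameter(s): ",
                            paste(missing, collapse = ", "))
  p <- p[CULTIVAR_KEYS]
  stopifnot(p$Gv > 0, p$Gr > 0, p$hm > 0, p$hm <= 1,
            p$Lc > 0, p$Lc < 24, p$aq > 0, p$k_beer > 0)
  structure(p, class = "cultivar_params")
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat("<cultivar_params>\n")
  for (k in names(x)) cat(sprintf("  %-13s %g\n", k, x[[k]]))
  invisible(x)
}
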