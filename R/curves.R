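#' True-stress / true-strain curve
#'
#' Container for a sampled material response: logarithmic (true) strain
#' against Cauchy (true) stress in kPa, tagged with a mode label
#' identifying the loading direction (one of the six simple-shear modes
#' or a uniaxial tissue direction).
#'
#' @param mode label, one of `"FN","FS","NF","NS","SF","SN",
#'   "circumferential","radial","basal","marginal"`.
#' @param strain numeric vector of true strains, strictly increasing.
#' @param stress numeric vector of true stresses (kPa), same length.
#' @param meta optional named list of provenance metadata (e.g. the
#'   generating parameters and RNG seed of a synthetic fixture).
#'
#' @return An object of class `stress_strain_curve` (also a data.frame
#'   with columns `strain`, `stress`).
#' @export
stress_strain_curve <- function(mode, strain, stress, meta = list()) {
  modes <- c("FN", "FS", "NF", "NS", "SF", "SN",
             "circumferential", "radial", "basal", "marginal")
  if (!(is.character(mode) && length(mode) == 1L && mode %in% modes))
    stop("stress_strain_curve: unknown mode label '", mode, "'")
  strain <- as.numeric(strain); stress <- as.numeric(stress)
  if (length(strain) != length(stress))
    stop("stress_strain_curve: strain and stress must have equal length")
  if (length(strain) < 1L || !all(is.finite(strain)) || !all(is.finite(stress)))
    stop("stress_strain_curve: strain/stress must be finite and non-empty")
  if (length(strain) > 1L && any(diff(strain) <= 0))
    stop("stress_strain_curve: strain must be strictly increasing")
  structure(data.frame(strain = strain, stress = stress),
            mode = mode, meta = meta,
            class = c("stress_strain_curve", "data.frame"))
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat("<stress_strain_curve> mode =", attr(x, "mode"),
      " n =", nrow(x),
      " strain in [", signif(min(x$strain), 4), ",",
      signif(max(x$strain), 4), "]\n")
  invisible(x)
}

#' Read / write stress-strain curves as CSV
#'
#' The on-disk format has a header `mode,strain,stress_kPa`; one file
#' may hold several modes.
#'
#' @param curves a list of [stress_strain_curve()] objects.
#' @param path file path.
#' @return `write_curves` returns `path` invisibly; `read_curves`
#'   returns a list of curves (one per mode, in file order).
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "stress_strain_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(mode = attr(cu, "mode"), strain = cu$strain,
               stress_kPa = cu$stress)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mode", "strain", "stress_kPa")
  if (!all(need %in% names(df)))
    stop("read_curves: file must have columns ", paste(need, collapse = ","))
  lapply(split(df, factor(df$mode, levels = unique(df$mode))), function(d)
    stress_strain_curve(d$mode[1], d$strain, d$stress_kPa))
}
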