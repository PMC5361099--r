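#' Assemble an assay layout from partition descriptions
#'
#' An assay layout is the physical design of a synergistic or digital assay:
#' an ordered set of partitions, each characterized by a dilution factor
#' `d_i` in (0, 1] and a volume `v_i` > 0. Their product, the modulation
#' factor `d_i * v_i`, sets the expected molecule count of the partition at
#' a given concentration and is the only quantity inference depends on.
#'
#' @param dilution Numeric vector of dilution factors, each in (0, 1].
#' @param volume Numeric vector of volumes (same unit throughout an assay),
#'   each > 0.
#' @param well_id Optional character vector of unique well labels; defaults
#'   to `W001`, `W002`, ...
#' @param common_ratio Common ratio x of the geometric modulation sequence,
#'   or 1 for identical partitions; stored as metadata.
#' @param delta_n Half-width of the active-stripe margin (number of extra
#'   compartments on each side), or `NA` when not designed.
#' @param mode `"synergistic"` or `"digital"`; how the layout is meant to be
#'   read out.
#' @param sigma_max,dyn_range,c_minus,library_copies Optional design-request
#'   metadata carried along for provenance.
#' @return An object of class `synpcr_layout`: a list with a `partitions`
#'   data frame (`well_id`, `dilution`, `volume`) and the design metadata.
#' @seealso [geometric_layout()], [classic_layout()], [design_assay()]
#' @export
assay_layout <- function(dilution, volume, well_id = NULL,
                         common_ratio = NA_real_, delta_n = NA_integer_,
                         mode = c("synergistic", "digital"),
                         sigma_max = NA_real_, dyn_range = NA_real_,
                         c_minus = NA_real_, library_copies = 1L) {
  mode <- match.arg(mode)
  n <- length(dilution)
  if (length(volume) != n) stop("'dilution' and 'volume' must have the same length")
  if (n < 1) stop("a layout needs at least one partition")
  if (any(!is.finite(dilution)) || any(dilution <= 0) || any(dilution > 1))
    stop("every dilution factor must lie in (0, 1]")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("every volume must be > 0")
  if (is.null(well_id)) well_id <- sprintf("W%03d", seq_len(n))
  well_id <- as.character(well_id)
  if (anyDuplicated(well_id)) stop("'well_id' labels must be unique within a layout")
  structure(
    list(
      partitions = data.frame(well_id = well_id, dilution = dilution,
                              volume = volume, stringsAsFactors = FALSE),
      mode = mode,
      common_ratio = common_ratio,
      delta_n = delta_n,
      sigma_max = sigma_max,
      dyn_range = dyn_range,
      c_minus = c_minus,
      library_copies = as.integer(library_copies)
    ),
    class = "synpcr_layout"
  )
}

#' Modulation factors of a layout
#'
#' @param layout A [assay_layout()] object.
#' @return Numeric vector `d_i * v_i`, one entry per partition, in layout
#'   order.
#' @export
modulations <- function(layout) {
  stopifnot(inherits(layout, "synpcr_layout"))
  layout$partitions$dilution * layout$partitions$volume
}

#' Number of partitions in a layout
#' @param layout A [assay_layout()] object.
#' @return Integer partition count.
#' @export
n_partitions <- function(layout) nrow(layout$partitions)

#' Geometric (multivolume) assay layout
#'
#' Builds the ladder of non-identical partitions at the core of the method:
#' modulation factors form a geometric sequence
#' `dv_i = first_modulation * x^i`, `i = 0, ..., n - 1`, so that the
#' characteristic concentrations of consecutive partitions are uniformly
#' spaced on the logarithmic concentration axis with step `-log10(x)`.
#' Partitions are realized as a multi-dilution series: constant volume,
#' geometrically decreasing dilution factor.
#'
#' @param first_modulation Modulation `d0 * v0` of the first (largest)
#'   partition.
#' @param common_ratio Common ratio x, strictly between 0 and 1. Identical
#'   partitions are built with [classic_layout()] instead.
#' @param n Number of partitions, >= 1.
#' @inheritParams assay_layout
#' @return A `synpcr_layout`.
#' @examples
#' lay <- geometric_layout(1, 0.5, 4)
#' modulations(lay)   # 1 0.5 0.25 0.125
#' @export
geometric_layout <- function(first_modulation, common_ratio, n,
                             mode = "synergistic") {
  if (!is.finite(common_ratio) || common_ratio <= 0 || common_ratio >= 1)
    stop("'common_ratio' must lie strictly between 0 and 1; ",
         "use classic_layout() for identical partitions")
  if (first_modulation <= 0) stop("'first_modulation' must be > 0")
  if (n < 1 || n != floor(n)) stop("'n' must be a positive integer")
  assay_layout(
    dilution = common_ratio^(seq_len(n) - 1),
    volume = rep(first_modulation, n),
    common_ratio = common_ratio,
    mode = mode
  )
}

#' Classic layout of identical partitions
#'
#' The layout of a conventional digital PCR assay: `n` partitions with the
#' same modulation factor. Recorded with common ratio 1.
#'
#' @param modulation Shared modulation `d * v` of every partition.
#' @param n Number of partitions.
#' @return A `synpcr_layout` with `common_ratio = 1`.
#' @export
classic_layout <- function(modulation, n) {
  if (modulation <= 0) stop("'modulation' must be > 0")
  if (n < 1 || n != floor(n)) stop("'n' must be a positive integer")
  assay_layout(
    dilution = rep(1, n),
    volume = rep(modulation, n),
    common_ratio = 1,
    mode = "digital"
  )
}

#' @export
print.synpcr_layout <- function(x, ...) {
  dv <- modulations(x)
  cat(sprintf("Assay layout: %d partitions (%s readout)\n",
              n_partitions(x), x$mode))
  if (is.finite(x$common_ratio))
    cat(sprintf("  common ratio x = %.4g\n", x$common_ratio))
  if (!is.na(x$delta_n))
    cat(sprintf("  active-stripe margin deltaN = %d\n", x$delta_n))
  if (x$library_copies > 1)
    cat(sprintf("  library copies per modulation: %d\n", x$library_copies))
  cat(sprintf("  modulation d*v: %.4g ... %.4g (span %.2f logs)\n",
              max(dv), min(dv), log10(max(dv) / min(dv))))
  cstar <- log(2) / dv
  cat(sprintf("  characteristic concentrations C*: %.4g ... %.4g\n",
              min(cstar), max(cstar)))
  invisible(x)
}

#' Write / read an assay layout as JSON
#'
#' Serializes a layout under the `synpcr-layout-v1` schema; the round trip
#' is lossless for all fields.
#'
#' @param layout A `synpcr_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   `synpcr_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "synpcr_layout"))
  obj <- list(
    schema = "synpcr-layout-v1",
    mode = layout$mode,
    x = layout$common_ratio,
    delta_n = layout$delta_n,
    sigma_max = layout$sigma_max,
    dyn_range = layout$dyn_range,
    c_minus = layout$c_minus,
    library_copies = layout$library_copies,
    n_partitions = n_partitions(layout),
    partitions = layout$partitions
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "synpcr-layout-v1"))
    stop("unknown layout schema: ", if (is.null(obj$schema)) "<missing>" else obj$schema)
  p <- obj$partitions
  if (!is.null(obj$n_partitions) && nrow(p) != obj$n_partitions)
    stop(sprintf("layout declares %d partitions but lists %d",
                 obj$n_partitions, nrow(p)))
  null2na <- function(z, cast = as.numeric) if (is.null(z) || length(z) == 0) cast(NA) else cast(z)
  assay_layout(
    dilution = p$dilution, volume = p$volume, well_id = p$well_id,
    common_ratio = null2na(obj$x),
    delta_n = null2na(obj$delta_n, as.integer),
    mode = obj$mode,
    sigma_max = null2na(obj$sigma_max),
    dyn_range = null2na(obj$dyn_range),
    c_minus = null2na(obj$c_minus),
    library_copies = null2na(obj$library_copies, as.integer)
  )
}
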