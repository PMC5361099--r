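#' Assemble an assay readout
#'
#' One experiment's observations on a layout: a binary signal per partition
#' and, for positive partitions read in real time, the threshold cycle
#' (Ct) at which its fluorescence crossed the detection threshold.
#'
#' @param layout The [assay_layout()] the observations belong to; readings
#'   are matched to partitions positionally (and must have the same length).
#' @param signal Integer/logical vector of binary outcomes, 1 = positive.
#' @param ct Numeric vector of threshold cycles; must be `NA` exactly where
#'   `signal == 0`. May be all-`NA` for an end-point (digital-only) readout.
#' @param censored Logical vector: `TRUE` for partitions whose amplification
#'   had not crossed the threshold within the cycling program (treated as
#'   digital information only).
#' @return An object of class `synpcr_readout`: list with `layout` and a
#'   `wells` data frame (`well_id`, `signal`, `ct`, `censored`).
#' @export
assay_readout <- function(layout, signal, ct = NULL, censored = NULL) {
  stopifnot(inherits(layout, "synpcr_layout"))
  n <- n_partitions(layout)
  if (n == 0 || length(signal) == 0) stop("empty readout")
  signal <- as.integer(signal)
  if (length(signal) != n)
    stop(sprintf("readout has %d signals but the layout has %d partitions",
                 length(signal), n))
  if (any(!signal %in% c(0L, 1L))) stop("'signal' must be 0 or 1")
  if (is.null(ct)) ct <- rep(NA_real_, n)
  if (length(ct) != n) stop("'ct' must have one entry per partition")
  if (is.null(censored)) censored <- rep(FALSE, n)
  bad <- which(signal == 0L & !is.na(ct))
  if (length(bad))
    stop("negative wells must not carry a ct value: ",
         paste(layout$partitions$well_id[bad], collapse = ", "))
  if (any(ct[!is.na(ct)] <= 0)) stop("'ct' values must be > 0")
  structure(
    list(layout = layout,
         wells = data.frame(well_id = layout$partitions$well_id,
                            signal = signal, ct = as.numeric(ct),
                            censored = censored, stringsAsFactors = FALSE)),
    class = "synpcr_readout"
  )
}

#' @export
print.synpcr_readout <- function(x, ...) {
  w <- x$wells
  cat(sprintf("Assay readout: %d wells, %d positive (%d with Ct)\n",
              nrow(w), sum(w$signal), sum(!is.na(w$ct))))
  if (any(w$censored)) cat(sprintf("  censored wells: %d\n", sum(w$censored)))
  invisible(x)
}

#' Read / write a well table as CSV
#'
#' Well tables use a fixed dialect: comma-separated, UTF-8, header
#' `well_id,dilution,volume,signal,ct`, `.` decimal mark, `signal` in
#' \{0, 1\}, and an empty `ct` field for negative wells.
#'
#' @param path File path.
#' @param layout Optional layout to attach; when omitted, one is rebuilt
#'   from the dilution and volume columns.
#' @return `read_well_table` returns a `synpcr_readout`;
#'   `write_well_table` returns `path` invisibly.
#' @export
read_well_table <- function(path, layout = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(well_id = "character"))
  required <- c("well_id", "dilution", "volume", "signal", "ct")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("well table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) stop("well table contains a header but no wells")
  if (anyDuplicated(tab$well_id)) {
    dup <- tab$well_id[duplicated(tab$well_id)][1]
    line <- which(tab$well_id == dup)[2] + 1L
    stop(sprintf("duplicate well_id '%s' (line %d)", dup, line))
  }
  bad <- which(tab$signal == 0 & !is.na(tab$ct))
  if (length(bad))
    stop(sprintf("negative well '%s' carries a ct value (line %d)",
                 tab$well_id[bad[1]], bad[1] + 1L))
  if (is.null(layout))
    layout <- assay_layout(dilution = tab$dilution, volume = tab$volume,
                           well_id = tab$well_id)
  assay_readout(layout, signal = tab$signal, ct = as.numeric(tab$ct))
}

#' @rdname read_well_table
#' @param readout A `synpcr_readout`.
#' @export
write_well_table <- function(readout, path) {
  stopifnot(inherits(readout, "synpcr_readout"))
  p <- readout$layout$partitions
  tab <- data.frame(well_id = p$well_id, dilution = p$dilution,
                    volume = p$volume, signal = readout$wells$signal,
                    ct = readout$wells$ct, stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
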