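#' Chromatin trace set
#'
#' A `trace_set` couples a record table of 3D barcode localizations (one row
#' per detected barcode per trace, coordinates in nm) with a barcode table
#' giving each barcode a genomic midpoint and an insulator/control label.
#' One trace corresponds to the barcode path of one chromosome copy in one
#' nucleus. At most one coordinate is kept per (trace, barcode); duplicates
#' are collapsed to the first occurrence with a logged count.
#'
#' @param records data frame with columns `trace_id`, `barcode_id`, `x`,
#'   `y`, `z` (nm).
#' @param barcodes data frame with columns `barcode_id`, `genomic_pos` (bp,
#'   strictly increasing along the locus) and optionally `label`
#'   (`"insulator"` or `"control"`).
#' @param n_traces optional total number of acquired traces (defaults to the
#'   number of distinct `trace_id`s); used as the denominator of
#'   [detection_efficiency].
#' @return A `trace_set` object.
#' @export
trace_set <- function(records, barcodes, n_traces = NULL) {
  req <- c("trace_id", "barcode_id", "x", "y", "z")
  if (!all(req %in% names(records)))
    stop("records need columns trace_id, barcode_id, x, y, z")
  if (!all(c("barcode_id", "genomic_pos") %in% names(barcodes)))
    stop("barcodes need columns barcode_id, genomic_pos")
  barcodes <- barcodes[order(barcodes$genomic_pos), , drop = FALSE]
  if (any(diff(barcodes$genomic_pos) <= 0))
    stop("barcode genomic positions must be strictly increasing")
  if (is.null(barcodes$label)) barcodes$label <- "control"
  rownames(barcodes) <- NULL
  unknown <- !(records$barcode_id %in% barcodes$barcode_id)
  if (any(unknown))
    stop("barcode_id not in barcode table: ",
         paste(unique(records$barcode_id[unknown]), collapse = ", "))
  coords <- as.matrix(records[, c("x", "y", "z")])
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("non-finite coordinate at record row ",
         which(!apply(is.finite(coords), 1L, all))[1])
  key <- paste(records$trace_id, records$barcode_id)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0L) message("collapsed ", n_dup, " duplicate (trace, barcode) record(s)")
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(n_traces)) n_traces <- length(unique(records$trace_id))
  structure(list(records = records, barcodes = barcodes,
                 n_traces = as.integer(n_traces), n_duplicates = n_dup),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("trace_set:", x$n_traces, "trace(s),", nrow(x$barcodes),
      "barcode(s),", nrow(x$records), "localization(s)\n")
  invisible(x)
}

#' Read chromatin traces from CSV
#'
#' Expects columns `trace_id`, `barcode_id`, `x`, `y`, `z` (nm), the layout
#' into which 4DN FOF-CT core tables are trivially mapped. Errors name the
#' offending data row for non-numeric coordinates and unknown barcodes.
#'
#' @param path CSV file.
#' @param barcode_map data frame with `barcode_id`, `genomic_pos`, `label`.
#' @return A [trace_set].
#' @export
read_traces <- function(path, barcode_map) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("trace_id", "barcode_id", "x", "y", "z")
  if (!all(req %in% names(tab)))
    stop("trace CSV needs columns ", paste(req, collapse = ", "))
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(v) & !(tab[[col]] %in% c("NA", ""))
    if (any(bad)) stop("non-numeric ", col, " at data row ", which(bad)[1])
    tab[[col]] <- v
  }
  trace_set(tab, barcode_map)
}

#' Write chromatin traces to CSV
#'
#' Coordinates are written at full double precision so the reader reproduces
#' them bit-exactly.
#'
#' @param traces a [trace_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  r <- traces$records
  lines <- c("trace_id,barcode_id,x,y,z",
             sprintf("%s,%s,%.17g,%.17g,%.17g",
                     r$trace_id, r$barcode_id, r$x, r$y, r$z))
  writeLines(lines, path)
  invisible(path)
}

#' Build a pairwise-distance ensemble directly from distance matrices
#'
#' Deposited single-nucleus pairwise-distance matrices can be analyzed
#' without raw coordinates by stacking them into the same ensemble container
#' that [pwd_matrices] produces.
#'
#' @param mats list of symmetric barcode-by-barcode distance matrices (nm),
#'   `NA` where either barcode was undetected.
#' @param barcodes barcode table as in [trace_set].
#' @return A `pwd_ensemble` (see [pwd_matrices]).
#' @export
pwd_ensemble_from_matrices <- function(mats, barcodes) {
  barcodes <- barcodes[order(barcodes$genomic_pos), , drop = FALSE]
  b <- nrow(barcodes)
  arr <- array(NA_real_, dim = c(b, b, length(mats)),
               dimnames = list(barcodes$barcode_id, barcodes$barcode_id, NULL))
  for (t in seq_along(mats)) {
    m <- as.matrix(mats[[t]])
    if (!all(dim(m) == b)) stop("matrix ", t, " has wrong dimensions")
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-6) stop("matrix ", t, " not symmetric")
    arr[, , t] <- m
  }
  structure(list(pwd = arr, barcodes = barcodes, n_traces = length(mats)),
            class = "pwd_ensemble")
}
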