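#' Balanced contact map aligned to genomic bins
#'
#' A `contact_map` holds one symmetric, non-negative matrix of balanced
#' contact frequencies per chromosome arm, plus a per-arm mask of invalid
#' bins. Bins whose row/column is entirely zero or missing (typically bins
#' filtered out by matrix balancing) are masked; their rows and columns are
#' set to `NA` so that every downstream mean is missing-aware.
#'
#' @param mats named list of square numeric matrices, one per arm, names
#'   matching `bins$arms`.
#' @param bins a [genomic_bins] object.
#' @param sym_tol maximum tolerated relative asymmetry; matrices within
#'   tolerance are symmetrized by averaging, larger asymmetries are an error.
#' @return An object of class `contact_map` with fields `mats`, `mask`
#'   (per-arm logical vector, `TRUE` = invalid bin) and `bins`.
#' @export
contact_map <- function(mats, bins, sym_tol = 1e-6) {
  stopifnot(inherits(bins, "genomic_bins"), is.list(mats))
  if (is.null(names(mats)) || !all(names(mats) %in% bins$arms))
    stop("mats must be a named list with names among bins$arms")
  mask <- list()
  for (arm in names(mats)) {
    m <- as.matrix(mats[[arm]])
    n <- bins$n_bins[[arm]]
    if (nrow(m) != n || ncol(m) != n)
      stop("dimension mismatch on arm ", arm, ": matrix is ", nrow(m), "x",
           ncol(m), " but arm has ", n, " bins")
    scale <- max(abs(m), na.rm = TRUE)
    if (!is.finite(scale)) scale <- 1
    asym <- max(abs(m - t(m)), na.rm = TRUE)
    if (is.finite(asym) && asym > sym_tol * max(scale, 1e-300))
      stop("matrix for arm ", arm, " is asymmetric beyond tolerance (",
           signif(asym / max(scale, 1e-300), 3), " relative)")
    m <- (m + t(m)) / 2
    if (any(m < 0, na.rm = TRUE))
      stop("negative contact frequencies on arm ", arm)
    bad <- apply(m, 1L, function(r) all(is.na(r) | r == 0))
    m[bad, ] <- NA_real_
    m[, bad] <- NA_real_
    mats[[arm]] <- m
    mask[[arm]] <- bad
  }
  structure(list(mats = mats, mask = mask, bins = bins), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", length(x$mats), "arm(s),",
      sum(vapply(x$mask, sum, 0L)), "masked bin(s)\n")
  invisible(x)
}

#' Write a contact map as a plain-text dense-matrix archive
#'
#' The archive is a directory holding a `manifest.tsv` (columns `arm`,
#' `n_bins`, `bin_size`, `file`) and one whitespace-delimited matrix file per
#' arm, written at full double precision so that a read/write cycle is
#' lossless to better than 1e-12.
#'
#' @param map a [contact_map].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_contact_map <- function(map, dir) {
  stopifnot(inherits(map, "contact_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(arm = names(map$mats),
                         n_bins = vapply(map$mats, nrow, 0L),
                         bin_size = map$bins$bin_size,
                         file = paste0("matrix_", names(map$mats), ".txt"),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(manifest))) {
    m <- map$mats[[manifest$arm[i]]]
    lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, file.path(dir, manifest$file[i]))
  }
  invisible(dir)
}

#' Read a contact map from a dense-matrix archive
#'
#' @param dir archive directory written by [write_contact_map] (or assembled
#'   by hand: a `manifest.tsv` plus per-arm dense matrix text files).
#' @param bins optional [genomic_bins]; reconstructed from the manifest when
#'   omitted. A mismatch between manifest and `bins` is an error naming the
#'   arm.
#' @inheritParams contact_map
#' @return A [contact_map].
#' @export
read_contact_map <- function(dir, bins = NULL, sym_tol = 1e-6) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv under ", dir)
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (is.null(bins)) {
    sizes <- stats::setNames(manifest$n_bins * manifest$bin_size[1], manifest$arm)
    bins <- genomic_bins(sizes, manifest$bin_size[1])
  }
  mats <- list()
  for (i in seq_len(nrow(manifest))) {
    arm <- manifest$arm[i]
    .check_arm(bins, arm)
    m <- as.matrix(utils::read.table(file.path(dir, manifest$file[i])))
    dimnames(m) <- NULL
    if (nrow(m) != bins$n_bins[[arm]])
      stop("dimension mismatch on arm ", arm, " between archive and bins")
    mats[[arm]] <- m
  }
  contact_map(mats, bins, sym_tol = sym_tol)
}
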