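#' Genomic bin bookkeeping for chromosome arms
#'
#' Defines a uniform tiling of each chromosome arm into fixed-width bins.
#' All coordinates in the package are 0-based half-open; the bin holding
#' position `p` is `floor(p / bin_size)`. Chromosome arms (e.g. 2L, 2R, 3L,
#' 3R, X in *Drosophila*) are the unit of analysis and inter-arm pairs are
#' excluded everywhere downstream.
#'
#' @param chrom_sizes named numeric vector of arm lengths in bp.
#' @param bin_size bin width in bp (default 5000, the resolution at which
#'   loop-anchor networks and insulation scores are computed here).
#' @return An object of class `genomic_bins` with fields `chrom_sizes`,
#'   `bin_size`, `n_bins` (bins per arm) and `arms`.
#' @examples
#' bins <- genomic_bins(c(`2L` = 1e6, `2R` = 2e6))
#' bins$n_bins
#' @export
genomic_bins <- function(chrom_sizes, bin_size = 5000) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of arm lengths")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated arm names in chrom_sizes")
  if (!is.numeric(chrom_sizes) || any(chrom_sizes <= 0))
    stop("arm lengths must be positive")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a positive scalar")
  n_bins <- as.integer(ceiling(chrom_sizes / bin_size))
  structure(
    list(chrom_sizes = chrom_sizes,
         bin_size = as.integer(bin_size),
         n_bins = stats::setNames(n_bins, names(chrom_sizes)),
         arms = names(chrom_sizes)),
    class = "genomic_bins")
}

#' @export
print.genomic_bins <- function(x, ...) {
  cat("genomic_bins:", length(x$arms), "arm(s) at", x$bin_size, "bp\n")
  print(x$n_bins)
  invisible(x)
}

#' Map genomic positions to bin indices
#'
#' @param bins a [genomic_bins] object.
#' @param arm arm name(s), recycled against `pos`.
#' @param pos genomic position(s) in bp (0-based).
#' @return Integer 0-based bin indices.
#' @export
bin_of <- function(bins, arm, pos) {
  stopifnot(inherits(bins, "genomic_bins"))
  bad <- !(arm %in% bins$arms)
  if (any(bad)) stop("unknown arm(s): ", paste(unique(arm[bad]), collapse = ", "))
  idx <- as.integer(pos %/% bins$bin_size)
  out_of_range <- idx < 0L | idx >= bins$n_bins[arm]
  if (any(out_of_range)) stop("position outside arm for ", sum(out_of_range), " record(s)")
  idx
}

# bin index -> start coordinate (bp)
bin_start <- function(bins, idx) as.numeric(idx) * bins$bin_size

.check_arm <- function(bins, arm) {
  if (!arm %in% bins$arms) stop("unknown arm: ", arm)
  invisible(TRUE)
}
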