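#' Cis loop list at bin resolution
#'
#' A `loop_list` is a data frame of cis (same-arm) loops with 0-based bin
#' indices `bin1 < bin2`. Duplicate records are collapsed; separation in bp
#' is `(bin2 - bin1) * bin_size`.
#'
#' @param df data frame with columns `arm`, `bin1`, `bin2` and optionally
#'   `score` (and extra columns, kept).
#' @param bins a [genomic_bins] object.
#' @return A `loop_list` data frame (attributes `bins`).
#' @export
loop_list <- function(df, bins) {
  stopifnot(inherits(bins, "genomic_bins"))
  req <- c("arm", "bin1", "bin2")
  if (!all(req %in% names(df))) stop("loop data frame needs columns arm, bin1, bin2")
  df$bin1 <- as.integer(df$bin1)
  df$bin2 <- as.integer(df$bin2)
  bad_arm <- !(df$arm %in% bins$arms)
  if (any(bad_arm)) stop("unknown arm(s) in loops: ",
                         paste(unique(df$arm[bad_arm]), collapse = ", "))
  swap <- df$bin1 > df$bin2
  if (any(swap)) {
    tmp <- df$bin1[swap]; df$bin1[swap] <- df$bin2[swap]; df$bin2[swap] <- tmp
  }
  if (any(df$bin1 == df$bin2)) stop("self-loop records (zero separation) not allowed")
  if (any(df$bin1 < 0L) || any(df$bin2 >= bins$n_bins[df$arm]))
    stop("loop anchors outside bins")
  key <- paste(df$arm, df$bin1, df$bin2)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$arm, df$bin1, df$bin2), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, bins = bins, class = c("loop_list", "data.frame"))
}

#' Read loops from a BEDPE file
#'
#' Anchor intervals are mapped to bins by their midpoint (Chromosight-style
#' anchors are single bins, so the midpoint rule is robust to dialect
#' differences in interval extension). Records with `anchor1 > anchor2` are
#' swapped; trans (inter-arm) records are dropped with a logged count
#' available as `attr(x, "n_trans_dropped")`.
#'
#' @param path BEDPE file with at least 6 columns
#'   (chrom1 start1 end1 chrom2 start2 end2 \[name score ...\]).
#' @param bins a [genomic_bins] object.
#' @return A [loop_list].
#' @export
read_bedpe_loops <- function(path, bins) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty BEDPE file: ", path)
    return(loop_list(data.frame(arm = character(), bin1 = integer(),
                                bin2 = integer()), bins))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed BEDPE line ", which(nf < 6L)[1], ": fewer than 6 fields")
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) stop("malformed BEDPE line ", which(is.na(v))[1],
                       ": non-numeric coordinate in column ", i)
    v
  }
  chrom1 <- get(1); chrom2 <- get(4)
  s1 <- num(2); e1 <- num(3); s2 <- num(5); e2 <- num(6)
  score <- if (all(nf >= 8L)) suppressWarnings(as.numeric(get(8))) else NA_real_
  cis <- chrom1 == chrom2
  n_trans <- sum(!cis)
  if (n_trans > 0L) message("dropped ", n_trans, " trans BEDPE record(s)")
  df <- data.frame(arm = chrom1[cis],
                   bin1 = bin_of(bins, chrom1[cis], floor((s1[cis] + e1[cis]) / 2)),
                   bin2 = bin_of(bins, chrom2[cis], floor((s2[cis] + e2[cis]) / 2)),
                   score = score[cis],
                   stringsAsFactors = FALSE)
  out <- loop_list(df, bins)
  attr(out, "n_trans_dropped") <- n_trans
  out
}

#' Write loops to a BEDPE file
#'
#' Each anchor is written as its full bin interval (0-based half-open).
#'
#' @param loops a [loop_list].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  bins <- attr(loops, "bins")
  bs <- bins$bin_size
  score <- if ("score" %in% names(loops)) loops$score else NA
  df <- data.frame(loops$arm, bin_start(bins, loops$bin1),
                   bin_start(bins, loops$bin1) + bs,
                   loops$arm, bin_start(bins, loops$bin2),
                   bin_start(bins, loops$bin2) + bs,
                   ".", ifelse(is.na(score), ".", as.character(score)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Peak / feature interval set
#'
#' Intervals are 0-based half-open on chromosome arms, sorted by
#' (arm, start), with an optional non-negative signal per interval.
#'
#' @param df data frame with columns `arm`, `start`, `end`, optionally
#'   `signal` and `name`.
#' @param feature optional feature name attached to the set.
#' @return A `peak_set` data frame.
#' @export
peak_set <- function(df, feature = NULL) {
  req <- c("arm", "start", "end")
  if (!all(req %in% names(df))) stop("peak data frame needs columns arm, start, end")
  if (any(df$start >= df$end)) stop("peak intervals must satisfy start < end")
  if ("signal" %in% names(df) && any(df$signal < 0, na.rm = TRUE))
    stop("peak signal must be non-negative")
  df <- df[order(df$arm, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, feature = feature, class = c("peak_set", "data.frame"))
}

#' Read peaks from a BED3+ or narrowPeak file
#'
#' narrowPeak (10 columns) uses column 7 (signalValue) as the signal; BED
#' files with 5+ columns use the score column.
#'
#' @param path input file.
#' @param format `"auto"` (by column count), `"bed"`, or `"narrowPeak"`.
#' @param feature optional feature name.
#' @return A [peak_set].
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak"),
                       feature = NULL) {
  format <- match.arg(format)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE, comment.char = "#")
  nc <- ncol(tab)
  if (format == "auto") format <- if (nc >= 10L) "narrowPeak" else "bed"
  df <- data.frame(arm = tab[[1]], start = tab[[2]], end = tab[[3]],
                   stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    df$name <- tab[[4]]
    df$signal <- as.numeric(tab[[7]])
  } else {
    if (nc >= 4L) df$name <- tab[[4]]
    if (nc >= 5L) df$signal <- suppressWarnings(as.numeric(tab[[5]]))
  }
  peak_set(df, feature = feature)
}

#' Unique anchor bins of a peak set
#'
#' Maps each peak to the bin holding its midpoint and drops duplicates.
#'
#' @param peaks a [peak_set].
#' @param bins a [genomic_bins] object.
#' @param keep_signal carry the signal column through (default FALSE).
#' @return Data frame (arm, bin \[, signal\]).
#' @export
anchor_bins <- function(peaks, bins, keep_signal = FALSE) {
  mid <- floor((peaks$start + peaks$end) / 2)
  df <- data.frame(arm = peaks$arm, bin = bin_of(bins, peaks$arm, mid),
                   stringsAsFactors = FALSE)
  if (keep_signal && "signal" %in% names(peaks)) df$signal <- peaks$signal
  df[!duplicated(paste(df$arm, df$bin)), , drop = FALSE]
}
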