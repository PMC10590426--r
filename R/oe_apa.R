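#' Expected contact frequency by genomic distance
#'
#' For each arm, the expected value at bin separation s is the mean
#' balanced contact frequency over all valid pairs (i, i+s); masked bins
#' are excluded from both numerator and denominator.
#'
#' @param map a [contact_map].
#' @return An `expected_profile`: named list (per arm) of numeric vectors
#'   indexed by separation + 1 (separation 0 .. n-1).
#' @export
expected_by_distance <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  out <- list()
  for (arm in names(map$mats)) {
    m <- map$mats[[arm]]
    n <- nrow(m)
    if (all(map$mask[[arm]])) {
      warning("arm ", arm, " has all bins masked; expected profile missing")
      out[[arm]] <- rep(NA_real_, n)
      next
    }
    e <- rep(NA_real_, n)
    for (s in 0:(n - 1L)) {
      i <- seq_len(n - s)
      v <- m[cbind(i, i + s)]
      if (any(!is.na(v))) e[s + 1L] <- mean(v, na.rm = TRUE)
    }
    out[[arm]] <- e
  }
  structure(out, class = "expected_profile")
}

#' Distance-normalized (log2 observed/expected) map
#'
#' log2(O/E) is positive where contacts occur more often than typical for
#' their genomic separation. Entries where the observed or the expected
#' value is missing or zero are missing.
#'
#' @param map a [contact_map].
#' @param expected optional precomputed [expected_by_distance] profile
#'   (e.g. the analytic decay of a matched null map); computed from `map`
#'   when omitted.
#' @return An `oe_map`: list with per-arm matrices (`mats`) and `bins`.
#' @export
oe_transform <- function(map, expected = NULL) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(expected)) expected <- expected_by_distance(map)
  mats <- list()
  for (arm in names(map$mats)) {
    m <- map$mats[[arm]]
    n <- nrow(m)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    e <- matrix(expected[[arm]][d + 1L], n, n)
    oe <- suppressWarnings(log2(m / e))
    oe[is.na(m) | m == 0 | is.na(e) | e == 0] <- NA_real_
    oe[!is.finite(oe)] <- NA_real_
    mats[[arm]] <- oe
  }
  structure(list(mats = mats, bins = map$bins), class = "oe_map")
}

#' Cis anchor pairs within separation bounds
#'
#' Enumerates all same-arm pairs of anchor bins (peak midpoints) with
#' genomic separation within `[min_sep, max_sep]`. Same-bin pairs are
#' excluded; with a single peak set each unordered pair appears once.
#' Defaults match the loop-detection bounds of the primary network
#' (20 kb - 2 Mb).
#'
#' @param peaksA a [peak_set] (or data frame with `arm`, `bin`).
#' @param peaksB optional second [peak_set]; defaults to `peaksA`.
#' @param bins a [genomic_bins] object.
#' @param min_sep,max_sep separation bounds in bp.
#' @return Data frame (arm, bin1, bin2, sep_bp); warns when empty.
#' @export
select_anchor_pairs <- function(peaksA, peaksB = NULL, bins,
                                min_sep = 20e3, max_sep = 2e6) {
  if (min_sep >= max_sep) stop("min_sep must be < max_sep")
  to_bins <- function(p) {
    if (inherits(p, "peak_set")) anchor_bins(p, bins)
    else p[!duplicated(paste(p$arm, p$bin)), c("arm", "bin"), drop = FALSE]
  }
  a <- to_bins(peaksA)
  same <- is.null(peaksB)
  b <- if (same) a else to_bins(peaksB)
  res <- list()
  for (arm in intersect(unique(a$arm), unique(b$arm))) {
    av <- sort(a$bin[a$arm == arm])
    bv <- sort(b$bin[b$arm == arm])
    g <- expand.grid(x = av, y = bv)
    lo <- pmin(g$x, g$y); hi <- pmax(g$x, g$y)
    keep <- lo < hi
    if (same) keep <- keep & g$x < g$y
    lo <- lo[keep]; hi <- hi[keep]
    key <- paste(lo, hi)
    d <- !duplicated(key)
    lo <- lo[d]; hi <- hi[d]
    sep <- (hi - lo) * bins$bin_size
    in_rng <- sep >= min_sep & sep <= max_sep
    if (any(in_rng))
      res[[arm]] <- data.frame(arm = arm, bin1 = lo[in_rng],
                               bin2 = hi[in_rng], sep_bp = sep[in_rng],
                               stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(arm = character(), bin1 = integer(),
                         bin2 = integer(), sep_bp = numeric())
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no anchor pairs within separation bounds")
  out
}

#' Aggregate peak analysis over anchor pairs
#'
#' Extracts the (2w+1) x (2w+1) log2(O/E) submatrix centered on each anchor
#' pair's pixel and averages them element-wise (missing-aware: missing
#' pixels are excluded from both numerator and denominator). Rows index the
#' lower-coordinate anchor's neighborhood. Pairs whose window exceeds the
#' arm or whose center pixel is missing are skipped and counted.
#'
#' @param oe an [oe_transform] result.
#' @param pairs anchor pairs from [select_anchor_pairs] (or a [loop_list]).
#' @param w half-window in bins (default 10, i.e. +/- 50 kb at 5 kb giving
#'   a 105 kb square around the intersection).
#' @return An `apa_result`: `matrix` (2w+1 square), `center`, `n_pairs`,
#'   `n_skipped`, `w`.
#' @export
apa_aggregate <- function(oe, pairs, w = 10) {
  stopifnot(inherits(oe, "oe_map"))
  if (w < 1) stop("w must be >= 1")
  side <- 2L * w + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0L, side, side)
  used <- 0L; skipped <- 0L
  for (p in seq_len(nrow(pairs))) {
    m <- oe$mats[[pairs$arm[p]]]
    n <- nrow(m)
    i <- pairs$bin1[p] + 1L
    j <- pairs$bin2[p] + 1L
    if (i - w < 1L || i + w > n || j - w < 1L || j + w > n ||
        is.na(m[i, j])) { skipped <- skipped + 1L; next }
    sub <- m[(i - w):(i + w), (j - w):(j + w)]
    ok <- !is.na(sub)
    acc[ok] <- acc[ok] + sub[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0L) stop("all anchor pairs were skipped (edge or missing center)")
  agg <- acc / cnt
  agg[cnt == 0L] <- NA_real_
  structure(list(matrix = agg, center = agg[w + 1L, w + 1L],
                 n_pairs = used, n_skipped = skipped, w = w),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA: center log2(O/E) = %.4f over %d pairs (%d skipped), window +/-%d bins\n",
              x$center, x$n_pairs, x$n_skipped, x$w))
  invisible(x)
}

#' @export
plot.apa_result <- function(x, ...) {
  side <- nrow(x$matrix)
  graphics::image(seq_len(side) - x$w - 1L, seq_len(side) - x$w - 1L,
                  t(x$matrix[side:1, ]), xlab = "bins from anchor 2",
                  ylab = "bins from anchor 1", main = "APA log2(O/E)", ...)
  invisible(x)
}

#' Center-pixel log2(O/E) values per anchor pair
#'
#' The mean of these values is the per-factor aggregate interaction
#' preference (the quantity correlated against assortativity Z-scores
#' across factors).
#'
#' @inheritParams apa_aggregate
#' @return List with `values` (one per non-missing pair), `mean`, `median`,
#'   `n_missing`.
#' @export
log2oe_values <- function(oe, pairs) {
  stopifnot(inherits(oe, "oe_map"))
  vals <- rep(NA_real_, nrow(pairs))
  for (arm in unique(pairs$arm)) {
    sel <- pairs$arm == arm
    m <- oe$mats[[arm]]
    vals[sel] <- m[cbind(pairs$bin1[sel] + 1L, pairs$bin2[sel] + 1L)]
  }
  miss <- is.na(vals)
  v <- vals[!miss]
  list(values = v, mean = mean(v), median = stats::median(v),
       n_missing = sum(miss))
}

#' Stratify scored anchors into equal-size groups
#'
#' Anchors are sorted by ascending score (stable sort with ties broken by
#' genomic position) and split into k contiguous groups of floor(n/k), the
#' remainder going to the highest-score groups. Group labels are Roman
#' numerals I..k in ascending score order, matching the convention of
#' quintile-stratified aggregate plots.
#'
#' @param anchors data frame with `arm`, `bin`, `score`.
#' @param k number of groups (default 5).
#' @return `anchors` reordered, with a `group` factor column.
#' @export
stratify_anchors <- function(anchors, k = 5) {
  n <- nrow(anchors)
  if (n < k) stop("fewer anchors (", n, ") than groups (", k, ")")
  ord <- order(anchors$score, anchors$arm, anchors$bin)
  anchors <- anchors[ord, , drop = FALSE]
  base <- n %/% k; rem <- n %% k
  sizes <- base + c(rep(0L, k - rem), rep(1L, rem))
  labels <- as.character(utils::as.roman(seq_len(k)))
  anchors$group <- factor(rep(labels, sizes), levels = labels)
  rownames(anchors) <- NULL
  anchors
}

#' Bootstrap of mean log2(O/E) over random anchor subsets
#'
#' For each subset size N, draws `iters` random subsets of N anchors
#' (without replacement) and records the mean center-pixel log2(O/E) over
#' all qualifying pairs (cis, within separation bounds, value present)
#' within the subset. Iterations with no qualifying pair are redrawn and
#' counted. This quantifies how many anchors must be aggregated before the
#' average interaction preference becomes reliably positive.
#'
#' @param oe an [oe_transform] result.
#' @param anchors data frame with `arm`, `bin` (e.g. from [anchor_bins]).
#' @param bins a [genomic_bins] object.
#' @param N_list subset sizes (default 2, 5, 10, 25, 50, 100, 250, 300);
#'   sizes exceeding the anchor count are skipped with a warning.
#' @param iters iterations per N (default 10000).
#' @param min_sep,max_sep pair separation bounds in bp.
#' @param seed integer seed.
#' @return List per N with `means` (length `iters`) and `n_resampled`.
#' @export
bootstrap_mean_log2oe <- function(oe, anchors, bins,
                                  N_list = c(2, 5, 10, 25, 50, 100, 250, 300),
                                  iters = 10000, min_sep = 20e3,
                                  max_sep = 2e6, seed = 1) {
  anchors <- anchors[!duplicated(paste(anchors$arm, anchors$bin)), , drop = FALSE]
  n_a <- nrow(anchors)
  if (!is.null(seed)) set.seed(seed)
  # precompute the pairwise center log2(O/E) among anchors (NA = non-qualifying)
  V <- matrix(NA_real_, n_a, n_a)
  for (arm in unique(anchors$arm)) {
    ia <- which(anchors$arm == arm)
    m <- oe$mats[[arm]]
    bb <- anchors$bin[ia]
    sep <- abs(outer(bb, bb, "-")) * bins$bin_size
    ok <- sep >= min_sep & sep <= max_sep
    vv <- m[cbind(rep(bb + 1L, length(bb)),
                  rep(bb + 1L, each = length(bb)))]
    vv <- matrix(vv, length(bb), length(bb))
    vv[!ok] <- NA_real_
    V[ia, ia] <- vv
  }
  diag(V) <- NA_real_
  out <- list()
  for (N in N_list) {
    if (N > n_a) { warning("N = ", N, " exceeds anchor count; skipped"); next }
    means <- numeric(iters)
    resampled <- 0L
    for (it in seq_len(iters)) {
      repeat {
        idx <- sample.int(n_a, N)
        sub <- V[idx, idx]
        v <- sub[upper.tri(sub)]
        v <- v[!is.na(v)]
        if (length(v) > 0L) break
        resampled <- resampled + 1L
        if (resampled > iters * 100L)
          stop("too many iterations without qualifying pairs at N = ", N)
      }
      means[it] <- mean(v)
    }
    out[[as.character(N)]] <- list(means = means, n_resampled = resampled)
  }
  out
}
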