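#' Insulation score profile of a contact map
#'
#' For each bin i, the raw insulation score is the missing-aware mean of the
#' window x window square of contacts spanning bins (i-window .. i-1) x
#' (i+1 .. i+window) — the contacts crossing over bin i. The profile is
#' normalized per arm as log2(IS / arm mean IS). Low values mark bins across
#' which few contacts occur, i.e. domain boundaries. The score is undefined
#' within `window` bins of arm edges.
#'
#' @param map a [contact_map] (balanced, 5 kb bins in the reference
#'   analysis).
#' @param window window size in bins (default 8).
#' @return An `is_profile`: per-arm list with `raw`, `score` (normalized)
#'   and the window size.
#' @export
insulation_score <- function(map, window = 8) {
  stopifnot(inherits(map, "contact_map"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  out <- list()
  for (arm in names(map$mats)) {
    m <- map$mats[[arm]]
    n <- nrow(m)
    raw <- rep(NA_real_, n)
    if (n < 2L * window + 1L) {
      warning("arm ", arm, " shorter than 2*window+1; profile missing")
    } else {
      for (r in (window + 1L):(n - window)) {
        blk <- m[(r - window):(r - 1L), (r + 1L):(r + window)]
        if (any(!is.na(blk))) raw[r] <- mean(blk, na.rm = TRUE)
      }
    }
    mu <- mean(raw, na.rm = TRUE)
    score <- if (is.finite(mu) && mu > 0) log2(raw / mu) else rep(NA_real_, n)
    score[!is.finite(score)] <- NA_real_
    out[[arm]] <- list(raw = raw, score = score)
  }
  structure(list(arms = out, window = window, bins = map$bins),
            class = "is_profile")
}

# delta vector per Crane: mean IS right of i minus mean IS left of i;
# crosses zero upward at insulation minima
.delta_vector <- function(score, dw) {
  n <- length(score)
  delta <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    l0 <- r - dw; l1 <- r - 1L; r0 <- r + 1L; r1 <- r + dw
    if (l0 < 1L || r1 > n) next
    left <- score[l0:l1]; right <- score[r0:r1]
    if (all(is.na(left)) || all(is.na(right))) next
    delta[r] <- mean(right, na.rm = TRUE) - mean(left, na.rm = TRUE)
  }
  delta
}

#' Call domain boundaries from an insulation profile
#'
#' Boundaries are local minima of the normalized insulation score whose
#' boundary strength — the difference between the neighboring extremes of
#' the delta vector (mean score right of the bin minus mean score left of
#' it) — is at least `delta_span`. The strength is reported in the `signal`
#' column and serves as the border insulation-score for stratified
#' analyses.
#'
#' @param isp an [insulation_score] profile.
#' @param delta_span minimum boundary strength (default 0.1).
#' @param delta_window span of the delta vector in bins (default: the
#'   insulation window).
#' @return A [peak_set] of single-bin boundaries with strength as signal.
#' @export
call_boundaries <- function(isp, delta_span = 0.1, delta_window = NULL) {
  stopifnot(inherits(isp, "is_profile"))
  dw <- if (is.null(delta_window)) isp$window else as.integer(delta_window)
  bins <- isp$bins
  res <- list()
  for (arm in names(isp$arms)) {
    s <- isp$arms[[arm]]$score
    n <- length(s)
    if (all(is.na(s))) next
    delta <- .delta_vector(s, dw)
    for (r in 2:(n - 1L)) {
      if (is.na(s[r]) || is.na(s[r - 1L]) || is.na(s[r + 1L])) next
      if (!(s[r] < s[r - 1L] && s[r] <= s[r + 1L])) next
      lo <- max(1L, r - dw); hi <- min(n, r + dw)
      dl <- delta[lo:r]; dr <- delta[r:hi]
      if (all(is.na(dl)) || all(is.na(dr))) next
      strength <- max(dr, na.rm = TRUE) - min(dl, na.rm = TRUE)
      if (strength >= delta_span)
        res[[length(res) + 1L]] <- data.frame(arm = arm, bin = r - 1L,
                                              signal = strength,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(peak_set(data.frame(arm = character(), start = numeric(),
                               end = numeric(), signal = numeric()),
                    feature = "boundary"))
  df <- do.call(rbind, res)
  peak_set(data.frame(arm = df$arm,
                      start = bin_start(bins, df$bin),
                      end = bin_start(bins, df$bin) + bins$bin_size,
                      signal = df$signal, stringsAsFactors = FALSE),
           feature = "boundary")
}

# border bin lookup: per arm, sorted border bins
.border_bins <- function(borders, bins) {
  ab <- anchor_bins(borders, bins)
  split(ab$bin, ab$arm)
}

.is_near <- function(bin, arm, border_map, slop) {
  bb <- border_map[[arm]]
  if (is.null(bb) || !length(bb)) return(rep(FALSE, length(bin)))
  vapply(bin, function(b) any(abs(bb - b) <= slop), logical(1))
}

#' Classify loops by border participation of their anchors
#'
#' An anchor is a border-anchor iff its bin lies within `slop_bins` of a
#' called boundary bin (the default 1-bin slop absorbs the different
#' procedures producing boundaries and loop anchors). Each loop falls in
#' exactly one of three categories: border/border, border/non-border,
#' non-border/non-border.
#'
#' @param loops a [loop_list].
#' @param borders boundary [peak_set] (e.g. from [call_boundaries]).
#' @param slop_bins matching slop in bins (default 1).
#' @return A `loop_classification`: per-loop data frame (`category`) plus
#'   `summary` (category, n, percent; percentages sum to 100).
#' @export
classify_loops <- function(loops, borders, slop_bins = 1) {
  bins <- attr(loops, "bins")
  cats <- c("border/border", "border/non-border", "non-border/non-border")
  if (nrow(borders) == 0L) {
    warning("empty border set: all loops non-border/non-border")
    bmap <- list()
  } else bmap <- .border_bins(borders, bins)
  df <- as.data.frame(loops)
  b1 <- logical(nrow(df)); b2 <- logical(nrow(df))
  for (arm in unique(df$arm)) {
    sel <- df$arm == arm
    b1[sel] <- .is_near(df$bin1[sel], arm, bmap, slop_bins)
    b2[sel] <- .is_near(df$bin2[sel], arm, bmap, slop_bins)
  }
  nb <- b1 + b2
  df$category <- factor(cats[3L - nb], levels = cats)
  n <- as.vector(table(df$category))
  summary <- data.frame(category = cats, n = n,
                        percent = 100 * n / nrow(df))
  structure(list(loops = df, summary = summary, slop_bins = slop_bins),
            class = "loop_classification")
}

#' @export
print.loop_classification <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Per-loop anchor occupancy by a family of feature sets
#'
#' An anchor is occupied iff at least one of the listed peak sets overlaps
#' its bin (within `slop_bins`). Each loop gets an occupancy in {0, 1, 2};
#' proportions are reported overall and, when a [classify_loops] result is
#' supplied, per loop category.
#'
#' @param loops a [loop_list].
#' @param peak_sets non-empty list of [peak_set]s (e.g. one per insulator).
#' @param slop_bins matching slop in bins (default 0).
#' @param classification optional `loop_classification` aligned to `loops`.
#' @return List with `occupancy` (per loop), `proportions` (0/1/2) and,
#'   when classified, `by_category`.
#' @export
anchor_occupancy <- function(loops, peak_sets, slop_bins = 0,
                             classification = NULL) {
  if (!length(peak_sets)) stop("peak_sets must be a non-empty list")
  bins <- attr(loops, "bins")
  # bin-level binary overlap tracks (>= 1 bp rule), so wide peaks count
  # in every bin they touch
  tracks <- lapply(peak_sets, feature_track, bins = bins, mode = "binary")
  occupied <- function(arm, bin) {
    vapply(bin, function(b) {
      win <- max(0L, b - slop_bins):min(bins$n_bins[[arm]] - 1L, b + slop_bins)
      any(vapply(tracks, function(tr) any(tr[[arm]][win + 1L] > 0),
                 logical(1)))
    }, logical(1))
  }
  df <- as.data.frame(loops)
  o1 <- logical(nrow(df)); o2 <- logical(nrow(df))
  for (arm in unique(df$arm)) {
    sel <- df$arm == arm
    o1[sel] <- occupied(arm, df$bin1[sel])
    o2[sel] <- occupied(arm, df$bin2[sel])
  }
  occ <- o1 + o2
  prop <- as.vector(table(factor(occ, levels = 0:2))) / length(occ)
  out <- list(occupancy = occ,
              proportions = stats::setNames(prop, c("0", "1", "2")))
  if (!is.null(classification)) {
    out$by_category <- tapply(occ, classification$loops$category,
                              function(v) table(factor(v, levels = 0:2)) / length(v))
  }
  out
}

#' Fraction of borders (or any anchor set) participating in loops
#'
#' A border participates when its bin lies within `slop_bins` of at least
#' one loop anchor. The participating fraction is split into borders found
#' in at least one loop whose other anchor is also a border (both-anchor
#' loops) versus borders only in mixed loops.
#'
#' @param borders boundary [peak_set] (or any anchor set).
#' @param loops a [loop_list].
#' @param slop_bins matching slop in bins (default 1).
#' @return List with `fraction`, `fraction_both_anchors`,
#'   `fraction_single_anchor`, `n_borders`.
#' @export
border_participation <- function(borders, loops, slop_bins = 1) {
  if (nrow(borders) == 0L) stop("empty border set")
  bins <- attr(loops, "bins")
  bmap <- .border_bins(borders, bins)
  df <- as.data.frame(loops)
  ab <- anchor_bins(borders, bins)
  participates <- logical(nrow(ab))
  in_both <- logical(nrow(ab))
  for (i in seq_len(nrow(ab))) {
    sel <- df$arm == ab$arm[i]
    if (!any(sel)) next
    hit1 <- abs(df$bin1[sel] - ab$bin[i]) <= slop_bins
    hit2 <- abs(df$bin2[sel] - ab$bin[i]) <= slop_bins
    hit <- hit1 | hit2
    participates[i] <- any(hit)
    if (any(hit)) {
      other <- ifelse(hit1[hit], df$bin2[sel][hit], df$bin1[sel][hit])
      in_both[i] <- any(.is_near(other, ab$arm[i], bmap, slop_bins))
    }
  }
  list(fraction = mean(participates),
       fraction_both_anchors = mean(participates & in_both),
       fraction_single_anchor = mean(participates & !in_both),
       n_borders = nrow(ab))
}
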