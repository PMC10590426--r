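#' Per-trace pairwise distance matrices
#'
#' Computes the Euclidean distance between every detected barcode pair of
#' every trace; entries involving an undetected barcode are missing. Traces
#' with fewer than two detected barcodes contribute an all-missing matrix
#' (their count is reported in `n_uninformative`).
#'
#' @param traces a [trace_set].
#' @return A `pwd_ensemble`: `pwd` array (barcode x barcode x trace, nm,
#'   zero diagonal where detected), `barcodes`, `n_traces`.
#' @export
pwd_matrices <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  bc <- traces$barcodes
  b <- nrow(bc)
  tid <- unique(traces$records$trace_id)
  t_n <- length(tid)
  ti <- match(traces$records$trace_id, tid)
  bi <- match(traces$records$barcode_id, bc$barcode_id)
  X <- Y <- Z <- matrix(NA_real_, t_n, b)
  X[cbind(ti, bi)] <- traces$records$x
  Y[cbind(ti, bi)] <- traces$records$y
  Z[cbind(ti, bi)] <- traces$records$z
  arr <- array(NA_real_, dim = c(b, b, t_n),
               dimnames = list(bc$barcode_id, bc$barcode_id, NULL))
  for (i in seq_len(b)) {
    arr[i, i, ] <- ifelse(is.na(X[, i]), NA_real_, 0)
    if (i == b) next
    for (j in (i + 1L):b) {
      d <- sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2 +
                (Z[, i] - Z[, j])^2)
      arr[i, j, ] <- d
      arr[j, i, ] <- d
    }
  }
  n_det <- rowSums(!is.na(X))
  structure(list(pwd = arr, barcodes = bc, n_traces = traces$n_traces,
                 n_uninformative = sum(n_det < 2L)),
            class = "pwd_ensemble")
}

#' @export
print.pwd_ensemble <- function(x, ...) {
  cat("pwd_ensemble:", dim(x$pwd)[1], "barcodes x", dim(x$pwd)[3],
      "traces\n")
  invisible(x)
}

#' Ensemble median pairwise-distance map
#'
#' Element-wise median over traces, missing-aware. Entries supported by
#' fewer than `min_count` traces are flagged low-confidence (attribute
#' `low_confidence`); the default of 50 keeps only statistically
#' representative entries.
#'
#' @param ensemble a [pwd_matrices] ensemble.
#' @param min_count minimum trace count per entry (default 50).
#' @return Barcode x barcode matrix of median distances (nm).
#' @export
median_pwd <- function(ensemble, min_count = 50) {
  stopifnot(inherits(ensemble, "pwd_ensemble"))
  med <- apply(ensemble$pwd, c(1, 2), stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  cnt <- apply(!is.na(ensemble$pwd), c(1, 2), sum)
  attr(med, "low_confidence") <- cnt < min_count
  attr(med, "n_per_entry") <- cnt
  med
}

#' Proximity-frequency map at a distance cutoff
#'
#' Per barcode pair: the number of traces in which the pairwise distance is
#' within `cutoff_nm`, normalized by the number of traces in which both
#' barcodes were detected. The diagonal is 1 by convention; pairs never
#' co-detected are missing.
#'
#' @param ensemble a [pwd_matrices] ensemble.
#' @param cutoff_nm distance cutoff in nm (default 200, the threshold that
#'   maximizes agreement between imaging and Hi-C maps).
#' @return A `proximity_map`: `freq` (in \[0, 1\]), `n` (denominators),
#'   `cutoff_nm`, `barcodes`.
#' @export
proximity_map <- function(ensemble, cutoff_nm = 200) {
  stopifnot(inherits(ensemble, "pwd_ensemble"))
  num <- apply(ensemble$pwd <= cutoff_nm, c(1, 2), sum, na.rm = TRUE)
  den <- apply(!is.na(ensemble$pwd), c(1, 2), sum)
  freq <- ifelse(den > 0, num / den, NA_real_)
  diag(freq) <- 1
  structure(list(freq = freq, n = den, cutoff_nm = cutoff_nm,
                 barcodes = ensemble$barcodes),
            class = "proximity_map")
}

#' @export
print.proximity_map <- function(x, ...) {
  off <- x$freq[upper.tri(x$freq)]
  cat(sprintf("proximity_map: %d barcodes, cutoff %g nm, mean off-diagonal frequency %.3f\n",
              nrow(x$freq), x$cutoff_nm, mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Per-barcode detection efficiency
#'
#' Fraction of acquired traces in which each barcode was detected.
#'
#' @param traces a [trace_set].
#' @return Named numeric vector in \[0, 1\].
#' @export
detection_efficiency <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  counts <- table(factor(traces$records$barcode_id,
                         levels = traces$barcodes$barcode_id))
  stats::setNames(as.vector(counts) / traces$n_traces,
                  traces$barcodes$barcode_id)
}

#' Imaging insulation score from a median distance map
#'
#' Moves an n x n square window along the diagonal of the median pairwise
#' distance map and sums the distances within the square spanning barcodes
#' (b-n+1 .. b) x (b+1 .. b+n). The sum is missing-aware and scaled to the
#' full block size (mean of present entries times n^2). High values mean
#' large cross-window distances, i.e. strong insulation between the
#' flanking barcode groups; the profile is undefined within n-1 barcodes of
#' the locus ends.
#'
#' @param med median distance matrix from [median_pwd].
#' @param n window size in barcodes.
#' @return Numeric profile, one value per barcode (NA where undefined).
#' @export
him_insulation <- function(med, n = 2) {
  b <- nrow(med)
  n <- as.integer(n)
  if (n < 1L || n > (b - 1L) %/% 2L)
    stop("window must satisfy 1 <= n <= (#barcodes - 1) / 2")
  prof <- rep(NA_real_, b)
  for (k in n:(b - n)) {
    blk <- med[(k - n + 1L):k, (k + 1L):(k + n), drop = FALSE]
    if (any(!is.na(blk))) prof[k] <- mean(blk, na.rm = TRUE) * n^2
  }
  names(prof) <- rownames(med)
  prof
}

# centered moving average, NA-aware, same length
.moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- (width - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    if (any(!is.na(v))) out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Domainogram of imaging insulation profiles
#'
#' Stacks [him_insulation] profiles for a range of window sizes, each
#' smoothed along barcodes with a centered moving average, to visualize the
#' persistence of domain junctions across scales.
#'
#' @param med median distance matrix from [median_pwd].
#' @param n_range window sizes (default 1..6).
#' @param smooth moving-average width in barcodes (default 3; 1 = none).
#' @return Matrix with one row per window size, one column per barcode.
#' @export
domainogram <- function(med, n_range = 1:6, smooth = 3) {
  rows <- lapply(n_range, function(n)
    .moving_average(him_insulation(med, n), smooth))
  out <- do.call(rbind, rows)
  rownames(out) <- paste0("n", n_range)
  colnames(out) <- rownames(med)
  out
}

# pairs (i < j) within a barcode-id set, as index matrix
.set_pairs <- function(barcodes, set) {
  idx <- match(set, barcodes$barcode_id)
  if (anyNA(idx)) stop("unknown barcode id(s): ",
                       paste(set[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  if (length(idx) < 2L) stop("need at least 2 barcodes in the set")
  t(utils::combn(idx, 2L))
}

#' Mean proximity frequency versus cutoff distance
#'
#' For each cutoff, the mean over all unordered barcode pairs of the set of
#' the pairwise proximity frequency (pairs weighted equally; pairs with no
#' co-detected trace are excluded). The curve is non-decreasing in cutoff.
#'
#' @param ensemble a [pwd_matrices] ensemble.
#' @param barcode_set barcode ids (>= 2).
#' @param cutoffs cutoff distances in nm (default 100..500 by 50).
#' @return Data frame (cutoff_nm, mean_freq) with attribute `per_pair`
#'   (pair x cutoff frequency matrix).
#' @export
cumulative_proximity_curve <- function(ensemble, barcode_set,
                                       cutoffs = seq(100, 500, by = 50)) {
  stopifnot(inherits(ensemble, "pwd_ensemble"))
  pr <- .set_pairs(ensemble$barcodes, barcode_set)
  freqs <- matrix(NA_real_, nrow(pr), length(cutoffs))
  for (p in seq_len(nrow(pr))) {
    d <- ensemble$pwd[pr[p, 1L], pr[p, 2L], ]
    den <- sum(!is.na(d))
    if (den == 0L) next
    freqs[p, ] <- vapply(cutoffs, function(ct) sum(d <= ct, na.rm = TRUE) / den, 0)
  }
  out <- data.frame(cutoff_nm = cutoffs,
                    mean_freq = colMeans(freqs, na.rm = TRUE))
  attr(out, "per_pair") <- freqs
  out
}

#' Distance-matched control barcode sets
#'
#' Draws `n_sets` sets of non-insulator barcodes, each the size of the
#' insulator set, whose pairwise genomic-separation distribution matches
#' the insulator set's: starting from a random eligible barcode, the set is
#' grown greedily, each step adding the eligible barcode whose new pairwise
#' separations best fill the insulator set's remaining separation slots
#' (nearest-separation matching without replacement within a set).
#' Matching quality (mean pairwise separation per set) is reported as an
#' attribute.
#'
#' @param barcode_table barcode table (`barcode_id`, `genomic_pos`,
#'   `label`).
#' @param insulator_set insulator barcode ids.
#' @param n_sets number of control sets (default 10).
#' @param seed integer seed.
#' @return List of barcode-id vectors with attribute `mean_separation`
#'   (insulator set first, then one entry per control set).
#' @export
control_sets <- function(barcode_table, insulator_set, n_sets = 10,
                         seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  tab <- barcode_table[order(barcode_table$genomic_pos), , drop = FALSE]
  ins_idx <- match(insulator_set, tab$barcode_id)
  if (anyNA(ins_idx)) stop("unknown insulator barcode id(s)")
  eligible <- setdiff(seq_len(nrow(tab)), ins_idx)
  m <- length(ins_idx)
  if (length(eligible) < m)
    stop("too few control-eligible barcodes: need ", m, ", have ",
         length(eligible))
  pos <- tab$genomic_pos
  mean_sep <- function(idx) mean(stats::dist(pos[idx]))
  target <- sort(as.vector(stats::dist(pos[ins_idx])))
  # cost of adding candidate c: its separations to the chosen barcodes,
  # each matched (and consumed) against the nearest remaining target slot
  match_cost <- function(seps, slots) {
    cost <- 0
    for (s in seps) {
      i <- which.min(abs(slots - s))
      cost <- cost + abs(slots[i] - s)
      slots <- slots[-i]
    }
    list(cost = cost, slots = slots)
  }
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    avail <- eligible
    seed_pick <- sample(avail, 1L)
    chosen <- seed_pick
    avail <- setdiff(avail, seed_pick)
    slots <- target
    while (length(chosen) < m) {
      costs <- vapply(avail, function(c)
        match_cost(abs(pos[c] - pos[chosen]), slots)$cost, 0)
      best <- avail[which(costs == min(costs))]
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      slots <- match_cost(abs(pos[pick] - pos[chosen]), slots)$slots
      chosen <- c(chosen, pick)
      avail <- setdiff(avail, pick)
    }
    sets[[s]] <- tab$barcode_id[sort(chosen)]
  }
  attr(sets, "mean_separation") <-
    c(insulator = mean_sep(ins_idx),
      stats::setNames(vapply(sets, function(ids)
        mean_sep(match(ids, tab$barcode_id)), 0),
        paste0("control", seq_len(n_sets))))
  sets
}

#' Proximity frequency versus genomic distance with polynomial fit
#'
#' Scatters the per-pair proximity frequency at a fixed cutoff against the
#' pair's genomic separation for each barcode set, fits a polynomial of the
#' stated degree per set, and derives a 95% confidence band by
#' bootstrapping traces.
#'
#' @param ensemble a [pwd_matrices] ensemble.
#' @param sets named list of barcode-id sets (e.g. insulator and matched
#'   controls).
#' @param cutoff_nm proximity cutoff, nm (default 200).
#' @param fit_degree polynomial degree (default 3).
#' @param n_boot bootstrap replicates over traces (default 500).
#' @param seed integer seed.
#' @return List with `points` (set, sep_bp, freq) and `fits` (per set:
#'   sep_bp grid, fit, lo, hi).
#' @export
proximity_vs_distance <- function(ensemble, sets, cutoff_nm = 200,
                                  fit_degree = 3, n_boot = 500, seed = 1) {
  stopifnot(inherits(ensemble, "pwd_ensemble"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  pos <- ensemble$barcodes$genomic_pos
  t_n <- dim(ensemble$pwd)[3]
  points <- list(); fits <- list()
  for (nm in names(sets)) {
    pr <- .set_pairs(ensemble$barcodes, sets[[nm]])
    n_pr <- nrow(pr)
    if (n_pr < fit_degree + 1)
      stop("set ", nm, ": fewer pairs (", n_pr, ") than fit_degree + 1")
    close_m <- matrix(FALSE, n_pr, t_n)
    det_m <- matrix(FALSE, n_pr, t_n)
    sep <- numeric(n_pr)
    for (p in seq_len(n_pr)) {
      d <- ensemble$pwd[pr[p, 1L], pr[p, 2L], ]
      det_m[p, ] <- !is.na(d)
      close_m[p, ] <- !is.na(d) & d <= cutoff_nm
      sep[p] <- abs(pos[pr[p, 2L]] - pos[pr[p, 1L]])
    }
    freq <- rowSums(close_m) / pmax(rowSums(det_m), 1L)
    keep <- rowSums(det_m) > 0
    df <- data.frame(set = nm, sep_bp = sep[keep], freq = freq[keep])
    points[[nm]] <- df
    fit <- stats::lm(freq ~ poly(sep_bp, fit_degree, raw = TRUE), data = df)
    grid <- seq(min(df$sep_bp), max(df$sep_bp), length.out = 50)
    pred <- stats::predict(fit, data.frame(sep_bp = grid))
    # bootstrap over traces: multinomial weights, matrix products give
    # per-pair numerators/denominators per replicate
    W <- stats::rmultinom(n_boot, t_n, rep(1 / t_n, t_n))
    num_b <- close_m %*% W
    den_b <- det_m %*% W
    boot_pred <- matrix(NA_real_, n_boot, length(grid))
    for (bb in seq_len(n_boot)) {
      fb <- num_b[keep, bb] / pmax(den_b[keep, bb], 1L)
      dfb <- data.frame(sep_bp = df$sep_bp, freq = fb)
      fitb <- stats::lm(freq ~ poly(sep_bp, fit_degree, raw = TRUE), data = dfb)
      boot_pred[bb, ] <- stats::predict(fitb, data.frame(sep_bp = grid))
    }
    fits[[nm]] <- data.frame(
      set = nm, sep_bp = grid, fit = pred,
      lo = apply(boot_pred, 2L, stats::quantile, 0.025),
      hi = apply(boot_pred, 2L, stats::quantile, 0.975))
  }
  list(points = do.call(rbind, points), fits = do.call(rbind, fits))
}

#' Multiway proximity clusters around anchor barcodes
#'
#' For every anchor barcode a of the set and every trace in which a is
#' detected, counts the number k of other anchors lying within `cutoff_nm`
#' of a (undetected partners count as non-proximal; `strict = TRUE`
#' restricts to traces where every partner is detected). Reports, per
#' anchor and pooled: the observed frequency of each cluster size k, and
#' the cluster-size counts normalized by the anchor's total number of
#' pairwise proximity events.
#'
#' @param ensemble a [pwd_matrices] ensemble.
#' @param anchor_set barcode ids (>= 3; multiway is undefined below that).
#' @param cutoff_nm proximity cutoff, nm (default 200).
#' @param strict require all partners detected (default FALSE).
#' @return A `multiway_result`: `per_anchor` data frame (anchor, k, count,
#'   freq, normalized), `pooled` data frame, `n_detected` per anchor,
#'   `cutoff_nm`.
#' @export
multiway_clusters <- function(ensemble, anchor_set, cutoff_nm = 200,
                              strict = FALSE) {
  stopifnot(inherits(ensemble, "pwd_ensemble"))
  idx <- match(anchor_set, ensemble$barcodes$barcode_id)
  if (anyNA(idx)) stop("unknown anchor barcode id(s)")
  if (length(idx) < 3L) stop("multiway analysis needs >= 3 anchors")
  a_n <- length(idx)
  kmax <- a_n - 1L
  per <- list(); n_det <- integer(a_n)
  for (ai in seq_len(a_n)) {
    a <- idx[ai]
    partners <- idx[-ai]
    D <- ensemble$pwd[a, partners, , drop = TRUE]   # partners x traces
    detected_a <- !is.na(ensemble$pwd[a, a, ])
    use <- detected_a
    if (strict) use <- use & colSums(is.na(D)) == 0L
    k <- colSums(!is.na(D[, use, drop = FALSE]) &
                 D[, use, drop = FALSE] <= cutoff_nm)
    n_det[ai] <- sum(use)
    counts <- tabulate(k + 1L, nbins = kmax + 1L)   # k = 0..kmax
    total_pairwise <- sum(k)
    per[[ai]] <- data.frame(
      anchor = anchor_set[ai], k = 0:kmax, count = counts,
      freq = if (n_det[ai] > 0) counts / n_det[ai] else NA_real_,
      normalized = ifelse(0:kmax >= 1L,
                          if (total_pairwise > 0) counts / total_pairwise
                          else NA_real_, NA_real_))
  }
  per <- do.call(rbind, per)
  pooled <- stats::aggregate(cbind(count = per$count), list(k = per$k), sum)
  pooled$freq <- pooled$count / sum(n_det)
  tot_pw <- sum(per$count[per$k >= 1L] * per$k[per$k >= 1L])
  pooled$normalized <- ifelse(pooled$k >= 1L,
                              if (tot_pw > 0) pooled$count / tot_pw else NA_real_,
                              NA_real_)
  structure(list(per_anchor = per, pooled = pooled,
                 n_detected = stats::setNames(n_det, anchor_set),
                 cutoff_nm = cutoff_nm, strict = strict),
            class = "multiway_result")
}

#' @export
print.multiway_result <- function(x, ...) {
  cat("multiway_result at", x$cutoff_nm, "nm; pooled cluster sizes:\n")
  print(x$pooled)
  invisible(x)
}

#' Expected k-partner proximity frequency under independence
#'
#' Treats all pairwise proximity events of an anchor as independent: the
#' expected frequency of a k-partner event for anchor a is the mean over
#' all k-subsets S of the other anchors of the product of the pairwise
#' frequencies p(a, s), s in S.
#'
#' @param proximity a [proximity_map].
#' @param anchor_set barcode ids.
#' @param k number of partners (1 <= k < set size).
#' @return List with `per_anchor` (named vector) and `pooled` (mean).
#' @export
expected_multiway <- function(proximity, anchor_set, k) {
  stopifnot(inherits(proximity, "proximity_map"))
  idx <- match(anchor_set, proximity$barcodes$barcode_id)
  if (anyNA(idx)) stop("unknown anchor barcode id(s)")
  a_n <- length(idx)
  if (k >= a_n) stop("k must be < |anchor_set|")
  if (k < 1L) stop("k must be >= 1")
  per <- numeric(a_n)
  for (ai in seq_len(a_n)) {
    p <- proximity$freq[idx[ai], idx[-ai]]
    subs <- utils::combn(length(p), k)
    per[ai] <- mean(apply(subs, 2L, function(s) prod(p[s])))
  }
  list(per_anchor = stats::setNames(per, anchor_set), pooled = mean(per))
}

#' Observed vs expected k-way proximity under the independence null
#'
#' The observed k-way frequency of anchor a is the mean over all k-subsets
#' S of its partners of the fraction of traces (with a detected) in which
#' every member of S lies within the cutoff of a simultaneously; the
#' expected value is [expected_multiway] computed from the pairwise
#' proximity map of the same ensemble. Approximate standard errors
#' (binomial for the observed, delta-method for the expected product)
#' accompany the pooled values.
#'
#' @param ensemble a [pwd_matrices] ensemble.
#' @param anchor_set barcode ids (>= 3).
#' @param cutoff_nm proximity cutoff, nm.
#' @param k_values partner counts to evaluate (default 2:4).
#' @return Data frame (k, anchor, observed, expected, se_observed,
#'   se_expected); one `"pooled"` row per k plus one row per anchor.
#' @export
multiway_independence <- function(ensemble, anchor_set, cutoff_nm = 200,
                                  k_values = 2:4) {
  stopifnot(inherits(ensemble, "pwd_ensemble"))
  idx <- match(anchor_set, ensemble$barcodes$barcode_id)
  if (anyNA(idx)) stop("unknown anchor barcode id(s)")
  a_n <- length(idx)
  if (a_n < 3L) stop("multiway analysis needs >= 3 anchors")
  prox <- proximity_map(ensemble, cutoff_nm)
  out <- list()
  for (k in k_values) {
    if (k >= a_n) next
    obs_a <- se_a <- exp_se_a <- numeric(a_n)
    for (ai in seq_len(a_n)) {
      a <- idx[ai]
      partners <- idx[-ai]
      D <- ensemble$pwd[a, partners, , drop = TRUE]
      use <- !is.na(ensemble$pwd[a, a, ])
      Dm <- !is.na(D[, use, drop = FALSE]) & D[, use, drop = FALSE] <= cutoff_nm
      n_use <- sum(use)
      subs <- utils::combn(length(partners), k)
      ps <- apply(subs, 2L, function(s) mean(colSums(Dm[s, , drop = FALSE]) == k))
      obs_a[ai] <- mean(ps)
      se_a[ai] <- sqrt(max(obs_a[ai] * (1 - obs_a[ai]), 1e-12) / max(n_use, 1L))
      p <- prox$freq[a, partners]
      n_pair <- prox$n[a, partners]
      prods <- apply(subs, 2L, function(s) prod(p[s]))
      vars <- apply(subs, 2L, function(s) {
        pr <- prod(p[s])
        if (pr == 0) return(0)
        pr^2 * sum((1 - p[s]) / pmax(p[s] * n_pair[s], 1e-12))
      })
      exp_se_a[ai] <- sqrt(mean(vars)) / sqrt(1)
    }
    ex <- expected_multiway(prox, anchor_set, k)
    out[[as.character(k)]] <- data.frame(
      k = k, anchor = c("pooled", anchor_set),
      observed = c(mean(obs_a), obs_a),
      expected = c(ex$pooled, unname(ex$per_anchor)),
      se_observed = c(sqrt(mean(se_a^2)) / sqrt(a_n), se_a),
      se_expected = c(sqrt(mean(exp_se_a^2)) / sqrt(a_n), exp_se_a))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
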