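#' Simulate a binned contact map with planted TADs and loops
#'
#' Generates per-arm contact intensities
#' \deqn{\lambda(i,j) = C\,|i-j|^{-\alpha} \cdot T(i,j) \cdot L(i,j)}
#' where the power law emulates the genomic-distance decay of contact
#' frequency, \eqn{T} multiplies intra-domain pairs by a compaction factor
#' (planted TAD boundaries partition each arm into domains), and \eqn{L}
#' multiplies planted loop pixels by their enrichment factor, with a one-bin
#' halo at half strength. With a finite sequencing `depth`, counts are drawn
#' as a Poisson sample of the intensities (total expected count = `depth`)
#' and returned as frequencies; with `depth = Inf` the noiseless intensities
#' are returned unscaled, so observed/expected ratios are analytic.
#'
#' @param bins a [genomic_bins] object.
#' @param decay_exponent power-law decay exponent \eqn{\alpha > 0}
#'   (default 1, the classical fractal-globule regime).
#' @param tad_boundaries named list (per arm) of 0-based boundary bins; each
#'   boundary starts a new domain.
#' @param compaction intensity multiplier for intra-domain pairs
#'   (default 2).
#' @param loops optional [loop_list] of planted loops; a numeric
#'   `enrichment` column overrides the scalar `enrichment`.
#' @param enrichment default per-loop enrichment factor (>= 1).
#' @param depth expected total read count across all arms, or `Inf` for the
#'   noiseless intensity matrix.
#' @param seed integer seed; the draw is reproducible per seed.
#' @return A list with `map` (a [contact_map]) and `truth` (planted
#'   boundaries, loops with enrichments, generator parameters).
#' @export
simulate_contact_map <- function(bins, decay_exponent = 1,
                                 tad_boundaries = NULL, compaction = 2,
                                 loops = NULL, enrichment = 3,
                                 depth = 5e6, seed = 1) {
  stopifnot(inherits(bins, "genomic_bins"))
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(loops)) {
    enr <- if ("enrichment" %in% names(loops)) loops$enrichment
           else rep(enrichment, nrow(loops))
    if (any(enr < 1)) stop("loop enrichment factors must be >= 1")
  }
  lam <- list()
  for (arm in bins$arms) {
    n <- bins$n_bins[[arm]]
    d <- abs(outer(seq_len(n) - 1L, seq_len(n) - 1L, "-"))
    m <- pmax(d, 1L)^(-decay_exponent)
    bnd <- sort(unique(as.integer(tad_boundaries[[arm]])))
    if (length(bnd)) {
      if (any(bnd < 0L | bnd >= n)) stop("TAD boundary outside arm ", arm)
      seg <- findInterval(seq_len(n) - 1L, bnd)
      m <- m * ifelse(outer(seg, seg, "=="), compaction, 1)
    }
    if (!is.null(loops)) {
      sel <- loops$arm == arm
      if (any(sel)) {
        fac <- matrix(1, n, n)
        b1 <- loops$bin1[sel] + 1L; b2 <- loops$bin2[sel] + 1L
        e <- enr[sel]
        if (any(b1 < 1L | b2 > n)) stop("loop anchors outside bins on arm ", arm)
        for (k in seq_along(b1)) {
          halo <- 1 + (e[k] - 1) / 2
          ri <- max(1L, b1[k] - 1L):min(n, b1[k] + 1L)
          ci <- max(1L, b2[k] - 1L):min(n, b2[k] + 1L)
          fac[ri, ci] <- pmax(fac[ri, ci], halo)
          fac[b1[k], b2[k]] <- max(fac[b1[k], b2[k]], e[k])
        }
        fac <- pmax(fac, t(fac))
        m <- m * fac
      }
    }
    lam[[arm]] <- m
  }
  truth <- list(tad_boundaries = tad_boundaries,
                loops = loops,
                enrichment = if (is.null(loops)) NULL else enr,
                decay_exponent = decay_exponent, compaction = compaction,
                depth = depth, seed = seed)
  if (is.infinite(depth)) {
    return(list(map = contact_map(lam, bins), truth = truth))
  }
  total <- sum(vapply(lam, function(m) sum(m[upper.tri(m, diag = TRUE)]), 0))
  mats <- list()
  for (arm in bins$arms) {
    m <- lam[[arm]]
    n <- nrow(m)
    up <- upper.tri(m, diag = TRUE)
    counts <- matrix(0, n, n)
    counts[up] <- stats::rpois(sum(up), depth * m[up] / total)
    counts <- counts + t(counts) - diag(diag(counts))
    mats[[arm]] <- counts / depth
  }
  list(map = contact_map(mats, bins), truth = truth)
}

#' Simulate a peak track coinciding with planted loop anchors
#'
#' Writes one single-bin peak per planted loop anchor with a signal derived
#' from the anchor's planted enrichment (so that signal-stratified recovery
#' of the enrichment gradient is testable), plus `n_background` peaks at
#' uniformly sampled non-anchor bins with baseline signal.
#'
#' @param bins a [genomic_bins] object.
#' @param truth the `truth` component returned by [simulate_contact_map]
#'   (must contain planted loops).
#' @param n_background number of background (non-anchor) peaks.
#' @param signal_law function mapping a vector of enrichment factors to peak
#'   signals (default: identity); background peaks get `signal_law(1)`.
#' @param seed integer seed.
#' @return A [peak_set] of single-bin peaks.
#' @export
simulate_peaks <- function(bins, truth, n_background = 0,
                           signal_law = identity, seed = 1) {
  if (is.null(truth$loops)) stop("truth contains no planted loops")
  if (!is.null(seed)) set.seed(seed)
  loops <- truth$loops
  enr <- truth$enrichment
  anch <- data.frame(arm = c(loops$arm, loops$arm),
                     bin = c(loops$bin1, loops$bin2),
                     enr = c(enr, enr), stringsAsFactors = FALSE)
  key <- paste(anch$arm, anch$bin)
  anch <- do.call(rbind, lapply(split(anch, key), function(g)
    data.frame(arm = g$arm[1], bin = g$bin[1], enr = max(g$enr))))
  taken <- paste(anch$arm, anch$bin)
  bg <- list()
  if (n_background > 0) {
    arm_prob <- bins$n_bins / sum(bins$n_bins)
    for (i in seq_len(n_background)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        arm <- sample(bins$arms, 1L, prob = arm_prob)
        bin <- sample.int(bins$n_bins[[arm]], 1L) - 1L
        if (!(paste(arm, bin) %in% taken)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place background peak ", i,
                    " off-anchor after 1000 tries")
      taken <- c(taken, paste(arm, bin))
      bg[[i]] <- data.frame(arm = arm, bin = bin, enr = 1)
    }
  }
  all <- rbind(anch, do.call(rbind, bg))
  sig <- signal_law(all$enr)
  peak_set(data.frame(arm = all$arm,
                      start = bin_start(bins, all$bin),
                      end = bin_start(bins, all$bin) + bins$bin_size,
                      signal = sig,
                      name = sprintf("peak_%04d", seq_len(nrow(all))),
                      stringsAsFactors = FALSE),
           feature = "simulated")
}

#' Simulate polymer-like chromatin traces with planted colocalization
#'
#' Each trace is a 3D Gaussian random walk over the barcodes in genomic
#' order: the per-axis step between adjacent barcodes has standard deviation
#' `backbone_step * sqrt(gap_kb)` (nm), giving the monotone decay of spatial
#' proximity with genomic separation expected of a polymer. Independently
#' per trace and per planted pair (i, j) with probability `p_table[i, j]`,
#' the pair is collapsed: barcode j is resampled uniformly inside a ball of
#' radius `cutoff_nm` around barcode i. Optionally, with probability
#' `hub_prob` per trace, every barcode of `hub_set` is collapsed onto the
#' set's first barcode (a genuine multiway hub, used to test sensitivity of
#' the multiway analysis). Finally each (trace, barcode) observation is
#' dropped independently with probability `1 - efficiency`.
#'
#' Because pairwise collapses are applied independently per pair, observed
#' k-way frequencies match the independence expectation, giving a calibrated
#' null for the multiway analysis; `hub_prob > 0` plants true excess
#' multiway clustering.
#'
#' @param n_traces number of traces (nuclei) to simulate.
#' @param barcode_map barcode table (`barcode_id`, `genomic_pos`, `label`).
#' @param backbone_step random-walk step scale, nm per sqrt(kb)
#'   (default 40, giving adjacent-barcode 3D distances of a few hundred nm
#'   at ~12 kb spacing).
#' @param p_table symmetric matrix of planted pairwise colocalization
#'   probabilities with zero diagonal (default: none).
#' @param cutoff_nm collapse radius, nm (default 200).
#' @param efficiency per-barcode detection probability in (0, 1]; scalar or
#'   vector.
#' @param hub_prob per-trace probability of a planted multiway collapse.
#' @param hub_set barcode ids collapsing together when `hub_prob > 0`.
#' @param seed integer seed.
#' @return A list with `traces` (a [trace_set]) and `truth` (planted
#'   parameters).
#' @export
simulate_traces <- function(n_traces, barcode_map, backbone_step = 40,
                            p_table = NULL, cutoff_nm = 200, efficiency = 1,
                            hub_prob = 0, hub_set = NULL, seed = 1) {
  if (backbone_step <= 0) stop("backbone_step must be > 0")
  barcode_map <- barcode_map[order(barcode_map$genomic_pos), , drop = FALSE]
  b <- nrow(barcode_map)
  if (b < 2L) stop("need at least 2 barcodes")
  if (!is.null(p_table)) {
    p_table <- as.matrix(p_table)
    if (!all(dim(p_table) == b)) stop("p_table must be ", b, "x", b)
    if (any(p_table < 0 | p_table > 1)) stop("p_table entries must be in [0, 1]")
    if (max(abs(p_table - t(p_table))) > 0) stop("p_table must be symmetric")
    if (any(diag(p_table) != 0)) stop("p_table diagonal must be zero")
  }
  eff <- rep_len(efficiency, b)
  if (any(eff <= 0 | eff > 1)) stop("efficiency must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  t_n <- as.integer(n_traces)
  gaps_kb <- diff(barcode_map$genomic_pos) / 1000
  sds <- backbone_step * sqrt(gaps_kb)
  X <- Y <- Z <- matrix(0, t_n, b)
  for (k in 2:b) {
    X[, k] <- X[, k - 1L] + stats::rnorm(t_n, sd = sds[k - 1L])
    Y[, k] <- Y[, k - 1L] + stats::rnorm(t_n, sd = sds[k - 1L])
    Z[, k] <- Z[, k - 1L] + stats::rnorm(t_n, sd = sds[k - 1L])
  }
  collapse_onto <- function(sel, i, j) {
    # resample j uniformly in a ball of radius cutoff_nm around i
    ns <- length(sel)
    if (ns == 0L) return(invisible())
    r <- cutoff_nm * stats::runif(ns)^(1 / 3)
    gx <- stats::rnorm(ns); gy <- stats::rnorm(ns); gz <- stats::rnorm(ns)
    nrm <- sqrt(gx^2 + gy^2 + gz^2)
    nrm[nrm == 0] <- 1
    X[sel, j] <<- X[sel, i] + r * gx / nrm
    Y[sel, j] <<- Y[sel, i] + r * gy / nrm
    Z[sel, j] <<- Z[sel, i] + r * gz / nrm
  }
  if (!is.null(p_table)) {
    for (i in seq_len(b - 1L)) for (j in (i + 1L):b) {
      p <- p_table[i, j]
      if (p > 0) collapse_onto(which(stats::runif(t_n) < p), i, j)
    }
  }
  if (hub_prob > 0) {
    if (is.null(hub_set) || length(hub_set) < 3L)
      stop("hub_set must name >= 3 barcodes when hub_prob > 0")
    hub_idx <- match(hub_set, barcode_map$barcode_id)
    if (anyNA(hub_idx)) stop("hub_set contains unknown barcode ids")
    hub_idx <- sort(hub_idx)
    sel <- which(stats::runif(t_n) < hub_prob)
    for (j in hub_idx[-1L]) collapse_onto(sel, hub_idx[1L], j)
  }
  det <- matrix(stats::runif(t_n * b), t_n, b) <= rep(eff, each = t_n)
  idx <- which(det, arr.ind = TRUE)
  records <- data.frame(
    trace_id = sprintf("T%06d", idx[, 1L]),
    barcode_id = barcode_map$barcode_id[idx[, 2L]],
    x = X[idx], y = Y[idx], z = Z[idx],
    stringsAsFactors = FALSE)
  records <- records[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  truth <- list(p_table = p_table, cutoff_nm = cutoff_nm,
                efficiency = stats::setNames(eff, barcode_map$barcode_id),
                backbone_step = backbone_step, hub_prob = hub_prob,
                hub_set = hub_set, seed = seed)
  list(traces = trace_set(records, barcode_map, n_traces = t_n),
       truth = truth)
}

#' Simulate a locus-scale multiplexed imaging study
#'
#' Bundles the default conditions of the locus-scale trace analysis: 34
#' equally spaced barcodes (~12.2 kb apart, ~400 kb locus), ten of them
#' insulator-bound (I1..I10), a random-walk backbone calibrated so that
#' distance-matched control pairs colocalize at ~10-11% at the 200 nm
#' cutoff, a planted colocalization excess of `p_excess` on every
#' insulator-insulator pair bringing insulator pairs to ~12%, and a
#' uniform detection efficiency of 0.8.
#'
#' @param n_traces number of traces (default 5000).
#' @param p_excess planted colocalization probability added independently
#'   to each insulator pair (default 0.016).
#' @param backbone_step random-walk step scale, nm per sqrt(kb)
#'   (default 27).
#' @param efficiency per-barcode detection probability (default 0.8).
#' @param hub_prob optional planted multiway collapse probability over the
#'   insulator barcodes (default 0: pairwise-independent planting).
#' @param seed integer seed.
#' @return As [simulate_traces], with `barcode_map` attached to the truth.
#' @export
simulate_him_study <- function(n_traces = 5000, p_excess = 0.016,
                               backbone_step = 27, efficiency = 0.8,
                               hub_prob = 0, seed = 1) {
  ins_pos <- c(3L, 6L, 9L, 13L, 16L, 20L, 23L, 27L, 30L, 33L)
  barcode_map <- data.frame(
    barcode_id = sprintf("b%02d", 1:34),
    genomic_pos = seq(0, by = 12200, length.out = 34),
    label = ifelse(1:34 %in% ins_pos, "insulator", "control"),
    stringsAsFactors = FALSE)
  p <- matrix(0, 34, 34)
  p[ins_pos, ins_pos] <- p_excess
  diag(p) <- 0
  out <- simulate_traces(n_traces, barcode_map,
                         backbone_step = backbone_step, p_table = p,
                         cutoff_nm = 200, efficiency = efficiency,
                         hub_prob = hub_prob,
                         hub_set = if (hub_prob > 0)
                           barcode_map$barcode_id[ins_pos] else NULL,
                         seed = seed)
  out$truth$barcode_map <- barcode_map
  out$truth$insulator_set <- barcode_map$barcode_id[ins_pos]
  out
}
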