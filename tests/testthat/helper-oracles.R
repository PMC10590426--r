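# Independent brute-force oracles and fixture builders used across tests.

# endpoint-pair Pearson over both orientations of every edge, written from
# the definition with explicit sums (no call into the package)
bf_endpoint_pearson <- function(a1, a2, b1, b2 = NULL) {
  if (is.null(b2)) { b2 <- a2; b1 <- a1 }
  x <- c(rbind(a1, a2))
  y <- c(rbind(b2, b1))
  mx <- mean(x); my <- mean(y)
  sx <- sum((x - mx)^2); sy <- sum((y - my)^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / sqrt(sx * sy)
}

# random multi-arm bins fixture
fix_bins <- function(sizes = c(armA = 2e6, armB = 1.5e6), bin_size = 5000) {
  genomic_bins(sizes, bin_size)
}

# random cis loop list with separations in [min_sep, max_sep] bins
fix_loops <- function(bins, n_edges, min_sep = 4, max_sep = 60) {
  arm <- sample(bins$arms, n_edges, replace = TRUE)
  sep <- sample(min_sep:max_sep, n_edges, replace = TRUE)
  nmax <- bins$n_bins[arm] - 1L - sep
  b1 <- floor(runif(n_edges) * nmax)
  loop_list(data.frame(arm = arm, bin1 = b1, bin2 = b1 + sep), bins)
}

# paint a continuous random feature on every bin
fix_random_track <- function(bins, binary = FALSE, density = 0.2) {
  lapply(bins$n_bins, function(n) {
    if (binary) as.numeric(runif(n) < density) else runif(n)
  })
}

# brute-force per-bin signal totals: each peak contributes
# signal * overlap / width to each bin it overlaps
bf_signal_track <- function(bins, peaks) {
  out <- lapply(bins$n_bins, function(n) numeric(n))
  for (i in seq_len(nrow(peaks))) {
    arm <- peaks$arm[i]
    bs <- bins$bin_size
    for (b in seq_len(bins$n_bins[[arm]]) - 1L) {
      lo <- max(peaks$start[i], b * bs)
      hi <- min(peaks$end[i], (b + 1) * bs)
      if (hi > lo)
        out[[arm]][b + 1L] <- out[[arm]][b + 1L] +
          peaks$signal[i] * (hi - lo) / (peaks$end[i] - peaks$start[i])
    }
  }
  out
}

# brute-force double loop over anchor pairs within separation bounds
bf_anchor_pairs <- function(anchorsA, anchorsB, bin_size, min_sep, max_sep) {
  hits <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(anchorsA))) for (j in seq_len(nrow(anchorsB))) {
    if (anchorsA$arm[i] != anchorsB$arm[j]) next
    lo <- min(anchorsA$bin[i], anchorsB$bin[j])
    hi <- max(anchorsA$bin[i], anchorsB$bin[j])
    if (lo == hi) next
    sep <- (hi - lo) * bin_size
    if (sep < min_sep || sep > max_sep) next
    key <- paste(anchorsA$arm[i], lo, hi)
    if (key %in% seen) next
    seen <- c(seen, key)
    hits <- hits + 1L
  }
  hits
}

# two-domain median distance matrix: small distances within blocks,
# large across; junction after barcode `j`
fix_two_domain_median <- function(b = 12, j = 6, near = 150, far = 700) {
  m <- matrix(far, b, b)
  m[1:j, 1:j] <- near
  m[(j + 1):b, (j + 1):b] <- near
  diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("b%02d", 1:b)
  m
}

# barcode table fixture
fix_barcodes <- function(b = 10, spacing = 12000, insulators = integer(0)) {
  data.frame(barcode_id = sprintf("b%02d", seq_len(b)),
             genomic_pos = seq(0, by = spacing, length.out = b),
             label = ifelse(seq_len(b) %in% insulators, "insulator", "control"),
             stringsAsFactors = FALSE)
}
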