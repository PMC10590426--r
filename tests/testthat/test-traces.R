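make_ts <- function(records, b = 3) trace_set(records, fix_barcodes(b))

test_that("pairwise distances are Euclidean with missing propagation", {
  rec <- data.frame(trace_id = c("t1", "t1", "t2", "t2", "t2"),
                    barcode_id = c("b01", "b02", "b01", "b02", "b03"),
                    x = c(0, 300, 0, 1, 2), y = c(0, 400, 0, 1, 2),
                    z = c(0, 0, 0, 1, 2))
  ens <- pwd_matrices(make_ts(rec))
  expect_equal(ens$pwd["b01", "b02", 1], 500)           # 3-4-5 triangle
  expect_true(all(is.na(ens$pwd["b03", , 1])))          # undetected barcode
  expect_equal(ens$pwd["b01", "b03", 2], sqrt(12), tolerance = 1e-12)
  expect_equal(ens$pwd[, , 2], t(ens$pwd[, , 2]))
  # brute force on random fixtures
  set.seed(3)
  sim <- simulate_traces(20, fix_barcodes(6), efficiency = 0.7, seed = 3)
  ens2 <- pwd_matrices(sim$traces)
  r <- sim$traces$records
  for (t in sample(unique(r$trace_id), 5)) {
    rt <- r[r$trace_id == t, ]
    ti <- which(unique(r$trace_id) == t)
    if (nrow(rt) < 2) next
    for (i in 1:(nrow(rt) - 1)) for (j in (i + 1):nrow(rt)) {
      d <- sqrt(sum((rt[i, c("x", "y", "z")] - rt[j, c("x", "y", "z")])^2))
      expect_equal(ens2$pwd[rt$barcode_id[i], rt$barcode_id[j], ti], d,
                   tolerance = 1e-9)
    }
  }
})

test_that("median map matches a sort-based oracle and flags sparse entries", {
  set.seed(9)
  sim <- simulate_traces(101, fix_barcodes(5), efficiency = 1, seed = 9)
  ens <- pwd_matrices(sim$traces)
  med <- median_pwd(ens, min_count = 50)
  v <- sort(ens$pwd[2, 4, ])
  expect_equal(med[2, 4], v[51])  # odd count: middle order statistic
  expect_false(any(attr(med, "low_confidence")))
  sim2 <- simulate_traces(20, fix_barcodes(5), efficiency = 1, seed = 2)
  med2 <- median_pwd(pwd_matrices(sim2$traces), min_count = 50)
  expect_true(all(attr(med2, "low_confidence")))
  # median distance grows with genomic separation on backbone traces
  sim3 <- simulate_traces(800, fix_barcodes(8), efficiency = 1, seed = 4)
  med3 <- median_pwd(pwd_matrices(sim3$traces))
  expect_true(all(diff(med3[1, ]) > 0))
})

test_that("proximity frequency is a monotone function of the cutoff", {
  sim <- simulate_traces(300, fix_barcodes(6), efficiency = 0.8, seed = 6)
  ens <- pwd_matrices(sim$traces)
  maps <- lapply(c(100, 200, 300, 400), function(ct) proximity_map(ens, ct)$freq)
  for (k in 2:4) expect_true(all(maps[[k]] - maps[[k - 1]] >= 0, na.rm = TRUE))
  pm <- proximity_map(ens, 200)
  expect_equal(diag(pm$freq), rep(1, 6), ignore_attr = TRUE)
  expect_equal(pm$freq, t(pm$freq))
  num <- apply(ens$pwd <= 200, c(1, 2), sum, na.rm = TRUE)
  expect_equal(pm$freq[1, 2], num[1, 2] / pm$n[1, 2])
})

test_that("imaging insulation score and domainogram locate the junction", {
  med <- fix_two_domain_median(b = 12, j = 6)
  # constant map -> constant profile
  const <- matrix(500, 12, 12); diag(const) <- 0
  prof_c <- him_insulation(const, 3)
  expect_equal(length(unique(round(stats::na.omit(prof_c), 9))), 1L)
  # n = 1 profile equals the first off-diagonal
  p1 <- him_insulation(med, 1)
  expect_equal(unname(p1[2:10]), med[cbind(2:10, 3:11)])
  # junction barcode maximizes every window size
  for (n in 1:5) {
    prof <- him_insulation(med, n)
    expect_equal(unname(which.max(prof)), 6L)
  }
  # symmetric two-level fixture: smoothing can tie the junction with its
  # neighbors, so the argmax check uses the unsmoothed rows
  dg <- domainogram(med, n_range = 1:5, smooth = 1)
  expect_equal(unname(apply(dg, 1, which.max)), rep(6L, 5))
  # unsmoothed domainogram rows are the insulation profiles
  dg1 <- domainogram(med, n_range = 2:3, smooth = 1)
  expect_equal(unname(dg1[1, ]), unname(him_insulation(med, 2)))
  expect_error(him_insulation(med, 6), "window")
})

test_that("cumulative proximity curves are consistent and monotone", {
  sim <- simulate_traces(400, fix_barcodes(8), efficiency = 0.9, seed = 12)
  ens <- pwd_matrices(sim$traces)
  ids <- sim$traces$barcodes$barcode_id
  cc <- cumulative_proximity_curve(ens, ids, cutoffs = seq(50, 400, 50))
  expect_true(all(diff(cc$mean_freq) >= 0))
  expect_true(all(cc$mean_freq >= 0 & cc$mean_freq <= 1))
  # at 200 nm the curve equals the mean of proximity-map entries
  pm <- proximity_map(ens, 200)
  expect_equal(cc$mean_freq[cc$cutoff_nm == 200],
               mean(pm$freq[upper.tri(pm$freq)]))
  # huge cutoff on complete data -> 1
  cc2 <- cumulative_proximity_curve(ens, ids, cutoffs = 1e9)
  expect_equal(cc2$mean_freq, 1)
  expect_error(cumulative_proximity_curve(ens, ids[1]), "at least 2")
})

test_that("control sets exclude insulators and match separations", {
  bm <- fix_barcodes(34, spacing = 12200,
                     insulators = c(3, 6, 9, 13, 16, 20, 23, 27, 30, 33))
  ins <- bm$barcode_id[bm$label == "insulator"]
  cs <- control_sets(bm, ins, n_sets = 10, seed = 5)
  expect_length(cs, 10L)
  for (s in cs) {
    expect_length(s, length(ins))
    expect_length(intersect(s, ins), 0L)
  }
  ms <- attr(cs, "mean_separation")
  expect_true(all(abs(ms[-1] / ms[1] - 1) < 0.1))
  # deterministic per seed
  cs2 <- control_sets(bm, ins, n_sets = 10, seed = 5)
  expect_identical(cs, cs2)
  # insulator set covering everything leaves no controls
  expect_error(control_sets(bm, bm$barcode_id, n_sets = 1), "too few")
})

test_that("proximity-distance fits are flat on constants, decreasing on walks", {
  sim <- simulate_traces(1500, fix_barcodes(14, spacing = 20000),
                         backbone_step = 30, efficiency = 1, seed = 21)
  ens <- pwd_matrices(sim$traces)
  ids <- sim$traces$barcodes$barcode_id
  pv <- proximity_vs_distance(ens, list(all = ids), cutoff_nm = 200,
                              fit_degree = 3, n_boot = 50, seed = 2)
  fit <- pv$fits$fit
  # decaying: short-range maximum, steep initial drop, low tail (a cubic
  # may wiggle slightly around the near-zero tail)
  expect_equal(which.max(fit), 1L)
  expect_true(all(diff(fit[1:20]) < 0))
  expect_lt(max(fit[26:50]), 0.2 * fit[1])
  expect_true(all(pv$fits$lo <= pv$fits$hi))
  # constant frequencies -> constant fitted curve (collapse all coordinates)
  simc <- simulate_traces(200, fix_barcodes(6), backbone_step = 1e-6,
                          efficiency = 1, seed = 3)
  ensc <- pwd_matrices(simc$traces)
  pvc <- proximity_vs_distance(ensc, list(all = simc$traces$barcodes$barcode_id),
                               n_boot = 20, seed = 1)
  expect_true(all(abs(pvc$fits$fit - 1) < 1e-9))
  expect_error(proximity_vs_distance(ens, list(small = ids[1:2]),
                                     fit_degree = 3, n_boot = 5), "pairs")
})

test_that("multiway cluster counts match a per-trace enumeration oracle", {
  set.seed(33)
  bm <- fix_barcodes(8)
  p <- matrix(0, 8, 8)
  p[1, 4] <- p[4, 1] <- 0.3; p[1, 7] <- p[7, 1] <- 0.2
  sim <- simulate_traces(300, bm, backbone_step = 60, p_table = p,
                         efficiency = 0.9, seed = 7)
  ens <- pwd_matrices(sim$traces)
  aset <- c("b01", "b04", "b07", "b02")
  mw <- multiway_clusters(ens, aset, cutoff_nm = 200)
  # brute-force: enumerate every trace for anchor b01
  idx <- match(aset, rownames(ens$pwd))
  k_oracle <- integer(0)
  for (t in seq_len(dim(ens$pwd)[3])) {
    if (is.na(ens$pwd[idx[1], idx[1], t])) next
    d <- ens$pwd[idx[1], idx[-1], t]
    k_oracle <- c(k_oracle, sum(!is.na(d) & d <= 200))
  }
  per <- mw$per_anchor[mw$per_anchor$anchor == "b01", ]
  expect_equal(per$count, tabulate(k_oracle + 1L, nbins = 4L))
  expect_equal(sum(per$count), sum(mw$n_detected["b01"]), ignore_attr = TRUE)
  # normalization: counts over total pairwise interaction events
  expect_equal(per$normalized[per$k >= 1],
               per$count[per$k >= 1] / sum(k_oracle))
  # degenerate geometries
  simc <- simulate_traces(50, bm, backbone_step = 1e-6, efficiency = 1, seed = 1)
  mwc <- multiway_clusters(pwd_matrices(simc$traces), aset, 200)
  expect_true(all(mwc$per_anchor$count[mwc$per_anchor$k == 3] ==
                  mwc$n_detected))
  expect_error(multiway_clusters(ens, aset[1:2], 200), ">= 3")
})

test_that("independence expectation matches subset enumeration", {
  set.seed(35)
  bm <- fix_barcodes(10)
  sim <- simulate_traces(400, bm, backbone_step = 45, efficiency = 0.9,
                         seed = 15)
  ens <- pwd_matrices(sim$traces)
  pm <- proximity_map(ens, 200)
  aset <- bm$barcode_id
  for (k in c(1, 2, 4)) {
    ex <- expected_multiway(pm, aset, k)
    # brute force over all k-subsets per anchor
    bf <- vapply(seq_along(aset), function(ai) {
      p <- pm$freq[ai, -ai]
      subs <- combn(9, k)
      mean(apply(subs, 2, function(s) prod(p[s])))
    }, 0)
    expect_equal(unname(ex$per_anchor), bf, tolerance = 1e-12)
  }
  # k = 1 reduces to the anchor's mean pairwise frequency
  ex1 <- expected_multiway(pm, aset, 1)
  expect_equal(unname(ex1$per_anchor[1]), mean(pm$freq[1, -1]))
  # all frequencies 1 -> expected 1 for every k
  pm1 <- pm; pm1$freq[] <- 1
  expect_equal(expected_multiway(pm1, aset, 3)$pooled, 1)
  expect_error(expected_multiway(pm, aset, 10), "k must be <")
})
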