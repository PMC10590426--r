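test_that("expected-by-distance reproduces distance-only maps and masks", {
  bins <- genomic_bins(c(a = 40000), 5000)  # 8 bins
  f <- function(s) 10 / (s + 1)
  m <- outer(0:7, 0:7, function(i, j) f(abs(i - j)))
  cm <- contact_map(list(a = m), bins)
  ex <- expected_by_distance(cm)
  expect_equal(ex$a, f(0:7), tolerance = 1e-12)
  # masked bin: expected computed over remaining pairs, hand-counted
  m2 <- m; m2[3, ] <- 0; m2[, 3] <- 0
  cm2 <- contact_map(list(a = m2), bins)
  ex2 <- expected_by_distance(cm2)
  # separation 1 keeps pairs (1,2),(4,5),(5,6),(6,7),(7,8) of 7 -> mean f(1)
  expect_equal(ex2$a[2], f(1), tolerance = 1e-12)
  # all values still equal f(s) since the map is distance-only
  expect_equal(ex2$a, f(0:7), tolerance = 1e-12)
})

test_that("O/E transform obeys log arithmetic and propagates missingness", {
  bins <- genomic_bins(c(a = 50000), 5000)
  set.seed(5)
  base <- outer(0:9, 0:9, function(i, j) 5 / (abs(i - j) + 1))
  cm <- contact_map(list(a = base), bins)
  oe <- oe_transform(cm)
  expect_true(all(abs(oe$mats$a) < 1e-12, na.rm = TRUE))
  # doubling one pixel raises its log2 O/E by exactly 1 (fixed expected)
  ex <- expected_by_distance(cm)
  m2 <- base; m2[2, 7] <- m2[7, 2] <- 2 * m2[2, 7]
  oe2 <- oe_transform(contact_map(list(a = m2), bins), ex)
  expect_equal(oe2$mats$a[2, 7], oe$mats$a[2, 7] + 1, tolerance = 1e-12)
  # zero observed is missing, not -Inf
  m3 <- base; m3[1, 9] <- m3[9, 1] <- 0
  oe3 <- oe_transform(contact_map(list(a = m3), bins), ex)
  expect_true(is.na(oe3$mats$a[1, 9]))
})

test_that("anchor-pair selection matches brute-force counting", {
  bins <- genomic_bins(c(a = 1e6), 5000)
  # 3 anchors at 0 / 100 kb / 300 kb with bounds [50 kb, 250 kb] -> 2 pairs
  anch <- data.frame(arm = "a", bin = c(0, 20, 60))
  pr <- select_anchor_pairs(anch, bins = bins, min_sep = 50e3, max_sep = 250e3)
  expect_equal(nrow(pr), 2L)
  # n mutually in-range anchors -> n(n-1)/2 pairs
  anch2 <- data.frame(arm = "a", bin = seq(10, 82, by = 8))
  pr2 <- select_anchor_pairs(anch2, bins = bins, min_sep = 20e3, max_sep = 2e6)
  n <- nrow(anch2)
  expect_equal(nrow(pr2), n * (n - 1) / 2)
  # random sets against the double-loop oracle
  set.seed(13)
  bins2 <- fix_bins()
  for (rep in 1:100) {
    a <- data.frame(arm = sample(bins2$arms, 8, TRUE),
                    bin = sample(0:250, 8))
    b <- data.frame(arm = sample(bins2$arms, 6, TRUE),
                    bin = sample(0:250, 6))
    pr <- select_anchor_pairs(a, b, bins2, min_sep = 20e3, max_sep = 500e3)
    expect_equal(nrow(pr),
                 bf_anchor_pairs(a, b, 5000, 20e3, 500e3))
  }
})

test_that("APA aggregates submatrices with the averaging identities", {
  bins <- genomic_bins(c(a = 60 * 5000), 5000)
  zero <- matrix(1, 60, 60)
  for (s in 0:59) for (i in 1:(60 - s)) {
    zero[i, i + s] <- 2^(-s); zero[i + s, i] <- 2^(-s)
  }
  cm <- contact_map(list(a = zero), bins)
  oe <- oe_transform(cm)
  pairs <- data.frame(arm = "a", bin1 = 20, bin2 = 40, sep_bp = 1e5)
  apa <- apa_aggregate(oe, pairs, w = 5)
  expect_true(all(abs(apa$matrix) < 1e-9))
  expect_equal(apa$center, apa$matrix[6, 6])
  expect_equal(apa$n_pairs, 1L)
  # mean of k identical submatrices equals the submatrix
  pairs3 <- pairs[rep(1, 3), ]
  apa3 <- apa_aggregate(oe, pairs3, w = 5)
  expect_equal(apa3$matrix, apa$matrix, tolerance = 1e-12)
  # pairs whose window exceeds the arm are skipped and counted
  pr_edge <- data.frame(arm = "a", bin1 = 2, bin2 = 40, sep_bp = 1.9e5)
  apa_e <- apa_aggregate(oe, rbind(pairs, pr_edge), w = 5)
  expect_equal(apa_e$n_skipped, 1L)
  expect_error(apa_aggregate(oe, pr_edge, w = 5), "skipped")
})

test_that("per-pair center values agree with APA centers and summaries", {
  bins <- genomic_bins(c(a = 5e5), 5000)
  lo <- loop_list(data.frame(arm = "a", bin1 = c(30, 50), bin2 = c(50, 70)),
                  bins)
  sim <- simulate_contact_map(bins, loops = lo, enrichment = 3, depth = Inf)
  ex <- expected_by_distance(simulate_contact_map(bins, depth = Inf)$map)
  oe <- oe_transform(sim$map, ex)
  pairs <- data.frame(arm = "a", bin1 = lo$bin1, bin2 = lo$bin2)
  vals <- log2oe_values(oe, pairs)
  centers <- vapply(seq_len(nrow(pairs)), function(i)
    apa_aggregate(oe, pairs[i, , drop = FALSE], w = 2)$center, 0)
  expect_equal(vals$values, centers, tolerance = 1e-12)
  expect_equal(vals$mean, log2(3), tolerance = 1e-9)
})

test_that("stratification partitions anchors with the documented tie rule", {
  anch <- data.frame(arm = "a", bin = 1:10, score = 10:1)
  g <- stratify_anchors(anch, k = 5)
  expect_equal(as.vector(table(g$group)), rep(2L, 5))
  expect_true(all(diff(g$score) >= 0))
  # remainder goes to the highest groups
  anch2 <- data.frame(arm = "a", bin = 1:12, score = runif(12))
  g2 <- stratify_anchors(anch2, k = 5)
  expect_equal(as.vector(table(g2$group)), c(2L, 2L, 2L, 3L, 3L))
  # equal scores: ordering by position, reproducible
  anch3 <- data.frame(arm = "a", bin = sample(1:10), score = 1)
  g3 <- stratify_anchors(anch3, k = 5)
  expect_equal(g3$bin, 1:10)
  expect_error(stratify_anchors(anch[1:3, ], k = 5), "fewer")
})

test_that("anchor bootstrap is degenerate at full size and tightens with N", {
  bins <- genomic_bins(c(a = 1.25e6), 5000)  # 250 bins
  set.seed(17)
  b1 <- sort(sample(0:200, 30))
  lo <- loop_list(data.frame(arm = "a", bin1 = b1, bin2 = b1 + 30), bins)
  sim <- simulate_contact_map(bins, loops = lo, enrichment = 3, depth = 5e6,
                              seed = 3)
  oe <- oe_transform(sim$map)
  anch <- unique(data.frame(arm = "a", bin = c(lo$bin1, lo$bin2)))
  n_a <- nrow(anch)
  bs <- bootstrap_mean_log2oe(oe, anch, bins, N_list = c(5, 20, n_a),
                              iters = 200, seed = 4)
  # N = all anchors: every iteration equals the full-set mean
  expect_equal(length(unique(round(bs[[as.character(n_a)]]$means, 12))), 1L)
  # spread decreases with N
  expect_gt(sd(bs[["5"]]$means), sd(bs[["20"]]$means))
  expect_gt(sd(bs[["20"]]$means), sd(bs[[as.character(n_a)]]$means))
  # oversized N is skipped with a warning
  expect_warning(bootstrap_mean_log2oe(oe, anch, bins, N_list = n_a + 1,
                                       iters = 10, seed = 1), "skipped")
})

test_that("insulation score is flat on uniform maps and dips at block joins", {
  bins <- genomic_bins(c(a = 40 * 5000), 5000)
  uni <- contact_map(list(a = matrix(1, 40, 40)), bins)
  isp <- insulation_score(uni, 5)
  mid <- isp$arms$a$score[10:30]
  expect_true(all(abs(mid) < 1e-12))
  expect_true(all(is.na(isp$arms$a$score[1:5])))
  # two-block diagonal map: minimum at the boundary
  blk <- matrix(0.05, 40, 40)
  blk[1:20, 1:20] <- 1; blk[21:40, 21:40] <- 1
  cmb <- contact_map(list(a = blk), bins)
  isb <- insulation_score(cmb, 5)
  expect_lte(abs(which.min(isb$arms$a$score) - 21L), 1L)
  bd <- call_boundaries(isb)
  expect_equal(nrow(bd), 1L)
  expect_lte(abs(anchor_bins(bd, bins)$bin - 20L), 1L)
  # monotone profile -> no boundaries
  mono <- outer(1:40, 1:40, function(i, j) 1 / (1 + pmax(i, j)))
  mono <- (mono + t(mono)) / 2
  ism <- insulation_score(contact_map(list(a = mono), bins), 5)
  expect_true(all(diff(stats::na.omit(ism$arms$a$score)) < 0) ||
              all(diff(stats::na.omit(ism$arms$a$score)) > 0))
  expect_equal(nrow(call_boundaries(ism)), 0L)
})

test_that("loop classification counts categories against a brute force", {
  bins <- genomic_bins(c(a = 1e6), 5000)
  # toy: 10 loops, 1 border/border, 2 border/non-border
  # borders at 10, 20, 30: loop (10,20) is border/border, loops (30,45)
  # and (20,65) are border/non-border, the remaining 7 have no border
  lo <- loop_list(data.frame(arm = "a",
                             bin1 = c(10, 30, 20, 70, 90, 110, 130, 150, 170, 190),
                             bin2 = c(20, 45, 65, 85, 105, 125, 145, 165, 185, 199)),
                  bins)
  borders <- peak_set(data.frame(arm = "a", start = c(10, 20, 30) * 5000,
                                 end = c(11, 21, 31) * 5000, signal = 1))
  cl <- classify_loops(lo, borders, slop_bins = 0)
  expect_equal(cl$summary$percent, c(10, 20, 70))
  expect_equal(sum(cl$summary$percent), 100)
  expect_equal(sum(cl$summary$n), nrow(lo))
  # random fixtures vs brute force
  set.seed(23)
  for (rep in 1:100) {
    lo2 <- fix_loops(fix_bins(), sample(10:40, 1))
    bins2 <- attr(lo2, "bins")
    bb <- data.frame(arm = sample(bins2$arms, 8, TRUE), bin = sample(0:290, 8))
    bset <- peak_set(data.frame(arm = bb$arm, start = bb$bin * 5000,
                                end = (bb$bin + 1) * 5000))
    slop <- sample(0:2, 1)
    cl2 <- classify_loops(lo2, bset, slop_bins = slop)
    bf_cat <- vapply(seq_len(nrow(lo2)), function(i) {
      near <- function(b) any(bb$arm == lo2$arm[i] & abs(bb$bin - b) <= slop)
      sum(near(lo2$bin1[i]), near(lo2$bin2[i]))
    }, 0)
    expect_equal(as.vector(table(factor(2 - bf_cat, levels = 0:2))),
                 cl2$summary$n)
  }
})

test_that("anchor occupancy and border participation match brute force", {
  bins <- genomic_bins(c(a = 1e6), 5000)
  lo <- loop_list(data.frame(arm = "a", bin1 = c(10, 30, 50),
                             bin2 = c(25, 60, 90)), bins)
  cover_all <- peak_set(data.frame(arm = "a", start = 0, end = 1e6))
  occ <- anchor_occupancy(lo, list(cover_all))
  expect_equal(unname(occ$proportions["2"]), 1)
  left <- peak_set(data.frame(arm = "a", start = c(10, 30, 50) * 5000,
                              end = c(11, 31, 51) * 5000))
  occ1 <- anchor_occupancy(lo, list(left))
  expect_equal(unname(occ1$proportions["1"]), 1)
  expect_error(anchor_occupancy(lo, list()), "non-empty")
  # participation: all borders in loops -> 1; disjoint -> error-free 0
  bset <- peak_set(data.frame(arm = "a", start = c(10, 25) * 5000,
                              end = c(11, 26) * 5000))
  bp <- border_participation(bset, lo, slop_bins = 0)
  expect_equal(bp$fraction, 1)
  expect_equal(bp$fraction_both_anchors, 1)  # loop (10,25) joins two borders
  far <- peak_set(data.frame(arm = "a", start = c(150, 180) * 5000,
                             end = c(151, 181) * 5000))
  expect_equal(border_participation(far, lo, slop_bins = 0)$fraction, 0)
  # random fixtures vs membership counting
  set.seed(29)
  for (rep in 1:50) {
    lo2 <- fix_loops(fix_bins(), 20)
    bins2 <- attr(lo2, "bins")
    bb <- data.frame(arm = sample(bins2$arms, 6, TRUE), bin = sample(0:290, 6))
    bset2 <- peak_set(data.frame(arm = bb$arm, start = bb$bin * 5000,
                                 end = (bb$bin + 1) * 5000))
    bp2 <- border_participation(bset2, lo2, slop_bins = 1)
    bf <- mean(vapply(seq_len(nrow(bb)), function(i) {
      sel <- lo2$arm == bb$arm[i]
      any(abs(lo2$bin1[sel] - bb$bin[i]) <= 1 | abs(lo2$bin2[sel] - bb$bin[i]) <= 1)
    }, logical(1)))
    expect_equal(bp2$fraction, bf)
  }
})
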