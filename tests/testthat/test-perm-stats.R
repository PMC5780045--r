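# Permutation machinery: pointwise maps, cluster correction, regression,
# repeated-measures ANOVA.

test_that("sign-flip test handles degenerate and symmetric inputs", {
  zero_maps <- lapply(1:10, function(i) matrix(0, 4, 6))
  sm <- signflip_test(zero_maps, n_perm = 100, seed = 1)
  expect_true(all(sm$z == 0))
  expect_false(any(sm$p < 0.05))
  # constant positive maps: observed is the ensemble maximum
  cmaps <- lapply(1:10, function(i) matrix(2, 4, 6))
  smc <- signflip_test(cmaps, n_perm = 200, seed = 2)
  expect_true(all(smc$observed >= apply(rbind(smc$surr_mean), 2, max)))
  expect_lt(max(smc$p), 0.005)
  expect_error(signflip_test(list(matrix(0, 2, 2))), ">= 2")
  expect_warning(signflip_test(zero_maps, n_perm = 10, seed = 1), "n_perm")
})

test_that("pointwise p is calibrated on iid normal units", {
  set.seed(10)
  maps <- lapply(1:20, function(i) rnorm(10000))
  sm <- signflip_test(maps, n_perm = 400, seed = 3)
  expect_lt(abs(mean(sm$p < 0.05) - 0.05), 0.02)
})

test_that("global sign flip leaves |z| invariant; constant shift leaves the
           label contrast unchanged", {
  set.seed(4)
  maps <- lapply(1:8, function(i) matrix(rnorm(30, 0.2), 5, 6))
  s1 <- signflip_test(maps, n_perm = 300, seed = 9)
  s2 <- signflip_test(lapply(maps, function(m) -m), n_perm = 300, seed = 9)
  expect_equal(abs(s1$z), abs(s2$z), tolerance = 1e-10)
  a <- lapply(1:8, function(i) rnorm(20))
  b <- lapply(1:8, function(i) rnorm(20))
  l1 <- label_permutation_test(a, b, n_perm = 300, seed = 5)
  l2 <- label_permutation_test(lapply(a, `+`, 11), lapply(b, `+`, 11),
                               n_perm = 300, seed = 5)
  expect_equal(l1$z, l2$z, tolerance = 1e-10)
  # a == b gives z ~ 0
  l0 <- label_permutation_test(a, a, n_perm = 200, seed = 6)
  expect_true(all(l0$z == 0))
})

test_that("cluster correction recovers a coherent block and ignores specks", {
  set.seed(11)
  inject <- matrix(0, 15, 40)
  inject[4:8, 10:25] <- 1.2
  hits <- 0; covered <- 0
  for (r in 1:10) {
    maps <- lapply(1:20, function(i) matrix(rnorm(600), 15, 40) + inject)
    sm <- signflip_test(maps, n_perm = 200, seed = 100 + r)
    cl <- cluster_correct(sm)
    sig_pos <- cl$clusters$id[cl$clusters$significant & cl$clusters$sign > 0]
    if (length(sig_pos)) {
      hits <- hits + 1
      cov <- sum(cl$mask[4:8, 10:25] %in% sig_pos) / (5 * 16)
      covered <- covered + (cov >= 0.5)
    }
  }
  expect_gte(hits, 9)
  expect_gte(covered, 9)
  # an isolated strong point is usually not significant
  speck <- matrix(0, 15, 40); speck[8, 20] <- 1.2
  sig <- vapply(1:10, function(r) {
    maps <- lapply(1:20, function(i) matrix(rnorm(600), 15, 40) + speck)
    cl <- cluster_correct(signflip_test(maps, n_perm = 200, seed = 200 + r))
    any(cl$clusters$significant)
  }, logical(1))
  expect_lte(sum(sig), 2)
})

test_that("no significant cluster falls below the 95th percentile of maxima", {
  set.seed(12)
  for (r in 1:5) {
    maps <- lapply(1:15, function(i) matrix(rnorm(300, 0.15), 10, 30))
    cl <- cluster_correct(signflip_test(maps, n_perm = 200, seed = 300 + r))
    if (any(cl$clusters$significant)) {
      thr <- stats::quantile(cl$max_stats, 0.95)
      expect_true(all(abs(cl$clusters$stat[cl$clusters$significant]) >= thr))
    }
    # empty map case: no suprathreshold points is a valid empty result
  }
  flat <- lapply(1:10, function(i) rep(0, 50))
  clf <- cluster_correct(signflip_test(flat, n_perm = 100, seed = 1))
  expect_equal(nrow(clf$clusters), 0)
  expect_false(any(clf$sig_mask))
})

test_that("family-wise error of the 2D cluster test is near nominal", {
  set.seed(13)
  any_sig <- vapply(1:40, function(r) {
    maps <- lapply(1:15, function(i) matrix(rnorm(450), 15, 30))
    any(cluster_correct(signflip_test(maps, n_perm = 200, seed = 400 + r))$clusters$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.1)
})

test_that("band cluster test recovers a 1D effect and returns empty on flat data", {
  set.seed(14)
  tser <- lapply(1:16, function(i) { x <- rnorm(80); x[30:50] <- x[30:50] + 1; x })
  bt <- band_cluster_test(tser, "vs-baseline", n_perm = 200, seed = 7)
  sig <- bt$clusters$clusters
  expect_true(any(sig$significant & sig$sign > 0))
  flat <- lapply(1:16, function(i) rep(0, 80))
  bt0 <- band_cluster_test(flat, "vs-baseline", n_perm = 100, seed = 8)
  expect_equal(nrow(bt0$clusters$clusters), 0)
})

test_that("per-electrode trial-level tests separate effect and null contacts", {
  set.seed(15)
  mk_contact <- function(effect) {
    lapply(1:60, function(i) {
      m <- matrix(rnorm(8 * 30), 8, 30)
      if (effect) m[3:6, 10:20] <- m[3:6, 10:20] - 0.6
      m
    })
  }
  labels <- rep(c("target", "distractor"), 30)
  contacts <- c(lapply(1:10, function(i) mk_contact(TRUE)),
                lapply(1:10, function(i) mk_contact(FALSE)))
  names(contacts) <- paste0("c", 1:20)
  res <- per_electrode_tests(contacts, labels, n_perm = 200, seed = 16)
  expect_equal(nrow(res), 20)
  expect_gte(sum(res$sig_baseline[1:10]), 8)   # sensitivity >= 80%
  expect_lte(sum(res$sig_baseline[11:20]), 2)  # false positives <= ~10% + slack
  # single contact and too-few-trials paths
  one <- per_electrode_tests(contacts[1], labels, n_perm = 100, seed = 1)
  expect_equal(nrow(one), 1)
  tiny <- per_electrode_tests(list(x = contacts[[1]][1:5]), labels[1:5],
                              n_perm = 100, seed = 1)
  expect_false(tiny$testable)
})

test_that("trial-number regression behaves on exact, null, and noisy inputs", {
  # perfectly linear decline, no noise: rho = -1 each session
  pw <- lapply(1:5, function(i) rep(8:1, 10) + 0)
  pos <- lapply(1:5, function(i) rep(1:8, 10))
  r <- regress_band_vs_trialnum(pw, pos)
  expect_equal(r$rho, rep(-1, 5), tolerance = 1e-12)
  expect_equal(r$p, 0)
  # null: mean rho ~ 0
  set.seed(17)
  pw0 <- lapply(1:12, function(i) rnorm(80))
  r0 <- regress_band_vs_trialnum(pw0, rep(pos[1], 12))
  expect_lt(abs(mean(r0$rho)), 0.1)
  # constant session excluded with a warning
  pwc <- c(pw0[1:3], list(rep(2, 80)))
  expect_warning(rc <- regress_band_vs_trialnum(pwc, rep(pos[1], 4)),
                 "excluded")
  expect_equal(rc$excluded, 4L)
  expect_error(regress_band_vs_trialnum(list(1:4, 1:4),
                                        list(rep(1, 4), rep(1, 4))),
               "positions")
})

test_that("injected block slope is recovered through the full spectral path", {
  bank <- build_wavelet_bank(15, 4, 5)
  pw <- list(); pos <- list()
  for (i in 1:12) {
    s <- quick_session(12, ground_truth(), seed = 20 + i)
    np <- session_normpower(s$recording, s$events, bank, 1, time_step = 20,
                            per_trial = FALSE)
    ba <- band_average(np, c(15, 30))
    pw[[i]] <- rowMeans(ba$values[, ba$times >= 0 & ba$times <= 1000])
    pos[[i]] <- s$events$trial_in_block[np$trial_index]
  }
  reg <- regress_band_vs_trialnum(pw, pos)
  expect_lt(mean(reg$rho), -0.05)
  expect_lt(reg$p, 0.01)
})

test_that("repeated-measures ANOVA: calibration, recovery, degenerate input", {
  set.seed(18)
  pvals <- vapply(1:200, function(r)
    rm_anova_trialnum(matrix(rnorm(80), 10, 8))$p, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  # strong decline: df1 = positions - 1, tiny p
  decl <- matrix(rep(seq(4, -4, length.out = 8), each = 10), 10, 8) +
    matrix(rnorm(80, sd = 0.5), 10, 8)
  a <- rm_anova_trialnum(decl)
  expect_equal(a$df1, 7)
  expect_lt(a$p, 0.001)
  # identical values everywhere: degenerate, flagged
  expect_warning(deg <- rm_anova_trialnum(matrix(1, 6, 8)), "degenerate")
  expect_true(is.na(deg$F))
  expect_error(rm_anova_trialnum(matrix(c(1, NA), 2, 2)), "missing")
  expect_error(rm_anova_trialnum(matrix(1:4, 4, 1)), ">= 2")
})

test_that("two-way repeated-measures ANOVA returns all three terms", {
  set.seed(19)
  x <- array(rnorm(10 * 4 * 2), c(10, 4, 2),
             dimnames = list(NULL, NULL, c("target", "distractor")))
  x[, , 2] <- x[, , 2] + 1                    # condition main effect
  x <- x + rep(rep(seq(1, -1, length.out = 4), each = 10), 2) # position effect
  a2 <- rm_anova_trialnum(x)
  expect_setequal(a2$term, c("pos", "cond", "pos:cond"))
  expect_equal(a2$df1[a2$term == "pos"], 3)
  expect_equal(a2$df1[a2$term == "cond"], 1)
  expect_lt(a2$p[a2$term == "cond"], 0.01)
  expect_lt(a2$p[a2$term == "pos"], 0.01)
  expect_gt(a2$p[a2$term == "pos:cond"], 0.05)
})
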