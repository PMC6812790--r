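test_that("event matching handles the canonical small cases", {
  m <- match_events(event_list(1.0), event_list(1.0))
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  # 1.0-1.4 matches within 500 ms; 2.6 is 600 ms from 2.0
  m2 <- match_events(event_list(c(1.0, 2.0)), event_list(c(1.4, 2.6)))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 1L))
  # chain case: one estimate cannot match two references
  m3 <- match_events(event_list(c(0.0, 0.4)), event_list(0.3))
  expect_equal(c(m3$tp, m3$fn), c(1L, 1L))
  expect_equal(nrow(m3$pairs), 1)
  expect_error(match_events(event_list(1), event_list(1), tolerance = -1),
               "nonnegative")
  m4 <- match_events(event_list(), event_list(c(1, 2)))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0L, 2L, 0L))
})

test_that("matching cardinality equals exhaustive enumeration", {
  set.seed(17)
  for (i in 1:100) {
    nr <- sample(0:6, 1); ne <- sample(0:6, 1)
    ref <- sort(runif(nr, 0, 5)); est <- sort(runif(ne, 0, 5))
    ref <- ref[!duplicated(ref)]; est <- est[!duplicated(est)]
    m <- match_events(event_list(ref), event_list(est))
    expect_equal(m$tp, oracle_max_matching(ref, est))
    # symmetry: swapping the lists swaps FP and FN
    ms <- match_events(event_list(est), event_list(ref))
    expect_equal(ms$tp, m$tp)
    expect_equal(c(ms$fp, ms$fn), c(m$fn, m$fp))
  }
})

test_that("matched pairs are unique and within tolerance", {
  set.seed(18)
  ref <- sort(runif(15, 0, 10))
  est <- sort(runif(20, 0, 10))
  m <- match_events(event_list(ref), event_list(est), 0.5)
  expect_equal(anyDuplicated(m$pairs[, "ref"]), 0)
  expect_equal(anyDuplicated(m$pairs[, "est"]), 0)
  expect_true(all(abs(ref[m$pairs[, "ref"]] - est[m$pairs[, "est"]]) <= 0.5))
  expect_equal(m$tp, nrow(m$pairs))
  expect_equal(m$fp, 20 - m$tp)
  expect_equal(m$fn, 15 - m$tp)
})

test_that("an ideal EDF yields AUPRC 1 and a useless one yields 0", {
  ref <- event_list(c(1.075, 2.075, 3.075))
  vals <- rep(0.001, 100)
  idx <- round((ref$time_s - 0.075) / 0.05) + 1
  vals[idx] <- 0.999
  pr <- pr_curve(make_edf(vals), ref)
  expect_equal(pr$auprc, 1)
  # peaks far from every reference: precision 0 everywhere
  vals2 <- rep(0.001, 200)
  vals2[c(140, 160, 180)] <- 0.999
  pr2 <- pr_curve(make_edf(vals2), ref)
  expect_equal(pr2$auprc, 0)
  expect_true(all(pr2$curve$precision == 0 | pr2$curve$tp + pr2$curve$fp == 0))
  expect_error(pr_curve(make_edf(vals), event_list()), "undefined recall")
})

test_that("the PR curve matches an independent recomputation", {
  set.seed(19)
  ref <- event_list(sort(sample(seq(0.5, 19.5, by = 0.35), 20)))
  vals <- stats::plogis(rnorm(400, sd = 2))
  edf <- make_edf(vals)
  taus <- seq(0.1, 0.9, by = 0.1)
  pr <- pr_curve(edf, ref, thresholds = taus)
  # oracle: recompute TP/FP/FN per threshold with the greedy sweep
  # matcher (maximum for 1-D tolerance graphs) and integrate the sorted
  # curve by hand
  recompute <- lapply(taus, function(tau) {
    est <- pick_peaks(edf, tau)
    tp <- oracle_greedy_matching(ref$time_s, est$time_s)
    c(p = if (nrow(est) == 0) 1 else tp / nrow(est), r = tp / nrow(ref))
  })
  tab <- do.call(rbind, recompute)
  expect_equal(pr$curve$precision, unname(tab[, "p"]))
  expect_equal(pr$curve$recall, unname(tab[, "r"]))
  o <- order(tab[, "r"], tab[, "p"])
  r <- c(0, tab[o, "r"]); p <- c(tab[o, "p"][1], tab[o, "p"])
  auprc_oracle <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  expect_equal(pr$auprc, auprc_oracle)
  # duplicated thresholds leave the integral unchanged
  pr_dup <- pr_curve(edf, ref, thresholds = rep(taus, 2))
  expect_equal(pr_dup$auprc, pr$auprc)
  # detection counts shrink monotonically with the threshold
  expect_true(all(diff(pr$curve$tp + pr$curve$fp) <= 0))
  expect_true(all(diff(pr$curve$tp + pr$curve$fn) <= 0))
})

test_that("segmented recall splits by time and band under a global matching", {
  ref <- event_list(c(10, 50, 100, 130), band_label = c("low", "high",
                                                        "low", "high"))
  est_all <- event_list(c(10, 50, 100, 130) + 0.1)
  sr <- segmented_recall(ref, est_all, segment = 60)
  expect_true(all(sr$recall[sr$n_ref > 0] == 1))
  # drop the high-band events from the estimates
  est_low <- event_list(c(10, 100) + 0.1)
  sr2 <- segmented_recall(ref, est_low, segment = 60)
  expect_true(all(sr2$recall[sr2$band == "low" & sr2$n_ref > 0] == 1))
  expect_true(all(sr2$recall[sr2$band == "high" & sr2$n_ref > 0] == 0))
  expect_error(segmented_recall(event_list(1), event_list(1)), "band label")
})

test_that("PR export writes CSV and a JSON summary", {
  ref <- event_list(c(1.075, 2.075))
  vals <- rep(0.001, 100); vals[c(21, 41)] <- 0.9
  pr <- pr_curve(make_edf(vals), ref)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_pr_curve(pr, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(pr$curve))
  j <- jsonlite::read_json(js)
  expect_equal(j$auprc, pr$auprc)
  expect_true(j$best_f1 >= 0 && j$best_f1 <= 1)
  unlink(c(csv, js))
})
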