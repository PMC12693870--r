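test_that("matching handles identical lists and nearest-assignment ties", {
  truth <- make_truth(c(1, 2, 3))
  det <- make_det(c(1, 2, 3))
  m <- match_events(det, truth, match_config(tol_s = 1e-3))
  expect_identical(nrow(m$pairs), 3L)
  expect_length(m$unmatched_det, 0)
  expect_length(m$unmatched_truth, 0)

  # two detections near one truth event: the nearer wins, the other is a FP
  truth1 <- make_truth(1.000)
  det2 <- make_det(c(1.0002, 1.0008))
  m2 <- match_events(det2, truth1, match_config(tol_s = 1e-3))
  expect_identical(nrow(m2$pairs), 1L)
  expect_identical(m2$pairs$det_idx, 1L)
  expect_identical(m2$unmatched_det, 2L)
})

test_that("greedy matching tracks the optimal assignment on random instances", {
  skip_if_not_installed("igraph")
  set.seed(19)
  n_equal <- 0L
  n_inst <- 300L
  for (r in seq_len(n_inst)) {
    # domain-like instances: Poisson-spaced truth, jittered detections with
    # drops and stray false positives, tolerance well below mean spacing
    nt <- sample(5:50, 1)
    tol <- 0.02
    truth_t <- sort(runif(nt, 0, nt / 5))
    det_t <- truth_t + rnorm(nt, 0, tol / 3)
    det_t <- det_t[runif(nt) < 0.9]
    det_t <- sort(c(det_t, runif(rbinom(1, 8, 0.5), 0, nt / 5)))
    if (!length(det_t)) next
    nd <- length(det_t)
    truth <- make_truth(truth_t)
    det <- make_det(det_t)
    m <- match_events(det, truth, match_config(tol_s = tol))
    # maximum-cardinality bipartite matching as the independent oracle
    dd <- abs(outer(event_centers(det), truth$t0_s, "-"))
    pairs <- which(dd <= tol, arr.ind = TRUE)
    opt <- if (nrow(pairs)) {
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, nd), rep(TRUE, nt)),
        edges = as.vector(t(cbind(pairs[, 1], nd + pairs[, 2]))))
      igraph::max_bipartite_match(g)$matching_size
    } else 0L
    expect_lte(opt - nrow(m$pairs), 1L)
    if (opt == nrow(m$pairs)) n_equal <- n_equal + 1L
  }
  expect_gte(n_equal / n_inst, 0.95)
})

test_that("metric arithmetic and the FDR identity hold", {
  truth <- make_truth(seq(0.1, 1.0, by = 0.1))      # 10 truths
  det <- make_det(c(seq(0.1, 0.9, by = 0.1), 5))    # 9 hits + 1 stray
  m <- compute_metrics(match_events(det, truth, match_config(tol_s = 1e-3)))
  expect_identical(c(m$tp, m$fp, m$fn), c(9L, 1L, 1L))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(m$fdr, 0.1)
  expect_identical(m$fdr, 1 - m$precision)

  # matched exactly in time and amplitude: both error percentages ~ 0
  expect_lt(m$peak_pos_err_pct, 1e-9)
  expect_lt(m$p2p_err_pct, 1e-9)
})

test_that("empty denominators are flagged, never silently zero", {
  truth <- make_truth(c(1, 2))
  m <- compute_metrics(match_events(make_det(numeric(0)), truth,
                                    match_config(tol_s = 1e-3)))
  expect_identical(m$recall, 0)
  expect_true(is.nan(m$precision))
  expect_true("precision" %in% attr(m, "undefined"))
  m0 <- compute_metrics(match_events(make_det(numeric(0)), truth[0, ],
                                     match_config(tol_s = 1e-3)))
  expect_true(is.nan(m0$precision) && is.nan(m0$recall))
})

test_that("metrics are invariant to input row order", {
  set.seed(4)
  truth <- make_truth(sort(runif(30)))
  det <- make_det(sort(runif(25)))
  m1 <- compute_metrics(match_events(det, truth, match_config(tol_s = 0.02)))
  perm_d <- det[sample.int(nrow(det)), ]
  perm_t <- truth[sample.int(nrow(truth)), ]
  m2 <- compute_metrics(match_events(perm_d, perm_t,
                                     match_config(tol_s = 0.02)))
  expect_identical(m1[c("tp", "fp", "fn")], m2[c("tp", "fp", "fn")])
  expect_equal(m1$peak_pos_err_pct, m2$peak_pos_err_pct)
})

test_that("the benchmark grid is the four paired flow/bandwidth conditions", {
  g <- benchmark_conditions()
  expect_identical(g$Q_uL_min, c(0.3, 1, 2, 3))
  expect_identical(g$BW_Hz, c(100, 300, 500, 1000))
})

test_that("benchmark sweep pairs methods on identical streams", {
  conds <- data.frame(Q_uL_min = 2, BW_Hz = 500)
  tab <- benchmark_sweep(conds, n_seeds = 2,
                         base_config = quick_config(duration_s = 2),
                         master_seed = 3)
  expect_identical(nrow(tab), 4L)
  # paired design: both methods saw the same stream seeds
  expect_identical(sort(unique(tab$seed[tab$method == "derivative"])),
                   sort(unique(tab$seed[tab$method == "baseline"])))
  expect_true(all(tab$fdr == 1 - tab$precision, na.rm = TRUE))
})
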