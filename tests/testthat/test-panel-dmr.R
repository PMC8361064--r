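test_that("region methylation percentage handles zeros and missingness", {
  expect_equal(region_methylation(30, 70), 30)
  expect_equal(region_methylation(0, 50), 0)
  expect_equal(region_methylation(50, 0), 100)
  expect_true(is.na(region_methylation(0, 0)))
  expect_error(region_methylation(-1, 5), "non-negative")
})

test_that("Wilcoxon p is exact for small untied samples", {
  # complete separation, 10 vs 8: two-sided p = 2 / C(18, 8)
  x <- 11:20
  y <- 1:8
  expect_equal(wilcoxon_rank_sum(x, y), 2 / choose(18, 8))
  expect_equal(wilcoxon_rank_sum(x, y), 4.57e-5, tolerance = 1e-2)
  # symmetric in its arguments
  expect_equal(wilcoxon_rank_sum(y, x), wilcoxon_rank_sum(x, y))
  # identical groups: degenerate, p = 1
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_error(wilcoxon_rank_sum(1, c(2, 3)), ">= 2")
})

test_that("exact Wilcoxon agrees with full enumeration for combined n <= 12", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- round(rnorm(n1, 0, 10), 4)
    y <- round(rnorm(n2, sample(c(0, 8), 1), 10), 4)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_rank_sum(x, y), enumerate_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon type-I error is calibrated under an exchangeable null", {
  set.seed(32)
  reps <- 2000
  hits <- 0
  for (i in seq_len(reps)) {
    x <- rnorm(9)
    y <- rnorm(8)
    if (wilcoxon_rank_sum(x, y) < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("BH adjustment matches a hand step-up computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(33)
  for (i in 1:5) {
    p <- runif(25)^2
    q <- bh_adjust(p)
    expect_equal(q, bh_by_hand(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))  # monotone in sorted p order
  }
})

make_pct_matrix <- function(a_rows, b_rows, n_regions, f) {
  m <- t(sapply(seq_len(a_rows + b_rows), function(i) f(i <= a_rows)))
  rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("R%03d", seq_len(n_regions))
  m
}

test_that("group label swap negates log2FC and swaps the calls", {
  set.seed(34)
  pct <- make_pct_matrix(6, 5, 30, function(is_a) {
    runif(30, 20, 40) + if (is_a) c(rep(35, 10), rep(-15, 5), rep(0, 15)) else 0
  })
  g <- rep(c("on", "off"), c(6, 5))
  d1 <- call_dmrs(pct, factor(g, levels = c("on", "off")))
  d2 <- call_dmrs(pct, factor(g, levels = c("off", "on")))
  expect_equal(d2$log2fc, -d1$log2fc)
  expect_equal(d2$p, d1$p)
  expect_equal(d2$q, d1$q)
  swapped <- c(hyper = "hypo", hypo = "hyper", none = "none")
  expect_identical(d2$call, unname(swapped[d1$call]))
})

test_that("a log2FC of exactly 1 is not called (strict inequality)", {
  # perfectly separated ranks, group means exactly 61 and 30:
  # log2((61+1)/(30+1)) = 1
  a <- c(60.5, 60.9, 61.1, 61.5)
  b <- c(29.5, 29.9, 30.1, 30.5)
  pct <- matrix(c(a, b), ncol = 1,
                dimnames = list(sprintf("S%d", 1:8), "R1"))
  d <- call_dmrs(pct, factor(rep(c("A", "B"), each = 4),
                             levels = c("A", "B")))
  expect_equal(d$log2fc, 1)
  expect_lt(d$q, 0.05)
  expect_identical(d$call, "none")
})

test_that("null panels produce no DMR calls at FDR 0.05", {
  set.seed(35)
  pct <- make_pct_matrix(11, 8, 100, function(is_a) runif(100, 20, 60))
  d <- call_dmrs(pct, factor(rep(c("on", "off"), c(11, 8)),
                             levels = c("on", "off")))
  expect_lte(sum(d$call != "none"), 2)
})

test_that("poorly covered regions are excluded with a reason", {
  pct <- make_pct_matrix(4, 4, 3, function(is_a) c(50, 50, 50) +
                           rnorm(3, 0, 4))
  pct[1:3, 2] <- NA       # 3/4 of group A missing
  pct[, 3] <- NA          # all missing
  d <- call_dmrs(pct, factor(rep(c("A", "B"), each = 4)))
  expect_true(d$tested[1])
  expect_false(d$tested[2])
  expect_match(d$reason[2], "coverage")
  expect_false(d$tested[3])
  expect_match(d$reason[3], "missing")
  # q computed across tested regions only
  expect_true(is.na(d$q[2]) && is.na(d$q[3]))
})

test_that("the long-to-matrix reshape preserves values and missingness", {
  counts <- data.frame(sample_id = rep(c("S1", "S2"), each = 2),
                       region_id = rep(c("R1", "R2"), 2),
                       meth_c = c(30, 0, 10, 5),
                       unmeth_c = c(70, 0, 90, 15))
  m <- region_methylation_matrix(counts)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["S1", "R1"], 30)
  expect_true(is.na(m["S1", "R2"]))  # zero observations -> missing
  expect_equal(m["S2", "R2"], 25)
})

test_that("shifted panel regions are recovered with correct direction", {
  cfg <- sim_config(seed = 44, n_regions = 60, n_hyper = 20,
                    n_hypo_regions = 10)
  design <- simulate_panel_design(cfg)
  groups <- rep(c("on_target", "off_target"), c(11, 8))
  counts <- do.call(rbind, lapply(seq_along(groups), function(i) {
    simulate_panel(cfg, design, group = groups[i], index = i,
                   sample_id = sprintf("S%02d", i))
  }))
  pct <- region_methylation_matrix(counts)
  d <- call_dmrs(pct, factor(groups, levels = c("on_target", "off_target")))
  cls <- design$class[match(d$region_id, design$region_id)]
  expect_gte(mean(d$call[cls == "hyper"] == "hyper"), 0.95)
  expect_gte(mean(d$call[cls == "hypo"] == "hypo"), 0.95)
  expect_lte(mean(d$call[cls == "null"] != "none"), 0.05)
})
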