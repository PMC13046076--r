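usage_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("proportions divide by the group total and clip to [0.001, 0.999]", {
  u <- usage_tbl(
    transcript_id = c("t1", "t2", "solo"),
    gene_id = c("g1", "g1", "g2"),
    promoter_group = c(1L, 1L, 1L),
    young_1 = c(6, 4, 5), young_2 = c(3, 7, 2), young_3 = c(5, 5, 1),
    aged_1 = c(2, 8, 4), aged_2 = c(1, 9, 3), aged_3 = c(4, 6, 2))
  p <- compute_proportions(u)
  expect_equal(p$proportion[p$transcript_id == "t1" & p$sample == "young_1"],
               0.6)
  expect_equal(p$proportion[p$transcript_id == "t2" & p$sample == "young_1"],
               0.4)
  # a sole transcript always has raw proportion 1, stored clipped
  expect_equal(unique(p$proportion[p$transcript_id == "solo"]), 0.999)
  # pre-clipping proportions sum to 1 per group and sample
  sums <- p |>
    dplyr::summarise(s = sum(proportion_raw),
                     .by = c(gene_id, promoter_group, sample))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("groups with no expression in one condition are dropped", {
  u <- usage_tbl(
    transcript_id = c("a1", "a2", "b1", "b2"),
    gene_id = c("g1", "g1", "g2", "g2"),
    promoter_group = c(1L, 1L, 1L, 1L),
    young_1 = c(5, 5, 4, 6), young_2 = c(5, 5, 3, 7), young_3 = c(5, 5, 2, 8),
    aged_1 = c(0, 0, 5, 5), aged_2 = c(0, 0, 6, 4), aged_3 = c(0, 0, 7, 3))
  p <- compute_proportions(u)
  expect_false("g1" %in% p$gene_id)
  expect_true("g2" %in% p$gene_id)
})

test_that("a zero group total in a retained sample falls back to 1/k", {
  u <- usage_tbl(
    transcript_id = c("t1", "t2"),
    gene_id = "g1", promoter_group = 1L,
    young_1 = c(5, 5), young_2 = c(0, 0), young_3 = c(6, 4),
    aged_1 = c(2, 8), aged_2 = c(3, 7), aged_3 = c(1, 9))
  expect_warning(p <- compute_proportions(u), "zero total")
  expect_equal(p$proportion[p$sample == "young_2"], c(0.5, 0.5))
})

test_that("the HPD interval matches an exhaustive shortest-interval search", {
  set.seed(99)
  for (r in 1:5) {
    draws <- switch(r %% 3 + 1, rnorm(1000), rexp(1000), rbeta(1000, 2, 5))
    got <- hpd_interval(draws, 0.95)
    x <- sort(draws)
    n <- length(x)
    k <- ceiling(0.95 * n)
    best <- c(-Inf, Inf)
    for (i in 1:(n - k + 1)) {
      if (x[i + k - 1] - x[i] < best[2] - best[1]) {
        best <- c(x[i], x[i + k - 1])
      }
    }
    expect_equal(got, best)
    expect_gte(mean(draws >= got[1] & draws <= got[2]), 0.95)
  }
})

test_that("the decision rule requires both the HPD and probability criteria", {
  s <- tibble::tibble(
    transcript_id = c("a", "b", "c"),
    log2fc = c(0.2, 0.7, 0.5),
    hpd_lower = c(-0.2, 0.3, 0.05), hpd_upper = c(0.5, 1.2, 0.9),
    prob_up = c(0.8, 0.99, 0.93), prob_down = c(0.2, 0.01, 0.07),
    converged = TRUE)
  out <- call_differential(s)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("none", "up", "none"))
})

test_that("identical conditions give a symmetric posterior", {
  prop <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", promoter_group = 1L,
    sample = c(paste0("young_", 1:3), paste0("aged_", 1:3)),
    condition = rep(c("young", "aged"), each = 3),
    replicate = rep(as.character(1:3), 2),
    proportion_raw = rep(c(0.3, 0.5, 0.4), 2),
    proportion = rep(c(0.3, 0.5, 0.4), 2))
  fit <- fit_beta_model(prop, seed = 21)
  s <- tidy(fit)
  expect_lt(abs(s$prob_up - 0.5), 0.1)
  expect_true(s$hpd_lower < 0 && s$hpd_upper > 0)
  expect_false(s$significant)
})

test_that("a large usage shift is recovered with the right direction", {
  prop <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", promoter_group = 1L,
    sample = c(paste0("young_", 1:3), paste0("aged_", 1:3)),
    condition = rep(c("young", "aged"), each = 3),
    replicate = rep(as.character(1:3), 2),
    proportion_raw = c(0.1, 0.12, 0.08, 0.9, 0.88, 0.92),
    proportion = c(0.1, 0.12, 0.08, 0.9, 0.88, 0.92))
  fit <- fit_beta_model(prop, seed = 22)
  s <- tidy(fit)
  expect_true(s$significant)
  expect_equal(s$direction, "up")
  expect_gt(s$prob_up, 0.95)
  # swapping the condition labels flips the call
  fit2 <- fit_beta_model(prop, reference = "aged", treatment = "young",
                         seed = 22)
  s2 <- tidy(fit2)
  expect_equal(s2$direction, "down")
  expect_lt(abs(s2$log2fc + s$log2fc), 0.2)
  expect_lt(abs(s2$prob_down - s$prob_up), 0.05)
})

test_that("fits are reproducible under a fixed seed", {
  prop <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", promoter_group = 1L,
    sample = c(paste0("young_", 1:3), paste0("aged_", 1:3)),
    condition = rep(c("young", "aged"), each = 3),
    replicate = rep(as.character(1:3), 2),
    proportion_raw = c(0.2, 0.3, 0.25, 0.6, 0.7, 0.65),
    proportion = c(0.2, 0.3, 0.25, 0.6, 0.7, 0.65))
  f1 <- fit_beta_model(prop, seed = 5)
  f2 <- fit_beta_model(prop, seed = 5)
  expect_identical(tidy(f1), tidy(f2))
})
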