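fake_ps <- function(ids, ps, sig, dir) {
  tibble::tibble(transcript_id = ids, gene_id = "g1", promoter_group = 1L,
                 ps = ps, significant = sig, direction = dir)
}

fake_events <- function(...) {
  rows <- list(...)
  tibble::tibble(
    event_id = sprintf("ev%d", seq_along(rows)),
    event_class = vapply(rows, `[[`, "", "class"),
    gene_id = "g1",
    including_ids = lapply(rows, `[[`, "incl"),
    excluding_ids = lapply(rows, `[[`, "excl"))
}

test_that("PS is the posterior median log2fc with empirical ratio alongside", {
  s <- tibble::tibble(
    transcript_id = c("t1", "t2"), gene_id = "g1", promoter_group = 1L,
    log2fc = c(2.01, -1.2), significant = c(TRUE, TRUE),
    direction = c("up", "down"))
  prop <- tibble::tibble(
    transcript_id = rep(c("t1", "t2"), each = 6),
    condition = rep(rep(c("young", "aged"), each = 3), 2),
    proportion = c(rep(0.2, 3), rep(0.8, 3), rep(0.8, 3), rep(0.2, 3)))
  ps <- assign_ps(s, prop)
  expect_equal(ps$ps, c(2.01, -1.2))
  expect_equal(ps$ps_empirical, c(2, -2))  # log2(0.8/0.2)
})

test_that("events inherit PS from every member transcript with its role", {
  ev <- fake_events(list(class = "CE", incl = "t1", excl = "t2"),
                    list(class = "IR", incl = "t1", excl = "t2"),
                    list(class = "ALT5", incl = "t2", excl = "t1"))
  ps <- fake_ps(c("t1", "t2"), c(1.5, -0.7), c(TRUE, TRUE), c("up", "down"))
  rec <- propagate_to_events(ev, ps)
  # one record per (event, member) pair
  expect_equal(nrow(rec), 6)
  r1 <- rec[rec$event_id == "ev1", ]
  expect_equal(r1$role[r1$transcript_id == "t1"], "inclusion")
  expect_equal(r1$role[r1$transcript_id == "t2"], "exclusion")
  expect_equal(r1$ps[r1$transcript_id == "t1"], 1.5)
  # a transcript embedded in several events shares its ps across them
  expect_equal(unique(rec$ps[rec$transcript_id == "t1"]), 1.5)
})

test_that("propagation fails loudly when a transcript has no PS value", {
  ev <- fake_events(list(class = "CE", incl = "t1", excl = "tX"))
  ps <- fake_ps("t1", 1, TRUE, "up")
  expect_error(propagate_to_events(ev, ps), "absent from PS")
})

test_that("direction summaries count significant records and test imbalance", {
  ev <- fake_events(
    list(class = "CE", incl = "a", excl = "e"),
    list(class = "CE", incl = "b", excl = "e"),
    list(class = "CE", incl = "c", excl = "e"),
    list(class = "CE", incl = "d", excl = "e"))
  ps <- fake_ps(c("a", "b", "c", "d", "e"),
                c(1, 1, 1, -1, 0),
                c(TRUE, TRUE, TRUE, TRUE, FALSE),
                c("up", "up", "up", "down", "none"))
  s <- summarize_direction(propagate_to_events(ev, ps))
  incl <- s[s$role == "inclusion", ]
  expect_equal(incl$up, 3)
  expect_equal(incl$down, 1)
  expect_equal(incl$binomial_p, 0.625)
  excl <- s[s$role == "exclusion", ]
  expect_equal(excl$up + excl$down, 0)
  expect_equal(excl$binomial_p, 1)
  expect_true(excl$degenerate)
})

test_that("direction summaries are invariant to record order and label swap", {
  ev <- fake_events(
    list(class = "CE", incl = "a", excl = "b"),
    list(class = "IR", incl = "c", excl = "d"))
  ps <- fake_ps(c("a", "b", "c", "d"), c(1, -1, 2, -2),
                rep(TRUE, 4), c("up", "down", "up", "down"))
  rec <- propagate_to_events(ev, ps)
  s1 <- summarize_direction(rec)
  s2 <- summarize_direction(rec[sample(nrow(rec)), ])
  expect_equal(dplyr::arrange(s2, event_class, role), s1)
  # swapping condition labels negates ps and flips directions
  ps_sw <- dplyr::mutate(ps, ps = -ps,
                         direction = c(up = "down", down = "up")[direction])
  s3 <- summarize_direction(propagate_to_events(ev, ps_sw))
  expect_equal(s3$up, s1$down)
  expect_equal(s3$down, s1$up)
  expect_equal(s3$binomial_p, s1$binomial_p)
})

test_that("boundary classes come from cluster fractions and 2x2 tests", {
  # 30/10 proximal/distal among affected, 10/30 among unaffected -> OR 9
  n <- 80
  promoters <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    transcript_id = sprintf("t%02d", seq_len(n)),
    promoter_group = 1L,
    tss = 100,
    tss_fraction = c(rep(0, 30), rep(0.5, 10), rep(0, 10), rep(0.5, 30)))
  ends <- tibble::tibble(
    gene_id = promoters$gene_id, transcript_id = promoters$transcript_id,
    end_cluster = 1L, tes = 500, tes_fraction = 0)
  ps <- tibble::tibble(
    transcript_id = promoters$transcript_id,
    significant = c(rep(TRUE, 40), rep(FALSE, 40)))
  out <- classify_boundaries(promoters, ends, ps)
  expect_equal(out$calls$tss_class[1], "proximal")
  expect_equal(sum(out$calls$tss_class == "distal"), 40)
  # single end cluster: everything proximal at the TES
  expect_equal(unique(out$calls$tes_class), "proximal")
  tss_test <- out$tests[out$tests$boundary == "tss", ]
  expect_equal(tss_test$odds_ratio, 9)
  expect_equal(out$tests$p_bonferroni, pmin(1, out$tests$p * 2))
})
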