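group_events <- function(exons) {
  profile <- build_coverage_profile(exons)
  strand <- exons$strand[1]
  structs <- split(exons[, c("start", "end")], exons$transcript_id)
  tss <- vapply(structs, function(ex)
    if (strand == "+") min(ex$start) else max(ex$end), numeric(1))
  tes <- vapply(structs, function(ex)
    if (strand == "+") max(ex$end) else min(ex$start), numeric(1))
  dplyr::bind_rows(
    detect_splice_sites(exons, profile,
                        end_positions = oracle_greedy_cluster(tes, strand),
                        tss_positions = oracle_greedy_cluster(tss, strand)),
    detect_cassette_exons(exons, profile),
    detect_retained_introns(exons, profile))
}

test_that("identical exon chains yield no events", {
  ex <- make_exons(list(A = chain(0, 100, 300, 500),
                        B = chain(0, 100, 300, 500)))
  expect_equal(nrow(group_events(ex)), 0)
})

test_that("a donor extension is called as one ALT5 at the short boundary", {
  ex <- make_exons(list(A = chain(0, 200, 400, 500),
                        B = chain(0, 210, 400, 500)))
  ev <- group_events(ex)
  expect_equal(ev$event_class, "ALT5")
  expect_equal(ev$start, 200)
  expect_equal(ev$including_ids[[1]], "A")
  expect_equal(ev$excluding_ids[[1]], "B")
})

test_that("an acceptor extension is called as one ALT3 at the short boundary", {
  ex <- make_exons(list(A = chain(0, 200, 340, 500),
                        B = chain(0, 200, 400, 500)))
  ev <- group_events(ex)
  expect_equal(ev$event_class, "ALT3")
  expect_equal(ev$start, 400)
  expect_equal(ev$including_ids[[1]], "B")
  expect_equal(ev$excluding_ids[[1]], "A")
})

test_that("a skipped middle exon is one CE with height below 1", {
  ex <- make_exons(list(A = chain(0, 100, 300, 400, 600, 700),
                        B = chain(0, 100, 600, 700)))
  p <- build_coverage_profile(ex)
  ev <- detect_cassette_exons(ex, p)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(300, 400))
  expect_equal(ev$including_ids[[1]], "A")
  expect_equal(ev$excluding_ids[[1]], "B")
  pk <- p$peaks[p$peaks$start == 300, ]
  expect_equal(pk$height, 0.5)
})

test_that("mutually exclusive exons yield two CE events", {
  ex <- make_exons(list(A = chain(0, 100, 300, 400, 700, 800),
                        B = chain(0, 100, 500, 600, 700, 800)))
  ev <- group_events(ex)
  ce <- ev[ev$event_class == "CE", ]
  expect_equal(nrow(ce), 2)
  expect_equal(sort(ce$start), c(300, 500))
  expect_equal(ce$including_ids[[which(ce$start == 300)]], "A")
  expect_equal(ce$including_ids[[which(ce$start == 500)]], "B")
})

test_that("first and last exons never become cassette exons", {
  ex <- make_exons(list(A = chain(0, 100, 300, 400),
                        B = chain(300, 400)))
  # A's unique first exon is promoter variation, not a CE; with distinct
  # TSS clusters these transcripts are not even co-grouped, but the
  # detector must also refuse the call within a forced group
  ev <- detect_cassette_exons(make_exons(list(
    A = chain(0, 100, 300, 400, 500, 600),
    B = chain(0, 100, 500, 600),
    C = chain(300, 400, 500, 600))),
    build_coverage_profile(make_exons(list(
      A = chain(0, 100, 300, 400, 500, 600),
      B = chain(0, 100, 500, 600),
      C = chain(300, 400, 500, 600)))))
  expect_true(all(ev$start == 300 & ev$end == 400))
  expect_false("C" %in% unlist(ev$including_ids))  # first exon of C
})

test_that("a spanned intron is IR; unspanned zero-coverage introns are not", {
  ex <- make_exons(list(A = chain(100, 200, 300, 400),
                        B = chain(100, 400)))
  ev <- group_events(ex)
  ir <- ev[ev$event_class == "IR", ]
  expect_equal(nrow(ir), 1)
  expect_equal(c(ir$start, ir$end), c(200, 300))
  expect_equal(ir$including_ids[[1]], "B")
  expect_equal(ir$excluding_ids[[1]], "A")

  ex2 <- make_exons(list(A = chain(100, 200, 300, 400),
                         B = chain(100, 200, 300, 400)))
  expect_equal(nrow(group_events(ex2)), 0)
})

test_that("structural and coverage IR routes agree on two-transcript one-intron fixtures", {
  # exhaustive: A has one intron on a grid; B is a single exon
  grid <- seq(0, 60, by = 10)
  quads <- utils::combn(grid, 4)
  pairs <- utils::combn(grid, 2)
  for (q in seq_len(ncol(quads))) {
    a <- chain(quads[1, q], quads[2, q], quads[3, q], quads[4, q])
    for (p in seq_len(ncol(pairs))) {
      b <- chain(pairs[1, p], pairs[2, p])
      if (b[1] != a[1]) next  # same promoter group
      ex <- make_exons(list(A = a, B = b))
      ev <- detect_retained_introns(ex, build_coverage_profile(ex))
      structural <- b[1] <= a[1, 2] && b[2] >= a[2, 1]
      if (structural) {
        expect_true(any(ev$source %in% c("structural", "both")),
                    info = paste("A:", paste(a, collapse = ","),
                                 "B:", paste(b, collapse = ",")))
      } else {
        expect_false(any(ev$source %in% c("structural", "both")),
                     info = paste("A:", paste(a, collapse = ","),
                                  "B:", paste(b, collapse = ",")))
      }
    }
  }
})

test_that("drops at alternative end sites are not donor events", {
  ex <- make_exons(list(A = chain(0, 200, 400, 500),
                        B = chain(0, 200, 400, 700)))
  ev <- group_events(ex)
  expect_false("ALT5" %in% ev$event_class)
})

test_that("strand mirror symmetry holds for the detectors", {
  fixtures <- list(
    make_exons(list(A = chain(0, 200, 400, 500),
                    B = chain(0, 210, 400, 500))),
    make_exons(list(A = chain(0, 200, 340, 500),
                    B = chain(0, 200, 400, 500))),
    make_exons(list(A = chain(0, 100, 300, 400, 600, 700),
                    B = chain(0, 100, 600, 700))),
    make_exons(list(A = chain(100, 200, 300, 400),
                    B = chain(100, 400)))
  )
  swap <- c(ALT5 = "ALT3", ALT3 = "ALT5", CE = "CE", IR = "IR")
  for (ex in fixtures) {
    ev <- group_events(ex)
    # reflect + flip strand is the same molecule: classes preserved
    mev <- group_events(mirror_exons(ex, 1000, flip = TRUE))
    expect_equal(sort(paste(mev$event_class, mev$start, mev$end)),
                 sort(paste(ev$event_class, 1000 - ev$end, 1000 - ev$start)))
    # reflect keeping the strand reverses transcription: ALT5 <-> ALT3
    rev <- group_events(mirror_exons(ex, 1000, flip = FALSE))
    expect_equal(sort(paste(rev$event_class, rev$start, rev$end)),
                 sort(paste(unname(swap[ev$event_class]),
                            1000 - ev$end, 1000 - ev$start)))
  }
})
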