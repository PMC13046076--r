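test_that("the ORF stand-in finds the longest ATG-to-stop frame", {
  ex <- make_exons(list(t1 = chain(0, 13)))
  ex1 <- ex[ex$transcript_id == "t1", ]
  orf <- annotate_orf("t1", ex1, sequence = "AAATGGCCTAAGG")
  expect_equal(c(orf$cds_start, orf$cds_end), c(2, 11))  # ATG GCC TAA
  expect_equal(orf$stop_position, 8)
  expect_true(orf$stop_in_last_exon)  # single exon

  # no ATG-initiated frame with a stop -> no annotation
  none <- annotate_orf("t1", ex1, sequence = "CCCCCCCCCCCCC")
  expect_equal(nrow(none), 0)
})

test_that("an externally supplied CDS is passed through unmodified", {
  ex <- make_exons(list(t1 = chain(0, 60)))
  orf <- annotate_orf("t1", ex, cds = c(9, 30))
  expect_equal(c(orf$cds_start, orf$cds_end), c(9, 30))
  expect_equal(orf$stop_position, 27)
})

test_that("stop-in-last-exon agrees with a base-by-base genomic walk", {
  set.seed(31)
  for (r in 1:25) {
    n_ex <- sample(2:4, 1)
    bounds <- sort(sample(seq(0, 2000, by = 10), 2 * n_ex))
    ch <- matrix(bounds, ncol = 2, byrow = TRUE)
    strand <- sample(c("+", "-"), 1)
    ex <- make_exons(list(t1 = ch), strand = strand)
    tlen <- sum(ch[, 2] - ch[, 1])
    cds_len <- 3 * sample(2:floor(tlen / 3), 1)
    cds_start <- sample(0:(tlen - cds_len), 1)
    orf <- annotate_orf("t1", ex, cds = c(cds_start, cds_start + cds_len))
    # oracle: enumerate transcript bases in transcription order
    bases <- unlist(apply(ch, 1, function(e) seq(e[1], e[2] - 1)))
    if (strand == "-") bases <- rev(bases)
    stop_genomic <- bases[orf$stop_position + 1]
    last_exon <- if (strand == "+") ch[nrow(ch), ] else ch[1, ]
    expect_equal(orf$stop_in_last_exon,
                 stop_genomic >= last_exon[1] && stop_genomic < last_exon[2])
  }
})

test_that("domain mapping is exact arithmetic with junction conservation", {
  ex <- make_exons(list(t1 = chain(0, 50, 100, 160)))
  orf <- annotate_orf("t1", ex, cds = c(0, 96))  # 31 aa + stop
  d <- map_domain_to_transcript("PF00001", 1, 10, orf, ex)
  expect_equal(c(d$nt_start, d$nt_end), c(0, 30))

  # a domain spanning the exon junction splits into two genomic pieces
  d2 <- map_domain_to_transcript("PF00002", 11, 30, orf, ex)
  g <- d2$genomic_intervals[[1]]
  expect_equal(nrow(g), 2)
  expect_equal(sum(g$end - g$start), 3 * 20)
  expect_equal(g$start[1], 30)   # nt 30..50 in exon 1
  expect_equal(g$end[2], 140)    # nt 50..90 -> genomic 100..140

  # beyond the protein -> domain error
  expect_error(map_domain_to_transcript("PF00003", 50, 60, orf, ex),
               "outside protein")
})

test_that("event consequences tag ORF, stop and domain overlaps", {
  ex <- make_exons(list(t1 = chain(0, 50, 100, 200, 300, 400)))
  orf <- annotate_orf("t1", ex, cds = c(10, 130))  # ends inside exon 2
  dom <- map_domain_to_transcript("PF1", 1, 20, orf, ex)  # nt 10..70

  # CE-style interval fully inside CDS and domain body
  expect_setequal(classify_event_consequence(100, 115, orf, ex, dom),
                  c("in_orf", "domain_body"))
  # interval covering the domain's first coding base (genomic 10)
  expect_true("domain_start" %in%
                classify_event_consequence(0, 20, orf, ex, dom))
  # interval in the 3' UTR with no domain
  expect_equal(classify_event_consequence(300, 400, orf, ex, dom),
               character(0))
  # the stop codon is nt 127..130 -> genomic 177..180
  expect_setequal(classify_event_consequence(170, 260, orf, ex, dom),
                  c("in_orf", "contains_stop"))
})

test_that("the domain-by-event matrix is row-stochastic with argmax dominant", {
  tagged <- tibble::tibble(
    pfam_id = c(rep("PF_A", 4), "PF_B", rep("PF_C", 2)),
    event_class = c("CE", "CE", "CE", "IR", "ALT5", "CE", "IR"))
  m <- build_domain_event_matrix(tagged)
  expect_true(all(abs(rowSums(m$matrix) - 1) < 1e-9))
  expect_equal(m$matrix["PF_A", "CE"], 0.75)
  expect_equal(m$matrix["PF_A", "IR"], 0.25)
  expect_equal(unname(m$dominant["PF_A"]), "CE")
  # one-event domain -> unit vector
  expect_equal(unname(m$matrix["PF_B", "ALT5"]), 1)
  # tie broken by canonical order (CE before IR)
  expect_equal(unname(m$dominant["PF_C"]), "CE")
})
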