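# Fixture builders and an independent brute-force oracle for event calling.
# The oracle re-derives everything naively (per-base loops, no shared code
# with the package) so caller/oracle agreement is a genuine dual route.

make_exons <- function(chains, strand = "+", gene = "g1",
                       seqname = "chr1", source = "test") {
  rows <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    tibble::tibble(
      seqname = seqname, source = source, gene_id = gene,
      transcript_id = names(chains)[i] %||% paste0("t", i),
      strand = strand,
      start = ch[, 1], end = ch[, 2]
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(transcript_id, start)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1]) || a[1] == "") b else a

chain <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2, byrow = TRUE)
}

# --- naive brute-force oracle -----------------------------------------

oracle_coverage <- function(structs, origin, len) {
  cov <- numeric(len)
  for (b in seq_len(len)) {
    pos <- origin + b - 1
    n <- 0
    for (ex in structs) {
      if (any(ex$start <= pos & pos < ex$end)) n <- n + 1
    }
    cov[b] <- n / length(structs)
  }
  cov
}

# maximal constant runs; returns data.frame(value, from, to) in R indices
oracle_runs <- function(cov) {
  r <- rle(cov)
  to <- cumsum(r$lengths)
  data.frame(value = r$values, from = c(1, head(to, -1) + 1), to = to)
}

oracle_greedy_cluster <- function(pos, strand) {
  ord <- if (strand == "+") order(pos) else order(-pos)
  founders <- c()
  for (i in ord) {
    if (!any(abs(founders - pos[i]) <= 1)) founders <- c(founders, pos[i])
  }
  founders
}

# Full naive re-derivation of ALT5/ALT3/CE/IR calls for one promoter group.
oracle_calls <- function(exons) {
  strand <- exons$strand[1]
  structs <- split(exons[, c("start", "end")], exons$transcript_id)
  structs <- lapply(structs, function(d) d[order(d$start), ])
  n_tx <- length(structs)
  origin <- min(exons$start)
  len <- max(exons$end) - origin
  cov <- oracle_coverage(structs, origin, len)
  runs <- oracle_runs(cov)
  nr <- nrow(runs)
  left_v <- c(NA, runs$value[-nr]); right_v <- c(runs$value[-1], NA)
  is_valley <- !is.na(left_v) & !is.na(right_v) &
    runs$value < left_v & runs$value < right_v
  is_peak <- (is.na(left_v) | runs$value > left_v) &
    (is.na(right_v) | runs$value > right_v)
  in_valley <- rep(FALSE, len)
  for (k in which(is_valley)) in_valley[runs$from[k]:runs$to[k]] <- TRUE

  tss <- vapply(structs, function(ex)
    if (strand == "+") min(ex$start) else max(ex$end), numeric(1))
  tes <- vapply(structs, function(ex)
    if (strand == "+") max(ex$end) else min(ex$start), numeric(1))
  tss_f <- oracle_greedy_cluster(tss, strand)
  tes_f <- oracle_greedy_cluster(tes, strand)

  spanning <- function(p) {
    names(structs)[vapply(structs, function(ex)
      any(ex$start < p & ex$end > p), logical(1))]
  }
  events <- list()
  add <- function(class, s, e, incl, excl) {
    events[[length(events) + 1]] <<- list(class = class, start = s, end = e,
                                          incl = sort(incl),
                                          excl = sort(excl))
  }
  # donors: coverage drop in transcription direction
  for (b in seq_len(len)) {
    if (in_valley[b]) next
    if (strand == "+") {
      if (b == 1 || !(cov[b] < cov[b - 1])) next
      p <- origin + b - 1
      incl <- names(structs)[vapply(structs, function(ex)
        any(ex$end == p), logical(1))]
    } else {
      if (b == len || !(cov[b] < cov[b + 1])) next
      p <- origin + b
      incl <- names(structs)[vapply(structs, function(ex)
        any(ex$start == p), logical(1))]
    }
    if (any(abs(p - tes_f) <= 1)) next
    excl <- spanning(p)
    if (length(incl) > 0 && length(excl) > 0) add("ALT5", p, p, incl, excl)
  }
  # acceptors: coverage step-up scanning toward transcription start
  for (b in seq_len(len)) {
    if (in_valley[b]) next
    if (strand == "+") {
      if (b == len || !(cov[b] < cov[b + 1])) next
      p <- origin + b
      incl <- names(structs)[vapply(structs, function(ex)
        any(ex$start == p), logical(1))]
    } else {
      if (b == 1 || !(cov[b] < cov[b - 1])) next
      p <- origin + b - 1
      incl <- names(structs)[vapply(structs, function(ex)
        any(ex$end == p), logical(1))]
    }
    if (any(abs(p - tss_f) <= 1)) next
    excl <- spanning(p)
    if (length(incl) > 0 && length(excl) > 0) add("ALT3", p, p, incl, excl)
  }
  # cassette exons: sub-unity peaks flanked by valleys
  internal_exons <- do.call(rbind, lapply(names(structs), function(tid) {
    ex <- structs[[tid]]
    if (nrow(ex) < 3) return(NULL)
    data.frame(tid = tid, start = ex$start[-c(1, nrow(ex))],
               end = ex$end[-c(1, nrow(ex))])
  }))
  seen_ce <- character(0)
  for (k in which(is_peak)) {
    h <- runs$value[k]
    if (h == 0 || h >= 1 - 1 / (2 * n_tx)) next
    lv <- which(is_valley & runs$to < runs$from[k])
    rv <- which(is_valley & runs$from > runs$to[k])
    if (length(lv) == 0 || length(rv) == 0) next
    lbound <- origin + runs$from[max(lv)] - 1
    rbound <- origin + runs$to[min(rv)]
    pk_s <- origin + runs$from[k] - 1
    pk_e <- origin + runs$to[k]
    if (is.null(internal_exons)) next
    cand <- internal_exons[internal_exons$start >= lbound &
                             internal_exons$end <= rbound &
                             internal_exons$start < pk_e &
                             internal_exons$end > pk_s, ]
    if (nrow(cand) == 0) next
    for (key in unique(paste(cand$start, cand$end))) {
      if (key %in% seen_ce) next
      se <- as.numeric(strsplit(key, " ")[[1]])
      incl <- unique(cand$tid[cand$start == se[1] & cand$end == se[2]])
      excl <- names(structs)[vapply(structs, function(ex)
        !any(ex$start < se[2] & ex$end > se[1]), logical(1))]
      if (length(incl) > 0 && length(excl) > 0) {
        add("CE", se[1], se[2], incl, excl)
        seen_ce <- c(seen_ce, key)
      }
    }
  }
  # retained introns: structural + positive-coverage valleys
  splices_out <- function(s, e) {
    names(structs)[vapply(structs, function(ex)
      !any(ex$start < e & ex$end > s) &&
        min(ex$start) <= s && max(ex$end) >= e, logical(1))]
  }
  seen_ir <- character(0)
  ir_iv <- list()
  for (tid in names(structs)) {
    ex <- structs[[tid]]
    if (nrow(ex) < 2) next
    for (j in seq_len(nrow(ex) - 1)) {
      s <- ex$end[j]; e <- ex$start[j + 1]
      key <- paste(s, e)
      if (key %in% seen_ir) next
      span <- setdiff(names(structs)[vapply(structs, function(oe)
        any(oe$start <= s & oe$end >= e), logical(1))], tid)
      if (length(span) == 0) next
      excl <- splices_out(s, e)
      if (length(excl) == 0) next
      add("IR", s, e, span, excl)
      seen_ir <- c(seen_ir, key)
      ir_iv[[length(ir_iv) + 1]] <- c(s, e)
    }
  }
  for (k in which(is_valley)) {
    s <- origin + runs$from[k] - 1
    e <- origin + runs$to[k]
    if (mean(cov[runs$from[k]:runs$to[k]]) <= 0) next
    covered <- any(vapply(ir_iv, function(iv)
      iv[1] <= s && iv[2] >= e, logical(1)))
    if (covered) next
    incl <- names(structs)[vapply(structs, function(ex)
      any(ex$start < e & ex$end > s), logical(1))]
    excl <- splices_out(s, e)
    if (length(incl) > 0 && length(excl) > 0) add("IR", s, e, incl, excl)
  }
  events
}

# canonical string form for comparing caller output with the oracle
event_key <- function(class, start, end, incl, excl) {
  paste(class, start, end, paste(sort(incl), collapse = ","),
        paste(sort(excl), collapse = ","), sep = "|")
}

caller_keys <- function(exons) {
  profile <- splicetide::build_coverage_profile(exons)
  strand <- exons$strand[1]
  structs <- split(exons[, c("start", "end")], exons$transcript_id)
  tss <- vapply(structs, function(ex)
    if (strand == "+") min(ex$start) else max(ex$end), numeric(1))
  tes <- vapply(structs, function(ex)
    if (strand == "+") max(ex$end) else min(ex$start), numeric(1))
  ev <- dplyr::bind_rows(
    splicetide::detect_splice_sites(
      exons, profile,
      end_positions = oracle_greedy_cluster(tes, strand),
      tss_positions = oracle_greedy_cluster(tss, strand)),
    splicetide::detect_cassette_exons(exons, profile),
    splicetide::detect_retained_introns(exons, profile)
  )
  if (nrow(ev) == 0) return(character(0))
  sort(unname(mapply(event_key, ev$event_class, ev$start, ev$end,
                     ev$including_ids, ev$excluding_ids)))
}

oracle_keys <- function(exons) {
  ev <- oracle_calls(exons)
  if (length(ev) == 0) return(character(0))
  sort(vapply(ev, function(e)
    event_key(e$class, e$start, e$end, e$incl, e$excl), character(1)))
}

# enumerate exon chains over an ascending boundary grid (1-3 exons)
enumerate_chains <- function(grid, max_exons = 3) {
  out <- list()
  for (k in seq_len(max_exons)) {
    combs <- utils::combn(grid, 2 * k)
    for (j in seq_len(ncol(combs))) {
      out[[length(out) + 1]] <- matrix(combs[, j], ncol = 2, byrow = TRUE)
    }
  }
  out
}

# reflect a fixture about coordinate c0; optionally flip the strand label.
# Reflect+flip is the same molecule (classes preserved); reflect keeping
# the strand reverses the transcription direction (ALT5 <-> ALT3).
mirror_exons <- function(exons, c0, flip = TRUE) {
  exons |>
    dplyr::mutate(s2 = c0 - end, e2 = c0 - start,
                  start = s2, end = e2,
                  strand = if (flip) ifelse(strand == "+", "-", "+")
                           else strand) |>
    dplyr::select(-s2, -e2) |>
    dplyr::arrange(transcript_id, start)
}
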