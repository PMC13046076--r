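# Event detectors operating on one promoter group and its coverage profile.
# Event positions use the package's 0-based half-open convention: a splice
# site event is the half-open boundary coordinate shared by the short and
# long exon forms.

EVENT_CLASSES <- c("ALT_PRO", "ALT5", "ALT3", "CE", "IR", "ALT_END")
EVENT_TAGS <- c(ALT_PRO = "alt_pro", ALT5 = "alt5", ALT3 = "alt3",
                CE = "ce", IR = "ir", ALT_END = "alt_end")

empty_events <- function() {
  tibble::tibble(event_class = character(), start = numeric(),
                 end = numeric(), including_ids = list(),
                 excluding_ids = list(), source = character())
}

event_row <- function(class, start, end, incl, excl, source = NA_character_) {
  tibble::tibble(event_class = class, start = start, end = end,
                 including_ids = list(sort(incl)),
                 excluding_ids = list(sort(excl)), source = source)
}

# Per-transcript exon structure helpers ---------------------------------

tx_structures <- function(exons) {
  split(exons[, c("start", "end")], exons$transcript_id)
}

# transcripts with an exon strictly spanning position p (covers bases p-1, p)
spanners <- function(structs, p) {
  names(structs)[vapply(structs, function(ex) {
    any(ex$start < p & ex$end > p)
  }, logical(1))]
}

#' Detect alternative 5' and 3' splice-site events
#'
#' Scans the normalized coverage profile of a promoter group for the
#' coverage steps that signal donor and acceptor variation.
#'
#' Alternative 5' sites (donors): a strand-aware scan in the transcription
#' direction flags positions where coverage drops relative to the
#' preceding base, meaning one transcript's exon ends while another's
#' continues. Positions inside intron intervals are skipped, and positions
#' within +/-1 nt of an end-site cluster are excluded so termination
#' differences are not misread as donor variation.
#'
#' Alternative 3' sites (acceptors): from each coverage peak center the
#' scan moves toward the transcription-start side and flags positions
#' where coverage steps up, meaning one transcript starts its exon at a
#' downstream acceptor while another includes extra upstream sequence.
#' Intronic positions are skipped, the scan stops on reaching another
#' peak or the group's most-upstream start, and positions within +/-1 nt
#' of a promoter-cluster TSS are excluded so TSS variation is not
#' misread as acceptor variation.
#'
#' Each event records the transcripts whose exon boundary sits at the
#' flagged position (`including_ids`) and those whose exon spans past it
#' (`excluding_ids`); both sets must be non-empty for an event to be
#' emitted.
#'
#' @param exons Exon table of one promoter group.
#' @param profile Its [build_coverage_profile()] result.
#' @param end_positions Genomic TES cluster positions of the gene.
#' @param tss_positions Genomic TSS cluster positions of the gene.
#' @return Event tibble with classes `ALT5`/`ALT3`; `start == end` is the
#'   flagged boundary coordinate.
#' @export
detect_splice_sites <- function(exons, profile, end_positions = numeric(),
                                tss_positions = numeric()) {
  vals <- profile$values
  len <- length(vals)
  origin <- profile$origin
  strand <- profile$strand
  structs <- tx_structures(exons)
  intronic <- logical(len)
  iv <- profile$intron_intervals
  for (k in seq_len(nrow(iv))) {
    intronic[(iv$start[k] - origin + 1):(iv$end[k] - origin)] <- TRUE
  }
  near <- function(p, ref) length(ref) > 0 && any(abs(p - ref) <= 1)
  out <- list()

  # --- donors (ALT5) : single pass in transcription direction ---
  if (strand == "+") {
    drop_i <- which(vals[-1] < vals[-len]) + 1L  # index of the lower base
    for (i in drop_i) {
      if (intronic[i]) next
      p <- origin + i - 1
      if (near(p, end_positions)) next
      incl <- names(structs)[vapply(structs, function(ex) any(ex$end == p),
                                    logical(1))]
      excl <- spanners(structs, p)
      if (length(incl) > 0 && length(excl) > 0) {
        out[[length(out) + 1]] <- event_row("ALT5", p, p, incl, excl)
      }
    }
  } else {
    drop_i <- which(vals[-len] < vals[-1])  # lower base going leftward
    for (i in drop_i) {
      if (intronic[i]) next
      p <- origin + i  # exon-start boundary coordinate
      if (near(p, end_positions)) next
      incl <- names(structs)[vapply(structs, function(ex) any(ex$start == p),
                                    logical(1))]
      excl <- spanners(structs, p)
      if (length(incl) > 0 && length(excl) > 0) {
        out[[length(out) + 1]] <- event_row("ALT5", p, p, incl, excl)
      }
    }
  }

  # --- acceptors (ALT3) : scan from each peak toward transcription start ---
  pk <- profile$peaks
  seen <- numeric(0)
  for (k in seq_len(nrow(pk))) {
    c_i <- pk$position[k] - origin + 1
    in_other_peak <- function(i) {
      any(pk$start[-k] - origin + 1 <= i & i <= pk$end[-k] - origin)
    }
    if (strand == "+") {
      i <- c_i - 1
      while (i >= 1) {
        if (in_other_peak(i)) break
        if (!intronic[i] && vals[i] < vals[i + 1]) {
          p <- origin + i  # acceptor = start of the shorter exon form
          if (!near(p, tss_positions) && !(p %in% seen)) {
            incl <- names(structs)[vapply(structs, function(ex)
              any(ex$start == p), logical(1))]
            excl <- spanners(structs, p)
            if (length(incl) > 0 && length(excl) > 0) {
              out[[length(out) + 1]] <- event_row("ALT3", p, p, incl, excl)
              seen <- c(seen, p)
            }
          }
        }
        i <- i - 1
      }
    } else {
      i <- c_i + 1
      while (i <= len) {
        if (in_other_peak(i)) break
        if (!intronic[i] && vals[i] < vals[i - 1]) {
          p <- origin + i - 1  # acceptor = end of the shorter exon form
          if (!near(p, tss_positions) && !(p %in% seen)) {
            incl <- names(structs)[vapply(structs, function(ex)
              any(ex$end == p), logical(1))]
            excl <- spanners(structs, p)
            if (length(incl) > 0 && length(excl) > 0) {
              out[[length(out) + 1]] <- event_row("ALT3", p, p, incl, excl)
              seen <- c(seen, p)
            }
          }
        }
        i <- i + 1
      }
    }
  }
  if (length(out) == 0) return(empty_events())
  dplyr::bind_rows(out)
}

#' Detect cassette (alternative) exons
#'
#' A cassette exon is an internal coverage peak whose height is below
#' 1 - 1/(2T) (so at most (T-1)/T of the T group members include it),
#' flanked by a coverage valley on both sides. The exact exon coordinates
#' are the member exons lying between the nearest flanking valleys; one
#' event is emitted per distinct internal exon interval there, so mutually
#' exclusive exon pairs yield two events. First and last exons of a
#' transcript never qualify, which keeps promoter/end variation out of
#' this class.
#'
#' @inheritParams detect_splice_sites
#' @return Event tibble with class `CE`; `start`/`end` are the exon
#'   interval.
#' @export
detect_cassette_exons <- function(exons, profile) {
  n_tx <- profile$n_transcripts
  eps <- 1 / (2 * n_tx)
  pk <- profile$peaks
  vl <- profile$valleys
  structs <- tx_structures(exons)
  internal <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(.internal = .data$start > min(.data$start) &
                    .data$end < max(.data$end)) |>
    dplyr::ungroup()
  out <- list()
  seen <- character(0)
  for (k in seq_len(nrow(pk))) {
    h <- pk$height[k]
    if (h >= 1 - eps || h == 0) next
    lv <- vl[vl$end <= pk$start[k], ]
    rv <- vl[vl$start >= pk$end[k], ]
    if (nrow(lv) == 0 || nrow(rv) == 0) next  # needs valleys on both sides
    lbound <- max(lv$start)
    rv_first <- rv[which.min(rv$start), ]
    rbound <- rv_first$end
    cand <- internal |>
      dplyr::filter(.data$.internal,
                    .data$start >= lbound, .data$end <= rbound,
                    .data$start < pk$end[k], .data$end > pk$start[k])
    if (nrow(cand) == 0) next
    for (iv in unique(paste(cand$start, cand$end))) {
      if (iv %in% seen) next
      se <- as.numeric(strsplit(iv, " ")[[1]])
      incl <- unique(cand$transcript_id[cand$start == se[1] & cand$end == se[2]])
      excl <- names(structs)[vapply(structs, function(ex)
        !any(ex$start < se[2] & ex$end > se[1]), logical(1))]
      if (length(incl) > 0 && length(excl) > 0) {
        out[[length(out) + 1]] <- event_row("CE", se[1], se[2], incl, excl)
        seen <- c(seen, iv)
      }
    }
  }
  if (length(out) == 0) return(empty_events())
  dplyr::bind_rows(out)
}

#' Detect retained introns
#'
#' Two complementary routes are combined. Structural: an intron of one
#' transcript fully spanned by a continuous exon of another member is
#' retained; the spanning transcripts include the event and the
#' transcripts splicing the interval out exclude it. Coverage: a
#' valley-derived intron interval with mean normalized coverage above zero
#' indicates some member contributes exonic sequence there; coverage-only
#' calls not contained in a structural call are appended with
#' `source = "coverage"` so any disagreement between the two definitions
#' stays visible. Zero-coverage introns spanned by no exon are never
#' retained.
#'
#' @inheritParams detect_splice_sites
#' @return Event tibble with class `IR`; `start`/`end` are the intron
#'   interval; `source` is `"structural"`, `"both"` or `"coverage"`.
#' @export
detect_retained_introns <- function(exons, profile) {
  structs <- tx_structures(exons)
  origin <- profile$origin
  vals <- profile$values
  splices_out <- function(int_s, int_e) {
    names(structs)[vapply(structs, function(ex) {
      !any(ex$start < int_e & ex$end > int_s) &&
        min(ex$start) <= int_s && max(ex$end) >= int_e
    }, logical(1))]
  }
  out <- list()
  seen <- character(0)
  # structural route
  for (tid in names(structs)) {
    ex <- structs[[tid]]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    for (j in seq_len(nrow(ex) - 1)) {
      int_s <- ex$end[j]
      int_e <- ex$start[j + 1]
      key <- paste(int_s, int_e)
      if (key %in% seen) next
      span <- names(structs)[vapply(structs, function(oe)
        any(oe$start <= int_s & oe$end >= int_e), logical(1))]
      span <- setdiff(span, tid)
      if (length(span) == 0) next
      excl <- splices_out(int_s, int_e)
      if (length(excl) == 0) next
      mean_cov <- mean(vals[(int_s - origin + 1):(int_e - origin)])
      src <- if (mean_cov > 0) "both" else "structural"
      out[[length(out) + 1]] <- event_row("IR", int_s, int_e, span, excl, src)
      seen <- c(seen, key)
    }
  }
  called <- dplyr::bind_rows(out)
  # coverage route: valley intervals with non-zero mean coverage
  iv <- profile$intron_intervals
  for (k in seq_len(nrow(iv))) {
    int_s <- iv$start[k]
    int_e <- iv$end[k]
    mean_cov <- mean(vals[(int_s - origin + 1):(int_e - origin)])
    if (mean_cov <= 0) next
    contained <- nrow(called) > 0 &&
      any(called$start <= int_s & called$end >= int_e)
    if (contained) next
    incl <- names(structs)[vapply(structs, function(ex)
      any(ex$start < int_e & ex$end > int_s), logical(1))]
    excl <- splices_out(int_s, int_e)
    if (length(incl) > 0 && length(excl) > 0) {
      out[[length(out) + 1]] <- event_row("IR", int_s, int_e, incl, excl,
                                          "coverage")
    }
  }
  if (length(out) == 0) return(empty_events())
  dplyr::bind_rows(out)
}
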