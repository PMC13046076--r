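#' Build a normalized exon-coverage profile for a promoter group
#'
#' Superimposes the exons of all transcripts in a promoter group onto a
#' single per-base axis spanning the group's first exon start to its last
#' exon end. The value at each base is the fraction of member transcripts
#' whose exons cover that base, so constitutive exonic bases are exactly
#' 1.0, bases intronic in every member are 0.0, and all values are
#' multiples of 1/T for group size T. The profile is the expression-support
#' signal from which splice-site, cassette-exon and retained-intron events
#' are called.
#'
#' Peaks and valleys are located by a plateau-aware local-extremum search
#' on the run-length encoded profile: a peak is a maximal constant run
#' higher than its neighbouring runs (profile-boundary runs compare against
#' their single neighbour), a valley is an interior run strictly lower than
#' both neighbours. Each valley's contiguous minimum run is its intron
#' interval.
#'
#' @param exons Exon table for the transcripts of one promoter group (one
#'   gene, one strand).
#' @return A `coverage_profile` object: a list with `origin` (genomic
#'   coordinate of profile start), `values` (per-base fractions), `strand`,
#'   `n_transcripts`, and tibbles `plateaus`, `peaks` (center `position`,
#'   `height`, extent), `valleys` and `intron_intervals` (genomic
#'   half-open intervals).
#' @export
build_coverage_profile <- function(exons) {
  if (nrow(exons) == 0L) rlang::abort("empty promoter group")
  strand <- unique(exons$strand)
  stopifnot(length(strand) == 1L)
  origin <- min(exons$start)
  len <- max(exons$end) - origin
  ids <- unique(exons$transcript_id)
  n_tx <- length(ids)
  counts <- numeric(len)
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i] - origin
    e <- exons$end[i] - origin
    counts[(s + 1):e] <- counts[(s + 1):e] + 1
  }
  values <- counts / n_tx

  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  plateaus <- tibble::tibble(
    value = r$values,
    start = origin + starts - 1,  # genomic half-open
    end = origin + ends
  )
  np <- nrow(plateaus)
  left <- c(NA, plateaus$value[-np])
  right <- c(plateaus$value[-1], NA)
  is_peak <- (is.na(left) | plateaus$value > left) &
    (is.na(right) | plateaus$value > right)
  is_valley <- !is.na(left) & !is.na(right) &
    plateaus$value < left & plateaus$value < right

  center <- function(s, e) {
    off <- (e - s) - 1
    if (strand == "+") s + floor(off / 2) else s + ceiling(off / 2)
  }
  peaks <- plateaus[is_peak, ]
  peaks$position <- mapply(center, peaks$start, peaks$end)
  peaks <- tibble::tibble(position = peaks$position, height = peaks$value,
                          start = peaks$start, end = peaks$end)
  valleys <- plateaus[is_valley, ]
  valleys <- tibble::tibble(
    position = mapply(center, valleys$start, valleys$end),
    depth = valleys$value, start = valleys$start, end = valleys$end
  )
  structure(list(
    origin = origin, values = values, strand = strand,
    n_transcripts = n_tx, member_ids = ids,
    plateaus = plateaus, peaks = peaks, valleys = valleys,
    intron_intervals = valleys[, c("start", "end")]
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d transcripts, span [%g, %g) on %s\n",
              x$n_transcripts, x$origin, x$origin + length(x$values),
              x$strand))
  cat(sprintf("  %d peaks, %d valleys\n", nrow(x$peaks), nrow(x$valleys)))
  invisible(x)
}

#' Tidy a coverage profile into a per-base tibble
#'
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @return A tibble with `position` (genomic) and `value`.
#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble::tibble(position = x$origin + seq_along(x$values) - 1,
                 value = x$values)
}

#' Plot a coverage profile
#'
#' Step plot of the normalized per-base exon-inclusion signal with peak
#' centers and intron intervals marked.
#'
#' @param object A `coverage_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  d <- tidy.coverage_profile(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "genomic position", y = "fraction of transcripts",
                  title = sprintf("Normalized exon coverage (%d transcripts, %s strand)",
                                  object$n_transcripts, object$strand))
  if (nrow(object$intron_intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$intron_intervals,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue",
      inherit.aes = FALSE)
  }
  if (nrow(object$peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$peaks,
      ggplot2::aes(x = .data$position, y = .data$height),
      colour = "firebrick", shape = 17)
  }
  p
}
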