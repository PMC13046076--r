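#' Annotate splicing events for one gene
#'
#' Runs the full per-gene pipeline: promoter and end-site clustering, a
#' normalized coverage profile per promoter group, the splice-site,
#' cassette-exon and retained-intron detectors within each group, and
#' ALT_PRO / ALT_END events for downstream promoter and end clusters.
#'
#' @param exons Exon table for a single gene.
#' @return A list with `events` (tibble: `event_class`, `gene_id`,
#'   `promoter_group`, `start`, `end`, `including_ids`, `excluding_ids`,
#'   `source`), `exon_labels` (per exon composite label), and
#'   `transcript_attributes` (per transcript event counts and fractional
#'   boundary positions), plus the `promoters` and `end_clusters` tables.
#' @export
annotate_gene <- function(exons) {
  stopifnot(length(unique(exons$gene_id)) == 1L)
  gene <- exons$gene_id[1]
  strand <- exons$strand[1]
  promoters <- cluster_promoters(exons)
  ends <- cluster_end_sites(exons)
  tss_positions <- unique(promoters$tss[!duplicated(promoters$promoter_group)])
  # founding positions per cluster: first member in transcription order
  founders <- function(tbl, idx_col, pos_col, frac_col) {
    tbl |>
      dplyr::group_by(.data[[idx_col]]) |>
      dplyr::summarise(position = dplyr::first(.data[[pos_col]]),
                       fraction = dplyr::first(.data[[frac_col]]),
                       members = list(.data$transcript_id), .groups = "drop")
  }
  pro_cl <- founders(promoters, "promoter_group", "tss", "tss_fraction")
  end_cl <- founders(ends, "end_cluster", "tes", "tes_fraction")

  events <- list()
  # within-group detectors
  for (g in sort(unique(promoters$promoter_group))) {
    member <- promoters$transcript_id[promoters$promoter_group == g]
    gex <- exons[exons$transcript_id %in% member, ]
    profile <- build_coverage_profile(gex)
    ev <- dplyr::bind_rows(
      detect_splice_sites(gex, profile, end_positions = end_cl$position,
                          tss_positions = pro_cl$position),
      detect_cassette_exons(gex, profile),
      detect_retained_introns(gex, profile)
    )
    if (nrow(ev) > 0) {
      ev$promoter_group <- g
      events[[length(events) + 1]] <- ev
    }
  }
  # alternative promoters: downstream clusters vs the most-upstream one
  upstream_pro <- pro_cl$members[[which.min(pro_cl$fraction)]]
  for (k in which(pro_cl$fraction > 0)) {
    events[[length(events) + 1]] <- event_row(
      "ALT_PRO", pro_cl$position[k], pro_cl$position[k],
      pro_cl$members[[k]], upstream_pro) |>
      dplyr::mutate(promoter_group = pro_cl$promoter_group[k])
  }
  # alternative end sites: downstream clusters vs the most-proximal one
  upstream_end <- end_cl$members[[which.min(end_cl$fraction)]]
  for (k in which(end_cl$fraction > 0)) {
    events[[length(events) + 1]] <- event_row(
      "ALT_END", end_cl$position[k], end_cl$position[k],
      end_cl$members[[k]], upstream_end) |>
      dplyr::mutate(promoter_group = NA_integer_)
  }
  events <- if (length(events) > 0) dplyr::bind_rows(events) else
    dplyr::mutate(empty_events(), promoter_group = integer())
  events$gene_id <- gene
  events <- events[, c("gene_id", "promoter_group", "event_class",
                       "start", "end", "including_ids", "excluding_ids",
                       "source")]

  exon_labels <- label_exons(exons, events, strand)
  tattr <- transcript_attributes(exons, events, promoters, ends)
  list(events = events, exon_labels = exon_labels,
       transcript_attributes = tattr, promoters = promoters,
       end_clusters = ends)
}

# Composite per-exon labels: "exon" plus underscore-joined tags in the
# canonical order alt_pro, alt5, alt3, ce, ir, alt_end.
label_exons <- function(exons, events, strand) {
  plus <- strand == "+"
  firsts <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(
      .first_tx = if (.env$plus) .data$start == min(.data$start)
                  else .data$end == max(.data$end),
      .last_tx = if (.env$plus) .data$end == max(.data$end)
                 else .data$start == min(.data$start)
    ) |>
    dplyr::ungroup()
  ev_by_class <- split(events, events$event_class)
  boundary_hits <- function(ev, use_end) {
    # transcripts in including_ids whose exon boundary sits at the event site
    hit <- rep(FALSE, nrow(exons))
    for (r in seq_len(nrow(ev))) {
      p <- ev$start[r]
      ids <- ev$including_ids[[r]]
      b <- if (use_end) exons$end else exons$start
      hit <- hit | (exons$transcript_id %in% ids & b == p)
    }
    hit
  }
  tags <- list(
    alt_pro = rep(FALSE, nrow(exons)), alt5 = rep(FALSE, nrow(exons)),
    alt3 = rep(FALSE, nrow(exons)), ce = rep(FALSE, nrow(exons)),
    ir = rep(FALSE, nrow(exons)), alt_end = rep(FALSE, nrow(exons)))
  if (!is.null(ev_by_class$ALT_PRO)) {
    ids <- unique(unlist(ev_by_class$ALT_PRO$including_ids))
    tags$alt_pro <- exons$transcript_id %in% ids & firsts$.first_tx
  }
  if (!is.null(ev_by_class$ALT5)) {
    tags$alt5 <- boundary_hits(ev_by_class$ALT5, use_end = strand == "+")
  }
  if (!is.null(ev_by_class$ALT3)) {
    tags$alt3 <- boundary_hits(ev_by_class$ALT3, use_end = strand == "-")
  }
  if (!is.null(ev_by_class$CE)) {
    ev <- ev_by_class$CE
    for (r in seq_len(nrow(ev))) {
      tags$ce <- tags$ce | (exons$start == ev$start[r] &
                              exons$end == ev$end[r] &
                              exons$transcript_id %in% ev$including_ids[[r]])
    }
  }
  if (!is.null(ev_by_class$IR)) {
    ev <- ev_by_class$IR
    for (r in seq_len(nrow(ev))) {
      tags$ir <- tags$ir | (exons$start < ev$end[r] & exons$end > ev$start[r])
    }
  }
  if (!is.null(ev_by_class$ALT_END)) {
    ids <- unique(unlist(ev_by_class$ALT_END$including_ids))
    tags$alt_end <- exons$transcript_id %in% ids & firsts$.last_tx
  }
  tag_mat <- do.call(cbind, tags)
  label <- apply(tag_mat, 1, function(row) {
    paste(c("exon", names(tags)[row]), collapse = "_")
  })
  tibble::tibble(gene_id = exons$gene_id, transcript_id = exons$transcript_id,
                 start = exons$start, end = exons$end, label = label)
}

# Per-transcript involvement counts (a5, a3, ce, i), promoter-group totals
# (a5t, a3t, cet, it) and fractional boundary positions (ap, ae).
transcript_attributes <- function(exons, events, promoters, ends) {
  ids <- unique(exons$transcript_id)
  count_for <- function(tid, class) {
    ev <- events[events$event_class == class, ]
    if (nrow(ev) == 0) return(0L)
    sum(vapply(ev$including_ids, function(s) tid %in% s, logical(1)))
  }
  group_total <- function(tid, class) {
    g <- promoters$promoter_group[promoters$transcript_id == tid]
    sum(events$event_class == class & !is.na(events$promoter_group) &
          events$promoter_group == g)
  }
  tibble::tibble(
    gene_id = exons$gene_id[1],
    transcript_id = ids,
    promoter_group = promoters$promoter_group[match(ids, promoters$transcript_id)],
    a5 = vapply(ids, count_for, integer(1), class = "ALT5", USE.NAMES = FALSE),
    a3 = vapply(ids, count_for, integer(1), class = "ALT3", USE.NAMES = FALSE),
    ce = vapply(ids, count_for, integer(1), class = "CE", USE.NAMES = FALSE),
    i = vapply(ids, count_for, integer(1), class = "IR", USE.NAMES = FALSE),
    a5t = vapply(ids, group_total, integer(1), class = "ALT5", USE.NAMES = FALSE),
    a3t = vapply(ids, group_total, integer(1), class = "ALT3", USE.NAMES = FALSE),
    cet = vapply(ids, group_total, integer(1), class = "CE", USE.NAMES = FALSE),
    it = vapply(ids, group_total, integer(1), class = "IR", USE.NAMES = FALSE),
    ap = promoters$tss_fraction[match(ids, promoters$transcript_id)],
    ae = ends$tes_fraction[match(ids, ends$transcript_id)]
  )
}

#' Annotate splicing events across a transcriptome
#'
#' Applies [annotate_gene()] gene by gene and assembles the results into a
#' single `splice_annotation` object.
#'
#' @param exons Exon table (see [read_gtf()]).
#' @return A `splice_annotation` list with tibbles `events` (with an
#'   `event_id`), `exon_labels`, `transcript_attributes`, `promoters` and
#'   `end_clusters`.
#' @export
annotate_transcriptome <- function(exons) {
  per_gene <- exons |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(annotate_gene)
  events <- purrr::map_dfr(per_gene, "events")
  if (nrow(events) > 0) {
    events$event_id <- sprintf("ev%04d", seq_len(nrow(events)))
  } else {
    events$event_id <- character(0)
  }
  structure(list(
    events = events,
    exon_labels = purrr::map_dfr(per_gene, "exon_labels"),
    transcript_attributes = purrr::map_dfr(per_gene, "transcript_attributes"),
    promoters = purrr::map_dfr(per_gene, "promoters"),
    end_clusters = purrr::map_dfr(per_gene, "end_clusters")
  ), class = "splice_annotation")
}

#' @export
print.splice_annotation <- function(x, ...) {
  cat(sprintf("<splice_annotation> %d events across %d genes\n",
              nrow(x$events), length(unique(x$transcript_attributes$gene_id))))
  print(dplyr::count(x$events, .data$event_class))
  invisible(x)
}

#' Write an annotated GTF
#'
#' Convenience wrapper for [write_gtf()] with an annotation attached: exon
#' feature columns carry composite labels such as `exon_ce`, `exon_ir` or
#' `exon_alt3_ce`, and transcript rows carry the promoter-group identifier
#' and numeric splicing attributes. Coordinates are restored to 1-based
#' inclusive GTF convention.
#'
#' @param annotation A `splice_annotation`.
#' @param exons The exon table the annotation was computed from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_gtf <- function(annotation, exons, path) {
  write_gtf(exons, path, annotation = annotation)
}
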