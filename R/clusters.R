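#' Cluster transcripts into promoter groups
#'
#' Transcripts of a gene are clustered by transcription start site (TSS):
#' walking TSS positions in ascending transcription order, a TSS joins an
#' existing cluster iff it lies within +/-1 bp of that cluster's founding
#' TSS, otherwise it founds a new cluster. Promoter groups are the unit
#' within which isoform usage proportions are computed downstream.
#'
#' Fractional distances place each cluster along the gene: 0.0 for the
#' most-upstream cluster (in the transcription sense, so strand-aware) up
#' to 1.0 for the most-downstream when at least two clusters exist, with
#' intermediate clusters linearly interpolated between the extremes.
#' Single-cluster genes get fraction 0.0.
#'
#' @param exons Exon table (see [read_gtf()]); may contain several genes.
#' @return A tibble with one row per transcript: `gene_id`,
#'   `transcript_id`, `strand`, `promoter_group` (integer index in
#'   transcription order, 1 = most upstream), `tss` and `tss_fraction`.
#' @export
cluster_promoters <- function(exons) {
  if (nrow(exons) == 0L) rlang::abort("no transcripts to cluster")
  tx <- transcript_bounds(exons)
  tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$strand)) != 1L) {
        rlang::abort(paste0("mixed strands within gene ", key$gene_id))
      }
      cl <- greedy_cluster(d$tss, d$strand[1])
      tibble::tibble(transcript_id = d$transcript_id, strand = d$strand,
                     promoter_group = cl$index, tss = d$tss,
                     tss_fraction = cl$fraction)
    }) |>
    dplyr::ungroup()
}

#' Cluster transcript end sites
#'
#' The same greedy +/-1 nt clustering as [cluster_promoters()], applied to
#' transcription end sites (TES). End sites closer to the gene 3' end get
#' higher fractional values (inverted on the minus strand, where a smaller
#' genomic coordinate lies downstream in transcription).
#'
#' @inheritParams cluster_promoters
#' @return A tibble with `gene_id`, `transcript_id`, `strand`,
#'   `end_cluster`, `tes` and `tes_fraction` per transcript.
#' @export
cluster_end_sites <- function(exons) {
  if (nrow(exons) == 0L) rlang::abort("no transcripts to cluster")
  tx <- transcript_bounds(exons)
  tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      cl <- greedy_cluster(d$tes, d$strand[1])
      tibble::tibble(transcript_id = d$transcript_id, strand = d$strand,
                     end_cluster = cl$index, tes = d$tes,
                     tes_fraction = cl$fraction)
    }) |>
    dplyr::ungroup()
}

# Per-transcript genomic bounds and strand-aware termini.
# TSS: first-exon start on +, last-exon end on -; TES is the opposite.
transcript_bounds <- function(exons) {
  exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$strand) |>
    dplyr::summarise(gstart = min(.data$start), gend = max(.data$end),
                     .groups = "drop") |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$gstart, .data$gend),
      tes = ifelse(.data$strand == "+", .data$gend, .data$gstart)
    )
}

# Greedy anchored clustering of positions in ascending transcription order.
# A position joins a cluster iff within +/-1 of the founding position.
# Returns per-input cluster index (1 = most upstream in transcription) and
# fractional distance of the cluster between the extreme founders.
greedy_cluster <- function(pos, strand, window = 1) {
  ord <- if (strand == "+") order(pos) else order(-pos)
  founders <- numeric(0)
  idx <- integer(length(pos))
  for (i in ord) {
    hit <- which(abs(founders - pos[i]) <= window)
    if (length(hit) > 0L) {
      idx[i] <- hit[1]
    } else {
      founders <- c(founders, pos[i])
      idx[i] <- length(founders)
    }
  }
  k <- length(founders)
  if (k == 1L) {
    frac_by_cluster <- 0
  } else {
    span <- abs(founders[k] - founders[1])
    frac_by_cluster <- abs(founders - founders[1]) / span
  }
  list(index = idx, fraction = frac_by_cluster[idx], founders = founders)
}
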