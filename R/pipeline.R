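#' Run the full differential-splicing pipeline
#'
#' Chains the stages on an exon table and abundance table: event
#' annotation, usage proportions, the Bayesian beta usage model, PS
#' assignment and propagation, direction summaries and boundary
#' classification.
#'
#' @param exons Exon table ([read_gtf()] or
#'   [simulate_transcriptome()]`$exons`).
#' @param counts Abundance table with `transcript_id`, `gene_id`,
#'   `promoter_group` and `<condition>_<rep>` sample columns.
#' @param seed,chains,draws Passed to [fit_beta_model()].
#' @param reference,treatment Condition labels.
#' @return A `splicetide_result` list: `annotation`, `proportions`,
#'   `fit`, `ps`, `records`, `direction_summary`, `boundaries`.
#' @export
run_splicing_pipeline <- function(exons, counts, seed = 1L,
                                  reference = "young", treatment = "aged",
                                  chains = 2L, draws = 2000L) {
  annotation <- annotate_transcriptome(exons)
  proportions <- compute_proportions(counts)
  fit <- fit_beta_model(proportions, reference = reference,
                        treatment = treatment, seed = seed,
                        chains = chains, draws = draws)
  ps <- assign_ps(fit, proportions)
  # events may reference transcripts whose groups were depth-filtered out;
  # restrict propagation to the fitted universe
  fitted <- ps$transcript_id
  ev <- annotation$events |>
    dplyr::filter(purrr::map_lgl(.data$including_ids,
                                 ~ all(.x %in% fitted)) &
                    purrr::map_lgl(.data$excluding_ids,
                                   ~ all(.x %in% fitted)))
  records <- propagate_to_events(ev, ps)
  direction_summary <- summarize_direction(records)
  boundaries <- classify_boundaries(annotation$promoters,
                                    annotation$end_clusters, ps)
  structure(list(annotation = annotation, proportions = proportions,
                 fit = fit, ps = ps, records = records,
                 direction_summary = direction_summary,
                 boundaries = boundaries),
            class = "splicetide_result")
}

#' @export
print.splicetide_result <- function(x, ...) {
  cat("<splicetide_result>\n")
  print(x$annotation)
  print(x$fit)
  invisible(x)
}
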