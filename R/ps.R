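#' Assign percent-spliced (PS) values to transcripts
#'
#' The PS of a transcript is the log2 fold-change of its within-promoter
#' usage proportion between conditions. The canonical point estimate is
#' the posterior median log2fc from the beta model, so PS shares the
#' significance machinery; the plug-in empirical log2 ratio of mean
#' clipped proportions is also exported for comparison.
#'
#' @param fit A `beta_usage_fit` (or its tidy summary).
#' @param proportions Optional [compute_proportions()] output; when given,
#'   `ps_empirical` is added.
#' @return A tibble: `transcript_id`, `gene_id`, `promoter_group`, `ps`,
#'   `ps_empirical` (if available), `significant`, `direction`.
#' @export
assign_ps <- function(fit, proportions = NULL) {
  s <- if (inherits(fit, "beta_usage_fit")) fit$summary else fit
  out <- s |>
    dplyr::transmute(.data$transcript_id, .data$gene_id,
                     .data$promoter_group, ps = .data$log2fc,
                     .data$significant, .data$direction)
  if (!is.null(proportions)) {
    trt <- if (inherits(fit, "beta_usage_fit")) fit$treatment else "aged"
    ref <- if (inherits(fit, "beta_usage_fit")) fit$reference else "young"
    emp <- proportions |>
      dplyr::group_by(.data$transcript_id, .data$condition) |>
      dplyr::summarise(m = mean(.data$proportion), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "m") |>
      dplyr::transmute(.data$transcript_id,
                       ps_empirical = log2(.data[[trt]] / .data[[ref]]))
    out <- dplyr::left_join(out, emp, by = "transcript_id") |>
      dplyr::relocate("ps_empirical", .after = "ps")
  }
  out
}

#' Propagate transcript PS values to embedded events
#'
#' Every alternative splicing event is physically embedded in full-length
#' isoforms, so an event inherits the PS of each transcript that includes
#' it (role `"inclusion"`) and of each transcript that skips it (role
#' `"exclusion"`). One record is produced per (event, member transcript)
#' pair.
#'
#' @param events Event tibble (from [annotate_transcriptome()], needs
#'   `event_id`).
#' @param ps [assign_ps()] output covering every transcript the events
#'   reference.
#' @return A tibble: `event_id`, `event_class`, `gene_id`,
#'   `transcript_id`, `role`, `ps`, `significant`, `direction`.
#' @export
propagate_to_events <- function(events, ps) {
  long <- events |>
    dplyr::select("event_id", "event_class", "gene_id",
                  "including_ids", "excluding_ids") |>
    tidyr::pivot_longer(c("including_ids", "excluding_ids"),
                        names_to = "role", values_to = "transcript_id") |>
    dplyr::mutate(role = dplyr::if_else(.data$role == "including_ids",
                                        "inclusion", "exclusion")) |>
    tidyr::unnest_longer("transcript_id")
  missing <- setdiff(long$transcript_id, ps$transcript_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("transcripts in events but absent from PS table: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  dplyr::left_join(long,
                   dplyr::select(ps, "transcript_id", "ps", "significant",
                                 "direction"),
                   by = "transcript_id")
}

#' Summarise event-record direction counts
#'
#' Counts significant up-, significant down- and unaffected records per
#' event class and role, with a two-sided exact binomial test (p0 = 0.5)
#' for the up/down imbalance. A class with no significant records in
#' either direction reports p = 1 with `degenerate = TRUE`.
#'
#' @param records [propagate_to_events()] output.
#' @return A tibble per (event_class, role): `up`, `down`, `unaffected`,
#'   `binomial_p`, `degenerate`.
#' @export
summarize_direction <- function(records) {
  records |>
    dplyr::group_by(.data$event_class, .data$role) |>
    dplyr::summarise(
      up = sum(.data$significant & .data$direction == "up", na.rm = TRUE),
      down = sum(.data$significant & .data$direction == "down", na.rm = TRUE),
      unaffected = sum(!.data$significant | is.na(.data$significant)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      binomial_p = purrr::map2_dbl(.data$up, .data$down, binomial_imbalance),
      degenerate = .data$up + .data$down == 0
    )
}

#' Classify transcript boundaries as proximal or distal
#'
#' A transcript's TSS is proximal iff its promoter cluster is the group's
#' most-upstream cluster (fractional distance 0.0), else distal; the TES
#' class is defined analogously from the end clusters. "Affected"
#' transcripts are those with a significant usage shift; unaffected
#' transcripts are the internal baseline. For each boundary type a 2x2
#' contingency table (affected/unaffected x proximal/distal) is tested
#' with Fisher's exact test, Bonferroni-corrected across the boundary
#' comparisons.
#'
#' @param promoters [cluster_promoters()] output.
#' @param end_clusters [cluster_end_sites()] output.
#' @param ps [assign_ps()] output.
#' @return A list with `calls` (per transcript: `tss_class`, `tes_class`,
#'   `affected`) and `tests` (per boundary: the 2x2 counts, sample odds
#'   ratio, Fisher p and Bonferroni-adjusted p).
#' @export
classify_boundaries <- function(promoters, end_clusters, ps) {
  calls <- promoters |>
    dplyr::select("gene_id", "transcript_id", "tss_fraction") |>
    dplyr::left_join(dplyr::select(end_clusters, "transcript_id",
                                   "tes_fraction"),
                     by = "transcript_id") |>
    dplyr::mutate(
      tss_class = dplyr::if_else(.data$tss_fraction == 0, "proximal", "distal"),
      tes_class = dplyr::if_else(.data$tes_fraction == 0, "proximal", "distal")
    ) |>
    dplyr::left_join(dplyr::select(ps, "transcript_id", "significant"),
                     by = "transcript_id") |>
    dplyr::mutate(affected = !is.na(.data$significant) & .data$significant)
  one_test <- function(cls) {
    tab <- rbind(
      affected = c(proximal = sum(calls$affected & calls[[cls]] == "proximal"),
                   distal = sum(calls$affected & calls[[cls]] == "distal")),
      unaffected = c(sum(!calls$affected & calls[[cls]] == "proximal"),
                     sum(!calls$affected & calls[[cls]] == "distal"))
    )
    f <- fisher_2x2(tab)
    tibble::tibble(boundary = sub("_class", "", cls),
                   affected_proximal = tab[1, 1], affected_distal = tab[1, 2],
                   unaffected_proximal = tab[2, 1],
                   unaffected_distal = tab[2, 2],
                   odds_ratio = f$odds_ratio, p = f$p)
  }
  tests <- dplyr::bind_rows(one_test("tss_class"), one_test("tes_class"))
  tests$p_bonferroni <- adjust_bonferroni(tests$p, m = nrow(tests))
  list(calls = calls, tests = tests)
}

#' Bar plot of direction summaries
#'
#' @param summary [summarize_direction()] output.
#' @return A ggplot object with significant up/down counts per event class
#'   and role.
#' @export
plot_direction_summary <- function(summary) {
  d <- summary |>
    tidyr::pivot_longer(c("up", "down"), names_to = "direction",
                        values_to = "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$event_class, y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$role) +
    ggplot2::scale_fill_manual(values = c(up = "firebrick",
                                          down = "steelblue")) +
    ggplot2::labs(x = "event class", y = "significant records")
}
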