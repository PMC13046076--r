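#' Describe a synthetic transcriptome study design
#'
#' The design mirrors a two-condition direct RNA-seq comparison with three
#' replicates per condition. Each gene carries one or more promoter
#' groups; each group realizes one planned splicing event through a
#' designed transcript contrast (e.g. a cassette exon is two otherwise
#' identical chains, one lacking the middle exon). A fraction of groups
#' receives a true usage shift of the stated log2 magnitude; replicate
#' counts are drawn multinomially around the true usages with a Poisson
#' group total.
#'
#' Defaults are the desk-scale study conditions used throughout the
#' package's tests: depth 200 expected molecules per group and sample,
#' usage 0.8 vs 0.2 in shifted groups (log2 fold-change 2 in usage odds
#' scale), 3 vs 3 replicates.
#'
#' @param n_genes Number of genes.
#' @param groups_per_gene Promoter groups per gene (>= 2 realizes
#'   ALT_PRO events).
#' @param transcripts_per_group Transcripts per promoter group (>= 2).
#' @param event_classes Within-group event classes cycled across groups.
#' @param effect_fraction Fraction of groups with a true usage shift.
#' @param effect_log2fc Magnitude of the shift: the focal transcript's
#'   usage is `2^e / (2^e + 1)` in the aged condition and the complement
#'   in young (0.8 vs 0.2 at the default e = 2, two transcripts).
#' @param depth Expected molecules per group per sample.
#' @param replicates Replicates per condition.
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return A `splice_sim_design` list.
#' @export
splice_sim_design <- function(n_genes = 50, groups_per_gene = 1,
                              transcripts_per_group = 2,
                              event_classes = c("CE", "IR", "ALT5",
                                                "ALT3", "ALT_END"),
                              effect_fraction = 0.5, effect_log2fc = 2,
                              depth = 200, replicates = 3, seed = 1L) {
  stopifnot(n_genes >= 1, groups_per_gene >= 1,
            effect_fraction >= 0, effect_fraction <= 1,
            depth > 0, replicates >= 1)
  if (transcripts_per_group < 2) {
    rlang::abort("within-group events need at least 2 transcripts per group")
  }
  stopifnot(all(event_classes %in% c("CE", "IR", "ALT5", "ALT3", "ALT_END")))
  structure(list(n_genes = n_genes, groups_per_gene = groups_per_gene,
                 transcripts_per_group = transcripts_per_group,
                 event_classes = event_classes,
                 effect_fraction = effect_fraction,
                 effect_log2fc = effect_log2fc, depth = depth,
                 replicates = replicates, seed = as.integer(seed)),
            class = "splice_sim_design")
}

# Exon chains in transcription coordinates realizing one event for the
# first two transcripts; extra transcripts copy the first chain shifted
# usage-wise only (identical structure adds no events).
realize_event <- function(class, geom) {
  e1 <- c(0, geom$x1)
  i1 <- geom$in1
  e2s <- geom$x1 + i1
  e2 <- c(e2s, e2s + geom$x2)
  i2 <- geom$in2
  e3s <- e2[2] + i2
  e3 <- c(e3s, e3s + geom$x3)
  d <- geom$delta
  switch(class,
    CE = list(t1 = rbind(e1, e2, e3), t2 = rbind(e1, e3)),
    IR = list(t1 = rbind(e1, e2), t2 = rbind(c(0, e2[2]))),
    ALT5 = list(t1 = rbind(e1, e2), t2 = rbind(c(0, geom$x1 + d), e2)),
    # the acceptor shift must leave a positive exon remainder
    ALT3 = list(t1 = rbind(c(0, geom$x1), c(e2s, e2[2])),
                t2 = rbind(c(0, geom$x1),
                           c(e2s + min(d, geom$x2 - 50), e2[2]))),
    ALT_END = list(t1 = rbind(e1, e2), t2 = rbind(e1, c(e2[1], e2[2] + d)))
  )
}

#' Simulate a collapsed transcriptome with designed usage shifts
#'
#' Generates exon models (GTF-compatible), a replicate abundance table
#' and the ground truth for a [splice_sim_design()]. Gene strands
#' alternate between + and - (architectures are built in transcription
#' space and reflected for minus-strand genes) so strand-aware logic is
#' exercised. Deterministic under the design seed: the same design gives
#' byte-identical outputs.
#'
#' @param design A `splice_sim_design`.
#' @param dir Optional output directory; when given, `models.gtf`,
#'   `abundance.tsv`, `truth_usage.tsv` and `truth_events.tsv` are
#'   written there.
#' @return A list: `exons` (exon table as from [read_gtf()]), `counts`
#'   (abundance table for [compute_proportions()]), `truth` (list with
#'   `usage` and `events` tibbles), and `design`.
#' @export
simulate_transcriptome <- function(design, dir = NULL) {
  stopifnot(inherits(design, "splice_sim_design"))
  set.seed(design$seed)
  exon_rows <- list()
  usage_rows <- list()
  event_rows <- list()
  count_rows <- list()
  n_groups_total <- design$n_genes * design$groups_per_gene
  n_effect <- round(design$effect_fraction * n_groups_total)
  p_eff <- 2^design$effect_log2fc / (2^design$effect_log2fc + 1)
  samples <- c(outer(seq_len(design$replicates), c("young", "aged"),
                     function(r, c) paste0(c, "_", r)))
  group_counter <- 0
  for (g in seq_len(design$n_genes)) {
    gene <- sprintf("gene%03d", g)
    strand <- if (g %% 2 == 1) "+" else "-"
    anchor <- 100000 * g
    for (pg in seq_len(design$groups_per_gene)) {
      group_counter <- group_counter + 1
      cls <- design$event_classes[
        (group_counter - 1) %% length(design$event_classes) + 1]
      geom <- list(
        x1 = sample(100:300, 1), x2 = sample(100:300, 1),
        x3 = sample(100:300, 1), in1 = sample(200:1000, 1),
        in2 = sample(200:1000, 1), delta = sample(50:150, 1)
      )
      chains <- realize_event(cls, geom)
      # promoter offset separates groups (>= 2 bp apart by construction)
      tss_off <- (pg - 1) * 5000
      k <- design$transcripts_per_group
      tids <- sprintf("%s.g%d.t%d", gene, pg, seq_len(k))
      tx_chains <- c(chains, lapply(seq_len(max(0, k - 2)),
                                    function(j) chains$t1))
      has_effect <- group_counter <= n_effect
      usage_young <- if (has_effect) {
        c(1 - p_eff, rep(p_eff / (k - 1), k - 1))
      } else rep(1 / k, k)
      usage_aged <- if (has_effect) {
        c(p_eff, rep((1 - p_eff) / (k - 1), k - 1))
      } else rep(1 / k, k)
      for (t in seq_len(k)) {
        ch <- tx_chains[[t]]
        # transcription -> genomic coordinates
        if (strand == "+") {
          gs <- anchor + tss_off + ch[, 1]
          ge <- anchor + tss_off + ch[, 2]
        } else {
          gs <- anchor + 50000 - tss_off - ch[, 2]
          ge <- anchor + 50000 - tss_off - ch[, 1]
        }
        ord <- order(gs)
        exon_rows[[length(exon_rows) + 1]] <- tibble::tibble(
          seqname = "chrS", source = "splicetide_sim", gene_id = gene,
          transcript_id = tids[t], strand = strand,
          start = unname(gs[ord]), end = unname(ge[ord]))
        for (cond in c("young", "aged")) {
          usage_rows[[length(usage_rows) + 1]] <- tibble::tibble(
            transcript_id = tids[t], gene_id = gene, promoter_group = pg,
            condition = cond,
            true_usage = if (cond == "young") usage_young[t] else usage_aged[t],
            true_differential = has_effect,
            true_direction = if (!has_effect) "none"
              else if ((usage_aged[t] > usage_young[t])) "up" else "down")
        }
      }
      event_rows[[length(event_rows) + 1]] <- tibble::tibble(
        gene_id = gene, promoter_group = pg, event_class = cls,
        includer = tids[1], excluder = tids[2])
      if (pg > 1) {
        event_rows[[length(event_rows) + 1]] <- tibble::tibble(
          gene_id = gene, promoter_group = pg, event_class = "ALT_PRO",
          includer = tids[1], excluder = NA_character_)
      }
      # replicate counts: Poisson total, multinomial split
      cnt <- matrix(0L, nrow = k, ncol = length(samples),
                    dimnames = list(tids, samples))
      for (s in samples) {
        usage <- if (startsWith(s, "young")) usage_young else usage_aged
        total <- stats::rpois(1, design$depth)
        cnt[, s] <- as.integer(stats::rmultinom(1, total, usage))
      }
      count_rows[[length(count_rows) + 1]] <- tibble::tibble(
        transcript_id = tids, gene_id = gene, promoter_group = pg) |>
        dplyr::bind_cols(tibble::as_tibble(cnt))
    }
  }
  exons <- dplyr::bind_rows(exon_rows) |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)
  counts <- dplyr::bind_rows(count_rows)
  truth <- list(usage = dplyr::bind_rows(usage_rows),
                events = dplyr::bind_rows(event_rows))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gtf(exons, file.path(dir, "models.gtf"))
    readr::write_tsv(counts, file.path(dir, "abundance.tsv"))
    readr::write_tsv(truth$usage, file.path(dir, "truth_usage.tsv"))
    readr::write_tsv(truth$events, file.path(dir, "truth_events.tsv"))
  }
  list(exons = exons, counts = counts, truth = truth, design = design)
}

#' Score pipeline calls against simulation ground truth
#'
#' Transcript-level differential-usage metrics: sensitivity (truly
#' shifted transcripts called significant with the correct direction),
#' false-call rate (null transcripts called significant) and direction
#' accuracy among true positives. Event-level detection metrics compare
#' called events to planned events per gene and class (precision and
#' recall over matched multiplicities).
#'
#' @param calls Per-transcript calls: a tibble with `transcript_id`,
#'   `significant`, `direction` (e.g. `tidy()` of a fit, or
#'   [assign_ps()] output).
#' @param truth The `truth` element of [simulate_transcriptome()].
#' @param events Optional called events tibble (from
#'   [annotate_transcriptome()]) for detection metrics.
#' @return A list with `usage` (one-row tibble of the three rates) and,
#'   when `events` is given, `events` (per-class precision/recall).
#' @export
evaluate_recovery <- function(calls, truth, events = NULL) {
  tu <- truth$usage |>
    dplyr::distinct(.data$transcript_id, .data$true_differential,
                    .data$true_direction)
  unknown <- setdiff(calls$transcript_id, tu$transcript_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("calls contain transcripts absent from truth: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  j <- tu |>
    dplyr::left_join(dplyr::select(calls, "transcript_id", "significant",
                                   "direction"),
                     by = "transcript_id") |>
    dplyr::mutate(significant = !is.na(.data$significant) & .data$significant)
  pos <- dplyr::filter(j, .data$true_differential)
  neg <- dplyr::filter(j, !.data$true_differential)
  tp <- pos$significant & pos$direction == pos$true_direction
  usage <- tibble::tibble(
    sensitivity = if (nrow(pos) > 0) mean(tp) else NA_real_,
    false_call_rate = if (nrow(neg) > 0) mean(neg$significant) else NA_real_,
    direction_accuracy = if (sum(pos$significant) > 0) {
      mean(pos$direction[pos$significant] ==
             pos$true_direction[pos$significant])
    } else NA_real_
  )
  out <- list(usage = usage)
  if (!is.null(events)) {
    called <- events |>
      dplyr::count(.data$gene_id, .data$event_class, name = "n_called")
    planned <- truth$events |>
      dplyr::count(.data$gene_id, .data$event_class, name = "n_true")
    m <- dplyr::full_join(called, planned,
                          by = c("gene_id", "event_class")) |>
      tidyr::replace_na(list(n_called = 0L, n_true = 0L)) |>
      dplyr::mutate(matched = pmin(.data$n_called, .data$n_true))
    out$events <- m |>
      dplyr::group_by(.data$event_class) |>
      dplyr::summarise(n_true = sum(.data$n_true),
                       n_called = sum(.data$n_called),
                       matched = sum(.data$matched), .groups = "drop") |>
      dplyr::mutate(
        precision = ifelse(.data$n_called > 0,
                           .data$matched / .data$n_called, NA_real_),
        recall = ifelse(.data$n_true > 0,
                        .data$matched / .data$n_true, NA_real_))
  }
  out
}
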