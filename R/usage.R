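#' Convert transcript abundances to within-promoter-group usage proportions
#'
#' Within each promoter group and sample, abundances are divided by the
#' group total so the entries are the fraction of the group's molecules
#' contributed by each isoform. Groups lacking a non-zero count in either
#' condition are dropped entirely (no usage signal to compare). Retained
#' samples whose group total is zero get the uninformative value 1/k for
#' the k group members. Finally all proportions are clipped to
#' [0.001, 0.999] to keep the beta likelihood away from the boundaries.
#'
#' @param usage Abundance table: columns `transcript_id`, `gene_id`,
#'   `promoter_group`, then one numeric column per sample named
#'   `<condition>_<replicate>` (e.g. `young_1`, `aged_3`). Counts or TPM.
#' @param conditions Character vector of the two condition labels; by
#'   default inferred from the sample column prefixes.
#' @return A long tibble: `transcript_id`, `gene_id`, `promoter_group`,
#'   `sample`, `condition`, `replicate`, `proportion_raw` (pre-clipping)
#'   and `proportion` (clipped).
#' @export
compute_proportions <- function(usage, conditions = NULL) {
  id_cols <- c("transcript_id", "gene_id", "promoter_group")
  stopifnot(all(id_cols %in% names(usage)))
  sample_cols <- setdiff(names(usage), id_cols)
  cond_of <- sub("_[^_]*$", "", sample_cols)
  if (is.null(conditions)) conditions <- unique(cond_of)
  if (length(conditions) != 2L) {
    rlang::abort("exactly two conditions are required")
  }
  long <- usage |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample",
                        values_to = "abundance") |>
    dplyr::mutate(condition = sub("_[^_]*$", "", .data$sample),
                  replicate = sub("^.*_", "", .data$sample))
  # filter: a group needs at least one non-zero count in both conditions
  keep <- long |>
    dplyr::group_by(.data$gene_id, .data$promoter_group, .data$condition) |>
    dplyr::summarise(any_nz = any(.data$abundance > 0), .groups = "drop") |>
    dplyr::group_by(.data$gene_id, .data$promoter_group) |>
    dplyr::summarise(keep = all(.data$any_nz), .groups = "drop")
  long <- long |>
    dplyr::inner_join(dplyr::filter(keep, .data$keep),
                      by = c("gene_id", "promoter_group")) |>
    dplyr::select(-"keep")
  zero_totals <- 0L
  out <- long |>
    dplyr::group_by(.data$gene_id, .data$promoter_group, .data$sample) |>
    dplyr::mutate(
      .total = sum(.data$abundance),
      proportion_raw = dplyr::if_else(.data$.total > 0,
                                      .data$abundance / .data$.total,
                                      1 / dplyr::n())
    ) |>
    dplyr::ungroup()
  n_zero <- out |>
    dplyr::distinct(.data$gene_id, .data$promoter_group, .data$sample,
                    .data$.total) |>
    dplyr::filter(.data$.total == 0) |>
    nrow()
  if (n_zero > 0) {
    rlang::warn(sprintf(
      "%d retained group/sample combinations had zero total; set to 1/k",
      n_zero))
  }
  out |>
    dplyr::mutate(proportion = pmin(pmax(.data$proportion_raw, 0.001), 0.999)) |>
    dplyr::select("transcript_id", "gene_id", "promoter_group", "sample",
                  "condition", "replicate", "proportion_raw", "proportion")
}

#' Fit the Bayesian beta model for differential isoform usage
#'
#' Replicate usage proportions of each transcript are modelled, per
#' condition, as draws from a Beta(alpha, beta) distribution with
#' weakly-informative Gamma(shape = 5, scale = 1) priors on both shape
#' parameters. The posterior is sampled by MCMC (JAGS) over all
#' transcripts jointly (parameters are independent across transcripts, so
#' the joint fit equals per-transcript fits while paying one model
#' compilation). From the posterior draws of the mean usage
#' mu_c = alpha_c / (alpha_c + beta_c) the model derives the log2
#' fold-change of usage (treatment over reference), its 95% highest
#' posterior density interval, and the posterior probability of a usage
#' increase in each direction.
#'
#' A transcript is significantly differentially used iff the 95% HPD of
#' its log2 fold-change excludes zero and max(prob_up, prob_down) > 0.95.
#' Chains must pass a split-R-hat convergence check (threshold 1.1, via
#' coda); non-convergent transcripts are excluded from calls with a
#' warning.
#'
#' @param proportions Output of [compute_proportions()].
#' @param reference,treatment Condition labels; `log2fc > 0` means higher
#'   usage in `treatment`.
#' @param seed Integer seed controlling the MCMC chains.
#' @param chains Number of chains (>= 2).
#' @param draws Posterior draws per chain after warm-up.
#' @param adapt,burnin JAGS adaptation and burn-in iterations.
#' @return A `beta_usage_fit` object; `tidy()` gives the per-transcript
#'   summary (`mu_ref`, `mu_trt`, `log2fc`, `hpd_lower`, `hpd_upper`,
#'   `prob_up`, `prob_down`, `rhat`, `converged`, `significant`,
#'   `direction`), `glance()` the fit-level summary.
#' @export
fit_beta_model <- function(proportions, reference = "young",
                           treatment = "aged", seed = 1L, chains = 2L,
                           draws = 2000L, adapt = 500L, burnin = 500L) {
  stopifnot(chains >= 2L)
  conds <- c(reference, treatment)
  d <- proportions |>
    dplyr::filter(.data$condition %in% conds) |>
    dplyr::mutate(cid = match(.data$condition, conds))
  tids <- unique(d$transcript_id)
  d$tid <- match(d$transcript_id, tids)
  n_tx <- length(tids)
  model_str <- "model {
    for (i in 1:N) { y[i] ~ dbeta(alpha[tid[i], cid[i]], beta[tid[i], cid[i]]) }
    for (t in 1:T) { for (c in 1:2) {
      alpha[t, c] ~ dgamma(5, 1)
      beta[t, c] ~ dgamma(5, 1)
      mu[t, c] <- alpha[t, c] / (alpha[t, c] + beta[t, c])
    } }
  }"
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + i) %% .Machine$integer.max)
  })
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = d$proportion, tid = d$tid,
                                      cid = d$cid, N = nrow(d), T = n_tx),
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = TRUE)
  update(jm, burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "mu", n.iter = draws, progress.bar = "none")
  rhat <- coda::gelman.diag(samp, multivariate = FALSE)$psrf[, 1]
  # pool chains: matrix (chains*draws) x (T*2)
  mu <- do.call(rbind, lapply(samp, as.matrix))
  col_of <- function(t, c) paste0("mu[", t, ",", c, "]")
  summary <- purrr::map_dfr(seq_len(n_tx), function(t) {
    mu_ref <- mu[, col_of(t, 1)]
    mu_trt <- mu[, col_of(t, 2)]
    l2 <- log2(mu_trt / mu_ref)
    hpd <- hpd_interval(l2, 0.95)
    prob_up <- mean(l2 > 0)
    r <- max(rhat[c(col_of(t, 1), col_of(t, 2))])
    tibble::tibble(
      transcript_id = tids[t],
      mu_ref = mean(mu_ref), mu_trt = mean(mu_trt),
      log2fc = stats::median(l2),
      hpd_lower = hpd[1], hpd_upper = hpd[2],
      prob_up = prob_up, prob_down = 1 - prob_up,
      rhat = r, converged = is.finite(r) && r < 1.1
    )
  })
  if (any(!summary$converged)) {
    rlang::warn(sprintf("%d transcripts failed the convergence check (Rhat >= 1.1) and are excluded from calls",
                        sum(!summary$converged)))
  }
  summary <- call_differential(summary)
  meta <- proportions |>
    dplyr::distinct(.data$transcript_id, .data$gene_id, .data$promoter_group)
  summary <- dplyr::left_join(summary, meta, by = "transcript_id") |>
    dplyr::relocate("gene_id", "promoter_group", .after = "transcript_id")
  structure(list(summary = summary, log2fc_draws = NULL,
                 reference = reference, treatment = treatment,
                 chains = chains, draws = draws, seed = seed),
            class = "beta_usage_fit")
}

#' Apply the differential-usage decision rule
#'
#' A transcript is significant iff its 95% HPD interval of log2 usage
#' fold-change excludes zero and the posterior probability of a usage
#' shift in one direction exceeds 0.95; non-convergent transcripts are
#' never called. Direction is the sign of the posterior median log2fc.
#'
#' @param summary Per-transcript posterior summary tibble (from
#'   [fit_beta_model()]) with columns `hpd_lower`, `hpd_upper`, `prob_up`,
#'   `prob_down`, `log2fc`, `converged`.
#' @return The tibble with `significant` (logical) and `direction`
#'   (`"up"`, `"down"` or `"none"`) columns.
#' @export
call_differential <- function(summary) {
  if (inherits(summary, "beta_usage_fit")) summary <- summary$summary
  summary |>
    dplyr::mutate(
      significant = .data$converged &
        (.data$hpd_lower > 0 | .data$hpd_upper < 0) &
        pmax(.data$prob_up, .data$prob_down) > 0.95,
      direction = dplyr::case_when(
        !.data$significant ~ "none",
        .data$log2fc > 0 ~ "up",
        TRUE ~ "down"
      )
    )
}

#' Shortest 95% highest posterior density interval
#'
#' The HPD interval is the shortest contiguous interval containing the
#' requested fraction of the draws: over the sorted draws, every window of
#' ceiling(prob * n) consecutive values is a candidate and the narrowest
#' one wins.
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Coverage probability (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(prob * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' @export
print.beta_usage_fit <- function(x, ...) {
  cat(sprintf("<beta_usage_fit> %d transcripts, %s vs %s, %d chains x %d draws\n",
              nrow(x$summary), x$treatment, x$reference, x$chains, x$draws))
  cat(sprintf("  significant: %d up, %d down\n",
              sum(x$summary$direction == "up"),
              sum(x$summary$direction == "down")))
  invisible(x)
}

#' @rdname fit_beta_model
#' @param x,object A `beta_usage_fit`.
#' @param ... Unused.
#' @export
tidy.beta_usage_fit <- function(x, ...) x$summary

#' @rdname fit_beta_model
#' @export
glance.beta_usage_fit <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_transcripts = nrow(s),
    n_significant = sum(s$significant, na.rm = TRUE),
    n_up = sum(s$direction == "up"), n_down = sum(s$direction == "down"),
    n_nonconverged = sum(!s$converged),
    chains = x$chains, draws = x$draws, seed = x$seed
  )
}

#' Volcano-style plot of a usage fit
#'
#' @param object A `beta_usage_fit`.
#' @param ... Unused.
#' @return A ggplot object: posterior median log2 usage fold-change vs the
#'   posterior probability of the dominant direction.
#' @export
autoplot.beta_usage_fit <- function(object, ...) {
  d <- object$summary |>
    dplyr::mutate(prob_max = pmax(.data$prob_up, .data$prob_down))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$prob_max,
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            none = "grey60")) +
    ggplot2::labs(x = sprintf("log2 usage fold-change (%s / %s)",
                              object$treatment, object$reference),
                  y = "max posterior direction probability")
}
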