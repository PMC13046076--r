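# Transcript-coordinate arithmetic ------------------------------------

#' Transcript length from an exon chain
#' @param exons Exon rows of one transcript.
#' @return Total exonic length in nt.
#' @export
transcript_length <- function(exons) sum(exons$end - exons$start)

# Project a transcript-coordinate half-open interval onto the genome.
# Transcript coordinates run 5'->3' in the transcription direction, so the
# walk is ascending-genomic on + and descending-genomic on -.
project_interval <- function(t_start, t_end, exons, strand) {
  ex <- exons[order(exons$start), ]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  out <- list()
  offset <- 0
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i]
    lo <- max(t_start, offset)
    hi <- min(t_end, offset + w)
    if (lo < hi) {
      if (strand == "+") {
        g_s <- ex$start[i] + (lo - offset)
        g_e <- ex$start[i] + (hi - offset)
      } else {
        g_e <- ex$end[i] - (lo - offset)
        g_s <- ex$end[i] - (hi - offset)
      }
      out[[length(out) + 1]] <- c(g_s, g_e)
    }
    offset <- offset + w
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  tibble::tibble(start = m[, 1], end = m[, 2])
}

# Genomic base coordinate of a single transcript position.
transcript_to_genomic <- function(pos, exons, strand) {
  iv <- project_interval(pos, pos + 1, exons, strand)
  iv$start[1]
}

#' Annotate the open reading frame of a transcript
#'
#' When a CDS interval is supplied it is passed through unmodified;
#' otherwise a stand-in prediction is used: the longest ATG-initiated
#' reading frame ending in a stop codon (the stop codon is included in
#' the CDS interval). The stop codon's transcript position is mapped
#' through the exon chain to decide whether termination falls in the
#' transcript's last exon ("Last") or upstream of it ("Not Last").
#'
#' @param transcript_id Identifier.
#' @param exons Exon rows of the transcript.
#' @param sequence Spliced transcript nucleotide sequence (5'->3');
#'   required unless `cds` is given.
#' @param cds Optional externally supplied CDS as `c(start, end)` in
#'   transcript coordinates (0-based half-open, length divisible by 3,
#'   stop codon included).
#' @return A one-row tibble (`transcript_id`, `cds_start`, `cds_end`,
#'   `stop_position`, `stop_in_last_exon`), or a zero-row tibble when no
#'   ORF is found.
#' @export
annotate_orf <- function(transcript_id, exons, sequence = NULL, cds = NULL) {
  tlen <- transcript_length(exons)
  if (is.null(cds)) {
    if (is.null(sequence)) rlang::abort("need a sequence or a CDS interval")
    if (nchar(sequence) != tlen) {
      rlang::abort("sequence length does not match the exon chain")
    }
    cds <- longest_orf(toupper(sequence))
    if (is.null(cds)) {
      return(tibble::tibble(transcript_id = character(),
                            cds_start = numeric(), cds_end = numeric(),
                            stop_position = numeric(),
                            stop_in_last_exon = logical()))
    }
  } else {
    stopifnot(length(cds) == 2L, (cds[2] - cds[1]) %% 3 == 0,
              cds[1] >= 0, cds[2] <= tlen)
  }
  stop_position <- cds[2] - 3
  # transcript-coordinate extent of the transcription-last exon
  last_len <- if (exons$strand[1] == "+") {
    e <- exons[which.max(exons$end), ]
    e$end - e$start
  } else {
    e <- exons[which.min(exons$start), ]
    e$end - e$start
  }
  tibble::tibble(
    transcript_id = transcript_id,
    cds_start = cds[1], cds_end = cds[2],
    stop_position = stop_position,
    stop_in_last_exon = stop_position >= tlen - last_len
  )
}

# Longest ATG..stop reading frame; leftmost wins ties. Returns
# c(start, end) transcript coordinates including the stop codon, or NULL.
longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  best_len <- 0
  codon_at <- function(i) substr(seq, i, i + 2)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    open_start <- NA
    i <- frame + 1
    while (i + 2 <= n) {
      cod <- codon_at(i)
      if (is.na(open_start) && cod == "ATG") open_start <- i
      if (!is.na(open_start) && cod %in% stops) {
        len <- i + 3 - open_start
        if (len > best_len) {
          best_len <- len
          best <- c(open_start - 1, i + 2)
        }
        open_start <- NA
      }
      i <- i + 3
    }
  }
  best
}

#' Map a protein-domain hit to transcript and genomic coordinates
#'
#' Amino-acid coordinates (1-based inclusive, as in Pfam tables) are
#' converted to transcript nucleotide coordinates relative to the CDS
#' start and projected through the exon chain onto the genome; a domain
#' spanning an exon junction yields several genomic intervals whose
#' lengths sum to 3x the amino-acid length.
#'
#' @param pfam_id Domain identifier.
#' @param aa_start,aa_end Amino-acid interval (1-based inclusive).
#' @param orf [annotate_orf()] row for the transcript.
#' @param exons Exon rows of the transcript.
#' @return A one-row tibble: `transcript_id`, `pfam_id`, `aa_start`,
#'   `aa_end`, `nt_start`, `nt_end` (transcript coordinates),
#'   `genomic_intervals` (list of tibbles), and the transcription-order
#'   first/last genomic coding base (`start_pos_genomic`,
#'   `stop_pos_genomic`).
#' @export
map_domain_to_transcript <- function(pfam_id, aa_start, aa_end, orf, exons) {
  protein_len <- (orf$cds_end - orf$cds_start - 3) / 3
  if (aa_start < 1 || aa_end > protein_len || aa_start > aa_end) {
    rlang::abort(sprintf("amino-acid interval %d-%d outside protein of %d aa",
                         aa_start, aa_end, protein_len))
  }
  nt_start <- orf$cds_start + 3 * (aa_start - 1)
  nt_end <- orf$cds_start + 3 * aa_end
  strand <- exons$strand[1]
  g <- project_interval(nt_start, nt_end, exons, strand)
  first_base <- transcript_to_genomic(nt_start, exons, strand)
  last_base <- transcript_to_genomic(nt_end - 1, exons, strand)
  tibble::tibble(
    transcript_id = orf$transcript_id, pfam_id = pfam_id,
    aa_start = aa_start, aa_end = aa_end,
    nt_start = nt_start, nt_end = nt_end,
    genomic_intervals = list(g),
    start_pos_genomic = first_base, stop_pos_genomic = last_base
  )
}

#' Classify the coding consequence of a splicing event
#'
#' Tags an event interval by its relationship to a transcript's CDS and
#' mapped domains: `in_orf` when it intersects the genomic CDS
#' projection, `contains_stop` when it covers the stop codon's first
#' base, `domain_body` when it intersects any domain interval, and
#' `domain_start` / `domain_stop` when it covers a domain's first / last
#' genomic coding position. Site events (zero-width boundary coordinates)
#' are treated as their single junction position.
#'
#' @param event_start,event_end Genomic event interval (half-open;
#'   `start == end` for splice-site events).
#' @param orf [annotate_orf()] row.
#' @param exons Exon rows of the transcript.
#' @param domains Optional [map_domain_to_transcript()] rows for the
#'   transcript.
#' @return Character vector of tags (possibly empty).
#' @export
classify_event_consequence <- function(event_start, event_end, orf, exons,
                                       domains = NULL) {
  strand <- exons$strand[1]
  q_s <- event_start
  q_e <- max(event_end, event_start + 1)  # point events span their base
  hits_interval <- function(s, e) q_s < e & q_e > s
  covers_base <- function(b) q_s <= b & b < q_e
  tags <- character(0)
  cds_g <- project_interval(orf$cds_start, orf$cds_end, exons, strand)
  if (any(hits_interval(cds_g$start, cds_g$end))) tags <- c(tags, "in_orf")
  stop_g <- transcript_to_genomic(orf$stop_position, exons, strand)
  if (covers_base(stop_g)) tags <- c(tags, "contains_stop")
  if (!is.null(domains) && nrow(domains) > 0) {
    body <- any(vapply(domains$genomic_intervals, function(g)
      any(hits_interval(g$start, g$end)), logical(1)))
    if (body) tags <- c(tags, "domain_body")
    if (any(covers_base(domains$start_pos_genomic))) {
      tags <- c(tags, "domain_start")
    }
    if (any(covers_base(domains$stop_pos_genomic))) {
      tags <- c(tags, "domain_stop")
    }
  }
  tags
}

#' Build the row-normalized domain-by-event matrix
#'
#' Counts, per Pfam domain, the splicing events of each class that
#' intersect it, row-normalizes so every row sums to 1, and assigns each
#' domain to the event class contributing the largest share (ties broken
#' by the canonical class order ALT5, ALT3, CE, IR, ALT_END). Rows are
#' ordered by average-linkage hierarchical clustering of the normalized
#' profiles (Euclidean distance).
#'
#' @param tagged A tibble with one row per intersecting (domain, event)
#'   pair: columns `pfam_id` and `event_class`.
#' @param classes Event-class universe for the columns.
#' @return A `domain_event_matrix`: list with `matrix` (row-stochastic),
#'   `counts`, and `dominant` (named class per domain).
#' @export
build_domain_event_matrix <- function(tagged,
                                      classes = c("ALT5", "ALT3", "CE",
                                                  "IR", "ALT_END")) {
  tagged <- dplyr::filter(tagged, .data$event_class %in% classes)
  if (nrow(tagged) == 0) rlang::abort("no events intersect any domain")
  counts <- table(factor(tagged$pfam_id),
                  factor(tagged$event_class, levels = classes))
  counts <- unclass(counts)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  mat <- counts / rowSums(counts)
  dominant <- classes[apply(mat, 1, which.max)]
  names(dominant) <- rownames(mat)
  if (nrow(mat) > 2) {
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "average")
    mat <- mat[hc$order, , drop = FALSE]
    counts <- counts[hc$order, , drop = FALSE]
    dominant <- dominant[hc$order]
  }
  structure(list(matrix = mat, counts = counts, dominant = dominant),
            class = "domain_event_matrix")
}

#' @export
print.domain_event_matrix <- function(x, ...) {
  cat(sprintf("<domain_event_matrix> %d domains x %d event classes\n",
              nrow(x$matrix), ncol(x$matrix)))
  tab <- table(x$dominant)
  cat("  dominant classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the domain-by-event matrix
#' @param x A `domain_event_matrix`.
#' @param ... Unused.
#' @return A long tibble: `pfam_id`, `event_class`, `count`, `fraction`,
#'   `dominant`.
#' @export
tidy.domain_event_matrix <- function(x, ...) {
  idx <- expand.grid(pfam_id = rownames(x$matrix),
                     event_class = colnames(x$matrix),
                     stringsAsFactors = FALSE)
  tibble::tibble(
    pfam_id = idx$pfam_id, event_class = idx$event_class,
    count = x$counts[cbind(idx$pfam_id, idx$event_class)],
    fraction = x$matrix[cbind(idx$pfam_id, idx$event_class)],
    dominant = unname(x$dominant[idx$pfam_id])
  )
}

#' Heatmap of the domain-by-event matrix
#' @param object A `domain_event_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot of the row-normalized fractions.
#' @export
autoplot.domain_event_matrix <- function(object, ...) {
  d <- tidy.domain_event_matrix(object)
  d$pfam_id <- factor(d$pfam_id, levels = rownames(object$matrix))
  d$event_class <- factor(d$event_class, levels = colnames(object$matrix))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$event_class, y = .data$pfam_id,
                                  fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "event class", y = "Pfam domain",
                  fill = "row fraction")
}
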