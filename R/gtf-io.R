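#' Read transcript models from a GTF file
#'
#' Parses exon rows of a collapsed transcriptome GTF (Ensembl attribute
#' dialect, as produced by long-read collapsing tools such as FLAIR) into a
#' tidy exon table. GTF 1-based inclusive coordinates are converted to
#' 0-based half-open intervals; all downstream coordinate arithmetic in the
#' package uses that convention and converts back only on write.
#'
#' @param path Path to a GTF file. Only rows whose feature column starts
#'   with `"exon"` are used; other rows (gene, transcript, CDS, ...) are
#'   ignored.
#' @return A tibble with one row per exon: `seqname`, `source`, `gene_id`,
#'   `transcript_id`, `strand`, `start`, `end` (0-based half-open), sorted
#'   by gene, transcript and ascending genomic position.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tx\texon\t101\t200\t.\t+\t.",
#'                  'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' read_gtf(gtf)
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("GTF file not found: ", path))
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    rlang::abort("GTF file contains no feature rows")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    rlang::abort(sprintf("malformed GTF row (fewer than 9 columns) at line %d",
                         line_no[which(nf < 9L)[1]]))
  }
  feat <- vapply(fields, `[[`, "", 3L)
  is_exon <- startsWith(feat, "exon")
  fields <- fields[is_exon]
  line_no <- line_no[is_exon]
  if (length(fields) == 0L) {
    rlang::abort("GTF file contains no exon rows")
  }
  attrs <- vapply(fields, `[[`, "", 9L)
  gene_id <- gtf_attr(attrs, "gene_id")
  transcript_id <- gtf_attr(attrs, "transcript_id")
  for (nm in c("gene_id", "transcript_id")) {
    vals <- if (nm == "gene_id") gene_id else transcript_id
    if (anyNA(vals)) {
      rlang::abort(sprintf("exon row missing %s attribute at line %d",
                           nm, line_no[which(is.na(vals))[1]]))
    }
  }
  exons <- tibble::tibble(
    seqname = vapply(fields, `[[`, "", 1L),
    source = vapply(fields, `[[`, "", 2L),
    gene_id = gene_id,
    transcript_id = transcript_id,
    strand = vapply(fields, `[[`, "", 7L),
    start = as.numeric(vapply(fields, `[[`, "", 4L)) - 1,
    end = as.numeric(vapply(fields, `[[`, "", 5L))
  )
  bad_strand <- exons |>
    dplyr::distinct(.data$transcript_id, .data$strand) |>
    dplyr::count(.data$transcript_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(bad_strand) > 0L) {
    rlang::abort(paste0("mixed strands within transcript ",
                        bad_strand$transcript_id[1]))
  }
  exons |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start) |>
    validate_exons()
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(paste0(key, ' "'), attrs, fixed = TRUE)
  out[hit] <- sub(paste0('^', key, ' "([^"]*)"$'), "\\1", m)
  out
}

validate_exons <- function(exons) {
  chk <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      ok = all(diff(.data$start) > 0) && all(.data$end[-dplyr::n()] < .data$start[-1]),
      .groups = "drop"
    )
  bad <- chk$transcript_id[!chk$ok]
  if (length(bad) > 0L) {
    rlang::abort(paste0("overlapping or unordered exons in transcript ", bad[1]))
  }
  exons
}

#' Write transcript models (optionally annotated) to a GTF file
#'
#' Writes one transcript row and its exon rows per transcript, restoring
#' 1-based inclusive coordinates. When an annotation from
#' [annotate_transcriptome()] is supplied, the exon feature column carries
#' the composite splicing labels (`exon`, `exon_ce`, `exon_alt3_ce`, ...)
#' and transcript rows carry the promoter-group identifier and the numeric
#' splicing attributes (`a5`, `a3`, `ce`, `i`, their group totals `a5t`,
#' `a3t`, `cet`, `it`, and the fractional positions `ap`, `ae`).
#'
#' @param exons Exon table as returned by [read_gtf()].
#' @param path Output file path.
#' @param annotation Optional `splice_annotation` from
#'   [annotate_transcriptome()].
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, annotation = NULL) {
  labels <- NULL
  tattr <- NULL
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "splice_annotation"))
    labels <- annotation$exon_labels
    tattr <- annotation$transcript_attributes
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) rlang::abort(paste0("cannot write to ", path)))
  on.exit(close(con))
  tx <- exons |>
    dplyr::group_by(.data$seqname, .data$source, .data$gene_id,
                    .data$transcript_id, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene_id, .data$transcript_id)
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        t$gene_id, t$transcript_id)
    if (!is.null(tattr)) {
      a <- tattr[tattr$transcript_id == t$transcript_id, ]
      if (nrow(a) == 1L) {
        attr_str <- paste0(attr_str, sprintf(
          ' promoter_group "%s"; a5 "%d"; a3 "%d"; ce "%d"; i "%d"; a5t "%d"; a3t "%d"; cet "%d"; it "%d"; ap "%g"; ae "%g";',
          a$promoter_group, a$a5, a$a3, a$ce, a$i,
          a$a5t, a$a3t, a$cet, a$it, a$ap, a$ae))
      }
    }
    writeLines(paste(t$seqname, t$source, "transcript",
                     format_coord(t$start + 1), format_coord(t$end),
                     ".", t$strand, ".", attr_str, sep = "\t"), con)
    ex <- exons[exons$transcript_id == t$transcript_id &
                  exons$gene_id == t$gene_id, ]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex))) {
      e <- ex[j, ]
      feat <- "exon"
      if (!is.null(labels)) {
        l <- labels$label[labels$gene_id == e$gene_id &
                            labels$transcript_id == e$transcript_id &
                            labels$start == e$start & labels$end == e$end]
        if (length(l) == 1L) feat <- l
      }
      writeLines(paste(e$seqname, e$source, feat,
                       format_coord(e$start + 1), format_coord(e$end),
                       ".", e$strand, ".",
                       sprintf('gene_id "%s"; transcript_id "%s";',
                               e$gene_id, e$transcript_id), sep = "\t"), con)
    }
  }
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
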