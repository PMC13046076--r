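#' Assess 3' tail uniqueness within promoter groups
#'
#' For isoform-resolvable target selection, the terminal 300 nt of each
#' transcript is split into two subwindows matching a 210/90 paired-end
#' read design: window A covers positions -300..-210 (90 nt) and window B
#' positions -150..0 (150 nt) relative to the 3' end. A window is unique
#' iff its exact sequence occurs in no group co-member's corresponding
#' window; a transcript is tail-unique when either window is unique.
#' Transcripts shorter than 300 nt are evaluated on the available suffix
#' and flagged `truncated`. Singleton groups are tail-unique vacuously.
#'
#' @param seqs A tibble with `transcript_id` and `sequence`; optional
#'   grouping columns `gene_id` / `promoter_group` scope the co-member
#'   comparison (otherwise the whole table is one group).
#' @return A tibble per transcript: `window_a`, `window_b`, `unique_a`,
#'   `unique_b`, `tail_unique`, `truncated`.
#' @export
tail_uniqueness <- function(seqs) {
  if (nrow(seqs) == 0) rlang::abort("empty group")
  group_cols <- intersect(c("gene_id", "promoter_group"), names(seqs))
  windows <- function(s) {
    len <- nchar(s)
    wa <- if (len >= 211) substr(s, max(1, len - 299), len - 210) else ""
    wb <- substr(s, max(1, len - 149), len)
    c(wa, wb)
  }
  w <- t(vapply(seqs$sequence, windows, character(2), USE.NAMES = FALSE))
  seqs$window_a <- w[, 1]
  seqs$window_b <- w[, 2]
  seqs$truncated <- nchar(seqs$sequence) < 300
  seqs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(
      unique_a = !duplicated(.data$window_a) &
        !duplicated(.data$window_a, fromLast = TRUE),
      unique_b = !duplicated(.data$window_b) &
        !duplicated(.data$window_b, fromLast = TRUE),
      tail_unique = .data$unique_a | .data$unique_b
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"sequence")
}

#' Correct raw cell barcodes against a whitelist
#'
#' Substitution-only Hamming-distance assignment with radius 2: a raw
#' barcode is assigned to the whitelist entry at minimal Hamming distance
#' when that distance is at most 2 and the minimizer is unique; ties at
#' the minimal distance, or no entry within the radius, leave the barcode
#' unassigned. Exact whitelist members always map to themselves and the
#' correction is idempotent.
#'
#' @param raw Character vector of observed barcodes.
#' @param whitelist Character vector of reference barcodes (all the same
#'   length as the raw barcodes).
#' @param radius Maximum substitutions (default 2).
#' @return A tibble: `raw`, `assigned` (NA when unassigned), `distance`,
#'   `n_best` (entries tied at the minimal distance).
#' @export
correct_barcodes <- function(raw, whitelist, radius = 2) {
  if (length(whitelist) == 0) rlang::abort("empty whitelist")
  lens <- unique(nchar(c(raw, whitelist)))
  if (length(lens) != 1L) {
    rlang::abort("all barcodes must have the same length")
  }
  wl <- do.call(rbind, strsplit(whitelist, ""))
  purrr::map_dfr(raw, function(b) {
    bc <- strsplit(b, "")[[1]]
    d <- rowSums(wl != matrix(bc, nrow(wl), lens, byrow = TRUE))
    dmin <- min(d)
    best <- which(d == dmin)
    ok <- dmin <= radius && length(best) == 1L
    tibble::tibble(raw = b,
                   assigned = if (ok) whitelist[best] else NA_character_,
                   distance = dmin, n_best = length(best))
  })
}
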