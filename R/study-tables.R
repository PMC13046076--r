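#' Reference contingency tables from an aging-ovary splicing study
#'
#' Published summary tables from a long-read differential-splicing
#' analysis of young versus reproductively aged mouse ovaries under two
#' gonadotropin stimulations (PMSG and PMSG + hCG): single- versus
#' multi-transcript promoter usage at age-biased versus age-neutral loci,
#' stop-codon position (last versus upstream exon), and the splice-class
#' composition of Pfam-domain body/start/stop alterations. They serve as
#' worked inputs for the contingency layer ([chisq_test()],
#' [fisher_2x2()]): each printed chi-square statistic and odds ratio is
#' recomputable from these counts.
#'
#' @return A named list of count matrices; rows are the affected
#'   (age-biased) and neutral (age-neutral) sets, columns the outcome
#'   categories in the order they are reported.
#' @export
study_contingency_tables <- function() {
  path <- system.file("extdata", "study_contingency_tables.tsv",
                      package = "splicetide", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (an in unique(d$analysis)) {
    da <- d[d$analysis == an, ]
    cats <- unique(da$category)
    groups <- unique(da$group)
    m <- matrix(NA_real_, length(groups), length(cats),
                dimnames = list(groups, cats))
    for (i in seq_len(nrow(da))) {
      m[da$group[i], da$category[i]] <- da$count[i]
    }
    out[[an]] <- m
  }
  out
}
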