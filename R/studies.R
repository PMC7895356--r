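#' Read a multi-study non-adherence count table
#'
#' Study tables are long-format CSV with columns
#' `study_id,NoP,DoM,factor,count`: one row per (study, factor) pair that the
#' study actually observed. A factor absent from a study is "not observed" —
#' this is distinct from an observed count of zero and is excluded from that
#' study's rates (but the study's NoP still enters the pooled denominator).
#'
#' @param path CSV file path.
#' @return a `nata_studies` data frame.
#' @details Per-study invariants enforced: `NoP > 0`, `DoM >= 1`, counts
#'   `>= 0` with total count `<= NoP`, and a single consistent (NoP, DoM)
#'   pair per study id.
#' @examples
#' studies <- read_studies(nata_example("six_studies"))
#' wnar(studies, "SidEff")
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_studies(df)
}

#' @rdname read_studies
#' @param df a data frame with the same columns as the CSV.
#' @export
as_studies <- function(df) {
  need <- c("study_id", "NoP", "DoM", "factor", "count")
  if (!all(need %in% names(df)))
    stop("study table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$study_id <- as.character(df$study_id)
  df$factor <- as.character(df$factor)
  for (s in split(df, df$study_id)) {
    id <- s$study_id[1]
    if (length(unique(s$NoP)) != 1L || length(unique(s$DoM)) != 1L)
      stop("study '", id, "' has inconsistent NoP/DoM", call. = FALSE)
    if (s$NoP[1] <= 0) stop("study '", id, "': NoP must be > 0", call. = FALSE)
    if (s$DoM[1] < 1) stop("study '", id, "': DoM must be >= 1", call. = FALSE)
    if (any(s$count < 0)) stop("study '", id, "': negative count",
                               call. = FALSE)
    if (anyDuplicated(s$factor))
      stop("study '", id, "': duplicated factor rows", call. = FALSE)
    if (sum(s$count) > s$NoP[1])
      stop("study '", id, "': total non-adherent count exceeds NoP",
           call. = FALSE)
  }
  class(df) <- c("nata_studies", "data.frame")
  df
}

study_row <- function(studies, study_id, factor) {
  r <- studies[studies$study_id == study_id & studies$factor == factor, ]
  if (!nrow(r))
    stop("factor '", factor, "' not observed in study '", study_id,
         "' (not observed is distinct from zero)", call. = FALSE)
  r
}

#' Non-adherence count (NAC) of one study
#'
#' The NAC is the number of non-adherent participants: the sum of the counts
#' of all observed non-adherence factors in the study.
#'
#' @param studies a `nata_studies` table.
#' @param study_id which study.
#' @return integer count.
#' @export
nac <- function(studies, study_id) {
  stopifnot(inherits(studies, "nata_studies"))
  sum(studies$count[studies$study_id == study_id])
}

#' Per-study non-adherence rate and proportion
#'
#' `nars()` is the per-study non-adherence proportion for one factor:
#' count / NoP (dimensionless). `nar()` is its per-day rate: NARS / DoM —
#' the study-level hazard of that factor.
#'
#' @inheritParams nac
#' @param factor factor id; must be observed in the study (an unobserved
#'   factor is an error, not zero).
#' @return `nars()` a proportion in `[0, 1]`; `nar()` a rate per day.
#' @examples
#' studies <- read_studies(nata_example("six_studies"))
#' nars(studies, "S1", "NoTabs")  # 5 / 201
#' nar(studies, "S1", "NoTabs")   # (5 / 201) / 10
#' @export
nars <- function(studies, study_id, factor) {
  stopifnot(inherits(studies, "nata_studies"))
  r <- study_row(studies, study_id, factor)
  r$count / r$NoP
}

#' @rdname nars
#' @export
nar <- function(studies, study_id, factor) {
  stopifnot(inherits(studies, "nata_studies"))
  r <- study_row(studies, study_id, factor)
  r$count / r$NoP / r$DoM
}

#' Pooled participant total across studies
#' @inheritParams nac
#' @return `sum(NoP)` over all studies in the table.
#' @export
grand_nop <- function(studies) {
  stopifnot(inherits(studies, "nata_studies"))
  nop <- tapply(studies$NoP, studies$study_id, `[`, 1L)
  sum(nop)
}

#' NoP-weighted pooled non-adherence rate (WNAR)
#'
#' Pools a factor's per-study daily rates across studies, weighting each
#' study's NAR by its share of the grand participant total:
#' `sum_i NAR_i * NoP_i / GrandNoP`. The denominator sums NoP over *all*
#' studies in the table, including studies that did not observe the factor
#' (their numerator contribution is zero); this makes the WNAR of a factor
#' seen in a single small study appropriately small.
#'
#' @inheritParams nars
#' @param studies a `nata_studies` table; at least one study must observe
#'   `factor`.
#' @return pooled rate per day, always within the range of the contributing
#'   per-study NARs.
#' @export
wnar <- function(studies, factor) {
  stopifnot(inherits(studies, "nata_studies"))
  obs <- studies[studies$factor == factor, ]
  if (!nrow(obs))
    stop("factor '", factor, "' not observed in any study", call. = FALSE)
  sum(obs$count / obs$DoM) / grand_nop(studies)
}

#' Mean per-study NAC-to-NoP ratio
#'
#' Unweighted mean, over studies, of each study's non-adherent fraction
#' (NAC / NoP) — a crude pooled non-adherence proportion used as a sanity
#' anchor for simulated cohorts.
#'
#' @inheritParams nac
#' @return proportion in `[0, 1]`.
#' @export
mean_nac_ratio <- function(studies) {
  stopifnot(inherits(studies, "nata_studies"))
  ids <- unique(studies$study_id)
  if (!length(ids)) stop("empty study table", call. = FALSE)
  nop <- tapply(studies$NoP, studies$study_id, `[`, 1L)
  cnt <- tapply(studies$count, studies$study_id, sum)
  mean(cnt[ids] / nop[ids])
}

#' Full rate table: NARS, NAR and WNAR for every factor
#'
#' @inheritParams nac
#' @return a `nata_rate_table` list with elements `per_study` (data frame
#'   `study_id, factor, count, nars, nar`), `wnar` (named per-day rate
#'   vector) and `grand_nop`.
#' @export
rate_table <- function(studies) {
  stopifnot(inherits(studies, "nata_studies"))
  per <- studies
  per$nars <- per$count / per$NoP
  per$nar <- per$nars / per$DoM
  factors <- unique(per$factor)
  w <- vapply(factors, function(f) wnar(studies, f), 0)
  structure(list(per_study = per[c("study_id", "factor", "count",
                                   "nars", "nar")],
                 wnar = w, grand_nop = grand_nop(studies)),
            class = "nata_rate_table")
}

#' @export
print.nata_rate_table <- function(x, ...) {
  cat(sprintf("<nata_rate_table> %d factors pooled over GrandNoP = %d\n",
              length(x$wnar), x$grand_nop))
  w <- sort(x$wnar, decreasing = TRUE)
  for (f in names(w)) cat(sprintf("  %-8s WNAR = %.4g /day\n", f, w[[f]]))
  invisible(x)
}
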