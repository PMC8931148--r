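# Randomised-PAM depletion-assay statistics: PPDV, depletion logos, PAM
# wheels, sgRNA evenness indices, GUIDE-seq on:off ratios.

#' Enumerate the full randomized-PAM universe
#'
#' All `4^k` DNA strings of length `k`, lexicographically sorted. A 6-nt
#' randomized PAM library therefore has exactly 4096 members.
#'
#' @param k PAM length (default 6).
#' @return Character vector of length `4^k`.
#' @export
enumerate_pams <- function(k = 6L) {
  stopifnot(k >= 1L, k <= 10L)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}

# Normalise count input (tibble with pam/count columns, or a named vector)
# to a full-universe tibble over 4^k PAMs, absent PAMs counted 0.
as_pam_counts <- function(x, k = NULL) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble(pam = names(x), count = as.numeric(x))
  }
  stopifnot(is.data.frame(x), all(c("pam", "count") %in% names(x)))
  x <- as_tibble(x[, c("pam", "count")])
  if (nrow(x) == 0 && is.null(k)) {
    abort("cannot infer PAM length from an empty table",
          class = "pamscape_parameter_error")
  }
  lens <- unique(nchar(x$pam))
  if (length(lens) > 1L) {
    abort("PAM strings of unequal length", class = "pamscape_consistency_error")
  }
  if (is.null(k)) k <- lens
  if (length(lens) == 1L && lens != k) {
    abort("PAM length does not match k", class = "pamscape_consistency_error")
  }
  if (any(x$count < 0)) {
    abort("negative PAM counts", class = "pamscape_parameter_error")
  }
  universe <- tibble(pam = enumerate_pams(k))
  out <- left_join(universe, x, by = "pam") %>%
    mutate(count = dplyr::coalesce(count, 0))
  out
}

#' Post-selection PAM depletion values (PPDV)
#'
#' For every PAM in the `4^k` universe, the PPDV is the ratio of its
#' frequency in the selected (nuclease-exposed) library to its frequency in
#' the control library. Functional PAMs are cleaved and drop out, so PPDV
#' values well below 1 mark active PAMs; depletion efficacy is inversely
#' related to PPDV and is reported as an ascending rank (1 = most depleted).
#'
#' @param selected,control Count tables: tibbles with columns `pam`, `count`
#'   (or named numeric vectors). Absent PAMs count 0.
#' @param pseudocount Added to every count before frequencies are formed
#'   (default 0, the raw-ratio definition; 0.5 is a reasonable choice for
#'   noisy libraries). With `pseudocount = 0`, a PAM unobserved in the
#'   control has an undefined PPDV and is flagged, not an error.
#' @return A tibble of class `ppdv_tbl` with columns `pam`, `sel_count`,
#'   `ctl_count`, `ppdv`, `undefined`, `efficacy_rank` (ascending PPDV,
#'   lexicographic tie-break, undefined PPDVs ranked last).
#' @examples
#' ctl <- c(AATA = 50, AACC = 50)
#' sel <- c(AATA = 10, AACC = 90)
#' p <- compute_ppdv(sel, ctl)
#' p[p$ctl_count > 0, ]
#' @export
compute_ppdv <- function(selected, control, pseudocount = 0) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)
  sel <- as_pam_counts(selected)
  ctl <- as_pam_counts(control, k = nchar(sel$pam[1]))
  if (sum(ctl$count) <= 0) {
    abort("control library has zero total reads", class = "pamscape_parameter_error")
  }
  sel_tot <- sum(sel$count + pseudocount)
  ctl_tot <- sum(ctl$count + pseudocount)
  out <- tibble(
    pam = sel$pam,
    sel_count = sel$count,
    ctl_count = ctl$count,
    sel_freq = (sel$count + pseudocount) / sel_tot,
    ctl_freq = (ctl$count + pseudocount) / ctl_tot
  ) %>%
    mutate(
      undefined = ctl_freq == 0,
      ppdv = dplyr::if_else(undefined, NA_real_, sel_freq / ctl_freq)
    ) %>%
    arrange(is.na(ppdv), ppdv, pam) %>% # defined first, ascending, lexicographic
    mutate(efficacy_rank = row_number()) %>%
    arrange(pam) %>%
    select(pam, sel_count, ctl_count, ppdv, undefined, efficacy_rank)
  class(out) <- c("ppdv_tbl", class(out))
  out
}

#' Most-depleted PAMs by quantile
#'
#' The `floor(quantile * n_pams)` PAMs with smallest PPDV (ties broken
#' lexicographically; PAMs with undefined PPDV are never selected). The
#' top-10% depleted set is the conventional input to a depletion logo.
#'
#' @param ppdv A `ppdv_tbl` from [compute_ppdv()].
#' @param quantile Fraction in `(0, 1]` (default 0.1).
#' @return Character vector of PAM strings, in selection order.
#' @export
top_depleted <- function(ppdv, quantile = 0.1) {
  stopifnot(is.data.frame(ppdv))
  if (!(quantile > 0 && quantile <= 1)) {
    abort("quantile must be in (0, 1]", class = "pamscape_parameter_error")
  }
  if (nrow(ppdv) == 0) return(character(0))
  n_take <- floor(quantile * nrow(ppdv))
  defined <- ppdv %>% filter(!undefined) %>% arrange(ppdv, pam)
  head(defined$pam, n_take)
}

#' Position frequency matrix and log2 enrichment for a PAM set
#'
#' Builds the per-position base frequency matrix of a set of equal-length
#' PAMs (typically the top-decile depleted set) and its log2 fold-change
#' against the uniform background 0.25 — the matrix behind a depletion
#' weblogo.
#'
#' @param pams Non-empty character vector of equal-length PAM strings.
#' @return An object of class `depletion_logo`: list with `pfm`
#'   (positions x ACGT frequency matrix, rows sum to 1), `log2fc`
#'   (`log2(pfm / 0.25)`, `-Inf` where a base is absent) and `n_pams`.
#' @export
depletion_logo <- function(pams) {
  stopifnot(is.character(pams), length(pams) > 0)
  lens <- unique(nchar(pams))
  if (length(lens) != 1L) {
    abort("PAMs of unequal length", class = "pamscape_consistency_error")
  }
  m <- lens
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(pams, "")), ncol = m, byrow = TRUE)
  pfm <- t(apply(mat, 2, function(col) {
    tabulate(factor(col, levels = bases), nbins = 4) / length(col)
  }))
  dimnames(pfm) <- list(position = seq_len(m), base = bases)
  structure(
    list(pfm = pfm, log2fc = log2(pfm / 0.25), n_pams = length(pams)),
    class = "depletion_logo"
  )
}

#' @export
print.depletion_logo <- function(x, ...) {
  cat(sprintf("<depletion_logo> %d PAMs, %d positions\n",
              x$n_pams, nrow(x$pfm)))
  print(round(x$pfm, 3))
  invisible(x)
}

#' PAM-wheel weights over a nucleotide triple
#'
#' Restricted to the "positive depleted" PAMs (PPDV < 1), each PAM
#' contributes weight `1 - PPDV` to the 3-mer formed by the bases at the
#' chosen PAM positions (default 2-4); weights are normalised to sum 1.
#' This is the table behind a PAM-wheel plot.
#'
#' @param ppdv A `ppdv_tbl` from [compute_ppdv()].
#' @param positions Integer triple of 1-based PAM positions (default `2:4`).
#' @return Tibble of class `pam_wheel_tbl` with columns `trimer`, `weight`
#'   (summing to 1), sorted by descending weight. Empty, with a warning, if
#'   no PAM is depleted.
#' @export
pam_wheel <- function(ppdv, positions = 2:4) {
  stopifnot(is.data.frame(ppdv), length(positions) == 3L)
  m <- nchar(ppdv$pam[1])
  if (any(positions < 1L | positions > m)) {
    abort("positions outside PAM length", class = "pamscape_parameter_error")
  }
  depleted <- ppdv %>% filter(!undefined, ppdv < 1)
  if (nrow(depleted) == 0) {
    warn("no depleted PAMs (all PPDV >= 1); empty PAM wheel")
    out <- tibble(trimer = character(0), weight = double(0))
    class(out) <- c("pam_wheel_tbl", class(out))
    return(out)
  }
  trimers <- vapply(strsplit(depleted$pam, ""), function(ch) {
    paste(ch[positions], collapse = "")
  }, character(1))
  out <- tibble(trimer = trimers, weight = pmax(0, 1 - depleted$ppdv)) %>%
    group_by(trimer) %>%
    summarise(weight = sum(weight), .groups = "drop") %>%
    mutate(weight = weight / sum(weight)) %>%
    arrange(dplyr::desc(weight), trimer)
  class(out) <- c("pam_wheel_tbl", class(out))
  out
}

#' sgRNA evenness index
#'
#' Library-normalisation factor for pooled screens:
#' `index_i = total_reads / (N * reads_i)` with `N` the number of sgRNAs.
#' A guide at exactly average abundance has index 1; the indices satisfy
#' `sum(1 / (N * index)) = 1` identically.
#'
#' @param read_counts Tibble with columns `sgrna`, `count`, or a named
#'   numeric vector of per-guide read counts. All counts must be positive.
#' @return Tibble with columns `sgrna`, `count`, `index`; attributes `N` and
#'   `total`.
#' @export
evenness_index <- function(read_counts) {
  if (is.numeric(read_counts) && !is.null(names(read_counts))) {
    read_counts <- tibble(sgrna = names(read_counts), count = as.numeric(read_counts))
  }
  stopifnot(is.data.frame(read_counts),
            all(c("sgrna", "count") %in% names(read_counts)))
  if (any(read_counts$count <= 0)) {
    abort("all sgRNA read counts must be positive (zero-count index undefined)",
          class = "pamscape_parameter_error")
  }
  N <- nrow(read_counts)
  total <- sum(read_counts$count)
  out <- as_tibble(read_counts[, c("sgrna", "count")]) %>%
    mutate(index = total / (N * count))
  attr(out, "N") <- N
  attr(out, "total") <- total
  out
}

#' Evenness-corrected indel rate
#'
#' Multiplies a raw per-guide indel rate by the guide's evenness index,
#' capped at 1.
#'
#' @param raw_rate Raw indel fraction(s) in `[0, 1]`.
#' @param index Positive evenness index (recycled).
#' @return Corrected rate(s) in `[0, 1]`.
#' @export
corrected_indel <- function(raw_rate, index) {
  if (any(raw_rate < 0 | raw_rate > 1) || any(index < 0)) {
    abort("raw_rate must be in [0, 1] and index nonnegative",
          class = "pamscape_parameter_error")
  }
  pmin(1, raw_rate * index)
}

#' GUIDE-seq on:off read ratio
#'
#' On-target reads divided by the summed off-target reads. A site with no
#' detected off-targets uses denominator 1 (so fully specific sites remain
#' finite, plottable and rankable).
#'
#' @param on_reads Nonnegative on-target read count.
#' @param off_reads Numeric vector of per-off-target read counts (may be
#'   empty).
#' @return Nonnegative ratio.
#' @examples
#' on_off_ratio(100, c(10, 10)) # 5
#' on_off_ratio(100, numeric(0)) # 100: zero-off policy
#' @export
on_off_ratio <- function(on_reads, off_reads = numeric(0)) {
  stopifnot(length(on_reads) == 1L, on_reads >= 0, all(off_reads >= 0))
  total_off <- sum(off_reads)
  on_reads / max(1, total_off)
}

#' Per-site GUIDE-seq summaries
#'
#' @param df Tibble with columns `site_id`, `on_reads` and either a list
#'   column `off_reads` (per-off-target counts) or a numeric `total_off`.
#' @return The input with `total_off` and `ratio` columns added.
#' @export
guideseq_ratios <- function(df) {
  stopifnot(is.data.frame(df), all(c("site_id", "on_reads") %in% names(df)))
  if (!"total_off" %in% names(df)) {
    stopifnot("off_reads" %in% names(df))
    df$total_off <- vapply(df$off_reads, function(x) sum(as.numeric(x)), 0)
  }
  df %>% mutate(ratio = on_reads / pmax(1, total_off))
}

#' Tally PAM counts from fixed-layout reads
#'
#' For libraries sequenced as fixed-layout amplicons, extracts the `k`-nt PAM
#' at a fixed offset in each read and tallies counts over the full universe.
#'
#' @param reads Character vector of reads.
#' @param pam_offset 0-based offset of the PAM's first base within each read.
#' @param k PAM length (default 6).
#' @return Count tibble (`pam`, `count`) over all `4^k` PAMs; reads whose
#'   extracted PAM contains a non-ACGT character are dropped.
#' @export
count_pams_from_reads <- function(reads, pam_offset, k = 6L) {
  stopifnot(is.character(reads), pam_offset >= 0)
  pams <- substring(reads, pam_offset + 1L, pam_offset + k)
  pams <- pams[nchar(pams) == k & !stringr::str_detect(pams, "[^ACGT]")]
  tab <- table(factor(pams, levels = enumerate_pams(k)))
  tibble(pam = names(tab), count = as.numeric(tab))
}
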