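# Amplicon indel quantification with background subtraction.

#' Indel rate at a cut site from merged amplicon reads
#'
#' Aligns every merged read globally to the amplicon reference, calls a read
#' indel-positive when an insertion or deletion overlaps the `±flank` bp
#' window around the cut site, and reports the indel-positive fraction. When
#' control (no-nuclease) reads are supplied their rate is subtracted and the
#' corrected rate clamped at zero — the standard background correction for
#' sequencing and PCR artefacts. Reads whose best alignment exceeds
#' `max_mismatch_frac` mismatches over aligned columns are discarded as
#' unalignable and counted separately.
#'
#' @param reads Character vector of merged reads (>= 1).
#' @param reference Amplicon reference sequence.
#' @param cut_offset 0-based reference coordinate of the expected cut.
#' @param control_reads Optional character vector of control reads.
#' @param flank Window half-width around the cut (default 10 bp).
#' @param site_id Label carried into the output.
#' @param max_mismatch_frac QC threshold on the mismatch fraction (default
#'   0.4).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring, passed to
#'   [global_align()].
#' @return One-row tibble of class `site_indel_rate`: `site_id`, `n_reads`,
#'   `n_indel_reads`, `n_discarded`, `raw_rate`, `control_rate`,
#'   `corrected_rate`.
#' @export
indel_rate <- function(reads, reference, cut_offset,
                       control_reads = character(0), flank = 10L,
                       site_id = "site", max_mismatch_frac = 0.4,
                       match = 2, mismatch = -4, gap_open = -8,
                       gap_extend = -1) {
  stopifnot(is.character(reads), length(reads) >= 1L,
            is.character(reference), length(reference) == 1L)
  if (nchar(reference) < flank || cut_offset < 0 ||
      cut_offset > nchar(reference)) {
    abort("reference shorter than the flank window or cut_offset out of range",
          class = "pamscape_parameter_error")
  }
  tally <- function(rds) {
    n_used <- 0L
    n_indel <- 0L
    n_discard <- 0L
    for (rd in rds) {
      aln <- global_align(rd, reference, match, mismatch, gap_open, gap_extend)
      if (alignment_mismatch_frac(aln) > max_mismatch_frac) {
        n_discard <- n_discard + 1L
        next
      }
      n_used <- n_used + 1L
      if (read_has_indel_near_cut(aln, cut_offset, flank)) {
        n_indel <- n_indel + 1L
      }
    }
    list(n = n_used, indel = n_indel, discarded = n_discard,
         rate = if (n_used > 0) n_indel / n_used else NA_real_)
  }
  exp_t <- tally(reads)
  ctl_rate <- 0
  if (length(control_reads)) {
    ctl <- tally(control_reads)
    ctl_rate <- if (is.na(ctl$rate)) 0 else ctl$rate
  }
  out <- tibble(
    site_id = site_id,
    n_reads = exp_t$n,
    n_indel_reads = exp_t$indel,
    n_discarded = exp_t$discarded,
    raw_rate = exp_t$rate,
    control_rate = ctl_rate,
    corrected_rate = max(0, exp_t$rate - ctl_rate)
  )
  class(out) <- c("site_indel_rate", class(out))
  out
}
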