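# Affine-gap global alignment of amplicon reads against a reference.

#' Global alignment with affine gap penalties
#'
#' Optimal global (Needleman-Wunsch/Gotoh) alignment of a read against a
#' reference. A gap of length `k` costs `gap_open + k * gap_extend`. The
#' traceback is deterministic: at equal score, match/mismatch is preferred
#' over a deletion, and a deletion over an insertion, so repeated runs give
#' identical alignments.
#'
#' The default scoring (match +2, mismatch -4, gap open -8, gap extend -1)
#' penalises gaps strongly relative to substitutions, so sequencing
#' substitution errors never surface as indel operations.
#'
#' @param read,reference Non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An `alignment_result`: list with `score` and `ops`, a tibble of
#'   run-length-encoded operations (`op` in match/mismatch/insertion/
#'   deletion, `length`, `ref_offset`). `ref_offset` is the 0-based
#'   reference offset where the run starts; for insertions it is the
#'   boundary index the inserted bases sit before. Reference and read are
#'   both fully consumed.
#' @examples
#' global_align("ACGACGT", "ACGTACGT")$ops
#' @export
global_align <- function(read, reference, match = 2, mismatch = -4,
                         gap_open = -8, gap_extend = -1) {
  if (!is.character(read) || !is.character(reference) ||
      length(read) != 1L || length(reference) != 1L ||
      !nzchar(read) || !nzchar(reference)) {
    abort("read and reference must be single non-empty strings",
          class = "pamscape_parameter_error")
  }
  res <- gotoh_align(reference, read, match, mismatch, gap_open, gap_extend)
  structure(
    list(
      score = res$score,
      ops = tibble(
        op = res$op,
        length = as.integer(res$length),
        ref_offset = as.integer(res$ref_offset)
      ),
      read_len = nchar(read),
      ref_len = nchar(reference)
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.1f, %d op runs\n",
              x$score, nrow(x$ops)))
  print(x$ops)
  invisible(x)
}

#' Does an alignment carry an indel near the cut site?
#'
#' True when any insertion or deletion operation overlaps the window
#' `[cut_offset - flank, cut_offset + flank]` on the reference. A deletion
#' of length `l` at offset `o` occupies `[o, o + l)`; an insertion sits at
#' its boundary offset.
#'
#' @param aln An `alignment_result` from [global_align()].
#' @param cut_offset 0-based reference coordinate of the expected cut.
#' @param flank Window half-width in bp (default 10).
#' @return Logical scalar.
#' @export
read_has_indel_near_cut <- function(aln, cut_offset, flank = 10L) {
  stopifnot(inherits(aln, "alignment_result"),
            cut_offset >= 0, cut_offset <= aln$ref_len)
  lo <- cut_offset - flank
  hi <- cut_offset + flank
  ops <- aln$ops
  any(
    (ops$op == "deletion" & ops$ref_offset <= hi & ops$ref_offset + ops$length > lo) |
      (ops$op == "insertion" & ops$ref_offset >= lo & ops$ref_offset <= hi)
  )
}

# fraction of aligned (match + mismatch) columns that are mismatches
alignment_mismatch_frac <- function(aln) {
  ops <- aln$ops
  aligned <- sum(ops$length[ops$op %in% c("match", "mismatch")])
  if (aligned == 0) return(1)
  sum(ops$length[ops$op == "mismatch"]) / aligned
}
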