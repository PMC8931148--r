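# Sequence primitives: genome records, the DNA alphabet, IUPAC degeneracy.

# IUPAC degeneracy sets. Names are the codes; values the concrete bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# IUPAC complement (set-wise): complement of the degeneracy set.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Construct a genome record
#'
#' A genome record holds one sequence over the alphabet `{A,C,G,T,N}` together
#' with an identifier and a circularity flag. Lowercase input is uppercased;
#' `U` (RNA) and any other character outside the alphabet are rejected.
#'
#' @param id Non-empty record identifier.
#' @param seq DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param circular Is the record circular (e.g. a plasmid or viral episome)?
#'
#' @return An object of class `genome_record`: a list with elements `id`,
#'   `seq` (uppercased), `circular` and `length`.
#' @examples
#' genome_record("plasmid", "acgtACGT", circular = TRUE)
#' @export
genome_record <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  stopifnot(is.logical(circular), length(circular) == 1L, !is.na(circular))
  seq <- toupper(seq)
  check_dna(seq)
  structure(
    list(id = id, seq = seq, circular = circular, length = nchar(seq)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record> %s: %d bp, %s\n", x$id, x$length,
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

check_dna <- function(seq, alphabet = "ACGTN") {
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (any(nzchar(bad))) {
    abort(sprintf(
      "sequence contains characters outside {%s}: %s",
      paste(strsplit(alphabet, "")[[1]], collapse = ","),
      paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = " ")
    ), class = "pamscape_alphabet_error")
  }
  invisible(seq)
}

check_iupac <- function(motif) {
  codes <- strsplit(motif, "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (!nzchar(motif) || length(bad) > 0) {
    abort(sprintf(
      "invalid IUPAC motif '%s'%s", motif,
      if (length(bad)) paste0(" (bad codes: ", paste(bad, collapse = " "), ")") else ""
    ), class = "pamscape_alphabet_error")
  }
  invisible(motif)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. Restricted to the `{A,C,G,T,N}`
#' alphabet (`N` maps to `N`); applying it twice returns the input.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @examples
#' reverse_complement("AATA") # "TATT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  check_dna(paste(seq, collapse = ""))
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse complement for IUPAC motifs (set-wise complement).
iupac_reverse_complement <- function(motif) {
  check_iupac(motif)
  paste(rev(IUPAC_COMPLEMENT[strsplit(motif, "")[[1]]]), collapse = "")
}

#' Does a base match an IUPAC code?
#'
#' @param base Concrete base, one of `A`, `C`, `G`, `T` (vectorised).
#' @param code IUPAC degeneracy code (vectorised, recycled).
#' @return Logical: is `base` in the degeneracy set of `code`?
#'   (`N` = \{A,C,G,T\}, `R` = \{A,G\}, ...)
#' @examples
#' iupac_matches("G", "R") # TRUE
#' iupac_matches("C", "R") # FALSE
#' @export
iupac_matches <- function(base, code) {
  stopifnot(all(base %in% c("A", "C", "G", "T")))
  if (!all(code %in% names(IUPAC_SETS))) {
    abort("invalid IUPAC code", class = "pamscape_alphabet_error")
  }
  mapply(function(b, k) b %in% IUPAC_SETS[[k]], base, code, USE.NAMES = FALSE)
}

#' Is a PAM motif palindromic?
#'
#' A motif is palindromic when its concrete match set is closed under reverse
#' complement, i.e. its set-wise IUPAC reverse complement equals the motif
#' itself. Note `NNTA` is *not* palindromic as a full 4-mer (the palindrome is
#' its `TA` core, which is what makes back-to-back guide pairs possible);
#' `NTAN` or `TA` are.
#'
#' @param motif IUPAC motif string.
#' @return Logical scalar.
#' @examples
#' pam_is_palindromic("TA")   # TRUE
#' pam_is_palindromic("NTAN") # TRUE
#' pam_is_palindromic("NNTA") # FALSE (core TA is the palindrome)
#' @export
pam_is_palindromic <- function(motif) {
  check_iupac(motif)
  identical(iupac_reverse_complement(motif), motif)
}

# For motifs of the shape N^j TA N^k (all non-core positions fully
# degenerate), return list(offset = j, j = j, k = k); otherwise NULL.
# These motifs carry a palindromic TA core, the geometry behind
# back-to-back pairs.
ta_core_offset <- function(motif) {
  check_iupac(motif)
  codes <- strsplit(motif, "")[[1]]
  m <- length(codes)
  for (j in seq_len(m - 1L) - 1L) {
    if (codes[j + 1L] == "T" && j + 2L <= m && codes[j + 2L] == "A") {
      others <- codes[-(j + (1:2))]
      if (all(others == "N")) {
        return(list(offset = j, j = j, k = m - j - 2L))
      }
    }
  }
  NULL
}
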