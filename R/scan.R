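# PAM-adjacent target-site enumeration, back-to-back pair geometry, and
# direct-repeat anti-repeat search.
#
# Coordinate conventions (BED-compatible): 0-based, half-open, reported on
# the plus strand. Minus-strand features store plus-strand intervals plus a
# strand flag. On circular records an interval may wrap: its start is reduced
# modulo the record length and its end is start + width (possibly > length).

# 0-based start positions of IUPAC motif matches in a character vector.
# N in the subject never matches (degeneracy sets contain concrete bases only).
motif_match_starts <- function(chars, motif) {
  codes <- strsplit(motif, "")[[1]]
  m <- length(codes)
  L <- length(chars)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(L - m + j)] %in% IUPAC_SETS[[codes[j]]]
  }
  which(ok) - 1L
}

empty_sites <- function(record_id = character(0)) {
  tibble(
    record_id = character(0), strand = character(0),
    proto_start = integer(0), proto_end = integer(0),
    pam_start = integer(0), pam_end = integer(0),
    spacer_len = integer(0), pam_seq = character(0),
    cut_pos = integer(0), site_id = character(0)
  )
}

#' Enumerate PAM-adjacent target sites
#'
#' Scans both strands of a genome record for occurrences of an IUPAC PAM
#' motif with a full-length protospacer immediately 5' of the PAM (on the
#' site strand). On circular records sites may wrap the origin; wrapping is
#' handled by scanning the doubled sequence and keeping one canonical
#' representative per locus.
#'
#' The inferred blunt-cut coordinate is placed `cut_offset` nt 5' of the PAM
#' on the site strand (default 3, the SpCas9-style convention; double-strand
#' break mapping for this nuclease family localises cuts to the 3rd or 4th
#' base upstream of the PAM).
#'
#' @param genome A [genome_record()].
#' @param motif IUPAC PAM motif, matched immediately 3' of the protospacer on
#'   the site strand. Default `"NNTA"`.
#' @param spacer_len Protospacer length in nt (default 22, the optimal guide
#'   length for FrCas9).
#' @param cut_offset Distance (nt) of the blunt cut from the PAM-proximal end
#'   of the protospacer, on the site strand. Default 3.
#' @param drop_n Drop sites whose protospacer or PAM overlaps an `N`
#'   (default `TRUE`; set `FALSE` to retain sites with `N` only in the
#'   protospacer — the PAM itself must always match concretely).
#'
#' @return A tibble with one row per site, sorted by `(cut_pos, strand)`:
#'   `record_id`, `strand` (`"+"`/`"-"`), `proto_start`, `proto_end`,
#'   `pam_start`, `pam_end` (0-based half-open plus-strand intervals; on
#'   circular records `end` may exceed the record length, meaning the feature
#'   wraps), `spacer_len`, `pam_seq` (5'->3' on the site strand), `cut_pos`
#'   (plus-strand cut coordinate) and `site_id`. Attributes `genome_len`,
#'   `circular`, `motif` and `record_id` are attached for downstream
#'   geometry.
#' @examples
#' g <- genome_record("toy", "TTTTTTTA")
#' find_pam_sites(g, "NNTA", spacer_len = 4)
#' @export
find_pam_sites <- function(genome, motif = "NNTA", spacer_len = 22L,
                           cut_offset = 3L, drop_n = TRUE) {
  stopifnot(inherits(genome, "genome_record"))
  check_iupac(motif)
  stopifnot(spacer_len >= 1L, cut_offset >= 0L)
  spacer_len <- as.integer(spacer_len)
  cut_offset <- as.integer(cut_offset)

  L <- genome$length
  m <- nchar(motif)
  out <- empty_sites()
  finish <- function(df) {
    df <- arrange(df, cut_pos, strand)
    attr(df, "genome_len") <- L
    attr(df, "circular") <- genome$circular
    attr(df, "motif") <- motif
    attr(df, "record_id") <- genome$id
    df
  }
  if (spacer_len + m > L) return(finish(out))

  scan_seq <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  chars <- strsplit(scan_seq, "")[[1]]
  rc_motif <- iupac_reverse_complement(motif)

  # Plus strand: PAM match at s, protospacer [s - spacer_len, s).
  s_plus <- motif_match_starts(chars, motif)
  if (genome$circular) {
    s_plus <- s_plus[s_plus >= spacer_len & s_plus < spacer_len + L]
  } else {
    s_plus <- s_plus[s_plus >= spacer_len & s_plus + m <= L]
  }

  # Minus strand: plus-strand image of the PAM is revcomp(motif) at s;
  # protospacer occupies [s + m, s + m + spacer_len) on the plus strand.
  s_minus <- motif_match_starts(chars, rc_motif)
  if (genome$circular) {
    s_minus <- s_minus[s_minus < L]
  } else {
    s_minus <- s_minus[s_minus + m + spacer_len <= L]
  }

  substr_at <- function(start0, width) {
    substring(scan_seq, start0 + 1L, start0 + width)
  }

  rows <- list()
  if (length(s_plus)) {
    pam_seq <- substr_at(s_plus, m)
    proto_seq <- substr_at(s_plus - spacer_len, spacer_len)
    keep <- if (drop_n) {
      !stringr::str_detect(pam_seq, "N") & !stringr::str_detect(proto_seq, "N")
    } else {
      !stringr::str_detect(pam_seq, "N")
    }
    s <- s_plus[keep]
    rows$plus <- tibble(
      record_id = genome$id, strand = "+",
      proto_start = as.integer((s - spacer_len) %% L),
      pam_start = as.integer(s %% L),
      spacer_len = spacer_len,
      pam_seq = pam_seq[keep],
      cut_pos = as.integer((s - cut_offset) %% L)
    )
  }
  if (length(s_minus)) {
    pam_plus <- substr_at(s_minus, m)
    proto_plus <- substr_at(s_minus + m, spacer_len)
    keep <- if (drop_n) {
      !stringr::str_detect(pam_plus, "N") & !stringr::str_detect(proto_plus, "N")
    } else {
      !stringr::str_detect(pam_plus, "N")
    }
    s <- s_minus[keep]
    rows$minus <- tibble(
      record_id = genome$id, strand = "-",
      proto_start = as.integer((s + m) %% L),
      pam_start = as.integer(s %% L),
      spacer_len = spacer_len,
      pam_seq = reverse_complement(pam_plus[keep]),
      cut_pos = as.integer((s + m + cut_offset) %% L)
    )
  }
  if (length(rows)) {
    out <- bind_rows(rows) %>%
      mutate(
        proto_end = proto_start + spacer_len,
        pam_end = pam_start + !!m,
        site_id = sprintf("%s:%s:%d", record_id, strand, pam_start)
      ) %>%
      select(
        record_id, strand, proto_start, proto_end, pam_start, pam_end,
        spacer_len, pam_seq, cut_pos, site_id
      )
  }
  finish(out)
}

#' Pair back-to-back divergent sites sharing one palindromic TA core
#'
#' For a PAM motif whose only constrained positions are a central `TA`
#' (shape `N^j TA N^k`, e.g. `NNTA`), every plus-strand `TA` dinucleotide
#' with sufficient flank on both sides anchors exactly one plus-strand and
#' one minus-strand site. This pairs them: the two protospacers are
#' divergent, separated by `2*j + 2` bp (6 bp for `NNTA`: the `NNTANN`
#' core between their PAM-proximal ends).
#'
#' @param sites Site tibble from [find_pam_sites()] (one record).
#' @param motif The PAM motif; defaults to the motif attribute on `sites`.
#'
#' @return A tibble with one row per pair: `ta_pos` (plus-strand coordinate
#'   of the shared TA's T), `plus_site_id`, `minus_site_id`, the two
#'   protospacer intervals, and `protospacer_gap`.
#' @examples
#' g <- genome_record("toy", paste0(strrep("A", 10), "TA", strrep("A", 10)))
#' s <- find_pam_sites(g, "NNTA", spacer_len = 4)
#' find_back_to_back_pairs(s)
#' @export
find_back_to_back_pairs <- function(sites, motif = attr(sites, "motif")) {
  stopifnot(is.data.frame(sites))
  if (length(unique(sites$record_id)) > 1L) {
    abort("sites must come from a single record", class = "pamscape_consistency_error")
  }
  core <- ta_core_offset(motif)
  if (is.null(core)) {
    abort(
      sprintf("motif '%s' has no palindromic TA core of shape N^j TA N^k", motif),
      class = "pamscape_motif_error"
    )
  }
  L <- attr(sites, "genome_len")
  modL <- function(x) if (!is.null(L)) x %% L else x

  plus <- sites %>%
    filter(strand == "+") %>%
    mutate(ta_pos = as.integer(modL(pam_start + core$j)))
  minus <- sites %>%
    filter(strand == "-") %>%
    mutate(ta_pos = as.integer(modL(pam_start + core$k)))

  pairs <- inner_join(
    plus %>% select(
      ta_pos,
      plus_site_id = site_id, plus_proto_start = proto_start,
      plus_proto_end = proto_end
    ),
    minus %>% select(
      ta_pos,
      minus_site_id = site_id, minus_proto_start = proto_start,
      minus_proto_end = proto_end
    ),
    by = "ta_pos"
  ) %>%
    mutate(
      protospacer_gap = as.integer(modL(minus_proto_start - plus_proto_end))
    ) %>%
    arrange(ta_pos)
  pairs
}

#' Search for anti-repeats complementary to a CRISPR direct repeat
#'
#' Slides an ungapped full-length window of the direct repeat's reverse
#' complement along both strands of a genome and reports windows at or above
#' an identity threshold (the classic screen for the tracrRNA anti-repeat
#' next to a *cas9* locus). Overlapping hits on a strand are merged, keeping
#' the best identity.
#'
#' @param genome A [genome_record()].
#' @param direct_repeat Direct-repeat DNA string (`{A,C,G,T}`).
#' @param min_identity Minimum fraction identity in `(0, 1]` (default 0.8).
#' @param min_len Minimum repeat length accepted (default 15).
#' @return A tibble sorted by descending identity: `record_id`, `start`,
#'   `end` (plus-strand interval), `strand`, `identity`, `aligned_len`.
#' @export
find_antirepeats <- function(genome, direct_repeat, min_identity = 0.8,
                             min_len = 15L) {
  stopifnot(inherits(genome, "genome_record"))
  check_dna(direct_repeat, "ACGT")
  if (!(min_identity > 0 && min_identity <= 1)) {
    abort("min_identity must be in (0, 1]", class = "pamscape_parameter_error")
  }
  if (nchar(direct_repeat) < min_len) {
    abort("direct_repeat shorter than min_len", class = "pamscape_parameter_error")
  }
  m <- nchar(direct_repeat)
  L <- genome$length
  empty <- tibble(
    record_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), identity = double(0), aligned_len = integer(0)
  )
  if (L < m) return(empty)

  scan_seq <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  chars <- strsplit(scan_seq, "")[[1]]
  n_start <- if (genome$circular) L else L - m + 1L

  window_identity <- function(target) {
    tchars <- strsplit(target, "")[[1]]
    acc <- numeric(n_start)
    for (j in seq_len(m)) {
      acc <- acc + (chars[j:(n_start + j - 1L)] == tchars[j])
    }
    acc / m
  }

  # Plus-strand anti-repeat: window matches revcomp(direct_repeat).
  # Minus-strand anti-repeat: minus window matches revcomp(DR), i.e. the
  # plus-strand window matches the DR itself.
  hit_rows <- function(ident, strand) {
    idx <- which(ident >= min_identity)
    if (!length(idx)) return(NULL)
    tibble(
      record_id = genome$id,
      start = as.integer((idx - 1L) %% L), width = m,
      strand = strand, identity = ident[idx], aligned_len = m
    )
  }
  hits <- bind_rows(
    hit_rows(window_identity(reverse_complement(direct_repeat)), "+"),
    hit_rows(window_identity(direct_repeat), "-")
  )
  if (is.null(hits) || nrow(hits) == 0) return(empty)

  # Merge overlapping windows per strand (linear coordinates; a wrapped and
  # an unwrapped window overlapping across the origin are left unmerged).
  merged <- hits %>%
    group_by(strand) %>%
    arrange(start, .by_group = TRUE) %>%
    mutate(
      new_block = start > dplyr::lag(cummax(start + width), default = -1L),
      block = cumsum(new_block)
    ) %>%
    group_by(strand, block) %>%
    summarise(
      record_id = record_id[1],
      start = min(start), end = max(start + width),
      identity = max(identity), aligned_len = aligned_len[1],
      .groups = "drop"
    ) %>%
    select(record_id, start, end, strand, identity, aligned_len) %>%
    arrange(dplyr::desc(identity), start)
  merged
}
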