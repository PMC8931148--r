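# Independent oracles used across the suite. These deliberately re-derive
# results by naive means (regex scans, exhaustive recursion, per-position
# masks) so they share no code path with the implementation they check.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  # local reverse complement, independent of the package's
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

iupac_regex <- function(motif) {
  sets <- c(
    A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
    W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
    V = "ACG", N = "ACGT"
  )
  paste(vapply(strsplit(motif, "")[[1]],
               function(k) paste0("[", sets[[k]], "]"), ""),
        collapse = "")
}

# 0-based starts of (overlapping) regex matches
regex_starts <- function(s, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Naive degenerate-match site enumerator over both strands. Returns the
# canonical columns (strand, proto_start, pam_start, cut_pos, pam_seq)
# reduced modulo the record length, sorted.
oracle_find_sites <- function(genome, motif, spacer_len, cut_offset = 3L,
                              drop_n = TRUE) {
  L <- genome$length
  m <- nchar(motif)
  empty <- data.frame(
    strand = character(0), proto_start = integer(0), pam_start = integer(0),
    cut_pos = integer(0), pam_seq = character(0), stringsAsFactors = FALSE
  )
  if (spacer_len + m > L) return(empty)
  S <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  SL <- nchar(S)
  pat <- iupac_regex(motif)
  rows <- list()

  for (s in regex_starts(S, pat)) { # plus strand, PAM at s
    if (s < spacer_len) next
    if (s + m > SL) next
    proto <- substr(S, s - spacer_len + 1, s)
    pam <- substr(S, s + 1, s + m)
    if (drop_n && grepl("N", paste0(proto, pam))) next
    rows[[length(rows) + 1L]] <- data.frame(
      strand = "+", proto_start = (s - spacer_len) %% L,
      pam_start = s %% L, cut_pos = (s - cut_offset) %% L,
      pam_seq = pam, stringsAsFactors = FALSE
    )
  }

  RC <- revcomp_chr(S) # minus strand, scanned on the reverse complement
  for (s2 in regex_starts(RC, pat)) {
    if (s2 < spacer_len) next
    if (s2 + m > SL) next
    proto <- substr(RC, s2 - spacer_len + 1, s2)
    pam <- substr(RC, s2 + 1, s2 + m)
    if (drop_n && grepl("N", paste0(proto, pam))) next
    pam_start_plus <- SL - s2 - m
    proto_start_plus <- SL - s2 - m + m # = SL - s2
    rows[[length(rows) + 1L]] <- data.frame(
      strand = "-", proto_start = proto_start_plus %% L,
      pam_start = pam_start_plus %% L,
      cut_pos = (proto_start_plus + cut_offset) %% L,
      pam_seq = pam, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  out[order(out$cut_pos, out$strand, out$pam_start), , drop = FALSE]
}

canonical_sites <- function(sites) {
  df <- as.data.frame(sites)[, c("strand", "proto_start", "pam_start",
                                 "cut_pos", "pam_seq")]
  df <- df[order(df$cut_pos, df$strand, df$pam_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# count plus-strand TA dinucleotides with room for a full site on both sides
oracle_flanked_ta_count <- function(seq, spacer_len, circular = FALSE) {
  L <- nchar(seq)
  S <- if (circular) paste0(seq, seq) else seq
  tas <- regex_starts(S, "TA")
  if (circular) {
    # on a circle every TA has full flanks (given spacer + 4 <= L)
    return(length(tas[tas < L]))
  }
  sum(tas - 2 - spacer_len >= 0 & tas + 2 + 2 + spacer_len <= L)
}

# score-only Gotoh in plain R (gap of length k costs open + k * extend)
gotoh_score_oracle <- function(ref, read, match = 2, mismatch = -4,
                               gap_open = -8, gap_extend = -1) {
  n <- nchar(ref)
  m <- nchar(read)
  rc <- strsplit(ref, "")[[1]]
  dc <- strsplit(read, "")[[1]]
  M <- matrix(-Inf, n + 1, m + 1)
  D <- matrix(-Inf, n + 1, m + 1)
  I <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) D[2:(n + 1), 1] <- gap_open + (1:n) * gap_extend
  if (m > 0) I[1, 2:(m + 1)] <- gap_open + (1:m) * gap_extend
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1 && j > 1) {
        s <- if (rc[i - 1] == dc[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], D[i - 1, j - 1], I[i - 1, j - 1]) + s
      }
      if (i > 1 && !(i == 2 && j == 1)) {
        D[i, j] <- max(
          max(M[i - 1, j], I[i - 1, j]) + gap_open + gap_extend,
          D[i - 1, j] + gap_extend
        )
      }
      if (j > 1 && !(j == 2 && i == 1)) {
        I[i, j] <- max(
          max(M[i, j - 1], D[i, j - 1]) + gap_open + gap_extend,
          I[i, j - 1] + gap_extend
        )
      }
    }
  }
  max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

# exhaustive alignment enumeration (exponential; tiny strings only)
exhaustive_align_score <- function(ref, read, match = 2, mismatch = -4,
                                   gap_open = -8, gap_extend = -1) {
  n <- nchar(ref)
  m <- nchar(read)
  rc <- strsplit(ref, "")[[1]]
  dc <- strsplit(read, "")[[1]]
  rec <- function(i, j, state) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (rc[i + 1] == dc[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {
      cost <- if (state == "D") gap_extend else gap_open + gap_extend
      best <- max(best, cost + rec(i + 1, j, "D"))
    }
    if (j < m) {
      cost <- if (state == "I") gap_extend else gap_open + gap_extend
      best <- max(best, cost + rec(i, j + 1, "I"))
    }
    best
  }
  rec(0, 0, "M")
}

# recompute an alignment's score from its op runs
score_from_ops <- function(aln, match = 2, mismatch = -4, gap_open = -8,
                           gap_extend = -1) {
  ops <- aln$ops
  total <- 0
  for (r in seq_len(nrow(ops))) {
    total <- total + switch(ops$op[r],
      match = ops$length[r] * match,
      mismatch = ops$length[r] * mismatch,
      insertion = gap_open + ops$length[r] * gap_extend,
      deletion = gap_open + ops$length[r] * gap_extend
    )
  }
  total
}

# Brute-force correctability oracle: enumerate every site on the patient
# sequence (via the naive regex enumerator), rebuild the spacer string, and
# test every window position explicitly. Linear genomes only.
oracle_correctable <- function(variant, genome, motif, spacer_len, editor,
                               cut_offset = 3L) {
  stopifnot(!genome$circular)
  L <- genome$length
  patient <- genome$seq
  substr(patient, variant$pos + 1, variant$pos + 1) <- variant$alt
  pg <- pamscape::genome_record(genome$id, patient)
  sites <- oracle_find_sites(pg, motif, spacer_len, cut_offset)
  correctable <- FALSE
  precise <- FALSE
  comp <- function(b) chartr("ACGT", "TGCA", b)
  if (nrow(sites)) {
    for (r in seq_len(nrow(sites))) {
      st <- sites[r, ]
      if (st$strand == "+") {
        proto_plus <- substr(patient, st$proto_start + 1,
                             st$proto_start + spacer_len)
        spacer_str <- proto_plus
        coord_of <- function(i) st$proto_start + i - 1L
      } else {
        proto_plus <- substr(patient, st$proto_start + 1,
                             st$proto_start + spacer_len)
        spacer_str <- revcomp_chr(proto_plus)
        coord_of <- function(i) st$proto_start + spacer_len - i
      }
      win <- editor$window_start:editor$window_end
      win_chars <- strsplit(substr(spacer_str, editor$window_start,
                                   editor$window_end), "")[[1]]
      hit <- which(vapply(win, coord_of, numeric(1)) == variant$pos)
      if (!length(hit)) next
      if (win_chars[hit] != editor$from_base) next
      ref_site <- if (st$strand == "+") variant$ref else comp(variant$ref)
      if (ref_site != editor$to_base) next
      correctable <- TRUE
      if (sum(win_chars == editor$from_base) == 1L) precise <- TRUE
    }
  }
  list(correctable = correctable, precise = precise)
}

# minimal site tibble for spacing tests
fabricate_sites <- function(cut_pos, record_id = "x") {
  tibble::tibble(record_id = record_id, cut_pos = as.integer(cut_pos))
}
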