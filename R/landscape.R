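# Genome-scale target-landscape statistics: coverage, inter-site spacing,
# dinucleotide-anchor spacing, TATA-box targeting.

new_spacing_summary <- function(distances, n_anchors, circular, genome_len) {
  distances <- as.numeric(distances)
  structure(
    list(
      n_anchors = as.integer(n_anchors),
      distances = distances,
      mean = if (length(distances)) mean(distances) else NA_real_,
      median = if (length(distances)) stats::median(distances) else NA_real_,
      undefined = length(distances) == 0L,
      circular = circular,
      genome_len = as.integer(genome_len)
    ),
    class = "spacing_summary"
  )
}

#' @export
print.spacing_summary <- function(x, ...) {
  cat(sprintf(
    "<spacing_summary> %d anchors on a %d bp %s record\n",
    x$n_anchors, x$genome_len, if (x$circular) "circular" else "linear"
  ))
  if (x$undefined) {
    cat("  mean spacing undefined (< 2 anchors on a linear record)\n")
  } else {
    cat(sprintf("  mean = %.4g bp, median = %.4g bp (%d gaps)\n",
                x$mean, x$median, length(x$distances)))
  }
  invisible(x)
}

# Gaps between consecutive sorted anchors; circular records add the
# wrap-around gap (so the gaps always sum to the record length).
anchor_distances <- function(anchors, circular, genome_len) {
  anchors <- sort(as.numeric(anchors))
  k <- length(anchors)
  if (k == 0L) return(numeric(0))
  if (circular) {
    if (k == 1L) return(as.numeric(genome_len))
    c(diff(anchors), genome_len - anchors[k] + anchors[1])
  } else {
    if (k < 2L) return(numeric(0))
    diff(anchors)
  }
}

#' Spacing between target-site cut positions
#'
#' Summarises the distances between consecutive cut positions (both strands
#' merged; co-located cuts contribute zero-length gaps). Circular records
#' include the wrap-around gap, so gaps sum exactly to the record length and
#' the mean equals `length / n_sites`.
#'
#' @param sites Site tibble from [find_pam_sites()].
#' @param genome The [genome_record()] the sites came from.
#' @return A `spacing_summary` object (see [glance.spacing_summary()]). With
#'   fewer than two sites on a linear record the distance set is empty and
#'   the mean is flagged undefined rather than raising an error.
#' @export
site_spacing <- function(sites, genome) {
  stopifnot(is.data.frame(sites), inherits(genome, "genome_record"))
  if (nrow(sites) && !all(sites$record_id == genome$id)) {
    abort("sites do not belong to this record", class = "pamscape_consistency_error")
  }
  new_spacing_summary(
    anchor_distances(sites$cut_pos, genome$circular, genome$length),
    n_anchors = nrow(sites), circular = genome$circular,
    genome_len = genome$length
  )
}

#' Spacing between dinucleotide anchors
#'
#' Anchors are plus-strand start positions of a 2-nt word (all overlapping
#' occurrences count). With `count_both_strands = TRUE`, a non-palindromic
#' word also contributes the start positions of its reverse complement
#' (e.g. `GG` also counts `CC`); a palindromic word (`TA`, `AT`, `GC`, `CG`)
#' contributes *two* anchors per occurrence — one per strand orientation —
#' so duplicated loci appear as zero-length gaps and the circular mean
#' becomes `L / (2 * n_occurrences)`.
#'
#' @param genome A [genome_record()].
#' @param word 2-nt DNA word.
#' @param count_both_strands Count both strand orientations (default `TRUE`).
#' @return A `spacing_summary`.
#' @export
dinucleotide_spacing <- function(genome, word, count_both_strands = TRUE) {
  stopifnot(inherits(genome, "genome_record"))
  if (!is.character(word) || length(word) != 1L || nchar(word) != 2L) {
    abort("word must be a single 2-nt string", class = "pamscape_parameter_error")
  }
  check_dna(word, "ACGT")
  L <- genome$length
  scan_seq <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  chars <- strsplit(scan_seq, "")[[1]]
  starts_of <- function(w) {
    s <- motif_match_starts(chars, w)
    if (genome$circular) s[s < L] else s
  }
  anchors <- starts_of(word)
  if (count_both_strands) {
    rc <- reverse_complement(word)
    anchors <- if (identical(rc, word)) {
      rep(anchors, each = 2L) # palindromic: one anchor per orientation
    } else {
      c(anchors, starts_of(rc))
    }
  }
  new_spacing_summary(
    anchor_distances(anchors, genome$circular, L),
    n_anchors = length(anchors), circular = genome$circular, genome_len = L
  )
}

#' Pool per-record spacing summaries
#'
#' Spacing never crosses record boundaries; this combines per-record
#' summaries into one by concatenating gap sets (equivalently, a
#' gap-count-weighted mean).
#'
#' @param summaries List of `spacing_summary` objects.
#' @return A `spacing_summary` whose distances are the pooled gaps.
#' @export
pool_spacing <- function(summaries) {
  stopifnot(length(summaries) > 0, all(vapply(summaries, inherits, TRUE, "spacing_summary")))
  new_spacing_summary(
    unlist(lapply(summaries, `[[`, "distances")),
    n_anchors = sum(vapply(summaries, `[[`, 1L, "n_anchors")),
    circular = all(vapply(summaries, `[[`, TRUE, "circular")),
    genome_len = sum(vapply(summaries, `[[`, 1L, "genome_len"))
  )
}

#' Fraction of a genome covered by protospacers
#'
#' The fraction of genome positions overlapped by at least one protospacer
#' interval (union over both strands). PAM bases are excluded by default —
#' "target coverage" refers to editable sequence — with `include_pam = TRUE`
#' provided as the alternative convention.
#'
#' @param sites Site tibble from [find_pam_sites()].
#' @param genome The [genome_record()] the sites came from.
#' @param include_pam Also count PAM bases as covered (default `FALSE`).
#' @return A one-row tibble: `covered_positions`, `genome_len`, `fraction`.
#' @export
target_coverage <- function(sites, genome, include_pam = FALSE) {
  stopifnot(is.data.frame(sites), inherits(genome, "genome_record"))
  L <- genome$length
  mask <- logical(L)
  add_intervals <- function(starts, ends) {
    if (!length(starts)) return(invisible())
    if (!genome$circular && any(ends > L | starts < 0)) {
      abort("site interval outside linear record bounds",
            class = "pamscape_consistency_error")
    }
    pos <- unlist(Map(function(s, e) if (e > s) s:(e - 1L) else integer(0),
                      starts, ends))
    mask[(pos %% L) + 1L] <<- TRUE
    invisible()
  }
  if (nrow(sites)) {
    add_intervals(sites$proto_start, sites$proto_end)
    if (include_pam) add_intervals(sites$pam_start, sites$pam_end)
  }
  covered <- sum(mask)
  tibble(
    covered_positions = covered, genome_len = L,
    fraction = if (L > 0) covered / L else NA_real_
  )
}

#' Target sites whose PAM TA core falls inside a TATA box
#'
#' Enumerates PAM-adjacent sites on a promoter sequence and keeps those whose
#' PAM's palindromic TA core lies inside an occurrence of the TATA-box core
#' element (default `TATAAATAAT`). Because every TA dinucleotide inside the
#' core anchors one site per strand (flanks permitting), a TA-core PAM makes
#' TATA boxes dense targets for promoter-directed cleavage, CRISPRi and
#' CRISPRa.
#'
#' @param promoter A [genome_record()] holding the promoter sequence.
#' @param motif IUPAC PAM motif with a TA core (shape `N^j TA N^k`).
#' @param spacer_len Protospacer length (default 22).
#' @param tata_core TATA-box core sequence (default `"TATAAATAAT"`).
#' @param cut_offset Passed to [find_pam_sites()].
#' @return Site tibble (as [find_pam_sites()]) restricted to TATA-box-core
#'   PAMs, with an extra `tata_start` column giving the core occurrence each
#'   site's TA falls in.
#' @export
tata_box_targets <- function(promoter, motif = "NNTA", spacer_len = 22L,
                             tata_core = "TATAAATAAT", cut_offset = 3L) {
  stopifnot(inherits(promoter, "genome_record"))
  check_dna(tata_core, "ACGT")
  core <- ta_core_offset(motif)
  if (is.null(core)) {
    abort(
      sprintf("motif '%s' has no palindromic TA core of shape N^j TA N^k", motif),
      class = "pamscape_motif_error"
    )
  }
  sites <- find_pam_sites(promoter, motif, spacer_len, cut_offset)
  L <- promoter$length
  scan_seq <- if (promoter$circular) paste0(promoter$seq, promoter$seq) else promoter$seq
  occ <- motif_match_starts(strsplit(scan_seq, "")[[1]], tata_core)
  if (promoter$circular) occ <- occ[occ < L]
  out <- sites %>%
    mutate(
      ta_pos = dplyr::if_else(
        strand == "+",
        (pam_start + core$j) %% L,
        (pam_start + core$k) %% L
      )
    )
  # the TA dinucleotide [ta, ta+2) must sit inside [occ, occ + |core|)
  w <- nchar(tata_core)
  inside <- purrr::map_int(out$ta_pos, function(t) {
    hit <- occ[t >= occ & t + 2L <= occ + w]
    if (length(hit)) hit[1] else NA_integer_
  })
  out <- out %>%
    mutate(tata_start = inside) %>%
    filter(!is.na(tata_start)) %>%
    select(-ta_pos)
  for (a in c("genome_len", "circular", "motif", "record_id")) {
    attr(out, a) <- attr(sites, a)
  }
  out
}
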