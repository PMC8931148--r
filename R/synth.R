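# Seed-deterministic synthetic-data generators. Every generator takes an
# explicit seed and scopes it with withr::with_seed, so global RNG state is
# never touched and identical configs are byte-identical.

#' Random genome with controlled GC content
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Sequence length (>= 0).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param circular Circular record? (default `FALSE`).
#' @param seed Integer seed.
#' @param id Record id.
#' @return A [genome_record()].
#' @export
random_genome <- function(length, gc = 0.5, circular = FALSE, seed,
                          id = "synthetic") {
  if (!(is.numeric(gc) && gc >= 0 && gc <= 1)) {
    abort("gc must be in [0, 1]", class = "pamscape_parameter_error")
  }
  stopifnot(length >= 0)
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  genome_record(id, seq, circular = circular)
}

# does a PAM string match an IUPAC rule applied to its first |rule| bases?
pam_matches_rule <- function(pams, rule) {
  codes <- strsplit(rule, "")[[1]]
  ok <- rep(TRUE, length(pams))
  for (j in seq_along(codes)) {
    ok <- ok & substring(pams, j, j) %in% IUPAC_SETS[[codes[j]]]
  }
  ok
}

#' Simulate a randomized-PAM depletion assay
#'
#' The control library draws `depth` reads from a uniform multinomial over
#' all `4^k` PAMs (the randomized plasmid library). The selected library
#' draws from the same universe with the survival weight of every
#' rule-matching PAM multiplied by `retention` (renormalised): `retention`
#' 0 is complete depletion of functional PAMs, 1 is no selection. The rule
#' is an IUPAC motif applied to the PAM's first bases (e.g. `"NNTA"` on a
#' 6-nt PAM constrains positions 3-4).
#'
#' @param k PAM length (default 6).
#' @param rule IUPAC depletion rule (default `"NNTA"`).
#' @param retention Survival fraction of rule-matching PAMs in `[0, 1]`.
#' @param depth Total reads per library.
#' @param seed Integer seed.
#' @return List with `control` and `selected` count tibbles (`pam`,
#'   `count`), `rule`, and `matching` (the rule-matching PAM strings — the
#'   hidden truth).
#' @export
simulate_depletion <- function(k = 6L, rule = "NNTA", retention = 0.1,
                               depth = 1e6, seed) {
  check_iupac(rule)
  if (nchar(rule) > k) {
    abort("rule longer than PAM", class = "pamscape_parameter_error")
  }
  if (!(retention >= 0 && retention <= 1)) {
    abort("retention must be in [0, 1]", class = "pamscape_parameter_error")
  }
  stopifnot(depth > 0)
  pams <- enumerate_pams(k)
  matches <- pam_matches_rule(pams, rule)
  n <- length(pams)
  counts <- withr::with_seed(seed, {
    ctl <- as.vector(rmultinom(1, depth, rep(1 / n, n)))
    w <- ifelse(matches, retention, 1)
    sel <- as.vector(rmultinom(1, depth, w / sum(w)))
    list(ctl = ctl, sel = sel)
  })
  list(
    control = tibble(pam = pams, count = counts$ctl),
    selected = tibble(pam = pams, count = counts$sel),
    rule = rule,
    matching = pams[matches]
  )
}

#' Simulate an amplicon read set with planted indels
#'
#' Each read is a copy of the reference; with probability `indel_fraction`
#' one indel (size drawn from `indel_sizes` with weights `indel_probs`) is
#' planted within `±placement_jitter` bp of the cut site, mimicking the
#' clustering of NHEJ repair products around the break. Uniform substitution
#' errors are then applied at `error_rate` per base. Truth labels are
#' emitted per read.
#'
#' @param reference A [genome_record()] or DNA string (the amplicon).
#' @param cut_offset 0-based cut coordinate; must leave at least
#'   `placement_jitter + max(|size|)` margin on both sides.
#' @param indel_fraction Planted indel probability `q` in `[0, 1]`.
#' @param depth Number of reads.
#' @param error_rate Per-base substitution error rate in `[0, 0.05]`.
#' @param indel_sizes,indel_probs Signed indel sizes (negative = deletion)
#'   and their weights; default sizes `±1..±10` with weight `0.6^(|s|-1)`,
#'   so single-base events dominate.
#' @param placement_jitter Max distance of the indel from the cut (default
#'   3 bp).
#' @param seed Integer seed.
#' @return List with `reads` (character vector) and `truth` (tibble:
#'   `read_id`, `has_indel`, `indel_size`, `indel_pos`).
#' @export
simulate_amplicon <- function(reference, cut_offset, indel_fraction,
                              depth, error_rate = 0.005,
                              indel_sizes = c(-10:-1, 1:10),
                              indel_probs = 0.6^(abs(c(-10:-1, 1:10)) - 1),
                              placement_jitter = 3L, seed) {
  ref <- if (inherits(reference, "genome_record")) reference$seq else toupper(reference)
  check_dna(ref, "ACGT")
  if (!(indel_fraction >= 0 && indel_fraction <= 1)) {
    abort("indel_fraction must be in [0, 1]", class = "pamscape_parameter_error")
  }
  if (!(error_rate >= 0 && error_rate <= 0.05)) {
    abort("error_rate must be in [0, 0.05]", class = "pamscape_parameter_error")
  }
  L <- nchar(ref)
  margin <- placement_jitter + max(abs(indel_sizes))
  if (cut_offset < margin || L - cut_offset < margin) {
    abort("cut_offset too close to the reference ends for the indel model",
          class = "pamscape_parameter_error")
  }
  stopifnot(depth >= 1, length(indel_sizes) == length(indel_probs))
  bases <- c("A", "C", "G", "T")

  out <- withr::with_seed(seed, {
    has_indel <- runif(depth) < indel_fraction
    sizes <- integer(depth)
    poss <- rep(NA_integer_, depth)
    reads <- character(depth)
    for (r in seq_len(depth)) {
      rd <- ref
      if (has_indel[r]) {
        s <- sample(indel_sizes, 1, prob = indel_probs)
        p <- cut_offset + sample(-placement_jitter:placement_jitter, 1)
        sizes[r] <- s
        poss[r] <- p
        if (s < 0) {
          rd <- paste0(substring(rd, 1, p), substring(rd, p - s + 1L, L))
        } else {
          ins <- paste(sample(bases, s, replace = TRUE), collapse = "")
          rd <- paste0(substring(rd, 1, p), ins, substring(rd, p + 1L, L))
        }
      }
      if (error_rate > 0) {
        ch <- strsplit(rd, "")[[1]]
        hit <- which(runif(length(ch)) < error_rate)
        for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1)
        rd <- paste(ch, collapse = "")
      }
      reads[r] <- rd
    }
    list(reads = reads, has_indel = has_indel, sizes = sizes, poss = poss)
  })
  list(
    reads = out$reads,
    truth = tibble(
      read_id = sprintf("read_%05d", seq_len(depth)),
      has_indel = out$has_indel,
      indel_size = out$sizes,
      indel_pos = out$poss
    )
  )
}

#' Simulate variants with known base-editor correctability
#'
#' Plants single-nucleotide variants on a genome so that their
#' correctability class under a base editor is known: `correctable_precise`
#' (a supporting site with a bystander-free window), `correctable_bystander`
#' (correctable, but every supporting window carries at least one bystander
#' substrate base) and `uncorrectable` (chemistry impossible on both
#' strands). Variants are constructed from enumerated sites — the healthy
#' base is the editor's product base on the site strand and the pathogenic
#' allele its substrate base — and each planted class is certified by
#' direct evaluation on the constructed patient sequence; infeasible
#' placements are retried up to `max_tries` and a placement error is raised
#' if a class cannot be realised.
#'
#' @param genome A [genome_record()].
#' @param motif,spacer_len,cut_offset Site-enumeration parameters.
#' @param editor A [base_editor()].
#' @param n_per_class Named integer vector with any of
#'   `correctable_precise`, `correctable_bystander`, `uncorrectable`.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per requested variant (default 200).
#' @return List with `variants` (tibble: `variant_id`, `record_id`, `pos`,
#'   `ref`, `alt`, `significance`) and `truth` (tibble: `variant_id`,
#'   `class`, `correctable`, `precise`).
#' @export
simulate_variants <- function(genome, motif = "NNTA", spacer_len = 22L,
                              editor, n_per_class = c(
                                correctable_precise = 2L,
                                correctable_bystander = 2L,
                                uncorrectable = 2L
                              ), seed, cut_offset = 3L, max_tries = 200L) {
  stopifnot(inherits(genome, "genome_record"), inherits(editor, "base_editor"))
  sites <- find_pam_sites(genome, motif, spacer_len, cut_offset)
  L <- genome$length
  from <- editor$from_base
  to <- editor$to_base
  plus_alt_for <- function(strand) if (strand == "+") from else complement_base(from)

  call_for <- function(pos, ref, alt) {
    v <- tibble(variant_id = "probe", pos = pos, ref = ref, alt = alt)
    correctable_variants(v, genome, motif, spacer_len, editor, cut_offset)
  }

  withr::with_seed(seed, {
    used_pos <- integer(0)
    rows <- list()
    truths <- list()
    vi <- 0L
    for (cls in names(n_per_class)) {
      for (rep_i in seq_len(n_per_class[[cls]])) {
        placed <- FALSE
        for (try_i in seq_len(max_tries)) {
          if (cls == "uncorrectable") {
            pos <- sample.int(L, 1) - 1L
            ref <- base_at(genome$seq, pos, L)
            if (ref == "N") next
            # exclude both chemistry-valid (alt, ref) pairs on either strand
            forbidden <- c(from, complement_base(from))
            alts <- setdiff(c("A", "C", "G", "T"), c(ref, forbidden))
            if (!length(alts)) next
            alt <- sample(alts, 1)
          } else {
            if (nrow(sites) == 0) break
            site <- sites[sample.int(nrow(sites), 1), ]
            coords <- window_coords(site, editor) %% L
            sbase <- vapply(coords, function(p) base_at(genome$seq, p, L), "")
            if (site$strand == "-") sbase <- complement_base(sbase)
            cand <- coords[sbase == to]
            if (!length(cand)) next
            pos <- sample(rep(cand, 2L), 1) # rep() guards length-1 sample()
            ref <- base_at(genome$seq, pos, L)
            alt <- plus_alt_for(site$strand)
            if (alt == ref) next
          }
          if (pos %in% used_pos) next
          call <- call_for(pos, ref, alt)
          ok <- switch(cls,
            correctable_precise = call$correctable && call$precise,
            correctable_bystander = call$correctable && !call$precise,
            uncorrectable = !call$correctable
          )
          if (!ok) next
          vi <- vi + 1L
          used_pos <- c(used_pos, pos)
          rows[[vi]] <- tibble(
            variant_id = sprintf("var_%03d", vi), record_id = genome$id,
            pos = pos, ref = ref, alt = alt, significance = "pathogenic"
          )
          truths[[vi]] <- tibble(
            variant_id = sprintf("var_%03d", vi), class = cls,
            correctable = call$correctable, precise = call$precise
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          abort(sprintf("could not place a '%s' variant in %d tries", cls, max_tries),
                class = "pamscape_placement_error")
        }
      }
    }
    list(variants = bind_rows(rows), truth = bind_rows(truths))
  })
}
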