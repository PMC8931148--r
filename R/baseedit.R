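# Base-editor models, correctable-variant scoping, double editing windows.

#' Construct a base-editor model
#'
#' A base editor converts one base into another (CBE: C->T; ABE: A->G)
#' within a protospacer editing window. Window positions are 1-based and
#' counted from the PAM-distal 5' end of the protospacer, the standard
#' base-editor convention.
#'
#' @param name Editor name.
#' @param from_base,to_base Conversion chemistry; must be `C->T` or `A->G`.
#' @param window_start,window_end Inclusive window bounds (1-based,
#'   PAM-distal origin).
#' @return A `base_editor` object.
#' @seealso [base_editor_presets()] for the bundled editor models.
#' @export
base_editor <- function(name, from_base, to_base, window_start, window_end) {
  ok <- (from_base == "C" && to_base == "T") ||
    (from_base == "A" && to_base == "G")
  if (!ok) {
    abort("conversion must be C->T (CBE) or A->G (ABE)",
          class = "pamscape_parameter_error")
  }
  if (!(window_start >= 1L && window_start <= window_end)) {
    abort("require 1 <= window_start <= window_end",
          class = "pamscape_parameter_error")
  }
  structure(
    list(
      name = name, from_base = from_base, to_base = to_base,
      window_start = as.integer(window_start),
      window_end = as.integer(window_end)
    ),
    class = "base_editor"
  )
}

#' @export
print.base_editor <- function(x, ...) {
  cat(sprintf("<base_editor> %s: %s->%s, window %d-%d\n",
              x$name, x$from_base, x$to_base, x$window_start, x$window_end))
  invisible(x)
}

#' Bundled base-editor models
#'
#' FrCas9 fusions use the windows measured for this nuclease (BE4Gam:
#' positions 6-10; ABE7.10: positions 6-8, of a 22-nt spacer). The SpCas9
#' comparators use the canonical literature window 4-8 of a 20-nt spacer;
#' both are plain [base_editor()] objects and fully configurable.
#'
#' @return Named list of `base_editor` objects: `frcas9_be4gam`,
#'   `frcas9_abe710`, `spcas9_be4gam`, `spcas9_abe710`.
#' @export
base_editor_presets <- function() {
  list(
    frcas9_be4gam = base_editor("FrCas9-BE4Gam", "C", "T", 6L, 10L),
    frcas9_abe710 = base_editor("FrCas9-ABE7.10", "A", "G", 6L, 8L),
    spcas9_be4gam = base_editor("SpCas9-BE4Gam", "C", "T", 4L, 8L),
    spcas9_abe710 = base_editor("SpCas9-ABE7.10", "A", "G", 4L, 8L)
  )
}

base_at <- function(seq, pos0, L) {
  substring(seq, (pos0 %% L) + 1L, (pos0 %% L) + 1L)
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Plus-strand coordinates of a site's editing-window positions, in window
# order (position window_start first).
window_coords <- function(site, editor) {
  i <- editor$window_start:editor$window_end
  if (site$strand == "+") site$proto_start + i - 1L else site$proto_end - i
}

#' Editable genomic positions of a site under a base editor
#'
#' Maps the editor's protospacer window (counted from the PAM-distal 5' end
#' on the site strand) to plus-strand genomic coordinates and keeps the
#' positions whose site-strand base equals the editor's substrate base.
#'
#' @param site One site: a one-row tibble from [find_pam_sites()].
#' @param editor A [base_editor()].
#' @param genome The [genome_record()] the site was found on.
#' @return Integer vector of plus-strand coordinates (window order).
#' @export
editable_positions <- function(site, editor, genome) {
  stopifnot(is.data.frame(site), nrow(site) == 1L,
            inherits(editor, "base_editor"),
            inherits(genome, "genome_record"))
  if (editor$window_end > site$spacer_len) {
    abort("editing window exceeds spacer length",
          class = "pamscape_parameter_error")
  }
  L <- genome$length
  coords <- window_coords(site, editor) %% L
  strand_base <- vapply(coords, function(p) base_at(genome$seq, p, L), "")
  if (site$strand == "-") strand_base <- complement_base(strand_base)
  coords[strand_base == editor$from_base]
}

#' Scope base-editor-correctable variants
#'
#' Evaluates, for each single-nucleotide variant, whether a base editor can
#' revert the pathogenic allele back to the reference allele. Scanning is
#' performed on the patient sequence (the genome with `alt` substituted at
#' the variant position), since that is the molecule the editor acts on. A
#' variant is *correctable* when some target site places it inside the
#' editing window with the site-strand base equal to the editor's substrate
#' (`alt = C, ref = T` on either strand for a CBE; `alt = A, ref = G` for an
#' ABE). It is *precise* when at least one supporting site has no bystander
#' — no additional substrate base inside that site's window on the site
#' strand.
#'
#' @param variants Tibble with columns `variant_id`, `pos` (0-based
#'   plus-strand), `ref`, `alt` (single bases; `ref` must match the genome).
#' @param genome Reference [genome_record()].
#' @param motif,spacer_len,cut_offset Passed to [find_pam_sites()].
#' @param editor A [base_editor()].
#' @return Tibble with one row per variant: `variant_id`, `editor`,
#'   `correctable`, `precise`, `n_supporting`, `supporting_sites` (list
#'   column of site ids with a bystander-free flag per site).
#' @export
correctable_variants <- function(variants, genome, motif = "NNTA",
                                 spacer_len = 22L, editor,
                                 cut_offset = 3L) {
  stopifnot(is.data.frame(variants), inherits(genome, "genome_record"),
            inherits(editor, "base_editor"))
  need <- c("variant_id", "pos", "ref", "alt")
  stopifnot(all(need %in% names(variants)))
  if (editor$window_end > spacer_len) {
    abort("editing window exceeds spacer length",
          class = "pamscape_parameter_error")
  }
  L <- genome$length
  obs_ref <- vapply(variants$pos, function(p) base_at(genome$seq, p, L), "")
  bad <- which(obs_ref != variants$ref)
  if (length(bad)) {
    abort(
      sprintf("variant ref mismatch with genome: %s",
              paste(variants$variant_id[bad], collapse = ", ")),
      class = "pamscape_data_error"
    )
  }

  m <- nchar(motif)
  calls <- purrr::pmap(
    variants[, need],
    function(variant_id, pos, ref, alt) {
      # patient sequence: genome carrying the pathogenic alt allele
      patient <- genome$seq
      substring(patient, pos + 1L, pos + 1L) <- alt
      if (genome$circular) {
        pg <- genome_record(genome$id, patient, circular = TRUE)
        sites <- find_pam_sites(pg, motif, spacer_len, cut_offset)
        region_offset <- 0L
      } else {
        a <- max(0L, pos - (spacer_len + m))
        b <- min(L, pos + spacer_len + m + 1L)
        pg <- genome_record(genome$id, substring(patient, a + 1L, b))
        sites <- find_pam_sites(pg, motif, spacer_len, cut_offset)
        region_offset <- a
      }
      supporting <- character(0)
      bystander_free <- logical(0)
      if (nrow(sites)) {
        pL <- pg$length
        for (r in seq_len(nrow(sites))) {
          site <- sites[r, ]
          local_pos <- pos - region_offset
          coords <- window_coords(site, editor) %% pL
          if (!(local_pos %in% coords)) next
          sbase <- vapply(coords, function(p) base_at(pg$seq, p, pL), "")
          if (site$strand == "-") sbase <- complement_base(sbase)
          at_var <- sbase[match(local_pos, coords)]
          ref_site <- if (site$strand == "+") ref else complement_base(ref)
          if (at_var != editor$from_base || ref_site != editor$to_base) next
          n_bystanders <- sum(sbase == editor$from_base & coords != local_pos)
          supporting <- c(supporting, site$site_id)
          bystander_free <- c(bystander_free, n_bystanders == 0L)
        }
      }
      tibble(
        variant_id = variant_id, editor = editor$name,
        correctable = length(supporting) > 0,
        precise = any(bystander_free),
        n_supporting = length(supporting),
        supporting_sites = list(setNames(bystander_free, supporting))
      )
    }
  )
  bind_rows(calls)
}

#' Fractional difference between two editor scopes
#'
#' Given the correctable-variant id sets of two editors, the fraction of the
#' first scope that the second cannot reach: `|A \ B| / |A|`.
#'
#' @param scope_a,scope_b Character vectors (or sets) of variant ids.
#' @return Fraction in `[0, 1]`; `NA` with a warning when `scope_a` is
#'   empty.
#' @examples
#' # 235 of 260 correctable events unique to one editor:
#' scope_difference(as.character(1:260), as.character(236:260)) # 0.9038...
#' @export
scope_difference <- function(scope_a, scope_b) {
  scope_a <- unique(as.character(scope_a))
  scope_b <- unique(as.character(scope_b))
  if (length(scope_a) == 0) {
    warn("scope_a is empty; scope difference undefined")
    return(NA_real_)
  }
  length(setdiff(scope_a, scope_b)) / length(scope_a)
}

#' Double editing windows of a back-to-back pair
#'
#' A back-to-back pair carries one editing window per site, on opposite
#' sides of the shared TA core; this returns both as plus-strand genomic
#' intervals. The intervals are disjoint and flank the `N^j TA N^k` core
#' between the two protospacers.
#'
#' @param pair One row of [find_back_to_back_pairs()] output.
#' @param editor A [base_editor()].
#' @return Two-row tibble: `site_id`, `strand`, `start`, `end` (0-based
#'   half-open plus-strand window intervals).
#' @export
double_window <- function(pair, editor) {
  stopifnot(is.data.frame(pair), nrow(pair) == 1L,
            inherits(editor, "base_editor"))
  spacer <- pair$plus_proto_end - pair$plus_proto_start
  if (editor$window_end > spacer) {
    abort("editing window exceeds spacer length",
          class = "pamscape_parameter_error")
  }
  ws <- editor$window_start
  we <- editor$window_end
  tibble(
    site_id = c(pair$plus_site_id, pair$minus_site_id),
    strand = c("+", "-"),
    start = c(pair$plus_proto_start + ws - 1L, pair$minus_proto_end - we),
    end = c(pair$plus_proto_start + we, pair$minus_proto_end - ws + 1L)
  )
}
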