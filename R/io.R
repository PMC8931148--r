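# File interfaces: FASTA genomes, BED6/TSV site tables, PAM count tables,
# variant tables (TSV or minimal VCF). All tables are tab-separated with a
# single header line beginning '#'.

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (multi-record supported).
#' @param circular Logical scalar applied to all records, or a character
#'   vector of record ids that are circular.
#' @return Named list of [genome_record()] objects (names = record ids,
#'   the first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  circ <- if (is.character(circular)) ids %in% circular else rep(circular, length(set))
  recs <- purrr::map2(seq_along(set), circ, function(i, cc) {
    genome_record(ids[i], as.character(set[[i]]), circular = cc)
  })
  setNames(recs, ids)
}

#' Write genome records to a FASTA file
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path.
#' @export
write_genome_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

write_commented_tsv <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

read_commented_tsv <- function(path, col_types) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  readr::read_tsv(path, skip = 1L, col_names = cols, col_types = col_types,
                  progress = FALSE)
}

#' Write target sites as BED6
#'
#' One line per site: chrom, protospacer start, protospacer end, name (the
#' PAM sequence as read on the site strand), score 0, strand. Coordinates
#' are 0-based half-open; wrapped circular features keep `end > record
#' length` and are flagged by `end` exceeding the chrom size.
#'
#' @param sites Site tibble from [find_pam_sites()].
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$record_id, start = sites$proto_start,
    end = sites$proto_end, name = sites$pam_seq, score = 0L,
    strand = sites$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 site file written by [write_sites_bed()]
#'
#' @param path BED path.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_sites_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
}

#' Write the full site table as commented TSV
#'
#' @param sites Site tibble from [find_pam_sites()].
#' @param path Output path.
#' @export
write_sites_tsv <- function(sites, path) {
  write_commented_tsv(as_tibble(sites), path)
}

#' Read a site table written by [write_sites_tsv()]
#'
#' @param path TSV path.
#' @return Site tibble with the [find_pam_sites()] columns.
#' @export
read_sites_tsv <- function(path) {
  read_commented_tsv(path, readr::cols(
    record_id = "c", strand = "c", proto_start = "i", proto_end = "i",
    pam_start = "i", pam_end = "i", spacer_len = "i", pam_seq = "c",
    cut_pos = "i", site_id = "c"
  ))
}

#' Read a PAM count table
#'
#' Tab-separated with columns `pam` and `count`; a leading `#` on the
#' header line is accepted.
#'
#' @param path TSV path.
#' @return Tibble with `pam`, `count`.
#' @export
read_pam_counts <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    out <- read_commented_tsv(path, readr::cols(pam = "c", count = "d"))
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(pam = "c", count = "d"),
                           progress = FALSE)
  }
  out[, c("pam", "count")]
}

#' Write a PAM count table
#'
#' @param counts Tibble with `pam`, `count`.
#' @param path Output path.
#' @export
write_pam_counts <- function(counts, path) {
  write_commented_tsv(counts[, c("pam", "count")], path)
}

#' Read a variant table (TSV or minimal VCF)
#'
#' Accepts either the package's variant TSV (columns `variant_id`,
#' `record_id`, `pos` 0-based, `ref`, `alt`, optional `significance`) or a
#' minimal VCF (`#CHROM POS ID REF ALT ...`, 1-based positions, `##`
#' meta-lines ignored). Only single-nucleotide records are kept from VCF
#' input.
#'
#' @param path Input path.
#' @return Tibble with columns `variant_id`, `record_id`, `pos` (0-based),
#'   `ref`, `alt`, `significance`.
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_vcf <- any(startsWith(lines, "##")) ||
    startsWith(lines[1], "#CHROM") ||
    grepl("^#?CHROM\tPOS", lines[1])
  if (is_vcf) {
    body <- lines[!startsWith(lines, "##")]
    cols <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
    df <- readr::read_tsv(I(paste(body[-1], collapse = "\n")),
                          col_names = cols, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    out <- tibble(
      variant_id = df$ID,
      record_id = df$CHROM,
      pos = as.integer(df$POS) - 1L,
      ref = toupper(df$REF),
      alt = toupper(df$ALT),
      significance = NA_character_
    )
    out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L, ]
  } else {
    first <- lines[1]
    cols <- strsplit(sub("^#", "", first), "\t")[[1]]
    df <- readr::read_tsv(I(paste(lines[-1], collapse = "\n")),
                          col_names = cols, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    out <- tibble(
      variant_id = df$variant_id,
      record_id = df$record_id,
      pos = as.integer(df$pos),
      ref = toupper(df$ref),
      alt = toupper(df$alt),
      significance = if ("significance" %in% names(df)) df$significance else NA_character_
    )
  }
  out
}

#' Write a variant table as commented TSV
#'
#' @param variants Tibble with `variant_id`, `record_id`, `pos`, `ref`,
#'   `alt` (and optionally `significance`).
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  keep <- intersect(
    c("variant_id", "record_id", "pos", "ref", "alt", "significance"),
    names(variants)
  )
  write_commented_tsv(as_tibble(variants)[, keep], path)
}
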