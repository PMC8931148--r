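test_that("base-editor models validate chemistry and windows", {
  be <- base_editor("CBE", "C", "T", 6, 10)
  expect_s3_class(be, "base_editor")
  expect_error(base_editor("bad", "C", "G", 6, 10),
               class = "pamscape_parameter_error")
  expect_error(base_editor("bad", "A", "G", 8, 6),
               class = "pamscape_parameter_error")
  pr <- base_editor_presets()
  expect_identical(pr$frcas9_be4gam$window_start, 6L)
  expect_identical(pr$frcas9_be4gam$window_end, 10L)
  expect_identical(pr$frcas9_abe710$window_end, 8L)
  expect_identical(pr$spcas9_be4gam$window_start, 4L)
})

test_that("editable positions map windows to genomic coordinates on both strands", {
  cbe <- base_editor("CBE", "C", "T", 6, 10)
  # plus-strand site with protospacer [100, 122): window 6-10 occupies 105..109
  set.seed(23)
  seq <- rand_dna(150, c("A", "G", "T")) # no C anywhere yet
  for (p in c(105, 108)) substr(seq, p + 1, p + 1) <- "C"
  seq <- paste0(substr(seq, 1, 121), "C", "GGTA", substr(seq, 127, 150))
  g <- genome_record("g", seq)
  site <- tibble::tibble(record_id = "g", strand = "+", proto_start = 100L,
                         proto_end = 122L, pam_start = 122L, pam_end = 126L,
                         spacer_len = 22L, pam_seq = "GGTA", cut_pos = 119L,
                         site_id = "g:+:122")
  expect_identical(editable_positions(site, cbe, g), c(105L, 108L))

  # reconstructing the spacer string gives the same answer (oracle)
  spacer_str <- substr(g$seq, 101, 122)
  want <- 100L + which(strsplit(spacer_str, "")[[1]][6:10] == "C") + 4L
  expect_identical(editable_positions(site, cbe, g), want)

  # minus-strand site: window coordinates descend from the plus-strand 3' end
  gm <- genome_record("m", paste0("TANN", strrep("G", 22), "AAAA") |> gsub("N", "C", x = _))
  site_m <- tibble::tibble(record_id = "m", strand = "-", proto_start = 4L,
                           proto_end = 26L, pam_start = 0L, pam_end = 4L,
                           spacer_len = 22L, pam_seq = "NNTA", cut_pos = 7L,
                           site_id = "m:-:0")
  # site strand reads the complement: G-runs become C runs
  got_m <- editable_positions(site_m, cbe, gm)
  spacer_m <- revcomp_chr(substr(gm$seq, 5, 26))
  idx <- which(strsplit(spacer_m, "")[[1]][6:10] == "C") + 5L
  expect_identical(sort(got_m), sort(vapply(idx, function(i) 26L - i, 0L)))

  # no substrate base in window -> empty
  g0 <- genome_record("z", strrep("A", 60))
  site0 <- tibble::tibble(record_id = "z", strand = "+", proto_start = 10L,
                          proto_end = 32L, pam_start = 32L, pam_end = 36L,
                          spacer_len = 22L, pam_seq = "AATA", cut_pos = 29L,
                          site_id = "z:+:32")
  expect_identical(length(editable_positions(site0, cbe, g0)), 0L)
  tiny <- site0
  tiny$spacer_len <- 8L
  expect_error(editable_positions(tiny, cbe, g0),
               class = "pamscape_parameter_error")
})

test_that("correctable-variant calls: chemistry, windows, bystanders", {
  cbe <- base_editor("CBE", "C", "T", 6, 10)
  # build a genome with a + site whose window position 7 holds a T (ref);
  # the pathogenic variant is T>C there, and the window has no other C-target
  backbone <- strrep("G", 30)
  spacer <- "AAAAAATAAAAAAAAAAAAAAA" # T at spacer position 7
  g <- genome_record("g", paste0(backbone, spacer, "GGTA", strrep("G", 30)))
  pos_t <- 30L + 6L # 0-based genomic position of that T
  v <- tibble::tibble(variant_id = "v1", pos = pos_t, ref = "T", alt = "C")
  call <- correctable_variants(v, g, "NNTA", 22, cbe)
  expect_true(call$correctable)
  expect_true(call$precise)

  # add a second C in the window (plant a C at spacer position 9 = ref C? no:
  # bystander = another C on the patient strand, i.e. a genomic C in window)
  g2seq <- g$seq
  substr(g2seq, 30L + 9L, 30L + 9L) <- "C" # spacer position 9
  g2 <- genome_record("g", g2seq)
  call2 <- correctable_variants(v, g2, "NNTA", 22, cbe)
  expect_true(call2$correctable)
  expect_false(call2$precise)

  # wrong chemistry on both strands: G>A under a CBE
  vg <- tibble::tibble(variant_id = "v2", pos = 2L, ref = "G", alt = "A")
  expect_false(correctable_variants(vg, g, "NNTA", 22, cbe)$correctable)

  # ref mismatch is a data error naming the variant
  vbad <- tibble::tibble(variant_id = "oops", pos = pos_t, ref = "A", alt = "C")
  expect_error(correctable_variants(vbad, g, "NNTA", 22, cbe),
               class = "pamscape_data_error")
})

test_that("scoping equals the brute-force site-by-window oracle", {
  cbe <- base_editor("CBE", "C", "T", 6, 10)
  abe <- base_editor("ABE", "A", "G", 6, 8)
  set.seed(53)
  for (i in 1:40) {
    g <- genome_record("g", rand_dna(160))
    editor <- if (i %% 2 == 0) cbe else abe
    pos <- sample(0:159, 1)
    ref <- substr(g$seq, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- tibble::tibble(variant_id = "v", pos = pos, ref = ref, alt = alt)
    got <- correctable_variants(v, g, "NNTA", 12, editor)
    want <- oracle_correctable(list(pos = pos, ref = ref, alt = alt), g,
                               "NNTA", 12, editor)
    expect_identical(got$correctable, want$correctable)
    expect_identical(got$precise, want$precise)
    expect_true(!got$precise || got$correctable) # precise implies correctable
  }
})

test_that("chemistry symmetry: reverse-complementing genome and variant preserves calls", {
  cbe <- base_editor("CBE", "C", "T", 6, 10)
  set.seed(71)
  for (i in 1:10) {
    g <- genome_record("g", rand_dna(140))
    pos <- sample(20:119, 1)
    ref <- substr(g$seq, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- tibble::tibble(variant_id = "v", pos = pos, ref = ref, alt = alt)
    a <- correctable_variants(v, g, "NNTA", 12, cbe)
    L <- g$length
    g_rc <- genome_record("g", revcomp_chr(g$seq))
    v_rc <- tibble::tibble(
      variant_id = "v", pos = L - 1L - pos,
      ref = chartr("ACGT", "TGCA", ref), alt = chartr("ACGT", "TGCA", alt)
    )
    b <- correctable_variants(v_rc, g_rc, "NNTA", 12, cbe)
    expect_identical(a$correctable, b$correctable)
    expect_identical(a$precise, b$precise)
  }
})

test_that("editor scope differences reproduce the reported percentages", {
  a <- sprintf("v%04d", 1:260)
  b <- c(sprintf("v%04d", 236:260), sprintf("x%04d", 1:50))
  expect_equal(round(100 * scope_difference(a, b), 2), 90.38) # 235/260
  a2 <- sprintf("v%04d", 1:1297)
  b2 <- c(sprintf("v%04d", 1197:1297), sprintf("y%04d", 1:10))
  expect_equal(round(100 * scope_difference(a2, b2), 2), 92.21) # 1196/1297
  expect_identical(scope_difference(a, a), 0)
  expect_warning(nd <- scope_difference(character(0), a))
  expect_true(is.na(nd))
})

test_that("double windows flank the shared TA core symmetrically", {
  g <- genome_record("p", paste0(strrep("A", 30), "TA", strrep("A", 30)))
  s <- find_pam_sites(g, "NNTA", spacer_len = 22)
  pair <- find_back_to_back_pairs(s)
  expect_identical(nrow(pair), 1L)

  be <- base_editor("CBE", "C", "T", 6, 10)
  dw <- double_window(pair, be)
  expect_identical(dw$end - dw$start, c(5L, 5L))
  # symmetric about the centre of the 6-bp NNTANN core (positions 28..34)
  centre <- (pair$plus_proto_end + pair$minus_proto_start) / 2
  expect_equal(centre - dw$start[1], dw$end[2] - centre)
  expect_equal(centre - dw$end[1], dw$start[2] - centre)
  # disjoint, on opposite sides of the TA
  expect_lte(dw$end[1], pair$ta_pos)
  expect_gte(dw$start[2], pair$ta_pos + 2L)

  # window = full spacer abuts the 6-bp gap
  full <- base_editor("full", "C", "T", 1, 22)
  dwf <- double_window(pair, full)
  expect_identical(dwf$end[1], pair$plus_proto_end)
  expect_identical(dwf$start[2], pair$minus_proto_start)

  abe <- base_editor("ABE", "A", "G", 6, 8)
  expect_identical(double_window(pair, abe)$end - double_window(pair, abe)$start,
                   c(3L, 3L))
  wide <- base_editor("wide", "C", "T", 6, 30)
  expect_error(double_window(pair, wide), class = "pamscape_parameter_error")
})

test_that("removing the bystander flips a call from imprecise to precise", {
  cbe <- base_editor("CBE", "C", "T", 6, 10)
  backbone <- strrep("G", 30)
  spacer <- "AAAAAATACAAAAAAAAAAAAA" # T at pos 7 (target), C at pos 9 (bystander)
  g_with <- genome_record("g", paste0(backbone, spacer, "GGTA", strrep("G", 30)))
  v <- tibble::tibble(variant_id = "v", pos = 36L, ref = "T", alt = "C")
  with_b <- correctable_variants(v, g_with, "NNTA", 22, cbe)
  expect_true(with_b$correctable)
  expect_false(with_b$precise)

  seq2 <- g_with$seq
  substr(seq2, 39, 39) <- "A" # remove the bystander C (genomic 0-based 38)
  without_b <- correctable_variants(v, genome_record("g", seq2), "NNTA", 22, cbe)
  expect_true(without_b$correctable)
  expect_true(without_b$precise)
})
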