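test_that("PPDV: frequency-ratio arithmetic and flags", {
  ctl <- c(AATA = 50, AACC = 50)
  sel <- c(AATA = 10, AACC = 90)
  p <- compute_ppdv(sel, ctl)
  expect_identical(nrow(p), 256L) # full 4^4 universe
  expect_equal(p$ppdv[p$pam == "AATA"], 0.2)
  expect_equal(p$ppdv[p$pam == "AACC"], 1.8)
  # PAMs unseen in the control carry an undefined flag, not an error
  expect_true(all(p$undefined[!p$pam %in% c("AATA", "AACC")]))
  expect_true(all(is.na(p$ppdv[p$undefined])))

  # PAM absent from the selected library only: fully depleted, PPDV 0
  p2 <- compute_ppdv(c(AATA = 0, AACC = 100), ctl)
  expect_identical(p2$ppdv[p2$pam == "AATA"], 0)

  # efficacy rank: ascending PPDV, most depleted first, undefined last
  expect_identical(p2$efficacy_rank[p2$pam == "AATA"], 1L)
  expect_true(all(p2$efficacy_rank[p2$undefined] > 2L))
  expect_error(compute_ppdv(sel, c(AATA = 0, AACC = 0)),
               class = "pamscape_parameter_error")
})

test_that("PPDV identity: proportional libraries give 1 for every pseudocount", {
  set.seed(41)
  pams <- enumerate_pams(3)
  base <- sample(1:500, length(pams), replace = TRUE)
  ctl <- setNames(base, pams)
  sel <- setNames(base * 7, pams) # proportional
  for (pc in c(0, 0.5, 1)) {
    p <- compute_ppdv(sel, ctl, pseudocount = pc)
    if (pc == 0) {
      expect_true(all(abs(p$ppdv - 1) < 1e-12))
    } else {
      # with a pseudocount the ratio is only asymptotically 1; identical
      # *frequencies* (not counts) still give exactly 1
      p_eq <- compute_ppdv(ctl, ctl, pseudocount = pc)
      expect_true(all(abs(p_eq$ppdv - 1) < 1e-12))
    }
  }
})

test_that("top-depleted selection floors the quantile and breaks ties lexicographically", {
  sim <- simulate_depletion(k = 6, rule = "NNTA", retention = 0.05,
                            depth = 2e5, seed = 9)
  p <- compute_ppdv(sim$selected, sim$control)
  expect_identical(length(top_depleted(p, 0.1)), 409L) # floor(0.1 * 4096)
  expect_identical(length(top_depleted(p, 1.0)), sum(!p$undefined))

  tied <- tibble::tibble(
    pam = c("AA", "AC", "CA", "CC"), sel_count = c(0, 0, 50, 50),
    ctl_count = c(25, 25, 25, 25), ppdv = c(0, 0, 2, 2),
    undefined = FALSE, efficacy_rank = 1:4
  )
  class(tied) <- c("ppdv_tbl", class(tied))
  expect_identical(top_depleted(tied, 0.25), "AA")
  expect_error(top_depleted(tied, 0), class = "pamscape_parameter_error")
})

test_that("depletion logo frequencies and log2 enrichment", {
  # all PAMs share T at position 3
  lg <- depletion_logo(c("AATA", "CCTA", "GGTA", "TTTA"))
  expect_equal(lg$pfm[3, "T"], 1)
  expect_equal(lg$log2fc[3, "T"], 2) # log2(1 / 0.25)
  expect_equal(lg$pfm[1, ], c(A = .25, C = .25, G = .25, T = .25))
  expect_true(all(abs(lg$log2fc[1, ]) < 1e-12))
  # freq 0.5 -> log2fc 1
  lg2 <- depletion_logo(c("GA", "GC", "TA", "CC"))
  expect_equal(lg2$log2fc[1, "G"], 1)
  expect_true(all(abs(rowSums(lg$pfm) - 1) < 1e-12))
  expect_error(depletion_logo(c("AA", "AAA")), class = "pamscape_consistency_error")
  # random sets keep rows stochastic
  set.seed(3)
  for (i in 1:5) {
    lgr <- depletion_logo(replicate(50, rand_dna(6)))
    expect_true(all(abs(rowSums(lgr$pfm) - 1) < 1e-12))
  }
})

test_that("PAM wheel weights are normalised 1 - PPDV over depleted PAMs", {
  mk <- function(pams, ppdv) {
    out <- tibble::tibble(pam = pams, sel_count = 0, ctl_count = 1,
                          ppdv = ppdv, undefined = FALSE,
                          efficacy_rank = seq_along(pams))
    class(out) <- c("ppdv_tbl", class(out))
    out
  }
  w1 <- pam_wheel(mk(c("AGGTAT", "ACCCCC"), c(0.0, 1.3)))
  expect_identical(nrow(w1), 1L)
  expect_identical(w1$trimer, "GGT")
  expect_equal(w1$weight, 1)

  w2 <- pam_wheel(mk(c("AGGTAT", "ATTTTT"), c(0.2, 0.8)))
  expect_equal(w2$weight[w2$trimer == "GGT"], 0.8)
  expect_equal(w2$weight[w2$trimer == "TTT"], 0.2)
  expect_equal(sum(w2$weight), 1)

  expect_warning(w0 <- pam_wheel(mk(c("AAAAAA", "CCCCCC"), c(1, 1.5))))
  expect_identical(nrow(w0), 0L)
  expect_error(pam_wheel(mk("AAAAAA", 0.5), positions = c(5, 6, 7)),
               class = "pamscape_parameter_error")
})

test_that("evenness index formula and its algebraic identity", {
  expect_true(all(evenness_index(c(a = 10, b = 10, c = 10))$index == 1))
  ev <- evenness_index(c(g1 = 50, g2 = 100, g3 = 200, g4 = 50))
  expect_equal(ev$index[ev$sgrna == "g1"], 400 / (4 * 50)) # = 2
  expect_identical(evenness_index(c(only = 123))$index, 1)
  expect_error(evenness_index(c(a = 0, b = 5)), class = "pamscape_parameter_error")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    counts <- setNames(sample(1:1000, n, replace = TRUE), paste0("g", 1:n))
    ev <- evenness_index(counts)
    expect_equal(sum(1 / (n * ev$index)), 1)
  }
})

test_that("evenness-corrected indel rates multiply and cap at 1", {
  expect_equal(corrected_indel(0.1, 2.0), 0.2)
  expect_equal(corrected_indel(0.3, 1.0), 0.3)
  expect_equal(corrected_indel(0.8, 2.0), 1.0)
  expect_error(corrected_indel(-0.1, 1), class = "pamscape_parameter_error")
})

test_that("GUIDE-seq on:off ratio and the zero-off policy", {
  expect_equal(on_off_ratio(100, c(10, 10)), 5)
  expect_equal(on_off_ratio(0, 5), 0)
  expect_equal(on_off_ratio(100, numeric(0)), 100)
  df <- tibble::tibble(
    site_id = c("s1", "s2"), on_reads = c(100, 40),
    off_reads = list(c(10, 10), numeric(0))
  )
  out <- guideseq_ratios(df)
  expect_equal(out$ratio, c(5, 40))
})

test_that("PAM tallying from fixed-layout reads drops ambiguous extractions", {
  reads <- c("GGGGAATAGGTT", "GGGGAATAGGTT", "GGGGCCCCCCTT", "GGGGNATAGGTT",
             "SHORT")
  tab <- count_pams_from_reads(reads, pam_offset = 4, k = 6)
  expect_identical(sum(tab$count), 3)
  expect_identical(tab$count[tab$pam == "AATAGG"], 2)
  expect_identical(tab$count[tab$pam == "CCCCCC"], 1)
})

test_that("hidden-rule recovery: NNTA depletion surfaces T/A at core positions", {
  sim <- simulate_depletion(k = 6, rule = "NNTA", retention = 0.05,
                            depth = 5e5, seed = 77)
  p <- compute_ppdv(sim$selected, sim$control)
  # rule-matching PAMs separate cleanly from the rest
  match_ppdv <- p$ppdv[p$pam %in% sim$matching]
  other_ppdv <- p$ppdv[!p$pam %in% sim$matching]
  expect_lt(max(match_ppdv), min(other_ppdv))
  expect_setequal(top_depleted(p, length(sim$matching) / 4096), sim$matching)
  lg <- depletion_logo(top_depleted(p, 0.1))
  expect_identical(names(which.max(lg$log2fc[3, ])), "T")
  expect_identical(names(which.max(lg$log2fc[4, ])), "A")
  expect_gt(lg$log2fc[3, "T"], 1)
  expect_gt(lg$log2fc[4, "A"], 1)
  expect_true(all(abs(lg$log2fc[c(1, 2, 5, 6), ]) < 0.3))
  # wheel mass concentrates on *TA trimers (positions 2-4)
  w <- pam_wheel(p)
  ta_mass <- sum(w$weight[substr(w$trimer, 2, 3) == "TA"])
  expect_gt(ta_mass, 0.6)
  expect_true(all(substr(w$trimer[1:4], 2, 3) == "TA"))
})
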