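be3_like <- editor_spec("BE3like", "NGG", "three_prime", 20, 4, 8)

test_that("match_pam follows IUPAC degeneracy, conservatively", {
  expect_true(match_pam("NGG", "AGG"))
  expect_false(match_pam("TTTV", "TTTT"))   # V excludes T
  expect_true(match_pam("TTTV", "TTTC"))
  expect_true(match_pam("NNGRRT", "AAGAGT"))
  expect_false(match_pam("NNGRRT", "AAGACT"))
  expect_false(match_pam("NGG", "NGG"))     # ambiguous observed base fails
  expect_error(match_pam("NGG", "AG"), "length")
  expect_error(match_pam("QGG", "AGG"), "IUPAC")
})

test_that("a constructed single-PAM site yields one preferential guide", {
  # target C at window position 6 of an NGG guide: protospacer starts at
  # offset 30-5 in the 61-mer; one AGG right after it, no other C in window
  s <- strrep("A", 61)
  substr(s, 31, 31) <- "C"               # target, protospacer pos 6
  substr(s, 46, 48) <- "AGG"             # PAM at protospacer end (26..45)
  tgt <- flanked_target(s, 30L, "+")
  got <- enumerate_guides(tgt, be3_like)
  expect_identical(nrow(got), 1L)
  expect_identical(got$window_pos, 6L)
  expect_identical(got$protospacer_start, 25L)
  expect_identical(got$protospacer_end, 45L)
  expect_identical(got$pam_seq, "AGG")
  expect_true(got$preferential)
  expect_true(classify_preferential(got[1, ]))
  expect_identical(strip_diag(got), strip_diag(brute_force_guides(tgt, be3_like)))
})

test_that("bystander cytosines on the target strand flip preferential off", {
  s <- strrep("A", 61)
  substr(s, 31, 31) <- "C"
  substr(s, 29, 29) <- "C"               # window pos 4: a bystander
  substr(s, 46, 48) <- "AGG"
  tgt <- flanked_target(s, 30L, "+")
  got <- enumerate_guides(tgt, be3_like)
  expect_identical(nrow(got), 1L)
  expect_false(got$preferential)
  expect_identical(got$bystanders, "4")
  # a G in the window is NOT a bystander (deaminase acts on one strand)
  s2 <- strrep("A", 61)
  substr(s2, 31, 31) <- "C"
  substr(s2, 29, 29) <- "G"
  substr(s2, 46, 48) <- "AGG"
  got2 <- enumerate_guides(flanked_target(s2, 30L, "+"), be3_like)
  expect_true(got2$preferential)
})

test_that("no PAM anywhere means zero candidates", {
  s <- strrep("A", 61)
  substr(s, 31, 31) <- "C"
  tgt <- flanked_target(s, 30L, "+")
  got <- enumerate_guides(tgt, be3_like)
  expect_identical(nrow(got), 0L)
})

test_that("degenerate all-N PAM with full window gives window-width count", {
  nnn <- editor_spec("open", "NNN", "three_prime", 20, 1, 20)
  set.seed(33)
  for (i in 1:20) {
    tgt <- random_center_target()
    got <- enumerate_guides(tgt, nnn)
    # centre of a 61-mer has >= 20+3 nt on both sides: all 20 placements fit
    expect_identical(nrow(got), 20L)
    expect_identical(got$window_pos, 1:20)
    expect_identical(strip_diag(got), strip_diag(brute_force_guides(tgt, nnn)))
  }
})

test_that("ambiguity codes in protospacer or PAM reject the placement", {
  s <- strrep("A", 61)
  substr(s, 31, 31) <- "C"
  substr(s, 46, 48) <- "AGG"
  substr(s, 27, 27) <- "N"               # inside the pos-6 protospacer
  got <- enumerate_guides(flanked_target(s, 30L, "+"), be3_like)
  expect_identical(nrow(got), 0L)
  # the N falls inside the protospacer of 4 of the 5 window placements
  expect_identical(attr(got, "rejected_ambiguous"), 4L)
})

test_that("oracle equivalence holds on random sequences and editors", {
  set.seed(101)
  panel <- load_panel()
  for (i in 1:150) {
    tgt <- random_center_target()
    e <- if (i %% 3 == 0) random_editor() else
      panel$editors[[sample(length(panel$editors), 1)]]
    expect_identical(strip_diag(enumerate_guides(tgt, e)),
                     strip_diag(brute_force_guides(tgt, e)),
                     info = paste("case", i, e$name))
  }
})

test_that("strand symmetry: reverse-complement leaves verdicts invariant", {
  set.seed(55)
  panel <- load_panel()
  for (i in 1:60) {
    tgt <- random_center_target()
    n <- nchar(tgt$sequence)
    mirror <- flanked_target(rc(tgt$sequence), n - 1L - tgt$target_offset,
                             if (tgt$target_strand == "+") "-" else "+")
    e <- panel$editors[[sample(length(panel$editors), 1)]]
    a <- enumerate_guides(tgt, e)
    b <- enumerate_guides(mirror, e)
    expect_identical(nrow(a), nrow(b))
    expect_identical(a$window_pos, b$window_pos)
    expect_identical(a$spacer_seq, b$spacer_seq)
    expect_identical(a$pam_seq, b$pam_seq)
    expect_identical(a$preferential, b$preferential)
    # intervals mirror: start' = n - end
    expect_identical(b$protospacer_start, n - a$protospacer_end)
  }
})

test_that("window widening and PAM tightening are monotone", {
  set.seed(77)
  for (i in 1:40) {
    tgt <- random_center_target()
    L <- 20L
    ws <- sample(3:10, 1); we <- ws + sample(0:4, 1)
    narrow <- editor_spec("narrow", "NG", "three_prime", L, ws, we)
    wide <- editor_spec("wide", "NG", "three_prime", L,
                        max(1L, ws - 2L), min(L, we + 2L))
    expect_lte(nrow(enumerate_guides(tgt, narrow)),
               nrow(enumerate_guides(tgt, wide)))
    loose <- editor_spec("loose", "NNG", "three_prime", L, ws, we)
    tight <- editor_spec("tight", "GNG", "three_prime", L, ws, we)
    expect_gte(nrow(enumerate_guides(tgt, loose)),
               nrow(enumerate_guides(tgt, tight)))
  }
})

test_that("window coordinate conventions match both Cas families", {
  # 3'-PAM editor: position 1 is PAM-DISTAL. A C at the 5'-most protospacer
  # base (20 nt upstream-of-PAM end) is window position 1.
  cas9 <- editor_spec("cas9", "NGG", "three_prime", 20, 1, 1)
  s <- strrep("A", 61)
  substr(s, 11, 11) <- "C"               # protospacer 11..30, PAM 31..33
  substr(s, 31, 33) <- "AGG"
  got <- enumerate_guides(flanked_target(s, 10L, "+"), cas9)
  expect_identical(nrow(got), 1L)
  expect_identical(got$window_pos, 1L)
  # the same C is NOT reachable at window position 1 when the PAM would sit
  # adjacent on the other side (no second AGG present)
  cas9b <- editor_spec("cas9b", "NGG", "three_prime", 20, 2, 2)
  expect_identical(nrow(enumerate_guides(flanked_target(s, 10L, "+"),
                                         cas9b)), 0L)

  # 5'-PAM (Cpf1-type) editor: position 1 is PAM-PROXIMAL. With PAM TTTA
  # immediately 5' of the protospacer, a C at protospacer base 8 is window
  # position 8.
  cpf1 <- editor_spec("cpf1", "TTTV", "five_prime", 23, 8, 8)
  s2 <- strrep("G", 61)
  substr(s2, 11, 14) <- "TTTA"           # PAM; protospacer 15..37
  substr(s2, 22, 22) <- "C"              # protospacer position 8
  got2 <- enumerate_guides(flanked_target(s2, 21L, "+"), cpf1)
  expect_identical(nrow(got2), 1L)
  expect_identical(got2$window_pos, 8L)
  expect_identical(got2$pam_seq, "TTTA")
  # shifting the window bound off position 8 loses the site
  cpf1b <- editor_spec("cpf1b", "TTTV", "five_prime", 23, 9, 9)
  expect_identical(nrow(enumerate_guides(flanked_target(s2, 21L, "+"),
                                         cpf1b)), 0L)
})

test_that("assess_variant fills consistent report sets", {
  fa <- generate_genome(1, 3000, 0.5, seed = 21)
  g <- read_genome(fa)
  panel <- load_panel()
  pv <- plant_variants(g, 30, seed = 21)
  for (v in pv$variants[1:10]) {
    rpt <- assess_variant(v, g, panel)
    expect_true(all(rpt$preferential_editors %in% rpt$targetable_editors))
    expect_identical(rpt$any_targetable,
                     length(rpt$targetable_editors) > 0L)
    gt <- pv$ground_truth[pv$ground_truth$variant_id == v$variant_id, ]
    expect_setequal(rpt$targetable_editors, gt$editor[gt$targetable])
    expect_setequal(rpt$preferential_editors, gt$editor[gt$preferential])
  }
  # poly-A context is untargetable by the whole panel
  g2 <- Biostrings::DNAStringSet(c(chr = paste0(strrep("A", 60), "C",
                                                strrep("A", 60))))
  rpt <- assess_variant(variant_record("chr", 61, "C", "T"), g2, panel)
  expect_false(rpt$any_targetable)
})

test_that("combine_panel implements union and intersection set algebra", {
  fa <- generate_genome(1, 3000, 0.6, seed = 31)
  g <- read_genome(fa)
  panel <- load_panel()
  pv <- plant_variants(g, 25, seed = 31)
  reports <- lapply(pv$variants, assess_variant, genome = g, panel = panel)
  sel <- c("BE3", "VQR-BE3", "dCpf1-eBE")
  u <- combine_panel(reports, "union", sel)
  x <- combine_panel(reports, "intersection", sel)
  for (i in seq_along(reports)) {
    hits <- reports[[i]]$targetable_editors
    expect_identical(u$targetable[i], length(intersect(hits, sel)) > 0L)
    expect_identical(x$targetable[i], all(sel %in% hits))
  }
  expect_true(all(x$targetable <= u$targetable))
  # single-editor selection: union equals intersection
  u1 <- combine_panel(reports, "union", "BE3")
  x1 <- combine_panel(reports, "intersection", "BE3")
  expect_identical(u1, x1)
  expect_error(combine_panel(reports, "union", character(0)), "empty")
})

test_that("panel_statistics counts match a brute-force tally", {
  fa <- generate_genome(1, 4000, 0.5, seed = 41)
  g <- read_genome(fa)
  panel <- load_panel()
  pv <- plant_variants(g, 40, seed = 41)
  reports <- lapply(pv$variants, assess_variant, genome = g, panel = panel)
  attr(reports, "panel_editors") <- names(panel$editors)
  st <- panel_statistics(reports)
  gt <- pv$ground_truth
  for (e in names(panel$editors)) {
    expect_identical(st$n_targetable[st$editor == e],
                     sum(gt$targetable[gt$editor == e]))
    expect_identical(st$n_preferential[st$editor == e],
                     sum(gt$preferential[gt$editor == e]))
  }
  any_true <- sum(tapply(gt$targetable, gt$variant_id, any))
  expect_identical(st$n_targetable[st$editor == "any"], as.integer(any_true))
  expect_equal(st$frac_targetable[st$editor == "any"], any_true / 40)
})

test_that("scan_sequence matches per-site enumeration and symmetry", {
  set.seed(61)
  panel <- select_editors(load_panel(), c("BE3", "dCpf1-eBE", "SaKKH-BE3"))
  s <- random_seq(200)
  got <- scan_sequence(s, panel)
  # brute-force: every C/G site, every editor, via the naive oracle
  chars <- strsplit(s, "")[[1]]
  exp_rows <- 0L
  for (i in which(chars %in% c("C", "G"))) {
    tgt <- flanked_target(s, i - 1L, if (chars[i] == "C") "+" else "-")
    for (e in panel$editors) {
      o <- brute_force_guides(tgt, e)
      exp_rows <- exp_rows + nrow(o)
      sub <- got[got$target_index == i - 1L & got$editor == e$name, ]
      expect_identical(sub$spacer_seq, o$spacer_seq)
      expect_identical(sub$window_pos, o$window_pos)
      expect_identical(sub$preferential, o$preferential)
    }
  }
  expect_identical(nrow(got), exp_rows)
  # palindromic-context property: mirror scan has the same candidate count
  got_rc <- scan_sequence(rc(s), panel)
  expect_identical(nrow(got_rc), nrow(got))
  expect_identical(sort(got_rc$spacer_seq), sort(got$spacer_seq))
  # no C and no G -> no targets
  at_editor <- editor_spec("at", "WWW", "three_prime", 5, 1, 5)
  expect_identical(nrow(scan_sequence(strrep("AT", 30), at_editor)), 0L)
  expect_error(scan_sequence("ACGTX", load_panel()), "non-nucleotide")
})
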