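frame <- read_reference_frame()

test_that("the alpha motif filter keeps exactly AP-x(9-10)-C carriers", {
  cand <- alpha_candidates(
    id = c("nine", "eight", "ten", "none"),
    sequence = c(paste0("MAP", strrep("Q", 9), "CKL"),
                 paste0("MAP", strrep("Q", 8), "CKL"),
                 paste0("MAP", strrep("Q", 10), "CKL"),
                 "MKLQQQQQQQQQQQQQQQ"))
  kept <- filter_by_alpha_motif(cand)
  expect_identical(kept$id, c("nine", "ten"))
  # idempotent
  expect_identical(filter_by_alpha_motif(kept), kept)
  expect_warning(filter_by_alpha_motif(cand[0, ]), "empty")
})

test_that("generator-planted motifs are recovered exactly among decoys", {
  g <- gen_alpha_sequences(class_mix = c(closed = 6, open = 4, open_braced = 2),
                           strain_count = 1, n_decoys = 38, seed = 21)
  expect_identical(nrow(g$candidates), 50L)
  kept <- filter_by_alpha_motif(g$candidates)
  expect_identical(sort(kept$id), sort(g$truth$id))
})

test_that("maturation cleaves after the AxA site nearest the frame start", {
  cand <- alpha_candidates("t1", paste0("MKLSASA", "AP", strrep("N", 9), "CGG"))
  m <- cleave_mature(cand, frame)
  expect_identical(substr(m$mature_sequence, 1, 2), "AP")
  expect_identical(m$cleavage_site_index, 7L)
  expect_identical(m$flags[[1]], character(0))

  # two AxA sites: the one giving the smaller N-terminal extension wins
  sig <- paste0("MATA", strrep("L", 16), "ASA")        # AxA at 2 and 21
  cand2 <- alpha_candidates("t2", paste0(sig, "AP", strrep("N", 9), "CGG"))
  m2 <- cleave_mature(cand2, frame)
  expect_identical(m2$cleavage_site_index, nchar(sig))

  # no AxA: full sequence, flagged
  cand3 <- alpha_candidates("t3", paste0("MKLS", "AP", strrep("N", 9), "CGG"))
  m3 <- cleave_mature(cand3, frame)
  expect_identical(m3$mature_sequence, cand3$sequence)
  expect_true("no_AxA_site" %in% m3$flags[[1]])

  expect_error(cleave_mature(alpha_candidates("t4", "MK"), frame), "malformed")
})

test_that("mature length plus cleavage index reconstructs the precursor", {
  g <- gen_alpha_sequences(seed = 4, strain_count = 3)
  hits <- filter_by_alpha_motif(g$candidates)
  for (i in seq_len(nrow(hits))) {
    m <- cleave_mature(hits[i, ], frame)
    expect_identical(m$cleavage_site_index + nchar(m$mature_sequence),
                     nchar(m$precursor))
  }
})

test_that("cross-strain deduplication keeps the most complete read", {
  base <- paste0("AP", strrep("N", 9), "CGG", strrep("K", 20))
  subs <- tibble::tibble(
    id = c("b", "a", "trunc", "noisy"),
    strain = c("s1", "s2", "s3", "s4"),
    precursor = base,
    mature_sequence = c(base, base, substr(base, 6, nchar(base)),
                        sub("KKKK$", "KXKX", base)),
    cleavage_site_index = 0L,
    flags = list(character(0), character(0), character(0), character(0)))
  out <- deduplicate_across_strains(subs)
  expect_identical(nrow(out), 1L)
  expect_identical(out$id, "a")  # longest, fewest X, then smallest id
})

test_that("tandem double-motif reads are flagged and excluded", {
  unit <- paste0("AP", strrep("N", 9), "CGG", strrep("K", 10))
  subs <- tibble::tibble(
    id = c("tandem", "left", "right"),
    strain = "s1",
    precursor = c(paste0(unit, "ADA", unit), unit, unit),
    mature_sequence = c(paste0(unit, "ADA", unit), unit, unit),
    cleavage_site_index = 0L,
    flags = list(character(0), character(0), character(0)))
  out <- deduplicate_across_strains(subs)
  expect_identical(nrow(out), 1L)
  excl <- attr(out, "excluded")
  expect_identical(excl$id, "tandem")
  expect_true("tandem_read" %in% excl$flags[[1]])
})

test_that("form classification reads the diagnostic insertions", {
  ref <- frame$sequence
  expect_identical(as.character(classify_form(ref, frame)$form_class),
                   "closed")
  cys <- frame$chromophore_cys_column
  open_seq <- paste0(substr(ref, 1, cys - 1), "D", substr(ref, cys, nchar(ref)))
  expect_identical(as.character(classify_form(open_seq, frame)$form_class),
                   "open")
  at <- frame$s2_h1_gap_span[1] + 3L
  braced <- paste0(substr(open_seq, 1, at + 1L), "GDSGVAT",
                   substr(open_seq, at + 2L, nchar(open_seq)))
  expect_identical(as.character(classify_form(braced, frame)$form_class),
                   "open_braced")
  # insertions of 1-4 residues in the S2-H1 span stay open
  small <- paste0(substr(open_seq, 1, at + 1L), "GDS",
                  substr(open_seq, at + 2L, nchar(open_seq)))
  expect_identical(as.character(classify_form(small, frame)$form_class),
                   "open")
  # an unrelated sequence is unclassifiable
  junk <- classify_form(strrep("KLMNQRST", 8), frame)
  expect_identical(as.character(junk$form_class), "unclassified")
})

test_that("generator class labels are recovered for all noiseless cases", {
  for (seed in c(2, 13, 101)) {
    g <- gen_alpha_sequences(seed = seed, tandem = TRUE)
    ct <- catalog_alpha_subunits(g$candidates)
    expect_identical(nrow(ct), 22L)
    truth <- unique(g$truth[, c("mature_true", "class")])
    got <- merge(ct, truth, by.x = "mature_sequence", by.y = "mature_true")
    expect_identical(nrow(got), 22L)
    expect_identical(as.character(got$form_class), got$class)
  }
})

test_that("theoretical masses follow the residue table and bilin arithmetic", {
  # independent oracle: 3 glycines + one water
  expect_equal(compute_mature_mass("GGG", n_bilins = 0), 189.17,
               tolerance = 1e-4)
  # one PEB adds exactly 586.7 Da, at any k
  for (k in 0:3) {
    expect_equal(compute_mature_mass("ACDEFGHIKLMNPQRSTVWY", k + 1) -
                   compute_mature_mass("ACDEFGHIKLMNPQRSTVWY", k), 586.7)
  }
  # +16 Da methionine-oxidation ladder
  expect_equal(compute_mature_mass("MMM", 0, 2) - compute_mature_mass("MMM", 0, 0),
               32)
  err <- tryCatch(compute_mature_mass("GGXGGX"), error = identity)
  expect_match(conditionMessage(err), "3, 6")
})

test_that("candidates round-trip through FASTA with strain tags", {
  g <- gen_alpha_sequences(class_mix = c(closed = 2, open = 1, open_braced = 0),
                           seed = 3, strain_count = 2)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alpha_fasta(g$candidates, f)
  back <- read_alpha_fasta(f)
  expect_identical(back$id, g$candidates$id)
  expect_identical(back$strain, g$candidates$strain)
  expect_identical(back$sequence, g$candidates$sequence)
})
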