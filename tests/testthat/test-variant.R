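test_that("codon numbering maps coding positions to residues", {
  expect_equal(codon_index(1376), 459L)
  expect_equal(codon_index(559), 187L)
  expect_equal(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  # non-decreasing, and positions 3k-2..3k map to k
  for (k in c(1L, 2L, 187L, 459L, 1000L)) {
    expect_equal(codon_index(c(3 * k - 2, 3 * k - 1, 3 * k)), rep(k, 3))
  }
  expect_error(codon_index(0), ">= 1")
})

test_that("variants apply with reference checking", {
  expect_equal(apply_variant("ATGTTT", gene_variant("substitution", 4, "T", "A")),
               "ATGATT")
  expect_equal(apply_variant("ATGGGAATAA", gene_variant("deletion", 4, "G")),
               "ATGGAATAA")
  expect_equal(
    apply_variant("ATGTCCTAA", gene_variant("multi_substitution", 4, "TCC", "ATT")),
    "ATGATTTAA")
  expect_error(
    apply_variant("ATGTTT", gene_variant("substitution", 4, "G", "A")),
    "expected 'G', found 'T'")
  expect_error(
    apply_variant("ATG", gene_variant("substitution", 9, "G", "A")),
    "past the end")
  expect_error(gene_variant("multi_substitution", 1, "AC", "A"), "ref")
  expect_error(gene_variant("deletion", 1, "A", "C"), "empty alt")
})

test_that("consequences cover missense, nonsense, synonymous, frameshift", {
  cons <- call_consequence("ATGTCCTAA", gene_variant("substitution", 5, "C", "T"))
  expect_length(cons, 1L)
  expect_equal(cons[[1]]$kind, "missense")
  expect_equal(cons[[1]]$residue_index, 2L)
  expect_equal(cons[[1]]$wt_aa, "S")
  expect_equal(cons[[1]]$mut_aa, "F")

  # adjacent substitutions hitting two codons: one missense, one nonsense
  cons <- call_consequence("ATGCAACAGTGA",
                           list(gene_variant("substitution", 6, "A", "T"),
                                gene_variant("substitution", 7, "C", "T")))
  expect_length(cons, 2L)
  expect_equal(cons[[1]]$kind, "missense")
  expect_equal(format(cons[[1]]), "Q2H")
  expect_equal(cons[[2]]$kind, "nonsense")
  expect_equal(format(cons[[2]]), "Q3*")

  # triple substitution within one codon: a single missense call
  cons <- call_consequence("ATGTCCTAA",
                           gene_variant("multi_substitution", 4, "TCC", "ATT"))
  expect_length(cons, 1L)
  expect_equal(cons[[1]]$kind, "missense")
  expect_equal(cons[[1]]$wt_aa, "S")
  expect_equal(cons[[1]]$mut_aa, "I")

  # single-base deletion: frameshift at codon 2 with a stop at codon 3
  # (manual oracle: ATGGAATAA translates M-E-*)
  cons <- call_consequence("ATGGGAATAA", gene_variant("deletion", 4, "G"))
  expect_equal(cons[[1]]$kind, "frameshift")
  expect_equal(cons[[1]]$residue_index, 2L)
  expect_equal(cons[[1]]$stop_codon_index, 3L)
  expect_false(cons[[1]]$no_stop_found)

  # frameshift with no downstream in-frame stop is flagged
  cons <- call_consequence("ATGAAAAAAAAA", gene_variant("deletion", 4, "A"))
  expect_true(cons[[1]]$no_stop_found)
  expect_true(is.na(cons[[1]]$stop_codon_index))

  cons <- call_consequence("ATGTCCTAA", gene_variant("substitution", 6, "C", "T"))
  expect_equal(cons[[1]]$kind, "synonymous")

  expect_error(call_consequence("TTGTCCTAA",
                                gene_variant("substitution", 5, "C", "T")),
               "ATG")
  expect_error(call_consequence("ATGTCCTAA",
                                list(gene_variant("substitution", 5, "C", "T"),
                                     gene_variant("substitution", 5, "C", "G"))),
               "overlap")
})

test_that("single-base reversion design enumerates codon neighbors", {
  rev <- design_single_base_reversion("ATT", "S")
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$position, 2L)
  expect_equal(rev$base, "G")
  expect_equal(rev$codon, "AGT")

  # stop-reachable edits of TGG, checked against full enumeration
  rev <- design_single_base_reversion("TGG", "*")
  expect_equal(rev$codon, c("TAG", "TGA"))
  expect_equal(rev$position, c(2L, 3L))

  expect_message(rev <- design_single_base_reversion("GGG", "G"), "already")
  expect_equal(nrow(rev), 0L)
  expect_true(isTRUE(attr(rev, "already_encodes")))
})

test_that("reversion design is exhaustive over all codons and targets", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  targets <- c(unique(Biostrings::GENETIC_CODE), "*")
  for (codon in codons) {
    for (aa in sample(targets, 5)) {
      res <- suppressMessages(design_single_base_reversion(codon, aa))
      if (nrow(res) == 0) next
      for (r in seq_len(nrow(res))) {
        got <- res$codon[r]
        # differs at exactly one position and translates to the target
        expect_equal(sum(strsplit(got, "")[[1]] != strsplit(codon, "")[[1]]), 1L)
        expect_equal(translate_codon(got), aa)
      }
    }
  }
  # completeness on one full pair set: every neighbor reaching the target
  # is returned
  for (codon in sample(codons, 8)) {
    for (aa in targets) {
      res <- suppressMessages(design_single_base_reversion(codon, aa))
      expected_n <- 0L
      for (pos in 1:3) for (b in setdiff(bases, substr(codon, pos, pos))) {
        cand <- codon; substr(cand, pos, pos) <- b
        if (unname(Biostrings::GENETIC_CODE[[cand]]) == aa &&
            unname(Biostrings::GENETIC_CODE[[codon]]) != aa) {
          expected_n <- expected_n + 1L
        }
      }
      expect_equal(nrow(res), expected_n, info = paste(codon, aa))
    }
  }
})

test_that("degenerate site scanning matches the printed decamers", {
  hits <- scan_restriction_sites("TTCTACAGTA", "SfcI")
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "+")
  expect_equal(nrow(scan_restriction_sites("TTCTACATTA", "SfcI")), 0L)
  expect_equal(nrow(scan_restriction_sites("TTCTACTCCA", "SfcI")), 0L)
  expect_error(scan_restriction_sites("TTCUACAGTA", "SfcI"), "A/C/G/T")
  expect_error(scan_restriction_sites("ACGT", list(pattern = "CZG")), "IUPAC")
})

test_that("site scanning equals naive matching on random sequences", {
  withr::with_seed(99, {
    enzymes <- restriction_enzymes()
    for (i in 1:25) {
      seq <- random_dna(sample(10:120, 1))
      nm <- sample(names(enzymes), 1)
      got <- scan_restriction_sites(seq, nm, both_strands = TRUE)
      want <- oracle_scan(seq, enzymes[[nm]], both_strands = TRUE)
      expect_equal(got$start, want$start, info = paste(nm, seq))
    }
    # both-strand scan of a palindromic pattern equals single-strand scan
    for (i in 1:10) {
      seq <- random_dna(60)
      both <- scan_restriction_sites(seq, "SfcI", both_strands = TRUE)
      fwd <- scan_restriction_sites(seq, "SfcI", both_strands = FALSE)
      expect_equal(both$start, fwd$start)
    }
  })
})
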