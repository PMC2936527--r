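test_that("default configuration partitions the 20 amino acids into 8 groups", {
  cfg <- colorfy_config()
  expect_length(cfg$groups, 8L)
  expect_setequal(unlist(cfg$groups), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_error(colorfy_config(groups = list(all = LETTERS[1:20])),
               "partition")
})

test_that("composition profiles count residues, groups, and gaps", {
  aln <- alignment(sprintf("s%d", 1:4), c("A", "A", "A", "V"))
  prof <- column_composition(aln, 1)
  expect_equal(prof$residue_counts, c(A = 3L, V = 1L))
  expect_equal(prof$group_counts, c(GA = 3L, VLI = 1L))
  expect_equal(prof$occupancy, 4L)

  gappy <- alignment(sprintf("s%d", 1:4), c("A", "A", "-", "-"))
  prof2 <- column_composition(gappy, 1)
  expect_equal(prof2$occupancy, 2L)
  expect_equal(prof2$gap_count, 2L)
  # percentages use occupancy, so A is at 100%
  ann <- classify_column(prof2)
  expect_equal(ann$driving_percent, 100)
  expect_equal(ann$band, "Red")

  expect_error(column_composition(aln, 2), "out of range")
})

test_that("the three categories follow the printed thresholds and precedence", {
  mk <- function(residues) pkg_classify_column(residues)

  ann <- mk(c(rep("A", 7), rep("V", 3)))
  expect_equal(ann$category, "MajorityIdentity")
  expect_equal(ann$driving_percent, 70)
  expect_equal(ann$band, "Blue")
  expect_equal(sum(ann$residue_shades == "dark"), 7L)
  expect_true(all(ann$residue_shades[8:10] == "uncolored"))

  ann <- mk(c(rep("L", 6), rep("V", 4)))
  expect_equal(ann$category, "ConservedMinority")
  expect_equal(ann$driving_percent, 100)
  expect_equal(ann$band, "Red")
  expect_true(all(ann$residue_shades == "light"))

  ann <- mk(c(rep("A", 5), rep("D", 5)))
  expect_equal(ann$category, "InsufficientConservation")
  expect_null(ann$band)
  expect_true(all(ann$residue_shades == "uncolored"))

  # identity at 70% takes precedence over same-group at 100%
  ann <- mk(c(rep("S", 7), rep("T", 3)))
  expect_equal(ann$category, "MajorityIdentity")
  expect_equal(ann$driving_percent, 70)
  expect_equal(ann$band, "Blue")
  expect_true(all(ann$residue_shades[1:7] == "dark"))
  expect_true(all(ann$residue_shades[8:10] == "light"))
})

test_that("percentage bands are half-open with a closed top", {
  cfg <- colorfy_config()
  expect_equal(percent_band(61, cfg), "Blue")
  expect_equal(percent_band(70, cfg), "Blue")
  expect_equal(percent_band(70.5, cfg), "Blue")
  expect_equal(percent_band(71, cfg), "Green")
  expect_equal(percent_band(80.9, cfg), "Green")
  expect_equal(percent_band(81, cfg), "Gold")
  expect_equal(percent_band(91, cfg), "Red")
  expect_equal(percent_band(100, cfg), "Red")
  expect_null(percent_band(60.9, cfg))
  expect_null(percent_band(0, cfg))
  expect_error(percent_band(101, cfg), "0, 100")
})

test_that("whole alignments classify column by column", {
  aln <- alignment(c("a", "b", "c"), c("AAA", "AAA", "AAV"))
  anns <- colorfy_alignment(aln)
  expect_length(anns, 3L)
  expect_equal(vapply(anns, `[[`, "", "category"),
               rep("MajorityIdentity", 3))
  expect_equal(vapply(anns, `[[`, 0, "driving_percent"),
               c(100, 100, 200 / 3), tolerance = 1e-9)
  expect_equal(vapply(anns, `[[`, "", "band"), c("Red", "Red", "Blue"))
  expect_equal(anns[[3]]$residue_shades, c("dark", "dark", "uncolored"))

  ident <- alignment(c("a", "b"), c("MKV", "MKV"))
  for (ann in colorfy_alignment(ident)) {
    expect_equal(ann$category, "MajorityIdentity")
    expect_equal(ann$band, "Red")
    expect_true(all(ann$residue_shades == "dark"))
  }
})

test_that("classification matches the brute-force oracle on all small columns", {
  # every column of 2..6 residues over a 4-letter alphabet spanning
  # same-group and cross-group compositions
  alphabet <- c("A", "V", "S", "P")
  for (n in 2:6) {
    grids <- expand.grid(rep(list(alphabet), n), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grids))) {
      col <- unlist(grids[r, ], use.names = FALSE)
      got <- pkg_classify_column(col)
      want <- oracle_classify(col)
      expect_equal(got$category, want$category,
                   info = paste(col, collapse = ""))
      if (want$category != "InsufficientConservation") {
        expect_equal(got$driving_percent, want$percent, tolerance = 1e-9)
        expect_equal(got$band, oracle_band(want$percent))
      }
    }
  }
})

test_that("classification invariants hold on random columns", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(2:15, 1)
      col <- sample(aas, n, replace = TRUE,
                    prob = c(10, rep(1, 19))[sample(20)])
      ann <- pkg_classify_column(col)
      # exactly one category, band iff not InsufficientConservation
      expect_true(ann$category %in% c("MajorityIdentity", "ConservedMinority",
                                      "InsufficientConservation"))
      expect_equal(is.null(ann$band),
                   ann$category == "InsufficientConservation")
      if (!is.null(ann$band)) expect_gte(ann$driving_percent, 61)
      # conserved minority never uses dark shades
      if (ann$category == "ConservedMinority") {
        expect_false(any(ann$residue_shades == "dark"))
      }
      # row permutation leaves the category and percent unchanged
      perm <- sample(n)
      ann2 <- pkg_classify_column(col[perm])
      expect_equal(ann2$category, ann$category)
      expect_equal(ann2$driving_percent, ann$driving_percent)
    }
  })
})

test_that("gap-only columns warn and stay uncolored", {
  aln <- alignment(c("a", "b"), c("-A", "-A"))
  expect_warning(ann <- classify_column(column_composition(aln, 1)),
                 "only gaps")
  expect_equal(ann$category, "InsufficientConservation")
  expect_null(ann$band)
})

test_that("ambiguity letters count toward occupancy but never lead", {
  # 3 X vs 2 A: X is the most common letter but cannot be the majority
  ann <- pkg_classify_column(c("X", "X", "X", "A", "A"))
  expect_equal(ann$category, "InsufficientConservation")
  # X dilutes the denominator: 3 A of 5 residues is 60%, not 100%
  ann2 <- pkg_classify_column(c("A", "A", "A", "X", "X"))
  expect_equal(ann2$category, "InsufficientConservation")
})

test_that("mutation boxes map ungapped positions through gaps", {
  aln <- alignment(c("q", "r"), c("M-KV", "MAKV"))
  anns <- colorfy_alignment(aln)
  box <- annotate_mutation_box(aln, anns, "q", 2, "AAA", "AGA")
  expect_equal(box$column, 3L)
  expect_equal(box$wt_aa, "K")
  expect_equal(box$mut_aa, "R")
  expect_error(annotate_mutation_box(aln, anns, "q", 5, "AAA", "AGA"),
               "beyond")
  expect_error(annotate_mutation_box(aln, anns, "zz", 1, "AAA", "AGA"),
               "unknown")
  expect_error(annotate_mutation_box(aln, anns, "q", 1, "AUX", "AGA"),
               "codon")
})

test_that("a planted fully conserved column reports MajorityIdentity/Red", {
  plan <- data.frame(category = c("InsufficientConservation",
                                  "MajorityIdentity",
                                  "InsufficientConservation"),
                     percent = c(NA, 100, NA))
  g <- gen_alignment(11, plan, seed = 3)
  anns <- colorfy_alignment(g$alignment)
  id <- g$alignment$ids[1]
  box <- annotate_mutation_box(g$alignment, anns, id, 2, "TCC", "TTC")
  expect_equal(box$category, "MajorityIdentity")
  expect_equal(box$band, "Red")
})

test_that("rendering is deterministic and covers all formats", {
  plan <- data.frame(category = rep(c("MajorityIdentity",
                                      "ConservedMinority",
                                      "InsufficientConservation"),
                                    length.out = 20),
                     percent = rep(c(80, 100, NA), length.out = 20))
  g <- gen_alignment(5, plan, seed = 11)
  anns <- colorfy_alignment(g$alignment)
  html1 <- render_colorfy(g$alignment, anns, format = "html")
  html2 <- render_colorfy(g$alignment, anns, format = "html")
  expect_identical(html1, html2)
  expect_true(any(grepl("legend", html1)))
  ansi <- render_colorfy(g$alignment, anns, format = "ansi")
  expect_length(ansi, 5L)
  tsv <- render_colorfy(g$alignment, anns, format = "tsv")
  expect_length(tsv, 21L)
  expect_error(render_colorfy(g$alignment, anns, format = "pdf"))

  # single-residue alignment: one span, dark red
  one <- alignment("a", "A")
  h <- render_colorfy(one, colorfy_alignment(one), format = "html")
  expect_equal(sum(grepl("span class=\"res red-dark\"", h, fixed = TRUE)), 1L)
})
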