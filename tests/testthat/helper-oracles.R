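# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive and separate from the package code paths they check.

oracle_groups <- list(
  GA = c("G", "A"), VLI = c("V", "L", "I"), FYW = c("F", "Y", "W"),
  CM = c("C", "M"), KRH = c("K", "R", "H"), DENQ = c("D", "E", "N", "Q"),
  ST = c("S", "T"), P = "P"
)

oracle_group_of <- function(aa) {
  for (g in names(oracle_groups)) {
    if (aa %in% oracle_groups[[g]]) return(g)
  }
  NA_character_
}

# direct transcription of the three classification rules on a gap-free
# residue vector
oracle_classify <- function(residues) {
  n <- length(residues)
  counts <- table(residues)
  id_pct <- 100 * max(counts) / n
  grp <- vapply(residues, oracle_group_of, "")
  gcounts <- table(grp[!is.na(grp)])
  grp_pct <- if (length(gcounts)) 100 * max(gcounts) / n else 0
  if (id_pct >= 61) {
    list(category = "MajorityIdentity", percent = id_pct)
  } else if (grp_pct >= 61 && id_pct <= 60) {
    list(category = "ConservedMinority", percent = grp_pct)
  } else {
    list(category = "InsufficientConservation", percent = NA_real_)
  }
}

oracle_band <- function(pct) {
  if (is.na(pct) || pct < 61) return(NA_character_)
  if (pct < 71) "Blue" else if (pct < 81) "Green" else if (pct < 91) "Gold" else "Red"
}

# classify one column through the package, from a residue vector
pkg_classify_column <- function(residues) {
  aln <- alignment(sprintf("s%d", seq_along(residues)), residues)
  classify_column(column_composition(aln, 1L))
}

# naive O(n*m) IUPAC matcher over both strands
iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  match_at <- function(s, pat, i) {
    all(vapply(seq_len(nchar(pat)), function(j) {
      grepl(substr(s, i + j - 1L, i + j - 1L),
            iupac_expand[[substr(pat, j, j)]], fixed = TRUE)
    }, TRUE))
  }
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  m <- nchar(pattern)
  hits <- data.frame(start = integer(0), strand = character(0))
  for (i in seq_len(max(nchar(seq) - m + 1L, 0L))) {
    if (match_at(seq, pattern, i)) {
      hits <- rbind(hits, data.frame(start = i, strand = "+"))
    }
  }
  if (both_strands) {
    rs <- revcomp(seq)
    for (i in seq_len(max(nchar(seq) - m + 1L, 0L))) {
      if (match_at(rs, pattern, i)) {
        fstart <- nchar(seq) - (i + m - 1L) + 1L
        if (!fstart %in% hits$start) {
          hits <- rbind(hits, data.frame(start = fstart, strand = "-"))
        }
      }
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

# brute-force metabolite reachability by path enumeration (fixed point on
# explicit path extension, not a graph library)
oracle_reachable <- function(reactions, active_enzymes, sources) {
  rx <- reactions[reactions$enzyme %in% active_enzymes, , drop = FALSE]
  reach <- unique(sources)
  repeat {
    add <- rx$product[rx$substrate %in% reach & !rx$product %in% reach]
    if (length(add) == 0L) break
    reach <- c(reach, unique(add))
  }
  reach
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
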