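test_that("codon_index maps cDNA positions onto codons", {
  expect_equal(codon_index(244), 82L)
  expect_equal(codon_index(1), 1L)
  expect_equal(codon_index(1279), 427L)
  expect_equal(codon_index(c(3, 4, 564)), c(1L, 2L, 188L))
  expect_error(codon_index(0), "positive")
})

test_that("substitutions apply with reference checking and are involutions", {
  cds <- synthetic_fuca1_cds()
  mut <- apply_substitution(cds, "c.244C>T")
  expect_equal(substr(mut$cds, 244, 246), "TAG")
  expect_equal(substr(cds$cds, 244, 246), "CAG")  # original untouched
  back <- apply_substitution(mut, list(position = 244, ref = "T", alt = "C"))
  expect_identical(back$cds, cds$cds)
  expect_error(apply_substitution(cds, "c.244G>T"), "expected G, found C")
  expect_error(
    apply_substitution(cds, list(position = 10, ref = "A", alt = "A")),
    "must differ"
  )
})

test_that("the three clinical substitutions produce the printed stops", {
  cds <- synthetic_fuca1_cds()
  rep <- variant_report(cds, c("c.244C>T", "c.564G>A", "c.1279C>T"))
  expect_equal(rep$codon_index, c(82L, 188L, 427L))
  expect_equal(rep$class, rep("nonsense", 3))
  expect_equal(rep$stop_codon, c("UAG", "UGA", "UAA"))
  expect_equal(rep$leakiness_rank, c(2L, 1L, 3L))
  expect_equal(rep$near_cognate,
               c("Gln/Tyr/Lys", "Trp/Cys/Arg", "Gln/Tyr/Lys"))
})

test_that("classify_variant distinguishes nonsense, silent and missense", {
  cds <- coding_sequence("ATGCTGAAATTTCAGGGCTAA")
  non <- classify_variant(cds, apply_substitution(cds, "c.13C>T"))
  expect_equal(non$class, "nonsense")
  expect_equal(non$context$stop_codon, "TAG")
  # CTG -> CTA is synonymous (both Leu)
  sil <- classify_variant(cds, apply_substitution(cds, "c.6G>A"))
  expect_equal(sil$class, "silent")
  mis <- classify_variant(cds, apply_substitution(cds, "c.7A>C"))
  expect_equal(mis$class, "missense")
  expect_error(classify_variant(cds$cds, cds$cds), "exactly 1")
})

test_that("extract_scc returns the 23-nt window with padding at the ends", {
  # stop at codon 5 of a 60-nt CDS: 12 nt upstream available, full window
  cds60 <- paste0("ATG", "AAA", "CCC", "GGG", "TGA",
                  paste(rep("ACT", 14), collapse = ""), "TAA")
  ctx <- extract_scc(cds60, 5)
  expect_equal(nchar(ctx$scc_23nt), 23)
  expect_false(ctx$padded)
  expect_equal(ctx$upstream_10nt, "GAAACCCGGG")
  # stop at codon 2: only 3 nt upstream, padded
  ctx2 <- extract_scc(paste0("ATG", "TGA", strrep("ACT", 5), "TAA"), 2)
  expect_true(ctx2$padded)
  expect_equal(ctx2$upstream_10nt, "-------ATG")
  expect_equal(nchar(ctx2$scc_23nt), 23)
  expect_error(extract_scc(cds60, 3), "not a stop")
})

test_that("leakiness ranks follow UGA < UAG < UAA and reject non-stops", {
  expect_equal(leakiness_rank("UGA"), 1L)
  expect_equal(leakiness_rank("UAA"), 3L)
  expect_equal(leakiness_rank(c("TGA", "TAG", "TAA")), c(1L, 2L, 3L))
  expect_true(leakiness_rank("UGA") < leakiness_rank("UAG"))
  expect_true(leakiness_rank("UAG") < leakiness_rank("UAA"))
  expect_equal(leakiness_class("TGA"), "leaky")
  expect_error(leakiness_rank("AAA"), "Not a stop codon")
})

test_that("motif distance measures the 7-nt window against UGA CUAG", {
  expect_equal(motif_distance("TGACTAG"), 0L)
  expect_equal(motif_distance("UGACUAG"), 0L)  # RNA normalization
  # positionwise oracle: TAAGGGG vs TGACTAG differs at positions 2,4,5,6
  expect_equal(motif_distance("TAAGGGG"), 4L)
  ctx <- extract_scc(paste0("ATG", "TGA", "CTAGAAACTT", "TAA"), 2)
  expect_equal(ctx$motif_distance, 0L)
  expect_error(motif_distance("TGACT"), "7 nucleotides")
})

test_that("near-cognate candidates decode within one mismatch of the stop", {
  expect_setequal(near_cognate_candidates("UGA"), c("Trp", "Cys", "Arg"))
  expect_setequal(near_cognate_candidates("UAG"), c("Gln", "Tyr", "Lys"))
  expect_setequal(near_cognate_candidates("UAA"), c("Gln", "Tyr", "Lys"))
  # brute force over the standard genetic code
  gc <- Biostrings::GENETIC_CODE
  three <- c(W = "Trp", C = "Cys", R = "Arg", Q = "Gln", Y = "Tyr", K = "Lys")
  hamming1 <- function(codon) {
    out <- character(0)
    for (i in 1:3) for (b in c("A", "C", "G", "T")) {
      cand <- codon
      substr(cand, i, i) <- b
      if (cand != codon) out <- c(out, cand)
    }
    out
  }
  for (stop in c("TGA", "TAG", "TAA")) {
    aa_near <- unique(gc[hamming1(stop)])
    for (cand in near_cognate_candidates(stop)) {
      one_letter <- names(three)[three == cand]
      expect_true(one_letter %in% aa_near)
    }
  }
})

test_that("truncation size follows the stated conventions", {
  cds <- synthetic_fuca1_cds()
  t1 <- predicted_truncation(cds, 2)
  expect_equal(t1$residues, 1L)
  t427 <- predicted_truncation(cds, 427, convention = "precursor",
                               mean_residue_da = 110)
  expect_equal(t427$residues, 426L)
  expect_equal(t427$mass_kda, 46.86, tolerance = 1e-8)
  t_mat <- predicted_truncation(cds, 427, convention = "mature")
  expect_equal(t_mat$residues, 426L - 27L)
  t_tab <- predicted_truncation(cds, 82, method = "table")
  expect_gt(t_tab$mass_kda, 5)
  expect_lt(t_tab$mass_kda, 12)
  expect_error(predicted_truncation(cds, 1), "exceed 1")
})

test_that("codon_index agrees with a translation scan on random sequences", {
  # oracle: translate with Biostrings and find the first stop
  for (seed in 1:200) {
    cds <- simulate_cds(sample(10:60, 1), seed = seed)
    pos <- sample.int(nchar(cds$cds) - 6, 1) + 3  # avoid ATG and stop
    idx <- codon_index(pos)
    start <- 3 * idx - 2
    codon <- substr(cds$cds, start, start + 2)
    # force a stop at this codon and check the translation stops there
    mutated <- cds$cds
    substr(mutated, start, start + 2) <- "TGA"
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(mutated), no.init.codon = TRUE
    ))
    first_stop <- regexpr("*", aa, fixed = TRUE)[1]
    expect_equal(first_stop, idx)
  }
})

test_that("nonsense variants shorten the translated protein", {
  for (seed in 1:20) {
    cds <- simulate_cds(40, seed = 100 + seed)
    # pick a codon and mutate its first base to T where that creates a stop
    done <- FALSE
    for (ci in 2:38) {
      start <- 3 * ci - 2
      codon <- substr(cds$cds, start, start + 2)
      cand <- paste0("T", substr(codon, 2, 3))
      if (cand %in% c("TAA", "TAG", "TGA") && substr(codon, 1, 1) != "T") {
        mut <- apply_substitution(cds, list(position = start,
                                            ref = substr(codon, 1, 1),
                                            alt = "T"))
        cls <- classify_variant(cds, mut)
        expect_equal(cls$class, "nonsense")
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(mut$cds), no.init.codon = TRUE))
        trunc_len <- regexpr("*", aa, fixed = TRUE)[1] - 1
        expect_lt(trunc_len, 39)
        expect_equal(trunc_len, ci - 1)
        done <- TRUE
        break
      }
    }
  }
  succeed()
})

test_that("reporter oligos contain a stop codon after adapter trimming", {
  oligos <- reporter_scc_oligos()
  for (i in seq_len(nrow(oligos))) {
    insert <- trim_reporter_oligo(oligos$sequence[i])
    expect_true(grepl("TAA|TAG|TGA", insert))
  }
  expect_error(trim_reporter_oligo("AAAA"), "adapter")
})

test_that("FASTA input round-trips into a coding sequence", {
  cds <- synthetic_fuca1_cds()
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">FUCA1-synthetic", cds$cds), path)
  back <- read_cds_fasta(path, signal_peptide_len = 27)
  expect_equal(back$cds, cds$cds)
  expect_equal(back$signal_peptide_len, 27)
})

test_that("coding_sequence enforces its invariants", {
  expect_error(coding_sequence("ATGAA"), "divisible")
  expect_error(coding_sequence("AAATTTTAA"), "ATG")
  expect_error(coding_sequence("ATGAAACCC"), "stop codon")
  expect_error(coding_sequence("ATGTAAACCTAA"), "stop codons")
  expect_silent(coding_sequence("ATGTAAACCTAA", allow_internal_stops = TRUE))
  expect_error(coding_sequence("ATGNNNTAA"), "alphabet")
  # RNA input is normalized
  expect_equal(coding_sequence("AUGAAAUAA")$cds, "ATGAAATAA")
})
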