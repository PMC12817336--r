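# Stop-codon-context analysis of nonsense variants in a coding sequence.
#
# Coordinates are 1-based cDNA positions within the CDS, starting at the A
# of the initiator ATG (HGVS-like c. numbering). Codon k spans positions
# 3k - 2 .. 3k. Sequences are stored in the DNA alphabet; RNA input (U) is
# normalized to DNA (T) on entry.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Average residue masses (Da), monoisotopic water excluded; standard values.
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS_AVG <- 18.0153

normalize_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

dna_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds) - 2, by = 3), seq(3, nchar(cds), by = 3))
}

#' Construct a validated coding sequence
#'
#' A CDS in the DNA alphabet, starting with ATG, with length divisible by 3
#' and a single in-frame stop codon at its end. RNA input is normalized to
#' DNA.
#'
#' @param cds Character scalar of A/C/G/T (or RNA with U).
#' @param id Sequence identifier.
#' @param signal_peptide_len Optional signal-peptide length in residues
#'   (27 for the lysosomal alpha-L-fucosidase precursor), used by the
#'   `"mature"` truncation convention.
#' @param allow_internal_stops Skip the single-terminal-stop invariant;
#'   used for sequences carrying a premature termination codon.
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(cds, id = "cds", signal_peptide_len = NULL,
                            allow_internal_stops = FALSE) {
  if (!is.character(cds) || length(cds) != 1L) {
    abort("`cds` must be a single character string.")
  }
  cds <- normalize_dna(cds)
  if (grepl("[^ACGT]", cds)) {
    abort("`cds` contains characters outside the A/C/G/T alphabet.")
  }
  if (nchar(cds) %% 3 != 0) {
    abort(sprintf("CDS length (%d) is not divisible by 3.", nchar(cds)))
  }
  if (substr(cds, 1, 3) != "ATG") {
    abort("CDS must begin with the initiator codon ATG.")
  }
  codons <- dna_codons(cds)
  if (!tail(codons, 1) %in% STOP_CODONS) {
    abort("CDS must end with an in-frame stop codon.")
  }
  stops <- which(codons %in% STOP_CODONS)
  if (!allow_internal_stops && length(stops) > 1) {
    abort(sprintf(
      "CDS has %d in-frame stop codons; expected exactly one terminal stop.",
      length(stops)
    ))
  }
  if (!is.null(signal_peptide_len)) {
    check_scalar(signal_peptide_len, "signal_peptide_len", lower = 0)
  }
  structure(
    list(id = id, cds = cds, signal_peptide_len = signal_peptide_len),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons)\n",
              x$id, nchar(x$cds), nchar(x$cds) / 3))
  invisible(x)
}

as_cds_string <- function(seq) {
  if (inherits(seq, "coding_sequence")) seq$cds else normalize_dna(seq)
}

#' Read a coding sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @param ... Passed to [coding_sequence()].
#' @return A `coding_sequence`.
#' @export
read_cds_fasta <- function(path, ...) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort("FASTA file contains no sequences.")
  coding_sequence(as.character(set[[1]]), id = names(set)[1], ...)
}

#' Simulate a random coding sequence
#'
#' Uniform sense codons (no internal stops), initiator ATG, terminal stop.
#' Useful as a test substrate with known codon content.
#'
#' @param n_codons Total codon count including start and stop.
#' @param seed Integer seed.
#' @param stop_codon Terminal stop codon.
#' @return A `coding_sequence`.
#' @export
simulate_cds <- function(n_codons, seed = NULL, stop_codon = "TAA") {
  check_scalar(n_codons, "n_codons", lower = 3)
  stopifnot(stop_codon %in% STOP_CODONS)
  sense <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste0, collapse = ""),
    STOP_CODONS
  )
  with_seed(seed, {
    body <- sample(sense, n_codons - 2, replace = TRUE)
    coding_sequence(paste0("ATG", paste0(body, collapse = ""), stop_codon))
  })
}

#' Synthetic stand-in for the alpha-L-fucosidase coding sequence
#'
#' A deterministic synthetic CDS with the length of the FUCA1 precursor
#' (466 codons plus stop) carrying glutamine codons CAG at codon 82 and CAA
#' at codon 427 and the tryptophan codon TGG at codon 188, so that the
#' clinically described substitutions c.244C>T, c.564G>A and c.1279C>T
#' create the UAG, UGA and UAA premature termination codons at codons 82,
#' 188 and 427. The remaining codons are arbitrary sense codons; this is a
#' synthetic sequence, not the RefSeq mRNA.
#'
#' @return A `coding_sequence` with `signal_peptide_len = 27`.
#' @export
synthetic_fuca1_cds <- function() {
  base <- simulate_cds(467, seed = 20260101)
  codons <- dna_codons(base$cds)
  codons[82] <- "CAG"
  codons[188] <- "TGG"
  codons[427] <- "CAA"
  coding_sequence(paste0(codons, collapse = ""), id = "FUCA1-synthetic",
                  signal_peptide_len = 27)
}

#' Codon index of a cDNA position
#'
#' Codon k spans cDNA positions 3k - 2 .. 3k, so the index is
#' `ceiling(position / 3)`: c.244 falls in codon 82, c.1279 in codon 427.
#'
#' @param position 1-based cDNA position(s) within the CDS.
#' @return Integer codon number(s).
#' @export
codon_index <- function(position) {
  if (!is.numeric(position) || any(!is.finite(position)) ||
      any(position < 1)) {
    abort("`position` must contain positive cDNA coordinates.")
  }
  as.integer(ceiling(position / 3))
}

#' Parse an HGVS-like coding substitution
#'
#' @param x Strings like `"c.244C>T"` (the `c.` prefix is optional).
#' @return A tibble with columns `position`, `ref`, `alt`.
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec("^(?:c\\.)?(\\d+)([ACGTUacgtu])>([ACGTUacgtu])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    abort(sprintf("Cannot parse variant(s): %s.",
                  paste(x[bad], collapse = ", ")))
  }
  tibble(
    position = as.integer(vapply(m, `[`, "", 2)),
    ref = normalize_dna(vapply(m, `[`, "", 3)),
    alt = normalize_dna(vapply(m, `[`, "", 4))
  )
}

#' Apply a single-nucleotide substitution to a coding sequence
#'
#' The reference base must match the sequence at the given position;
#' applying the substitution with `ref`/`alt` swapped restores the original
#' sequence.
#'
#' @param seq A [coding_sequence()] (or DNA string).
#' @param sub A one-row data frame from [parse_variant()], a variant string
#'   like `"c.244C>T"`, or a list with `position`, `ref`, `alt`.
#' @return A `coding_sequence` copy with the base replaced (internal stops
#'   permitted, since nonsense substitutions create one).
#' @export
apply_substitution <- function(seq, sub) {
  if (is.character(sub)) sub <- parse_variant(sub)
  cds <- as_cds_string(seq)
  pos <- sub$position
  ref <- normalize_dna(sub$ref)
  alt <- normalize_dna(sub$alt)
  check_scalar(pos, "position", lower = 1, upper = nchar(cds))
  if (ref == alt) {
    abort("`ref` and `alt` must differ.")
  }
  found <- substr(cds, pos, pos)
  if (found != ref) {
    abort(sprintf(
      "Reference mismatch at position %d: expected %s, found %s.",
      pos, ref, found
    ))
  }
  substr(cds, pos, pos) <- alt
  coding_sequence(
    cds,
    id = if (inherits(seq, "coding_sequence")) seq$id else "cds",
    signal_peptide_len = if (inherits(seq, "coding_sequence")) {
      seq$signal_peptide_len
    } else {
      NULL
    },
    allow_internal_stops = TRUE
  )
}

#' Rank stop-codon leakiness
#'
#' UGA is the most readthrough-prone (leaky) stop codon, UAG is
#' intermediate, and UAA terminates most efficiently: rank 1 (UGA), 2
#' (UAG), 3 (UAA).
#'
#' @param stop_codon Stop codon(s), DNA or RNA alphabet.
#' @return Integer rank(s); 1 is most leaky.
#' @export
leakiness_rank <- function(stop_codon) {
  sc <- normalize_dna(stop_codon)
  bad <- !sc %in% STOP_CODONS
  if (any(bad)) {
    abort(sprintf("Not a stop codon: %s.",
                  paste(unique(stop_codon[bad]), collapse = ", ")))
  }
  unname(c(TGA = 1L, TAG = 2L, TAA = 3L)[sc])
}

#' @rdname leakiness_rank
#' @return `leakiness_class()` returns `"leaky"`, `"intermediate"` or
#'   `"tight"`.
#' @export
leakiness_class <- function(stop_codon) {
  c("leaky", "intermediate", "tight")[leakiness_rank(stop_codon)]
}

#' Distance to the high-readthrough motif UGA CUAG
#'
#' Hamming distance of the 7-nucleotide window (stop codon plus the four
#' downstream nucleotides) to the high-readthrough motif UGA CUAG, after
#' T/U normalization. Zero means the context carries the motif exactly.
#'
#' @param context A `stop_context` (from [extract_scc()]) or a character
#'   string of at least 7 nt beginning at the stop codon.
#' @return Integer Hamming distance in `0..7`.
#' @export
motif_distance <- function(context) {
  window <- if (inherits(context, "stop_context")) {
    down <- gsub("-", "", context$downstream_10nt)
    if (nchar(down) < 4) {
      abort("Need at least 4 downstream nucleotides for the motif window.")
    }
    paste0(context$stop_codon, substr(down, 1, 4))
  } else {
    s <- normalize_dna(context)
    if (nchar(s) < 7) {
      abort("Need at least 7 nucleotides (stop + 4 downstream).")
    }
    substr(s, 1, 7)
  }
  motif <- "TGACTAG"
  sum(strsplit(window, "")[[1]] != strsplit(motif, "")[[1]])
}

#' Near-cognate amino acids incorporated at a stop codon
#'
#' Trp, Cys and Arg are favored for incorporation at UGA stop codons; Gln,
#' Tyr and Lys at UAG and UAA. Every candidate decodes via a codon within
#' one mismatch of the stop.
#'
#' @param stop_codon A stop codon, DNA or RNA alphabet.
#' @return Character vector of three-letter amino-acid codes.
#' @export
near_cognate_candidates <- function(stop_codon) {
  sc <- normalize_dna(stop_codon)
  if (length(sc) != 1L || !sc %in% STOP_CODONS) {
    abort(sprintf("Not a stop codon: %s.", stop_codon))
  }
  if (sc == "TGA") c("Trp", "Cys", "Arg") else c("Gln", "Tyr", "Lys")
}

#' Extract the 23-nucleotide stop codon context
#'
#' Ten nucleotides upstream, the stop codon, and ten nucleotides
#' downstream. Near the CDS ends the flank is truncated and padded with
#' `-`, and the padding is recorded.
#'
#' @param seq A [coding_sequence()] or DNA string (internal stop allowed).
#' @param codon_index 1-based codon number of the stop codon.
#' @return An object of class `stop_context` with fields `codon_index`,
#'   `stop_codon`, `stop_codon_rna`, `upstream_10nt`, `downstream_10nt`,
#'   `scc_23nt`, `leakiness_rank`, `leakiness_class`, `motif_distance`
#'   (NA with fewer than 4 downstream nt), `padded`.
#' @export
extract_scc <- function(seq, codon_index) {
  cds <- as_cds_string(seq)
  check_scalar(codon_index, "codon_index", lower = 1, upper = nchar(cds) / 3)
  start <- 3 * codon_index - 2
  stop_codon <- substr(cds, start, start + 2)
  if (!stop_codon %in% STOP_CODONS) {
    abort(sprintf("Codon %d is %s, not a stop codon.",
                  codon_index, stop_codon))
  }
  up_start <- max(1, start - 10)
  up <- substr(cds, up_start, start - 1)
  down <- substr(cds, start + 3, min(nchar(cds), start + 12))
  pad_up <- 10 - nchar(up)
  pad_down <- 10 - nchar(down)
  up_p <- paste0(strrep("-", pad_up), up)
  down_p <- paste0(down, strrep("-", pad_down))
  structure(
    list(
      codon_index = as.integer(codon_index),
      stop_codon = stop_codon,
      stop_codon_rna = chartr("T", "U", stop_codon),
      upstream_10nt = up_p,
      downstream_10nt = down_p,
      scc_23nt = paste0(up_p, stop_codon, down_p),
      leakiness_rank = leakiness_rank(stop_codon),
      leakiness_class = leakiness_class(stop_codon),
      motif_distance = if (nchar(down) >= 4) {
        motif_distance(paste0(stop_codon, substr(down, 1, 4)))
      } else {
        NA_integer_
      },
      padded = pad_up > 0 || pad_down > 0
    ),
    class = "stop_context"
  )
}

#' @export
print.stop_context <- function(x, ...) {
  cat(sprintf("<stop_context> codon %d, stop %s (%s, rank %d)\n",
              x$codon_index, x$stop_codon_rna, x$leakiness_class,
              x$leakiness_rank))
  cat(sprintf("  SCC: %s | motif distance %s\n", x$scc_23nt,
              format(x$motif_distance)))
  invisible(x)
}

#' @rdname extract_scc
#' @param x A `stop_context`.
#' @param ... Unused.
#' @export
tidy.stop_context <- function(x, ...) {
  tibble(
    codon_index = x$codon_index,
    stop_codon = x$stop_codon,
    stop_codon_rna = x$stop_codon_rna,
    scc_23nt = x$scc_23nt,
    leakiness_rank = x$leakiness_rank,
    leakiness_class = x$leakiness_class,
    motif_distance = x$motif_distance,
    padded = x$padded
  )
}

#' Classify a single-nucleotide change between two coding sequences
#'
#' Finds the one differing position, compares the affected codon, and
#' classifies the change as `nonsense` (the codon becomes a stop upstream
#' of the natural terminator), `silent` (same encoded amino acid) or
#' `missense`. For nonsense changes the stop codon context is attached.
#'
#' @param seq_before,seq_after Coding sequences ([coding_sequence()] or DNA
#'   strings) of equal length differing at exactly one position.
#' @return A list with `class`, `position`, `codon_index`, `codon_before`,
#'   `codon_after`, and `context` (a `stop_context`, nonsense only).
#' @export
classify_variant <- function(seq_before, seq_after) {
  a <- as_cds_string(seq_before)
  b <- as_cds_string(seq_after)
  if (nchar(a) != nchar(b)) {
    abort("Sequences have unequal length.")
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  diff <- which(av != bv)
  if (length(diff) != 1L) {
    abort(sprintf("Sequences differ at %d positions; expected exactly 1.",
                  length(diff)))
  }
  pos <- diff
  idx <- codon_index(pos)
  start <- 3 * idx - 2
  codon_before <- substr(a, start, start + 2)
  codon_after <- substr(b, start, start + 2)
  n_codons <- nchar(a) / 3

  gc <- Biostrings::GENETIC_CODE
  cls <- if (codon_after %in% STOP_CODONS && idx < n_codons) {
    "nonsense"
  } else if (gc[[codon_before]] == gc[[codon_after]]) {
    "silent"
  } else {
    "missense"
  }
  out <- list(
    class = cls,
    position = pos,
    codon_index = idx,
    codon_before = codon_before,
    codon_after = codon_after,
    context = NULL
  )
  if (cls == "nonsense") {
    out$context <- extract_scc(b, idx)
  }
  out
}

#' Truncated-protein size under a readthrough-failure scenario
#'
#' Residue count and approximate mass of the polypeptide terminated at a
#' premature stop codon. The `"precursor"` convention counts every codon
#' before the stop; `"mature"` additionally subtracts the signal peptide.
#' Mass is either the sum of average residue masses of the encoded protein
#' plus water (`method = "table"`) or residue count times a configurable
#' mean residue mass (`method = "mean"`). Glycosylation (which adds roughly
#' 2-3 kDa to the mature lysosomal enzyme) is not modeled.
#'
#' @param seq A [coding_sequence()]; required for `method = "table"`.
#' @param codon_index Codon number of the premature stop (> 1, before the
#'   natural stop).
#' @param convention `"precursor"` (default) or `"mature"`.
#' @param method `"mean"` (default) or `"table"`.
#' @param mean_residue_da Mean residue mass for `method = "mean"` (Da).
#' @return A tibble with `residues`, `mass_kda`, `convention`, `method`.
#' @export
predicted_truncation <- function(seq, codon_index,
                                 convention = c("precursor", "mature"),
                                 method = c("mean", "table"),
                                 mean_residue_da = 110) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  cds <- as_cds_string(seq)
  check_scalar(codon_index, "codon_index", lower = 1,
               upper = nchar(cds) / 3)
  if (codon_index <= 1) abort("`codon_index` must exceed 1.")
  residues <- codon_index - 1
  offset <- 0
  if (convention == "mature") {
    spl <- if (inherits(seq, "coding_sequence")) seq$signal_peptide_len else NULL
    if (is.null(spl)) {
      abort("Mature convention needs `signal_peptide_len` on the sequence.")
    }
    offset <- spl
  }
  residues <- residues - offset
  if (residues < 0) {
    abort("Truncation lies within the signal peptide under this convention.")
  }

  mass_kda <- if (method == "mean") {
    residues * mean_residue_da / 1000
  } else {
    aa_start <- offset + 1
    codons <- dna_codons(cds)[seq(aa_start, aa_start + residues - 1)]
    aa <- Biostrings::GENETIC_CODE[codons]
    if (any(aa == "*")) abort("Encountered a stop codon before the index.")
    (sum(RESIDUE_MASS_AVG[aa]) + WATER_MASS_AVG) / 1000
  }
  tibble(residues = as.integer(residues), mass_kda = mass_kda,
         convention = convention, method = method)
}

#' Per-variant stop-codon-context report
#'
#' Applies each substitution to the coding sequence, classifies it, and for
#' nonsense variants reports the stop codon, its 23-nt context, leakiness
#' rank, motif distance, near-cognate amino-acid candidates and predicted
#' truncation size.
#'
#' @param seq A [coding_sequence()].
#' @param variants Character vector of HGVS-like substitutions
#'   (`"c.244C>T"`) or a data frame from [parse_variant()].
#' @param ... Passed to [predicted_truncation()].
#' @return A tibble with one row per variant.
#' @export
variant_report <- function(seq, variants, ...) {
  subs <- if (is.character(variants)) parse_variant(variants) else variants
  labels <- if (is.character(variants)) {
    variants
  } else {
    sprintf("c.%d%s>%s", subs$position, subs$ref, subs$alt)
  }
  purrr::pmap(subs, function(position, ref, alt) {
    mutated <- apply_substitution(seq, list(position = position, ref = ref,
                                            alt = alt))
    cls <- classify_variant(seq, mutated)
    base <- tibble(
      position = position, ref = ref, alt = alt,
      codon_index = cls$codon_index, class = cls$class
    )
    if (cls$class == "nonsense") {
      ctx <- cls$context
      trunc <- predicted_truncation(seq, cls$codon_index, ...)
      base %>% mutate(
        stop_codon = ctx$stop_codon_rna,
        scc_23nt = ctx$scc_23nt,
        leakiness_rank = ctx$leakiness_rank,
        leakiness_class = ctx$leakiness_class,
        motif_distance = ctx$motif_distance,
        near_cognate = paste(near_cognate_candidates(ctx$stop_codon),
                             collapse = "/"),
        truncated_residues = trunc$residues,
        truncated_mass_kda = trunc$mass_kda
      )
    } else {
      base %>% mutate(
        stop_codon = NA_character_, scc_23nt = NA_character_,
        leakiness_rank = NA_integer_, leakiness_class = NA_character_,
        motif_distance = NA_integer_, near_cognate = NA_character_,
        truncated_residues = NA_integer_, truncated_mass_kda = NA_real_
      )
    }
  }) %>%
    bind_rows() %>%
    mutate(variant = labels, .before = 1)
}

#' Printed reporter-cloning oligos carrying the three stop-codon contexts
#'
#' The sense-strand oligonucleotides used to clone each 23-nt stop codon
#' context into the dual reporter, with their cloning adapters still
#' attached. [trim_reporter_oligo()] removes the declared adapters.
#'
#' @return A tibble with `name` and `sequence`.
#' @export
reporter_scc_oligos <- function() {
  tibble(
    name = c("Q82X_SCC", "W188X_SCC", "Q427X_SCC"),
    sequence = c(
      "GTCACCGGTGGCACTGGTAGGGCGAGGGGCT",
      "GTCACCGACTCTTAGAGTGATTCCATCCACT",
      "GTCACCGGCTGGGAATTTAAGGAGATCTGAT"
    )
  )
}

#' Trim declared cloning adapters from a reporter oligo
#'
#' Adapter boundaries are a property of the cloning vector junction, so they
#' are parameters, not constants: by default the leading `GTCACC` overhang
#' and a single trailing base are removed.
#'
#' @param oligo Oligo sequence (sense strand).
#' @param leading Leading adapter expected at the 5' end.
#' @param trailing_n Number of 3' bases to drop.
#' @return The insert sequence.
#' @export
trim_reporter_oligo <- function(oligo, leading = "GTCACC", trailing_n = 1) {
  s <- normalize_dna(oligo)
  if (!startsWith(s, leading)) {
    abort(sprintf("Oligo does not start with adapter %s.", leading))
  }
  substr(s, nchar(leading) + 1, nchar(s) - trailing_n)
}
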