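# Mature alpha-subunit cataloguing: motif filter, signal-peptide cleavage,
# cross-strain deduplication and theoretical masses.

ALPHA_MOTIF <- "AP[A-Z]{9,10}C"
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# average residue masses (Da); peptide mass = sum + one water
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.01524

#' Mass of one phycoerythrobilin (PEB) chromophore, average Da
#' @export
PEB_MASS <- 586.7

#' Read alpha-subunit candidates from FASTA
#'
#' Record ids carry strain tags as `"id|strain"`; a missing tag leaves the
#' strain `NA`. Sequences are upper-cased; the alphabet is restricted to the
#' 20 amino acids plus the ambiguity character `X` and the stop marker `*`.
#'
#' @param file FASTA path.
#' @return candidate tibble: `id`, `strain`, `sequence`, `source_note`.
#' @export
read_alpha_fasta <- function(file) {
  ss <- Biostrings::readAAStringSet(file)
  full <- names(ss)
  id_tok <- stringr::str_split_fixed(stringr::word(full, 1), stringr::fixed("|"), 2)
  alpha_candidates(
    id = id_tok[, 1],
    strain = ifelse(id_tok[, 2] == "", NA_character_, id_tok[, 2]),
    sequence = unname(as.character(ss)),
    source_note = ifelse(stringr::str_detect(full, " "),
                         stringr::str_trim(stringr::str_remove(full, "^\\S+\\s")),
                         "")
  )
}

#' Construct a validated candidate tibble
#'
#' @param id,strain,sequence,source_note character vectors (recycled).
#' @return tibble of candidates with the sequence alphabet validated.
#' @export
alpha_candidates <- function(id, sequence, strain = NA_character_,
                             source_note = "") {
  out <- tibble(id = id, strain = strain,
                sequence = toupper(sequence), source_note = source_note)
  if (any(!nzchar(out$sequence))) abort("empty sequence in candidates")
  bad <- stringr::str_detect(out$sequence, "[^ACDEFGHIKLMNPQRSTVWYX*]")
  if (any(bad)) {
    abort(sprintf("invalid residues in candidate(s): %s",
                  paste(out$id[bad], collapse = ", ")))
  }
  out
}

#' Filter candidates by the cryptophyte alpha-subunit motif
#'
#' Retains exactly the candidates whose sequence contains the known
#' cryptophyte alpha motif: `AP` followed by 9 or 10 arbitrary residues
#' followed by `C`. Order is preserved; the filter is idempotent.
#'
#' @param candidates candidate tibble (see [alpha_candidates()]).
#' @return the retained rows.
#' @export
filter_by_alpha_motif <- function(candidates) {
  if (nrow(candidates) == 0) {
    warn("filter_by_alpha_motif: empty candidate set")
    return(candidates)
  }
  filter(candidates, stringr::str_detect(.data$sequence, ALPHA_MOTIF))
}

find_axa_sites <- function(sequence) {
  # 1-based start positions i of A-x-A; cleavage falls after i + 2
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  i[chars[i] == "A" & chars[i + 2] == "A"]
}

#' Cleave a precursor into its mature alpha subunit
#'
#' Signal peptides are removed at an `A-x-A` cut site (cleavage after the
#' second `A`). When several sites exist, the site whose resulting mature
#' N-terminus carries the fewest extension residues relative to the
#' reference frame start (the conserved `AP` of the motif) is selected.
#' A precursor with no `A-x-A` site is returned in full and flagged
#' `no_AxA_site`; an externally predicted non-canonical site (e.g. SFS) can
#' be imposed through `override_cleave_after`.
#'
#' @param candidate one-row candidate tibble (must have passed the motif
#'   filter).
#' @param frame reference frame from [read_reference_frame()].
#' @param override_cleave_after optional 1-based position of the last
#'   signal-peptide residue; bypasses `A-x-A` search.
#' @return one-row tibble: `id`, `strain`, `precursor`, `mature_sequence`,
#'   `cleavage_site_index` (0-based index of the mature start in the
#'   precursor), `flags` (list column).
#' @export
cleave_mature <- function(candidate, frame, override_cleave_after = NULL) {
  seqc <- candidate$sequence
  if (nchar(seqc) < 3) abort("malformed input: sequence shorter than 3 residues")
  seqc <- stringr::str_remove(seqc, "\\*+$")
  flags <- character(0)

  if (!is.null(override_cleave_after)) {
    start <- override_cleave_after + 1L
  } else {
    sites <- find_axa_sites(seqc)
    motif_pos <- stringr::str_locate(seqc, ALPHA_MOTIF)[1, 1]
    # sites that would cut into or beyond the motif destroy the subunit
    sites <- sites[sites + 3L <= motif_pos]
    if (length(sites) == 0) {
      flags <- "no_AxA_site"
      start <- 1L
    } else {
      # N-terminal extension of each candidate mature, relative to the
      # frame start (residues between mature start and the AP motif,
      # corrected for residues the frame itself carries before AP)
      ext <- (motif_pos - (sites + 3L)) - (frame$motif_start_column - 1L)
      best <- which(abs(ext) == min(abs(ext)))
      start <- sites[max(best)] + 3L
    }
  }
  if (stringr::str_detect(seqc, "X")) flags <- c(flags, "ambiguous_residues")

  tibble(
    id = candidate$id, strain = candidate$strain,
    precursor = candidate$sequence,
    mature_sequence = substr(seqc, start, nchar(seqc)),
    cleavage_site_index = start - 1L,
    flags = list(flags)
  )
}

# X-wildcard, truncation-tolerant equivalence of two mature sequences:
# the shorter must match a contiguous region of the longer
mature_equivalent <- function(a, b) {
  if (nchar(a) < nchar(b)) { s <- a; l <- b } else { s <- b; l <- a }
  ns <- nchar(s); nl <- nchar(l)
  sc <- strsplit(s, "")[[1]]; lc <- strsplit(l, "")[[1]]
  for (off in 0:(nl - ns)) {
    seg <- lc[(off + 1):(off + ns)]
    if (all(seg == sc | seg == "X" | sc == "X")) return(TRUE)
  }
  FALSE
}

#' Deduplicate mature subunits across strains
#'
#' Transcriptomes of several strains carry redundant reads of the same
#' subunit, differing only by truncation or `X` misreads. Sequences whose
#' mature regions are identical up to `X`-ambiguity and truncation are
#' grouped; the most complete read per group is kept (longest, then fewest
#' `X`, then lexicographically smallest id). Tandem reads - concatenations
#' carrying two copies of the motif - are non-biological artefacts: they
#' are flagged `tandem_read` and excluded from grouping; they are returned
#' in the `excluded` attribute, not in the deduplicated set.
#'
#' @param subunits tibble of mature subunits (from [cleave_mature()]).
#' @return deduplicated tibble, one row per group, with a `group` column;
#'   attribute `excluded` holds tandem-flagged rows.
#' @export
deduplicate_across_strains <- function(subunits) {
  if (nrow(subunits) == 0) return(subunits)
  n_motif <- stringr::str_count(subunits$mature_sequence, ALPHA_MOTIF)
  tandem <- n_motif >= 2
  excl <- subunits[tandem, , drop = FALSE]
  if (nrow(excl)) {
    excl$flags <- map(excl$flags, ~ union(.x, "tandem_read"))
  }
  keep <- subunits[!tandem, , drop = FALSE]
  n <- nrow(keep)
  parent <- seq_len(n)
  uf_find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (mature_equivalent(keep$mature_sequence[i], keep$mature_sequence[j])) {
        ri <- uf_find(i); rj <- uf_find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  keep$group <- vapply(seq_len(n), uf_find, integer(1))
  # a read whose signal peptide could not be cleaved carries spurious
  # N-terminal residues: it is less complete however long it is
  out <- keep |>
    mutate(n_x = stringr::str_count(.data$mature_sequence, "X"),
           len = nchar(.data$mature_sequence),
           uncut = map_lgl(.data$flags, ~ "no_AxA_site" %in% .x)) |>
    group_by(.data$group) |>
    arrange(.data$uncut, desc(.data$len), .data$n_x, .data$id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-"n_x", -"len", -"uncut")
  attr(out, "excluded") <- excl
  out
}

#' Theoretical average mass of a mature subunit
#'
#' Average peptide mass (standard residue masses plus one water) plus
#' 586.7 Da per phycoerythrobilin chromophore and 16 Da per oxidised
#' methionine (the +16 ladders seen by intact mass spectrometry).
#'
#' @param sequence mature amino-acid string (no `X`).
#' @param n_bilins number of PEB chromophores to add (default 1: the
#'   single alpha-chain bilin).
#' @param n_met_ox number of oxidised methionines (default 0).
#' @return mass in Da.
#' @export
compute_mature_mass <- function(sequence, n_bilins = 1, n_met_ox = 0) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  xpos <- which(chars == "X")
  if (length(xpos)) {
    abort(sprintf("ambiguous residues (X) at position(s) %s: no mass estimate",
                  paste(xpos, collapse = ", ")),
          class = "phycoantenna_ambiguous_mass")
  }
  bad <- which(!chars %in% names(AA_AVG_MASS))
  if (length(bad)) abort(sprintf("non-standard residues at position(s) %s",
                                 paste(bad, collapse = ", ")))
  sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS + PEB_MASS * n_bilins + 16.0 * n_met_ox
}
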