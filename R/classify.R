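# Quaternary-form classification of mature alpha subunits against a
# packaged reference frame, via pairwise global alignment.

#' Read the packaged alpha-subunit reference frame
#'
#' The frame is a single closed-form reference sequence (a synthetic
#' consensus; the frame starts at the conserved `AP` of the
#' `AP-x(9-10)-C` motif) with annotated columns: the chromophore-binding
#' Cys column, the insertion point immediately before it that marks the
#' open form, and the span between beta-strand S2 and helix H1 where the
#' seven-residue L1 brace of the open-braced form lands.
#'
#' @param fasta,yaml optional paths; default to the packaged files.
#' @return a `reference_frame` list: `sequence`, `chromophore_cys_column`,
#'   `open_insertion_column`, `s2_h1_gap_span`, `motif_start_column`,
#'   `self_score` (alignment score of the reference against itself).
#' @export
read_reference_frame <- function(fasta = NULL, yaml = NULL) {
  fasta <- fasta %||% system.file("extdata", "reference_frame.fasta",
                                  package = "phycoantenna", mustWork = TRUE)
  yaml <- yaml %||% system.file("extdata", "reference_frame.yaml",
                                package = "phycoantenna", mustWork = TRUE)
  seqs <- Biostrings::readAAStringSet(fasta)
  ann <- yaml::read_yaml(yaml)
  stopifnot(ann$open_insertion_column == ann$chromophore_cys_column - 1L)
  ref <- as.character(seqs[[1]])
  frame <- list(
    sequence = ref,
    chromophore_cys_column = as.integer(ann$chromophore_cys_column),
    open_insertion_column = as.integer(ann$open_insertion_column),
    s2_h1_gap_span = as.integer(ann$s2_h1_gap_span),
    motif_start_column = as.integer(ann$motif_start_column)
  )
  frame$self_score <- align_to_frame(ref, frame)$score
  class(frame) <- "reference_frame"
  frame
}

align_to_frame <- function(mature, frame) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pattern = frame$sequence, subject = mature, type = "global",
    substitutionMatrix = get("BLOSUM62"), gapOpening = 10, gapExtension = 0.5
  )
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  list(score = Biostrings::score(aln), pattern = pat, subject = sub)
}

# insertions in the subject relative to the reference: runs of '-' in the
# aligned pattern, each anchored after a reference column (0 = before col 1)
subject_insertions <- function(pat, sub) {
  refcol <- 0L
  anchors <- integer(0); lengths <- integer(0)
  run <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] == "-") {
      run <- run + 1L
    } else {
      if (run > 0L) { anchors <- c(anchors, refcol); lengths <- c(lengths, run) }
      run <- 0L
      refcol <- refcol + 1L
    }
  }
  if (run > 0L) { anchors <- c(anchors, refcol); lengths <- c(lengths, run) }
  tibble(anchor = anchors, length = lengths)
}

# subject character aligned to a given reference column ("-" if deleted)
subject_at_refcol <- function(pat, sub, col) {
  refcol <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") {
      refcol <- refcol + 1L
      if (refcol == col) return(sub[k])
    }
  }
  NA_character_
}

#' Classify the quaternary form of a mature alpha subunit
#'
#' The subunit is aligned globally (affine gaps, BLOSUM62) to the
#' reference frame. A one-residue insertion landing immediately before the
#' chromophore-binding Cys column marks the *open* form (the insertion
#' that opens the central cavity of the dimer). An *open* subunit with an
#' additional insertion of `brace_window[1]`-`brace_window[2]` residues
#' (default 5-8; the canonical L1 brace is 7) in the S2-H1 span is
#' *open-braced*; smaller insertions in that span leave the form *open*.
#' Neither insertion gives *closed*. Alignments scoring below the floor,
#' or with no alignable chromophore Cys, are *unclassified*.
#'
#' @param mature mature amino-acid string, or a one-row subunit tibble
#'   with a `mature_sequence` column.
#' @param frame reference frame (see [read_reference_frame()]).
#' @param brace_window integer length-2: insertion lengths in the S2-H1
#'   span that count as the L1 brace.
#' @param score_floor minimum alignment score; default 30% of the
#'   reference self-alignment score.
#' @return one-row tibble: `form_class` (factor: closed/open/open_braced/
#'   unclassified), `n_term_extension`, `c_term_extension`,
#'   `alignment_score`, `diagnostic`.
#' @export
classify_form <- function(mature, frame, brace_window = c(5L, 8L),
                          score_floor = 0.3 * frame$self_score) {
  if (is.data.frame(mature)) mature <- mature$mature_sequence
  stopifnot(length(mature) == 1)
  lv <- c("closed", "open", "open_braced", "unclassified")
  res <- function(class, n_ext = NA_integer_, c_ext = NA_integer_,
                  score = NA_real_, diag = "") {
    tibble(form_class = factor(class, levels = lv),
           n_term_extension = n_ext, c_term_extension = c_ext,
           alignment_score = score, diagnostic = diag)
  }

  aln <- align_to_frame(mature, frame)
  if (aln$score < score_floor) {
    return(res("unclassified",
               diag = sprintf("alignment score %.1f below floor %.1f",
                              aln$score, score_floor)))
  }
  cys <- subject_at_refcol(aln$pattern, aln$subject, frame$chromophore_cys_column)
  if (is.na(cys) || !cys %in% c("C", "X")) {
    return(res("unclassified", score = aln$score,
               diag = "no chromophore Cys alignable at the reference column"))
  }

  ins <- subject_insertions(aln$pattern, aln$subject)
  nref <- nchar(frame$sequence)
  interior <- filter(ins, .data$anchor > 0L, .data$anchor < nref)
  n_ext <- sum(ins$length[ins$anchor == 0L])
  c_ext <- sum(ins$length[ins$anchor == nref])

  open <- any(interior$anchor == frame$open_insertion_column)
  braced <- open && any(
    interior$anchor >= frame$s2_h1_gap_span[1] &
      interior$anchor <= frame$s2_h1_gap_span[2] &
      interior$length >= brace_window[1] &
      interior$length <= brace_window[2]
  )
  cls <- if (braced) "open_braced" else if (open) "open" else "closed"
  res(cls, n_ext, c_ext, aln$score)
}

#' Build the full mature alpha-subunit catalogue
#'
#' End-to-end sequence stage: motif filter, signal-peptide cleavage,
#' cross-strain deduplication, quaternary-form classification and
#' theoretical masses (peptide + one PEB bilin; no mass for reads with
#' ambiguous residues).
#'
#' @param candidates candidate tibble (see [alpha_candidates()] /
#'   [read_alpha_fasta()]).
#' @param frame reference frame; default the packaged one.
#' @param brace_window,score_floor passed to [classify_form()].
#' @param n_bilins bilins added to each theoretical mass (default 1).
#' @return catalogue tibble: id, strain, mature_sequence,
#'   cleavage_site_index, n/c-terminal extensions, form_class,
#'   theoretical_mass, flags; attribute `excluded` carries tandem reads.
#' @export
catalog_alpha_subunits <- function(candidates, frame = read_reference_frame(),
                                   brace_window = c(5L, 8L),
                                   score_floor = NULL, n_bilins = 1) {
  hits <- filter_by_alpha_motif(candidates)
  cleaved <- list_rbind(map(seq_len(nrow(hits)),
                            ~ cleave_mature(hits[.x, ], frame)))
  dedup <- deduplicate_across_strains(cleaved)
  floor <- score_floor %||% (0.3 * frame$self_score)
  cls <- list_rbind(map(dedup$mature_sequence,
                        ~ classify_form(.x, frame, brace_window, floor)))
  out <- bind_cols(dedup, cls)
  out$theoretical_mass <- map_dbl(seq_len(nrow(out)), function(i) {
    if ("ambiguous_residues" %in% out$flags[[i]]) return(NA_real_)
    compute_mature_mass(out$mature_sequence[i], n_bilins = n_bilins)
  })
  attr(out, "excluded") <- attr(dedup, "excluded")
  out
}

#' Write the catalogue as TSV plus mature-sequence FASTA
#'
#' @param catalog catalogue tibble from [catalog_alpha_subunits()].
#' @param path_tsv,path_fasta output paths; `NULL` skips.
#' @return the catalogue, invisibly.
#' @export
write_alpha_catalog <- function(catalog, path_tsv = NULL, path_fasta = NULL) {
  if (!is.null(path_tsv)) {
    flat <- catalog |>
      mutate(flags = map_chr(.data$flags, paste, collapse = ";")) |>
      select(-dplyr::any_of(c("precursor", "group")))
    readr::write_tsv(flat, path_tsv)
  }
  if (!is.null(path_fasta)) {
    ss <- Biostrings::AAStringSet(setNames(
      catalog$mature_sequence,
      paste0(catalog$id, "|", ifelse(is.na(catalog$strain), "", catalog$strain))
    ))
    Biostrings::writeXStringSet(ss, path_fasta)
  }
  invisible(catalog)
}
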