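# Atomic coordinate input (PDB / mmCIF) and selection helpers. Atom sets
# are tibbles: atom, element, resname, resid, chain, x, y, z (angstrom),
# occupancy, b, provenance.

#' Read atomic coordinates from PDB or mmCIF
#'
#' PDB files are parsed with bio3d; mmCIF `atom_site` loops with a small
#' built-in reader (both dialects of column naming are accepted). Where a
#' residue has alternate conformers, the highest-occupancy conformer is
#' kept (ties broken by conformer id).
#'
#' @param file path to a `.pdb` or `.cif`/`.mmcif` file.
#' @return atom tibble.
#' @export
read_structure <- function(file) {
  ext <- tolower(tools::file_ext(file))
  atoms <- if (ext %in% c("cif", "mmcif")) read_mmcif_atoms(file)
           else read_pdb_atoms(file)
  atoms <- resolve_altloc(atoms)
  atoms$provenance <- basename(file)
  stopifnot(all(is.finite(atoms$x + atoms$y + atoms$z)))
  atoms
}

read_pdb_atoms <- function(file) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  a <- pdb$atom
  tibble(
    atom = trimws(a$elety),
    element = trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                            substr(trimws(a$elety), 1, 1), a$elesy)),
    resname = trimws(a$resid),
    resid = as.integer(a$resno),
    chain = as.character(a$chain),
    alt = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b)
  )
}

# minimal atom_site reader for mmCIF; no installed R package parses mmCIF
read_mmcif_atoms <- function(file) {
  lines <- readLines(file, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) abort("no _atom_site loop found in mmCIF file")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body <- lines[seq(max(tag_idx) + 1L, length(lines))]
  stop_at <- grep("^(loop_|#|_)", body)
  if (length(stop_at)) body <- body[seq_len(min(stop_at) - 1L)]
  body <- body[nzchar(trimws(body))]
  tok <- strsplit(trimws(body), "\\s+")
  ok <- lengths(tok) == length(tags)
  if (!any(ok)) abort("malformed _atom_site rows in mmCIF file")
  m <- do.call(rbind, tok[ok])
  colnames(m) <- tags
  g <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  unquote <- function(v) gsub('^["\']|["\']$', "", v)
  tibble(
    atom = unquote(g("auth_atom_id", "label_atom_id")),
    element = unquote(g("type_symbol")),
    resname = unquote(g("auth_comp_id", "label_comp_id")),
    resid = suppressWarnings(as.integer(g("auth_seq_id", "label_seq_id"))),
    chain = unquote(g("auth_asym_id", "label_asym_id")),
    alt = ifelse(g("label_alt_id") %in% c(".", "?", NA), "", g("label_alt_id")),
    x = as.numeric(g("Cartn_x")),
    y = as.numeric(g("Cartn_y")),
    z = as.numeric(g("Cartn_z")),
    occupancy = ifelse(is.na(suppressWarnings(as.numeric(g("occupancy")))), 1,
                       suppressWarnings(as.numeric(g("occupancy")))),
    b = ifelse(is.na(suppressWarnings(as.numeric(g("B_iso_or_equiv")))), 0,
               suppressWarnings(as.numeric(g("B_iso_or_equiv"))))
  )
}

# keep the highest-occupancy alternate conformer (tie: smallest alt id)
resolve_altloc <- function(atoms) {
  if (!"alt" %in% names(atoms) || all(atoms$alt == "")) {
    atoms$alt <- NULL
    return(atoms)
  }
  atoms |>
    group_by(.data$chain, .data$resid, .data$resname, .data$atom) |>
    arrange(desc(.data$occupancy), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-"alt")
}

#' Select atoms by chain / residue / name
#'
#' @param atoms atom tibble.
#' @param chain,resname,atom optional character vectors to keep.
#' @param resid optional integer vector of residue numbers.
#' @param element optional element symbols to keep.
#' @param strip_solvent drop waters and common ions (default `FALSE`).
#' @return filtered atom tibble.
#' @export
select_atoms <- function(atoms, chain = NULL, resid = NULL, resname = NULL,
                         atom = NULL, element = NULL, strip_solvent = FALSE) {
  out <- atoms
  if (!is.null(chain)) out <- filter(out, .data$chain %in% !!chain)
  if (!is.null(resid)) out <- filter(out, .data$resid %in% !!resid)
  if (!is.null(resname)) out <- filter(out, .data$resname %in% !!resname)
  if (!is.null(atom)) out <- filter(out, .data$atom %in% !!atom)
  if (!is.null(element)) out <- filter(out, .data$element %in% !!element)
  if (strip_solvent) {
    out <- filter(out, !.data$resname %in%
                    c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA",
                      "ZN", "SO4", "PO4", "GOL", "PEG", "PG4", "TRS", "BTB"))
  }
  out
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
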