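#' @importFrom stats setNames
NULL

# Condition helper: classed errors so callers/tests can discriminate failure
# modes without string matching.
kd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kirdock_error")))
}

#' Parse a macromolecular structure file
#'
#' Reads a PDB (fixed-column) or mmCIF file into a `kir_structure`: an
#' ordered atom table carrying author residue numbering, insertion codes,
#' alternate-location indicators and occupancies. Hydrogen (and deuterium)
#' atoms are dropped on parse; alternate locations are retained and resolved
#' later by [select_atoms()] according to an altloc policy.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param dialect `"auto"` (default, from the file extension), `"pdb"` or
#'   `"mmcif"`.
#' @return An object of class `kir_structure`: a list with `atoms`
#'   (data frame with columns `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `elesy`, `alt`, `o`, `x`, `y`, `z`, `het`), `title` and `dialect`.
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    kd_stop(sprintf("cannot read structure file '%s'", path), "kirdock_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- if (dialect == "mmcif") {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE, verbose = FALSE,
                    hex = TRUE)
  }
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0L) {
    kd_stop(sprintf("no atoms found in '%s'", path), "kirdock_malformed_input")
  }
  elesy <- as.character(at$elesy)
  elesy[is.na(elesy) | elesy == ""] <- NA_character_
  # element fallback from the atom name: strip digits/primes, first letter
  guess <- toupper(substr(gsub("[^A-Za-z].*$|[0-9]", "", at$elety), 1L, 1L))
  elesy <- ifelse(is.na(elesy), guess, toupper(trimws(elesy)))
  atoms <- data.frame(
    chain  = as.character(at$chain),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    elesy  = elesy,
    alt    = ifelse(is.na(at$alt), "", as.character(at$alt)),
    o      = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) {
    kd_stop(sprintf("'%s' contains no heavy atoms", path), "kirdock_malformed_input")
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    kd_stop("non-finite coordinates in input", "kirdock_malformed_input")
  }
  rownames(atoms) <- NULL
  new_kir_structure(atoms, title = basename(path), dialect = dialect)
}

new_kir_structure <- function(atoms, title = "", dialect = "pdb") {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, title = title, dialect = dialect),
            class = "kir_structure")
}

#' @export
print.kir_structure <- function(x, ...) {
  cat(sprintf("<kir_structure> %d atoms, %d chains (%s), dialect %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ","), x$dialect))
  invisible(x)
}

#' Write a structure to PDB or mmCIF
#'
#' The output re-parses (via [parse_structure()]) to an atom table equal in
#' labels and in coordinates at the format's precision (3 decimals).
#'
#' @param structure A `kir_structure`.
#' @param path Output file path.
#' @param dialect `"pdb"` (default) or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(structure, "kir_structure"))
  at <- structure$atoms
  if (nrow(at) == 0L) kd_stop("structure has no atoms", "kirdock_malformed_input")
  dir <- dirname(path)
  if (!dir.exists(dir)) kd_stop(sprintf("directory '%s' does not exist", dir),
                                "kirdock_io_error")
  if (dialect == "pdb") {
    lines <- sprintf(
      "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$het, "HETATM", "ATOM"),
      seq_len(nrow(at)) %% 100000L,
      formatC(ifelse(nchar(at$elety) >= 4L, at$elety,
                     paste0(" ", at$elety)), width = -4),
      substr(at$alt, 1L, 1L),
      formatC(at$resid, width = 3),
      at$chain, at$resno, substr(at$insert, 1L, 1L),
      at$x, at$y, at$z, at$o, 0,
      formatC(at$elesy, width = 2)
    )
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_kirdock", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
    q <- function(v) ifelse(v == "", ".", v)
    rows <- sprintf(
      "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)),
      at$elesy, at$elety, q(at$alt), at$resid, at$chain, at$resno,
      q(at$insert), at$x, at$y, at$z, at$o, 0,
      at$resno, at$resid, at$chain, at$elety
    )
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Atom selection specifier
#'
#' @param chain Chain identifier (author asym id).
#' @param range Inclusive residue-number interval `c(start, end)`, or `NULL`
#'   for the whole chain.
#' @param filter One of `"calpha"` (C-alpha only), `"heavy"` (all non-water
#'   polymer heavy atoms) or `"all"`.
#' @param altloc Alternate-location policy: `"highest_occupancy"` (ties broken
#'   alphabetically by altloc code) or `"first"` (first record encountered).
#' @return An object of class `kir_selection`.
#' @export
selection <- function(chain, range = NULL,
                      filter = c("calpha", "heavy", "all"),
                      altloc = c("highest_occupancy", "first")) {
  filter <- match.arg(filter)
  altloc <- match.arg(altloc)
  if (!is.null(range)) {
    range <- as.integer(range)
    stopifnot(length(range) == 2L)
    if (range[1] > range[2]) kd_stop("selection range start > end",
                                     "kirdock_config_error")
  }
  structure(list(chain = chain, range = range, filter = filter,
                 altloc = altloc), class = "kir_selection")
}

#' Parse a `chain:start-end:filter` selection string
#'
#' @param spec String such as `"A:1-180:calpha"`; the filter part is optional
#'   and defaults to `"calpha"`.
#' @return A `kir_selection`.
#' @export
parse_selection <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) kd_stop("selection string must be chain:start-end[:filter]",
                                  "kirdock_config_error")
  rng <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
  filt <- if (length(parts) >= 3L) parts[3] else "calpha"
  selection(parts[1], rng, filter = filt)
}

#' Extract a coordinate set from a structure
#'
#' Applies a [selection()] and returns the matching atoms as a `coordset`:
#' a label table plus an N x 3 coordinate matrix, ordered by residue number
#' (then insertion code), with exactly one atom per (residue, atom name)
#' after the altloc policy. Waters and other heteroatoms are excluded by the
#' `"calpha"` and `"heavy"` filters.
#'
#' @param structure A `kir_structure`.
#' @param sel A `kir_selection` (or a string accepted by [parse_selection()]).
#' @return A `coordset`: list with `labels` (data frame `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `elesy`) and `xyz` (N x 3 matrix, Angstrom).
#' @export
select_atoms <- function(structure, sel) {
  stopifnot(inherits(structure, "kir_structure"))
  if (is.character(sel)) sel <- parse_selection(sel)
  stopifnot(inherits(sel, "kir_selection"))
  at <- structure$atoms
  keep <- at$chain == sel$chain
  if (!is.null(sel$range)) {
    keep <- keep & at$resno >= sel$range[1] & at$resno <= sel$range[2]
  }
  keep <- keep & switch(sel$filter,
    calpha = at$elety == "CA" & !at$het,
    heavy  = !at$het,
    all    = TRUE)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    kd_stop(sprintf("selection %s:%s matched no atoms", sel$chain,
                    if (is.null(sel$range)) "*" else
                      paste(sel$range, collapse = "-")),
            "kirdock_empty_selection")
  }
  # resolve altlocs within each (residue, atom name)
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- if (sel$altloc == "highest_occupancy") {
      order(key, -at$o, at$alt)
    } else {
      order(key, seq_len(nrow(at)))
    }
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "\r")), ,
             drop = FALSE]
  }
  at <- at[order(at$resno, at$insert, at$elety), , drop = FALSE]
  new_coordset(at[, c("chain", "resno", "insert", "resid", "elety", "elesy")],
               as.matrix(at[, c("x", "y", "z")]))
}

new_coordset <- function(labels, xyz) {
  xyz <- unname(as.matrix(xyz))
  stopifnot(nrow(labels) == nrow(xyz), ncol(xyz) == 3L, nrow(xyz) >= 1L)
  rownames(labels) <- NULL
  structure(list(labels = labels, xyz = xyz), class = "coordset")
}

#' @export
print.coordset <- function(x, ...) {
  cat(sprintf("<coordset> %d atoms (%d residues)\n", nrow(x$xyz),
              length(unique(paste(x$labels$resno, x$labels$insert)))))
  invisible(x)
}

#' Restrict two C-alpha coordinate sets to their common residues
#'
#' Pairing is by author residue number (plus insertion code) only; residue
#' identity is allowed to differ, as it does between allotypes, and between
#' models that resolve different residue ranges.
#'
#' @param a,b `coordset`s containing only C-alpha atoms.
#' @return A list `list(a = , b = )` of equal-length `coordset`s restricted
#'   to the shared residue numbers, in ascending residue order.
#' @export
pair_common_residues <- function(a, b) {
  stopifnot(inherits(a, "coordset"), inherits(b, "coordset"))
  if (!all(a$labels$elety == "CA") || !all(b$labels$elety == "CA")) {
    kd_stop("pair_common_residues expects C-alpha-only coordinate sets",
            "kirdock_config_error")
  }
  ka <- paste(a$labels$resno, a$labels$insert)
  kb <- paste(b$labels$resno, b$labels$insert)
  common <- intersect(ka, kb)
  if (length(common) < 3L) {
    kd_stop(sprintf("only %d residues in common; need at least 3",
                    length(common)), "kirdock_insufficient_pairs")
  }
  ia <- which(ka %in% common)
  ib <- match(ka[ia], kb)
  list(a = new_coordset(a$labels[ia, , drop = FALSE], a$xyz[ia, , drop = FALSE]),
       b = new_coordset(b$labels[ib, , drop = FALSE], b$xyz[ib, , drop = FALSE]))
}

#' Default KIR2D loop definitions
#'
#' Residue intervals (author numbering on the receptor chain) for the loops
#' that form the HLA-binding footprint: D1 A-B, C-C', E-F, the D1-D2
#' interdomain loop, and D2 B-C and F-F'.
#' @return Named list of inclusive `c(start, end)` intervals.
#' @export
default_kir_loops <- function() {
  list(`D1:A-B` = c(14L, 22L), `D1:C-C'` = c(41L, 47L), `D1:E-F` = c(67L, 74L),
       interdomain = c(103L, 107L),
       `D2:B-C` = c(132L, 135L), `D2:F-F'` = c(181L, 187L))
}

#' Default HLA class I platform elements
#'
#' Standard helix spans on the heavy chain: alpha1 50-84, alpha2 138-180.
#' @return Named list of inclusive `c(start, end)` intervals.
#' @export
default_hla_elements <- function() {
  list(alpha1 = c(50L, 84L), alpha2 = c(138L, 180L))
}

#' Assemble a role-annotated ternary complex model
#'
#' Assigns the four roles of a KIR2D-peptide-HLA ternary complex (HLA heavy
#' chain, beta-2 microglobulin, peptide, receptor) to chains of a parsed
#' structure, together with the receptor domain boundaries and the HLA
#' platform range used for superposition. For crystals with several copies
#' of the complex in the asymmetric unit, the copy is chosen explicitly by
#' the chain identifiers passed here.
#'
#' @param structure A `kir_structure`.
#' @param chains Named list with elements `hla`, `b2m`, `peptide`, `kir`
#'   giving chain ids.
#' @param d1_range,d2_range,interdomain_range Inclusive residue intervals on
#'   the receptor chain (defaults 1-102, 108-200, 103-107).
#' @param platform_range Inclusive residue interval on the HLA heavy chain
#'   used for platform superposition (default 1-180).
#' @param loops Named loop intervals on the receptor chain
#'   (default [default_kir_loops()]).
#' @param hla_elements Named helix intervals on the HLA chain
#'   (default [default_hla_elements()]).
#' @return An object of class `complex_model`.
#' @export
build_complex_model <- function(structure, chains,
                                d1_range = c(1L, 102L),
                                d2_range = c(108L, 200L),
                                interdomain_range = c(103L, 107L),
                                platform_range = c(1L, 180L),
                                loops = default_kir_loops(),
                                hla_elements = default_hla_elements()) {
  stopifnot(inherits(structure, "kir_structure"))
  need <- c("hla", "b2m", "peptide", "kir")
  if (!all(need %in% names(chains))) {
    kd_stop(sprintf("chains must name %s", paste(need, collapse = ", ")),
            "kirdock_config_error")
  }
  have <- unique(structure$atoms$chain)
  missing <- setdiff(unlist(chains[need]), have)
  if (length(missing)) {
    kd_stop(sprintf("chain role(s) refer to absent chain(s): %s",
                    paste(missing, collapse = ", ")), "kirdock_config_error")
  }
  rngs <- list(D1 = as.integer(d1_range), interdomain = as.integer(interdomain_range),
               D2 = as.integer(d2_range))
  for (nm in names(rngs)) {
    if (rngs[[nm]][1] > rngs[[nm]][2])
      kd_stop(sprintf("%s range start > end", nm), "kirdock_config_error")
  }
  seqs <- lapply(rngs, function(r) seq(r[1], r[2]))
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(seqs[[i]], seqs[[j]]))) {
      kd_stop(sprintf("receptor ranges %s and %s overlap",
                      names(rngs)[i], names(rngs)[j]), "kirdock_config_error")
    }
  }
  pep <- structure$atoms$chain == chains$peptide &
    structure$atoms$elety == "CA" & !structure$atoms$het
  npep <- length(unique(structure$atoms$resno[pep]))
  if (npep < 8L || npep > 11L) {
    warning(sprintf("peptide chain '%s' has %d residues; expected 8-11",
                    chains$peptide, npep))
  }
  structure(list(structure = structure, chains = chains[need],
                 d1_range = rngs$D1, d2_range = rngs$D2,
                 interdomain_range = rngs$interdomain,
                 platform_range = as.integer(platform_range),
                 loops = loops, hla_elements = hla_elements),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf(paste0("<complex_model> HLA %s, b2m %s, peptide %s, KIR %s | ",
                     "D1 %d-%d, D2 %d-%d, platform %d-%d\n"),
              x$chains$hla, x$chains$b2m, x$chains$peptide, x$chains$kir,
              x$d1_range[1], x$d1_range[2], x$d2_range[1], x$d2_range[2],
              x$platform_range[1], x$platform_range[2]))
  invisible(x)
}

# Internal: coordinate sets for the standard parts of a complex model.
model_part <- function(model, part = c("d1", "d2", "platform", "peptide",
                                       "kir", "b2m", "interdomain"),
                       filter = "calpha") {
  part <- match.arg(part)
  spec <- switch(part,
    d1          = list(model$chains$kir, model$d1_range),
    d2          = list(model$chains$kir, model$d2_range),
    interdomain = list(model$chains$kir, model$interdomain_range),
    platform    = list(model$chains$hla, model$platform_range),
    peptide     = list(model$chains$peptide, NULL),
    kir         = list(model$chains$kir, NULL),
    b2m         = list(model$chains$b2m, NULL))
  select_atoms(model$structure, selection(spec[[1]], spec[[2]], filter = filter))
}
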