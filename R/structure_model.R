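#' Structure model: read, represent and write protein structures
#'
#' Structures are held as flat atom tables (one row per atom), the idiom of
#' the field's R toolchain. Reading goes through bio3d (PDB and mmCIF);
#' writing is a package-local PDB emitter because chimeric templates carry
#' per-residue provenance as REMARK 99 records with a fixed grammar.
#'
#' @name structure_model
NULL

# standard amino acids plus modified residues mapped to their parent type
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.MODIFIED_PARENT <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                      CSO = "CYS", MLY = "LYS", HYP = "PRO", CME = "CYS",
                      KCX = "LYS", PCA = "GLU")

.residue_letter <- function(resname) {
  parent <- .MODIFIED_PARENT[resname]
  resname <- ifelse(is.na(parent), resname, parent)
  letter <- .AA3[resname]
  ifelse(is.na(letter), "X", letter)
}

.is_protein_resname <- function(resname) {
  resname %in% names(.AA3) | resname %in% names(.MODIFIED_PARENT)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Retains protein polymer atoms only (waters and non-polymer heteroatoms
#' are dropped); modified amino acids with a standard backbone (MSE, SEP,
#' TPO, ...) are kept and renamed to their parent residue type. Altloc
#' groups are preserved until a chain is selected. REMARK 99 provenance
#' records written by [write_structure()] are parsed back when present.
#'
#' @param path file path.
#' @param format one of "pdb", "mmcif", "auto" (by extension).
#' @return a `protein_structure`: atom table (with `model` column, 0-based)
#'   plus source metadata.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = TRUE),
    error = function(e) stop(sprintf("could not parse %s as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE))
  at <- pdb$atom
  n_models <- max(1L, nrow(pdb$xyz))
  rows <- list()
  for (m in seq_len(n_models)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    a <- data.frame(
      serial = at$eleno,
      name = trimws(at$elety),
      altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
      resname = trimws(at$resid),
      chain = ifelse(is.na(at$chain), "", at$chain),
      resno = at$resno,
      icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = ifelse(is.na(at$o), 1, at$o),
      bfactor = ifelse(is.na(at$b), 0, at$b),
      element = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
      model = m - 1L,
      stringsAsFactors = FALSE)
    rows[[m]] <- a
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[.is_protein_resname(atoms$resname) &
                   !grepl("^H", atoms$name) & atoms$name != "", , drop = FALSE]
  # map modified residues to their parent type
  parent <- .MODIFIED_PARENT[atoms$resname]
  atoms$resname <- ifelse(is.na(parent), atoms$resname, parent)
  atoms$name[atoms$name == "SE"] <- "SD"  # selenomethionine selenium
  if (nrow(atoms) == 0) stop(sprintf("no protein chains in %s", path))
  provenance <- if (format == "pdb") .read_provenance_remarks(path) else NULL
  structure(list(atoms = atoms,
                 source = list(path = path, format = format),
                 provenance = provenance),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d atoms, chains {%s}, %d model(s) [%s]\n",
              nrow(x$atoms),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              length(unique(x$atoms$model)), x$source$path))
  invisible(x)
}

#' Select one chain and model; collapse altlocs
#'
#' Returns a single-chain, single-model view. Within each (residue, atom
#' name) group the highest-occupancy alternate location wins; ties break
#' alphabetically by altloc identifier for reproducibility.
#'
#' @param structure a `protein_structure`.
#' @param chain_id chain identifier.
#' @param model_index 0-based model index (default 0).
#' @return a `chain_structure`.
#' @export
select_chain <- function(structure, chain_id, model_index = 0L) {
  atoms <- structure$atoms
  models <- sort(unique(atoms$model))
  if (!model_index %in% models) {
    stop(sprintf("model %d not present; available: {%s}", model_index,
                 paste(models, collapse = ",")))
  }
  atoms <- atoms[atoms$model == model_index, , drop = FALSE]
  chains <- sort(unique(atoms$chain))
  if (!chain_id %in% chains) {
    stop(sprintf("chain %s not present; available: {%s}", chain_id,
                 paste(chains, collapse = ",")))
  }
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  # collapse altlocs: highest occupancy, ties alphabetical
  key <- paste(atoms$resno, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$resno, atoms$icode, atoms$name,
                                   sep = "\r")), , drop = FALSE]
  atoms$altloc <- ""
  # strict residue order by (resno, icode)
  atoms <- atoms[order(atoms$resno, atoms$icode, atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chain_id = chain_id,
                 model_index = as.integer(model_index),
                 source = structure$source,
                 provenance = structure$provenance),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  res <- unique(paste(x$atoms$resno, x$atoms$icode))
  cat(sprintf("chain_structure %s (model %d): %d residues, %d atoms\n",
              x$chain_id, x$model_index, length(res), nrow(x$atoms)))
  invisible(x)
}

#' Residue table of a chain
#'
#' One row per residue in chain order: position (1-based), author number,
#' insertion code and residue name.
#'
#' @param chain a `chain_structure` (or numbered domain).
#' @return a tibble.
#' @export
chain_residues <- function(chain) {
  atoms <- chain$atoms
  key <- paste(atoms$resno, atoms$icode, sep = "\r")
  first <- !duplicated(key)
  tibble::tibble(position = seq_len(sum(first)),
                 resno = atoms$resno[first],
                 icode = atoms$icode[first],
                 resname = atoms$resname[first])
}

#' Extract the one-letter sequence of a chain
#'
#' Nonstandard residues map to "X"; gaps in author numbering are recorded
#' as missing-residue annotations, never as inserted letters.
#'
#' @param chain a `chain_structure`.
#' @return a `chain_sequence`: list with `sequence` (string), `positions`
#'   (tibble position/resno/icode/resname/letter) and `gaps` (tibble of
#'   numbering gaps: after_position, resno_before, resno_after).
#' @export
extract_sequence <- function(chain) {
  res <- chain_residues(chain)
  if (nrow(res) == 0) stop("empty chain")
  letters1 <- .residue_letter(res$resname)
  gap_at <- which(diff(res$resno) > 1 & res$icode[-nrow(res)] == "")
  gaps <- tibble::tibble(after_position = gap_at,
                         resno_before = res$resno[gap_at],
                         resno_after = res$resno[gap_at + 1])
  structure(list(sequence = paste(letters1, collapse = ""),
                 positions = tibble::tibble(res, letter = letters1),
                 gaps = gaps),
            class = "chain_sequence")
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat(sprintf("chain_sequence: %d residues, %d numbering gap(s)\n%s\n",
              nrow(x$positions), nrow(x$gaps), x$sequence))
  invisible(x)
}

# REMARK 99 provenance grammar:
#   REMARK  99 DFGOUT SEGMENT <tag> RESID <first>:<last> SOURCE <source>
.format_provenance_remarks <- function(provenance) {
  vapply(provenance, function(p) {
    sprintf("REMARK  99 DFGOUT SEGMENT %s RESID %d:%d SOURCE %s",
            p$segment, p$first, p$last, p$source)
  }, character(1))
}

.read_provenance_remarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("^REMARK  99 DFGOUT SEGMENT ", lines, value = TRUE)
  if (length(hits) == 0) return(NULL)
  lapply(hits, function(ln) {
    m <- regmatches(ln, regexec(
      "^REMARK  99 DFGOUT SEGMENT (\\S+) RESID (-?\\d+):(-?\\d+) SOURCE (.+)$",
      ln))[[1]]
    if (length(m) == 0) return(NULL)
    list(segment = m[2], first = as.integer(m[3]), last = as.integer(m[4]),
         source = m[5])
  })
}

#' Write a single-chain structure as PDB
#'
#' Serial numbers are renumbered contiguously from 1. Provenance segments
#' (for chimeric templates) are written as REMARK 99 records and round-trip
#' through [read_structure()]. Coordinates round-trip to 3 decimals.
#'
#' @param chain a `chain_structure`, `numbered_domain` or
#'   `chimeric_template`.
#' @param path output file path.
#' @param provenance optional list of segments, each
#'   `list(segment, first, last, source)`; defaults to the object's own
#'   provenance when present.
#' @return `path`, invisibly.
#' @export
write_structure <- function(chain, path, provenance = NULL) {
  atoms <- chain$atoms
  if (is.null(atoms) || nrow(atoms) == 0) stop("no atoms to write")
  res_key <- paste(atoms$resno, atoms$icode, sep = "\r")
  n_atoms_per_res <- table(res_key)
  if (any(n_atoms_per_res == 0)) stop("residue without atoms")
  if (is.null(provenance)) provenance <- chain$provenance
  lines <- character(0)
  if (!is.null(provenance) && length(provenance) > 0) {
    lines <- .format_provenance_remarks(provenance)
  }
  chain_id <- chain$chain_id %||% "A"
  element <- atoms$element
  element[is.na(element) | element == ""] <-
    substr(atoms$name[is.na(element) | element == ""], 1, 1)
  rec <- sprintf(
    "ATOM  %5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    vapply(atoms$name, function(n) {
      # atom-name column convention: names of <4 chars start in column 14
      if (nchar(n) >= 4) substr(n, 1, 4) else sprintf(" %-3s", n)
    }, character(1)),
    " ", atoms$resname, chain_id, atoms$resno,
    ifelse(atoms$icode == "", " ", atoms$icode),
    atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$bfactor, element)
  lines <- c(lines, rec, "TER", "END")
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write %s: %s", path,
                                            conditionMessage(e)), call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
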