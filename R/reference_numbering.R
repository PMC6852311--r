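#' Reference numbering: map kinase domains onto PKACalpha (1ATP) IDs
#'
#' Every classifier anchor is addressed in the residue numbering of the
#' PKACalpha structure 1ATP. A target chain is numbered by global pairwise
#' alignment (free end gaps, BLOSUM62) against the packaged 1ATP catalytic
#' domain sequence, followed by motif verification at the conserved
#' G-loop / HRD / DFG / APE anchors.
#'
#' @name reference_numbering
NULL

#' Classifier anchor IDs in 1ATP numbering
#'
#' @return named integer list of anchor reference IDs.
#' @export
anchor_set <- function() {
  list(psi_pre_id = 49L,        # psi_G-motif-1
       gmotif_phi_id = 54L,     # Phi of GxGxPhiG
       psi_post_id = 56L,       # psi_G-motif+1
       xi_gmotif_start_id = 55L, # window 55-58
       lys_id = 72L,            # catalytic Lys (atom NZ)
       glu_id = 91L,            # alphaC Glu (atoms OE1/OE2)
       hrd_minus4_id = 160L,
       hrd_plus4_id = 170L,
       dfg_asp_id = 184L,
       dfg_phe_id = 185L,
       dfg_gly_id = 186L,
       dfg_plus3_id = 189L)
}

#' The packaged PKACalpha (1ATP) reference profile
#'
#' One-letter sequence of reference IDs 40-300 with the anchor motif
#' patterns. PKACalpha carries Tyr rather than His at position 164, so the
#' catalytic-loop pattern is `[HY]RD`.
#'
#' @return a `reference_profile`: list with `sequence`, `start_id`, `ids`
#'   and `motifs`.
#' @export
reference_profile <- function() {
  path <- system.file("extdata", "reference_1atp.fasta", package = "dfgout")
  lines <- readLines(path, warn = FALSE)
  seq <- paste(lines[!grepl("^>", lines)], collapse = "")
  start_id <- 40L
  ids <- seq.int(start_id, start_id + nchar(seq) - 1L)
  motifs <- list(
    gloop = list(ids = 50:55, pattern = "G.G.[FYWLIVM]G"),
    hrd = list(ids = 164:166, pattern = "[HY]RD"),
    dfg = list(ids = 184:186, pattern = "DFG"),
    ape = list(ids = 206:208, pattern = "APE"))
  prof <- structure(list(sequence = seq, start_id = start_id, ids = ids,
                         motifs = motifs),
                    class = "reference_profile")
  for (m in names(motifs)) {
    sub <- .profile_subseq(prof, motifs[[m]]$ids)
    if (!grepl(paste0("^", motifs[[m]]$pattern, "$"), sub)) {
      stop(sprintf("packaged reference violates %s motif: %s", m, sub))
    }
  }
  prof
}

.profile_subseq <- function(profile, ids) {
  pos <- ids - profile$start_id + 1L
  paste(strsplit(profile$sequence, "")[[1]][pos], collapse = "")
}

#' Align a target sequence to the reference profile
#'
#' Global pairwise alignment with free end gaps (Biostrings, BLOSUM62,
#' gap open 10 / extend 0.5 by default). Fails below a configurable score
#' floor, which separates kinase domains from shuffled-composition decoys.
#'
#' @param target_seq one-letter amino-acid string, length >= 100.
#' @param profile a `reference_profile` (default: packaged).
#' @param scoring list: `gap_open`, `gap_extend`, `score_floor`.
#' @return an `alignment_map`: tibble `pairs` (target_pos, ref_id), score.
#' @export
align_to_reference <- function(target_seq,
                               profile = reference_profile(),
                               scoring = list(gap_open = 10,
                                              gap_extend = 0.5,
                                              score_floor = 150)) {
  target_seq <- toupper(gsub("\\s", "", target_seq))
  if (nchar(target_seq) < 100) {
    stop("target sequence shorter than 100 residues: not a plausible kinase catalytic domain")
  }
  aln <- .pairwise_overlap(target_seq, profile$sequence, scoring)
  if (aln$score < scoring$score_floor) {
    stop(sprintf(
      "not a recognizable kinase domain (alignment score %.1f below floor %.1f)",
      aln$score, scoring$score_floor))
  }
  pairs <- .aligned_pairs(aln$a, aln$b)
  pairs$ref_id <- profile$start_id - 1L + pairs$b_pos
  structure(list(pairs = tibble::tibble(target_pos = pairs$a_pos,
                                        ref_id = pairs$ref_id),
                 score = aln$score),
            class = "alignment_map")
}

# global alignment with free end gaps; returns aligned strings + score
.pairwise_overlap <- function(a, b, scoring) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "overlap",
    substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  # reconstruct full-length aligned rows including the free end overhangs
  pa_a <- as.character(Biostrings::alignedPattern(pa))
  pa_b <- as.character(Biostrings::alignedSubject(pa))
  sa <- Biostrings::start(Biostrings::pattern(pa))
  ea <- Biostrings::end(Biostrings::pattern(pa))
  sb <- Biostrings::start(Biostrings::subject(pa))
  eb <- Biostrings::end(Biostrings::subject(pa))
  pre_a <- substr(a, 1, sa - 1); pre_b <- substr(b, 1, sb - 1)
  post_a <- substr(a, ea + 1, nchar(a)); post_b <- substr(b, eb + 1, nchar(b))
  pad <- function(x, n) paste0(x, strrep("-", n - nchar(x)))
  pre_n <- max(nchar(pre_a), nchar(pre_b))
  post_n <- max(nchar(post_a), nchar(post_b))
  full_a <- paste0(strrep("-", pre_n - nchar(pre_a)), pre_a, pa_a,
                   pad(post_a, post_n))
  full_b <- paste0(strrep("-", pre_n - nchar(pre_b)), pre_b, pa_b,
                   pad(post_b, post_n))
  list(a = full_a, b = full_b, score = Biostrings::score(pa))
}

.aligned_pairs <- function(row_a, row_b) {
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  list(a_pos = ia[keep], b_pos = ib[keep])
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map: %d matched positions, score %.1f\n",
              nrow(x$pairs), x$score))
  invisible(x)
}

#' Assign reference IDs to a chain from an alignment map
#'
#' Matched residues receive reference IDs; insertions relative to the
#' reference carry none and are ignored by the classifiers. Errors when
#' any classifier anchor ID is unmapped.
#'
#' @param chain a `chain_structure`.
#' @param map an `alignment_map` produced from this chain's sequence.
#' @param kinase optional kinase name tag.
#' @param anchors anchor ID set (default [anchor_set()]).
#' @return a `numbered_domain`.
#' @export
assign_reference_ids <- function(chain, map, kinase = NULL,
                                 anchors = anchor_set()) {
  res <- chain_residues(chain)
  ref_id <- rep(NA_integer_, nrow(res))
  ok <- map$pairs$target_pos <= nrow(res)
  ref_id[map$pairs$target_pos[ok]] <- map$pairs$ref_id[ok]
  need <- unique(unlist(anchors))
  missing_anchor <- setdiff(need, ref_id)
  if (length(missing_anchor) > 0) {
    names_missing <- names(anchors)[vapply(anchors, function(a)
      any(a %in% missing_anchor), logical(1))]
    stop(sprintf("anchor unresolved: %s", paste(names_missing, collapse = ", ")),
         call. = FALSE)
  }
  numbering <- tibble::tibble(position = res$position, resno = res$resno,
                              icode = res$icode, resname = res$resname,
                              ref_id = ref_id)
  atoms <- chain$atoms
  key <- paste(atoms$resno, atoms$icode, sep = "\r")
  res_key <- paste(res$resno, res$icode, sep = "\r")
  atoms$ref_id <- ref_id[match(key, res_key)]
  dom <- structure(list(atoms = atoms, chain_id = chain$chain_id,
                        model_index = chain$model_index,
                        source = chain$source, numbering = numbering,
                        anchors = anchors, kinase = kinase,
                        noncanonical = FALSE, anchor_report = NULL),
                   class = c("numbered_domain", "chain_structure"))
  dom$anchor_report <- locate_anchors(dom)
  dom$noncanonical <- any(!dom$anchor_report$ok)
  dom
}

#' @export
print.numbered_domain <- function(x, ...) {
  n_ref <- sum(!is.na(x$numbering$ref_id))
  cat(sprintf("numbered_domain%s: %d residues (%d with reference IDs)%s\n",
              if (is.null(x$kinase)) "" else paste0(" [", x$kinase, "]"),
              nrow(x$numbering), n_ref,
              if (isTRUE(x$noncanonical)) " — noncanonical motifs" else ""))
  invisible(x)
}

#' Reference IDs present in a numbered domain
#' @param domain a `numbered_domain`.
#' @return sorted integer vector.
#' @export
domain_reference_ids <- function(domain) {
  sort(unique(domain$atoms$ref_id[!is.na(domain$atoms$ref_id)]))
}

#' Coordinate of a named atom at a reference ID (or NULL)
#' @param domain a `numbered_domain`.
#' @param ref_id reference ID.
#' @param name atom name (e.g. "CA").
#' @return numeric 3-vector or NULL when absent.
#' @export
domain_atom_coord <- function(domain, ref_id, name) {
  at <- domain$atoms
  i <- which(at$ref_id == ref_id & at$name == name)
  if (length(i) == 0) return(NULL)
  c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
}

#' Residue name (3-letter) at a reference ID (or NULL)
#' @inheritParams domain_atom_coord
#' @export
domain_residue_name <- function(domain, ref_id) {
  at <- domain$atoms
  i <- which(at$ref_id == ref_id)
  if (length(i) == 0) return(NULL)
  at$resname[i[1]]
}

#' Verify residue types at the conserved motif anchors
#'
#' Checks DFG, HRD ([HY]RD), G-loop and APE anchors. Mismatches are
#' warnings, not errors; the domain is flagged noncanonical.
#'
#' @param domain a `numbered_domain`.
#' @return tibble: anchor, ref_id, expected, observed, ok.
#' @export
locate_anchors <- function(domain) {
  checks <- list(
    list(anchor = "gloop_G50", id = 50L, pattern = "G"),
    list(anchor = "gloop_G52", id = 52L, pattern = "G"),
    list(anchor = "gloop_Phi54", id = 54L, pattern = "[FYWLIVM]"),
    list(anchor = "gloop_G55", id = 55L, pattern = "G"),
    list(anchor = "beta3_Lys72", id = 72L, pattern = "K"),
    list(anchor = "alphaC_Glu91", id = 91L, pattern = "E"),
    list(anchor = "hrd_H164", id = 164L, pattern = "[HY]"),
    list(anchor = "hrd_R165", id = 165L, pattern = "R"),
    list(anchor = "hrd_D166", id = 166L, pattern = "D"),
    list(anchor = "dfg_D184", id = 184L, pattern = "D"),
    list(anchor = "dfg_F185", id = 185L, pattern = "F"),
    list(anchor = "dfg_G186", id = 186L, pattern = "G"))
  rows <- lapply(checks, function(ck) {
    resname <- domain_residue_name(domain, ck$id)
    obs <- if (is.null(resname)) NA_character_ else .residue_letter(resname)
    ok <- !is.na(obs) && grepl(paste0("^", ck$pattern, "$"), obs)
    if (!ok && !is.na(obs)) {
      warning(sprintf("%s mismatch at reference %d: expected %s, found %s",
                      ck$anchor, ck$id, ck$pattern, obs), call. = FALSE)
    }
    tibble::tibble(anchor = ck$anchor, ref_id = ck$id,
                   expected = ck$pattern, observed = obs, ok = ok)
  })
  do.call(rbind, rows)
}

#' Number a chain against the packaged reference in one step
#'
#' Convenience wrapper: extract the sequence, align it to the 1ATP
#' profile and assign reference IDs.
#'
#' @inheritParams assign_reference_ids
#' @param scoring see [align_to_reference()].
#' @return a `numbered_domain`.
#' @export
number_domain <- function(chain, kinase = NULL,
                          scoring = list(gap_open = 10, gap_extend = 0.5,
                                         score_floor = 150)) {
  seq <- extract_sequence(chain)
  map <- align_to_reference(seq$sequence, scoring = scoring)
  assign_reference_ids(chain, map, kinase = kinase)
}
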