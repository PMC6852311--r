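#' Chimeric template construction
#'
#' A template is assembled from three sources: the C-lobe core of a DFG-in
#' acceptor, the N-lobe of a DFG-out donor carrying a chosen P-loop/alphaC
#' combination, and the activation loop of a donor carrying a chosen
#' A-loop class. Donors are rigidly superposed onto the acceptor over the
#' common C-lobe core backbone before their segments are excised and
#' joined; steric clashes across segments are detected deterministically
#' and optionally relieved by side-chain truncation (never by moving
#' backbone atoms).
#'
#' @name chimera_builder
NULL

#' Segment boundaries in reference numbering
#'
#' @param config validated configuration.
#' @return list with `nlobe_start`, `nlobe_end`, `aloop_start`,
#'   `aloop_end`.
#' @export
segment_boundaries <- function(config = default_config()) {
  config$boundaries
}

.segment_of_ids <- function(ref_ids, bounds) {
  seg <- ifelse(is.na(ref_ids), NA_character_,
                ifelse(ref_ids <= bounds$nlobe_end, "n_lobe",
                       ifelse(ref_ids >= bounds$aloop_start &
                                ref_ids <= bounds$aloop_end, "a_loop",
                              "c_lobe_core")))
  # insertions follow the segment of their preceding numbered residue
  for (i in seq_along(seg)) {
    if (is.na(seg[i])) seg[i] <- if (i > 1) seg[i - 1] else "n_lobe"
  }
  seg
}

#' Partition a numbered domain into N-lobe, C-lobe core and A-loop
#'
#' Disjoint cover of the domain's residues; residues without reference IDs
#' (insertions) are assigned to the segment of their preceding numbered
#' residue.
#'
#' @param domain a `numbered_domain`.
#' @param bounds segment boundaries (see [segment_boundaries()]).
#' @return list of three integer vectors of residue positions
#'   (`n_lobe`, `c_lobe_core`, `a_loop`) plus `segment` (per-position
#'   labels).
#' @export
partition_domain <- function(domain, bounds = segment_boundaries()) {
  num <- domain$numbering
  required <- c(bounds$nlobe_end, bounds$aloop_start, bounds$aloop_end)
  missing_ids <- setdiff(required, num$ref_id)
  if (length(missing_ids) > 0) {
    stop(sprintf("boundary residue(s) missing: reference %s",
                 paste(missing_ids, collapse = ", ")))
  }
  seg <- .segment_of_ids(num$ref_id, bounds)
  list(n_lobe = num$position[seg == "n_lobe"],
       c_lobe_core = num$position[seg == "c_lobe_core"],
       a_loop = num$position[seg == "a_loop"],
       segment = seg)
}

#' Superpose a donor onto an acceptor over the C-lobe core
#'
#' Kabsch fit over the backbone atoms (N, CA, C, O) of the reference IDs
#' in the C-lobe core (excluding the A-loop) present with complete
#' backbone in both structures, as used for template construction.
#'
#' @param donor,acceptor `numbered_domain` objects.
#' @param bounds segment boundaries.
#' @return the donor with transformed coordinates; the
#'   `superposition_result` is attached as attribute `superposition`.
#' @export
superpose_donor <- function(donor, acceptor, bounds = segment_boundaries()) {
  core_ids <- function(d) {
    ids <- domain_reference_ids(d)
    ids[ids > bounds$nlobe_end &
          !(ids >= bounds$aloop_start & ids <= bounds$aloop_end)]
  }
  common <- intersect(core_ids(donor), core_ids(acceptor))
  bb <- c("N", "CA", "C", "O")
  xm <- list(); xr <- list(); used <- integer(0)
  for (id in common) {
    cm <- lapply(bb, function(n) domain_atom_coord(donor, id, n))
    cr <- lapply(bb, function(n) domain_atom_coord(acceptor, id, n))
    if (!any(vapply(cm, is.null, logical(1))) &&
        !any(vapply(cr, is.null, logical(1)))) {
      xm[[length(xm) + 1]] <- do.call(rbind, cm)
      xr[[length(xr) + 1]] <- do.call(rbind, cr)
      used <- c(used, id)
    }
  }
  if (length(used) < 20) {
    stop(sprintf(
      "insufficient C-lobe core overlap: %d common reference IDs with complete backbone (need >= 20)",
      length(used)))
  }
  sp <- superpose(do.call(rbind, xm), do.call(rbind, xr))
  out <- donor
  xyz <- apply_transform(as.matrix(donor$atoms[, c("x", "y", "z")]), sp)
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  attr(out, "superposition") <- sp
  out
}

#' Splice acceptor core with superposed donor segments
#'
#' Draws N-lobe residues from the N-lobe donor, C-lobe core residues from
#' the acceptor and A-loop residues from the A-loop donor, ordered by
#' reference ID, and checks the covalent plausibility of each junction
#' (C-N distance <= 2.5 A, else flagged).
#'
#' @param acceptor DFG-in acceptor (`numbered_domain`).
#' @param nlobe_donor_t,aloop_donor_t donors already transformed by
#'   [superpose_donor()].
#' @param bounds segment boundaries.
#' @param spec optional `template_spec` to record.
#' @return a `chimeric_template`.
#' @export
splice <- function(acceptor, nlobe_donor_t, aloop_donor_t,
                   bounds = segment_boundaries(), spec = NULL) {
  take <- function(domain, segment) {
    seg <- .segment_of_ids(domain$atoms$ref_id, bounds)
    at <- domain$atoms[seg == segment & !is.na(domain$atoms$ref_id), ,
                       drop = FALSE]
    at$provenance <- c(n_lobe = "nlobe_donor", c_lobe_core = "acceptor_clobe",
                       a_loop = "aloop_donor")[[segment]]
    at
  }
  atoms <- rbind(take(nlobe_donor_t, "n_lobe"),
                 take(acceptor, "c_lobe_core"),
                 take(aloop_donor_t, "a_loop"))
  if (anyDuplicated(paste(atoms$ref_id, atoms$name))) {
    stop("internal error: duplicate reference IDs across segments")
  }
  atoms <- atoms[order(atoms$ref_id, atoms$serial), , drop = FALSE]
  atoms$resno <- atoms$ref_id
  atoms$icode <- ""
  atoms$chain <- "A"
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  ids <- sort(unique(atoms$ref_id))
  gap_warnings <- character(0)
  expected <- seq(min(ids), max(ids))
  if (length(setdiff(expected, ids)) > 0) {
    gap_warnings <- sprintf("missing reference IDs: %s",
                            paste(setdiff(expected, ids), collapse = ","))
  }
  first <- !duplicated(atoms$ref_id)
  numbering <- tibble::tibble(position = seq_len(sum(first)),
                              resno = atoms$resno[first], icode = "",
                              resname = atoms$resname[first],
                              ref_id = atoms$ref_id[first])
  tmpl <- structure(list(atoms = atoms, chain_id = "A", model_index = 0L,
                         source = list(path = NA_character_,
                                       format = "chimera"),
                         numbering = numbering, anchors = anchor_set(),
                         kinase = acceptor$kinase, noncanonical = FALSE,
                         anchor_report = NULL, spec = spec,
                         gap_warnings = gap_warnings,
                         edits = character(0)),
                    class = c("chimeric_template", "numbered_domain",
                              "chain_structure"))
  # junction covalent plausibility: C(i) - N(i+1) across provenance changes
  seg_by_id <- atoms$provenance[first]
  junctions <- list()
  for (k in which(seg_by_id[-length(seg_by_id)] != seg_by_id[-1])) {
    id_l <- numbering$ref_id[k]; id_r <- numbering$ref_id[k + 1]
    cl <- domain_atom_coord(tmpl, id_l, "C")
    nr <- domain_atom_coord(tmpl, id_r, "N")
    d <- if (is.null(cl) || is.null(nr)) NA_real_ else .vnorm(cl - nr)
    junctions[[length(junctions) + 1]] <-
      list(left = id_l, right = id_r, distance = d,
           ok = !is.na(d) && d <= 2.5)
  }
  tmpl$junctions <- junctions
  tmpl$superpositions <- list(
    nlobe = attr(nlobe_donor_t, "superposition"),
    aloop = attr(aloop_donor_t, "superposition"))
  tmpl$provenance <- .template_provenance_segments(tmpl)
  tmpl$anchor_report <- locate_anchors(tmpl)
  tmpl$noncanonical <- any(!tmpl$anchor_report$ok)
  tmpl
}

.template_provenance_segments <- function(tmpl) {
  num <- tmpl$numbering
  seg <- tmpl$atoms$provenance[!duplicated(tmpl$atoms$ref_id)]
  runs <- rle(seg)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  src <- c(nlobe_donor = if (!is.null(tmpl$spec)) tmpl$spec$nlobe_donor else "nlobe_donor",
           acceptor_clobe = if (!is.null(tmpl$spec)) tmpl$spec$acceptor else "acceptor",
           aloop_donor = if (!is.null(tmpl$spec)) tmpl$spec$aloop_donor else "aloop_donor")
  lapply(seq_along(runs$values), function(i) {
    list(segment = runs$values[i], first = num$ref_id[starts[i]],
         last = num$ref_id[ends[i]],
         source = unname(src[runs$values[i]]))
  })
}

#' @export
print.chimeric_template <- function(x, ...) {
  cat(sprintf("chimeric_template: %d residues; junctions %s; %d edit(s)\n",
              nrow(x$numbering),
              paste(vapply(x$junctions, function(j)
                sprintf("%d|%d %.2fA%s", j$left, j$right, j$distance,
                        if (j$ok) "" else "!"), character(1)),
                collapse = ", "),
              length(x$edits)))
  invisible(x)
}

#' Detect steric clashes across provenance segments
#'
#' Heavy-atom pairs from different provenance segments closer than
#' `cutoff`; pairs between residues adjacent in reference numbering
#' (junction-bonded neighbours) are excluded. Deterministic ordering.
#'
#' @param template a `chimeric_template`.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 2.5).
#' @return tibble: ref_a, atom_a, seg_a, ref_b, atom_b, seg_b, distance.
#' @export
detect_clashes <- function(template, cutoff = 2.5) {
  at <- template$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(at)
  res <- list()
  segs <- unique(at$provenance)
  for (i in seq_len(length(segs) - 1)) {
    for (j in seq((i + 1), length(segs))) {
      ia <- which(at$provenance == segs[i])
      ib <- which(at$provenance == segs[j])
      d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                  rowSums(xyz[ib, , drop = FALSE]^2), `+`) -
        2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        ka <- ia[hit[, 1]]; kb <- ib[hit[, 2]]
        keep <- abs(at$ref_id[ka] - at$ref_id[kb]) > 1
        ka <- ka[keep]; kb <- kb[keep]
        if (length(ka) > 0) {
          res[[length(res) + 1]] <- tibble::tibble(
            ref_a = at$ref_id[ka], atom_a = at$name[ka],
            seg_a = at$provenance[ka],
            ref_b = at$ref_id[kb], atom_b = at$name[kb],
            seg_b = at$provenance[kb],
            distance = sqrt(pmax(0, d2[cbind(match(ka, ia), match(kb, ib))])))
        }
      }
    }
  }
  out <- if (length(res) == 0) {
    tibble::tibble(ref_a = integer(0), atom_a = character(0),
                   seg_a = character(0), ref_b = integer(0),
                   atom_b = character(0), seg_b = character(0),
                   distance = numeric(0))
  } else {
    do.call(rbind, res)
  }
  out[order(out$ref_a, out$ref_b, out$atom_a, out$atom_b), , drop = FALSE]
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

#' Relieve clashes by donor-side side-chain truncation
#'
#' `truncate_sidechain` removes side-chain atoms beyond C-beta of clashing
#' donor-segment residues, re-checks and records every edit; `flag_only`
#' leaves coordinates untouched. Clashes between backbone atoms cannot be
#' relieved and are flagged fatal-for-template (the template is still
#' emitted, with a warning).
#'
#' @param template a `chimeric_template`.
#' @param policy "truncate_sidechain" or "flag_only".
#' @param cutoff clash cutoff in Angstrom.
#' @return the template, with `clashes`, `edits` and `fatal_clash` fields
#'   updated.
#' @export
relieve_clashes <- function(template,
                            policy = c("truncate_sidechain", "flag_only"),
                            cutoff = 2.5) {
  policy <- match.arg(policy)
  cl <- detect_clashes(template, cutoff)
  template$clashes <- cl
  template$fatal_clash <- FALSE
  if (policy == "flag_only" || nrow(cl) == 0) return(template)
  for (pass in 1:4) {
    if (nrow(cl) == 0) break
    drop_keys <- character(0)
    for (r in seq_len(nrow(cl))) {
      sides <- list(list(ref = cl$ref_a[r], atom = cl$atom_a[r],
                         seg = cl$seg_a[r]),
                    list(ref = cl$ref_b[r], atom = cl$atom_b[r],
                         seg = cl$seg_b[r]))
      for (s in sides) {
        if (s$seg != "acceptor_clobe" && !(s$atom %in% .BACKBONE_ATOMS)) {
          drop_keys <- c(drop_keys, sprintf("%d", s$ref))
        }
      }
    }
    drop_keys <- unique(drop_keys)
    if (length(drop_keys) == 0) break
    at <- template$atoms
    sel <- at$ref_id %in% as.integer(drop_keys) &
      !(at$name %in% .BACKBONE_ATOMS) & at$provenance != "acceptor_clobe"
    if (!any(sel)) break
    template$edits <- c(template$edits, sprintf(
      "truncated sidechain beyond CB: residue %s (%s)",
      at$ref_id[sel][!duplicated(at$ref_id[sel])],
      at$provenance[sel][!duplicated(at$ref_id[sel])]))
    template$atoms <- at[!sel, , drop = FALSE]
    template$atoms$serial <- seq_len(nrow(template$atoms))
    cl <- detect_clashes(template, cutoff)
  }
  template$clashes <- cl
  if (nrow(cl) > 0) {
    template$fatal_clash <- TRUE
    warning(sprintf(
      "unrelievable clash(es) remain after side-chain truncation (%d pair(s))",
      nrow(cl)), call. = FALSE)
  }
  template
}

#' Target-to-template alignment for a chimeric template
#'
#' Globally aligns the target sequence against the template's
#' concatenated segment sequence (free end gaps); the provenance of every
#' template column is kept as an auxiliary track.
#'
#' @param target_seq target kinase one-letter sequence.
#' @param template a `chimeric_template`.
#' @param scoring list: `gap_open`, `gap_extend`, `score_floor`.
#' @return a `template_alignment`: `target`, `template` (aligned rows),
#'   `segments` (per-column provenance track), `score`.
#' @export
build_template_alignment <- function(target_seq, template,
                                     scoring = list(gap_open = 10,
                                                    gap_extend = 0.5,
                                                    score_floor = 150)) {
  target_seq <- toupper(gsub("\\s", "", target_seq))
  if (nchar(target_seq) == 0) stop("empty target sequence")
  tmpl_seq <- extract_sequence(template)
  aln <- .pairwise_overlap(target_seq, tmpl_seq$sequence, scoring)
  if (aln$score < scoring$score_floor) {
    stop(sprintf(
      "target/template too dissimilar (alignment score %.1f below floor %.1f)",
      aln$score, scoring$score_floor))
  }
  seg_by_pos <- template$atoms$provenance[!duplicated(template$atoms$ref_id)]
  cb <- strsplit(aln$b, "")[[1]]
  ib <- cumsum(cb != "-")
  seg_track <- ifelse(cb == "-", "-",
                      c(nlobe_donor = "N", acceptor_clobe = "C",
                        aloop_donor = "A")[seg_by_pos[ib]])
  structure(list(target = aln$a, template = aln$b,
                 segments = paste(seg_track, collapse = ""),
                 score = aln$score,
                 target_name = "target",
                 template_name = template$kinase %||% "template"),
            class = "template_alignment")
}

#' @export
print.template_alignment <- function(x, ...) {
  cat(sprintf("template_alignment (score %.1f):\n%s\n%s\n%s\n", x$score,
              x$target, x$template, x$segments))
  invisible(x)
}

#' Write a template alignment in PIR format
#'
#' Structure-aware PIR with populated structure/sequence headers, directly
#' consumable by standard comparative-modelling engines.
#'
#' @param alignment a `template_alignment`.
#' @param path output file.
#' @param template_file PDB file name recorded in the structure header.
#' @param first_res,last_res template residue range for the header.
#' @return `path`, invisibly.
#' @export
write_pir <- function(alignment, path, template_file = "template.pdb",
                      first_res = "", last_res = "") {
  chunk <- function(s) sub("\n$", "", gsub("(.{60})", "\\1\n", s))
  lines <- c(
    sprintf(">P1;%s", alignment$template_name),
    sprintf("structureX:%s:%s:A:%s:A::::", template_file, first_res, last_res),
    paste0(chunk(alignment$template), "*"),
    "",
    sprintf(">P1;%s", alignment$target_name),
    sprintf("sequence:%s:::::::", alignment$target_name),
    paste0(chunk(alignment$target), "*"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a template alignment as aligned FASTA
#'
#' @inheritParams write_pir
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  chunk <- function(s) gsub("(.{60})", "\\1\n", s)
  lines <- c(sprintf(">%s", alignment$target_name),
             strsplit(chunk(alignment$target), "\n")[[1]],
             sprintf(">%s", alignment$template_name),
             strsplit(chunk(alignment$template), "\n")[[1]])
  writeLines(lines, path)
  invisible(path)
}
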