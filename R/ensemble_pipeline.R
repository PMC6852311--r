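#' Ensemble pipeline: 18 chimeric templates per kinase
#'
#' Orchestrates donor-library validation, enumeration of the 2 x 3 x 3
#' template specifications in the canonical HM ordering, template
#' construction with alignments, batch classification and model-vs-
#' experiment matching.
#'
#' @name ensemble_pipeline
NULL

.PLOOP_CLASSES <- c("collapsed", "stretched")
.ALPHAC_CLASSES <- c("in", "inter", "out")
.ALOOP_CLASSES <- c("closed_type2", "open_dfg_out", "closed_a_under_p")

#' Assemble and validate a donor library
#'
#' Six N-lobe donors labelled by (P-loop, alphaC) and three A-loop donors
#' labelled by A-loop class. Every entry is re-classified at load time;
#' a label that the classifiers do not reproduce is an error.
#'
#' @param nlobe named list: key "ploop/alphac", value
#'   `list(domain, ploop, alphac, id)`.
#' @param aloop named list: key A-loop class, value `list(domain, aloop,
#'   id)`.
#' @param config validated configuration.
#' @return a `donor_library`.
#' @export
donor_library <- function(nlobe, aloop, config = default_config()) {
  lib <- structure(list(nlobe = nlobe, aloop = aloop),
                   class = "donor_library")
  validate_donor_library(lib, config)
  lib
}

#' Validate a donor library against the classifiers
#'
#' @param library a `donor_library`.
#' @param config validated configuration.
#' @return the library, invisibly; errors listing missing or mislabelled
#'   slots.
#' @export
validate_donor_library <- function(library, config = default_config()) {
  need_n <- as.vector(outer(.PLOOP_CLASSES, .ALPHAC_CLASSES, paste, sep = "/"))
  missing_n <- setdiff(need_n, names(library$nlobe))
  missing_a <- setdiff(.ALOOP_CLASSES, names(library$aloop))
  if (length(missing_n) + length(missing_a) > 0) {
    stop(sprintf("incomplete donor library; missing slots: %s",
                 paste(c(missing_n, missing_a), collapse = ", ")))
  }
  for (key in need_n) {
    e <- library$nlobe[[key]]
    lab <- classify_structure(e$domain, config)
    if (lab$ploop != e$ploop || lab$alphac != e$alphac) {
      stop(sprintf(
        "N-lobe donor %s (%s) classifies as ploop=%s/alphac=%s, not %s/%s",
        key, e$id, lab$ploop, lab$alphac, e$ploop, e$alphac))
    }
    if (lab$dfg != "out") {
      warning(sprintf("N-lobe donor %s (%s) is not DFG-out (dfg=%s)",
                      key, e$id, lab$dfg), call. = FALSE)
    }
  }
  for (key in .ALOOP_CLASSES) {
    e <- library$aloop[[key]]
    lab <- classify_structure(e$domain, config)
    if (lab$aloop != e$aloop) {
      stop(sprintf("A-loop donor %s (%s) classifies as aloop=%s, not %s",
                   key, e$id, lab$aloop, e$aloop))
    }
  }
  invisible(library)
}

#' @export
print.donor_library <- function(x, ...) {
  cat(sprintf("donor_library: %d N-lobe donors, %d A-loop donors\n",
              length(x$nlobe), length(x$aloop)))
  invisible(x)
}

#' Enumerate the 18 template specifications in HM order
#'
#' Cartesian product of \{collapsed, stretched\} x \{in, inter, out\} x
#' \{closed type 2, open DFG-out, closed A-under-P\}, ordered by the
#' canonical HM index (A-loop fastest, then alphaC, then P-loop; HM 1 =
#' closed type 2 / collapsed / alphaC-in, HM 18 = closed A-under-P /
#' stretched / alphaC-out).
#'
#' @param library a validated `donor_library`.
#' @return tibble of 18 rows: model_type_index, aloop, ploop, alphac,
#'   nlobe_donor, aloop_donor.
#' @export
enumerate_specs <- function(library) {
  validate_donor_library(library)
  rows <- list()
  hm <- 0L
  for (pl in .PLOOP_CLASSES) {
    for (ac in .ALPHAC_CLASSES) {
      for (al in .ALOOP_CLASSES) {
        hm <- hm + 1L
        key <- paste(pl, ac, sep = "/")
        rows[[hm]] <- tibble::tibble(
          model_type_index = hm, aloop = al, ploop = pl, alphac = ac,
          nlobe_donor = library$nlobe[[key]]$id,
          aloop_donor = library$aloop[[al]]$id)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the 18-template DFG-out ensemble for one kinase
#'
#' For every template specification: superpose the donors onto the
#' acceptor over the C-lobe core, splice, relieve clashes, and emit a
#' provenance-tagged PDB plus PIR and aligned-FASTA target alignments.
#' Individual template failures are recorded and do not abort the run.
#'
#' @param target_seq target kinase one-letter sequence (drives the
#'   alignments).
#' @param acceptor DFG-in acceptor as a `numbered_domain` (a warning is
#'   given when it does not classify DFG-in).
#' @param library a validated `donor_library`.
#' @param config validated configuration.
#' @param out_dir output directory (created if needed).
#' @param clash_policy "truncate_sidechain" (default) or "flag_only".
#' @return an `ensemble_manifest`: list with `kinase`, `records` (tibble,
#'   18 rows), `config_hash`, `created`; written as manifest.json in
#'   `out_dir`.
#' @export
build_ensemble <- function(target_seq, acceptor, library,
                           config = default_config(),
                           out_dir = tempfile("ensemble"),
                           clash_policy = "truncate_sidechain") {
  acc_label <- classify_structure(acceptor, config)
  if (acc_label$dfg != "in") {
    warning(sprintf("acceptor classifies dfg=%s, expected DFG-in",
                    acc_label$dfg), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- enumerate_specs(library)
  bounds <- config$boundaries
  scoring <- config$alignment
  # superpose each donor once
  nl_t <- lapply(library$nlobe, function(e)
    superpose_donor(e$domain, acceptor, bounds))
  al_t <- lapply(library$aloop, function(e)
    superpose_donor(e$domain, acceptor, bounds))
  records <- list()
  for (r in seq_len(nrow(specs))) {
    s <- specs[r, ]
    key <- paste(s$ploop, s$alphac, sep = "/")
    rec <- tryCatch({
      spec <- list(model_type_index = s$model_type_index, aloop = s$aloop,
                   ploop = s$ploop, alphac = s$alphac,
                   nlobe_donor = s$nlobe_donor, aloop_donor = s$aloop_donor,
                   acceptor = acceptor$kinase %||% "acceptor")
      tmpl <- splice(acceptor, nl_t[[key]], al_t[[s$aloop]], bounds, spec)
      tmpl <- relieve_clashes(tmpl, clash_policy, config$clash$cutoff)
      pdb_path <- file.path(out_dir, sprintf("hm_%02d.pdb",
                                             s$model_type_index))
      write_structure(tmpl, pdb_path, provenance = tmpl$provenance)
      aln <- build_template_alignment(target_seq, tmpl, scoring)
      aln$template_name <- sprintf("hm_%02d", s$model_type_index)
      aln$target_name <- acceptor$kinase %||% "target"
      pir_path <- file.path(out_dir, sprintf("hm_%02d.pir",
                                             s$model_type_index))
      fasta_path <- file.path(out_dir, sprintf("hm_%02d.afa",
                                               s$model_type_index))
      ids <- range(tmpl$numbering$ref_id)
      write_pir(aln, pir_path, basename(pdb_path), ids[1], ids[2])
      write_alignment_fasta(aln, fasta_path)
      tibble::tibble(
        model_type_index = s$model_type_index, aloop = s$aloop,
        ploop = s$ploop, alphac = s$alphac,
        nlobe_donor = s$nlobe_donor, aloop_donor = s$aloop_donor,
        pdb = basename(pdb_path), pir = basename(pir_path),
        fasta = basename(fasta_path),
        n_clashes = nrow(tmpl$clashes %||% detect_clashes(tmpl)),
        n_edits = length(tmpl$edits),
        fatal_clash = isTRUE(tmpl$fatal_clash),
        junction_ok = all(vapply(tmpl$junctions, `[[`, logical(1), "ok")),
        error = NA_character_)
    }, error = function(e) {
      tibble::tibble(
        model_type_index = s$model_type_index, aloop = s$aloop,
        ploop = s$ploop, alphac = s$alphac,
        nlobe_donor = s$nlobe_donor, aloop_donor = s$aloop_donor,
        pdb = NA_character_, pir = NA_character_, fasta = NA_character_,
        n_clashes = NA_integer_, n_edits = NA_integer_,
        fatal_clash = NA, junction_ok = NA,
        error = conditionMessage(e))
    })
    records[[r]] <- rec
  }
  manifest <- structure(
    list(kinase = acceptor$kinase %||% "target",
         acceptor = acceptor$source$path %||% "synthetic",
         records = do.call(rbind, records),
         config_hash = .config_hash(config),
         tool_version = as.character(utils::packageVersion("dfgout")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         out_dir = out_dir),
    class = "ensemble_manifest")
  jsonlite::write_json(
    list(kinase = manifest$kinase, acceptor = manifest$acceptor,
         config_hash = manifest$config_hash,
         tool_version = manifest$tool_version, created = manifest$created,
         records = manifest$records),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest
}

#' @export
print.ensemble_manifest <- function(x, ...) {
  ok <- sum(is.na(x$records$error))
  cat(sprintf("ensemble_manifest [%s]: %d/%d templates built (%s)\n",
              x$kinase, ok, nrow(x$records), x$out_dir))
  invisible(x)
}

#' Classify a batch of structure files
#'
#' One row per requested chain with the four element labels and all
#' feature values; unreadable entries are reported in the `error` column,
#' never fatal.
#'
#' @param paths structure file paths.
#' @param chains chain IDs (recycled; default "A").
#' @param config validated configuration.
#' @return tibble.
#' @export
classify_batch <- function(paths, chains = "A", config = default_config()) {
  if (length(paths) == 0) {
    return(tibble::tibble(path = character(0), chain = character(0),
                          dfg = character(0), aloop = character(0),
                          ploop = character(0), alphac = character(0),
                          error = character(0)))
  }
  chains <- rep_len(chains, length(paths))
  rows <- lapply(seq_along(paths), function(i) {
    tryCatch({
      chain <- select_chain(read_structure(paths[i]), chains[i])
      dom <- number_domain(chain, scoring = config$alignment)
      lab <- classify_structure(dom, config)
      fv <- lab$features$values
      tibble::tibble(path = paths[i], chain = chains[i],
                     dfg = lab$dfg, aloop = lab$aloop, ploop = lab$ploop,
                     alphac = lab$alphac,
                     tibble::as_tibble(as.list(fv)),
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(path = paths[i], chain = chains[i],
                     dfg = NA_character_, aloop = NA_character_,
                     ploop = NA_character_, alphac = NA_character_,
                     error = conditionMessage(e))
    })
  })
  out <- rows[[1]][0, ]
  for (r in rows) {
    miss <- setdiff(names(out), names(r))
    for (m in miss) r[[m]] <- NA
    out <- rbind(out, r[, names(out)])
  }
  if (length(rows) == 0) out else out
}

#' Match candidate structures against experimental references
#'
#' All-vs-all backbone RMSD over the common reference IDs (with fitting);
#' a pair is "similar" below the threshold (default 0.7 A), and a
#' "classification match" when the A-loop, P-loop and alphaC labels all
#' agree. The minimal-RMSD reference per candidate is flagged.
#'
#' @param candidates,references named lists of `numbered_domain` objects.
#' @param threshold backbone RMSD threshold in Angstrom.
#' @param config validated configuration.
#' @return a `match_report` tibble: candidate, reference, rmsd, n_ids,
#'   similar, classification_match, is_min_rmsd.
#' @export
match_experimental <- function(candidates, references, threshold = 0.7,
                               config = default_config()) {
  if (is.null(names(candidates))) names(candidates) <- paste0("cand", seq_along(candidates))
  if (is.null(names(references))) names(references) <- paste0("ref", seq_along(references))
  lab_c <- lapply(candidates, classify_structure, config = config)
  lab_r <- lapply(references, classify_structure, config = config)
  rows <- list()
  for (i in names(candidates)) {
    for (j in names(references)) {
      rec <- tryCatch({
        ids <- intersect(domain_reference_ids(candidates[[i]]),
                         domain_reference_ids(references[[j]]))
        if (length(ids) == 0) stop("no common reference IDs")
        rmsd <- backbone_rmsd(candidates[[i]], references[[j]], ids,
                              fit = TRUE)
        cm <- lab_c[[i]]$aloop == lab_r[[j]]$aloop &&
          lab_c[[i]]$ploop == lab_r[[j]]$ploop &&
          lab_c[[i]]$alphac == lab_r[[j]]$alphac
        tibble::tibble(candidate = i, reference = j,
                       rmsd = as.numeric(rmsd), n_ids = length(ids),
                       similar = as.numeric(rmsd) < threshold,
                       classification_match = cm,
                       skipped = NA_character_)
      }, error = function(e) {
        tibble::tibble(candidate = i, reference = j, rmsd = NA_real_,
                       n_ids = 0L, similar = NA,
                       classification_match = NA,
                       skipped = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$is_min_rmsd <- FALSE
  for (i in unique(out$candidate)) {
    sel <- which(out$candidate == i & !is.na(out$rmsd))
    if (length(sel) > 0) {
      out$is_min_rmsd[sel[which.min(out$rmsd[sel])]] <- TRUE
    }
  }
  out
}
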