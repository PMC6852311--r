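test_that("domain partition covers the chain disjointly with the DFG motif in the A-loop", {
  dom <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  part <- partition_domain(dom, bounds)
  n <- nrow(dom$numbering)
  expect_equal(sort(c(part$n_lobe, part$c_lobe_core, part$a_loop)), 1:n)
  aloop_ids <- dom$numbering$ref_id[part$a_loop]
  expect_true(all(184:186 %in% aloop_ids))
  # insertions follow their preceding numbered residue
  ins <- dom
  row100 <- which(ins$numbering$ref_id == 100)
  ins$numbering <- rbind(ins$numbering[1:row100, ],
                         tibble::tibble(position = 0L, resno = 1000L,
                                        icode = "", resname = "GLY",
                                        ref_id = NA_integer_),
                         ins$numbering[(row100 + 1):nrow(ins$numbering), ])
  ins$numbering$position <- seq_len(nrow(ins$numbering))
  part2 <- partition_domain(ins, bounds)
  expect_true((row100 + 1) %in% part2$n_lobe)
  # missing boundary residue is fatal and named
  cut <- dom
  cut$numbering <- cut$numbering[cut$numbering$ref_id != 120 |
                                   is.na(cut$numbering$ref_id), ]
  expect_error(partition_domain(cut, bounds), "120")
})

test_that("donor superposition is exact for identical structures and recovers known motions", {
  acc <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  same <- superpose_donor(acc, acc, bounds)
  sp <- attr(same, "superposition")
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(max(abs(same$atoms$x - acc$atoms$x)), 0, tolerance = 1e-8)
  set.seed(55)
  tr <- random_rigid()
  moved <- transform_domain(acc, tr)
  back <- superpose_donor(moved, acc, bounds)
  expect_lt(attr(back, "superposition")$rmsd, 1e-8)
  expect_lt(max(abs(back$atoms$x - acc$atoms$x)), 1e-7)
  # donor lacking its C-lobe cannot be superposed
  nolobe <- acc
  nolobe$atoms <- nolobe$atoms[nolobe$atoms$ref_id <= 120, ]
  expect_error(superpose_donor(nolobe, acc, bounds), "insufficient")
})

test_that("self-chimera reproduces the original structure exactly", {
  acc <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  nl <- superpose_donor(acc, acc, bounds)
  al <- superpose_donor(acc, acc, bounds)
  tm <- splice(acc, nl, al, bounds)
  expect_s3_class(tm, "chimeric_template")
  expect_equal(nrow(tm$numbering), nrow(acc$numbering))
  expect_lt(as.numeric(backbone_rmsd(tm, acc)), 1e-9)
  # provenance partitions the residues per the boundaries
  prov <- tm$atoms$provenance[!duplicated(tm$atoms$ref_id)]
  ids <- tm$numbering$ref_id
  expect_true(all(prov[ids <= 120] == "nlobe_donor"))
  expect_true(all(prov[ids >= 183 & ids <= 208] == "aloop_donor"))
  expect_true(all(prov[(ids > 120 & ids < 183) | ids > 208] ==
                    "acceptor_clobe"))
  # hinge and DFG-side junctions are covalently exact; the APE-side
  # junction reproduces the acceptor's own closure geometry
  jd <- vapply(tm$junctions, `[[`, numeric(1), "distance")
  jl <- vapply(tm$junctions, `[[`, numeric(1), "left")
  expect_true(all(jd[jl %in% c(120, 182)] < 2.5))
  own_gap <- sqrt(sum((domain_atom_coord(acc, 208, "C") -
                         domain_atom_coord(acc, 209, "N"))^2))
  expect_equal(jd[jl == 208], own_gap, tolerance = 1e-9)
  expect_equal(detect_clashes(tm)$distance, numeric(0))
})

test_that("the A-loop of a chimera comes verbatim from the A-loop donor", {
  acc <- fx_acceptor()
  lib <- fx_library()
  bounds <- segment_boundaries(fx_config())
  nl <- superpose_donor(lib$nlobe[["stretched/in"]]$domain, acc, bounds)
  al <- superpose_donor(lib$aloop$closed_type2$domain, acc, bounds)
  tm <- splice(acc, nl, al, bounds)
  sub_t <- tm$atoms[tm$atoms$ref_id %in% 183:208, c("name", "x", "y", "z")]
  sub_d <- al$atoms[al$atoms$ref_id %in% 183:208, c("name", "x", "y", "z")]
  expect_equal(sub_t$x, sub_d$x)
  expect_equal(sub_t$y, sub_d$y)
  expect_equal(sub_t$z, sub_d$z)
})

test_that("clash detection reports planted clashes and excludes junction-bonded pairs", {
  acc <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  tm <- splice(acc, superpose_donor(acc, acc, bounds),
               superpose_donor(acc, acc, bounds), bounds)
  expect_equal(nrow(detect_clashes(tm)), 0)
  # plant an N-lobe side-chain atom 1.0 A from a C-lobe atom
  evil <- tm
  target <- which(evil$atoms$ref_id == 150 & evil$atoms$name == "CA")
  src <- which(evil$atoms$ref_id == 91 & evil$atoms$name == "OE1")
  evil$atoms[src, c("x", "y", "z")] <-
    evil$atoms[target, c("x", "y", "z")] + c(1, 0, 0)
  cl <- detect_clashes(evil)
  expect_gt(nrow(cl), 0)
  # every reported pair involves the planted atom, and the planted
  # contact itself is reported at its exact distance
  expect_true(all(cl$ref_a == 91 & cl$atom_a == "OE1"))
  planted <- cl[cl$ref_b == 150 & cl$atom_b == "CA", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$distance, 1, tolerance = 1e-9)
  expect_equal(planted$seg_a, "nlobe_donor")
  expect_equal(planted$seg_b, "acceptor_clobe")
  # junction-bonded C-N pair at ~1.33 A is not reported
  jd <- vapply(tm$junctions, `[[`, numeric(1), "distance")
  expect_true(any(jd < 2.5))
})

test_that("clash relief truncates donor side chains but never backbone", {
  acc <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  tm <- splice(acc, superpose_donor(acc, acc, bounds),
               superpose_donor(acc, acc, bounds), bounds)
  evil <- tm
  target <- which(evil$atoms$ref_id == 150 & evil$atoms$name == "CA")
  src <- which(evil$atoms$ref_id == 91 & evil$atoms$name == "OE1")
  evil$atoms[src, c("x", "y", "z")] <-
    evil$atoms[target, c("x", "y", "z")] + c(1, 0, 0)
  # flag_only leaves coordinates untouched
  flagged <- relieve_clashes(evil, "flag_only")
  expect_equal(flagged$atoms, evil$atoms)
  expect_gt(nrow(flagged$clashes), 0)
  # truncation removes the Glu91 side chain beyond CB and clears the clash
  fixed <- relieve_clashes(evil, "truncate_sidechain")
  expect_equal(nrow(fixed$clashes), 0)
  expect_false(fixed$fatal_clash)
  expect_gt(length(fixed$edits), 0)
  left91 <- fixed$atoms$name[fixed$atoms$ref_id == 91]
  expect_true(all(left91 %in% c("N", "CA", "C", "O", "CB")))
  # backbone-backbone clash cannot be relieved: fatal flag, still emitted
  bb <- tm
  srcb <- which(bb$atoms$ref_id == 45 & bb$atoms$name == "N")
  bb$atoms[srcb, c("x", "y", "z")] <-
    bb$atoms[target, c("x", "y", "z")] + c(1, 0, 0)
  expect_warning(bad <- relieve_clashes(bb, "truncate_sidechain"),
                 "unrelievable")
  expect_true(bad$fatal_clash)
})

test_that("target-to-template alignments are exact for identity and track insertions", {
  acc <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  tm <- splice(acc, superpose_donor(acc, acc, bounds),
               superpose_donor(acc, acc, bounds), bounds)
  tseq <- extract_sequence(tm)$sequence
  aln <- build_template_alignment(tseq, tm)
  expect_equal(aln$target, tseq)
  expect_equal(aln$template, tseq)
  expect_false(grepl("-", aln$template))
  expect_equal(nchar(aln$segments), nchar(aln$template))
  # degapped rows equal the inputs (alignment invariant)
  ins_seq <- paste0(substr(tseq, 1, 150), "GG", substr(tseq, 151, nchar(tseq)))
  aln2 <- build_template_alignment(ins_seq, tm)
  expect_equal(gsub("-", "", aln2$target), ins_seq)
  expect_equal(gsub("-", "", aln2$template), tseq)
  # exactly one 2-column gap in the template row
  expect_equal(nchar(aln2$template) - nchar(tseq), 2)
  expect_true(grepl("--", aln2$template) &&
                length(gregexpr("-+", aln2$template)[[1]]) == 1)
  # unrelated sequence fails the floor
  set.seed(8)
  rnd <- paste(sample(strsplit(tseq, "")[[1]]), collapse = "")
  expect_error(build_template_alignment(rnd, tm), "too dissimilar")
  expect_error(build_template_alignment("", tm), "empty target")
})

test_that("PIR and aligned-FASTA writers emit consumable files", {
  acc <- fx_acceptor()
  bounds <- segment_boundaries(fx_config())
  tm <- splice(acc, superpose_donor(acc, acc, bounds),
               superpose_donor(acc, acc, bounds), bounds)
  tseq <- extract_sequence(tm)$sequence
  aln <- build_template_alignment(tseq, tm)
  pir <- tempfile(fileext = ".pir")
  write_pir(aln, pir, "template.pdb", 40, 300)
  txt <- readLines(pir)
  expect_equal(sum(grepl("^>P1;", txt)), 2)
  expect_true(any(grepl("^structureX:template.pdb:40:A:300:A", txt)))
  body <- paste(txt[3:(grep("^$", txt)[1] - 1)], collapse = "")
  expect_equal(gsub("[*\n]", "", body), tseq)
  fa <- tempfile(fileext = ".afa")
  write_alignment_fasta(aln, fa)
  ftxt <- readLines(fa)
  expect_equal(sum(grepl("^>", ftxt)), 2)
  expect_equal(paste(ftxt[2:(grep("^>", ftxt)[2] - 1)], collapse = ""), tseq)
})
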