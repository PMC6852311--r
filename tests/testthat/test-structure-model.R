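test_that("hand-written PDB text parses to the expected residues and sequence", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(mini_residue_lines(1, "ALA", c(0, 0, 0), serial0 = 0),
             mini_residue_lines(2, "GLY", c(4, 0, 0), serial0 = 4),
             mini_residue_lines(3, "ASP", c(8, 0, 0), serial0 = 8))
  write_mini_pdb(path, lines)
  s <- read_structure(path)
  ch <- select_chain(s, "A")
  expect_equal(nrow(chain_residues(ch)), 3)
  seq <- extract_sequence(ch)
  expect_equal(seq$sequence, "AGD")
  expect_equal(nrow(seq$positions), 3)
  expect_equal(nrow(seq$gaps), 0)
})

test_that("waters and ligands are dropped; MSE maps to Met", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(mini_residue_lines(1, "ALA", c(0, 0, 0)),
             sub("^ATOM  ", "HETATM",
                 mini_residue_lines(2, "MSE", c(4, 0, 0), serial0 = 4)),
             sub("^ATOM  ", "HETATM",
                 pdb_atom_line(9, "O", "HOH", "A", 100, c(20, 0, 0))),
             sub("^ATOM  ", "HETATM",
                 pdb_atom_line(10, "C1", "GOL", "A", 101, c(25, 0, 0))))
  write_mini_pdb(path, lines)
  ch <- select_chain(read_structure(path), "A")
  seq <- extract_sequence(ch)
  expect_equal(seq$sequence, "AM")
})

test_that("multi-model files expose selectable models with distinct coordinates", {
  path <- tempfile(fileext = ".pdb")
  lines <- c("MODEL        1",
             mini_residue_lines(1, "ALA", c(0, 0, 0)),
             "ENDMDL",
             "MODEL        2",
             mini_residue_lines(1, "ALA", c(10, 0, 0)),
             "ENDMDL")
  write_mini_pdb(path, lines)
  s <- read_structure(path)
  m0 <- select_chain(s, "A", 0)
  m1 <- select_chain(s, "A", 1)
  expect_equal(m1$atoms$x - m0$atoms$x, rep(10, 4))
  expect_error(select_chain(s, "A", 5), "available")
})

test_that("chain selection errors list available chains and is idempotent", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(mini_residue_lines(1, "ALA", c(0, 0, 0), chain = "A"),
             mini_residue_lines(1, "GLY", c(8, 0, 0), chain = "B", serial0 = 4))
  write_mini_pdb(path, lines)
  s <- read_structure(path)
  b <- select_chain(s, "B")
  expect_equal(chain_residues(b)$resname, "GLY")
  expect_error(select_chain(s, "Z"), "A,B")
  # selecting from an already-selected chain view is a no-op
  b2 <- select_chain(structure(list(atoms = b$atoms, source = b$source),
                               class = "protein_structure"), "B")
  expect_equal(b2$atoms[, c("x", "y", "z")], b$atoms[, c("x", "y", "z")])
})

test_that("altloc groups collapse to the highest occupancy with alphabetical ties", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(pdb_atom_line(1, "N", "ALA", "A", 1, c(0, 0, 0)),
             pdb_atom_line(2, "CA", "ALA", "A", 1, c(1, 0, 0),
                           occ = 0.6, altloc = "A"),
             pdb_atom_line(3, "CA", "ALA", "A", 1, c(2, 0, 0),
                           occ = 0.4, altloc = "B"),
             pdb_atom_line(4, "C", "ALA", "A", 1, c(3, 0, 0),
                           occ = 0.5, altloc = "B"),
             pdb_atom_line(5, "C", "ALA", "A", 1, c(4, 0, 0),
                           occ = 0.5, altloc = "A"))
  write_mini_pdb(path, lines)
  ch <- select_chain(read_structure(path), "A")
  ca <- ch$atoms[ch$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1)  # occupancy 0.6 wins
  cc <- ch$atoms[ch$atoms$name == "C", ]
  expect_equal(cc$x, 4)  # tie -> altloc "A" first alphabetically
})

test_that("numbering gaps are annotated, not filled with letters", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(mini_residue_lines(10, "ALA", c(0, 0, 0)),
             mini_residue_lines(11, "GLY", c(4, 0, 0), serial0 = 4),
             mini_residue_lines(15, "ASP", c(8, 0, 0), serial0 = 8))
  write_mini_pdb(path, lines)
  seq <- extract_sequence(select_chain(read_structure(path), "A"))
  expect_equal(seq$sequence, "AGD")
  expect_equal(nrow(seq$gaps), 1)
  expect_equal(seq$gaps$after_position, 2)
  expect_equal(seq$gaps$resno_before, 11)
  expect_equal(seq$gaps$resno_after, 15)
})

test_that("write/read round trip preserves coordinates and provenance remarks", {
  dom <- fx_scaffold()
  path <- tempfile(fileext = ".pdb")
  prov <- list(list(segment = "nlobe_donor", first = 40L, last = 120L,
                    source = "synthetic:nlobe"),
               list(segment = "acceptor_clobe", first = 121L, last = 182L,
                    source = "acceptor"),
               list(segment = "aloop_donor", first = 183L, last = 208L,
                    source = "synthetic:aloop"))
  write_structure(dom, path, provenance = prov)
  txt <- readLines(path)
  expect_equal(sum(grepl("^REMARK  99 DFGOUT SEGMENT", txt)), 3)
  back <- select_chain(read_structure(path), "A")
  expect_equal(nrow(back$atoms), nrow(dom$atoms))
  expect_lt(max(abs(back$atoms$x - dom$atoms$x)), 1e-3 + 1e-9)
  expect_lt(max(abs(back$atoms$y - dom$atoms$y)), 1e-3 + 1e-9)
  expect_lt(max(abs(back$atoms$z - dom$atoms$z)), 1e-3 + 1e-9)
  expect_equal(back$provenance[[2]]$segment, "acceptor_clobe")
  expect_equal(back$provenance[[3]]$first, 183L)
  # a second round trip is exact relative to the first (idempotence)
  path2 <- tempfile(fileext = ".pdb")
  write_structure(back, path2)
  back2 <- select_chain(read_structure(path2), "A")
  expect_equal(back2$atoms$x, back$atoms$x)
  expect_equal(back2$atoms$resname, back$atoms$resname)
  # empty input is an error
  empty <- dom; empty$atoms <- dom$atoms[0, ]
  expect_error(write_structure(empty, tempfile()), "no atoms")
})
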