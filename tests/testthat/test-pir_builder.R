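read_text <- function(path) {
  paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
}

# 10-residue template ACDEFGHIKL plus ADP and MG ligands (golden case 3)
pdb_lig_template <- pdb_text(
  atom_line("ATOM",  1, "CA", "ALA", "A", 1, " ", 0.0, 0, 0),
  atom_line("ATOM",  2, "CA", "CYS", "A", 2, " ", 3.8, 0, 0),
  atom_line("ATOM",  3, "CA", "ASP", "A", 3, " ", 7.6, 0, 0),
  atom_line("ATOM",  4, "CA", "GLU", "A", 4, " ", 11.4, 0, 0),
  atom_line("ATOM",  5, "CA", "PHE", "A", 5, " ", 15.2, 0, 0),
  atom_line("ATOM",  6, "CA", "GLY", "A", 6, " ", 19.0, 0, 0),
  atom_line("ATOM",  7, "CA", "HIS", "A", 7, " ", 22.8, 0, 0),
  atom_line("ATOM",  8, "CA", "ILE", "A", 8, " ", 26.6, 0, 0),
  atom_line("ATOM",  9, "CA", "LYS", "A", 9, " ", 30.4, 0, 0),
  atom_line("ATOM", 10, "CA", "LEU", "A", 10, " ", 34.2, 0, 0),
  atom_line("HETATM", 11, "C1", "ADP", "A", 101, " ", 40, 0, 0),
  atom_line("HETATM", 12, "MG", "MG",  "A", 102, " ", 42, 0, 0, "MG"))

test_that("render_pir_sequences maps status to '-' and '.'", {
  mk <- function(status) alignment(c("t", "p"), c("target", "template"),
                                   c("AKGS", "AXGS"),
                                   status = list(rep("observed_standard", 4),
                                                 status))
  base <- c("observed_standard", "missing", "observed_standard",
            "observed_standard")
  expect_equal(unname(render_pir_sequences(mk(base))[2]), "A-GS")
  base[2] <- "observed_modified"
  expect_equal(unname(render_pir_sequences(mk(base))[2]), "A.GS")
  clean <- alignment(c("t", "p"), c("target", "template"), c("AKGS", "AAGS"))
  expect_equal(unname(render_pir_sequences(clean)[2]), "AAGS")
  # unannotated non-gap template positions are a contract error
  broken <- mk(base)
  broken$status[[2]][1] <- NA
  expect_error(render_pir_sequences(broken), "lacks status annotation")
})

test_that("determine_span resolves author numbering and insertion codes", {
  ch <- make_numbered_chain(5, 104)
  m <- parse_pdb(ch$text)
  ann <- extract_chain_sequence(m, "A")
  full <- render_sequence(ann, "plain")
  # entry covering residues 7..60 (positions 3..56 of the chain)
  sub <- substr(full, 3, 56)
  sp <- determine_span(sub, m, "A")
  expect_equal(sp$start_res, "7")
  expect_equal(sp$end_res, "60")
  # full-chain entry
  sp2 <- determine_span(full, m, "A")
  expect_equal(sp2$start_res, "5")
  expect_equal(sp2$end_res, "104")
  # insertion codes are carried into the span
  mi <- parse_pdb(PDB_INSCODE)                     # VAL51 GLY52 ALA52A SER53
  sp3 <- determine_span("VGA", mi, "A")
  expect_equal(sp3$end_res, "52A")
  expect_error(determine_span("WWWW", m, "A"), "no contiguous match")
})

test_that("verify_template_sequence reports the first mismatch", {
  m <- parse_pdb(PDB_MISSING)                      # A (K missing) G S
  expect_true(verify_template_sequence("A-GS", m, "A")$valid)
  # wrong letter over an observed residue
  v <- verify_template_sequence("A-AS", m, "A")
  expect_false(v$valid)
  # '-' over an observed residue inside the span contradicts the structure
  v2 <- verify_template_sequence("A--S", m, "A",
                                 span = determine_span("A-GS", m, "A"))
  expect_false(v2$valid)
  # '.' must sit on modified residues
  mm <- parse_pdb(PDB_MODIFIED)                    # A G M(SE) S
  expect_true(verify_template_sequence("AG.S", mm, "A")$valid)
  v3 <- verify_template_sequence("AGMS", mm, "A",
                                 span = determine_span("AG.S", mm, "A"))
  expect_false(v3$valid)
  expect_match(v3$reason, "modified")
})

test_that("graft_ligands appends ligand columns and updates end residues", {
  m <- parse_pdb(pdb_lig_template, pdb_id = "tmpl3")
  aln <- alignment(c("tgt3", "tmpl3"), c("target", "template"),
                   c("ACDEFGHIKL", "ACDEFGHIKL"))
  pir <- build_pir(aln, list(tmpl3 = m), chains = c(tmpl3 = "A"))
  # both ligands selected: two '.' columns on template and target
  both <- graft_ligands(pir, list(tmpl3 = m),
                        data.frame(template = "tmpl3",
                                   het_code = c("ADP", "MG"),
                                   coord_index = c(0L, 1L)))
  expect_equal(both$entries[[1]]$seq, "ACDEFGHIKL..")
  expect_equal(both$entries[[2]]$seq, "ACDEFGHIKL..")
  expect_equal(both$entries[[1]]$end_res, "102")
  # MG only: ADP column still appended to the template but stays '-' in the target
  mg <- graft_ligands(pir, list(tmpl3 = m),
                      data.frame(template = "tmpl3", het_code = "MG",
                                 coord_index = 1L))
  expect_equal(mg$entries[[1]]$seq, "ACDEFGHIKL..")
  expect_equal(mg$entries[[2]]$seq, "ACDEFGHIKL-.")
  expect_equal(mg$entries[[1]]$end_res, "102")
  # empty selection leaves the file unchanged
  expect_identical(graft_ligands(pir, list(tmpl3 = m),
                                 data.frame(template = character(),
                                            het_code = character(),
                                            coord_index = integer())),
                   pir)
  # count conservation: target '.' count equals number of selected ligands
  expect_equal(lengths(regmatches(both$entries[[2]]$seq,
                                  gregexpr(".", both$entries[[2]]$seq,
                                           fixed = TRUE))), 2)
  # errors: unknown ligand; sequence-kind entry
  expect_error(graft_ligands(pir, list(tmpl3 = m),
                             data.frame(template = "tmpl3", het_code = "ZN",
                                        coord_index = 9L)),
               "not found")
  expect_error(graft_ligands(pir, list(tmpl3 = m),
                             data.frame(template = "tgt3", het_code = "ADP",
                                        coord_index = 0L)),
               "sequence-kind")
})

test_that("write_pir matches the hand-authored golden files byte for byte", {
  simple <- pir_file(list(
    list(name = "tmpl1", kind = "structure", pdb_file = "tmpl1.pdb",
         chain = "A", start_res = "1", start_chain = "A", end_res = "6",
         end_chain = "A", seq = "MKLVRT"),
    list(name = "tgt1", kind = "sequence", pdb_file = "", chain = "",
         start_res = "", start_chain = "", end_res = "", end_chain = "",
         seq = "MKLVRT")))
  expect_identical(write_pir(simple), read_text(test_path("golden", "pir_simple.pir")))

  body <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 4), collapse = "")
  wrap <- pir_file(list(
    list(name = "t80", kind = "structure", pdb_file = "t80.pdb", chain = "A",
         start_res = "1", start_chain = "A", end_res = "80", end_chain = "A",
         seq = body),
    list(name = "s80", kind = "sequence", pdb_file = "", chain = "",
         start_res = "", start_chain = "", end_res = "", end_chain = "",
         seq = body)))
  expect_identical(write_pir(wrap), read_text(test_path("golden", "pir_wrap75.pir")))

  # ligand-grafted case produced end-to-end from the structure
  m <- parse_pdb(pdb_lig_template, pdb_id = "tmpl3")
  aln <- alignment(c("tgt3", "tmpl3"), c("target", "template"),
                   c("ACDEFGHIKL", "ACDEFGHIKL"))
  pir <- build_pir(trim_termini(aln), list(tmpl3 = m), chains = c(tmpl3 = "A"))
  grafted <- graft_ligands(pir, list(tmpl3 = m),
                           data.frame(template = "tmpl3",
                                      het_code = c("ADP", "MG"),
                                      coord_index = c(0L, 1L)))
  expect_identical(write_pir(grafted), read_text(test_path("golden", "pir_ligand.pir")))
})

test_that("read_pir inverts write_pir on PirFile fields", {
  m <- parse_pdb(pdb_lig_template, pdb_id = "tmpl3")
  aln <- alignment(c("tgt3", "tmpl3"), c("target", "template"),
                   c("ACDEFGHIKL", "ACDEFGHIKL"))
  pir <- graft_ligands(build_pir(aln, list(tmpl3 = m), chains = c(tmpl3 = "A")),
                       list(tmpl3 = m),
                       data.frame(template = "tmpl3", het_code = "MG",
                                  coord_index = 1L))
  back <- read_pir(write_pir(pir))
  expect_equal(lapply(back$entries, unlist), lapply(pir$entries, unlist))
  expect_error(pir_file(list(list(kind = "structure", seq = ""))), "needs")
})

test_that("build_job_config derives read flags from the selection", {
  adp <- build_job_config(data.frame(template = "t", het_code = "ADP",
                                     coord_index = 0L))
  expect_true(adp$read_hetatm); expect_false(adp$read_water)
  hoh <- build_job_config(data.frame(template = "t", het_code = "HOH",
                                     coord_index = 2L))
  expect_true(hoh$read_water); expect_false(hoh$read_hetatm)
  default <- build_job_config()
  expect_equal(default$n_models, 10L)
  expect_equal(default$refinement, "very_slow")
  expect_false(default$read_hetatm); expect_false(default$read_water)
  expect_error(build_job_config(refinement = "ultra"), "unknown refinement")
  # YAML serialization and the script stub reflect the configuration
  expect_match(write_job_config(adp), "read_hetatm: yes")
  scr <- render_modeling_script(adp, "job.pir", knowns = "tmpl3", target = "tgt3")
  expect_match(scr, "env.io.hetatm = True")
  expect_match(scr, "a.ending_model = 10")
  expect_match(scr, "refine.very_slow")
})
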