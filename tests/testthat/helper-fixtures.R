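# Small hand-crafted PDB texts used across the parser tests. Expected values
# in the tests were derived by hand from these literals.

atom_line <- function(record, serial, name, resn, chain, resno, icode, x, y, z,
                      element = "C") {
  name4 <- if (nchar(name) <= 3) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, resn, chain, resno, icode, x, y, z, 1, 0,
          element)
}

pdb_text <- function(...) paste(c(..., "END"), collapse = "\n")

# 3-residue chain A (ALA, GLY, SER), no remarks
PDB_THREE_RES <- pdb_text(
  atom_line("ATOM", 1, "CA", "ALA", "A", 1, " ", 0, 0, 0),
  atom_line("ATOM", 2, "CA", "GLY", "A", 2, " ", 3.8, 0, 0),
  atom_line("ATOM", 3, "CA", "SER", "A", 3, " ", 7.6, 0, 0))

# ALA(1) [LYS(2) missing] GLY(3) SER(4): REMARK 465 declares the gap
PDB_MISSING <- pdb_text(
  "REMARK 465 MISSING RESIDUES",
  "REMARK 465   M RES C SSSEQI",
  "REMARK 465     LYS A     2",
  atom_line("ATOM", 1, "CA", "ALA", "A", 1, " ", 0, 0, 0),
  atom_line("ATOM", 2, "CA", "GLY", "A", 3, " ", 3.8, 0, 0),
  atom_line("ATOM", 3, "CA", "SER", "A", 4, " ", 7.6, 0, 0))

# ALA GLY MSE SER polymer (MSE via in-chain HETATM + MODRES) then ADP ligand
PDB_MODIFIED <- pdb_text(
  "MODRES XXXX MSE A    3  MET  SELENOMETHIONINE",
  atom_line("ATOM",   1, "CA", "ALA", "A", 1, " ", 0, 0, 0),
  atom_line("ATOM",   2, "CA", "GLY", "A", 2, " ", 3.8, 0, 0),
  atom_line("HETATM", 3, "CA", "MSE", "A", 3, " ", 7.6, 0, 0),
  atom_line("ATOM",   4, "CA", "SER", "A", 4, " ", 11.4, 0, 0),
  atom_line("HETATM", 5, "C1", "ADP", "A", 101, " ", 15, 2, 2))

# ligand ordering fixture: ADP, MG, then three waters
PDB_LIGANDS <- pdb_text(
  atom_line("ATOM",   1, "CA", "ALA", "A", 1, " ", 0, 0, 0),
  atom_line("ATOM",   2, "CA", "GLY", "A", 2, " ", 3.8, 0, 0),
  atom_line("ATOM",   3, "CA", "SER", "A", 3, " ", 7.6, 0, 0),
  atom_line("HETATM", 4, "C1", "ADP", "A", 101, " ", 12, 0, 0),
  atom_line("HETATM", 5, "MG", "MG",  "A", 102, " ", 14, 0, 0, "MG"),
  atom_line("HETATM", 6, "O",  "HOH", "A", 201, " ", 16, 0, 0, "O"),
  atom_line("HETATM", 7, "O",  "HOH", "A", 202, " ", 17, 0, 0, "O"),
  atom_line("HETATM", 8, "O",  "HOH", "A", 203, " ", 18, 0, 0, "O"))

# insertion codes: 52, 52A, 53 (GLY, ALA, SER) preceded by VAL 51
PDB_INSCODE <- pdb_text(
  atom_line("ATOM", 1, "CA", "VAL", "A", 51, " ", 0, 0, 0),
  atom_line("ATOM", 2, "CA", "GLY", "A", 52, " ", 3.8, 0, 0),
  atom_line("ATOM", 3, "CA", "ALA", "A", 52, "A", 7.6, 0, 0),
  atom_line("ATOM", 4, "CA", "SER", "A", 53, " ", 11.4, 0, 0))

# SEQRES present, no REMARK 465: LYS at position 2 only in SEQRES
PDB_SEQRES_GAP <- pdb_text(
  "SEQRES   1 A    4  ALA LYS GLY SER",
  atom_line("ATOM", 1, "CA", "ALA", "A", 1, " ", 0, 0, 0),
  atom_line("ATOM", 2, "CA", "GLY", "A", 3, " ", 3.8, 0, 0),
  atom_line("ATOM", 3, "CA", "SER", "A", 4, " ", 7.6, 0, 0))

# duplicate observed residue (same chain/number/icode twice, non-altloc)
PDB_DUPLICATE <- pdb_text(
  atom_line("ATOM", 1, "CA", "ALA", "A", 1, " ", 0, 0, 0),
  atom_line("ATOM", 2, "CA", "GLY", "A", 2, " ", 3.8, 0, 0),
  atom_line("ATOM", 3, "CA", "SER", "A", 1, " ", 7.6, 0, 0))

# chain numbered 5..104 for span resolution; aperiodic sequence so interior
# windows resolve to a unique position
make_numbered_chain <- function(from = 5, to = 104) {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  n <- to - from + 1
  resn <- withr::with_seed(97, sample(aa3, n, replace = TRUE))
  lines <- vapply(seq_len(n), function(i)
    atom_line("ATOM", i, "CA", resn[i], "A", from + i - 1, " ",
              3.8 * i, 0, 0), "")
  list(text = pdb_text(lines), resn = resn)
}

# a tiny BLAST XML with explicit numbers (identities 90 over 100 columns,
# query 1..100 of a 120-residue query)
BLAST_XML_ONE_HIT <- paste0(
  "<?xml version=\"1.0\"?><BlastOutput><BlastOutput_iterations><Iteration>",
  "<Iteration_hits><Hit><Hit_num>1</Hit_num>",
  "<Hit_id>pdb|1ABC|A</Hit_id><Hit_def>test subject</Hit_def>",
  "<Hit_len>100</Hit_len><Hit_hsps><Hsp><Hsp_num>1</Hsp_num>",
  "<Hsp_bit-score>180</Hsp_bit-score><Hsp_evalue>2e-20</Hsp_evalue>",
  "<Hsp_query-from>1</Hsp_query-from><Hsp_query-to>100</Hsp_query-to>",
  "<Hsp_hit-from>1</Hsp_hit-from><Hsp_hit-to>100</Hsp_hit-to>",
  "<Hsp_identity>90</Hsp_identity><Hsp_align-len>100</Hsp_align-len>",
  sprintf("<Hsp_qseq>%s</Hsp_qseq><Hsp_hseq>%s</Hsp_hseq>",
          paste(rep("A", 100), collapse = ""),
          paste(rep("A", 100), collapse = "")),
  "</Hsp></Hit_hsps></Hit></Iteration_hits></Iteration>",
  "</BlastOutput_iterations></BlastOutput>")

BLAST_XML_EMPTY <- paste0(
  "<?xml version=\"1.0\"?><BlastOutput><BlastOutput_iterations><Iteration>",
  "<Iteration_hits></Iteration_hits></Iteration>",
  "</BlastOutput_iterations></BlastOutput>")

# two-block hhr hit (40 + 20 columns), identities field present
HHR_TWO_BLOCK <- local({
  q1 <- paste(rep("A", 40), collapse = ""); t1 <- q1
  q2 <- paste(rep("G", 20), collapse = ""); t2 <- q2
  paste(c(
    "Query         query1",
    "Match_columns 80",
    "",
    " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM",
    "  1 1abc_A test hit                99.9   1e-30   1e-35  200.0   0.0   60    3-62      1-60 (60)",
    "",
    "No 1",
    ">1abc_A test hit",
    "Probab=99.90  E-value=1e-30  Score=200.00  Aligned_cols=60  Identities=35%  Similarity=0.700  Sum_probs=0.0",
    "",
    sprintf("Q query1          3 %s   42 (80)", q1),
    sprintf("T 1abc_A          1 %s   40 (60)", t1),
    "",
    sprintf("Q query1         43 %s   62 (80)", q2),
    sprintf("T 1abc_A         41 %s   60 (60)", t2),
    ""), collapse = "\n")
})
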