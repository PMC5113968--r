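#' Parse a PDB-format file into an annotated structure model
#'
#' Reads ATOM/HETATM coordinates (via \pkg{bio3d}) together with the header
#' records that matter for sequence extraction: \code{REMARK 465} (missing
#' residues), \code{MODRES} (chemically modified residues) and \code{SEQRES}.
#' Polymer residues are classified as \code{observed_standard},
#' \code{observed_modified} or \code{missing}; every other HETATM record
#' becomes a ligand. In-chain HETATMs whose code has a known parent amino
#' acid (e.g. MSE) are treated as modified residues, not ligands.
#'
#' Missing residues are taken from \code{REMARK 465} when present; otherwise,
#' if SEQRES is present, missing runs are inferred by anchoring the observed
#' residues inside the SEQRES sequence; with neither, the chain is assumed
#' complete. Alternate locations are collapsed to the first conformer.
#'
#' @param text A character scalar holding a PDB file, a character vector of
#'   its lines, or a path to a PDB file.
#' @param pdb_id Identifier recorded on the model (defaults to the HEADER id
#'   if present, else \code{"xxxx"}).
#' @return A \code{StructureModel}: list with \code{pdb_id}, \code{residues}
#'   (data.frame: chain, res_name, resno, icode, one_letter, status),
#'   \code{ligands} (data.frame: het_code, chain, resno, icode, coord_index,
#'   is_water, n_atoms), \code{atoms} (per-atom coordinate table) and
#'   \code{seqres} (named list of 3-letter code vectors, or NULL).
#' @export
parse_pdb <- function(text, pdb_id = NULL) {
  lines <- as_pdb_lines(text)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("PDB format error: no ATOM or HETATM coordinate records found")

  if (is.null(pdb_id)) {
    hdr <- grep("^HEADER", lines, value = TRUE)
    pdb_id <- if (length(hdr) && nchar(hdr[1]) >= 66)
      tolower(trimws(substr(hdr[1], 63, 66))) else "xxxx"
    if (identical(pdb_id, "")) pdb_id <- "xxxx"
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""

  missing_df <- parse_remark465(lines)
  modres_df  <- parse_modres(lines)
  seqres     <- seqres_as_list(pdb$seqres)

  # residue-level view of the coordinate section, in file order
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first_idx <- !duplicated(key)
  res <- at[first_idx, c("chain", "resid", "resno", "insert", "type")]
  names(res) <- c("chain", "res_name", "resno", "icode", "rec_type")
  res$key <- key[first_idx]
  res$n_atoms <- as.integer(table(key)[res$key])

  res$is_standard <- res$res_name %in% names(AA_THREE_TO_ONE) &
    res$rec_type == "ATOM"
  res$in_modres <- res_key(res$chain, res$resno, res$icode) %in%
    res_key(modres_df$chain, modres_df$resno, modres_df$icode)

  # per-chain polymer numbering range of unambiguous polymer residues
  polymer_seed <- res$is_standard | res$in_modres
  res$is_polymer <- polymer_seed
  for (ch in unique(res$chain)) {
    sel <- res$chain == ch & polymer_seed
    if (!any(sel)) next
    rng <- range(res$resno[sel])
    cand <- res$chain == ch & !res$is_polymer &
      res$res_name %in% names(MODIFIED_PARENT) &
      res$resno >= rng[1] & res$resno <= rng[2]
    res$is_polymer[cand] <- TRUE
  }
  # ATOM records with non-standard residue names are still polymer
  res$is_polymer[res$rec_type == "ATOM"] <- TRUE

  # a residue identity reappearing after other residues intervened is a
  # duplicate (contiguous repeats are altloc/multi-atom records, already
  # collapsed above)
  runs <- rle(key)$values
  dup_run <- runs[duplicated(runs)]
  poly <- res[res$is_polymer, , drop = FALSE]
  bad <- intersect(dup_run, poly$key)
  if (length(bad)) {
    d <- poly[match(bad[1], poly$key), ]
    stop(sprintf("PDB format error: duplicate observed residue %s %s%s in chain %s",
                 d$res_name, d$resno, d$icode, d$chain))
  }

  poly$status <- ifelse(poly$is_standard, "observed_standard", "observed_modified")
  poly$one_letter <- one_letter_code(poly$res_name)

  # assemble chains: observed residues in file order + missing insertions
  chains <- unique(res$chain)
  residues <- do.call(rbind, lapply(chains, function(ch) {
    obs <- poly[poly$chain == ch,
                c("chain", "res_name", "resno", "icode", "one_letter",
                  "status", "n_atoms")]
    miss <- missing_df[missing_df$chain == ch, , drop = FALSE]
    if (nrow(miss) == 0 && !is.null(seqres[[ch]]) && nrow(obs) > 0)
      miss <- infer_missing_from_seqres(obs, seqres[[ch]], ch)
    merge_missing(obs, miss)
  }))
  rownames(residues) <- NULL

  # ligands: non-polymer HETATMs, global coordinate-section order
  lig <- res[!res$is_polymer, , drop = FALSE]
  ligands <- data.frame(
    het_code = lig$res_name, chain = lig$chain, resno = lig$resno,
    icode = lig$icode, coord_index = seq_len(nrow(lig)) - 1L,
    is_water = lig$res_name %in% WATER_CODES, n_atoms = lig$n_atoms,
    stringsAsFactors = FALSE
  )
  rownames(ligands) <- NULL

  atoms <- at[, c("type", "chain", "resid", "resno", "insert", "elety",
                  "x", "y", "z")]
  names(atoms)[names(atoms) == "insert"] <- "icode"
  names(atoms)[names(atoms) == "resid"] <- "res_name"
  atoms$role <- ifelse(key %in% poly$key, "polymer", "ligand")

  structure(
    list(pdb_id = pdb_id, residues = residues, ligands = ligands,
         atoms = atoms, seqres = seqres),
    class = "StructureModel"
  )
}

as_pdb_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

res_key <- function(chain, resno, icode) paste(chain, resno, icode, sep = "\r")

one_letter_code <- function(res_name) {
  out <- unname(AA_THREE_TO_ONE[res_name])
  mod <- is.na(out)
  out[mod] <- unname(MODIFIED_PARENT[res_name[mod]])
  out[is.na(out)] <- "X"
  out
}

# REMARK 465 entries: "REMARK 465     ALA A     2" (model column optional)
parse_remark465 <- function(lines) {
  rem <- grep("^REMARK 465", lines, value = TRUE)
  pat <- "^REMARK 465\\s+(?:\\d+\\s+)?([A-Z0-9]{2,3})\\s+([A-Za-z0-9])\\s+(-?\\d+)([A-Za-z]?)\\s*$"
  hit <- grepl(pat, rem)
  m <- regmatches(rem[hit], regexec(pat, rem[hit]))
  keep <- vapply(m, function(x) x[2] != "RES", logical(1))
  m <- m[keep]
  data.frame(
    res_name = vapply(m, `[`, "", 2),
    chain    = vapply(m, `[`, "", 3),
    resno    = as.integer(vapply(m, `[`, "", 4)),
    icode    = vapply(m, `[`, "", 5),
    stringsAsFactors = FALSE
  )
}

# MODRES idCode resName chain seqNum iCode stdRes comment
parse_modres <- function(lines) {
  mod <- grep("^MODRES", lines, value = TRUE)
  pat <- "^MODRES\\s+\\S+\\s+([A-Z0-9]{1,3})\\s+([A-Za-z0-9])\\s+(-?\\d+)([A-Za-z]?)\\s"
  m <- regmatches(mod, regexec(pat, mod))
  m <- m[vapply(m, length, 0L) == 5]
  data.frame(
    res_name = vapply(m, `[`, "", 2),
    chain    = vapply(m, `[`, "", 3),
    resno    = as.integer(vapply(m, `[`, "", 4)),
    icode    = vapply(m, `[`, "", 5),
    stringsAsFactors = FALSE
  )
}

seqres_as_list <- function(seqres) {
  if (is.null(seqres) || length(seqres) == 0) return(NULL)
  split(unname(seqres), names(seqres))
}

# Insert missing residues among observed ones by author numbering; observed
# file order is never re-sorted.
merge_missing <- function(obs, miss) {
  if (is.null(miss) || nrow(miss) == 0) return(obs)
  miss$one_letter <- one_letter_code(miss$res_name)
  miss$status <- "missing"
  miss$n_atoms <- 0L
  miss <- miss[order(miss$resno, miss$icode), ]
  out <- obs
  for (i in seq_len(nrow(miss))) {
    pos <- which(out$status != "missing" &
                   (out$resno > miss$resno[i] |
                      (out$resno == miss$resno[i] & out$icode > miss$icode[i])))
    at <- if (length(pos)) min(pos) else nrow(out) + 1L
    row <- miss[i, c("chain", "res_name", "resno", "icode", "one_letter",
                     "status", "n_atoms")]
    out <- if (at > nrow(out)) rbind(out, row)
    else rbind(out[seq_len(at - 1L), , drop = FALSE], row,
               out[at:nrow(out), , drop = FALSE])
  }
  out
}

# Greedy exact-match anchoring of observed residues inside SEQRES; leftover
# SEQRES positions become missing residues with interpolated author numbers.
infer_missing_from_seqres <- function(obs, seqres, chain) {
  miss <- list()
  j <- 1L
  prev_no <- if (nrow(obs)) obs$resno[1] - 1L else 0L
  for (i in seq_along(seqres)) {
    if (j <= nrow(obs) && seqres[i] == obs$res_name[j]) {
      prev_no <- obs$resno[j]
      j <- j + 1L
    } else {
      prev_no <- prev_no + 1L
      # avoid colliding with the next observed author number
      if (j <= nrow(obs) && prev_no >= obs$resno[j]) prev_no <- obs$resno[j] - 1L
      miss[[length(miss) + 1L]] <- data.frame(
        res_name = seqres[i], chain = chain, resno = prev_no, icode = "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(miss) == 0)
    return(data.frame(res_name = character(), chain = character(),
                      resno = integer(), icode = character()))
  do.call(rbind, miss)
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s': %d chain(s), %d polymer residue(s) (%d missing, %d modified), %d ligand record(s)\n",
              x$pdb_id, length(unique(x$residues$chain)), nrow(x$residues),
              sum(x$residues$status == "missing"),
              sum(x$residues$status == "observed_modified"),
              nrow(x$ligands)))
  invisible(x)
}

#' Extract the annotated sequence of one chain
#'
#' One position per polymer residue (observed + missing), in chain order.
#' The alignment-stage rendering masks missing and modified positions with
#' \code{'X'}; the PIR-stage rendering maps missing to \code{'-'} and
#' modified to \code{'.'} (see \code{\link{render_sequence}}).
#'
#' @param model A \code{StructureModel}.
#' @param chain Chain identifier.
#' @return An \code{AnnotatedSequence}: data.frame with columns
#'   \code{one_letter}, \code{status}, \code{res_name}, \code{resno},
#'   \code{icode}, plus \code{chain}/\code{pdb_id} attributes.
#' @export
extract_chain_sequence <- function(model, chain) {
  stopifnot(inherits(model, "StructureModel"))
  if (!chain %in% model$residues$chain)
    stop(sprintf("chain '%s' not present in model '%s'", chain, model$pdb_id))
  r <- model$residues[model$residues$chain == chain,
                      c("one_letter", "status", "res_name", "resno", "icode")]
  rownames(r) <- NULL
  structure(r, class = c("AnnotatedSequence", "data.frame"),
            chain = chain, pdb_id = model$pdb_id)
}

#' Render an annotated sequence for a pipeline stage
#'
#' @param x An \code{AnnotatedSequence}.
#' @param mode \code{"alignment"} ('X' at missing and modified positions),
#'   \code{"pir"} ('-' at missing, '.' at modified) or \code{"plain"}
#'   (one-letter codes everywhere).
#' @return Single character string.
#' @export
render_sequence <- function(x, mode = c("alignment", "pir", "plain")) {
  mode <- match.arg(mode)
  ch <- switch(mode,
    alignment = ifelse(x$status == "observed_standard", x$one_letter, "X"),
    pir = ifelse(x$status == "missing", "-",
                 ifelse(x$status == "observed_modified", ".", x$one_letter)),
    plain = x$one_letter
  )
  paste(ch, collapse = "")
}

#' List HETATM ligand records of a model
#'
#' @param model A \code{StructureModel}.
#' @param chain Optional chain filter.
#' @param include_water Include solvent (HOH/WAT/DOD) records?
#' @return Ligand data.frame in coordinate-section order (possibly 0 rows).
#' @export
list_ligands <- function(model, chain = NULL, include_water = FALSE) {
  stopifnot(inherits(model, "StructureModel"))
  lig <- model$ligands
  if (!is.null(chain)) lig <- lig[lig$chain == chain, , drop = FALSE]
  if (!include_water) lig <- lig[!lig$is_water, , drop = FALSE]
  lig <- lig[order(lig$coord_index), , drop = FALSE]
  rownames(lig) <- NULL
  lig
}

#' Write extracted chain sequences as FASTA
#'
#' @param model A \code{StructureModel}.
#' @param path Output file.
#' @param mode Rendering mode passed to \code{\link{render_sequence}}.
#' @export
write_chain_fasta <- function(model, path, mode = "alignment") {
  chains <- unique(model$residues$chain)
  seqs <- vapply(chains, function(ch)
    render_sequence(extract_chain_sequence(model, ch), mode), "")
  aa <- Biostrings::AAStringSet(gsub("-", "", seqs))
  names(aa) <- paste0(model$pdb_id, "_", chains)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
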