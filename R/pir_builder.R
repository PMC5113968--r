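# MODELLER-dialect PIR construction: render '-'/'.' from residue status,
# resolve template start/end residues, verify against the structure, graft
# selected ligands, and serialize byte-stable PIR text.

#' Render PIR-stage sequence text from a trimmed alignment
#'
#' Template positions render by status: missing -> '-', modified -> '.',
#' observed -> one-letter code; the target renders verbatim with '-' gaps.
#'
#' @param aln A trimmed, annotated \code{Alignment}.
#' @return Named character vector of equal-length PIR sequence bodies.
#' @export
render_pir_sequences <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  out <- character(length(aln$seqs))
  for (i in seq_along(aln$seqs)) {
    ch <- strsplit(aln$seqs[i], "")[[1]]
    if (aln$roles[i] == "target") {
      out[i] <- paste(ch, collapse = "")
      next
    }
    st <- aln$status[[i]]
    nong <- ch != "-"
    if (any(nong & is.na(st)))
      stop(sprintf("template entry %s lacks status annotation at position %d",
                   aln$names[i], which(nong & is.na(st))[1]))
    ch[!is.na(st) & st == "missing"] <- "-"
    ch[!is.na(st) & st == "observed_modified"] <- "."
    out[i] <- paste(ch, collapse = "")
  }
  names(out) <- aln$names
  out
}

res_id <- function(resno, icode) paste0(resno, icode)

#' Resolve the template span covered by a PIR entry
#'
#' Matches the entry's sequence (gaps removed; '.' matches any modified
#' residue) against the chain's observed residues and returns the author
#' numbers, with insertion codes, of the first and last matched residue.
#'
#' @param entry_sequence PIR-stage sequence body of a template entry.
#' @param model The template's \code{StructureModel}.
#' @param chain Chain identifier.
#' @return List with \code{start_res}, \code{end_res} (author number +
#'   insertion code, as character) and observed-residue indices
#'   \code{start_idx}, \code{end_idx}.
#' @export
determine_span <- function(entry_sequence, model, chain) {
  ann <- extract_chain_sequence(model, chain)
  obs <- ann[ann$status != "missing", , drop = FALSE]
  ch <- strsplit(gsub("-", "", entry_sequence, fixed = TRUE), "")[[1]]
  ch <- ch[ch != "*"]
  m <- length(ch); n <- nrow(obs)
  if (m == 0) stop("determine_span: entry sequence is empty after removing gaps")
  if (m > n) stop("determine_span: entry is longer than the observed chain")
  matches <- integer(0)
  for (s in seq_len(n - m + 1L)) {
    win <- obs[s:(s + m - 1L), ]
    ok <- ifelse(ch == ".",
                 win$status == "observed_modified",
                 win$status == "observed_standard" & win$one_letter == ch)
    if (all(ok)) matches <- c(matches, s)
  }
  if (length(matches) == 0)
    stop(sprintf("determine_span: no contiguous match of entry in chain %s of %s",
                 chain, model$pdb_id))
  if (length(matches) > 1)
    stop(sprintf("determine_span: ambiguous match in chain %s of %s; candidate starts at residues %s",
                 chain, model$pdb_id,
                 paste(res_id(obs$resno[matches], obs$icode[matches]),
                       collapse = ", ")))
  s <- matches[1]
  list(start_res = res_id(obs$resno[s], obs$icode[s]),
       end_res = res_id(obs$resno[s + m - 1L], obs$icode[s + m - 1L]),
       start_idx = s, end_idx = s + m - 1L)
}

#' Verify a PIR template entry against its structure
#'
#' Walks the entry and the chain's polymer positions inside the resolved span
#' simultaneously: letters must match observed standard residues, '.' must
#' sit on modified residues and '-' either consumes a missing residue at that
#' polymer position or is an alignment gap. Returns a verdict, never throws.
#'
#' @param entry_sequence PIR-stage sequence body.
#' @param model Template \code{StructureModel}.
#' @param chain Chain identifier.
#' @param span Result of \code{\link{determine_span}} (computed when NULL).
#' @return List \code{valid} (logical), \code{position} (first mismatching
#'   entry position or NA), \code{reason}.
#' @export
verify_template_sequence <- function(entry_sequence, model, chain, span = NULL) {
  bad <- function(pos, reason) list(valid = FALSE, position = pos, reason = reason)
  if (is.null(span)) {
    span <- tryCatch(determine_span(entry_sequence, model, chain),
                     error = function(e) conditionMessage(e))
    if (is.character(span)) return(bad(NA_integer_, span))
  }
  ann <- extract_chain_sequence(model, chain)
  obs_idx <- which(ann$status != "missing")
  # polymer positions (observed + missing) spanned by the entry
  p <- obs_idx[span$start_idx]
  p_end <- obs_idx[span$end_idx]
  ch <- strsplit(entry_sequence, "")[[1]]
  ch <- ch[ch != "*"]
  for (k in seq_along(ch)) {
    c_k <- ch[k]
    if (c_k == "-") {
      if (p <= p_end && ann$status[p] == "missing") p <- p + 1L
      next
    }
    if (p > p_end)
      return(bad(k, "entry extends beyond the resolved span"))
    st <- ann$status[p]
    if (c_k == ".") {
      if (st != "observed_modified")
        return(bad(k, sprintf("'.' over %s residue %s",
                              sub("observed_", "", st),
                              res_id(ann$resno[p], ann$icode[p]))))
    } else {
      if (st == "missing")
        return(bad(k, sprintf("residue letter over missing residue %s",
                              res_id(ann$resno[p], ann$icode[p]))))
      if (st == "observed_modified")
        return(bad(k, sprintf("letter '%s' over modified residue %s (expected '.')",
                              c_k, res_id(ann$resno[p], ann$icode[p]))))
      if (ann$one_letter[p] != c_k)
        return(bad(k, sprintf("letter '%s' disagrees with %s at residue %s",
                              c_k, ann$res_name[p],
                              res_id(ann$resno[p], ann$icode[p]))))
    }
    p <- p + 1L
  }
  if (p <= p_end)
    return(bad(length(ch), "entry ends before the resolved span is exhausted"))
  list(valid = TRUE, position = NA_integer_, reason = NA_character_)
}

#' Construct a PIR file object from a trimmed alignment and templates
#'
#' Renders PIR sequence bodies, resolves each template's start/end residues,
#' verifies every template entry against its structure, and assembles the
#' entries with the target last.
#'
#' @param aln Trimmed, annotated \code{Alignment}.
#' @param models Named list of template \code{StructureModel}s.
#' @param chains Named character vector: template name -> chain id.
#' @param pdb_files Named character vector of on-disk template filenames
#'   written into the structure headers (defaults to \code{<name>.pdb}).
#' @param target_name Optional name override for the target entry.
#' @return A \code{PirFile} object.
#' @export
build_pir <- function(aln, models, chains, pdb_files = NULL, target_name = NULL) {
  seqs <- render_pir_sequences(aln)
  entries <- list()
  for (i in which(aln$roles == "template")) {
    nm <- aln$names[i]
    model <- models[[nm]]
    if (is.null(model)) stop("no StructureModel supplied for template ", nm)
    chain <- chains[[nm]]
    span <- determine_span(seqs[[i]], model, chain)
    v <- verify_template_sequence(seqs[[i]], model, chain, span)
    if (!v$valid)
      stop(sprintf("template %s failed verification at position %s: %s",
                   nm, v$position, v$reason))
    pf <- if (!is.null(pdb_files)) pdb_files[[nm]] else paste0(nm, ".pdb")
    entries[[length(entries) + 1L]] <- list(
      name = nm, kind = "structure", pdb_file = pf, chain = chain,
      start_res = span$start_res, start_chain = chain,
      end_res = span$end_res, end_chain = chain, seq = unname(seqs[[i]]))
  }
  ti <- which(aln$roles == "target")
  entries[[length(entries) + 1L]] <- list(
    name = if (is.null(target_name)) aln$names[ti] else target_name,
    kind = "sequence", pdb_file = "", chain = "",
    start_res = "", start_chain = "", end_res = "", end_chain = "",
    seq = unname(seqs[[ti]]))
  pir_file(entries)
}

#' Assemble a PirFile from entries
#' @param entries List of PIR entries (target last, one sequence-kind entry).
#' @return A \code{PirFile}.
#' @export
pir_file <- function(entries) {
  if (length(entries) < 2) stop("a PIR file needs >= 1 template and the target")
  w <- unique(vapply(entries, function(e) nchar(e$seq), 0L))
  if (length(w) != 1) stop("PIR entries must all have equal sequence length")
  kinds <- vapply(entries, function(e) e$kind, "")
  if (sum(kinds == "sequence") != 1 || kinds[length(kinds)] != "sequence")
    stop("PIR file must contain exactly one sequence-kind entry, placed last")
  structure(list(entries = entries), class = "PirFile")
}

#' @export
print.PirFile <- function(x, ...) {
  cat(sprintf("PirFile: %d entries, width %d\n", length(x$entries),
              nchar(x$entries[[1]]$seq)))
  for (e in x$entries)
    cat(sprintf("  %-10s %-9s %s\n", e$name, e$kind,
                if (e$kind == "structure")
                  sprintf("%s:%s..%s:%s", e$pdb_file, e$start_res, e$end_res,
                          e$start_chain) else ""))
  invisible(x)
}

#' Graft selected ligands onto a PIR file
#'
#' For each template with selected ligands, the last selected ligand (by
#' coordinate-section order) becomes the template's ending residue. Every
#' polymer residue after the old span end and every HETATM record up to and
#' including that ligand is appended to the template entry (letters / '.' /
#' '-' by status for polymer, '.' for HETATMs). The target is padded with
#' '-' to the new width and the padding is switched to '.' exactly at the
#' columns of \emph{selected} ligands; unselected HETATM columns stay '-'.
#' All other entries are padded with '-'.
#'
#' @param pir A verified \code{PirFile}.
#' @param models Named list of template \code{StructureModel}s.
#' @param selection Data frame with columns \code{template}, \code{het_code},
#'   \code{coord_index} (the ligand's coordinate-section ordinal as reported
#'   by \code{\link{list_ligands}}).
#' @return The extended \code{PirFile}; unchanged when selection is empty.
#' @export
graft_ligands <- function(pir, models, selection) {
  stopifnot(inherits(pir, "PirFile"))
  if (is.null(selection) || nrow(selection) == 0) return(pir)
  entries <- pir$entries
  names_v <- vapply(entries, function(e) e$name, "")
  kinds <- vapply(entries, function(e) e$kind, "")
  ti <- which(kinds == "sequence")
  # each selected template gets its own column block appended after the old
  # width, in entry order; other entries are '-' across that block
  blocks <- list()   # per block: entry index, template chars, target chars

  for (nm in unique(selection$template)) {
    ei <- which(names_v == nm)
    if (length(ei) != 1) stop("selection names unknown template entry: ", nm)
    if (kinds[ei] == "sequence")
      stop("ligands cannot be grafted onto a sequence-kind entry: ", nm)
    model <- models[[nm]]
    sel <- selection[selection$template == nm, , drop = FALSE]
    ligs <- model$ligands
    for (j in seq_len(nrow(sel))) {
      hit <- ligs$coord_index == sel$coord_index[j] &
        ligs$het_code == sel$het_code[j]
      if (!any(hit))
        stop(sprintf("selected ligand %s (coord_index %d) not found in template %s",
                     sel$het_code[j], sel$coord_index[j], nm))
    }
    last_idx <- max(sel$coord_index)
    lig_in <- ligs[ligs$coord_index <= last_idx, , drop = FALSE]
    lig_in <- lig_in[order(lig_in$coord_index), , drop = FALSE]

    e <- entries[[ei]]
    ann <- extract_chain_sequence(model, e$chain)
    span <- determine_span(e$seq, model, e$chain)
    obs_idx <- which(ann$status != "missing")
    p_end <- obs_idx[span$end_idx]
    tail_poly <- if (p_end < nrow(ann)) ann[(p_end + 1L):nrow(ann), , drop = FALSE]
    else ann[0, , drop = FALSE]
    poly_ch <- if (nrow(tail_poly) == 0) character(0)
    else ifelse(tail_poly$status == "missing", "-",
                ifelse(tail_poly$status == "observed_modified", ".",
                       tail_poly$one_letter))
    lig_ch <- rep(".", nrow(lig_in))

    # target: '-' everywhere, '.' at selected ligand columns
    tgt_ch <- rep("-", length(poly_ch) + length(lig_ch))
    sel_cols <- length(poly_ch) + match(sel$coord_index, lig_in$coord_index)
    tgt_ch[sel_cols] <- "."
    blocks[[length(blocks) + 1L]] <- list(entry = ei,
                                          tmpl = c(poly_ch, lig_ch),
                                          tgt = tgt_ch)

    last_lig <- lig_in[nrow(lig_in), ]
    entries[[ei]]$end_res <- res_id(last_lig$resno, last_lig$icode)
    entries[[ei]]$end_chain <- last_lig$chain
  }

  blocks <- blocks[order(vapply(blocks, function(b) b$entry, 0L))]
  for (i in seq_along(entries)) {
    extra <- unlist(lapply(blocks, function(b) {
      if (i == ti) b$tgt
      else if (b$entry == i) b$tmpl
      else rep("-", length(b$tmpl))
    }))
    entries[[i]]$seq <- paste0(entries[[i]]$seq, paste(extra, collapse = ""))
  }
  pir_file(entries)
}

#' Serialize a PirFile to MODELLER-dialect text
#'
#' Each entry is written as \code{>P1;name}, a colon-delimited header line
#' (\code{structureX:file:start:chain:end:chain::::} for templates,
#' \code{sequence:name::::::::} for the target) and the sequence body,
#' wrapped at 75 columns and terminated by \code{'*'}. LF line endings.
#'
#' @param pir A \code{PirFile}.
#' @param path Optional output file.
#' @return The PIR text, invisibly when \code{path} is given.
#' @export
write_pir <- function(pir, path = NULL) {
  stopifnot(inherits(pir, "PirFile"))
  out <- character(0)
  for (e in pir$entries) {
    if (nchar(e$seq) == 0) stop("write_pir: refusing to serialize empty entry")
    if (e$kind == "structure" && (e$start_res == "" || e$end_res == ""))
      stop("write_pir: structure entry lacks start/end residues")
    hdr <- if (e$kind == "structure")
      sprintf("structureX:%s:%s:%s:%s:%s::::",
              e$pdb_file, e$start_res, e$start_chain, e$end_res, e$end_chain)
    else sprintf("sequence:%s::::::::", e$name)
    body <- paste0(e$seq, "*")
    starts <- seq(1L, nchar(body), by = 75L)
    wrapped <- vapply(starts, function(s) substr(body, s, min(s + 74L, nchar(body))), "")
    out <- c(out, paste0(">P1;", e$name), hdr, wrapped)
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, "wb")
    writeChar(txt, con, eos = NULL)
    close(con)
    return(invisible(txt))
  }
  txt
}

#' Minimal PIR reader (round-trip checks)
#'
#' Parses the dialect emitted by \code{\link{write_pir}} back into a
#' \code{PirFile}.
#'
#' @param text PIR text, lines, or a file path.
#' @return A \code{PirFile}.
#' @export
read_pir <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text
  starts <- grep("^>P1;", lines)
  if (length(starts) == 0) stop("not a PIR file: no >P1; headers")
  ends <- c(starts[-1] - 1L, length(lines))
  entries <- lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    name <- sub("^>P1;", "", blk[1])
    f <- strsplit(blk[2], ":", fixed = TRUE)[[1]]
    f <- c(f, rep("", 10 - length(f)))
    seq <- paste(blk[-(1:2)], collapse = "")
    seq <- sub("\\*\\s*$", "", seq)
    if (f[1] == "sequence")
      list(name = name, kind = "sequence", pdb_file = "", chain = "",
           start_res = "", start_chain = "", end_res = "", end_chain = "",
           seq = seq)
    else
      list(name = name, kind = "structure", pdb_file = f[2], chain = f[4],
           start_res = f[3], start_chain = f[4], end_res = f[5],
           end_chain = f[6], seq = seq)
  })
  pir_file(entries)
}

#' Build a modeling-job configuration
#'
#' Defaults mirror a standard automated run: 10 models with very slow
#' refinement. HETATM/water read flags are derived from the ligand selection.
#'
#' @param selection Ligand selection data frame (columns \code{template},
#'   \code{het_code}, \code{coord_index}) or NULL.
#' @param n_models Number of models to request (>= 1).
#' @param refinement One of \code{"none"}, \code{"fast"}, \code{"very_slow"}.
#' @return A \code{ModelJobConfig} list.
#' @export
build_job_config <- function(selection = NULL, n_models = 10,
                             refinement = "very_slow") {
  if (!refinement %in% c("none", "fast", "very_slow"))
    stop("unknown refinement level: ", refinement)
  if (n_models < 1) stop("n_models must be >= 1")
  sel <- if (is.null(selection)) data.frame(template = character(),
                                            het_code = character(),
                                            coord_index = integer())
  else selection
  is_water <- sel$het_code %in% WATER_CODES
  structure(list(
    n_models = as.integer(n_models), refinement = refinement,
    read_hetatm = any(!is_water), read_water = any(is_water),
    selected_ligands = sel), class = "ModelJobConfig")
}

#' Serialize a job configuration to YAML
#' @param config A \code{ModelJobConfig}.
#' @param path Optional output file.
#' @return YAML text.
#' @export
write_job_config <- function(config, path = NULL) {
  x <- unclass(config)
  x$selected_ligands <- if (nrow(x$selected_ligands))
    lapply(seq_len(nrow(x$selected_ligands)), function(i)
      as.list(x$selected_ligands[i, ])) else list()
  txt <- yaml::as.yaml(x)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Render a modeling-script stub for a job
#'
#' Fills a template of the comparative-modeling script (automodel
#' parameters, refinement level, HETATM/water flags). The stub is emitted
#' for inspection only and is not executed by this package.
#'
#' @param config A \code{ModelJobConfig}.
#' @param pir_path Path of the PIR file referenced by the script.
#' @param knowns Template entry names.
#' @param target Target entry name.
#' @return Script text.
#' @export
render_modeling_script <- function(config, pir_path, knowns, target) {
  refine <- c(none = "None", fast = "refine.fast",
              very_slow = "refine.very_slow")[[config$refinement]]
  paste0(
    "from modeller import *\n",
    "from modeller.automodel import *\n\n",
    "env = environ()\n",
    sprintf("env.io.hetatm = %s\n", if (config$read_hetatm) "True" else "False"),
    sprintf("env.io.water = %s\n", if (config$read_water) "True" else "False"),
    sprintf("a = automodel(env, alnfile='%s',\n", pir_path),
    sprintf("              knowns=(%s),\n",
            paste(sprintf("'%s'", knowns), collapse = ", ")),
    sprintf("              sequence='%s')\n", target),
    "a.starting_model = 1\n",
    sprintf("a.ending_model = %d\n", config$n_models),
    if (config$refinement == "none") "" else
      sprintf("a.md_level = %s\n", refine),
    "a.make()\n")
}
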