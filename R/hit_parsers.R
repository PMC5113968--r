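# Template-search report parsers. Both produce the same uniform hit table so
# downstream alignment/PIR stages never care which search program ran.

hit_table <- function(rows) {
  cols <- c("pdb_id", "chain_id", "seq_identity_pct", "query_coverage_pct",
            "evalue", "aligned_query", "aligned_template",
            "query_start", "query_end", "template_start", "template_end",
            "source")
  if (length(rows) == 0) {
    df <- data.frame(pdb_id = character(), chain_id = character(),
                     seq_identity_pct = numeric(), query_coverage_pct = numeric(),
                     evalue = numeric(), aligned_query = character(),
                     aligned_template = character(), query_start = integer(),
                     query_end = integer(), template_start = integer(),
                     template_end = integer(), source = character(),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("template_hits", "data.frame")))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r[cols])))
  # rank: ascending e-value, ties by identity descending
  df <- df[order(df$evalue, -df$seq_identity_pct), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("template_hits", "data.frame"))
}

# subject ids look like "pdb|1ABC|A", "1ABC_A" or "1abc_A description"
split_subject_id <- function(id, def = "") {
  for (s in c(id, def)) {
    m <- regexec("pdb\\|([0-9][A-Za-z0-9]{3})\\|([A-Za-z0-9])", s)[[1]]
    if (m[1] > 0) {
      g <- regmatches(s, regexec("pdb\\|([0-9][A-Za-z0-9]{3})\\|([A-Za-z0-9])", s))[[1]]
      return(list(pdb_id = tolower(g[2]), chain = g[3]))
    }
    m <- regexec("^([0-9][A-Za-z0-9]{3})_([A-Za-z0-9])(\\s|$)", s)[[1]]
    if (m[1] > 0) {
      g <- regmatches(s, regexec("^([0-9][A-Za-z0-9]{3})_([A-Za-z0-9])(\\s|$)", s))[[1]]
      return(list(pdb_id = tolower(g[2]), chain = g[3]))
    }
  }
  NULL
}

#' Parse a BLAST XML (outfmt 5) template search report
#'
#' One hit per subject is kept: its best HSP by e-value. Sequence identity is
#' BLAST's own convention, \code{100 * identities / alignment_length}
#' (gap columns included in the denominator); query coverage is
#' \code{100 * (query_end - query_start + 1) / query_length}.
#'
#' @param text BLAST XML as a single string, a character vector of lines, or
#'   a file path.
#' @param query_length Length of the query sequence (residues).
#' @return A \code{template_hits} data.frame sorted by ascending e-value
#'   (ties broken by identity, descending). Subjects whose id encodes no
#'   PDB chain are skipped with a warning.
#' @export
parse_blast_xml <- function(text, query_length) {
  stopifnot(query_length >= 1)
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("malformed BLAST XML: ",
                                           conditionMessage(e)))
  hits <- xml2::xml_find_all(doc, ".//Hit")
  rows <- list()
  for (h in hits) {
    id  <- xml2::xml_text(xml2::xml_find_first(h, "./Hit_id"))
    def <- xml2::xml_text(xml2::xml_find_first(h, "./Hit_def"))
    sub <- split_subject_id(id, def)
    if (is.null(sub)) {
      warning(sprintf("subject '%s' has no extractable PDB chain; hit skipped", id))
      next
    }
    hsps <- xml2::xml_find_all(h, ".//Hsp")
    if (length(hsps) == 0) next
    ev <- vapply(hsps, function(x)
      as.numeric(xml2::xml_text(xml2::xml_find_first(x, "./Hsp_evalue"))), 0)
    hsp <- hsps[[which.min(ev)]]
    num <- function(f) as.numeric(xml2::xml_text(xml2::xml_find_first(hsp, paste0("./", f))))
    chr <- function(f) xml2::xml_text(xml2::xml_find_first(hsp, paste0("./", f)))
    qs <- num("Hsp_query-from"); qe <- num("Hsp_query-to")
    rows[[length(rows) + 1L]] <- list(
      pdb_id = sub$pdb_id, chain_id = sub$chain,
      seq_identity_pct = 100 * num("Hsp_identity") / num("Hsp_align-len"),
      query_coverage_pct = 100 * (qe - qs + 1) / query_length,
      evalue = min(ev),
      aligned_query = chr("Hsp_qseq"), aligned_template = chr("Hsp_hseq"),
      query_start = as.integer(qs), query_end = as.integer(qe),
      template_start = as.integer(num("Hsp_hit-from")),
      template_end = as.integer(num("Hsp_hit-to")),
      source = "blast")
  }
  hit_table(rows)
}

#' Parse an HHsearch .hhr template search report
#'
#' Reassembles each hit's pairwise alignment by concatenating its Q/T line
#' pairs across alignment blocks (consensus and secondary-structure lines
#' are ignored). Identity is taken verbatim from the hit's
#' \code{Identities=NN\%} field when present, else recomputed from the
#' concatenated alignment over both-non-gap columns; coverage is recomputed
#' from the query start/end over \code{query_length}.
#'
#' @inheritParams parse_blast_xml
#' @return A \code{template_hits} data.frame (source \code{"hhsearch"}).
#' @export
parse_hhr <- function(text, query_length) {
  stopifnot(query_length >= 1)
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text

  # summary table: lines " <No> <Hit> ... " after the " No Hit" header
  hdr <- grep("^\\s*No\\s+Hit", lines)
  if (length(hdr) == 0) stop("malformed hhr report: summary table header not found")
  i <- hdr[1] + 1L
  n_summary <- 0L
  while (i <= length(lines) && grepl("^\\s*\\d+\\s+\\S", lines[i])) {
    n_summary <- n_summary + 1L
    i <- i + 1L
  }

  starts <- grep("^No (\\d+)\\s*$", lines)
  if (n_summary > length(starts))
    stop(sprintf("malformed hhr report: summary lists %d hits but alignment block %d is absent",
                 n_summary, length(starts) + 1L))
  ends <- c(starts[-1] - 1L, length(lines))

  rows <- lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    name <- sub("^>\\s*", "", grep("^>", blk, value = TRUE)[1])
    sub <- split_subject_id(trimws(strsplit(name, "\\s+")[[1]][1]))
    stat <- grep("^Probab=", blk, value = TRUE)[1]
    get_num <- function(field) {
      m <- regmatches(stat, regexec(paste0(field, "=([-0-9.eE+]+)"), stat))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NA_real_
    }
    idm <- regmatches(stat, regexec("Identities=([0-9.]+)%", stat))[[1]]

    qpat <- "^Q\\s+(\\S+)\\s+(\\d+)\\s+([A-Za-z.~-]+)\\s+(\\d+)"
    tpat <- "^T\\s+(\\S+)\\s+(\\d+)\\s+([A-Za-z.~-]+)\\s+(\\d+)"
    skip <- function(nm) nm == "Consensus" || grepl("^ss_", nm)
    qseq <- character(); tseq <- character()
    qs <- qe <- ts <- te <- integer()
    for (ln in blk) {
      if (grepl(qpat, ln)) {
        g <- regmatches(ln, regexec(qpat, ln))[[1]]
        if (!skip(g[2])) {
          qseq <- c(qseq, g[4]); qs <- c(qs, as.integer(g[3])); qe <- c(qe, as.integer(g[5]))
        }
      } else if (grepl(tpat, ln)) {
        g <- regmatches(ln, regexec(tpat, ln))[[1]]
        if (!skip(g[2])) {
          tseq <- c(tseq, g[4]); ts <- c(ts, as.integer(g[3])); te <- c(te, as.integer(g[5]))
        }
      }
    }
    if (length(qseq) == 0 || length(tseq) == 0)
      stop(sprintf("malformed hhr report: hit %d has no alignment lines", k))
    aq <- toupper(paste(qseq, collapse = ""))
    at <- toupper(paste(tseq, collapse = ""))
    ident <- if (length(idm) == 2) as.numeric(idm[2])
    else compute_identity(aq, at)
    list(pdb_id = if (is.null(sub)) tolower(substr(name, 1, 4)) else sub$pdb_id,
         chain_id = if (is.null(sub)) "" else sub$chain,
         seq_identity_pct = ident,
         query_coverage_pct = 100 * (max(qe) - min(qs) + 1) / query_length,
         evalue = get_num("E-value"),
         aligned_query = aq, aligned_template = at,
         query_start = min(qs), query_end = max(qe),
         template_start = min(ts), template_end = max(te),
         source = "hhsearch")
  })
  hit_table(rows)
}

#' Export a hit table as TSV
#'
#' @param hits A \code{template_hits} data.frame.
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(
    hits[, c("pdb_id", "chain_id", "seq_identity_pct", "query_coverage_pct",
             "evalue", "source")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
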