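# Target-template alignment container and the identity / binning / trimming
# / edit-validation rules applied before PIR construction.

#' Construct a target-template alignment
#'
#' @param names Entry names.
#' @param roles One of \code{"target"}/\code{"template"} per entry; exactly
#'   one target, at least one template.
#' @param seqs Equal-length gapped sequences over A-Z and '-'.
#' @param status Optional list of per-entry status vectors (one element per
#'   alignment column; \code{NA} at gap columns; otherwise
#'   \code{observed_standard}, \code{observed_modified} or \code{missing}).
#'   When omitted, every non-gap template position is assumed observed.
#' @return An \code{Alignment} object.
#' @export
alignment <- function(names, roles, seqs, status = NULL) {
  stopifnot(length(names) == length(roles), length(roles) == length(seqs))
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("alignment entries must all have equal length")
  if (sum(roles == "target") != 1) stop("alignment must contain exactly one target")
  if (sum(roles == "template") < 1) stop("alignment must contain >= 1 template")
  if (is.null(status)) {
    status <- lapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ifelse(ch == "-", NA_character_, "observed_standard")
    })
  }
  stopifnot(length(status) == length(seqs))
  for (i in seq_along(status)) {
    if (length(status[[i]]) != w)
      stop("status vector length must equal alignment width for entry ", names[i])
  }
  structure(list(names = names, roles = roles, seqs = seqs, status = status),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d entries, width %d\n",
              length(x$seqs), nchar(x$seqs[1])))
  for (i in seq_along(x$seqs))
    cat(sprintf("  %-10s %-8s %s\n", x$names[i], x$roles[i],
                if (nchar(x$seqs[i]) > 60) paste0(substr(x$seqs[i], 1, 57), "...")
                else x$seqs[i]))
  invisible(x)
}

aln_chars <- function(aln) lapply(aln$seqs, function(s) strsplit(s, "")[[1]])

#' Attach structure-derived status annotations to template entries
#'
#' Maps each non-gap position of a template's gapped sequence to the
#' corresponding position of its \code{\link{extract_chain_sequence}} result,
#' carrying the observed/missing/modified status into the alignment so the
#' PIR stage can render '-' and '.' correctly.
#'
#' @param aln An \code{Alignment} whose template entries were aligned from
#'   alignment-mode renderings (X-masked) of the given annotated sequences.
#' @param annotated Named list of \code{AnnotatedSequence}, keyed by template
#'   entry name. A template may also cover only a suffix/prefix window of its
#'   chain: the ungapped entry must then match a contiguous run of the
#'   chain's alignment-mode rendering.
#' @return The alignment with template status vectors populated.
#' @export
annotate_alignment <- function(aln, annotated) {
  stopifnot(inherits(aln, "Alignment"))
  for (i in which(aln$roles == "template")) {
    nm <- aln$names[i]
    ann <- annotated[[nm]]
    if (is.null(ann)) stop("no annotated sequence supplied for template ", nm)
    ch <- strsplit(aln$seqs[i], "")[[1]]
    idx <- which(ch != "-")
    full <- strsplit(render_sequence(ann, "alignment"), "")[[1]]
    sub <- paste(ch[idx], collapse = "")
    offs <- find_all_runs(paste(full, collapse = ""), sub)
    if (length(offs) == 0)
      stop(sprintf("template entry %s does not match its chain sequence", nm))
    off <- offs[1]
    st <- rep(NA_character_, length(ch))
    st[idx] <- ann$status[seq(off, off + length(idx) - 1L)]
    aln$status[[i]] <- st
  }
  aln
}

find_all_runs <- function(hay, needle) {
  n <- nchar(needle); h <- nchar(hay)
  if (n == 0 || n > h) return(integer())
  which(vapply(seq_len(h - n + 1L),
               function(s) substr(hay, s, s + n - 1L) == needle, logical(1)))
}

#' Percent sequence identity of two gapped sequences
#'
#' \code{100 * identical both-non-gap columns / both-non-gap columns}.
#' \code{'X'} (masked missing/modified positions) never counts as identical.
#'
#' @param a,b Equal-length gapped sequences (strings or character vectors).
#' @return Percentage in [0, 100].
#' @export
compute_identity <- function(a, b) {
  ca <- if (length(a) == 1) strsplit(a, "")[[1]] else a
  cb <- if (length(b) == 1) strsplit(b, "")[[1]] else b
  if (length(ca) != length(cb))
    stop("compute_identity: sequences have unequal lengths")
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("compute_identity: no both-non-gap columns; identity undefined")
  same <- both & ca == cb & ca != "X"
  100 * sum(same) / sum(both)
}

#' Assign a decade sequence-identity bin
#'
#' Bins are lower-inclusive, upper-exclusive decades: an identity of exactly
#' 30 falls in [30,40), not [20,30). Identities outside [20, 90) return
#' \code{NA} (excluded from benchmarking).
#'
#' @param identity Numeric vector of percentages.
#' @return Character vector of bin labels like \code{"[30,40)"}, or NA.
#' @export
assign_bin <- function(identity) {
  lower <- 10 * floor(identity / 10)
  out <- sprintf("[%d,%d)", lower, lower + 10)
  out[identity < 20 | identity >= 90] <- NA_character_
  out
}

#' Bin lower bounds in order
#' @return Integer vector c(20,30,...,80).
#' @export
bin_lowers <- function() seq(20L, 80L, 10L)

# columns where the target is non-gap and >=1 template is non-gap and not a
# masked missing residue
supported_columns <- function(aln) {
  ch <- aln_chars(aln)
  ti <- which(aln$roles == "target")
  target_res <- ch[[ti]] != "-"
  support <- rep(FALSE, length(ch[[ti]]))
  for (i in which(aln$roles == "template")) {
    ok <- ch[[i]] != "-" &
      (is.na(aln$status[[i]]) | aln$status[[i]] != "missing")
    ok[ch[[i]] == "-"] <- FALSE
    support <- support | ok
  }
  list(target_res = target_res, support = support)
}

#' Trim alignment termini to template-supported columns
#'
#' Removes leading and trailing columns up to the first/last column where
#' the target is non-gap and at least one template provides an observed
#' (non-gap, non-missing) residue, so no terminal region of the target is
#' modeled without template information. Interior columns are untouched.
#'
#' @param aln An \code{Alignment}.
#' @return The trimmed \code{Alignment}.
#' @export
trim_termini <- function(aln) {
  sc <- supported_columns(aln)
  keep <- which(sc$target_res & sc$support)
  if (length(keep) == 0)
    stop("trim_termini: no column has both a target residue and template support (empty overlap)")
  span <- keep[1]:keep[length(keep)]
  aln$seqs <- vapply(aln$seqs, function(s)
    paste(strsplit(s, "")[[1]][span], collapse = ""), "", USE.NAMES = FALSE)
  aln$status <- lapply(aln$status, function(st) st[span])
  aln
}

#' Percent of the target sequence that will be modeled
#'
#' Counts target residues inside the post-trim span that are supported by at
#' least one template (non-gap, non-missing) and divides by the full target
#' length including any trimmed-off termini, so heavy terminal trimming
#' lowers coverage.
#'
#' @param aln An \code{Alignment} (untrimmed; trimming is applied internally).
#' @return Percentage in [0, 100]; 0 when target and templates never overlap.
#' @export
compute_coverage <- function(aln) {
  sc <- supported_columns(aln)
  total <- sum(sc$target_res)
  if (total == 0) return(0)
  keep <- which(sc$target_res & sc$support)
  if (length(keep) == 0) return(0)
  span <- keep[1]:keep[length(keep)]
  100 * sum(sc$target_res[span] & sc$support[span]) / total
}

#' Validate a manual alignment edit
#'
#' Template sequences may have gaps moved/added anywhere but can only be
#' trimmed from the outside: the edit is valid iff its ungapped sequence is
#' a contiguous substring of the original ungapped sequence. The target may
#' be edited freely so long as only amino-acid letters and '-' are used.
#'
#' @param original,edited Gapped sequences.
#' @param role \code{"target"} or \code{"template"}.
#' @return A verdict list: \code{status} ("valid"/"invalid"), \code{reason},
#'   \code{position} (first offending position or NA).
#' @export
validate_edit <- function(original, edited, role = c("template", "target")) {
  role <- match.arg(role)
  verdict <- function(status, reason = NA_character_, position = NA_integer_)
    list(status = status, reason = reason, position = position)
  ch <- strsplit(edited, "")[[1]]
  bad <- which(!grepl("^[A-Za-z-]$", ch))
  if (length(bad))
    return(verdict("invalid", sprintf("invalid character '%s'", ch[bad[1]]),
                   bad[1]))
  if (role == "target") return(verdict("valid"))
  ug_orig <- gsub("-", "", toupper(original))
  ug_edit <- gsub("-", "", toupper(edited))
  if (!grepl(ug_edit, ug_orig, fixed = TRUE))
    return(verdict("invalid",
                   "edited sequence is not a contiguous substring of the original (internal residues may not be deleted)"))
  verdict("valid")
}

#' Serialize an edit verdict as JSON
#' @param v A verdict from \code{\link{validate_edit}}.
#' @return JSON string.
#' @export
verdict_json <- function(v) {
  jsonlite::toJSON(v, auto_unbox = TRUE, na = "null")
}

#' Read an aligned FASTA or Clustal file as named sequences
#'
#' Thin wrapper over \code{Biostrings::readAAMultipleAlignment}; lowercase
#' letters are uppercased.
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"clustal"}.
#' @return Named character vector of equal-length gapped sequences.
#' @export
read_alignment_file <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- toupper(as.character(msa))
  setNames(as.character(seqs), names(seqs))
}

#' Write gapped sequences as aligned FASTA
#' @param seqs Named character vector of equal-length gapped sequences.
#' @param path Output file.
#' @export
write_alignment_fasta <- function(seqs, path) {
  out <- character(0)
  for (i in seq_along(seqs))
    out <- c(out, paste0(">", names(seqs)[i]), seqs[[i]])
  writeLines(out, path)
  invisible(path)
}
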