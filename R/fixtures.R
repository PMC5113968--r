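# Deterministic synthetic fixture generator: idealized CA-trace structure
# pairs, search reports and miniature benchmark collections with controlled
# identity, coverage, missing/modified residues, ligands and planted filter
# failures, so the whole pipeline is testable offline.

#' Specify a synthetic target-template fixture
#'
#' @param seed Integer seed (all randomness in the generated pair derives
#'   from it; same seed, byte-identical output).
#' @param length Number of target residues.
#' @param target_identity_pct Requested target-template identity over the
#'   true alignment (achieved within 1 percentage point; rounding resolves
#'   toward lower identity).
#' @param coord_noise_sigma Isotropic Gaussian noise added to template
#'   coordinates, per axis, in Angstrom.
#' @param missing_runs List of \code{c(start, length)} runs of template
#'   residues present in the construct but absent from the coordinates
#'   (REMARK 465).
#' @param modified_positions Template positions recorded as MSE via MODRES +
#'   in-chain HETATM.
#' @param ligands Character vector of HET codes appended after the polymer
#'   (waters allowed, e.g. \code{"HOH"}).
#' @param terminal_deletions \code{c(n_term, c_term)} residues absent from
#'   the template construct entirely.
#' @param template_pdb_code 4-character code used in generated search
#'   reports.
#' @return A \code{FixtureSpec} list.
#' @export
fixture_spec <- function(seed, length, target_identity_pct = 100,
                         coord_noise_sigma = 0, missing_runs = list(),
                         modified_positions = integer(),
                         ligands = character(),
                         terminal_deletions = c(0L, 0L),
                         template_pdb_code = "1tpl") {
  stopifnot(length >= 10, target_identity_pct >= 0, target_identity_pct <= 100,
            coord_noise_sigma >= 0, length(terminal_deletions) == 2)
  keep_from <- terminal_deletions[1] + 1L
  keep_to <- length - terminal_deletions[2]
  if (keep_to - keep_from + 1L < 5)
    stop("unsatisfiable fixture spec: terminal deletions leave fewer than 5 residues")
  marked <- c(unlist(lapply(missing_runs, function(r) seq(r[1], r[1] + r[2] - 1L))),
              modified_positions)
  if (length(marked) && (any(marked < keep_from) || any(marked > keep_to)))
    stop("unsatisfiable fixture spec: missing/modified positions fall outside the template construct")
  if (anyDuplicated(marked))
    stop("unsatisfiable fixture spec: overlapping missing/modified positions")
  kept <- keep_to - keep_from + 1L
  n_x <- length(marked)
  n_match <- ceiling(kept * target_identity_pct / 100 - 0.5)
  if (n_match > kept - n_x)
    stop("unsatisfiable fixture spec: requested identity exceeds what missing/modified masking allows")
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 target_identity_pct = target_identity_pct,
                 coord_noise_sigma = coord_noise_sigma,
                 missing_runs = missing_runs,
                 modified_positions = as.integer(modified_positions),
                 ligands = as.character(ligands),
                 terminal_deletions = as.integer(terminal_deletions),
                 template_pdb_code = template_pdb_code),
            class = "FixtureSpec")
}

with_fixture_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# idealized helical CA trace: ~3.8 A between consecutive CA positions
helix_trace <- function(n) {
  t <- seq_len(n) - 1
  cbind(2.3 * cos(t * 100 * pi / 180),
        2.3 * sin(t * 100 * pi / 180),
        1.5 * t)
}

fmt_atom <- function(record, serial, name, resn, chain, resno, icode, xyz,
                     element) {
  name4 <- if (nchar(name) <= 3) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, resn, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

fmt_seqres <- function(chain, codes) {
  n <- length(codes)
  rows <- split(codes, ceiling(seq_along(codes) / 13))
  vapply(seq_along(rows), function(i)
    sprintf("SEQRES %3d %1s %4d  %s", i, chain, n,
            paste(rows[[i]], collapse = " ")), "")
}

#' Generate a synthetic target-template structure pair
#'
#' The target is a random sequence on an idealized helical CA trace. The
#' template derives from it by mutating a deterministic position subset to
#' reach the requested identity, adding coordinate noise, deleting terminal
#' runs, recording missing runs (REMARK 465 + absent ATOMs), marking
#' modified residues (MODRES + in-chain HETATM MSE) and appending ligand
#' HETATMs. Author numbering of the template equals the target position, so
#' the true alignment needs no gaps beyond the deleted termini.
#'
#' @param spec A \code{FixtureSpec}.
#' @return List: \code{target_pdb}, \code{template_pdb} (PDB text),
#'   \code{alignment} (annotated true \code{Alignment}, target first),
#'   \code{target_id}, \code{template_id}, \code{target_seq},
#'   \code{spec}.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_fixture_rng(spec$seed, {
    L <- spec$length
    target_id <- sprintf("tg%06d", spec$seed %% 1000000L)
    template_id <- sprintf("tp%06d", spec$seed %% 1000000L)
    aa <- names(AA_THREE_TO_ONE)
    target_seq <- unname(AA_THREE_TO_ONE[sample(aa, L, replace = TRUE)])

    keep_from <- spec$terminal_deletions[1] + 1L
    keep_to <- L - spec$terminal_deletions[2]
    kept <- keep_from:keep_to
    missing_pos <- unlist(lapply(spec$missing_runs,
                                 function(r) seq(r[1], r[1] + r[2] - 1L)))
    if (is.null(missing_pos)) missing_pos <- integer(0)
    mod_pos <- spec$modified_positions
    # MSE parent is MET: make the target methionine there so the pair is a
    # genuine modification, not also a mutation
    target_seq[mod_pos] <- "M"
    x_pos <- c(missing_pos, mod_pos)

    available <- setdiff(kept, x_pos)
    # nearest count; exact .5 ties resolve toward lower identity
    n_match <- ceiling(length(kept) * spec$target_identity_pct / 100 - 0.5)
    n_mut <- length(available) - n_match
    mut_pos <- if (n_mut > 0) sort(sample(available, n_mut)) else integer(0)
    template_seq <- target_seq
    for (p in mut_pos)
      template_seq[p] <- sample(setdiff(unname(AA_THREE_TO_ONE), target_seq[p]), 1)
    template_seq[mod_pos] <- "M"

    xyz_t <- helix_trace(L)
    xyz_p <- xyz_t + matrix(stats::rnorm(3 * L, sd = spec$coord_noise_sigma),
                            ncol = 3)

    target_pdb <- write_fixture_pdb(
      seq = target_seq, xyz = xyz_t, resno = seq_len(L), chain = "A",
      missing_pos = integer(0), mod_pos = integer(0),
      ligands = character(0))
    template_pdb <- write_fixture_pdb(
      seq = template_seq[kept], xyz = xyz_p[kept, , drop = FALSE],
      resno = kept, chain = "A",
      missing_pos = missing_pos, mod_pos = mod_pos,
      ligands = spec$ligands)

    # true alignment (alignment-stage rendering; no interior gaps)
    tmpl_ch <- template_seq
    tmpl_ch[x_pos] <- "X"
    tmpl_ch[setdiff(seq_len(L), kept)] <- "-"
    status <- rep(NA_character_, L)
    status[kept] <- "observed_standard"
    status[missing_pos] <- "missing"
    status[mod_pos] <- "observed_modified"
    status[setdiff(seq_len(L), kept)] <- NA_character_
    aln <- alignment(
      names = c(target_id, template_id),
      roles = c("target", "template"),
      seqs = c(paste(target_seq, collapse = ""), paste(tmpl_ch, collapse = "")),
      status = list(rep("observed_standard", L), status))

    list(target_pdb = target_pdb, template_pdb = template_pdb,
         alignment = aln, target_id = target_id, template_id = template_id,
         target_seq = paste(target_seq, collapse = ""), spec = spec)
  })
}

# seq: one-letter codes of construct residues (in resno order); missing
# positions get REMARK 465 + no ATOM; modified positions become HETATM MSE
write_fixture_pdb <- function(seq, xyz, resno, chain, missing_pos, mod_pos,
                              ligands) {
  lines <- character(0)
  three <- unname(AA_ONE_TO_THREE[seq])
  three[match(intersect(mod_pos, resno), resno)] <- "MSE"
  if (length(missing_pos)) {
    lines <- c(lines, "REMARK 465 MISSING RESIDUES",
               "REMARK 465   M RES C SSSEQI",
               vapply(missing_pos, function(p)
                 sprintf("REMARK 465     %3s %1s %5d",
                         three[match(p, resno)], chain, p), ""))
  }
  if (length(mod_pos))
    lines <- c(lines, vapply(mod_pos, function(p)
      sprintf("MODRES XXXX %3s %1s %4d  %3s  SELENOMETHIONINE",
              "MSE", chain, p, "MET"), ""))
  lines <- c(lines, fmt_seqres(chain, three))
  serial <- 0L
  for (i in seq_along(resno)) {
    if (resno[i] %in% missing_pos) next
    serial <- serial + 1L
    rec <- if (resno[i] %in% mod_pos) "HETATM" else "ATOM"
    lines <- c(lines, fmt_atom(rec, serial, "CA", three[i], chain, resno[i],
                               " ", xyz[i, ], "C"))
  }
  last <- max(resno)
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                            serial + 1L, three[length(three)], chain, last))
  serial <- serial + 1L
  end_xyz <- xyz[nrow(xyz), ]
  for (j in seq_along(ligands)) {
    serial <- serial + 1L
    het <- ligands[j]
    el <- if (het %in% WATER_CODES) "O" else substr(het, 1, 2)
    nm <- if (het %in% WATER_CODES) "O" else substr(het, 1, 2)
    lines <- c(lines, fmt_atom("HETATM", serial, nm, het, chain,
                               last + 100L + j, " ",
                               end_xyz + c(4 * j, 2, 2), el))
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a synthetic template-search report for a fixture pair
#'
#' The report encodes the pair's true alignment so that parsing it
#' round-trips the fixture's identity and coverage within rounding.
#'
#' @param pair Result of \code{\link{generate_pair}}.
#' @param format \code{"blast_xml"} or \code{"hhr"}.
#' @param n_hits Emit the hit this many times (0 gives an empty report).
#' @param include_identities For hhr: write the \code{Identities=} field.
#' @return Report text.
#' @export
generate_hit_report <- function(pair, format = c("blast_xml", "hhr"),
                                n_hits = 1, include_identities = TRUE) {
  format <- match.arg(format)
  ch_t <- strsplit(pair$alignment$seqs[1], "")[[1]]
  ch_p <- strsplit(pair$alignment$seqs[2], "")[[1]]
  span <- which(ch_p != "-")
  qs <- min(span); qe <- max(span)
  qseq <- paste(ch_t[span], collapse = "")
  hseq <- paste(ch_p[span], collapse = "")
  idn <- sum(ch_t[span] == ch_p[span] & ch_p[span] != "X")
  code <- pair$spec$template_pdb_code
  if (format == "blast_xml") {
    hit <- paste0(
      "<Hit><Hit_num>1</Hit_num>",
      sprintf("<Hit_id>pdb|%s|A</Hit_id>", toupper(code)),
      "<Hit_def>synthetic fixture template</Hit_def>",
      sprintf("<Hit_len>%d</Hit_len>", length(span)),
      "<Hit_hsps><Hsp><Hsp_num>1</Hsp_num>",
      "<Hsp_bit-score>200.0</Hsp_bit-score><Hsp_evalue>1e-30</Hsp_evalue>",
      sprintf("<Hsp_query-from>%d</Hsp_query-from><Hsp_query-to>%d</Hsp_query-to>", qs, qe),
      sprintf("<Hsp_hit-from>1</Hsp_hit-from><Hsp_hit-to>%d</Hsp_hit-to>", length(span)),
      sprintf("<Hsp_identity>%d</Hsp_identity><Hsp_align-len>%d</Hsp_align-len>",
              idn, length(span)),
      sprintf("<Hsp_qseq>%s</Hsp_qseq><Hsp_hseq>%s</Hsp_hseq>", qseq, hseq),
      "</Hsp></Hit_hsps></Hit>")
    paste0("<?xml version=\"1.0\"?>\n<BlastOutput>",
           sprintf("<BlastOutput_query-len>%d</BlastOutput_query-len>",
                   length(ch_t)),
           "<BlastOutput_iterations><Iteration><Iteration_hits>",
           paste(rep(hit, n_hits), collapse = ""),
           "</Iteration_hits></Iteration></BlastOutput_iterations></BlastOutput>")
  } else {
    head <- c(sprintf("Query         %s", pair$target_id),
              sprintf("Match_columns %d", length(ch_t)),
              "",
              " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM")
    out <- head
    for (h in seq_len(n_hits)) {
      out <- c(out, sprintf("  %d %s_A synthetic fixture      99.9   1e-30   1e-35  200.0   0.0  %3d  %4d-%-4d   1-%d (%d)",
                            h, code, length(span), qs, qe, length(span),
                            length(span)))
    }
    for (h in seq_len(n_hits)) {
      stat <- sprintf("Probab=99.90  E-value=1e-30  Score=200.00  Aligned_cols=%d%s  Similarity=0.800  Sum_probs=0.0",
                      length(span),
                      if (include_identities)
                        sprintf("  Identities=%d%%", round(100 * idn / length(span)))
                      else "")
      out <- c(out, "", sprintf("No %d", h),
               sprintf(">%s_A synthetic fixture template", code), stat, "")
      # alignment written in blocks of 40 columns (Q/T line pairs)
      starts <- seq(1, length(span), by = 40)
      qpos <- qs; tpos <- 1
      for (s in starts) {
        e <- min(s + 39, length(span))
        qblk <- substr(qseq, s, e); tblk <- substr(hseq, s, e)
        nq <- nchar(gsub("-", "", qblk)); nt <- nchar(gsub("-", "", tblk))
        out <- c(out,
                 sprintf("Q %-14s %4d %s %4d (%d)", pair$target_id, qpos,
                         qblk, qpos + nq - 1, length(ch_t)),
                 sprintf("T %-14s %4d %s %4d (%d)", paste0(code, "_A"), tpos,
                         tblk, tpos + nt - 1, length(span)),
                 "")
        qpos <- qpos + nq; tpos <- tpos + nt
      }
    }
    paste(out, collapse = "\n")
  }
}

BENCH_ALIGNERS <- c("mafft", "muscle", "clustalo", "tcoffee", "search_alignment")

# emulate aligner disagreement: misalign a short run by inserting a gap pair
# (template gap at column p, target gap after the run); returns an Alignment
misalign_variant <- function(aln, run_len, at = NULL) {
  if (run_len < 0) return(aln)
  ch_t <- strsplit(aln$seqs[1], "")[[1]]
  ch_p <- strsplit(aln$seqs[2], "")[[1]]
  st_t <- aln$status[[1]]; st_p <- aln$status[[2]]
  core <- which(ch_p != "-" & ch_t != "-")
  if (length(core) < run_len + 10) return(aln)
  p <- if (is.null(at)) core[floor(length(core) / 3)] else at
  q <- p + run_len
  new_t <- append(ch_t, "-", after = q)        # target gap after column q
  new_p <- append(ch_p, "-", after = p - 1L)   # template gap at column p
  nst_t <- append(st_t, NA_character_, after = q)
  nst_p <- append(st_p, NA_character_, after = p - 1L)
  # both are now length L+1
  alignment(aln$names, aln$roles,
            c(paste(new_t, collapse = ""), paste(new_p, collapse = "")),
            list(nst_t, nst_p))
}

#' Generate a miniature benchmark collection with planted filter failures
#'
#' For each decade identity bin in [20, 90), \code{n_per_bin} well-behaved
#' target-template sets are generated (coordinate noise increasing as
#' identity decreases) plus one planted template-target RMSD outlier per
#' bin. Two further planted sets are appended: one whose target coverage
#' falls below 80\% and one whose five per-aligner identities straddle a bin
#' boundary. Ground-truth labels record which filter should remove each set.
#'
#' @param n_per_bin Well-behaved sets per bin (>= 1).
#' @param seed Integer master seed; all per-set seeds derive from it.
#' @param length Residues per target.
#' @return A \code{BenchmarkFixture}: list with \code{sets} (each carrying
#'   the pair, five per-aligner alignments, a 10-model score table and its
#'   \code{truth} label) and a \code{manifest} data.frame.
#' @export
generate_benchmark <- function(n_per_bin, seed, length = 60) {
  stopifnot(n_per_bin >= 1)
  sets <- list()
  k <- 0L
  add_set <- function(bin_lower, truth, identity, sigma, terminal_deletions,
                      straddle = FALSE) {
    k <<- k + 1L
    sseed <- (seed * 1000L + k * 7L) %% 2147483647L
    spec <- fixture_spec(
      seed = sseed, length = length, target_identity_pct = identity,
      coord_noise_sigma = sigma,
      missing_runs = list(c(20L, 2L)), modified_positions = 35L,
      terminal_deletions = terminal_deletions)
    pair <- generate_pair(spec)
    base_id <- compute_identity(pair$alignment$seqs[1], pair$alignment$seqs[2])
    base_bin <- assign_bin(base_id)
    alns <- list()
    run_lens <- c(-1L, 0L, 0L, 1L, 1L)
    for (j in seq_along(BENCH_ALIGNERS)) {
      v <- misalign_variant(pair$alignment, run_lens[j])
      vid <- compute_identity(v$seqs[1], v$seqs[2])
      if (!straddle && !identical(assign_bin(vid), base_bin))
        v <- pair$alignment   # keep the set inside its bin
      alns[[BENCH_ALIGNERS[j]]] <- v
    }
    if (straddle) {
      # force one aligner across the lower bin edge by widening the misalignment
      run <- 2L
      repeat {
        v <- misalign_variant(pair$alignment, run)
        vid <- compute_identity(v$seqs[1], v$seqs[2])
        if (!identical(assign_bin(vid), base_bin) || run > 12L) break
        run <- run + 2L
      }
      alns[["tcoffee"]] <- v
    }
    scores <- with_fixture_rng(sseed + 1L, {
      do.call(rbind, lapply(BENCH_ALIGNERS, function(a)
        data.frame(aligner = a, model_id = seq_len(10L),
                   score = round(stats::rnorm(
                     10, mean = -2.8 + 2.8 * (88 - identity) / 68,
                     sd = 0.25), 4),
                   stringsAsFactors = FALSE)))
    })
    sets[[length(sets) + 1L]] <<- list(
      set_id = sprintf("set%03d", k), bin_nominal = bin_lower,
      truth = truth, pair = pair, alignments = alns, scores = scores,
      seed = sseed)
  }

  for (b in bin_lowers()) {
    for (i in seq_len(n_per_bin)) {
      identity <- b + 4 + 4 * (i - 1) / max(1, n_per_bin - 1)
      sigma <- 0.3 + (88 - identity) * 0.03
      add_set(b, "keep", identity, sigma, c(2L, 2L))
    }
    # planted template-target RMSD outlier: passes bin and coverage filters
    add_set(b, "rmsd_outlier", b + 5, 15, c(2L, 2L))
  }
  # planted coverage failure (heavy terminal deletion) in the 50s bin
  add_set(50L, "coverage", 55, 1.3, c(8L, 6L))
  # planted bin straddler near the lower edge of the 40s bin
  add_set(40L, "bin", 41, 1.7, c(2L, 2L), straddle = TRUE)

  manifest <- do.call(rbind, lapply(sets, function(s)
    data.frame(set_id = s$set_id, target_id = s$pair$target_id,
               template_id = s$pair$template_id, bin_nominal = s$bin_nominal,
               truth = s$truth, seed = s$seed, stringsAsFactors = FALSE)))
  structure(list(sets = sets, manifest = manifest, n_per_bin = n_per_bin,
                 seed = seed), class = "BenchmarkFixture")
}

#' Materialize the coordinates of one synthetic model
#'
#' A synthetic "model" of a benchmark set is the template's coordinates over
#' the aligned span, labeled by target position, with a small per-model
#' perturbation; its randomness derives only from (set seed, aligner,
#' model id).
#'
#' @param set One element of a \code{BenchmarkFixture}'s \code{sets}.
#' @param aligner Aligner name.
#' @param model_id Model index (1-10).
#' @return A \code{CoordSet} labeled by target residue number.
#' @export
model_coords <- function(set, aligner, model_id) {
  pair <- set$pair
  model <- parse_pdb(pair$template_pdb, pdb_id = pair$template_id)
  cs <- as_coord_set(model, chain = "A")
  # template author numbering equals target position in fixtures
  labels <- vapply(strsplit(cs$labels, ":"), `[`, "", 2)
  j <- match(aligner, BENCH_ALIGNERS)
  mseed <- (set$seed + 131L * j + 17L * model_id) %% 2147483647L
  with_fixture_rng(mseed, {
    xyz <- cs$xyz + matrix(stats::rnorm(3 * nrow(cs$xyz), sd = 0.15), ncol = 3)
    coord_set(xyz, labels)
  })
}
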