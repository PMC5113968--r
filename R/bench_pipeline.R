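# Benchmark protocol: per-set identity/bin/coverage across the five
# alignment options, the three filters (bin consistency, target coverage,
# template-target RMSD outliers), top-model selection by supplied quality
# scores, and per-bin summaries.

#' Evaluate benchmark sets: identity, bin, coverage, template-target RMSD
#'
#' Computes, for every set of a \code{BenchmarkFixture} (or any list shaped
#' like one), the per-aligner recomputed identity, its bin and the target
#' coverage, plus the CA RMSD between template and target paired by the
#' true-alignment labels.
#'
#' @param bench A \code{BenchmarkFixture} or its \code{sets} list.
#' @return The sets list with \code{aligner_stats} (data.frame) and
#'   \code{template_target_rmsd} filled in.
#' @export
evaluate_sets <- function(bench) {
  sets <- if (inherits(bench, "BenchmarkFixture")) bench$sets else bench
  lapply(sets, function(s) {
    stats_df <- do.call(rbind, lapply(names(s$alignments), function(a) {
      aln <- s$alignments[[a]]
      id <- compute_identity(aln$seqs[1], aln$seqs[2])
      data.frame(aligner = a, identity = id, bin = assign_bin(id),
                 coverage = compute_coverage(aln), stringsAsFactors = FALSE)
    }))
    s$aligner_stats <- stats_df
    tgt <- parse_pdb(s$pair$target_pdb, pdb_id = s$pair$target_id)
    tpl <- parse_pdb(s$pair$template_pdb, pdb_id = s$pair$template_id)
    cs_t <- as_coord_set(tgt, chain = "A")
    cs_p <- as_coord_set(tpl, chain = "A")
    # fixture template numbering equals target position: labels already pair
    p <- pair_by_label(cs_p, cs_t)
    s$template_target_rmsd <- kabsch_superpose(p$a, p$b)$rmsd
    s
  })
}

set_bins <- function(s) s$aligner_stats$bin

#' Keep only sets whose five aligner bins agree
#'
#' A set survives iff the identity bin is the same, and defined, for every
#' alignment option; realignment that pushes one option across a decade
#' boundary disqualifies the whole set.
#'
#' @param sets Evaluated sets list.
#' @return Filtered sets list.
#' @export
bin_consistency_filter <- function(sets) {
  Filter(function(s) {
    b <- set_bins(s)
    !anyNA(b) && length(unique(b)) == 1
  }, sets)
}

#' Keep only sets modeled over enough of the target
#'
#' A set survives iff the target coverage is at least \code{threshold}
#' percent for all five alignment options.
#'
#' @param sets Evaluated sets list.
#' @param threshold Coverage threshold in percent (default 80).
#' @return Filtered sets list.
#' @export
coverage_filter <- function(sets, threshold = 80) {
  Filter(function(s) all(s$aligner_stats$coverage >= threshold), sets)
}

#' Remove per-bin template-target RMSD outliers
#'
#' Within each consensus bin, sets whose template-target RMSD exceeds the
#' upper Tukey fence (Q3 + k * IQR) of the bin's RMSD distribution are
#' removed; such pairs were usually caught in different conformations, so
#' RMSD cannot measure modeling accuracy for them. Low RMSD is never
#' suspect.
#'
#' @param sets Evaluated sets list (after the bin-consistency filter, so
#'   every set has one well-defined bin).
#' @param k Fence multiplier (default 1.5).
#' @return Filtered sets list.
#' @export
rmsd_outlier_filter <- function(sets, k = 1.5) {
  if (length(sets) == 0) return(sets)
  bins <- vapply(sets, function(s) set_bins(s)[1], "")
  rmsds <- vapply(sets, function(s) s$template_target_rmsd, 0)
  keep <- rep(TRUE, length(sets))
  for (b in unique(bins)) {
    i <- which(bins == b)
    q <- stats::quantile(rmsds[i], c(0.25, 0.75), names = FALSE)
    fence <- q[2] + k * (q[2] - q[1])
    keep[i] <- rmsds[i] <= fence
  }
  sets[keep]
}

#' Run the full filter chain
#'
#' @param sets Evaluated sets list.
#' @param coverage_threshold Coverage threshold in percent.
#' @param outlier_k Tukey fence multiplier.
#' @return List: \code{kept} (surviving sets), \code{removed} (data.frame
#'   of set_id and the stage that removed it).
#' @export
apply_filters <- function(sets, coverage_threshold = 80, outlier_k = 1.5) {
  ids <- function(x) vapply(x, function(s) s$set_id, "")
  removed_df <- function(id, stage)
    data.frame(set_id = id, stage = rep(stage, length(id)),
               stringsAsFactors = FALSE)
  s1 <- bin_consistency_filter(sets)
  removed <- removed_df(setdiff(ids(sets), ids(s1)), "bin_consistency")
  s2 <- coverage_filter(s1, coverage_threshold)
  removed <- rbind(removed, removed_df(setdiff(ids(s1), ids(s2)), "coverage"))
  s3 <- rmsd_outlier_filter(s2, outlier_k)
  removed <- rbind(removed,
                   removed_df(setdiff(ids(s2), ids(s3)), "rmsd_outlier"))
  list(kept = s3, removed = removed)
}

#' Select the top model of a set by supplied quality scores
#'
#' The minimum (best) score wins; ties break to the earlier model id. A
#' model is flagged native-like when its score is -1.0 or below.
#'
#' @param model_scores Data frame with columns \code{model_id},
#'   \code{score} (e.g. normalized statistical-potential Z-scores supplied
#'   by the modeling engine; this package never computes them).
#' @return List: \code{model_id}, \code{score}, \code{native_like}.
#' @export
select_top_model <- function(model_scores) {
  stopifnot(nrow(model_scores) >= 1)
  i <- which.min(model_scores$score)
  list(model_id = model_scores$model_id[i],
       score = model_scores$score[i],
       native_like = model_scores$score[i] <= -1.0)
}

#' Build the self-template (remodel) control for a target
#'
#' Models a target using its own structure as template, the ideal-condition
#' control: the pairing has 100 percent identity and the template entry
#' renders the structure's missing residues as '-' and modified residues as
#' '.'.
#'
#' @param model The target's \code{StructureModel}.
#' @param chain Chain to remodel.
#' @param pdb_file Filename recorded in the template entry header.
#' @return A verified \code{PirFile} (template entry first, target last).
#' @export
remodel_control <- function(model, chain, pdb_file = NULL) {
  ann <- extract_chain_sequence(model, chain)
  plain <- render_sequence(ann, "plain")
  nm <- model$pdb_id
  aln <- alignment(names = c(nm, paste0(nm, "_target")),
                   roles = c("template", "target"),
                   seqs = c(plain, plain),
                   status = list(ann$status,
                                 rep("observed_standard", nchar(plain))))
  models <- setNames(list(model), nm)
  build_pir(aln, models, chains = setNames(chain, nm),
            pdb_files = if (is.null(pdb_file)) NULL
            else setNames(pdb_file, nm))
}

#' Per-bin, per-aligner score summary
#'
#' @param scores Data frame with columns \code{set_id}, \code{aligner},
#'   \code{bin} and any of \code{rmsd}, \code{tm}, \code{gdt_ha},
#'   \code{lddt}, \code{quality}.
#' @return Data frame of arithmetic means per (bin, aligner) with set
#'   counts; empty bins are omitted.
#' @export
summarize_bins <- function(scores) {
  metric_cols <- intersect(c("rmsd", "tm", "gdt_ha", "lddt", "quality"),
                           names(scores))
  grp <- interaction(scores$bin, scores$aligner, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    sub <- scores[grp == g, , drop = FALSE]
    out <- data.frame(bin = sub$bin[1], aligner = sub$aligner[1],
                      n_sets = length(unique(sub$set_id)),
                      stringsAsFactors = FALSE)
    for (m in metric_cols) out[[paste0("mean_", m)]] <- mean(sub[[m]])
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$bin, out$aligner), , drop = FALSE]
}

#' Model-count accounting for a filtered benchmark
#'
#' Total models produced = surviving sets x alignment options x models per
#' run.
#'
#' @param n_sets Number of surviving sets.
#' @param n_aligners Alignment options per set (default 5).
#' @param n_models Models per modeling run (default 10).
#' @return Integer total.
#' @export
model_count <- function(n_sets, n_aligners = 5, n_models = 10) {
  as.integer(n_sets) * as.integer(n_aligners) * as.integer(n_models)
}

#' Run the full benchmark protocol on a fixture collection
#'
#' Evaluates every set, applies the three filters, selects each surviving
#' set's top model per aligner from the supplied score table, computes its
#' model-vs-target score set and summarizes per bin.
#'
#' @param bench A \code{BenchmarkFixture}.
#' @param score_models Compute structure-comparison scores for survivors?
#'   (Disable for filter-only runs.)
#' @param coverage_threshold,outlier_k Filter parameters.
#' @return List: \code{sets} (evaluated), \code{kept}, \code{removed},
#'   \code{scores}, \code{summary}, \code{accounting}.
#' @export
run_benchmark <- function(bench, score_models = TRUE,
                          coverage_threshold = 80, outlier_k = 1.5) {
  sets <- evaluate_sets(bench)
  flt <- apply_filters(sets, coverage_threshold, outlier_k)
  scores <- NULL
  if (score_models && length(flt$kept)) {
    scores <- do.call(rbind, lapply(flt$kept, function(s) {
      tgt <- parse_pdb(s$pair$target_pdb, pdb_id = s$pair$target_id)
      cs_t <- as_coord_set(tgt, chain = "A")
      cs_t$labels <- vapply(strsplit(cs_t$labels, ":"), `[`, "", 2)
      do.call(rbind, lapply(s$aligner_stats$aligner, function(a) {
        top <- select_top_model(s$scores[s$scores$aligner == a, ])
        m <- model_coords(s, a, top$model_id)
        ss <- score_set(m, cs_t, template_vs_target = s$template_target_rmsd)
        cbind(data.frame(set_id = s$set_id, aligner = a,
                         bin = s$aligner_stats$bin[1],
                         quality = top$score,
                         native_like = top$native_like,
                         stringsAsFactors = FALSE), ss)
      }))
    }))
  }
  list(sets = sets, kept = flt$kept, removed = flt$removed,
       scores = scores,
       summary = if (!is.null(scores)) summarize_bins(scores) else NULL,
       accounting = list(
         n_sets = length(flt$kept),
         n_aligners = length(BENCH_ALIGNERS),
         n_models_per_run = 10L,
         total_models = model_count(length(flt$kept))))
}

#' Write a benchmark manifest TSV
#' @param bench A \code{BenchmarkFixture}.
#' @param path Output file.
#' @export
write_manifest <- function(bench, path) {
  utils::write.table(bench$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
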