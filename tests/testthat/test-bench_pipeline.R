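# a minimal hand-built evaluated set for filter unit tests
mock_set <- function(id, bins, coverages, rmsd) {
  list(set_id = id,
       aligner_stats = data.frame(
         aligner = c("mafft", "muscle", "clustalo", "tcoffee",
                     "search_alignment"),
         identity = 45, bin = bins, coverage = coverages,
         stringsAsFactors = FALSE),
       template_target_rmsd = rmsd)
}

test_that("bin_consistency_filter keeps only sets with five identical bins", {
  same <- mock_set("s1", rep("[40,50)", 5), rep(90, 5), 1)
  mixed <- mock_set("s2", c(rep("[40,50)", 4), "[30,40)"), rep(90, 5), 1)
  na_bin <- mock_set("s3", c(rep("[40,50)", 4), NA), rep(90, 5), 1)
  kept <- bin_consistency_filter(list(same, mixed, na_bin))
  expect_equal(vapply(kept, `[[`, "", "set_id"), "s1")
})

test_that("coverage_filter requires the threshold for all five aligners", {
  ok <- mock_set("c1", rep("[40,50)", 5), c(85, 90, 88, 92, 81), 1)
  onelow <- mock_set("c2", rep("[40,50)", 5), c(85, 90, 88, 92, 79.9), 1)
  boundary <- mock_set("c3", rep("[40,50)", 5), rep(80, 5), 1)
  kept <- coverage_filter(list(ok, onelow, boundary))
  expect_equal(vapply(kept, `[[`, "", "set_id"), c("c1", "c3"))
})

test_that("rmsd_outlier_filter removes values above the upper Tukey fence", {
  set.seed(41)
  vals <- c(runif(19, 1, 3), 25)
  sets <- lapply(seq_along(vals), function(i)
    mock_set(sprintf("r%02d", i), rep("[40,50)", 5), rep(90, 5), vals[i]))
  kept <- rmsd_outlier_filter(sets)
  expect_equal(length(kept), 19)
  expect_false("r20" %in% vapply(kept, `[[`, "", "set_id"))
  # all-equal values: nothing removed
  eq <- lapply(1:6, function(i)
    mock_set(sprintf("e%d", i), rep("[40,50)", 5), rep(90, 5), 2))
  expect_equal(length(rmsd_outlier_filter(eq)), 6)
  expect_equal(rmsd_outlier_filter(list()), list())
})

test_that("select_top_model picks the minimum score and flags native-like", {
  sc <- data.frame(model_id = 1:3, score = c(-0.5, -1.2, -0.9))
  top <- select_top_model(sc)
  expect_equal(top$model_id, 2)
  expect_true(top$native_like)
  # boundary: -1.0 counts as native-like
  expect_true(select_top_model(data.frame(model_id = 1, score = -1))$native_like)
  expect_false(select_top_model(data.frame(model_id = 1:2,
                                           score = c(0.3, 0.1)))$native_like)
  # ties break to the earlier model id
  expect_equal(select_top_model(data.frame(model_id = 1:3,
                                           score = c(-1, -1, -2)))$model_id, 3)
  expect_equal(select_top_model(data.frame(model_id = 1:2,
                                           score = c(-1, -1)))$model_id, 1)
})

test_that("remodel_control builds a valid self-template PIR", {
  spec <- fixture_spec(seed = 14, length = 30, target_identity_pct = 85,
                       missing_runs = list(c(10L, 3L)),
                       modified_positions = 20L)
  pair <- generate_pair(spec)
  m <- parse_pdb(pair$template_pdb, pdb_id = "self")
  pir <- remodel_control(m, "A")
  expect_s3_class(pir, "PirFile")
  tmpl <- pir$entries[[1]]$seq
  tgt <- pir$entries[[2]]$seq
  # template entry carries '-' exactly at the structure's missing residues
  expect_equal(lengths(regmatches(tmpl, gregexpr("-", tmpl, fixed = TRUE))), 3)
  expect_equal(lengths(regmatches(tmpl, gregexpr(".", tmpl, fixed = TRUE))), 1)
  # the pairing itself is 100% identity (self-template)
  ann <- extract_chain_sequence(m, "A")
  plain <- render_sequence(ann, "plain")
  expect_equal(compute_identity(plain, plain), 100)
  # and the entry verifies against the structure
  expect_true(verify_template_sequence(tmpl, m, "A")$valid)
})

test_that("summarize_bins matches an independent aggregation", {
  scores <- data.frame(
    set_id = rep(c("a", "b"), each = 2),
    aligner = rep(c("mafft", "muscle"), 2),
    bin = "[40,50)",
    rmsd = c(1, 2, 3, 4), tm = c(0.9, 0.8, 0.7, 0.6),
    stringsAsFactors = FALSE)
  s <- summarize_bins(scores)
  expect_equal(nrow(s), 2)
  mafft <- s[s$aligner == "mafft", ]
  expect_equal(mafft$mean_rmsd, mean(c(1, 3)))
  expect_equal(mafft$n_sets, 2)
  # independent aggregation oracle
  ora <- tapply(scores$rmsd, scores$aligner, mean)
  expect_equal(s$mean_rmsd, as.numeric(ora[s$aligner]))
})

test_that("the filter chain is idempotent and survivors satisfy every predicate", {
  bench <- generate_benchmark(n_per_bin = 2, seed = 3)
  sets <- evaluate_sets(bench)
  once <- apply_filters(sets)
  twice <- apply_filters(once$kept)
  expect_equal(vapply(twice$kept, `[[`, "", "set_id"),
               vapply(once$kept, `[[`, "", "set_id"))
  expect_equal(nrow(twice$removed), 0)
  for (s in once$kept) {
    expect_equal(length(unique(s$aligner_stats$bin)), 1)
    expect_true(all(s$aligner_stats$coverage >= 80))
  }
})

test_that("model-count accounting multiplies sets, aligners and models", {
  expect_identical(model_count(7), 350L)
  expect_identical(model_count(3, n_aligners = 2, n_models = 4), 24L)
  bench <- generate_benchmark(n_per_bin = 1, seed = 6)
  res <- run_benchmark(bench, score_models = FALSE)
  expect_equal(res$accounting$total_models,
               length(res$kept) * 5L * 10L)
})

test_that("per-bin mean RMSD rises as the generator noise rises (low-identity bins)", {
  bench <- generate_benchmark(n_per_bin = 3, seed = 8)
  sets <- evaluate_sets(bench)
  keep <- Filter(function(s) s$truth == "keep", sets)
  rmsd_by_bin <- tapply(vapply(keep, `[[`, 0, "template_target_rmsd"),
                        vapply(keep, function(s) s$bin_nominal, 0), mean)
  bins <- as.integer(names(rmsd_by_bin))
  # noise (and hence template-target RMSD) decreases with the bin lower bound
  expect_true(all(diff(rmsd_by_bin[order(bins)]) < 0))
})
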