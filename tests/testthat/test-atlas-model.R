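test_that("read_atlas round-trips well-formed signal and metadata files", {
  sig <- data.frame(probe_id = c("pA", "pB"), gene_symbol = c("a", "b"),
                    s1 = c(1.5, 0), s2 = c(10, 3))
  meta <- data.frame(sample_id = c("s1", "s2"), tissue = c("gut", "brain"),
                     life_stage = "adult", replicate = 1L)
  sp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write.table(sig, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)

  atlas <- read_atlas(sp, mp)
  expect_s3_class(atlas, "atlas_matrix")
  expect_equal(dim(atlas$signal), c(2L, 2L))
  expect_equal(atlas$signal["pA", "s2"], 10)
  expect_equal(atlas$samples$tissue, c("gut", "brain"))
})

test_that("read_atlas rejects malformed inputs", {
  sig <- data.frame(probe_id = c("pA", "pA"), gene_symbol = c("a", "a"),
                    s1 = c(1, 2))
  meta <- data.frame(sample_id = "s1", tissue = "gut", life_stage = "adult",
                     replicate = 1L)
  sp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write.table(sig, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(sp, mp), "duplicate probe_id")

  sig2 <- data.frame(probe_id = c("pA", "pB"), gene_symbol = c("a", "b"),
                     s1 = c(-1, 2))
  write.table(sig2, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(sp, mp), "negative signal")

  sig3 <- data.frame(probe_id = c("pA", "pB"), gene_symbol = c("a", "b"),
                     s1 = c(1, 2), s9 = c(1, 1))
  write.table(sig3, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(sp, mp), "do not match")
})

test_that("the published signal fixture loads with 102 probes, 11 tissues, and blank cells as missing", {
  pub <- load_published_signals()
  atlas <- pub$atlas
  expect_equal(nrow(atlas$signal), 102L)
  expect_equal(ncol(atlas$signal), 11L)
  # printed table leaves brain and testis blank for these probes
  expect_true(is.na(atlas$signal["CG1467", "adult_brain"]))
  expect_true(is.na(atlas$signal["CG1467", "adult_testis"]))
  expect_true(is.na(atlas$signal["SK-RA", "adult_brain"]))
  expect_equal(atlas$signal["CG1467", "whole_fly"], 275)
  # duplicated symbol kept as two probe records
  expect_equal(sum(atlas$probes$gene_symbol == "Vha16-1"), 2L)
  expect_equal(atlas$signal["Vha16-1#2", "adult_salivary_gland"], 13363)
  # zeros are zeros, not missing
  expect_equal(atlas$signal["SK", "larval_salivary_gland"], 0)
})

test_that("atlas_matrix enforces its invariants", {
  probes <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("g", "g"))
  samples <- data.frame(sample_id = c("a1", "a2"), tissue = "gut",
                        life_stage = "adult", replicate = c(1L, 2L))
  sig <- matrix(1:4, 2)
  expect_silent(atlas_matrix(sig, probes, samples))
  expect_error(atlas_matrix(-sig, probes, samples), "negative")
  samples2 <- samples; samples2$replicate <- c(1L, 1L)
  expect_error(atlas_matrix(sig, probes, samples2), "unique")
  expect_error(atlas_matrix(sig, probes, samples,
                            calls = matrix("X", 2, 2)), "P, M, A")
})

test_that("result tables round-trip through write_table/read_table", {
  set.seed(11)
  for (rep in 1:5) {
    ng <- sample(2:12, 1); nt <- sample(2:5, 1)
    tissues <- paste0("t", seq_len(nt))
    probes <- data.frame(probe_id = sprintf("p%02d", seq_len(ng)),
                         gene_symbol = sprintf("g%02d", sample(ng)),
                         stringsAsFactors = FALSE)
    ms <- matrix(signif(2^runif(ng * nt, 0, 14), 6), ng, nt,
                 dimnames = list(probes$probe_id, tissues))
    ms[sample(length(ms), 2)] <- NA
    pf <- matrix(sample(0:4, ng * nt, TRUE) / 4, ng, nt,
                 dimnames = dimnames(ms))
    pf[is.na(ms)] <- NA
    nr <- matrix(4L, ng, nt, dimnames = dimnames(ms))
    nr[is.na(ms)] <- 0L
    prof <- tissue_profile(ms, probes, present_fraction = pf,
                           n_replicates = nr)
    p <- withr::local_tempfile(fileext = ".tsv")
    write_table(prof, p)
    back <- read_table(p)
    expect_equal(back$mean_signal, prof$mean_signal)
    expect_equal(back$present_fraction, prof$present_fraction)
    expect_equal(back$n_replicates, prof$n_replicates)

    fc <- matrix(signif(2^runif(ng * nt, -4, 7), 6), ng, nt,
                 dimnames = dimnames(ms))
    fc[sample(length(fc), 2)] <- NA
    et <- enrichment_table(fc, probes, reference_tissue = "ref", floor = 0.5)
    write_table(et, p)
    back <- read_table(p)
    expect_equal(back$fold_change, et$fold_change)
    expect_equal(back$reference_tissue, "ref")
    expect_equal(back$floor, 0.5)
  }
})

test_that("missing cells survive a write/read cycle without becoming numbers", {
  probes <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("a", "b"))
  ms <- matrix(c(1, NA, 3, 0), 2,
               dimnames = list(probes$probe_id, c("t1", "t2")))
  nr <- matrix(c(1L, 0L, 1L, 1L), 2, dimnames = dimnames(ms))
  prof <- tissue_profile(ms, probes, n_replicates = nr)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_table(prof, p)
  back <- read_table(p)
  expect_true(is.na(back$mean_signal["p2", "t1"]))
  expect_equal(back$mean_signal["p2", "t2"], 0)
})

test_that("signature results serialize flags as pass/fail strings and round-trip", {
  tab <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("a", "b"),
                    evidence.t1 = c(3.5, 1.2), evidence.t2 = c(2.7, 4.1),
                    pass.t1 = c(TRUE, FALSE), pass.t2 = c(TRUE, TRUE),
                    overall_pass = c(TRUE, FALSE), stringsAsFactors = FALSE)
  res <- signature_result("consensus_fc", tab,
                          criterion = list(tau = 2.5, mode = "consensus_fc"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_table(res, p)
  raw <- readLines(p)
  expect_match(raw[2], "overall_pass$")
  expect_match(raw[3], "pass\tpass\tpass$")   # p1 flags: t1, t2, overall
  expect_match(raw[4], "fail\tpass\tfail$")   # p2 flags
  back <- read_table(p)
  expect_equal(back$mode, "consensus_fc")
  expect_equal(back$table$overall_pass, c(TRUE, FALSE))
  expect_equal(back$table$evidence.t1, c(3.5, 1.2))
  expect_equal(back$criterion$tau, 2.5)
})

test_that("empty results write header-only files that read back empty", {
  probes <- data.frame(probe_id = character(), gene_symbol = character())
  et <- enrichment_table(
    matrix(numeric(), 0, 2, dimnames = list(NULL, c("t1", "t2"))),
    probes, reference_tissue = "ref", floor = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_table(et, p)
  expect_length(readLines(p), 2L)  # metadata line + header
  back <- read_table(p)
  expect_equal(nrow(back$fold_change), 0L)
})

test_that("gene lists validate class labels and analysis_config enforces bounds", {
  expect_error(gene_list("a", ""), "non-empty")
  gl <- gene_list(c("a", "b"), c("K", "K"), c("f1", NA))
  expect_s3_class(gl, "gene_list")
  expect_error(analysis_config(tau = 0), "tau")
  expect_error(analysis_config(top_n = 0), "top_n")
  expect_error(analysis_config(floor = -1), "floor")
  expect_error(analysis_config(reference_tissue = "adult_midgut"),
               "reference_tissue")
})
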