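published_cfg <- analysis_config()

test_that("consensus signature on the published table keeps 20 of 25 genes at tau 2.5", {
  t2 <- load_published_enrichment()
  core <- core_signature(t2, published_cfg)
  expect_equal(nrow(core$table), 25L)
  expect_equal(sum(core$table$overall_pass), 20L)
  tab <- core$table
  # Bowl passes: every printed value is >= 2.5
  expect_true(tab$overall_pass[tab$gene_symbol == "Bowl"])
  # mthl3 fails the strict reading: 2.2 in the adult salivary gland
  expect_false(tab$overall_pass[tab$gene_symbol == "mthl3"])
  expect_false(tab$`pass.adult_salivary_gland`[tab$gene_symbol == "mthl3"])
  # rows are ordered by descending minimum fold change
  ev <- as.matrix(tab[grep("^evidence\\.", names(tab))])
  expect_true(!is.unsorted(rev(apply(ev, 1, min))))
})

test_that("a vacuous threshold passes every fully-defined gene", {
  t2 <- load_published_enrichment()
  core <- core_signature(t2, analysis_config(tau = 1e-12))
  expect_true(all(core$table$overall_pass))
})

test_that("consensus pass set equals an exhaustive per-gene scan on random tables", {
  set.seed(41)
  for (rep in 1:10) {
    et <- random_enrichment(ng = 20, nt = 6, na_frac = 0.1)
    tau <- 2^runif(1, -1, 3)
    cfg <- analysis_config(epithelial_tissues = colnames(et$fold_change)[1:4],
                           reference_tissue = "ref", tau = tau)
    got <- sort(passing_genes(core_signature(et, cfg)))
    want <- character()
    for (g in rownames(et$fold_change)) {
      v <- et$fold_change[g, cfg$epithelial_tissues]
      if (!anyNA(v) && all(v >= tau)) want <- c(want, g)
    }
    expect_equal(got, sort(want))
  }
})

test_that("pass sets shrink weakly as tau increases", {
  set.seed(43)
  for (rep in 1:5) {
    et <- random_enrichment(ng = 30, nt = 5, na_frac = 0.05)
    cfgs <- lapply(seq(0.5, 5, length.out = 10), function(tau)
      analysis_config(epithelial_tissues = colnames(et$fold_change),
                      reference_tissue = "ref", tau = tau))
    sets <- lapply(cfgs, function(cfg)
      passing_genes(core_signature(et, cfg)))
    for (i in seq_len(length(sets) - 1))
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("criterion audit flags exactly the printed cells below the stated threshold", {
  t2 <- load_published_enrichment()
  core <- core_signature(t2, published_cfg)
  aud <- criterion_audit(core)
  # hand enumeration of the 25 printed rows: the cells below 2.5
  expected <- data.frame(
    gene_symbol = c("l(1)G0168", "Lola", "mthl3", "Nhe1", "Smox", "Smox"),
    tissue = c("adult_midgut", "larval_midgut", "adult_salivary_gland",
               "adult_midgut", "adult_salivary_gland", "adult_midgut"),
    value = c(2.4, 2.3, 2.2, 2.4, 2.3, 2.4),
    stringsAsFactors = FALSE
  )
  got <- aud[order(aud$gene_symbol, aud$tissue),
             c("gene_symbol", "tissue", "value")]
  want <- expected[order(expected$gene_symbol, expected$tissue), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # audit is empty iff every audited gene passes
  expect_length(
    intersect(aud$gene_symbol,
              core$table$gene_symbol[core$table$overall_pass]), 0L)
  expect_equal(nrow(criterion_audit(core, analysis_config(tau = 1e-12))), 0L)
})

test_that("audit of a clean single-gene table is empty", {
  et <- enrichment_table(
    matrix(c(5, 7), 1, dimnames = list("g1", c("t1", "t2"))),
    probes = data.frame(probe_id = "g1", gene_symbol = "g1"),
    reference_tissue = "ref", floor = 1)
  cfg <- analysis_config(epithelial_tissues = c("t1", "t2"),
                         reference_tissue = "ref")
  expect_equal(nrow(criterion_audit(core_signature(et, cfg))), 0L)
})

test_that("strict call signature requires presence inside and absence outside", {
  # four genes: everywhere-present, perfect in/out, one inside absence,
  # one outside presence
  calls_in <- rbind(c("P", "P"), c("P", "P"), c("P", "A"), c("P", "P"))
  calls_out <- rbind(c("P", "P"), c("A", "A"), c("A", "A"), c("P", "A"))
  sig <- matrix(100, 4, 4)
  atlas <- toy_atlas(list(gut = sig[, 1:2], brain = sig[, 3:4]),
                     calls = cbind(calls_in, calls_out))
  prof <- aggregate_replicates(atlas)
  res <- strict_call_signature(prof, analysis_config(),
                               inside = "gut", outside = "brain")
  expect_equal(sort(passing_genes(res)), "p02")
  expect_error(strict_call_signature(prof, analysis_config(),
                                     inside = "gut",
                                     outside = c("gut", "brain")),
               "disjoint")
})

test_that("on a synthetic atlas the strict criterion detects fewer genes than the fold-change consensus", {
  gen <- generate_atlas(sim_config(rng_seed = 5L))
  cfg <- analysis_config()
  prof <- aggregate_replicates(gen$atlas, cfg)
  et <- fold_change(prof, cfg)
  n_core <- sum(core_signature(et, cfg)$table$overall_pass)
  panel <- default_tissue_panel()
  outside <- setdiff(panel$tissue[!panel$epithelial], "whole_fly")
  n_strict <- length(passing_genes(
    strict_call_signature(prof, cfg, inside = cfg$epithelial_tissues,
                          outside = outside)))
  expect_lt(n_strict, n_core)
})

test_that("top-N ranking matches the printed column maximum and full-sort oracle", {
  t2 <- load_published_enrichment()
  top1 <- tissue_specific_top_n(t2, "adult_salivary_gland",
                                analysis_config(top_n = 1))
  expect_equal(top1$table$gene_symbol, "Drip")
  expect_equal(top1$table$evidence.best, 63.1)
  # n beyond the table returns the full sorted list
  all_rows <- tissue_specific_top_n(t2, "adult_salivary_gland",
                                    analysis_config(top_n = 1000))
  expect_equal(nrow(all_rows$table), 25L)
  expect_true(!is.unsorted(rev(all_rows$table$evidence.best)))
  expect_error(tissue_specific_top_n(t2, "no_such_tissue"), "unknown tissue")
})

test_that("top-N equals sort-then-slice and extends by one as n grows", {
  set.seed(47)
  for (rep in 1:10) {
    et <- random_enrichment(ng = 30, nt = 3, na_frac = 0.1)
    t <- "t2"
    v <- et$fold_change[, t]
    ord <- order(-v, et$probes$gene_symbol, et$probes$probe_id,
                 na.last = NA)
    full <- et$probes$probe_id[ord]
    prev <- character()
    for (n in seq_len(min(length(full) + 2, 30))) {
      res <- tissue_specific_top_n(et, t, analysis_config(top_n = n))
      expect_equal(res$table$probe_id, head(full, n))
      expect_true(all(prev %in% res$table$probe_id))
      expect_lte(nrow(res$table) - length(prev), 1L)
      prev <- res$table$probe_id
    }
  }
})

test_that("merged cognate ranking uses the per-gene maximum of the pair", {
  t2 <- load_published_enrichment()
  pair <- c("adult_tubule", "larval_tubule")
  merged <- tissue_specific_top_n(t2, pair, analysis_config(top_n = 3))
  expect_equal(merged$table$gene_symbol[1], "mthl3")  # 56.7 in larval tubule
  expect_equal(merged$table$evidence.best[1], 56.7)
  adult_only <- tissue_specific_top_n(t2, "adult_tubule",
                                      analysis_config(top_n = 25))
  merged_all <- tissue_specific_top_n(t2, pair, analysis_config(top_n = 25))
  expect_true(all(merged_all$table$evidence.best >=
                    adult_only$table$evidence.best))
})

test_that("gene-list profiling reproduces the fixture and flags unknown symbols", {
  pub <- load_published_signals()
  prof <- aggregate_replicates(pub$atlas)
  gp <- profile_gene_list(prof, pub$gene_list)
  expect_equal(nrow(gp), 102L)  # one row per probe, duplicates included
  expect_true(all(gp$in_atlas))
  drip <- gp[gp$gene_symbol == "Drip", ]
  expect_equal(drip$adult_salivary_gland, 7135)
  expect_equal(drip$class_label, "Water channels")
  # V-ATPase class alone: 33 probe rows
  vha <- pub$gene_list[pub$gene_list$class_label == "V-ATPase subunits", ]
  expect_equal(nrow(profile_gene_list(prof, vha)), 33L)
  # unknown symbols are flagged, not dropped
  gl2 <- gene_list(c("Drip", "not_a_gene"), c("W", "W"))
  gp2 <- profile_gene_list(prof, gl2)
  expect_equal(nrow(gp2), 2L)
  expect_false(gp2$in_atlas[2])
  expect_true(is.na(gp2$adult_midgut[2]))
})

test_that("dominant isoform selection matches the printed family winners", {
  pub <- load_published_signals()
  prof <- aggregate_replicates(pub$atlas)
  d <- dominant_isoform(prof, c("vha68-1", "vha68-2", "vha68-3"),
                        "adult_salivary_gland")
  expect_equal(d$gene_symbol, "vha68-2")
  expect_equal(d$signal, 13958)
  expect_false(d$ambiguous)
  d2 <- dominant_isoform(prof,
                         c("vha100-1", "vha100-2", "Vha100-3", "Vha100-4",
                           "Vha100-5"), "adult_tubule")
  expect_equal(d2$gene_symbol, "vha100-2")
  expect_equal(d2$signal, 3657)
  # singleton family returns itself with no runner-up ratio
  ds <- dominant_isoform(prof, "Drip", "adult_midgut")
  expect_equal(ds$gene_symbol, "Drip")
  expect_true(is.na(ds$runner_up_ratio))
  expect_error(dominant_isoform(prof, c("nope1", "nope2"), "adult_midgut"),
               "no family member")
})

test_that("dominant isoform equals an exhaustive family scan; ties are flagged", {
  set.seed(53)
  for (rep in 1:10) {
    ng <- 8
    sig <- matrix(sample(0:50, ng * 2, TRUE), ng, 2)
    atlas <- toy_atlas(list(a = sig[, 1, drop = FALSE],
                            b = sig[, 2, drop = FALSE]),
                       gene_symbol = sprintf("fam%d", seq_len(ng)))
    prof <- aggregate_replicates(atlas)
    fam <- sprintf("fam%d", sample(ng, 5))
    d <- dominant_isoform(prof, fam, "a")
    v <- setNames(sig[match(fam, sprintf("fam%d", seq_len(ng))), 1], fam)
    expect_equal(d$signal, max(v))
    expect_equal(d$gene_symbol, sort(names(v)[v == max(v)])[1])
    expect_equal(d$ambiguous, sum(v == max(v)) > 1)
  }
})

test_that("family profiles report one dominant member per family and tissue", {
  pub <- load_published_signals()
  prof <- aggregate_replicates(pub$atlas)
  vha <- pub$gene_list[pub$gene_list$class_label == "V-ATPase subunits", ]
  fp <- family_profile(prof, vha, tissues = c("adult_tubule", "adult_midgut"))
  expect_equal(nrow(fp),
               2L * length(unique(vha$family_label[!is.na(vha$family_label)])))
  a_rows <- fp[fp$family_label == "A", ]
  expect_true(all(a_rows$dominant_symbol == "vha68-2"))
  expect_true(all(fp$runner_up_ratio >= 1 | is.na(fp$runner_up_ratio)))
})
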