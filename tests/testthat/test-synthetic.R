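test_that("repertoire generator conserves depth and is deterministic", {
  # single-clone degenerate case
  one <- generate_repertoire(1, 100, exponent = 2, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$count, 100)
  expect_equal(one$freq, 1)

  tab <- generate_repertoire(10, 1000, exponent = 1.5, seed = 7)
  expect_equal(sum(tab$count), 1000)
  expect_equal(length(unique(tab$cdr3aa)), 10)
  expect_equal(sum(tab$freq), 1, tolerance = 1e-9)
  # byte-identical under the same seed
  expect_identical(generate_repertoire(10, 1000, exponent = 1.5, seed = 7),
                   tab)
  expect_error(generate_repertoire(10, 5), "invalid sizes")
})

test_that("nonproductive spike-ins are labeled and removable by QC", {
  tab <- generate_repertoire(100, 10000, seed = 3, nonproductive_frac = 0.2)
  frac_bad <- mean(!is_productive_cdr3(tab$cdr3aa))
  expect_gt(frac_bad, 0.1)
  expect_lte(frac_bad, 0.2)
  expect_true(all(is_productive_cdr3(filter_productive(tab)$cdr3aa)))
})

test_that("paired generator plants the configured overlap and categories", {
  cfg <- cohort_config(n_clones = 200, repertoire_depth = 2e4)
  pp <- generate_paired_tumor_repertoires(cfg, "well", seed = 5)
  itcs <- identify_itcs(pp$pre, pp$post)
  expect_equal(length(itcs), round(cfg$itc_overlap_frac * 200))
  # ground-truth categories partition the post-treatment clonotypes
  post_keys <- clone_keys(pp$post)
  tr <- pp$truth
  expect_setequal(post_keys,
                  tr$key[tr$category %in% c("expanded", "contracted",
                                            "stable", "new")])
  # every new clone is absent from the pre table
  expect_length(intersect(tr$key[tr$category == "new"],
                          clone_keys(pp$pre)), 0)
  # every persistent clone appears in both tables
  pers <- tr$key[tr$category %in% c("expanded", "contracted", "stable")]
  expect_true(all(pers %in% clone_keys(pp$pre)))
  expect_true(all(pers %in% post_keys))
  expect_equal(sum(pp$post$count), 2e4)

  # disjoint case: zero overlap means no ITCs downstream
  cfg0 <- cohort_config(n_clones = 100, repertoire_depth = 5000,
                        itc_overlap_frac = 0)
  pp0 <- generate_paired_tumor_repertoires(cfg0, "well", seed = 2)
  expect_length(identify_itcs(pp0$pre, pp0$post), 0)
})

test_that("null dynamics leave shared clone frequencies unchanged in mean", {
  cfg <- cohort_config(expansion_factor_well = 1, contraction_factor = 1,
                       new_clone_frac = 0, new_clone_space = 0,
                       itc_overlap_frac = 1,
                       n_clones = 300, repertoire_depth = 1e5)
  ratios <- sapply(1:10, function(s) {
    pp <- generate_paired_tumor_repertoires(cfg, "well", seed = s)
    pr <- make_clone_pairs(pp$pre, pp$post)
    shared <- pr$count_pre > 0 & pr$count_post > 0
    mean(pr$freq_post[shared] / pr$freq_pre[shared])
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("planted expansion factor is recovered in the frequency ratios", {
  cfg <- cohort_config()
  ratios <- sapply(1:20, function(s) {
    pp <- generate_paired_tumor_repertoires(cfg, "well", seed = s)
    expk <- pp$truth$key[pp$truth$category == "expanded"]
    pr <- make_clone_pairs(pp$pre, pp$post)
    i <- pr$key %in% expk
    mean(pr$freq_post[i] / pr$freq_pre[i])
  })
  expect_gte(mean(ratios), 4)
  expect_lte(mean(ratios), 6)
})

test_that("blood series places circulating ITCs with the given dynamics", {
  cfg <- cohort_config(n_clones = 200, repertoire_depth = 2e4)
  pp <- generate_paired_tumor_repertoires(cfg, "well", seed = 8)
  itcs <- identify_itcs(pp$pre, pp$post)
  rec <- as.data.frame(pp$post)[clone_keys(pp$post) %in% itcs, ]

  # empty subset: no circulating ITCs downstream
  bs0 <- generate_blood_series(rec, c("baseline", "W3", "W6"),
                               c(1, 1, 1), seed = 4, depth = 2e4,
                               circulating_frac = 0)
  cc0 <- circulating_itcs(itcs, bs0)
  expect_equal(cc0$n_circulating, c(0, 0, 0))
  expect_equal(cc0$clonal_space, c(0, 0, 0))

  # planted W6 peak is recovered as the max mean frequency at W6
  peaks <- sapply(1:20, function(s) {
    bs <- generate_blood_series(rec, c("baseline", "W3", "W6"),
                                c(1, 1.5, 3), seed = s, depth = 1e5)
    cc <- circulating_itcs(itcs, bs)
    which.max(cc$clonal_space)
  })
  expect_gte(mean(peaks == 3), 0.95)
  expect_error(generate_blood_series(rec, character(0), numeric(0)),
               "nonempty")
})

test_that("cohort generator output is deterministic and conserves structure", {
  cfg <- cohort_config(n_patients = 6, n_genes = 400, n_neoantigens = 10)
  a <- generate_expression_and_clinical(cfg, seed = 31)
  b <- generate_expression_and_clinical(cfg, seed = 31)
  expect_identical(a, b)
  expect_equal(dim(a$expression), c(400, 6))
  expect_false(anyNA(a$expression))
  expect_true(all(a$expression >= 0))
  expect_true(all(a$clinical$responder %in% c("well", "poor")))
  # residual tumor consistent with responder labels
  expect_true(all(a$clinical$residual_tumor_percent[
    a$clinical$responder == "well"] <= 33))
  expect_true(all(a$clinical$residual_tumor_percent[
    a$clinical$responder == "poor"] > 33))
  # every mutation present at >= 1 timepoint
  expect_true(all(a$mutations$pre | a$mutations$post))
  expect_true(all(a$pairs$rank > 0 & a$pairs$rank <= 100))
  expect_error(
    generate_expression_and_clinical(
      cohort_config(n_patients = 6, n_genes = 100), seed = 1),
    "n_genes too small")
})

test_that("null signature effect centers the group score difference at 0", {
  cfg <- cohort_config(n_patients = 12, n_genes = 400,
                       signature_effect_size = 0, n_neoantigens = 5)
  d <- sapply(1:15, function(s) {
    om <- generate_expression_and_clinical(cfg, seed = s)
    resp <- om$truth$responder[colnames(om$expression)]
    sc <- colMeans(om$expression[om$truth$signature_genes, , drop = FALSE])
    mean(sc[resp == "well"]) - mean(sc[resp == "poor"])
  })
  expect_lt(abs(mean(d)), 0.2)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(frac_well_responders = 1.2), "proportions")
  expect_error(cohort_config(subtype_proportions = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(cohort_config(powerlaw_exponent = 0), "positive")
  expect_error(cohort_config(n_clones = 2000, repertoire_depth = 100),
               "at least n_clones")
})

test_that("simulate_cohort writes all standard-format tables", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 3, n_clones = 100,
                       repertoire_depth = 5000, n_genes = 400,
                       n_neoantigens = 5)
  out <- simulate_cohort(cfg, dir, seed = 17)
  expect_true(all(file.exists(file.path(
    dir, c("expression.tsv", "gene_sets.gmt", "clinical.tsv",
           "mutations.tsv", "neoantigens.tsv", "pairs.tsv",
           "ground_truth.json")))))
  pt <- out$omics$clinical$patient[1]
  tab <- read_clonotype_table(
    file.path(dir, paste0(pt, "_tumor_baseline.tsv")))
  expect_equal(sum(tab$count), 5000)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), c(400, 3))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_true("IFN_GAMMA" %in% names(sets))
})
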