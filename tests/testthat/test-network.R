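# Construct a lightweight sling_run with known content, bypassing the
# sampler, for aggregation-logic tests.
fake_run <- function(kept_names, spec = NULL, theta = NULL,
                     variant_id = 1L) {
  if (is.null(spec)) {
    spec <- enumerate_logic_variants(seam_topology("late-L1"))[[variant_id]]
  }
  params <- parameter_set(spec)
  pt <- params$table
  if (is.null(theta)) {
    theta <- stats::setNames(rep(0, nrow(pt)), pt$name)
    theta[kept_names] <- 30
  }
  kept <- stats::setNames(pt$name %in% kept_names, pt$name)
  chain <- matrix(rep(theta, 3), nrow = 3, byrow = TRUE,
                  dimnames = list(NULL, pt$name))
  structure(
    list(variant_id = spec$variant_id, spec = spec, chain = chain,
         distances = c(1, 1, 1), n_burn = 1L,
         final_fit = theta, final_distance = 1,
         kept_mask = kept, param_table = pt, bound = 500,
         alpha = stats::setNames(rep(1, 3), spec$genes),
         d = stats::setNames(rep(1, 3), spec$genes),
         target_mu = matrix(30, 3, 4, dimnames = list(spec$genes, NULL)),
         genotype_names = paste0("p", 1:4),
         config = list(ss_tol = 1e-8, ss_tmax = 1e4)),
    class = "sling_run"
  )
}

test_that("parameter presence percentages count final fits", {
  r_all <- fake_run(c("b_elt-1", "v_egl-18_ceh-16r", "k_ceh-16_r"))
  runs <- c(list(r_all),
            replicate(19, fake_run("b_elt-1"), simplify = FALSE))
  pres <- parameter_presence(runs)
  p <- pres$parameters
  expect_equal(p$pct_all[p$name == "b_elt-1"], 100)
  # kept in 1 of 20 runs
  expect_equal(p$pct_all[p$name == "v_egl-18_ceh-16r"], 5)
  # 3 of 20
  runs2 <- c(replicate(3, fake_run(c("b_elt-1", "v_ceh-16_elt-1a")),
                       simplify = FALSE),
             replicate(17, fake_run("b_elt-1"), simplify = FALSE))
  pres2 <- parameter_presence(runs2)
  expect_equal(
    pres2$parameters$pct_all[pres2$parameters$name == "v_ceh-16_elt-1a"],
    15)
  lk <- pres2$links
  expect_equal(lk$pct_all[lk$link == "elt-1->ceh-16"], 15)
  expect_error(parameter_presence(list()), class = "seamnet_parameter_error")
})

test_that("link presence aggregates AND-blocks across variants", {
  # all-AND variant: one kept block rate realizes all three ceh-16 links
  spec20 <- enumerate_logic_variants(seam_topology("late-L1"))[[20]]
  r20 <- fake_run(c("b_elt-1", "v_ceh-16_ceh-16sa+egl-18a+elt-1a"),
                  spec = spec20)
  pres <- parameter_presence(list(r20))
  lk <- pres$links
  for (nm in c("elt-1->ceh-16", "egl-18->ceh-16", "ceh-16->ceh-16")) {
    expect_equal(lk$pct_all[lk$link == nm], 100)
    expect_equal(lk$pct_all_AND[lk$link == nm], 100)
    expect_true(is.na(lk$pct_all_OR[lk$link == nm]))
  }
  expect_equal(lk$pct_all[lk$link == "ceh-16->egl-18"], 0)
})

test_that("double-mutant filter applies the d <= 2.5 rule inclusively", {
  # run whose parameters are exactly the final-L1 ground truth
  panel <- cached_panel(n_animals = 60L, seed = 8L)
  spec <- panel$gt$model
  run <- fake_run(names(which(panel$gt$params$theta != 0)), spec = spec,
                  theta = panel$gt$params$theta)
  run$target_mu <- panel$states[, 1:4]
  dm <- genotype_activities("egl-18(ga97);ceh-16(bp323)", "ode")
  s_dm <- panel$states[, "egl-18(ga97);ceh-16(bp323)"]

  # median of a constant chain is that state; prediction = ground truth
  pred <- predict_genotype(run, dm)
  expect_equal(ss_vec(pred), unname(s_dm), tolerance = 1e-6)

  # build the targets around the run's own (deterministic) prediction
  # so the boundary distances are exact
  sigma <- matrix(2, 3, 1)
  mk_dm <- function(shift) fit_target(matrix(ss_vec(pred) + shift, ncol = 1),
                                      sigma, genes = seam_genes,
                                      genotypes = "dm")
  v0 <- filter_by_double_mutant(list(run), mk_dm(0), dm)
  expect_equal(v0$status, "kept")
  expect_equal(v0$d_dm, 0, tolerance = 1e-6)
  # d exactly 2.5 -> kept; d = 2.6 -> discarded
  v_at <- filter_by_double_mutant(list(run), mk_dm(2 * 2.5), dm)
  expect_equal(round(v_at$d_dm, 6), 2.5)
  expect_equal(v_at$status, "kept")
  v_over <- filter_by_double_mutant(list(run), mk_dm(2 * 2.6), dm)
  expect_equal(v_over$status, "discarded")
  # partition is exhaustive and disjoint
  runs <- list(run, run)
  v <- filter_by_double_mutant(runs, mk_dm(2 * 2.6), dm)
  expect_setequal(v$run, seq_along(runs))
  expect_true(all(v$status %in% c("kept", "discarded")))
  expect_error(
    filter_by_double_mutant(list(run), panel$target, dm),
    class = "seamnet_parameter_error")
})

test_that("final network deletes links absent in >= 90% of kept runs", {
  present <- fake_run(c("b_elt-1", "v_egl-18_ceh-16r", "k_ceh-16_r"))
  absent <- fake_run("b_elt-1")
  # absent in 95% (19/20) -> deleted
  net <- final_network(c(list(present), replicate(19, absent,
                                                  simplify = FALSE)))
  expect_false("ceh-16->egl-18" %in% net$link)
  # absent in 0% -> retained, sign annotated
  net2 <- final_network(replicate(5, present, simplify = FALSE))
  expect_true("ceh-16->egl-18" %in% net2$link)
  expect_equal(net2$sign[net2$link == "ceh-16->egl-18"], "repression")
  # boundary: absent in exactly 90% -> deleted
  net3 <- final_network(c(replicate(1, present, simplify = FALSE),
                          replicate(9, absent, simplify = FALSE)))
  expect_false("ceh-16->egl-18" %in% net3$link)
  # monotone in discard_fraction: raising the threshold never removes
  # additional links
  net_low <- final_network(c(replicate(3, present, simplify = FALSE),
                             replicate(7, absent, simplify = FALSE)),
                           discard_fraction = 0.5)
  net_high <- final_network(c(replicate(3, present, simplify = FALSE),
                              replicate(7, absent, simplify = FALSE)),
                            discard_fraction = 0.95)
  expect_true(all(net_low$link %in% net_high$link))
  expect_error(final_network(list()), class = "seamnet_parameter_error")
})

test_that("cross-timepoint check returns z-scores and the ABC distance", {
  panel <- cached_panel(n_animals = 60L, seed = 8L)
  spec <- panel$gt$model
  run <- fake_run(names(which(panel$gt$params$theta != 0)), spec = spec,
                  theta = panel$gt$params$theta)
  run$target_mu <- panel$states[, 1:4]
  gts <- panel$genotypes
  same <- fit_target(panel$states[, 1:4], matrix(2, 3, 4))
  chk <- crosstimepoint_check(run, same, gts)
  expect_true(all(abs(chk$z) < 1e-5))
  expect_equal(chk$distance, abc_distance(chk$predicted, same))
  shifted <- fit_target(panel$states[, 1:4] + c(0, 8, 0), matrix(2, 3, 4))
  chk2 <- crosstimepoint_check(run, shifted, gts)
  expect_true(all(abs(chk2$z["egl-18", ]) > 3))
  expect_true(all(abs(chk2$z["elt-1", ]) < 1e-5))
})

test_that("report bundle is complete, deterministic, and degrades", {
  panel <- cached_panel(n_animals = 60L, seed = 8L)
  im <- bootstrap_mra(panel$dataset, "late-L1", n_iter = 20L, seed = 3L)
  pres <- parameter_presence(list(fake_run("b_elt-1")))
  dm <- genotype_activities("egl-18(ga97);ceh-16(bp323)", "ode")
  run <- fake_run(names(which(panel$gt$params$theta != 0)),
                  spec = panel$gt$model, theta = panel$gt$params$theta)
  run$target_mu <- panel$states[, 1:4]
  dm_target <- fit_target(panel$states[, 5, drop = FALSE], matrix(2, 3, 1))
  val <- filter_by_double_mutant(list(run), dm_target, dm)
  net <- final_network(list(run))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    report(d, summary_stats = panel$stats, mra = im, presence = pres,
           validation = val, network = net,
           manifest = list(seed = 1L))
  }
  expected <- c("summary_stats.csv", "mra_edges.csv", "mra_mean_matrix.csv",
                "presence_parameters.csv", "presence_links.csv",
                "validation_partition.csv", "final_network.csv",
                "manifest.json", "summary.txt")
  expect_setequal(list.files(d1), expected)
  for (f in expected) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = sprintf("%s byte-identical", f))
  }
  d3 <- withr::local_tempdir()
  expect_warning(report(d3, summary_stats = panel$stats),
                 "MRA")
  expect_error(report(withr::local_tempdir()),
               class = "seamnet_parameter_error")
})

test_that("scaled-down pipeline retains the generating links", {
  panel <- cached_panel()
  spec1 <- enumerate_logic_variants(seam_topology("late-L1"))[[1]]
  cfg <- sling_config(n_sweeps = 2000L, n_chains = 4L, seed = 23L)
  runs <- sling_chains(spec1, panel$target, panel$genotypes, cfg)
  dm <- genotype_activities("egl-18(ga97);ceh-16(bp323)", "ode")
  dm_stats <- panel$stats[panel$stats$genotype ==
                            "egl-18(ga97);ceh-16(bp323)", ]
  dm_target <- fit_target_from_summary(dm_stats)
  val <- filter_by_double_mutant(runs, dm_target, dm)
  kept_runs <- runs[val$status == "kept"]
  expect_gte(length(kept_runs), 1L)
  net <- final_network(kept_runs)
  expect_true("ceh-16->egl-18" %in% net$link)
  expect_true("egl-18->ceh-16" %in% net$link)
  expect_equal(net$sign[net$link == "ceh-16->egl-18"], "repression")
})
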