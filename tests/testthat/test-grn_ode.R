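`%+%` <- function(a, b) paste0(a, b)

# Brute-force set-partition counter used as an independent oracle:
# enumerate all assignment vectors and keep canonical (restricted
# growth) ones.
count_partitions_bruteforce <- function(n) {
  if (n == 0L) return(1L)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  ok <- apply(grid, 1L, function(a) {
    seen <- integer(0)
    for (v in a) {
      if (!v %in% seen) {
        if (v != length(seen) + 1L) return(FALSE)
        seen <- c(seen, v)
      }
    }
    TRUE
  })
  sum(ok)
}

test_that("logic-variant enumeration counts follow Bell numbers", {
  for (n in 0:4) {
    expect_equal(length(seamnet:::set_partitions(n)),
                 count_partitions_bruteforce(n))
  }
  # one gene, one regulator -> single variant
  topo1 <- grn_topology(regulation_term("g1", "g2"), genes = c("g1", "g2"))
  expect_length(enumerate_logic_variants(topo1), 1L)
  # one gene, three regulators -> the five partitions
  topo3 <- grn_topology(
    regulation_term("g1", "a"), regulation_term("g1", "b"),
    regulation_term("g1", "c"),
    genes = c("g1", "a", "b", "c"))
  vs <- enumerate_logic_variants(topo3)
  expect_length(vs, 5L)
  sizes <- lapply(vs, function(s)
    sort(vapply(s$partition$g1, length, integer(1L))))
  expect_equal(sizes[[1]], c(1L, 1L, 1L))  # all-OR first
  expect_equal(sizes[[5]], 3L)             # all-AND last
})

test_that("late-L1 topology yields the 20 documented variants", {
  vs <- enumerate_logic_variants(seam_topology("late-L1"))
  expect_length(vs, 20L)
  nblocks <- function(s) vapply(s$partition, length, integer(1L))
  expect_equal(unname(nblocks(vs[[1]])), c(2L, 2L, 3L))   # all-OR
  expect_equal(unname(nblocks(vs[[20]])), c(1L, 1L, 1L))  # all-AND
  expect_equal(vapply(vs, `[[`, integer(1L), "variant_id"), 1:20)
  # parameter sharing: all-OR has 14 free parameters, all-AND 10,
  # with one k per regulator gene and role (k1, k2, k3, k3s)
  expect_equal(nrow(param_table(vs[[1]])), 14L)
  expect_equal(nrow(param_table(vs[[20]])), 10L)
  kn <- param_table(vs[[1]])
  expect_setequal(kn$name[kn$class == "k"],
                  c("k_elt-1_a", "k_egl-18_a", "k_ceh-16_r", "k_ceh-16_a"))
})

test_that("Hill functions honor half-occupation and k = 0 conventions", {
  expect_equal(hill_activation(g = 8, f = 1, v = 6, k = 8), 3)   # v/2
  expect_equal(hill_activation(g = 16, f = 0.5, v = 6, k = 8), 3)
  expect_equal(hill_activation(g = 0, v = 5, k = 2), 0)
  expect_equal(hill_activation(g = 2, f = 1, v = 10, k = 0), 10)
  expect_equal(hill_activation(g = 0, v = 10, k = 0), 0)  # degenerate input
  expect_equal(hill_repression(g = 0, v = 7, k = 3), 7)
  expect_equal(hill_repression(g = 2, v = 7, k = 0), 0)
  expect_equal(hill_repression(g = 8, f = 1, v = 6, k = 8), 3)
  # cooperativity steepens the response around k
  expect_gt(hill_activation(12, v = 1, k = 8, alpha = 3),
            hill_activation(12, v = 1, k = 8, alpha = 1))
})

test_that("RHS builder composes basal, OR and AND terms correctly", {
  vs <- enumerate_logic_variants(seam_topology("late-L1"))
  basal <- preset_ground_truth("basal-only")
  wt <- genotype_activities("wild type", "ode")
  rhs <- build_rhs(basal$model, basal$params, wt)
  g <- c(4, 10, 2)
  expect_equal(rhs(g), c(30, 25, 40) - g)

  # model 1 with all v = 0 reduces to basal-only
  p0 <- parameter_set(vs[[1]], c("b_elt-1" = 30, "b_egl-18" = 25,
                                 "b_ceh-16" = 40))
  expect_equal(build_rhs(vs[[1]], p0, wt)(g), c(30, 25, 40) - g)

  # hand-composed evaluation of the AND/OR structure for ceh-16:
  # block {activation by ELT-1 AND by EGL-18} OR {self-activation}
  spec <- Filter(function(s) {
    "v_ceh-16_egl-18a+elt-1a" %in% param_table(s)$name &&
      "v_ceh-16_ceh-16sa" %in% param_table(s)$name &&
      nrow(param_table(s)) == 13L  # elt-1 and egl-18 still all-OR
  }, vs)[[1]]
  pt <- param_table(spec)
  vals <- c("b_ceh-16" = 3, "v_ceh-16_egl-18a+elt-1a" = 12,
            "v_ceh-16_ceh-16sa" = 7,
            "k_elt-1_a" = 5, "k_egl-18_a" = 4, "k_ceh-16_a" = 6)
  ps <- parameter_set(spec, vals)
  mut <- genotype_activities("ceh-16(bp323)", "ode")  # f3 = 0.25
  g <- c(10, 10, 10)
  hand <- 3 +
    12 * (10 / (5 + 10)) * (10 / (4 + 10)) +
    7 * (10 * 0.25 / (6 + 10 * 0.25)) -
    10
  expect_equal(build_rhs(spec, ps, mut)(g)[3], hand)
  expect_error(parameter_set(spec, c(nonsense = 1)),
               class = "seamnet_parameter_error")
})

test_that("compiled RHS agrees with the pure-R reference on every variant", {
  vs <- enumerate_logic_variants(seam_topology("late-L1"))
  gts <- genotype_panel_specs(stage = "ode")
  withr::with_seed(77, {
    for (spec in vs[c(1, 3, 7, 13, 20)]) {
      pt <- param_table(spec)
      th <- stats::setNames(runif(nrow(pt), 0, 60), pt$name)
      ps <- parameter_set(spec, th)
      desc <- seamnet:::compile_model(spec, ps)
      for (gt in gts[c(1, 4)]) {
        g <- runif(3, 0, 80)
        expect_equal(
          seamnet:::cpp_rhs(desc, ps$theta,
                            as.numeric(gt$activities[spec$genes]), g),
          unname(build_rhs(spec, ps, gt)(g)),
          tolerance = 1e-12)
      }
    }
  })
})

test_that("steady states match closed-form oracles", {
  basal <- preset_ground_truth("basal-only")
  wt <- genotype_activities("wild type", "ode")
  s <- steady_state(basal$model, basal$params, wt, g0 = c(1, 1, 1))
  expect_equal(ss_vec(s), c(30, 25, 40), tolerance = 1e-6)

  # single-gene self-activation: dg/dt = b + v g/(k+g) - g
  topo <- grn_topology(regulation_term("g1", "g1"), genes = "g1")
  spec <- ode_model_spec(topo)
  ps <- parameter_set(spec, c("b_g1" = 1, "v_g1_g1sa" = 4, "k_g1_a" = 2))
  gwt <- genotype_spec("wt", c(g1 = 1))
  s1 <- steady_state(spec, ps, gwt, g0 = 1)
  oracle <- self_activation_root(1, 4, 2)
  # positive root of g^2 - 3g - 2 (direct substitution confirms the
  # fixed point: 1 + 4*3.5616/5.5616 = 3.5616)
  expect_equal(oracle, (3 + sqrt(17)) / 2)
  expect_equal(ss_vec(s1), oracle, tolerance = 1e-6)
})

test_that("steady states stay non-negative and bounded by production", {
  vs <- enumerate_logic_variants(seam_topology("late-L1"))
  gts <- genotype_panel_specs(stage = "ode")
  withr::with_seed(55, {
    for (rep in 1:10) {
      spec <- vs[[sample(20, 1)]]
      pt <- param_table(spec)
      th <- stats::setNames(runif(nrow(pt), 0, 50), pt$name)
      ps <- parameter_set(spec, th)
      S <- genotype_panel(spec, ps, gts, init = runif(3, 0, 60))
      expect_true(all(S >= 0))
      vmax <- vapply(spec$genes, function(g) {
        vn <- pt$name[pt$class == "v" & pt$target == g]
        th[["b_" %+% g]] + sum(th[vn])
      }, numeric(1L), USE.NAMES = FALSE)
      expect_true(all(S <= vmax + 1e-6))
    }
  })
})

test_that("genotype differences enter only through activity fractions", {
  panel <- cached_panel(n_animals = 60L, seed = 8L)
  gt <- panel$gt
  wt <- genotype_activities("wild type", "ode")
  mut <- genotype_activities("ceh-16(bp323)", "ode")
  s_wt <- steady_state(gt$model, gt$params, wt, g0 = c(10, 10, 10))
  s_mut <- steady_state(gt$model, gt$params, mut, g0 = c(10, 10, 10))
  expect_false(isTRUE(all.equal(ss_vec(s_wt), ss_vec(s_mut))))
  # a genotype with all activities 1 equals wild type
  clone <- genotype_spec("clone", stats::setNames(rep(1, 3), seam_genes))
  s_clone <- steady_state(gt$model, gt$params, clone, g0 = c(10, 10, 10))
  expect_equal(ss_vec(s_clone), ss_vec(s_wt), tolerance = 1e-8)
  # m = 1 panel equals a single steady_state call
  P <- genotype_panel(gt$model, gt$params, list(mut),
                      init = c(10, 10, 10))
  expect_equal(unname(P[, 1]), ss_vec(s_mut), tolerance = 1e-10)
})

test_that("final-family equations arise as restrictions of the 20 variants", {
  vs <- enumerate_logic_variants(seam_topology("late-L1"))
  wt <- genotype_activities("wild type", "ode")
  g <- c(12, 20, 35)
  b1 <- 30; v2 <- 60; v3 <- 40; k1 <- 30; k2 <- 20; k3 <- 40

  # Eq4 + Eq5 + Eq8 (all-OR variant with the other parameters zeroed)
  ps <- parameter_set(vs[[1]], c(
    "b_elt-1" = b1, "v_egl-18_ceh-16r" = v2,
    "v_ceh-16_elt-1a" = v3, "v_ceh-16_egl-18a" = v3,
    "k_elt-1_a" = k1, "k_egl-18_a" = k2, "k_ceh-16_r" = k3))
  hand <- c(
    b1 - g[1],
    v2 * k3 / (k3 + g[3]) - g[2],
    v3 * g[1] / (k1 + g[1]) + v3 * g[2] / (k2 + g[2]) - g[3])
  expect_equal(unname(build_rhs(vs[[1]], ps, wt)(g)), hand)

  # Eq4 + Eq6 + Eq7: egl-18 AND-block {activation by ELT-1, repression
  # by CEH-16}; ceh-16 AND-block {activation by ELT-1, by EGL-18} with
  # the self-loop OR'd and zeroed
  target_spec <- Filter(function(s) {
    length(s$partition[["egl-18"]]) == 1L &&
      length(s$partition[["ceh-16"]]) == 2L &&
      any(vapply(s$partition[["ceh-16"]], length, 1L) == 2L) &&
      length(s$partition[["elt-1"]]) == 2L
  }, vs)
  # the two-block ceh-16 partitions include {a1,a2|self}; find it
  ok <- Filter(function(s) {
    blk <- s$partition[["ceh-16"]]
    two <- blk[[which(vapply(blk, length, 1L) == 2L)]]
    terms <- s$terms[s$terms_by_gene[["ceh-16"]][two], ]
    all(!terms$self)
  }, target_spec)
  expect_gte(length(ok), 1L)
  spec2 <- ok[[1]]
  pt2 <- param_table(spec2)
  vname_egl <- pt2$name[pt2$class == "v" & pt2$target == "egl-18"]
  blk <- spec2$partition[["ceh-16"]]
  two <- which(vapply(blk, length, 1L) == 2L)
  vname_ceh <- pt2$name[pt2$class == "v" & pt2$target == "ceh-16" &
                          pt2$block == two]
  ps2 <- parameter_set(spec2, stats::setNames(
    c(b1, v2, v3, k1, k2, k3),
    c("b_elt-1", vname_egl, vname_ceh, "k_elt-1_a", "k_egl-18_a",
      "k_ceh-16_r")))
  hand2 <- c(
    b1 - g[1],
    v2 * (g[1] / (k1 + g[1])) * (k3 / (k3 + g[3])) - g[2],
    v3 * (g[1] / (k1 + g[1])) * (g[2] / (k2 + g[2])) - g[3])
  expect_equal(unname(build_rhs(spec2, ps2, wt)(g)), hand2)
})
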