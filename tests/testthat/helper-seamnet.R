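# Shared fixtures, built in code at test time.

seam_genes <- c("elt-1", "egl-18", "ceh-16")

# A small hand-written count table: 2 genes x 2 genotypes, 3 animals of
# 2 cells each (V1/V2), plus head-lineage cells for filter tests.
tiny_records <- function() {
  expand <- expand.grid(
    gene = c("elt-1", "egl-18"), genotype = c("wild type", "ceh-16(bp323)"),
    animal_id = c("a1", "a2", "a3"), cell_id = c("V1", "V2"),
    stringsAsFactors = FALSE
  )
  # animal ids are globally unique (one animal has one genotype)
  expand$animal_id <- paste0(ifelse(expand$genotype == "wild type",
                                    "wt_", "mut_"), expand$animal_id)
  expand$timepoint <- "late-L1"
  expand$count <- seq_len(nrow(expand)) %% 7 + 3L
  expand[, c("gene", "genotype", "timepoint", "animal_id", "cell_id",
             "count")]
}

tiny_dataset <- function() expression_dataset(tiny_records())

# Generated late-L1 panel reused by the heavier fitting tests (cached
# across tests within one session).
.seamnet_cache <- new.env(parent = emptyenv())

cached_panel <- function(n_animals = 200L, seed = 5L) {
  key <- sprintf("panel_%d_%d", n_animals, seed)
  if (is.null(.seamnet_cache[[key]])) {
    gt <- preset_ground_truth("final-L1", n_animals = n_animals, seed = seed)
    ds <- generate_dataset(gt)
    st <- summarize_expression(ds, "late-L1", n_boot = 1000L, seed = 2L)
    singles <- c("wild type", "elt-1(ku491)", "egl-18(ga97)",
                 "ceh-16(bp323)")
    target <- fit_target_from_summary(
      st[st$genotype %in% singles, , drop = FALSE], genotypes = singles)
    .seamnet_cache[[key]] <- list(
      gt = gt, dataset = ds, stats = st, target = target,
      genotypes = genotype_panel_specs(singles, stage = "ode"),
      states = ground_truth_states(gt)
    )
  }
  .seamnet_cache[[key]]
}

# Quick sampler profile for unit tests (not the acceptance profile).
quick_config <- function(...) {
  sling_config(n_sweeps = 400L, n_starts = 2L, ...)
}

# Independent quadratic-root oracle for the single-gene
# self-activation fixed point b + v g/(k+g) - d g = 0.
self_activation_root <- function(b, v, k, d = 1) {
  # d g (k+g) = b (k+g) + v g  =>  d g^2 + (d k - b - v) g - b k = 0
  a2 <- d; a1 <- d * k - b - v; a0 <- -b * k
  (-a1 + sqrt(a1^2 - 4 * a2 * a0)) / (2 * a2)
}

# steady_state() return values carry a `converged` attribute; strip it
# for plain numeric comparisons.
ss_vec <- function(s) as.vector(s)
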