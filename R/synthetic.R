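# Synthetic smFISH-like count generator with a known ground-truth
# network: per-animal log-normal extrinsic factor (unit mean, shared
# across genes and cells of the animal) times Poisson intrinsic noise
# around the genotype steady state of the ground-truth ODE model.

#' Construct a ground truth for synthetic data generation
#'
#' @param model an [ode_model_spec()].
#' @param params a [parameter_set()] for `model`.
#' @param genotype_specs list of [genotype_spec()] objects; one block of
#'   animals is generated per genotype.
#' @param extrinsic_cv coefficient of variation of the shared per-animal
#'   extrinsic factor (>= 0; 0 gives pure Poisson counts).
#' @param n_animals animals per genotype.
#' @param cells_per_animal measured cells per animal (>= 2; labelled
#'   V1, V2, ...).
#' @param seed integer seed making the generated dataset fully
#'   reproducible.
#' @param timepoint timepoint label attached to the records.
#' @param shared_across_genes if `TRUE` (default) one extrinsic factor
#'   per animal is shared by all genes; if `FALSE` each gene draws its
#'   own.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(model, params, genotype_specs, extrinsic_cv = 0.8,
                         n_animals = 60L, cells_per_animal = 2L, seed = 1L,
                         timepoint = "late-L1", shared_across_genes = TRUE) {
  if (extrinsic_cv < 0) {
    stop_seamnet("extrinsic_cv must be >= 0", "seamnet_parameter_error")
  }
  if (cells_per_animal < 2L) {
    stop_seamnet("cells_per_animal must be >= 2", "seamnet_parameter_error")
  }
  structure(
    list(model = model, params = params, genotype_specs = genotype_specs,
         extrinsic_cv = extrinsic_cv, n_animals = as.integer(n_animals),
         cells_per_animal = as.integer(cells_per_animal),
         seed = as.integer(seed), timepoint = timepoint,
         shared_across_genes = shared_across_genes),
    class = "ground_truth"
  )
}

#' Steady-state panel of a ground truth
#'
#' @param gt a [ground_truth()].
#' @return Matrix (genes x genotypes) of ground-truth steady states.
#' @export
ground_truth_states <- function(gt) {
  genotype_panel(gt$model, gt$params, gt$genotype_specs,
                 init = rep(10, length(gt$model$genes)))
}

#' Generate a synthetic count dataset
#'
#' For each genotype the steady state `s_i` of the ground-truth model is
#' computed; each animal draws an extrinsic factor `E_a` from a
#' unit-mean log-normal with CV `extrinsic_cv` (shared across genes and
#' cells of the animal) and each cell's count is Poisson(`E_a * s_i`).
#' This mixed-Poisson model reproduces the hallmarks of smFISH seam-cell
#' data: Fano factor `1 + cv^2 * s` well above 1 and strongly positive
#' same-gene correlation between cells of one animal.
#'
#' @param gt a [ground_truth()].
#' @return An [expression_dataset()]; identical for identical `gt`.
#' @export
generate_dataset <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  S <- ground_truth_states(gt)
  if (any(!is.finite(S))) {
    stop_seamnet("ground-truth steady state is not finite",
                 "seamnet_convergence_error")
  }
  genes <- gt$model$genes
  n_g <- length(genes)
  cv2 <- gt$extrinsic_cv^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- -sdlog^2 / 2  # unit mean
  cells <- paste0("V", seq_len(gt$cells_per_animal))
  blocks <- list()
  withr::with_seed(gt$seed, {
    for (j in seq_along(gt$genotype_specs)) {
      gname <- gt$genotype_specs[[j]]$name
      for (a in seq_len(gt$n_animals)) {
        aid <- sprintf("g%d_a%04d", j, a)
        if (gt$shared_across_genes) {
          E <- rep(stats::rlnorm(1L, meanlog, sdlog), n_g)
        } else {
          E <- stats::rlnorm(n_g, meanlog, sdlog)
        }
        if (gt$extrinsic_cv == 0) E <- rep(1, n_g)
        lam <- E * S[, j]
        cnt <- stats::rpois(n_g * gt$cells_per_animal,
                            rep(lam, times = gt$cells_per_animal))
        blocks[[length(blocks) + 1L]] <- data.frame(
          gene = rep(genes, times = gt$cells_per_animal),
          genotype = gname, timepoint = gt$timepoint, animal_id = aid,
          cell_id = rep(cells, each = n_g), count = cnt,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  expression_dataset(
    do.call(rbind, blocks), genes = genes,
    genotypes = vapply(gt$genotype_specs, `[[`, "", "name")
  )
}

#' Expected paired-cell correlation under the mixed-Poisson model
#'
#' Closed-form oracle for [paired_cell_correlation()] on generated
#' data: two cells of one animal share the extrinsic factor, so their
#' counts correlate as `cv^2 s / (1 + cv^2 s)` (law of total
#' covariance). Tends to 0 as `cv -> 0` and to 1 as `s -> Inf`.
#'
#' @param extrinsic_cv extrinsic coefficient of variation (>= 0).
#' @param s mean expression (> 0).
#' @return Expected Pearson correlation.
#' @export
paired_correlation_expected <- function(extrinsic_cv, s) {
  if (any(s <= 0)) stop_seamnet("s must be > 0", "seamnet_parameter_error")
  x <- extrinsic_cv^2 * s
  x / (1 + x)
}

#' Shipped ground-truth presets
#'
#' Fully parameterized ground truths at the late-L1 stage whose
#' wild-type steady states lie in the tens-of-counts range and whose
#' generated CVs fall in the 0.6-1.2 band at the default extrinsic CV
#' of 0.8:
#'
#' * `"final-L1"`: the validated reduced network (elt-1 basal only;
#'   egl-18 repressed by CEH-16; ceh-16 activated by ELT-1 OR EGL-18).
#'   Because of the repression, egl-18 steady state is strictly higher
#'   in the ceh-16 hypomorph than in wild type.
#' * `"literature"`: the naive all-activation network, where egl-18 is
#'   instead strictly lower in the ceh-16 hypomorph.
#' * `"basal-only"`: no regulation; steady states are `b_i / d_i`.
#'
#' @param name preset name.
#' @param n_animals,cells_per_animal,extrinsic_cv,seed,timepoint
#'   passed to [ground_truth()].
#' @return A [ground_truth()].
#' @export
preset_ground_truth <- function(name = c("final-L1", "literature",
                                         "basal-only"),
                                n_animals = 60L, cells_per_animal = 2L,
                                extrinsic_cv = 0.8, seed = 1L,
                                timepoint = "late-L1") {
  name <- match.arg(name)
  genotypes <- genotype_panel_specs(stage = "ode")
  if (name == "basal-only") {
    topo <- grn_topology(
      data.frame(target = character(0), regulator = character(0),
                 sign = character(0), self = logical(0)),
      genes = SEAM_GENES
    )
    spec <- ode_model_spec(topo, variant_id = 1L)
    params <- parameter_set(spec, c("b_elt-1" = 30, "b_egl-18" = 25,
                                    "b_ceh-16" = 40))
  } else if (name == "final-L1") {
    spec <- ode_model_spec(seam_topology("final-L1"), variant_id = 1L)
    params <- parameter_set(spec, c(
      "b_elt-1" = 30,
      "v_egl-18_ceh-16r" = 60, "v_ceh-16_elt-1a" = 40,
      "v_ceh-16_egl-18a" = 40,
      "k_elt-1_a" = 30, "k_egl-18_a" = 20, "k_ceh-16_r" = 40
    ))
  } else {
    spec <- ode_model_spec(seam_topology("literature"), variant_id = 1L)
    params <- parameter_set(spec, c(
      "b_elt-1" = 30, "b_egl-18" = 2, "b_ceh-16" = 5,
      "v_egl-18_elt-1a" = 30, "v_egl-18_ceh-16a" = 30,
      "v_ceh-16_elt-1a" = 50,
      "k_elt-1_a" = 30, "k_ceh-16_a" = 40
    ))
  }
  ground_truth(spec, params, genotypes, extrinsic_cv = extrinsic_cv,
               n_animals = n_animals, cells_per_animal = cells_per_animal,
               seed = seed, timepoint = timepoint)
}

#' Serialize a ground truth as JSON
#'
#' Archives the generating model, parameters and noise settings beside
#' a simulated CSV so a dataset is traceable to its generator.
#'
#' @param gt a [ground_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  doc <- list(
    genes = gt$model$genes,
    variant_id = gt$model$variant_id,
    signed = gt$model$signed,
    terms = gt$model$terms,
    partition = gt$model$partition,
    theta = as.list(gt$params$theta),
    alpha = as.list(gt$params$alpha),
    d = as.list(gt$params$d),
    genotypes = lapply(gt$genotype_specs, function(s)
      list(name = s$name, activities = as.list(s$activities))),
    extrinsic_cv = gt$extrinsic_cv, n_animals = gt$n_animals,
    cells_per_animal = gt$cells_per_animal, seed = gt$seed,
    timepoint = gt$timepoint,
    shared_across_genes = gt$shared_across_genes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
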