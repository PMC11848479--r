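# Data model, file I/O and summary statistics for single-cell transcript
# counts across genotypes and timepoints.

DATASET_COLUMNS <- c("gene", "genotype", "timepoint", "animal_id",
                     "cell_id", "count")

#' Construct an expression dataset
#'
#' A long-format table of single-cell transcript counts. Each record is
#' one gene measured in one cell of one animal: columns `gene`,
#' `genotype`, `timepoint`, `animal_id`, `cell_id` (lineage label such
#' as `"V1"`) and `count` (non-negative integer mRNA spots per cell).
#'
#' @param records data.frame with the columns above.
#' @param genes ordered character vector of gene labels; defaults to the
#'   genes present, in order of first appearance.
#' @param genotypes ordered character vector of genotype labels.
#' @return An object of class `expression_dataset` (a data.frame with
#'   `genes` and `genotypes` attributes).
#' @export
expression_dataset <- function(records, genes = NULL, genotypes = NULL) {
  missing_cols <- setdiff(DATASET_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop_seamnet(
      sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      "seamnet_format_error"
    )
  }
  records <- as.data.frame(records)[DATASET_COLUMNS]
  for (col in setdiff(DATASET_COLUMNS, "count")) {
    records[[col]] <- as.character(records[[col]])
  }
  cnt <- records$count
  if (is.character(cnt)) cnt <- suppressWarnings(as.numeric(cnt))
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0L) {
    stop_seamnet(
      sprintf("count must be a non-negative integer; offending row(s): %s",
              paste(utils::head(bad, 5L), collapse = ", ")),
      "seamnet_validation_error"
    )
  }
  records$count <- as.integer(round(cnt))
  if (is.null(genes)) genes <- unique(records$gene)
  if (is.null(genotypes)) genotypes <- unique(records$genotype)
  if (!all(records$gene %in% genes)) {
    stop_seamnet("records contain genes outside the declared gene list",
                 "seamnet_validation_error")
  }
  if (!all(records$genotype %in% genotypes)) {
    stop_seamnet("records contain genotypes outside the declared list",
                 "seamnet_validation_error")
  }
  key <- paste(records$animal_id, records$cell_id, records$gene,
               records$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    stop_seamnet("duplicate (animal_id, cell_id, gene, timepoint) records",
                 "seamnet_validation_error")
  }
  structure(records, genes = genes, genotypes = genotypes,
            class = c("expression_dataset", "data.frame"))
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d records | %d gene(s) | %d genotype(s) | %d timepoint(s)\n",
    nrow(x), length(attr(x, "genes")), length(attr(x, "genotypes")),
    length(unique(x$timepoint))
  ))
  invisible(x)
}

#' Read a count dataset from CSV
#'
#' Reads a UTF-8 CSV with header
#' `gene,genotype,timepoint,animal_id,cell_id,count` and validates it.
#'
#' @param path file path.
#' @param lineage_filter optional character vector of cell lineage
#'   labels; rows whose `cell_id` is not in the set are dropped (e.g.
#'   `c("V1","V2","V3","V4")` to restrict to V1-V4 seam cells).
#' @param genes,genotypes optional declared label orders, passed on to
#'   [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(path, lineage_filter = NULL, genes = NULL,
                         genotypes = NULL) {
  if (!file.exists(path)) {
    stop_seamnet(sprintf("file not found: %s", path), "seamnet_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop_seamnet(
      sprintf("%s: missing column(s): %s", path,
              paste(missing_cols, collapse = ", ")),
      "seamnet_format_error"
    )
  }
  if (!is.null(lineage_filter)) {
    raw <- raw[raw$cell_id %in% lineage_filter, , drop = FALSE]
  }
  expression_dataset(raw, genes = genes, genotypes = genotypes)
}

#' Write a count dataset to CSV
#'
#' Inverse of [read_dataset()]: writes the standard six-column header so
#' that a read/write round trip preserves all records exactly.
#'
#' @param dataset an [expression_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  utils::write.csv(as.data.frame(dataset)[DATASET_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Fano factor of a count vector
#'
#' Sample variance (denominator n-1) divided by the mean. Equals 1 for
#' a Poisson process; values well above 1 indicate super-Poissonian
#' (e.g. shared extrinsic) variability.
#'
#' @param values numeric vector of counts, length >= 2, mean > 0.
#' @return Dimensionless Fano factor.
#' @export
fano_factor <- function(values) {
  if (length(values) < 2L) {
    stop_seamnet("need at least 2 values", "seamnet_parameter_error")
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop_seamnet("Fano factor undefined for mean <= 0",
                 "seamnet_undefined_error")
  }
  stats::var(values) / m
}

#' Coefficient of variation of a count vector
#'
#' Sample standard deviation divided by the mean; invariant to scaling
#' all values by a positive constant.
#'
#' @inheritParams fano_factor
#' @return Dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop_seamnet("need at least 2 values", "seamnet_parameter_error")
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop_seamnet("CV undefined for mean <= 0", "seamnet_undefined_error")
  }
  stats::sd(values) / m
}

#' Bootstrap summary statistics per gene and genotype
#'
#' For every gene x genotype group at one timepoint, cells are resampled
#' with replacement `n_boot` times; the reported mean `mu` is the mean
#' of the per-resample means and `sigma` is their standard deviation
#' (i.e. a bootstrap standard error of the mean, the uncertainty scale
#' later used by the ABC distance). Fano factor and CV are computed on
#' the raw counts of the group.
#'
#' @param dataset an [expression_dataset()].
#' @param timepoint timepoint label to summarize.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param genes,genotypes optional subsets (default: all declared labels
#'   present at the timepoint).
#' @return A data.frame of class `summary_stats` with one row per
#'   gene x genotype: `gene`, `genotype`, `timepoint`, `mu`, `sigma`,
#'   `fano`, `cv`, `paired_correlation` (NA when not computable),
#'   `n_cells`.
#' @export
summarize_expression <- function(dataset, timepoint, n_boot = 1000L,
                                 seed = 1L, genes = NULL, genotypes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (n_boot < 1L) {
    stop_seamnet("n_boot must be >= 1", "seamnet_parameter_error")
  }
  df <- dataset[dataset$timepoint == timepoint, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_seamnet(sprintf("no records at timepoint '%s'", timepoint),
                 "seamnet_empty_group_error")
  }
  if (is.null(genes)) genes <- attr(dataset, "genes")
  if (is.null(genotypes)) {
    genotypes <- intersect(attr(dataset, "genotypes"), unique(df$genotype))
  }
  rows <- vector("list", length(genes) * length(genotypes))
  idx <- 0L
  withr::with_seed(seed, {
    for (g in genes) {
      for (gt in genotypes) {
        counts <- df$count[df$gene == g & df$genotype == gt]
        n <- length(counts)
        if (n == 0L) {
          stop_seamnet(
            sprintf("no cells for gene '%s', genotype '%s' at timepoint '%s'",
                    g, gt, timepoint),
            "seamnet_empty_group_error"
          )
        }
        bm <- rowMeans(matrix(
          sample(counts, n * n_boot, replace = TRUE), nrow = n_boot
        ))
        pc <- tryCatch(
          paired_cell_correlation(dataset, g, gt, timepoint),
          seamnet_error = function(e) NA_real_
        )
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          gene = g, genotype = gt, timepoint = timepoint,
          mu = mean(bm),
          sigma = if (n_boot > 1L) stats::sd(bm) else 0,
          fano = if (n >= 2L && mean(counts) > 0) fano_factor(counts) else NA_real_,
          cv = if (n >= 2L && mean(counts) > 0) coefficient_of_variation(counts) else NA_real_,
          paired_correlation = pc,
          n_cells = n,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- do.call(rbind, rows[seq_len(idx)])
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Paired-cell expression correlation within animals
#'
#' Pearson correlation of the expression of one gene between two cells
#' of the same animal. Pairing is deterministic: per animal the two
#' cells with the lowest lineage labels (lexicographic sort of
#' `cell_id`) are used; animals contributing fewer than two cells are
#' dropped. A strong positive correlation indicates shared animal-level
#' extrinsic variability.
#'
#' @param dataset an [expression_dataset()].
#' @param gene,genotype,timepoint group selectors.
#' @param lineages cell lineage labels eligible for pairing (default
#'   V1-V4).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
paired_cell_correlation <- function(dataset, gene, genotype, timepoint,
                                    lineages = c("V1", "V2", "V3", "V4")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- dataset[dataset$gene == gene & dataset$genotype == genotype &
                  dataset$timepoint == timepoint &
                  dataset$cell_id %in% lineages, , drop = FALSE]
  pairs <- lapply(split(df, df$animal_id), function(a) {
    if (nrow(a) < 2L) return(NULL)
    a <- a[order(a$cell_id), , drop = FALSE]
    c(a$count[1L], a$count[2L])
  })
  pairs <- pairs[!vapply(pairs, is.null, logical(1L))]
  if (length(pairs) < 3L) {
    stop_seamnet(
      sprintf("need >= 3 animals with >= 2 cells for gene '%s', genotype '%s'",
              gene, genotype),
      "seamnet_insufficient_data_error"
    )
  }
  m <- do.call(rbind, pairs)
  if (stats::sd(m[, 1L]) == 0 || stats::sd(m[, 2L]) == 0) {
    stop_seamnet("paired correlation undefined: a pair member is constant",
                 "seamnet_undefined_error")
  }
  stats::cor(m[, 1L], m[, 2L])
}

# ---------------------------------------------------------------------
# Genotype activity fractions

#' Construct a genotype specification
#'
#' A genotype is described by an activity fraction per gene: the
#' fraction of fully functional protein produced per unit mRNA relative
#' to wild type. Wild type has all activities 1; a hypomorphic allele
#' reduces its gene's activity to gamma in `[0, 1)`.
#'
#' @param name genotype label.
#' @param activities named numeric vector in `[0, 1]`, one entry per
#'   gene (names = gene labels).
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, activities) {
  if (is.null(names(activities)) || any(!nzchar(names(activities)))) {
    stop_seamnet("activities must be a named vector (names = genes)",
                 "seamnet_parameter_error")
  }
  if (any(activities < 0 | activities > 1)) {
    stop_seamnet("activities must lie in [0, 1]", "seamnet_parameter_error")
  }
  structure(list(name = name, activities = activities),
            class = "genotype_spec")
}

# Stage-specific defaults for the reduced activity of each mutant
# allele. The partial-loss alleles (elt-1(ku491), ceh-16(bp323)) are
# modelled at 25% activity at both stages; the strong-loss allele
# egl-18(ga97) is modelled at 0.01% activity in the MRA stage and at
# 1% in the ODE stage.
default_allele_activities <- function(stage) {
  switch(stage,
    ode = c("elt-1" = 0.25, "egl-18" = 0.01, "ceh-16" = 0.25),
    mra = c("elt-1" = 0.25, "egl-18" = 0.0001, "ceh-16" = 0.25),
    stop_seamnet("stage must be 'ode' or 'mra'", "seamnet_parameter_error")
  )
}

# Which genes carry a mutant allele in each canonical genotype.
canonical_genotype_alleles <- function() {
  list(
    "wild type" = character(0),
    "elt-1(ku491)" = "elt-1",
    "egl-18(ga97)" = "egl-18",
    "ceh-16(bp323)" = "ceh-16",
    "egl-18(ga97);ceh-16(bp323)" = c("egl-18", "ceh-16"),
    "ceh-16(bp323);egl-18(ga97)" = c("egl-18", "ceh-16")
  )
}

#' Activity fractions for a named genotype
#'
#' Maps a canonical genotype label to its per-gene activity vector.
#' The defaults differ by analysis stage: the MRA stage uses 0.0001 for
#' the strong-loss egl-18 allele (0.01% activity) while the ODE stage
#' uses 0.01; both stages use 0.25 for the partial-loss elt-1 and
#' ceh-16 alleles. All values can be overridden.
#'
#' @param genotype canonical genotype label (`"wild type"`,
#'   `"elt-1(ku491)"`, `"egl-18(ga97)"`, `"ceh-16(bp323)"`, or the
#'   double `"egl-18(ga97);ceh-16(bp323)"` in either allele order), or
#'   any label if `activities` is supplied explicitly.
#' @param stage `"ode"` or `"mra"`; selects the default activity of the
#'   strong-loss allele.
#' @param activities optional explicit named activity vector overriding
#'   the defaults entirely.
#' @param overrides optional named vector of per-allele activities (name
#'   = gene) replacing the stage default for that gene.
#' @param genes gene order for the returned vector.
#' @return A [genotype_spec()].
#' @export
genotype_activities <- function(genotype, stage = c("ode", "mra"),
                                activities = NULL, overrides = NULL,
                                genes = SEAM_GENES) {
  stage <- match.arg(stage)
  if (!is.null(activities)) {
    act <- rep(1, length(genes))
    names(act) <- genes
    act[names(activities)] <- activities
    return(genotype_spec(genotype, act))
  }
  alleles <- canonical_genotype_alleles()
  if (!genotype %in% names(alleles)) {
    stop_seamnet(
      sprintf("unknown genotype '%s'; supply explicit activities", genotype),
      "seamnet_unknown_genotype_error"
    )
  }
  defaults <- default_allele_activities(stage)
  if (!is.null(overrides)) defaults[names(overrides)] <- overrides
  act <- rep(1, length(genes))
  names(act) <- genes
  mutated <- alleles[[genotype]]
  act[mutated] <- defaults[mutated]
  genotype_spec(genotype, act)
}

#' Canonical genotype panel
#'
#' Convenience constructor for the standard five-genotype panel (wild
#' type, three single mutants, the egl-18;ceh-16 double) at one stage.
#'
#' @inheritParams genotype_activities
#' @param genotypes genotype labels to include.
#' @return Named list of [genotype_spec()] objects.
#' @export
genotype_panel_specs <- function(genotypes = SEAM_GENOTYPES,
                                 stage = c("ode", "mra"), overrides = NULL) {
  stage <- match.arg(stage)
  specs <- lapply(genotypes, genotype_activities, stage = stage,
                  overrides = overrides)
  names(specs) <- genotypes
  specs
}

#' Write a summary-statistics table to CSV
#'
#' @param stats a `summary_stats` data.frame from
#'   [summarize_expression()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
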