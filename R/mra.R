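# Modular Response Analysis adapted to hypomorphic alleles: activity-
# corrected central fractional differences, local response matrices and
# bootstrap network summaries.

#' Central fractional difference
#'
#' The response of a transcript to a perturbation, measured as the
#' finite difference of relative levels: `2 (x_mut f - x_wt) /
#' (x_mut f + x_wt)`. `f` converts the perturbed gene's own transcript
#' level into an effective working-protein level (activity fraction of
#' the mutant allele); for transcripts other than the mutated gene
#' `f = 1`. The value is bounded in the open interval (-2, 2).
#'
#' @param x_wt mean level in the reference (wild type), >= 0.
#' @param x_mut mean level in the perturbed genotype, >= 0.
#' @param f activity fraction in (0, 1].
#' @return Dimensionless response in (-2, 2) (attaining +/-2 only when
#'   one of the two levels is exactly zero).
#' @export
central_fractional_difference <- function(x_wt, x_mut, f = 1) {
  if (any(x_wt < 0) || any(x_mut < 0)) {
    stop_seamnet("mean levels must be non-negative",
                 "seamnet_parameter_error")
  }
  if (any(f <= 0) || any(f > 1)) {
    stop_seamnet("activity fraction f must lie in (0, 1]",
                 "seamnet_parameter_error")
  }
  num <- x_mut * f - x_wt
  den <- x_mut * f + x_wt
  if (any(den == 0)) {
    stop_seamnet("central fractional difference undefined: both levels zero",
                 "seamnet_undefined_error")
  }
  2 * num / den
}

#' Response matrix from a mean-expression table
#'
#' Builds the matrix of central fractional differences `R[i, j]` (gene
#' i responding, gene j perturbed) from wild-type and single-mutant
#' means. The activity fraction is applied only on the diagonal
#' (`f = gamma_i` when `i == j`, else 1): only the mutated gene's own
#' transcript needs conversion to an effective protein level.
#'
#' @param means numeric matrix (genes x genotypes) of mean expression.
#'   The first column is the wild type; column `j + 1` is the mutant
#'   perturbing gene `j`, in row (gene) order.
#' @param gamma named (or ordered) vector of mutant activity fractions
#'   in (0, 1], one per gene.
#' @return Matrix of class `response_matrix` (genes x genes).
#' @export
response_matrix <- function(means, gamma) {
  n <- nrow(means)
  if (ncol(means) != n + 1L) {
    stop_seamnet(
      sprintf("means must have %d columns (wild type + one mutant per gene)",
              n + 1L),
      "seamnet_parameter_error"
    )
  }
  if (length(gamma) != n) {
    stop_seamnet("need one activity fraction per gene",
                 "seamnet_parameter_error")
  }
  genes <- rownames(means)
  if (!is.null(genes) && !is.null(names(gamma))) gamma <- gamma[genes]
  Rp <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      f <- if (i == j) gamma[[i]] else 1
      Rp[i, j] <- central_fractional_difference(means[i, 1L],
                                                means[i, j + 1L], f)
    }
  }
  structure(Rp, class = c("response_matrix", "matrix", "array"))
}

#' Local response matrix (single MRA sample)
#'
#' Converts a response matrix into local response coefficients via
#' `r = -(diag(diag(Rp^-1)))^-1 Rp^-1`, i.e. elementwise
#' `r_ij = -(Rp^-1)_ij / (Rp^-1)_ii`. The normalization encodes the
#' assumption `r_ii = -1` (each gene's level limits its own increase
#' through degradation); off-diagonal `r_ij` estimates the direct
#' effect of gene j on gene i (positive: activation; negative:
#' repression).
#'
#' @param Rp invertible square matrix of central fractional differences
#'   (a [response_matrix()] or plain matrix).
#' @param cond_cap condition-number cap; matrices with 2-norm condition
#'   estimate above it are rejected as numerically singular.
#' @return Matrix of local response coefficients with diagonal exactly
#'   -1.
#' @export
local_response_matrix <- function(Rp, cond_cap = 1e8) {
  Rp <- unclass(Rp)
  kp <- tryCatch(kappa(Rp, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kp) || kp > cond_cap) {
    cond <- simpleCondition(
      sprintf("response matrix is singular or ill-conditioned (condition number %.3g)",
              kp))
    class(cond) <- c("seamnet_numerical_error", "seamnet_error", "error",
                     "condition")
    attr(cond, "condition_number") <- kp
    stop(cond)
  }
  Rinv <- solve(Rp)
  r <- -sweep(Rinv, 1L, diag(Rinv), "/")
  dimnames(r) <- dimnames(Rp)
  r
}

#' Bootstrap Modular Response Analysis
#'
#' Resamples cells with replacement within every gene x genotype group,
#' recomputes group means, the response matrix and the local response
#' matrix for each bootstrap iteration, and summarizes the resulting
#' distribution: elementwise mean interaction matrix, percentile
#' confidence intervals and weak-link flags (interval straddles zero).
#' Resamples yielding a singular response matrix are skipped and logged.
#'
#' @param dataset an [expression_dataset()] containing the wild type
#'   and one single-mutant genotype per gene at `timepoint`.
#' @param timepoint timepoint label.
#' @param gamma named vector of mutant activity fractions per gene
#'   (MRA-stage defaults via [genotype_activities()] if omitted).
#' @param mutant_map named character vector mapping gene -> genotype
#'   label of its single mutant; defaults to the canonical seam-cell
#'   genotypes.
#' @param wild_type wild-type genotype label.
#' @param n_iter number of bootstrap iterations (>= 1).
#' @param seed integer seed.
#' @param ci_level confidence level for percentile intervals.
#' @param cond_cap condition-number cap passed to
#'   [local_response_matrix()].
#' @return An object of class `interaction_matrix`: list with `mean_r`,
#'   `ci_low`, `ci_high`, `weak_flags`, `samples` (n x n x iterations
#'   array of retained samples), `n_skipped`, `genes`, `gamma`.
#' @export
bootstrap_mra <- function(dataset, timepoint, gamma = NULL,
                          mutant_map = NULL, wild_type = "wild type",
                          n_iter = 1000L, seed = 1L, ci_level = 0.95,
                          cond_cap = 1e8) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (n_iter < 1L) {
    stop_seamnet("n_iter must be >= 1", "seamnet_parameter_error")
  }
  genes <- attr(dataset, "genes")
  n <- length(genes)
  if (is.null(mutant_map)) {
    mutant_map <- c("elt-1" = "elt-1(ku491)", "egl-18" = "egl-18(ga97)",
                    "ceh-16" = "ceh-16(bp323)")[genes]
    names(mutant_map) <- genes
  }
  if (is.null(gamma)) {
    defaults <- default_allele_activities("mra")
    gamma <- defaults[genes]
  }
  gamma <- gamma[genes]
  genotype_cols <- c(wild_type, unname(mutant_map[genes]))
  df <- dataset[dataset$timepoint == timepoint, , drop = FALSE]
  counts <- vector("list", n * (n + 1L))
  dim(counts) <- c(n, n + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n + 1L)) {
      x <- df$count[df$gene == genes[i] & df$genotype == genotype_cols[j]]
      if (length(x) == 0L) {
        stop_seamnet(
          sprintf("no cells for gene '%s', genotype '%s' at timepoint '%s'",
                  genes[i], genotype_cols[j], timepoint),
          "seamnet_empty_group_error"
        )
      }
      counts[[i, j]] <- x
    }
  }
  samples <- array(NA_real_, c(n, n, n_iter))
  n_skipped <- 0L
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      means <- matrix(NA_real_, n, n + 1L,
                      dimnames = list(genes, genotype_cols))
      for (i in seq_len(n)) {
        for (j in seq_len(n + 1L)) {
          x <- counts[[i, j]]
          means[i, j] <- mean(x[sample.int(length(x), replace = TRUE)])
        }
      }
      r <- tryCatch({
        local_response_matrix(response_matrix(means, gamma), cond_cap)
      }, seamnet_error = function(e) NULL)
      if (is.null(r)) {
        n_skipped <- n_skipped + 1L
      } else {
        samples[, , it] <- r
      }
    }
  })
  ok <- !apply(is.na(samples[1L, 1L, , drop = FALSE]), 3L, any)
  if (!any(ok)) {
    stop_seamnet("all bootstrap resamples were singular",
                 "seamnet_numerical_error")
  }
  samples <- samples[, , ok, drop = FALSE]
  mean_r <- apply(samples, c(1L, 2L), mean)
  a <- (1 - ci_level) / 2
  ci_low <- apply(samples, c(1L, 2L), stats::quantile, probs = a)
  ci_high <- apply(samples, c(1L, 2L), stats::quantile, probs = 1 - a)
  weak <- ci_low <= 0 & ci_high >= 0
  diag(weak) <- FALSE
  dimnames(mean_r) <- dimnames(ci_low) <- dimnames(ci_high) <-
    dimnames(weak) <- list(genes, genes)
  structure(
    list(mean_r = mean_r, ci_low = ci_low, ci_high = ci_high,
         weak_flags = weak, samples = samples,
         n_skipped = n_skipped, n_iter = n_iter, ci_level = ci_level,
         genes = genes, gamma = gamma, timepoint = timepoint),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "<interaction_matrix> %d genes | %d bootstrap sample(s) (%d skipped)\n",
    length(x$genes), dim(x$samples)[3L], x$n_skipped))
  print(round(x$mean_r, 3))
  invisible(x)
}

#' Summarize an interaction matrix as an edge list
#'
#' One row per directed off-diagonal edge: mean strength, sign
#' (activation for positive, repression for negative), a magnitude
#' label (`"amplified"` for |r| > 1, `"attenuated"` for 0 < |r| < 1)
#' and the weak-link flag (bootstrap interval straddles zero).
#'
#' @param im an `interaction_matrix` from [bootstrap_mra()].
#' @return data.frame with columns `from`, `to`, `strength`, `sign`,
#'   `magnitude`, `weak`, `ci_low`, `ci_high`.
#' @export
summarize_interactions <- function(im) {
  stopifnot(inherits(im, "interaction_matrix"))
  genes <- im$genes
  rows <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      s <- im$mean_r[i, j]
      rows[[length(rows) + 1L]] <- data.frame(
        from = genes[j], to = genes[i], strength = s,
        sign = if (s >= 0) "activation" else "repression",
        magnitude = if (abs(s) > 1) "amplified" else if (abs(s) > 0)
          "attenuated" else "none",
        weak = im$weak_flags[i, j],
        ci_low = im$ci_low[i, j], ci_high = im$ci_high[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
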