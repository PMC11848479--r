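# Hill-function ODE model family over a signed regulatory topology with
# combinatorial AND/OR co-regulation logic.
#
# A topology is a set of regulation terms (target, regulator, sign).
# For each target gene, its terms are partitioned into AND-blocks: the
# Hill fractions of terms inside one block are multiplied and share one
# maximum rate v; blocks are combined by OR (summation). Enumerating
# every partition of every gene's term set yields the model family.

#' Construct a regulation term
#'
#' One directed regulatory action: `target` is transcriptionally
#' activated or repressed by the protein of `regulator`. A term with
#' `target == regulator` is a self-loop.
#'
#' @param target,regulator gene labels.
#' @param sign `"activation"` or `"repression"`.
#' @return A one-row data.frame with columns `target`, `regulator`,
#'   `sign`, `self`.
#' @export
regulation_term <- function(target, regulator,
                            sign = c("activation", "repression")) {
  sign <- match.arg(sign)
  data.frame(target = target, regulator = regulator, sign = sign,
             self = target == regulator, stringsAsFactors = FALSE)
}

#' Bundle regulation terms into a topology
#'
#' @param ... `regulation_term()` rows (or data.frames of them).
#' @param genes ordered gene list; defaults to all genes mentioned.
#' @return A `grn_topology` object (data.frame of terms with a `genes`
#'   attribute).
#' @export
grn_topology <- function(..., genes = NULL) {
  terms <- do.call(rbind, list(...))
  if (is.null(genes)) {
    genes <- unique(c(terms$target, terms$regulator))
  }
  key <- paste(terms$target, terms$regulator, terms$sign)
  if (anyDuplicated(key)) {
    stop_seamnet("duplicate (target, regulator, sign) regulation terms",
                 "seamnet_parameter_error")
  }
  structure(terms, genes = genes,
            class = c("grn_topology", "data.frame"))
}

#' Built-in seam-cell topologies
#'
#' * `"late-L1"`: the full candidate topology at the late L1 stage used
#'   for model discovery. elt-1 is activated by EGL-18 and repressed by
#'   CEH-16; egl-18 is activated by ELT-1 and repressed by CEH-16;
#'   ceh-16 is activated by ELT-1 and EGL-18 and self-activates.
#'   Enumerating its AND/OR logic yields 20 model variants.
#' * `"literature"`: the naive prior-literature network with only
#'   activations: ELT-1 activates egl-18 and ceh-16; CEH-16 activates
#'   egl-18.
#' * `"final-L1"`: the validated reduced network: egl-18 repressed by
#'   CEH-16; ceh-16 activated by ELT-1 and EGL-18 (elt-1 basal only).
#'
#' @param name topology name.
#' @return A [grn_topology()].
#' @export
seam_topology <- function(name = c("late-L1", "literature", "final-L1")) {
  name <- match.arg(name)
  switch(name,
    "late-L1" = grn_topology(
      regulation_term("elt-1", "egl-18", "activation"),
      regulation_term("elt-1", "ceh-16", "repression"),
      regulation_term("egl-18", "elt-1", "activation"),
      regulation_term("egl-18", "ceh-16", "repression"),
      regulation_term("ceh-16", "elt-1", "activation"),
      regulation_term("ceh-16", "egl-18", "activation"),
      regulation_term("ceh-16", "ceh-16", "activation"),
      genes = SEAM_GENES
    ),
    "literature" = grn_topology(
      regulation_term("egl-18", "elt-1", "activation"),
      regulation_term("egl-18", "ceh-16", "activation"),
      regulation_term("ceh-16", "elt-1", "activation"),
      genes = SEAM_GENES
    ),
    "final-L1" = grn_topology(
      regulation_term("egl-18", "ceh-16", "repression"),
      regulation_term("ceh-16", "elt-1", "activation"),
      regulation_term("ceh-16", "egl-18", "activation"),
      genes = SEAM_GENES
    )
  )
}

# ---------------------------------------------------------------------
# Set partitions (restricted growth strings)

# All partitions of 1..n as lists of integer blocks, ordered with the
# all-singleton partition (pure OR) first and the single-block partition
# (pure AND) last; ties broken lexicographically on the restricted
# growth string. For n = 0 returns the single empty partition.
set_partitions <- function(n) {
  if (n == 0L) return(list(list()))
  rgs <- list(integer(0))
  for (i in seq_len(n)) {
    rgs <- do.call(c, lapply(rgs, function(s) {
      top <- if (length(s)) max(s) else -1L
      lapply(0L:(top + 1L), function(v) c(s, v))
    }))
  }
  parts <- lapply(rgs, function(s) {
    unname(lapply(sort(unique(s)), function(v) which(s == v)))
  })
  nblocks <- vapply(parts, length, integer(1L))
  keys <- vapply(rgs, paste, character(1L), collapse = ",")
  parts[order(-nblocks, keys)]
}

# Bell number via the Bell triangle (independent oracle for tests).
bell_number <- function(n) {
  if (n == 0L) return(1)
  row <- 1
  for (i in seq_len(n - 1L)) {
    newrow <- numeric(i + 1L)
    newrow[1L] <- row[i]
    for (j in seq_len(i)) newrow[j + 1L] <- newrow[j] + row[j]
    row <- newrow
  }
  row[length(row)]
}

#' Construct an ODE model specification
#'
#' Combines a topology with a logic partition: for each gene, a list of
#' AND-blocks (integer vectors indexing that gene's terms); blocks are
#' joined by OR.
#'
#' @param topology a [grn_topology()].
#' @param partition named list (one entry per gene with terms) of lists
#'   of integer vectors partitioning that gene's term indices. Genes
#'   without terms may be omitted. Default: all singletons (pure OR).
#' @param variant_id integer label.
#' @param signed logical; if `TRUE` the model is in sign-relaxed mode
#'   (see [sign_relaxed_variant()]).
#' @return An object of class `ode_model_spec`.
#' @export
ode_model_spec <- function(topology, partition = NULL, variant_id = 1L,
                           signed = FALSE) {
  genes <- attr(topology, "genes")
  terms <- as.data.frame(topology)
  by_gene <- lapply(genes, function(g) which(terms$target == g))
  names(by_gene) <- genes
  if (is.null(partition)) {
    partition <- lapply(by_gene, function(ix) {
      unname(lapply(seq_along(ix), function(i) i))
    })
  }
  for (g in genes) {
    ix <- by_gene[[g]]
    blocks <- partition[[g]]
    if (is.null(blocks)) blocks <- if (length(ix)) as.list(seq_along(ix)) else list()
    got <- sort(unlist(blocks))
    if (!identical(as.integer(got), seq_along(ix))) {
      stop_seamnet(
        sprintf("partition for gene '%s' must cover its %d term(s) exactly",
                g, length(ix)),
        "seamnet_parameter_error"
      )
    }
    partition[[g]] <- lapply(blocks, as.integer)
  }
  structure(
    list(genes = genes, terms = terms, terms_by_gene = by_gene,
         partition = partition[genes], variant_id = as.integer(variant_id),
         signed = signed),
    class = "ode_model_spec"
  )
}

#' @export
print.ode_model_spec <- function(x, ...) {
  nb <- sum(vapply(x$partition, length, integer(1L)))
  cat(sprintf(
    "<ode_model_spec> variant %d | %d genes | %d terms in %d block(s)%s\n",
    x$variant_id, length(x$genes), nrow(x$terms), nb,
    if (isTRUE(x$signed)) " | sign-relaxed" else ""
  ))
  invisible(x)
}

#' Enumerate all AND/OR logic variants of a topology
#'
#' Every way of partitioning each gene's regulation terms into
#' AND-blocks (joined by OR) gives one model variant; the number of
#' variants is the product over genes of the Bell number of the gene's
#' term count. Ordering is deterministic: variant 1 is the all-OR model
#' (every block a singleton) and the last variant is the all-AND model
#' (one block per gene). For the late-L1 seam-cell topology this yields
#' 20 variants.
#'
#' @param topology a [grn_topology()].
#' @return List of [ode_model_spec()] objects with `variant_id`
#'   `1..N`.
#' @export
enumerate_logic_variants <- function(topology) {
  genes <- attr(topology, "genes")
  terms <- as.data.frame(topology)
  per_gene <- lapply(genes, function(g) {
    set_partitions(sum(terms$target == g))
  })
  names(per_gene) <- genes
  counts <- vapply(per_gene, length, integer(1L))
  total <- prod(counts)
  specs <- vector("list", total)
  # Mixed-radix enumeration, last gene's partition index varying
  # fastest, so all-OR (all indices 1) is first and all-AND (all
  # indices max) is last.
  idx <- rep(1L, length(genes))
  for (v in seq_len(total)) {
    partition <- lapply(seq_along(genes), function(i) per_gene[[i]][[idx[i]]])
    names(partition) <- genes
    specs[[v]] <- ode_model_spec(topology, partition, variant_id = v)
    for (i in rev(seq_along(genes))) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= counts[i]) break
      idx[i] <- 1L
    }
  }
  specs
}

# ---------------------------------------------------------------------
# Parameters

# Short role letter for a term: activator "a" / repressor "r".
role_letter <- function(sign) ifelse(sign == "activation", "a", "r")

#' Parameter table of a model specification
#'
#' Lists the free parameters of a variant under the sharing convention:
#' one basal production `b_<gene>` per gene, one maximum rate `v` per
#' AND-block (named after its target and member actions), and one
#' half-occupation constant `k_<regulator>_<a|r>` per regulator gene and
#' role (so a gene acting both as activator and repressor contributes
#' two k's, e.g. the ceh-16 self-activation k is distinct from the
#' ceh-16 repression k).
#'
#' @param spec an [ode_model_spec()].
#' @return data.frame with columns `name`, `class` (`"b"`, `"v"`,
#'   `"k"`), `target`, `block`, `regulator`, `role`.
#' @export
param_table <- function(spec) {
  genes <- spec$genes
  rows <- lapply(genes, function(g) {
    data.frame(name = paste0("b_", g), class = "b", target = g,
               block = NA_integer_, regulator = NA_character_,
               role = NA_character_, stringsAsFactors = FALSE)
  })
  terms <- spec$terms
  for (g in genes) {
    ix <- spec$terms_by_gene[[g]]
    blocks <- spec$partition[[g]]
    for (bi in seq_along(blocks)) {
      members <- terms[ix[blocks[[bi]]], , drop = FALSE]
      lab <- paste0(members$regulator,
                    ifelse(members$self, "s", ""),
                    role_letter(members$sign))
      lab <- paste(sort(lab), collapse = "+")
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("v_", g, "_", lab), class = "v", target = g,
        block = bi, regulator = NA_character_, role = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  kk <- unique(data.frame(regulator = terms$regulator,
                          role = role_letter(terms$sign),
                          stringsAsFactors = FALSE))
  if (nrow(kk) > 0L) {
    kk <- kk[order(kk$regulator, kk$role), , drop = FALSE]
    for (i in seq_len(nrow(kk))) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("k_", kk$regulator[i], "_", kk$role[i]), class = "k",
        target = NA_character_, block = NA_integer_,
        regulator = kk$regulator[i], role = kk$role[i],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Construct a parameter set for a model specification
#'
#' @param spec an [ode_model_spec()].
#' @param values named numeric vector covering (a subset of) the names
#'   in [param_table()]; unnamed parameters default to 0.
#' @param alpha Hill exponent(s): a single value or a named per-gene
#'   vector (exponent of the regulator gene), default 1.
#' @param d degradation rate(s): single value or named per-gene vector,
#'   default 1 (steady-state-only convention; other rates are measured
#'   in units of the degradation rate).
#' @return An object of class `parameter_set` holding the full `theta`
#'   vector plus `alpha` and `d`.
#' @export
parameter_set <- function(spec, values = numeric(0), alpha = 1, d = 1) {
  pt <- param_table(spec)
  theta <- rep(0, nrow(pt))
  names(theta) <- pt$name
  unknown <- setdiff(names(values), pt$name)
  if (length(unknown) > 0L) {
    stop_seamnet(
      sprintf("parameter(s) not in this model variant: %s",
              paste(unknown, collapse = ", ")),
      "seamnet_parameter_error"
    )
  }
  theta[names(values)] <- values
  genes <- spec$genes
  if (length(alpha) == 1L && is.null(names(alpha))) {
    alpha <- stats::setNames(rep(alpha, length(genes)), genes)
  }
  if (length(d) == 1L && is.null(names(d))) {
    d <- stats::setNames(rep(d, length(genes)), genes)
  }
  if (any(d[genes] <= 0)) {
    stop_seamnet("degradation rates must be > 0", "seamnet_parameter_error")
  }
  structure(list(theta = theta, alpha = alpha[genes], d = d[genes],
                 table = pt),
            class = "parameter_set")
}

# ---------------------------------------------------------------------
# Hill-Langmuir regulation functions

#' Hill-Langmuir activation
#'
#' `v * (g*f)^alpha / (k^alpha + (g*f)^alpha)`: production rate
#' contributed by an activator present at transcript level `g` with
#' activity fraction `f`. A zero `k` with `g*f > 0` saturates the
#' fraction at 1; the degenerate input `k = 0, g*f = 0` is defined as 0
#' (the limit along `g -> 0`).
#'
#' @param g regulator transcript level (counts), >= 0.
#' @param f activity fraction in `[0, 1]` (1 in wild type).
#' @param v maximum rate (counts/time).
#' @param k half-occupation constant (counts).
#' @param alpha Hill exponent (> 0); values > 1 encode cooperativity.
#' @return Production rate.
#' @export
hill_activation <- function(g, f = 1, v = 1, k = 1, alpha = 1) {
  x <- (g * f)^alpha
  ka <- k^alpha
  frac <- ifelse(ka + x > 0, x / (ka + x), 0)
  v * frac
}

#' Hill-Langmuir repression
#'
#' `v * k^alpha / (k^alpha + (g*f)^alpha)`: production rate contributed
#' by a repressor. With the repressor absent (`g = 0`) the full rate
#' `v` is produced; a zero `k` sets the fraction to 0 (including the
#' degenerate `k = 0, g*f = 0` input).
#'
#' @inheritParams hill_activation
#' @return Production rate.
#' @export
hill_repression <- function(g, f = 1, v = 1, k = 1, alpha = 1) {
  x <- (g * f)^alpha
  ka <- k^alpha
  frac <- ifelse(ka + x > 0, ka / (ka + x), 0)
  v * frac
}

# ---------------------------------------------------------------------
# Right-hand side and steady states

#' Build the ODE right-hand side for a genotype
#'
#' Returns `function(g) dg/dt` implementing, per gene i,
#' `b_i + sum over OR-blocks [ v_block * prod over block members of the
#' Hill fraction ] - d_i * g_i`, with the genotype's activity fractions
#' applied inside every Hill fraction. In sign-relaxed mode the sign of
#' a block's `v` selects the fraction form (positive: activation;
#' negative: repression) and `|v|` is the rate.
#'
#' This pure-R evaluator is the reference implementation; the steady
#' state solver uses an equivalent compiled evaluator.
#'
#' @param spec an [ode_model_spec()].
#' @param params a [parameter_set()].
#' @param genotype a [genotype_spec()].
#' @return Function mapping a state vector (length = number of genes,
#'   ordered as `spec$genes`) to its time derivative.
#' @export
build_rhs <- function(spec, params, genotype) {
  check_params_cover(spec, params)
  genes <- spec$genes
  theta <- params$theta
  alpha <- params$alpha
  dvec <- params$d
  f <- genotype$activities[genes]
  if (any(is.na(f))) {
    stop_seamnet("genotype activities missing for some model genes",
                 "seamnet_parameter_error")
  }
  pt <- params$table
  signed <- isTRUE(spec$signed)
  terms <- spec$terms
  function(g) {
    names(g) <- genes
    dg <- unname(theta[paste0("b_", genes)]) - unname(dvec[genes]) * unname(g)
    names(dg) <- genes
    for (tg in genes) {
      ix <- spec$terms_by_gene[[tg]]
      blocks <- spec$partition[[tg]]
      for (bi in seq_along(blocks)) {
        vname <- pt$name[pt$class == "v" & pt$target == tg & pt$block == bi]
        v <- theta[[vname]]
        rate <- if (signed) abs(v) else v
        if (rate == 0) next
        prod_frac <- 1
        for (ti in ix[blocks[[bi]]]) {
          reg <- terms$regulator[ti]
          sgn <- terms$sign[ti]
          if (signed) sgn <- if (v >= 0) "activation" else "repression"
          kname <- paste0("k_", reg, "_", role_letter(terms$sign[ti]))
          frac <- if (sgn == "activation") {
            hill_activation(g[[reg]], f[[reg]], 1, theta[[kname]], alpha[[reg]])
          } else {
            hill_repression(g[[reg]], f[[reg]], 1, theta[[kname]], alpha[[reg]])
          }
          prod_frac <- prod_frac * frac
        }
        dg[[tg]] <- dg[[tg]] + rate * prod_frac
      }
    }
    unname(dg)
  }
}

check_params_cover <- function(spec, params) {
  pt <- param_table(spec)
  if (!all(pt$name %in% names(params$theta))) {
    stop_seamnet(
      sprintf("parameter set does not cover model variant %d (missing: %s)",
              spec$variant_id,
              paste(setdiff(pt$name, names(params$theta)), collapse = ", ")),
      "seamnet_parameter_error"
    )
  }
  invisible(TRUE)
}

# Flatten a model spec into the integer descriptor consumed by the
# compiled steady-state solver. Indices are 0-based into theta.
compile_model <- function(spec, params) {
  check_params_cover(spec, params)
  genes <- spec$genes
  pt <- params$table
  name_idx <- stats::setNames(seq_along(params$theta) - 1L,
                              names(params$theta))
  b_idx <- name_idx[paste0("b_", genes)]
  block_target <- integer(0); block_v <- integer(0)
  term_block <- integer(0); term_reg <- integer(0)
  term_sign <- integer(0); term_k <- integer(0); term_alpha <- numeric(0)
  terms <- spec$terms
  nb <- 0L
  for (gi in seq_along(genes)) {
    tg <- genes[gi]
    ix <- spec$terms_by_gene[[tg]]
    blocks <- spec$partition[[tg]]
    for (bi in seq_along(blocks)) {
      vname <- pt$name[pt$class == "v" & pt$target == tg & pt$block == bi]
      block_target <- c(block_target, gi - 1L)
      block_v <- c(block_v, name_idx[[vname]])
      for (ti in ix[blocks[[bi]]]) {
        reg <- terms$regulator[ti]
        term_block <- c(term_block, nb)
        term_reg <- c(term_reg, match(reg, genes) - 1L)
        term_sign <- c(term_sign,
                       if (terms$sign[ti] == "activation") 1L else -1L)
        term_k <- c(term_k,
                    name_idx[[paste0("k_", reg, "_",
                                     role_letter(terms$sign[ti]))]])
        term_alpha <- c(term_alpha, params$alpha[[reg]])
      }
      nb <- nb + 1L
    }
  }
  list(n = length(genes), b_idx = unname(b_idx),
       block_target = block_target, block_v = block_v,
       term_block = term_block, term_reg = term_reg,
       term_sign = term_sign, term_k = term_k, term_alpha = term_alpha,
       d = unname(params$d), signed = isTRUE(spec$signed))
}

#' Steady state of a model under a genotype
#'
#' Integrates the ODE forward from `g0` with an adaptive embedded
#' Runge-Kutta method until the relative rate criterion
#' `max_i |dg_i/dt| / max(g_i, 1) < tol` is met, returning the limit
#' state. Non-convergence within `t_max` time units (oscillation or
#' divergence) raises an error unless `strict = FALSE`.
#'
#' @param spec an [ode_model_spec()].
#' @param params a [parameter_set()].
#' @param genotype a [genotype_spec()].
#' @param g0 initial state (finite, non-negative); in the fitting
#'   pipeline the data means are used, which converges quickly.
#' @param tol relative rate convergence tolerance.
#' @param t_max integration horizon.
#' @param strict error on non-convergence (default) or return the final
#'   state with `converged = FALSE`.
#' @return Named numeric steady-state vector with attribute
#'   `converged`; with `strict = FALSE` non-converged states are
#'   returned flagged rather than raising.
#' @export
steady_state <- function(spec, params, genotype, g0 = NULL, tol = 1e-8,
                         t_max = 1e4, strict = TRUE) {
  genes <- spec$genes
  if (is.null(g0)) g0 <- rep(1, length(genes))
  if (any(!is.finite(g0)) || any(g0 < 0)) {
    stop_seamnet("g0 must be finite and non-negative",
                 "seamnet_parameter_error")
  }
  desc <- compile_model(spec, params)
  f <- genotype$activities[genes]
  res <- cpp_steady_state(desc, params$theta, as.numeric(f),
                          as.numeric(g0), tol, t_max)
  s <- res$state
  names(s) <- genes
  if (!res$converged && strict) {
    stop_seamnet(
      sprintf(
        "steady state did not converge by t = %g (residual %.3g); tail state: %s",
        t_max, res$residual, paste(signif(s, 6), collapse = ", ")),
      "seamnet_convergence_error"
    )
  }
  attr(s, "converged") <- res$converged
  s
}

#' Steady-state panel across genotypes
#'
#' Computes one steady state per genotype; column j of the returned
#' matrix is the fixed point under genotype j.
#'
#' @inheritParams steady_state
#' @param genotypes list of [genotype_spec()] objects (or a single one).
#' @param init optional matrix of initial states (genes x genotypes);
#'   a vector is recycled across genotypes.
#' @return Numeric matrix (genes x genotypes) with attribute
#'   `converged` (logical per genotype when `strict = FALSE`).
#' @export
genotype_panel <- function(spec, params, genotypes, init = NULL,
                           tol = 1e-8, t_max = 1e4, strict = TRUE) {
  if (inherits(genotypes, "genotype_spec")) genotypes <- list(genotypes)
  genes <- spec$genes
  m <- length(genotypes)
  if (is.null(init)) init <- matrix(1, length(genes), m)
  if (is.vector(init)) init <- matrix(init, length(genes), m)
  S <- matrix(NA_real_, length(genes), m,
              dimnames = list(genes,
                              vapply(genotypes, `[[`, "", "name")))
  conv <- logical(m)
  for (j in seq_len(m)) {
    s <- tryCatch(
      steady_state(spec, params, genotypes[[j]], g0 = init[, j],
                   tol = tol, t_max = t_max, strict = strict),
      seamnet_convergence_error = function(e) {
        stop_seamnet(
          sprintf("genotype '%s': %s", genotypes[[j]]$name,
                  conditionMessage(e)),
          "seamnet_convergence_error"
        )
      }
    )
    S[, j] <- s
    conv[j] <- isTRUE(attr(s, "converged"))
  }
  attr(S, "converged") <- conv
  S
}
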