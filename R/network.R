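# Aggregation of sampler runs into link-presence statistics,
# double-mutant validation, final-network assembly and reporting.

# Links realized by a kept block rate v: every term in the block counts
# as present when the block's v parameter is kept. Returns a data.frame
# of link ids for one run's final fit.
run_links <- function(run) {
  spec <- run$spec
  pt <- run$param_table
  terms <- spec$terms
  rows <- list()
  for (tg in spec$genes) {
    ix <- spec$terms_by_gene[[tg]]
    blocks <- spec$partition[[tg]]
    for (bi in seq_along(blocks)) {
      vname <- pt$name[pt$class == "v" & pt$target == tg & pt$block == bi]
      kept <- run$kept_mask[[vname]]
      vval <- run$final_fit[[vname]]
      for (ti in ix[blocks[[bi]]]) {
        sgn <- terms$sign[ti]
        if (isTRUE(spec$signed) && kept) {
          sgn <- if (vval >= 0) "activation" else "repression"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          link = paste0(terms$regulator[ti], "->", tg),
          regulator = terms$regulator[ti], target = tg,
          sign = sgn, context = if (length(blocks[[bi]]) > 1L) "AND" else "OR",
          kept = kept, v_param = vname, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Parameter and link presence across runs
#'
#' For every parameter name appearing in any run, the percentage of
#' runs whose final fit keeps it; and for every regulatory link
#' (regulator -> target), the percentage of runs in which some kept
#' block rate realizes it, split by logic context (whether the link sat
#' in a multi-term AND block or a singleton OR block in that run's
#' variant).
#'
#' @param runs list of `sling_run` objects (>= 1).
#' @param status optional character vector (`"kept"` / `"discarded"`)
#'   per run from [filter_by_double_mutant()]; when given, presence is
#'   additionally reported within each subset.
#' @return An object of class `presence_table`: list with data.frames
#'   `parameters` (name, n_runs, n_present, pct, and per-subset pcts)
#'   and `links` (link, sign context columns, overall / AND / OR pcts).
#' @export
parameter_presence <- function(runs, status = NULL) {
  if (length(runs) == 0L) {
    stop_seamnet("need at least one run", "seamnet_parameter_error")
  }
  subsets <- list(all = seq_along(runs))
  if (!is.null(status)) {
    subsets$kept <- which(status == "kept")
    subsets$discarded <- which(status == "discarded")
  }
  all_params <- unique(unlist(lapply(runs, function(r) names(r$final_fit))))
  pres <- vapply(runs, function(r) {
    out <- stats::setNames(rep(NA, length(all_params)), all_params)
    out[names(r$kept_mask)] <- r$kept_mask
    out
  }, logical(length(all_params)))
  pres <- matrix(pres, nrow = length(all_params),
                 dimnames = list(all_params, NULL))
  param_df <- data.frame(name = all_params, stringsAsFactors = FALSE)
  for (sn in names(subsets)) {
    ix <- subsets[[sn]]
    n_in <- rowSums(!is.na(pres[, ix, drop = FALSE]))
    n_kept <- rowSums(pres[, ix, drop = FALSE], na.rm = TRUE)
    param_df[[paste0("n_", sn)]] <- n_in
    param_df[[paste0("pct_", sn)]] <-
      ifelse(n_in > 0, 100 * n_kept / n_in, NA_real_)
  }
  link_tabs <- lapply(runs, run_links)
  all_links <- unique(do.call(rbind, lapply(link_tabs, function(t)
    t[c("link", "regulator", "target")])))
  link_df <- all_links[order(all_links$link), , drop = FALSE]
  rownames(link_df) <- NULL
  link_present <- function(tab, lk, ctx = NULL) {
    sel <- tab$link == lk
    if (!is.null(ctx)) sel <- sel & tab$context == ctx
    if (!any(sel)) return(NA)
    any(tab$kept[sel])
  }
  for (sn in names(subsets)) {
    ix <- subsets[[sn]]
    for (ctx in list(NULL, "AND", "OR")) {
      col <- paste0("pct_", sn, if (is.null(ctx)) "" else paste0("_", ctx))
      vals <- vapply(link_df$link, function(lk) {
        p <- vapply(link_tabs[ix], link_present, logical(1L), lk = lk,
                    ctx = ctx)
        if (all(is.na(p))) NA_real_ else 100 * mean(p, na.rm = TRUE)
      }, numeric(1L))
      link_df[[col]] <- vals
    }
  }
  structure(list(parameters = param_df, links = link_df,
                 n_runs = length(runs)),
            class = "presence_table")
}

# Median parameter summary of a run: elementwise median over
# post-burn-in recorded states, restricted to parameters kept in the
# final fit (others forced to exact zero).
median_parameters <- function(run) {
  if (!is.null(run$median_theta)) return(run$median_theta)
  post <- seq.int(run$n_burn + 1L, nrow(run$chain))
  if (nrow(run$chain) <= run$n_burn) post <- seq_len(nrow(run$chain))
  med <- apply(run$chain[post, , drop = FALSE], 2L, stats::median)
  med[!run$kept_mask] <- 0
  med
}

#' Predict steady-state expression under a genotype from a fitted run
#'
#' Summarizes the run's posterior sample (elementwise median of
#' post-burn-in states of kept parameters, or the minimal-distance
#' final fit) and computes the steady state of that parameter set under
#' the requested genotype, e.g. a double mutant never used in fitting.
#'
#' @param run a `sling_run`.
#' @param genotype a [genotype_spec()] (for the double mutant both
#'   affected activities are reduced simultaneously).
#' @param summary `"median"` (default) or `"final"`.
#' @param g0 initial state; defaults to the fit's wild-type data means
#'   (first target column).
#' @return Named steady-state vector.
#' @export
predict_genotype <- function(run, genotype, summary = c("median", "final"),
                             g0 = NULL) {
  summary <- match.arg(summary)
  theta <- if (summary == "median") median_parameters(run) else run$final_fit
  params <- parameter_set(run$spec, theta, alpha = run$alpha, d = run$d)
  if (is.null(g0)) g0 <- run$target_mu[, 1L]
  steady_state(run$spec, params, genotype, g0 = g0,
               tol = run$config$ss_tol, t_max = run$config$ss_tmax)
}

#' Validate runs against double-mutant data
#'
#' Scores every run's predicted double-mutant steady state against the
#' held-out double-mutant target with the ABC distance (n genes, m = 1
#' phenotype) and partitions runs into kept (`d <= cutoff`) and
#' discarded (`d > cutoff`).
#'
#' @param runs list of `sling_run` objects.
#' @param dm_target a [fit_target()] with exactly one genotype column.
#' @param genotype the double-mutant [genotype_spec()].
#' @param cutoff distance cutoff (default 2.5).
#' @param summary parameter summary passed to [predict_genotype()].
#' @return data.frame of class `validation_partition` with one row per
#'   run: `run`, `variant_id`, `d_dm`, `status`.
#' @export
filter_by_double_mutant <- function(runs, dm_target, genotype,
                                    cutoff = 2.5,
                                    summary = c("median", "final")) {
  summary <- match.arg(summary)
  stopifnot(inherits(dm_target, "fit_target"))
  if (dm_target$m != 1L) {
    stop_seamnet("dm_target must have exactly one phenotype column",
                 "seamnet_parameter_error")
  }
  d_dm <- vapply(runs, function(run) {
    s <- predict_genotype(run, genotype, summary = summary)
    abc_distance(matrix(s, ncol = 1L), dm_target)
  }, numeric(1L))
  out <- data.frame(
    run = seq_along(runs),
    variant_id = vapply(runs, `[[`, integer(1L), "variant_id"),
    d_dm = d_dm,
    status = ifelse(d_dm <= cutoff, "kept", "discarded"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("validation_partition", "data.frame")
  out
}

#' Assemble the final network from validated runs
#'
#' A link is deleted when it is absent from the final fits of at least
#' `discard_fraction` of the kept runs (boundary inclusive: absent in
#' exactly 90% of runs is deleted at the default). Surviving links are
#' annotated with their overall and AND/OR-context presence
#' percentages.
#'
#' @param kept_runs non-empty list of `sling_run` objects that passed
#'   validation.
#' @param discard_fraction deletion threshold (default 0.90).
#' @return data.frame of surviving links: `link`, `regulator`,
#'   `target`, `sign`, `pct_all`, `pct_all_AND`, `pct_all_OR`.
#' @export
final_network <- function(kept_runs, discard_fraction = 0.90) {
  if (length(kept_runs) == 0L) {
    stop_seamnet("kept run set is empty", "seamnet_parameter_error")
  }
  pres <- parameter_presence(kept_runs)
  links <- pres$links
  keep <- (100 - links$pct_all) / 100 < discard_fraction
  out <- links[keep, , drop = FALSE]
  sign_of <- function(lk) {
    tabs <- lapply(kept_runs, run_links)
    sgns <- unlist(lapply(tabs, function(t) t$sign[t$link == lk & t$kept]))
    if (length(sgns) == 0L) return(NA_character_)
    names(sort(table(sgns), decreasing = TRUE))[1L]
  }
  out$sign <- vapply(out$link, sign_of, character(1L))
  rownames(out) <- NULL
  out[, c("link", "regulator", "target", "sign", "pct_all",
          "pct_all_AND", "pct_all_OR")]
}

#' Cross-timepoint consistency check
#'
#' Compares predictions of a calibrated run with data from another
#' timepoint: per-entry z-scores `(mu_other - s_pred) / sigma_other`
#' plus the aggregate ABC distance on the same inputs.
#'
#' @param run a `sling_run`.
#' @param other_target a [fit_target()] with the same genes/genotypes
#'   as the calibration target.
#' @param genotypes list of [genotype_spec()] objects matching the
#'   target columns.
#' @param summary parameter summary passed to [predict_genotype()].
#' @return List with `z` (genes x genotypes matrix) and `distance`.
#' @export
crosstimepoint_check <- function(run, other_target, genotypes,
                                 summary = c("median", "final")) {
  summary <- match.arg(summary)
  stopifnot(inherits(other_target, "fit_target"))
  if (length(genotypes) != other_target$m) {
    stop_seamnet("need one genotype spec per target column",
                 "seamnet_parameter_error")
  }
  S <- vapply(genotypes, function(g)
    as.numeric(predict_genotype(run, g, summary = summary)),
    numeric(other_target$n))
  dimnames(S) <- dimnames(other_target$mu)
  z <- (other_target$mu - S) / other_target$sigma
  list(z = z, distance = abc_distance(S, other_target), predicted = S)
}

#' Write a report bundle
#'
#' Writes whatever stage outputs are available as deterministic CSV /
#' JSON tables plus a plain-text summary and a run manifest (package
#' version, seeds, configuration). Missing stages degrade gracefully
#' with a warning.
#'
#' @param out_dir output directory (created if needed).
#' @param summary_stats optional `summary_stats` table.
#' @param mra optional `interaction_matrix` from [bootstrap_mra()].
#' @param presence optional `presence_table`.
#' @param validation optional `validation_partition`.
#' @param network optional [final_network()] table.
#' @param manifest optional named list folded into the manifest JSON.
#' @return Character vector of files written, invisibly.
#' @export
report <- function(out_dir, summary_stats = NULL, mra = NULL,
                   presence = NULL, validation = NULL, network = NULL,
                   manifest = list()) {
  if (is.null(summary_stats) && is.null(mra) && is.null(presence) &&
        is.null(validation) && is.null(network)) {
    stop_seamnet("no stage outputs supplied", "seamnet_parameter_error")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_seamnet(sprintf("cannot create directory %s", out_dir),
                          "seamnet_io_error")
  }
  written <- character(0)
  put_csv <- function(df, fname) {
    p <- file.path(out_dir, fname)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    written <<- c(written, p)
  }
  if (!is.null(summary_stats)) put_csv(as.data.frame(summary_stats),
                                       "summary_stats.csv")
  if (!is.null(mra)) {
    put_csv(summarize_interactions(mra), "mra_edges.csv")
    m <- as.data.frame(mra$mean_r)
    m <- cbind(gene = rownames(mra$mean_r), m)
    put_csv(m, "mra_mean_matrix.csv")
  } else {
    warning("no MRA output supplied; bundle is partial")
  }
  if (!is.null(presence)) {
    put_csv(presence$parameters, "presence_parameters.csv")
    put_csv(presence$links, "presence_links.csv")
  } else if (!is.null(validation) || !is.null(network)) {
    warning("no presence table supplied; bundle is partial")
  }
  if (!is.null(validation)) put_csv(as.data.frame(validation),
                                    "validation_partition.csv")
  if (!is.null(network)) put_csv(network, "final_network.csv")
  man <- c(list(package = "seamnet",
                version = as.character(utils::packageVersion("seamnet"))),
           manifest)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, p)
  summary_lines <- c(
    "seamnet report bundle",
    sprintf("tables: %s", paste(basename(written), collapse = ", "))
  )
  p <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, p)
  written <- c(written, p)
  invisible(written)
}
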