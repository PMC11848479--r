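test_that("dataset round-trips through CSV exactly", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  expect_equal(as.data.frame(ds2), as.data.frame(ds))
  expect_equal(nrow(ds2), nrow(tiny_records()))
})

test_that("lineage filter drops non-matching rows", {
  rec <- tiny_records()[1:10, ]
  rec$animal_id <- paste0(rec$animal_id, "_", seq_len(10))  # unique keys
  rec$cell_id[1:3] <- "H1"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  expect_equal(nrow(read_dataset(path)), 10L)
  ds <- read_dataset(path, lineage_filter = c("V1", "V2", "V3", "V4"))
  expect_equal(nrow(ds), 7L)
})

test_that("malformed input is rejected with informative errors", {
  rec <- tiny_records()
  rec$count[4] <- -2L
  expect_error(expression_dataset(rec), class = "seamnet_validation_error")
  rec <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec[, -6], path, row.names = FALSE)
  expect_error(read_dataset(path), class = "seamnet_format_error")
  dup <- rbind(rec, rec[1, ])
  expect_error(expression_dataset(dup), class = "seamnet_validation_error")
})

test_that("bootstrap summaries: constant data, SE oracle, determinism", {
  rec <- expand.grid(animal_id = paste0("a", 1:6), cell_id = c("V1", "V2"),
                     stringsAsFactors = FALSE)
  rec$gene <- "elt-1"; rec$genotype <- "wild type"
  rec$timepoint <- "late-L1"; rec$count <- 5L
  ds <- expression_dataset(rec)
  st <- summarize_expression(ds, "late-L1", n_boot = 200L, seed = 1L)
  expect_equal(st$mu, 5)
  expect_equal(st$sigma, 0)
  expect_equal(st$fano, 0)
  expect_equal(st$cv, 0)

  rec2 <- data.frame(gene = "elt-1", genotype = "wild type",
                     timepoint = "late-L1",
                     animal_id = c("a1", "a2", "a3"), cell_id = "V1",
                     count = c(2L, 4L, 6L))
  ds2 <- expression_dataset(rec2)
  st2 <- summarize_expression(ds2, "late-L1", n_boot = 5000L, seed = 3L)
  # mean of resample means -> group mean; sd -> SE of the mean with the
  # bootstrap (n) denominator: sd_pop/sqrt(3) = sqrt(8/3)/sqrt(3)
  expect_equal(st2$mu, 4, tolerance = 0.1)
  se_oracle <- sqrt(mean((c(2, 4, 6) - 4)^2) / 3)
  expect_equal(st2$sigma, se_oracle, tolerance = 0.1)

  a <- summarize_expression(tiny_dataset(), "late-L1", n_boot = 50L,
                            seed = 7L)
  b <- summarize_expression(tiny_dataset(), "late-L1", n_boot = 50L,
                            seed = 7L)
  expect_identical(a, b)
})

test_that("summarize_expression rejects empty groups and bad n_boot", {
  ds <- tiny_dataset()
  expect_error(summarize_expression(ds, "late-L1", n_boot = 0L),
               class = "seamnet_parameter_error")
  expect_error(summarize_expression(ds, "early-L2"),
               class = "seamnet_empty_group_error")
})

test_that("fano factor and CV match hand computations and properties", {
  expect_equal(fano_factor(c(7, 7, 7)), 0)
  expect_equal(fano_factor(c(2, 4, 6)), 1)       # var 4 (ddof 1) / mean 4
  expect_equal(coefficient_of_variation(c(7, 7, 7)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  withr::with_seed(11, {
    x <- rpois(20000, 50)
    expect_equal(fano_factor(x), 1, tolerance = 0.1)
    y <- sample(x)  # order invariance
    expect_identical(fano_factor(y), fano_factor(x))
    expect_equal(coefficient_of_variation(3 * x),
                 coefficient_of_variation(x))
  })
  expect_error(fano_factor(c(0, 0, 0)), class = "seamnet_undefined_error")
  expect_error(coefficient_of_variation(5), class = "seamnet_parameter_error")
})

test_that("paired-cell correlation: perfect, null and shared-factor cases", {
  mk <- function(counts1, counts2, n = length(counts1)) {
    data.frame(gene = "elt-1", genotype = "wild type", timepoint = "late-L1",
               animal_id = rep(paste0("a", seq_len(n)), 2),
               cell_id = rep(c("V1", "V2"), each = n),
               count = c(counts1, counts2))
  }
  x <- c(3L, 9L, 15L, 30L)
  expect_equal(
    paired_cell_correlation(expression_dataset(mk(x, x)),
                            "elt-1", "wild type", "late-L1"), 1)
  withr::with_seed(21, {
    a <- rpois(200, 20); b <- rpois(200, 20)
    r0 <- paired_cell_correlation(expression_dataset(mk(a, b)),
                                  "elt-1", "wild type", "late-L1")
    expect_lt(abs(r0), 0.2)
  })
  expect_error(
    paired_cell_correlation(expression_dataset(mk(x[1:2], x[1:2], 2)),
                            "elt-1", "wild type", "late-L1"),
    class = "seamnet_insufficient_data_error")
})

test_that("genotype activities follow stage defaults and compose", {
  wt <- genotype_activities("wild type", "ode")
  expect_equal(unname(wt$activities), c(1, 1, 1))
  ceh <- genotype_activities("ceh-16(bp323)", "ode")
  expect_equal(unname(ceh$activities), c(1, 1, 0.25))
  dbl <- genotype_activities("egl-18(ga97);ceh-16(bp323)", "ode")
  expect_equal(unname(dbl$activities), c(1, 0.01, 0.25))
  # allele order in the double-mutant label is irrelevant
  dbl2 <- genotype_activities("ceh-16(bp323);egl-18(ga97)", "ode")
  expect_equal(dbl2$activities, dbl$activities)
  # MRA stage models the strong-loss allele at 0.01% activity
  egl <- genotype_activities("egl-18(ga97)", "mra")
  expect_equal(unname(egl$activities), c(1, 1e-4, 1))
  expect_error(genotype_activities("unknown-mutant"),
               class = "seamnet_unknown_genotype_error")
  ovr <- genotype_activities("elt-1(ku491)", "ode",
                             overrides = c("elt-1" = 0.5))
  expect_equal(unname(ovr$activities), c(0.5, 1, 1))
  expl <- genotype_activities("custom", activities = c("egl-18" = 0.3))
  expect_equal(unname(expl$activities), c(1, 0.3, 1))
  expect_error(genotype_spec("bad", c("elt-1" = 1.5)),
               class = "seamnet_parameter_error")
})
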