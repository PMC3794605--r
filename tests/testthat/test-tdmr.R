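# A hand-built probe set: 30 genomic probes on one chromosome plus controls.
make_probe_set <- function(n = 30, n_ctrl = 40, spacing = 40, len = 50,
                           input_level = 10, ctrl_level = 6, seed = 1) {
  set.seed(seed)
  probes <- data.frame(
    probe_id = sprintf("p%03d", seq_len(n + n_ctrl)),
    chrom = c(rep("chr1", n), rep(NA, n_ctrl)),
    start = c(seq(0, by = spacing, length.out = n), rep(NA, n_ctrl)),
    end = c(seq(0, by = spacing, length.out = n) + len, rep(NA, n_ctrl)),
    is_control = rep(c(FALSE, TRUE), c(n, n_ctrl)))
  samples <- data.frame(sample = paste0(rep(c("A", "B"), each = 3), 1:3),
                        tissue = rep(c("A", "B"), each = 3))
  input <- matrix(rnorm(6 * (n + n_ctrl), input_level, 0.2), ncol = 6)
  input[probes$is_control, ] <- rnorm(6 * n_ctrl, ctrl_level, 0.2)
  enriched <- input + 1 + matrix(rnorm(6 * (n + n_ctrl), 0, 0.05), ncol = 6)
  dimnames(input) <- dimnames(enriched) <-
    list(probes$probe_id, samples$sample)
  probe_set(probes, input, enriched, samples)
}

test_that("quantile normalization equalizes sorted sample distributions", {
  ps <- normalize_probes(make_probe_set())
  s <- apply(ps$enriched, 2, sort)
  expect_lt(max(abs(s - s[, 1])), 1e-10)
  s2 <- apply(ps$input, 2, sort)
  expect_lt(max(abs(s2 - s2[, 1])), 1e-10)
})

test_that("lowess on controls removes a planted intensity-dependent bias", {
  ps <- make_probe_set(n = 200, n_ctrl = 400, seed = 2)
  # controls span the genomic intensity range so the bias is interpolated
  ps$input[ps$probes$is_control, ] <-
    matrix(runif(6 * 400, 5, 11), ncol = 6)
  bias <- 0.5 * (ps$input - 8)   # linear enrichment bias in every probe
  ps$enriched <- ps$input + 1 + bias
  norm <- normalize_probes(ps)
  m <- norm$enriched - norm$input
  g <- m[!ps$probes$is_control, ]
  # after correction the genomic relative methylation is flat again
  expect_lt(max(abs(g - mean(g))), 0.15)
})

test_that("too few controls skips lowess with a warning", {
  ps <- make_probe_set(n_ctrl = 5)
  expect_warning(normalize_probes(ps), "control probes")
})

test_that("background filtering drops low-input probes and all controls", {
  ps <- make_probe_set()
  # push two genomic probes 10 units below the control median
  ps$input[2, ] <- ps$input[2, ] - 14
  ps$input[5, ] <- ps$input[5, ] - 14
  f <- filter_background(ps)
  expect_false(any(f$probes$is_control))
  expect_false(any(f$probes$probe_id %in% c("p002", "p005")))
  expect_equal(attr(f, "n_removed"), 2)
  expect_equal(nrow(f$probes), 28)
  # a clean set removes nothing
  f0 <- filter_background(make_probe_set())
  expect_equal(attr(f0, "n_removed"), 0)
})

test_that("relative methylation is the log2 enriched/input difference", {
  ps <- make_probe_set()
  m <- relative_methylation(ps)
  expect_equal(m, ps$enriched - ps$input)
  ps$enriched <- ps$input
  expect_true(all(relative_methylation(ps) == 0))
  ps$enriched <- ps$input + 1
  expect_true(all(relative_methylation(ps) == 1))
  # matches a linear-scale ratio oracle
  lin_ratio <- 2^ps$enriched[1, 1] / 2^ps$input[1, 1]
  expect_equal(relative_methylation(ps)[1, 1], log2(lin_ratio))
})

# Methylation matrix with chosen per-probe deltas, tiny noise.
delta_matrix <- function(deltas, sd = 0.02, seed = 3) {
  set.seed(seed)
  n <- length(deltas)
  m <- matrix(rnorm(6 * n, 1, sd), ncol = 6)
  m[, 1:3] <- m[, 1:3] + deltas / 2
  m[, 4:6] <- m[, 4:6] - deltas / 2
  rownames(m) <- sprintf("p%03d", seq_len(n))
  m
}

tdmr_fixture_probes <- function(n) {
  data.frame(probe_id = sprintf("p%03d", seq_len(n)), chrom = "chr1",
             start = seq(0, by = 40, length.out = n),
             end = seq(0, by = 40, length.out = n) + 50,
             is_control = FALSE)
}

tdmr_samples <- data.frame(sample = paste0(rep(c("A", "B"), each = 3), 1:3),
                           tissue = rep(c("A", "B"), each = 3))

test_that("two significant neighbours are not enough for a T-DMR", {
  deltas <- c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0)
  res <- call_tdmrs(delta_matrix(deltas), tdmr_fixture_probes(10),
                    tdmr_samples, method = "welch")
  expect_equal(nrow(res$tdmrs), 0)
})

test_that("three consistent significant neighbours become exactly one T-DMR", {
  deltas <- c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0)
  res <- call_tdmrs(delta_matrix(deltas), tdmr_fixture_probes(10),
                    tdmr_samples, method = "welch")
  expect_equal(nrow(res$tdmrs), 1)
  expect_equal(res$tdmrs$n_probes, 3)
  expect_equal(res$tdmrs$start, 80)    # probe 3 starts at 80
  expect_equal(res$tdmrs$end, 210)     # probe 5 ends at 4*40+50
  expect_equal(res$tdmrs$direction, "A-hyper")
  expect_equal(res$tdmrs$mean_delta, 1, tolerance = 0.1)
})

test_that("a direction flip splits the run (+ + - + + calls nothing)", {
  deltas <- c(0, 0, 1, 1, -1, 1, 1, 0, 0, 0)
  res <- call_tdmrs(delta_matrix(deltas), tdmr_fixture_probes(10),
                    tdmr_samples, method = "welch")
  expect_equal(nrow(res$tdmrs), 0)
})

test_that("runs are maximal and gaps above max_gap break them", {
  deltas <- rep(c(0, 1), c(3, 6))
  probes <- tdmr_fixture_probes(9)
  # open a 500 bp hole between the 6th and 7th probe
  probes$start[7:9] <- probes$start[7:9] + 500
  probes$end[7:9] <- probes$end[7:9] + 500
  res <- call_tdmrs(delta_matrix(deltas, seed = 5), probes, tdmr_samples,
                    method = "welch", max_gap = 300)
  expect_equal(nrow(res$tdmrs), 2)     # the hole splits probes 4-6 and 7-9
  expect_equal(res$tdmrs$n_probes, c(3, 3))
  res2 <- call_tdmrs(delta_matrix(deltas, seed = 5), probes, tdmr_samples,
                     method = "welch", max_gap = 600)
  expect_equal(nrow(res2$tdmrs), 1)
  expect_equal(res2$tdmrs$n_probes, 6)
})

test_that("unsorted probe input is sorted internally with a note", {
  deltas <- c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0)
  m <- delta_matrix(deltas)
  probes <- tdmr_fixture_probes(10)
  ord <- rev(seq_len(10))
  expect_message(
    res <- call_tdmrs(m[ord, ], probes[ord, ], tdmr_samples,
                      method = "welch"),
    "sorting")
  expect_equal(nrow(res$tdmrs), 1)
  expect_equal(res$tdmrs$n_probes, 3)
})

test_that("moderated and Welch tests agree on well-separated probes", {
  deltas <- c(rep(0, 20), rep(1.5, 5), rep(0, 20))
  m <- delta_matrix(deltas, sd = 0.05, seed = 9)
  res_m <- call_tdmrs(m, tdmr_fixture_probes(45), tdmr_samples,
                      method = "moderated")
  res_w <- call_tdmrs(m, tdmr_fixture_probes(45), tdmr_samples,
                      method = "welch")
  expect_equal(res_m$tdmrs$start, res_w$tdmrs$start)
  expect_equal(res_m$tdmrs$n_probes, res_w$tdmrs$n_probes)
})
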