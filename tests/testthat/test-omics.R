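test_that("log2 fold change matches the elementwise definition", {
  set.seed(31)
  ab <- matrix(rexp(6 * 5, 1 / 50), 6,
               dimnames = list(paste0("g", 1:6), NULL))
  m <- omics_matrix(ab, c(-2, -1, 1, 3, 5), kind = "transcript")
  lfc <- compute_log2fc(m, pseudocount = 1)
  # brute-force oracle, cell by cell
  ctrl <- rowMeans(ab[, 1:2])
  for (i in 1:6) for (j in 1:3) {
    expect_equal(unname(lfc[i, j]), unname(log2((ab[i, j + 2] + 1) / (ctrl[i] + 1))))
  }
  expect_equal(om_timepoints(lfc), c(1, 3, 5))
  # a feature equal to its control mean is 0 everywhere
  flat <- omics_matrix(matrix(7, 2, 5), c(-2, -1, 1, 3, 5))
  expect_true(all(compute_log2fc(flat, pseudocount = 0) == 0))
  # 4x control with no pseudocount is exactly 2
  ab2 <- matrix(c(1, 1, 4), 1)
  m2 <- omics_matrix(ab2, c(-2, -1, 3))
  expect_equal(as.numeric(compute_log2fc(m2, pseudocount = 0)), 2)
  expect_error(compute_log2fc(m2, control_columns = integer(0)), "control")
})

test_that("transcript filter applies both thresholds jointly", {
  lfc <- make_lfc(rbind(a = c(1.2, 0.2), b = c(3, 3), c = c(0.5, 0.5)),
                  days = c(5, 6),
                  fdr = rbind(a = c(5e-4, 0.5), b = c(0.01, 0.01),
                              c = c(1e-5, 1e-5)))
  keep <- filter_transcripts(lfc)
  expect_equal(as.character(keep), "a")   # b fails FDR, c fails |lfc|
  expect_error(filter_transcripts(make_lfc(matrix(1, 1, 2), c(5, 6))),
               "stand_in_de_test")
})

test_that("transcript filter equals a brute-force scan on random input", {
  set.seed(77)
  lfc_m <- matrix(rnorm(200 * 4, 0, 1.2), 200,
                  dimnames = list(sprintf("g%03d", 1:200), NULL))
  fdr_m <- matrix(runif(200 * 4)^3, 200, dimnames = dimnames(lfc_m))
  lfc <- make_lfc(lfc_m, days = c(2, 5, 6, 8), fdr = fdr_m)
  keep <- filter_transcripts(lfc)
  manual <- character(0)
  for (g in rownames(lfc_m)) {
    if (any(fdr_m[g, ] <= 0.001 & abs(lfc_m[g, ]) >= 1)) {
      manual <- c(manual, g)
    }
  }
  expect_setequal(as.character(keep), manual)
})

test_that("metabolite filter retains |log2FC| >= 2 at any timepoint", {
  lfc <- make_lfc(rbind(a = c(1.9, 1.5), b = c(0.1, -2.5), c = c(0, 0)),
                  days = c(5, 6), kind = "metabolite")
  expect_equal(filter_metabolites(lfc), "b")
  raw <- omics_matrix(matrix(1, 1, 2), c(5, 6), kind = "metabolite",
                      log2fc = FALSE)
  expect_error(filter_metabolites(raw), "log2FC")
  # exhaustive scan on random input
  set.seed(9)
  m <- matrix(rnorm(50 * 6, 0, 1.5), 50,
              dimnames = list(sprintf("c%02d", 1:50), NULL))
  got <- filter_metabolites(make_lfc(m, days = 1:6, kind = "metabolite"))
  expect_setequal(got, rownames(m)[apply(abs(m) >= 2, 1, any)])
})

test_that("stand-in test is calibrated and handles degeneracies", {
  set.seed(123)
  ab <- matrix(rnorm(1000 * 6, 100, 10), 1000)
  res <- stand_in_de_test(ab, rep(c("ctrl", "t1"), each = 3), "ctrl")
  expect_equal(mean(res$p < 0.05), 0.05, tolerance = 0.2)
  # zero variance, different means: certain call
  ab2 <- rbind(c(1, 1, 1, 2, 2, 2), c(3, 3, 3, 3, 3, 3))
  r2 <- stand_in_de_test(ab2, rep(c("ctrl", "t1"), each = 3), "ctrl")
  expect_equal(as.numeric(r2$p), c(0, 1))
  expect_error(stand_in_de_test(ab2[, c(1, 4)], c("ctrl", "t1"), "ctrl"),
               "replicates")
})

test_that("FDR adjustment is BH within each timepoint and rank-monotone", {
  set.seed(2)
  ab <- matrix(rnorm(60 * 8, 50, 5), 60)
  ab[1:10, 5:8] <- ab[1:10, 5:8] + 15   # some real shifts
  res <- stand_in_de_test(ab, rep(c("ctrl", "t1"), each = 4), "ctrl")
  # hand BH: p * n / rank, cumulative minimum from the largest rank down
  p <- res$p[, 1]
  o <- order(p)
  hand <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  expect_equal(unname(res$fdr[o, 1]), pmin(hand, 1))
  # adjusted values never decrease with raw rank
  expect_true(all(diff(res$fdr[o, 1]) >= -1e-15))
})

test_that("pair screen retains identity patterns and rejects doubled ones", {
  g <- rbind(gene1 = c(0, 1, 2, 3, 2.5, 3.5))
  cm <- rbind(cmpA = g[1, ], cmpB = 2 * g[1, ], cmpC = rep(1, 6))
  scr <- pair_screen(make_lfc(cm, days = 4:9, kind = "metabolite"),
                     make_lfc(g, days = 4:9))
  a <- scr[scr$compound_id == "cmpA", ]
  expect_equal(a$slope, 1)
  expect_lt(a$p_value, 0.05)
  expect_true(a$retained)
  b <- scr[scr$compound_id == "cmpB", ]
  expect_equal(b$slope, 2)
  expect_false(b$retained)
  expect_true(all(scr$n_points == 6))
})

test_that("scaling a gene pattern scales the fitted slope inversely", {
  set.seed(4)
  g <- rbind(g1 = rnorm(6, 0, 2))
  cm <- rbind(c1 = g[1, ] + rnorm(6, 0, 0.01))
  for (cc in c(0.5, 2, 3)) {
    s1 <- pair_screen(make_lfc(cm, 1:6, "metabolite"), make_lfc(g, 1:6),
                      min_points = 3)
    s2 <- pair_screen(make_lfc(cm, 1:6, "metabolite"),
                      make_lfc(cc * g, 1:6), min_points = 3)
    expect_equal(s2$slope, s1$slope / cc, tolerance = 1e-9)
  }
})

test_that("zero-variance gene patterns are skipped with a reason", {
  g <- rbind(flat = rep(2, 5), live = c(0, 1, 2, 3, 4))
  cm <- rbind(c1 = c(0, 1, 2, 3, 4))
  scr <- pair_screen(make_lfc(cm, 1:5, "metabolite"), make_lfc(g, 1:5))
  flat_row <- scr[scr$gene_id == "flat", ]
  expect_true(is.na(flat_row$slope))
  expect_match(flat_row$skip_reason, "zero-variance")
  expect_false(flat_row$retained)
  expect_error(pair_screen(make_lfc(cm[, 1:2, drop = FALSE], 1:2, "metabolite"),
                           make_lfc(g[, 1:2, drop = FALSE], 1:2)),
               "shared timepoints")
})

test_that("pair screen equals the exhaustive lm() oracle on a 50x50 problem", {
  set.seed(88)
  G <- matrix(rnorm(50 * 6, 0, 1.5), 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  C <- matrix(rnorm(50 * 6, 0, 2), 50,
              dimnames = list(sprintf("c%02d", 1:50), NULL))
  # plant a few unit-slope relations
  for (i in 1:5) C[i, ] <- G[i, ] + rnorm(6, 0, 0.02)
  scr <- pair_screen(make_lfc(C, 1:6, "metabolite"), make_lfc(G, 1:6))
  orc <- oracle_pair_screen(C, G)
  key <- function(d) paste(d$compound_id, d$gene_id)
  scr_o <- scr[match(key(orc), key(scr)), ]
  expect_equal(scr_o$slope, orc$slope, tolerance = 1e-9)
  expect_equal(scr_o$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(scr_o$p_value, orc$p_value, tolerance = 1e-9)
  expect_equal(scr_o$retained, orc$retained)
})

test_that("the pooled 10/11 timepoint maps to the mean of days 10 and 11", {
  g <- rbind(g1 = c(0, 1, 2, 4, 6))
  gm <- make_lfc(g, days = c(4, 5, 6, 10, 11))
  cm <- make_lfc(rbind(c1 = c(0, 1, 2, 5)), days = c(4, 5, 6, 10.5),
                 kind = "metabolite")
  scr <- pair_screen(cm, gm)
  expect_equal(scr$slope, 1)          # 5 against mean(4, 6) = 5
  expect_true(scr$retained)
})

test_that("strict positive-slope mode drops inverse relations", {
  g <- rbind(g1 = c(0, 1, 2, 3, 4, 5))
  cm <- rbind(cneg = -g[1, ])
  both <- pair_screen(make_lfc(cm, 1:6, "metabolite"), make_lfc(g, 1:6))
  expect_true(both$retained)          # |slope| window keeps the sign
  expect_equal(both$slope, -1)
  pos <- pair_screen(make_lfc(cm, 1:6, "metabolite"), make_lfc(g, 1:6),
                     positive_only = TRUE)
  expect_false(pos$retained)
})

test_that("phase averaging collapses member days and passes singletons", {
  days <- c(2, 4, 5, 6, 7, 8, 15)
  vals <- rbind(const = rep(3, 7), idx = days)
  m <- make_lfc(vals, days)
  ph <- five_phase_labels(ifelse(days <= 4, "NRep",
                                 ifelse(days <= 6, "transition", "NS")), days)
  avg <- phase_average(m, ph)
  expect_equal(colnames(avg), c("NRep", "D5", "D6", "NS", "D15"))
  expect_true(all(avg["const", ] == 3))
  expect_equal(unname(avg["idx", ]), c(mean(c(2, 4)), 5, 6, mean(c(7, 8)), 15))
  # missing phase warns and is omitted
  m2 <- make_lfc(vals[, 1:4, drop = FALSE], days[1:4])
  expect_warning(a2 <- phase_average(m2, ph[1:4]), "omitted")
  expect_false("D15" %in% colnames(a2))
})
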